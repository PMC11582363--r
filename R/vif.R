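#' Variance inflation factor from a coefficient of determination
#'
#' `VIF = 1 / (1 - R^2)`; `Inf` when `R^2` reaches 1 (perfect collinearity).
#'
#' @param r_squared Coefficient of determination in `[0, 1]`.
#' @return The variance inflation factor (>= 1, possibly `Inf`).
#' @examples
#' vif_from_r2(0.9)   # 10
#' @export
vif_from_r2 <- function(r_squared) {
  if (any(r_squared < 0 | r_squared > 1, na.rm = TRUE))
    stop("R^2 must lie in [0, 1]", call. = FALSE)
  ifelse(r_squared >= 1 - 1e-12, Inf, 1 / (1 - r_squared))
}

# minimum-norm least squares of y on cbind(1, X); returns R^2 and a
# rank-deficiency flag.  Uses the pseudo-inverse so that underdetermined
# designs (more coefficients than observations) give the deterministic
# minimum-norm solution instead of an arbitrary dropped-column fit.
ols_r2 <- function(y, X) {
  D <- cbind(`(Intercept)` = 1, X)
  coef <- MASS::ginv(D) %*% y
  fitted <- D %*% coef
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) return(list(r2 = NA_real_, rank_deficient = TRUE))
  r2 <- 1 - sum((y - fitted)^2) / sst
  r2 <- min(max(r2, 0), 1)
  list(r2 = r2, rank_deficient = qr(D)$rank < ncol(D))
}

#' Variance inflation factor of one attribute
#'
#' Regresses the attribute (ordinary least squares with intercept) on all
#' other numeric conditional attributes of the system and returns the
#' coefficient of determination and `VIF = 1/(1 - R^2)`.  The decision,
#' time, event and categorical attributes are excluded from the design
#' unless `include_decision` adds the decision column (the literal
#' worked-example mode).
#'
#' @param is An [information_system()].
#' @param attribute Name of a numeric attribute (or the decision attribute
#'   when `include_decision = TRUE`).
#' @param include_decision Admit the decision attribute into the design
#'   (and as a target).  Default `FALSE`.
#' @return A list with `attribute`, `r_squared`, `vif` (possibly `Inf`) and
#'   `rank_deficient`.
#' @export
compute_vif <- function(is, attribute, include_decision = FALSE) {
  stopifnot(inherits(is, "information_system"))
  pool <- conditional_attributes(is, "numeric")
  if (include_decision && !is.null(is$decision_attribute))
    pool <- c(pool, is$decision_attribute)
  if (!attribute %in% pool)
    stop("attribute '", attribute,
         "' is not a numeric attribute of the regression pool", call. = FALSE)
  others <- setdiff(pool, attribute)
  if (length(others) < 2)
    stop("need at least 2 other numeric attributes", call. = FALSE)
  y <- is$values[, attribute]
  if (stats::var(y) == 0)
    stop("degenerate attribute '", attribute, "' (zero variance)",
         call. = FALSE)
  keep <- others[apply(is$values[, others, drop = FALSE], 2, stats::var) > 0]
  fit <- ols_r2(y, is$values[, keep, drop = FALSE])
  list(attribute = attribute, r_squared = fit$r2,
       vif = vif_from_r2(fit$r2), rank_deficient = fit$rank_deficient)
}

vif_band <- function(vif, threshold_low, threshold_high) {
  ifelse(vif < threshold_low, "low",
         ifelse(vif < threshold_high, "moderate", "high"))
}

#' Reduce an information system by iterative VIF screening
#'
#' Attributes whose VIF falls in the high band (`vif >= threshold_high`)
#' are removed one at a time, highest VIF first, with all VIFs recomputed
#' after each removal, until no attribute remains in the high band.  The
#' decision, time and event attributes are never candidates.
#'
#' @inheritParams compute_vif
#' @param threshold_low Low/moderate band boundary (default 10).
#' @param threshold_high Moderate/high band boundary (default 15).
#' @return A list with `system` (the reduced [information_system()]) and
#'   `report`, a data frame of class `vif_report` with one row per numeric
#'   conditional attribute: `attribute`, `r_squared`, `vif`, `band`,
#'   `removed_rank` (`NA` for survivors; 1 = first removed) and
#'   `rank_deficient`.  VIFs of surviving attributes are those of the final
#'   recomputation; removed attributes report the VIF that triggered their
#'   removal.
#' @examples
#' s <- generate_synthetic(200, n_genes = 6, seed = 1)
#' red <- reduce_by_vif(s)
#' red$report
#' @export
reduce_by_vif <- function(is, threshold_low = 10, threshold_high = 15,
                          include_decision = FALSE) {
  stopifnot(inherits(is, "information_system"),
            threshold_low > 1, threshold_high >= threshold_low)
  pool <- conditional_attributes(is, "numeric")
  pool <- pool[apply(is$values[, pool, drop = FALSE], 2, stats::var) > 0]
  if (length(pool) < 3)
    stop("need at least 3 non-degenerate numeric conditional attributes",
         call. = FALSE)

  removed <- character()
  removed_vif <- numeric()
  current <- is
  repeat {
    active <- intersect(pool, colnames(current$values))
    # never reduce below the minimum estimable design of three numeric
    # conditionals
    if (length(active) <= 3) break
    stats_now <- lapply(active, function(a)
      compute_vif(current, a, include_decision = include_decision))
    vifs <- vapply(stats_now, `[[`, numeric(1), "vif")
    names(vifs) <- active
    high <- vifs[vifs >= threshold_high]
    if (!length(high)) break
    worst <- names(high)[which.max(high)]
    removed <- c(removed, worst)
    removed_vif <- c(removed_vif, vifs[[worst]])
    current <- replace_values(
      current, current$values[, setdiff(colnames(current$values), worst),
                              drop = FALSE])
  }

  active <- intersect(pool, colnames(current$values))
  final <- lapply(active, function(a) tryCatch(
    compute_vif(current, a, include_decision = include_decision),
    error = function(e) list(attribute = a, r_squared = NA_real_,
                             vif = NA_real_, rank_deficient = NA)))
  report <- data.frame(
    attribute = c(active, removed),
    r_squared = c(vapply(final, `[[`, numeric(1), "r_squared"),
                  rep(NA_real_, length(removed))),
    vif = c(vapply(final, `[[`, numeric(1), "vif"), removed_vif),
    removed_rank = c(rep(NA_integer_, length(active)),
                     seq_along(removed)),
    rank_deficient = c(vapply(final, `[[`, logical(1), "rank_deficient"),
                       rep(NA, length(removed))),
    stringsAsFactors = FALSE)
  report$band <- vif_band(report$vif, threshold_low, threshold_high)
  report <- report[order(match(report$attribute, is$attributes$name)), ]
  rownames(report) <- NULL
  attr(report, "threshold_low") <- threshold_low
  attr(report, "threshold_high") <- threshold_high
  class(report) <- c("vif_report", class(report))
  list(system = current, report = report)
}
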