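#' Generate a synthetic stage-labelled information system
#'
#' Emulates the statistical structure the pipeline assumes: clinical
#' covariates drawn over their printed ranges, gene-expression columns with
#' additive stage-dependent mean shifts, and right-censored Weibull survival
#' times whose scale shrinks with stage so that later stages fail earlier.
#'
#' Each gene attribute reuses one of the seventeen printed probe ranges
#' (recycled when `n_genes > 17`).  Within a range `[lo, hi]` of width `w`,
#' a patient at stage `s` (0--3) receives
#' `mid + (s - 1.5) * effect_size * w / 4 + N(0, (noise_frac * w)^2)`,
#' so `effect_size = 1` spreads the four stage means across three quarters
#' of the printed range and `effect_size = 0` removes the stage signal
#' entirely.  Survival times are `Weibull(weibull_shape, weibull_scale *
#' stage_factor)`; a `censor_frac` fraction of records is censored at a
#' uniformly drawn time below the event time (note this mechanism is
#' informative: the censoring time depends on the latent event time).
#'
#' @param n_objects Number of patients (>= 1).
#' @param n_genes Number of gene-expression attributes (>= 1, default 17).
#' @param stage_probs Probabilities of stages 0--3; must sum to 1.
#' @param effect_size Magnitude of the per-stage additive shift of the gene
#'   means, as a multiple of a quarter of each probe's printed range width.
#' @param weibull_shape,weibull_scale Baseline Weibull parameters of the
#'   survival times (months); shape > 1 gives a hazard rising with time.
#' @param censor_frac Fraction of records to right-censor, in `[0, 1]`.
#' @param seed Integer seed; identical seeds give identical systems.
#' @param noise_frac Within-stage gene standard deviation as a fraction of
#'   the printed range width (default 0.05).
#' @param stage_scale_factors Multipliers of `weibull_scale` per stage
#'   0--3; decreasing so later stages fail earlier.
#' @return An [information_system()] with columns `Age`, `DFS` (time role),
#'   `Gender`, `Location`, `AdjRadio`, `AdjChem`, `n_genes` gene columns,
#'   the stage decision `d` and the `event` indicator.
#' @examples
#' s <- generate_synthetic(50, n_genes = 5, seed = 1)
#' table(s$values[, "d"])
#' @export
generate_synthetic <- function(n_objects, n_genes = 17,
                               stage_probs = rep(0.25, 4),
                               effect_size = 0.5,
                               weibull_shape = 1.5, weibull_scale = 60,
                               censor_frac = 0.3, seed = 1,
                               noise_frac = 0.05,
                               stage_scale_factors = c(1, 0.8, 0.6, 0.5)) {
  if (n_objects < 1 || n_genes < 1)
    stop("counts must be >= 1", call. = FALSE)
  if (length(stage_probs) != 4 || any(stage_probs < 0) ||
      abs(sum(stage_probs) - 1) > 1e-9)
    stop("stage_probs must be a 4-vector of probabilities summing to 1",
         call. = FALSE)
  if (weibull_shape <= 0 || weibull_scale <= 0)
    stop("weibull shape and scale must be positive", call. = FALSE)
  if (censor_frac < 0 || censor_frac > 1)
    stop("censor_frac must lie in [0, 1]", call. = FALSE)
  if (length(stage_scale_factors) != 4 || any(stage_scale_factors <= 0))
    stop("stage_scale_factors must be 4 positive multipliers", call. = FALSE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  stage <- sample(0:3, n_objects, replace = TRUE, prob = stage_probs)

  clin <- cbind(
    Age      = sample(28:78, n_objects, replace = TRUE),
    DFS      = NA_real_,
    Gender   = sample(1:2, n_objects, replace = TRUE),
    Location = sample(1:4, n_objects, replace = TRUE),
    AdjRadio = sample(0:1, n_objects, replace = TRUE),
    AdjChem  = sample(0:1, n_objects, replace = TRUE))

  rng <- gene_ranges()
  idx <- rep_len(seq_len(nrow(rng)), n_genes)
  genes <- matrix(NA_real_, n_objects, n_genes)
  gname <- rownames(rng)[idx]
  if (anyDuplicated(gname)) gname <- make.unique(gname, sep = "_")
  colnames(genes) <- gname
  for (j in seq_len(n_genes)) {
    lo <- rng[idx[j], "lo"]; hi <- rng[idx[j], "hi"]; w <- hi - lo
    mu <- (lo + hi) / 2 + (stage - 1.5) * effect_size * w / 4
    genes[, j] <- stats::rnorm(n_objects, mu, noise_frac * w)
  }

  event_time <- stats::rweibull(n_objects, shape = weibull_shape,
                                scale = weibull_scale *
                                  stage_scale_factors[stage + 1])
  censored <- stats::rbinom(n_objects, 1, censor_frac) == 1
  time <- ifelse(censored, stats::runif(n_objects) * event_time, event_time)
  time <- pmax(time, 1e-6)
  clin[, "DFS"] <- time

  values <- cbind(clin, genes, d = stage, event = as.integer(!censored))
  rownames(values) <- paste0("s", seq_len(n_objects))
  information_system(values, decision = "d", time = "DFS", event = "event",
                     categorical = c("Gender", "Location",
                                     "AdjRadio", "AdjChem"))
}
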