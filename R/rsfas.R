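#' Fuzzy proximity membership of two attribute values
#'
#' Degree to which two values of one attribute are "almost equal":
#' `1 - |v_i - v_j| / max(v_i, v_j)`, clipped to `[0, 1]`.  Equal values
#' (including both zero) have membership 1.  The ratio form makes the
#' membership scale-invariant for positive values.  When
#' `max(v_i, v_j) <= 0` the definition is vacuous, so the implementation
#' falls back to `1 - |v_i - v_j| / max(|v_i|, |v_j|, 1e-12)` (clipped),
#' which only guards synthetic edge cases: expression values and clinical
#' covariates are positive.
#'
#' @param v_i,v_j Numeric vectors (recycled).
#' @return Memberships in `[0, 1]`.
#' @examples
#' fuzzy_membership(3.09, 3.04)   # ~0.984: 98% degree of belongingness
#' @export
fuzzy_membership <- function(v_i, v_j) {
  m <- pmax(v_i, v_j)
  d <- abs(v_i - v_j)
  denom <- ifelse(m > 0, m, pmax(abs(v_i), abs(v_j), 1e-12))
  out <- ifelse(d == 0, 1, 1 - d / denom)
  pmin(pmax(out, 0), 1)
}

#' Fuzzy proximity matrix of one attribute
#'
#' Pairwise [fuzzy_membership()] over all objects of the system for a
#' numeric attribute, optionally rounded.  The matrix is symmetric with a
#' unit diagonal.  Printed reference tables show memberships at two
#' decimals and their worked partitions only reproduce when the comparison
#' happens on the rounded values, so rounding (default 2 decimals) is
#' applied before any alpha-cut; pass `rounding_dp = NULL` for exact
#' memberships.
#'
#' @param is An [information_system()].
#' @param attribute Name of a numeric (or time) attribute.
#' @param rounding_dp Decimal places to round memberships to, or `NULL`.
#' @return An object of class `proximity_matrix`: `attribute`, `objects`,
#'   `values` (the membership matrix) and `attribute_values` (used later to
#'   order classes), plus `rounding_dp`.
#' @export
proximity_matrix <- function(is, attribute, rounding_dp = 2) {
  stopifnot(inherits(is, "information_system"))
  if (!attribute %in% is$attributes$name)
    stop("unknown attribute '", attribute, "'", call. = FALSE)
  kind <- is$attributes$kind[is$attributes$name == attribute]
  if (kind == "categorical")
    stop(structure(
      class = c("rsfas_skip_attribute", "error", "condition"),
      list(message = paste0("attribute '", attribute,
                            "' is categorical; fuzzy proximity is not computed"),
           call = NULL)))
  v <- is$values[, attribute]
  M <- outer(v, v, fuzzy_membership)
  M <- (M + t(M)) / 2            # enforce exact symmetry against fp noise
  diag(M) <- 1
  if (!is.null(rounding_dp)) M <- round(M, rounding_dp)
  dimnames(M) <- list(is$object_ids, is$object_ids)
  structure(list(attribute = attribute, objects = is$object_ids,
                 values = M, attribute_values = v,
                 rounding_dp = rounding_dp),
            class = "proximity_matrix")
}

#' Alpha-equivalence classes of a fuzzy proximity matrix
#'
#' Thresholds the proximity relation at `alpha` and closes it
#' transitively: two objects fall in the same class when they are joined by
#' a chain of pairs whose membership is at least `alpha` (connected
#' components of the alpha-cut graph, computed by union-find).  Classes are
#' listed by their smallest object index; `class_order` additionally ranks
#' them by ascending mean attribute value when the matrix carries the
#' attribute values.
#'
#' @param pm A [proximity_matrix()] (or a plain symmetric membership
#'   matrix with unit diagonal).
#' @param alpha Cut level in `[0, 1]`.
#' @return An object of class `alpha_partition`: `attribute`, `alpha`,
#'   `classes` (list of character vectors partitioning the objects),
#'   `class_order` (permutation ranking classes by ascending class mean,
#'   or by first member when no values are attached) and `objects`.
#' @examples
#' t3 <- crc_fixture("table3")
#' alpha_classes(proximity_matrix(t3, "a1"), alpha = 0.98)$classes
#' @export
alpha_classes <- function(pm, alpha) {
  if (is.matrix(pm))
    pm <- structure(list(attribute = NA_character_,
                         objects = rownames(pm) %||%
                           paste0("o", seq_len(nrow(pm))),
                         values = pm, attribute_values = NULL,
                         rounding_dp = NULL),
                    class = "proximity_matrix")
  stopifnot(inherits(pm, "proximity_matrix"),
            alpha >= 0, alpha <= 1)
  M <- pm$values
  n <- nrow(M)

  # union-find with path compression; linking the larger root under the
  # smaller makes each final root the smallest object index of its class
  parent <- seq_len(n)
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) { nxt <- parent[i]; parent[i] <<- r; i <- nxt }
    r
  }
  eps <- 1e-12
  if (alpha - eps > min(M)) {
    edges <- which(M >= alpha - eps & upper.tri(M), arr.ind = TRUE)
    for (e in seq_len(nrow(edges))) {
      ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  } else parent[] <- 1L      # cut level at or below every membership
  root <- vapply(seq_len(n), find, integer(1))
  comp_ids <- sort(unique(root))
  classes <- lapply(comp_ids, function(r) pm$objects[root == r])

  class_order <- if (!is.null(pm$attribute_values)) {
    means <- vapply(comp_ids, function(r)
      mean(pm$attribute_values[root == r]), numeric(1))
    order(means, comp_ids)     # ties broken by smallest member index
  } else seq_along(classes)

  structure(list(attribute = pm$attribute, alpha = alpha,
                 classes = classes, class_order = class_order,
                 objects = pm$objects),
            class = "alpha_partition")
}

#' Rough lower and upper approximation of a target set
#'
#' Approximates an arbitrary target set by unions of alpha-equivalence
#' classes: the lower approximation collects the classes wholly inside the
#' target (certain members), the upper approximation the classes meeting it
#' (possible members); their difference is the boundary, and the target is
#' alpha-rough exactly when the boundary is non-empty.
#'
#' @param partition An [alpha_classes()] result.
#' @param target Character vector of object ids, a subset of the
#'   partition's objects.
#' @return An object of class `rough_approximation`: `target`, `lower`,
#'   `upper`, `boundary`, `is_alpha_rough`.
#' @export
lower_upper <- function(partition, target) {
  stopifnot(inherits(partition, "alpha_partition"))
  target <- unique(as.character(target))
  unknown <- setdiff(target, partition$objects)
  if (length(unknown))
    stop("target contains unknown object(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  inside <- vapply(partition$classes,
                   function(z) all(z %in% target), logical(1))
  meets <- vapply(partition$classes,
                  function(z) any(z %in% target), logical(1))
  lower <- unlist(partition$classes[inside], use.names = FALSE) %||% character()
  upper <- unlist(partition$classes[meets], use.names = FALSE) %||% character()
  if (is.null(lower)) lower <- character()
  if (is.null(upper)) upper <- character()
  boundary <- setdiff(upper, lower)
  structure(list(target = target, lower = lower, upper = upper,
                 boundary = boundary,
                 is_alpha_rough = length(boundary) > 0),
            class = "rough_approximation")
}

ordinal_labels <- function(k) {
  if (k == 3) c("L", "M", "H")
  else if (k == 5) c("VL", "L", "M", "H", "VH")
  else paste0("R", seq_len(k))
}

#' Quantize an information system through alpha-equivalence classes
#'
#' Transforms every numeric conditional attribute (including the follow-up
#' time) into an ordinal one: the attribute's alpha-equivalence classes are
#' ranked by ascending class mean and weighted `1..k` (ascending value,
#' ascending weight), with the field's label vocabulary attached (L/M/H for
#' three classes, VL..VH for five, generic ranks otherwise, with a warning
#' above five).  Categorical, decision and event attributes pass through
#' unchanged -- the stage decision is already ordinal.
#'
#' @param is An [information_system()].
#' @param alpha Cut level in `[0, 1]` (default 0.97), or a named vector for
#'   per-attribute overrides (unnamed element or `.default` = fallback).
#' @param rounding_dp Membership rounding before the cut; see
#'   [proximity_matrix()].
#' @return An object of class `ordinal_system` (also an
#'   `information_system`): quantized integer `values`, a character
#'   `labels` matrix, and `partitions`, the per-attribute
#'   [alpha_classes()] results.
#' @examples
#' ord <- quantize(crc_fixture("table3"), alpha = 0.98)
#' ord$values
#' @export
quantize <- function(is, alpha = 0.97, rounding_dp = 2) {
  stopifnot(inherits(is, "information_system"))
  default_alpha <- if (is.null(names(alpha))) alpha[1] else {
    d <- alpha[names(alpha) %in% c("", ".default")]
    if (length(d)) d[1] else 0.97
  }
  targets <- is$attributes$name[is$attributes$kind %in% c("numeric", "time")]
  values <- is$values
  labels <- matrix(as.character(is$values), nrow(is$values),
                   dimnames = dimnames(is$values))
  partitions <- list()
  for (a in targets) {
    al <- if (!is.null(names(alpha)) && a %in% names(alpha))
      alpha[[a]] else default_alpha
    part <- alpha_classes(proximity_matrix(is, a, rounding_dp), al)
    k <- length(part$classes)
    if (k > 5)
      warning("attribute '", a, "' yields ", k,
              " classes; using generic rank labels", call. = FALSE)
    vocab <- ordinal_labels(k)
    weight_of_class <- integer(k)
    weight_of_class[part$class_order] <- seq_len(k)
    w <- integer(length(part$objects))
    for (ci in seq_len(k))
      w[part$objects %in% part$classes[[ci]]] <- weight_of_class[ci]
    values[, a] <- w
    labels[, a] <- vocab[w]
    partitions[[a]] <- part
  }
  out <- replace_values(is, values)
  out$labels <- labels
  out$partitions <- partitions
  class(out) <- c("ordinal_system", class(out))
  out
}
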