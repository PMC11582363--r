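# Independent oracles used by the property and acceptance tests.  They are
# deliberately naive (brute force / closed form) and share no code with the
# implementation paths they check.

# max-min transitive closure by Floyd-Warshall; components are then the
# groups whose closed membership reaches `alpha`
fw_closure_components <- function(M, alpha) {
  n <- nrow(M)
  C <- M
  for (k in seq_len(n))
    C <- pmax(C, outer(C[, k], C[k, ], pmin))
  reach <- C >= alpha - 1e-12
  diag(reach) <- TRUE
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  split(rownames(M) %||% as.character(seq_len(n)), comp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random symmetric fuzzy proximity matrix with unit diagonal, 2-dp values
random_proximity <- function(n, seed) {
  set.seed(seed)
  M <- matrix(round(runif(n * n), 2), n)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- 1
  rownames(M) <- colnames(M) <- paste0("o", seq_len(n))
  M
}

# O(n^2) pair-counting AUC with half credit for ties
auc_paircount <- function(pos, scores) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# survival records with conventional independent Weibull censoring
# calibrated so that P(censored) = censor_frac
simulate_censored_weibull <- function(n, shape, scale, censor_frac, seed) {
  set.seed(seed)
  tt <- rweibull(n, shape, scale)
  if (censor_frac > 0) {
    c_scale <- scale * ((1 - censor_frac) / censor_frac)^(1 / shape)
    cc <- rweibull(n, shape, c_scale)
    list(time = pmin(tt, cc), event = as.integer(tt <= cc))
  } else list(time = tt, event = rep(1L, n))
}

# compact strongly stage-separated synthetic system for classifier checks
separable_system <- function(n, seed, n_genes = 6) {
  generate_synthetic(n, n_genes = n_genes, effect_size = 1,
                     noise_frac = 0.015, seed = seed)
}
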