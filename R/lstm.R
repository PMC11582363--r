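sigmoid <- function(x) 1 / (1 + exp(-x))

# add a bias row-vector to every row of a batch matrix
addb <- function(A, b) A + rep(b, each = nrow(A))

#' LSTM classifier configuration
#'
#' Collects the hyperparameters of the stage classifier.  Defaults follow
#' the selected tuning choices of the study the pipeline reproduces, scaled
#' to a single hidden layer.  Each patient row is treated as a sequence
#' with one feature per conditional attribute (one ordinal token per step),
#' so the number of timesteps equals the number of conditional attributes.
#'
#' @param direction `"uni"` (forward pass only) or `"bi"` (forward and
#'   backward passes combined).
#' @param units Hidden units per LSTM layer (>= 1).
#' @param hidden_layers Number of stacked LSTM layers (>= 1).
#' @param epochs Training epochs (>= 0; 0 returns the initialized model).
#' @param batch_size Mini-batch size (>= 1).
#' @param learning_rate Positive step size.
#' @param dropout Dropout rate in `[0, 1)` applied between layers and
#'   before the softmax head (training only).
#' @param optimizer One of `"adam"`, `"rmsprop"`, `"nadam"`, `"adamax"`.
#' @param seed Integer seed controlling initialization, the train/test
#'   split, epoch shuffling and dropout masks.
#' @param bidirectional_combiner `"concat"` (default; final forward and
#'   backward hidden states concatenated) -- the printed convex-mixing
#'   combination is available for cell-level experiments through
#'   [bidirectional_combine()].
#' @return A list of class `lstm_config`.
#' @export
lstm_config <- function(direction = c("uni", "bi"), units = 16,
                        hidden_layers = 1, epochs = 50, batch_size = 32,
                        learning_rate = 0.01, dropout = 0,
                        optimizer = c("nadam", "adam", "rmsprop", "adamax"),
                        seed = 1,
                        bidirectional_combiner = c("concat", "paper_eq20")) {
  direction <- match.arg(direction)
  optimizer <- match.arg(optimizer)
  bidirectional_combiner <- match.arg(bidirectional_combiner)
  stopifnot(units >= 1, hidden_layers >= 1, epochs >= 0, batch_size >= 1,
            learning_rate > 0, dropout >= 0, dropout < 1)
  structure(list(direction = direction, units = as.integer(units),
                 hidden_layers = as.integer(hidden_layers),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, dropout = dropout,
                 optimizer = optimizer, seed = as.integer(seed),
                 bidirectional_combiner = bidirectional_combiner),
            class = "lstm_config")
}

#' One LSTM cell step
#'
#' Computes the gate activations and state update of a single LSTM cell:
#' input, forget and output gates through the logistic function, the
#' candidate through `tanh`, then `C_t = f_t * C_{t-1} + i_t * Ctilde_t`
#' and `h_t = O_t * tanh(C_t)`.
#'
#' `params` holds input weights `w_i, w_f, w_o, w_c` (input-dim x units),
#' recurrent weights `u_i, u_f, u_o, u_c` (units x units) and biases
#' `b_i, b_f, b_o, b_c` (or a single shared `b`, the printed form reusing
#' one bias across gates).  The default gate pre-activation is the standard
#' affine map `x w + h u + b`; `form = "literal"` reproduces the printed
#' bracketing `w (x + u h) + b`, which requires the input width to equal
#' the unit count.
#'
#' @param x Input at this step: vector of length d or a batch matrix (rows
#'   = batch).
#' @param h_prev,c_prev Previous hidden and cell state (length-units
#'   vector or batch matrix).
#' @param params Named list of weights as above.
#' @param form `"standard"` or `"literal"`.
#' @return A list with `h`, `c` and `gates` (`i`, `f`, `o`, `candidate`),
#'   each shaped like `h_prev`.
#' @examples
#' U <- 2
#' p <- list(w_i = matrix(0, 1, U), w_f = matrix(0, 1, U),
#'           w_o = matrix(0, 1, U), w_c = matrix(0, 1, U),
#'           u_i = matrix(0, U, U), u_f = matrix(0, U, U),
#'           u_o = matrix(0, U, U), u_c = matrix(0, U, U), b = rep(0, U))
#' lstm_cell_forward(5, c(0.3, -0.2), c(1, 2), p)$gates$i   # all 0.5
#' @export
lstm_cell_forward <- function(x, h_prev, c_prev, params,
                              form = c("standard", "literal")) {
  form <- match.arg(form)
  vec_in <- !is.matrix(x) || !is.matrix(h_prev)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(h_prev)) h_prev <- matrix(h_prev, nrow = 1)
  if (!is.matrix(c_prev)) c_prev <- matrix(c_prev, nrow = 1)
  U <- ncol(h_prev)
  if (ncol(params$w_i) != U || nrow(params$w_i) != ncol(x))
    stop("dimension error: weights inconsistent with input/hidden widths",
         call. = FALSE)
  bias <- function(g) params[[paste0("b_", g)]] %||% params$b %||% rep(0, U)
  pre <- function(g) {
    w <- params[[paste0("w_", g)]]; u <- params[[paste0("u_", g)]]
    if (form == "standard")
      addb(x %*% w + h_prev %*% u, bias(g))
    else {
      if (ncol(x) != U)
        stop("literal form needs input width equal to units", call. = FALSE)
      addb((x + h_prev %*% u) %*% w, bias(g))
    }
  }
  i <- sigmoid(pre("i")); f <- sigmoid(pre("f")); o <- sigmoid(pre("o"))
  g <- tanh(pre("c"))
  cc <- f * c_prev + i * g
  h <- o * tanh(cc)
  if (vec_in) {
    list(h = drop(h), c = drop(cc),
         gates = list(i = drop(i), f = drop(f), o = drop(o),
                      candidate = drop(g)))
  } else list(h = h, c = cc, gates = list(i = i, f = f, o = o, candidate = g))
}

#' Combine forward and backward LSTM representations
#'
#' The default combiner concatenates the final forward and backward hidden
#' states (a d-dimensional state per direction gives a 2d-dimensional
#' representation).  `method = "paper_eq20"` instead evaluates the printed
#' convex mixing `Total_h = (1 - O_t) * h_{t-1} + O_t * Ctilde_t`, for
#' which `h_backward` must be a state list carrying `o` (output gate),
#' `candidate` and `h_prev`.
#'
#' @param h_forward Final forward hidden state (vector or batch matrix).
#' @param h_backward Final backward hidden state, or for `"paper_eq20"` a
#'   list with elements `o`, `candidate`, `h_prev`.
#' @param method `"concat"` or `"paper_eq20"`.
#' @return The combined representation.
#' @export
bidirectional_combine <- function(h_forward, h_backward,
                                  method = c("concat", "paper_eq20")) {
  method <- match.arg(method)
  if (method == "concat") {
    if (is.matrix(h_forward)) {
      if (nrow(h_forward) != nrow(h_backward))
        stop("dimension error: batch sizes differ", call. = FALSE)
      cbind(h_forward, h_backward)
    } else {
      if (length(h_forward) != length(h_backward))
        stop("dimension error: state lengths differ", call. = FALSE)
      c(h_forward, h_backward)
    }
  } else {
    st <- h_backward
    if (!all(c("o", "candidate", "h_prev") %in% names(st)))
      stop("paper_eq20 needs a state list with o, candidate, h_prev",
           call. = FALSE)
    (1 - st$o) * st$h_prev + st$o * st$candidate
  }
}

# ---- internal stacked-LSTM machinery (training path) ---------------------

cell_params_init <- function(input_dim, units) {
  r <- sqrt(6 / (input_dim + units))
  ru <- sqrt(6 / (2 * units))
  mk <- function(n, m, rr) matrix(stats::runif(n * m, -rr, rr), n, m)
  list(W = list(i = mk(input_dim, units, r), f = mk(input_dim, units, r),
                o = mk(input_dim, units, r), g = mk(input_dim, units, r)),
       U = list(i = mk(units, units, ru), f = mk(units, units, ru),
                o = mk(units, units, ru), g = mk(units, units, ru)),
       b = list(i = rep(0, units), f = rep(1, units),   # forget bias 1
                o = rep(0, units), g = rep(0, units)))
}

layer_forward <- function(X, p) {
  Tn <- length(X); B <- nrow(X[[1]]); U <- ncol(p$W$i)
  h <- matrix(0, B, U); cc <- matrix(0, B, U)
  cache <- vector("list", Tn); hs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- X[[t]]
    i <- sigmoid(addb(x %*% p$W$i + h %*% p$U$i, p$b$i))
    f <- sigmoid(addb(x %*% p$W$f + h %*% p$U$f, p$b$f))
    o <- sigmoid(addb(x %*% p$W$o + h %*% p$U$o, p$b$o))
    g <- tanh(addb(x %*% p$W$g + h %*% p$U$g, p$b$g))
    cn <- f * cc + i * g
    tc <- tanh(cn)
    hn <- o * tc
    cache[[t]] <- list(x = x, h_prev = h, c_prev = cc, i = i, f = f,
                       o = o, g = g, tc = tc)
    h <- hn; cc <- cn; hs[[t]] <- hn
  }
  list(hs = hs, cache = cache,
       last_state = list(o = o, candidate = g, h_prev = cache[[Tn]]$h_prev))
}

layer_backward <- function(cache, p, dhs) {
  Tn <- length(cache)
  zW <- lapply(p$W, function(m) m * 0)
  zU <- lapply(p$U, function(m) m * 0)
  zb <- lapply(p$b, function(v) v * 0)
  dh_next <- 0; dc_next <- 0
  dX <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    k <- cache[[t]]
    dh <- dhs[[t]] + dh_next
    do <- dh * k$tc
    dc <- dc_next + dh * k$o * (1 - k$tc^2)
    di <- dc * k$g
    dg <- dc * k$i
    df <- dc * k$c_prev
    dc_next <- dc * k$f
    dai <- di * k$i * (1 - k$i)
    daf <- df * k$f * (1 - k$f)
    dao <- do * k$o * (1 - k$o)
    dag <- dg * (1 - k$g^2)
    zW$i <- zW$i + crossprod(k$x, dai); zU$i <- zU$i + crossprod(k$h_prev, dai)
    zW$f <- zW$f + crossprod(k$x, daf); zU$f <- zU$f + crossprod(k$h_prev, daf)
    zW$o <- zW$o + crossprod(k$x, dao); zU$o <- zU$o + crossprod(k$h_prev, dao)
    zW$g <- zW$g + crossprod(k$x, dag); zU$g <- zU$g + crossprod(k$h_prev, dag)
    zb$i <- zb$i + colSums(dai); zb$f <- zb$f + colSums(daf)
    zb$o <- zb$o + colSums(dao); zb$g <- zb$g + colSums(dag)
    dh_next <- dai %*% t(p$U$i) + daf %*% t(p$U$f) +
      dao %*% t(p$U$o) + dag %*% t(p$U$g)
    dX[[t]] <- dai %*% t(p$W$i) + daf %*% t(p$W$f) +
      dao %*% t(p$W$o) + dag %*% t(p$W$g)
  }
  list(grads = list(W = zW, U = zU, b = zb), dX = dX)
}

# forward through the whole network for a batch matrix (B x T features).
# masks: optional dropout masks (training); NULL at inference.
net_forward <- function(Xb, params, config, masks = NULL) {
  Tn <- ncol(Xb)
  X <- lapply(seq_len(Tn), function(t) Xb[, t, drop = FALSE])
  dirs <- names(params$layers[[1]])
  caches <- list()
  finals <- list()
  for (d in dirs) {
    seqs <- if (d == "bwd") rev(X) else X
    for (l in seq_along(params$layers)) {
      fw <- layer_forward(seqs, params$layers[[l]][[d]])
      caches[[paste(d, l)]] <- fw
      seqs <- fw$hs
      if (!is.null(masks) && l < length(params$layers))
        seqs <- lapply(seqs, function(h) h * masks[[paste(d, l)]])
    }
    finals[[d]] <- seqs[[Tn]]
  }
  comb <- if (length(dirs) == 2)
    bidirectional_combine(finals$fwd, finals$bwd) else finals$fwd
  if (!is.null(masks)) comb <- comb * masks$head
  logits <- addb(comb %*% params$head$W, params$head$b)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs, comb = comb, caches = caches, Tn = Tn)
}

net_backward <- function(fw, Y, params, config, masks = NULL) {
  B <- nrow(Y)
  dlogits <- (fw$probs - Y) / B
  gW_head <- crossprod(fw$comb, dlogits)
  gb_head <- colSums(dlogits)
  dcomb <- dlogits %*% t(params$head$W)
  if (!is.null(masks)) dcomb <- dcomb * masks$head
  dirs <- names(params$layers[[1]])
  U <- config$units
  gl <- vector("list", length(params$layers))
  for (li in seq_along(gl)) gl[[li]] <- list()
  for (di in seq_along(dirs)) {
    d <- dirs[di]
    dfinal <- dcomb[, ((di - 1) * U + 1):(di * U), drop = FALSE]
    dhs <- NULL
    for (l in rev(seq_along(params$layers))) {
      cache <- fw$caches[[paste(d, l)]]$cache
      if (is.null(dhs)) {
        dhs <- lapply(seq_len(fw$Tn), function(t) dfinal * 0)
        dhs[[fw$Tn]] <- dfinal
      }
      bk <- layer_backward(cache, params$layers[[l]][[d]], dhs)
      gl[[l]][[d]] <- bk$grads
      if (l > 1) {
        dhs <- bk$dX
        if (!is.null(masks))
          dhs <- lapply(dhs, function(g) g * masks[[paste(d, l - 1)]])
      }
    }
  }
  list(layers = gl, head = list(W = gW_head, b = gb_head))
}

# flatten/relist parameter trees so optimizers and finite-difference
# checks can treat the model as one numeric vector
params_flatten <- function(p) unlist(p, use.names = FALSE)

params_relist <- function(template, v) {
  rel <- utils::relist(v, skeleton = template)
  rel
}

make_optimizer <- function(name, lr, n_par) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; rho <- 0.9
  state <- list(m = numeric(n_par), v = numeric(n_par), t = 0)
  function(theta, grad) {
    state$t <<- state$t + 1
    tt <- state$t
    if (name == "rmsprop") {
      state$v <<- rho * state$v + (1 - rho) * grad^2
      return(theta - lr * grad / (sqrt(state$v) + eps))
    }
    state$m <<- b1 * state$m + (1 - b1) * grad
    if (name == "adamax") {
      state$v <<- pmax(b2 * state$v, abs(grad))
      return(theta - (lr / (1 - b1^tt)) * state$m / (state$v + eps))
    }
    state$v <<- b2 * state$v + (1 - b2) * grad^2
    vhat <- state$v / (1 - b2^tt)
    if (name == "adam") {
      mhat <- state$m / (1 - b1^tt)
      theta - lr * mhat / (sqrt(vhat) + eps)
    } else {                       # nadam: Nesterov momentum on top of adam
      mhat <- state$m / (1 - b1^(tt + 1))
      theta - lr * (b1 * mhat + (1 - b1) * grad / (1 - b1^tt)) /
        (sqrt(vhat) + eps)
    }
  }
}

init_params <- function(config, n_features, n_classes) {
  dirs <- if (config$direction == "bi") c("fwd", "bwd") else "fwd"
  layers <- vector("list", config$hidden_layers)
  for (l in seq_len(config$hidden_layers)) {
    input_dim <- if (l == 1) 1L else config$units
    layers[[l]] <- stats::setNames(
      lapply(dirs, function(d) cell_params_init(input_dim, config$units)),
      dirs)
  }
  H <- config$units * length(dirs)
  r <- sqrt(6 / (H + n_classes))
  list(layers = layers,
       head = list(W = matrix(stats::runif(H * n_classes, -r, r),
                              H, n_classes),
                   b = rep(0, n_classes)))
}

#' Train an LSTM stage classifier
#'
#' Shapes each row of the (typically quantized) information system into a
#' sequence -- one conditional attribute per timestep, one feature per
#' step -- and trains a unidirectional or bidirectional LSTM with a
#' softmax head by backpropagation through time on categorical
#' cross-entropy, using the configured optimizer.  Features are the
#' numeric, categorical and time attributes (the event indicator and the
#' decision are excluded); each is standardized on the training split.
#' The split is stratified by class.  Identical seed and configuration
#' reproduce the run exactly.
#'
#' @param ordinal An [information_system()] (usually a [quantize()]
#'   result) with a decision attribute holding >= 2 classes.
#' @param config An [lstm_config()].
#' @param split Train/test fractions, e.g. `c(0.7, 0.3)`.
#' @return An object of class `lstm_model`: `params`, `config`, `classes`,
#'   `feature_names`, `center`/`scale`, `history` (per-epoch data frame of
#'   `epoch`, `accuracy`, `loss`; empty for 0 epochs), `train_ids`,
#'   `test_ids`, and `train_accuracy`/`test_accuracy` of the final model.
#' @examples
#' s <- generate_synthetic(80, n_genes = 4, effect_size = 1,
#'                         noise_frac = 0.015, seed = 2)
#' m <- lstm_train(quantize(s), lstm_config(units = 4, epochs = 3, seed = 2))
#' m$history
#' @export
lstm_train <- function(ordinal, config = lstm_config(),
                       split = c(0.7, 0.3)) {
  stopifnot(inherits(ordinal, "information_system"),
            inherits(config, "lstm_config"))
  if (is.null(ordinal$decision_attribute))
    stop("training needs a decision attribute", call. = FALSE)
  if (config$bidirectional_combiner != "concat")
    stop("training supports the concat combiner; see bidirectional_combine()",
         call. = FALSE)
  feats <- ordinal$attributes$name[
    ordinal$attributes$kind %in% c("numeric", "categorical", "time")]
  y_raw <- ordinal$values[, ordinal$decision_attribute]
  classes <- sort(unique(y_raw))
  if (length(classes) < 2)
    stop("training error: decision attribute has a single class",
         call. = FALSE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n <- nrow(ordinal$values)
  train_idx <- integer()
  for (cl in classes) {
    rows <- which(y_raw == cl)
    n_tr <- round(split[1] * length(rows))
    train_idx <- c(train_idx, sample(rows)[seq_len(n_tr)])
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)

  Xall <- ordinal$values[, feats, drop = FALSE]
  ctr <- colMeans(Xall[train_idx, , drop = FALSE])
  scl <- apply(Xall[train_idx, , drop = FALSE], 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(Xall, 2, ctr), 2, scl, "/")

  K <- length(classes)
  Yall <- matrix(0, n, K)
  Yall[cbind(seq_len(n), match(y_raw, classes))] <- 1

  params <- init_params(config, length(feats), K)
  template <- params
  theta <- params_flatten(params)
  step <- make_optimizer(config$optimizer, config$learning_rate,
                         length(theta))

  hist <- data.frame(epoch = integer(), accuracy = numeric(),
                     loss = numeric())
  dirs <- if (config$direction == "bi") c("fwd", "bwd") else "fwd"
  for (ep in seq_len(config$epochs)) {
    ord <- sample(train_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_hits <- 0
    for (bi in batches) {
      Xb <- Xs[bi, , drop = FALSE]; Yb <- Yall[bi, , drop = FALSE]
      masks <- NULL
      if (config$dropout > 0) {
        keep <- 1 - config$dropout
        masks <- list(head = matrix(
          stats::rbinom(length(bi) * config$units * length(dirs), 1, keep),
          length(bi)) / keep)
        for (d in dirs) for (l in seq_len(config$hidden_layers - 1))
          masks[[paste(d, l)]] <- matrix(
            stats::rbinom(length(bi) * config$units, 1, keep),
            length(bi)) / keep
      }
      fw <- net_forward(Xb, params, config, masks)
      loss <- -mean(log(pmax(fw$probs[Yb == 1], 1e-300)))
      if (!is.finite(loss))
        stop("divergence error: NaN loss at epoch ", ep, call. = FALSE)
      gr <- net_backward(fw, Yb, params, config, masks)
      theta <- step(theta, params_flatten(gr))
      params <- params_relist(template, theta)
      ep_loss <- ep_loss + loss * length(bi)
      ep_hits <- ep_hits +
        sum(apply(fw$probs, 1, which.max) == apply(Yb, 1, which.max))
    }
    hist <- rbind(hist, data.frame(epoch = ep,
                                   accuracy = ep_hits / length(train_idx),
                                   loss = ep_loss / length(train_idx)))
  }

  model <- structure(
    list(params = params, config = config, classes = classes,
         feature_names = feats, center = ctr, scale = scl,
         history = hist,
         train_ids = ordinal$object_ids[train_idx],
         test_ids = ordinal$object_ids[test_idx]),
    class = "lstm_model")
  model$train_accuracy <- mean(
    predict(model, ordinal$values[train_idx, , drop = FALSE]) ==
      as.character(y_raw[train_idx]))
  model$test_accuracy <- if (length(test_idx))
    mean(predict(model, ordinal$values[test_idx, , drop = FALSE]) ==
           as.character(y_raw[test_idx])) else NA_real_
  model
}

#' Predict stages from a trained LSTM model
#'
#' @param object An [lstm_train()] result.
#' @param newdata An `information_system`, `ordinal_system` or numeric
#'   matrix containing every training feature column.
#' @param type `"class"` for labels (argmax, lowest index on ties) or
#'   `"prob"` for the class-probability matrix (rows sum to 1).
#' @param ... Unused.
#' @return Character vector of class labels, or a probability matrix.
#' @export
predict.lstm_model <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  vals <- if (inherits(newdata, "information_system")) newdata$values
  else as.matrix(newdata)
  missing <- setdiff(object$feature_names, colnames(vals))
  if (length(missing))
    stop("feature error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  X <- vals[, object$feature_names, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  fw <- net_forward(Xs, object$params, object$config, masks = NULL)
  if (type == "prob") {
    dimnames(fw$probs) <- list(rownames(vals), as.character(object$classes))
    fw$probs
  } else {
    as.character(object$classes)[apply(fw$probs, 1, which.max)]
  }
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf("%sdirectional LSTM: %d layer(s) x %d units, %s, %d epochs\n",
              if (x$config$direction == "bi") "bi" else "uni",
              x$config$hidden_layers, x$config$units, x$config$optimizer,
              x$config$epochs))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  if (nrow(x$history))
    cat(sprintf("  final train accuracy %.3f (loss %.4f); test accuracy %.3f\n",
                x$train_accuracy, x$history$loss[nrow(x$history)],
                x$test_accuracy))
  invisible(x)
}
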