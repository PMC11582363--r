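zero_cell_params <- function(U, d = 1) {
  z <- function(n, m) matrix(0, n, m)
  list(w_i = z(d, U), w_f = z(d, U), w_o = z(d, U), w_c = z(d, U),
       u_i = z(U, U), u_f = z(U, U), u_o = z(U, U), u_c = z(U, U),
       b = rep(0, U))
}

test_that("the zero-parameter cell follows its closed form", {
  p <- zero_cell_params(2)
  out <- lstm_cell_forward(5, c(0.3, -0.2), c(1, 2), p)
  expect_equal(out$gates$i, c(0.5, 0.5))
  expect_equal(out$gates$f, c(0.5, 0.5))
  expect_equal(out$gates$o, c(0.5, 0.5))
  expect_equal(out$gates$candidate, c(0, 0))
  expect_equal(out$c, 0.5 * c(1, 2))
  expect_equal(out$h, 0.5 * tanh(0.5 * c(1, 2)))
})

test_that("a hand-computed 2-unit cell matches to 1e-10", {
  # small integer weights; the oracle below is spelled out step by step
  # with plain arithmetic, independent of the implementation
  p <- list(w_i = matrix(c(1, -1), 1, 2), w_f = matrix(c(2, 0), 1, 2),
            w_o = matrix(c(0, 1), 1, 2), w_c = matrix(c(1, 1), 1, 2),
            u_i = matrix(c(0, 1, 1, 0), 2, 2),
            u_f = matrix(c(1, 0, 0, 1), 2, 2),
            u_o = matrix(c(0, 0, 1, 1), 2, 2),
            u_c = matrix(c(1, -1, 0, 2), 2, 2),
            b_i = c(0.1, -0.1), b_f = c(0.2, 0.2),
            b_o = c(0, 0.3), b_c = c(-0.2, 0))
  x <- 0.5; h0 <- c(0.2, -0.4); c0 <- c(0.6, 0.1)
  sg <- function(z) 1 / (1 + exp(-z))
  ai <- c(x * 1 + h0[1] * 0 + h0[2] * 1 + 0.1,
          x * -1 + h0[1] * 1 + h0[2] * 0 - 0.1)
  af <- c(x * 2 + h0[1] * 1 + 0.2, x * 0 + h0[2] * 1 + 0.2)
  ao <- c(x * 0 + 0, x * 1 + h0[1] * 1 + h0[2] * 1 + 0.3)
  ac <- c(x * 1 + h0[1] * 1 + h0[2] * -1 - 0.2,
          x * 1 + h0[2] * 2 + 0)
  i <- sg(ai); f <- sg(af); o <- sg(ao); g <- tanh(ac)
  c1 <- f * c0 + i * g
  h1 <- o * tanh(c1)

  out <- lstm_cell_forward(x, h0, c0, p)
  expect_equal(out$h, h1, tolerance = 1e-10)
  expect_equal(out$c, c1, tolerance = 1e-10)
})

test_that("a saturated forget gate preserves the cell memory", {
  p <- zero_cell_params(2)
  p$b_f <- c(20, 20)                 # f -> 1
  set.seed(51)
  c0 <- rnorm(2); h0 <- rnorm(2)
  out <- lstm_cell_forward(1.3, h0, c0, p)
  expect_equal(out$c, c0 + out$gates$i * out$gates$candidate,
               tolerance = 1e-6)
})

test_that("the literal bracketing form is available when widths match", {
  p <- zero_cell_params(2, d = 2)
  out <- lstm_cell_forward(c(1, 2), c(0, 0), c(0, 0), p,
                           form = "literal")
  expect_equal(out$gates$i, c(0.5, 0.5))
  p1 <- zero_cell_params(2, d = 1)
  expect_error(lstm_cell_forward(1, c(0, 0), c(0, 0), p1,
                                 form = "literal"), "literal")
  expect_error(lstm_cell_forward(c(1, 2, 3), c(0, 0), c(0, 0), p1),
               "dimension")
})

test_that("bidirectional combination concatenates or convex-mixes", {
  expect_equal(bidirectional_combine(c(1, 2), c(3, 4)), c(1, 2, 3, 4))
  expect_equal(dim(bidirectional_combine(matrix(1, 3, 2),
                                         matrix(2, 3, 2))), c(3, 4))
  expect_error(bidirectional_combine(c(1, 2), c(1, 2, 3)), "dimension")

  st <- list(o = c(1, 1), candidate = c(0.7, -0.2), h_prev = c(5, 5))
  expect_equal(bidirectional_combine(NULL, st, "paper_eq20"),
               c(0.7, -0.2))
  st$o <- c(0, 0)
  expect_equal(bidirectional_combine(NULL, st, "paper_eq20"), c(5, 5))
})

test_that("analytic gradients match central finite differences", {
  set.seed(52)
  cfg <- lstm_config(units = 2, hidden_layers = 1, seed = 52)
  worst <- 0
  for (draw in 1:20) {
    params <- rsfas:::init_params(cfg, 3, 3)
    theta <- rsfas:::params_flatten(params)
    theta <- theta + rnorm(length(theta), 0, 0.3)
    params <- rsfas:::params_relist(params, theta)
    Xb <- matrix(rnorm(2 * 3), 2, 3)
    Y <- diag(3)[sample(1:3, 2, replace = TRUE), , drop = FALSE]
    lossfn <- function(th) {
      p <- rsfas:::params_relist(params, th)
      fw <- rsfas:::net_forward(Xb, p, cfg)
      -mean(log(fw$probs[Y == 1]))
    }
    fw <- rsfas:::net_forward(Xb, params, cfg)
    g <- rsfas:::params_flatten(rsfas:::net_backward(fw, Y, params, cfg))
    idx <- sample(seq_along(theta), 12)
    eps <- 1e-6
    for (i in idx) {
      tp <- theta; tp[i] <- tp[i] + eps
      tm <- theta; tm[i] <- tm[i] - eps
      gn <- (lossfn(tp) - lossfn(tm)) / (2 * eps)
      rel <- abs(g[i] - gn) / max(abs(g[i]) + abs(gn), 1e-6)
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("all four optimizers descend a convex quadratic", {
  for (opt in c("adam", "rmsprop", "nadam", "adamax")) {
    step <- rsfas:::make_optimizer(opt, 0.05, 4)
    theta <- c(3, -2, 1.5, -4)
    losses <- numeric(60)
    for (it in 1:60) {
      losses[it] <- sum(theta^2)
      theta <- step(theta, 2 * theta)
    }
    expect_true(all(diff(losses[-(1:5)]) <= 1e-10),
                info = paste("optimizer", opt))
    expect_lt(losses[60], losses[6])
  }
})

test_that("training is reproducible and learns a separable problem", {
  ord <- suppressWarnings(quantize(separable_system(240, seed = 53)))
  cfg <- lstm_config(direction = "uni", units = 12, epochs = 25,
                     batch_size = 32, learning_rate = 0.02,
                     optimizer = "adam", seed = 53)
  m1 <- lstm_train(ord, cfg)
  m2 <- lstm_train(ord, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_gte(m1$test_accuracy, 0.9)
  expect_gte(m1$train_accuracy, m1$history$accuracy[25] - 0.05)

  # bidirectional with dropout also learns it
  cfgb <- lstm_config(direction = "bi", units = 12, epochs = 25,
                      batch_size = 32, learning_rate = 0.02,
                      dropout = 0.1, optimizer = "nadam", seed = 53)
  mb <- lstm_train(ord, cfgb)
  expect_gte(mb$test_accuracy, 0.9)
})

test_that("label-shuffled data trains to chance-level accuracy", {
  s <- separable_system(240, seed = 54)
  v <- s$values
  set.seed(54)
  v[, "d"] <- sample(v[, "d"])
  shuffled <- information_system(v, decision = "d", time = "DFS",
                                 event = "event",
                                 categorical = c("Gender", "Location",
                                                 "AdjRadio", "AdjChem"))
  ord <- suppressWarnings(quantize(shuffled))
  cfg <- lstm_config(direction = "uni", units = 8, epochs = 15,
                     batch_size = 32, seed = 54)
  m <- lstm_train(ord, cfg)
  majority <- max(table(v[, "d"])) / nrow(v)
  expect_lt(abs(m$test_accuracy - majority), 0.15)
})

test_that("zero epochs returns the initialized model", {
  ord <- suppressWarnings(quantize(separable_system(60, seed = 55)))
  m <- lstm_train(ord, lstm_config(units = 4, epochs = 0, seed = 55))
  expect_equal(nrow(m$history), 0)
  expect_length(predict(m, ord$values), 60)
})

test_that("prediction is deterministic, normalized and schema-checked", {
  ord <- suppressWarnings(quantize(separable_system(80, seed = 56)))
  m <- lstm_train(ord, lstm_config(units = 4, epochs = 2, seed = 56))
  row <- ord$values[3, , drop = FALSE]
  ten <- row[rep(1, 10), , drop = FALSE]
  expect_length(unique(predict(m, ten)), 1)
  probs <- predict(m, ord$values, type = "prob")
  expect_equal(unname(rowSums(probs)), rep(1, 80), tolerance = 1e-6)
  expect_error(predict(m, ord$values[, 1:3, drop = FALSE]),
               "feature error")
})

test_that("degenerate training inputs raise typed errors", {
  s <- separable_system(40, seed = 57)
  v <- s$values; v[, "d"] <- 1
  one <- information_system(v, decision = "d")
  expect_error(lstm_train(suppressWarnings(quantize(one)),
                          lstm_config(epochs = 1)), "single class")
})
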