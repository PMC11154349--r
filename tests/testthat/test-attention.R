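test_that("attention_reconstruct matches the loop oracle and is row-stochastic", {
  set.seed(21)
  params <- attention_params(m = 2, d_model = 4, n_heads = 2)
  x <- matrix(rnorm(6), 3, 2)
  st <- attention_reconstruct(x, params)
  or <- oracle_attention(x, params)
  expect_equal(st$reconstruction, or$reconstruction, tolerance = 1e-10)
  expect_equal(st$scores, or$scores, tolerance = 1e-10)

  # N = 1: softmax over a single key gives a score of exactly 1 per head
  st1 <- attention_reconstruct(x[1, , drop = FALSE], params)
  expect_equal(as.vector(st1$scores), c(1, 1))

  # row-stochastic for random inputs, and deterministic
  x2 <- matrix(rnorm(40), 10, 4)
  p2 <- attention_params(m = 4, d_model = 8, n_heads = 2)
  st2 <- attention_reconstruct(x2, p2)
  for (h in 1:2)
    expect_equal(rowSums(st2$scores[h, , ]), rep(1, 10), tolerance = 1e-6)
  expect_identical(st2$reconstruction,
                   attention_reconstruct(x2, p2)$reconstruction)
  expect_error(attention_reconstruct(x2, params), "channel")
})

test_that("blocked attention is block-diagonal and consistent", {
  set.seed(3)
  x <- matrix(rnorm(24), 12, 2)
  params <- attention_params(m = 2, d_model = 4, n_heads = 2)
  full <- attention_reconstruct(x, params)
  blocked <- attention_reconstruct(x, params, block_size = 4L)
  # each block equals full attention applied to the block alone
  expect_length(blocked$scores, 3)
  for (b in 1:3) {
    idx <- ((b - 1) * 4 + 1):(b * 4)
    sub <- attention_reconstruct(x[idx, ], params)
    expect_equal(blocked$reconstruction[idx, ], sub$reconstruction,
                 tolerance = 1e-12)
  }
  expect_false(isTRUE(all.equal(blocked$reconstruction,
                                full$reconstruction)))
})

test_that("reconstruction_errors is the row-wise residual norm", {
  x <- matrix(rnorm(12), 4, 3)
  expect_equal(reconstruction_errors(x, x), rep(0, 4))
  expect_equal(reconstruction_errors(matrix(c(3, 4), 1, 2),
                                     matrix(0, 1, 2)), 5)
  xp <- x + matrix(rnorm(12), 4, 3)
  expect_equal(reconstruction_errors(x, x + 3 * (xp - x)),
               3 * reconstruction_errors(x, xp))
  expect_error(reconstruction_errors(x, x[1:2, ]), "shapes")
})

test_that("search_threshold picks the F1-optimal of 50 uniform candidates", {
  set.seed(5)
  train_err <- runif(200, 0, 1)
  val_err <- c(runif(50, 0, 0.5), runif(30, 0.8, 1))
  val_fine <- c(rep(0L, 50), rep(1L, 30))
  res <- search_threshold(train_err, val_err, val_fine)
  expect_length(res$candidates, 50)
  expect_equal(res$candidates,
               seq(min(train_err), max(train_err), length.out = 50))
  # a separating threshold exists, so the chosen tau separates
  expect_gt(res$tau, 0.5)
  expect_lte(res$tau, 0.8)
  # exhaustive optimality of the selected candidate
  f1_at <- function(tau) {
    pred <- val_err > tau
    tp <- sum(pred & val_fine == 1); fp <- sum(pred & val_fine == 0)
    fn <- sum(!pred & val_fine == 1)
    2 * tp / (2 * tp + fp + fn)
  }
  expect_true(all(f1_at(res$tau) >= sapply(res$candidates, f1_at)))

  # degenerate training errors collapse all candidates
  resd <- search_threshold(rep(0.4, 10), val_err, val_fine)
  expect_equal(resd$tau, 0.4)
  expect_equal(unique(resd$candidates), 0.4)

  # no positive validation step: specificity fallback, with a warning
  expect_warning(resf <- search_threshold(train_err, val_err,
                                          rep(0L, 80)), "specificity")
  expect_identical(resf$criterion, "specificity")
  expect_error(search_threshold(numeric(0), val_err, val_fine), "non-empty")
})

test_that("true/predicted step sets follow the strict threshold rule", {
  ss <- true_and_predicted_steps(c(0, 1, 1, 0), c(0.1, 0.9, 0.9, 0.2), 0.5)
  expect_identical(ss$true_steps, c(2L, 3L))
  expect_identical(ss$predicted_steps, c(2L, 3L))
  # tau >= max error leaves T2 empty (strict inequality)
  expect_length(true_and_predicted_steps(c(0, 1), c(0.3, 0.9),
                                         0.9)$predicted_steps, 0)
})

test_that("constrained reconstruction loss matches the hand cases", {
  x <- matrix(0, 2, 2)
  ss0 <- list(true_steps = 1:2, predicted_steps = 3:4)
  expect_equal(constrained_reconstruction_loss(x, x, ss0, 4), 0)

  # single unit residual entry, |T1| = 2, |T2| = 0, N = 4 -> 1 + 2/4
  xp <- matrix(c(1, 0, 0, 0), 2, 2)
  ss <- list(true_steps = 1:2, predicted_steps = integer(0))
  expect_equal(constrained_reconstruction_loss(x, xp, ss, 4), 1.5)
  # swapping T1 and T2 leaves the loss unchanged
  ss_sw <- list(true_steps = integer(0), predicted_steps = 1:2)
  expect_equal(constrained_reconstruction_loss(x, xp, ss_sw, 4), 1.5)
})

test_that("soft anomaly count approximates the hard count", {
  expect_lt(soft_anomaly_count(c(0.01, 0.02), tau = 5, temperature = 0.1),
            1e-8)
  expect_equal(soft_anomaly_count(c(0.1, 0.9), 0.5, 1e-6), 1, tolerance = 1e-6)
  expect_error(soft_anomaly_count(1, 0.5, 0), "positive")
  # monotone nondecreasing in each error
  set.seed(8)
  e <- runif(10)
  s0 <- soft_anomaly_count(e, 0.5, 0.1)
  for (i in 1:10) {
    e2 <- e; e2[i] <- e2[i] + 0.05
    expect_gte(soft_anomaly_count(e2, 0.5, 0.1), s0)
  }
  # soft -> hard convergence when no error sits near tau
  set.seed(9)
  for (rep in 1:5) {
    e <- runif(50)
    tau <- 0.5
    e <- e[abs(e - tau) > 1e-3]
    hard <- sum(e > tau)
    expect_lt(abs(soft_anomaly_count(e, tau, 1e-6) - hard), 0.01 * 50)
  }
})

test_that("attention_backward agrees with finite differences", {
  set.seed(31)
  params <- attention_params(m = 3, d_model = 4, n_heads = 2)
  x <- matrix(rnorm(15), 5, 3)
  target <- matrix(rnorm(15), 5, 3)
  loss <- function(p) {
    st <- attention_reconstruct(x, p)
    sum((st$reconstruction - target)^2) / 2
  }
  st <- attention_reconstruct(x, params, keep_cache = TRUE)
  g <- attention_backward(st, st$reconstruction - target)
  for (nm in c("Wq", "Wk", "Wv", "Wo")) {
    for (i in sample(length(params[[nm]]), 3)) {
      h <- 1e-6
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (loss(pp) - loss(pm)) / (2 * h)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-5)
    }
  }
})
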