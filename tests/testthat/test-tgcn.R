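tgcn_test_params <- function(f, dh, seed = 12) {
  set.seed(seed)
  g <- function(a, b) matrix(rnorm(a * b, sd = 0.4), a, b)
  list(Wu = g(f + dh, dh), Wr = g(f + dh, dh), Wc = g(f + dh, dh),
       bu = matrix(0, 1, dh), br = matrix(0, 1, dh),
       bc = matrix(0, 1, dh))
}

test_that("tgcn_cell matches the loop oracle and respects gate limits", {
  set.seed(13)
  feat <- matrix(rnorm(8), 4, 2)
  hid <- matrix(rnorm(12), 4, 3)
  adj <- matrix(runif(16), 4, 4); diag(adj) <- 0
  params <- tgcn_test_params(2, 3)
  st <- tgcn_cell(feat, hid, adj, params)
  or <- oracle_tgcn_cell(feat, hid, adj, params)
  expect_equal(st$hidden, or$hidden, tolerance = 1e-10)
  expect_equal(st$u, or$u, tolerance = 1e-10)
  expect_true(all(st$u > 0 & st$u < 1))
  expect_true(all(st$r > 0 & st$r < 1))
  expect_true(all(abs(st$c) < 1))
  # h_t is an elementwise convex combination of h_{t-1} and c_t
  expect_true(all(st$hidden <= pmax(hid, st$c) + 1e-12))
  expect_true(all(st$hidden >= pmin(hid, st$c) - 1e-12))
})

test_that("saturated update gate freezes or replaces the hidden state", {
  set.seed(14)
  feat <- matrix(rnorm(6), 3, 2)
  hid <- matrix(rnorm(6), 3, 2)
  adj <- matrix(runif(9), 3, 3); diag(adj) <- 0
  params <- tgcn_test_params(2, 2)
  pu1 <- params; pu1$bu <- matrix(20, 1, 2)      # u -> 1: h_t = h_{t-1}
  expect_lt(max(abs(tgcn_cell(feat, hid, adj, pu1)$hidden - hid)), 1e-6)
  pu0 <- params; pu0$bu <- matrix(-20, 1, 2)     # u -> 0: h_t = c_t
  st0 <- tgcn_cell(feat, hid, adj, pu0)
  expect_lt(max(abs(st0$hidden - st0$c)), 1e-6)
})

test_that("a 2-node cell reproduces a pencil-and-paper step", {
  # scalar feature and hidden per node, all weights set by hand
  feat <- matrix(c(1, -1), 2, 1)
  hid <- matrix(c(0.5, 0), 2, 1)
  adj <- rbind(c(0, 1), c(1, 0))
  params <- list(Wu = matrix(c(0.3, 0.1), 2, 1),
                 Wr = matrix(c(-0.2, 0.4), 2, 1),
                 Wc = matrix(c(0.5, -0.3), 2, 1),
                 bu = matrix(0.1, 1, 1), br = matrix(0, 1, 1),
                 bc = matrix(-0.1, 1, 1))
  # hand evaluation: self-loop weight = mean positive entry = 1, so
  # B = [[1,1],[1,1]], degrees (2,2), A_hat = [[.5,.5],[.5,.5]]
  a <- 0.5
  z1 <- cbind(feat, hid)
  agg1 <- rbind(a * z1[1, ] + a * z1[2, ], a * z1[1, ] + a * z1[2, ])
  u <- plogis(agg1 %*% params$Wu + 0.1)
  r <- plogis(agg1 %*% params$Wr)
  z2 <- cbind(feat, r * hid)
  agg2 <- rbind(a * z2[1, ] + a * z2[2, ], a * z2[1, ] + a * z2[2, ])
  cc <- tanh(agg2 %*% params$Wc - 0.1)
  h_by_hand <- u * hid + (1 - u) * cc
  st <- tgcn_cell(feat, hid, adj, params)
  expect_equal(st$hidden, h_by_hand, tolerance = 1e-12)
})

test_that("encode_clip is deterministic and handles a length-1 clip", {
  model <- tiny_model()
  clip <- random_clip(n = 20, m = 5, seed = 2)
  h1 <- encode_clip(clip, model)$hidden
  h2 <- encode_clip(clip, model)$hidden
  expect_identical(h1, h2)
  expect_equal(dim(h1), c(5, 4))
  # a single-step matrix input runs one cell step from h_0 = 0
  x1 <- matrix(rnorm(5), 1, 5)
  h_one <- encode_clip(x1, model)$hidden
  expect_equal(dim(h_one), c(5, 4))
  expect_error(encode_clip(matrix(0, 4, 3), model), "channel count")
})

test_that("compiled and plain-R encoders agree on random clips", {
  for (seed in 1:3) {
    model <- tiny_model(seed = seed)
    clip <- random_clip(n = 15, m = 5, seed = seed)
    a <- encode_clip(clip, model, collect_adjacency = TRUE, compiled = TRUE)
    b <- encode_clip(clip, model, collect_adjacency = TRUE, compiled = FALSE)
    expect_equal(a$hidden, b$hidden, tolerance = 1e-12)
    expect_equal(a$mean_adjacency, b$mean_adjacency, tolerance = 1e-12)
    expect_equal(a$max_row_edges, b$max_row_edges)
  }
  # static-graph ablation path
  model_s <- tiny_model(static_dist_graph = TRUE)
  clip <- random_clip(n = 15, m = 5, seed = 5)
  expect_equal(encode_clip(clip, model_s, compiled = TRUE)$hidden,
               encode_clip(clip, model_s, compiled = FALSE)$hidden,
               tolerance = 1e-12)
})

test_that("encoding is equivariant under channel permutation", {
  m <- 5L
  model <- tiny_model(m)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  lay <- tiny_layout(m)
  lay_p <- electrode_layout(lay$names[perm], lay$coords[perm, ])
  model_p <- dtgcn_model(tiny_config(m), layout = lay_p)
  model_p$params <- model$params
  model_p$params$Wq <- model$params$Wq[perm, ]
  model_p$params$Wk <- model$params$Wk[perm, ]
  model_p$params$Wv <- model$params$Wv[perm, ]
  model_p$params$Wo <- model$params$Wo[, perm]
  clip <- random_clip(n = 12, m = m, seed = 6)
  h <- encode_clip(clip, model)$hidden
  h_p <- encode_clip(clip$signal[, perm], model_p)$hidden
  expect_equal(h_p, h[perm, ], tolerance = 1e-10)
})

test_that("classify produces simplex outputs on the right head", {
  model <- tiny_model(task = "multitask")
  h <- matrix(rnorm(20), 5, 4)
  out <- classify(model, h, "detection")
  expect_equal(sum(out$class_probabilities), 1)
  expect_named(out$class_probabilities, c("non-seizure", "seizure"))
  out4 <- classify(model, h, "classification")
  expect_length(out4$class_probabilities, 4)
  expect_equal(sum(out4$class_probabilities), 1)
  expect_equal(unname(which.max(out4$class_probabilities)),
               unname(which.max(out4$logits)))
  # zero weights give uniform probabilities
  model$params$Wdet[] <- 0; model$params$bdet[] <- 0
  expect_equal(unname(classify(model, h, "detection")$class_probabilities),
               c(0.5, 0.5))
  det_only <- tiny_model(task = "detection")
  expect_error(classify(det_only, h, "classification"), "head")
})

test_that("total_loss combines cross-entropy and the reconstruction term", {
  out <- list(class_probabilities = c(a = 1, b = 0), logits = c(9, 0))
  expect_equal(suppressWarnings(total_loss(out, 1, 0, 0.3))$total, 0)
  out2 <- list(class_probabilities = c(a = 0.5, b = 0.5))
  lt <- total_loss(out2, "a", l_re = 2, lambda = 0.3)
  expect_equal(lt$total, -log(0.5) + 0.6, tolerance = 1e-12)
  expect_equal(lt$cross_entropy, 0.6931, tolerance = 1e-4)
  expect_equal(total_loss(out2, 2, l_re = 5, lambda = 0)$total, -log(0.5))
  expect_warning(total_loss(list(class_probabilities = c(0, 1)), 1, 0, 0),
                 "clamped")
  expect_error(total_loss(out2, "zz", 0, 0), "valid class")
})
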