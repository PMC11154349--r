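#' Multi-head self-attention parameters
#'
#' Creates the learnable projections of the attention reconstructor: three
#' separate query/key/value projections of the raw signal
#' (`M -> d_model`) and an output projection back to the `M` channels.
#' Initialisation is Glorot-uniform, seeded by the caller's RNG state.
#'
#' @param m number of channels.
#' @param d_model model width; must be divisible by `n_heads`.
#' @param n_heads number of attention heads.
#' @return An object of class `attention_params`: list with `Wq`, `Wk`,
#'   `Wv` (`M x d_model`), `Wo` (`d_model x M`), `d_model`, `n_heads`.
#' @export
attention_params <- function(m, d_model = 64L, n_heads = 4L) {
  if (d_model %% n_heads != 0L)
    stop("d_model must be divisible by n_heads", call. = FALSE)
  structure(
    list(Wq = glorot(m, d_model), Wk = glorot(m, d_model),
         Wv = glorot(m, d_model), Wo = glorot(d_model, m),
         d_model = as.integer(d_model), n_heads = as.integer(n_heads)),
    class = "attention_params")
}

glorot <- function(fan_in, fan_out) {
  r <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -r, r), fan_in, fan_out)
}

row_softmax <- function(z) {
  mx <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - mx)
  e / rowSums(e)
}

#' Reconstruct a clip with multi-head self-attention
#'
#' Attention operates over time steps: queries/keys/values are per-step
#' channel vectors projected to `d_model` dimensions, scores are
#' `softmax(Q K' / sqrt(d_model))` per head, and the weighted values are
#' projected back to the channel space, giving the reconstruction `X'`.
#' For long clips the computation runs in non-overlapping blocks of
#' `block_size` time steps (block-diagonal attention) to bound the
#' `O(N^2)` score matrices; each score row is row-stochastic within its
#' block.
#'
#' @param x numeric `N x M` signal matrix.
#' @param params an [attention_params].
#' @param block_size maximum block length (default 1024).
#' @param keep_cache keep intermediates needed by [attention_backward()].
#' @param keep_scores assemble the `heads x N x N` score array (set to
#'   `FALSE` on hot paths that only need the reconstruction; the per-head
#'   score matrices are still retained in the cache when
#'   `keep_cache = TRUE`).
#' @return An `attention_state`: list with `reconstruction` (`N x M`),
#'   `scores` (array `heads x N x N` when a single block suffices,
#'   otherwise a list of per-block arrays), `step_errors` (length-N vector
#'   of per-step residual l2 norms).
#' @export
attention_reconstruct <- function(x, params, block_size = 1024L,
                                  keep_cache = FALSE, keep_scores = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 1L || m < 1L) stop("x must be a non-empty matrix", call. = FALSE)
  if (nrow(params$Wq) != m)
    stop("channel count does not match attention parameters", call. = FALSE)
  h <- params$n_heads; dm <- params$d_model; dk <- dm %/% h
  starts <- seq(1L, n, by = block_size)
  blocks <- vector("list", length(starts))
  xp <- matrix(0, n, m)
  for (b in seq_along(starts)) {
    idx <- starts[b]:min(starts[b] + block_size - 1L, n)
    xb <- x[idx, , drop = FALSE]
    q <- xb %*% params$Wq; k <- xb %*% params$Wk; v <- xb %*% params$Wv
    s_heads <- vector("list", h)
    o <- matrix(0, length(idx), dm)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1L) * dk + 1L):(hh * dk)
      sc <- (q[, cols, drop = FALSE] %*% t(k[, cols, drop = FALSE])) /
        sqrt(dm)
      s <- row_softmax(sc)
      s_heads[[hh]] <- s
      o[, cols] <- s %*% v[, cols, drop = FALSE]
    }
    xp[idx, ] <- o %*% params$Wo
    blocks[[b]] <- list(idx = idx, x = if (keep_cache) xb, q = if (keep_cache) q,
                        k = if (keep_cache) k, v = if (keep_cache) v,
                        s = s_heads, o = if (keep_cache) o)
  }
  scores <- if (!keep_scores) NULL else if (length(blocks) == 1L) {
    arr <- array(0, c(h, n, n))
    for (hh in seq_len(h)) arr[hh, , ] <- blocks[[1L]]$s[[hh]]
    arr
  } else {
    lapply(blocks, function(bl) {
      nb <- length(bl$idx)
      arr <- array(0, c(h, nb, nb))
      for (hh in seq_len(h)) arr[hh, , ] <- bl$s[[hh]]
      arr
    })
  }
  structure(
    list(reconstruction = xp, scores = scores,
         step_errors = reconstruction_errors(x, xp),
         cache = if (keep_cache) list(blocks = blocks, params = params)),
    class = "attention_state")
}

#' Backpropagate through the attention reconstruction
#'
#' Analytic gradients of a scalar loss with respect to the attention
#' projections, given the gradient with respect to the reconstruction.
#'
#' @param state an `attention_state` produced with `keep_cache = TRUE`.
#' @param d_xprime numeric `N x M` gradient of the loss w.r.t. `X'`.
#' @return List of gradients `Wq`, `Wk`, `Wv`, `Wo` matching
#'   [attention_params()] shapes.
#' @export
attention_backward <- function(state, d_xprime) {
  cache <- state$cache
  if (is.null(cache)) stop("state was built without keep_cache", call. = FALSE)
  params <- cache$params
  h <- params$n_heads; dm <- params$d_model; dk <- dm %/% h
  g <- list(Wq = params$Wq * 0, Wk = params$Wk * 0,
            Wv = params$Wv * 0, Wo = params$Wo * 0)
  for (bl in cache$blocks) {
    dxp <- d_xprime[bl$idx, , drop = FALSE]
    g$Wo <- g$Wo + t(bl$o) %*% dxp
    d_o <- dxp %*% t(params$Wo)
    dq <- matrix(0, length(bl$idx), dm); dk_ <- dq; dv <- dq
    for (hh in seq_len(h)) {
      cols <- ((hh - 1L) * dk + 1L):(hh * dk)
      s <- bl$s[[hh]]
      d_oh <- d_o[, cols, drop = FALSE]
      ds <- d_oh %*% t(bl$v[, cols, drop = FALSE])
      dv[, cols] <- t(s) %*% d_oh
      dsc <- s * (ds - rowSums(ds * s))      # softmax rows
      dq[, cols] <- (dsc %*% bl$k[, cols, drop = FALSE]) / sqrt(dm)
      dk_[, cols] <- (t(dsc) %*% bl$q[, cols, drop = FALSE]) / sqrt(dm)
    }
    g$Wq <- g$Wq + t(bl$x) %*% dq
    g$Wk <- g$Wk + t(bl$x) %*% dk_
    g$Wv <- g$Wv + t(bl$x) %*% dv
  }
  g
}

#' Per-time-step reconstruction errors
#'
#' Entry `t` is the Euclidean norm of the row residual
#' `||x_t - x'_t||_2`; high-error steps are treated as anomaly (seizure)
#' instances.
#'
#' @param x,xprime matrices of equal shape.
#' @return Non-negative vector of length `N`.
#' @export
reconstruction_errors <- function(x, xprime) {
  x <- as.matrix(x); xprime <- as.matrix(xprime)
  if (!all(dim(x) == dim(xprime)))
    stop("x and xprime must have identical shapes", call. = FALSE)
  sqrt(rowSums((x - xprime)^2))
}

#' Search the anomaly threshold over 50 uniform candidates
#'
#' Candidates are 50 equally spaced values spanning the minimum to the
#' maximum of the training reconstruction errors. The threshold is the
#' candidate maximising step-level F1 of `val_errors > tau` against the
#' validation fine-grained labels; ties go to the smallest candidate. If
#' the validation set contains no positive step the criterion falls back to
#' specificity (with a warning).
#'
#' @param train_errors numeric vector of training step errors.
#' @param val_errors numeric vector of validation step errors.
#' @param val_fine_labels binary vector aligned with `val_errors`.
#' @return A `threshold_result`: list with `tau`, `candidates` (50),
#'   `criterion_values` (50), `criterion` (`"f1"` or `"specificity"`).
#' @export
search_threshold <- function(train_errors, val_errors, val_fine_labels) {
  if (!length(train_errors) || !length(val_errors))
    stop("error vectors must be non-empty", call. = FALSE)
  if (length(val_errors) != length(val_fine_labels))
    stop("val_errors and val_fine_labels must align", call. = FALSE)
  candidates <- seq(min(train_errors), max(train_errors), length.out = 50L)
  pos <- val_fine_labels == 1
  criterion <- if (!any(pos)) {
    warning("validation set has no positive steps; falling back to specificity")
    "specificity"
  } else "f1"
  crit <- vapply(candidates, function(tau) {
    pred <- val_errors > tau
    if (criterion == "f1") {
      tp <- sum(pred & pos); fp <- sum(pred & !pos); fn <- sum(!pred & pos)
      if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    } else {
      tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
      if (tn + fp == 0) 0 else tn / (tn + fp)
    }
  }, numeric(1))
  structure(list(tau = candidates[which.max(crit)], candidates = candidates,
                 criterion_values = crit, criterion = criterion),
            class = "threshold_result")
}

#' True and predicted seizure step sets
#'
#' `true_steps` collects the time steps whose fine-grained label is 1;
#' `predicted_steps` collects the steps whose reconstruction error strictly
#' exceeds the threshold. Indices are 1-based (R convention).
#'
#' @param fine_labels binary vector of length `N`.
#' @param step_errors numeric vector of length `N`.
#' @param tau threshold.
#' @return A `seizure_step_sets`: list with integer vectors `true_steps`
#'   and `predicted_steps`.
#' @export
true_and_predicted_steps <- function(fine_labels, step_errors, tau) {
  if (length(fine_labels) != length(step_errors))
    stop("fine_labels and step_errors must align", call. = FALSE)
  structure(list(true_steps = which(fine_labels == 1),
                 predicted_steps = which(step_errors > tau)),
            class = "seizure_step_sets")
}

#' Fine-grained-label constrained reconstruction loss
#'
#' `L_re = ||X - X'||_F + |card(T1) - card(T2)| / N`: the Frobenius-norm
#' reconstruction loss plus a count-matching penalty that pushes the number
#' of predicted anomalous steps toward the number of truly seizing steps.
#'
#' @param x,xprime signal and reconstruction, equal shapes.
#' @param step_sets a `seizure_step_sets` (see
#'   [true_and_predicted_steps()]).
#' @param n_steps the number of time steps `N` in the clip.
#' @return Non-negative scalar.
#' @export
constrained_reconstruction_loss <- function(x, xprime, step_sets, n_steps) {
  stopifnot(n_steps > 0)
  x <- as.matrix(x); xprime <- as.matrix(xprime)
  if (!all(dim(x) == dim(xprime)))
    stop("x and xprime must have identical shapes", call. = FALSE)
  sqrt(sum((x - xprime)^2)) +
    abs(length(step_sets$true_steps) - length(step_sets$predicted_steps)) /
      n_steps
}

#' Differentiable surrogate for the predicted-anomaly count
#'
#' `sum_t logistic((e_t - tau) / temperature)`: a smooth stand-in for
#' `card(T2)` used during gradient training (the hard cardinality is
#' piecewise constant with zero gradient). Converges to the hard count as
#' `temperature -> 0` whenever no error sits exactly at `tau`, and is
#' monotone nondecreasing in every error.
#'
#' @param step_errors numeric vector.
#' @param tau threshold.
#' @param temperature positive softness parameter (training default 0.1).
#' @return Scalar in `[0, N]`.
#' @export
soft_anomaly_count <- function(step_errors, tau, temperature) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive", call. = FALSE)
  sum(stats::plogis((step_errors - tau) / temperature))
}

# Soft constrained reconstruction loss and its gradient wrt X'.
# Used by the training loop; tau is treated as a constant during a gradient
# step (it is re-searched at each validation pass).
recon_loss_soft <- function(x, xprime, fine_labels, tau, temperature) {
  d <- x - xprime
  fro <- sqrt(sum(d^2))
  g <- if (fro > 0) -d / fro else d * 0
  value <- fro
  if (is.finite(tau)) {
    e <- sqrt(rowSums(d^2))
    n <- nrow(x)
    z <- (e - tau) / temperature
    sc <- sum(stats::plogis(z))
    c1 <- sum(fine_labels)
    value <- value + abs(c1 - sc) / n
    dsc <- -sign(c1 - sc) / n
    de <- dsc * stats::dlogis(z) / temperature     # d value / d e_t
    nz <- e > 0
    if (any(nz))
      g[nz, ] <- g[nz, ] + (-de[nz] / e[nz]) * d[nz, , drop = FALSE]
  }
  list(value = value, d_xprime = g)
}
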