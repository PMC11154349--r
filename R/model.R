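#' Model configuration
#'
#' Collects every architecture hyper-parameter of the dynamic temporal
#' graph convolutional network. Defaults follow the reference protocol:
#' window `K = 10`, adjacency averaging horizon `n = 4`, saturation
#' `alpha = 3`, `k_edges = 5` retained edges per node, reconstruction-loss
#' weight `lambda = 0.3`, 4 attention heads of total width `d_model = 64`.
#'
#' @param n_channels number of electrodes `M` (default 19).
#' @param d_model attention width (divisible by `n_heads`).
#' @param n_heads attention heads.
#' @param window_K window length `K` for the dynamic node features.
#' @param avg_n number of consecutive instantaneous adjacencies averaged
#'   into `M_t`.
#' @param alpha saturation rate of the tanh activations in graph learning.
#' @param k_edges retained edges per node after sparsification.
#' @param diffusion_dim output width `F'` of the predefined-graph
#'   diffusion.
#' @param hidden_dim per-node hidden size `d_h` of the recurrent unit.
#' @param task `"detection"` (2 classes), `"classification"` (4 seizure
#'   classes) or `"multitask"` (both heads on a shared encoder).
#' @param lambda weight of the constrained reconstruction loss.
#' @param temperature softness of the differentiable anomaly count used
#'   during training.
#' @param attention_block block length for block-diagonal attention on long
#'   clips.
#' @param normalize_input z-score each clip per channel before the model
#'   sees it (default `TRUE`). Raw microvolt amplitudes saturate the tanh
#'   and sigmoid nonlinearities; the model is amplitude-scale-free by
#'   design, and relative (within-clip) amplitude changes survive the
#'   normalisation.
#' @param no_seizure_attention ablation: bypass the attention module
#'   (`X' = X`, `L_re = 0`).
#' @param static_dist_graph ablation: feed the static distance graph to the
#'   recurrent unit instead of the learned dynamic adjacency.
#' @param seed integer seed used when initialising parameters.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_channels = 19L, d_model = 64L, n_heads = 4L,
                         window_K = 10L, avg_n = 4L, alpha = 3,
                         k_edges = 5L, diffusion_dim = 16L,
                         hidden_dim = 32L,
                         task = c("detection", "classification", "multitask"),
                         lambda = 0.3, temperature = 0.1,
                         attention_block = 1024L,
                         normalize_input = TRUE,
                         no_seizure_attention = FALSE,
                         static_dist_graph = FALSE,
                         seed = 1L) {
  task <- match.arg(task)
  stopifnot(n_channels >= 2L, d_model %% n_heads == 0L, window_K >= 1L,
            avg_n >= 1L, alpha > 0, k_edges >= 1L, hidden_dim >= 1L,
            lambda >= 0, temperature > 0)
  if (k_edges > n_channels - 1L)
    stop("k_edges must be <= n_channels - 1", call. = FALSE)
  structure(
    list(n_channels = as.integer(n_channels), d_model = as.integer(d_model),
         n_heads = as.integer(n_heads), window_K = as.integer(window_K),
         avg_n = as.integer(avg_n), alpha = alpha,
         k_edges = as.integer(k_edges),
         diffusion_dim = as.integer(diffusion_dim),
         hidden_dim = as.integer(hidden_dim), task = task,
         lambda = lambda, temperature = temperature,
         attention_block = as.integer(attention_block),
         normalize_input = isTRUE(normalize_input),
         no_seizure_attention = isTRUE(no_seizure_attention),
         static_dist_graph = isTRUE(static_dist_graph),
         seed = as.integer(seed)),
    class = "model_config")
}

n_head_classes <- function(head) if (head == "detection") 2L else 4L

#' Construct an untrained model
#'
#' Allocates all learnable parameters and precomputes the static distance
#' graph from the electrode layout. Initialisation (seeded by
#' `config$seed`) is Glorot-uniform with two standard refinements that
#' make desk-scale training converge within a few epochs: the attention
#' projections start at an identity channel embedding plus small noise
#' (when `d_model >= n_channels`), so the initial reconstruction is a
#' similarity-kernel smoothing of the input rather than noise, and the
#' update-gate bias starts at +2 so the recurrent unit initially retains
#' its state over long clips (the forget-gate-bias trick).
#'
#' @param config a [model_config].
#' @param layout an [electrode_layout] with `config$n_channels`
#'   electrodes; defaults to the 19-channel 10-20 montage.
#' @return An object of class `dtgcn_model`: list with `config`, `params`
#'   (named list of matrices), `layout`, `graph` (the Dist-Graph), and the
#'   anomaly threshold `tau` (`NA` until trained).
#' @export
dtgcn_model <- function(config, layout = standard_1020_layout()) {
  stopifnot(inherits(config, "model_config"))
  if (length(layout$names) != config$n_channels)
    stop("layout size does not match config$n_channels", call. = FALSE)
  set.seed(config$seed)
  m <- config$n_channels
  dh <- config$hidden_dim
  fin <- config$window_K + dh          # node feature width of I_t
  fgate <- fin + dh                    # [I_t, h] width entering the gates
  rowm <- function(v) matrix(v, nrow = 1L)
  id_embed <- function() {           # identity channel embedding + noise
    cbind(diag(m), matrix(0, m, config$d_model - m)) +
      0.02 * matrix(stats::rnorm(m * config$d_model), m, config$d_model)
  }
  attn_init <- if (config$d_model >= m) {
    list(Wq = id_embed(), Wk = id_embed(), Wv = id_embed(),
         Wo = t(id_embed()))
  } else {
    list(Wq = glorot(m, config$d_model), Wk = glorot(m, config$d_model),
         Wv = glorot(m, config$d_model), Wo = glorot(config$d_model, m))
  }
  params <- c(attn_init, list(
    theta1 = glorot(fin, config$diffusion_dim),
    theta2 = glorot(fin, config$diffusion_dim),
    Wu = glorot(fgate, dh), Wr = glorot(fgate, dh), Wc = glorot(fgate, dh),
    bu = rowm(rep(2, dh)), br = rowm(numeric(dh)), bc = rowm(numeric(dh))))
  if (config$task %in% c("detection", "multitask")) {
    params$Wdet <- glorot(m * dh, 2L)
    params$bdet <- rowm(numeric(2L))
  }
  if (config$task %in% c("classification", "multitask")) {
    params$Wcls <- glorot(m * dh, 4L)
    params$bcls <- rowm(numeric(4L))
  }
  graph <- build_dist_graph(layout)
  structure(
    list(config = config, params = params, layout = layout, graph = graph,
         apre = normalize_adjacency(graph$weights), tau = NA_real_),
    class = "dtgcn_model")
}

#' @export
print.dtgcn_model <- function(x, ...) {
  npar <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<dtgcn_model>  %d channels, task %s, %d parameters, tau %s\n",
              x$config$n_channels, x$config$task, npar,
              ifelse(is.na(x$tau), "unset", sprintf("%.4g", x$tau))))
  invisible(x)
}

# Per-clip per-channel z-scoring (sd floored to avoid division by zero).
scale_signal <- function(x) {
  mu <- colMeans(x)
  sd_ <- pmax(sqrt(colMeans(x^2) - mu^2), 1e-8)
  sweep(sweep(x, 2L, mu), 2L, sd_, `/`)
}

model_input <- function(x, cfg) if (cfg$normalize_input) scale_signal(x) else x

attention_view <- function(model) {
  structure(list(Wq = model$params$Wq, Wk = model$params$Wk,
                 Wv = model$params$Wv, Wo = model$params$Wo,
                 d_model = model$config$d_model,
                 n_heads = model$config$n_heads),
            class = "attention_params")
}

#' One step of the graph-convolutional gated recurrent unit
#'
#' A GRU whose linear maps are replaced by graph convolutions on the given
#' adjacency (normalised with self-loops as in [normalize_adjacency()]):
#' `u = sigmoid(GC([I, h]; Wu) + bu)`, `r` analogous,
#' `c = tanh(GC([I, r * h]; Wc) + bc)`, `h' = u * h + (1 - u) * c`.
#' Reference R implementation; the training path runs the same arithmetic
#' in C++.
#'
#' @param node_features `M x F` dynamic node features `I_t`.
#' @param hidden `M x d_h` previous hidden state.
#' @param adjacency `M x M` non-negative weight matrix (the sparsified
#'   dynamic adjacency, or the static distance graph under ablation).
#' @param params list with `Wu`, `Wr`, `Wc` (`(F + d_h) x d_h`) and row
#'   vectors `bu`, `br`, `bc`.
#' @return A `tgcn_state`: list with `hidden` and the gate activations
#'   `u`, `r`, `c`.
#' @export
tgcn_cell <- function(node_features, hidden, adjacency, params) {
  node_features <- as.matrix(node_features)
  hidden <- as.matrix(hidden)
  if (nrow(node_features) != nrow(hidden))
    stop("node_features and hidden disagree on node count", call. = FALSE)
  a_hat <- normalize_adjacency(adjacency)
  sweep1 <- function(z, b) sweep(z, 2L, as.vector(b), `+`)
  z1 <- cbind(node_features, hidden)
  u <- stats::plogis(sweep1(a_hat %*% z1 %*% params$Wu, params$bu))
  r <- stats::plogis(sweep1(a_hat %*% z1 %*% params$Wr, params$br))
  z2 <- cbind(node_features, r * hidden)
  cc <- tanh(sweep1(a_hat %*% z2 %*% params$Wc, params$bc))
  structure(list(hidden = u * hidden + (1 - u) * cc, u = u, r = r, c = cc),
            class = "tgcn_state")
}

#' Encode a clip into its final hidden state
#'
#' Runs the full pipeline: one global attention reconstruction of the clip,
#' then for every time step the window / feature-fusion / diffusion /
#' dynamic-adjacency / temporal-average / sparsification chain feeding the
#' graph-convolutional recurrent cell. Returns the hidden state after the
#' last time step (the representation sent to the classification heads).
#'
#' @param clip an [eeg_clip] (or bare `N x M` matrix).
#' @param model a [dtgcn_model].
#' @param collect_adjacency also return the time-averaged sparsified
#'   adjacency (used by connectivity analysis) and the maximum per-row edge
#'   count observed.
#' @param compiled use the C++ encoder (default); `FALSE` runs the plain-R
#'   reference loop built from the exported module operations.
#' @return List with `hidden` (`M x d_h`), `xprime`, `step_errors`, and,
#'   when requested, `mean_adjacency` and `max_row_edges`.
#' @export
encode_clip <- function(clip, model, collect_adjacency = FALSE,
                        compiled = TRUE) {
  x <- if (inherits(clip, "eeg_clip")) clip$signal else as.matrix(clip)
  cfg <- model$config
  if (ncol(x) != cfg$n_channels)
    stop("clip channel count does not match the model", call. = FALSE)
  x <- model_input(x, cfg)
  if (cfg$no_seizure_attention) {
    xp <- x
    errs <- numeric(nrow(x))
  } else {
    st <- attention_reconstruct(x, attention_view(model),
                                block_size = cfg$attention_block,
                                keep_scores = FALSE)
    xp <- st$reconstruction
    errs <- st$step_errors
  }
  enc <- if (compiled) {
    dtgcn_encode_cpp(xp, model$params, model$apre, cfg$window_K, cfg$avg_n,
                     cfg$alpha, cfg$k_edges, cfg$hidden_dim,
                     cfg$static_dist_graph, collect_adjacency)
  } else {
    encode_loop_r(xp, model, collect_adjacency)
  }
  out <- list(hidden = enc$hidden, xprime = xp, step_errors = errs)
  if (collect_adjacency) {
    if (cfg$static_dist_graph && compiled) {
      out$mean_adjacency <- model$graph$weights
      out$max_row_edges <- max(rowSums(model$graph$weights != 0))
    } else {
      out$mean_adjacency <- enc$mean_adjacency
      out$max_row_edges <- enc$max_row_edges
    }
    dimnames(out$mean_adjacency) <- list(model$layout$names,
                                         model$layout$names)
  }
  out
}

# Plain-R encoder built from the exported module operations; the compiled
# path is tested against this loop.
encode_loop_r <- function(xp, model, collect_adjacency = FALSE) {
  cfg <- model$config
  p <- model$params
  m <- cfg$n_channels
  h <- matrix(0, m, cfg$hidden_dim)
  buffer <- list()
  adj_sum <- matrix(0, m, m)
  max_nnz <- 0L
  gate_params <- list(Wu = p$Wu, Wr = p$Wr, Wc = p$Wc,
                      bu = p$bu, br = p$br, bc = p$bc)
  for (t in seq_len(nrow(xp))) {
    it <- fuse_hidden(make_window(xp, t, cfg$window_K), h)
    if (cfg$static_dist_graph) {
      adj <- model$graph$weights
    } else {
      df <- predefined_diffusion(it, model$graph,
                                 list(theta1 = p$theta1, theta2 = p$theta2))
      de <- dynamic_embeddings(df$df1, df$df2, cfg$alpha)
      et <- dynamic_adjacency(de$de1, de$de2, cfg$alpha)
      buffer <- c(buffer, list(et))
      if (length(buffer) > cfg$avg_n) buffer <- buffer[-1L]
      adj <- sparsify_topk(temporal_average(buffer, cfg$avg_n), cfg$k_edges)
    }
    if (collect_adjacency) {
      adj_sum <- adj_sum + adj
      max_nnz <- max(max_nnz, max(rowSums(adj != 0)))
    }
    h <- tgcn_cell(it, h, adj, gate_params)$hidden
  }
  list(hidden = unname(h), mean_adjacency = unname(adj_sum) / nrow(xp),
       max_row_edges = as.integer(max_nnz))
}

#' Classify a final hidden state
#'
#' Flattens `h_N`, applies the affine head and a softmax. The detection
#' head has 2 classes (non-seizure / seizure); the classification head has
#' the 4 seizure classes CF, GN, AB, CT.
#'
#' @param model a [dtgcn_model] whose task includes the requested head.
#' @param hidden `M x d_h` final hidden state.
#' @param head `"detection"` or `"classification"`.
#' @return A `model_output`: list with `class_probabilities` (simplex
#'   vector) and `logits`.
#' @export
classify <- function(model, hidden, head = c("detection", "classification")) {
  head <- match.arg(head)
  w <- switch(head, detection = model$params$Wdet,
              classification = model$params$Wcls)
  b <- switch(head, detection = model$params$bdet,
              classification = model$params$bcls)
  if (is.null(w))
    stop(sprintf("model (task '%s') has no %s head", model$config$task, head),
         call. = FALSE)
  logits <- as.vector(matrix(as.vector(hidden), nrow = 1L) %*% w + b)
  z <- logits - max(logits)
  p <- exp(z) / sum(exp(z))
  names(p) <- names(logits) <- if (head == "detection")
    c("non-seizure", "seizure") else c("CF", "GN", "AB", "CT")
  structure(list(class_probabilities = p, logits = logits),
            class = "model_output")
}

#' Combined training objective for one clip
#'
#' `L = -log p(e) + lambda * L_re`: cross-entropy of the true class under
#' the head's probabilities plus the weighted constrained reconstruction
#' loss. A zero probability on the true class is clamped at 1e-12 with a
#' warning.
#'
#' @param output a `model_output` (see [classify()]).
#' @param true_label class index (1-based) or class name.
#' @param l_re non-negative constrained reconstruction loss.
#' @param lambda non-negative weight.
#' @return A `loss_terms`: list with `cross_entropy`, `l_re`, `lambda`,
#'   `total`.
#' @export
total_loss <- function(output, true_label, l_re, lambda) {
  stopifnot(l_re >= 0, lambda >= 0)
  p <- output$class_probabilities
  idx <- if (is.character(true_label)) match(true_label, names(p))
  else as.integer(true_label)
  if (is.na(idx) || idx < 1L || idx > length(p))
    stop("true_label is not a valid class", call. = FALSE)
  pe <- p[[idx]]
  if (pe < 1e-12) {
    warning("probability of the true class underflowed; clamped at 1e-12")
    pe <- 1e-12
  }
  ce <- -log(pe)
  structure(list(cross_entropy = ce, l_re = l_re, lambda = lambda,
                 total = ce + lambda * l_re),
            class = "loss_terms")
}
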