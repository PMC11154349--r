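#' Extract the length-K window ending at time t
#'
#' Rows are the reconstructed signal at steps `t - K + 1, ..., t` (1-based);
#' steps before the start of the clip are zero-filled (left padding), so the
#' window always has exactly `K` rows.
#'
#' @param xprime `N x M` reconstructed signal.
#' @param t time step in `1..N`.
#' @param k window length `K >= 1`.
#' @return `K x M` matrix.
#' @export
make_window <- function(xprime, t, k) {
  xprime <- as.matrix(xprime)
  if (k < 1L) stop("window length K must be >= 1", call. = FALSE)
  if (t < 1L || t > nrow(xprime)) stop("t out of range", call. = FALSE)
  out <- matrix(0, k, ncol(xprime))
  lo <- max(1L, t - k + 1L)
  out[(k - (t - lo)):k, ] <- xprime[lo:t, , drop = FALSE]
  out
}

#' Fuse a signal window with the recurrent hidden state
#'
#' Builds the dynamic node features `I_t`: node (channel) `m` gets the
#' concatenation of its length-K window column with its hidden-state row,
#' giving an `M x (K + d_h)` matrix.
#'
#' @param window `K x M` window (see [make_window()]).
#' @param hidden `M x d_h` hidden state (d_h may be 0).
#' @return `M x (K + d_h)` node-feature matrix.
#' @export
fuse_hidden <- function(window, hidden) {
  window <- as.matrix(window)
  hidden <- as.matrix(hidden)
  if (ncol(window) != nrow(hidden) && length(hidden) > 0L)
    stop("hidden must have one row per channel", call. = FALSE)
  if (length(hidden) == 0L) return(t(window))
  cbind(t(window), hidden)
}

#' Symmetrically normalised adjacency with scale-covariant self-loops
#'
#' Returns `D^-1/2 B D^-1/2` with `B = W + s I`, where the self-loop weight
#' `s` is 0 when `W` already has a nonzero diagonal and otherwise the mean
#' of the positive entries of `W` (so that rescaling all edge weights leaves
#' the operator unchanged, and isolated nodes retain their own features).
#' An all-zero `W` yields the identity.
#'
#' @param w non-negative `M x M` weight matrix.
#' @return `M x M` normalised operator.
#' @export
normalize_adjacency <- function(w) {
  w <- as.matrix(w)
  if (any(w < 0)) stop("adjacency weights must be non-negative", call. = FALSE)
  if (all(w == 0)) return(diag(nrow(w)))
  b <- w
  if (all(diag(w) == 0)) {
    s <- mean(w[w > 0])
    diag(b) <- s
  }
  d <- rowSums(b)
  d[d == 0] <- 1
  dm <- 1 / sqrt(d)
  b * outer(dm, dm)
}

#' Message passing on the predefined distance graph
#'
#' Two parallel graph-convolution branches over the static Dist-Graph:
#' each computes `A_hat %*% I_t %*% Theta` with independent learnable
#' `Theta` for the source and destination embeddings
#' (`A_hat` as in [normalize_adjacency()]).
#'
#' @param node_features `M x F` dynamic node features `I_t`.
#' @param graph a `dist_graph` (or bare `M x M` weight matrix).
#' @param weights list with `theta1`, `theta2`, each `F x F'`.
#' @return List with `df1`, `df2` (`M x F'` diffusion features).
#' @export
predefined_diffusion <- function(node_features, graph, weights) {
  w <- if (inherits(graph, "dist_graph")) graph$weights else as.matrix(graph)
  node_features <- as.matrix(node_features)
  if (nrow(node_features) != nrow(w))
    stop("graph and node features disagree on the number of nodes",
         call. = FALSE)
  if (nrow(weights$theta1) != ncol(node_features))
    stop("theta dimensions do not match node features", call. = FALSE)
  a_hat <- normalize_adjacency(w)
  ax <- a_hat %*% node_features
  list(df1 = ax %*% weights$theta1, df2 = ax %*% weights$theta2)
}

#' Saturated dynamic node embeddings
#'
#' `DE = tanh(alpha * DF)` elementwise; `alpha` controls the saturation
#' rate (larger `alpha` saturates faster, sharpening the subsequent
#' adjacency and promoting sparsity after ReLU).
#'
#' @param df1,df2 diffusion features (`M x F'`).
#' @param alpha positive saturation hyper-parameter.
#' @return List with `de1`, `de2`, entries in `(-1, 1)`.
#' @export
dynamic_embeddings <- function(df1, df2, alpha) {
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  list(de1 = tanh(alpha * as.matrix(df1)), de2 = tanh(alpha * as.matrix(df2)))
}

#' Instantaneous dynamic adjacency
#'
#' `E_t = ReLU(tanh(alpha * (DE1 DE2' - DE2 DE1')))`. The argument is
#' antisymmetric, so `E_t` has zero diagonal and no reciprocal positive
#' edges: `E_t[i, j] > 0` implies `E_t[j, i] = 0` (a directed graph).
#'
#' @param de1,de2 source / destination embeddings (`M x F'`).
#' @param alpha positive saturation hyper-parameter.
#' @return Non-negative `M x M` matrix.
#' @export
dynamic_adjacency <- function(de1, de2, alpha) {
  de1 <- as.matrix(de1); de2 <- as.matrix(de2)
  if (!all(dim(de1) == dim(de2)))
    stop("de1 and de2 must have identical shapes", call. = FALSE)
  a <- de1 %*% t(de2) - de2 %*% t(de1)
  pmax(tanh(alpha * a), 0)
}

#' Average the last n instantaneous adjacencies
#'
#' Smooths the graph over time: the brain network should not change faster
#' than the signal warrants, so `M_t` is the entrywise mean of the most
#' recent `n` matrices `E_{t-n+1}, ..., E_t` (fewer at the start of a
#' sequence, before `n` matrices exist).
#'
#' @param buffer list of `M x M` matrices, oldest first, length
#'   `<= n` (the caller maintains the rolling buffer).
#' @param n averaging horizon (used only to validate the buffer length).
#' @return `M x M` matrix.
#' @export
temporal_average <- function(buffer, n) {
  if (!length(buffer)) stop("buffer must be non-empty", call. = FALSE)
  if (length(buffer) > n) stop("buffer longer than n", call. = FALSE)
  Reduce(`+`, buffer) / length(buffer)
}

#' Keep the k largest entries of every row
#'
#' Sparsifies an adjacency so each node keeps at most `k_edges` outgoing
#' edges (default 5). Ties are broken toward the lower column index; rows
#' that already have `k` or fewer nonzero entries are unchanged.
#'
#' @param m `M x M` non-negative matrix.
#' @param k_edges number of entries to keep per row.
#' @return Matrix of the same shape with `<= k_edges` nonzeros per row.
#' @export
sparsify_topk <- function(m, k_edges = 5L) {
  m <- as.matrix(m)
  if (k_edges < 1L) stop("k_edges must be >= 1", call. = FALSE)
  if (k_edges >= ncol(m)) return(m)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    keep <- order(m[i, ], decreasing = TRUE)[seq_len(k_edges)]
    out[i, keep] <- m[i, keep]
  }
  dimnames(out) <- dimnames(m)
  out
}

#' Export an adjacency snapshot as an edge list
#'
#' @param adj `M x M` weighted adjacency.
#' @param names optional node names.
#' @return `data.frame` with columns `source`, `target`, `weight`
#'   (nonzero entries only).
#' @export
adjacency_edge_list <- function(adj, names = NULL) {
  adj <- as.matrix(adj)
  idx <- which(adj != 0, arr.ind = TRUE)
  nm <- if (is.null(names)) as.character(seq_len(nrow(adj))) else names
  data.frame(source = nm[idx[, 1L]], target = nm[idx[, 2L]],
             weight = adj[idx], stringsAsFactors = FALSE)
}
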