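# Independent loop-based reference implementations ("oracles").
# Deliberately written with explicit scalar loops and no batched linear
# algebra, so they share no code path with the package implementation.

oracle_softmax_row <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

oracle_attention <- function(x, params) {
  n <- nrow(x); m <- ncol(x)
  h <- params$n_heads; dm <- params$d_model; dk <- dm / h
  q <- matrix(0, n, dm); k <- matrix(0, n, dm); v <- matrix(0, n, dm)
  for (i in seq_len(n)) for (j in seq_len(dm)) {
    for (c in seq_len(m)) {
      q[i, j] <- q[i, j] + x[i, c] * params$Wq[c, j]
      k[i, j] <- k[i, j] + x[i, c] * params$Wk[c, j]
      v[i, j] <- v[i, j] + x[i, c] * params$Wv[c, j]
    }
  }
  o <- matrix(0, n, dm)
  scores <- array(0, c(h, n, n))
  for (hh in seq_len(h)) {
    cols <- ((hh - 1) * dk + 1):(hh * dk)
    for (i in seq_len(n)) {
      logits <- numeric(n)
      for (j in seq_len(n))
        logits[j] <- sum(q[i, cols] * k[j, cols]) / sqrt(dm)
      s <- oracle_softmax_row(logits)
      scores[hh, i, ] <- s
      for (cc in cols) o[i, cc] <- sum(s * v[, cc])
    }
  }
  xp <- matrix(0, n, m)
  for (i in seq_len(n)) for (c in seq_len(m))
    xp[i, c] <- sum(o[i, ] * params$Wo[, c])
  list(reconstruction = xp, scores = scores)
}

# normalisation rule, spelled out per entry
oracle_normalize <- function(w) {
  m <- nrow(w)
  if (all(w == 0)) return(diag(m))
  b <- w
  if (all(diag(w) == 0)) {
    pos <- w[w > 0]
    for (i in seq_len(m)) b[i, i] <- sum(pos) / length(pos)
  }
  d <- numeric(m)
  for (i in seq_len(m)) d[i] <- sum(b[i, ])
  d[d == 0] <- 1
  out <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    out[i, j] <- b[i, j] / sqrt(d[i] * d[j])
  out
}

oracle_diffusion <- function(feat, w, theta1, theta2) {
  a <- oracle_normalize(w)
  m <- nrow(feat); fdim <- ncol(feat)
  agg <- matrix(0, m, fdim)
  for (i in seq_len(m)) for (f in seq_len(fdim))
    for (j in seq_len(m)) agg[i, f] <- agg[i, f] + a[i, j] * feat[j, f]
  mult <- function(th) {
    out <- matrix(0, m, ncol(th))
    for (i in seq_len(m)) for (k in seq_len(ncol(th)))
      out[i, k] <- sum(agg[i, ] * th[, k])
    out
  }
  list(df1 = mult(theta1), df2 = mult(theta2))
}

oracle_dynamic_adjacency <- function(de1, de2, alpha) {
  m <- nrow(de1)
  e <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    a <- sum(de1[i, ] * de2[j, ]) - sum(de2[i, ] * de1[j, ])
    e[i, j] <- max(tanh(alpha * a), 0)
  }
  e
}

oracle_temporal_average <- function(buffer) {
  out <- buffer[[1]] * 0
  for (b in buffer) out <- out + b
  out / length(buffer)
}

oracle_topk <- function(m, k) {
  out <- m * 0
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    kept <- integer(0)
    for (pick in seq_len(min(k, length(row)))) {
      best <- NA
      for (j in seq_along(row)) {
        if (j %in% kept) next
        if (is.na(best) || row[j] > row[best]) best <- j
      }
      kept <- c(kept, best)
    }
    out[i, kept] <- row[kept]
  }
  out
}

oracle_tgcn_cell <- function(feat, hidden, adjacency, params) {
  a <- oracle_normalize(adjacency)
  m <- nrow(feat); dh <- ncol(hidden)
  gc <- function(z, w, b) {
    agg <- matrix(0, m, ncol(z))
    for (i in seq_len(m)) for (f in seq_len(ncol(z)))
      for (j in seq_len(m)) agg[i, f] <- agg[i, f] + a[i, j] * z[j, f]
    out <- matrix(0, m, dh)
    for (i in seq_len(m)) for (k in seq_len(dh))
      out[i, k] <- sum(agg[i, ] * w[, k]) + b[1, k]
    out
  }
  z1 <- cbind(feat, hidden)
  u <- 1 / (1 + exp(-gc(z1, params$Wu, params$bu)))
  r <- 1 / (1 + exp(-gc(z1, params$Wr, params$br)))
  z2 <- cbind(feat, r * hidden)
  cc <- tanh(gc(z2, params$Wc, params$bc))
  list(hidden = u * hidden + (1 - u) * cc, u = u, r = r, c = cc)
}

# Straight-line reference for the whole dynamic pipeline (windows ->
# fusion -> diffusion -> embeddings -> E_t -> M_t -> top-k -> GRU cell).
oracle_pipeline <- function(xp, params, cfg, dist_weights) {
  n <- nrow(xp); m <- ncol(xp)
  h <- matrix(0, m, cfg$hidden_dim)
  buffer <- list()
  for (t in seq_len(n)) {
    win <- matrix(0, cfg$window_K, m)
    for (j in seq_len(cfg$window_K)) {
      tm <- t - cfg$window_K + j
      if (tm >= 1) win[j, ] <- xp[tm, ]
    }
    feat <- cbind(t(win), h)
    df <- oracle_diffusion(feat, dist_weights, params$theta1, params$theta2)
    de1 <- tanh(cfg$alpha * df$df1)
    de2 <- tanh(cfg$alpha * df$df2)
    et <- oracle_dynamic_adjacency(de1, de2, cfg$alpha)
    buffer <- c(buffer, list(et))
    if (length(buffer) > cfg$avg_n) buffer <- buffer[-1]
    adj <- oracle_topk(oracle_temporal_average(buffer), cfg$k_edges)
    h <- oracle_tgcn_cell(feat, h, adj, params)$hidden
  }
  h
}

# O(n^2) pairwise-concordance AUROC with half credit for ties
oracle_auroc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  s <- 0
  for (i in pos) for (j in neg)
    s <- s + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  s / (length(pos) * length(neg))
}

oracle_weighted_f1 <- function(pred, true) {
  total <- 0; wsum <- 0
  for (k in unique(true)) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(true)) {
      if (pred[i] == k && true[i] == k) tp <- tp + 1
      if (pred[i] == k && true[i] != k) fp <- fp + 1
      if (pred[i] != k && true[i] == k) fn <- fn + 1
    }
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    w <- sum(true == k)
    total <- total + w * f1
    wsum <- wsum + w
  }
  total / wsum
}

oracle_confusion <- function(pred, true, classes) {
  cm <- matrix(0, length(classes), length(classes))
  for (i in seq_along(classes)) {
    ni <- sum(true == classes[i])
    if (ni == 0) next
    for (j in seq_along(classes))
      cm[i, j] <- sum(true == classes[i] & pred == classes[j]) / ni
  }
  cm
}
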