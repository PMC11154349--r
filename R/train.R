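#' Training configuration
#'
#' Optimisation protocol: adaptive-moment (Adam) optimiser, learning rate
#' 5e-5, at most 100 epochs, early stopping when the validation loss fails
#' to improve for 5 consecutive epochs. Desk-scale runs typically raise the
#' learning rate (see the package vignette).
#'
#' @param learning_rate Adam step size.
#' @param max_epochs maximum number of epochs.
#' @param patience consecutive non-improving validation epochs tolerated
#'   before stopping.
#' @param batch_size clips per gradient step.
#' @param seed RNG seed for shuffling and initial threshold search.
#' @param no_seizure_attention,static_dist_graph ablation switches copied
#'   onto the model configuration before training.
#' @param tau_train_clips number of training clips sampled per epoch to
#'   build the threshold-candidate range.
#' @param verbose print one line per epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-5, max_epochs = 100L,
                         patience = 5L, batch_size = 16L, seed = 1L,
                         no_seizure_attention = FALSE,
                         static_dist_graph = FALSE,
                         tau_train_clips = 20L, verbose = FALSE) {
  stopifnot(learning_rate > 0, max_epochs >= 1L, patience >= 1L,
            batch_size >= 1L)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 no_seizure_attention = isTRUE(no_seizure_attention),
                 static_dist_graph = isTRUE(static_dist_graph),
                 tau_train_clips = as.integer(tau_train_clips),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Early-stopping rule
#'
#' Stop after the epoch at which the validation loss has failed to improve
#' on the running best for `patience` consecutive epochs. Exposed as a pure
#' function so the rule itself is testable.
#'
#' @param val_losses numeric vector of per-epoch validation losses so far.
#' @param patience consecutive tolerated non-improvements.
#' @return `TRUE` if training should stop after the last recorded epoch.
#' @export
should_stop_early <- function(val_losses, patience) {
  if (length(val_losses) <= patience) return(FALSE)
  best_idx <- which.min(val_losses)
  (length(val_losses) - best_idx) >= patience
}

head_label <- function(clip, head) {
  if (head == "detection") clip$coarse_label + 1L
  else match(clip$seizure_class, c("CF", "GN", "AB", "CT"))
}

model_heads <- function(model) {
  switch(model$config$task,
         detection = "detection",
         classification = "classification",
         multitask = c("detection", "classification"))
}

head_param_names <- function(head)
  if (head == "detection") c("Wdet", "bdet") else c("Wcls", "bcls")

# Forward + full analytic backward for one clip. Returns the loss pieces
# and gradients named like model$params (only for parameters in use).
clip_grad <- function(clip, model) {
  cfg <- model$config
  x <- model_input(clip$signal, cfg)
  if (cfg$no_seizure_attention) {
    xp <- x
    att <- NULL
  } else {
    att <- attention_reconstruct(x, attention_view(model),
                                 block_size = cfg$attention_block,
                                 keep_cache = TRUE, keep_scores = FALSE)
    xp <- att$reconstruction
  }
  heads <- model_heads(model)
  labels <- vapply(heads, function(h) head_label(clip, h), 1L)
  use <- !is.na(labels)
  heads <- heads[use]; labels <- labels[use]
  if (!length(heads)) return(NULL)
  head_list <- lapply(seq_along(heads), function(i) {
    nm <- head_param_names(heads[i])
    list(W = model$params[[nm[1L]]], b = model$params[[nm[2L]]],
         y = labels[i])
  })
  res <- dtgcn_train_step_cpp(xp, model$params, model$apre, cfg$window_K,
                              cfg$avg_n, cfg$alpha, cfg$k_edges,
                              cfg$hidden_dim, cfg$static_dist_graph,
                              head_list)
  grads <- res$grads[c("theta1", "theta2", "Wu", "Wr", "Wc",
                       "bu", "br", "bc")]
  for (i in seq_along(heads)) {
    nm <- head_param_names(heads[i])
    grads[[nm[1L]]] <- res$grads$heads[[i]]$W
    grads[[nm[2L]]] <- res$grads$heads[[i]]$b
  }
  lre <- 0
  if (!cfg$no_seizure_attention) {
    rl <- recon_loss_soft(x, xp, clip$fine_labels, model$tau,
                          cfg$temperature)
    lre <- rl$value
    dxp <- res$dxprime + cfg$lambda * rl$d_xprime
    ag <- attention_backward(att, dxp)
    grads$Wq <- ag$Wq; grads$Wk <- ag$Wk; grads$Wv <- ag$Wv
    grads$Wo <- ag$Wo
  }
  list(loss = sum(res$ce) + cfg$lambda * lre, ce = sum(res$ce), lre = lre,
       grads = grads,
       step_errors = if (is.null(att)) NULL else att$step_errors)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

clips_for_task <- function(clips, task) {
  if (task == "classification")
    clips <- Filter(function(cl) cl$coarse_label == 1L, clips)
  clips
}

#' Train a model
#'
#' Mini-batch Adam on the combined objective (cross-entropy plus
#' `lambda` times the soft constrained reconstruction loss), early stopping
#' on the validation loss, best-validation checkpointing, and a re-search
#' of the anomaly threshold `tau` at every validation pass. Fully seeded:
#' the same seed and data reproduce the run exactly.
#'
#' @param model an untrained (or warm) [dtgcn_model].
#' @param data list with clip lists `train` and `val` (see
#'   [generate_dataset()]).
#' @param cfg a [train_config].
#' @return The trained model; `$history` holds one row per epoch
#'   (train/val loss, tau, seconds) and `$best_epoch` the checkpointed
#'   epoch.
#' @export
train_dtgcn <- function(model, data, cfg = train_config()) {
  stopifnot(inherits(model, "dtgcn_model"), inherits(cfg, "train_config"))
  model$config$no_seizure_attention <-
    model$config$no_seizure_attention || cfg$no_seizure_attention
  model$config$static_dist_graph <-
    model$config$static_dist_graph || cfg$static_dist_graph
  task <- model$config$task
  train_clips <- clips_for_task(data$train, task)
  val_clips <- clips_for_task(data$val, task)
  if (!length(train_clips) || !length(val_clips))
    stop("train and validation sets must be non-empty for the task",
         call. = FALSE)
  set.seed(cfg$seed)
  state <- list(m = lapply(model$params, function(p) p * 0),
                v = lapply(model$params, function(p) p * 0), t = 0L)
  history <- list()
  best <- list(loss = Inf, params = model$params, tau = model$tau,
               epoch = 0L)
  val_losses <- numeric(0)
  for (epoch in seq_len(cfg$max_epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- sample(length(train_clips))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    epoch_loss <- 0
    n_used <- 0L
    train_errs <- list()
    for (b in batches) {
      acc <- NULL
      for (i in b) {
        cg <- clip_grad(train_clips[[i]], model)
        if (is.null(cg)) next
        if (!is.finite(cg$loss))
          stop(sprintf("training diverged (non-finite loss at epoch %d)",
                       epoch), call. = FALSE)
        epoch_loss <- epoch_loss + cg$loss
        n_used <- n_used + 1L
        if (!is.null(cg$step_errors) &&
            length(train_errs) < cfg$tau_train_clips)
          train_errs[[length(train_errs) + 1L]] <- cg$step_errors
        if (is.null(acc)) {
          acc <- cg$grads
        } else {
          for (nm in names(cg$grads))
            acc[[nm]] <- if (is.null(acc[[nm]])) cg$grads[[nm]]
            else acc[[nm]] + cg$grads[[nm]]
        }
      }
      if (is.null(acc)) next
      acc <- lapply(acc, `/`, length(b))
      upd <- adam_update(model$params, acc, state, cfg$learning_rate)
      model$params <- upd$params
      state <- upd$state
    }
    # validation pass: forward, re-search tau, objective
    val <- validate_pass(model, val_clips, unlist(train_errs))
    model$tau <- val$tau
    val_losses <- c(val_losses, val$loss)
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = epoch_loss / max(n_used, 1L),
      val_loss = val$loss, tau = model$tau,
      seconds = proc.time()[["elapsed"]] - t0)
    if (cfg$verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  tau %.3g",
                      epoch, epoch_loss / max(n_used, 1L), val$loss,
                      model$tau))
    if (val$loss < best$loss) {
      best <- list(loss = val$loss, params = model$params, tau = model$tau,
                   epoch = epoch)
    }
    if (should_stop_early(val_losses, cfg$patience)) break
  }
  model$params <- best$params
  model$tau <- best$tau
  model$best_epoch <- best$epoch
  model$history <- do.call(rbind, history)
  model
}

validate_pass <- function(model, val_clips, train_errors) {
  cfg <- model$config
  total <- 0
  errs <- list(); fines <- list()
  for (cl in val_clips) {
    enc <- encode_clip(cl, model)
    ce <- 0
    for (h in model_heads(model)) {
      y <- head_label(cl, h)
      if (is.na(y)) next
      out <- classify(model, enc$hidden, h)
      ce <- ce + (-log(max(out$class_probabilities[[y]], 1e-12)))
    }
    total <- total + ce
    if (!cfg$no_seizure_attention) {
      errs[[length(errs) + 1L]] <- enc$step_errors
      fines[[length(fines) + 1L]] <- cl$fine_labels
    }
  }
  tau <- model$tau
  lre_total <- 0
  if (!cfg$no_seizure_attention && length(train_errors)) {
    thr <- search_threshold(train_errors, unlist(errs), unlist(fines))
    tau <- thr$tau
    for (i in seq_along(val_clips)) {
      cl <- val_clips[[i]]
      e <- errs[[i]]
      sc <- soft_anomaly_count(e, tau, cfg$temperature)
      # ||X - X'||_F = sqrt(sum_t e_t^2) since e_t is the row residual norm
      lre_total <- lre_total + sqrt(sum(e^2)) +
        abs(sum(cl$fine_labels) - sc) / length(e)
    }
  }
  n <- length(val_clips)
  list(loss = (total + cfg$lambda * lre_total) / n, tau = tau)
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, ties counted one half (rank / Mann-Whitney formulation).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary 0/1 vector.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must align", call. = FALSE)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Support-weighted F1 score
#'
#' Mean of per-class F1 scores weighted by the class support in the true
#' labels; a class never predicted gets F1 = 0.
#'
#' @param pred_classes,true_classes vectors of class labels (any atomic
#'   type).
#' @return Weighted F1 in `[0, 1]`.
#' @export
weighted_f1 <- function(pred_classes, true_classes) {
  if (!length(true_classes)) stop("empty input", call. = FALSE)
  classes <- unique(true_classes)
  f1 <- vapply(classes, function(k) {
    tp <- sum(pred_classes == k & true_classes == k)
    fp <- sum(pred_classes == k & true_classes != k)
    fn <- sum(pred_classes != k & true_classes == k)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  support <- vapply(classes, function(k) sum(true_classes == k), numeric(1))
  sum(f1 * support) / sum(support)
}

#' Row-normalised confusion matrix
#'
#' Entry `(i, j)` is the fraction of true-class-`i` examples predicted as
#' class `j`; rows of non-empty classes sum to 1.
#'
#' @param pred,true vectors of class labels.
#' @param classes class enumeration fixing the row/column order.
#' @return `length(classes) x length(classes)` matrix.
#' @export
confusion_normalized <- function(pred, true, classes) {
  cm <- matrix(0, length(classes), length(classes),
               dimnames = list(true = classes, predicted = classes))
  for (i in seq_along(classes)) {
    sel <- true == classes[i]
    if (!any(sel)) next
    for (j in seq_along(classes))
      cm[i, j] <- sum(pred[sel] == classes[j]) / sum(sel)
  }
  cm
}

#' Predict class probabilities for clips
#'
#' @param object a trained [dtgcn_model].
#' @param clips list of [eeg_clip] objects.
#' @param head which head to use (defaults to the model's task, detection
#'   for multitask).
#' @param ... unused.
#' @return Matrix of class probabilities, one row per clip.
#' @export
predict.dtgcn_model <- function(object, clips,
                                head = model_heads(object)[1L], ...) {
  probs <- t(vapply(clips, function(cl) {
    enc <- encode_clip(cl, object)
    classify(object, enc$hidden, head)$class_probabilities
  }, numeric(n_head_classes(head))))
  probs
}

#' Evaluate a trained model on a clip set
#'
#' @param model a trained [dtgcn_model].
#' @param clips list of [eeg_clip] objects (classification evaluation uses
#'   only the seizure clips).
#' @param head `"detection"` or `"classification"`.
#' @return An `eval_report`: list with `auroc` (detection only),
#'   `weighted_f1`, row-normalised `confusion`, `per_class`
#'   (precision/recall data frame), `threshold` (the model's tau) and the
#'   raw `scores`/`predicted`/`true` vectors.
#' @export
evaluate_model <- function(model, clips, head = model_heads(model)[1L]) {
  clips <- clips_for_task(clips, if (head == "classification")
    "classification" else "detection")
  if (!length(clips)) stop("no clips to evaluate", call. = FALSE)
  probs <- predict(model, clips, head = head)
  classes <- colnames(probs)
  pred <- classes[max.col(probs, ties.method = "first")]
  true <- vapply(clips, function(cl) classes[head_label(cl, head)], "")
  auc <- if (head == "detection" && length(unique(true)) == 2L)
    auroc(probs[, "seizure"], as.integer(true == "seizure")) else NA_real_
  per_class <- do.call(rbind, lapply(classes, function(k) {
    tp <- sum(pred == k & true == k)
    fp <- sum(pred == k & true != k)
    fn <- sum(pred != k & true == k)
    data.frame(class = k,
               precision = ifelse(tp + fp == 0, NA, tp / (tp + fp)),
               recall = ifelse(tp + fn == 0, NA, tp / (tp + fn)),
               support = sum(true == k))
  }))
  structure(list(auroc = auc, weighted_f1 = weighted_f1(pred, true),
                 confusion = confusion_normalized(pred, true, classes),
                 per_class = per_class, threshold = model$tau,
                 scores = if (head == "detection") probs[, "seizure"],
                 predicted = pred, true = true),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  if (!is.na(x$auroc)) cat(sprintf("  AUROC        %.4f\n", x$auroc))
  cat(sprintf("  weighted F1  %.4f\n", x$weighted_f1))
  cat("  confusion (row-normalised):\n")
  print(round(x$confusion, 3))
  invisible(x)
}

#' Class-wise dynamic-connectivity analysis
#'
#' For each group of clips, averages the sparsified dynamic adjacency over
#' time and clips, then reports difference matrices (seizure class minus
#' the non-seizure group) and their Frobenius norms — the learned-graph
#' summary used to compare how strongly each seizure type disrupts the
#' baseline connectivity pattern.
#'
#' @param model a trained [dtgcn_model].
#' @param clips_by_class named list of clip lists; the group named
#'   `"none"` is the non-seizure reference.
#' @return A `connectivity_report`: list with `mean_adjacency` (per
#'   class), `difference` (per seizure class, class minus none) and
#'   `frobenius` (named numeric).
#' @export
connectivity_analysis <- function(model, clips_by_class) {
  groups <- names(clips_by_class)
  means <- list()
  for (g in groups) {
    clips <- clips_by_class[[g]]
    if (!length(clips)) {
      warning(sprintf("group '%s' is empty; skipped", g))
      next
    }
    acc <- NULL
    for (cl in clips) {
      enc <- encode_clip(cl, model, collect_adjacency = TRUE)
      acc <- if (is.null(acc)) enc$mean_adjacency
      else acc + enc$mean_adjacency
    }
    means[[g]] <- acc / length(clips)
  }
  diffs <- list(); fro <- numeric(0)
  if (!is.null(means$none)) {
    for (g in setdiff(names(means), "none")) {
      diffs[[g]] <- means[[g]] - means$none
      fro[g] <- sqrt(sum(diffs[[g]]^2))
    }
  }
  structure(list(mean_adjacency = means, difference = diffs,
                 frobenius = fro),
            class = "connectivity_report")
}
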