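#' Training configuration
#'
#' Mirrors the published protocol: Adam, initial learning rate 1e-3, batch
#' size 128, at most 30 epochs, with the learning rate halved (floor 1e-5)
#' after `lr_patience + 1` consecutive epochs without validation-loss
#' improvement, and unweighted categorical cross-entropy loss. The model
#' returned by [train_fold()] is the best-validation-loss checkpoint.
#'
#' @param lr0 initial learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param lr_factor,lr_patience,lr_floor reduce-on-plateau schedule: multiply
#'   the rate by `lr_factor` after `lr_patience + 1` consecutive
#'   non-improving epochs, never below `lr_floor`.
#' @param stop_acc optional early-stop threshold on validation accuracy.
#' @param seed integer RNG seed for shuffling, dropout and initialisation.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr0 = 1e-3, batch_size = 128L, max_epochs = 30L,
                         lr_factor = 0.5, lr_patience = 3L, lr_floor = 1e-5,
                         stop_acc = NULL, seed = 1L) {
  if (lr0 <= 0) stop("lr0 must be > 0")
  if (max_epochs < 1) stop("max_epochs must be >= 1")
  structure(list(lr0 = lr0, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience), lr_floor = lr_floor,
                 stop_acc = stop_acc, seed = as.integer(seed)),
            class = "train_config")
}

#' Reduce-on-plateau learning-rate scheduler
#'
#' Stateful closure: call `sch$step(val_loss)` after each epoch; `sch$lr()`
#' returns the current rate. The rate is multiplied by `factor` when
#' `patience + 1` consecutive epochs fail to improve on the best loss seen.
#'
#' @param lr0 initial rate.
#' @param factor multiplicative decay.
#' @param patience tolerated consecutive non-improving epochs.
#' @param floor minimum rate.
#' @param min_delta improvement smaller than this counts as no improvement.
#' @return list of closures `step(val_loss)` and `lr()`.
#' @export
plateau_scheduler <- function(lr0 = 1e-3, factor = 0.5, patience = 3L,
                              floor = 1e-5, min_delta = 1e-8) {
  lr <- lr0; best <- Inf; bad <- 0L
  list(step = function(val_loss) {
    if (val_loss < best - min_delta) {
      best <<- val_loss; bad <<- 0L
    } else {
      bad <<- bad + 1L
      if (bad >= patience + 1L) {
        lr <<- max(lr * factor, floor)
        bad <<- 0L
      }
    }
    invisible(lr)
  }, lr = function() lr)
}

adam_init <- function() list(t = 0L, m = list(), v = list())

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (slot in param_slots(model)) {
    g <- get_at(grads, slot$path)
    if (is.null(g)) next
    nm <- slot$name
    w <- get_at(model, slot$path)
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- numeric(length(w))
      state$v[[nm]] <- numeric(length(w))
      dim(state$m[[nm]]) <- dim(w); dim(state$v[[nm]]) <- dim(w)
    }
    # adam_fused updates the moment vectors in place; they are owned solely
    # by this optimizer state
    w <- adam_fused(w, g, state$m[[nm]], state$v[[nm]], lr, beta1, beta2,
                    bc1, bc2, eps)
    # keep pruned positions at exactly zero (their gradients and moments are
    # zero, so this is a safety net rather than a correction)
    lpath <- slot$path[-length(slot$path)]
    ly <- get_at(model, lpath)
    if (!is.null(ly$zidx) &&
        slot$path[[length(slot$path)]] == "W" && length(ly$zidx))
      w[ly$zidx] <- 0
    model <- set_at(model, slot$path, w)
  }
  list(model = model, state = state)
}

dataset_xy <- function(dataset) {
  list(x = dataset$beats, y = as.integer(dataset$labels),
       class_names = dataset$class_names)
}

eval_loss_acc <- function(model, x, y, batch_size = 256L) {
  n <- nrow(x); loss <- 0; correct <- 0
  for (s in seq.int(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    fw <- forward_model(model, x[s:e, , drop = FALSE])
    lg <- t(fw$logits)
    lo <- ce_loss_grad(lg, y[s:e])
    loss <- loss + lo$loss * (e - s + 1L)
    correct <- correct + sum(max.col(fw$probs, ties.method = "first") == y[s:e])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train a model on one train/validation split
#'
#' Minibatch Adam with reduce-on-plateau scheduling and best-validation-loss
#' model selection. Pruning masks set by [prune_l1()] are enforced
#' throughout: masked gradients are zeroed and masked weights re-zeroed after
#' every step.
#'
#' @param model a built (optionally pruned) `hpr_model`.
#' @param train_set,val_set disjoint [beat_dataset()]s with identical class
#'   sets matching `model$cfg$num_classes`.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `model` (best-validation-loss checkpoint) and `history`
#'   (data.frame: epoch, train_loss, train_acc, val_loss, val_acc, lr).
#' @export
train_fold <- function(model, train_set, val_set, cfg = train_config(),
                       verbose = FALSE) {
  stopifnot(inherits(model, "hpr_model"), inherits(cfg, "train_config"))
  tr <- dataset_xy(train_set); va <- dataset_xy(val_set)
  if (nrow(tr$x) == 0L || nrow(va$x) == 0L) stop("empty train or validation split")
  if (length(tr$class_names) != model$cfg$num_classes)
    stop("dataset has ", length(tr$class_names), " classes; model expects ",
         model$cfg$num_classes)
  set.seed(cfg$seed)
  state <- adam_init()
  sch <- plateau_scheduler(cfg$lr0, cfg$lr_factor, cfg$lr_patience, cfg$lr_floor)
  best <- list(loss = Inf, model = model)
  hist <- NULL
  n <- nrow(tr$x)
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    big <- count_parameters(model$cfg) > 5e6   # free aggressively on large models
    for (s in seq.int(1L, n, by = cfg$batch_size)) {
      idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
      fw <- forward_model(model, tr$x[idx, , drop = FALSE], train = TRUE,
                          keep_cache = TRUE)
      model <- fw$model                      # BN running stats advanced
      lo <- ce_loss_grad(t(fw$logits), tr$y[idx])
      bw <- backward_model(model, fw$cache, t(lo$dlogits))
      ep_loss <- ep_loss + lo$loss * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(fw$probs, ties.method = "first") == tr$y[idx])
      fw <- NULL                             # drop caches before the update
      upd <- adam_step(model, bw$grads, state, sch$lr())
      model <- upd$model; state <- upd$state
      bw <- NULL; upd <- NULL
      if (big) gc(FALSE)
    }
    ev <- eval_loss_acc(model, va$x, va$y)
    sch$step(ev$loss)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / n,
                                   train_acc = ep_correct / n,
                                   val_loss = ev$loss, val_acc = ev$acc,
                                   lr = sch$lr()))
    if (verbose)
      message(sprintf("epoch %2d  loss %.4f acc %.3f | val loss %.4f acc %.3f | lr %g",
                      epoch, ep_loss / n, ep_correct / n, ev$loss, ev$acc, sch$lr()))
    if (ev$loss < best$loss) best <- list(loss = ev$loss, model = model)
    if (!is.null(cfg$stop_acc) && ev$acc >= cfg$stop_acc) break
  }
  list(model = best$model, history = hist)
}

#' Confusion table
#'
#' @param truth,pred factors (or coercible) over the same class set; rows of
#'   the matrix are true classes, columns predictions.
#' @param class_names class order; defaults to `levels(truth)`.
#' @return object of class `confusion_table`: the raw C x C count matrix
#'   with per-class TP/FP/FN/TN in `attr(, "ovr")`.
#' @export
confusion_table <- function(truth, pred, class_names = NULL) {
  if (is.null(class_names))
    class_names <- if (is.factor(truth)) levels(truth) else sort(unique(truth))
  truth <- factor(as.character(truth), levels = class_names)
  pred <- factor(as.character(pred), levels = class_names)
  m <- table(truth = truth, pred = pred)
  cm <- matrix(as.numeric(m), nrow(m), ncol(m),
               dimnames = list(truth = class_names, pred = class_names))
  n <- sum(cm)
  ovr <- data.frame(class = class_names,
                    TP = diag(cm),
                    FP = colSums(cm) - diag(cm),
                    FN = rowSums(cm) - diag(cm))
  ovr$TN <- n - ovr$TP - ovr$FP - ovr$FN
  structure(cm, ovr = ovr, class = c("confusion_table", "matrix"))
}

#' Classification metrics from a confusion table
#'
#' Per class (one-vs-rest): precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2PR/(P+R); overall accuracy is the diagonal fraction of the table
#' (identical to the pooled one-vs-rest (TP+TN)/(TP+TN+FP+FN)). Macro
#' averages are unweighted means over classes. An undefined ratio (empty
#' denominator, e.g. a class absent from the test set) is reported as 0 with
#' a warning.
#'
#' @param cm a [confusion_table()].
#' @return object of class `metrics_report`: list with `accuracy`,
#'   `per_class` (data.frame: class, precision, recall, f1, support),
#'   `macro_precision`, `macro_recall`, `macro_f1`, `confusion`.
#' @export
metrics_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_table"))
  ovr <- attr(cm, "ovr")
  safe <- function(num, den, what) {
    bad <- den == 0
    if (any(bad))
      warning(what, " undefined for class(es) ",
              paste(ovr$class[bad], collapse = ", "), "; reported as 0",
              call. = FALSE)
    ifelse(den == 0, 0, num / den)
  }
  prec <- safe(ovr$TP, ovr$TP + ovr$FP, "precision")
  rec <- safe(ovr$TP, ovr$TP + ovr$FN, "recall")
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  structure(list(
    accuracy = sum(diag(unclass(cm))) / sum(cm),
    per_class = data.frame(class = ovr$class, precision = prec, recall = rec,
                           f1 = f1, support = ovr$TP + ovr$FN,
                           stringsAsFactors = FALSE),
    macro_precision = mean(prec), macro_recall = mean(rec),
    macro_f1 = mean(f1), confusion = cm),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%% | macro P %.2f%% R %.2f%% F1 %.2f%%\n",
              100 * x$accuracy, 100 * x$macro_precision,
              100 * x$macro_recall, 100 * x$macro_f1))
  pc <- x$per_class
  for (i in seq_len(nrow(pc)))
    cat(sprintf("  %-10s P %6.2f  R %6.2f  F1 %6.2f  (n=%d)\n", pc$class[i],
                100 * pc$precision[i], 100 * pc$recall[i], 100 * pc$f1[i],
                pc$support[i]))
  invisible(x)
}

#' Evaluate a model on a test set
#'
#' @param model a trained `hpr_model`.
#' @param test_set a [beat_dataset()].
#' @return list with `confusion` ([confusion_table()]) and `metrics`
#'   ([metrics_report()]).
#' @export
evaluate_model <- function(model, test_set) {
  pr <- predict_model(model, test_set)
  cm <- confusion_table(test_set$labels, pr$labels, test_set$class_names)
  list(confusion = cm, metrics = metrics_report(cm))
}

#' Macro F1 from per-class F1 scores
#'
#' Unweighted mean, the convention used for all averaged results.
#'
#' @param f1s numeric vector of per-class F1 values (any common scale).
#' @return their mean.
#' @export
macro_f1 <- function(f1s) mean(f1s)

#' Stratified k-fold assignments
#'
#' Beats of each class are shuffled and dealt round-robin over the k folds,
#' so per-class fold counts differ by at most one. The fold unit is the beat
#' (intra-patient protocol).
#'
#' @param labels factor (or coercible) of beat classes.
#' @param k number of folds.
#' @param seed RNG seed; the same seed reproduces the assignment.
#' @return object of class `fold_split`: list with `k`, `assignments`
#'   (integer fold id 1..k per beat), `seed`, `strategy`.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.factor(labels)
  cnt <- table(labels)
  small <- names(cnt)[cnt < k & cnt > 0]
  if (length(small))
    stop("class(es) with fewer than k = ", k, " beats: ",
         paste(small, collapse = ", "))
  set.seed(seed)
  assignments <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (!length(idx)) next
    idx <- idx[sample.int(length(idx))]
    assignments[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(list(k = as.integer(k), assignments = assignments,
                 seed = as.integer(seed), strategy = "stratified-beat"),
            class = "fold_split")
}

#' Write fold assignments to CSV
#'
#' @param folds a [make_folds()] result.
#' @param path output path; columns `beat_index` (1-based) and `fold`.
#' @export
write_folds_csv <- function(folds, path) {
  utils::write.csv(data.frame(beat_index = seq_along(folds$assignments),
                              fold = folds$assignments),
                   path, row.names = FALSE)
  invisible(path)
}

#' k-fold cross-validated training and evaluation
#'
#' Fold f is held out for testing; the remaining beats are split
#' stratified into training and validation (fraction `val_frac` for
#' validation, used for model selection and the learning-rate schedule). The
#' averaged report is the unweighted mean of per-fold metrics.
#'
#' @param dataset a [beat_dataset()].
#' @param folds a [make_folds()] result over `dataset$labels`.
#' @param model_cfg a [hpr_config()] with `num_classes` matching the dataset.
#' @param train_cfg a [train_config()].
#' @param val_frac fraction of each training split carved out for validation.
#' @param prune_cfg optional [prune_config()] applied to each fold's freshly
#'   initialised model before training.
#' @param verbose print per-epoch progress.
#' @return object of class `cv_report`: list with `fold_reports` (list of
#'   [metrics_report()]), `average` (data.frame of averaged metrics) and
#'   `histories`.
#' @export
cross_validate <- function(dataset, folds, model_cfg, train_cfg = train_config(),
                           val_frac = 0.1, prune_cfg = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "beat_dataset"), inherits(folds, "fold_split"))
  if (folds$k < 2L) stop("k must be >= 2")
  reports <- vector("list", folds$k)
  histories <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    test_idx <- which(folds$assignments == f)
    rest_idx <- which(folds$assignments != f)
    # stratified validation carve-out, deterministic per fold
    set.seed(train_cfg$seed + f)
    lab <- dataset$labels[rest_idx]
    val_pick <- unlist(lapply(levels(lab), function(cl) {
      idx <- which(lab == cl)
      if (!length(idx)) return(integer(0))
      idx[sample.int(length(idx), max(1L, round(val_frac * length(idx))))]
    }))
    val_idx <- rest_idx[val_pick]
    tr_idx <- setdiff(rest_idx, val_idx)
    set.seed(train_cfg$seed + 1000L * f)
    model <- build_model(model_cfg)
    if (!is.null(prune_cfg)) model <- prune_l1(model, prune_cfg)
    fit <- train_fold(model, subset_beats(dataset, tr_idx),
                      subset_beats(dataset, val_idx), train_cfg,
                      verbose = verbose)
    ev <- evaluate_model(fit$model, subset_beats(dataset, test_idx))
    reports[[f]] <- ev$metrics
    histories[[f]] <- fit$history
  }
  avg <- data.frame(
    accuracy = mean(vapply(reports, `[[`, 0, "accuracy")),
    macro_precision = mean(vapply(reports, `[[`, 0, "macro_precision")),
    macro_recall = mean(vapply(reports, `[[`, 0, "macro_recall")),
    macro_f1 = mean(vapply(reports, `[[`, 0, "macro_f1")))
  structure(list(fold_reports = reports, average = avg, histories = histories),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  for (f in seq_along(x$fold_reports))
    cat(sprintf("fold %d: accuracy %.2f%%, macro F1 %.2f%%\n", f,
                100 * x$fold_reports[[f]]$accuracy,
                100 * x$fold_reports[[f]]$macro_f1))
  cat(sprintf("average: accuracy %.2f%%, macro F1 %.2f%%\n",
              100 * x$average$accuracy, 100 * x$average$macro_f1))
  invisible(x)
}
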