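# Multi-level pruning optimisation: unstructured L1-magnitude pruning applied
# per tensor at network level (front conv + fully connected weight) and block
# level (all REB convolution weights), with stable tie-breaking and exact
# sparsity accounting.

get_at <- function(obj, path) Reduce(function(o, k) o[[k]], path, obj)

set_at <- function(obj, path, value) {
  k <- path[[1]]
  if (length(path) == 1L) obj[[k]] <- value
  else obj[[k]] <- set_at(obj[[k]], path[-1], value)
  obj
}

# every trainable tensor of a built model: name matches model_tensor_table
# (bn gamma/beta and fc bias are listed individually here)
param_slots <- function(model) {
  slots <- list()
  add <- function(name, path, scope = "") {
    slots[[length(slots) + 1L]] <<- list(name = name, path = path, scope = scope)
  }
  add("front.conv.W", list("front", "conv", "W"), "net")
  add("front.bn.gamma", list("front", "bn", "gamma"))
  add("front.bn.beta", list("front", "bn", "beta"))
  tags <- names(model$layers)
  for (l in seq_along(model$layers)) {
    for (i in seq_along(model$layers[[l]])) {
      p <- sprintf("%s.REB%d.", tags[l], i - 1L)
      base <- list("layers", l, i)
      add(paste0(p, "bn1.gamma"), c(base, list("bn1", "gamma")))
      add(paste0(p, "bn1.beta"), c(base, list("bn1", "beta")))
      add(paste0(p, "conv1.W"), c(base, list("conv1", "W")), "blk")
      add(paste0(p, "bn2.gamma"), c(base, list("bn2", "gamma")))
      add(paste0(p, "bn2.beta"), c(base, list("bn2", "beta")))
      add(paste0(p, "conv2.W"), c(base, list("conv2", "W")), "blk")
      if (!is.null(model$layers[[l]][[i]]$skip))
        add(paste0(p, "skip.W"), c(base, list("skip", "W")), "blk")
    }
  }
  add("fc.W", list("fc", "W"), "net")
  if (!is.null(model$fc$b)) add("fc.b", list("fc", "b"))
  slots
}

#' Pruning configuration
#'
#' @param ratio fraction `r` of each selected tensor to zero, `0 <= r < 1`.
#'   The pruned amount per tensor is `round(r * numel)`.
#' @param scope `"mlpo"` (network + block level, the default strategy),
#'   `"network_level"` (front conv weight + fully connected weight),
#'   `"block_level"` (every REB convolution weight, including the first-REB
#'   1x1 skip convs), or `"none"`. Batch-norm parameters and biases are never
#'   selected.
#' @return an object of class `prune_config`.
#' @export
prune_config <- function(ratio = 0.9,
                         scope = c("mlpo", "network_level", "block_level", "none")) {
  scope <- match.arg(scope)
  if (ratio < 0 || ratio >= 1) stop("ratio must be in [0, 1)")
  structure(list(ratio = ratio, scope = scope), class = "prune_config")
}

scope_tags <- function(scope) {
  switch(scope, network_level = "net", block_level = "blk",
         mlpo = c("net", "blk"), none = character(0),
         stop("unknown scope '", scope, "'"))
}

#' Select prunable weight tensors
#'
#' @param model a built `hpr_model`.
#' @param scope pruning scope (see [prune_config()]).
#' @return named list of weight-tensor paths, in model order.
#' @export
select_prunable <- function(model, scope = "mlpo") {
  stopifnot(inherits(model, "hpr_model"))
  tags <- scope_tags(scope)
  slots <- Filter(function(s) s$scope %in% tags, param_slots(model))
  stats::setNames(lapply(slots, `[[`, "path"), vapply(slots, `[[`, "", "name"))
}

# indices of the round(r*n) smallest-|w| entries; on equal magnitude the
# lower flat index is pruned first (stable tie-break)
l1_prune_indices <- function(w, ratio) {
  n <- length(w)
  np <- round(ratio * n)
  if (np <= 0L) return(integer(0))
  if (np >= n) return(seq_len(n))
  av <- abs(as.vector(w))
  thr <- sort(av, partial = np)[np]
  below <- which(av < thr)
  ties <- which(av == thr)
  need <- np - length(below)
  c(below, ties[seq_len(need)])
}

#' Apply L1-magnitude unstructured pruning
#'
#' For every tensor in the configured scope, the `round(ratio * numel)`
#' smallest-magnitude weights are set to zero. The pruned index set is stored
#' on the layer (`zidx`) so that training keeps those positions at exactly
#' zero: their gradients are zeroed and the weights re-zeroed after every
#' optimizer step (sparse training; there is no separate fine-tuning phase).
#'
#' @param model a built `hpr_model`.
#' @param pcfg a [prune_config()].
#' @return the pruned model.
#' @export
prune_l1 <- function(model, pcfg) {
  stopifnot(inherits(model, "hpr_model"), inherits(pcfg, "prune_config"))
  if (pcfg$scope == "none" || pcfg$ratio == 0) return(model)
  for (path in select_prunable(model, pcfg$scope)) {
    W <- get_at(model, path)
    idx <- l1_prune_indices(W, pcfg$ratio)
    if (length(idx)) {
      W[idx] <- 0
      model <- set_at(model, path, W)
    }
    lpath <- path[-length(path)]
    ly <- get_at(model, lpath)
    ly$zidx <- idx
    model <- set_at(model, lpath, ly)
  }
  model
}

#' Surviving-parameter count under pruning, without materialising the mask
#'
#' Runs the same per-tensor L1 magnitude ranking as [prune_l1()] and counts
#' the parameters that survive, but never builds the pruned model — only one
#' tensor's magnitudes are held at a time, which keeps the peak memory close
#' to the unpruned model itself. Useful for model-size studies on
#' configurations with hundreds of millions of weights. Equals
#' `nonzero_count(prune_l1(model, pcfg))` exactly.
#'
#' @param model a built `hpr_model`.
#' @param pcfg a [prune_config()].
#' @return surviving parameter count (double).
#' @export
pruned_nonzero_count <- function(model, pcfg) {
  stopifnot(inherits(model, "hpr_model"), inherits(pcfg, "prune_config"))
  total <- nonzero_count(model)
  if (pcfg$scope == "none" || pcfg$ratio == 0) return(total)
  for (path in select_prunable(model, pcfg$scope)) {
    W <- get_at(model, path)
    total <- total - length(l1_prune_indices(W, pcfg$ratio))
  }
  total
}

#' Count remaining (nonzero) trainable parameters
#'
#' Enumerates every trainable tensor of the built model and counts the
#' entries not fixed at zero by a pruning mask — the model-size convention
#' used when reporting pruned networks. Parameters that merely happen to
#' hold the value zero (for instance zero-initialised biases and batch-norm
#' shifts) still count; masked positions are verified to be exactly zero.
#' On an unpruned model this equals [count_parameters()] of its config; on a
#' pruned model it equals the closed form with the matching
#' [prune_config()].
#'
#' @param model a built `hpr_model`.
#' @return remaining parameter count (double).
#' @export
nonzero_count <- function(model) {
  stopifnot(inherits(model, "hpr_model"))
  s <- 0
  for (slot in param_slots(model)) {
    w <- get_at(model, slot$path)
    npruned <- 0L
    if (slot$path[[length(slot$path)]] == "W") {
      ly <- get_at(model, slot$path[-length(slot$path)])
      if (!is.null(ly$zidx)) {
        npruned <- length(ly$zidx)
        if (any(w[ly$zidx] != 0))
          stop("pruned positions of ", slot$name, " are not zero")
      }
    }
    s <- s + length(w) - npruned
  }
  s
}

#' Sparsity report
#'
#' Per-tensor and global sparsity of `model_after` relative to
#' `model_before`, plus histograms of absolute nonzero weight values over 64
#' uniform bins spanning `[0, max|w_before|]` (exact zeros are excluded from
#' the histograms, so pruning empties the low-magnitude bins).
#'
#' @param model_before,model_after two `hpr_model`s of identical
#'   architecture, typically before and after [prune_l1()].
#' @param bins number of histogram bins.
#' @return object of class `sparsity_report`: list with `tensors`
#'   (data.frame: name, total, nonzero, fraction_pruned), `global` totals,
#'   and `histogram` (data.frame: bin_lo, bin_hi, count_before, count_after).
#' @export
sparsity_report <- function(model_before, model_after, bins = 64L) {
  sb <- param_slots(model_before)
  sa <- param_slots(model_after)
  if (length(sb) != length(sa) ||
      !all(vapply(sb, `[[`, "", "name") == vapply(sa, `[[`, "", "name")))
    stop("models have different architectures")
  nm <- vapply(sb, `[[`, "", "name")
  nmask <- function(model, slot) {
    if (slot$path[[length(slot$path)]] != "W") return(0L)
    ly <- get_at(model, slot$path[-length(slot$path)])
    if (is.null(ly$zidx)) 0L else length(ly$zidx)
  }
  total <- numeric(length(sb)); nzb <- numeric(length(sb)); nza <- numeric(length(sb))
  maxw <- 0
  for (i in seq_along(sb)) {
    wb <- get_at(model_before, sb[[i]]$path)
    wa <- get_at(model_after, sa[[i]]$path)
    if (length(wb) != length(wa))
      stop("models have different architectures (tensor ", nm[i], ")")
    total[i] <- length(wb)
    nzb[i] <- length(wb) - nmask(model_before, sb[[i]])
    nza[i] <- length(wa) - nmask(model_after, sa[[i]])
    maxw <- max(maxw, abs(wb))
  }
  edges <- seq(0, maxw, length.out = bins + 1L)
  hb <- numeric(bins); ha <- numeric(bins)
  for (i in seq_along(sb)) {
    wb <- abs(as.vector(get_at(model_before, sb[[i]]$path)))
    wa <- abs(as.vector(get_at(model_after, sa[[i]]$path)))
    hb <- hb + tabulate(pmin(findInterval(wb[wb > 0], edges,
                                          rightmost.closed = TRUE), bins), bins)
    ha <- ha + tabulate(pmin(findInterval(wa[wa > 0], edges,
                                          rightmost.closed = TRUE), bins), bins)
  }
  structure(list(
    tensors = data.frame(name = nm, total = total, nonzero = nza,
                         fraction_pruned = (nzb - nza) / total,
                         stringsAsFactors = FALSE),
    global = list(total = sum(total), nonzero_before = sum(nzb),
                  nonzero_after = sum(nza),
                  fraction_pruned = (sum(nzb) - sum(nza)) / sum(total)),
    histogram = data.frame(bin_lo = edges[-(bins + 1L)], bin_hi = edges[-1L],
                           count_before = hb, count_after = ha)),
    class = "sparsity_report")
}

#' @export
print.sparsity_report <- function(x, ...) {
  g <- x$global
  cat(sprintf("<sparsity_report> %s / %s nonzero (%.2f%% pruned)\n",
              format(g$nonzero_after, big.mark = ","),
              format(g$total, big.mark = ","), 100 * g$fraction_pruned))
  invisible(x)
}

#' Write a sparsity report to CSV + JSON
#'
#' @param report a [sparsity_report()].
#' @param prefix output path prefix; writes `<prefix>_tensors.csv`,
#'   `<prefix>_histogram.csv` and `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_sparsity_report <- function(report, prefix) {
  stopifnot(inherits(report, "sparsity_report"))
  utils::write.csv(report$tensors, paste0(prefix, "_tensors.csv"),
                   row.names = FALSE)
  utils::write.csv(report$histogram, paste0(prefix, "_histogram.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$global, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
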