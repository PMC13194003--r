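#' 1D Grad-CAM saliency for a single beat
#'
#' Gradient-weighted class activation mapping at a chosen backbone depth:
#' channel weights are the temporal average of the gradient of the target
#' class logit (pre-softmax) with respect to the selected ResLayer's output
#' activations; the map is the ReLU of the weighted channel sum, linearly
#' upsampled to the beat length and min-max normalised to [0, 1]. A map
#' whose pre-normalisation values are identically zero stays all zero.
#'
#' @param model a built (usually trained) `hpr_model`.
#' @param beat numeric vector of `model$cfg$input_len` samples (or 1 x L
#'   matrix).
#' @param target_class class index (1-based) whose logit is explained.
#' @param layer_tag name of the probed ResLayer, e.g. `"ResLayer0"`
#'   (shallow), `"ResLayer3"` (intermediate), `"ResLayer5"` (deep); see
#'   `names(model$layers)` for the valid tags.
#' @param beat_id identifier stored on the output.
#' @return object of class `saliency_map`: list with `values` (length-L
#'   trace in [0, 1]), `layer_tag`, `target_class`, `beat_id`.
#' @export
gradcam <- function(model, beat, target_class, layer_tag, beat_id = NA) {
  stopifnot(inherits(model, "hpr_model"))
  if (!layer_tag %in% names(model$layers))
    stop("invalid layer_tag '", layer_tag, "'; valid tags: ",
         paste(names(model$layers), collapse = ", "))
  if (is.null(dim(beat))) beat <- matrix(beat, 1L)
  if (target_class < 1L || target_class > model$cfg$num_classes)
    stop("target_class out of range 1..", model$cfg$num_classes)
  fw <- forward_model(model, beat, train = FALSE, keep_cache = TRUE,
                      collect = layer_tag)
  act <- fw$acts[[layer_tag]]                       # (C_l, L_l, 1)
  dlogits <- matrix(0, 1L, model$cfg$num_classes)
  dlogits[1L, target_class] <- 1
  bw <- backward_model(model, fw$cache, dlogits, want_grads = FALSE,
                       stop_at = layer_tag)
  grad <- bw$dact                                   # (C_l, L_l, 1)
  Ll <- dim(act)[2]
  gmat <- matrix(grad, dim(grad)[1], Ll)
  amat <- matrix(act, dim(act)[1], Ll)
  alpha <- rowMeans(gmat)                           # channel weights
  raw <- pmax(colSums(alpha * amat), 0)             # ReLU'd weighted sum
  L <- model$cfg$input_len
  up <- if (Ll == 1L) rep(raw, L) else
    stats::approx(seq(0, 1, length.out = Ll), raw,
                  xout = seq(0, 1, length.out = L))$y
  lo <- min(up); hi <- max(up)
  values <- if (hi == 0) rep(0, L) else if (hi == lo) rep(1, L) else
    (up - lo) / (hi - lo)
  structure(list(values = values, layer_tag = layer_tag,
                 target_class = target_class, beat_id = beat_id),
            class = "saliency_map")
}

#' Saliency panel over beats and layers
#'
#' Computes [gradcam()] maps for each beat at each requested depth and
#' returns them in long format, ready for CSV export or plotting.
#'
#' @param model a built `hpr_model`.
#' @param beats matrix (B x L) or [beat_dataset()].
#' @param classes target class index per beat (recycled if length 1); when
#'   `NULL` and `beats` is a labelled dataset, the true labels are used.
#' @param layer_tags character vector of ResLayer tags.
#' @return data.frame with columns `beat_id`, `layer_tag`, `target_class`,
#'   `sample_index` (1-based), `value`.
#' @export
saliency_panel <- function(model, beats, classes = NULL, layer_tags) {
  if (inherits(beats, "beat_dataset")) {
    if (is.null(classes)) classes <- as.integer(beats$labels)
    beats <- beats$beats
  }
  if (is.null(dim(beats))) beats <- matrix(beats, 1L)
  if (nrow(beats) == 0L || length(layer_tags) == 0L)
    stop("saliency_panel needs at least one beat and one layer tag")
  if (is.null(classes)) stop("classes must be given for unlabelled beats")
  classes <- rep_len(as.integer(classes), nrow(beats))
  out <- vector("list", nrow(beats) * length(layer_tags))
  k <- 1L
  for (b in seq_len(nrow(beats))) {
    for (tag in layer_tags) {
      sm <- gradcam(model, beats[b, ], classes[b], tag, beat_id = b)
      out[[k]] <- data.frame(beat_id = b, layer_tag = tag,
                             target_class = classes[b],
                             sample_index = seq_along(sm$values),
                             value = sm$values, stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  do.call(rbind, out)
}
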