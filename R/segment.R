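#' AAMI symbol maps
#'
#' Beat-annotation symbols of the MIT-BIH and INCART databases mapped to the
#' AAMI(-like) classes N (normal / bundle-branch block / escape),
#' S (supraventricular ectopic), V (ventricular ectopic), F (fusion),
#' Q (unknown / paced). Symbols not listed map to `EXCLUDED` and are dropped
#' during segmentation.
#'
#' @param dataset_tag `"mitbih"` or `"incart"`.
#' @return object of class `aami_map`: list with `dataset_tag` and
#'   `symbol_to_class` (named character vector).
#' @export
aami_map <- function(dataset_tag = c("mitbih", "incart")) {
  dataset_tag <- match.arg(dataset_tag)
  s2c <- if (dataset_tag == "mitbih") c(
    "N" = "N", "L" = "N", "R" = "N", "e" = "N", "j" = "N",
    "A" = "S", "a" = "S", "J" = "S", "S" = "S",
    "V" = "V", "E" = "V",
    "F" = "F",
    "/" = "Q", "f" = "Q", "Q" = "Q"
  ) else c(
    "N" = "N", "R" = "N", "j" = "N", "n" = "N", "B" = "N",
    "A" = "S", "S" = "S",
    "V" = "V",
    "Q" = "Q"
  )
  structure(list(dataset_tag = dataset_tag, symbol_to_class = s2c),
            class = "aami_map")
}

#' Map an annotation symbol to its AAMI class
#'
#' @param symbol character vector of single-character annotation symbols.
#' @param amap an [aami_map()].
#' @return character vector of classes (`"N","S","V","F","Q"`) or
#'   `"EXCLUDED"` for symbols outside the map.
#' @export
map_symbol <- function(symbol, amap) {
  stopifnot(inherits(amap, "aami_map"))
  out <- unname(amap$symbol_to_class[symbol])
  out[is.na(out)] <- "EXCLUDED"
  out
}

#' Segment fixed-length beats around annotated fiducials
#'
#' For every annotation whose symbol maps to an AAMI class, a window of `L`
#' samples centred on the annotated sample (`L/2` before, `L/2` after,
#' half-open) is cut from the signal. Annotations too close to the record
#' edges are skipped and counted. Each beat is optionally z-scored (mean 0,
#' sd 1; a constant window becomes all zeros). Segmentation is conservative:
#' emitted + edge-skipped + excluded-symbol counts equal the number of
#' annotations.
#'
#' @param signal numeric signal vector.
#' @param annotations data.frame with `sample` (0-based) and `symbol`, as
#'   returned by [read_wfdb_record()].
#' @param amap an [aami_map()].
#' @param L window length in samples (even; default 128).
#' @param normalize z-score each beat (default TRUE).
#' @param fs,lead,record_id provenance stored on the dataset.
#' @param class_names label space of the output (default the five AAMI
#'   classes).
#' @return a [beat_dataset()]; `meta$skipped_edge` and `meta$excluded` hold
#'   the bookkeeping counts.
#' @export
segment_beats <- function(signal, annotations, amap, L = 128L, normalize = TRUE,
                          fs = NA_real_, lead = NA_character_,
                          record_id = NA_character_,
                          class_names = c("N", "S", "V", "F", "Q")) {
  L <- as.integer(L)
  if (L %% 2L != 0L) stop("L must be even")
  if (length(signal) < L) stop("signal shorter than the window length")
  cls <- map_symbol(annotations$symbol, amap)
  excluded <- sum(cls == "EXCLUDED")
  keep <- cls != "EXCLUDED"
  r <- annotations$sample[keep]
  cls <- cls[keep]
  half <- L %/% 2L
  ok <- r - half >= 0 & r + half <= length(signal)
  skipped <- sum(!ok)
  r <- r[ok]; cls <- cls[ok]
  if (length(r) == 0L)
    stop("no mappable beats: ", excluded, " excluded symbol(s), ",
         skipped, " edge-skipped")
  beats <- matrix(0, length(r), L)
  for (i in seq_along(r))
    beats[i, ] <- signal[(r[i] - half + 1L):(r[i] + half)]
  if (normalize) {
    mu <- rowMeans(beats)
    sdv <- apply(beats, 1, stats::sd)
    zero <- sdv == 0
    beats <- (beats - mu) / ifelse(sdv == 0, 1, sdv)
    beats[zero, ] <- 0
  }
  beat_dataset(beats, cls, class_names = class_names,
               source_ids = record_id, fs = fs, lead = lead,
               meta = list(skipped_edge = skipped, excluded = excluded,
                           normalized = normalize, window = L))
}

#' Prepare a beat dataset from a directory of WFDB records
#'
#' Runs read (one lead) -> optional denoise -> segment -> AAMI map over every
#' record and concatenates the results.
#'
#' @param records character vector of record paths (no extension).
#' @param lead lead name; `NULL` takes each record's first lead.
#' @param amap an [aami_map()].
#' @param L window length.
#' @param normalize per-beat z-scoring.
#' @param denoise `NULL`, or a [denoise_config()] applied to each record's
#'   signal before segmentation.
#' @return a [beat_dataset()] pooling all records; per-record skip counts
#'   are summed in `meta`.
#' @export
prepare_beats <- function(records, amap, lead = NULL, L = 128L,
                          normalize = TRUE, denoise = NULL) {
  parts <- lapply(records, function(rec) {
    rd <- read_wfdb_record(rec, lead = lead)
    sig <- if (is.null(denoise)) rd$signal else wavelet_denoise(rd$signal, denoise)
    segment_beats(sig, rd$annotations, amap, L = L, normalize = normalize,
                  fs = rd$fs, lead = rd$lead, record_id = rd$record)
  })
  beats <- do.call(rbind, lapply(parts, `[[`, "beats"))
  labels <- unlist(lapply(parts, function(p) as.character(p$labels)))
  src <- unlist(lapply(parts, `[[`, "source_ids"))
  beat_dataset(beats, labels, class_names = parts[[1]]$class_names,
               source_ids = src, fs = parts[[1]]$fs, lead = parts[[1]]$lead,
               meta = list(
                 skipped_edge = sum(vapply(parts, function(p) p$meta$skipped_edge, 0)),
                 excluded = sum(vapply(parts, function(p) p$meta$excluded, 0)),
                 denoised = !is.null(denoise), normalized = normalize))
}
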