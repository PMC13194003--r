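#' Beat dataset container
#'
#' Bundles a matrix of fixed-length heartbeat waveforms with their class labels
#' and provenance. This is the common currency passed between the synthetic
#' generator, the WFDB segmenter, and the training/evaluation routines.
#'
#' @param beats numeric matrix, one beat per row (N x L).
#' @param labels class label per beat; coerced to a factor with levels
#'   `class_names`.
#' @param class_names ordered character vector of class names. Defaults to the
#'   levels present in `labels`.
#' @param source_ids per-beat identifier of the originating record (recycled if
#'   length 1).
#' @param fs sampling rate of the originating signal in Hz.
#' @param lead name of the ECG lead the beats were cut from.
#' @param meta free-form list of provenance metadata (generator config, seed,
#'   skip counters, ...).
#'
#' @return An object of class `beat_dataset`: a list with elements `beats`,
#'   `labels`, `class_names`, `source_ids`, `fs`, `lead`, `meta`.
#' @export
beat_dataset <- function(beats, labels, class_names = NULL, source_ids = NULL,
                         fs = NA_real_, lead = NA_character_, meta = list()) {
  beats <- as.matrix(beats)
  storage.mode(beats) <- "double"
  if (any(!is.finite(beats))) stop("beats contain non-finite values")
  if (is.null(class_names)) {
    class_names <- if (is.factor(labels)) levels(labels) else unique(as.character(labels))
  }
  labels <- factor(as.character(labels), levels = class_names)
  if (anyNA(labels)) stop("labels outside class_names")
  if (length(labels) != nrow(beats)) stop("length(labels) must equal nrow(beats)")
  if (is.null(source_ids)) source_ids <- rep(NA_character_, nrow(beats))
  if (length(source_ids) == 1L) source_ids <- rep(source_ids, nrow(beats))
  if (length(source_ids) != nrow(beats)) stop("length(source_ids) must equal nrow(beats)")
  structure(list(beats = beats, labels = labels, class_names = class_names,
                 source_ids = as.character(source_ids), fs = fs, lead = lead,
                 meta = meta),
            class = "beat_dataset")
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat(sprintf("<beat_dataset> %d beats x %d samples, fs = %s Hz, lead = %s\n",
              nrow(x$beats), ncol(x$beats),
              format(x$fs), format(x$lead)))
  print(class_counts(x))
  invisible(x)
}

#' Per-class beat counts
#'
#' @param dataset a [beat_dataset()].
#' @return named integer vector of counts, one entry per class (including
#'   empty classes), summing to the number of beats.
#' @export
class_counts <- function(dataset) {
  stopifnot(inherits(dataset, "beat_dataset"))
  table(dataset$labels)
}

#' Subset a beat dataset by row index
#'
#' @param dataset a [beat_dataset()].
#' @param idx integer or logical row index.
#' @param drop_levels drop class levels absent after subsetting.
#' @return a new [beat_dataset()].
#' @export
subset_beats <- function(dataset, idx, drop_levels = FALSE) {
  stopifnot(inherits(dataset, "beat_dataset"))
  lab <- dataset$labels[idx]
  cls <- dataset$class_names
  if (drop_levels) {
    cls <- cls[cls %in% unique(as.character(lab))]
    lab <- factor(as.character(lab), levels = cls)
  }
  beat_dataset(dataset$beats[idx, , drop = FALSE], lab, cls,
               dataset$source_ids[idx], dataset$fs, dataset$lead, dataset$meta)
}

#' Map a dataset onto a classification task's label space
#'
#' The five-symbol AAMI(-like) space {N, S, V, F, Q} is reduced to the label
#' set of a specific task: the MIT-BIH four-class task keeps {N, S, V, F} and
#' drops Q beats; the INCART binary task maps N to `normal` and {S, V} to
#' `abnormal`; the INCART three-class task keeps {N, S, V}. Beats whose class
#' is not part of the task are removed.
#'
#' @param dataset a [beat_dataset()] labelled in {N, S, V, F, Q} (a subset is
#'   fine).
#' @param task one of `"mitbih-4class"`, `"incart-binary"`, `"incart-3class"`.
#' @return a [beat_dataset()] in the task's label space.
#' @export
relabel_task <- function(dataset, task = c("mitbih-4class", "incart-binary", "incart-3class")) {
  stopifnot(inherits(dataset, "beat_dataset"))
  task <- match.arg(task)
  if (!all(dataset$class_names %in% c("N", "S", "V", "F", "Q")))
    stop("relabel_task expects labels in the AAMI(-like) space {N,S,V,F,Q}; got: ",
         paste(dataset$class_names, collapse = ","))
  lab <- as.character(dataset$labels)
  if (task == "mitbih-4class") {
    keep <- lab %in% c("N", "S", "V", "F")
    newlab <- lab[keep]
    cls <- c("N", "S", "V", "F")
  } else if (task == "incart-binary") {
    keep <- lab %in% c("N", "S", "V")
    newlab <- ifelse(lab[keep] == "N", "normal", "abnormal")
    cls <- c("normal", "abnormal")
  } else {
    keep <- lab %in% c("N", "S", "V")
    newlab <- lab[keep]
    cls <- c("N", "S", "V")
  }
  if (!any(keep)) stop("no beats remain after relabelling for task ", task)
  out <- beat_dataset(dataset$beats[keep, , drop = FALSE], newlab, cls,
                      dataset$source_ids[keep], dataset$fs, dataset$lead,
                      dataset$meta)
  out$meta$task <- task
  out$meta$dropped <- sum(!keep)
  out
}

#' Write / read a beat dataset as CSV
#'
#' One beat per row, waveform samples in columns `s1..sL`, label in the final
#' `label` column. A JSON sidecar (`<path>.meta.json`) records class names,
#' sampling rate, lead and generator metadata so the dataset round-trips.
#'
#' @param dataset a [beat_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_beats_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "beat_dataset"))
  df <- as.data.frame(dataset$beats)
  names(df) <- paste0("s", seq_len(ncol(dataset$beats)))
  df$label <- as.character(dataset$labels)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(class_names = dataset$class_names, fs = dataset$fs,
               lead = dataset$lead, source_ids = dataset$source_ids,
               meta = dataset$meta)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_beats_csv
#' @export
read_beats_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  lab <- df$label
  beats <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  metapath <- paste0(path, ".meta.json")
  if (file.exists(metapath)) {
    meta <- jsonlite::read_json(metapath, simplifyVector = TRUE)
    beat_dataset(beats, lab, class_names = meta$class_names,
                 source_ids = meta$source_ids,
                 fs = if (is.null(meta$fs)) NA_real_ else meta$fs,
                 lead = if (is.null(meta$lead)) NA_character_ else meta$lead,
                 meta = as.list(meta$meta))
  } else {
    beat_dataset(beats, lab)
  }
}
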