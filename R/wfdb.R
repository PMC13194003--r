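# Minimal WFDB (PhysioNet waveform-database) support: header parsing, signal
# formats 212 and 16, and the MIT annotation format. Covers what the MIT-BIH
# and INCART arrhythmia databases use; annotations are taken as ground truth
# (no R-peak detection).

# PhysioNet annotation code -> symbol (beat codes 1..13 plus the common
# non-beat codes; extended codes 36-38 follow the wfdb-python label table)
wfdb_code_symbols <- local({
  s <- rep(NA_character_, 49)
  s[1:13] <- c("N", "L", "R", "a", "V", "F", "J", "A", "S", "E", "j", "/", "Q")
  s[14] <- "~"; s[16] <- "|"; s[18] <- "s"; s[19] <- "T"; s[20] <- "*"
  s[21] <- "D"; s[22] <- "\""; s[23] <- "="; s[24] <- "p"; s[25] <- "B"
  s[26] <- "^"; s[27] <- "t"; s[28] <- "+"; s[29] <- "u"; s[30] <- "?"
  s[31] <- "!"; s[32] <- "x"; s[33] <- "("; s[34] <- ")"; s[35] <- "f"
  s[36] <- "e"; s[37] <- "n"; s[38] <- "r"
  s
})

symbol_to_code <- function(symbol) {
  code <- match(symbol, wfdb_code_symbols)
  if (anyNA(code))
    stop("no annotation code for symbol(s): ",
         paste(unique(symbol[is.na(code)]), collapse = " "))
  code
}

parse_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*$", "", rec[3])) else 250
  sig <- lapply(seq_len(nsig), function(i) {
    tok <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    gainspec <- if (length(tok) >= 3) tok[3] else "200"
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gainspec)))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gainspec))
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gainspec)) else 0
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ")
            else paste0("ch", i)
    list(file = tok[1], format = sub("[x:+].*$", "", tok[2]),
         gain = gain, baseline = baseline, description = desc)
  })
  list(record = rec[1], nsig = nsig, fs = fs,
       nsamp = if (length(rec) >= 4) as.numeric(rec[4]) else NA_real_,
       signals = sig)
}

read_dat <- function(dat_path, format, nsig, nsamp = NA) {
  raw <- readBin(dat_path, "raw", file.info(dat_path)$size)
  if (format == "212") {
    n3 <- (length(raw) %/% 3L) * 3L
    b <- as.integer(raw[seq_len(n3)])
    b1 <- b[seq(1, n3, 3)]; b2 <- b[seq(2, n3, 3)]; b3 <- b[seq(3, n3, 3)]
    s1 <- bitwAnd(b2, 15L) * 256L + b1
    s2 <- bitwAnd(b2, 240L) * 16L + b3
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    samples <- as.vector(rbind(s1, s2))
  } else if (format == "16") {
    samples <- readBin(dat_path, "integer", n = length(raw) %/% 2L, size = 2L,
                       signed = TRUE, endian = "little")
  } else stop("unsupported WFDB signal format '", format, "'")
  nframes <- length(samples) %/% nsig
  if (!is.na(nsamp)) nframes <- min(nframes, nsamp)
  matrix(samples[seq_len(nframes * nsig)], ncol = nsig, byrow = TRUE)
}

#' Read WFDB beat annotations
#'
#' Parses the MIT annotation format (.atr and friends): 16-bit little-endian
#' words holding a 6-bit type code and 10-bit time increment, with the
#' standard pseudo-annotations (SKIP, NUM, SUB, CHN, AUX) handled.
#'
#' @param path annotation file path.
#' @return data.frame with `sample` (0-based sample index) and `symbol`.
#' @export
read_wfdb_annotations <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  words <- readBin(path, "integer", n = length(raw) %/% 2L, size = 2L,
                   signed = FALSE, endian = "little")
  t <- 0; i <- 1L
  samples <- numeric(0); symbols <- character(0)
  while (i <= length(words)) {
    w <- words[i]
    code <- w %/% 1024L
    interval <- w %% 1024L
    if (w == 0L) break                        # EOF
    if (code == 59L) {                        # SKIP: next two words = interval
      if (i + 2L > length(words)) break
      t <- t + words[i + 1L] * 65536 + words[i + 2L]
      i <- i + 3L
      next
    } else if (code %in% c(60L, 61L, 62L)) {  # NUM / SUB / CHN: no time
      i <- i + 1L
      next
    } else if (code == 63L) {                 # AUX: interval = byte count
      i <- i + 1L + (interval + interval %% 2L) %/% 2L
      next
    }
    t <- t + interval
    sym <- if (code >= 1L && code <= length(wfdb_code_symbols))
      wfdb_code_symbols[code] else NA_character_
    samples <- c(samples, t)
    symbols <- c(symbols, if (is.na(sym)) paste0("<", code, ">") else sym)
    i <- i + 1L
  }
  data.frame(sample = samples, symbol = symbols, stringsAsFactors = FALSE)
}

#' Read an annotated WFDB record
#'
#' Reads the header/signal pair of a record, selects one lead, converts it
#' to physical units via the header gain and baseline, and attaches the beat
#' annotations.
#'
#' @param record record path without extension (e.g. `"mitdb/100"`).
#' @param lead lead name (header description), e.g. `"MLII"`; defaults to
#'   the first lead.
#' @param annotator annotation file extension (default `"atr"`); `NULL`
#'   skips annotations.
#' @return list with `signal` (numeric, physical units), `fs`, `lead`,
#'   `record`, `annotations` (data.frame `sample`, `symbol`).
#' @export
read_wfdb_record <- function(record, lead = NULL, annotator = "atr") {
  hea <- paste0(record, ".hea")
  if (!file.exists(hea)) stop("header not found: ", hea)
  hd <- parse_header(hea)
  leads <- vapply(hd$signals, `[[`, "", "description")
  if (is.null(lead)) lead <- leads[1]
  ch <- match(lead, leads)
  if (is.na(ch))
    stop("lead '", lead, "' not in record ", hd$record,
         "; available leads: ", paste(leads, collapse = ", "))
  dat <- file.path(dirname(record), hd$signals[[ch]]$file)
  if (!file.exists(dat)) stop("signal file not found: ", dat)
  m <- read_dat(dat, hd$signals[[ch]]$format, hd$nsig, hd$nsamp)
  sig <- (m[, ch] - hd$signals[[ch]]$baseline) / hd$signals[[ch]]$gain
  ann <- NULL
  if (!is.null(annotator)) {
    ap <- paste0(record, ".", annotator)
    if (!file.exists(ap)) stop("annotation file not found: ", ap)
    ann <- read_wfdb_annotations(ap)
    if (nrow(ann) && any(ann$sample >= length(sig) | ann$sample < 0))
      stop("annotation sample indices outside the signal range")
  }
  list(signal = sig, fs = hd$fs, lead = lead, record = hd$record,
       annotations = ann)
}

#' Write a toy WFDB record (test fixture helper)
#'
#' Emits a header, a format-16 signal file and a MIT-format annotation file
#' that [read_wfdb_record()] can read back. Intended for constructing small
#' synthetic records in tests and examples.
#'
#' @param dir output directory.
#' @param name record name.
#' @param signals numeric matrix, one column per lead (physical units).
#' @param fs sampling rate in Hz.
#' @param leads lead names, one per column.
#' @param annotations data.frame with `sample` (0-based) and `symbol`;
#'   must be sorted by sample.
#' @param gain ADC gain (units per physical unit).
#' @return the record path (without extension), invisibly.
#' @export
write_wfdb_record <- function(dir, name, signals, fs, leads,
                              annotations = NULL, gain = 200) {
  signals <- as.matrix(signals)
  nsig <- ncol(signals)
  stopifnot(length(leads) == nsig)
  rec <- file.path(dir, name)
  adc <- round(signals * gain)
  if (any(abs(adc) > 32767)) stop("signal exceeds 16-bit ADC range")
  hdr <- c(sprintf("%s %d %g %d", name, nsig, fs, nrow(signals)),
           sprintf("%s.dat 16 %g(0)/mV 16 0 0 0 0 %s", name, gain, leads))
  writeLines(hdr, paste0(rec, ".hea"))
  inter <- as.integer(t(adc))
  writeBin(inter, paste0(rec, ".dat"), size = 2L, endian = "little")
  if (!is.null(annotations) && nrow(annotations)) {
    if (is.unsorted(annotations$sample)) stop("annotations must be sorted")
    codes <- symbol_to_code(annotations$symbol)
    words <- integer(0)
    t_prev <- 0
    for (k in seq_len(nrow(annotations))) {
      dt <- annotations$sample[k] - t_prev
      while (dt >= 1024L) {                # long gap: SKIP pseudo-annotation
        words <- c(words, 59L * 1024L, dt %/% 65536L, dt %% 65536L)
        t_prev <- t_prev + dt
        dt <- 0L
      }
      words <- c(words, codes[k] * 1024L + dt)
      t_prev <- annotations$sample[k]
    }
    words <- c(words, 0L)                  # EOF word
    writeBin(as.integer(words), paste0(rec, ".atr"), size = 2L,
             endian = "little")
  }
  invisible(rec)
}
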