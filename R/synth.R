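#' Synthetic ECG beat generator configuration
#'
#' Parameterises a generator of labelled single-beat waveforms built from
#' Gaussian bumps mimicking the P-QRS-T morphology of a heartbeat. Each class
#' is a list of `(center, width, amp)` triples on the unit interval; the beat
#' is the sum of the bumps evaluated at `length` equally spaced points, plus a
#' baseline-wander sinusoid and white noise. The generator exists so that
#' every downstream stage (training, pruning, saliency) is exercisable with
#' no data download; it makes no claim of physiological fidelity.
#'
#' Class variants follow the usual clinical sketch: `N` has all five bumps
#' (P, Q, R, S, T); `S`-like beats lack the P wave and have a narrow QRS;
#' `V`-like beats have a wide, high-amplitude QRS (R width 3x that of `N`)
#' and an inverted T wave; `F` is the average of the `N` and `V` templates.
#' Amplitudes are in arbitrary units normalised so the R bump of `N` is 1;
#' per-beat z-scoring downstream makes the absolute scale irrelevant.
#'
#' @param length samples per beat (>= 16). The R bump centre falls on sample
#'   index `length/2` (0-based).
#' @param fs nominal sampling rate in Hz (used only to express the wander
#'   frequency in physical units).
#' @param classes ordered class names; each must have an entry in
#'   `wave_params`.
#' @param n_per_class beats generated per class by [synth_dataset()].
#' @param wave_params named list: per class, a 3-column matrix/data.frame of
#'   `(center, width, amp)` Gaussian bump triples (fractions of the beat for
#'   center/width). `NULL` uses the built-in four-class templates.
#' @param noise_sd standard deviation of additive white noise, as a fraction
#'   of the N-class R amplitude (which is 1).
#' @param wander_amp,wander_freq amplitude (same units) and frequency (Hz) of
#'   the baseline-wander sinusoid; the phase is drawn per beat.
#' @param seed integer RNG seed; identical config + seed reproduces the
#'   dataset bit for bit.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(length = 128L, fs = 360, classes = c("N", "S", "V", "F"),
                         n_per_class = 100L, wave_params = NULL,
                         noise_sd = 0.05, wander_amp = 0.1, wander_freq = 0.5,
                         seed = 1L) {
  length <- as.integer(length)
  if (length < 16L) stop("length must be >= 16")
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(wave_params)) wave_params <- default_wave_params()
  missing <- setdiff(classes, names(wave_params))
  if (length(missing) > 0)
    stop("no wave_params for class(es): ", paste(missing, collapse = ", "))
  for (cl in classes) {
    wp <- as.matrix(wave_params[[cl]])
    if (ncol(wp) != 3) stop("wave_params[['", cl, "']] must have 3 columns")
    if (any(wp[, 2] <= 0)) stop("all width fractions must be > 0")
    wave_params[[cl]] <- wp
  }
  structure(list(length = length, fs = fs, classes = classes,
                 n_per_class = as.integer(n_per_class),
                 wave_params = wave_params, noise_sd = noise_sd,
                 wander_amp = wander_amp, wander_freq = wander_freq,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# built-in bump triples (center, width, amp); R bump always centred at 0.5 so
# the peak sits on sample length/2 (0-based)
default_wave_params <- function() {
  n <- rbind(P = c(0.28, 0.045, 0.15),
             Q = c(0.455, 0.018, -0.12),
             R = c(0.500, 0.022, 1.00),
             S = c(0.545, 0.018, -0.20),
             T = c(0.77, 0.080, 0.30))
  s <- rbind(Q = c(0.455, 0.012, -0.10),
             R = c(0.500, 0.015, 1.00),
             S = c(0.545, 0.012, -0.18),
             T = c(0.73, 0.060, 0.25))
  v <- rbind(Q = c(0.42, 0.030, -0.15),
             R = c(0.500, 0.066, 1.00),   # QRS width 3x the N template
             S = c(0.60, 0.035, -0.30),
             T = c(0.78, 0.090, -0.30))   # inverted T
  f <- rbind(n / c(rep(1, 5), rep(1, 5), rep(2, 5)),      # N at half amplitude
             v / c(rep(1, 4), rep(1, 4), rep(2, 4)))      # V at half amplitude
  list(N = n, S = s, V = v, F = f)
}

#' Noiseless class templates
#'
#' @param cfg a [synth_config()].
#' @return matrix `length(cfg$classes) x cfg$length`, one noiseless template
#'   per row, in the order of `cfg$classes`.
#' @export
class_templates <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  t(vapply(cfg$classes, function(cl) eval_bumps(cfg$wave_params[[cl]], cfg$length),
           numeric(cfg$length)))
}

eval_bumps <- function(wp, L) {
  tt <- (seq_len(L) - 1) / L
  y <- numeric(L)
  for (i in seq_len(nrow(wp)))
    y <- y + wp[i, 3] * exp(-0.5 * ((tt - wp[i, 1]) / wp[i, 2])^2)
  y
}

#' Generate one synthetic beat
#'
#' Draws from the current RNG state: the baseline-wander phase and the white
#' noise are the only stochastic ingredients, so with `noise_sd = 0` and
#' `wander_amp = 0` the output is exactly the class template.
#'
#' @param class_name one of `cfg$classes`.
#' @param cfg a [synth_config()].
#' @return numeric waveform of `cfg$length` samples.
#' @export
synth_beat <- function(class_name, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!class_name %in% cfg$classes)
    stop("unknown class '", class_name, "'; valid classes: ",
         paste(cfg$classes, collapse = ", "))
  L <- cfg$length
  y <- eval_bumps(cfg$wave_params[[class_name]], L)
  if (cfg$wander_amp > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    tt_sec <- (seq_len(L) - 1) / cfg$fs
    y <- y + cfg$wander_amp * sin(2 * pi * cfg$wander_freq * tt_sec + phase)
  }
  if (cfg$noise_sd > 0) y <- y + stats::rnorm(L, 0, cfg$noise_sd)
  y
}

#' Generate a labelled synthetic beat dataset
#'
#' Produces `n_per_class` beats for every class in `cfg$classes`, in class
#' order, seeded by `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return a [beat_dataset()] with exactly `n_per_class` beats per class; the
#'   generating config and seed are recorded in `meta`.
#' @export
synth_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n_total <- cfg$n_per_class * length(cfg$classes)
  beats <- matrix(0, n_total, cfg$length)
  labels <- character(n_total)
  row <- 1L
  for (cl in cfg$classes) {
    for (i in seq_len(cfg$n_per_class)) {
      beats[row, ] <- synth_beat(cl, cfg)
      labels[row] <- cl
      row <- row + 1L
    }
  }
  beat_dataset(beats, labels, class_names = cfg$classes,
               source_ids = "synthetic", fs = cfg$fs, lead = "synthetic",
               meta = list(generator = "synth_dataset", seed = cfg$seed,
                           noise_sd = cfg$noise_sd, wander_amp = cfg$wander_amp,
                           wander_freq = cfg$wander_freq))
}

#' Nearest-template classification by maximum correlation
#'
#' A deliberately simple reference classifier: each beat is assigned to the
#' class whose noiseless template has the highest Pearson correlation with
#' it. Used to check that generated classes are separable.
#'
#' @param beats matrix of beats (N x L) or a [beat_dataset()].
#' @param cfg the [synth_config()] whose templates to match against.
#' @return factor of predicted class labels.
#' @export
template_classify <- function(beats, cfg) {
  if (inherits(beats, "beat_dataset")) beats <- beats$beats
  tpl <- class_templates(cfg)
  cors <- stats::cor(t(beats), t(tpl))   # N x K
  factor(cfg$classes[max.col(cors, ties.method = "first")], levels = cfg$classes)
}
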