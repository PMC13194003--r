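test_that("WFDB fixture round-trips signals and annotations", {
  fx <- toy_wfdb_record()
  rd <- read_wfdb_record(fx$record, lead = "V5")
  # quantisation error bounded by half an ADC step
  expect_lt(max(abs(rd$signal - fx$signals[, 2])), 1 / (2 * 200) + 1e-12)
  expect_equal(rd$fs, 360)
  expect_equal(rd$annotations$sample, fx$annotations$sample)
  expect_equal(rd$annotations$symbol, fx$annotations$symbol)
})

test_that("lead selection picks the requested channel and errors helpfully", {
  fx <- toy_wfdb_record()
  r1 <- read_wfdb_record(fx$record, lead = "MLII")
  r2 <- read_wfdb_record(fx$record, lead = "V5")
  expect_false(isTRUE(all.equal(r1$signal, r2$signal)))
  expect_error(read_wfdb_record(fx$record, lead = "aVR"),
               "available leads: MLII, V5")
})

test_that("long annotation gaps survive via SKIP pseudo-annotations", {
  dir <- withr::local_tempdir()
  sig <- matrix(sin(seq(0, 100, length.out = 9000)), ncol = 1)
  ann <- data.frame(sample = c(50, 8200), symbol = c("N", "V"))
  rec <- write_wfdb_record(dir, "gap", sig, 360, "MLII", ann)
  rd <- read_wfdb_record(rec)
  expect_equal(rd$annotations$sample, c(50, 8200))
})

test_that("format-212 signal files decode 12-bit packed samples", {
  dir <- withr::local_tempdir()
  # hand-packed triplets for samples 100, -200, 300, 5 (12-bit two's compl.)
  adc <- c(100L, -200L, 300L, 5L)
  enc <- function(s1, s2) {
    u1 <- ifelse(s1 < 0, s1 + 4096L, s1)
    u2 <- ifelse(s2 < 0, s2 + 4096L, s2)
    as.raw(c(bitwAnd(u1, 255L),
             bitwOr(bitwAnd(u1 %/% 256L, 15L), bitwAnd(u2 %/% 256L, 15L) * 16L),
             bitwAnd(u2, 255L)))
  }
  writeBin(c(enc(100L, -200L), enc(300L, 5L)), file.path(dir, "p212.dat"))
  writeLines(c("p212 1 360 4", "p212.dat 212 200(0)/mV 12 0 0 0 0 MLII"),
             file.path(dir, "p212.hea"))
  rd <- read_wfdb_record(file.path(dir, "p212"), annotator = NULL)
  expect_equal(rd$signal, adc / 200)
  expect_equal(rd$lead, "MLII")
})

test_that("AAMI symbol mapping follows the published tables", {
  am <- aami_map("mitbih")
  expect_equal(map_symbol(c("N", "L", "R", "e", "j"), am), rep("N", 5))
  expect_equal(map_symbol(c("A", "a", "J", "S"), am), rep("S", 4))
  expect_equal(map_symbol(c("V", "E"), am), rep("V", 2))
  expect_equal(map_symbol("F", am), "F")
  expect_equal(map_symbol(c("/", "f", "Q"), am), rep("Q", 3))
  expect_equal(map_symbol("+", am), "EXCLUDED")   # rhythm-change marker
  expect_equal(map_symbol("~", am), "EXCLUDED")
  ai <- aami_map("incart")
  expect_equal(map_symbol(c("n", "B"), ai), rep("N", 2))
  expect_equal(map_symbol("F", ai), "EXCLUDED")   # no fusion class on INCART
})

test_that("segmentation windows, edge rule and conservation hold", {
  am <- aami_map("mitbih")
  sig <- stats::rnorm(128)
  ann <- data.frame(sample = 64, symbol = "N")
  ds <- segment_beats(sig, ann, am, L = 128, normalize = FALSE)
  expect_equal(as.vector(ds$beats[1, ]), sig)          # boundary-exact window

  sig2 <- stats::rnorm(400)
  ann2 <- data.frame(sample = c(10, 200, 395, 250, 260),
                     symbol = c("N", "V", "N", "+", "A"))
  ds2 <- segment_beats(sig2, ann2, am, L = 128)
  expect_equal(nrow(ds2$beats), 2L)                    # samples 200 and 260 fit
  expect_equal(ds2$meta$skipped_edge, 2L)              # samples 10 and 395
  expect_equal(ds2$meta$excluded, 1L)                  # the '+' marker
  expect_equal(nrow(ds2$beats) + ds2$meta$skipped_edge + ds2$meta$excluded,
               nrow(ann2))
  expect_equal(ncol(ds2$beats), 128L)
  # z-score invariants
  expect_lt(max(abs(rowMeans(ds2$beats))), 1e-6)
  expect_lt(max(abs(apply(ds2$beats, 1, stats::sd) - 1)), 1e-6)
})

test_that("constant windows z-score to all-zero beats", {
  am <- aami_map("mitbih")
  ds <- segment_beats(rep(2.5, 200), data.frame(sample = 100, symbol = "N"), am)
  expect_true(all(ds$beats == 0))
  expect_true(all(is.finite(ds$beats)))
})

test_that("segmentation with no usable beats raises", {
  am <- aami_map("mitbih")
  expect_error(
    segment_beats(stats::rnorm(200), data.frame(sample = 100, symbol = "+"), am),
    "no mappable beats")
  expect_error(segment_beats(stats::rnorm(200),
                             data.frame(sample = 100, symbol = "N"),
                             am, L = 127), "even")
})

test_that("class counts sum to the number of beats", {
  ds <- synth_dataset(synth_config(n_per_class = 7L))
  expect_equal(sum(class_counts(ds)), nrow(ds$beats))
})

test_that("task relabelling follows the class-set rules", {
  mk <- function(labs) beat_dataset(matrix(0, length(labs), 8),
                                    labs, c("N", "S", "V", "F", "Q"))
  d1 <- relabel_task(mk(c("N", "Q", "V")), "mitbih-4class")
  expect_equal(as.character(d1$labels), c("N", "V"))
  expect_equal(d1$class_names, c("N", "S", "V", "F"))

  d2 <- relabel_task(mk(c("N", "S", "V")), "incart-binary")
  expect_equal(as.character(d2$labels), c("normal", "abnormal", "abnormal"))

  d3 <- relabel_task(mk(c("N", "S", "V", "Q")), "incart-3class")
  expect_equal(nrow(d3$beats), 3L)
  expect_equal(d3$class_names, c("N", "S", "V"))

  bad <- beat_dataset(matrix(0, 2, 8), c("a", "b"), c("a", "b"))
  expect_error(relabel_task(bad, "mitbih-4class"), "AAMI")
})

test_that("stratified folds are balanced, disjoint and reproducible", {
  labs <- factor(rep(c("N", "S", "V", "F"), each = 25))
  f <- make_folds(labs, k = 5, seed = 3)
  for (k in 1:5)
    expect_equal(unname(as.vector(table(labs[f$assignments == k]))), rep(5L, 4))
  expect_identical(f$assignments, make_folds(labs, k = 5, seed = 3)$assignments)
  expect_false(identical(f$assignments, make_folds(labs, k = 5, seed = 4)$assignments))
  # fold union is everything, folds are disjoint by construction of a partition
  expect_equal(sort(unique(f$assignments)), 1:5)
  expect_equal(length(f$assignments), length(labs))

  # 26 beats in one class: fold sizes 6,5,5,5,5 in some order
  f2 <- make_folds(factor(rep("N", 26)), k = 5, seed = 1)
  expect_equal(sort(as.vector(table(f2$assignments))), c(5L, 5L, 5L, 5L, 6L))

  expect_error(make_folds(factor(rep(c("N", "V"), c(20, 3))), k = 5),
               "fewer than k = 5 beats: V")
})

test_that("prepare_beats runs the read-segment-map pipeline over records", {
  dir <- withr::local_tempdir()
  t <- seq(0, 6, length.out = 2160)
  for (nm in c("r1", "r2"))
    write_wfdb_record(dir, nm, cbind(sin(2 * pi * t)), 360, "MLII",
                      data.frame(sample = c(10, 400, 900), symbol = c("N", "V", "N")))
  ds <- prepare_beats(file.path(dir, c("r1", "r2")), aami_map("mitbih"))
  expect_equal(nrow(ds$beats), 4L)           # one edge skip per record
  expect_equal(ds$meta$skipped_edge, 2L)
  expect_equal(sort(unique(ds$source_ids)), c("r1", "r2"))
  # denoised variant runs end to end as well
  ds2 <- prepare_beats(file.path(dir, "r1"), aami_map("mitbih"),
                       denoise = denoise_config())
  expect_equal(ncol(ds2$beats), 128L)
  expect_true(ds2$meta$denoised)
})
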