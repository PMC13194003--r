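# Shared fixtures: small architectures and datasets built in code, plus a
# lazily trained small classifier reused across test files.

tiny_cfg <- function(num_classes = 3L) {
  hpr_config(input_len = 32L, front_channels = 4L, kernel = 5L,
             reb_counts = c(2L, 1L),
             layer_channels = list(c(4L, 6L), c(6L, 8L)),
             layer_strides = c(1L, 2L), dropout_p = 0, num_classes = num_classes)
}

small_cfg <- function() {
  # 4-class model small enough to train in seconds on synthetic beats
  hpr_config(input_len = 128L, front_channels = 8L, kernel = 17L,
             reb_counts = rep(1L, 4L),
             layer_channels = list(c(8L, 12L), c(12L, 12L), c(12L, 16L),
                                   c(16L, 16L)),
             layer_strides = c(1L, 2L, 2L, 2L), dropout_p = 0.2,
             num_classes = 4L)
}

random_small_cfg <- function() {
  # randomized architecture for accounting property tests
  nl <- sample(1:3, 1)
  ch <- sample(c(2L, 3L, 4L, 6L), nl + 1, replace = TRUE)
  hpr_config(input_len = 32L, front_channels = ch[1],
             kernel = sample(c(3L, 5L, 7L), 1),
             reb_counts = sample(1:3, nl, replace = TRUE),
             layer_channels = lapply(seq_len(nl), function(l) ch[l:(l + 1)]),
             layer_strides = c(1L, rep(2L, nl - 1L)),
             num_classes = sample(2:5, 1))
}

.fixture_env <- new.env()

trained_small_model <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  sc <- synth_config(n_per_class = 100L, noise_sd = 0.1, seed = 0L)
  ds <- synth_dataset(sc)
  set.seed(7)
  m <- build_model(small_cfg())
  idx <- sample(nrow(ds$beats))
  fit <- train_fold(m, subset_beats(ds, idx[1:320]),
                    subset_beats(ds, idx[321:400]),
                    train_config(max_epochs = 6L, batch_size = 64L, seed = 1L))
  .fixture_env$fit <- list(fit = fit, dataset = ds, synth = sc,
                           val_idx = idx[321:400])
  .fixture_env$fit
}

toy_wfdb_record <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  t <- seq(0, 6, length.out = 2160)        # 6 s at 360 Hz
  sig <- cbind(sin(2 * pi * t) * 0.5, cos(2 * pi * t) * 0.5)
  ann <- data.frame(sample = c(10, 400, 900, 1500, 1504),
                    symbol = c("N", "N", "V", "A", "+"))
  rec <- write_wfdb_record(dir, "toy", sig, 360, c("MLII", "V5"), ann)
  list(record = rec, signals = sig, annotations = ann, fs = 360)
}
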