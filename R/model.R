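#' HPRNet architecture configuration
#'
#' Describes the hierarchical pyramidal residual network: a front-end
#' convolution with batch normalisation, nine residual layers (ResLayers)
#' each a cascade of residual extraction blocks (REBs), and a classifier head
#' (dropout, global average pooling, fully connected layer, softmax).
#'
#' Each REB has a pre-activation main branch (BN-ReLU-Conv, twice, kernel 17,
#' padding 8, no conv bias) and a skip branch. The first REB of each ResLayer
#' carries that layer's stride and channel change: its first conv maps
#' `c_in -> c_out` with the layer stride, and its skip branch is a strided
#' 1x1 convolution followed by a shape-preserving max pool (kernel 3, stride
#' 1, padding 1). The remaining REBs of a layer are stride-1, same-channel,
#' with a parameter-free skip (max pool only). The front-end convolution and
#' all REB convolutions carry no bias; the fully connected layer does.
#'
#' The default `num_classes` is 8, the head used throughout the complexity
#' accounting (it corresponds to classifying the eight representative MIT-BIH
#' beat types rather than the four merged AAMI groups); classification tasks
#' pass their own class count, e.g. 4 for the AAMI task.
#'
#' @param input_len samples per beat (default 128).
#' @param front_channels channels produced by the front-end conv (32).
#' @param kernel temporal kernel size of all large convs (odd; default 17).
#' @param reb_counts integer vector, REBs per ResLayer
#'   (default `c(3,4,4,4,4,4,4,4,3)`).
#' @param layer_channels list of `c(in, out)` channel pairs per ResLayer.
#' @param layer_strides stride of each ResLayer's first REB.
#' @param dropout_p classifier dropout probability.
#' @param num_classes size of the softmax output.
#' @return an object of class `hpr_config`.
#' @export
hpr_config <- function(input_len = 128L, front_channels = 32L, kernel = 17L,
                       reb_counts = c(3L, 4L, 4L, 4L, 4L, 4L, 4L, 4L, 3L),
                       layer_channels = NULL, layer_strides = NULL,
                       dropout_p = 0.5, num_classes = 8L) {
  if (is.null(layer_channels))
    layer_channels <- list(c(32L, 64L), c(64L, 64L), c(64L, 128L), c(128L, 128L),
                           c(128L, 256L), c(256L, 256L), c(256L, 512L),
                           c(512L, 512L), c(512L, 1024L))
  if (is.null(layer_strides))
    layer_strides <- c(1L, rep(2L, length(layer_channels) - 1L))
  if (kernel %% 2L != 1L) stop("kernel must be odd")
  nl <- length(reb_counts)
  if (length(layer_channels) != nl || length(layer_strides) != nl)
    stop("reb_counts, layer_channels and layer_strides must have equal length")
  if (any(reb_counts < 1L)) stop("all reb_counts must be >= 1")
  if (layer_channels[[1]][1] != front_channels)
    stop("first ResLayer input channels (", layer_channels[[1]][1],
         ") must equal front_channels (", front_channels, ")")
  for (l in seq_len(nl - 1L)) {
    if (layer_channels[[l]][2] != layer_channels[[l + 1L]][1])
      stop("channel schedule mismatch: ResLayer ", l - 1L, " outputs ",
           layer_channels[[l]][2], " channels but ResLayer ", l,
           " expects ", layer_channels[[l + 1L]][1])
  }
  structure(list(input_len = as.integer(input_len), input_channels = 1L,
                 front_channels = as.integer(front_channels),
                 kernel = as.integer(kernel),
                 padding = (as.integer(kernel) - 1L) %/% 2L,
                 reb_counts = as.integer(reb_counts),
                 layer_channels = lapply(layer_channels, as.integer),
                 layer_strides = as.integer(layer_strides),
                 dropout_p = dropout_p, num_classes = as.integer(num_classes),
                 skip_pool_kernel = 3L),
            class = "hpr_config")
}

layer_tags <- function(n_layers) {
  if (n_layers == 9L)
    c("ResLayer0", "ResLayer1", "ResLayer2", "ResLayer2_", "ResLayer3",
      "ResLayer3_", "ResLayer4", "ResLayer4_", "ResLayer5")
  else paste0("ResLayer", seq_len(n_layers) - 1L)
}

new_reb <- function(c_in, c_out, k, stride, first) {
  list(bn1 = new_bn1d(c_in),
       conv1 = new_conv1d(c_in, c_out, k, stride = stride, bias = FALSE),
       bn2 = new_bn1d(c_out),
       conv2 = new_conv1d(c_out, c_out, k, stride = 1L, bias = FALSE),
       skip = if (first) new_conv1d(c_in, c_out, 1L, stride = stride,
                                    pad = 0L, bias = FALSE) else NULL)
}

#' Build an HPRNet model
#'
#' Instantiates the architecture described by a [hpr_config()] with random
#' (He) weight initialisation drawn from the current RNG state.
#'
#' @param cfg a [hpr_config()].
#' @return an object of class `hpr_model`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "hpr_config"))
  layers <- vector("list", length(cfg$reb_counts))
  for (l in seq_along(cfg$reb_counts)) {
    ch <- cfg$layer_channels[[l]]
    rebs <- vector("list", cfg$reb_counts[l])
    for (i in seq_len(cfg$reb_counts[l])) {
      first <- i == 1L
      rebs[[i]] <- new_reb(if (first) ch[1] else ch[2], ch[2], cfg$kernel,
                           if (first) cfg$layer_strides[l] else 1L, first)
    }
    layers[[l]] <- rebs
  }
  names(layers) <- layer_tags(length(layers))
  structure(list(cfg = cfg,
                 front = list(conv = new_conv1d(cfg$input_channels,
                                                cfg$front_channels, cfg$kernel,
                                                bias = FALSE),
                              bn = new_bn1d(cfg$front_channels)),
                 layers = layers,
                 fc = new_dense(cfg$layer_channels[[length(cfg$layer_channels)]][2],
                                cfg$num_classes, bias = TRUE)),
            class = "hpr_model")
}

#' @export
print.hpr_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<hpr_model> input 1x%d, %d ResLayers (REBs: %s), %d classes\n",
              cfg$input_len, length(cfg$reb_counts),
              paste(cfg$reb_counts, collapse = ","), cfg$num_classes))
  cat(sprintf("  parameters: %s (nonzero %s)\n",
              format(count_parameters(cfg), big.mark = ","),
              format(nonzero_count(x), big.mark = ",")))
  invisible(x)
}

reb_fwd <- function(reb, x, train) {
  c1 <- bn_fwd(reb$bn1, x, train); reb$bn1 <- c1$layer
  r1 <- relu_fwd(c1$y)
  c2 <- conv_fwd(reb$conv1, r1$y)
  c3 <- bn_fwd(reb$bn2, c2$y, train); reb$bn2 <- c3$layer
  r2 <- relu_fwd(c3$y)
  c4 <- conv_fwd(reb$conv2, r2$y)
  sk_in <- if (is.null(reb$skip)) list(y = x, x = NULL) else conv_fwd(reb$skip, x)
  pl <- pool3_fwd(sk_in$y)
  list(y = c4$y + pl$y, reb = reb,
       cache = list(bn1 = c1, relu1 = r1, conv1 = c2, bn2 = c3, relu2 = r2,
                    conv2 = c4, skip = sk_in, pool = pl))
}

reb_bwd <- function(reb, cache, dy, want_grads = TRUE) {
  # skip branch
  dsk <- pool3_bwd(cache$pool, dy)
  gskip <- NULL
  if (is.null(reb$skip)) {
    dx_skip <- dsk
  } else {
    bs <- conv_bwd(reb$skip, cache$skip, dsk, want_grads)
    dx_skip <- bs$dx; gskip <- bs$grads
  }
  # main branch
  b4 <- conv_bwd(reb$conv2, cache$conv2, dy, want_grads)
  dr2 <- relu_bwd(cache$relu2, b4$dx)
  b3 <- bn_bwd(reb$bn2, cache$bn2, dr2, want_grads)
  b2 <- conv_bwd(reb$conv1, cache$conv1, b3$dx, want_grads)
  dr1 <- relu_bwd(cache$relu1, b2$dx)
  b1 <- bn_bwd(reb$bn1, cache$bn1, dr1, want_grads)
  list(dx = b1$dx + dx_skip,
       grads = if (want_grads) list(bn1 = b1$grads, conv1 = b2$grads,
                                    bn2 = b3$grads, conv2 = b4$grads,
                                    skip = gskip) else NULL)
}

#' Forward pass
#'
#' @param model an [build_model()] result.
#' @param beats numeric matrix of beats (B x L), a single beat vector, or a
#'   [beat_dataset()].
#' @param train logical; training mode enables batch statistics and dropout.
#' @param keep_cache retain intermediate values for a subsequent backward
#'   pass.
#' @param collect character vector of ResLayer tags whose output activations
#'   to return (used by Grad-CAM).
#' @return list with `logits` (B x C), `probs` (B x C, softmax rows), the
#'   updated `model` (batch-norm running statistics move in training mode),
#'   and optionally `cache` / `acts`.
#' @export
forward_model <- function(model, beats, train = FALSE, keep_cache = FALSE,
                          collect = NULL) {
  stopifnot(inherits(model, "hpr_model"))
  if (inherits(beats, "beat_dataset")) beats <- beats$beats
  if (is.null(dim(beats))) beats <- matrix(beats, 1L)
  cfg <- model$cfg
  if (ncol(beats) != cfg$input_len)
    stop("input has ", ncol(beats), " samples; model expects L = ", cfg$input_len)
  B <- nrow(beats)
  x <- array(t(beats), c(1L, cfg$input_len, B))

  cache <- list()
  cf <- conv_fwd(model$front$conv, x)
  cb <- bn_fwd(model$front$bn, cf$y, train); model$front$bn <- cb$layer
  cr <- relu_fwd(cb$y)
  if (keep_cache) cache$front <- list(conv = cf, bn = cb, relu = cr)
  h <- cr$y

  acts <- list()
  cache$layers <- vector("list", length(model$layers))
  for (l in seq_along(model$layers)) {
    lcache <- vector("list", length(model$layers[[l]]))
    for (i in seq_along(model$layers[[l]])) {
      step <- reb_fwd(model$layers[[l]][[i]], h, train)
      model$layers[[l]][[i]] <- step$reb
      h <- step$y
      if (keep_cache) lcache[[i]] <- step$cache
    }
    if (keep_cache) cache$layers[[l]] <- lcache
    tag <- names(model$layers)[l]
    if (!is.null(collect) && tag %in% collect) acts[[tag]] <- h
  }

  dp <- dropout_fwd(h, cfg$dropout_p, train)
  gp <- gap_fwd(dp$y)
  fc <- dense_fwd(model$fc, gp$y)
  if (keep_cache) cache$head <- list(dropout = dp, gap = gp, fc = fc)

  logits <- t(fc$y)
  out <- list(logits = logits, probs = t(softmax_probs(fc$y)), model = model)
  if (keep_cache) out$cache <- cache
  if (length(acts)) out$acts <- acts
  out
}

# Backward pass from dlogits (B x C). stop_at: a ResLayer tag; when set the
# gradient flowing into that layer's *output* is returned and parameter
# gradients for earlier stages are not computed.
backward_model <- function(model, cache, dlogits, want_grads = TRUE,
                           stop_at = NULL) {
  dfc <- t(dlogits)
  bfc <- dense_bwd(model$fc, cache$head$fc, dfc, want_grads)
  dgap <- gap_bwd(cache$head$gap, bfc$dx)
  dh <- dropout_bwd(cache$head$dropout, dgap)

  grads <- list(fc = bfc$grads, layers = vector("list", length(model$layers)))
  for (l in rev(seq_along(model$layers))) {
    tag <- names(model$layers)[l]
    if (!is.null(stop_at) && tag == stop_at) {
      return(list(grads = grads, dact = dh, dact_tag = tag))
    }
    lgr <- vector("list", length(model$layers[[l]]))
    for (i in rev(seq_along(model$layers[[l]]))) {
      bb <- reb_bwd(model$layers[[l]][[i]], cache$layers[[l]][[i]], dh,
                    want_grads)
      dh <- bb$dx
      lgr[[i]] <- bb$grads
    }
    grads$layers[[l]] <- lgr
  }
  dr <- relu_bwd(cache$front$relu, dh)
  bb <- bn_bwd(model$front$bn, cache$front$bn, dr, want_grads)
  bc <- conv_bwd(model$front$conv, cache$front$conv, bb$dx, want_grads)
  grads$front <- list(conv = bc$grads, bn = bb$grads)
  list(grads = grads, dinput = bc$dx)
}

#' Predict class labels for a set of beats
#'
#' @param model a built (usually trained) `hpr_model`.
#' @param beats matrix B x L or [beat_dataset()].
#' @param class_names labels for the output factor; defaults to the column
#'   index as character.
#' @param batch_size evaluation minibatch size.
#' @return list with `labels` (factor) and `probs` (B x C matrix).
#' @export
predict_model <- function(model, beats, class_names = NULL, batch_size = 256L) {
  if (inherits(beats, "beat_dataset")) {
    if (is.null(class_names)) class_names <- beats$class_names
    beats <- beats$beats
  }
  if (is.null(class_names)) class_names <- as.character(seq_len(model$cfg$num_classes))
  n <- nrow(beats)
  probs <- matrix(0, n, model$cfg$num_classes)
  for (s in seq.int(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    probs[s:e, ] <- forward_model(model, beats[s:e, , drop = FALSE])$probs
  }
  labels <- factor(class_names[max.col(probs, ties.method = "first")],
                   levels = class_names)
  list(labels = labels, probs = probs)
}

#' Per-ResLayer output shapes
#'
#' Applies the stride arithmetic
#' `len_out = floor((len_in + 2*padding - kernel)/stride) + 1` through the
#' backbone.
#'
#' @param cfg a [hpr_config()].
#' @param input_len beat length; defaults to `cfg$input_len`.
#' @return data.frame with `stage`, `channels`, `length` for the front-end
#'   and every ResLayer.
#' @export
layer_output_shapes <- function(cfg, input_len = cfg$input_len) {
  stopifnot(inherits(cfg, "hpr_config"))
  len <- conv_out_len(input_len, cfg$kernel, 1L, cfg$padding)
  out <- data.frame(stage = "front", channels = cfg$front_channels,
                    length = len, stringsAsFactors = FALSE)
  tags <- layer_tags(length(cfg$reb_counts))
  for (l in seq_along(cfg$reb_counts)) {
    len <- conv_out_len(len, cfg$kernel, cfg$layer_strides[l], cfg$padding)
    out <- rbind(out, data.frame(stage = tags[l],
                                 channels = cfg$layer_channels[[l]][2],
                                 length = len, stringsAsFactors = FALSE))
  }
  out
}

#' Tensor table of an architecture
#'
#' Closed-form enumeration of every trainable tensor with its element count
#' and pruning-scope membership. `net` scope holds the front conv weight and
#' the fully connected weight; `blk` scope holds every REB convolution weight
#' (both main-branch convs and the first-REB 1x1 skip convs). Batch-norm
#' scale/shift and biases belong to no pruning scope.
#'
#' @param cfg a [hpr_config()].
#' @return data.frame with columns `name`, `numel`, `scope`
#'   (`"net"`, `"blk"` or `""`).
#' @export
model_tensor_table <- function(cfg) {
  stopifnot(inherits(cfg, "hpr_config"))
  k <- cfg$kernel
  rows <- list(
    list("front.conv.W", cfg$input_channels * cfg$front_channels * k, "net"),
    list("front.bn", 2L * cfg$front_channels, ""))
  tags <- layer_tags(length(cfg$reb_counts))
  for (l in seq_along(cfg$reb_counts)) {
    ch <- cfg$layer_channels[[l]]
    for (i in seq_len(cfg$reb_counts[l])) {
      ci <- if (i == 1L) ch[1] else ch[2]; co <- ch[2]
      p <- sprintf("%s.REB%d.", tags[l], i - 1L)
      rows <- c(rows, list(
        list(paste0(p, "bn1"), 2L * ci, ""),
        list(paste0(p, "conv1.W"), ci * co * k, "blk"),
        list(paste0(p, "bn2"), 2L * co, ""),
        list(paste0(p, "conv2.W"), co * co * k, "blk")))
      if (i == 1L)
        rows <- c(rows, list(list(paste0(p, "skip.W"), ci * co, "blk")))
    }
  }
  cf <- cfg$layer_channels[[length(cfg$layer_channels)]][2]
  rows <- c(rows, list(list("fc.W", cf * cfg$num_classes, "net"),
                       list("fc.b", cfg$num_classes, "")))
  data.frame(name = vapply(rows, `[[`, "", 1),
             numel = vapply(rows, function(r) as.numeric(r[[2]]), 0),
             scope = vapply(rows, `[[`, "", 3),
             stringsAsFactors = FALSE)
}

#' Closed-form trainable-parameter count
#'
#' Sums the tensor table; with a [prune_config()] the per-tensor pruned
#' amounts `round(ratio * numel)` are subtracted over the configured scope,
#' yielding the nonzero parameter count of the pruned model. Agrees exactly
#' with enumeration over a built model (see [nonzero_count()]).
#'
#' @param cfg a [hpr_config()].
#' @param prune optional [prune_config()].
#' @return parameter count (double, exact for counts below 2^53).
#' @export
count_parameters <- function(cfg, prune = NULL) {
  tab <- model_tensor_table(cfg)
  total <- sum(tab$numel)
  if (is.null(prune) || prune$scope == "none" || prune$ratio == 0) return(total)
  scopes <- switch(prune$scope,
                   network_level = "net", block_level = "blk",
                   mlpo = c("net", "blk"))
  sel <- tab$numel[tab$scope %in% scopes]
  total - sum(round(prune$ratio * sel))
}

#' FLOPs per single-beat inference
#'
#' Convolution cost is counted as `2 * c_in * c_out * k * len_out` (one
#' multiply plus one add per MAC), the fully connected layer as
#' `2 * n_in * n_out`; batch norm, pooling, activations and the softmax are
#' excluded. Reported in millions of floating-point operations (MFLOPs).
#' FLOP conventions differ across tools (MACs vs FLOPs, which ops count), so
#' treat cross-paper comparisons as order-of-magnitude only.
#'
#' @param cfg a [hpr_config()].
#' @param input_len beat length; defaults to `cfg$input_len`.
#' @return MFLOPs (double).
#' @export
count_flops <- function(cfg, input_len = cfg$input_len) {
  stopifnot(inherits(cfg, "hpr_config"))
  k <- cfg$kernel
  len <- conv_out_len(input_len, k, 1L, cfg$padding)
  fl <- 2 * cfg$input_channels * cfg$front_channels * k * len
  for (l in seq_along(cfg$reb_counts)) {
    ch <- cfg$layer_channels[[l]]
    len_out <- conv_out_len(len, k, cfg$layer_strides[l], cfg$padding)
    for (i in seq_len(cfg$reb_counts[l])) {
      ci <- if (i == 1L) ch[1] else ch[2]; co <- ch[2]
      fl <- fl + 2 * ci * co * k * len_out + 2 * co * co * k * len_out
      if (i == 1L) fl <- fl + 2 * ci * co * 1 * len_out
    }
    len <- len_out
  }
  cf <- cfg$layer_channels[[length(cfg$layer_channels)]][2]
  fl <- fl + 2 * cf * cfg$num_classes
  fl / 1e6
}
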