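# Minimal 1D conv-net engine: forward/backward passes expressed as BLAS matrix
# products (im2col convolution). Internal data layout is an array (C, L, B):
# channels x temporal length x batch, so that flattening to (C, L*B) keeps the
# channel axis contiguous for row-wise statistics.

new_conv1d <- function(c_in, c_out, k, stride = 1L, pad = (k - 1L) %/% 2L,
                       bias = FALSE) {
  # He initialisation for ReLU networks
  W <- matrix(stats::rnorm(c_out * c_in * k, 0, sqrt(2 / (c_in * k))),
              c_out, c_in * k)
  list(type = "conv1d", c_in = c_in, c_out = c_out, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       W = W, b = if (bias) numeric(c_out) else NULL, zidx = NULL)
}

conv_out_len <- function(len, k, stride, pad) {
  (len + 2L * pad - k) %/% stride + 1L
}

im2col <- function(x, k, stride, pad) {
  d <- dim(x)
  Lout <- conv_out_len(d[2], k, stride, pad)
  im2col_cpp(x, d[1], d[2], d[3], k, stride, pad, Lout)
}

col2im <- function(dcol, C, L, B, k, stride, pad) {
  Lout <- conv_out_len(L, k, stride, pad)
  col2im_cpp(dcol, C, L, B, k, stride, pad, Lout)
}

conv_fwd <- function(ly, x) {
  d <- dim(x)
  Lout <- conv_out_len(d[2], ly$k, ly$stride, ly$pad)
  Xc <- im2col(x, ly$k, ly$stride, ly$pad)
  Y <- ly$W %*% Xc
  if (!is.null(ly$b)) Y <- Y + ly$b
  dim(Y) <- c(ly$c_out, Lout, d[3])
  list(y = Y, x = x)
}

conv_bwd <- function(ly, cache, dy, want_grads = TRUE) {
  x <- cache$x; d <- dim(x)
  dym <- dy; dim(dym) <- c(ly$c_out, length(dy) / ly$c_out)
  g <- NULL
  if (want_grads) {
    Xc <- im2col(x, ly$k, ly$stride, ly$pad)
    dW <- tcrossprod(dym, Xc)
    if (!is.null(ly$zidx)) dW[ly$zidx] <- 0   # frozen pruned positions
    g <- list(W = dW, b = if (!is.null(ly$b)) rowSums(dym) else NULL)
  }
  dXc <- crossprod(ly$W, dym)
  dx <- col2im(dXc, d[1], d[2], d[3], ly$k, ly$stride, ly$pad)
  list(dx = dx, grads = g)
}

new_bn1d <- function(c) {
  list(type = "bn1d", c = c, gamma = rep(1, c), beta = numeric(c),
       rmean = numeric(c), rvar = rep(1, c), momentum = 0.1, eps = 1e-5)
}

bn_fwd <- function(ly, x, train) {
  d <- dim(x); n <- d[2] * d[3]
  xm <- x; dim(xm) <- c(d[1], n)
  if (train && n > 1L) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    v[v < 0] <- 0
    invstd <- 1 / sqrt(v + ly$eps)
    xhat <- (xm - mu) * invstd
    ly$rmean <- (1 - ly$momentum) * ly$rmean + ly$momentum * mu
    ly$rvar <- (1 - ly$momentum) * ly$rvar + ly$momentum * v * n / max(n - 1, 1)
  } else {
    invstd <- 1 / sqrt(ly$rvar + ly$eps)
    xhat <- (xm - ly$rmean) * invstd
  }
  y <- ly$gamma * xhat + ly$beta
  dim(y) <- d
  list(y = y, layer = ly, xhat = xhat, invstd = invstd, train = train && n > 1L)
}

bn_bwd <- function(ly, cache, dy, want_grads = TRUE) {
  d <- dim(dy); n <- d[2] * d[3]
  dym <- dy; dim(dym) <- c(d[1], n)
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  if (cache$train) {
    dx <- (ly$gamma * cache$invstd / n) *
      (n * dym - dbeta - cache$xhat * dgamma)
  } else {
    dx <- ly$gamma * cache$invstd * dym
  }
  dim(dx) <- d
  list(dx = dx,
       grads = if (want_grads) list(gamma = dgamma, beta = dbeta) else NULL)
}

relu_fwd <- function(x) {
  y <- x; y[y < 0] <- 0
  list(y = y)
}

relu_bwd <- function(cache, dy) {
  dy * (cache$y > 0)
}

# shape-preserving max pool, kernel 3 / stride 1 / pad 1
pool3_fwd <- function(x) {
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  xp <- array(-Inf, c(C, L + 2L, B))
  xp[, 2:(L + 1L), ] <- x
  y <- pmax(xp[, 1:L, , drop = FALSE],
            xp[, 2:(L + 1L), , drop = FALSE],
            xp[, 3:(L + 2L), , drop = FALSE])
  list(y = y, xp = xp)
}

pool3_bwd <- function(cache, dy) {
  d <- dim(dy); C <- d[1]; L <- d[2]; B <- d[3]
  xp <- cache$xp
  ymax <- pmax(xp[, 1:L, , drop = FALSE], xp[, 2:(L + 1L), , drop = FALSE],
               xp[, 3:(L + 2L), , drop = FALSE])
  dxp <- array(0, c(C, L + 2L, B))
  taken <- array(FALSE, d)
  for (j in 0:2) {                       # ties go to the leftmost position
    sl <- xp[, (1 + j):(L + j), , drop = FALSE]
    m <- (sl == ymax) & !taken
    taken <- taken | m
    dxp[, (1 + j):(L + j), ] <- dxp[, (1 + j):(L + j), , drop = FALSE] + dy * m
  }
  dxp[, 2:(L + 1L), , drop = FALSE]
}

gap_fwd <- function(x) {
  d <- dim(x)
  y <- colMeans(aperm(x, c(2, 1, 3)))       # (C, B)
  if (is.null(dim(y))) y <- matrix(y, d[1], d[3])
  list(y = y, L = d[2])
}

gap_bwd <- function(cache, dy) {
  C <- nrow(dy); B <- ncol(dy); L <- cache$L
  dx <- array(0, c(C, L, B))                 # spread dy/L over the temporal axis
  for (t in seq_len(L)) dx[, t, ] <- dy / L
  dx
}

new_dense <- function(n_in, n_out, bias = TRUE) {
  W <- matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in)
  list(type = "dense", n_in = n_in, n_out = n_out, W = W,
       b = if (bias) numeric(n_out) else NULL, zidx = NULL)
}

dense_fwd <- function(ly, x) {
  y <- ly$W %*% x
  if (!is.null(ly$b)) y <- y + ly$b
  list(y = y, x = x)
}

dense_bwd <- function(ly, cache, dy, want_grads = TRUE) {
  g <- NULL
  if (want_grads) {
    dW <- tcrossprod(dy, cache$x)
    if (!is.null(ly$zidx)) dW[ly$zidx] <- 0
    g <- list(W = dW, b = if (!is.null(ly$b)) rowSums(dy) else NULL)
  }
  list(dx = crossprod(ly$W, dy), grads = g)
}

dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(y = x, mask = NULL))
  mask <- (stats::runif(length(x)) >= p) / (1 - p)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(cache, dy) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

# categorical cross-entropy on logits (C, B); labels are 1-based integers
softmax_probs <- function(logits) {
  z <- logits - apply(logits, 2, max)[col(logits)]
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

ce_loss_grad <- function(logits, labels) {
  p <- softmax_probs(logits)
  B <- ncol(logits)
  picked <- p[cbind(labels, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dl <- p
  dl[cbind(labels, seq_len(B))] <- dl[cbind(labels, seq_len(B))] - 1
  list(loss = loss, probs = p, dlogits = dl / B)
}
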