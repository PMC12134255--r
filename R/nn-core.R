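# Minimal deterministic NN core: explicit forward/backward primitives over
# (H, W, C, N) arrays and (T, D) token matrices, plus Adam. Heavy gathers run
# through the C++ im2col/maxpool kernels; all GEMMs go through BLAS.

conv_out_dim <- function(n, k, stride, pad) (n + 2 * pad - k) %/% stride + 1L

# 2-D convolution; x is (H, W, Cin, N), W is (k, k, Cin, Cout). The heavy
# im2col + GEMM work happens in C++ against persistent workspaces; backward
# recomputes im2col from the cached input rather than caching the (much
# larger) column matrix.
conv_fwd <- function(x, W, b, stride = 1L, pad = 1L) {
  list(out = cpp_conv_fwd(x, W, b, stride, pad),
       cache = list(x = x, stride = stride, pad = pad))
}

conv_bwd <- function(dout, cache, W) {
  cpp_conv_bwd(cache$x, W, dout, cache$stride, cache$pad)
}

maxpool_fwd <- function(x, k, stride, pad = 0L) {
  r <- cpp_maxpool(x, k, stride, pad)
  list(out = r$out, cache = list(argmax = r$argmax, xdim = dim(x)))
}

maxpool_bwd <- function(dout, cache) {
  d <- cache$xdim
  cpp_maxpool_bwd(dout, cache$argmax, d[1], d[2], d[3], d[4])
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dout, cache) dout * cache

gelu_fwd <- function(x) list(out = x * stats::pnorm(x), cache = x)
gelu_bwd <- function(dout, cache)
  dout * (stats::pnorm(cache) + cache * stats::dnorm(cache))

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
}

upsample2_bwd <- function(dout) {
  d <- dim(dout)
  o1 <- seq(1, d[1], by = 2); o2 <- seq(2, d[1], by = 2)
  p1 <- seq(1, d[2], by = 2); p2 <- seq(2, d[2], by = 2)
  dout[o1, p1, , , drop = FALSE] + dout[o1, p2, , , drop = FALSE] +
    dout[o2, p1, , , drop = FALSE] + dout[o2, p2, , , drop = FALSE]
}

# token-matrix linear layer: X (T, Din) %*% W (Din, Dout) + b
linear_fwd <- function(X, W, b) list(out = X %*% W + rep(b, each = nrow(X)),
                                     cache = X)
linear_bwd <- function(dout, cache, W) {
  list(dx = dout %*% t(W), dW = t(cache) %*% dout, db = colSums(dout))
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  list(out = xhat * rep(g, each = nrow(X)) + rep(b, each = nrow(X)),
       cache = list(xhat = xhat, istd = istd, g = g))
}

layernorm_bwd <- function(dout, cache) {
  xhat <- cache$xhat; istd <- cache$istd; D <- ncol(dout)
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- dout * rep(cache$g, each = nrow(dout))
  dx <- istd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

softmax_rows <- function(X) {
  m <- apply(X, 1L, max)
  e <- exp(X - m)
  e / rowSums(e)
}

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = NULL))
  keep <- array(runif(length(x)) >= p, dim2(x))
  list(out = x * keep / (1 - p), cache = list(keep = keep, p = p))
}
dropout_bwd <- function(dout, cache) {
  if (is.null(cache)) return(dout)
  dout * cache$keep / (1 - cache$p)
}

# initializers ---------------------------------------------------------------

he_conv <- function(k, cin, cout)
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))), c(k, k, cin, cout))

glorot <- function(din, dout)
  matrix(runif(din * dout, -sqrt(6 / (din + dout)), sqrt(6 / (din + dout))),
         din, dout)

zeros_like <- function(p) if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p))

# Adam -----------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, zeros_like), v = lapply(params, zeros_like), t = 0L)
}

#' @noRd
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      decay_filter = NULL) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0 && (is.null(decay_filter) || decay_filter(nm)))
      g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# accumulate gradient lists (named, possibly missing entries)
acc_grads <- function(total, g) {
  for (nm in names(g)) {
    total[[nm]] <- if (is.null(total[[nm]])) g[[nm]] else total[[nm]] + g[[nm]]
  }
  total
}
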