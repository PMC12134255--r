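# Compact vision transformer with wavelet position embedding (WPE).
# Pipeline: conv tokenizer (3 blocks of conv/ReLU/maxpool) -> token grid ->
# WPE (Haar DWT -> linear scale field -> depthwise conv -> sin/cos gating ->
# residual add) -> pre-norm transformer encoder -> sequence pooling -> linear
# classifier. Everything is written as explicit forward/backward passes so
# training, Grad-CAM and the deterministic-inference contract need no
# external framework.

#' EVT architecture configuration
#'
#' The tokenizer always has three convolution blocks (conv 3x3 stride 1 pad 1,
#' ReLU, maxpool 3x3 stride 2 pad 1); channel widths run
#' `3 -> tokenizer_channels[1] -> tokenizer_channels[2] -> embed_dim`.
#'
#' @param embed_dim token embedding width (divisible by `attention_heads`).
#' @param tokenizer_channels widths of the first two tokenizer blocks.
#' @param encoder_layers transformer encoder depth.
#' @param attention_heads number of attention heads.
#' @param mlp_ratio MLP hidden width as a multiple of `embed_dim`.
#' @param n_classes output classes (2: benign/malignant).
#' @param dropout dropout probability in the encoder (training only).
#' @param wpe_enabled include the wavelet position embedding?
#' @param wavelet wavelet family; only `"haar"` is implemented.
#' @return object of class `evt_config`.
#' @export
evt_config <- function(embed_dim = 256, tokenizer_channels = c(64, 128),
                       encoder_layers = 7, attention_heads = 4,
                       mlp_ratio = 2, n_classes = 2, dropout = 0.1,
                       wpe_enabled = TRUE, wavelet = "haar") {
  if (embed_dim %% attention_heads != 0)
    stopf("embed_dim must be divisible by attention_heads")
  if (!identical(tolower(wavelet), "haar")) stopf("only the Haar wavelet is implemented")
  structure(list(embed_dim = embed_dim, tokenizer_channels = tokenizer_channels,
                 tokenizer_blocks = 3L, conv_kernel = 3L, pool_kernel = 3L,
                 pool_stride = 2L, encoder_layers = encoder_layers,
                 attention_heads = attention_heads, mlp_ratio = mlp_ratio,
                 n_classes = n_classes, dropout = dropout,
                 wpe_enabled = wpe_enabled, wavelet = "haar",
                 flatten_order = "row-major"),
            class = "evt_config")
}

#' Classifier training configuration
#'
#' Defaults are the reference hyperparameters: 100 epochs, 5 warmup steps,
#' batch size 2, initial learning rate 0.001, L2 regularization 1e-4, Adam.
#'
#' @param epochs total training epochs.
#' @param warmup linear warmup epochs (< epochs); the rate reaches
#'   `initial_lr` at epoch `warmup` and then follows cosine decay to 0.
#' @param batch_size samples per training iteration.
#' @param initial_lr peak Adam learning rate.
#' @param weight_decay L2 regularization factor (applied to weight matrices).
#' @param seed RNG seed for all training randomness.
#' @return object of class `cls_train_config`.
#' @export
cls_train_config <- function(epochs = 100, warmup = 5, batch_size = 2,
                             initial_lr = 0.001, weight_decay = 1e-4,
                             seed = 42) {
  stopifnot(warmup < epochs, epochs > 0, batch_size > 0, initial_lr > 0,
            weight_decay >= 0)
  structure(list(epochs = epochs, warmup = warmup, batch_size = batch_size,
                 initial_lr = initial_lr, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "cls_train_config")
}

#' Warmup + cosine learning-rate schedule
#'
#' Linear warmup to `initial_lr` reached exactly at epoch `warmup`, then
#' cosine decay to 0 at `epochs`.
#'
#' @param epoch zero-based epoch index.
#' @param epochs total epochs.
#' @param warmup warmup epochs.
#' @param initial_lr peak rate.
#' @return learning rate.
#' @export
warmup_cosine_lr <- function(epoch, epochs = 100, warmup = 5,
                             initial_lr = 0.001) {
  if (epoch < warmup) return(initial_lr * (epoch + 1) / (warmup + 1))
  initial_lr * 0.5 * (1 + cos(pi * (epoch - warmup) / (epochs - warmup)))
}

#' Build an EVT model with freshly initialized weights
#'
#' WPE parameters are always allocated; `config$wpe_enabled` only gates their
#' use, so the same weights can be run with and without the embedding
#' (ablation wiring).
#'
#' @param config an [evt_config()].
#' @param seed seed for weight initialization.
#' @return object of class `evt` (config + named parameter list).
#' @export
build_evt <- function(config = evt_config(), seed = 42) {
  stopifnot(inherits(config, "evt_config"))
  D <- config$embed_dim
  tc <- c(config$tokenizer_channels, D)
  params <- list()
  with_seed(seed, {
    cin <- 3L
    for (b in 1:3) {
      params[[sprintf("tok%d.W", b)]] <- he_conv(3, cin, tc[b])
      params[[sprintf("tok%d.b", b)]] <- numeric(tc[b])
      cin <- tc[b]
    }
    params[["wpe.lin.W"]] <- glorot(4L * D, D) * 0.1
    params[["wpe.lin.b"]] <- numeric(D)
    params[["wpe.dw.W"]] <- array(rnorm(9 * D, 0, 0.05), c(3, 3, D))
    params[["wpe.dw.b"]] <- numeric(D)
    for (l in seq_len(config$encoder_layers)) {
      pre <- sprintf("enc%d.", l)
      params[[paste0(pre, "ln1.g")]] <- rep(1, D)
      params[[paste0(pre, "ln1.b")]] <- numeric(D)
      for (nm in c("Wq", "Wk", "Wv", "Wo")) {
        params[[paste0(pre, nm)]] <- glorot(D, D)
        params[[paste0(pre, sub("W", "b", nm))]] <- numeric(D)
      }
      params[[paste0(pre, "ln2.g")]] <- rep(1, D)
      params[[paste0(pre, "ln2.b")]] <- numeric(D)
      params[[paste0(pre, "W1")]] <- glorot(D, config$mlp_ratio * D)
      params[[paste0(pre, "b1")]] <- numeric(config$mlp_ratio * D)
      params[[paste0(pre, "W2")]] <- glorot(config$mlp_ratio * D, D)
      params[[paste0(pre, "b2")]] <- numeric(D)
    }
    params[["final.ln.g"]] <- rep(1, D)
    params[["final.ln.b"]] <- numeric(D)
    params[["pool.u"]] <- glorot(D, 1L)
    params[["pool.b"]] <- numeric(1)
    params[["head.W"]] <- glorot(D, config$n_classes)
    params[["head.b"]] <- numeric(config$n_classes)
  })
  structure(list(config = config, params = params, seed = seed,
                 classes = c("benign", "malignant")),
            class = "evt")
}

#' Zero all wavelet-position-embedding weights of a model
#'
#' With all-zero WPE parameters the embedding contributes exactly nothing, so
#' the network output is bit-identical to the same weights run with
#' `wpe_enabled = FALSE` (identity limit).
#'
#' @param model an `evt` model.
#' @return the model with zeroed WPE parameters.
#' @export
zero_wpe <- function(model) {
  for (nm in grep("^wpe\\.", names(model$params), value = TRUE))
    model$params[[nm]] <- zeros_like(model$params[[nm]])
  model
}

# tokens (row-major flatten) <-> grid (gh, gw, D)
grid_to_tokens <- function(G) {
  d <- dim(G)
  matrix(aperm(G, c(2, 1, 3)), d[1] * d[2], d[3])
}
tokens_to_grid <- function(tokens, gh, gw) {
  aperm(array(tokens, c(gw, gh, ncol(tokens))), c(2, 1, 3))
}

# accept either a 3 x H x W normalized array or an (H, W, 3) array
as_chw_input <- function(x) {
  d <- dim(x)
  if (length(d) != 3L) stopf("expected a 3-channel image array")
  if (d[1] == 3L) return(x)
  if (d[3] == 3L) return(aperm(x, c(3, 1, 2)))
  stopf("cannot identify the channel axis of input dims [%s]",
        paste(d, collapse = ","))
}

#' Tokenize a normalized image into a token grid
#'
#' Three blocks of (3x3 conv stride 1 pad 1, ReLU, 3x3 maxpool stride 2
#' pad 1); each block halves the resolution, so H x W inputs give an
#' (H/8) x (W/8) token lattice, flattened row-major.
#'
#' @param model an `evt` model.
#' @param x normalized input, 3 x H x W (H, W divisible by 32).
#' @return list with `tokens` (T x embed_dim matrix), `grid_h`, `grid_w`.
#' @export
tokenize <- function(model, x) {
  f <- tokenizer_fwd(model$params, as_chw_input(x))
  list(tokens = f$tokens, grid_h = f$gh, grid_w = f$gw)
}

tokenizer_fwd <- function(params, xchw) {
  d <- dim(xchw)
  if (any(d[2:3] %% 32 != 0))
    stopf("input dims [%d x %d] must be divisible by 32; use resize_to_multiple()",
          d[2], d[3])
  h <- array(aperm(xchw, c(2, 3, 1)), c(d[2], d[3], 3, 1))
  caches <- list()
  acts <- list()
  for (b in 1:3) {
    cv <- conv_fwd(h, params[[sprintf("tok%d.W", b)]],
                   params[[sprintf("tok%d.b", b)]], 1L, 1L)
    rl <- relu_fwd(cv$out)
    mp <- maxpool_fwd(rl$out, 3L, 2L, 1L)
    caches[[b]] <- list(conv = cv$cache, relu = rl$cache, pool = mp$cache)
    acts[[b]] <- list(conv = cv$out, relu = rl$out, pool = mp$out)
    h <- mp$out
  }
  gh <- dim(h)[1]; gw <- dim(h)[2]
  G <- array(h, dim(h)[1:3])
  list(tokens = grid_to_tokens(G), gh = gh, gw = gw,
       caches = caches, acts = acts)
}

# dtok: gradient w.r.t. tokens; returns param grads and (optionally) grads of
# every tokenizer activation (for Grad-CAM)
tokenizer_bwd <- function(params, dtok, fw, want_act_grads = FALSE) {
  gh <- fw$gh; gw <- fw$gw
  dG <- tokens_to_grid(dtok, gh, gw)
  dh <- array(dG, c(gh, gw, dim(dG)[3], 1))
  grads <- list()
  act_grads <- if (want_act_grads) list() else NULL
  for (b in 3:1) {
    cache <- fw$caches[[b]]
    if (want_act_grads) act_grads[[paste0(b, ".pool")]] <- dh
    dr <- maxpool_bwd(dh, cache$pool)
    if (want_act_grads) act_grads[[paste0(b, ".relu")]] <- dr
    dc <- relu_bwd(dr, cache$relu)
    if (want_act_grads) act_grads[[paste0(b, ".conv")]] <- dc
    cb <- conv_bwd(dc, cache$conv, params[[sprintf("tok%d.W", b)]])
    grads[[sprintf("tok%d.W", b)]] <- cb$dW
    grads[[sprintf("tok%d.b", b)]] <- cb$db
    dh <- cb$dx
  }
  list(grads = grads, act_grads = act_grads, dx = dh)
}

# single-level orthonormal 2-D Haar DWT of a (gh, gw, D) grid (even dims)
haar_dwt2 <- function(G) {
  gh <- dim(G)[1]; gw <- dim(G)[2]
  oi <- seq(1, gh, 2); ei <- seq(2, gh, 2)
  oj <- seq(1, gw, 2); ej <- seq(2, gw, 2)
  a <- G[oi, oj, , drop = FALSE]; b <- G[oi, ej, , drop = FALSE]
  cc <- G[ei, oj, , drop = FALSE]; d <- G[ei, ej, , drop = FALSE]
  list(LL = (a + b + cc + d) / 2, LH = (a - b + cc - d) / 2,
       HL = (a + b - cc - d) / 2, HH = (a - b - cc + d) / 2)
}

# adjoint (= inverse, orthonormal) of haar_dwt2 applied to subband gradients
haar_dwt2_adj <- function(dsub, gh, gw) {
  da <- (dsub$LL + dsub$LH + dsub$HL + dsub$HH) / 2
  db <- (dsub$LL - dsub$LH + dsub$HL - dsub$HH) / 2
  dc <- (dsub$LL + dsub$LH - dsub$HL - dsub$HH) / 2
  dd <- (dsub$LL - dsub$LH - dsub$HL + dsub$HH) / 2
  dG <- array(0, c(gh, gw, dim(da)[3]))
  oi <- seq(1, gh, 2); ei <- seq(2, gh, 2)
  oj <- seq(1, gw, 2); ej <- seq(2, gw, 2)
  dG[oi, oj, ] <- da; dG[oi, ej, ] <- db
  dG[ei, oj, ] <- dc; dG[ei, ej, ] <- dd
  dG
}

# depthwise 3x3 convolution (zero padding) of a (gh, gw, D) grid
depthwise_fwd <- function(G, W, b) {
  gh <- dim(G)[1]; gw <- dim(G)[2]; D <- dim(G)[3]
  P <- array(0, c(gh + 2, gw + 2, D))
  P[2:(gh + 1), 2:(gw + 1), ] <- G
  out <- array(rep(b, each = gh * gw), c(gh, gw, D))
  for (dy in 1:3) for (dx in 1:3) {
    w <- rep(W[dy, dx, ], each = gh * gw)
    out <- out + P[(dy - 1) + seq_len(gh), (dx - 1) + seq_len(gw), , drop = FALSE] * w
  }
  out
}

depthwise_bwd <- function(dout, G, W) {
  gh <- dim(G)[1]; gw <- dim(G)[2]; D <- dim(G)[3]
  P <- array(0, c(gh + 2, gw + 2, D))
  P[2:(gh + 1), 2:(gw + 1), ] <- G
  dP <- array(0, c(gh + 2, gw + 2, D))
  dW <- array(0, c(3, 3, D))
  for (dy in 1:3) for (dx in 1:3) {
    sl <- P[(dy - 1) + seq_len(gh), (dx - 1) + seq_len(gw), , drop = FALSE]
    dW[dy, dx, ] <- colSums(matrix(sl * dout, gh * gw, D))
    w <- rep(W[dy, dx, ], each = gh * gw)
    dP[(dy - 1) + seq_len(gh), (dx - 1) + seq_len(gw), ] <-
      dP[(dy - 1) + seq_len(gh), (dx - 1) + seq_len(gw), , drop = FALSE] + dout * w
  }
  list(dx = dP[2:(gh + 1), 2:(gw + 1), , drop = FALSE],
       dW = dW, db = colSums(matrix(dout, gh * gw, D)))
}

#' Wavelet position embedding of a token grid
#'
#' The token sequence is (1) reshaped to its 2-D grid; (2) decomposed by a
#' single-level Haar DWT, and a learned linear map of the concatenated
#' subbands gives a per-position scale field, upsampled back to grid size;
#' (3) the grid is passed through a depthwise 3x3 convolution; (4) the scale
#' field is taken through sine and cosine; (5) the convolved grid is gated by
#' their sum; (6) the result is added residually to the input tokens. Shape
#' is preserved exactly, and all-zero WPE weights give the identity.
#'
#' @param model an `evt` model.
#' @param grid list with `tokens`, `grid_h`, `grid_w` (from [tokenize()]).
#' @return token grid of the same shape with the embedding added.
#' @export
wavelet_position_embedding <- function(model, grid) {
  f <- wpe_fwd(model$params, grid$tokens, grid$grid_h, grid$grid_w)
  list(tokens = f$out, grid_h = grid$grid_h, grid_w = grid$grid_w)
}

wpe_fwd <- function(params, tokens, gh, gw) {
  stopifnot(gh >= 2, gw >= 2, gh %% 2 == 0, gw %% 2 == 0)
  D <- ncol(tokens)
  G <- tokens_to_grid(tokens, gh, gw)
  sub <- haar_dwt2(G)
  submat <- cbind(matrix(sub$LL, ncol = D), matrix(sub$LH, ncol = D),
                  matrix(sub$HL, ncol = D), matrix(sub$HH, ncol = D))
  slow_mat <- submat %*% params$wpe.lin.W +
    rep(params$wpe.lin.b, each = nrow(submat))
  slow <- array(slow_mat, c(gh / 2, gw / 2, D))
  s <- slow[rep(seq_len(gh / 2), each = 2), rep(seq_len(gw / 2), each = 2), ,
            drop = FALSE]
  cv <- depthwise_fwd(G, params$wpe.dw.W, params$wpe.dw.b)
  gate <- sin(s) + cos(s)
  e <- cv * gate
  out <- tokens + grid_to_tokens(e)
  list(out = out, cache = list(G = G, submat = submat, s = s, cv = cv,
                               gate = gate, gh = gh, gw = gw, D = D))
}

wpe_bwd <- function(params, dtokens, cache) {
  gh <- cache$gh; gw <- cache$gw; D <- cache$D
  de <- tokens_to_grid(dtokens, gh, gw)
  dcv <- de * cache$gate
  ds <- de * cache$cv * (cos(cache$s) - sin(cache$s))
  dw <- depthwise_bwd(dcv, cache$G, params$wpe.dw.W)
  # downsample ds by summing each 2x2 block
  oi <- seq(1, gh, 2); ei <- seq(2, gh, 2)
  oj <- seq(1, gw, 2); ej <- seq(2, gw, 2)
  dslow <- ds[oi, oj, , drop = FALSE] + ds[oi, ej, , drop = FALSE] +
    ds[ei, oj, , drop = FALSE] + ds[ei, ej, , drop = FALSE]
  dslow_mat <- matrix(dslow, ncol = D)
  dlinW <- t(cache$submat) %*% dslow_mat
  dlinb <- colSums(dslow_mat)
  dsubmat <- dslow_mat %*% t(params$wpe.lin.W)
  np <- nrow(dsubmat)
  sh <- c(gh / 2, gw / 2, D)
  dsub <- list(LL = array(dsubmat[, seq_len(D)], sh),
               LH = array(dsubmat[, D + seq_len(D)], sh),
               HL = array(dsubmat[, 2 * D + seq_len(D)], sh),
               HH = array(dsubmat[, 3 * D + seq_len(D)], sh))
  dG <- haar_dwt2_adj(dsub, gh, gw) + dw$dx
  dtok <- dtokens + grid_to_tokens(dG)
  list(dtokens = dtok,
       grads = list(wpe.lin.W = dlinW, wpe.lin.b = dlinb,
                    wpe.dw.W = dw$dW, wpe.dw.b = dw$db))
}

# one pre-norm encoder layer, single sample -----------------------------------

attn_fwd <- function(params, pre, X, heads, dropout, training) {
  D <- ncol(X)
  dh <- D %/% heads
  ln <- layernorm_fwd(X, params[[paste0(pre, "ln1.g")]],
                      params[[paste0(pre, "ln1.b")]])
  Xn <- ln$out
  Q <- Xn %*% params[[paste0(pre, "Wq")]] + rep(params[[paste0(pre, "bq")]], each = nrow(X))
  K <- Xn %*% params[[paste0(pre, "Wk")]] + rep(params[[paste0(pre, "bk")]], each = nrow(X))
  V <- Xn %*% params[[paste0(pre, "Wv")]] + rep(params[[paste0(pre, "bv")]], each = nrow(X))
  A <- vector("list", heads)
  O <- matrix(0, nrow(X), D)
  for (h in seq_len(heads)) {
    ix <- (h - 1) * dh + seq_len(dh)
    S <- Q[, ix, drop = FALSE] %*% t(K[, ix, drop = FALSE]) / sqrt(dh)
    A[[h]] <- softmax_rows(S)
    O[, ix] <- A[[h]] %*% V[, ix, drop = FALSE]
  }
  proj <- O %*% params[[paste0(pre, "Wo")]] + rep(params[[paste0(pre, "bo")]], each = nrow(X))
  dp <- dropout_fwd(proj, dropout, training)
  list(out = X + dp$out,
       cache = list(ln = ln$cache, Xn = Xn, Q = Q, K = K, V = V, A = A,
                    O = O, dp = dp$cache, heads = heads, dh = dh))
}

attn_bwd <- function(params, pre, dout, cache) {
  heads <- cache$heads; dh <- cache$dh
  dproj <- dropout_bwd(dout, cache$dp)
  grads <- list()
  grads[[paste0(pre, "Wo")]] <- t(cache$O) %*% dproj
  grads[[paste0(pre, "bo")]] <- colSums(dproj)
  dO <- dproj %*% t(params[[paste0(pre, "Wo")]])
  dQ <- dK <- dV <- matrix(0, nrow(dout), ncol(dout))
  for (h in seq_len(heads)) {
    ix <- (h - 1) * dh + seq_len(dh)
    A <- cache$A[[h]]
    dOh <- dO[, ix, drop = FALSE]
    dV[, ix] <- t(A) %*% dOh
    dA <- dOh %*% t(cache$V[, ix, drop = FALSE])
    dS <- A * (dA - rowSums(dA * A))
    dQ[, ix] <- dS %*% cache$K[, ix, drop = FALSE] / sqrt(dh)
    dK[, ix] <- t(dS) %*% cache$Q[, ix, drop = FALSE] / sqrt(dh)
  }
  dXn <- dQ %*% t(params[[paste0(pre, "Wq")]]) +
    dK %*% t(params[[paste0(pre, "Wk")]]) +
    dV %*% t(params[[paste0(pre, "Wv")]])
  grads[[paste0(pre, "Wq")]] <- t(cache$Xn) %*% dQ
  grads[[paste0(pre, "bq")]] <- colSums(dQ)
  grads[[paste0(pre, "Wk")]] <- t(cache$Xn) %*% dK
  grads[[paste0(pre, "bk")]] <- colSums(dK)
  grads[[paste0(pre, "Wv")]] <- t(cache$Xn) %*% dV
  grads[[paste0(pre, "bv")]] <- colSums(dV)
  lb <- layernorm_bwd(dXn, cache$ln)
  grads[[paste0(pre, "ln1.g")]] <- lb$dg
  grads[[paste0(pre, "ln1.b")]] <- lb$db
  list(dx = dout + lb$dx, grads = grads)
}

mlp_fwd <- function(params, pre, X, dropout, training) {
  ln <- layernorm_fwd(X, params[[paste0(pre, "ln2.g")]],
                      params[[paste0(pre, "ln2.b")]])
  l1 <- linear_fwd(ln$out, params[[paste0(pre, "W1")]], params[[paste0(pre, "b1")]])
  g1 <- gelu_fwd(l1$out)
  l2 <- linear_fwd(g1$out, params[[paste0(pre, "W2")]], params[[paste0(pre, "b2")]])
  dp <- dropout_fwd(l2$out, dropout, training)
  list(out = X + dp$out,
       cache = list(ln = ln$cache, l1 = l1$cache, g1 = g1$cache,
                    l2 = l2$cache, dp = dp$cache))
}

mlp_bwd <- function(params, pre, dout, cache) {
  d2 <- dropout_bwd(dout, cache$dp)
  grads <- list()
  lb2 <- linear_bwd(d2, cache$l2, params[[paste0(pre, "W2")]])
  grads[[paste0(pre, "W2")]] <- lb2$dW
  grads[[paste0(pre, "b2")]] <- lb2$db
  dg1 <- gelu_bwd(lb2$dx, cache$g1)
  lb1 <- linear_bwd(dg1, cache$l1, params[[paste0(pre, "W1")]])
  grads[[paste0(pre, "W1")]] <- lb1$dW
  grads[[paste0(pre, "b1")]] <- lb1$db
  lnb <- layernorm_bwd(lb1$dx, cache$ln)
  grads[[paste0(pre, "ln2.g")]] <- lnb$dg
  grads[[paste0(pre, "ln2.b")]] <- lnb$db
  list(dx = dout + lnb$dx, grads = grads)
}

#' Transformer encoder over a token grid
#'
#' A stack of pre-norm blocks, `x <- x + MHA(LN(x)); x <- x + MLP(LN(x))`,
#' with GELU activations; shape is preserved for any layer count.
#'
#' @param model an `evt` model.
#' @param grid token grid (list with `tokens`, `grid_h`, `grid_w`).
#' @return token grid of identical shape.
#' @export
encoder <- function(model, grid) {
  X <- grid$tokens
  for (l in seq_len(model$config$encoder_layers)) {
    pre <- sprintf("enc%d.", l)
    X <- attn_fwd(model$params, pre, X, model$config$attention_heads, 0, FALSE)$out
    X <- mlp_fwd(model$params, pre, X, 0, FALSE)$out
  }
  list(tokens = X, grid_h = grid$grid_h, grid_w = grid$grid_w)
}

#' Attention-weighted sequence pooling
#'
#' Token weights are the softmax of a learned scalar projection; the output
#' is the weighted sum of tokens (one `embed_dim` vector).
#'
#' @param model an `evt` model.
#' @param tokens T x embed_dim matrix (>= 1 token).
#' @return embedding vector of length `embed_dim`.
#' @export
sequence_pool <- function(model, tokens) {
  stopifnot(nrow(tokens) >= 1)
  seqpool_fwd(model$params, tokens)$out
}

seqpool_fwd <- function(params, tokens) {
  z <- tokens %*% params$pool.u + params$pool.b
  w <- softmax_rows(t(z))          # 1 x T
  out <- as.numeric(w %*% tokens)
  list(out = out, cache = list(tokens = tokens, w = w))
}

seqpool_bwd <- function(params, dout, cache) {
  tokens <- cache$tokens; w <- as.numeric(cache$w)
  dw <- as.numeric(tokens %*% dout)            # T
  dz <- w * (dw - sum(dw * w))
  dtok <- outer(w, dout) + dz %*% t(params$pool.u)
  list(dtokens = dtok,
       grads = list(pool.u = t(tokens) %*% dz, pool.b = sum(dz)))
}

#' Linear classification head
#'
#' @param model an `evt` model.
#' @param embedding embed_dim vector from [sequence_pool()].
#' @return list with `logits` (length `n_classes`) and softmax `probs`.
#' @export
classify <- function(model, embedding) {
  logits <- as.numeric(embedding %*% model$params$head.W + model$params$head.b)
  e <- exp(logits - max(logits))
  list(logits = logits, probs = e / sum(e))
}

# full forward for one sample; training toggles dropout
evt_fwd <- function(model, xchw, training = FALSE) {
  cfg <- model$config
  tk <- tokenizer_fwd(model$params, xchw)
  tokens <- tk$tokens
  wcache <- NULL
  if (cfg$wpe_enabled) {
    wf <- wpe_fwd(model$params, tokens, tk$gh, tk$gw)
    tokens <- wf$out
    wcache <- wf$cache
  }
  ecaches <- vector("list", cfg$encoder_layers)
  X <- tokens
  for (l in seq_len(cfg$encoder_layers)) {
    pre <- sprintf("enc%d.", l)
    af <- attn_fwd(model$params, pre, X, cfg$attention_heads, cfg$dropout, training)
    mf <- mlp_fwd(model$params, pre, af$out, cfg$dropout, training)
    ecaches[[l]] <- list(attn = af$cache, mlp = mf$cache)
    X <- mf$out
  }
  fl <- layernorm_fwd(X, model$params$final.ln.g, model$params$final.ln.b)
  sp <- seqpool_fwd(model$params, fl$out)
  logits <- as.numeric(sp$out %*% model$params$head.W + model$params$head.b)
  e <- exp(logits - max(logits))
  list(logits = logits, probs = e / sum(e),
       cache = list(tk = tk, wpe = wcache, enc = ecaches, fl = fl$cache,
                    sp = sp$cache, emb = sp$out))
}

# backward from dlogits; returns grads (+ tokenizer activation grads on request)
evt_bwd <- function(model, dlogits, fw, want_act_grads = FALSE) {
  cfg <- model$config
  grads <- list()
  grads$head.W <- outer(fw$cache$emb, dlogits)
  grads$head.b <- dlogits
  demb <- as.numeric(model$params$head.W %*% dlogits)
  spb <- seqpool_bwd(model$params, demb, fw$cache$sp)
  grads <- acc_grads(grads, spb$grads)
  flb <- layernorm_bwd(spb$dtokens, fw$cache$fl)
  grads$final.ln.g <- flb$dg
  grads$final.ln.b <- flb$db
  dX <- flb$dx
  for (l in rev(seq_len(cfg$encoder_layers))) {
    pre <- sprintf("enc%d.", l)
    mb <- mlp_bwd(model$params, pre, dX, fw$cache$enc[[l]]$mlp)
    grads <- acc_grads(grads, mb$grads)
    ab <- attn_bwd(model$params, pre, mb$dx, fw$cache$enc[[l]]$attn)
    grads <- acc_grads(grads, ab$grads)
    dX <- ab$dx
  }
  if (cfg$wpe_enabled) {
    wb <- wpe_bwd(model$params, dX, fw$cache$wpe)
    grads <- acc_grads(grads, wb$grads)
    dX <- wb$dtokens
  }
  tb <- tokenizer_bwd(model$params, dX, fw$cache$tk, want_act_grads)
  grads <- acc_grads(grads, tb$grads)
  list(grads = grads, act_grads = tb$act_grads)
}

#' Forward-classify one image with an EVT model
#'
#' @param model an `evt` model.
#' @param image H x W x 3 array in \[0, 255\] (dims divisible by 32) or an
#'   already-normalized 3 x H x W array.
#' @return list with `label`, `probs` (named by class), `logits`.
#' @export
predict_class <- function(model, image) {
  x <- if (length(dim(image)) == 3L && dim(image)[3] == 3L &&
           max(image) > 4) normalize_for_classifier(image) else image
  fw <- evt_fwd(model, as_chw_input(unclass(x)), training = FALSE)
  probs <- setNames(fw$probs, model$classes)
  list(label = model$classes[which.max(fw$probs)], probs = probs,
       logits = fw$logits)
}

# read classification samples from a manifest: image column + label
load_cls_samples <- function(manifest) {
  m <- if (is.character(manifest)) read_manifest(manifest) else manifest
  if (is.null(m$label) || any(is.na(m$label) | m$label == ""))
    stopf("manifest row %s has no label",
          paste(which(is.na(m$label) | m$label == ""), collapse = ","))
  lapply(seq_len(nrow(m)), function(i) {
    img <- read_image(m$image[i])
    list(id = m$id[i], x = unclass(normalize_for_classifier(img)),
         label = m$label[i])
  })
}

#' Train an EVT classifier
#'
#' Adam with linear warmup to `initial_lr` followed by cosine decay, L2
#' weight decay on weight matrices, cross-entropy loss, and
#' best-by-validation-accuracy checkpointing. All randomness (shuffling,
#' dropout) derives from `train_config$seed`.
#'
#' @param train_manifest,val_manifest manifests (data.frame or CSV path) with
#'   `id,image,label` columns; labels must be `benign`/`malignant`.
#' @param config an [evt_config()].
#' @param train_config a [cls_train_config()].
#' @param verbose print per-epoch progress.
#' @return object of class `cls_fit`: `model` (best checkpoint),
#'   `final_model`, `history` data.frame
#'   (`epoch,lr,train_loss,train_acc,val_loss,val_acc`), `best_epoch`.
#' @export
train_classifier <- function(train_manifest, val_manifest,
                             config = evt_config(),
                             train_config = cls_train_config(),
                             verbose = FALSE) {
  tc <- train_config
  train <- load_cls_samples(train_manifest)
  val <- load_cls_samples(val_manifest)
  model <- build_evt(config, seed = tc$seed)
  classes <- model$classes
  ytr <- match(vapply(train, `[[`, character(1), "label"), classes)
  yva <- match(vapply(val, `[[`, character(1), "label"), classes)
  if (any(is.na(ytr)) || any(is.na(yva)))
    stopf("labels must be one of: %s", paste(classes, collapse = ", "))
  opt <- adam_init(model$params)
  decay_filter <- function(nm) grepl("\\.W$|W[qkvo12]$", nm)  # weight matrices only
  hist_rows <- vector("list", tc$epochs)
  best <- list(acc = -Inf, params = model$params, epoch = NA_integer_)
  eval_set <- function(samples, y) {
    loss <- 0; correct <- 0
    for (i in seq_along(samples)) {
      fw <- evt_fwd(model, samples[[i]]$x, training = FALSE)
      loss <- loss - log(max(fw$probs[y[i]], 1e-12))
      correct <- correct + (which.max(fw$probs) == y[i])
    }
    c(loss / length(samples), correct / length(samples))
  }
  with_seed(derive_seed(tc$seed, 555L), {
    for (epoch in seq_len(tc$epochs) - 1L) {
      lr <- warmup_cosine_lr(epoch, tc$epochs, tc$warmup, tc$initial_lr)
      ord <- sample.int(length(train))
      ep_loss <- 0; ep_correct <- 0
      for (bs in split(ord, ceiling(seq_along(ord) / tc$batch_size))) {
        grads <- list()
        for (i in bs) {
          fw <- evt_fwd(model, train[[i]]$x, training = TRUE)
          p <- fw$probs
          ep_loss <- ep_loss - log(max(p[ytr[i]], 1e-12))
          ep_correct <- ep_correct + (which.max(p) == ytr[i])
          dlogits <- p
          dlogits[ytr[i]] <- dlogits[ytr[i]] - 1
          g <- evt_bwd(model, dlogits / length(bs), fw)
          grads <- acc_grads(grads, g$grads)
        }
        st <- adam_step(model$params, grads, opt, lr, tc$weight_decay,
                        decay_filter = decay_filter)
        model$params <- st$params; opt <- st$state
      }
      vm <- eval_set(val, yva)
      hist_rows[[epoch + 1L]] <- data.frame(
        epoch = epoch, lr = lr, train_loss = ep_loss / length(train),
        train_acc = ep_correct / length(train),
        val_loss = vm[1], val_acc = vm[2])
      if (vm[2] > best$acc) {
        best <- list(acc = vm[2], params = model$params, epoch = epoch)
      }
      if (verbose)
        message(sprintf("epoch %3d  lr %.5f  loss %.4f  train acc %.3f  val acc %.3f",
                        epoch, lr, ep_loss / length(train),
                        ep_correct / length(train), vm[2]))
    }
  })
  best_model <- model
  best_model$params <- best$params
  structure(list(model = best_model, final_model = model,
                 history = do.call(rbind, hist_rows), best_epoch = best$epoch,
                 config = config, train_config = tc),
            class = "cls_fit")
}

#' Deterministic batch-1 inference over a manifest
#'
#' Evaluation mode (dropout off), batch size fixed to 1, samples processed in
#' manifest order with no stochastic operations, so repeated invocations are
#' bit-identical.
#'
#' @param model trained `evt` model.
#' @param manifest data.frame or CSV path with `id,image` (optionally
#'   `label`).
#' @return data.frame `id,true_label,pred_label,p_malignant` in manifest
#'   order.
#' @export
deterministic_inference <- function(model, manifest) {
  m <- if (is.character(manifest)) read_manifest(manifest) else manifest
  rows <- lapply(seq_len(nrow(m)), function(i) {
    img <- read_image(m$image[i])
    pr <- predict_class(model, img)
    data.frame(id = m$id[i],
               true_label = if (!is.null(m$label)) m$label[i] else NA_character_,
               pred_label = pr$label,
               p_malignant = unname(pr$probs["malignant"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
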