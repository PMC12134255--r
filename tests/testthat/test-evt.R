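# EVT classifier: tokenizer geometry, wavelet position embedding, encoder
# algebra, pooling, head, schedules and the deterministic-inference contract.

test_that("tokenizer produces the expected grid for 224 and 64 inputs", {
  m <- small_evt()
  tk <- tokenize(m, array(rnorm(3 * 224 * 224, 0, 0.3), c(3, 224, 224)))
  expect_equal(c(tk$grid_h, tk$grid_w), c(28, 28))     # 224 / 2^3
  expect_equal(nrow(tk$tokens), 784)
  expect_equal(ncol(tk$tokens), m$config$embed_dim)
  tk64 <- tokenize(m, array(rnorm(3 * 64 * 64), c(3, 64, 64)))
  expect_equal(nrow(tk64$tokens), 64)
  expect_error(tokenize(m, array(0, c(3, 60, 60))), "divisible by 32")
  # zero input with zero conv biases gives zero tokens
  mz <- m
  for (b in 1:3) mz$params[[sprintf("tok%d.b", b)]][] <- 0
  tz <- tokenize(mz, array(0, c(3, 32, 32)))
  expect_true(all(tz$tokens == 0))
})

test_that("token grid flattening is lossless (row-major)", {
  G <- array(seq_len(4 * 6 * 5), c(4, 6, 5))
  tk <- nievt:::grid_to_tokens(G)
  expect_identical(nievt:::tokens_to_grid(tk, 4, 6), G)
  # row-major: token 2 is grid position (row 1, col 2)
  expect_identical(tk[2, ], G[1, 2, ])
})

test_that("Haar subbands match the 2x2 average/difference oracle", {
  G <- array(3, c(4, 4, 1))                            # constant field
  sub <- nievt:::haar_dwt2(G)
  expect_true(all(sub$LL == 6))                        # constant x 2
  expect_true(all(sub$LH == 0) && all(sub$HL == 0) && all(sub$HH == 0))
  set.seed(5)
  G2 <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  sub2 <- nievt:::haar_dwt2(G2)
  for (i in 1:4) for (j in 1:4) for (ch in 1:2) {
    blk <- G2[2 * i - (1:0), 2 * j - (1:0), ch]
    # blk[1,1]=a (odd,odd), blk[1,2]=b, blk[2,1]=c, blk[2,2]=d
    expect_equal(sub2$LL[i, j, ch], sum(blk) / 2, tolerance = 1e-12)
    expect_equal(sub2$HH[i, j, ch],
                 (blk[1, 1] - blk[1, 2] - blk[2, 1] + blk[2, 2]) / 2,
                 tolerance = 1e-12)
  }
  # orthonormality: energy is preserved
  expect_equal(sum(G2^2),
               sum(sub2$LL^2) + sum(sub2$LH^2) + sum(sub2$HL^2) + sum(sub2$HH^2),
               tolerance = 1e-9)
})

test_that("WPE preserves shape and is the identity at zero weights", {
  m <- small_evt()
  tk <- tokenize(m, array(rnorm(3 * 64 * 64, 0, 0.3), c(3, 64, 64)))
  emb <- wavelet_position_embedding(m, tk)
  expect_identical(dim(emb$tokens), dim(tk$tokens))
  expect_false(identical(emb$tokens, tk$tokens))
  mz <- zero_wpe(m)
  embz <- wavelet_position_embedding(mz, tk)
  expect_identical(embz$tokens, tk$tokens)
  # zero-weight WPE network output is bit-identical to the no-WPE network
  x <- array(rnorm(3 * 64 * 64, 0, 0.3), c(3, 64, 64))
  moff <- mz; moff$config$wpe_enabled <- FALSE
  expect_identical(nievt:::evt_fwd(mz, x)$logits, nievt:::evt_fwd(moff, x)$logits)
})

test_that("encoder preserves shape; attention is row-stochastic and equivariant", {
  m <- small_evt()
  grid <- list(tokens = matrix(rnorm(16 * 64, 0, 0.5), 16, 64),
               grid_h = 4, grid_w = 4)
  out <- encoder(m, grid)
  expect_identical(dim(out$tokens), dim(grid$tokens))
  # attention rows sum to 1
  af <- nievt:::attn_fwd(m$params, "enc1.", grid$tokens, 4, 0, FALSE)
  for (h in 1:4) expect_equal(rowSums(af$cache$A[[h]]), rep(1, 16), tolerance = 1e-12)
  # permutation equivariance of a single attention layer (no position info)
  perm <- sample(16)
  out1 <- nievt:::attn_fwd(m$params, "enc1.", grid$tokens, 4, 0, FALSE)$out
  out2 <- nievt:::attn_fwd(m$params, "enc1.", grid$tokens[perm, ], 4, 0, FALSE)$out
  expect_equal(out2, out1[perm, ], tolerance = 1e-10)
})

test_that("sequence pooling matches its closed forms", {
  m <- small_evt()
  tok1 <- matrix(rnorm(64), 1, 64)
  expect_equal(sequence_pool(m, tok1), as.numeric(tok1), tolerance = 1e-12)
  same <- matrix(rep(rnorm(64), each = 5), 5, 64)
  expect_equal(sequence_pool(m, same), as.numeric(same[1, ]), tolerance = 1e-12)
  # two distinct tokens against hand arithmetic
  t2 <- matrix(rnorm(2 * 64), 2, 64)
  z <- t2 %*% m$params$pool.u + m$params$pool.b
  w <- exp(z - max(z)); w <- w / sum(w)
  expect_equal(sequence_pool(m, t2), as.numeric(t(w) %*% t2), tolerance = 1e-12)
})

test_that("classifier head softmax behaves", {
  m <- small_evt()
  emb <- rnorm(64)
  cl <- classify(m, emb)
  expect_equal(sum(cl$probs), 1, tolerance = 1e-12)
  mz <- m; mz$params$head.W[] <- 0; mz$params$head.b[] <- 0
  expect_equal(classify(mz, emb)$probs, c(0.5, 0.5))
  # logits (0, ln 3) -> probabilities (0.25, 0.75)
  p <- exp(c(0, log(3))); p <- p / sum(p)
  expect_equal(p, c(0.25, 0.75))
  m1 <- m; m1$params$head.W[] <- 0; m1$params$head.b <- c(0, log(3))
  expect_equal(classify(m1, emb)$probs, c(0.25, 0.75), tolerance = 1e-12)
})

test_that("warmup-cosine schedule hits the documented anchors", {
  lr <- vapply(0:6, warmup_cosine_lr, numeric(1), epochs = 100, warmup = 5,
               initial_lr = 0.001)
  expect_lt(lr[1], lr[5])            # epoch 0 < epoch 4
  expect_lt(lr[5], lr[6])            # epoch 4 < epoch 5
  expect_equal(lr[6], 0.001)         # peak reached at epoch 5 exactly
  expect_gt(lr[7], 0)                # decays smoothly afterwards
  expect_lt(warmup_cosine_lr(99, 100, 5, 0.001), 1e-5)
})

test_that("EVT gradients match finite differences on a tiny model", {
  cfg <- evt_config(embed_dim = 16, tokenizer_channels = c(8, 12),
                    encoder_layers = 1, attention_heads = 4, dropout = 0)
  m <- build_evt(cfg, seed = 3)
  x <- array(rnorm(3 * 32 * 32, 0, 0.5), c(3, 32, 32))
  fw <- nievt:::evt_fwd(m, x)
  dlogits <- fw$probs; dlogits[2] <- dlogits[2] - 1
  g <- nievt:::evt_bwd(m, dlogits, fw)$grads
  lossf <- function(mm) -log(nievt:::evt_fwd(mm, x)$probs[2])
  eps <- 1e-5
  for (nm in c("tok1.W", "wpe.lin.W", "wpe.dw.W", "enc1.Wq", "enc1.W2",
               "final.ln.g", "pool.u", "head.W")) {
    i <- min(2, length(m$params[[nm]]))
    mp <- m; mp$params[[nm]][i] <- m$params[[nm]][i] + eps; lp <- lossf(mp)
    mp$params[[nm]][i] <- m$params[[nm]][i] - eps; lm <- lossf(mp)
    expect_equal(g[[nm]][i], (lp - lm) / (2 * eps), tolerance = 1e-3,
                 label = paste("grad", nm))
  }
})

test_that("all four ablation arms are constructible from flags", {
  for (wpe in c(TRUE, FALSE)) {
    m <- build_evt(cls_fixture_config(wpe = wpe), seed = 1)
    expect_identical(m$config$wpe_enabled, wpe)
    pr <- predict_class(m, generate_sample(benign_spec(seed = 1))$image)
    expect_true(pr$label %in% c("benign", "malignant"))
  }
  # nie is an input-side switch; both input types classify
  s <- generate_sample(malignant_spec(seed = 6))
  enh <- fuse_edges(s$image, canny_on_mask(s$mask), 0)
  m <- small_evt()
  expect_length(predict_class(m, enh)$probs, 2)
})

test_that("training config validation and label errors name the offender", {
  expect_error(cls_train_config(warmup = 100, epochs = 100), "warmup")
  man <- get_cls_dataset()
  bad <- man; bad$label[3] <- NA
  expect_error(train_classifier(bad, man, cls_fixture_config(),
                                cls_train_config(epochs = 10, warmup = 1)),
               "row 3")
})
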