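# Shared fixtures, built in code and cached for the session. The two trained
# models are the expensive pieces (a few minutes each); every test that needs
# a converged network reuses them. Training scale follows the synthetic-data
# acceptance protocol: 20/5 images, 50 epochs for segmentation; 16 images,
# 100 epochs for classification. Widths are reduced relative to the full-size
# defaults to stay inside the CPU time budget (see the methods vignette).

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# alternating benign/malignant samples from the default presets
synth_samples <- function(idx, master_seed = 1L) {
  lapply(idx, function(i) {
    sp <- if (i %% 2 == 1) benign_spec(seed = nievt:::derive_seed(master_seed, i))
          else malignant_spec(seed = nievt:::derive_seed(master_seed, i))
    generate_sample(sp)
  })
}

seg_fixture_config <- function() resunet_config(depth = 3, base_channels = 16)

# 20 train / 5 val synthetic images, 50 epochs
get_seg_fit <- function() {
  cache_fixture("seg_fit", function() {
    train <- synth_samples(1:20)
    val <- synth_samples(21:25)
    fit <- train_segmentation(train, val,
                              config = seg_fixture_config(),
                              train_config = seg_train_config(epochs = 50,
                                                              batch_size = 4,
                                                              seed = 42))
    list(fit = fit, train = train, val = val)
  })
}

cls_fixture_config <- function(wpe = TRUE, dropout = 0.1)
  evt_config(embed_dim = 64, tokenizer_channels = c(16, 32),
             encoder_layers = 2, attention_heads = 4, dropout = dropout,
             wpe_enabled = wpe)

# 16-image (8/8) on-disk dataset + manifest
get_cls_dataset <- function() {
  cache_fixture("cls_dataset", function() {
    dir <- file.path(tempdir(), "nievt_cls16")
    generate_dataset(8, benign_spec(), malignant_spec(), seed = 7,
                     out_dir = dir)
  })
}

# EVT trained for 100 epochs on the 16-image set (train == val: capacity run)
get_cls_fit <- function() {
  cache_fixture("cls_fit", function() {
    man <- get_cls_dataset()
    train_classifier(man, man, cls_fixture_config(),
                     cls_train_config(epochs = 100, warmup = 5, seed = 42))
  })
}

# small untrained EVT for shape/identity tests
small_evt <- function(seed = 3, ...) build_evt(cls_fixture_config(...), seed = seed)

# flood-fill connected-component count (8-connectivity) — oracle
count_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W); ncomp <- 0L
  for (start in which(mask == 1)) {
    if (lab[start] > 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      if (lab[cur] > 0L) next
      lab[cur] <- ncomp
      r <- (cur - 1L) %% H + 1L; cc <- (cur - 1L) %/% H + 1L
      for (dy in -1:1) for (dx in -1:1) {
        rr <- r + dy; c2 <- cc + dx
        if (rr >= 1 && rr <= H && c2 >= 1 && c2 <= W) {
          j <- (c2 - 1L) * H + rr
          if (mask[j] == 1 && lab[j] == 0L) queue <- c(queue, j)
        }
      }
    }
  }
  ncomp
}
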