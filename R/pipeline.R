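# Orchestration: stratified splitting, the three-stage workflow (segment ->
# enhance -> classify) with its four ablation arms, and the command-line
# interface. A run is a pure function of (config, seed): no stage consults
# the wall clock or ambient RNG state.

#' Stratified train/validation/test split of a manifest
#'
#' Per class (when stratified): rows are shuffled with the seed, then
#' assigned by cumulative ratio with largest-remainder rounding, giving
#' disjoint exhaustive partitions; 10 items at 7:2:1 split exactly (7, 2, 1).
#'
#' @param manifest data.frame (or CSV path) with at least `id`; needs `label`
#'   when stratifying.
#' @param ratios positive (train, val, test) weights, default `c(7, 2, 1)`.
#' @param seed shuffle seed.
#' @param stratify_by_label split within each label separately (default TRUE).
#' @return named list of data.frames: `train`, `val`, `test`.
#' @export
split_dataset <- function(manifest, ratios = c(7, 2, 1), seed = 42,
                          stratify_by_label = TRUE) {
  m <- if (is.character(manifest)) read_manifest(manifest) else manifest
  stopifnot(all(ratios > 0))
  if (stratify_by_label && is.null(m$label))
    stopf("stratified split needs a label column")
  if (stratify_by_label && nrow(m) < 10)
    stopf("stratified split needs >= 10 items")
  largest_remainder <- function(n) {
    exact <- n * ratios / sum(ratios)
    base <- floor(exact)
    rem <- n - sum(base)
    if (rem > 0) {
      ord <- order(-(exact - base), -ratios, seq_along(ratios))
      base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
    }
    base
  }
  parts <- list(train = m[0, ], val = m[0, ], test = m[0, ])
  groups <- if (stratify_by_label) split(seq_len(nrow(m)), m$label)
            else list(all = seq_len(nrow(m)))
  with_seed(seed, {
    for (g in groups) {
      if (stratify_by_label && length(g) < length(ratios))
        warning(sprintf("class with %d items cannot fill %d split parts",
                        length(g), length(ratios)))
      idx <- g[sample.int(length(g))]
      sizes <- largest_remainder(length(g))
      off <- 0
      for (p in seq_along(sizes)) {
        take <- idx[off + seq_len(sizes[p])]
        parts[[p]] <- rbind(parts[[p]], m[take, , drop = FALSE])
        off <- off + sizes[p]
      }
    }
  })
  lapply(parts, function(d) { rownames(d) <- NULL; d })
}

#' Full-pipeline run configuration
#'
#' Controls the end-to-end workflow: synthetic data generation, segmentation
#' training, nuclear enhancement, classifier training on the four ablation
#' arms, and evaluation. Defaults are smoke-test scale (single CPU, minutes);
#' the reference protocol's values (100 epochs etc.) can be set explicitly.
#'
#' @param out_dir output root directory.
#' @param seed master seed; every stage seed derives from it.
#' @param n_per_class synthetic samples per class.
#' @param split_ratios train/val/test weights.
#' @param seg_config,seg_train ResUnet architecture / training configs.
#' @param evt,cls_train EVT architecture / training configs (`wpe_enabled`
#'   is overridden per arm).
#' @param edge_gain enhancement fusion gain.
#' @param arms subset of `c("evt", "evt_wpe", "evt_nie", "evt_wpe_nie")`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 42, n_per_class = 8,
                            split_ratios = c(7, 2, 1),
                            seg_config = resunet_config(depth = 3, base_channels = 16),
                            seg_train = seg_train_config(epochs = 10, batch_size = 4),
                            evt = evt_config(embed_dim = 32,
                                             tokenizer_channels = c(8, 16),
                                             encoder_layers = 1,
                                             attention_heads = 4,
                                             dropout = 0),
                            cls_train = cls_train_config(epochs = 8, warmup = 2),
                            edge_gain = 0,
                            arms = c("evt", "evt_wpe", "evt_nie", "evt_wpe_nie")) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_per_class = n_per_class, split_ratios = split_ratios,
                 seg_config = seg_config, seg_train = seg_train,
                 evt = evt, cls_train = cls_train, edge_gain = edge_gain,
                 arms = arms),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full three-stage pipeline
#'
#' Stages: (1) generate a synthetic two-class dataset and split it 7:2:1;
#' (2) train the ResUnet segmenter and build the nuclear-information-enhanced
#' copy of every image; (3) train one EVT classifier per ablation arm (plain,
#' +wpe, +nie, +wpe+nie) and evaluate each on the held-out test set with
#' deterministic batch-1 inference. Every arm's metric report and a combined
#' `summary.json` are written under `config$out_dir`; reruns with an
#' identical config produce identical summaries.
#'
#' @param config a [pipeline_config()].
#' @return the summary list (one entry per arm), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  log_run_metadata(config)

  manifest <- run_stage("generate", generate_dataset(
    config$n_per_class, benign_spec(), malignant_spec(),
    seed = derive_seed(seed, 1L), out_dir = file.path(out, "data")))
  splits <- run_stage("split", split_dataset(
    manifest, config$split_ratios, seed = derive_seed(seed, 2L)))
  for (p in names(splits))
    write_manifest(splits[[p]], file.path(out, paste0(p, ".csv")))

  st <- config$seg_train; st$seed <- derive_seed(seed, 3L)
  seg_fit <- run_stage("train-seg", train_segmentation(
    splits$train, splits$val, config$seg_config, st))
  save_checkpoint(seg_fit, file.path(out, "seg_model.rds"))
  utils::write.csv(seg_fit$history, file.path(out, "seg_history.csv"),
                   row.names = FALSE)

  enhanced <- run_stage("enhance", {
    lapply(splits, function(s)
      enhance_dataset(s, seg_fit$model,
                      out_dir = file.path(out, "enhanced"),
                      edge_gain = config$edge_gain))
  })

  arm_defs <- list(
    evt = list(wpe = FALSE, nie = FALSE),
    evt_wpe = list(wpe = TRUE, nie = FALSE),
    evt_nie = list(wpe = FALSE, nie = TRUE),
    evt_wpe_nie = list(wpe = TRUE, nie = TRUE))
  summary <- list()
  for (arm in config$arms) {
    def <- arm_defs[[arm]]
    pick <- function(part) {
      s <- if (def$nie) enhanced[[part]] else splits[[part]]
      if (def$nie) s$image <- s$enhanced
      s
    }
    ecfg <- config$evt
    ecfg$wpe_enabled <- def$wpe
    ct <- config$cls_train; ct$seed <- derive_seed(seed, 4L)
    fit <- run_stage(paste0("train-cls:", arm), train_classifier(
      pick("train"), pick("val"), ecfg, ct))
    preds <- run_stage(paste0("evaluate:", arm), deterministic_inference(
      fit$model, pick("test")))
    rep <- classification_report(preds$pred_label, preds$true_label,
                                 scores = preds$p_malignant,
                                 positive = "malignant")
    rep$arm <- arm
    rep$wpe <- def$wpe
    rep$nie <- def$nie
    write_report(rep, file.path(out, paste0("report_", arm, ".json")))
    utils::write.csv(preds, file.path(out, paste0("predictions_", arm, ".csv")),
                     row.names = FALSE)
    summary[[arm]] <- rep
  }
  write_report(summary, file.path(out, "summary.json"))
  invisible(summary)
}

# record package/library versions, seed and a config hash alongside artifacts
log_run_metadata <- function(config) {
  cfgjson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE)
  tmp <- file.path(config$out_dir, "config.json")
  writeLines(cfgjson, tmp)
  meta <- list(
    package = as.character(utils::packageVersion("nievt")),
    r_version = R.version.string,
    seed = config$seed,
    config_md5 = unname(tools::md5sum(tmp)))
  write_report(meta, file.path(config$out_dir, "run_metadata.json"))
}

# -- minimal CLI --------------------------------------------------------------

parse_cli_args <- function(args) {
  opts <- list(); pos <- character(0); i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3))
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      } else { opts[[key]] <- TRUE; i <- i + 1L }
    } else { pos <- c(pos, a); i <- i + 1L }
  }
  list(cmd = if (length(pos)) pos[1] else "", opts = opts)
}

opt_num <- function(opts, key, default) if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
opt_chr <- function(opts, key, default = NULL) if (is.null(opts[[key]])) default else opts[[key]]

#' Command-line entry point
#'
#' Subcommands: `generate-synthetic`, `split`, `train-seg`, `enhance`,
#' `train-cls`, `evaluate`, `ablation`, `visualize`. Invoke as e.g.
#' `Rscript -e 'nievt::cli_main()' generate-synthetic --out data --seed 42`.
#'
#' @param args command-line arguments (default: `commandArgs(TRUE)`).
#' @return exit status 0, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  p <- parse_cli_args(args)
  o <- p$opts
  switch(p$cmd,
    "generate-synthetic" = {
      generate_dataset(opt_num(o, "n_per_class", 8),
                       benign_spec(), malignant_spec(),
                       seed = opt_num(o, "seed", 42),
                       out_dir = opt_chr(o, "out", "synthetic"))
    },
    "split" = {
      sp <- split_dataset(opt_chr(o, "manifest"),
                          ratios = as.numeric(strsplit(opt_chr(o, "ratios", "7,2,1"), ",")[[1]]),
                          seed = opt_num(o, "seed", 42))
      outdir <- opt_chr(o, "out", ".")
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      for (nm in names(sp))
        write_manifest(sp[[nm]], file.path(outdir, paste0(nm, ".csv")))
    },
    "train-seg" = {
      fit <- train_segmentation(
        opt_chr(o, "train"), opt_chr(o, "val"),
        resunet_config(depth = opt_num(o, "depth", 4),
                       base_channels = opt_num(o, "base_channels", 32)),
        seg_train_config(epochs = opt_num(o, "epochs", 100),
                         seed = opt_num(o, "seed", 42)))
      save_checkpoint(fit, opt_chr(o, "out", "seg_model.rds"))
      utils::write.csv(fit$history, sub("\\.rds$", "_history.csv",
                                        opt_chr(o, "out", "seg_model.rds")),
                       row.names = FALSE)
    },
    "enhance" = {
      model <- if (!is.null(o$model)) load_checkpoint(o$model)$model
      enhance_dataset(opt_chr(o, "manifest"), model,
                      out_dir = opt_chr(o, "out", "enhanced"),
                      edge_gain = opt_num(o, "edge_gain", 0),
                      multiple = opt_num(o, "multiple", 32))
    },
    "train-cls" = {
      fit <- train_classifier(
        opt_chr(o, "train"), opt_chr(o, "val"),
        evt_config(wpe_enabled = !isTRUE(o$no_wpe)),
        cls_train_config(epochs = opt_num(o, "epochs", 100),
                         seed = opt_num(o, "seed", 42)))
      save_checkpoint(fit, opt_chr(o, "out", "cls_model.rds"))
    },
    "evaluate" = {
      fit <- load_checkpoint(opt_chr(o, "model"))
      preds <- deterministic_inference(fit$model, opt_chr(o, "manifest"))
      rep <- classification_report(preds$pred_label, preds$true_label,
                                   scores = preds$p_malignant,
                                   positive = "malignant")
      write_report(rep, opt_chr(o, "out", "report.json"))
    },
    "ablation" = {
      run_pipeline(pipeline_config(out_dir = opt_chr(o, "out", "ablation"),
                                   seed = opt_num(o, "seed", 42),
                                   n_per_class = opt_num(o, "n_per_class", 8)))
    },
    "visualize" = {
      fit <- load_checkpoint(opt_chr(o, "model"))
      img <- read_image(opt_chr(o, "input"))
      kind <- opt_chr(o, "kind", "gradcam")
      outp <- opt_chr(o, "out", paste0(kind, ".png"))
      if (kind == "gradcam") {
        hm <- grad_cam(fit$model, opt_chr(o, "layer",
                                          "model.tokenizer.conv_layers[2][2]"), img)
        write_image(hm$overlay, outp)
      } else {
        acts <- tokenizer_activations(fit$model, img)
        write_image(featuremap_colormap(acts), outp)
      }
    },
    stopf("unknown command '%s'; see ?cli_main", p$cmd))
  invisible(0L)
}
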