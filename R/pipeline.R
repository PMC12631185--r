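#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end run; all randomness descends from
#' `seed`. With no `manifest`, a synthetic dataset is generated from
#' `specs`.
#'
#' @param workdir Output directory for all artifacts.
#' @param manifest Optional path to an existing `path,label` manifest CSV
#'   (paths relative to its directory); NULL to simulate.
#' @param specs Class specifications for simulation (default
#'   [default_class_specs()]).
#' @param n_per_class Simulated images per class (default 12).
#' @param image_side Simulated image side (default 256).
#' @param balance_cap Per-class cap of [balance_classes()] (default 150).
#' @param split_fractions Train/val/test fractions (default 0.70/0.15/0.15).
#' @param feature_params Handcrafted overrides (see [extract_handcrafted()]).
#' @param backbone A [backbone_spec()] (default seeded surrogate, D = 64).
#' @param pca Either `list(k = ...)` or
#'   `list(variance_threshold = ...)` (default threshold 0.95).
#' @param learners Character subset of rf/xgb/gb/knn/lr (default `"lr"`;
#'   `"all"` expands to all five).
#' @param train_cfg DNN head training settings (see [fit_hybrid()]).
#' @param lime LIME settings (see [lime_config()]); `n_explained` instances
#'   per learner are explained (default 2).
#' @param n_explained Test instances to explain per learner.
#' @param seed Master seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(workdir, manifest = NULL,
                       specs = default_class_specs(), n_per_class = 12,
                       image_side = 256, balance_cap = 150,
                       split_fractions = c(0.70, 0.15, 0.15),
                       feature_params = list(),
                       backbone = backbone_spec(seed = 7, output_dim = 64),
                       pca = list(variance_threshold = 0.95),
                       learners = "lr",
                       train_cfg = list(),
                       lime = list(n_samples = 500, n_features = 5),
                       n_explained = 2, seed = 1) {
  if (identical(learners, "all")) learners <- c("rf", "xgb", "gb", "knn", "lr")
  stopifnot(all(learners %in% c("rf", "xgb", "gb", "knn", "lr")))
  structure(list(workdir = workdir, manifest = manifest, specs = specs,
                 n_per_class = n_per_class, image_side = image_side,
                 balance_cap = balance_cap,
                 split_fractions = split_fractions,
                 feature_params = feature_params, backbone = backbone,
                 pca = pca, learners = learners, train_cfg = train_cfg,
                 lime = lime, n_explained = n_explained,
                 seed = as.integer(seed)),
            class = "run_config")
}

pipeline_log <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  writeLines(msg, con)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline end to end
#'
#' simulate/ingest -> balance -> stratified split -> handcrafted + deep
#' feature extraction -> fusion -> PCA -> hybrid stack fit(s) -> test-set
#' evaluation -> local explanations. All artifacts are written under
#' `config$workdir`: the manifest, fused feature CSVs per split, the PCA
#' sidecar JSON, per-learner metrics report JSON, confusion CSV, training
#' history CSV, explanation JSONs, and `run.log`. Runs are fully seeded:
#' the same config yields byte-identical reports.
#'
#' @param config A [run_config()].
#' @return (Invisibly) list with per-learner `reports`, `models`, and the
#'   artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  wd <- config$workdir
  if (!dir.exists(wd)) dir.create(wd, recursive = TRUE)
  logf <- file(file.path(wd, "run.log"), open = "wt")
  on.exit(close(logf))

  if (is.null(config$manifest)) {
    img_dir <- file.path(wd, "images")
    manifest <- stage("simulate", {
      pipeline_log(logf, "simulating ", length(config$specs), " classes x ",
                   config$n_per_class, " images")
      generate_dataset(config$specs, config$n_per_class, img_dir,
                       seed = derive_seed(config$seed, 10),
                       side = config$image_side)
    })
  } else {
    img_dir <- dirname(config$manifest)
    manifest <- stage("ingest", read_manifest(config$manifest))
  }

  manifest <- stage("balance", suppressWarnings(
    balance_classes(manifest, cap = config$balance_cap,
                    seed = derive_seed(config$seed, 11))))
  splits <- stage("split", stratified_split(
    manifest, fractions = config$split_fractions,
    seed = derive_seed(config$seed, 12)))
  pipeline_log(logf, "split sizes: train ", nrow(splits$train), " / val ",
               nrow(splits$val), " / test ", nrow(splits$test))

  fparams <- utils::modifyList(config$feature_params,
                               list(seed = derive_seed(config$seed, 13)))
  feats <- stage("features", lapply(splits, function(s)
    fuse_manifest(s, img_dir, backbone = config$backbone, params = fparams)))
  for (nm in names(feats)) {
    df <- data.frame(feats[[nm]]$X, check.names = FALSE)
    df$label <- feats[[nm]]$y
    utils::write.csv(df, file.path(wd, paste0("features_", nm, ".csv")),
                     row.names = FALSE)
  }

  pca_model <- stage("pca", do.call(fit_pca, c(list(X = feats$train$X),
                                               config$pca)))
  pipeline_log(logf, "PCA: d ", ncol(feats$train$X), " -> k ", pca_model$k,
               sprintf(" (%.1f%% variance)", 100 * pca_model$retained_fraction))
  save_pca(pca_model, file.path(wd, "pca_model.json"))
  Z <- lapply(feats, function(f) transform_pca(pca_model, f$X))

  reports <- models <- list()
  for (learner in config$learners) {
    cfg <- base_learner_config(learner, seed = derive_seed(config$seed, 20))
    model <- stage(paste0("train:", learner), fit_hybrid(
      cfg, Z$train, feats$train$y, Z$val, feats$val$y,
      train_cfg = config$train_cfg, seed = derive_seed(config$seed, 21)))
    pred <- stage(paste0("evaluate:", learner), predict(model, Z$test))
    report <- suppressWarnings(
      classification_report(feats$test$y, pred$labels,
                            class_set = model$classes))
    auc <- suppressWarnings(
      roc_auc_ovr(feats$test$y, pred$probabilities,
                  class_set = model$classes))
    pipeline_log(logf, learner, ": test accuracy ",
                 sprintf("%.4f", report$accuracy), ", macro AUC ",
                 sprintf("%.4f", auc$macro))
    jsonlite::write_json(report_to_list(report, auc),
                         file.path(wd, paste0("report_", learner, ".json")),
                         digits = 10, auto_unbox = TRUE, pretty = TRUE)
    utils::write.csv(as.data.frame(report$confusion),
                     file.path(wd, paste0("confusion_", learner, ".csv")))
    utils::write.csv(model$history,
                     file.path(wd, paste0("history_", learner, ".csv")),
                     row.names = FALSE)

    n_exp <- min(config$n_explained, nrow(Z$test))
    if (n_exp > 0) {
      fstats <- list(mean = colMeans(Z$train), sd = apply(Z$train, 2, sd))
      fstats$sd[fstats$sd < 1e-12] <- 1
      lcfg <- do.call(lime_config, utils::modifyList(
        config$lime, list(seed = derive_seed(config$seed, 22))))
      black_box <- function(Znew) predict(model, Znew)$probabilities
      for (i in seq_len(n_exp)) {
        expl <- stage(paste0("explain:", learner), explain_instance(
          black_box, Z$test[i, ], pred$labels[i], cfg = lcfg,
          stats = fstats, instance_id = splits$test$path[i]))
        write_explanation(expl, file.path(
          wd, sprintf("explanation_%s_%02d.json", learner, i)))
      }
    }
    reports[[learner]] <- report
    models[[learner]] <- model
  }
  invisible(list(reports = reports, models = models, workdir = wd,
                 pca = pca_model))
}
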