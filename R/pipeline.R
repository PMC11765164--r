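#' Default pipeline configuration
#'
#' One flat, human-readable configuration driving the full pipeline:
#' screen tissue-specific sites -> rank disease sites per tissue ->
#' summarise the panel -> train the diagnosis model -> cross-validated
#' evaluation. Every stage constant (tau_p = 0.01, 10 bins, top 400 sites,
#' 5 folds) is a named default here, never hard-coded downstream. When
#' \code{betas}/\code{metadata} are NULL the synthetic generator block is
#' used instead, which makes \code{run_pipeline} a self-contained demo.
#'
#' @param betas,metadata input TSV paths, or NULL to simulate.
#' @param out_dir output directory.
#' @param seed root seed for every stage.
#' @param tau_p,n_bins stage-1 screening parameters.
#' @param top_k,signed stage-2 ranking parameters.
#' @param layers,heads,use_dynamic_residual,tokens model architecture.
#' @param epochs,batch_size,learning_rate,dropout,patience training.
#' @param k_folds evaluation folds.
#' @param synthetic list of \code{\link{cohort_config}} overrides for the
#'   simulated cohort.
#' @return nested configuration list.
#' @export
pipeline_config <- function(betas = NULL, metadata = NULL,
                            out_dir = "methyldx_run", seed = 1L,
                            tau_p = 0.01, n_bins = 10L,
                            top_k = 400L, signed = FALSE,
                            layers = 2L, heads = 4L,
                            use_dynamic_residual = TRUE,
                            tokens = "channel",
                            epochs = 60L, batch_size = 32L,
                            learning_rate = 1e-3, dropout = 0.1,
                            patience = 10L, k_folds = 5L,
                            synthetic = list()) {
  list(paths = list(betas = betas, metadata = metadata, out_dir = out_dir),
       seed = as.integer(seed),
       screening = list(tau_p = tau_p, n_bins = as.integer(n_bins)),
       ranking = list(top_k = as.integer(top_k), signed = signed),
       model = list(layers = as.integer(layers), heads = as.integer(heads),
                    use_dynamic_residual = use_dynamic_residual,
                    tokens = tokens),
       training = list(epochs = as.integer(epochs),
                       batch_size = as.integer(batch_size),
                       learning_rate = learning_rate, dropout = dropout,
                       patience = as.integer(patience)),
       evaluation = list(k = as.integer(k_folds)),
       synthetic = synthetic)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror \code{\link{pipeline_config}}
#'   arguments (flat or nested under paths/screening/ranking/model/
#'   training/evaluation/synthetic).
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  flat <- y[setdiff(names(y), c("paths", "screening", "ranking", "model",
                                "training", "evaluation", "synthetic"))]
  nested <- unlist(unname(
    y[intersect(names(y), c("paths", "screening", "ranking", "model",
                            "training", "evaluation"))]), recursive = FALSE)
  args <- c(flat, nested)
  if (!is.null(y$evaluation$k)) { args$k_folds <- y$evaluation$k; args$k <- NULL }
  if (!is.null(y$synthetic)) args$synthetic <- y$synthetic
  keep <- intersect(names(args), names(formals(pipeline_config)))
  do.call(pipeline_config, args[keep])
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg), file = con)
  message(msg)
}

#' Run the full screening-to-diagnosis pipeline
#'
#' Executes all stages in order, writes every intermediate table under the
#' output directory, a run log with parameters and per-stage sample/site
#' counts, and a JSON manifest of the produced artifacts. Rerunning with the
#' same configuration reproduces identical result tables.
#'
#' @param config a \code{\link{pipeline_config}} list (or YAML path).
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  paths <- config$paths
  if (!is.null(paths$betas) && !file.exists(paths$betas))
    stop("betas file not found: ", paths$betas, call. = FALSE)
  if (!is.null(paths$metadata) && !file.exists(paths$metadata))
    stop("metadata file not found: ", paths$metadata, call. = FALSE)
  out <- paths$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out, "run.log"), open = "wt")
  on.exit(close(logf))
  manifest <- list(package_version = as.character(utils::packageVersion("methyldx")),
                   seed = config$seed, config = config, artifacts = list())
  add <- function(name, file) manifest$artifacts[[name]] <<- file

  # stage 0: inputs
  if (is.null(paths$betas)) {
    syn_args <- config$synthetic
    if (is.null(syn_args$seed)) syn_args$seed <- config$seed
    cohort <- generate_cohort(do.call(cohort_config, syn_args))
    betas <- cohort$betas
    metadata <- cohort$metadata
    write_beta_matrix(betas, file.path(out, "betas.tsv"))
    write_result_table(metadata, file.path(out, "metadata.tsv"))
    write_result_table(ground_truth_table(cohort$truth),
                       file.path(out, "ground_truth.tsv"))
    add("betas", "betas.tsv"); add("metadata", "metadata.tsv")
    add("ground_truth", "ground_truth.tsv")
    log_line(logf, "simulate: %d samples x %d sites (seed %d)",
             nrow(betas), ncol(betas), config$seed)
  } else {
    betas <- read_beta_matrix(paths$betas)
    metadata <- read_sample_metadata(paths$metadata,
                                     tissue_vocabulary = unique(
                                       utils::read.table(paths$metadata,
                                                         header = TRUE,
                                                         sep = "\t")$tissue))
    log_line(logf, "load: %d samples x %d sites", nrow(betas), ncol(betas))
  }

  # stage 1: tissue-specificity screen (healthy samples only)
  t0 <- proc.time()[3]
  screen <- screen_tissue_specific(betas, metadata,
                                   tau_p = config$screening$tau_p,
                                   n_bins = config$screening$n_bins)
  write_result_table(screen$results, file.path(out, "tissue_screen.tsv"))
  write_result_table(data.frame(site_id = screen$selected_sites),
                     file.path(out, "tissue_sites.tsv"))
  add("tissue_screen", "tissue_screen.tsv")
  add("tissue_sites", "tissue_sites.tsv")
  log_line(logf,
           "screen tissue: %d sites tested, %d tissue-specific at p < %g (%.1fs)",
           nrow(screen$results), length(screen$selected_sites),
           config$screening$tau_p, proc.time()[3] - t0)
  if (length(screen$selected_sites) == 0)
    stop("pipeline stage 'screen tissue' selected no sites", call. = FALSE)

  # stages 2-5 per tissue with both statuses present
  tissues <- intersect(unique(metadata$tissue),
                       unique(metadata$tissue[metadata$status == 1L]))
  metrics_all <- list()
  for (tis in tissues) {
    t0 <- proc.time()[3]
    rk <- rank_disease_sites(betas, metadata, tis, screen$selected_sites,
                             top_k = config$ranking$top_k,
                             signed = config$ranking$signed)
    write_result_table(rk$ranking,
                       file.path(out, sprintf("ranking_%s.tsv", tis)))
    add(paste0("ranking_", tis), sprintf("ranking_%s.tsv", tis))
    panel <- rk$selected_sites
    summ <- site_summary_table(betas, metadata, tis, panel)
    write_result_table(summ,
                       file.path(out, sprintf("summary_%s.tsv", tis)))
    add(paste0("summary_", tis), sprintf("summary_%s.tsv", tis))
    log_line(logf, "screen disease [%s]: %d candidates -> top %d (%.1fs)",
             tis, nrow(rk$ranking), length(panel), proc.time()[3] - t0)

    t0 <- proc.time()[3]
    rows <- metadata$sample_id[metadata$tissue == tis]
    x <- betas[rownames(betas) %in% rows, panel, drop = FALSE]
    y <- metadata$status[match(rownames(x), metadata$sample_id)]
    cfg <- train_config(epochs = config$training$epochs,
                        batch_size = config$training$batch_size,
                        learning_rate = config$training$learning_rate,
                        dropout = config$training$dropout,
                        patience = config$training$patience,
                        seed = config$seed)
    fit <- train_model(methyl_matrix(x), y, cfg,
                       layers = config$model$layers,
                       heads = config$model$heads,
                       use_dynamic_residual = config$model$use_dynamic_residual,
                       tokens = config$model$tokens)
    mdir <- file.path(out, sprintf("model_%s", tis))
    save_diagnosis_model(fit$model, mdir)
    write_result_table(fit$history,
                       file.path(out, sprintf("history_%s.tsv", tis)))
    add(paste0("model_", tis), sprintf("model_%s", tis))
    log_line(logf, "train [%s]: %d epochs, final loss %.4f (%.1fs)",
             tis, nrow(fit$history),
             fit$history$train_loss[nrow(fit$history)],
             proc.time()[3] - t0)

    t0 <- proc.time()[3]
    cv <- crossval_evaluate(betas, metadata, tis, panel,
                            model_spec = list(
                              name = if (config$model$use_dynamic_residual)
                                "transformer" else "baseline",
                              model = config$model[c("layers", "heads",
                                                     "tokens")],
                              train = config$training),
                            k = config$evaluation$k, seed = config$seed)
    metrics_all[[tis]] <- list(tissue = tis,
                               mean_accuracy = cv$mean_accuracy,
                               mean_recall = cv$mean_recall,
                               mean_f1 = cv$mean_f1, auc = cv$auc)
    write_result_table(cv$per_fold,
                       file.path(out, sprintf("cv_folds_%s.tsv", tis)))
    write_result_table(cv$roc, file.path(out, sprintf("roc_%s.tsv", tis)))
    add(paste0("cv_folds_", tis), sprintf("cv_folds_%s.tsv", tis))
    add(paste0("roc_", tis), sprintf("roc_%s.tsv", tis))
    log_line(logf, "evaluate [%s]: accuracy %.3f, AUC %.3f (%.1fs)",
             tis, cv$mean_accuracy, cv$auc, proc.time()[3] - t0)
  }
  jsonlite::write_json(metrics_all, file.path(out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  add("metrics", "metrics.json")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
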