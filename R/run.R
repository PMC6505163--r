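#' Experiment configuration
#'
#' Everything a full cross-validated run needs: the trait list, the model kind
#' (`"MTDLMP"` trains one multi-output network per fold; `"UDL"` one
#' single-output network per trait per fold), whether the G-by-E feature block
#' enters the input (`interaction_mode "I"`) or not (`"WI"`), the fixed number
#' of hidden layers, the tuning grid, CV settings, optimizer settings, marker
#' QC thresholds and the master seed from which every fold/tuning/training
#' seed is derived.
#'
#' @param trait_specs list of [trait_spec()] objects.
#' @param model_kind `"MTDLMP"` or `"UDL"`.
#' @param interaction_mode `"I"` (with G-by-E) or `"WI"` (without).
#' @param n_hidden_layers 1, 2 or 3 (fixed per run, never tuned).
#' @param grid a [tuning_grid()].
#' @param n_outer_folds outer CV folds, default 5.
#' @param inner_fraction inner validation fraction, default 0.20.
#' @param dropout_rate,learning_rate,batch_size optimizer settings.
#' @param qc `NULL` to skip marker QC, or a named list of [marker_qc()]
#'   thresholds (empty list for the defaults).
#' @param jitter starting Cholesky jitter.
#' @param scale_inputs rescale columns of X to unit variance? Default `FALSE`
#'   (only continuous responses are standardized, per fold).
#' @param seed master seed.
#' @param verbose emit per-fold progress messages?
#' @return object of class `run_config`.
#' @export
run_config <- function(trait_specs, model_kind = c("MTDLMP", "UDL"),
                       interaction_mode = c("I", "WI"), n_hidden_layers = 1L,
                       grid = tuning_grid(), n_outer_folds = 5L,
                       inner_fraction = 0.20, dropout_rate = 0.3,
                       learning_rate = 0.001, batch_size = 32L,
                       qc = list(), jitter = 1e-6, scale_inputs = FALSE,
                       seed = 1L, verbose = FALSE) {
  trait_specs <- check_trait_specs(trait_specs)
  model_kind <- match.arg(model_kind)
  interaction_mode <- match.arg(interaction_mode)
  if (!inherits(grid, "tuning_grid")) stop("'grid' must be a tuning_grid")
  if (n_outer_folds < 2L) stop("n_outer_folds must be >= 2")
  if (inner_fraction <= 0 || inner_fraction >= 1)
    stop("inner_fraction must be in (0, 1)")
  if (!n_hidden_layers %in% 1:3) stop("n_hidden_layers must be 1, 2 or 3")
  structure(list(trait_specs = trait_specs, model_kind = model_kind,
                 interaction_mode = interaction_mode,
                 n_hidden_layers = as.integer(n_hidden_layers), grid = grid,
                 n_outer_folds = as.integer(n_outer_folds),
                 inner_fraction = inner_fraction, dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), qc = qc,
                 jitter = jitter, scale_inputs = scale_inputs,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

metric_for <- function(kind) if (kind == "continuous") "pearson" else "pccc"

check_fold_categories <- function(phenotypes, specs, train_idx, fold) {
  for (sp in specs) {
    if (sp$kind == "continuous") next
    present <- unique(phenotypes[[sp$name]][train_idx])
    missing_cat <- setdiff(seq_len(sp$n_categories), present)
    if (length(missing_cat))
      stop(sprintf(
        "training set of fold %d lacks category %s of trait '%s'",
        fold, paste(missing_cat, collapse = ","), sp$name))
  }
}

# Tune, retrain on the full outer-training set, and predict the test records
# for one network (all traits for MTDLMP, a single trait for UDL).
fit_and_predict <- function(X, phenotypes, specs, config, train_idx, test_idx,
                            fold, seed_key) {
  stand <- list()
  targets <- encode_targets(phenotypes[train_idx, , drop = FALSE], specs)
  for (sp in specs) {
    if (sp$kind != "continuous") next
    st <- standardize_continuous(targets[[sp$name]])
    targets[[sp$name]] <- st$values
    stand[[sp$name]] <- list(mean = st$mean, sd = st$sd)
  }
  base_cfg <- network_config(n_hidden_layers = config$n_hidden_layers,
                             units = config$grid$unit_candidates[1L],
                             epochs = 0L, dropout_rate = config$dropout_rate,
                             learning_rate = config$learning_rate,
                             batch_size = config$batch_size, seed = 1L)
  tuned <- grid_search(X[train_idx, , drop = FALSE], targets, config$grid,
                       base_cfg, specs,
                       seed = derive_seed(config$seed, fold, seed_key),
                       inner_fraction = config$inner_fraction)
  final_cfg <- base_cfg
  final_cfg$units <- tuned$units
  final_cfg$epochs <- tuned$epochs
  final_cfg$seed <- derive_seed(config$seed, fold, seed_key, 9999L)
  fit <- train_network(X[train_idx, , drop = FALSE], targets, final_cfg, specs)
  preds <- predict_traits(X[test_idx, , drop = FALSE], fit$weights, specs, stand)
  list(preds = preds, tuned = tuned)
}

#' Run the full cross-validated genomic-prediction experiment
#'
#' Pipeline: marker QC (optional) -> mode imputation -> genomic relationship
#' matrix -> upper Cholesky factor -> feature matrix X (with or without the
#' G-by-E block) -> seeded CV2 fold assignment -> per fold: inner-validation
#' grid search, retraining on the full outer-training set with the selected
#' (units, epochs), prediction of the test records -> Pearson correlation
#' (continuous) or PCCC (categorical) per trait-environment per fold, averaged
#' over folds. Continuous traits are standardized with training-fold
#' statistics only; test records never reach training, tuning or
#' standardization.
#'
#' @param config a [run_config()].
#' @param markers validated marker matrix covering every phenotyped line.
#' @param phenotypes phenotype data frame (see [read_phenotype_table()]).
#' @return object of class `metric_report`: list with `rows` (trait,
#'   environment, fold, metric, value), `summary` (fold-averaged, see
#'   [aggregate_metrics()]), `plan` (the CV2 fold assignment), `tuning`
#'   (chosen units/epochs per fold and network) and `predictions`
#'   (record-level observed/predicted values).
#' @export
run_experiment <- function(config, markers, phenotypes) {
  stopifnot(inherits(config, "run_config"))
  specs <- config$trait_specs
  phenotypes <- validate_phenotypes(phenotypes, specs)
  if (!is.null(config$qc))
    markers <- do.call(marker_qc, c(list(markers), config$qc))
  markers <- impute_markers(markers)
  absent <- setdiff(unique(phenotypes$line), rownames(markers))
  if (length(absent))
    stop("phenotyped line(s) without marker data (after QC): ",
         paste(utils::head(absent, 5L), collapse = ", "),
         if (length(absent) > 5L) sprintf(" (and %d more)", length(absent) - 5L))
  G <- compute_grm(markers)
  Q <- cholesky_upper(G, config$jitter)$Q
  line_ids <- rownames(markers)
  env_ids <- sort(unique(phenotypes$environment))
  design <- build_design_matrices(phenotypes, line_ids, env_ids)
  X <- assemble_feature_matrix(design, Q, config$interaction_mode)$X
  if (config$scale_inputs) {
    s <- apply(X, 2L, stats::sd)
    X[, s > 0] <- sweep(X[, s > 0, drop = FALSE], 2L, s[s > 0], "/")
  }
  plan <- make_cv2_folds(phenotypes, config$n_outer_folds,
                         derive_seed(config$seed, 7L))
  rows <- list(); tuning <- list(); pred_rows <- list()
  for (f in seq_len(config$n_outer_folds)) {
    test_idx <- which(plan$fold == f)
    train_idx <- which(plan$fold != f)
    check_fold_categories(phenotypes, specs, train_idx, f)
    nets <- if (config$model_kind == "MTDLMP") list(all = specs) else {
      nm <- lapply(specs, list)
      names(nm) <- vapply(specs, `[[`, "", "name")
      nm
    }
    fold_preds <- list()
    for (net in names(nets)) {
      res <- fit_and_predict(X, phenotypes, nets[[net]], config, train_idx,
                             test_idx, f, derive_seed(0L, match(net, names(nets))))
      fold_preds <- c(fold_preds, res$preds)
      tuning[[length(tuning) + 1L]] <- data.frame(
        fold = f, network = net, units = res$tuned$units,
        epochs = res$tuned$epochs, val_loss = res$tuned$val_loss,
        stringsAsFactors = FALSE)
    }
    test_env <- phenotypes$environment[test_idx]
    for (sp in specs) {
      obs_all <- phenotypes[[sp$name]][test_idx]
      pr <- fold_preds[[sp$name]]
      pred_all <- if (sp$kind == "continuous") pr$values else pr$labels
      for (e in unique(test_env)) {
        sel <- test_env == e
        value <- if (sp$kind == "continuous")
          pearson_correlation(obs_all[sel], pred_all[sel])
        else pccc(obs_all[sel], pred_all[sel])
        rows[[length(rows) + 1L]] <- data.frame(
          trait = sp$name, environment = e, fold = f,
          metric = metric_for(sp$kind), value = value,
          stringsAsFactors = FALSE)
      }
      pred_rows[[length(pred_rows) + 1L]] <- data.frame(
        trait = sp$name, kind = sp$kind, environment = test_env, fold = f,
        line = phenotypes$line[test_idx], observed = obs_all,
        predicted = pred_all, stringsAsFactors = FALSE)
    }
    if (config$verbose) {
      tn <- tuning[[length(tuning)]]
      message(sprintf("fold %d/%d done (last network: U*=%d, E*=%d)", f,
                      config$n_outer_folds, tn$units, tn$epochs))
    }
  }
  rows <- do.call(rbind, rows)
  structure(list(rows = rows, summary = aggregate_metrics(rows), plan = plan,
                 tuning = do.call(rbind, tuning),
                 predictions = do.call(rbind, pred_rows), config = config),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("%s run: %d traits, %d folds (%d metric rows)\n",
              x$config$model_kind, length(x$config$trait_specs),
              x$config$n_outer_folds, nrow(x$rows)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Recompute fold-averaged metrics from record-level predictions
#'
#' Rebuilds the per-fold metric rows (Pearson for continuous traits, PCCC for
#' categorical) from a predictions table as emitted by [run_experiment()] and
#' averages them over folds.
#'
#' @param predictions data frame with columns `trait`, `kind`, `environment`,
#'   `fold`, `observed`, `predicted`.
#' @return list with `rows` and `summary` as in [run_experiment()].
#' @export
metrics_from_predictions <- function(predictions) {
  need <- c("trait", "kind", "environment", "fold", "observed", "predicted")
  stopifnot(all(need %in% names(predictions)))
  keys <- unique(predictions[, c("trait", "kind", "environment", "fold")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- predictions$trait == keys$trait[i] &
      predictions$environment == keys$environment[i] &
      predictions$fold == keys$fold[i]
    value <- if (keys$kind[i] == "continuous")
      pearson_correlation(predictions$observed[sel], predictions$predicted[sel])
    else pccc(predictions$observed[sel], predictions$predicted[sel])
    data.frame(trait = keys$trait[i], environment = keys$environment[i],
               fold = keys$fold[i], metric = metric_for(keys$kind[i]),
               value = value, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  list(rows = rows, summary = aggregate_metrics(rows))
}

#' Write a metric report to disk
#'
#' Emits `<prefix>_metrics.tsv` (per-fold rows), `<prefix>_summary.json`
#' (fold-averaged values), `<prefix>_predictions.tsv`, `<prefix>_plan.tsv`
#' and `<prefix>_tuning.tsv`.
#'
#' @param report a `metric_report`.
#' @param prefix output path prefix.
#' @return invisible character vector of the written paths.
#' @export
write_metric_report <- function(report, prefix) {
  paths <- c(metrics = paste0(prefix, "_metrics.tsv"),
             summary = paste0(prefix, "_summary.json"),
             predictions = paste0(prefix, "_predictions.tsv"),
             plan = paste0(prefix, "_plan.tsv"),
             tuning = paste0(prefix, "_tuning.tsv"))
  utils::write.table(report$rows, paths["metrics"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(report$summary, paths["summary"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  utils::write.table(report$predictions, paths["predictions"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$plan, paths["plan"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$tuning, paths["tuning"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
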