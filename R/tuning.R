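#' Grid of tuning candidates
#'
#' The default grid follows the full search used for the real data: epochs 1
#' to 100 and hidden units from 10 to 490 in steps of 20. The `"reduced"`
#' preset (epochs 10/50/100, units 10/50) keeps test suites desk-scale; the
#' number of hidden layers is fixed per run, never tuned.
#'
#' @param epoch_candidates strictly increasing positive integers.
#' @param unit_candidates strictly increasing positive integers.
#' @param preset `"paper_scale"` (default grid) or `"reduced"`.
#' @return object of class `tuning_grid`.
#' @export
tuning_grid <- function(epoch_candidates = NULL, unit_candidates = NULL,
                        preset = c("paper_scale", "reduced")) {
  preset <- match.arg(preset)
  if (is.null(epoch_candidates))
    epoch_candidates <- if (preset == "reduced") c(10L, 50L, 100L) else 1:100
  if (is.null(unit_candidates))
    unit_candidates <- if (preset == "reduced") c(10L, 50L) else seq(10L, 490L, 20L)
  for (v in list(epoch_candidates, unit_candidates))
    if (!length(v) || any(v < 1L) || is.unsorted(v, strictly = TRUE))
      stop("candidates must be non-empty, positive and strictly increasing")
  structure(list(epoch_candidates = as.integer(epoch_candidates),
                 unit_candidates = as.integer(unit_candidates)),
            class = "tuning_grid")
}

#' Split outer-training records into inner-train and validation sets
#'
#' Seeded shuffle; the validation set holds `round(fraction * n)` records and
#' the two sets partition the input exactly.
#'
#' @param n_records number of outer-training records.
#' @param fraction validation fraction in (0, 1), default 0.20.
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `validation`.
#' @export
split_inner_validation <- function(n_records, fraction = 0.20, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (n_records < 2L) stop("need at least 2 records to split")
  n_val <- round(fraction * n_records)
  if (n_val == 0L) stop("validation set would be empty")
  if (n_val == n_records) stop("inner-training set would be empty")
  set.seed(seed)
  ord <- sample.int(n_records)
  list(train = sort(ord[-seq_len(n_val)]), validation = sort(ord[seq_len(n_val)]))
}

#' Grid search over epochs and hidden units
#'
#' For each unit candidate a single network is trained for the largest epoch
#' candidate on the inner-training records, and the validation loss is read
#' off the per-epoch trace at every epoch candidate (equivalent to retraining
#' per epoch value, since epoch-nested training passes through all smaller
#' epochs, and about |epochs| times cheaper). Returns the pair minimizing
#' validation total loss; ties break to the smaller unit count, then the
#' smaller epoch count. Only outer-training data ever reaches this function.
#'
#' @param X_train,targets_train outer-training features and encoded targets
#'   (continuous targets standardized on the outer-training records).
#' @param grid a [tuning_grid()].
#' @param base_config a [network_config()] supplying layers, dropout,
#'   optimizer settings.
#' @param specs list of [trait_spec()] objects.
#' @param seed seed for the inner split and the candidate trainings.
#' @param inner_fraction inner-validation fraction, default 0.20.
#' @return list with `units`, `epochs`, `val_loss`, and `loss_table`
#'   (data frame: units, epochs, val_loss over the whole grid).
#' @export
grid_search <- function(X_train, targets_train, grid, base_config, specs,
                        seed = 1L, inner_fraction = 0.20) {
  specs <- check_trait_specs(specs)
  split <- split_inner_validation(nrow(X_train), inner_fraction,
                                  derive_seed(seed, 101L))
  Xi <- X_train[split$train, , drop = FALSE]
  Xv <- X_train[split$validation, , drop = FALSE]
  ti <- subset_targets(targets_train, specs, split$train)
  tv <- subset_targets(targets_train, specs, split$validation)
  max_e <- max(grid$epoch_candidates)
  tabs <- list()
  for (u in grid$unit_candidates) {
    cfg <- base_config
    cfg$units <- u
    cfg$epochs <- max_e
    cfg$seed <- derive_seed(seed, u)
    fit <- train_network(Xi, ti, cfg, specs, validation = list(X = Xv, targets = tv))
    tabs[[as.character(u)]] <- data.frame(
      units = u, epochs = grid$epoch_candidates,
      val_loss = fit$trace$val_loss[grid$epoch_candidates])
  }
  loss_table <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  if (all(!is.finite(loss_table$val_loss)))
    stop("all tuning candidates diverged")
  best <- which(loss_table$val_loss == min(loss_table$val_loss, na.rm = TRUE))[1L]
  list(units = loss_table$units[best], epochs = loss_table$epochs[best],
       val_loss = loss_table$val_loss[best], loss_table = loss_table)
}

# Deterministic seed derivation: fold a key sequence into [1, 2^31 - 2].
derive_seed <- function(seed, ...) {
  x <- 0
  for (k in c(seed, ...)) x <- (x * 69069 + as.numeric(k)) %% 2147483646
  as.integer(x) + 1L
}
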