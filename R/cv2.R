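#' Assign phenotype records to CV2 folds
#'
#' Partitions the (line, environment) records uniformly at random into `k`
#' folds whose sizes differ by at most one. Because cells rather than whole
#' lines are partitioned, a line typically has training records in some
#' environments while its remaining cells are in the test fold — the CV2
#' setting of incomplete field trials.
#'
#' @param phenotypes data frame with columns `line` and `environment`
#'   (unique pairs).
#' @param k number of folds (>= 2), default 5.
#' @param seed RNG seed.
#' @return data frame (class `cv2_plan`) with columns `line`, `environment`,
#'   `fold`.
#' @export
make_cv2_folds <- function(phenotypes, k = 5L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  n <- nrow(phenotypes)
  if (n < k) stop(sprintf("fewer records (%d) than folds (%d)", n, k))
  key <- paste(phenotypes$line, phenotypes$environment, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (line, environment) record: ",
         sub("\r", " / ", key[duplicated(key)][1L]))
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  structure(data.frame(line = as.character(phenotypes$line),
                       environment = as.character(phenotypes$environment),
                       fold = fold, stringsAsFactors = FALSE),
            class = c("cv2_plan", "data.frame"), k = k, seed = seed)
}

#' Pearson correlation between observed and predicted values
#'
#' Sample product-moment correlation. If either vector is constant (or fewer
#' than 3 pairs are available) the value is undefined: `NA` is returned with a
#' warning and the entry is excluded from fold averaging downstream.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return correlation in \[-1, 1\], or `NA`.
#' @export
pearson_correlation <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3L) {
    warning("fewer than 3 pairs: Pearson correlation undefined, returning NA")
    return(NA_real_)
  }
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("constant vector: Pearson correlation undefined, returning NA")
    return(NA_real_)
  }
  stats::cor(observed, predicted)
}

#' Percentage of cases correctly classified (as a fraction)
#'
#' @param observed_labels,predicted_labels integer category vectors of equal
#'   length.
#' @return fraction of matching positions, in \[0, 1\].
#' @export
pccc <- function(observed_labels, predicted_labels) {
  if (length(observed_labels) != length(predicted_labels))
    stop("length mismatch between observed and predicted labels")
  if (!length(observed_labels)) stop("empty label vectors")
  mean(observed_labels == predicted_labels)
}

#' Average per-fold metrics over folds
#'
#' Computes the unweighted mean over folds for every trait-environment cell,
#' excluding missing fold values and recording how many valid folds entered
#' each mean. Cells with no valid fold value get an `NA` summary.
#'
#' @param rows data frame with columns `trait`, `environment`, `fold`,
#'   `metric`, `value` (one row per trait x environment x fold).
#' @return data frame with columns `trait`, `environment`, `metric`, `value`
#'   (fold mean) and `n_folds` (valid folds).
#' @export
aggregate_metrics <- function(rows) {
  stopifnot(all(c("trait", "environment", "fold", "metric", "value") %in% names(rows)))
  keys <- unique(rows[, c("trait", "environment", "metric")])
  keys <- keys[order(keys$trait, keys$environment), , drop = FALSE]
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- rows$trait == keys$trait[i] & rows$environment == keys$environment[i] &
      rows$metric == keys$metric[i]
    v <- rows$value[sel]
    valid <- v[!is.na(v)]
    data.frame(trait = keys$trait[i], environment = keys$environment[i],
               metric = keys$metric[i],
               value = if (length(valid)) mean(valid) else NA_real_,
               n_folds = length(valid), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
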