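#' Construct and validate a marker dosage matrix
#'
#' A marker matrix is a plain numeric matrix of allele dosages (0, 1, 2 or
#' `NA`) with line identifiers as row names and marker identifiers as column
#' names. All downstream functions accept the validated matrix directly.
#'
#' @param dosages numeric matrix, lines x markers, entries in \{0, 1, 2\} or
#'   `NA`; row names are line IDs (unique), column names marker IDs.
#' @return the validated dosage matrix.
#' @export
marker_matrix <- function(dosages) {
  if (!is.matrix(dosages)) stop("'dosages' must be a matrix")
  storage.mode(dosages) <- "double"
  if (nrow(dosages) < 2L) stop("marker matrix needs at least 2 lines")
  if (ncol(dosages) < 1L) stop("marker matrix needs at least 1 marker")
  if (is.null(rownames(dosages))) stop("marker matrix requires line IDs as row names")
  if (anyDuplicated(rownames(dosages)))
    stop("duplicated line IDs: ",
         paste(unique(rownames(dosages)[duplicated(rownames(dosages))]), collapse = ", "))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("M", seq_len(ncol(dosages)))
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("dosage outside {0,1,2}: value %g at line '%s', marker '%s'",
                 dosages[idx[1L], idx[2L]], rownames(dosages)[idx[1L]],
                 colnames(dosages)[idx[2L]]))
  }
  dosages
}

#' Marker and line quality control
#'
#' Removes markers with excessive missingness, low minor allele frequency or
#' excessive heterozygosity, then lines with excessive missingness, using
#' strict inequalities (a marker is dropped when missingness > `max_marker_missing`,
#' MAF < `min_maf`, or heterozygosity > `max_het`; a line when missingness
#' > `max_line_missing`). Heterozygosity is the fraction of dosage-1 calls
#' among non-missing calls. Survivors keep their original order.
#'
#' @param markers validated marker matrix (see [marker_matrix()]).
#' @param max_marker_missing,min_maf,max_het,max_line_missing thresholds in
#'   \[0, 1\]; defaults 0.60, 0.05, 0.10, 0.50.
#' @return filtered marker matrix.
#' @export
marker_qc <- function(markers, max_marker_missing = 0.60, min_maf = 0.05,
                      max_het = 0.10, max_line_missing = 0.50) {
  thr <- c(max_marker_missing, min_maf, max_het, max_line_missing)
  if (any(thr < 0 | thr > 1)) stop("QC thresholds must lie in [0, 1]")
  miss <- colMeans(is.na(markers))
  freq <- colMeans(markers, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0 # all-missing marker: let the missingness rule handle it
  het <- colMeans(markers == 1, na.rm = TRUE)
  het[is.nan(het)] <- 0
  keep_m <- !(miss > max_marker_missing | maf < min_maf | het > max_het)
  if (!any(keep_m)) stop("marker QC removed all markers")
  out <- markers[, keep_m, drop = FALSE]
  keep_l <- rowMeans(is.na(out)) <= max_line_missing
  if (!any(keep_l)) stop("marker QC removed all lines")
  out[keep_l, , drop = FALSE]
}

#' Impute missing dosages by the per-marker mode
#'
#' Each missing entry is replaced by the most frequent observed dosage of its
#' marker; ties are broken towards the smaller dosage for determinism.
#'
#' @param markers validated marker matrix.
#' @return marker matrix with no missing entries.
#' @export
impute_markers <- function(markers) {
  if (!anyNA(markers)) return(markers)
  for (k in seq_len(ncol(markers))) {
    col <- markers[, k]
    nas <- is.na(col)
    if (!any(nas)) next
    obs <- col[!nas]
    if (length(obs) == 0L)
      stop(sprintf("marker '%s' has no observed calls (run marker_qc first)",
                   colnames(markers)[k]))
    tab <- tabulate(obs + 1L, nbins = 3L)
    markers[nas, k] <- which.max(tab) - 1L # which.max ties to smaller dosage
  }
  markers
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = W W' / (2 * sum_k p_k (1 - p_k)), where p_k is the observed allele
#' frequency of marker k (mean dosage / 2) and W the column-centered dosage
#' matrix (w_ik = dosage_ik - 2 p_k).
#'
#' @param markers complete (imputed) marker matrix.
#' @return symmetric positive semi-definite J x J matrix with line IDs as
#'   dimnames.
#' @export
compute_grm <- function(markers) {
  if (anyNA(markers)) stop("markers must be imputed before computing the GRM")
  p <- colMeans(markers) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers are monomorphic; GRM denominator is zero")
  W <- sweep(markers, 2L, 2 * p, "-")
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(rownames(markers), rownames(markers))
  G
}

#' Upper Cholesky factor with escalating jitter
#'
#' Returns the upper-triangular Q with Q'Q = G (the usual [chol()] convention,
#' so the feature transform ZG Q' induces covariance ZG G ZG'). If the plain
#' factorization fails, `jitter * I` is added to the diagonal, escalating by
#' factors of 10 up to 1e-2 before giving up.
#'
#' @param G symmetric matrix.
#' @param jitter starting jitter (default 1e-6), used only on failure.
#' @return list with `Q` (upper triangular) and `jitter_used` (0 when the
#'   plain factorization succeeded).
#' @export
cholesky_upper <- function(G, jitter = 1e-6) {
  if (jitter < 0) stop("jitter must be >= 0")
  if (max(abs(G - t(G))) > 1e-8) stop("G is not symmetric")
  Q <- tryCatch(chol(G), error = function(e) NULL)
  if (!is.null(Q)) return(list(Q = Q, jitter_used = 0))
  j <- if (jitter > 0) jitter else 1e-6
  while (j <= 1e-2) {
    Q <- tryCatch(chol(G + diag(j, nrow(G))), error = function(e) NULL)
    if (!is.null(Q)) return(list(Q = Q, jitter_used = j))
    j <- j * 10
  }
  ev <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  stop(sprintf("Cholesky failed at maximum jitter 1e-2; smallest eigenvalue %.3e", ev))
}
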