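#' Build environment, genotype and G-by-E incidence matrices
#'
#' One row per phenotype record. ZE (n x I) marks the record's environment,
#' ZG (n x J) its line, and ZGE (n x I*J) its environment-line cell with
#' environment-major column order: cell (env i, line j) maps to column
#' (i-1)*J + j, matching the block structure of `I_I` \%x\% `Q'`.
#'
#' @param phenotypes data frame with columns `line` and `environment`.
#' @param line_ids ordered character vector of all lines (columns of ZG).
#' @param environment_ids ordered character vector of environments.
#' @return list with matrices `ZE`, `ZG`, `ZGE` and the index vectors
#'   `env_idx`, `line_idx` plus the two ID vectors.
#' @export
build_design_matrices <- function(phenotypes, line_ids, environment_ids) {
  stopifnot(is.data.frame(phenotypes),
            all(c("line", "environment") %in% names(phenotypes)))
  J <- length(line_ids); I <- length(environment_ids)
  line_idx <- match(as.character(phenotypes$line), line_ids)
  env_idx <- match(as.character(phenotypes$environment), environment_ids)
  if (anyNA(line_idx))
    stop("unknown line(s) in phenotypes: ",
         paste(unique(phenotypes$line[is.na(line_idx)]), collapse = ", "))
  if (anyNA(env_idx))
    stop("unknown environment(s) in phenotypes: ",
         paste(unique(phenotypes$environment[is.na(env_idx)]), collapse = ", "))
  n <- nrow(phenotypes)
  ZE <- matrix(0, n, I, dimnames = list(NULL, environment_ids))
  ZE[cbind(seq_len(n), env_idx)] <- 1
  ZG <- matrix(0, n, J, dimnames = list(NULL, line_ids))
  ZG[cbind(seq_len(n), line_idx)] <- 1
  ZGE <- matrix(0, n, I * J)
  colnames(ZGE) <- paste(rep(environment_ids, each = J), rep(line_ids, I), sep = ":")
  ZGE[cbind(seq_len(n), (env_idx - 1L) * J + line_idx)] <- 1
  list(ZE = ZE, ZG = ZG, ZGE = ZGE, env_idx = env_idx, line_idx = line_idx,
       line_ids = line_ids, environment_ids = environment_ids)
}

#' Assemble the network input matrix X
#'
#' Computes `ZG_star = ZG Q'` and, in interaction mode `"I"`,
#' `ZGE_star = ZGE (I_I \%x\% Q')`, then X = \[ZE | ZG_star | ZGE_star\]
#' (mode `"WI"` drops the interaction block: X = \[ZE | ZG_star\]). The
#' Kronecker product is never materialized: because every ZG/ZGE row is an
#' indicator, ZG_star rows are rows of Q' and ZGE_star rows place the same
#' row of Q' inside the record's environment block.
#'
#' @param design output of [build_design_matrices()].
#' @param Q upper Cholesky factor of the genomic relationship matrix
#'   (the `Q` element of [cholesky_upper()]).
#' @param interaction_mode `"I"` (with G-by-E block) or `"WI"` (without).
#' @return list with `X`, `ZG_star`, and `ZGE_star` (`NULL` in mode `"WI"`).
#' @export
assemble_feature_matrix <- function(design, Q, interaction_mode = c("I", "WI")) {
  interaction_mode <- match.arg(interaction_mode)
  J <- length(design$line_ids); I <- length(design$environment_ids)
  if (!all(dim(Q) == c(J, J)))
    stop(sprintf("Q is %dx%d but %d lines are present", nrow(Q), ncol(Q), J))
  tQ <- t(Q)
  n <- length(design$line_idx)
  ZG_star <- tQ[design$line_idx, , drop = FALSE]
  rownames(ZG_star) <- NULL
  colnames(ZG_star) <- paste0("g:", design$line_ids)
  if (interaction_mode == "WI") {
    X <- cbind(design$ZE, ZG_star)
    return(list(X = X, ZG_star = ZG_star, ZGE_star = NULL))
  }
  ZGE_star <- matrix(0, n, I * J)
  colnames(ZGE_star) <- paste0("ge:", colnames(design$ZGE))
  for (i in seq_len(I)) {
    r <- which(design$env_idx == i)
    if (length(r))
      ZGE_star[r, (i - 1L) * J + seq_len(J)] <- tQ[design$line_idx[r], , drop = FALSE]
  }
  X <- cbind(design$ZE, ZG_star, ZGE_star)
  list(X = X, ZG_star = ZG_star, ZGE_star = ZGE_star)
}
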