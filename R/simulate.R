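#' Simulation settings for marker and mixed-phenotype data
#'
#' Describes a multi-environment trial of J inbred-panel lines genotyped at p
#' biallelic markers and phenotyped for a mix of continuous, binary and
#' ordinal traits. Marker dosages are Hardy-Weinberg binomial draws; line
#' genetic values follow the infinitesimal model with line covariance equal to
#' the marker-derived relationship matrix and trait covariance given by
#' `genetic_correlation`; each environment adds a main effect and an
#' independent G-by-E deviation; categorical traits are produced by quantile
#' discretization of the latent values within each environment.
#'
#' Defaults describe the reference simulated world used throughout the test
#' suite: 500 lines, 1000 markers, 3 environments, two continuous traits and
#' one 3-category ordinal trait, all with latent heritability 0.8 and pairwise
#' genetic correlation 0.8, moderate G-by-E (ratio 0.2), 80% of the line x
#' environment grid observed.
#'
#' @param J,I,p lines, environments, markers.
#' @param maf_range allele-frequency range (low, high) in (0, 0.5].
#' @param traits list of per-trait settings: `name`, `kind`, optional
#'   `n_categories` and `quantile_cuts` (categorical), `h2` latent-scale
#'   heritability in \[0, 1\].
#' @param genetic_correlation T x T symmetric PSD matrix with unit diagonal.
#' @param gxe_variance_ratio variance of the per-environment genetic deviation
#'   relative to the main genetic variance (>= 0).
#' @param env_effect_sd standard deviation of environment main effects.
#' @param prop_observed fraction of the line x environment grid phenotyped.
#' @param seed RNG seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(J = 500L, I = 3L, p = 1000L,
                              maf_range = c(0.05, 0.5),
                              traits = NULL,
                              genetic_correlation = NULL,
                              gxe_variance_ratio = 0.2,
                              env_effect_sd = 1,
                              prop_observed = 0.8,
                              seed = 1L) {
  if (is.null(traits))
    traits <- list(
      list(name = "trait1", kind = "continuous", h2 = 0.8),
      list(name = "trait2", kind = "continuous", h2 = 0.8),
      list(name = "trait3", kind = "ordinal", n_categories = 3L,
           quantile_cuts = c(1 / 3, 2 / 3), h2 = 0.8))
  Tn <- length(traits)
  if (is.null(genetic_correlation)) {
    genetic_correlation <- matrix(0.8, Tn, Tn)
    diag(genetic_correlation) <- 1
  }
  if (!isTRUE(all.equal(genetic_correlation, t(genetic_correlation))) ||
      any(abs(diag(genetic_correlation) - 1) > 1e-12))
    stop("genetic_correlation must be symmetric with unit diagonal")
  if (min(eigen(genetic_correlation, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8)
    stop("genetic_correlation is not positive semi-definite")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must satisfy 0 < low <= high <= 0.5")
  for (tr in traits) {
    if (is.null(tr$h2) || tr$h2 < 0 || tr$h2 > 1)
      stop("each trait needs heritability h2 in [0, 1]")
    if (tr$kind != "continuous" && is.null(tr$quantile_cuts))
      stop("categorical traits need quantile_cuts")
  }
  if (gxe_variance_ratio < 0) stop("gxe_variance_ratio must be >= 0")
  if (prop_observed <= 0 || prop_observed > 1)
    stop("prop_observed must be in (0, 1]")
  structure(list(J = as.integer(J), I = as.integer(I), p = as.integer(p),
                 maf_range = maf_range, traits = traits,
                 genetic_correlation = genetic_correlation,
                 gxe_variance_ratio = gxe_variance_ratio,
                 env_effect_sd = env_effect_sd, prop_observed = prop_observed,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate Hardy-Weinberg marker dosages
#'
#' Per marker, an allele frequency is drawn uniformly from `maf_range` and
#' dosages are independent binomial(2, freq) draws per line.
#'
#' @param config a [simulation_config()].
#' @return marker matrix (see [marker_matrix()]), lines `L0001`... x markers
#'   `M0001`...
#' @export
simulate_markers <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  freqs <- stats::runif(config$p, config$maf_range[1], config$maf_range[2])
  M <- vapply(freqs, function(f) stats::rbinom(config$J, 2L, f),
              numeric(config$J))
  dimnames(M) <- list(sprintf("L%04d", seq_len(config$J)),
                      sprintf("M%04d", seq_len(config$p)))
  M
}

#' Quantile discretization of a continuous vector
#'
#' Thresholds are the empirical quantiles of `values` at `quantile_cuts`
#' (linear-interpolation convention, R quantile type 7). A value falls in
#' category `1 + #(thresholds strictly below it)`; a value equal to a
#' threshold goes to the lower category. Massive ties leaving a category empty
#' raise a warning, not an error.
#'
#' @param values numeric vector.
#' @param quantile_cuts strictly increasing fractions in (0, 1).
#' @return integer categories in 1..(length(cuts) + 1).
#' @export
discretize_by_quantiles <- function(values, quantile_cuts) {
  if (any(quantile_cuts <= 0) || any(quantile_cuts >= 1) ||
      is.unsorted(quantile_cuts, strictly = TRUE))
    stop("quantile_cuts must be strictly increasing within (0, 1)")
  if (length(values) < length(quantile_cuts) + 1L)
    stop("need at least length(cuts) + 1 values")
  thr <- stats::quantile(values, quantile_cuts, type = 7, names = FALSE)
  cats <- vapply(values, function(v) 1L + sum(thr < v), integer(1L))
  k <- length(quantile_cuts) + 1L
  if (length(unique(cats)) < k)
    warning(sprintf("ties left %d of %d categories empty",
                    k - length(unique(cats)), k))
  cats
}

#' Simulate mixed-trait phenotypes over environments
#'
#' Line genetic values for all traits are drawn jointly with line covariance
#' equal to the (jittered) marker-derived relationship matrix and trait
#' covariance `genetic_correlation` (unit genetic variances on the latent
#' scale). Each environment contributes a main effect (per trait) and an
#' independent G-by-E genetic deviation scaled by `gxe_variance_ratio`.
#' Residual noise is calibrated so each trait's latent-scale heritability —
#' total genetic variance (main + G-by-E) over within-environment phenotypic
#' variance — equals its `h2`. Continuous traits are the latent values;
#' categorical traits are quantile-discretized within each environment.
#'
#' @param markers marker matrix from [simulate_markers()].
#' @param config the same [simulation_config()].
#' @return list with `markers`, `phenotypes` (data frame: line, environment,
#'   one column per trait), `truth` (same shape, total genetic values),
#'   `latent` (pre-discretization phenotypes) and `config`.
#' @export
simulate_multitrait_phenotypes <- function(markers, config) {
  J <- nrow(markers); I <- config$I; Tn <- length(config$traits)
  G <- compute_grm(markers)
  Lg <- t(cholesky_upper(G, 1e-6)$Q)
  Ct <- chol(config$genetic_correlation + diag(1e-10, Tn))
  set.seed(derive_seed(config$seed, 2L))
  # line main genetic values: matrix-normal(0, G, R)
  U <- Lg %*% matrix(stats::rnorm(J * Tn), J, Tn) %*% Ct
  mean_diag <- mean(diag(G))
  var_g_total <- mean_diag * (1 + config$gxe_variance_ratio)
  env_eff <- matrix(stats::rnorm(I * Tn, 0, config$env_effect_sd), I, Tn)
  cells <- expand.grid(line = seq_len(J), env = seq_len(I))
  n_obs <- max(1L, round(config$prop_observed * nrow(cells)))
  obs <- sort(sample.int(nrow(cells), n_obs))
  cells <- cells[obs, , drop = FALSE]
  truth_g <- latent <- matrix(NA_real_, nrow(cells), Tn)
  ge_list <- lapply(seq_len(I), function(i)
    sqrt(config$gxe_variance_ratio) *
      (Lg %*% matrix(stats::rnorm(J * Tn), J, Tn) %*% Ct))
  for (t in seq_len(Tn)) {
    h2 <- config$traits[[t]]$h2
    # h2 = 0: genetic values are still drawn (and reported as truth) but get
    # zero weight in the phenotype, which is then pure environment + noise
    sd_e <- if (h2 > 0) sqrt(var_g_total * (1 - h2) / h2) else sqrt(var_g_total)
    g_ge <- vapply(seq_len(nrow(cells)),
                   function(r) ge_list[[cells$env[r]]][cells$line[r], t],
                   numeric(1L))
    truth_g[, t] <- U[cells$line, t] + g_ge
    latent[, t] <- env_eff[cells$env, t] + (h2 > 0) * truth_g[, t] +
      stats::rnorm(nrow(cells), 0, sd_e)
  }
  env_ids <- sprintf("E%02d", seq_len(I))
  pheno <- data.frame(line = rownames(markers)[cells$line],
                      environment = env_ids[cells$env],
                      stringsAsFactors = FALSE)
  truth <- pheno
  for (t in seq_len(Tn)) {
    tr <- config$traits[[t]]
    truth[[tr$name]] <- truth_g[, t]
    if (tr$kind == "continuous") {
      pheno[[tr$name]] <- latent[, t]
    } else {
      lab <- integer(nrow(pheno))
      for (i in seq_len(I)) {
        sel <- cells$env == i
        if (any(sel))
          lab[sel] <- discretize_by_quantiles(latent[sel, t], tr$quantile_cuts)
      }
      pheno[[tr$name]] <- lab
    }
  }
  colnames(latent) <- vapply(config$traits, `[[`, "", "name")
  list(markers = markers, phenotypes = pheno, truth = truth,
       latent = cbind(pheno[, 1:2], as.data.frame(latent)), config = config)
}

#' Trait specs implied by a simulation config
#' @param config a [simulation_config()].
#' @return list of [trait_spec()] objects.
#' @export
simulated_trait_specs <- function(config) {
  lapply(config$traits, function(tr)
    trait_spec(tr$name, tr$kind,
               n_categories = if (tr$kind == "ordinal")
                 length(tr$quantile_cuts) + 1L else NULL))
}
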