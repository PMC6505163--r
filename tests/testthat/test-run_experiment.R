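test_that("report has one row per trait x test-environment x fold", {
  sim <- tiny_dataset(seed = 3, J = 50L, I = 3L, prop_observed = 1)
  specs <- simulated_trait_specs(sim$config)
  cfg <- run_config(specs, grid = tuning_grid(c(2L, 5L), 8L),
                    n_outer_folds = 5L, qc = NULL, seed = 11L)
  rep5 <- suppressWarnings(run_experiment(cfg, sim$markers, sim$phenotypes))
  expect_identical(nrow(rep5$rows), 2L * 3L * 5L)
  expect_identical(nrow(rep5$summary), 2L * 3L)
  expect_true(all(rep5$rows$metric[rep5$rows$trait == "gy"] == "pearson"))
  expect_true(all(rep5$rows$metric[rep5$rows$trait == "ht"] == "pccc"))
  expect_true(all(rep5$rows$value[rep5$rows$metric == "pccc"] >= 0 &
                    rep5$rows$value[rep5$rows$metric == "pccc"] <= 1,
                  na.rm = TRUE))
  # summary equals the mean of that cell's fold values
  for (i in seq_len(nrow(rep5$summary))) {
    s <- rep5$summary[i, ]
    v <- rep5$rows$value[rep5$rows$trait == s$trait &
                           rep5$rows$environment == s$environment]
    expect_equal(s$value, mean(v, na.rm = TRUE))
  }
})

test_that("two folds, one trait, one environment gives two rows", {
  cfg_sim <- simulation_config(
    J = 30L, I = 1L, p = 60L,
    traits = list(list(name = "gy", kind = "continuous", h2 = 0.8)),
    genetic_correlation = matrix(1), prop_observed = 1, seed = 8L)
  sim <- simulate_multitrait_phenotypes(simulate_markers(cfg_sim), cfg_sim)
  cfg <- run_config(simulated_trait_specs(cfg_sim),
                    grid = tuning_grid(3L, 8L), n_outer_folds = 2L,
                    qc = NULL, seed = 4L)
  rep2 <- run_experiment(cfg, sim$markers, sim$phenotypes)
  expect_identical(nrow(rep2$rows), 2L)
  expect_identical(sort(rep2$rows$fold), 1:2)
})

test_that("UDL trains one network per trait with the same report shape", {
  sim <- tiny_dataset(seed = 6, J = 40L, I = 2L, prop_observed = 1)
  specs <- simulated_trait_specs(sim$config)
  base <- list(grid = tuning_grid(3L, 8L), n_outer_folds = 2L, qc = NULL,
               seed = 9L)
  rep_mt <- do.call(run_config, c(list(specs, model_kind = "MTDLMP"), base))
  rep_ud <- do.call(run_config, c(list(specs, model_kind = "UDL"), base))
  r1 <- suppressWarnings(run_experiment(rep_mt, sim$markers, sim$phenotypes))
  r2 <- suppressWarnings(run_experiment(rep_ud, sim$markers, sim$phenotypes))
  expect_identical(dim(r1$rows), dim(r2$rows))
  expect_identical(r1$rows[, c("trait", "environment", "fold", "metric")],
                   r2$rows[, c("trait", "environment", "fold", "metric")])
  # one tuning entry per fold for MTDLMP, one per trait per fold for UDL
  expect_identical(nrow(r1$tuning), 2L)
  expect_identical(nrow(r2$tuning), 2L * 2L)
  # identical fold plans (same master seed drives the partition)
  expect_identical(r1$plan, r2$plan)
})

test_that("identical config and seed reproduce the report", {
  sim <- tiny_dataset(seed = 12, J = 40L, I = 2L, prop_observed = 0.9)
  specs <- simulated_trait_specs(sim$config)
  cfg <- run_config(specs, grid = tuning_grid(c(2L, 4L), 8L),
                    n_outer_folds = 3L, qc = NULL, seed = 20L)
  ra <- suppressWarnings(run_experiment(cfg, sim$markers, sim$phenotypes))
  rb <- suppressWarnings(run_experiment(cfg, sim$markers, sim$phenotypes))
  expect_identical(ra$plan, rb$plan)
  expect_identical(ra$tuning, rb$tuning)
  expect_lt(max(abs(ra$rows$value - rb$rows$value), na.rm = TRUE), 1e-6)
  expect_equal(ra$summary, rb$summary)
})

test_that("phenotyped lines absent from the markers are rejected", {
  sim <- tiny_dataset(seed = 14, J = 30L, I = 2L, prop_observed = 1)
  specs <- simulated_trait_specs(sim$config)
  cfg <- run_config(specs, grid = tuning_grid(2L, 8L), n_outer_folds = 2L,
                    qc = NULL, seed = 3L)
  ph <- sim$phenotypes
  ph$line[1] <- "GHOST"
  expect_error(run_experiment(cfg, sim$markers, ph), "GHOST")
})

test_that("a training fold missing a category raises a descriptive error", {
  sim <- tiny_dataset(seed = 16, J = 30L, I = 2L, prop_observed = 1)
  specs <- simulated_trait_specs(sim$config)
  ph <- sim$phenotypes
  # make category 2 so rare it cannot appear in every training fold
  plan <- make_cv2_folds(ph, 2L, derive_seed(5L, 7L))
  ph$ht <- 1L
  ph$ht[which(plan$fold == 2L)[1]] <- 2L # only record with category 2 is in fold 2
  cfg <- run_config(specs, grid = tuning_grid(2L, 8L), n_outer_folds = 2L,
                    qc = NULL, seed = 5L)
  expect_error(run_experiment(cfg, sim$markers, ph),
               "training set of fold 2 lacks category 2 of trait 'ht'")
})

test_that("test-fold records never leak into training or standardization", {
  sim <- tiny_dataset(seed = 18, J = 40L, I = 2L, prop_observed = 1)
  specs <- simulated_trait_specs(sim$config)
  cfg <- run_config(specs, grid = tuning_grid(c(2L, 4L), 8L),
                    n_outer_folds = 2L, qc = NULL, seed = 6L)
  base <- suppressWarnings(run_experiment(cfg, sim$markers, sim$phenotypes))

  # poison the phenotype values (not line/env identity) of fold-1 test records
  plan <- base$plan
  poisoned <- sim$phenotypes
  sel <- plan$fold == 1L
  poisoned$gy[sel] <- 1e6 + seq_len(sum(sel))
  poisoned$ht[sel] <- ifelse(poisoned$ht[sel] == 1L, 2L, 1L)
  rep_p <- suppressWarnings(run_experiment(cfg, sim$markers, poisoned))

  expect_identical(rep_p$plan, base$plan)
  # fold-1 training/tuning saw no poisoned value: identical tuning choice and
  # identical fold-1 predictions
  t1 <- function(r) r$tuning[r$tuning$fold == 1L, ]
  expect_identical(t1(rep_p), t1(base))
  p1 <- function(r) r$predictions[r$predictions$fold == 1L, "predicted"]
  expect_identical(p1(rep_p), p1(base))
})
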