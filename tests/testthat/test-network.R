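mixed_specs <- function() list(trait_spec("y", "continuous"),
                               trait_spec("b", "binary"),
                               trait_spec("o", "ordinal", 3L))

test_that("trait_spec ties kind to activation and loss", {
  expect_identical(trait_spec("x", "continuous")$output_activation, "relu")
  expect_identical(trait_spec("x", "binary")$loss, "binary_crossentropy")
  sp <- trait_spec("x", "ordinal", 4L)
  expect_identical(sp$output_activation, "softmax")
  expect_identical(sp$n_categories, 4L)
  expect_error(trait_spec("x", "ordinal"), "n_categories")
  expect_error(trait_spec("x", "binary", 3L), "exactly 2")
})

test_that("encode_targets maps labels and passes continuous through", {
  ph <- data.frame(y = c(1.5, -0.2, 3), b = c(1L, 2L, 2L), o = c(2L, 1L, 3L))
  enc <- encode_targets(ph, mixed_specs())
  expect_identical(enc$y, ph$y)
  expect_identical(enc$b, c(0, 1, 1))
  expect_identical(enc$o[1, ], c(0, 1, 0))
  ph$o[2] <- 4L
  expect_error(encode_targets(ph, mixed_specs()), "outside 1..3")
  ph$o[2] <- NA
  expect_error(encode_targets(ph, mixed_specs()), "missing values")
})

test_that("standardization uses training statistics and inverts exactly", {
  st <- standardize_continuous(c(1, 3))
  expect_equal(st$values, c(-sqrt(2) / 2, sqrt(2) / 2))
  expect_equal(st$mean, 2)
  expect_equal(st$sd, sqrt(2))
  ap <- standardize_continuous(c(1, 3), apply_to = 4)
  expect_equal(ap$values, 2 / sqrt(2), tolerance = 1e-12)
  expect_equal(destandardize(1.4142135623730951, list(mean = 2, sd = sqrt(2))),
               4, tolerance = 1e-12)
  expect_error(standardize_continuous(c(5, 5, 5)), "constant")
})

test_that("forward_pass matches the straight-line nested-sum oracle", {
  specs <- mixed_specs()
  for (layers in 1:3) {
    w <- random_weights(3L, 2L, specs, n_layers = layers, seed = layers)
    set.seed(100 + layers)
    X <- matrix(rnorm(5 * 3), 5, 3)
    got <- forward_pass(X, w, specs)
    want <- forward_bruteforce(X, w, specs)
    expect_lt(max(abs(got$y - want$y)), 1e-10)
    expect_lt(max(abs(got$b - want$b)), 1e-10)
    expect_lt(max(abs(got$o - want$o)), 1e-10)
    expect_lt(max(abs(rowSums(got$o) - 1)), 1e-6)
    expect_true(all(got$o >= 0 & got$o <= 1) && all(got$b >= 0 & got$b <= 1))
  }
})

test_that("forward_pass edge activations: ReLU, sigmoid(0), uniform softmax", {
  specs <- list(trait_spec("b", "binary"), trait_spec("o", "ordinal", 3L))
  w <- list(hidden = list(list(W = diag(2), b = c(0, 0))),
            heads = list(b = list(W = matrix(0, 2, 1), b = 0),
                         o = list(W = matrix(0, 2, 3), b = c(0, 0, 0))))
  out <- forward_pass(matrix(c(1, -1), 1, 2), w, specs)
  expect_identical(out$b, 0.5)            # sigmoid at zero
  expect_equal(out$o[1, ], rep(1 / 3, 3)) # softmax symmetry
  # ReLU zeroes negatives in the hidden layer
  wc <- list(hidden = w$hidden,
             heads = list(y = list(W = matrix(c(1, 1), 2, 1), b = 0)))
  expect_identical(forward_pass(matrix(c(1, -1), 1, 2), wc,
                                list(trait_spec("y", "continuous")))$y, 1)
  expect_error(forward_pass(matrix(0, 1, 3), w, specs), "expects 2 inputs")
})

test_that("compute_total_loss sums per-trait means (hand example 1 + ln 2)", {
  specs <- list(trait_spec("y", "continuous"), trait_spec("b", "binary"))
  preds <- list(y = c(2, 1), b = c(0.5, 0.5))
  targets <- list(y = c(1, 2), b = c(0, 1))
  expect_equal(compute_total_loss(preds, targets, specs), 1 + log(2),
               tolerance = 1e-12)
  # perfect continuous predictions contribute zero
  expect_equal(compute_total_loss(list(y = c(1, 2)), list(y = c(1, 2)),
                                  list(specs[[1]])), 0)
  # indicator-matching ordinal prediction is ~0 after clipping
  o <- matrix(c(1, 0, 0), 1)
  expect_lt(compute_total_loss(list(o = o), list(o = o),
                               list(trait_spec("o", "ordinal", 3L))), 1e-6)
})

test_that("epochs = 0 returns the seeded initialization unchanged", {
  specs <- mixed_specs()
  X <- matrix(rnorm(40 * 4), 40, 4)
  cfg <- network_config(units = 6L, epochs = 0L, seed = 77L)
  targets <- list(y = rnorm(40), b = rep(c(0, 1), 20),
                  o = diag(3)[sample(3, 40, TRUE), ])
  fit <- train_network(X, targets, cfg, specs)
  expect_identical(fit$weights, init_network_weights(4L, cfg, specs, seed = 77L))
  expect_identical(nrow(fit$trace), 0L)
})

test_that("seeded training reduces loss, memorizes, and is reproducible", {
  set.seed(41)
  # linearly separable binary toy
  X <- rbind(matrix(rnorm(20, -2, 0.5), 10, 2), matrix(rnorm(20, 2, 0.5), 10, 2))
  spec_b <- list(trait_spec("b", "binary"))
  tb <- list(b = rep(c(0, 1), each = 10))
  cfg <- network_config(units = 8L, epochs = 200L, dropout_rate = 0,
                        batch_size = 8L, seed = 5L)
  fit <- train_network(X, tb, cfg, spec_b)
  expect_lt(fit$trace$train_loss[200], fit$trace$train_loss[1])
  expect_identical(nrow(fit$trace), 200L)

  # 8-record continuous toy memorized with enough capacity; targets kept
  # positive because the continuous head is ReLU-activated
  set.seed(42)
  Xc <- matrix(rnorm(8 * 3), 8, 3)
  yc <- runif(8, 0.5, 2)
  spec_c <- list(trait_spec("y", "continuous"))
  cfgc <- network_config(units = 32L, epochs = 600L, dropout_rate = 0,
                         learning_rate = 0.01, batch_size = 8L, seed = 6L)
  fitc <- train_network(Xc, list(y = yc), cfgc, spec_c)
  expect_lt(fitc$trace$train_loss[600], 0.01)

  # identical seed -> identical loss trace and weights
  fit2 <- train_network(X, tb, cfg, spec_b)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$weights, fit2$weights)
})

test_that("predict_traits decodes with the stated threshold and tie rules", {
  specs <- mixed_specs()
  w <- random_weights(3L, 4L, specs, seed = 8L)
  X <- matrix(rnorm(6 * 3), 6, 3)
  out <- predict_traits(X, w, specs,
                        stand_stats = list(y = list(mean = 2, sd = sqrt(2))))
  raw <- forward_pass(X, w, specs)
  expect_equal(out$y$values, raw$y * sqrt(2) + 2)
  expect_identical(out$b$labels, ifelse(raw$b >= 0.5, 2L, 1L))
  expect_identical(out$o$labels, max.col(raw$o, ties.method = "first"))
  expect_error(predict_traits(X, w, specs), "standardization statistics")

  # decision rules on exact boundary values
  wb <- list(hidden = list(list(W = matrix(0, 1, 1), b = 0)),
             heads = list(b = list(W = matrix(0, 1, 1), b = 0),
                          o = list(W = matrix(0, 1, 3), b = c(0.5, 0.5, 0))))
  sp2 <- list(trait_spec("b", "binary"), trait_spec("o", "ordinal", 3L))
  dec <- predict_traits(matrix(1), wb, sp2)
  expect_identical(dec$b$labels, 2L)  # p = 0.5 exactly -> upper category
  expect_identical(dec$o$labels, 1L)  # tied argmax -> lowest category
})

test_that("dropout is active only in training mode", {
  specs <- list(trait_spec("y", "continuous"))
  w <- random_weights(5L, 50L, specs, seed = 3L)
  X <- matrix(rnorm(10 * 5), 10, 5)
  a <- forward_pass(X, w, specs)
  b <- forward_pass(X, w, specs)
  expect_identical(a, b) # deterministic with training off
  set.seed(1); tr1 <- forward_pass(X, w, specs, training_mode = TRUE, dropout_rate = 0.5)
  set.seed(2); tr2 <- forward_pass(X, w, specs, training_mode = TRUE, dropout_rate = 0.5)
  expect_false(identical(tr1, tr2))
})

test_that("UDL single-trait network is architecturally identical to MTDLMP", {
  cfg <- network_config(units = 7L, seed = 9L)
  single <- list(trait_spec("y", "continuous"))
  w_mt <- init_network_weights(12L, cfg, single, seed = 9L)
  w_ud <- init_network_weights(12L, cfg, single, seed = 9L)
  expect_identical(w_mt, w_ud)
  n_par <- function(w) sum(vapply(unlist(w, recursive = FALSE),
                                  function(p) length(p$W) + length(p$b), 0))
  expect_equal(n_par(w_mt), 12 * 7 + 7 + 7 + 1)
})

test_that("weight archives round-trip bit-identically", {
  specs <- mixed_specs()
  w <- random_weights(4L, 5L, specs, n_layers = 2L, seed = 13L)
  path <- withr::local_tempfile(fileext = ".tsv")
  save_network_weights(w, path)
  w2 <- load_network_weights(path)
  X <- matrix(rnorm(8 * 4), 8, 4)
  expect_identical(forward_pass(X, w, specs), forward_pass(X, w2, specs))
})
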