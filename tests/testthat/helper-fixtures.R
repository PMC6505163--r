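# Shared fixture builders: everything is generated in code at test time.

tiny_sim_config <- function(seed = 3L, J = 40L, I = 2L, p = 100L,
                            prop_observed = 0.9) {
  simulation_config(
    J = J, I = I, p = p,
    traits = list(list(name = "gy", kind = "continuous", h2 = 0.8),
                  list(name = "ht", kind = "binary", quantile_cuts = 0.5,
                       h2 = 0.8)),
    genetic_correlation = matrix(c(1, 0.8, 0.8, 1), 2L),
    prop_observed = prop_observed, seed = seed)
}

tiny_dataset <- function(seed = 3L, ...) {
  cfg <- tiny_sim_config(seed = seed, ...)
  simulate_multitrait_phenotypes(simulate_markers(cfg), cfg)
}

# fast run config for shape/reproducibility tests (not for accuracy)
quick_run_config <- function(specs, ..., seed = 11L) {
  run_config(specs, grid = tuning_grid(c(3L, 8L), 8L), n_outer_folds = 3L,
             qc = NULL, seed = seed, ...)
}

random_markers <- function(J, p, seed, maf = c(0.1, 0.5)) {
  set.seed(seed)
  f <- runif(p, maf[1], maf[2])
  m <- vapply(f, function(x) rbinom(J, 2L, x), numeric(J))
  dimnames(m) <- list(sprintf("L%03d", seq_len(J)), sprintf("M%03d", seq_len(p)))
  m
}

# independent loop-based VanRaden GRM (oracle for compute_grm)
grm_bruteforce <- function(markers) {
  J <- nrow(markers); p <- ncol(markers)
  freq <- numeric(p)
  for (k in seq_len(p)) freq[k] <- mean(markers[, k]) / 2
  denom <- 0
  for (k in seq_len(p)) denom <- denom + 2 * freq[k] * (1 - freq[k])
  G <- matrix(0, J, J)
  for (i in seq_len(J)) for (j in seq_len(J)) {
    s <- 0
    for (k in seq_len(p))
      s <- s + (markers[i, k] - 2 * freq[k]) * (markers[j, k] - 2 * freq[k])
    G[i, j] <- s / denom
  }
  G
}

# straight-line nested-sum forward pass (oracle for forward_pass)
forward_bruteforce <- function(X, weights, specs) {
  n <- nrow(X)
  out <- list()
  for (sp in specs) out[[sp$name]] <-
    if (sp$kind == "ordinal") matrix(0, n, sp$n_categories) else numeric(n)
  for (i in seq_len(n)) {
    v <- X[i, ]
    for (l in seq_along(weights$hidden)) {
      W <- weights$hidden[[l]]$W; b <- weights$hidden[[l]]$b
      h <- numeric(ncol(W))
      for (j in seq_len(ncol(W))) {
        s <- b[j]
        for (p in seq_len(nrow(W))) s <- s + W[p, j] * v[p]
        h[j] <- max(s, 0)
      }
      v <- h
    }
    for (sp in specs) {
      W <- weights$heads[[sp$name]]$W; b <- weights$heads[[sp$name]]$b
      h <- numeric(ncol(W))
      for (t in seq_len(ncol(W))) {
        s <- b[t]
        for (k in seq_len(nrow(W))) s <- s + W[k, t] * v[k]
        h[t] <- s
      }
      if (sp$kind == "continuous") out[[sp$name]][i] <- max(h[1L], 0)
      else if (sp$kind == "binary") out[[sp$name]][i] <- 1 / (1 + exp(-h[1L]))
      else out[[sp$name]][i, ] <- exp(h - max(h)) / sum(exp(h - max(h)))
    }
  }
  out
}

random_weights <- function(n_inputs, units, specs, n_layers = 1L, seed = 1L) {
  init_network_weights(n_inputs,
                       network_config(n_hidden_layers = n_layers, units = units),
                       specs, seed = seed)
}
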