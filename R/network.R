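#' Network hyperparameters
#'
#' Architecture and optimizer settings for the densely connected multi-output
#' network: all hidden layers share the same unit count `units` and use ReLU
#' activations; each trait gets its own output head (ReLU for continuous,
#' sigmoid for binary, softmax for ordinal). Training minimizes the unweighted
#' sum of per-trait mean losses by mini-batch Adam with inverted dropout after
#' every hidden layer.
#'
#' @param n_hidden_layers 1, 2 or 3.
#' @param units hidden units per layer (shared across layers).
#' @param epochs training epochs (0 returns the initialization unchanged).
#' @param dropout_rate dropout probability in \[0, 1), default 0.3.
#' @param learning_rate Adam step size, default 0.001.
#' @param batch_size mini-batch size, default 32.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return object of class `network_config`.
#' @export
network_config <- function(n_hidden_layers = 1L, units = 50L, epochs = 50L,
                           dropout_rate = 0.3, learning_rate = 0.001,
                           batch_size = 32L, seed = 1L) {
  if (!n_hidden_layers %in% 1:3) stop("n_hidden_layers must be 1, 2 or 3")
  if (units < 1L) stop("units must be >= 1")
  if (epochs < 0L) stop("epochs must be >= 0")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 units = as.integer(units), epochs = as.integer(epochs),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "network_config")
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  x <- exp(x - apply(x, 1L, max))
  x / rowSums(x)
}

head_width <- function(sp) if (sp$kind == "ordinal") sp$n_categories else 1L

glorot_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize network weights
#'
#' Variance-scaled (Glorot) uniform weights and zero biases, drawn from the
#' current RNG stream unless `seed` is given.
#'
#' @param n_inputs number of input features (columns of X).
#' @param config a [network_config()].
#' @param specs list of [trait_spec()] objects (the output heads).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return list with `hidden` (per layer: `W`, `b`) and `heads`
#'   (per trait: `W`, `b`).
#' @export
init_network_weights <- function(n_inputs, config, specs, seed = NULL) {
  specs <- check_trait_specs(specs)
  if (!is.null(seed)) set.seed(seed)
  dims <- c(n_inputs, rep(config$units, config$n_hidden_layers))
  hidden <- lapply(seq_len(config$n_hidden_layers), function(l)
    list(W = glorot_uniform(dims[l], dims[l + 1L]), b = numeric(dims[l + 1L])))
  heads <- lapply(specs, function(sp)
    list(W = glorot_uniform(config$units, head_width(sp)),
         b = numeric(head_width(sp))))
  names(heads) <- vapply(specs, `[[`, "", "name")
  list(hidden = hidden, heads = heads)
}

# Forward pass keeping the per-layer cache needed for backpropagation.
# Dropout masks are drawn from the current RNG stream when training.
nn_forward_cache <- function(X, weights, specs, dropout_rate = 0, training = FALSE) {
  L <- length(weights$hidden)
  A <- vector("list", L + 1L); Z <- vector("list", L); masks <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    h <- weights$hidden[[l]]
    Z[[l]] <- sweep(A[[l]] %*% h$W, 2L, h$b, "+")
    a <- relu(Z[[l]])
    if (training && dropout_rate > 0) {
      masks[[l]] <- matrix(
        (stats::runif(length(a)) >= dropout_rate) / (1 - dropout_rate),
        nrow(a), ncol(a))
      a <- a * masks[[l]]
    }
    A[[l + 1L]] <- a
  }
  logits <- preds <- list()
  for (sp in specs) {
    hd <- weights$heads[[sp$name]]
    s <- sweep(A[[L + 1L]] %*% hd$W, 2L, hd$b, "+")
    logits[[sp$name]] <- s
    preds[[sp$name]] <- switch(sp$kind,
      continuous = as.numeric(relu(s)),
      binary = as.numeric(sigmoid(s)),
      ordinal = softmax_rows(s))
  }
  list(A = A, Z = Z, masks = masks, logits = logits, preds = preds)
}

#' Forward pass of the multi-output network
#'
#' Hidden layers apply ReLU; output heads apply the trait-specific activation.
#' Dropout is active only when `training_mode = TRUE` (masks drawn from the
#' current RNG stream); with it off, the pass is a deterministic function of
#' `(X, weights)`.
#'
#' @param X feature rows (n x N1 matrix).
#' @param weights weights from [init_network_weights()] or [train_network()].
#' @param specs list of [trait_spec()] objects.
#' @param training_mode apply dropout?
#' @param dropout_rate dropout probability used when `training_mode` is TRUE.
#' @return named list per trait: numeric vector (continuous on the model
#'   scale, binary probabilities) or row-stochastic matrix (ordinal).
#' @export
forward_pass <- function(X, weights, specs, training_mode = FALSE, dropout_rate = 0) {
  specs <- check_trait_specs(specs)
  if (ncol(X) != nrow(weights$hidden[[1L]]$W))
    stop(sprintf("X has %d columns but the network expects %d inputs",
                 ncol(X), nrow(weights$hidden[[1L]]$W)))
  nn_forward_cache(X, weights, specs, dropout_rate, training_mode)$preds
}

clip_prob <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)

#' Total multi-trait loss
#'
#' Unweighted sum over traits of the mean per-record loss: squared error for
#' continuous traits (on the standardized scale), binary cross-entropy, and
#' categorical cross-entropy, with probabilities clipped to
#' \[1e-7, 1 - 1e-7\] before taking logs.
#'
#' @param predictions output of [forward_pass()].
#' @param targets output of [encode_targets()] (continuous already standardized).
#' @param specs list of [trait_spec()] objects.
#' @return scalar total loss.
#' @export
compute_total_loss <- function(predictions, targets, specs) {
  specs <- check_trait_specs(specs)
  total <- 0
  for (sp in specs) {
    pred <- predictions[[sp$name]]; y <- targets[[sp$name]]
    total <- total + switch(sp$kind,
      continuous = mean((pred - y)^2),
      binary = {
        p <- clip_prob(pred)
        -mean(y * log(p) + (1 - y) * log(1 - p))
      },
      ordinal = {
        p <- clip_prob(pred)
        -mean(rowSums(y * log(p)))
      })
  }
  total
}

# Gradients of the total loss w.r.t. every weight, given a forward cache.
nn_backward <- function(cache, weights, targets, specs, dropout_rate) {
  L <- length(weights$hidden)
  nb <- nrow(cache$A[[1L]])
  AL <- cache$A[[L + 1L]]
  dAL <- matrix(0, nb, ncol(AL))
  g_heads <- list()
  for (sp in specs) {
    s <- cache$logits[[sp$name]]; y <- targets[[sp$name]]
    dS <- switch(sp$kind,
      continuous = (2 / nb) * (relu(s) - y) * (s > 0),
      binary = (sigmoid(s) - y) / nb,
      ordinal = (softmax_rows(s) - y) / nb)
    dS <- matrix(dS, nb)
    hd <- weights$heads[[sp$name]]
    g_heads[[sp$name]] <- list(W = crossprod(AL, dS), b = colSums(dS))
    dAL <- dAL + dS %*% t(hd$W)
  }
  g_hidden <- vector("list", L)
  dA <- dAL
  for (l in rev(seq_len(L))) {
    dZ <- dA
    if (!is.null(cache$masks[[l]])) dZ <- dZ * cache$masks[[l]]
    dZ <- dZ * (cache$Z[[l]] > 0)
    g_hidden[[l]] <- list(W = crossprod(cache$A[[l]], dZ), b = colSums(dZ))
    if (l > 1L) dA <- dZ %*% t(weights$hidden[[l]]$W)
  }
  list(hidden = g_hidden, heads = g_heads)
}

adam_init <- function(weights) {
  zero <- function(x) list(W = x$W * 0, b = x$b * 0)
  list(m = list(hidden = lapply(weights$hidden, zero),
                heads = lapply(weights$heads, zero)),
       v = list(hidden = lapply(weights$hidden, zero),
                heads = lapply(weights$heads, zero)),
       t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  upd <- function(group, key) {
    for (i in seq_along(weights[[group]])) {
      g <- grads[[group]][[i]][[key]]
      m <- beta1 * state$m[[group]][[i]][[key]] + (1 - beta1) * g
      v <- beta2 * state$v[[group]][[i]][[key]] + (1 - beta2) * g^2
      state$m[[group]][[i]][[key]] <<- m
      state$v[[group]][[i]][[key]] <<- v
      weights[[group]][[i]][[key]] <<-
        weights[[group]][[i]][[key]] - lr * (m / c1) / (sqrt(v / c2) + eps)
    }
  }
  for (grp in c("hidden", "heads")) for (key in c("W", "b")) upd(grp, key)
  list(weights = weights, state = state)
}

subset_targets <- function(targets, specs, idx) {
  out <- list()
  for (sp in specs) {
    y <- targets[[sp$name]]
    out[[sp$name]] <- if (is.matrix(y)) y[idx, , drop = FALSE] else y[idx]
  }
  out
}

#' Train the multi-output network
#'
#' Seeded mini-batch Adam training of the total multi-trait loss for
#' `config$epochs` epochs. Weights are initialized from the seeded RNG; with
#' `epochs = 0` the initialization is returned unchanged. After every epoch the
#' full-data training loss (and validation loss, if `validation` is supplied)
#' is recorded without dropout.
#'
#' @param X feature matrix (records x inputs).
#' @param targets encoded targets (see [encode_targets()]); continuous entries
#'   must already be standardized.
#' @param config a [network_config()].
#' @param specs list of [trait_spec()] objects.
#' @param validation optional list with elements `X` and `targets` monitored
#'   per epoch.
#' @return list with `weights` and `trace`
#'   (data frame: epoch, train_loss, val_loss).
#' @export
train_network <- function(X, targets, config, specs, validation = NULL) {
  specs <- check_trait_specs(specs)
  n <- nrow(X)
  if (n < 1L) stop("training requires at least one record")
  set.seed(config$seed)
  weights <- init_network_weights(ncol(X), config, specs)
  trace <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric())
  if (config$epochs == 0L) return(list(weights = weights, trace = trace))
  state <- adam_init(weights)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      cache <- nn_forward_cache(X[idx, , drop = FALSE], weights, specs,
                                config$dropout_rate, training = TRUE)
      grads <- nn_backward(cache, weights, subset_targets(targets, specs, idx),
                           specs, config$dropout_rate)
      stepped <- adam_step(weights, grads, state, config$learning_rate)
      weights <- stepped$weights; state <- stepped$state
    }
    tr_loss <- compute_total_loss(forward_pass(X, weights, specs), targets, specs)
    va_loss <- if (is.null(validation)) NA_real_ else
      compute_total_loss(forward_pass(validation$X, weights, specs),
                         validation$targets, specs)
    if (!is.finite(tr_loss) || (!is.null(validation) && !is.finite(va_loss)))
      stop(sprintf("non-finite loss at epoch %d; try a smaller learning rate", epoch))
    trace <- rbind(trace, data.frame(epoch = epoch, train_loss = tr_loss,
                                     val_loss = va_loss))
  }
  list(weights = weights, trace = trace)
}

#' Predict traits on new records
#'
#' Runs the deterministic forward pass, destandardizes continuous predictions
#' with the training-fold statistics, and decodes categorical labels: binary
#' probability >= 0.5 maps to category 2, ordinal by arg-max with ties to the
#' lowest category.
#'
#' @param X_test feature rows for the test records.
#' @param weights trained network weights.
#' @param specs list of [trait_spec()] objects.
#' @param stand_stats named list of `list(mean, sd)` per continuous trait.
#' @return named list per trait: continuous -> `list(values)`; binary ->
#'   `list(prob, labels)`; ordinal -> `list(prob, labels)`.
#' @export
predict_traits <- function(X_test, weights, specs, stand_stats = list()) {
  specs <- check_trait_specs(specs)
  preds <- forward_pass(X_test, weights, specs)
  out <- list()
  for (sp in specs) {
    p <- preds[[sp$name]]
    out[[sp$name]] <- switch(sp$kind,
      continuous = {
        st <- stand_stats[[sp$name]]
        if (is.null(st))
          stop("missing standardization statistics for continuous trait '",
               sp$name, "'")
        list(values = destandardize(p, st))
      },
      binary = list(prob = p, labels = ifelse(p >= 0.5, 2L, 1L)),
      ordinal = list(prob = p, labels = max.col(p, ties.method = "first")))
  }
  out
}
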