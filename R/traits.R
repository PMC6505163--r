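#' Trait specification
#'
#' Defines a trait's measurement kind, which fixes the output head: continuous
#' traits get a ReLU-activated linear head trained with squared error on the
#' standardized scale; binary traits a sigmoid head with binary cross-entropy;
#' ordinal traits a softmax head over `n_categories` with categorical
#' cross-entropy. Categorical labels are 1-based integers.
#'
#' @param name trait name (must match a phenotype column).
#' @param kind one of `"continuous"`, `"binary"`, `"ordinal"`.
#' @param n_categories number of categories: 2 for binary (implied), >= 3 for
#'   ordinal, ignored for continuous.
#' @return object of class `trait_spec`.
#' @export
trait_spec <- function(name, kind = c("continuous", "binary", "ordinal"),
                       n_categories = NULL) {
  kind <- match.arg(kind)
  if (kind == "binary") {
    if (!is.null(n_categories) && n_categories != 2L)
      stop("binary traits have exactly 2 categories")
    n_categories <- 2L
  } else if (kind == "ordinal") {
    if (is.null(n_categories) || n_categories < 3L)
      stop("ordinal traits need n_categories >= 3")
    n_categories <- as.integer(n_categories)
  } else {
    n_categories <- NA_integer_
  }
  structure(list(name = as.character(name), kind = kind,
                 n_categories = n_categories,
                 output_activation = switch(kind, continuous = "relu",
                                            binary = "sigmoid", ordinal = "softmax"),
                 loss = switch(kind, continuous = "squared_error",
                               binary = "binary_crossentropy",
                               ordinal = "categorical_crossentropy")),
            class = "trait_spec")
}

#' @export
print.trait_spec <- function(x, ...) {
  cat(sprintf("trait '%s': %s%s (%s head, %s loss)\n", x$name, x$kind,
              if (!is.na(x$n_categories)) sprintf(", %d categories", x$n_categories) else "",
              x$output_activation, x$loss))
  invisible(x)
}

check_trait_specs <- function(specs) {
  if (inherits(specs, "trait_spec")) specs <- list(specs)
  if (!length(specs) || !all(vapply(specs, inherits, TRUE, "trait_spec")))
    stop("'specs' must be a list of trait_spec objects")
  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicated trait names: ", nm[duplicated(nm)][1L])
  specs
}

#' Encode phenotype columns into network targets
#'
#' Binary labels in \{1, 2\} become 0/1 scalars; ordinal labels become one-hot
#' indicator rows; continuous values pass through unchanged (standardization
#' happens per training fold, see [standardize_continuous()]).
#'
#' @param phenotypes data frame holding one column per trait.
#' @param specs list of [trait_spec()] objects.
#' @return named list, one element per trait: numeric vector (continuous,
#'   binary) or indicator matrix (ordinal).
#' @export
encode_targets <- function(phenotypes, specs) {
  specs <- check_trait_specs(specs)
  out <- list()
  for (sp in specs) {
    v <- phenotypes[[sp$name]]
    if (is.null(v)) stop("phenotypes lack a column for trait '", sp$name, "'")
    if (anyNA(v))
      stop("trait '", sp$name, "' has missing values; complete trait vectors ",
           "are required per record for multi-trait training")
    if (sp$kind == "continuous") {
      out[[sp$name]] <- as.numeric(v)
    } else {
      v <- as.integer(v)
      if (any(v < 1L | v > sp$n_categories))
        stop(sprintf("trait '%s': category label outside 1..%d", sp$name, sp$n_categories))
      if (sp$kind == "binary") {
        out[[sp$name]] <- as.numeric(v - 1L)
      } else {
        Y <- matrix(0, length(v), sp$n_categories)
        Y[cbind(seq_along(v), v)] <- 1
        out[[sp$name]] <- Y
      }
    }
  }
  out
}

#' Standardize a continuous trait with training-fold statistics
#'
#' The mean and sample standard deviation (n - 1 denominator) are computed on
#' the training values only and applied to `apply_to`; predictions are mapped
#' back with [destandardize()].
#'
#' @param train_values numeric vector of training observations.
#' @param apply_to numeric vector to transform (defaults to `train_values`).
#' @return list with `values`, `mean`, `sd`.
#' @export
standardize_continuous <- function(train_values, apply_to = train_values) {
  if (length(unique(train_values)) < 2L)
    stop("constant training vector: cannot standardize")
  m <- mean(train_values)
  s <- stats::sd(train_values)
  list(values = (apply_to - m) / s, mean = m, sd = s)
}

#' Invert the training-fold standardization
#' @param values standardized predictions.
#' @param stats list with `mean` and `sd` from [standardize_continuous()].
#' @export
destandardize <- function(values, stats) values * stats$sd + stats$mean
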