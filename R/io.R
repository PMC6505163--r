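table_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a marker dosage table
#'
#' Expects a header row of marker IDs, a first column of line IDs, and dosage
#' entries 0/1/2 with `NA` (or an empty cell) for missing. Comma-separated for
#' `.csv` paths, tab-separated otherwise.
#'
#' @param path file path.
#' @return validated marker matrix.
#' @export
read_marker_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = table_sep(path),
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""), quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) stop("marker table needs a line-ID column plus markers")
  ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  bad <- !is.na(vals) & !(vals %in% c("0", "1", "2"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("malformed dosage '%s' at file line %d (line '%s', marker '%s')",
                 vals[idx[1L], idx[2L]], idx[1L] + 1L, ids[idx[1L]],
                 colnames(vals)[idx[2L]]))
  }
  m <- matrix(as.numeric(vals), nrow(vals), ncol(vals),
              dimnames = list(ids, colnames(vals)))
  marker_matrix(m)
}

#' Write a marker dosage table
#' @param markers marker matrix.
#' @param path output path (`.csv` for comma-separated, tab otherwise).
#' @export
write_marker_table <- function(markers, path) {
  df <- data.frame(line = rownames(markers), markers, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = table_sep(path), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

validate_phenotypes <- function(phenotypes, specs) {
  specs <- check_trait_specs(specs)
  need <- c("line", "environment", vapply(specs, `[[`, "", "name"))
  miss <- setdiff(need, names(phenotypes))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  key <- paste(phenotypes$line, phenotypes$environment, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (line, environment) record: ",
         sub("\r", " / ", key[duplicated(key)][1L]))
  for (sp in specs) {
    v <- phenotypes[[sp$name]]
    if (sp$kind == "continuous") {
      if (!is.numeric(v)) stop("trait '", sp$name, "' must be numeric")
    } else {
      obs <- v[!is.na(v)]
      if (any(obs != as.integer(obs)) ||
          any(obs < 1L) || any(obs > sp$n_categories))
        stop(sprintf("trait '%s': category label outside 1..%d",
                     sp$name, sp$n_categories))
    }
  }
  phenotypes
}

#' Read a long-format phenotype table
#'
#' Expects columns `line`, `environment`, plus one column per trait in
#' `specs`. Categorical labels are validated against the trait's category
#' count; duplicated (line, environment) records are rejected.
#'
#' @param path file path (`.csv` comma-separated, tab otherwise).
#' @param specs list of [trait_spec()] objects.
#' @return data frame with character `line`/`environment` and trait columns.
#' @export
read_phenotype_table <- function(path, specs) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = table_sep(path),
                          check.names = FALSE, na.strings = c("NA", ""),
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  if ("line" %in% names(df)) df$line <- as.character(df$line)
  if ("environment" %in% names(df)) df$environment <- as.character(df$environment)
  validate_phenotypes(df, specs)
}

#' Write a long-format phenotype table
#' @param phenotypes data frame.
#' @param path output path.
#' @export
write_phenotype_table <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = table_sep(path), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Save network weights to a plain-text archive
#'
#' A flat key-to-tensor archive: one line per tensor with its key, shape, and
#' values printed at 17 significant digits, so save then load then
#' [forward_pass()] is bit-identical.
#'
#' @param weights network weights.
#' @param path output path.
#' @export
save_network_weights <- function(weights, path) {
  con <- file(path, "w"); on.exit(close(con))
  emit <- function(key, x) {
    dims <- if (is.matrix(x)) dim(x) else length(x)
    cat(key, paste(dims, collapse = "x"),
        paste(sprintf("%.17g", as.numeric(x)), collapse = " "),
        file = con, sep = "\t")
    cat("\n", file = con)
  }
  for (l in seq_along(weights$hidden)) {
    emit(sprintf("hidden%d.W", l), weights$hidden[[l]]$W)
    emit(sprintf("hidden%d.b", l), weights$hidden[[l]]$b)
  }
  for (nm in names(weights$heads)) {
    emit(sprintf("head.%s.W", nm), weights$heads[[nm]]$W)
    emit(sprintf("head.%s.b", nm), weights$heads[[nm]]$b)
  }
  invisible(path)
}

#' Load network weights from a plain-text archive
#' @param path archive written by [save_network_weights()].
#' @return network weights list.
#' @export
load_network_weights <- function(path) {
  lines <- readLines(path)
  weights <- list(hidden = list(), heads = list())
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    dims <- as.integer(strsplit(parts[2L], "x", fixed = TRUE)[[1L]])
    vals <- as.numeric(strsplit(parts[3L], " ", fixed = TRUE)[[1L]])
    x <- if (length(dims) == 2L) matrix(vals, dims[1L], dims[2L]) else vals
    key <- parts[1L]
    if (grepl("^hidden", key)) {
      l <- as.integer(sub("^hidden(\\d+)\\..*", "\\1", key))
      slot <- sub(".*\\.", "", key)
      if (length(weights$hidden) < l) weights$hidden[[l]] <- list()
      weights$hidden[[l]][[slot]] <- x
    } else {
      nm <- sub("^head\\.(.*)\\.[Wb]$", "\\1", key)
      slot <- sub(".*\\.", "", key)
      if (is.null(weights$heads[[nm]])) weights$heads[[nm]] <- list()
      weights$heads[[nm]][[slot]] <- x
    }
  }
  weights
}
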