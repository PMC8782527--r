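#' Fit a variable schema (transform constants) on training data
#'
#' Computes per-variable z-scoring constants on the training split, after an
#' optional log transform for skewed variables whose raw values span orders of
#' magnitude. Constants must come from the training split only, so the same
#' frozen transform is applied to validation and test data.
#'
#' @param raw_table data frame of raw-scale health measurements, one row per
#'   visit, variables in columns; missing entries are `NA`.
#' @param log_flags logical vector, one per variable: apply `log()` before
#'   z-scoring. Auto-detection is deliberately not attempted.
#' @param background_names optional character vector of background covariate
#'   names carried in the schema.
#' @param ordinal_flags optional logical vector marking ordinal variables
#'   (treated as continuous throughout; metadata only).
#' @return An object of class `var_schema` with fields `names`, `log_flags`,
#'   `mean`, `sd` (transformed scale), `background_names`, `ordinal_flags`.
#' @export
fit_schema <- function(raw_table, log_flags, background_names = character(),
                       ordinal_flags = NULL) {
  vars <- names(raw_table)
  stopifnot(length(log_flags) == length(vars))
  mu <- sdv <- numeric(length(vars))
  for (i in seq_along(vars)) {
    x <- raw_table[[i]]
    x <- x[!is.na(x)]
    if (length(x) == 0L) {
      stop("zero observed variance in variable '", vars[i], "' (no observed values)")
    }
    if (log_flags[i]) {
      if (any(x <= 0)) {
        stop("non-positive value under log flag in variable '", vars[i], "'")
      }
      x <- log(x)
    }
    mu[i] <- mean(x)
    sdv[i] <- stats::sd(x)
    if (!is.finite(sdv[i]) || sdv[i] <= 0) {
      stop("zero observed variance in variable '", vars[i], "'")
    }
  }
  structure(
    list(
      names = vars, log_flags = as.logical(log_flags), mean = mu, sd = sdv,
      background_names = background_names,
      ordinal_flags = ordinal_flags %||% rep(FALSE, length(vars))
    ),
    class = "var_schema"
  )
}

#' Transform raw measurements to the modelling scale
#'
#' Applies per-column plausibility bounds (violations become missing), then the
#' schema's log transform and z-scoring. Entries flagged missing in `mask` are
#' left untouched.
#'
#' @param values numeric matrix (rows x variables) on the raw scale.
#' @param mask binary matrix, 1 = observed.
#' @param schema a [fit_schema()] result.
#' @param upper_bounds optional named numeric vector of per-variable upper
#'   plausibility bounds (e.g. a 4 m/s cap on gait speed); values above the
#'   bound are set to missing rather than transformed.
#' @return list with transformed `values` and the (possibly updated) `mask`.
#' @export
apply_transform <- function(values, mask, schema, upper_bounds = NULL) {
  values <- as.matrix(values); mask <- as.matrix(mask)
  stopifnot(ncol(values) == length(schema$names), all(dim(values) == dim(mask)))
  if (!is.null(upper_bounds)) {
    for (nm in names(upper_bounds)) {
      j <- match(nm, schema$names)
      if (is.na(j)) next
      bad <- mask[, j] == 1 & !is.na(values[, j]) & values[, j] > upper_bounds[[nm]]
      mask[bad, j] <- 0
    }
  }
  out <- values
  for (j in seq_along(schema$names)) {
    obs <- mask[, j] == 1 & !is.na(values[, j])
    v <- values[obs, j]
    if (schema$log_flags[j]) v <- log(v)
    out[obs, j] <- (v - schema$mean[j]) / schema$sd[j]
  }
  list(values = out, mask = mask)
}

#' Invert the modelling-scale transform back to raw units
#'
#' Un-z-scores and exponentiates log-flagged columns; exact inverse of
#' [apply_transform()] on observed entries.
#'
#' @param z_values numeric matrix on the transformed scale.
#' @param schema a [fit_schema()] result.
#' @return matrix on the raw scale.
#' @export
invert_transform <- function(z_values, schema) {
  z_values <- as.matrix(z_values)
  out <- z_values
  for (j in seq_along(schema$names)) {
    v <- z_values[, j] * schema$sd[j] + schema$mean[j]
    if (schema$log_flags[j]) v <- exp(v)
    out[, j] <- v
  }
  out
}

#' Fill privatized ages by the fixed wave interval
#'
#' Surveys often privatize exact ages above a threshold; with a fixed design
#' interval between waves the privatized ages can be reconstructed by adding
#' the wave gap to the last known age. Applies equally to death ages known
#' only by wave.
#'
#' @param age_sequence numeric vector of ages in wave order; privatized
#'   entries are `NA`.
#' @param wave_gap design interval between waves in years (default 2).
#' @return the filled age sequence.
#' @export
deprivatize_ages <- function(age_sequence, wave_gap = 2) {
  if (length(age_sequence) == 0L) return(age_sequence)
  if (is.na(age_sequence[1])) {
    stop("privatized entry with no preceding known age")
  }
  for (k in seq_along(age_sequence)[-1]) {
    if (is.na(age_sequence[k])) {
      age_sequence[k] <- age_sequence[k - 1] + wave_gap
    }
  }
  age_sequence
}

#' Serialize / read a schema as a plain-text config
#'
#' @param schema a `var_schema`.
#' @param path file path.
#' @return `read_schema` returns the `var_schema`.
#' @export
write_schema <- function(schema, path) {
  df <- data.frame(
    name = schema$names, log_flag = schema$log_flags,
    mean = schema$mean, sd = schema$sd, ordinal = schema$ordinal_flags
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# background: ", paste(schema$background_names, collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  first <- readLines(path, n = 1L)
  bg <- sub("^# background: ?", "", first)
  bg <- if (nzchar(bg)) strsplit(bg, ",")[[1]] else character()
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L)
  structure(
    list(
      names = as.character(df$name), log_flags = as.logical(df$log_flag),
      mean = df$mean, sd = df$sd, background_names = bg,
      ordinal_flags = as.logical(df$ordinal)
    ),
    class = "var_schema"
  )
}
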