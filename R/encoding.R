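# Encoding of mixed-type monitoring records into a standardized numeric
# feature matrix: dictionary/one-hot expansion of categorical columns and
# mean/unit-variance standardization of numeric columns, fitted on training
# rows only so held-out data are transformed without leakage.

CONTENT_UNITS <- c("mg/kg", "ug/kg", "CFU/g", "MPN/g")

# Domain-specific column preparation applied before schema fitting/encoding:
#  * `content` + `content_unit` are resolved into two numeric columns on
#    comparable scales: `content_chem` (log10 of the concentration in mg/kg,
#    with ug/kg scaled by 1e-3 first; chemical concentrations span orders of
#    magnitude, and exceedance of a limit is additive on the decadic log
#    scale) and `content_micro` (log10(1 + count) for CFU/g and MPN/g
#    counts). A record contributes to exactly one of the two; the other is 0.
#  * `production_date` ("YYYY.MM") becomes `production_month`, months since
#    2015.01.
# Columns not present are left untouched, so the encoder also accepts generic
# tabular data.
prepare_features <- function(data) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if ("content" %in% names(data) && "content_unit" %in% names(data)) {
    unit <- as.character(data$content_unit)
    unit[unit == "\u03bcg/kg"] <- "ug/kg"  # accept the Greek-mu spelling
    bad <- !is.na(unit) & !unit %in% CONTENT_UNITS
    if (any(bad)) {
      stop_dsn("unknown content unit(s): %s",
               paste(unique(unit[bad]), collapse = ", "))
    }
    val <- as.numeric(data$content)
    mgkg <- ifelse(unit == "mg/kg", val,
                   ifelse(unit == "ug/kg", val * 1e-3, 0))
    chem <- ifelse(unit %in% c("mg/kg", "ug/kg"),
                   log10(pmax(mgkg, 0) + 1e-6), 0)
    micro <- ifelse(unit %in% c("CFU/g", "MPN/g"), log10(1 + pmax(val, 0)), 0)
    data$content <- NULL
    data$content_unit <- unit
    data$content_chem <- chem
    data$content_micro <- micro
  }
  if ("production_date" %in% names(data)) {
    pd <- as.character(data$production_date)
    ok <- grepl("^[0-9]{4}\\.[0-9]{2}$", pd) | is.na(pd)
    if (!all(ok)) {
      stop_dsn("production_date must be 'YYYY.MM'; offending value(s): %s",
               paste(utils::head(unique(pd[!ok]), 3L), collapse = ", "))
    }
    yr <- as.integer(substr(pd, 1L, 4L))
    mo <- as.integer(substr(pd, 6L, 7L))
    data$production_date <- NULL
    data$production_month <- (yr - 2015L) * 12L + (mo - 1L)
  }
  data
}

#' Fit an encoding schema on training records
#'
#' Builds the per-column transform state used by [encode()]: for every
#' categorical (character or factor) column an ordered vocabulary (sorted
#' lexicographically for determinism) defining a one-hot block of width equal
#' to the number of distinct values; for every numeric column the training
#' mean and population standard deviation used for standardization. The schema
#' is fitted on training rows only — applying it to held-out rows reuses the
#' stored statistics, so no information flows from test to train.
#'
#' `content`/`content_unit` pairs are resolved into chemical (mg/kg) and
#' microbial (log10 count) concentration columns, and `production_date` into a
#' month index, before fitting; see the package vignette.
#'
#' @param data A data.frame of raw records (mixed categorical and numeric
#'   columns). At least two rows.
#' @param label_col Name of the label column to exclude from the feature
#'   schema, if present. Default `"risk_level"`.
#' @return An object of class `dsn_schema`.
#' @export
fit_schema <- function(data, label_col = "risk_level") {
  stopifnot(is.data.frame(data))
  if (nrow(data) < 2L) stop_dsn("need at least 2 records to fit a schema")
  data <- prepare_features(data)
  data[[label_col]] <- NULL
  if (ncol(data) == 0L) stop_dsn("no feature columns to fit")

  columns <- list()
  for (nm in names(data)) {
    x <- data[[nm]]
    if (all(is.na(x))) stop_dsn("column '%s' has no non-missing values", nm)
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      vocab <- sort(unique(as.character(x[!is.na(x)])), method = "radix")
      columns[[nm]] <- list(kind = "categorical", vocab = vocab)
    } else if (is.numeric(x)) {
      xx <- as.numeric(x[!is.na(x)])
      mu <- mean(xx)
      sd <- pop_sd(xx)
      constant <- sd <= 0
      if (constant) {
        warn_dsn("numeric column '%s' is constant; it will encode as zeros", nm)
      }
      columns[[nm]] <- list(kind = "numeric", mean = mu, sd = sd,
                            constant = constant)
    } else {
      stop_dsn("column '%s' has unsupported type '%s'", nm, class(x)[1L])
    }
  }

  feature_names <- unlist(lapply(names(columns), function(nm) {
    col <- columns[[nm]]
    if (col$kind == "categorical") paste(nm, col$vocab, sep = "=") else nm
  }), use.names = FALSE)

  structure(list(columns = columns,
                 input_names = names(data),
                 feature_names = feature_names,
                 label_col = label_col),
            class = "dsn_schema")
}

#' @export
print.dsn_schema <- function(x, ...) {
  kinds <- vapply(x$columns, `[[`, "", "kind")
  cat(sprintf("dsn_schema: %d columns (%d categorical, %d numeric) -> %d features\n",
              length(x$columns), sum(kinds == "categorical"),
              sum(kinds == "numeric"), length(x$feature_names)))
  invisible(x)
}

#' Encode records into the standardized feature matrix
#'
#' Applies a fitted [fit_schema()] transform: each categorical value becomes a
#' one-hot block (a value outside the training vocabulary encodes as an
#' all-zero block, so prediction never fails on unseen categories); each
#' numeric value is standardized with the schema's *training* mean and
#' population standard deviation, `(x - mu) / sd`. Missing numeric values are
#' imputed with the training mean (standardizing to 0); missing categorical
#' values encode as all-zero blocks.
#'
#' @param data data.frame of records with the columns seen at fit time.
#' @param schema A `dsn_schema` from [fit_schema()].
#' @return Numeric matrix `n x M` with column names; no missing values.
#' @export
encode <- function(data, schema) {
  stopifnot(inherits(schema, "dsn_schema"), is.data.frame(data))
  data <- prepare_features(data)
  missing_cols <- setdiff(schema$input_names, names(data))
  if (length(missing_cols) > 0L) {
    stop_dsn("records lack column(s): %s", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(data)
  blocks <- lapply(schema$input_names, function(nm) {
    col <- schema$columns[[nm]]
    x <- data[[nm]]
    if (col$kind == "categorical") {
      idx <- match(as.character(x), col$vocab)  # NA for unknown/missing
      out <- matrix(0, nrow = n, ncol = length(col$vocab))
      hit <- which(!is.na(idx))
      out[cbind(hit, idx[hit])] <- 1
      out
    } else {
      x <- as.numeric(x)
      x[is.na(x)] <- col$mean
      if (col$constant) matrix(0, nrow = n, ncol = 1L)
      else matrix((x - col$mean) / col$sd, ncol = 1L)
    }
  })
  out <- do.call(cbind, blocks)
  colnames(out) <- schema$feature_names
  out
}

#' Persist / restore an encoding schema as JSON
#'
#' @param schema A `dsn_schema`.
#' @param path File path.
#' @return `read_schema` returns the restored `dsn_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "dsn_schema"))
  jsonlite::write_json(unclass(schema), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$columns <- lapply(raw$columns, function(col) {
    if (identical(col$kind, "categorical")) {
      list(kind = "categorical", vocab = as.character(col$vocab))
    } else {
      list(kind = "numeric", mean = as.numeric(col$mean),
           sd = as.numeric(col$sd), constant = isTRUE(col$constant))
    }
  })
  structure(list(columns = raw$columns,
                 input_names = as.character(raw$input_names),
                 feature_names = as.character(raw$feature_names),
                 label_col = raw$label_col),
            class = "dsn_schema")
}
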