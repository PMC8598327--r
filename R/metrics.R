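# Evaluation suite: confusion matrices, accuracy/precision/recall/F1 with
# one-vs-rest reductions per class, area roll-ups, and the hyperparameter
# sweep harness.

#' Confusion matrix of true vs predicted classes
#'
#' @param true,predicted Vectors of equal length; factors or values coercible
#'   to the same factor levels.
#' @param levels Optional explicit class levels (defaults to the union of
#'   observed levels, or [risk_levels()] when all values are risk levels).
#' @return `P x P` integer matrix of class `dsn_confusion`; rows are true
#'   classes, columns predicted.
#' @export
confusion <- function(true, predicted, levels = NULL) {
  if (length(true) != length(predicted)) {
    stop_dsn("length mismatch: %d true vs %d predicted", length(true),
             length(predicted))
  }
  if (length(true) == 0L) stop_dsn("no samples to tabulate")
  if (is.null(levels)) {
    vals <- unique(c(as.character(true), as.character(predicted)))
    levels <- if (all(vals %in% risk_levels())) risk_levels()
              else sort(vals, method = "radix")
  }
  t_f <- factor(as.character(true), levels = levels)
  p_f <- factor(as.character(predicted), levels = levels)
  if (anyNA(t_f) || anyNA(p_f)) stop_dsn("labels outside the class levels")
  cm <- table(true = t_f, predicted = p_f)
  structure(matrix(as.integer(cm), nrow = length(levels),
                   dimnames = list(true = levels, predicted = levels)),
            class = c("dsn_confusion", "matrix"))
}

#' Row-normalize a confusion matrix
#'
#' @param cm A `dsn_confusion`.
#' @return Matrix whose rows sum to 1 (all-zero rows for absent classes).
#' @export
normalize_confusion <- function(cm) {
  stopifnot(inherits(cm, "dsn_confusion"))
  m <- unclass(cm)
  s <- rowSums(m)
  out <- m / ifelse(s > 0, s, 1)
  dimnames(out) <- dimnames(m)
  out
}

#' Classification metric report
#'
#' Overall accuracy plus per-class one-vs-rest precision, recall and F1
#' (harmonic mean of precision and recall), their macro averages, and
#' roll-ups over the safe/warning/danger supervision areas when the classes
#' are risk levels. Undefined 0/0 ratios (a class never predicted and never
#' present) are reported as 0 and flagged in the `undefined` column.
#'
#' @param cm A `dsn_confusion` from [confusion()].
#' @return List of class `dsn_metrics`: `accuracy`, `per_class` (data.frame
#'   with precision/recall/f1/support/undefined), `macro_precision`,
#'   `macro_recall`, `macro_f1`, and `per_area` when applicable.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "dsn_confusion"))
  m <- unclass(cm)
  n <- sum(m)
  if (n == 0L) stop_dsn("empty confusion matrix")
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  pre <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * pre * rec, pre + rec)
  undefined <- (tp + fp) == 0 & (tp + fn) == 0
  per_class <- data.frame(class = rownames(m), precision = pre, recall = rec,
                          f1 = f1, support = rowSums(m),
                          undefined = undefined, row.names = NULL,
                          stringsAsFactors = FALSE)
  out <- list(accuracy = sum(tp) / n,
              per_class = per_class,
              macro_precision = mean(pre),
              macro_recall = mean(rec),
              macro_f1 = mean(f1))
  if (all(rownames(m) %in% risk_levels())) {
    area_t <- risk_area(rownames(m))
    areas <- c("safe", "warning", "danger")
    am <- matrix(0L, 3L, 3L, dimnames = list(true = areas, predicted = areas))
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      am[area_t[i], area_t[j]] <- am[area_t[i], area_t[j]] + m[i, j]
    }
    atp <- diag(am)
    out$per_area <- data.frame(
      area = areas,
      precision = safe_div(atp, colSums(am)),
      recall = safe_div(atp, rowSums(am)),
      support = rowSums(am), row.names = NULL, stringsAsFactors = FALSE)
    out$area_accuracy <- sum(atp) / n
  }
  structure(out, class = "dsn_metrics")
}

#' @export
print.dsn_metrics <- function(x, ...) {
  cat(sprintf("accuracy: %.4f   macro P/R/F1: %.4f / %.4f / %.4f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$per_class, digits = 4)
  if (!is.null(x$per_area)) {
    cat(sprintf("area accuracy (safe/warning/danger): %.4f\n",
                x$area_accuracy))
  }
  invisible(x)
}

#' Write a metric report and confusion matrix to disk
#'
#' @param report A `dsn_metrics`.
#' @param cm Optional `dsn_confusion`.
#' @param json_path Report destination (JSON).
#' @param cm_path Optional confusion matrix destination (CSV).
#' @export
write_report <- function(report, cm = NULL, json_path, cm_path = NULL) {
  stopifnot(inherits(report, "dsn_metrics"))
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  if (!is.null(cm) && !is.null(cm_path)) {
    utils::write.csv(as.data.frame(unclass(cm)), cm_path)
  }
  invisible(json_path)
}

#' Hyperparameter sweep harness
#'
#' Re-fits and evaluates the network once per candidate value of a single
#' hyperparameter under a fixed seed, reporting a held-out accuracy curve.
#'
#' @param param One of `"batch_size"`, `"K"`, `"epochs"`, `"layers"`,
#'   `"windows"`.
#' @param values Vector of candidate values (for `"windows"`, a list of
#'   integer vectors).
#' @param data Labelled records (data.frame with the label column).
#' @param base_config A [dsn_config()] providing all other settings.
#' @param train_frac Train fraction of the evaluation split.
#' @param label_col Label column name.
#' @return data.frame with columns `param`, `value`, `accuracy`.
#' @export
sweep_hyperparam <- function(param, values, data, base_config = dsn_config(),
                             train_frac = 0.9, label_col = "risk_level") {
  allowed <- c("batch_size", "K", "epochs", "layers", "windows")
  if (!param %in% allowed) {
    stop_dsn("unknown sweep parameter '%s' (use one of: %s)", param,
             paste(allowed, collapse = ", "))
  }
  y <- as_level_factor(data[[label_col]])
  sp <- stratified_split(y, train_frac, derive_seed(base_config$seed, 99L))
  train <- data[sp$train, , drop = FALSE]
  test <- data[sp$test, , drop = FALSE]
  if (is.atomic(values)) values <- as.list(values)

  acc <- vapply(values, function(v) {
    cfg <- base_config
    switch(param,
           batch_size = { cfg$batch_size <- as.integer(v) },
           K = { cfg$K <- as.integer(v) },
           epochs = { cfg$epochs <- as.integer(v) },
           layers = { cfg$max_layers <- as.integer(v) },
           windows = { cfg$scan$windows <- as.integer(v) })
    model <- fit_dsn(train, config = cfg, label_col = label_col)
    pred <- predict(model, test)
    mean(as.character(pred$class) == as.character(test[[label_col]]))
  }, 0)

  data.frame(param = param,
             value = vapply(values, function(v) paste(v, collapse = "+"), ""),
             accuracy = acc, stringsAsFactors = FALSE)
}
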