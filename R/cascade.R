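# Deep-stacking cascade: layers of diverse base learners trained with K-fold
# out-of-fold stacking. Each layer's input is the cascade's base input (the
# encoded features, plus the scan representation in Architecture-2)
# concatenated with the previous layer's class-probability outputs; layers
# are added while out-of-fold accuracy keeps improving, and the final layer's
# component outputs are fused by the Gaussian-mixture head.

MODEL_FORMAT_VERSION <- 1L

#' Deep-stacking network configuration
#'
#' @param architecture `1` (no scanning; single-split layer validation) or
#'   `2` (multigranularity padded scanning and K-fold out-of-fold stacking).
#' @param K Fold count for out-of-fold stacking (default 5).
#' @param batch_size Batch size of the fusion head's unifying standardization
#'   (default 64).
#' @param epochs Iteration cap of the fusion EM (default 100).
#' @param max_layers Maximum cascade depth.
#' @param tol Minimum out-of-fold accuracy improvement required to add a
#'   layer.
#' @param roster Base-learner families per layer; see [DEFAULT_ROSTER].
#' @param learner_params Named list of per-family hyperparameter lists, e.g.
#'   `list(random_forest = list(trees = 100))`.
#' @param scan A [scan_config()] (Architecture-2 only).
#' @param include_original Architecture-2: prepend the encoded features to the
#'   scan representation as cascade input (default `TRUE`).
#' @param holdout_frac Architecture-1: fraction of training rows used to fit
#'   each layer, the rest validating it (default 0.9).
#' @param inference `"fold_average"` (default): at prediction time each
#'   learner's probabilities are the average over its K fold models, matching
#'   the distribution of the out-of-fold features the next layer was trained
#'   on; `"refit"`: use the single learner refit on all rows.
#' @param seed Master seed; all randomness is derived from it.
#' @return Object of class `dsn_config`.
#' @export
dsn_config <- function(architecture = 2L, K = 5L, batch_size = 64L,
                       epochs = 100L, max_layers = 8L, tol = 1e-4,
                       roster = DEFAULT_ROSTER, learner_params = list(),
                       scan = scan_config(), include_original = TRUE,
                       holdout_frac = 0.9,
                       inference = c("fold_average", "refit"), seed = 1L) {
  if (!architecture %in% c(1L, 2L)) stop_dsn("architecture must be 1 or 2")
  if (K < 2L) stop_dsn("K must be >= 2")
  if (length(roster) < 1L) stop_dsn("roster must not be empty")
  if (max_layers < 1L) stop_dsn("max_layers must be >= 1")
  if (holdout_frac <= 0 || holdout_frac >= 1) {
    stop_dsn("holdout_frac must be in (0, 1)")
  }
  inference <- match.arg(inference)
  structure(list(architecture = as.integer(architecture), K = as.integer(K),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 max_layers = as.integer(max_layers), tol = tol,
                 roster = roster, learner_params = learner_params,
                 scan = scan, include_original = isTRUE(include_original),
                 holdout_frac = holdout_frac, inference = inference,
                 seed = as.integer(seed)),
            class = "dsn_config")
}

#' Stratified K-fold assignment
#'
#' Shuffles each class separately (seeded) and deals its members round-robin
#' across folds, so per-class fold sizes differ by at most one and the folds
#' partition all indices.
#'
#' @param labels Label vector/factor.
#' @param K Fold count.
#' @param seed Seed.
#' @return Integer vector of fold ids in `1..K`, one per sample.
#' @export
stratified_folds <- function(labels, K, seed = 1L) {
  labels <- as.factor(labels)
  K <- as.integer(K)
  if (K < 2L) stop_dsn("K must be >= 2")
  counts <- table(labels)
  too_small <- names(counts)[counts > 0 & counts < K]
  if (length(too_small) > 0L) {
    stop_dsn("class(es) with fewer than K = %d members: %s", K,
             paste(too_small, collapse = ", "))
  }
  fold <- integer(length(labels))
  set.seed(seed)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) == 0L) next
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(K), length(idx))
  }
  fold
}

#' Concatenate original features with a layer's probability outputs
#'
#' Non-destructive column binding: the original block comes first, then the
#' per-learner probability blocks in roster order. Each layer of the cascade
#' receives the cascade's base input plus the immediately preceding layer's
#' outputs only (widths do not accumulate across layers).
#'
#' @param X_original Base input matrix.
#' @param layer_output `n x (P * roster size)` probability matrix.
#' @return Matrix of width `ncol(X_original) + ncol(layer_output)`.
#' @export
augment <- function(X_original, layer_output) {
  if (nrow(X_original) != nrow(layer_output)) {
    stop_dsn("row mismatch: %d original vs %d layer-output rows",
             nrow(X_original), nrow(layer_output))
  }
  cbind(X_original, layer_output)
}

oof_colnames <- function(roster, class_levels) {
  unlist(lapply(roster, function(r) paste0("oof_", r, "_", class_levels)),
         use.names = FALSE)
}

#' Train one cascade layer with out-of-fold stacking
#'
#' For every base learner in the roster and every fold, the learner is fitted
#' on the other `K - 1` folds and predicts class probabilities for the held
#' fold, so each sample receives exactly one leakage-free out-of-fold
#' probability vector per learner. The K fold models are retained (they
#' drive `"fold_average"` inference) and each learner is additionally refit
#' on all rows. The layer's accuracy is the mean over folds of the per-fold
#' accuracy of the combined (learner-averaged, argmax) out-of-fold
#' prediction.
#'
#' @param X Layer input matrix.
#' @param y Label factor.
#' @param config A [dsn_config()].
#' @param folds Fold assignment from [stratified_folds()] (length `nrow(X)`).
#' @param layer_index Used only for seed derivation.
#' @return List: `learners` (refit on all rows), `fold_learners` (per
#'   learner, the K fold models), `oof` (`n x (P * roster)` matrix),
#'   `oof_list` (per-learner matrices), `E` (mean of the per-fold accuracies
#'   `E_i`), `E_i`, `component_acc`, `folds`.
#' @export
train_layer <- function(X, y, config, folds, layer_index = 1L) {
  y <- as.factor(y)
  n <- nrow(X)
  stopifnot(length(y) == n, length(folds) == n)
  P <- nlevels(y)
  K <- max(folds)
  roster <- config$roster

  oof_list <- vector("list", length(roster))
  names(oof_list) <- roster
  fold_learners <- vector("list", length(roster))
  names(fold_learners) <- roster
  for (r in seq_along(roster)) {
    oof <- matrix(0, n, P, dimnames = list(NULL, levels(y)))
    fold_learners[[r]] <- vector("list", K)
    for (f in seq_len(K)) {
      hold <- folds == f
      seed <- derive_seed(config$seed, layer_index * 10000L + r * 100L + f)
      fit <- fit_learner_safely(roster[r], X[!hold, , drop = FALSE],
                                y[!hold], seed,
                                config$learner_params[[roster[r]]] %||% list())
      fold_learners[[r]][[f]] <- fit
      oof[hold, ] <- if (fit$kind == "uniform") {
        uniform_proba(fit, sum(hold))
      } else {
        align_classes(predict_proba(fit, X[hold, , drop = FALSE]),
                      fit$class_levels, levels(y))
      }
    }
    oof_list[[r]] <- oof
  }

  combined <- Reduce(`+`, oof_list) / length(oof_list)
  pred <- argmax_first(combined)
  E_i <- vapply(seq_len(K), function(f) {
    hold <- folds == f
    mean(pred[hold] == as.integer(y)[hold])
  }, 0)
  E <- mean(E_i)
  component_acc <- vapply(oof_list, function(p) {
    mean(argmax_first(p) == as.integer(y))
  }, 0)

  learners <- lapply(seq_along(roster), function(r) {
    seed <- derive_seed(config$seed, layer_index * 10000L + r * 100L)
    fit_learner_safely(roster[r], X, y, seed,
                       config$learner_params[[roster[r]]] %||% list())
  })
  names(learners) <- roster

  oof <- do.call(cbind, oof_list)
  colnames(oof) <- oof_colnames(roster, levels(y))
  list(learners = learners, fold_learners = fold_learners, oof = oof,
       oof_list = oof_list, E = E, E_i = E_i,
       component_acc = component_acc, folds = folds)
}

# Per-learner class-probability matrices of a fitted layer on new input.
# "fold_average" averages the K fold models (matching the out-of-fold
# feature distribution downstream consumers were trained on); "refit" uses
# the learner refit on all rows.
layer_scores <- function(layer, X, class_levels, inference = "fold_average") {
  roster <- names(layer$learners)
  lapply(seq_along(roster), function(r) {
    if (inference == "fold_average" && !is.null(layer$fold_learners)) {
      mats <- lapply(layer$fold_learners[[r]], function(ln) {
        if (ln$kind == "uniform") uniform_proba(ln, nrow(X))
        else align_classes(predict_proba(ln, X), ln$class_levels,
                           class_levels)
      })
      Reduce(`+`, mats) / length(mats)
    } else {
      ln <- layer$learners[[r]]
      if (ln$kind == "uniform") uniform_proba(ln, nrow(X))
      else align_classes(predict_proba(ln, X), ln$class_levels, class_levels)
    }
  })
}

# A learner trained on a subset may have seen fewer classes; re-align its
# probability columns to the canonical level order.
align_classes <- function(p, have, want) {
  if (identical(have, want)) return(p)
  out <- matrix(0, nrow(p), length(want), dimnames = list(NULL, want))
  out[, have] <- p
  out
}

# Architecture-1 layer: learners fitted on a stratified holdout_frac subset,
# probabilities predicted for all rows, accuracy measured on the validation
# remainder (single-split validation; no out-of-fold machinery).
train_layer_holdout <- function(X, y, config, val_idx, layer_index = 1L) {
  y <- as.factor(y)
  n <- nrow(X)
  P <- nlevels(y)
  roster <- config$roster
  fit_idx <- setdiff(seq_len(n), val_idx)

  out_list <- vector("list", length(roster))
  names(out_list) <- roster
  learners <- vector("list", length(roster))
  names(learners) <- roster
  for (r in seq_along(roster)) {
    seed <- derive_seed(config$seed, layer_index * 10000L + r * 100L)
    fit <- fit_learner_safely(roster[r], X[fit_idx, , drop = FALSE],
                              y[fit_idx], seed,
                              config$learner_params[[roster[r]]] %||% list())
    out_list[[r]] <- if (fit$kind == "uniform") {
      uniform_proba(fit, n)
    } else {
      align_classes(predict_proba(fit, X), fit$class_levels, levels(y))
    }
    learners[[r]] <- fit
  }
  combined <- Reduce(`+`, out_list) / length(out_list)
  pred <- argmax_first(combined)
  E <- mean(pred[val_idx] == as.integer(y)[val_idx])
  out <- do.call(cbind, out_list)
  colnames(out) <- oof_colnames(roster, levels(y))
  list(learners = learners, oof = out, oof_list = out_list,
       E = E, E_i = E, folds = NULL)
}

#' Fit the deep-stacking network
#'
#' End-to-end training: encode the records, optionally scan them
#' (Architecture-2), then grow cascade layers. Each layer is trained with
#' K-fold out-of-fold stacking (Architecture-2) or a single stratified
#' holdout split (Architecture-1); its input is the cascade base input
#' concatenated with the previous layer's probability outputs. Growth stops
#' when the layer accuracy no longer improves by more than `tol` (or at
#' `max_layers`); the prefix with the best traced accuracy is retained, and
#' the Gaussian-mixture fusion head is fitted on the final retained layer's
#' per-learner outputs.
#'
#' @param data data.frame of raw records. The label column (default
#'   `risk_level`) may be included, or labels passed separately.
#' @param labels Optional label vector; defaults to `data[[label_col]]`.
#' @param config A [dsn_config()].
#' @param label_col Label column name.
#' @return Object of class `dsn`, with the fitted schema, scanner (if any),
#'   layers, fusion parameters and the per-layer accuracy trace.
#' @export
fit_dsn <- function(data, labels = NULL, config = dsn_config(),
                    label_col = "risk_level") {
  stopifnot(is.data.frame(data), inherits(config, "dsn_config"))
  if (is.null(labels)) {
    if (!label_col %in% names(data)) {
      stop_dsn("no labels: column '%s' absent and none supplied", label_col)
    }
    labels <- data[[label_col]]
  }
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2L) stop_dsn("need at least 2 classes to fit")
  n <- nrow(data)
  if (n < 2L * config$K) stop_dsn("need at least 2K = %d samples", 2L * config$K)

  schema <- fit_schema(data, label_col = label_col)
  X <- encode(data, schema)

  folds <- NULL
  val_idx <- NULL
  if (config$architecture == 2L) {
    folds <- stratified_folds(y, config$K, derive_seed(config$seed, 2L))
  } else {
    holdout <- stratified_split(y, config$holdout_frac,
                                derive_seed(config$seed, 2L))
    val_idx <- holdout$test
  }

  # Architecture-2: scanning inside the cross-validation. One scanner per
  # fold, each fitted on the other K - 1 folds; every training row is
  # re-represented by the scanner that never saw it, so the scan features the
  # cascade trains on carry no label leakage and are distributed like the
  # fold-averaged features used at prediction time.
  scanners <- NULL
  base_input <- X
  if (config$architecture == 2L) {
    scan_cfg <- config$scan
    Z <- NULL
    scanners <- vector("list", config$K)
    for (f in seq_len(config$K)) {
      scan_cfg$seed <- derive_seed(config$seed, 1000L + f)
      hold <- folds == f
      scanners[[f]] <- fit_scan(X[!hold, , drop = FALSE], y[!hold], scan_cfg)
      Zf <- transform_scan(X[hold, , drop = FALSE], scanners[[f]])
      if (is.null(Z)) {
        Z <- matrix(0, n, ncol(Zf), dimnames = list(NULL, colnames(Zf)))
      }
      Z[hold, ] <- Zf
    }
    base_input <- if (config$include_original) cbind(X, Z) else Z
  }

  # Layer 1 consumes the full base input (scan representation included for
  # Architecture-2); deeper layers refine on the original encoded features
  # concatenated with the previous layer's probability outputs only.
  layers <- list()
  trace <- numeric(0)
  trace_E_i <- list()
  input <- base_input
  for (l in seq_len(config$max_layers)) {
    layer <- if (config$architecture == 2L) {
      train_layer(input, y, config, folds, layer_index = l)
    } else {
      train_layer_holdout(input, y, config, val_idx, layer_index = l)
    }
    layers[[l]] <- layer
    trace[l] <- layer$E
    trace_E_i[[l]] <- layer$E_i
    if (l > 1L && trace[l] <= trace[l - 1L] + config$tol) break
    if (l < config$max_layers) input <- augment(X, layer$oof)
  }

  depth <- which.max(trace)  # first maximum: shallower model on ties
  layers <- layers[seq_len(depth)]

  fusion <- fit_fusion(layers[[depth]]$oof_list, y,
                       max_iter = config$epochs,
                       batch_size = config$batch_size)

  structure(list(schema = schema, scanners = scanners, layers = layers,
                 fusion = fusion, config = config,
                 class_levels = levels(y), depth = depth,
                 trace = trace, trace_E_i = trace_E_i,
                 version = MODEL_FORMAT_VERSION),
            class = "dsn")
}

#' @export
print.dsn <- function(x, ...) {
  cat(sprintf("dsn: architecture %d, %d layer(s) retained (of %d traced)\n",
              x$config$architecture, x$depth, length(x$trace)))
  cat("layer accuracy trace:",
      paste(sprintf("%.4f", x$trace), collapse = " "), "\n")
  cat(sprintf("fusion weights (%s): %s\n",
              paste(x$config$roster, collapse = ", "),
              paste(sprintf("%.3f", x$fusion$weights), collapse = " ")))
  invisible(x)
}

#' Predict risk levels with a fitted deep-stacking network
#'
#' Records are encoded (and scanned, Architecture-2) exactly as at training
#' time, passed through the retained layers — each layer's refit learners
#' producing the probability block concatenated with the base input for the
#' next layer — and the final layer's component probabilities are fused with
#' the learned mixture weights. Ties in the fused probabilities break to the
#' lowest class index.
#'
#' @param object A fitted `dsn`.
#' @param data data.frame of records to classify.
#' @param ... Unused.
#' @return List of class `dsn_prediction`: `class` (factor of predicted
#'   labels), `prob` (`n x P` fused probabilities, rows summing to 1), and —
#'   when the classes are risk levels — `area` (safe/warning/danger).
#' @export
predict.dsn <- function(object, data, ...) {
  stopifnot(inherits(object, "dsn"), is.data.frame(data))
  X <- encode(data, object$schema)
  base_input <- X
  if (!is.null(object$scanners)) {
    Zs <- lapply(object$scanners, function(sc) transform_scan(X, sc))
    Z <- Reduce(`+`, Zs) / length(Zs)
    base_input <- if (object$config$include_original) cbind(X, Z) else Z
  }
  input <- base_input
  scores <- NULL
  for (l in seq_along(object$layers)) {
    layer <- object$layers[[l]]
    scores <- layer_scores(layer, input, object$class_levels,
                           object$config$inference %||% "fold_average")
    if (l < length(object$layers)) {
      out <- do.call(cbind, scores)
      colnames(out) <- oof_colnames(object$config$roster, object$class_levels)
      input <- augment(X, out)
    }
  }
  prob <- fuse_predict(scores, object$fusion)
  cls <- factor(object$class_levels[argmax_first(prob)],
                levels = object$class_levels)
  res <- list(class = cls, prob = prob)
  if (all(object$class_levels %in% risk_levels())) {
    res$area <- risk_area(as.character(cls))
  }
  structure(res, class = "dsn_prediction")
}

#' Persist / restore a fitted deep-stacking network
#'
#' The archive is a single RDS file carrying a format version; loading an
#' archive written by an incompatible version fails with an explicit error.
#'
#' @param model A fitted `dsn`.
#' @param path File path.
#' @return `load_dsn` returns the restored model.
#' @export
save_dsn <- function(model, path) {
  stopifnot(inherits(model, "dsn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_dsn
#' @export
load_dsn <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dsn")) stop_dsn("'%s' is not a dsn model archive", path)
  if (!identical(model$version, MODEL_FORMAT_VERSION)) {
    stop_dsn("model archive format version %s is not supported (expected %d)",
             as.character(model$version), MODEL_FORMAT_VERSION)
  }
  model
}
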