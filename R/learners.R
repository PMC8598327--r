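# Base-learner roster for cascade layers. Each family exposes fit(X, y, seed)
# returning an object with a predict_proba(X) method yielding an n x P matrix
# in canonical class order. The default roster mixes two randomized tree
# ensembles (one completely random, one bagged), a gradient-boosted ensemble
# and a ridge-regularized multinomial linear model, so that layer outputs come
# from structurally different hypothesis spaces.

#' Default base-learner roster
#'
#' The families stacked in every cascade layer: a completely random tree
#' ensemble (`extra_trees`), a bagged random forest (`random_forest`), a
#' gradient-boosted tree ensemble (`gradient_boosting`) and a
#' ridge-regularized multinomial linear model (`logistic`).
#'
#' @format Character vector of four family names.
#' @export
DEFAULT_ROSTER <- c("extra_trees", "random_forest", "gradient_boosting",
                    "logistic")

fit_learner <- function(family, X, y, seed, params = list()) {
  y <- as.factor(y)
  class_levels <- levels(y)
  obj <- switch(
    family,
    extra_trees = {
      df <- data.frame(X, check.names = FALSE); df$..label.. <- y
      fit <- ranger::ranger(dependent.variable.name = "..label..", data = df,
                            num.trees = params$trees %||% 100L,
                            probability = TRUE, splitrule = "extratrees",
                            num.random.splits = 1L, seed = seed,
                            num.threads = 1L, verbose = FALSE)
      list(kind = "ranger", fit = fit)
    },
    random_forest = {
      df <- data.frame(X, check.names = FALSE); df$..label.. <- y
      fit <- ranger::ranger(dependent.variable.name = "..label..", data = df,
                            num.trees = params$trees %||% 100L,
                            probability = TRUE, seed = seed,
                            num.threads = 1L, verbose = FALSE)
      list(kind = "ranger", fit = fit)
    },
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L,
                                     nthread = 1L)
      fit <- xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(class_levels),
                      max_depth = params$max_depth %||% 6L,
                      eta = params$eta %||% 0.3,
                      tree_method = "hist",
                      nthread = 1L, seed = seed,
                      verbosity = 0L),
        data = dtrain,
        nrounds = params$nrounds %||% 100L,
        verbose = 0L)
      list(kind = "xgboost", fit = fit)
    },
    logistic = {
      set.seed(seed)
      # a short ridge path (warm starts) is faster and more stable than a
      # single small lambda; predictions are taken at the smallest value
      lambda <- params$lambda %||% c(0.1, 0.01, 0.001)
      fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = 0,
                            lambda = lambda,
                            standardize = FALSE, maxit = params$maxit %||% 1e5)
      list(kind = "glmnet", fit = fit, lambda_use = min(lambda))
    },
    stop_dsn("unknown learner family '%s'", family)
  )
  structure(c(obj, list(family = family, class_levels = class_levels)),
            class = "dsn_learner")
}

predict_proba <- function(learner, X) {
  stopifnot(inherits(learner, "dsn_learner"))
  P <- length(learner$class_levels)
  p <- switch(
    learner$kind,
    uniform = uniform_proba(learner, nrow(X)),
    ranger = {
      pr <- stats::predict(learner$fit,
                           data = data.frame(X, check.names = FALSE),
                           num.threads = 1L, verbose = FALSE)$predictions
      out <- matrix(0, nrow(pr), P, dimnames = list(NULL, learner$class_levels))
      out[, colnames(pr)] <- pr
      out
    },
    xgboost = {
      pr <- stats::predict(learner$fit,
                           xgboost::xgb.DMatrix(X, nthread = 1L))
      if (!is.matrix(pr)) pr <- matrix(pr, ncol = P, byrow = TRUE)
      dimnames(pr) <- list(NULL, learner$class_levels)
      pr
    },
    glmnet = {
      pr <- stats::predict(learner$fit, newx = X, type = "response",
                           s = learner$lambda_use %||% NULL)
      out <- pr[, , 1L, drop = TRUE]
      out <- matrix(out, ncol = dim(pr)[2L], dimnames = dimnames(pr)[1:2])
      aligned <- matrix(0, nrow(out), P,
                        dimnames = list(NULL, learner$class_levels))
      aligned[, colnames(out)] <- out
      aligned
    },
    stop_dsn("unknown learner kind '%s'", learner$kind)
  )
  normalize_rows(pmax(p, 0))
}

# Fit with a uniform-probability fallback: a learner that errors out is
# replaced so that layer training stays total.
fit_learner_safely <- function(family, X, y, seed, params = list()) {
  tryCatch(
    fit_learner(family, X, y, seed, params),
    error = function(e) {
      warn_dsn("learner '%s' failed (%s); using uniform-probability fallback",
               family, conditionMessage(e))
      structure(list(kind = "uniform", family = family,
                     class_levels = levels(as.factor(y))),
                class = "dsn_learner")
    })
}

uniform_proba <- function(learner, n) {
  P <- length(learner$class_levels)
  matrix(1 / P, n, P, dimnames = list(NULL, learner$class_levels))
}
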