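# Independent oracles and fixture builders shared across tests.

# Brute-force sliding-window enumerator: explicitly builds the padded vector
# and collects windows with a plain loop. Deliberately naive; the scanning
# module is checked against it.
brute_force_windows <- function(x, k, s, padded) {
  if (padded) x <- c(rep(0, k - 1), x, rep(0, k - 1))
  out <- list()
  start <- 1
  while (start + k - 1 <= length(x)) {
    out[[length(out) + 1]] <- x[start:(start + k - 1)]
    start <- start + s
  }
  do.call(rbind, out)
}

# Per-sample counting oracle for classification metrics: tallies TP/FP/FN/TN
# one sample at a time.
counting_metrics <- function(true, pred, classes) {
  acc <- mean(true == pred)
  per <- lapply(classes, function(cl) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    pre <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
    c(pre = pre, rec = rec, f1 = f1)
  })
  list(accuracy = acc, per_class = do.call(rbind, per))
}

# Small, clearly separable labelled dataset: the label is a deterministic
# function of two numeric columns; extra columns are distractors.
make_separable_data <- function(n = 300, classes = 3, seed = 42) {
  set.seed(seed)
  x1 <- runif(n)
  cls <- cut(x1, breaks = seq(0, 1, length.out = classes + 1),
             labels = paste0("c", seq_len(classes)), include.lowest = TRUE)
  data.frame(
    x1 = x1,
    x2 = rnorm(n),
    cat1 = sample(c("a", "b", "c"), n, replace = TRUE),
    label = as.character(cls),
    stringsAsFactors = FALSE)
}

# Tiny risk-style dataset from the generator, scaled down for fast tests.
make_sim_data <- function(n = 600, seed = 7, eta = 0) {
  generate_records(sim_config(n = n, seed = seed, eta = eta))
}

# A fast dsn_config for functional tests (accuracy is not the point).
fast_config <- function(architecture = 1L, seed = 1L, K = 3L,
                        max_layers = 2L) {
  dsn_config(architecture = architecture, K = K, max_layers = max_layers,
             scan = scan_config(windows = 4L, stride = 2L, trees = 5L,
                                seed = seed),
             learner_params = list(
               extra_trees = list(trees = 20L),
               random_forest = list(trees = 20L),
               gradient_boosting = list(nrounds = 20L, max_depth = 4L),
               logistic = list(lambda = c(0.1, 0.01))),
             seed = seed)
}
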