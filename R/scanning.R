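# Multigranularity padded scanning: re-represent each sample's feature vector
# as the concatenated class-probability outputs of small window-level forests
# slid across the (optionally zero-padded) vector. Padding of length k - 1 at
# both ends gives every original feature equal window coverage; without it the
# first and last features fall in a single window each.

#' Scanning configuration
#'
#' @param windows Integer vector of window lengths (each >= 2). Windows longer
#'   than the feature width are clipped at fit time.
#' @param stride Step size between consecutive windows (>= 1).
#' @param padded Zero-pad `k - 1` positions at both ends before sliding, so
#'   every feature index is covered by the same number of windows at stride 1.
#' @param forests_per_window Number of window-level forests per granularity:
#'   the first is completely random (random split variable and point), the
#'   second a standard random forest; further forests alternate.
#' @param trees Trees per window-level forest.
#' @param seed Seed for forest training.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(windows = c(16L, 32L), stride = 8L, padded = TRUE,
                        forests_per_window = 2L, trees = 30L, seed = 1L) {
  windows <- as.integer(windows)
  if (length(windows) < 1L || any(windows < 2L)) {
    stop_dsn("window lengths must be integers >= 2")
  }
  if (stride < 1L) stop_dsn("stride must be >= 1")
  if (forests_per_window < 1L) stop_dsn("need at least one forest per window")
  structure(list(windows = windows, stride = as.integer(stride),
                 padded = isTRUE(padded),
                 forests_per_window = as.integer(forests_per_window),
                 trees = as.integer(trees), seed = as.integer(seed)),
            class = "scan_config")
}

#' Number of windows produced by a sliding scan
#'
#' Unpadded, a window of length `k` at stride `s` over `M` features yields
#' `floor((M - k) / s) + 1` windows (`M - k + 1` at stride 1). With zero
#' padding of length `k - 1` at both ends the padded width is `M + 2(k - 1)`
#' and the count becomes `floor((M + k - 2) / s) + 1`; any final partial step
#' is dropped.
#'
#' @param M Feature width (>= 1).
#' @param k Window length (>= 2; `k <= M` required when unpadded).
#' @param s Stride (>= 1).
#' @param padded Logical.
#' @return Integer window count `M'`.
#' @export
scan_output_count <- function(M, k, s = 1L, padded = TRUE) {
  M <- as.integer(M); k <- as.integer(k); s <- as.integer(s)
  if (M < 1L) stop_dsn("M must be >= 1")
  if (k < 2L) stop_dsn("window length k must be >= 2")
  if (s < 1L) stop_dsn("stride s must be >= 1")
  if (!padded && k > M) stop_dsn("window length k = %d exceeds M = %d without padding", k, M)
  if (padded) (M + k - 2L) %/% s + 1L else (M - k) %/% s + 1L
}

#' Slice a feature vector into sliding windows
#'
#' With `padded = TRUE` the vector is first extended with `k - 1` zeros at
#' both ends; windows then start at the first padded position and advance by
#' `s`. Scanning is applied after standardization, so the padding value 0 is
#' the training mean of each column.
#'
#' @param x Numeric vector of length `M`.
#' @inheritParams scan_output_count
#' @return Matrix of `M'` rows and `k` columns, one window per row.
#' @export
pad_and_slice <- function(x, k, s = 1L, padded = TRUE) {
  M <- length(x)
  m_prime <- scan_output_count(M, k, s, padded)
  if (padded) x <- c(rep(0, k - 1L), x, rep(0, k - 1L))
  starts <- seq.int(1L, by = s, length.out = m_prime)
  out <- matrix(0, nrow = m_prime, ncol = k)
  for (i in seq_len(m_prime)) out[i, ] <- x[starts[i]:(starts[i] + k - 1L)]
  out
}

# Window matrix for a whole sample matrix X (n x M): rows are sample-major
# blocks of M' windows each, i.e. row (i - 1) * M' + w is window w of sample i.
window_matrix <- function(X, k, s, padded) {
  M <- ncol(X)
  m_prime <- scan_output_count(M, k, s, padded)
  if (padded) {
    X <- cbind(matrix(0, nrow(X), k - 1L), X, matrix(0, nrow(X), k - 1L))
  }
  starts <- seq.int(1L, by = s, length.out = m_prime)
  # build column-block-wise, then interleave to sample-major order
  out <- matrix(0, nrow = nrow(X) * m_prime, ncol = k)
  for (w in seq_len(m_prime)) {
    rows <- (seq_len(nrow(X)) - 1L) * m_prime + w
    out[rows, ] <- X[, starts[w]:(starts[w] + k - 1L), drop = FALSE]
  }
  colnames(out) <- paste0("w", seq_len(k))
  out
}

ranger_forest <- function(X, y, completely_random, trees, seed) {
  df <- data.frame(X, check.names = FALSE)
  df$..label.. <- y
  if (completely_random) {
    ranger::ranger(dependent.variable.name = "..label..", data = df,
                   num.trees = trees, probability = TRUE,
                   splitrule = "extratrees", num.random.splits = 1L,
                   mtry = 1L, seed = seed, num.threads = 1L,
                   verbose = FALSE)
  } else {
    ranger::ranger(dependent.variable.name = "..label..", data = df,
                   num.trees = trees, probability = TRUE,
                   seed = seed, num.threads = 1L, verbose = FALSE)
  }
}

ranger_prob <- function(forest, X, class_levels) {
  p <- stats::predict(forest, data = data.frame(X, check.names = FALSE),
                      num.threads = 1L, verbose = FALSE)$predictions
  # align to canonical class order; classes absent from training get 0
  out <- matrix(0, nrow = nrow(p), ncol = length(class_levels),
                dimnames = list(NULL, class_levels))
  out[, colnames(p)] <- p
  out
}

#' Fit the multigranularity scanner
#'
#' For each window length, the windows of all training samples are pooled into
#' one `(n * M') x k` matrix — every window inherits its sample's label — and
#' `forests_per_window` forests are trained on the pool: one completely random
#' (splits on a random variable at a random point) and one standard random
#' forest per granularity by default, mirroring the use of partial and
#' complete random forests.
#'
#' @param X Encoded feature matrix (`n x M`).
#' @param y Label factor; every class level must be present.
#' @param config A [scan_config()].
#' @return An object of class `dsn_scanner`.
#' @export
fit_scan <- function(X, y, config = scan_config()) {
  stopifnot(is.matrix(X), inherits(config, "scan_config"))
  y <- as.factor(y)
  missing_classes <- setdiff(levels(y), unique(as.character(y)))
  if (length(missing_classes) > 0L) {
    stop_dsn("class(es) absent from training labels: %s",
             paste(missing_classes, collapse = ", "))
  }
  M <- ncol(X)
  windows <- unique(pmin(config$windows, M))
  windows <- windows[windows >= 2L]
  if (length(windows) == 0L) stop_dsn("no usable window length for M = %d", M)

  granularities <- lapply(seq_along(windows), function(g) {
    k <- windows[g]
    m_prime <- scan_output_count(M, k, config$stride, config$padded)
    W <- window_matrix(X, k, config$stride, config$padded)
    yw <- rep(y, each = m_prime)
    forests <- lapply(seq_len(config$forests_per_window), function(f) {
      forest <- ranger_forest(W, yw, completely_random = (f %% 2L == 1L),
                              trees = config$trees,
                              seed = derive_seed(config$seed, g * 100L + f))
      # out-of-bag class probabilities for the training windows: the honest
      # (leakage-reduced) representation of the rows the forests were fitted
      # on; rows never out of bag fall back to the uniform distribution
      oob <- forest$predictions
      bad <- !is.finite(rowSums(oob))
      if (any(bad)) oob[bad, ] <- 1 / ncol(oob)
      list(forest = forest, oob = oob)
    })
    list(k = k, m_prime = m_prime, forests = forests)
  })

  structure(list(granularities = granularities, M = M,
                 stride = config$stride, padded = config$padded,
                 class_levels = levels(y), n_train = nrow(X),
                 width = sum(vapply(granularities, function(g) {
                   g$m_prime * length(levels(y)) * length(g$forests)
                 }, 0L))),
            class = "dsn_scanner")
}

#' Transform samples through a fitted scanner
#'
#' Each sample's windows are scored by every window-level forest into
#' class-probability vectors; per forest these are concatenated into a vector
#' of length `M' * P`, and the per-forest vectors are spliced across forests
#' and granularities into the final scan representation.
#'
#' @param X Encoded feature matrix with the training feature width.
#' @param scanner A `dsn_scanner` from [fit_scan()].
#' @param use_oob Use the stored out-of-bag window probabilities instead of
#'   predicting; valid only for the exact matrix the scanner was fitted on.
#'   This is the leakage-reduced representation the cascade trains on.
#' @return Matrix `n x sum_g(M'_g * P * F)`; each probability block sums to 1.
#' @export
transform_scan <- function(X, scanner, use_oob = FALSE) {
  stopifnot(is.matrix(X), inherits(scanner, "dsn_scanner"))
  if (ncol(X) != scanner$M) {
    stop_dsn("feature width mismatch: scanner expects M = %d, got %d",
             scanner$M, ncol(X))
  }
  if (use_oob && nrow(X) != scanner$n_train) {
    stop_dsn("out-of-bag transform requires the training matrix (%d rows)",
             scanner$n_train)
  }
  n <- nrow(X)
  P <- length(scanner$class_levels)
  blocks <- lapply(scanner$granularities, function(g) {
    W <- if (use_oob) NULL else
      window_matrix(X, g$k, scanner$stride, scanner$padded)
    per_forest <- lapply(seq_along(g$forests), function(f) {
      p <- if (use_oob) {
        align_classes(g$forests[[f]]$oob,
                      colnames(g$forests[[f]]$oob), scanner$class_levels)
      } else {
        ranger_prob(g$forests[[f]]$forest, W, scanner$class_levels)
      }
      # (n * M') x P, sample-major -> reshape to n x (M' * P)
      out <- matrix(t(p), nrow = n, ncol = g$m_prime * P, byrow = TRUE)
      colnames(out) <- paste0("k", g$k, "_f", f, "_w",
                              rep(seq_len(g$m_prime), each = P), "_",
                              rep(scanner$class_levels, g$m_prime))
      out
    })
    do.call(cbind, per_forest)
  })
  do.call(cbind, blocks)
}
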