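# Synthetic generator for grain supply-chain monitoring records. It emulates
# the monitored attribute schema (categorical vocabularies and numeric
# ranges), the extended hazard/social/economic/regulatory indicators, and an
# eight-level ordinal risk label with a recoverable rule-based ground truth:
# a latent risk score combining hazard exceedance, storage-environment
# deviation, supply-link exposure and extended indicators, cut at fixed
# per-level target counts so the generated class distribution is exact.

PROVINCES <- c("Anhui", "Beijing", "Chongqing", "Fujian", "Guangdong",
               "Guangxi", "Guizhou", "Hainan", "Hebei", "Heilongjiang",
               "Henan", "Hubei", "Hunan", "Jiangsu", "Jiangxi", "Jilin",
               "Liaoning", "Qinghai", "Shaanxi", "Shandong", "Shanghai",
               "Shanxi", "Sichuan", "Tianjin", "Yunnan", "Zhejiang")

GRAIN_TYPES <- c("rice", "wheat", "corn", "roughage",
                 "rice-processed products", "wheat-processed products", "else")

LINKS <- c("production", "circulation", "sale")

SAMPLING_SITES <- c("planting bases", "warehouse", "workshop",
                    "transportation facility", "farmer markets",
                    "supermarkets", "restaurants", "hotel", "laboratories")

# Per-level target counts of the default configuration (levels I..VIII).
DEFAULT_LEVEL_COUNTS <- c(15566L, 3752L, 1288L, 2117L, 2575L, 1726L, 1386L,
                          5760L)

#' Regulatory limit table for the synthetic hazards
#'
#' Fixed plausible limits per hazard type, on that hazard's reporting scale
#' (mycotoxins in ug/kg, heavy metals and pesticide residues in mg/kg,
#' microbial counts in CFU/g or MPN/g). These are generator configuration —
#' convenient constants of the right order of magnitude — not regulatory
#' claims; override per hazard as needed.
#'
#' @return data.frame with columns `hazard_type`, `risk_item`, `unit`,
#'   `limit`.
#' @export
hazard_limits <- function() {
  data.frame(
    hazard_type = c("AFB1", "OTA", "ZON", "DON", "T2", "fumonisin",
                    "Al", "As", "Cd", "Cr", "Hg", "Pb",
                    "COLI", "Salmonella", "MRSA",
                    "tebuconazole", "benzopyrene (BaP)", "malathion"),
    risk_item = c(rep("mycotoxins", 6L), rep("heavy metals", 6L),
                  rep("microorganisms", 3L), rep("pesticide residues", 3L)),
    unit = c(rep("ug/kg", 6L), rep("mg/kg", 6L),
             "MPN/g", "CFU/g", "CFU/g", rep("mg/kg", 3L)),
    limit = c(10, 5, 60, 1000, 100, 1000,
              100, 0.5, 0.1, 1.0, 0.02, 0.2,
              100, 10, 10,
              0.5, 0.005, 1.0),
    stringsAsFactors = FALSE)
}

#' Generator configuration
#'
#' @param counts Per-level target counts for levels I..VIII. The default is
#'   the heavily imbalanced reference distribution (15566, 3752, 1288, 2117,
#'   2575, 1726, 1386, 5760; 34170 records in total).
#' @param n Optional total size; when given, `counts` are rescaled
#'   proportionally (largest-remainder rounding) to sum to `n`.
#' @param seed Seed; the same configuration and seed reproduce the dataset
#'   byte for byte.
#' @param eta Label-noise rate in `[0, 0.5)`: this fraction of labels is
#'   shifted one level up or down after assignment. With `eta = 0` (the
#'   default) per-level counts are exact.
#' @param weights Named weights of the latent-score rule:
#'   `hazard` (content / regulatory-limit exceedance), `environment`
#'   (deviation of temperature/humidity/oxygen/CO2 from storage-optimal
#'   bands), `link` (supply-link exposure, production > circulation > sale)
#'   and `extended` (toxicity/social/regulatory indicators).
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   latent score.
#' @param limits Hazard limit table; see [hazard_limits()].
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(counts = DEFAULT_LEVEL_COUNTS, n = NULL, seed = 1L,
                       eta = 0, weights = c(hazard = 2, environment = 0.04,
                                            link = 0.03, extended = 0.03),
                       noise_sd = 0.01, limits = hazard_limits()) {
  counts <- as.integer(counts)
  if (length(counts) != 8L || any(counts < 0L)) {
    stop_dsn("counts must be 8 non-negative integers (levels I..VIII)")
  }
  if (!is.null(n)) {
    n <- as.integer(n)
    if (n < 8L) stop_dsn("n must be >= 8")
    frac <- counts / sum(counts) * n
    counts <- floor(frac)
    rem <- n - sum(counts)
    if (rem > 0L) {
      top <- order(frac - floor(frac), decreasing = TRUE)[seq_len(rem)]
      counts[top] <- counts[top] + 1L
    }
  }
  if (sum(counts) < 1L) stop_dsn("total record count must be positive")
  if (sum(as.numeric(counts)) > 5e6) stop_dsn("record count exceeds guard (5e6)")
  if (eta < 0 || eta >= 0.5) stop_dsn("eta must lie in [0, 0.5)")
  stopifnot(all(c("hazard", "environment", "link", "extended") %in%
                  names(weights)), all(is.finite(weights)))
  structure(list(counts = counts, seed = as.integer(seed), eta = eta,
                 weights = weights, noise_sd = noise_sd, limits = limits),
            class = "sim_config")
}

# Latent-score ingredients; exposed internally so the generator's rule can be
# asserted structurally (monotone in the exceedance ratio).
latent_score <- function(ratio, env_dev, link, ext, weights, noise = 0) {
  link_mult <- c(production = 1, circulation = 0.6, sale = 0.3)[link]
  weights[["hazard"]] * log10(ratio) +
    weights[["environment"]] * env_dev +
    weights[["link"]] * unname(link_mult) +
    weights[["extended"]] * ext +
    noise
}

# Normalized storage-environment deviation: the fraction of the four
# monitored conditions outside their storage-optimal bands (temperature
# 10-20 C, humidity 30-60 %, oxygen 19-21 %, CO2 below 400 ppm). A discrete
# 0, 0.25, ..., 1 score, in the penalty-point style of risk-assessment
# protocols.
environment_deviation <- function(temperature, humidity, oxygen, co2) {
  oob <- (temperature < 10 | temperature > 20) +
    (humidity < 30 | humidity > 60) +
    (oxygen < 19 | oxygen > 21) +
    (co2 > 400)
  oob / 4
}

#' Generate a synthetic monitoring dataset
#'
#' Samples categorical fields from their vocabularies and numeric fields
#' uniformly within the monitored ranges (temperature -10..40 C, humidity
#' 0..100 %, light 0..1500 Lux, oxygen 17..25 %, CO2 0..1200 ppm, weight
#' 0..100 kg, expiration 3..24 months), draws a contamination level per
#' record as a log-normal multiple of the hazard's regulatory limit, computes
#' the latent risk score, and assigns levels by ranking the score and cutting
#' at the cumulative per-level target counts — so level counts are exact.
#' With `eta > 0`, a fraction of labels is then shifted one level.
#'
#' @param config A [sim_config()].
#' @return data.frame of records with a `risk_level` factor column; the
#'   latent scores are attached as attribute `"latent"`.
#' @export
generate_records <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- sum(config$counts)
  set.seed(derive_seed(config$seed, 101L))
  lim <- config$limits

  hz_idx <- sample.int(nrow(lim), n, replace = TRUE)
  ratio <- exp(stats::rnorm(n, mean = -0.7, sd = 1.1))
  content <- signif(ratio * lim$limit[hz_idx], 6)

  temperature <- round(stats::runif(n, -10, 40), 1)
  humidity <- round(stats::runif(n, 0, 100), 1)
  light <- round(stats::runif(n, 0, 1500), 0)
  oxygen <- round(stats::runif(n, 17, 25), 2)
  co2 <- round(stats::runif(n, 0, 1200), 0)

  tox_levels <- c("low", "moderate", "high")
  carc_levels <- c("non-carcinogenic", "possibly", "probably", "known")
  acc_levels <- c("low", "medium", "high")
  toxicity <- sample(tox_levels, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  carcinogenicity <- sample(carc_levels, n, replace = TRUE,
                            prob = c(0.4, 0.3, 0.2, 0.1))
  accessibility <- sample(acc_levels, n, replace = TRUE)
  social_attention <- round(stats::runif(n, 0, 100), 1)
  event_frequency <- round(stats::runif(n, 0, 50), 0)

  link <- sample(LINKS, n, replace = TRUE, prob = c(0.45, 0.3, 0.25))

  # Extended-indicator score: graded toxicity and carcinogenicity, scaled to
  # [0, 1]. The remaining extended indicators are realistic context columns
  # that do not enter the rule.
  ext <- ((match(toxicity, tox_levels) - 1) / 2 +
            (match(carcinogenicity, carc_levels) - 1) / 3) / 2

  env_dev <- environment_deviation(temperature, humidity, oxygen, co2)
  z <- latent_score(ratio, env_dev, link, ext, config$weights,
                    noise = stats::rnorm(n, 0, config$noise_sd))

  month_idx <- sample.int(55L, n, replace = TRUE) - 1L  # 2015.01 .. 2019.07
  records <- data.frame(
    province = sample(PROVINCES, n, replace = TRUE),
    grain_type = sample(GRAIN_TYPES, n, replace = TRUE),
    link = link,
    production_area = sample(c("city", "village"), n, replace = TRUE),
    sampling_site = sample(SAMPLING_SITES, n, replace = TRUE),
    hazard_type = lim$hazard_type[hz_idx],
    risk_item = lim$risk_item[hz_idx],
    content = content,
    content_unit = lim$unit[hz_idx],
    temperature = temperature,
    humidity = humidity,
    light = light,
    oxygen = oxygen,
    co2 = co2,
    weight = round(stats::runif(n, 0, 100), 2),
    expiration_months = sample(3:24, n, replace = TRUE),
    production_date = sprintf("%04d.%02d", 2015L + month_idx %/% 12L,
                              month_idx %% 12L + 1L),
    ld50 = round(stats::runif(n, 10, 5000), 1),
    adi = signif(stats::runif(n, 0.001, 1), 4),
    iesti = signif(stats::runif(n, 0, 1), 4),
    carcinogenicity = carcinogenicity,
    toxicity = toxicity,
    social_attention = social_attention,
    security = round(stats::runif(n, 0, 100), 1),
    event_frequency = event_frequency,
    hot_search_index = round(stats::runif(n, 0, 100), 1),
    annual_output = round(stats::runif(n, 100, 5000), 0),
    planting_area = round(stats::runif(n, 50, 3000), 0),
    production_price = round(stats::runif(n, 1, 10), 2),
    consumption_price = round(stats::runif(n, 2, 15), 2),
    regulatory_accessibility = accessibility,
    standard_quantity = sample(1:50, n, replace = TRUE),
    stringsAsFactors = FALSE)

  # Rank-cut label assignment: the safest level gets the lowest scores.
  lev <- integer(n)
  ord <- order(z)
  bounds <- cumsum(config$counts)
  start <- 1L
  for (l in seq_len(8L)) {
    if (config$counts[l] > 0L) lev[ord[start:bounds[l]]] <- l
    start <- bounds[l] + 1L
  }
  if (config$eta > 0) {
    n_noise <- floor(config$eta * n)
    if (n_noise > 0L) {
      pick <- sample.int(n, n_noise)
      shift <- sample(c(-1L, 1L), n_noise, replace = TRUE)
      lev[pick] <- pmin(pmax(lev[pick] + shift, 1L), 8L)
    }
  }
  records$risk_level <- factor(risk_levels()[lev], levels = risk_levels())
  attr(records, "latent") <- z
  records
}

#' Write / read a record CSV
#'
#' UTF-8 CSV with the snake_case monitoring-attribute header expected by
#' [fit_schema()]; the same configuration and seed yield a byte-identical
#' file.
#'
#' @param records data.frame from [generate_records()].
#' @param path File path.
#' @return `read_records` returns the data.frame (with `risk_level` as a
#'   level factor when present).
#' @export
write_records <- function(records, path) {
  df <- records
  attr(df, "latent") <- NULL
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE,
                        fileEncoding = "UTF-8",
                        colClasses = c(production_date = "character"))
  if ("risk_level" %in% names(df)) df$risk_level <- as_level_factor(df$risk_level)
  df
}

# Stratified train/test index split; returns list(train, test).
stratified_split <- function(labels, train_frac, seed = 1L) {
  labels <- as.factor(labels)
  if (train_frac <= 0 || train_frac >= 1) {
    stop_dsn("train_frac must be in (0, 1)")
  }
  counts <- table(labels)
  too_small <- names(counts)[counts > 0 & counts < 2L]
  if (length(too_small) > 0L) {
    stop_dsn("class(es) with fewer than 2 members: %s",
             paste(too_small, collapse = ", "))
  }
  set.seed(seed)
  test <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) == 0L) next
    n_test <- max(1L, round((1 - train_frac) * length(idx)))
    test <- c(test, idx[sample.int(length(idx), n_test)])
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Stratified train/test partition of records
#'
#' @param records Labelled data.frame.
#' @param train_frac Training fraction in (0, 1); default 0.9.
#' @param seed Seed.
#' @param label_col Label column.
#' @return List with `train` and `test` data.frames.
#' @export
split_records <- function(records, train_frac = 0.9, seed = 1L,
                          label_col = "risk_level") {
  y <- as.factor(records[[label_col]])
  sp <- stratified_split(y, train_frac, seed)
  list(train = records[sp$train, , drop = FALSE],
       test = records[sp$test, , drop = FALSE])
}

#' Distribution summaries of a labelled dataset
#'
#' Stand-in for the case-study link analyses: per-link risk-level counts
#' (with danger-area shares) and per-contaminant link shares.
#'
#' @param records Labelled data.frame with `link`, `risk_item` and the label
#'   column.
#' @param label_col Label column.
#' @return List with `level_counts`, `level_by_link` (link x level counts),
#'   `danger_share_by_link`, and `contaminant_link_share` (rows sum to 1).
#' @export
summarize_records <- function(records, label_col = "risk_level") {
  y <- as_level_factor(records[[label_col]])
  link <- factor(records$link, levels = LINKS)
  lvl_by_link <- table(link = link, level = y)
  danger <- risk_area(as.character(y)) == "danger"
  danger_share <- tapply(danger, link, mean)
  item_link <- table(risk_item = records$risk_item, link = link)
  item_share <- prop.table(item_link, margin = 1L)
  list(level_counts = table(y),
       level_by_link = lvl_by_link,
       danger_share_by_link = danger_share,
       contaminant_link_share = item_share)
}
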