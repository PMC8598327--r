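test_that("categorical columns get sorted vocabularies and one-hot blocks", {
  df <- data.frame(grain = c("rice", "wheat", "corn", "rice"),
                   v = c(2, 4, 6, 4), stringsAsFactors = FALSE)
  schema <- fit_schema(df, label_col = "none")
  expect_identical(schema$columns$grain$vocab, c("corn", "rice", "wheat"))
  X <- encode(df, schema)
  block <- X[, paste("grain", c("corn", "rice", "wheat"), sep = "=")]
  expect_true(all(block %in% c(0, 1)))
  expect_equal(unname(rowSums(block)), rep(1, 4))
  # argmax of the block recovers the vocabulary index
  expect_equal(apply(block, 1, which.max),
               match(df$grain, schema$columns$grain$vocab))
  # two distinct one-hot codes sit at Euclidean distance sqrt(2)
  expect_equal(sqrt(sum((block[1, ] - block[2, ])^2)), sqrt(2))
})

test_that("numeric standardization uses the population convention", {
  df <- data.frame(v = c(2, 4, 6))
  schema <- fit_schema(df, label_col = "none")
  expect_equal(schema$columns$v$mean, 4)
  expect_equal(schema$columns$v$sd, 1.632993, tolerance = 1e-6)
  X <- encode(df, schema)
  expect_equal(unname(X[, "v"]), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  # a value at the training mean standardizes to exactly 0
  expect_equal(unname(encode(data.frame(v = 4), schema)[, "v"]), 0)
})

test_that("standardized training columns have mean 0 and sd 1 within 1e-9", {
  set.seed(1)
  df <- data.frame(a = rnorm(50, 10, 3), b = runif(50, -5, 5))
  X <- encode(df, fit_schema(df, label_col = "none"))
  for (cn in c("a", "b")) {
    expect_lt(abs(mean(X[, cn])), 1e-9)
    expect_lt(abs(sqrt(mean((X[, cn] - mean(X[, cn]))^2)) - 1), 1e-9)
  }
  expect_false(anyNA(X))
})

test_that("held-out encoding reuses training statistics (no leakage)", {
  set.seed(2)
  train <- data.frame(v = rnorm(40, 0, 1))
  test <- data.frame(v = rnorm(40, 5, 1))  # shifted
  schema <- fit_schema(train, label_col = "none")
  Xte <- encode(test, schema)
  # test column standardized with training stats is far from mean zero
  expect_gt(abs(mean(Xte[, "v"])), 1)
  # refitting on the union changes the schema
  schema2 <- fit_schema(rbind(train, test), label_col = "none")
  expect_false(isTRUE(all.equal(schema$columns$v$mean,
                                schema2$columns$v$mean)))
})

test_that("unknown categories and missing values encode safely", {
  df <- data.frame(g = c("a", "b", "a"), v = c(1, 2, 3),
                   stringsAsFactors = FALSE)
  schema <- fit_schema(df, label_col = "none")
  new <- data.frame(g = c("zzz", NA, "b"), v = c(NA, 2, 2),
                    stringsAsFactors = FALSE)
  X <- encode(new, schema)
  expect_equal(unname(rowSums(X[, c("g=a", "g=b")])), c(0, 0, 1))
  expect_equal(unname(X[1, "v"]), 0)  # imputed with training mean
  expect_false(anyNA(X))
})

test_that("degenerate columns are rejected or flagged", {
  expect_error(fit_schema(data.frame(v = c(NA_real_, NA_real_)),
                          label_col = "none"), "non-missing")
  expect_warning(schema <- fit_schema(data.frame(v = c(3, 3, 3), w = 1:3),
                                      label_col = "none"), "constant")
  X <- encode(data.frame(v = c(3, 9), w = c(1, 2)), schema)
  expect_equal(unname(X[, "v"]), c(0, 0))
  expect_error(fit_schema(data.frame(v = 1), label_col = "none"), "at least 2")
})

test_that("content units are resolved onto comparable scales", {
  df <- data.frame(content = c(1000, 1, 100, 100),
                   content_unit = c("ug/kg", "mg/kg", "CFU/g", "MPN/g"),
                   stringsAsFactors = FALSE)
  prep <- dsnrisk:::prepare_features(df)
  # 1000 ug/kg is 1 mg/kg: identical log-scale chemical content
  expect_equal(prep$content_chem[1], prep$content_chem[2])
  expect_equal(prep$content_micro[3], log10(101))
  expect_equal(prep$content_chem[3], 0)
  expect_error(dsnrisk:::prepare_features(
    data.frame(content = 1, content_unit = "oz/gal")), "unknown content unit")
})

test_that("production_date becomes a month index", {
  prep <- dsnrisk:::prepare_features(
    data.frame(production_date = c("2015.01", "2016.03", "2019.07"),
               stringsAsFactors = FALSE))
  expect_equal(prep$production_month, c(0L, 14L, 54L))
  expect_error(dsnrisk:::prepare_features(
    data.frame(production_date = "March 2016")), "YYYY.MM")
})

test_that("schema JSON round trip preserves the encoding", {
  df <- make_sim_data(n = 60, seed = 3)
  schema <- fit_schema(df)
  path <- tempfile(fileext = ".json")
  write_schema(schema, path)
  schema2 <- read_schema(path)
  expect_equal(encode(df, schema2), encode(df, schema))
})

test_that("risk levels map to indices, areas and back", {
  expect_equal(encode_labels(c("I", "III", "VIII")), c(0L, 2L, 7L))
  d <- decode_labels(c(0, 2, 7))
  expect_equal(as.character(d$level), c("I", "III", "VIII"))
  expect_equal(d$area, c("safe", "warning", "danger"))
  # round trip is the identity on all levels
  expect_equal(as.character(decode_labels(encode_labels(risk_levels()))$level),
               risk_levels())
  expect_equal(risk_area(c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")),
               c("safe", "safe", "warning", rep("danger", 5)))
  expect_error(decode_labels(8), "0..7")
  expect_error(encode_labels("IX"), "unknown risk level")
})
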