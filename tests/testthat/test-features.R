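test_that("the default feature set has 34 uniquely named features", {
  fn <- feature_names()
  expect_length(fn, 34)
  expect_false(anyDuplicated(fn) > 0)
  f <- extract_features(rnorm(256), 200)
  expect_named(f, fn)
})

test_that("constant segments produce defined features, never NaN", {
  f <- extract_features(rep(3, 256), 200)
  expect_false(any(is.na(f)))
  expect_equal(unname(f["mean"]), 3)
  expect_equal(unname(f["variance"]), 0)
  expect_equal(unname(f["skewness"]), 0)
  expect_equal(unname(f["kurtosis"]), 0)
  expect_equal(unname(f["pow_alpha"]), 0, tolerance = 1e-12)
  expect_equal(unname(f["pow_total"]), 0, tolerance = 1e-12)
})

test_that("a 10 Hz sine concentrates in the alpha band at the right bin", {
  t <- (0:255) / 200
  f <- extract_features(sin(2 * pi * 10 * t), 200)
  bin <- 200 / 256
  expect_lte(abs(f[["dom_freq"]] - 10), bin)
  expect_gt(f[["pow_alpha"]] / f[["pow_total"]], 0.90)
})

test_that("feature extraction is deterministic", {
  set.seed(11)
  x <- rnorm(256)
  expect_identical(extract_features(x, 200), extract_features(x, 200))
})

test_that("variance filter drops flat features and keeps maximal-variance ones", {
  set.seed(12)
  n <- 40
  df <- data.frame(record_id = "r", segment_index = 1:n,
                   label = rep(c("ictal", "non_ictal"), n / 2),
                   flat = rep(7, n),
                   alternating = rep(c(0, 1), n / 2),
                   noisy = rnorm(n))
  tab <- ictal:::as_feature_table(df)
  out <- variance_filter(tab, threshold = 0.20)
  kept <- attr(out, "feature_names")
  expect_false("flat" %in% kept)
  expect_true("alternating" %in% kept)   # scaled variance ~0.25, the maximum
  # threshold 0 only removes strictly-zero-variance features
  out0 <- variance_filter(tab, threshold = 0)
  expect_setequal(attr(out0, "feature_names"), c("alternating", "noisy"))
  # values of surviving columns are unchanged
  expect_identical(out$alternating, df$alternating)
})

test_that("correlation filter drops the later member of correlated pairs", {
  set.seed(13)
  n <- 60
  base <- rnorm(n)
  df <- data.frame(record_id = "r", segment_index = 1:n,
                   label = rep(c("ictal", "non_ictal"), n / 2),
                   a = base,
                   b = -base,                    # r = -1, absolute correlation
                   c = base + rnorm(n, sd = 2),  # weakly correlated
                   d = base)                     # duplicate of a
  tab <- ictal:::as_feature_table(df)
  out <- correlation_filter(tab, threshold = 0.95)
  expect_setequal(attr(out, "feature_names"), c("a", "c"))
})

test_that("three mutually correlated features leave exactly the earliest", {
  set.seed(14)
  n <- 2000
  base <- rnorm(n)
  jitter <- function() base + rnorm(n, sd = 0.15)  # pairwise r ~ 0.98
  df <- data.frame(record_id = "r", segment_index = 1:n,
                   label = rep(c("ictal", "non_ictal"), n / 2),
                   f1 = jitter(), f2 = jitter(), f3 = jitter())
  cm <- abs(cor(df[c("f1", "f2", "f3")]))
  skip_if(min(cm[upper.tri(cm)]) < 0.955, "fixture correlation too low")
  tab <- ictal:::as_feature_table(df)
  out <- correlation_filter(tab, threshold = 0.95)
  expect_identical(attr(out, "feature_names"), "f1")
})

test_that("filters are row-order invariant and rescale-invariant", {
  set.seed(15)
  n <- 50
  for (rep_i in 1:5) {
    m <- matrix(rnorm(n * 6), ncol = 6)
    m[, 4] <- m[, 1] * 0.999 + rnorm(n, sd = 0.01)  # near-duplicate
    df <- data.frame(record_id = "r", segment_index = 1:n,
                     label = rep(c("ictal", "non_ictal"), n / 2))
    df <- cbind(df, as.data.frame(m))
    tab <- ictal:::as_feature_table(df)
    kept <- attr(correlation_filter(tab), "feature_names")
    # row permutation
    perm <- tab[sample(n), ]
    expect_setequal(attr(correlation_filter(ictal:::as_feature_table(perm)),
                         "feature_names"), kept)
    # affine rescaling of an arbitrary column
    resc <- tab
    resc$V2 <- resc$V2 * 37 - 5
    expect_setequal(attr(correlation_filter(ictal:::as_feature_table(resc)),
                         "feature_names"), kept)
  }
})

test_that("an all-dropped variance filter is an explicit error", {
  df <- data.frame(record_id = "r", segment_index = 1:4,
                   label = rep(c("ictal", "non_ictal"), 2),
                   flat1 = rep(1, 4), flat2 = rep(2, 4))
  tab <- ictal:::as_feature_table(df)
  expect_error(variance_filter(tab), "all features dropped")
})

test_that("sample entropy is positive for noise and zero for constants", {
  set.seed(16)
  expect_gt(sample_entropy(rnorm(256)), 0)
  expect_equal(sample_entropy(rep(1, 256)), 0)
})
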