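make_table <- function(n_ictal, n_non, seed = 1) {
  set.seed(seed)
  n <- n_ictal + n_non
  df <- data.frame(record_id = "r", segment_index = seq_len(n),
                   label = c(rep("ictal", n_ictal), rep("non_ictal", n_non)),
                   f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  ictal:::as_feature_table(df)
}

test_that("undersampling balances to the minority count, deterministically", {
  tab <- make_table(300, 90)
  out <- undersample(tab, seed = 4)
  expect_equal(unname(table(out$label)["ictal"]), 90)
  expect_equal(unname(table(out$label)["non_ictal"]), 90)
  expect_identical(undersample(tab, seed = 4), out)
  balanced <- make_table(50, 50)
  expect_equal(sort(undersample(balanced, seed = 1)$segment_index),
               balanced$segment_index)
  single <- ictal:::as_feature_table(make_table(10, 10)[1:10, ])
  expect_error(undersample(single), "both labels")
})

test_that("stratified split respects per-class rounding", {
  tab <- make_table(100, 100)
  sp <- split_table(tab, 0.8, seed = 2)
  expect_equal(nrow(sp$train), 160)
  expect_equal(nrow(sp$test), 40)
  # disjoint and exhaustive
  expect_length(intersect(sp$train$segment_index, sp$test$segment_index), 0)
  expect_setequal(c(sp$train$segment_index, sp$test$segment_index),
                  tab$segment_index)
  # per-class counts within 1 of the exact 20%
  for (lb in c("ictal", "non_ictal")) {
    expect_lte(abs(sum(sp$test$label == lb) - 20), 1)
  }
  expect_error(split_table(tab, 1), "strictly between")
})

test_that("min-max + PCA retains the smallest sufficient component count", {
  n <- 100
  df <- data.frame(record_id = "r", segment_index = 1:n,
                   label = rep(c("ictal", "non_ictal"), n / 2),
                   f1 = rep(c(0, 1), n / 2),            # scaled var ~ 0.25
                   f2 = c(0, 1, rep(0.5, n - 2)))       # tiny variance
  tab <- ictal:::as_feature_table(df)
  tf <- fit_transform(tab, pca_target_variance = 0.80)
  # independent oracle: eigen-decomposition of the scaled covariance
  ev <- eigen(cov(as.matrix(df[c("f1", "f2")])))$values
  expect_gte(ev[1] / sum(ev), 0.80)
  expect_equal(tf$pipeline$n_components, 1)
  expect_equal(tf$pipeline$explained_variance[1], ev[1] / sum(ev),
               tolerance = 1e-10)
  # target 1.0 keeps all components with nonzero variance
  tf_all <- fit_transform(tab, pca_target_variance = 1.0)
  expect_equal(tf_all$pipeline$n_components, 2)
  # the training mean projects to the origin
  mu <- colMeans(as.matrix(df[c("f1", "f2")]))
  mu_tab <- df[1, ]
  mu_tab$f1 <- mu[1]; mu_tab$f2 <- mu[2]
  proj <- ictal:::apply_pipeline(tf$pipeline,
                                 ictal:::as_feature_table(mu_tab))
  expect_equal(as.numeric(proj), 0, tolerance = 1e-12)
})

test_that("a zero-range feature scales to zero with a warning", {
  tab <- make_table(20, 20)
  tab$f3 <- 5
  expect_warning(tf <- fit_transform(tab), "zero-range")
  expect_equal(tf$pipeline$n_components,
               which(cumsum(tf$pipeline$explained_variance) >= 0.8)[1])
})

test_that("grid search logs fits, honours one-cell grids and is deterministic", {
  tab <- separable_table()
  tf <- fit_transform(tab, pca_target_variance = 0.95)
  spec1 <- classifier_spec("decision_tree",
                           grid = list(maxdepth = 5, minsplit = 8))
  tuned1 <- tune(spec1, tf$train$x, tf$train$y, folds = 5, seed = 3)
  expect_equal(attr(tuned1, "n_fits"), 5)
  expect_equal(tuned1$best_params$maxdepth, 5)
  spec2 <- classifier_spec("svc")
  t_a <- tune(spec2, tf$train$x, tf$train$y, seed = 9)
  t_b <- tune(spec2, tf$train$x, tf$train$y, seed = 9)
  expect_identical(t_a$best_params, t_b$best_params)
  expect_gte(max(t_a$cv_results$mean_mcc), 0.95)  # separable data
})

test_that("every classifier family reaches high MCC on separable data", {
  tab <- separable_table(n_per_class = 150)
  for (alg in c("decision_tree", "random_forest", "svc", "knn",
                "gradient_boosting")) {
    sp <- split_table(tab, 0.8, seed = 21)
    tf <- fit_transform(sp$train, sp$test, 0.95)
    spec <- tune(classifier_spec(alg), tf$train$x, tf$train$y, seed = 21)
    fit <- ictal:::fit_model(alg, spec$best_params, tf$train$x, tf$train$y,
                             seed = 21)
    rep <- evaluate(fit, tf$test$x, tf$test$y)
    expect_gte(rep$mcc, 0.9)
  }
})

test_that("confusion metrics match hand-computed values and guard zeros", {
  m <- metrics_from_confusion(50, 50, 0, 0)
  expect_equal(m$accuracy, 1)
  expect_equal(m$mcc, 1)
  inv <- metrics_from_confusion(0, 0, 50, 50)
  expect_equal(inv$mcc, -1)
  z <- metrics_from_confusion(0, 10, 0, 5)
  expect_true(z$zero_denominator)
  expect_equal(unname(z$precision["ictal"]), 0)
  # weighted F1 equals the support-weighted per-class mean
  m2 <- metrics_from_confusion(30, 40, 10, 20)
  w <- (m2$f1[["ictal"]] * 50 + m2$f1[["non_ictal"]] * 50) / 100
  expect_equal(m2$weighted_f1, w)
})

test_that("MCC is invariant under simultaneous class swap", {
  set.seed(30)
  for (i in 1:1000) {
    cc <- sample(0:50, 4, replace = TRUE)
    if (sum(cc) == 0) next
    a <- metrics_from_confusion(cc[1], cc[2], cc[3], cc[4])$mcc
    b <- metrics_from_confusion(cc[2], cc[1], cc[4], cc[3])$mcc
    expect_identical(a, b)
  }
})

test_that("evaluation is internally consistent with the confusion counts", {
  tab <- separable_table(n_per_class = 80)
  sp <- split_table(tab, 0.8, seed = 8)
  tf <- fit_transform(sp$train, sp$test, 0.95)
  fit <- ictal:::fit_model("random_forest", list(ntree = 50, nodesize = 1),
                           tf$train$x, tf$train$y, seed = 8)
  rep <- evaluate(fit, tf$test$x, tf$test$y)
  again <- metrics_from_confusion(rep$tp, rep$tn, rep$fp, rep$fn)
  expect_equal(rep$accuracy, again$accuracy)
  expect_equal(rep$mcc, again$mcc)
  expect_equal(rep$n, nrow(sp$test))
  expect_gte(rep$roc_auc, 0.95)
})

test_that("Cochran's Q matches the textbook formula and its edge cases", {
  # identical correctness vectors
  same <- matrix(rep(c(1, 0, 1, 1), 3), ncol = 3)
  expect_equal(cochran_q(same)$statistic, 0)
  expect_equal(cochran_q(same)$p_value, 1)
  # hand-built 6-item, 3-classifier matrix against the deviation form
  m <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 1, 1),
             c(1, 1, 1), c(0, 0, 0), c(1, 0, 1))
  k <- 3; G <- colSums(m); L <- rowSums(m)
  q_oracle <- k * (k - 1) * sum((G - mean(G))^2) /
    (k * sum(L) - sum(L^2))
  res <- cochran_q(m)
  expect_equal(res$statistic, q_oracle, tolerance = 1e-12)
  expect_equal(res$df, 2)
  # invariance to item order
  expect_equal(cochran_q(m[sample(6), ])$statistic, res$statistic)
  expect_error(cochran_q(m[, 1:2]), "at least 3")
})

test_that("McNemar handles corrections, exactness and symmetry", {
  a <- c(rep(1, 60), rep(0, 40))
  b <- c(rep(1, 50), rep(0, 10), rep(1, 30), rep(0, 10))
  # discordant: b = 10 (a right, b wrong), c = 30
  res <- mcnemar(a, b, continuity_correction = FALSE)
  expect_equal(res$statistic, (10 - 30)^2 / 40, tolerance = 1e-12)
  # b = 40, c = 10 without correction gives 30^2/50 = 18
  a2 <- c(rep(1, 40), rep(0, 10), rep(1, 50))
  b2 <- c(rep(0, 40), rep(1, 10), rep(1, 50))
  expect_equal(mcnemar(a2, b2, continuity_correction = FALSE)$statistic, 18)
  # symmetric in argument swap
  expect_equal(mcnemar(b2, a2, continuity_correction = FALSE)$statistic, 18)
  # no discordance
  expect_equal(mcnemar(a, a)$p_value, 1)
  # few discordant pairs fall back to the exact binomial test
  a3 <- c(rep(1, 5), rep(0, 2), rep(1, 20))
  b3 <- c(rep(0, 5), rep(1, 2), rep(1, 20))
  res3 <- mcnemar(a3, b3)
  expect_equal(res3$method, "exact_binomial")
  expect_equal(res3$p_value, binom.test(5, 7, 0.5)$p.value)
})
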