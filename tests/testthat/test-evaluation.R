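test_that("AUC handles the canonical cases", {
  expect_identical(roc_auc(c(1, 2, 3), c(0, 0, 1))$auc, 1)
  expect_identical(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_identical(roc_auc(c(3, 1, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  r <- roc_auc(c(3, 1, 2, 4), c(0, 0, 1, 1))
  expect_identical(r$n_pos, 2L)
  expect_identical(r$n_neg, 2L)
  expect_false(r$orientation_applied)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("midrank AUC equals brute-force pair counting (with ties)", {
  set.seed(31)
  for (i in 1:500) {
    n <- sample(3:12, 1)
    scores <- sample(1:5, n, replace = TRUE)  # heavy ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_identical(roc_auc(scores, labels)$auc, brute_auc(scores, labels))
  }
})

test_that("AUC symmetry, orientation and rank invariance", {
  set.seed(32)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    scores <- rnorm(n)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    a <- roc_auc(scores, labels)$auc
    expect_identical(a + roc_auc(-scores, labels)$auc, 1)
    r <- roc_auc(scores, labels, higher_is_positive = FALSE)
    expect_identical(r$auc, roc_auc(-scores, labels)$auc)
    expect_true(r$orientation_applied)
    # invariant under strictly increasing transforms
    expect_identical(roc_auc(exp(scores), labels)$auc, a)
    expect_identical(roc_auc(rank(scores), labels)$auc, a)
  }
})

test_that("logistic fit matches glm on regular data", {
  set.seed(33)
  for (i in 1:20) {
    n <- 60
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x))
    if (length(unique(y)) < 2) next
    fit <- logistic_fit(x, y)
    ref <- suppressWarnings(glm(y ~ x, family = binomial()))
    expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
    expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 1e-6)
    expect_equal(fit$chi2, unname(ref$null.deviance - ref$deviance),
                 tolerance = 1e-6)
    expect_true(fit$converged)
    expect_false(fit$separation_detected)
  }
})

test_that("chi2 is twice the gain in directly evaluated log-likelihood", {
  set.seed(34)
  n <- 80
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 * x))
  fit <- logistic_fit(x, y)
  ll_model <- direct_loglik(fit$intercept, fit$slope, x, y)
  ll_null <- direct_loglik(qlogis(mean(y)), 0, x, y)
  expect_equal(fit$chi2, 2 * (ll_model - ll_null), tolerance = 1e-6)
  expect_equal(fit$loglik_model, ll_model, tolerance = 1e-8)
  expect_equal(fit$loglik_null, ll_null, tolerance = 1e-10)
})

test_that("uninformative and degenerate inputs are handled", {
  fit <- logistic_fit(rep(3, 10), c(rep(0, 4), rep(1, 6)))
  expect_identical(fit$slope, 0)
  expect_identical(fit$chi2, 0)
  expect_error(logistic_fit(1:5, rep(1, 5)), "both classes")
})

test_that("separation is detected and reported without blowing up", {
  fit <- logistic_fit(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_true(fit$separation_detected)
  expect_false(fit$converged)
  expect_true(is.finite(fit$chi2))
  # chi2 approaches the saturated bound 2 * (-LL_null) from below
  expect_lte(fit$chi2, -2 * fit$loglik_null + 1e-9)
  # quasi-separation: ranges touch at one tied point
  fit <- logistic_fit(c(1, 2, 3, 3, 4, 5), c(0, 0, 0, 1, 1, 1))
  expect_true(fit$separation_detected)
})

test_that("the generating slope is recovered from a large simulation", {
  set.seed(35)
  n <- 2000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 + 1.5 * x))
  fit <- logistic_fit(x, y)
  expect_lt(abs(fit$slope - 1.5), 0.15)
  expect_lt(abs(fit$intercept - 0.5), 0.15)
})

test_that("chi2 is invariant under affine rescaling of the metric", {
  set.seed(36)
  x <- rnorm(50)
  y <- rbinom(50, 1, plogis(x))
  f1 <- logistic_fit(x, y)
  f2 <- logistic_fit(1000 * x - 77, y)
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-7)
  expect_equal(f2$slope, f1$slope / 1000, tolerance = 1e-7)
})

test_that("pearson_r2 squares the product-moment correlation", {
  x <- 1:10
  expect_equal(pearson_r2(x, 2 * x + 1), 1)
  expect_equal(pearson_r2(x, -x), 1)  # sign-blind
  set.seed(37)
  a <- rnorm(1e4); b <- rnorm(1e4)
  expect_lt(pearson_r2(a, b), 0.01)
  expect_error(pearson_r2(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r2(1:2, 1:2), "at least 3")
})

test_that("two_sample_t is Welch by default with a pooled option", {
  a <- c(1.2, 1.9, 2.4, 0.8)
  expect_identical(two_sample_t(a, a)$t, 0)
  expect_identical(two_sample_t(a, a)$p, 1)
  b <- c(2.5, 3.1, 4.0)
  r1 <- two_sample_t(a, b)
  r2 <- two_sample_t(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  pooled <- two_sample_t(a, b, var_equal = TRUE)
  expect_false(isTRUE(all.equal(r1$df, pooled$df)))
  set.seed(38)
  big <- two_sample_t(rnorm(50), rnorm(50, 2))
  expect_lt(big$p, 0.001)
  expect_error(two_sample_t(1, 1:5), "at least 2")
})

test_that("evaluate_metrics assembles the report over both dichotomies", {
  risk <- rep(c("low", "intermediate", "high"), times = c(9, 11, 8))
  latent <- c(seq(-40, -20, length.out = 9),
              seq(0, 20, length.out = 11),
              seq(40, 60, length.out = 8))
  df <- data.frame(drug = sprintf("d%02d", seq_along(risk)), risk = risk,
                   exact = latent, copy = latent,
                   tms_like = -latent)
  rep <- evaluate_metrics(df, c("exact", "copy", "tms_like"),
                          reference_metric = "exact",
                          higher_is_riskier = c(exact = TRUE, copy = TRUE,
                                                tms_like = FALSE))
  tab <- rep$table
  expect_identical(tab$roc_auc_low_vs_rest, c(1, 1, 1))
  expect_identical(tab$roc_auc_high_vs_rest, c(1, 1, 1))
  # identical metrics give identical statistics rows
  stat_cols <- c("roc_auc_low_vs_rest", "roc_auc_high_vs_rest", "chi2",
                 "t", "df", "p")
  expect_equal(tab[tab$metric == "copy", stat_cols],
               tab[tab$metric == "exact", stat_cols],
               ignore_attr = TRUE)
  expect_equal(tab$r2_vs_reference[tab$metric == "copy"], 1)
  expect_true(is.na(tab$r2_vs_reference[tab$metric == "exact"]))
  # a correctly declared lower-is-riskier metric scores identically
  expect_equal(tab[tab$metric == "tms_like", c(2, 3, 5)],
               tab[tab$metric == "exact", c(2, 3, 5)],
               ignore_attr = TRUE)

  expect_error(evaluate_metrics(data.frame(risk = rep(NA_character_, 3),
                                           m = 1:3), "m"),
               "no drugs with risk labels")
  expect_error(evaluate_metrics(df, "nope"), "not found")
})

test_that("a pure-noise metric is a coin flip on average", {
  set.seed(39)
  risk <- rep(c("low", "intermediate", "high"), times = c(9, 11, 8))
  aucs <- replicate(400, {
    df <- data.frame(drug = seq_along(risk), risk = risk,
                     noise = rnorm(length(risk)))
    evaluate_metrics(df, "noise")$table$roc_auc_low_vs_rest
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("reports serialise deterministically", {
  risk <- rep(c("low", "intermediate", "high"), times = c(3, 3, 3))
  df <- data.frame(drug = 1:9, risk = risk, m = c(1:3, 4:6, 7:9) + 0.5)
  rep <- evaluate_metrics(df, "m")
  j1 <- withr::local_tempfile(fileext = ".json")
  j2 <- withr::local_tempfile(fileext = ".json")
  c1 <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, json_path = j1, csv_path = c1)
  write_report(rep, json_path = j2)
  expect_identical(readLines(j1), readLines(j2))
  tab <- utils::read.csv(c1)
  expect_identical(names(tab),
                   c("metric", "roc_auc_low_vs_rest", "roc_auc_high_vs_rest",
                     "r2_vs_reference", "chi2"))
})
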