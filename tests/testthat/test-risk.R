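test_that("balanced split produces the right sizes, deterministically", {
  sim <- make_small_sim(n = 400, seed = 2)
  s1 <- balanced_split(sim$cohort, seed = 99)
  expect_equal(as.vector(table(s1$.split)), c(200, 100, 100))
  s2 <- balanced_split(sim$cohort, seed = 99)
  expect_identical(s1$.split, s2$.split)
  s3 <- balanced_split(sim$cohort, seed = 100)
  expect_false(identical(s1$.split, s3$.split))
  # balance holds on the accepted split
  expect_gt(kruskal.test(s1$age, s1$.split)$p.value, 0.05)
  expect_gt(chisq.test(table(s1$gender, s1$.split))$p.value, 0.05)
})

test_that("under the null most seeds accept a split on the first attempt", {
  sim <- make_small_sim(n = 200, seed = 3)
  cohort <- sim$cohort
  first_try <- vapply(1:60, function(sd) {
    withr::with_seed(sd, {
      split <- sample(factor(rep(c("train", "test1", "test2"),
                                 times = c(100, 50, 50))))
    })
    htn <- cohort$hypertension
    p <- c(
      kruskal.test(cohort$age, split)$p.value,
      suppressWarnings(chisq.test(table(cohort$gender, split))$p.value),
      suppressWarnings(chisq.test(table(htn, split))$p.value)
    )
    all(p > 0.05)
  }, logical(1))
  # three independent 0.05-level screens: expect acceptance ~0.86 of the time
  expect_gt(mean(first_try), 0.7)
})

test_that("logistic fit matches an independent Newton oracle", {
  withr::with_seed(31, {
    X <- matrix(rnorm(50 * 3), 50)
    eta <- 0.5 + X %*% c(1, -0.5, 0)
    y <- runif(50) < plogis(eta)
  })
  features <- tibble::tibble(
    patient_id = as.character(1:50),
    f1 = X[, 1], f2 = X[, 2], f3 = X[, 3], label = as.logical(y)
  )
  model <- fit_ckd_lr(features)
  beta_oracle <- oracle_logistic(X, as.numeric(y))
  td <- tidy(model)
  expect_equal(td$estimate[td$term == "(Intercept)"], beta_oracle[1], tolerance = 1e-6)
  expect_equal(td$estimate[match(c("f1", "f2", "f3"), td$term)],
               beta_oracle[2:4], tolerance = 1e-6)
})

test_that("permuted labels give uniform flux p-values", {
  sim <- make_small_sim(n = 300, seed = 12)
  prof <- fit_gmf(sim$cohort, gmf_network("incomplete-11"))
  lab <- horizon_labels(sim$cohort, 3)
  feats <- gmf_features(prof, sim$cohort, lab$label)
  pvals <- c()
  withr::with_seed(77, {
    for (b in 1:25) {
      perm <- feats
      perm$label <- sample(perm$label)
      m <- try(suppressWarnings(fit_ckd_lr(perm)), silent = TRUE)
      if (inherits(m, "try-error")) next
      td <- tidy(m)
      pvals <- c(pvals, td$p.value[!td$term %in% c("(Intercept)", "age", "gender")])
    }
  })
  # fraction below 0.05 should be near the nominal level
  expect_lt(mean(pvals < 0.05), 0.12)
  expect_gt(mean(pvals < 0.5), 0.35)
})

test_that("risk prediction is the inverse logit of the linear predictor", {
  features <- tibble::tibble(
    patient_id = c("a", "b", "c"),
    f1 = c(0, 1, 2), f2 = c(1, 0, -1),
    label = c(TRUE, FALSE, TRUE)
  )
  model <- list(
    fit = structure(list(coefficients = c("(Intercept)" = 0.5, x001 = 1, x002 = -2)),
                    class = c("glm", "lm")),
    predictors = c("f1", "f2"), aliased = character(),
    age_center = 0, age_scale = 1,
    term_map = c(x001 = "f1", x002 = "f2"), converged = TRUE
  )
  class(model) <- "ckd_lr"
  out <- predict_risk(model, features)
  expect_equal(out$.risk, plogis(c(0.5 - 2, 1.5, 2.5 + 2)), tolerance = 1e-12)
  expect_error(predict_risk(model, features[, c("patient_id", "f1", "label")]),
               class = "gmftwin_schema_error")
})

test_that("zero-coefficient model predicts one half everywhere", {
  sim <- make_small_sim(n = 60, seed = 14)
  prof <- fit_gmf(sim$cohort, gmf_network("incomplete-11"))
  feats <- gmf_features(prof, sim$cohort, rep(c(TRUE, FALSE), 30))
  model <- fit_ckd_lr(feats)
  model$fit$coefficients[] <- 0
  expect_equal(predict_risk(model, feats)$.risk, rep(0.5, 60))
})

test_that("operating-point metrics match hand-counted confusion matrices", {
  m1 <- evaluate_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), threshold = 0.5)
  expect_equal(m1$sn, 1); expect_equal(m1$sp, 1); expect_equal(m1$auc, 1)
  m2 <- evaluate_metrics(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0), threshold = 0.5)
  expect_equal(m2$sn, 0.5); expect_equal(m2$sp, 0.5)
  expect_equal(m2$npv, 0.5); expect_equal(m2$ppv, 0.5)
  expect_equal(m2$auc, 0.75)
  expect_error(evaluate_metrics(c(0.2, 0.8), c(1, 0), threshold = 1.2))
})

test_that("rank AUC equals all-pairs concordance and is monotone-invariant", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      n <- sample(10:200, 1)
      scores <- sample(seq(0.01, 0.99, by = 0.01), n, replace = TRUE) # ties likely
      labels <- runif(n) < 0.4
      if (!any(labels) || all(labels)) next
      expect_equal(rank_auc(scores, labels), oracle_auc(scores, labels))
      expect_equal(rank_auc(plogis(5 * scores - 2), labels),
                   rank_auc(scores, labels))
    }
  })
  expect_warning(one <- rank_auc(c(0.1, 0.9), c(TRUE, TRUE)))
  expect_true(is.na(one))
  # cross-check against an established ROC implementation
  withr::with_seed(43, {
    scores <- runif(150)
    labels <- runif(150) < plogis(3 * scores - 1.5)
  })
  expect_equal(rank_auc(scores, labels),
               as.numeric(suppressMessages(pROC::auc(labels, scores))),
               tolerance = 1e-12)
})

test_that("bootstrap AUC is reproducible, degenerate when separable, honest under the null", {
  withr::with_seed(51, {
    x <- c(rnorm(40, 0), rnorm(40, 4))
    feats <- tibble::tibble(patient_id = as.character(1:80), f1 = x,
                            label = rep(c(FALSE, TRUE), each = 40))
  })
  r1 <- suppressWarnings(bootstrap_auc(feats, B = 50, seed = 7))
  r2 <- suppressWarnings(bootstrap_auc(feats, B = 50, seed = 7))
  expect_identical(r1$aucs, r2$aucs)
  expect_equal(r1$median, 1)
  expect_equal(r1$ci_lower, 1)

  # fixed-model test-set resampling centres on the point AUC
  model <- suppressWarnings(fit_ckd_lr(feats))  # separable toy data
  rt <- suppressWarnings(bootstrap_auc(feats, B = 50, seed = 3,
                                       scheme = "resample_test", model = model))
  expect_equal(rt$point, rank_auc(predict_risk(model, feats)$.risk, feats$label))
  expect_lt(abs(rt$median - rt$point), 0.05)
  expect_error(bootstrap_auc(feats, B = 10, scheme = "resample_test"),
               "needs a fitted model")

  # labels independent of features: CI should cover 0.5 in most replicates
  covered <- vapply(1:15, function(sd) {
    withr::with_seed(sd, {
      nullf <- tibble::tibble(patient_id = as.character(1:200),
                              f1 = rnorm(200), f2 = rnorm(200),
                              label = runif(200) < 0.5)
    })
    r <- suppressWarnings(bootstrap_auc(nullf, B = 60, seed = sd))
    r$ci_lower <= 0.5 && r$ci_upper >= 0.5
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("significant predictors are filtered, sorted, and empty when nothing passes", {
  sim <- make_small_sim(n = 200, seed = 33)
  prof <- fit_gmf(sim$cohort, gmf_network("incomplete-11"))
  withr::with_seed(1, labels <- runif(200) < 0.5)  # pure noise labels
  m <- suppressWarnings(fit_ckd_lr(gmf_features(prof, sim$cohort, labels)))
  sig_strict <- significant_predictors(m, alpha = 1e-12)
  expect_tibble(sig_strict)
  expect_equal(nrow(sig_strict), 0)
  expect_named(sig_strict, c("predictor", "estimate", "p.value"))
  sig_all <- significant_predictors(m, alpha = 1)
  expect_false(is.unsorted(sig_all$p.value))
  expect_false("(Intercept)" %in% sig_all$predictor)
})

test_that("planted two-flux effects are recovered as significant predictors", {
  # d_true with exactly two nonzero components; moderate n
  d <- c("Ex.HbA1c → ACR" = 1.3, "Hb.ROM → HbA1c" = 1.1)
  hits <- vapply(1:10, function(sd) {
    sim <- simulate_cohort(cohort_spec(n = 2000, d_true = d), seed = sd)
    prof <- fit_gmf(sim$cohort, gmf_network("incomplete-11"))
    lab <- horizon_labels(sim$cohort, 3)
    m <- suppressWarnings(fit_ckd_lr(gmf_features(prof, sim$cohort, lab$label)))
    all(names(d) %in% significant_predictors(m)$predictor)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ablation drops discrimination when informative predictors are removed", {
  sim <- make_small_sim(n = 800, seed = 44)
  prof <- fit_gmf(sim$cohort, gmf_network("incomplete-11"))
  lab <- horizon_labels(sim$cohort, 3)
  feats <- gmf_features(prof, sim$cohort, lab$label)
  ab <- suppressWarnings(ablation_auc(feats, k = 3, B = 40, seed = 1))
  expect_length(ab$top, 3)
  expect_gt(ab$full$median, ab$drop_top$median)
  # all-noise features: keep-only ablation hovers at chance
  withr::with_seed(13, {
    noise <- tibble::tibble(
      patient_id = as.character(1:400),
      n1 = rnorm(400), n2 = rnorm(400), n3 = rnorm(400), n4 = rnorm(400),
      label = runif(400) < 0.4
    )
  })
  r <- suppressWarnings(bootstrap_auc(noise[, c("patient_id", "n1", "n2", "n3", "label")],
                                      B = 40, seed = 2))
  expect_lt(abs(r$median - 0.5), 0.08)
})
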