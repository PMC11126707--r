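test_that("horizon labels honor events, follow-up and the censoring exclusion", {
  cohort <- tibble::tibble(
    patient_id = paste0("p", 1:5),
    ckd_event = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    event_time_years = c(2.1, NA, NA, 6, NA),
    followup_years = c(2.1, 4, 7, 6, 3)
  )
  l3 <- horizon_labels(cohort, 3)
  expect_equal(l3$label, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_true(all(l3$eligible))
  l5 <- horizon_labels(cohort, 5)
  # event-free with follow-up shorter than the horizon -> excluded (NA)
  expect_equal(l5$label, c(TRUE, NA, FALSE, FALSE, NA))
  expect_equal(l5$eligible, c(TRUE, FALSE, TRUE, TRUE, FALSE))

  # nesting across horizons on a simulated cohort
  sim <- make_small_sim(n = 300, seed = 15)
  h3 <- horizon_labels(sim$cohort, 3)
  h5 <- horizon_labels(sim$cohort, 5)
  pos3 <- which(!is.na(h3$label) & h3$label)
  pos5 <- which(!is.na(h5$label) & h5$label)
  expect_true(all(pos3 %in% pos5))
})

test_that("Kaplan-Meier matches the hand product-limit calculation", {
  km <- km_curves(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # no events: survival stays at 1
  km0 <- km_curves(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(km0$survival == 1))
  # a subject censored after the last event adds no step: the curve's last
  # drop stays at the final event time and its value matches the risk-set
  # product with the censored subject counted at risk throughout
  km_c <- km_curves(c(1, 2, 3, 3.5), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(km_c$survival[km_c$time <= 3], c(3 / 4, 1 / 2, 1 / 4))
  expect_equal(max(km_c$time[km_c$n_event > 0]), 3)
  expect_equal(km_c$survival[km_c$time == 3.5], km_c$survival[km_c$time == 3])

  # brute-force risk-set product on random censored fixtures up to 50 subjects
  withr::with_seed(37, {
    for (rep in 1:10) {
      n <- sample(10:50, 1)
      times <- round(rexp(n, 0.3), 2)
      events <- runif(n) < 0.7
      km_pkg <- km_curves(times, events)
      oracle <- oracle_km(times, events)
      merged <- merge(km_pkg, oracle, by = "time")
      expect_equal(merged$survival.x, merged$survival.y, tolerance = 1e-12)
    }
  })
})

test_that("log-rank behaves on duplicated groups and matches a hand computation", {
  t6 <- c(1, 2, 3, 1.5, 2.5, 4)
  e6 <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  g6 <- rep(c("a", "b"), each = 3)
  # hand computation: observed minus expected over shared event times
  ts <- sort(unique(t6[e6]))
  o_a <- e_a <- v <- 0
  for (tt in ts) {
    at_a <- sum(t6 >= tt & g6 == "a"); at_b <- sum(t6 >= tt & g6 == "b")
    n_t <- at_a + at_b
    d_t <- sum(t6 == tt & e6)
    o_a <- o_a + sum(t6 == tt & e6 & g6 == "a")
    e_a <- e_a + d_t * at_a / n_t
    if (n_t > 1) v <- v + d_t * (at_a / n_t) * (at_b / n_t) * (n_t - d_t) / (n_t - 1)
  }
  hand_chisq <- (o_a - e_a)^2 / v
  res <- logrank_test(t6, e6, g6)
  expect_equal(res$statistic, hand_chisq, tolerance = 1e-10)

  # identical groups (duplicated data): p near 1
  td <- c(t6, t6); ed <- c(e6, e6); gd <- rep(c("x", "y"), each = 6)
  res_dup <- logrank_test(td, ed, gd)
  expect_gt(res_dup$p.value, 0.95)
  expect_error(logrank_test(t6, e6, rep("a", 6)), class = "gmftwin_domain_error")
})

test_that("log-rank detects a planted hazard ratio with high power", {
  detected <- vapply(1:10, function(sd) {
    withr::with_seed(sd, {
      g <- rep(c(FALSE, TRUE), each = 500)
      times <- rexp(1000, rate = ifelse(g, 0.3, 0.1))
      cens <- runif(1000, 3, 6)
      obs <- pmin(times, cens)
      ev <- times <= cens
    })
    logrank_test(obs, ev, g)$p.value < 0.01
  }, logical(1))
  expect_gte(mean(detected), 0.95)
})

test_that("Cox hazard ratio: null on identical arms, recovery of HR 3.5, rescaling invariance", {
  t6 <- c(1, 2, 3, 1.5, 2.5, 4); e6 <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  res_same <- cox_hr(c(t6, t6), c(e6, e6), rep(c(FALSE, TRUE), each = 6))
  expect_equal(res_same$hr, 1, tolerance = 1e-6)

  recovered <- vapply(1:10, function(sd) {
    withr::with_seed(sd, {
      g <- rep(c(FALSE, TRUE), each = 1000)
      times <- rexp(2000, rate = ifelse(g, 0.35, 0.1))
      cens <- runif(2000, 3, 6)
    })
    fit <- cox_hr(pmin(times, cens), times <= cens, g)
    abs(fit$hr - 3.5) / 3.5 < 0.15
  }, logical(1))
  expect_gte(mean(recovered), 0.9)

  withr::with_seed(61, {
    times <- rexp(200, 0.2); g <- runif(200) < 0.5; ev <- runif(200) < 0.8
  })
  expect_equal(cox_hr(times, ev, g)$hr, cox_hr(times * 7.3, ev, g)$hr,
               tolerance = 1e-8)
  w <- capture_warnings(
    unb <- cox_hr(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE), c(0, 0, 1, 1))
  )
  expect_match(w, "no events", all = FALSE)
  expect_true(unb$unbounded)
})

test_that("k-means selection conserves sums of squares and is deterministic", {
  withr::with_seed(71, {
    blob1 <- matrix(rnorm(200, 0), ncol = 2)
    blob2 <- matrix(rnorm(200, 8), ncol = 2)
    X <- rbind(blob1, blob2)
  })
  cl2 <- kmeans_bss(X, k_range = 2, bss_target = 0, seed = 1)
  expect_gt(cl2$bss_fraction, 0.9)

  sim <- make_small_sim(n = 300, seed = 18)
  prof <- fit_gmf(sim$cohort, gmf_network("incomplete-11"))
  M <- cbind(flux_matrix(prof), age = sim$cohort$age)
  cl <- suppressWarnings(kmeans_bss(M, k_range = 5:12, seed = 4))
  # conservation identity on the selected clustering
  expect_equal(cl$betweenss + cl$withinss, cl$totss, tolerance = 1e-8)
  expect_equal(cl2$betweenss + cl2$withinss, cl2$totss, tolerance = 1e-8)
  cl_b <- suppressWarnings(kmeans_bss(M, k_range = 5:12, seed = 4))
  expect_identical(cl$assignments, cl_b$assignments)
  expect_equal(cl$k, cl_b$k)
  expect_error(kmeans_bss(M[1:10, ], k_range = 5:20),
               class = "gmftwin_domain_error")
})

test_that("cluster-distance analysis: zero self-distance, tau one on a monotone line", {
  # construct clusters along a line with rates rising with position
  withr::with_seed(81, {
    centers_pos <- c(0, 2, 4, 6, 8)
    X <- do.call(rbind, lapply(centers_pos, function(m) {
      cbind(rnorm(60, m, 0.1), rnorm(60, 0, 0.1))
    }))
  })
  # deterministic per-blob outcome counts: rates exactly 5%, 20%, ..., 90%
  labels <- unlist(lapply(c(0.05, 0.2, 0.4, 0.6, 0.9), function(r) {
    rep(c(TRUE, FALSE), c(round(60 * r), 60 - round(60 * r)))
  }))
  cl <- kmeans_bss(X, k_range = 5, bss_target = 0, seed = 3)
  out <- cluster_distance_outcome(cl, labels)
  expect_equal(out$table$distance[1], 0)
  expect_equal(out$tau, 1)
  expect_lt(out$p.value, 0.05)
  expect_true(!is.unsorted(out$table$ckd_rate))
  expect_error(cluster_distance_outcome(
    kmeans_bss(X, k_range = 2, bss_target = 0, seed = 1), labels
  ), class = "gmftwin_domain_error")
})

test_that("severity-driven cohorts show positive distance-rate correlation", {
  hits <- vapply(1:6, function(sd) {
    sim <- make_small_sim(n = 800, seed = sd)
    prof <- fit_gmf(sim$cohort, gmf_network("incomplete-11"))
    lab <- horizon_labels(sim$cohort, 3)
    M <- cbind(flux_matrix(prof), age = sim$cohort$age,
               gender = as.numeric(sim$cohort$gender == "male"))
    cl <- suppressWarnings(kmeans_bss(M, seed = sd))
    out <- cluster_distance_outcome(cl, lab$label)
    out$tau > 0 && out$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
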