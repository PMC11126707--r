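net14 <- gmf_network("complete-14")
A14 <- gmftwin:::observable_incidence(net14)
refs14 <- gmftwin:::reference_levels(net14)

# build a one-row cohort whose log deviations are exactly y (NA rows dropped)
cohort_from_y <- function(y, network = net14) {
  refs <- gmftwin:::reference_levels(network)
  panel <- refs * exp(y)
  tibble::as_tibble_row(as.list(panel)) |>
    dplyr::mutate(patient_id = "x", age = 50, gender = "female")
}

test_that("fit matches the ridge/pseudoinverse closed form on random instances", {
  withr::with_seed(17, {
    for (rep in 1:100) {
      u_star <- rnorm(ncol(A14), sd = 0.3)
      y <- drop(A14 %*% u_star) + rnorm(nrow(A14), sd = 0.05)
      # random row deletion: missingness must equal row drop exactly
      keep <- runif(nrow(A14)) > 0.3
      if (!any(keep)) keep[sample(nrow(A14), 1)] <- TRUE
      y_obs <- ifelse(keep, y, NA)
      lambda <- sample(c(0, 0.1, 1), 1)
      prof <- suppressWarnings(
        fit_gmf(cohort_from_y(y_obs), net14, fit_settings(lambda = lambda))
      )
      u_hat <- log(flux_matrix(prof))[1, ]
      u_oracle <- oracle_ridge(A14[keep, , drop = FALSE], y[keep], lambda = lambda)
      expect_equal(unname(u_hat), u_oracle, tolerance = 1e-8)
    }
  })
})

test_that("noise-free row-space solutions are recovered at lambda -> 0", {
  withr::with_seed(23, {
    for (rep in 1:20) {
      # u* in the row space of A_obs: u* = A' z
      z <- rnorm(nrow(A14))
      u_star <- drop(crossprod(A14, z))
      y <- drop(A14 %*% u_star)
      prof <- fit_gmf(cohort_from_y(y), net14, fit_settings(lambda = 0))
      expect_equal(unname(log(flux_matrix(prof))[1, ]), unname(u_star),
                   tolerance = 1e-8)
      expect_lt(prof$residual_norm[1], 1e-10)
    }
    # second independent route: Moore-Penrose pseudoinverse
    y <- drop(A14 %*% rnorm(ncol(A14), sd = 0.3))
    prof <- fit_gmf(cohort_from_y(y), net14, fit_settings(lambda = 0))
    expect_equal(unname(log(flux_matrix(prof))[1, ]),
                 drop(MASS::ginv(A14) %*% y), tolerance = 1e-8)
  })
})

test_that("ridge shrinkage is monotone and the empty panel collapses to the reference", {
  withr::with_seed(9, y <- rnorm(nrow(A14), sd = 0.3))
  norms <- vapply(c(0.01, 0.1, 1, 10, 100), function(l) {
    prof <- fit_gmf(cohort_from_y(y), net14, fit_settings(lambda = l))
    sqrt(sum(log(flux_matrix(prof))[1, ]^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[5], 0.05)

  empty <- cohort_from_y(rep(NA_real_, nrow(A14)))
  expect_warning(prof <- fit_gmf(empty, net14), "no observed biomarker")
  expect_true(prof$all_missing[1])
  expect_equal(unname(flux_matrix(prof)[1, ]), rep(1, 21))
  expect_warning(prof0 <- fit_gmf(empty, net14, fit_settings(lambda = 0)))
  expect_true(all(is.na(flux_matrix(prof0)[1, ])))
})

test_that("batch fitting equals per-patient fitting and is order equivariant", {
  sim <- make_small_sim(n = 30, seed = 5)
  batch <- fit_gmf(sim$cohort, gmf_network("incomplete-11"))
  for (i in c(1, 7, 30)) {
    single <- fit_gmf(sim$cohort[i, ], gmf_network("incomplete-11"))
    expect_equal(flux_matrix(batch)[i, ], flux_matrix(single)[1, ])
  }
  withr::with_seed(1, perm <- sample(30))
  permuted <- fit_gmf(sim$cohort[perm, ], gmf_network("incomplete-11"))
  expect_equal(flux_matrix(permuted), flux_matrix(batch)[perm, ])
})

test_that("a dropped biomarker reproduces the fit with that biomarker absent", {
  sim <- make_small_sim(n = 5, seed = 8, pattern = "complete-14", rate = 0)
  cohort <- sim$cohort
  cohort_missing <- dplyr::mutate(cohort, hb = NA_real_, tg = NA_real_)
  prof_a <- fit_gmf(cohort_missing, net14)
  # same patients with the columns never present at all
  cohort_dropped <- dplyr::select(cohort, -"hb", -"tg")
  prof_b <- fit_gmf(cohort_dropped, net14)
  expect_equal(flux_matrix(prof_a), flux_matrix(prof_b))
  expect_equal(prof_a$n_observed, rep(12, 5))
})

test_that("reference calibration takes per-class component-wise medians", {
  sim <- make_small_sim(n = 50, seed = 3)
  prof <- fit_gmf(sim$cohort, gmf_network("incomplete-11"))
  withr::with_seed(4, labels <- runif(50) < 0.4)
  refs <- calibrate_references(prof, labels)
  U <- log(flux_matrix(prof))
  # sort-based oracle per component
  med_sort <- function(v) {
    s <- sort(v); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  expect_equal(unname(refs$u_A), unname(apply(U[!labels, ], 2, med_sort)))
  expect_equal(unname(refs$u_B), unname(apply(U[labels, ], 2, med_sort)))
  # antisymmetry under label swap
  refs_swap <- calibrate_references(prof, !labels)
  expect_equal(refs_swap$d, -refs$d)
  expect_error(calibrate_references(prof, rep(TRUE, 50)),
               class = "gmftwin_domain_error")
})

test_that("generalized extent is 0 at state A, 1 at state B, linear between", {
  sim <- make_small_sim(n = 40, seed = 6)
  prof <- fit_gmf(sim$cohort, gmf_network("incomplete-11"))
  labels <- seq_len(40) <= 15
  refs <- calibrate_references(prof, labels)
  at <- function(u) {
    p <- prof[1, ]
    for (j in seq_along(refs$flux_ids)) p[[refs$flux_ids[j]]] <- exp(u[j])
    unname(generalized_extent(p, refs))
  }
  expect_equal(at(refs$u_A), 0, tolerance = 1e-12)
  expect_equal(at(refs$u_B), 1, tolerance = 1e-12)
  expect_equal(at((refs$u_A + refs$u_B) / 2), 0.5, tolerance = 1e-12)
  # beyond-B states score above 1, unclipped
  expect_gt(at(refs$u_B + refs$d), 1.5)
})

test_that("severity recovery: fitted extent rank-correlates with the planted truth", {
  spec <- cohort_spec(n = 500, sigma_obs = 0.05,
                      missingness = list(pattern = "complete-14", rate = 0))
  sim <- simulate_cohort(spec, seed = 21)
  prof <- fit_gmf(sim$cohort, net14)
  lab <- horizon_labels(sim$cohort, 3)
  prof <- add_extent(prof, calibrate_references(prof, lab$label))
  expect_gt(cor(sim$truth$severity, prof$extent, method = "spearman"), 0.9)
})
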