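#' Settings for the flux fit
#'
#' The per-patient fit minimizes the ridge-regularized weighted least squares
#' objective \deqn{\|W^{1/2}(y - A u)\|^2 + \lambda \|u\|^2} over the rows of
#' the observable incidence where the biomarker is present; missing biomarkers
#' are dropped rows, never imputed.  With at most 14 observations informing 21
#' fluxes the problem is underdetermined, and the ridge term shrinks the
#' solution toward the population reference (`u = 0`, i.e. all relative fluxes
#' at 1).
#'
#' @param lambda Ridge weight (>= 0, default 0.1; mild shrinkage).  At
#'   `lambda = 0` the minimum-norm least-squares solution is returned.
#' @param weights Optional named vector of positive per-biomarker residual
#'   weights (default 1 for every biomarker; the log transform already puts
#'   biomarkers on comparable scales).
#' @param tol Solver tolerance used when checking the closed form (default
#'   1e-10).
#' @return A list with class `"fit_settings"`.
#' @export
fit_settings <- function(lambda = 0.1, weights = NULL, tol = 1e-10) {
  if (lambda < 0) abort("Ridge weight lambda must be >= 0.")
  if (!is.null(weights) && any(weights <= 0)) {
    abort("Residual weights must be positive.")
  }
  structure(list(lambda = lambda, weights = weights, tol = tol),
            class = "fit_settings")
}

#' Fit per-patient flux profiles
#'
#' Estimates the log flux deviation vector of every patient in a cohort by
#' the ridge closed form \eqn{u = (A^T W A + \lambda I)^{-1} A^T W y}, where
#' `y` holds the log deviations `log(x / reference)` of the patient's present
#' biomarkers and `A` is the observable incidence restricted to those rows.
#' Patients are grouped by missingness pattern and solved in batch; results
#' are identical to row-by-row fits.  A patient with every biomarker missing
#' collapses to the population reference (`g = 1`) and is flagged
#' (`all_missing`); with `lambda = 0` such a row has undefined fluxes (`NA`).
#'
#' @param cohort Cohort tibble with biomarker columns in canonical units
#'   (`NA` = missing).  A `patient_id` column is carried through (one is
#'   created if absent).
#' @param network A [gmf_network()]; only biomarkers in its input set are
#'   used.
#' @param settings A [fit_settings()].
#' @return A `gmf_profiles` tibble: `patient_id`, `n_observed`,
#'   `residual_norm`, `all_missing`, and one column per informative flux
#'   holding the relative flux `g = exp(u)` (population reference = 1).
#' @examples
#' sim <- simulate_cohort(cohort_spec(n = 20), seed = 1)
#' net <- gmf_network("incomplete-11")
#' fit_gmf(sim$cohort, net)
#' @export
fit_gmf <- function(cohort, network, settings = fit_settings()) {
  stopifnot(inherits(network, "gmf_network"))
  cohort <- as_tibble(cohort)
  if (nrow(cohort) == 0) abort("Cohort is empty.")
  if (!"patient_id" %in% names(cohort)) {
    cohort$patient_id <- sprintf("p%04d", seq_len(nrow(cohort)))
  }

  A <- observable_incidence(network)
  refs <- reference_levels(network)
  inputs <- network$inputs
  missing_cols <- setdiff(inputs, names(cohort))
  for (mc in missing_cols) cohort[[mc]] <- NA_real_

  X <- as.matrix(cohort[, inputs, drop = FALSE])
  bad <- which(!is.na(X) & X <= 0)
  if (length(bad) > 0) {
    abort("Biomarker values must be strictly positive.", class = "gmftwin_domain_error")
  }
  Y <- log(sweep(X, 2, refs[inputs], "/"))
  present <- !is.na(Y)

  w_all <- rep(1, length(inputs))
  names(w_all) <- inputs
  if (!is.null(settings$weights)) {
    w_all[names(settings$weights)] <- settings$weights
  }

  p <- ncol(A)
  U <- matrix(NA_real_, nrow(cohort), p, dimnames = list(NULL, colnames(A)))
  resnorm <- rep(NA_real_, nrow(cohort))

  pattern <- apply(present, 1, function(z) paste(as.integer(z), collapse = ""))
  for (key in unique(pattern)) {
    rows <- which(pattern == key)
    obs <- present[rows[1], ]
    if (!any(obs)) {
      if (settings$lambda > 0) {
        U[rows, ] <- 0
        resnorm[rows] <- 0
      }
      next
    }
    A_p <- A[obs, , drop = FALSE]
    w_p <- w_all[obs]
    Yg <- t(Y[rows, obs, drop = FALSE])          # obs x patients
    U[rows, ] <- t(ridge_solve(A_p, Yg, w_p, settings$lambda))
    R <- Yg - A_p %*% t(U[rows, , drop = FALSE])
    resnorm[rows] <- sqrt(colSums(w_p * R^2))
  }

  all_missing <- rowSums(present) == 0
  if (any(all_missing)) {
    warn(paste0(sum(all_missing), " patient(s) with no observed biomarker ",
                if (settings$lambda > 0) "collapse to the population reference."
                else "have undefined fluxes (lambda = 0)."))
  }

  out <- tibble(
    patient_id = cohort$patient_id,
    n_observed = rowSums(present),
    residual_norm = resnorm,
    all_missing = all_missing
  )
  G <- exp(U)
  for (j in seq_len(p)) out[[colnames(A)[j]]] <- G[, j]
  class(out) <- c("gmf_profiles", class(out))
  attr(out, "input_set") <- network$input_set
  attr(out, "flux_ids") <- colnames(A)
  attr(out, "identifiable") <- identifiable_fluxes(network)
  out
}

# closed-form ridge / minimum-norm least squares for a single missingness
# pattern; Y is obs x patients
ridge_solve <- function(A_p, Y, w, lambda) {
  if (lambda > 0) {
    H <- crossprod(A_p, w * A_p)
    diag(H) <- diag(H) + lambda
    solve(H, crossprod(A_p, w * Y))
  } else {
    sw <- sqrt(w)
    sv <- svd(sw * A_p)
    keep <- sv$d > max(sv$d[1], 1) * 1e-10
    dinv <- ifelse(keep, 1 / sv$d, 0)
    sv$v %*% (dinv * crossprod(sv$u, sw * Y))
  }
}

#' Extract the relative flux matrix from fitted profiles
#'
#' @param profiles A `gmf_profiles` tibble from [fit_gmf()].
#' @param log Return log fluxes `u = log(g)` instead of `g`?
#' @return Numeric matrix, patients x fluxes.
#' @export
flux_matrix <- function(profiles, log = FALSE) {
  ids <- attr(profiles, "flux_ids") %||%
    setdiff(names(profiles), c("patient_id", "n_observed", "residual_norm",
                               "all_missing", "extent"))
  M <- as.matrix(profiles[, ids, drop = FALSE])
  rownames(M) <- profiles$patient_id
  if (log) base::log(M) else M
}

#' Calibrate reference health states from fitted profiles
#'
#' Defines the two reference health states of the progression axis: state A
#' (diabetes without CKD) as the component-wise median log flux vector over
#' label-negative patients, and state B (diabetes with CKD) over
#' label-positive patients.  The difference `d = u_B - u_A` spans the A-to-B
#' progression axis used by [generalized_extent()].
#'
#' @param profiles A `gmf_profiles` tibble.
#' @param labels Logical vector (CKD state per patient, baseline or horizon);
#'   both classes must be represented.
#' @return A `gmf_references` object: list with `u_A`, `u_B`, `d`,
#'   `flux_ids`.
#' @export
calibrate_references <- function(profiles, labels) {
  labels <- as.logical(labels)
  if (length(labels) != nrow(profiles)) {
    abort("labels must have one entry per profile row.")
  }
  keep <- !is.na(labels)
  if (!any(labels[keep]) || !any(!labels[keep])) {
    abort("Both label classes must be represented to calibrate references.",
          class = "gmftwin_domain_error")
  }
  U <- flux_matrix(profiles, log = TRUE)[keep, , drop = FALSE]
  lab <- labels[keep]
  u_A <- apply(U[!lab, , drop = FALSE], 2, median)
  u_B <- apply(U[lab, , drop = FALSE], 2, median)
  d <- u_B - u_A
  if (sqrt(sum(d^2)) == 0) {
    abort("Degenerate reference states: u_A and u_B coincide.",
          class = "gmftwin_domain_error")
  }
  structure(list(u_A = u_A, u_B = u_B, d = d, flux_ids = colnames(U)),
            class = "gmf_references")
}

#' @export
print.gmf_references <- function(x, ...) {
  cat("<gmf_references> progression axis over", length(x$d), "fluxes;")
  cat(" ||d|| =", format(sqrt(sum(x$d^2)), digits = 4), "\n")
  invisible(x)
}

#' @describeIn calibrate_references Tidy the reference states into a tibble
#'   (one row per flux with `u_A`, `u_B`, `d`).
#' @param x A `gmf_references` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gmf_references <- function(x, ...) {
  tibble(flux_id = x$flux_ids, u_A = unname(x$u_A), u_B = unname(x$u_B),
         d = unname(x$d))
}

#' Generalized extent along the A-to-B progression axis
#'
#' Scalar projection of a patient's log flux deviation onto the axis between
#' the reference health states: `extent = (u - u_A) . d / ||d||^2`.  A
#' patient at state A scores 0 and at state B scores 1; values outside
#' `[0, 1]` are legal and reported unclipped.
#'
#' @param profiles A `gmf_profiles` tibble.
#' @param refs A [calibrate_references()] object.
#' @return Numeric vector, one extent per patient.
#' @export
generalized_extent <- function(profiles, refs) {
  stopifnot(inherits(refs, "gmf_references"))
  d2 <- sum(refs$d^2)
  if (d2 == 0) abort("Degenerate progression axis.", class = "gmftwin_domain_error")
  U <- flux_matrix(profiles, log = TRUE)[, refs$flux_ids, drop = FALSE]
  drop(sweep(U, 2, refs$u_A) %*% refs$d) / d2
}

#' @describeIn generalized_extent Add the extent as a column to the profiles.
#' @export
add_extent <- function(profiles, refs) {
  profiles$extent <- generalized_extent(profiles, refs)
  profiles
}
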