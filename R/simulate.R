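#' Default biomarker marginals for the synthetic cohort
#'
#' Means and standard deviations typical of a tertiary-care type-2-diabetes
#' EMR cohort (the same population the default network reference levels
#' describe).  Means double as the generative reference levels; standard
#' deviations are descriptive metadata used for reporting and positivity
#' checks.
#'
#' @return Tibble with `biomarker`, `mean`, `sd`.
#' @export
default_marginals <- function() {
  tibble::tribble(
    ~biomarker,      ~mean,  ~sd,
    "fbg",             8.7,   3.2,
    "total_chol",      4.5,   1.0,
    "hdl",             1.2,   0.4,
    "ldl",             2.6,   0.8,
    "tg",              1.5,   1.0,
    "scr",            74.0,  22.7,
    "bmi",            26.8,   5.6,
    "hba1c",           8.0,   1.8,
    "hb",             13.1,   1.7,
    "sbp",           133.8,  17.9,
    "acr",             1.3,   0.8,
    "serum_albumin",   4.0,   0.7,
    "alt",            33.4,  20.0,
    "ast",            34.2,  20.0,
    "hematocrit",     39.6,   5.2
  )
}

#' Default planted flux effects of disease severity
#'
#' Log flux deviation per unit of (centred) latent severity.  The two
#' largest components sit on the HbA1c-to-ACR and Hb/ROM-to-HbA1c fluxes
#' (glycation products spilling into urine; oxidative glycation of
#' hemoglobin), with broad milder involvement of the glucose, circulation /
#' blood-pressure, lipid and creatinine pathways and depressed albumin
#' handling — the multi-pathway deterioration pattern of progressive
#' diabetic kidney disease.  Spreading the signal across pathways matters:
#' it makes the planted severity recoverable from many complementary
#' biomarkers rather than a couple of dominant ones, as in real cohorts.
#'
#' @return Named numeric vector over the default informative fluxes.
#' @export
default_flux_effects <- function() {
  c(
    "Ex.HbA1c → ACR"         =  1.10,
    "Hb.ROM → HbA1c"         =  1.00,
    "intake → Glucose"       =  0.95,
    "Glucose → utilization"  = -0.35,
    "Glucose → ROM"          =  0.35,
    "erythropoiesis → Hb"    =  0.30,
    "Hb → circulation"       =  0.20,
    "circulation → SBP"      =  0.70,
    "Glucose → Fat-lipids"   =  0.25,
    "FFA → BMI"              =  0.60,
    "Fat-lipids → TG"        =  0.95,
    "TG → LDL"               =  0.35,
    "LDL → Cholesterol"      = -0.05,
    "Cholesterol → HDL"      = -0.35,
    "muscle → Creatinine"    =  0.45,
    "Creatinine → excretion" = -0.35,
    "liver → Albumin"        = -0.60,
    "Albumin → ACR"          = -0.35
  )
}

#' Specification of a synthetic patient cohort
#'
#' Describes the generative model behind [simulate_cohort()]: a
#' one-dimensional latent disease severity `s ~ Beta(a, b)` drives true log
#' flux deviations `u_true = (s - E[s]) d_true + flux noise`, observables are
#' `x = reference * exp(A_obs u_true + obs noise)` (mean-bias corrected so
#' marginal means match the configured targets), and CKD event times are
#' exponential with hazard proportional to `exp(log_hr * s)`, right-censored
#' uniformly on `(horizon, 2 horizon)`.  SGLT2 inhibitor use shifts the lipid
#' fluxes when the effect is on.
#'
#' @param n Number of patients (default 2000, the scale of a single-centre
#'   diabetes EMR extract).
#' @param marginals Tibble of biomarker means/sds ([default_marginals()]);
#'   means act as generative reference levels.
#' @param severity_shape Beta shape parameters of the latent severity
#'   (default `c(2, 5)`: right-skewed, most patients mildly affected).
#' @param d_true Named planted flux-effect vector
#'   ([default_flux_effects()]).
#' @param sigma_obs Observation noise sd in log units (default 0.1).
#' @param sigma_flux Patient-level flux noise sd in log units (default 0.05).
#' @param missingness List: `pattern` (`"complete-14"` or `"incomplete-11"`)
#'   and MCAR `rate` (default `incomplete-11` at rate 0.15, the structure of
#'   a chronic-disease datamart where the liver panel and hematocrit are
#'   absent and routine labs are irregularly observed).
#' @param sglt2i List: `prevalence` (default 0.15) and named `effect` vector
#'   on lipid fluxes (default +0.2 on "Fat-lipids <-> FFA", -0.2 on
#'   "FFA -> BMI": enhanced lipolysis, reduced fat deposition).  Set
#'   `effect = NULL` to switch the medication effect off.
#' @param hazard List: `event_rate` (3-year CKD event probability, default
#'   0.34), `log_hr` (log hazard ratio per unit severity, default 7),
#'   `horizon` (years, default 3).
#' @param age_mean,age_sd Age distribution (truncated to `[20, 80]`).
#' @param age_severity_cor Gaussian-copula correlation between age and the
#'   latent severity (default 0.35; older patients carry more advanced
#'   disease, as in real cohorts).  The severity marginal stays
#'   `Beta(a, b)`.
#' @param male_fraction Probability of male gender (default 0.528).
#' @return A list with class `"cohort_spec"`.
#' @export
cohort_spec <- function(n = 2000,
                        marginals = default_marginals(),
                        severity_shape = c(2, 5),
                        d_true = default_flux_effects(),
                        sigma_obs = 0.1,
                        sigma_flux = 0.05,
                        missingness = list(pattern = "incomplete-11", rate = 0.15),
                        sglt2i = list(
                          prevalence = 0.15,
                          effect = c("Fat-lipids ↔ FFA" = 0.2,
                                     "FFA → BMI" = -0.2)
                        ),
                        hazard = list(event_rate = 0.34, log_hr = 7, horizon = 3),
                        age_mean = 57, age_sd = 12.4,
                        age_severity_cor = 0.35,
                        male_fraction = 0.528) {
  if (any(marginals$sd <= 0)) abort("Marginal sds must be positive.")
  if (any(marginals$mean <= 0)) {
    abort("Marginal means must be positive.", class = "gmftwin_domain_error")
  }
  rate <- missingness$rate %||% 0
  if (rate < 0 || rate > 1) abort("Missingness rate must lie in [0, 1].")
  if (!is.null(sglt2i$prevalence) &&
      (sglt2i$prevalence < 0 || sglt2i$prevalence > 1)) {
    abort("SGLT2i prevalence must lie in [0, 1].")
  }
  structure(
    list(n = n, marginals = marginals, severity_shape = severity_shape,
         d_true = d_true, sigma_obs = sigma_obs, sigma_flux = sigma_flux,
         missingness = missingness, sglt2i = sglt2i, hazard = hazard,
         age_mean = age_mean, age_sd = age_sd,
         age_severity_cor = age_severity_cor,
         male_fraction = male_fraction),
    class = "cohort_spec"
  )
}

# observable incidence over every biomarker-mapped species of the default
# network, rows named by biomarker
generator_incidence <- function(network) {
  sp <- network$species
  obs <- sp[!is.na(sp$biomarker), ]
  A <- network$incidence[obs$species_id, network$flux_ids, drop = FALSE]
  rownames(A) <- obs$biomarker
  A
}

#' Simulate a synthetic diabetes cohort with ground truth
#'
#' Draws a cohort from the generative model described in [cohort_spec()].
#' Reproducible bit-for-bit from `(spec, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed governing every random draw.
#' @param network The [gmf_network()] whose incidence defines the observable
#'   model (defaults to the shipped network; the input set does not matter
#'   here, generation uses every biomarker-mapped species).
#' @return A list with class `"gmf_cohort"`:
#'   * `cohort`: patient tibble (demographics, biomarker panel in canonical
#'     units with `NA` missingness, `on_sglt2i`, `hypertension`,
#'     `followup_years`, `ckd_event`, `event_time_years`);
#'   * `truth`: tibble `patient_id`, `severity`, `hazard`, with the true log
#'     flux matrix in `attr(truth, "u_true")`;
#'   * `spec`, `seed`, and `spec_hash`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1,
                            network = gmf_network("complete-14")) {
  stopifnot(inherits(spec, "cohort_spec"))
  A <- generator_incidence(network)
  flux_ids <- colnames(A)
  marg <- spec$marginals
  marg <- marg[match(rownames(A), marg$biomarker), ]
  if (any(is.na(marg$mean))) {
    abort("Marginals missing for some network biomarkers.")
  }

  d_true <- setNames(rep(0, length(flux_ids)), flux_ids)
  d_true[names(spec$d_true)] <- spec$d_true
  d_sglt <- setNames(rep(0, length(flux_ids)), flux_ids)
  if (!is.null(spec$sglt2i$effect)) d_sglt[names(spec$sglt2i$effect)] <- spec$sglt2i$effect
  prev <- spec$sglt2i$prevalence %||% 0

  a <- spec$severity_shape[1]; b <- spec$severity_shape[2]
  s_bar <- a / (a + b)

  # per-biomarker multiplicative mean-bias factors so that E[x] = reference
  c_sev <- drop(A %*% d_true)
  c_sglt <- drop(A %*% d_sglt)
  row_ss <- rowSums(A^2)
  mf_sev <- vapply(c_sev, function(cc) {
    if (cc == 0) return(1)
    stats::integrate(function(t) exp(cc * (t - s_bar)) * stats::dbeta(t, a, b),
                     0, 1, rel.tol = 1e-10)$value
  }, numeric(1))
  mf_sglt <- exp(-c_sglt * prev) * (1 - prev + prev * exp(c_sglt))
  mean_factor <- mf_sev * mf_sglt *
    exp((spec$sigma_flux^2 * row_ss + spec$sigma_obs^2) / 2)

  withr::with_seed(seed, {
    n <- spec$n

    # age (truncated normal) and severity (Beta marginal) tied by a Gaussian
    # copula: older patients sit higher on the severity scale
    lo <- pnorm((20 - spec$age_mean) / spec$age_sd)
    hi <- pnorm((80 - spec$age_mean) / spec$age_sd)
    u_age <- runif(n, lo, hi)
    age <- spec$age_mean + spec$age_sd * qnorm(u_age)
    z_age <- qnorm((u_age - lo) / (hi - lo))
    rho <- spec$age_severity_cor %||% 0
    z_sev <- rho * z_age + sqrt(1 - rho^2) * rnorm(n)
    severity <- stats::qbeta(pnorm(z_sev), a, b)

    on_sglt2i <- rbinom(n, 1, prev) == 1
    U <- outer(severity - s_bar, d_true) +
      outer(as.numeric(on_sglt2i) - prev, d_sglt) +
      matrix(rnorm(n * length(flux_ids), sd = spec$sigma_flux), n)
    colnames(U) <- flux_ids

    E <- matrix(rnorm(n * nrow(A), sd = spec$sigma_obs), n)
    X <- exp(sweep(U %*% t(A) + E, 2,
                   base::log(marg$mean) - base::log(mean_factor), "+"))
    colnames(X) <- rownames(A)
    X[, "hba1c"] <- pmin(X[, "hba1c"], 24.9)
    X[, "hematocrit"] <- pmin(X[, "hematocrit"], 99)

    gender <- ifelse(rbinom(n, 1, spec$male_fraction) == 1, "male", "female")

    # time to first CKD event: exponential hazard scaled so that the
    # population 3-year event probability matches the configured rate
    hz <- spec$hazard
    target <- hz$event_rate
    expected_rate <- function(h0) {
      stats::integrate(function(t) {
        (1 - exp(-h0 * exp(hz$log_hr * t) * hz$horizon)) * stats::dbeta(t, a, b)
      }, 0, 1, rel.tol = 1e-9)$value - target
    }
    h0 <- uniroot(expected_rate, c(1e-8, 10), tol = 1e-10)$root
    haz <- h0 * exp(hz$log_hr * severity)
    t_event <- rexp(n, rate = haz)
    t_cens <- runif(n, hz$horizon, 2 * hz$horizon)
    ckd_event <- t_event <= t_cens
    followup <- pmin(t_event, t_cens)

    cohort <- dplyr::bind_cols(
      tibble(
        patient_id = sprintf("p%05d", seq_len(n)),
        age = age, gender = gender
      ),
      as_tibble(X),
      tibble(
        on_sglt2i = on_sglt2i,
        hypertension = X[, "sbp"] >= 140,
        followup_years = followup,
        ckd_event = ckd_event,
        event_time_years = ifelse(ckd_event, t_event, NA_real_)
      )
    )
    cohort <- apply_missingness(cohort, spec$missingness$pattern,
                                rate = spec$missingness$rate %||% 0)

    truth <- tibble(patient_id = cohort$patient_id, severity = severity,
                    hazard = haz)
    attr(truth, "u_true") <- U
  })

  structure(
    list(cohort = cohort, truth = truth, spec = spec, seed = seed,
         spec_hash = rlang::hash(spec)),
    class = "gmf_cohort"
  )
}

#' @export
print.gmf_cohort <- function(x, ...) {
  cat("<gmf_cohort> n =", nrow(x$cohort), "| seed", x$seed,
      "| pattern", x$spec$missingness$pattern %||% "complete-14",
      "| events", sum(x$cohort$ckd_event), "\n")
  invisible(x)
}

#' Apply a missingness pattern to a cohort
#'
#' Pure function: returns a modified copy.  Pattern `"incomplete-11"` blanks
#' the serum albumin, ALT, AST and hematocrit columns entirely (structural
#' absence) and masks the remaining eleven biomarker columns missing
#' completely at random at the given rate; `"complete-14"` leaves the panel
#' untouched.
#'
#' @param cohort Cohort tibble.
#' @param pattern `"complete-14"` or `"incomplete-11"`.
#' @param rate MCAR masking rate in `[0, 1]` (only used by
#'   `"incomplete-11"`).
#' @param seed Optional seed; by default draws from the current RNG stream.
#' @return The cohort with masked biomarker cells set to `NA`.
#' @export
apply_missingness <- function(cohort, pattern = "incomplete-11", rate = 0.1,
                              seed = NULL) {
  if (rate < 0 || rate > 1) abort("Missingness rate must lie in [0, 1].")
  if (!pattern %in% c("complete-14", "incomplete-11")) {
    abort(paste0("Unknown missingness pattern '", pattern, "'."))
  }
  if (pattern == "complete-14") return(cohort)
  run <- function() {
    structural <- c("serum_albumin", "alt", "ast", "hematocrit")
    for (col in intersect(structural, names(cohort))) {
      cohort[[col]] <- NA_real_
    }
    maskable <- intersect(
      setdiff(biomarker_registry()$biomarker, structural), names(cohort)
    )
    for (col in maskable) {
      mask <- runif(nrow(cohort)) < rate
      cohort[[col]][mask] <- NA_real_
    }
    cohort
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Deterministic 12-patient toy cohort
#'
#' A small hand-written cohort used throughout the examples and tests: it
#' covers complete and partially missing panels, both genders, one SGLT2i
#' user, CKD events at 1, 2, 4 and 7 years, two administratively censored
#' subjects, and a first row that is CKD-negative under both diagnostic
#' criteria.  Values are in canonical units.
#'
#' @return A cohort tibble of 12 patients.
#' @export
toy_cohort <- function() {
  tibble::tribble(
    ~patient_id, ~age, ~gender, ~fbg, ~total_chol, ~hdl, ~ldl, ~tg, ~scr, ~bmi, ~hba1c, ~hb, ~sbp, ~acr, ~on_sglt2i, ~followup_years, ~ckd_event, ~event_time_years,
    "t01", 45, "female",  6.1, 4.2, 1.4, 2.2, 1.1,  60, 24.0, 6.8, 13.5, 122,  1.0, FALSE, 6.0, FALSE, NA,
    "t02", 58, "male",    9.5, 5.1, 1.0, 3.0, 2.1,  95, 29.0, 8.9, 12.8, 145,  4.5, FALSE, 1.0, TRUE,  1.0,
    "t03", 64, "female", 10.8, 4.8, 1.1, 2.8, 1.8, 130, 27.5, 9.6, 11.9, 152,  8.0, FALSE, 2.0, TRUE,  2.0,
    "t04", 51, "male",    7.9, 4.6, 1.2, 2.5, 1.4,  78, 26.0, 7.5, 14.1, 131,  2.0, TRUE,  5.0, FALSE, NA,
    "t05", 70, "female",  8.8, 4.4, 1.3, 2.4, 1.6, 110, 25.5, 8.2, 12.2, 148,  NA,  FALSE, 4.0, TRUE,  4.0,
    "t06", 39, "male",    7.2, 4.9, 1.1, 2.9, 1.9,  82, 31.0, 7.9, 15.0, 128,  1.5, FALSE, 8.0, FALSE, NA,
    "t07", 62, "male",    9.9, 5.3, 0.9, 3.3, 2.4,  88, 28.5, 9.1, 13.2, 156, 12.0, FALSE, 7.0, TRUE,  7.0,
    "t08", 47, "female",  6.8, 4.1, 1.5, 2.1, 1.0,  64, 23.0, 7.0, 13.8, 118,  0.8, FALSE, 5.5, FALSE, NA,
    "t09", 55, "male",    NA,  4.7, 1.2, 2.6, 1.5,  90, 27.0, 8.4, 13.0, 137,  2.8, FALSE, 3.5, FALSE, NA,
    "t10", 68, "female",  9.2, NA,  NA,  2.7, 1.7, 120, 26.5, 8.8, 12.5, 150,  5.5, FALSE, 2.5, FALSE, NA,
    "t11", 33, "male",    6.5, 4.3, 1.3, 2.3, 1.2,  70, 25.0, 7.2, 14.6, 124,  1.2, FALSE, 6.5, FALSE, NA,
    "t12", 75, "female",  NA,  NA,  NA,  NA,  NA,  NA,  NA,   NA,  NA,   NA,   NA,  FALSE, 3.0, FALSE, NA
  ) |>
    dplyr::mutate(hypertension = !is.na(.data$sbp) & .data$sbp >= 140)
}
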