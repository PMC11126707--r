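#' Biomarker registry
#'
#' The biomarker panel handled by the package: canonical units, the cohort-CSV
#' column headers, and the unit aliases [normalize_units()] accepts.  Values in
#' a cohort tibble are always stored in the canonical unit; a missing
#' measurement is an `NA` cell.
#'
#' @return A tibble with one row per biomarker: `biomarker` (internal column
#'   name), `csv_header` (cohort CSV header), `canonical_unit`, and `optional`
#'   (whether the biomarker may be structurally absent from an input set).
#' @examples
#' biomarker_registry()
#' @export
biomarker_registry <- function() {
  tibble::tribble(
    ~biomarker,      ~csv_header,   ~canonical_unit, ~optional,
    "fbg",           "FBG",         "mmol/L",        FALSE,
    "total_chol",    "Cholesterol", "mmol/L",        FALSE,
    "hdl",           "HDL",         "mmol/L",        FALSE,
    "ldl",           "LDL",         "mmol/L",        FALSE,
    "tg",            "TG",          "mmol/L",        FALSE,
    "scr",           "Creatinine",  "umol/L",        FALSE,
    "bmi",           "BMI",         "kg/m2",         FALSE,
    "hba1c",         "HbA1c",       "%",             FALSE,
    "hb",            "Hb",          "g/dL",          FALSE,
    "sbp",           "SBP",         "mmHg",          FALSE,
    "acr",           "ACR",         "mg/mmol",       TRUE,
    "serum_albumin", "Albumin",     "g/dL",          TRUE,
    "alt",           "ALT",         "U/L",           TRUE,
    "ast",           "AST",         "U/L",           TRUE,
    "hematocrit",    "Hct",         "%",             TRUE
  )
}

# Unit alias table: multiplicative factor canonical = raw * factor.
# mg/dL conversions use the molar masses of glucose (180.16), cholesterol
# (386.65 -> 38.67 mg/dL per mmol/L), triglyceride (885.7), creatinine (113.12,
# i.e. 1 mg/dL = 88.4 umol/L); ACR mg/g -> mg/mmol divides by 8.84 (creatinine
# molar mass ratio).
unit_aliases <- function() {
  list(
    fbg           = c("mmol/L" = 1, "mg/dL" = 1 / 18.016),
    total_chol    = c("mmol/L" = 1, "mg/dL" = 1 / 38.67),
    hdl           = c("mmol/L" = 1, "mg/dL" = 1 / 38.67),
    ldl           = c("mmol/L" = 1, "mg/dL" = 1 / 38.67),
    tg            = c("mmol/L" = 1, "mg/dL" = 1 / 88.57),
    scr           = c("umol/L" = 1, "μmol/L" = 1, "mg/dL" = 88.4),
    bmi           = c("kg/m2" = 1, "kg/m²" = 1),
    hba1c         = c("%" = 1, "percent" = 1),
    hb            = c("g/dL" = 1, "g/L" = 0.1),
    sbp           = c("mmHg" = 1, "mm/Hg" = 1),
    acr           = c("mg/mmol" = 1, "mg/g" = 1 / 8.84),
    serum_albumin = c("g/dL" = 1, "g/L" = 0.1),
    alt           = c("U/L" = 1),
    ast           = c("U/L" = 1),
    hematocrit    = c("%" = 1, "percent" = 1, "fraction" = 100)
  )
}

#' Convert a biomarker measurement to its canonical unit
#'
#' @param raw_value Numeric vector of measurements.
#' @param quantity Biomarker name (a `biomarker` value of
#'   [biomarker_registry()]).
#' @param unit Unit the measurement was made in; must be a recognized alias
#'   for the quantity.
#' @return Numeric vector in the canonical unit of the biomarker.
#' @examples
#' normalize_units(1, "scr", "mg/dL") # 88.4 umol/L
#' normalize_units(30, "acr", "mg/g") # 3.39 mg/mmol
#' @export
normalize_units <- function(raw_value, quantity, unit) {
  aliases <- unit_aliases()
  if (!quantity %in% names(aliases)) {
    abort(paste0("Unknown biomarker '", quantity, "'."), class = "gmftwin_unit_error")
  }
  factors <- aliases[[quantity]]
  if (!unit %in% names(factors)) {
    abort(
      paste0("Unknown unit '", unit, "' for biomarker '", quantity, "'."),
      class = "gmftwin_unit_error"
    )
  }
  raw_value * unname(factors[[unit]])
}

#' eGFR coefficient sets
#'
#' Coefficients of the piecewise power-law eGFR family
#' \deqn{\mathrm{eGFR} = I \cdot \min(S/\kappa, 1)^{\alpha}
#'   \cdot \max(S/\kappa, 1)^{s} \cdot \delta^{\mathrm{age}} \cdot m_{sex}}
#' with serum creatinine \eqn{S} in mg/dL.  The shipped default is the
#' CKD-EPI 2009 equation with the race term omitted unless requested.
#' Alternative sets (e.g. locally modified Asian variants whose coefficients
#' a site uses) can be supplied as a named list with the same fields or as a
#' YAML file with one named set per formula.
#'
#' @param formula Name of a shipped set (currently `"ckd_epi_2009"`), or a
#'   list with fields `intercept`, `kappa` (per sex), `alpha` (per sex),
#'   `slope`, `age_decay`, `female_multiplier`, and optionally
#'   `race_multiplier`.
#' @param file Optional path to a YAML file of named coefficient sets;
#'   `formula` then selects a set from that file.
#' @return A list of coefficients with class `"egfr_coefficients"`.
#' @export
egfr_coefficients <- function(formula = "ckd_epi_2009", file = NULL) {
  if (is.list(formula)) {
    coeffs <- formula
  } else {
    sets <- yaml::read_yaml(
      file %||% system.file("extdata", "egfr_coefficients.yaml", package = "gmftwin")
    )
    if (!formula %in% names(sets)) {
      abort(paste0("Unknown eGFR coefficient set '", formula, "'."))
    }
    coeffs <- sets[[formula]]
  }
  needed <- c("intercept", "kappa", "alpha", "slope", "age_decay", "female_multiplier")
  missing <- setdiff(needed, names(coeffs))
  if (length(missing) > 0) {
    abort(paste0("eGFR coefficients missing fields: ", paste(missing, collapse = ", ")))
  }
  if (any(unlist(coeffs$kappa) <= 0)) abort("eGFR kappa must be positive.")
  decay <- coeffs$age_decay
  if (decay <= 0.9 || decay >= 1.0) abort("eGFR age decay must lie in (0.9, 1).")
  structure(coeffs, class = "egfr_coefficients")
}

#' Estimated glomerular filtration rate
#'
#' Evaluates the piecewise power-law eGFR equation (default CKD-EPI 2009) at
#' serum creatinine in umol/L.  Vectorized over `scr`, `age` and `sex`.
#'
#' @param scr Serum creatinine, umol/L (> 0).
#' @param age Age in years, in (0, 120).
#' @param sex `"female"` or `"male"` (recycled).
#' @param coeffs An [egfr_coefficients()] set.
#' @param race Optional; `"black"` applies the race multiplier of the
#'   coefficient set.  Default omits it.
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' compute_egfr(61.9, age = 50, sex = "female") # ~101
#' compute_egfr(79.6, age = 60, sex = "male")   # ~92.5
#' @export
compute_egfr <- function(scr, age, sex, coeffs = egfr_coefficients(), race = NULL) {
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    abort("Serum creatinine must be positive.", class = "gmftwin_domain_error")
  }
  if (any(age <= 0 | age >= 120)) {
    abort("Age must lie in (0, 120).", class = "gmftwin_domain_error")
  }
  sex <- match_sex(sex)
  n <- max(length(scr), length(age), length(sex))
  scr <- rep_len(scr, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  scr_mgdl <- scr / 88.4
  kappa <- ifelse(sex == "female", coeffs$kappa$female, coeffs$kappa$male)
  alpha <- ifelse(sex == "female", coeffs$alpha$female, coeffs$alpha$male)
  ratio <- scr_mgdl / kappa
  out <- coeffs$intercept *
    pmin(ratio, 1)^alpha *
    pmax(ratio, 1)^coeffs$slope *
    coeffs$age_decay^age *
    ifelse(sex == "female", coeffs$female_multiplier, 1)
  if (!is.null(race) && identical(race, "black")) {
    out <- out * (coeffs$race_multiplier %||% 1)
  }
  out
}

match_sex <- function(sex) {
  key <- tolower(as.character(sex))
  out <- dplyr::case_match(
    key,
    c("f", "female", "0") ~ "female",
    c("m", "male", "1") ~ "male",
    .default = NA_character_
  )
  if (any(is.na(out) & !is.na(key))) {
    bad <- unique(key[is.na(out) & !is.na(key)])
    abort(paste0("Unrecognized gender value(s): ", paste(bad, collapse = ", ")),
          class = "gmftwin_domain_error")
  }
  out
}

#' CKD classification criteria
#'
#' @param use_acr Should the albuminuria clause (ACR strictly above
#'   `acr_threshold`) be applied when ACR is available?
#' @param acr_threshold ACR threshold, mg/mmol (default 3.3, i.e. 30 mg/g).
#' @param egfr_threshold eGFR threshold, mL/min/1.73 m^2 (default 60).
#' @param egfr_formula Name (or list) of the eGFR coefficient set.
#' @return A list with class `"ckd_criteria"`.
#' @export
ckd_criteria <- function(use_acr = TRUE, acr_threshold = 3.3,
                         egfr_threshold = 60, egfr_formula = "ckd_epi_2009") {
  if (acr_threshold <= 0 || egfr_threshold <= 0) {
    abort("CKD thresholds must be positive.")
  }
  structure(
    list(use_acr = use_acr, acr_threshold = acr_threshold,
         egfr_threshold = egfr_threshold, egfr_formula = egfr_formula),
    class = "ckd_criteria"
  )
}

#' Classify CKD status from eGFR and ACR
#'
#' A patient is CKD positive iff ACR exceeds the ACR threshold (when the
#' albuminuria clause is in use and ACR is observed) or eGFR falls below the
#' eGFR threshold.  Both inequalities are strict; boundary values are
#' negative.  With ACR missing, only the eGFR clause applies.
#'
#' @param egfr eGFR, mL/min/1.73 m^2.
#' @param acr ACR, mg/mmol; `NA` for missing.
#' @param criteria A [ckd_criteria()] object.
#' @return Logical vector.
#' @examples
#' classify_ckd(85, acr = 5)              # TRUE via albuminuria
#' classify_ckd(55, acr = NA)             # TRUE via eGFR
#' classify_ckd(60, acr = 3.3)            # FALSE: strict thresholds
#' @export
classify_ckd <- function(egfr, acr = NA_real_, criteria = ckd_criteria()) {
  if (any(is.na(egfr))) abort("eGFR must be present for CKD classification.")
  n <- max(length(egfr), length(acr))
  egfr <- rep_len(egfr, n); acr <- rep_len(acr, n)
  acr_pos <- criteria$use_acr & !is.na(acr) & acr > criteria$acr_threshold
  acr_pos | (egfr < criteria$egfr_threshold)
}

#' Classify albuminuria category from ACR
#'
#' Normoalbuminuria at ACR of at most 3.3 mg/mmol, microalbuminuria strictly
#' between 3.3 and 30, macroalbuminuria at 30 and above.
#'
#' @param acr ACR, mg/mmol (non-negative).
#' @return Factor with levels `normo`, `micro`, `macro` (`NA` for missing ACR).
#' @export
classify_albuminuria <- function(acr) {
  if (any(acr < 0, na.rm = TRUE)) {
    abort("ACR must be non-negative.", class = "gmftwin_domain_error")
  }
  factor(
    dplyr::case_when(
      is.na(acr) ~ NA_character_,
      acr <= 3.3 ~ "normo",
      acr < 30 ~ "micro",
      .default = "macro"
    ),
    levels = c("normo", "micro", "macro")
  )
}

#' Aggregate repeated measurements into a baseline panel
#'
#' Collapses timestamped laboratory measurements to a single baseline panel by
#' taking, per biomarker, the median of the values observed in the window
#' `[baseline - window_years, baseline]`.  A biomarker with no in-window
#' measurement is missing (`NA`); an even number of values uses the midpoint
#' median convention.
#'
#' @param measurements A data frame with columns `biomarker`, `time`
#'   (years, same clock as `baseline`), and `value` (canonical units).
#' @param baseline Baseline time anchoring the window.
#' @param window_years Window length in years (default 1).
#' @return A one-row tibble with one column per registry biomarker.
#' @export
aggregate_panel <- function(measurements, baseline, window_years = 1) {
  stopifnot(all(c("biomarker", "time", "value") %in% names(measurements)))
  reg <- biomarker_registry()
  in_window <- measurements |>
    dplyr::filter(.data$time <= baseline, .data$time >= baseline - window_years)
  med <- in_window |>
    dplyr::group_by(.data$biomarker) |>
    dplyr::summarise(value = median(.data$value), .groups = "drop")
  out <- setNames(rep(NA_real_, nrow(reg)), reg$biomarker)
  out[med$biomarker[med$biomarker %in% names(out)]] <-
    med$value[med$biomarker %in% names(out)]
  tibble::as_tibble_row(as.list(out))
}

#' Label baseline CKD status for a cohort
#'
#' Computes eGFR from serum creatinine, age and gender and applies
#' [classify_ckd()].  Adds `egfr` and `baseline_ckd` columns.
#'
#' @param cohort Cohort tibble (see [read_cohort_csv()] for the schema).
#' @param criteria A [ckd_criteria()] object.
#' @return The cohort with `egfr` and `baseline_ckd` columns added.
#' @export
label_baseline_ckd <- function(cohort, criteria = ckd_criteria()) {
  coeffs <- egfr_coefficients(criteria$egfr_formula)
  acr <- if ("acr" %in% names(cohort)) cohort$acr else rep(NA_real_, nrow(cohort))
  has_scr <- !is.na(cohort$scr)
  egfr <- rep(NA_real_, nrow(cohort))
  egfr[has_scr] <- compute_egfr(cohort$scr[has_scr], cohort$age[has_scr],
                                cohort$gender[has_scr], coeffs = coeffs)
  ckd <- rep(NA, nrow(cohort))
  ckd[has_scr] <- classify_ckd(egfr[has_scr], acr[has_scr], criteria = criteria)
  # a patient without creatinine can still be positive on the ACR clause
  acr_only <- !has_scr & criteria$use_acr & !is.na(acr) & acr > criteria$acr_threshold
  ckd[acr_only] <- TRUE
  dplyr::mutate(cohort, egfr = egfr, baseline_ckd = ckd)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
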