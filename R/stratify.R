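#' Risk bands for predicted CKD probability
#'
#' Three bands partitioning the probability scale: high above 0.30, low
#' below 0.10, moderate in between.  Boundary probabilities (exactly 0.10 or
#' 0.30) fall in the moderate band.  Each band carries the expected median
#' CKD percentage and expected interval used to judge observed band rates.
#'
#' @param low Upper (exclusive) bound of the low band (default 0.10).
#' @param high Lower (exclusive) bound of the high band (default 0.30).
#' @param expected_median Expected median CKD percentage per band
#'   (low, moderate, high), default `c(5, 20, 65)`.
#' @return A list with class `"risk_bands"`.
#' @export
risk_bands <- function(low = 0.10, high = 0.30,
                       expected_median = c(low = 5, moderate = 20, high = 65)) {
  stopifnot(low > 0, high < 1, low < high)
  structure(list(low = low, high = high, expected_median = expected_median),
            class = "risk_bands")
}

#' Assign patients to risk bands
#'
#' @param p Predicted probabilities in `[0, 1]`.
#' @param bands A [risk_bands()] object.
#' @return Factor with levels `low`, `moderate`, `high`.
#' @examples
#' assign_risk_group(c(0.45, 0.05, 0.30, 0.10))
#' @export
assign_risk_group <- function(p, bands = risk_bands()) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("Probabilities must lie in [0, 1].", class = "gmftwin_domain_error")
  }
  factor(
    dplyr::case_when(
      p > bands$high ~ "high",
      p < bands$low ~ "low",
      .default = "moderate"
    ),
    levels = c("low", "moderate", "high")
  )
}

#' Observed-versus-expected risk stratification table
#'
#' Counts future-CKD outcomes per risk band and flags whether the observed
#' band percentage falls inside the expected interval (< 10% for low, 10-30%
#' for moderate, > 30% for high).  An empty band is reported with `n = 0` and
#' an undefined percentage.
#'
#' @param groups Risk-band factor from [assign_risk_group()].
#' @param labels Logical outcome labels aligned with `groups`.
#' @param bands The [risk_bands()] the groups were assigned with.
#' @return Tibble: `risk_group`, `n_no_ckd`, `n_ckd`, `pct_ckd` (one
#'   decimal), `expected_median_pct`, `within_expected`.
#' @export
risk_outcome_table <- function(groups, labels, bands = risk_bands()) {
  stopifnot(length(groups) == length(labels))
  labels <- as.logical(labels)
  lvl <- c("low", "moderate", "high")
  out <- purrr::map_dfr(lvl, function(g) {
    in_g <- groups == g
    n_ckd <- sum(labels & in_g)
    n_no <- sum(!labels & in_g)
    pct <- if (n_ckd + n_no > 0) round(100 * n_ckd / (n_ckd + n_no), 1) else NA_real_
    within <- if (is.na(pct)) {
      NA
    } else if (g == "low") {
      pct < 100 * bands$low
    } else if (g == "high") {
      pct > 100 * bands$high
    } else {
      pct >= 100 * bands$low & pct <= 100 * bands$high
    }
    tibble(
      risk_group = g, n_no_ckd = n_no, n_ckd = n_ckd, pct_ckd = pct,
      expected_median_pct = unname(bands$expected_median[g]),
      within_expected = within
    )
  })
  out$risk_group <- factor(out$risk_group, levels = lvl)
  out
}
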