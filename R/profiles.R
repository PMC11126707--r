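#' Kendall correlation between input biomarkers and fitted fluxes
#'
#' Computes the tie-corrected Kendall tau-b between every input biomarker of
#' the network's input set and every informative flux.  Missing biomarker
#' values are replaced by the cohort median of the column before
#' correlation; all columns are z-score normalized first (rank correlation
#' is unaffected, but the normalized matrix also feeds the clustering).
#' Rows and columns are ordered by hierarchical clustering of the
#' correlation matrix (Euclidean distance, complete linkage).
#'
#' @param cohort Cohort tibble with the biomarker columns.
#' @param profiles A `gmf_profiles` tibble from [fit_gmf()] for the same
#'   patients.
#' @param inputs Character vector of biomarker columns to correlate
#'   (default: every registry biomarker present in the cohort with at least
#'   one observation).
#' @return A `gmf_correlation` object: list with the `tau` matrix (inputs x
#'   fluxes), `row_order`, `col_order` (dendrogram orders), and `flagged`
#'   (constant columns whose tau is undefined and reported as 0).
#' @export
input_flux_correlation <- function(cohort, profiles, inputs = NULL) {
  if (nrow(cohort) < 10) {
    abort("Need at least 10 patients for the correlation map.",
          class = "gmftwin_domain_error")
  }
  if (is.null(inputs)) {
    inputs <- intersect(biomarker_registry()$biomarker, names(cohort))
    inputs <- inputs[vapply(inputs, function(cc) any(!is.na(cohort[[cc]])), logical(1))]
  }
  X <- as.matrix(cohort[, inputs, drop = FALSE])
  for (j in seq_len(ncol(X))) {
    med <- median(X[, j], na.rm = TRUE)
    X[is.na(X[, j]), j] <- med
  }
  G <- flux_matrix(profiles)

  zscore <- function(M) {
    apply(M, 2, function(v) {
      s <- sd(v)
      if (s == 0) v - mean(v) else (v - mean(v)) / s
    })
  }
  X <- zscore(X); G <- zscore(G)

  flagged <- character()
  tau <- matrix(0, ncol(X), ncol(G), dimnames = list(inputs, colnames(G)))
  for (i in seq_len(ncol(X))) {
    for (j in seq_len(ncol(G))) {
      if (sd(X[, i]) == 0 || sd(G[, j]) == 0) {
        flagged <- union(flagged, c(inputs[i], colnames(G)[j])[c(sd(X[, i]) == 0, sd(G[, j]) == 0)])
        tau[i, j] <- 0
      } else {
        tau[i, j] <- cor(X[, i], G[, j], method = "kendall")
      }
    }
  }
  if (length(flagged) > 0) {
    warn(paste0("Constant column(s), tau reported as 0: ",
                paste(flagged, collapse = ", ")))
  }

  row_order <- if (nrow(tau) > 2) {
    hclust(dist(tau, method = "euclidean"), method = "complete")$order
  } else {
    seq_len(nrow(tau))
  }
  col_order <- if (ncol(tau) > 2) {
    hclust(dist(t(tau), method = "euclidean"), method = "complete")$order
  } else {
    seq_len(ncol(tau))
  }
  structure(
    list(tau = tau, row_order = row_order, col_order = col_order,
         flagged = flagged),
    class = "gmf_correlation"
  )
}

#' @export
print.gmf_correlation <- function(x, ...) {
  cat("<gmf_correlation>", nrow(x$tau), "inputs x", ncol(x$tau), "fluxes;",
      "tau range", paste(format(range(x$tau), digits = 2), collapse = " to "), "\n")
  invisible(x)
}

#' @describeIn input_flux_correlation Long-format tidy view (`input`,
#'   `flux_id`, `tau`), ordered by the dendrogram orders.
#' @param x A `gmf_correlation` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gmf_correlation <- function(x, ...) {
  m <- x$tau[x$row_order, x$col_order, drop = FALSE]
  tibble(
    input = factor(rep(rownames(m), times = ncol(m)), levels = rownames(m)),
    flux_id = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    tau = as.vector(m)
  )
}

#' Subgroup flux-profile comparison
#'
#' For each informative flux, compares a patient group against a reference
#' group by the ratio of group medians of the relative flux `g`, with a
#' two-sided Wilcoxon-Mann-Whitney test of no difference.  A flux is
#' `elevated` if the ratio exceeds 1 with p < `alpha`, `reduced` if below 1
#' with p < `alpha`, otherwise `unchanged` (the red/blue/black rendering of
#' profile maps).  P-values are reported unadjusted for multiplicity, as is
#' conventional for these profile maps; treat borderline calls accordingly.
#'
#' @param profiles A `gmf_profiles` tibble.
#' @param group_mask Logical vector selecting the comparison group.
#' @param reference_mask Logical vector selecting the reference group
#'   (disjoint from `group_mask`).
#' @param alpha Significance level for the category call (default 0.05).
#' @return Tibble: `flux_id`, `pathway_group` is joined by callers who have
#'   a network; here `flux_id`, `median_ratio`, `p.value`, `category`,
#'   `n_group`, `n_reference`.
#' @export
subgroup_profile <- function(profiles, group_mask, reference_mask,
                             alpha = 0.05) {
  group_mask <- as.logical(group_mask); reference_mask <- as.logical(reference_mask)
  if (!any(group_mask) || !any(reference_mask)) {
    abort("Both masks must select at least one patient.",
          class = "gmftwin_domain_error")
  }
  if (any(group_mask & reference_mask)) {
    abort("Group and reference masks must be disjoint.",
          class = "gmftwin_domain_error")
  }
  G <- flux_matrix(profiles)
  purrr::map_dfr(colnames(G), function(f) {
    g1 <- G[group_mask, f]; g0 <- G[reference_mask, f]
    m0 <- median(g0)
    ratio <- if (m0 == 0) NA_real_ else median(g1) / m0
    p <- if (sd(c(g1, g0)) == 0) {
      1
    } else {
      suppressWarnings(wilcox.test(g1, g0, alternative = "two.sided")$p.value)
    }
    category <- if (is.na(ratio)) {
      "undefined"
    } else if (p < alpha && ratio > 1) {
      "elevated"
    } else if (p < alpha && ratio < 1) {
      "reduced"
    } else {
      "unchanged"
    }
    tibble(flux_id = f, median_ratio = ratio, p.value = p,
           category = category, n_group = sum(group_mask),
           n_reference = sum(reference_mask))
  })
}

#' SGLT2 inhibitor flux-profile analysis
#'
#' Compares patients on SGLT2 inhibitors against untreated patients,
#' separately within the future-CKD and future-non-CKD strata, using
#' [subgroup_profile()].  Lipid-pathway fluxes are where the medication
#' effect is expected.  A stratum with fewer than 5 treated patients is
#' reported with a small-sample warning.
#'
#' @param profiles A `gmf_profiles` tibble.
#' @param cohort Matching cohort tibble with `on_sglt2i`.
#' @param future_ckd Logical vector: future CKD outcome per patient (`NA`
#'   rows are dropped).
#' @param network Optional [gmf_network()] used to annotate pathway groups.
#' @param alpha Significance level (default 0.05).
#' @return Tibble with a `stratum` column (`future_non_ckd` /
#'   `future_ckd`) prepended to the [subgroup_profile()] columns, plus
#'   `pathway_group` when a network is given.  Empty when no stratum has
#'   treated patients.
#' @export
sglt2i_analysis <- function(profiles, cohort, future_ckd, network = NULL,
                            alpha = 0.05) {
  if (!"on_sglt2i" %in% names(cohort)) {
    abort("Cohort lacks the on_sglt2i flag.")
  }
  future_ckd <- as.logical(future_ckd)
  out <- purrr::map_dfr(c(FALSE, TRUE), function(stratum) {
    in_stratum <- !is.na(future_ckd) & future_ckd == stratum
    treated <- in_stratum & cohort$on_sglt2i
    control <- in_stratum & !cohort$on_sglt2i
    name <- if (stratum) "future_ckd" else "future_non_ckd"
    if (!any(treated)) {
      warn(paste0("Stratum ", name, ": no treated patients; empty report."))
      return(tibble())
    }
    if (sum(treated) < 5) {
      warn(paste0("Stratum ", name, ": only ", sum(treated),
                  " treated patients; interpret with caution."))
    }
    subgroup_profile(profiles, treated, control, alpha = alpha) |>
      dplyr::mutate(stratum = name, .before = 1)
  })
  if (nrow(out) > 0 && !is.null(network)) {
    groups <- network$fluxes[, c("flux_id", "pathway_group")]
    out <- dplyr::left_join(out, groups, by = "flux_id")
  }
  out
}
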