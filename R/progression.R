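#' Outcome labels at a prediction horizon
#'
#' A patient is horizon-positive if their first CKD event occurred within
#' `horizon` years, horizon-negative if event-free with follow-up of at
#' least `horizon` years, and ineligible (excluded) if event-free but
#' followed for less than the horizon.  Excluded patients keep `NA` labels
#' and remain available (censored) for the time-to-event analyses.
#'
#' @param cohort Cohort tibble with `ckd_event`, `event_time_years`,
#'   `followup_years`.
#' @param horizon Horizon in years (3, 5 and 10 are the conventional
#'   choices).
#' @return Tibble `patient_id`, `label` (logical, `NA` when ineligible),
#'   `eligible`.
#' @export
horizon_labels <- function(cohort, horizon = 3) {
  event_in <- cohort$ckd_event & !is.na(cohort$event_time_years) &
    cohort$event_time_years <= horizon
  negative <- !event_in & cohort$followup_years >= horizon
  eligible <- event_in | negative
  tibble(
    patient_id = cohort$patient_id,
    label = ifelse(eligible, event_in, NA),
    eligible = eligible
  )
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimates of event-free survival, honoring right
#' censoring.  Curves start at survival 1; an empty group is omitted with a
#' warning.
#'
#' @param times Follow-up times (years, >= 0).
#' @param events Logical event indicators (FALSE = censored).
#' @param groups Optional grouping vector (single group when omitted).
#' @return Tidy tibble: `group`, `time`, `n_risk`, `n_event`, `survival` —
#'   one row per distinct event/censoring time per group.
#' @export
km_curves <- function(times, events, groups = NULL) {
  if (any(times < 0)) abort("Times must be non-negative.")
  groups <- groups %||% rep("all", length(times))
  if (is.factor(groups) && any(table(groups) == 0)) {
    warn(paste0("Empty group(s) omitted: ",
                paste(names(which(table(groups) == 0)), collapse = ", ")))
    groups <- droplevels(groups)
  }
  fit <- survival::survfit(
    survival::Surv(times, as.numeric(events)) ~ grp,
    data = data.frame(grp = groups)
  )
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) {
    rep(as.character(unique(groups))[1], length(sm$time))
  } else {
    sub("^grp=", "", as.character(sm$strata))
  }
  tibble(
    group = grp, time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    survival = sm$surv
  )
}

#' Log-rank test between survival curves
#'
#' @param times Follow-up times.
#' @param events Logical event indicators.
#' @param groups Grouping vector with at least two groups.
#' @return One-row tibble: `statistic` (chi-square), `df`, `p.value`.
#' @export
logrank_test <- function(times, events, groups) {
  if (length(unique(groups)) < 2) {
    abort("Log-rank test needs at least two groups.",
          class = "gmftwin_domain_error")
  }
  sd_ <- survival::survdiff(
    survival::Surv(times, as.numeric(events)) ~ grp,
    data = data.frame(grp = groups)
  )
  df <- length(sd_$n) - 1
  tibble(statistic = sd_$chisq, df = df,
         p.value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards ratio for a binary risk group
#'
#' Partial-likelihood hazard ratio (Efron tie handling) of the indicated
#' group versus the rest.  An arm without events yields an unbounded
#' estimate, which is flagged rather than hidden.
#'
#' @param times Follow-up times.
#' @param events Logical event indicators.
#' @param group Logical (or 0/1) covariate: TRUE = high-risk arm.
#' @return One-row tibble: `hr`, `ci_lower`, `ci_upper`, `p.value`,
#'   `unbounded`.
#' @export
cox_hr <- function(times, events, group) {
  group <- as.numeric(as.logical(group))
  events <- as.logical(events)
  arm_events <- c(sum(events[group == 0]), sum(events[group == 1]))
  unbounded <- any(arm_events == 0)
  if (unbounded) {
    warn("An arm has no events: hazard ratio estimate is unbounded.")
  }
  fit <- survival::coxph(
    survival::Surv(times, as.numeric(events)) ~ grp,
    data = data.frame(grp = group), ties = "efron"
  )
  sm <- summary(fit)
  tibble(
    hr = unname(sm$conf.int[1, "exp(coef)"]),
    ci_lower = unname(sm$conf.int[1, "lower .95"]),
    ci_upper = unname(sm$conf.int[1, "upper .95"]),
    p.value = unname(sm$coefficients[1, "Pr(>|z|)"]),
    unbounded = unbounded
  )
}

#' K-means clustering with between-sum-of-squares model selection
#'
#' Z-scores the columns, runs k-means with 10 random restarts for each `k`
#' in `k_range`, and selects the smallest `k` whose explained-variance
#' fraction BSS/TSS reaches `bss_target` (0.50 by default).  If no `k` in
#' range reaches the target, the largest-BSS `k` is returned with a warning.
#' All restarts are governed by `seed`; repeated runs are identical.
#'
#' @param x Numeric matrix or data frame (patients x features; typically
#'   fluxes plus age and gender).
#' @param k_range Candidate cluster counts (default 5:20).
#' @param bss_target Target explained-variance fraction (default 0.50).
#' @param seed Integer seed.
#' @param nstart Random restarts per `k` (default 10).
#' @return A `gmf_clusters` object: list with `k`, `assignments`,
#'   `centers` (z-score space), `bss_fraction`, `per_k` tibble
#'   (`k`, `bss_fraction`), and the scaling constants.
#' @export
kmeans_bss <- function(x, k_range = 5:20, bss_target = 0.50, seed = 1,
                       nstart = 10) {
  X <- as.matrix(as.data.frame(x))
  storage.mode(X) <- "double"
  if (nrow(X) < max(k_range)) {
    abort("Fewer rows than the largest candidate k.",
          class = "gmftwin_domain_error")
  }
  centers_mu <- colMeans(X)
  centers_sd <- apply(X, 2, sd)
  centers_sd[centers_sd == 0] <- 1
  Z <- scale(X, center = centers_mu, scale = centers_sd)

  withr::with_seed(seed, {
    fits <- lapply(k_range, function(k) kmeans(Z, centers = k, nstart = nstart,
                                               iter.max = 50))
  })
  bss_frac <- vapply(fits, function(f) f$betweenss / f$totss, numeric(1))
  reach <- which(bss_frac >= bss_target)
  if (length(reach) > 0) {
    pick <- reach[1]
  } else {
    warn(paste0("No k in range reaches BSS/TSS >= ", bss_target,
                "; returning the largest-BSS k."))
    pick <- which.max(bss_frac)
  }
  fit <- fits[[pick]]
  structure(
    list(
      k = k_range[pick], assignments = fit$cluster, centers = fit$centers,
      bss_fraction = bss_frac[pick],
      betweenss = fit$betweenss, withinss = fit$tot.withinss,
      totss = fit$totss,
      per_k = tibble(k = k_range, bss_fraction = bss_frac),
      center = centers_mu, scale = centers_sd, seed = seed
    ),
    class = "gmf_clusters"
  )
}

#' @export
print.gmf_clusters <- function(x, ...) {
  cat(sprintf("<gmf_clusters> k = %d (BSS/TSS = %.3f over %d patients)\n",
              x$k, x$bss_fraction, length(x$assignments)))
  invisible(x)
}

#' @describeIn kmeans_bss The BSS/TSS profile over the candidate `k` values.
#' @param x A `gmf_clusters` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gmf_clusters <- function(x, ...) x$per_k

#' @describeIn kmeans_bss One-row summary of the selected clustering.
#' @exportS3Method generics::glance
glance.gmf_clusters <- function(x, ...) {
  tibble(k = x$k, bss_fraction = x$bss_fraction, n = length(x$assignments),
         seed = x$seed)
}

#' Cluster-distance versus outcome-rate analysis
#'
#' Orders clusters by ascending CKD outcome rate (index 1 = lowest rate;
#' rate ties broken by cluster size, larger first), computes the Euclidean
#' distance from each cluster centroid to the index-1 centroid, and
#' correlates distance with outcome rate by Kendall's tau (two-sided test).
#' A rising tau means that metabolic distance from the healthiest cluster
#' tracks the event rate.
#'
#' @param clusters A [kmeans_bss()] result.
#' @param labels Logical outcome labels aligned with the clustered patients
#'   (`NA` rows are ignored within each cluster).
#' @return A `cluster_outcome` object: list with `table` (tibble
#'   `cluster_index`, `cluster`, `n`, `ckd_rate`, `distance`), `tau`,
#'   `p.value`.
#' @export
cluster_distance_outcome <- function(clusters, labels) {
  stopifnot(inherits(clusters, "gmf_clusters"))
  labels <- as.logical(labels)
  if (length(labels) != length(clusters$assignments)) {
    abort("labels must align with the clustered patients.")
  }
  ids <- sort(unique(clusters$assignments))
  if (length(ids) < 3) {
    abort("Need at least 3 clusters for the distance-outcome analysis.",
          class = "gmftwin_domain_error")
  }
  stats_tbl <- purrr::map_dfr(ids, function(cl) {
    in_cl <- clusters$assignments == cl
    lab <- labels[in_cl]
    tibble(cluster = cl, n = sum(in_cl), ckd_rate = mean(lab, na.rm = TRUE))
  })
  ord <- order(stats_tbl$ckd_rate, -stats_tbl$n)
  stats_tbl <- stats_tbl[ord, ]
  stats_tbl$cluster_index <- seq_len(nrow(stats_tbl))
  ref <- clusters$centers[as.character(stats_tbl$cluster[1]), ]
  stats_tbl$distance <- unname(apply(
    clusters$centers[as.character(stats_tbl$cluster), , drop = FALSE], 1,
    function(cc) sqrt(sum((cc - ref)^2))
  ))
  ct <- suppressWarnings(
    cor.test(stats_tbl$distance, stats_tbl$ckd_rate, method = "kendall",
             alternative = "two.sided")
  )
  structure(
    list(
      table = stats_tbl[, c("cluster_index", "cluster", "n", "ckd_rate",
                            "distance")],
      tau = unname(ct$estimate), p.value = ct$p.value
    ),
    class = "cluster_outcome"
  )
}

#' @export
print.cluster_outcome <- function(x, ...) {
  cat(sprintf("<cluster_outcome> %d clusters; Kendall tau = %.3f (p = %.4g)\n",
              nrow(x$table), x$tau, x$p.value))
  invisible(x)
}

#' @describeIn cluster_distance_outcome Per-cluster table as a tibble.
#' @param x A `cluster_outcome` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cluster_outcome <- function(x, ...) x$table

#' @describeIn cluster_distance_outcome One-row tau summary.
#' @exportS3Method generics::glance
glance.cluster_outcome <- function(x, ...) {
  tibble(tau = x$tau, p.value = x$p.value, n_clusters = nrow(x$table))
}
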