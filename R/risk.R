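#' Balanced train/test/test split
#'
#' Randomly partitions a cohort into training (50%) and two testing sets
#' (25% each by default), redrawing until the balance covariates show no
#' significant difference across the three parts (age by Kruskal-Wallis rank
#' test, gender and hypertension by chi-square, all at p > 0.05).
#' Deterministic given `seed`; if no acceptable split is found within
#' `max_attempts`, the best-balance split seen is returned with a warning.
#'
#' @param cohort Cohort tibble with `age`, `gender` columns; hypertension is
#'   taken from a `hypertension` flag or SBP >= 140 mmHg.
#' @param fractions Numeric vector of three fractions summing to 1.
#' @param seed Integer seed.
#' @param max_attempts Maximum redraws (default 200).
#' @return The cohort with a `.split` factor column
#'   (`train`/`test1`/`test2`).
#' @export
balanced_split <- function(cohort, fractions = c(0.50, 0.25, 0.25), seed = 1,
                           max_attempts = 200) {
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3) {
    abort("fractions must be three numbers summing to 1.")
  }
  n <- nrow(cohort)
  if (n < 40) abort("Cohort too small to split (need >= 40 patients).")
  htn <- if ("hypertension" %in% names(cohort)) {
    cohort$hypertension
  } else {
    !is.na(cohort$sbp) & cohort$sbp >= 140
  }
  sizes <- c(round(n * fractions[1]), round(n * fractions[2]))
  sizes <- c(sizes, n - sum(sizes))
  labels <- factor(rep(c("train", "test1", "test2"), times = sizes),
                   levels = c("train", "test1", "test2"))

  balance_p <- function(split) {
    p_age <- kruskal.test(cohort$age, split)$p.value
    p_gen <- suppressWarnings(chisq.test(table(cohort$gender, split))$p.value)
    p_htn <- if (length(unique(htn)) > 1) {
      suppressWarnings(chisq.test(table(htn, split))$p.value)
    } else {
      1
    }
    c(p_age, p_gen, p_htn)
  }

  withr::with_seed(seed, {
    best <- NULL
    best_min_p <- -Inf
    accepted <- NULL
    for (attempt in seq_len(max_attempts)) {
      split <- sample(labels)
      p <- balance_p(split)
      if (all(p > 0.05)) {
        accepted <- split
        break
      }
      if (min(p) > best_min_p) {
        best_min_p <- min(p)
        best <- split
      }
    }
    if (is.null(accepted)) {
      warn(paste0("No balanced split found in ", max_attempts,
                  " attempts; returning the best-balance split (min p = ",
                  format(best_min_p, digits = 3), ")."))
      accepted <- best
    }
    cohort$.split <- accepted
  })
  cohort
}

#' Assemble the modelling feature table
#'
#' Joins fitted flux profiles with demographics and an outcome label into the
#' feature table used by [fit_ckd_lr()]: one column per informative flux
#' (relative flux `g`, untransformed), `age`, `gender`, and a logical
#' `label`.  Rows with `NA` label (e.g. horizon-ineligible patients) are
#' dropped.
#'
#' @param profiles A `gmf_profiles` tibble from [fit_gmf()].
#' @param cohort The matching cohort tibble (joined on `patient_id`).
#' @param label Logical vector aligned with `cohort` rows (CKD at baseline or
#'   within a horizon), or the name of a logical cohort column.
#' @return A tibble with `patient_id`, flux columns, `age`, `gender`,
#'   `label`.
#' @export
gmf_features <- function(profiles, cohort, label) {
  if (is.character(label) && length(label) == 1) label <- cohort[[label]]
  stopifnot(length(label) == nrow(cohort))
  flux_ids <- attr(profiles, "flux_ids")
  demo <- tibble(patient_id = cohort$patient_id, age = cohort$age,
                 gender = cohort$gender, label = as.logical(label))
  out <- dplyr::inner_join(
    profiles[, c("patient_id", flux_ids)], demo, by = "patient_id"
  ) |>
    dplyr::filter(!is.na(.data$label))
  attr(out, "flux_ids") <- flux_ids
  attr(out, "identifiable") <- attr(profiles, "identifiable")
  out
}

#' Logistic CKD identification/prediction model
#'
#' Plain maximum-likelihood logistic regression (IRLS via [stats::glm()]) of
#' the CKD label on the informative relative fluxes, standardized age
#' (z-score on the training data) and gender (female = 0, male = 1).  Wald
#' standard errors and p-values come from the observed information matrix.
#' Fluxes that are structurally aliased under the fitted input set (see
#' [identifiable_fluxes()]) are excluded from the regression — their fitted
#' values are exact linear functions of the kept fluxes, so they cannot
#' carry separable coefficients — and are listed in the model's `aliased`
#' field.  Perfect or quasi-perfect separation is flagged as
#' non-convergence and the coefficients are still reported.
#'
#' @param features A [gmf_features()] table (or any tibble with a logical
#'   `label`, `age`, `gender`, and numeric predictor columns).
#' @return A `ckd_lr` object: the glm fit plus the feature schema and age
#'   standardization constants.
#' @export
fit_ckd_lr <- function(features) {
  lab <- features$label
  if (sum(lab) < 10 || sum(!lab) < 10) {
    abort("Need at least 10 patients in each outcome class.",
          class = "gmftwin_domain_error")
  }
  predictors <- setdiff(names(features), c("patient_id", "label", ".split"))
  # structurally aliased fluxes (observable signature linearly dependent on
  # earlier fluxes for this input set) are exact linear functions of the kept
  # fluxes and cannot support coefficient inference: exclude them up front
  # instead of leaving the aliasing to the IRLS QR.
  aliased <- character()
  identifiable <- attr(features, "identifiable")
  flux_ids <- attr(features, "flux_ids")
  if (!is.null(identifiable) && !is.null(flux_ids)) {
    aliased <- intersect(setdiff(flux_ids, identifiable), predictors)
    predictors <- setdiff(predictors, aliased)
  }
  age_center <- if ("age" %in% predictors) mean(features$age) else 0
  age_scale <- if ("age" %in% predictors) sd(features$age) else 1
  X <- build_design(features, predictors, age_center, age_scale)
  dat <- as.data.frame(X)
  dat$.label <- as.numeric(lab)
  fit <- suppressWarnings(glm(.label ~ ., data = dat, family = binomial()))
  separated <- !fit$converged ||
    any(abs(predict(fit, type = "link")) > 25)
  if (separated) {
    warn("Possible separation: logistic fit flagged as non-converged.")
  }
  structure(
    list(fit = fit, predictors = predictors, aliased = aliased,
         age_center = age_center, age_scale = age_scale,
         term_map = attr(X, "term_map"), converged = !separated),
    class = "ckd_lr"
  )
}

# internal: code gender, z-score age, rename arbitrary predictor names to
# syntactic placeholders (term_map restores them)
build_design <- function(data, predictors, age_center, age_scale) {
  cols <- lapply(predictors, function(p) {
    if (p == "gender") {
      as.numeric(match_sex(data$gender) == "male")
    } else if (p == "age") {
      (data$age - age_center) / age_scale
    } else {
      as.numeric(data[[p]])
    }
  })
  X <- do.call(cbind, cols)
  safe <- sprintf("x%03d", seq_along(predictors))
  colnames(X) <- safe
  attr(X, "term_map") <- setNames(predictors, safe)
  X
}

#' @export
print.ckd_lr <- function(x, ...) {
  cat("<ckd_lr> logistic model:", length(x$predictors), "predictors,",
      length(x$fit$y), "patients,",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' @describeIn fit_ckd_lr Coefficients, Wald standard errors and p-values as
#'   a tibble (original predictor names restored).
#' @param x A `ckd_lr` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ckd_lr <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  term <- rownames(sm)
  term <- ifelse(term == "(Intercept)", "(Intercept)",
                 unname(x$term_map[term]))
  tibble(
    term = term,
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "z value"]),
    p.value = unname(sm[, "Pr(>|z|)"])
  )
}

#' @describeIn fit_ckd_lr One-row model summary (deviance, AIC, n, events,
#'   convergence).
#' @exportS3Method generics::glance
glance.ckd_lr <- function(x, ...) {
  tibble(
    null.deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    AIC = x$fit$aic,
    nobs = length(x$fit$y),
    n.events = sum(x$fit$y),
    converged = x$converged
  )
}

#' Predict CKD risk probabilities
#'
#' Inverse-logit of the linear predictor of a fitted [fit_ckd_lr()] model on
#' new data with the same feature schema (age is standardized with the
#' training constants).
#'
#' @param model A `ckd_lr` object.
#' @param newdata Feature tibble with the training predictor columns.
#' @return `newdata` with a `.risk` probability column appended.
#' @export
predict_risk <- function(model, newdata) {
  miss <- setdiff(model$predictors, names(newdata))
  if (length(miss) > 0) {
    abort(paste0("newdata lacks predictor column(s): ",
                 paste(miss, collapse = ", ")), class = "gmftwin_schema_error")
  }
  X <- build_design(newdata, model$predictors, model$age_center, model$age_scale)
  beta <- coef(model$fit)
  beta[is.na(beta)] <- 0  # columns aliased out by the IRLS QR contribute nothing
  eta <- drop(cbind(1, X) %*% beta)
  newdata$.risk <- plogis(eta)
  newdata
}

#' Rank (Mann-Whitney) AUC
#'
#' Probability that a random positive outranks a random negative, with ties
#' counted half: the Mann-Whitney formulation of the ROC area.
#'
#' @param probs Numeric scores.
#' @param labels Logical (or 0/1) outcome labels.
#' @return AUC in `[0, 1]`; `NA` with a warning if only one class present.
#' @export
rank_auc <- function(probs, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    warn("AUC undefined: only one outcome class present.")
    return(NA_real_)
  }
  r <- rank(probs, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap AUC with out-of-bag refitting
#'
#' Repeats `B` times: resample patients with replacement, refit the logistic
#' model on the resample, and score the out-of-bag patients.  Reports the
#' bootstrap median AUC and the 2.5-97.5 percentile interval; iterations
#' whose out-of-bag set contains a single class are skipped and counted.
#' Alternatively, scheme `"resample_test"` keeps a fixed fitted model and
#' bootstraps the evaluation set (the design used with a dedicated training
#' split).
#'
#' @param features A [gmf_features()] table (with `label`).
#' @param B Number of bootstrap iterations (default 2000).
#' @param scheme `"out_of_bag_refit"` (default) or `"resample_test"`.
#' @param seed Integer seed; results are reproducible bit-for-bit.
#' @param model For `"resample_test"`: the fitted `ckd_lr` model to evaluate.
#' @return An `auc_report`: list with `point` (full-data or test-set AUC),
#'   `median`, `ci_lower`, `ci_upper`, `B`, `B_effective`, `scheme`, `seed`,
#'   and the vector of per-iteration `aucs`.
#' @export
bootstrap_auc <- function(features, B = 2000, scheme = "out_of_bag_refit",
                          seed = 1, model = NULL) {
  scheme <- match.arg(scheme, c("out_of_bag_refit", "resample_test"))
  lab <- features$label
  if (!any(lab) || !any(!lab)) {
    abort("Both outcome classes must be present.", class = "gmftwin_domain_error")
  }
  n <- nrow(features)
  withr::with_seed(seed, {
    if (scheme == "out_of_bag_refit") {
      full <- fit_ckd_lr(features)
      point <- rank_auc(predict_risk(full, features)$.risk, lab)
      aucs <- rep(NA_real_, B)
      for (bb in seq_len(B)) {
        idx <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), idx)
        if (length(oob) == 0 || length(unique(lab[oob])) < 2 ||
            sum(lab[idx]) < 10 || sum(!lab[idx]) < 10) {
          next
        }
        m <- fit_ckd_lr(features[idx, ])
        aucs[bb] <- rank_auc(predict_risk(m, features[oob, ])$.risk, lab[oob])
      }
    } else {
      if (is.null(model)) {
        abort("scheme 'resample_test' needs a fitted model.")
      }
      probs <- predict_risk(model, features)$.risk
      point <- rank_auc(probs, lab)
      aucs <- rep(NA_real_, B)
      for (bb in seq_len(B)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(lab[idx])) < 2) next
        aucs[bb] <- rank_auc(probs[idx], lab[idx])
      }
    }
  })
  ok <- aucs[!is.na(aucs)]
  if (length(ok) < B) {
    warn(paste0(B - length(ok), " bootstrap iteration(s) skipped ",
                "(single-class resample)."))
  }
  structure(
    list(point = point, median = median(ok),
         ci_lower = unname(quantile(ok, 0.025)),
         ci_upper = unname(quantile(ok, 0.975)),
         B = B, B_effective = length(ok), scheme = scheme, seed = seed,
         aucs = ok),
    class = "auc_report"
  )
}

#' @export
print.auc_report <- function(x, ...) {
  cat(sprintf("<auc_report> AUC %.3f (bootstrap median %.3f, CI %.3f-%.3f, B = %d/%d, %s)\n",
              x$point, x$median, x$ci_lower, x$ci_upper, x$B_effective, x$B,
              x$scheme))
  invisible(x)
}

#' @describeIn bootstrap_auc One-row summary tibble of an `auc_report`.
#' @param x An `auc_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.auc_report <- function(x, ...) {
  tibble(auc = x$point, auc_median = x$median, ci_lower = x$ci_lower,
         ci_upper = x$ci_upper, B = x$B, B_effective = x$B_effective,
         scheme = x$scheme, seed = x$seed)
}

#' Operating-point classification metrics
#'
#' Confusion-matrix metrics (sensitivity, specificity, negative and positive
#' predictive value) at a probability threshold, plus the rank AUC.
#'
#' @param probs Predicted probabilities.
#' @param labels Logical outcome labels.
#' @param threshold Operating threshold in (0, 1); predictions strictly
#'   above it are called positive.  Default is the threshold maximizing
#'   Youden's J on the same data (see [youden_threshold()]).
#' @return One-row tibble: `auc`, `sn`, `sp`, `npv`, `ppv`, `threshold`
#'   (proportions in `[0, 1]`).
#' @export
evaluate_metrics <- function(probs, labels, threshold = NULL) {
  labels <- as.logical(labels)
  threshold <- threshold %||% youden_threshold(probs, labels)
  if (threshold <= 0 || threshold >= 1) {
    abort("threshold must lie strictly inside (0, 1).")
  }
  pred <- probs > threshold
  tp <- sum(pred & labels); fn <- sum(!pred & labels)
  tn <- sum(!pred & !labels); fp <- sum(pred & !labels)
  tibble(
    auc = rank_auc(probs, labels),
    sn = tp / (tp + fn),
    sp = tn / (tn + fp),
    npv = tn / (tn + fn),
    ppv = tp / (tp + fp),
    threshold = threshold
  )
}

#' @describeIn evaluate_metrics Threshold maximizing Youden's J
#'   (sensitivity + specificity - 1) over the observed probabilities.
#' @export
youden_threshold <- function(probs, labels) {
  labels <- as.logical(labels)
  cand <- sort(unique(probs))
  if (length(cand) > 1) {
    cand <- (cand[-1] + cand[-length(cand)]) / 2
  }
  cand <- pmin(pmax(cand, 1e-9), 1 - 1e-9)
  j <- vapply(cand, function(t) {
    pred <- probs > t
    sn <- sum(pred & labels) / sum(labels)
    sp <- sum(!pred & !labels) / sum(!labels)
    sn + sp - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Significant predictors of a fitted logistic model
#'
#' Features with Wald p-value below `alpha`, sorted by ascending p-value —
#' the model-card view of which fluxes and demographics carry the predictive
#' signal.
#'
#' @param model A `ckd_lr` model.
#' @param alpha Significance level (default 0.05).
#' @return Tibble `predictor`, `estimate`, `p.value` (possibly empty).
#' @export
significant_predictors <- function(model, alpha = 0.05) {
  td <- tidy(model) |>
    dplyr::filter(.data$term != "(Intercept)", .data$p.value < alpha) |>
    dplyr::arrange(.data$p.value)
  tibble(predictor = td$term, estimate = td$estimate, p.value = td$p.value)
}

#' Ablation of the top significant predictors
#'
#' Quantifies how much of the model's discrimination lives in its top-`k`
#' significant predictors by refitting with those predictors removed
#' (`drop_top_k`) or with only those predictors kept (`keep_only_top_k`),
#' each evaluated by the same out-of-bag bootstrap as the full model.
#'
#' @param features A [gmf_features()] table.
#' @param k Number of top significant predictors (default 3).
#' @param B Bootstrap iterations per model (default 2000).
#' @param seed Integer seed.
#' @param alpha Significance level for selecting the top predictors.
#' @return A list with `top` (character vector of ablated predictors) and
#'   `auc_report`s `full`, `drop_top`, `keep_top`.
#' @export
ablation_auc <- function(features, k = 3, B = 2000, seed = 1, alpha = 0.05) {
  full_model <- fit_ckd_lr(features)
  sig <- significant_predictors(full_model, alpha = alpha)
  if (nrow(sig) < k) {
    abort(paste0("Only ", nrow(sig), " significant predictor(s); need ", k, "."),
          class = "gmftwin_domain_error")
  }
  top <- sig$predictor[seq_len(k)]
  keep_cols <- function(cols) {
    out <- features[, c("patient_id", cols, "label")]
    attr(out, "flux_ids") <- intersect(attr(features, "flux_ids"), cols)
    out
  }
  predictors <- setdiff(names(features), c("patient_id", "label"))
  list(
    top = top,
    full = bootstrap_auc(features, B = B, seed = seed),
    drop_top = bootstrap_auc(keep_cols(setdiff(predictors, top)), B = B, seed = seed),
    keep_top = bootstrap_auc(keep_cols(top), B = B, seed = seed)
  )
}
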