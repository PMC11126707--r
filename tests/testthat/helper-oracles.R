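# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# minimum-norm / ridge least squares via explicit SVD (oracle for the fit)
oracle_ridge <- function(A, y, w = rep(1, nrow(A)), lambda = 0) {
  sw <- sqrt(w)
  sv <- svd(sw * A)
  d <- sv$d
  if (lambda > 0) {
    f <- d / (d^2 + lambda)
  } else {
    f <- ifelse(d > max(d[1], 1) * 1e-10, 1 / d, 0)
  }
  drop(sv$v %*% (f * crossprod(sv$u, sw * y)))
}

# all-pairs concordance AUC
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Kendall tau-b by explicit pair counting with tie correction
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# exact two-sided Wilcoxon-Mann-Whitney p by full enumeration of label
# assignments (small groups only)
oracle_mwu_exact <- function(g1, g0) {
  pooled <- c(g1, g0)
  n1 <- length(g1)
  u_stat <- function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  obs <- u_stat(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_stat)
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# hand product-limit Kaplan-Meier at each distinct time
oracle_km <- function(times, events) {
  ts <- sort(unique(times))
  surv <- numeric(length(ts))
  s <- 1
  for (k in seq_along(ts)) {
    at_risk <- sum(times >= ts[k])
    d <- sum(times == ts[k] & events)
    if (at_risk > 0) s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  tibble::tibble(time = ts, survival = surv)
}

# Newton-Raphson logistic MLE oracle (no glm)
oracle_logistic <- function(X, y, iter = 100) {
  X1 <- cbind(1, X)
  beta <- rep(0, ncol(X1))
  for (i in seq_len(iter)) {
    eta <- drop(X1 %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    grad <- crossprod(X1, y - p)
    H <- crossprod(X1, W * X1)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  drop(beta)
}

# small complete cohort with planted signal for fast module tests
make_small_sim <- function(n = 400, seed = 42, pattern = "incomplete-11",
                           rate = 0.15) {
  simulate_cohort(
    cohort_spec(n = n, missingness = list(pattern = pattern, rate = rate)),
    seed = seed
  )
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
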