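# Statistical primitives: variation level, two-tailed beta-binomial group
# test, Fisher exact test, Benjamini-Hochberg correction.

#' Variation level of a base-call observation
#'
#' The ratio of variant calls to the sum of variant and reference calls.
#' Vectorized; `NA` where both counts are zero (undefined level).
#'
#' @param variant_calls,ref_calls non-negative integer vectors.
#' @return numeric vector in `[0, 1]` (or `NA`).
#' @examples
#' variation_level(5, 95)   # 0.05
#' @export
variation_level <- function(variant_calls, ref_calls) {
  stopifnot(all(variant_calls >= 0, na.rm = TRUE),
            all(ref_calls >= 0, na.rm = TRUE))
  tot <- variant_calls + ref_calls
  ifelse(tot > 0, variant_calls / tot, NA_real_)
}

# Beta-binomial log-likelihood under the intraclass-correlation
# parameterization: alpha = mu(1-rho)/rho, beta = (1-mu)(1-rho)/rho.
# rho -> 0 recovers the binomial.
#' @noRd
bb_loglik <- function(k, n, mu, rho) {
  mu <- min(max(mu, 1e-9), 1 - 1e-9)
  if (rho < 1e-9)
    return(sum(stats::dbinom(k, n, mu, log = TRUE)))
  rho <- min(rho, 1 - 1e-9)
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

# Maximize the two-group beta-binomial likelihood with a shared rho.
# `common_mu = TRUE` fits the null (one mu); otherwise group-specific mus.
# Returns list(loglik, mu (length 1 or 2), rho).
#' @noRd
bb_fit <- function(ka, na, kb, nb, common_mu, rho = NULL) {
  pool_mu <- (sum(ka) + sum(kb)) / (sum(na) + sum(nb))
  mu_a <- sum(ka) / sum(na); mu_b <- sum(kb) / sum(nb)
  if (!is.null(rho)) {
    # fixed overdispersion: profile out mu only
    if (common_mu) {
      opt <- stats::optimize(function(m) bb_loglik(c(ka, kb), c(na, nb), m, rho),
                             c(1e-9, 1 - 1e-9), maximum = TRUE, tol = 1e-10)
      return(list(loglik = opt$objective, mu = opt$maximum, rho = rho))
    }
    oa <- stats::optimize(function(m) bb_loglik(ka, na, m, rho),
                          c(1e-9, 1 - 1e-9), maximum = TRUE, tol = 1e-10)
    ob <- stats::optimize(function(m) bb_loglik(kb, nb, m, rho),
                          c(1e-9, 1 - 1e-9), maximum = TRUE, tol = 1e-10)
    return(list(loglik = oa$objective + ob$objective,
                mu = c(oa$maximum, ob$maximum), rho = rho))
  }
  # profile likelihood over rho; inner 1-D mu optimizations are smooth
  prof <- function(lrho) {
    r <- exp(lrho) / (1 + exp(lrho))
    bb_fit(ka, na, kb, nb, common_mu, rho = r)$loglik
  }
  best <- stats::optimize(prof, c(stats::qlogis(1e-9), stats::qlogis(0.999)),
                          maximum = TRUE, tol = 1e-8)
  rho_hat <- stats::plogis(best$maximum)
  fit <- bb_fit(ka, na, kb, nb, common_mu, rho = rho_hat)
  # boundary check: the binomial limit can dominate
  fit0 <- bb_fit(ka, na, kb, nb, common_mu, rho = 1e-9)
  if (fit0$loglik > fit$loglik) fit <- fit0
  c(fit, list(mu_start = if (common_mu) pool_mu else c(mu_a, mu_b)))
}

#' Two-tailed beta-binomial test for a group difference in variation levels
#'
#' Likelihood-ratio test of a common beta-binomial proportion (H0) against
#' group-specific proportions (H1), with the between-replicate
#' overdispersion (intraclass correlation rho) shared between groups and
#' estimated by profile maximum likelihood. The two-sided p-value is
#' calibrated against a chi-square(1) reference; when either group's total
#' depth is below `boot_depth_threshold`, a parametric bootstrap under the
#' fitted null replaces the asymptotic reference.
#'
#' @param variant_a,total_a variant and total (variant + reference) call
#'   counts for the samples of group A.
#' @param variant_b,total_b likewise for group B.
#' @param rho optional fixed overdispersion; `rho = 0` gives the plain
#'   binomial likelihood-ratio test. `NULL` (default) estimates it.
#' @param boot_depth_threshold group total depth below which the parametric
#'   bootstrap is used (default 50).
#' @param n_boot bootstrap resamples (default 1000).
#' @return object of class `bbtest`: a list with `p.value`, `group_means`
#'   (fitted H1 proportions), `overdispersion` (estimated rho, clamped to
#'   `[1e-9, 0.999]`), `statistic` (LRT), and `method`.
#' @examples
#' beta_binomial_test(c(0, 0, 0), c(100, 120, 90),
#'                    c(20, 25, 18), c(100, 120, 90))$p.value
#' @export
beta_binomial_test <- function(variant_a, total_a, variant_b, total_b,
                               rho = NULL, boot_depth_threshold = 50,
                               n_boot = 1000) {
  stopifnot(length(variant_a) == length(total_a),
            length(variant_b) == length(total_b),
            length(variant_a) >= 2, length(variant_b) >= 2,
            all(total_a > 0), all(total_b > 0),
            all(variant_a <= total_a), all(variant_b <= total_b))
  res <- structure(list(p.value = 1, group_means = c(0, 0),
                        overdispersion = 0, statistic = 0,
                        method = "beta-binomial LRT (chi-square(1))"),
                   class = "bbtest")
  if (sum(variant_a) + sum(variant_b) == 0) return(res)
  # the overdispersion is shared by H0 and H1: estimated jointly with the
  # null fit (unless fixed by the user) and held there for the H1 fit,
  # which keeps the chi-square(1) reference calibrated at small replicate
  # numbers
  fit0 <- bb_fit(variant_a, total_a, variant_b, total_b, TRUE, rho = rho)
  fit1 <- bb_fit(variant_a, total_a, variant_b, total_b, FALSE,
                 rho = fit0$rho)
  lrt <- max(0, 2 * (fit1$loglik - fit0$loglik))
  res$statistic <- lrt
  res$group_means <- fit1$mu
  res$overdispersion <- max(fit0$rho, 1e-9)
  if (min(sum(total_a), sum(total_b)) < boot_depth_threshold &&
      is.null(rho)) {
    stat_boot <- numeric(n_boot)
    mu0 <- fit0$mu; rho0 <- fit0$rho
    for (b in seq_len(n_boot)) {
      sim <- function(nn) {
        p <- if (rho0 > 1e-8) {
          stats::rbeta(length(nn), mu0 * (1 - rho0) / rho0,
                       (1 - mu0) * (1 - rho0) / rho0)
        } else rep(mu0, length(nn))
        stats::rbinom(length(nn), nn, p)
      }
      ka <- sim(total_a); kb <- sim(total_b)
      if (sum(ka) + sum(kb) == 0) { stat_boot[b] <- 0; next }
      f0 <- bb_fit(ka, total_a, kb, total_b, TRUE)
      f1 <- bb_fit(ka, total_a, kb, total_b, FALSE, rho = f0$rho)
      stat_boot[b] <- max(0, 2 * (f1$loglik - f0$loglik))
    }
    res$p.value <- (1 + sum(stat_boot >= lrt - 1e-12)) / (n_boot + 1)
    res$method <- "beta-binomial LRT (parametric bootstrap)"
  } else {
    res$p.value <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  }
  res
}

#' @export
print.bbtest <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  LRT = %.4g, p = %.4g\n", x$statistic, x$p.value))
  cat(sprintf("  group means = %.4g / %.4g, rho = %.3g\n",
              x$group_means[1], x$group_means[2], x$overdispersion))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Minimum-likelihood two-sided convention: the p-value sums hypergeometric
#' probabilities of all tables (at the observed margins) no more probable
#' than the observed one.
#'
#' @param tab 2x2 non-negative integer matrix.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0))
  if (sum(tab) == 0) return(1)
  stats::fisher.test(tab)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment: order-preserving, each adjusted value at
#' least the raw p, capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}
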