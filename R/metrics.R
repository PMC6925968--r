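# Evaluation statistics: bias, variance, MSE, log-ratios with bootstrap
# confidence intervals, coverage probability with band classification,
# average confidence-interval length and information comparisons.

#' Bias of replicate estimates against the truth
#'
#' Mean of the replicate estimates minus the true value.
#' @param estimates replicate estimates (missings ignored).
#' @param truth the true value.
#' @return `mean(estimates) - truth`, or `NA` when all estimates are missing.
#' @export
bias <- function(estimates, truth) {
  x <- estimates[!is.na(estimates)]
  if (!length(x)) return(NA_real_)
  mean(x) - truth
}

#' Variance of replicate estimates (divisor R)
#'
#' The mean of squared deviations from the mean -- divisor `R`, not `R - 1`,
#' so that the decomposition `mse = bias^2 + variance` holds exactly.
#' @param estimates replicate estimates.
#' @return Population-style variance of the nonmissing estimates.
#' @export
variance_of_estimates <- function(estimates) {
  x <- estimates[!is.na(estimates)]
  if (!length(x)) return(NA_real_)
  mean((x - mean(x))^2)
}

#' Mean squared error from its bias-variance decomposition
#'
#' `bias^2 + variance`; algebraically equal to the direct mean squared
#' deviation from the truth when the variance uses divisor R.
#' @param bias,variance components as returned by [bias()] and
#'   [variance_of_estimates()].
#' @export
mse <- function(bias, variance) {
  bias^2 + variance
}

#' Natural log of a ratio
#'
#' @param num,den positive numerator and denominator (e.g. unweighted and
#'   weighted variances).  Nonpositive input yields `NA` with a warning.
#' @export
log_ratio <- function(num, den) {
  out <- rep(NA_real_, max(length(num), length(den)))
  ok <- is.finite(num) & is.finite(den) & num > 0 & den > 0
  if (any(!ok)) warning("nonpositive or missing ratio input; returning NA")
  out[ok] <- log(num[ok] / den[ok])
  out
}

#' Percentile bootstrap CI for a statistic of paired replicate estimates
#'
#' Resamples replicate indices with replacement `B_m` times, recomputes the
#' statistic each time, and returns the empirical 2.5%/97.5% quantiles.
#' Used for the confidence intervals on bias differences and variance/MSE
#' log-ratios, which are statistics of the full set of paired replicate
#' estimates.
#'
#' @param statistic function taking a data.frame (rows = replicates) and
#'   returning a scalar.
#' @param data data.frame of replicate-level inputs.
#' @param B_m bootstrap draws (default 1000).
#' @param seed optional seed.
#' @param level confidence level.
#' @return `c(low, high)`.
#' @export
replicate_bootstrap_ci <- function(statistic, data, B_m = 1000L, seed = NULL,
                                   level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  stats_b <- vapply(seq_len(B_m), function(b) {
    statistic(data[sample.int(n, n, replace = TRUE), , drop = FALSE])
  }, numeric(1))
  a <- (1 - level) / 2
  stats::quantile(stats_b, c(a, 1 - a), na.rm = TRUE, names = FALSE,
                  type = 7)
}

#' Coverage probability of a set of confidence intervals
#'
#' Proportion of replicates whose (closed) interval contains the truth;
#' missing intervals are excluded.
#' @param ci_low,ci_high interval endpoints across replicates.
#' @param truth the true value.
#' @return Proportion in `[0, 1]`, with attribute `n_used`.
#' @export
coverage_probability <- function(ci_low, ci_high, truth) {
  keep <- !is.na(ci_low) & !is.na(ci_high)
  if (!any(keep)) return(structure(NA_real_, n_used = 0L))
  p <- mean(ci_low[keep] <= truth & truth <= ci_high[keep])
  structure(p, n_used = sum(keep))
}

#' Classify a coverage probability into performance bands
#'
#' Good coverage is 0.93-0.97 (the nominal 0.95 plus/minus two Monte-Carlo
#' standard errors at R = 500), split into sub-bands 0.93-0.95 and
#' 0.95-0.97; fair is 0.91-0.93 (anti-conservative) or above 0.97 (overly
#' conservative); poor is below 0.91.
#'
#' @param p coverage probability (vectorized).
#' @param detail return the sub-band instead of the band?
#' @return Character vector: `"good"`/`"fair"`/`"poor"`, or with
#'   `detail = TRUE` one of `"good_0.93_0.95"`, `"good_0.95_0.97"`,
#'   `"fair_low"`, `"fair_high"`, `"poor"`.
#' @export
classify_coverage <- function(p, detail = FALSE) {
  band <- ifelse(is.na(p), NA_character_,
          ifelse(p < 0.91, "poor",
          ifelse(p < 0.93, if (detail) "fair_low" else "fair",
          ifelse(p < 0.95, if (detail) "good_0.93_0.95" else "good",
          ifelse(p <= 0.97, if (detail) "good_0.95_0.97" else "good",
                 if (detail) "fair_high" else "fair")))))
  band
}

#' Monte-Carlo standard error of a coverage probability
#'
#' `sqrt(p (1 - p) / R)` -- e.g. 0.00975 for a 95% coverage estimated from
#' 500 simulations, the rationale for the 0.93-0.97 "good" band.
#' @param p coverage probability.
#' @param R number of simulation replicates.
#' @export
coverage_se <- function(p, R) {
  stopifnot(all(p >= 0 & p <= 1), all(R >= 1))
  sqrt(p * (1 - p) / R)
}

#' Average confidence-interval length
#'
#' @param ci_low,ci_high interval endpoints across replicates (missing
#'   intervals excluded).
#' @export
average_ci_length <- function(ci_low, ci_high) {
  len <- ci_high - ci_low
  len <- len[!is.na(len)]
  if (!length(len)) return(NA_real_)
  mean(len)
}

#' Relative information of two methods from their CI lengths
#'
#' With information proportional to 1 / variance and variance proportional
#' to squared interval length, method `a` uses
#' `100 * ((len_b / len_a)^2 - 1)` percent more information than method `b`.
#' (For variances the analogous quantity is the variance ratio itself.)
#' @param len_a,len_b positive average CI lengths of methods a and b.
#' @return Percent more information used by method a relative to b.
#' @export
information_ratio <- function(len_a, len_b) {
  out <- rep(NA_real_, max(length(len_a), length(len_b)))
  ok <- is.finite(len_a) & is.finite(len_b) & len_a > 0 & len_b > 0
  out[ok] <- 100 * ((len_b[ok] / len_a[ok])^2 - 1)
  out
}

#' Weighting comparison metrics (bias / variance / MSE)
#'
#' For every indicator x domain cell of a simulation result: the truth, mean
#' weighted and unweighted replicate estimates, unweighted-vs-weighted bias
#' difference, variances (divisor R), MSEs, and the natural-log variance and
#' MSE ratios (unweighted/weighted), each ratio and the bias difference with
#' a percentile-bootstrap 95% CI over replicates and a significance flag (CI
#' excludes zero).
#'
#' @param sim a `simulation_result` from [run_simulation()].
#' @param B_m bootstrap draws for the CIs.
#' @param seed seed for the metric bootstrap.
#' @return data.frame, one row per indicator x domain.
#' @export
weighting_metrics <- function(sim, B_m = 1000L, seed = 1L) {
  est <- sim$estimates
  est <- est[est$replicate > 0L, , drop = FALSE]
  truth <- sim$truth
  seeds <- derive_seeds(seed, nrow(truth))
  out <- list()
  for (i in seq_len(nrow(truth))) {
    ind <- truth$indicator[i]
    d <- truth$domain[i]
    theta <- truth$truth[i]
    sub <- est[est$indicator == ind & est$domain == d, , drop = FALSE]
    xw <- sub$estimate[sub$estimator == "weighted"][order(
      sub$replicate[sub$estimator == "weighted"])]
    xu <- sub$estimate[sub$estimator == "unweighted"][order(
      sub$replicate[sub$estimator == "unweighted"])]
    if (!length(xw) || !length(xu)) next
    dat <- data.frame(xu = xu, xw = xw)

    b_u <- bias(xu, theta)
    b_w <- bias(xw, theta)
    v_u <- variance_of_estimates(xu)
    v_w <- variance_of_estimates(xw)
    m_u <- mse(b_u, v_u)
    m_w <- mse(b_w, v_w)

    set.seed(seeds[i])
    ci_bias <- replicate_bootstrap_ci(
      function(dd) mean(dd$xu, na.rm = TRUE) - mean(dd$xw, na.rm = TRUE),
      dat, B_m = B_m)
    ci_lvr <- replicate_bootstrap_ci(
      function(dd) {
        vu <- variance_of_estimates(dd$xu); vw <- variance_of_estimates(dd$xw)
        if (!is.na(vu) && !is.na(vw) && vu > 0 && vw > 0) log(vu / vw)
        else NA_real_
      }, dat, B_m = B_m)
    ci_lmr <- replicate_bootstrap_ci(
      function(dd) {
        mu <- mse(bias(dd$xu, theta), variance_of_estimates(dd$xu))
        mw <- mse(bias(dd$xw, theta), variance_of_estimates(dd$xw))
        if (!is.na(mu) && !is.na(mw) && mu > 0 && mw > 0) log(mu / mw)
        else NA_real_
      }, dat, B_m = B_m)

    lvr <- if (v_u > 0 && v_w > 0) log(v_u / v_w) else NA_real_
    lmr <- if (!is.na(m_u) && !is.na(m_w) && m_u > 0 && m_w > 0) {
      log(m_u / m_w)
    } else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      indicator = ind, domain = d, truth = theta,
      mean_weighted = mean(xw, na.rm = TRUE),
      mean_unweighted = mean(xu, na.rm = TRUE),
      bias_weighted = b_w, bias_unweighted = b_u,
      bias_diff = mean(xu, na.rm = TRUE) - mean(xw, na.rm = TRUE),
      bias_diff_ci_low = ci_bias[1L], bias_diff_ci_high = ci_bias[2L],
      bias_diff_sig = ci_bias[1L] > 0 | ci_bias[2L] < 0,
      var_unweighted = v_u, var_weighted = v_w,
      log_var_ratio = lvr,
      log_var_ratio_ci_low = ci_lvr[1L], log_var_ratio_ci_high = ci_lvr[2L],
      log_var_ratio_sig = ci_lvr[1L] > 0 | ci_lvr[2L] < 0,
      var_ratio = if (!is.na(lvr)) exp(lvr) else NA_real_,
      mse_unweighted = m_u, mse_weighted = m_w,
      log_mse_ratio = lmr,
      log_mse_ratio_ci_low = ci_lmr[1L], log_mse_ratio_ci_high = ci_lmr[2L],
      log_mse_ratio_sig = ci_lmr[1L] > 0 | ci_lmr[2L] < 0,
      n_replicates = length(xw),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Coverage and CI-length metrics per variance method
#'
#' For every indicator x domain x method cell: the coverage probability of
#' the nominal 95% intervals against the simulation truth, its Monte-Carlo
#' standard error, band and sub-band classification, the average interval
#' length, and the number of replicates used.
#'
#' @param sim a `simulation_result` whose config enabled variance methods.
#' @return data.frame, one row per indicator x domain x method.
#' @export
coverage_metrics <- function(sim) {
  vr <- sim$variance_results
  if (is.null(vr)) {
    stop("simulation was run without variance methods", call. = FALSE)
  }
  truth <- sim$truth
  cells <- unique(vr[, c("indicator", "domain", "method")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    ind <- cells$indicator[i]; d <- cells$domain[i]; m <- cells$method[i]
    theta <- truth$truth[truth$indicator == ind & truth$domain == d]
    if (!length(theta)) next
    sub <- vr[vr$indicator == ind & vr$domain == d & vr$method == m, ,
              drop = FALSE]
    cp <- coverage_probability(sub$ci_low, sub$ci_high, theta)
    out[[length(out) + 1L]] <- data.frame(
      indicator = ind, domain = d, method = m,
      coverage = as.numeric(cp),
      coverage_se = if (!is.na(cp) && cp > 0 && cp < 1) {
        coverage_se(as.numeric(cp), attr(cp, "n_used"))
      } else NA_real_,
      band = classify_coverage(as.numeric(cp)),
      sub_band = classify_coverage(as.numeric(cp), detail = TRUE),
      avg_ci_length = average_ci_length(sub$ci_low, sub$ci_high),
      n_used = attr(cp, "n_used"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
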