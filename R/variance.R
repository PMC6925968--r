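# The three standard-error methods compared by the package: stratified
# cluster bootstrap, single-stage design-based linearization ("svy1"), and
# recursive multi-stage linearization with finite population corrections
# ("svy3").  All operate on Taylor-linearized scores of the Hajek mean.

#' Taylor-linearization scores of the weighted mean
#'
#' Per-row scores `u_i = w_i (y_i - yhat_w) / sum(w)` where `yhat_w` is the
#' weighted mean over the estimation domain; the scores sum to zero exactly
#' and are invariant to weight rescaling.  The design variance of the Hajek
#' mean is estimated from cluster totals of these scores.
#'
#' @param table survey table (one estimation domain).
#' @param spec a [design_spec()].
#' @param indicator indicator column name.
#' @return Numeric vector aligned with the rows of `table` (`NA` where the
#'   indicator is missing).
#' @export
linearize_mean <- function(table, spec, indicator) {
  y <- table[[indicator]]
  w <- table[[spec$weight_col]]
  keep <- !is.na(y)
  u <- rep(NA_real_, length(y))
  if (!any(keep)) return(u)
  est <- sum(w[keep] * y[keep]) / sum(w[keep])
  u[keep] <- w[keep] * (y[keep] - est) / sum(w[keep])
  u
}

#' Symmetric t confidence interval for a proportion
#'
#' `estimate +/- t_{df, 1-(1-level)/2} * se`, clipped to `clip` (default the
#' unit interval; use `clip = NULL` for unbounded quantities).  With
#' nonpositive degrees of freedom, the normal quantile is used and a message
#' logged.
#'
#' @param estimate point estimate.
#' @param se standard error (>= 0).
#' @param df degrees of freedom (`Inf` gives the normal quantile).
#' @param level confidence level.
#' @param clip length-2 bounds or `NULL`.
#' @return `c(low, high)`.
#' @export
confidence_interval <- function(estimate, se, df, level = 0.95,
                                clip = c(0, 1)) {
  stopifnot(se >= 0 || is.na(se))
  q <- if (is.na(df) || df <= 0) {
    svysim_log("nonpositive design df; using normal quantile")
    stats::qnorm(1 - (1 - level) / 2)
  } else {
    stats::qt(1 - (1 - level) / 2, df)
  }
  ci <- c(estimate - q * se, estimate + q * se)
  if (!is.null(clip)) ci <- pmin(pmax(ci, clip[1L]), clip[2L])
  ci
}

# --- svy1: single-stage with-replacement stratified linearization ----------

# core on raw vectors; returns estimate/variance/df for one domain
.svy1_core <- function(y, w, psu, stratum) {
  keep <- !is.na(y)
  if (!any(keep)) {
    return(list(estimate = NA_real_, variance = NA_real_, df = NA_real_,
                n = 0L))
  }
  y <- y[keep]; w <- w[keep]; psu <- psu[keep]; stratum <- stratum[keep]
  est <- sum(w * y) / sum(w)
  u <- w * (y - est) / sum(w)

  key <- .path_key(stratum, psu)
  z <- rowsum(u, key)                      # PSU score totals, sorted by key
  first <- !duplicated(key)
  st_of_key <- stats::setNames(stratum[first], key[first])
  st <- unname(st_of_key[rownames(z)])
  z <- as.vector(z)

  n_h <- as.vector(rowsum(rep(1, length(z)), st))
  sum_h <- as.vector(rowsum(z, st))
  # guard the sum-of-squares shortcut against tiny negative round-off
  ss_h <- pmax(as.vector(rowsum(z^2, st)) - sum_h^2 / n_h, 0)
  V_h <- ifelse(n_h > 1, n_h / (n_h - 1) * ss_h, 0)
  lonely <- which(n_h == 1)
  if (length(lonely)) {
    # "adjust" convention: center singleton totals at the grand PSU mean
    gm <- mean(z)
    V_h[lonely] <- (sum_h[lonely] - gm)^2
  }
  list(estimate = est, variance = sum(V_h),
       df = length(z) - length(n_h), n = length(y))
}

.split_domains <- function(table, spec, domains) {
  dom <- as.character(table[[spec$domain_col]])
  doms <- switch(domains,
                 national = "national",
                 domains = sort(unique(dom)),
                 both = c(sort(unique(dom)), "national"))
  lapply(stats::setNames(doms, doms), function(d) {
    if (d == "national") seq_len(nrow(table)) else which(dom == d)
  })
}

#' Single-stage design-based variance (svy1)
#'
#' With-replacement stratified linearization: the facility (primary sampling
#' unit) is the only design stage, strata are the design strata, and no
#' finite population correction is applied.  Per stratum `h` with `n_h` PSU
#' score totals `z_hj`, the variance is
#' `sum_h n_h / (n_h - 1) * sum_j (z_hj - zbar_h)^2`.  Clustering of clients
#' within providers is deliberately not modelled.  Confidence intervals use
#' the t distribution with `df = #PSUs - #strata`.
#'
#' @param table client- (or facility-) level survey table.
#' @param spec a [design_spec()]; only the first stage and strata are used.
#' @param indicators indicator column name(s).
#' @param domains `"national"`, `"domains"` or `"both"`.
#' @param level confidence level.
#' @return data.frame: `indicator`, `domain`, `method`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `df`, `n`.
#' @export
svy1_variance <- function(table, spec, indicators, domains = "national",
                          level = 0.95) {
  psu <- as.character(table[[spec$stages[[1L]]$id_col]])
  stratum <- strata_key(table, spec)
  w <- table[[spec$weight_col]]
  dlist <- .split_domains(table, spec, match.arg(domains,
                                                 c("national", "domains",
                                                   "both")))
  out <- list()
  for (ind in indicators) {
    y <- table[[ind]]
    for (d in names(dlist)) {
      i <- dlist[[d]]
      co <- .svy1_core(y[i], w[i], psu[i], stratum[i])
      se <- sqrt(co$variance)
      ci <- confidence_interval(co$estimate, se, co$df, level)
      out[[length(out) + 1L]] <- data.frame(
        indicator = ind, domain = d, method = "svy1",
        estimate = co$estimate, se = se, ci_low = ci[1L], ci_high = ci[2L],
        df = co$df, n = co$n, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# --- svy3: recursive multi-stage linearization with fpc --------------------

# Recursive variance on linearized scores for a 1-3 stage design.
# At each stage, within each group (stratum at stage 1, parent unit below)
# with n sampled of N units and unit score totals T_j:
#   V = (1 - f) * n/(n-1) * sum_j (T_j - Tbar)^2 + f * sum_j V_next(j),
# f = min(n/N, 1) (clipping guards resampled tables where copies exceed N).
# Missing fpc at a stage means with-replacement there (f = 0, recursion
# stops).  Stage-1 singletons use the grand-mean "adjust" rule; deeper
# singletons contribute no between-unit term.
.svy_multistage_core <- function(y, w, id_cols, fpc_vals, stratum) {
  keep <- !is.na(y)
  if (!any(keep)) {
    return(list(estimate = NA_real_, variance = NA_real_, df = NA_real_,
                n = 0L))
  }
  y <- y[keep]; w <- w[keep]; stratum <- stratum[keep]
  id_cols <- lapply(id_cols, function(v) v[keep])
  fpc_vals <- lapply(fpc_vals, function(v) if (is.null(v)) NULL else v[keep])
  est <- sum(w * y) / sum(w)
  u <- w * (y - est) / sum(w)
  K <- length(id_cols)

  # full nesting path keys per row, per stage
  path <- vector("list", K)
  acc <- stratum
  for (k in seq_len(K)) {
    acc <- .path_key(acc, id_cols[[k]])
    path[[k]] <- acc
  }

  # walk from the deepest stage up, carrying W = per-unit inner variance
  units <- NULL; W <- NULL
  for (k in K:1) {
    first <- !duplicated(path[[k]])
    unit_key <- path[[k]][first]
    parent_key <- if (k > 1) path[[k - 1]][first] else stratum[first]
    Nk <- if (is.null(fpc_vals[[k]])) rep(Inf, sum(first)) else
      fpc_vals[[k]][first]
    ord <- order(unit_key)
    unit_key <- unit_key[ord]; parent_key <- parent_key[ord]; Nk <- Nk[ord]

    Tk <- rowsum(u, path[[k]])            # sorted by unit key
    Tk <- as.vector(Tk[unit_key, , drop = FALSE])
    Wk <- if (is.null(W)) rep(0, length(unit_key)) else {
      stopifnot(identical(names(W), unit_key))
      unname(W)
    }

    n_g <- as.vector(rowsum(rep(1, length(unit_key)), parent_key))
    sum_g <- as.vector(rowsum(Tk, parent_key))
    ss_g <- pmax(as.vector(rowsum(Tk^2, parent_key)) - sum_g^2 / n_g, 0)
    N_g <- as.vector(rowsum(Nk, parent_key)) / n_g   # constant within group
    f_g <- pmin(n_g / N_g, 1)
    f_g[!is.finite(N_g)] <- 0

    between <- ifelse(n_g > 1, (1 - f_g) * n_g / (n_g - 1) * ss_g, 0)
    if (k == 1L) {
      # lonely-PSU "adjust": center singleton stratum totals at the grand
      # mean of all PSU totals (certainty strata, N = 1, stay at zero)
      lone <- which(n_g == 1 & N_g > 1)
      if (length(lone)) {
        gm <- mean(Tk)
        between[lone] <- (1 - f_g[lone]) * (sum_g[lone] - gm)^2
      }
    }
    inner <- f_g * as.vector(rowsum(Wk, parent_key))
    Wparent <- between + inner
    group_names <- rownames(rowsum(rep(1, length(unit_key)), parent_key))

    if (k == 1L) {
      return(list(estimate = est, variance = sum(Wparent),
                  df = length(unit_key) - length(group_names),
                  n = length(y)))
    }
    W <- stats::setNames(Wparent, group_names)
    W <- W[order(names(W))]
  }
}

#' Multi-stage design-based variance with finite population corrections (svy3)
#'
#' Recursive linearization over all design stages.  Within each group with
#' `n` sampled of `N` units and unit score totals `T_j`,
#' `V = (1 - n/N) * n/(n-1) * sum_j (T_j - Tbar)^2 + (n/N) * sum_j V_next(j)`,
#' recursing into the sampled units and terminating below the last stage.
#' Fully enumerated stages (censuses, e.g. certainty hospital strata)
#' contribute no between-unit variance at that stage but propagate the
#' within-unit stages.  Every stage of `spec` must name an fpc column;
#' otherwise an error directs the caller to [svy1_variance()].
#'
#' @inheritParams svy1_variance
#' @return data.frame as in [svy1_variance()] with `method = "svy3"`.
#' @export
svy3_variance <- function(table, spec, indicators, domains = "national",
                          level = 0.95) {
  fpc_cols <- stage_fpc_cols(spec)
  for (k in seq_along(fpc_cols)) {
    if (is.null(fpc_cols[[k]]) || !(fpc_cols[[k]] %in% names(table))) {
      stop("svy3 requires an fpc column at every design stage (stage ", k,
           " has none); use svy1_variance() for a with-replacement ",
           "single-stage analysis", call. = FALSE)
    }
  }
  id_cols <- lapply(stage_id_cols(spec), function(cl) as.character(table[[cl]]))
  fpc_vals <- lapply(fpc_cols, function(cl) as.numeric(table[[cl]]))
  stratum <- strata_key(table, spec)
  w <- table[[spec$weight_col]]
  dlist <- .split_domains(table, spec, match.arg(domains,
                                                 c("national", "domains",
                                                   "both")))
  out <- list()
  for (ind in indicators) {
    y <- table[[ind]]
    for (d in names(dlist)) {
      i <- dlist[[d]]
      co <- .svy_multistage_core(
        y[i], w[i], lapply(id_cols, `[`, i), lapply(fpc_vals, `[`, i),
        stratum[i])
      se <- sqrt(co$variance)
      ci <- confidence_interval(co$estimate, se, co$df, level)
      out[[length(out) + 1L]] <- data.frame(
        indicator = ind, domain = d, method = "svy3",
        estimate = co$estimate, se = se, ci_low = ci[1L], ci_high = ci[2L],
        df = co$df, n = co$n, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# --- cluster bootstrap -----------------------------------------------------

#' Cluster bootstrap standard errors
#'
#' Resamples facilities (primary sampling units) with replacement within
#' resampling strata, matching each stratum's original facility count,
#' carries every resampled facility's clients (so clustering of clients
#' within providers and providers within facilities is respected), and
#' recomputes the weighted mean per domain.  The point estimate is the mean
#' of the `B` replicate estimates, the standard error their sample standard
#' deviation (divisor `B - 1`), and the confidence interval the empirical
#' 0.025/0.975 quantiles (type-7 interpolation).  Original design weights
#' are reused unchanged in every replicate.
#'
#' @param facilities facility-level table (one row per facility).
#' @param clients client-level table consistent with `facilities`.
#' @param spec a [design_spec()].
#' @param indicators indicator column name(s).
#' @param B number of bootstrap replicates (default 100).
#' @param seed optional seed.
#' @param resample_strata_cols columns of `facilities` defining the
#'   resampling strata; default the design strata (region x facility type).
#' @param domains `"national"`, `"domains"` or `"both"`.
#' @return data.frame: `indicator`, `domain`, `method = "bootstrap"`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `df` (replicates used), `n`.
#' @export
cluster_bootstrap <- function(facilities, clients, spec, indicators, B = 100L,
                              seed = NULL, resample_strata_cols = NULL,
                              domains = "national") {
  if (!is.null(seed)) set.seed(seed)
  domains <- match.arg(domains, c("national", "domains", "both"))
  B <- as.integer(B)
  stopifnot(B >= 2L)
  if (is.null(resample_strata_cols)) resample_strata_cols <- spec$strata_cols

  psu <- spec$stages[[1L]]$id_col
  fid <- as.character(facilities[[psu]])
  nfac <- length(fid)
  strat <- do.call(.path_key, lapply(resample_strata_cols,
                                     function(cl)
                                       as.character(facilities[[cl]])))
  dom_f <- as.character(facilities[[spec$domain_col]])
  cid <- as.character(clients[[psu]])
  orphan <- setdiff(unique(cid), fid)
  if (length(orphan)) {
    stop("client rows reference facilities absent from the facility table: ",
         orphan[1L], call. = FALSE)
  }
  w <- clients[[spec$weight_col]]

  # per-facility sufficient statistics per indicator (weighted-mean totals)
  ni <- length(indicators)
  SW <- SWY <- matrix(0, nrow = nfac, ncol = ni,
                      dimnames = list(fid, indicators))
  for (j in seq_len(ni)) {
    y <- clients[[indicators[j]]]
    keep <- !is.na(y)
    if (!any(keep)) next
    sw <- rowsum(w[keep], cid[keep])
    swy <- rowsum(w[keep] * y[keep], cid[keep])
    pos <- match(rownames(sw), fid)
    SW[pos, j] <- as.vector(sw)
    SWY[pos, j] <- as.vector(swy)
  }

  doms <- switch(domains,
                 national = "national",
                 domains = sort(unique(dom_f)),
                 both = c(sort(unique(dom_f)), "national"))
  num <- den <- array(0, dim = c(B, ni, length(doms)),
                      dimnames = list(NULL, indicators, doms))

  sidx <- split(seq_len(nfac), strat)
  for (s in names(sidx)) {
    rows <- sidx[[s]]
    n_h <- length(rows)
    draw <- matrix(rows[sample.int(n_h, n_h * B, replace = TRUE)],
                   nrow = n_h, ncol = B)
    touches <- intersect(doms, c(unique(dom_f[rows]), "national"))
    for (d in touches) {
      drows <- if (d == "national") rows else rows[dom_f[rows] == d]
      if (!length(drows)) next
      mask <- matrix(draw %in% drows, nrow = n_h)
      for (j in seq_len(ni)) {
        numadd <- .colSums(SWY[draw, j] * mask, n_h, B)
        denadd <- .colSums(SW[draw, j] * mask, n_h, B)
        num[, j, d] <- num[, j, d] + numadd
        den[, j, d] <- den[, j, d] + denadd
      }
    }
  }

  out <- list()
  for (j in seq_len(ni)) {
    for (d in doms) {
      estb <- num[, j, d] / den[, j, d]
      estb[!is.finite(estb)] <- NA_real_
      ok <- sum(!is.na(estb))
      qs <- if (ok) stats::quantile(estb, c(0.025, 0.975), na.rm = TRUE,
                                    names = FALSE, type = 7) else
        c(NA_real_, NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        indicator = indicators[j], domain = d, method = "bootstrap",
        estimate = if (ok) mean(estb, na.rm = TRUE) else NA_real_,
        se = if (ok > 1) stats::sd(estb, na.rm = TRUE) else NA_real_,
        ci_low = qs[1L], ci_high = qs[2L], df = ok, n = ok,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
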