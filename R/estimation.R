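# Point estimation: weighted (Hajek) and unweighted indicator proportions,
# by reporting domain and nationally.

#' Weighted (Hajek) mean of a binary indicator
#'
#' `sum(w * y) / sum(w)` over nonmissing `y` -- the ratio form of the
#' Horvitz-Thompson estimator used for survey proportions.  Invariant to
#' rescaling of the weights by any positive constant.  An empty input (after
#' missing removal) yields `NA`, never 0: "no data" is not "zero rate".
#'
#' @param y binary (0/1) values, possibly with missings.
#' @param w positive design weights, same length as `y`.
#' @return The weighted proportion, or `NA_real_` when no data remain.
#' @export
weighted_mean <- function(y, w) {
  stopifnot(length(y) == length(w))
  keep <- !is.na(y)
  y <- y[keep]
  w <- w[keep]
  if (!length(y)) return(NA_real_)
  if (anyNA(w) || any(w <= 0)) {
    stop("weights must be positive and nonmissing", call. = FALSE)
  }
  sum(w * y) / sum(w)
}

#' Unweighted mean of a binary indicator
#'
#' Arithmetic mean over nonmissing values; `NA` when empty.  Equals
#' [weighted_mean()] with unit weights.
#' @inheritParams weighted_mean
#' @export
unweighted_mean <- function(y) {
  y <- y[!is.na(y)]
  if (!length(y)) return(NA_real_)
  mean(y)
}

#' Weighted and unweighted estimates by domain and nationally
#'
#' One weighted and one unweighted estimate per indicator for every reporting
#' domain plus the `"national"` pseudo-domain (all rows).  Domains are
#' estimated by subsetting rows while keeping the full-sample weights
#' (standard domain estimation, no post-stratification).
#'
#' @param table survey table.
#' @param spec a [design_spec()].
#' @param indicators character vector of indicator column names.
#' @param replicate replicate index recorded in the output (0 = original).
#' @param domains `"both"` (default), `"national"` or `"domains"`.
#' @return data.frame with columns `indicator`, `domain`, `replicate`,
#'   `estimator` (`"weighted"`/`"unweighted"`), `estimate`, `n` (nonmissing
#'   rows used).
#' @export
domain_estimates <- function(table, spec, indicators, replicate = 0L,
                             domains = c("both", "national", "domains")) {
  domains <- match.arg(domains)
  absent <- setdiff(indicators, names(table))
  if (length(absent)) {
    stop("unknown indicator column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  w <- table[[spec$weight_col]]
  dom <- as.character(table[[spec$domain_col]])
  out <- vector("list", length(indicators))
  for (i in seq_along(indicators)) {
    ind <- indicators[i]
    y <- table[[ind]]
    keep <- !is.na(y)
    yk <- y[keep]
    wk <- w[keep]
    dk <- dom[keep]

    dnames <- character(0)
    west <- uest <- nn <- numeric(0)
    if (domains %in% c("both", "domains")) {
      if (length(yk)) {
        sw <- rowsum(wk, dk)
        swy <- rowsum(wk * yk, dk)
        cnt <- rowsum(rep(1, length(yk)), dk)
        dnames <- rownames(sw)
        west <- as.vector(swy) / as.vector(sw)
        uest <- as.vector(rowsum(yk, dk)) / as.vector(cnt)
        nn <- as.vector(cnt)
      }
      # domains present in the table but with no indicator data
      missing_dom <- setdiff(unique(dom), dnames)
      if (length(missing_dom)) {
        dnames <- c(dnames, missing_dom)
        west <- c(west, rep(NA_real_, length(missing_dom)))
        uest <- c(uest, rep(NA_real_, length(missing_dom)))
        nn <- c(nn, rep(0, length(missing_dom)))
      }
    }
    if (domains %in% c("both", "national")) {
      dnames <- c(dnames, "national")
      west <- c(west, if (length(yk)) sum(wk * yk) / sum(wk) else NA_real_)
      uest <- c(uest, if (length(yk)) mean(yk) else NA_real_)
      nn <- c(nn, length(yk))
    }
    out[[i]] <- data.frame(
      indicator = ind,
      domain = rep(dnames, 2L),
      replicate = as.integer(replicate),
      estimator = rep(c("weighted", "unweighted"), each = length(dnames)),
      estimate = c(west, uest),
      n = rep(nn, 2L),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
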