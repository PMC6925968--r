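# Synthetic household-survey universe (enumeration areas -> households ->
# women) and DHS-style sample drawing with probability-proportional-to-size
# selection of enumeration areas.

#' Systematic probability-proportional-to-size sampling
#'
#' Cumulative-total method: with interval `k = sum(sizes) / n` and a random
#' start `u ~ Uniform[0, k)`, the selection points are `u, u + k, ...,
#' u + (n - 1) k`; unit `i` is selected when a point falls in its cumulative
#' interval (left-open, right-closed).  The inclusion probability of unit `i`
#' is exactly `n * sizes[i] / sum(sizes)`.
#'
#' Callers must extract certainty units (those whose PPS inclusion
#' probability `n * size / sum(sizes)` reaches 1) beforehand; the function
#' refuses implicit certainty selections.
#' `n == length(sizes)` is a census and returns all units for any start.
#'
#' @param sizes positive unit sizes (e.g. households per enumeration area).
#' @param n number of units to select.
#' @param u optional fixed start in `[0, k)`; drawn uniformly when `NULL`.
#' @return Integer vector of selected indices (increasing).
#' @export
systematic_pps_sample <- function(sizes, n, u = NULL) {
  stopifnot(length(sizes) >= 1, all(sizes > 0), n >= 0, n <= length(sizes))
  n <- as.integer(n)
  if (n == 0L) return(integer(0))
  if (n == length(sizes)) return(seq_along(sizes))
  k <- sum(sizes) / n
  if (max(sizes) > k * (1 + 1e-12)) {
    stop("n * max(sizes) / sum(sizes) > 1: extract certainty units before ",
         "systematic PPS selection", call. = FALSE)
  }
  if (is.null(u)) u <- stats::runif(1, 0, k)
  stopifnot(u >= 0, u < k)
  points <- u + k * (0:(n - 1L))
  cum <- cumsum(sizes)
  idx <- findInterval(points, cum, left.open = TRUE) + 1L
  unique(idx)
}

#' Default indicator model for the household survey scenario
#'
#' Care-seeking indicators for women with a recent live birth, with
#' region-level and enumeration-area-level random effects (the latter induce
#' the household-survey clustering).
#' @return Named list of per-indicator parameters (`intercept`, `region_sd`,
#'   `ea_sd`, all logit scale).
#' @export
default_dhs_indicator_model <- function() {
  list(
    ind_anc4 = list(intercept = stats::qlogis(0.51), region_sd = 0.45,
                    ea_sd = 0.35),
    ind_iron = list(intercept = stats::qlogis(0.22), region_sd = 0.35,
                    ea_sd = 0.30))
}

#' Configuration of the synthetic household universe
#'
#' @param n_regions number of regions.
#' @param eas_per_region enumeration areas (EAs) per region in the frame.
#' @param ea_size_range `c(min, max)` households per EA (uniform integer).
#' @param n_eas_sampled_per_region EAs selected per region by systematic PPS
#'   (certainty EAs extracted first).
#' @param households_per_ea_sampled fixed number of households sampled per
#'   EA (simple random sample; EAs smaller than this are fully enumerated).
#' @param women_per_household_mean Poisson mean of women aged 15-49 per
#'   household.
#' @param eligibility_rate probability a woman is eligible (live birth in
#'   the preceding five years); all eligible women in sampled households are
#'   interviewed.
#' @param indicator_model see [default_dhs_indicator_model()].
#' @param seed integer seed.
#' @return A config list of class `household_population_config`.
#' @export
household_population_config <- function(
    n_regions = 25,
    eas_per_region = 40,
    ea_size_range = c(100, 200),
    n_eas_sampled_per_region = 8,
    households_per_ea_sampled = 22,
    women_per_household_mean = 1.2,
    eligibility_rate = 0.55,
    indicator_model = default_dhs_indicator_model(),
    seed = 1L) {
  cfg <- list(n_regions = as.integer(n_regions),
              eas_per_region = as.integer(eas_per_region),
              ea_size_range = ea_size_range,
              n_eas_sampled_per_region = as.integer(n_eas_sampled_per_region),
              households_per_ea_sampled = as.integer(households_per_ea_sampled),
              women_per_household_mean = women_per_household_mean,
              eligibility_rate = eligibility_rate,
              indicator_model = indicator_model,
              seed = as.integer(seed))
  stopifnot(cfg$n_regions >= 1, cfg$eas_per_region >= 1,
            length(cfg$ea_size_range) == 2, all(cfg$ea_size_range >= 1),
            cfg$n_eas_sampled_per_region >= 1,
            cfg$n_eas_sampled_per_region <= cfg$eas_per_region,
            cfg$households_per_ea_sampled >= 1,
            cfg$women_per_household_mean > 0,
            cfg$eligibility_rate > 0, cfg$eligibility_rate <= 1)
  class(cfg) <- "household_population_config"
  cfg
}

#' Generate the finite household population
#'
#' Creates every enumeration area, household and woman of the synthetic
#' universe.  Indicator values are generated for eligible women (recent live
#' birth); truth per domain is the plain mean over all eligible women.
#'
#' @param config a [household_population_config()].
#' @return A `finite_population` list with `eas`, `households`, `women`
#'   (eligible women only), `truth` and the config.
#' @export
generate_household_population <- function(
    config = household_population_config()) {
  stopifnot(inherits(config, "household_population_config"))
  set.seed(config$seed)
  regions <- sprintf("R%02d", seq_len(config$n_regions))

  eas <- data.frame(
    region = rep(regions, each = config$eas_per_region),
    stringsAsFactors = FALSE)
  eas$ea_id <- paste0(eas$region, "_EA",
                      sprintf("%03d", stats::ave(seq_len(nrow(eas)),
                                                 eas$region, FUN = seq_along)))
  eas$n_households <- config$ea_size_range[1] +
    floor(stats::runif(nrow(eas)) *
            (config$ea_size_range[2] - config$ea_size_range[1] + 1))

  households <- data.frame(
    ea_id = rep(eas$ea_id, eas$n_households),
    region = rep(eas$region, eas$n_households),
    stringsAsFactors = FALSE)
  households$hh_id <- paste0(
    households$ea_id, "_H",
    stats::ave(seq_len(nrow(households)), households$ea_id, FUN = seq_along))
  n_women <- stats::rpois(nrow(households), config$women_per_household_mean)

  women <- data.frame(
    hh_id = rep(households$hh_id, n_women),
    ea_id = rep(households$ea_id, n_women),
    region = rep(households$region, n_women),
    stringsAsFactors = FALSE)
  women$woman_id <- paste0(
    women$hh_id, "_W",
    stats::ave(seq_len(nrow(women)), women$hh_id, FUN = seq_along))
  eligible <- stats::runif(nrow(women)) < config$eligibility_rate
  women <- women[eligible, , drop = FALSE]
  rownames(women) <- NULL

  model <- config$indicator_model
  for (ind in names(model)) {
    m <- model[[ind]]
    reg_eff <- stats::setNames(stats::rnorm(length(regions), 0, m$region_sd),
                               regions)
    ea_eff <- stats::setNames(stats::rnorm(nrow(eas), 0, m$ea_sd), eas$ea_id)
    p <- stats::plogis(m$intercept + reg_eff[women$region] +
                         ea_eff[women$ea_id])
    women[[ind]] <- as.double(stats::rbinom(nrow(women), 1L, p))
  }

  truth <- .population_truth(women, "region", names(model))
  structure(list(eas = eas, households = households, women = women,
                 truth = truth, config = config),
            class = "finite_population")
}

#' The standard design specification for the household (DHS-style) sample
#'
#' Enumeration area within region, household within EA, woman within
#' household (all eligible women taken: a census stage).
#' @return A [design_spec()].
#' @export
dhs_design_spec <- function() {
  design_spec(
    stages = list(stage_spec("ea_id", "fpc_ea"),
                  stage_spec("hh_id", "fpc_household"),
                  stage_spec("woman_id", "fpc_woman")),
    strata_cols = "region",
    domain_col = "region",
    weight_col = "weight",
    notes = "EA (PPS) -> household (SRS) -> eligible women (census)")
}

#' Draw a household survey sample with exact design weights
#'
#' Per region: certainty EAs (PPS inclusion probability >= 1) are extracted
#' first, the remainder selected by [systematic_pps_sample()] on household
#' counts; a fixed number of households is then drawn by simple random
#' sampling within each selected EA (all, if the EA is smaller); all eligible
#' women in sampled households are interviewed.  The woman weight is
#' `1 / (pi_EA * m / M)`.
#'
#' @param pop a `finite_population` from [generate_household_population()].
#' @param seed optional draw seed.
#' @return List with `women` (woman-level survey table), `spec`
#'   ([dhs_design_spec()]) and `indicators`.
#' @export
draw_dhs_sample <- function(pop, seed = NULL) {
  stopifnot(inherits(pop, "finite_population"), !is.null(pop$eas))
  if (!is.null(seed)) set.seed(seed)
  cfg <- pop$config
  eas <- pop$eas
  hh_by_ea <- split(seq_len(nrow(pop$households)), pop$households$ea_id)
  wom_by_hh <- split(seq_len(nrow(pop$women)), pop$women$hh_id)

  rows_list <- list()
  for (r in unique(eas$region)) {
    idx <- which(eas$region == r)
    sizes <- eas$n_households[idx]
    n <- min(cfg$n_eas_sampled_per_region, length(idx))
    # extract certainty EAs (inclusion probability >= 1 under PPS)
    cert <- integer(0)
    rem <- seq_along(idx)
    repeat {
      pi_rem <- (n - length(cert)) * sizes[rem] / sum(sizes[rem])
      hit <- rem[pi_rem >= 1]
      if (!length(hit) || length(cert) + length(rem) <= n) break
      cert <- c(cert, hit)
      rem <- setdiff(rem, hit)
      if (length(cert) >= n) break
    }
    n_rem <- min(n - length(cert), length(rem))
    sel_rem <- if (n_rem > 0) {
      rem[systematic_pps_sample(sizes[rem], n_rem)]
    } else integer(0)
    pi_ea <- c(rep(1, length(cert)),
               n_rem * sizes[sel_rem] / sum(sizes[rem]))
    sel <- c(cert, sel_rem)

    for (j in seq_along(sel)) {
      ea_row <- idx[sel[j]]
      M <- eas$n_households[ea_row]
      m <- min(cfg$households_per_ea_sampled, M)
      hrows <- hh_by_ea[[eas$ea_id[ea_row]]]
      hsel <- if (m == M) hrows else hrows[sample.int(M, m)]
      wrows <- unlist(wom_by_hh[pop$households$hh_id[hsel]],
                      use.names = FALSE)
      if (!length(wrows)) next
      wt <- pop$women[wrows, , drop = FALSE]
      wt$weight <- 1 / (pi_ea[j] * (m / M))
      wt$fpc_ea <- length(idx)
      wt$fpc_household <- M
      n_in_hh <- vapply(wom_by_hh[wt$hh_id], length, integer(1))
      wt$fpc_woman <- as.numeric(n_in_hh)
      rows_list[[length(rows_list) + 1L]] <- wt
    }
  }

  women <- do.call(rbind, rows_list)
  rownames(women) <- NULL
  spec <- dhs_design_spec()
  validate_survey_table(women, spec)
  list(women = women, spec = spec, indicators = names(cfg$indicator_model))
}
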