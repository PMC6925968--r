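# Synthetic health-facility universe and SPA-style sample drawing.
#
# The generator emulates a national facility census stratified by region x
# facility type, with a small certainty stratum of hospitals (all sampled),
# providers nested in facilities and an expected daily roster of antenatal
# care (ANC) clients per provider.  Samples are drawn with exact inverse
# inclusion probabilities so Horvitz-Thompson identities hold by construction.

#' Default indicator model for the facility survey scenario
#'
#' Three binary indicators on the logit scale.  `ind_hb_test` is a
#' facility-level attribute (availability of haemoglobin testing) heavily
#' concentrated in hospitals, which makes the design informative: hospitals
#' are certainty units with small weights, so unweighted client-level
#' estimates overstate availability.  `ind_wait_ok` and `ind_weighed` are
#' client-level indicators with moderate facility-type effects and
#' facility-level random effects inducing intra-cluster correlation.
#'
#' @return Named list of per-indicator model parameters: `level`
#'   ("facility" or "client"), `intercept` (logit scale), `type_effects`
#'   (named, logit), `region_sd`, `facility_sd` (logit-scale SDs).
#' @export
default_spa_indicator_model <- function() {
  list(
    ind_hb_test = list(
      level = "facility", intercept = stats::qlogis(0.12),
      type_effects = c(hospital = 3.2, health_center = 1.2,
                       dispensary = 0, clinic = 0.8),
      region_sd = 0.3, facility_sd = 0.6),
    ind_wait_ok = list(
      level = "client", intercept = stats::qlogis(0.70),
      type_effects = c(hospital = -0.4, health_center = -0.1,
                       dispensary = 0, clinic = 0),
      region_sd = 0.25, facility_sd = 0.5),
    ind_weighed = list(
      level = "client", intercept = stats::qlogis(0.80),
      type_effects = c(hospital = 0.8, health_center = 0.3,
                       dispensary = 0, clinic = 0.2),
      region_sd = 0.3, facility_sd = 0.7))
}

#' Configuration of the synthetic facility universe
#'
#' Defaults describe a scaled-down national facility census: per region, a
#' handful of hospitals (all of which are sampled -- a certainty stratum,
#' mirroring hospital oversampling), many dispensaries sampled at a modest
#' fraction, and health centers / clinics in between.  Client observation
#' follows the field protocol: in facilities with fewer than
#' `provider_sample_threshold` providers all providers are taken, otherwise
#' `provider_sample_threshold` are sampled; at most `max_clients_per_provider`
#' clients are observed per provider and at most `max_clients_per_facility`
#' per facility.
#'
#' @param n_regions number of regions (default 25, the mainland region count
#'   the scenario emulates).
#' @param facility_types facility-type labels.
#' @param facilities_per_stratum named integer N_h: facilities of each type
#'   per region.
#' @param sample_per_stratum named integer n_h: facilities sampled per
#'   region x type stratum (capped at N_h; equality means certainty).
#' @param providers_per_facility named list of `c(min, max)` ranges for the
#'   number of ANC providers by facility type.
#' @param clients_per_provider_mean expected ANC clients on a provider's
#'   daily roster (Poisson).
#' @param provider_sample_threshold the "fewer than eight providers: take
#'   all" rule (default 8).
#' @param max_clients_per_provider,max_clients_per_facility observation caps.
#' @param facility_nonresponse_rate optional facility nonresponse
#'   probability; weights are adjusted at the stratum level
#'   (sampled / responding).
#' @param indicator_model see [default_spa_indicator_model()].
#' @param seed integer seed fully determining the generated universe.
#' @return A validated config list of class `facility_population_config`.
#' @export
facility_population_config <- function(
    n_regions = 25,
    facility_types = c("hospital", "health_center", "dispensary", "clinic"),
    facilities_per_stratum = c(hospital = 3, health_center = 30,
                               dispensary = 100, clinic = 10),
    sample_per_stratum = c(hospital = 3, health_center = 6,
                           dispensary = 10, clinic = 3),
    providers_per_facility = list(hospital = c(3, 8), health_center = c(2, 5),
                                  dispensary = c(1, 3), clinic = c(1, 3)),
    clients_per_provider_mean = 4,
    provider_sample_threshold = 8,
    max_clients_per_provider = 5,
    max_clients_per_facility = 15,
    facility_nonresponse_rate = 0,
    indicator_model = default_spa_indicator_model(),
    seed = 1L) {
  cfg <- list(n_regions = as.integer(n_regions),
              facility_types = facility_types,
              facilities_per_stratum = facilities_per_stratum,
              sample_per_stratum = sample_per_stratum,
              providers_per_facility = providers_per_facility,
              clients_per_provider_mean = clients_per_provider_mean,
              provider_sample_threshold = provider_sample_threshold,
              max_clients_per_provider = max_clients_per_provider,
              max_clients_per_facility = max_clients_per_facility,
              facility_nonresponse_rate = facility_nonresponse_rate,
              indicator_model = indicator_model,
              seed = as.integer(seed))
  stopifnot(cfg$n_regions >= 1,
            length(cfg$facility_types) >= 1,
            all(cfg$facility_types %in% names(cfg$facilities_per_stratum)),
            all(cfg$facility_types %in% names(cfg$sample_per_stratum)),
            all(cfg$facility_types %in% names(cfg$providers_per_facility)),
            cfg$clients_per_provider_mean > 0,
            cfg$max_clients_per_provider >= 1,
            cfg$max_clients_per_facility >= 1,
            cfg$facility_nonresponse_rate >= 0,
            cfg$facility_nonresponse_rate < 1)
  if (any(cfg$sample_per_stratum[cfg$facility_types] >
          cfg$facilities_per_stratum[cfg$facility_types])) {
    stop("sample_per_stratum may not exceed facilities_per_stratum",
         call. = FALSE)
  }
  class(cfg) <- "facility_population_config"
  cfg
}

.linpred_prob <- function(model, type, region_eff, fac_eff) {
  stats::plogis(model$intercept + unname(model$type_effects[type]) +
                  region_eff + fac_eff)
}

#' Generate the finite facility population
#'
#' Creates every facility, provider and rostered ANC client of the synthetic
#' universe, with true indicator values for all population clients.  Truth
#' (per region and national) is the plain mean over all population clients,
#' the estimand that design-weighted estimation targets.
#'
#' @param config a [facility_population_config()].
#' @return A `finite_population` list: `facilities`, `providers`, `clients`
#'   data.frames, a `truth` table (indicator x domain), and the config.
#' @export
generate_facility_population <- function(config = facility_population_config()) {
  stopifnot(inherits(config, "facility_population_config"))
  set.seed(config$seed)
  regions <- sprintf("R%02d", seq_len(config$n_regions))
  types <- config$facility_types

  grid <- expand.grid(region = regions, facility_type = types,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$region, grid$facility_type), , drop = FALSE]
  nfac <- config$facilities_per_stratum[grid$facility_type]
  facilities <- data.frame(
    region = rep(grid$region, nfac),
    facility_type = rep(grid$facility_type, nfac),
    stringsAsFactors = FALSE)
  facilities$facility_id <- paste0(
    facilities$region, "_", abbreviate(facilities$facility_type, 4), "_",
    sprintf("%04d", stats::ave(seq_len(nrow(facilities)),
                               .path_key(facilities$region,
                                         facilities$facility_type),
                               FUN = seq_along)))
  facilities$stratum <- .path_key(facilities$region, facilities$facility_type)

  prange <- config$providers_per_facility[facilities$facility_type]
  pmin_ <- vapply(prange, `[`, numeric(1), 1L)
  pmax_ <- vapply(prange, `[`, numeric(1), 2L)
  facilities$n_providers <- pmin_ +
    floor(stats::runif(nrow(facilities)) * (pmax_ - pmin_ + 1))

  model <- config$indicator_model
  inds <- names(model)
  region_eff <- lapply(model, function(m)
    stats::setNames(stats::rnorm(length(regions), 0, m$region_sd), regions))
  fac_eff <- lapply(model, function(m)
    stats::rnorm(nrow(facilities), 0, m$facility_sd))

  # facility-level indicator draws (one Bernoulli per facility)
  for (ind in inds) {
    m <- model[[ind]]
    if (identical(m$level, "facility")) {
      p <- .linpred_prob(m, facilities$facility_type,
                         region_eff[[ind]][facilities$region],
                         fac_eff[[ind]])
      facilities[[ind]] <- stats::rbinom(nrow(facilities), 1L, p)
    }
  }

  providers <- data.frame(
    facility_id = rep(facilities$facility_id, facilities$n_providers),
    region = rep(facilities$region, facilities$n_providers),
    facility_type = rep(facilities$facility_type, facilities$n_providers),
    stratum = rep(facilities$stratum, facilities$n_providers),
    stringsAsFactors = FALSE)
  providers$provider_id <- paste0(
    providers$facility_id, "_P",
    stats::ave(seq_len(nrow(providers)), providers$facility_id,
               FUN = seq_along))
  providers$roster <- stats::rpois(nrow(providers),
                                   config$clients_per_provider_mean)
  prov_fac_row <- match(providers$facility_id, facilities$facility_id)

  clients <- data.frame(
    provider_id = rep(providers$provider_id, providers$roster),
    facility_id = rep(providers$facility_id, providers$roster),
    region = rep(providers$region, providers$roster),
    facility_type = rep(providers$facility_type, providers$roster),
    stratum = rep(providers$stratum, providers$roster),
    stringsAsFactors = FALSE)
  clients$client_id <- paste0(
    clients$provider_id, "_C",
    stats::ave(seq_len(nrow(clients)), clients$provider_id, FUN = seq_along))
  cl_fac_row <- match(clients$facility_id, facilities$facility_id)

  for (ind in inds) {
    m <- model[[ind]]
    if (identical(m$level, "facility")) {
      clients[[ind]] <- as.double(facilities[[ind]][cl_fac_row])
    } else {
      p <- .linpred_prob(m, clients$facility_type,
                         region_eff[[ind]][clients$region],
                         fac_eff[[ind]][cl_fac_row])
      clients[[ind]] <- as.double(stats::rbinom(nrow(clients), 1L, p))
    }
  }

  truth <- .population_truth(clients, "region", inds)
  structure(list(facilities = facilities, providers = providers,
                 clients = clients, truth = truth, config = config),
            class = "finite_population")
}

.population_truth <- function(units, domain_col, inds) {
  dom <- as.character(units[[domain_col]])
  out <- list()
  for (ind in inds) {
    y <- units[[ind]]
    keep <- !is.na(y)
    by_dom <- rowsum(y[keep], dom[keep]) /
      as.vector(rowsum(rep(1, sum(keep)), dom[keep]))
    out[[ind]] <- data.frame(
      indicator = ind,
      domain = c(rownames(by_dom), "national"),
      truth = c(as.vector(by_dom), mean(y[keep])),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' The standard design specification for the facility (SPA-style) sample
#'
#' Three stages -- facility within region x type stratum, provider within
#' facility, client within provider -- each with its population count column,
#' client-level design weights, and region as the reporting domain.
#' @return A [design_spec()].
#' @export
spa_design_spec <- function() {
  design_spec(
    stages = list(stage_spec("facility_id", "fpc_facility"),
                  stage_spec("provider_id", "fpc_provider"),
                  stage_spec("client_id", "fpc_client")),
    strata_cols = c("region", "facility_type"),
    domain_col = "region",
    weight_col = "weight",
    notes = "facility -> provider -> client design with certainty hospitals")
}

# deterministic reallocation of per-provider observation quotas under the
# facility cap: repeatedly decrement the (first) largest quota
.apply_facility_cap <- function(quota, cap) {
  while (sum(quota) > cap) {
    i <- which.max(quota)
    quota[i] <- quota[i] - 1L
  }
  quota
}

#' Draw a facility survey sample with exact design weights
#'
#' Per region x type stratum, a simple random sample of `n_h` facilities from
#' `N_h` (certainty strata take all, weight 1).  Within a sampled facility,
#' all providers are taken when fewer than the threshold, otherwise a simple
#' random sample of the threshold size.  Within a sampled provider, clients
#' are a simple random subset of the roster obeying the per-provider and
#' per-facility caps (cap reallocation is deterministic given rosters, so
#' inclusion probabilities remain exact).  Weights are inverse inclusion
#' probabilities composed across stages; `fpc_*` columns carry the stage
#' population counts (N_h, providers in facility, provider roster).
#'
#' @param pop a `finite_population` from [generate_facility_population()].
#' @param seed optional seed for the draw (independent of the population
#'   seed).
#' @return List with `facilities` (facility-level table: one row per sampled
#'   facility, facility weight) and `clients` (client-level table with
#'   composed weights), both validated against [spa_design_spec()].
#' @export
draw_spa_sample <- function(pop, seed = NULL) {
  stopifnot(inherits(pop, "finite_population"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- pop$config
  fac <- pop$facilities
  inds <- names(cfg$indicator_model)

  sel_rows <- integer(0)
  wfac <- numeric(0)
  Nh_of <- numeric(0)
  for (s in unique(fac$stratum)) {
    rows <- which(fac$stratum == s)
    Nh <- length(rows)
    type <- fac$facility_type[rows[1L]]
    nh <- min(cfg$sample_per_stratum[[type]], Nh)
    if (Nh == 0L) {
      svysim_log("stratum ", s, " has no facilities; skipped")
      next
    }
    take <- if (nh == Nh) rows else rows[sample.int(Nh, nh)]
    if (cfg$facility_nonresponse_rate > 0 && nh < Nh) {
      resp <- stats::runif(length(take)) >= cfg$facility_nonresponse_rate
      if (!any(resp)) resp[sample.int(length(take), 1L)] <- TRUE
      w <- (Nh / nh) * (nh / sum(resp))
      take <- take[resp]
    } else {
      w <- Nh / nh
    }
    sel_rows <- c(sel_rows, take)
    wfac <- c(wfac, rep(w, length(take)))
    Nh_of <- c(Nh_of, rep(Nh, length(take)))
  }

  fac_s <- fac[sel_rows, , drop = FALSE]
  fac_s$weight <- wfac
  fac_s$fpc_facility <- Nh_of
  rownames(fac_s) <- NULL

  # provider stage
  prov <- pop$providers
  prov_by_fac <- split(seq_len(nrow(prov)), prov$facility_id)
  cl <- pop$clients
  cl_by_prov <- split(seq_len(nrow(cl)), cl$provider_id)

  client_rows <- integer(0)
  client_w <- numeric(0)
  client_fpc_prov <- numeric(0)
  client_fpc_cl <- numeric(0)
  client_wfac <- numeric(0)
  client_Nh <- numeric(0)

  for (i in seq_len(nrow(fac_s))) {
    fid <- fac_s$facility_id[i]
    prows <- prov_by_fac[[fid]]
    P <- length(prows)
    if (P == 0L) next
    if (P < cfg$provider_sample_threshold) {
      psel <- prows
    } else {
      psel <- prows[sample.int(P, cfg$provider_sample_threshold)]
    }
    p <- length(psel)
    w_prov <- fac_s$weight[i] * (P / p)

    rosters <- prov$roster[psel]
    quota <- pmin(cfg$max_clients_per_provider, rosters)
    quota <- .apply_facility_cap(quota, cfg$max_clients_per_facility)
    for (j in seq_along(psel)) {
      R <- rosters[j]
      cq <- quota[j]
      if (cq == 0L) next
      crows <- cl_by_prov[[prov$provider_id[psel[j]]]]
      csel <- if (cq == R) crows else crows[sample.int(R, cq)]
      client_rows <- c(client_rows, csel)
      client_w <- c(client_w, rep(w_prov * (R / cq), cq))
      client_fpc_prov <- c(client_fpc_prov, rep(P, cq))
      client_fpc_cl <- c(client_fpc_cl, rep(R, cq))
      client_wfac <- c(client_wfac, rep(fac_s$weight[i], cq))
      client_Nh <- c(client_Nh, rep(fac_s$fpc_facility[i], cq))
    }
  }

  cl_s <- cl[client_rows, , drop = FALSE]
  cl_s$weight <- client_w
  cl_s$weight_facility <- client_wfac
  cl_s$fpc_facility <- client_Nh
  cl_s$fpc_provider <- client_fpc_prov
  cl_s$fpc_client <- client_fpc_cl
  rownames(cl_s) <- NULL

  spec <- spa_design_spec()
  validate_survey_table(cl_s, spec)
  list(facilities = fac_s, clients = cl_s, spec = spec,
       indicators = inds)
}
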