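# Stratified with-replacement resampling harness: treat an original survey
# as the population truth, draw R resamples preserving per-stratum counts,
# and evaluate estimators and variance methods on each.

#' Simulation configuration
#'
#' @param R number of simulated surveys (default 500, which keeps the
#'   Monte-Carlo standard error of a 95% coverage probability below 0.01).
#' @param mode `"cluster_resample"` (facility-survey style: resample
#'   facilities with replacement and carry their clients) or
#'   `"unit_resample"` (household-survey style: resample women directly,
#'   ignoring their clustering).
#' @param resample_strata_col column defining the resampling strata (default
#'   `"region"`: each simulated survey has the same number of units per
#'   region as the original).
#' @param B bootstrap replicates within each simulated survey.
#' @param variance_methods subset of `c("bootstrap", "svy1", "svy3")` to run
#'   on the weighted estimates of each simulated survey (empty = none).
#' @param variance_domains domains at which variance methods run
#'   (`"national"`, `"domains"`, `"both"`).
#' @param estimate_domains domains for point estimation.
#' @param bootstrap_strata_cols resampling strata for the within-survey
#'   cluster bootstrap.  The default (`NULL`) uses `resample_strata_col`,
#'   so the bootstrap resamples facilities exactly the way the simulated
#'   surveys themselves are generated (the published procedure drew both
#'   with the same per-region machinery); pass the design strata columns to
#'   stratify the bootstrap more finely instead.
#' @param seed master seed; per-replicate substreams are derived from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(R = 500L,
                              mode = c("cluster_resample", "unit_resample"),
                              resample_strata_col = "region",
                              B = 100L,
                              variance_methods = character(0),
                              variance_domains = "national",
                              estimate_domains = "both",
                              bootstrap_strata_cols = NULL,
                              seed = 1L) {
  cfg <- list(R = as.integer(R), mode = match.arg(mode),
              resample_strata_col = resample_strata_col,
              B = as.integer(B),
              variance_methods = variance_methods,
              variance_domains = variance_domains,
              estimate_domains = estimate_domains,
              bootstrap_strata_cols = bootstrap_strata_cols,
              seed = as.integer(seed))
  stopifnot(cfg$R >= 2L,
            all(cfg$variance_methods %in% c("bootstrap", "svy1", "svy3")))
  if ("bootstrap" %in% cfg$variance_methods) stopifnot(cfg$B >= 2L)
  class(cfg) <- "simulation_config"
  cfg
}

#' Draw one stratified with-replacement resample of a survey
#'
#' Per resampling stratum, draws with replacement exactly the original
#' number of units: women in `unit_resample` mode, facilities in
#' `cluster_resample` mode (whose clients are then attached via
#' [merge_clients_to_facilities()], each facility copy becoming a distinct
#' cluster).  All original weight columns are carried unchanged.
#'
#' @param table the original ultimate-unit survey table.
#' @param spec a [design_spec()].
#' @param config a [simulation_config()].
#' @param facilities facility-level table (required in cluster mode).
#' @param seed optional seed.
#' @return The resampled ultimate-unit table.  In cluster mode the resampled
#'   facility table is attached as attribute `"facilities"`.
#' @export
resample_once <- function(table, spec, config, facilities = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scol <- config$resample_strata_col
  if (config$mode == "unit_resample") {
    strat <- as.character(table[[scol]])
    idx <- unlist(lapply(split(seq_len(nrow(table)), strat), function(i)
      i[sample.int(length(i), length(i), replace = TRUE)]),
      use.names = FALSE)
    out <- table[idx, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  if (is.null(facilities)) {
    stop("cluster_resample mode requires the facility-level table",
         call. = FALSE)
  }
  psu <- spec$stages[[1L]]$id_col
  strat <- as.character(facilities[[scol]])
  idx <- unlist(lapply(split(seq_len(nrow(facilities)), strat), function(i)
    i[sample.int(length(i), length(i), replace = TRUE)]),
    use.names = FALSE)
  fac_rs <- facilities[idx, , drop = FALSE]

  # keep only clients of resampled facilities, then merge with copy suffixes
  keep <- as.character(table[[psu]]) %in% unique(as.character(fac_rs[[psu]]))
  out <- merge_clients_to_facilities(fac_rs, table[keep, , drop = FALSE],
                                     spec)
  fid <- as.character(fac_rs[[psu]])
  fac_rs[[psu]] <- paste0(fid, "#", .facility_copies(fid))
  rownames(fac_rs) <- NULL
  attr(out, "facilities") <- fac_rs
  out
}

#' Run the resampling simulation
#'
#' Treats the original survey as the population: the truth table is the
#' weighted domain estimate on the original; for each of `R` replicates a
#' stratified with-replacement resample is drawn, weighted and unweighted
#' estimates computed, and each enabled variance method applied to the
#' weighted estimate.  Replicate random-number substreams are derived
#' deterministically from the master seed, so replicate order is immaterial.
#' Per-replicate failures are recorded as missing, never abort the run.
#'
#' @param table original ultimate-unit survey table.
#' @param spec a [design_spec()].
#' @param indicators indicator columns to evaluate.
#' @param config a [simulation_config()].
#' @param facilities facility-level table (cluster mode).
#' @return A `simulation_result` list: `truth` (weighted estimates on the
#'   original), `estimates` (replicate x indicator x domain x estimator),
#'   `variance_results` (replicate x indicator x domain x method, when any
#'   method is enabled), `config`, and `n_failed`.
#' @export
run_simulation <- function(table, spec, indicators, config,
                           facilities = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  truth_all <- domain_estimates(table, spec, indicators, replicate = 0L,
                                domains = "both")
  truth <- truth_all[truth_all$estimator == "weighted",
                     c("indicator", "domain", "estimate")]
  names(truth)[3L] <- "truth"
  rownames(truth) <- NULL

  R <- config$R
  seeds <- matrix(derive_seeds(config$seed, 2L * R), nrow = 2L)
  est_list <- vector("list", R)
  var_list <- vector("list", R)
  n_failed <- 0L
  for (r in seq_len(R)) {
    ok <- tryCatch({
      rs <- resample_once(table, spec, config, facilities = facilities,
                          seed = seeds[1L, r])
      est_list[[r]] <- domain_estimates(rs, spec, indicators, replicate = r,
                                        domains = config$estimate_domains)
      if (length(config$variance_methods)) {
        vparts <- list()
        if ("svy1" %in% config$variance_methods) {
          vparts$svy1 <- svy1_variance(rs, spec, indicators,
                                       domains = config$variance_domains)
        }
        if ("svy3" %in% config$variance_methods) {
          vparts$svy3 <- svy3_variance(rs, spec, indicators,
                                       domains = config$variance_domains)
        }
        if ("bootstrap" %in% config$variance_methods) {
          vparts$bootstrap <- cluster_bootstrap(
            attr(rs, "facilities"), rs, spec, indicators, B = config$B,
            seed = seeds[2L, r],
            resample_strata_cols = config$bootstrap_strata_cols %||%
              config$resample_strata_col,
            domains = config$variance_domains)
        }
        vr <- do.call(rbind, vparts)
        vr$replicate <- r
        var_list[[r]] <- vr
      }
      TRUE
    }, error = function(e) {
      svysim_log("replicate ", r, " failed: ", conditionMessage(e))
      FALSE
    })
    if (!ok) n_failed <- n_failed + 1L
  }
  if (n_failed > 0L) {
    svysim_log(n_failed, " of ", R, " replicates failed and are missing")
  }

  estimates <- do.call(rbind, est_list)
  rownames(estimates) <- NULL
  variance_results <- if (length(var_list) && any(lengths(var_list) > 0)) {
    vr <- do.call(rbind, var_list)
    rownames(vr) <- NULL
    vr
  } else NULL
  structure(list(truth = truth, estimates = estimates,
                 variance_results = variance_results, config = config,
                 n_failed = n_failed),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>", x$config$R, "replicates,",
      length(unique(x$truth$indicator)), "indicator(s),",
      length(unique(x$truth$domain)) - 1L, "domain(s) + national\n")
  if (!is.null(x$variance_results)) {
    cat("  variance methods:",
        paste(unique(x$variance_results$method), collapse = ", "), "\n")
  }
  if (x$n_failed > 0L) cat("  failed replicates:", x$n_failed, "\n")
  invisible(x)
}
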