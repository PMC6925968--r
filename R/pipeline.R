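# End-to-end orchestration: generate a synthetic universe, draw the survey,
# run the resampling simulation, compute metrics and render report tables,
# all from one config and master seed.

#' Pipeline configuration
#'
#' Bundles the population, simulation and reporting settings of a full run.
#' The default is a demonstration scale (2 regions, R = 50, B = 30) that
#' completes in well under two minutes on one CPU; the study scale the
#' package emulates (25 regions, R = 500, B = 100) is obtained with
#' `pipeline_config(n_regions = 25, R = 500, B = 100)` and runs for
#' considerably longer.
#'
#' @param n_regions regions in the synthetic universe.
#' @param R simulated surveys.
#' @param B bootstrap replicates within each simulated survey.
#' @param variance_methods methods to compare (default all three).
#' @param variance_domains domains for the variance comparison.
#' @param resample_strata_col stratification of the simulation resampling.
#' @param B_m metric-bootstrap draws.
#' @param facility_config_args named list of overrides passed to
#'   [facility_population_config()] (besides `n_regions` and `seed`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_regions = 2L, R = 50L, B = 30L,
                            variance_methods = c("bootstrap", "svy1", "svy3"),
                            variance_domains = "national",
                            resample_strata_col = "region",
                            B_m = 1000L,
                            facility_config_args = list()) {
  structure(list(n_regions = as.integer(n_regions), R = as.integer(R),
                 B = as.integer(B), variance_methods = variance_methods,
                 variance_domains = variance_domains,
                 resample_strata_col = resample_strata_col,
                 B_m = as.integer(B_m),
                 facility_config_args = facility_config_args),
            class = "pipeline_config")
}

#' Run the full generate / draw / simulate / metrics / report pipeline
#'
#' A single master seed fans out into named substreams (population, sample
#' draw, simulation, metric bootstrap), so reruns with the same seed produce
#' byte-identical CSV outputs.  All stage outputs plus a JSON run manifest
#' (config echo, derived seeds, package version, file digests) are written
#' to `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @param seed master seed.
#' @param stages subset of `c("generate", "simulate", "metrics", "report")`
#'   to run; later stages read the earlier stages' CSV outputs from
#'   `out_dir`, allowing partial re-runs.
#' @return `out_dir`, invisibly; side effect: files written.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1L,
                         stages = c("generate", "simulate", "metrics",
                                    "report")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(seed, 4L)
  names(seeds) <- c("population", "draw", "simulation", "metrics")
  spec <- spa_design_spec()
  pth <- function(f) file.path(out_dir, f)

  if ("generate" %in% stages) {
    pop_cfg <- do.call(facility_population_config,
                       c(list(n_regions = config$n_regions,
                              seed = seeds[["population"]]),
                         config$facility_config_args))
    pop <- generate_facility_population(pop_cfg)
    smp <- draw_spa_sample(pop, seed = seeds[["draw"]])
    write_survey_csv(smp$clients, pth("clients.csv"))
    write_survey_csv(smp$facilities, pth("facilities.csv"))
    write_design_spec(spec, pth("design.yaml"))
    utils::write.csv(pop$truth, pth("population_truth.csv"),
                     row.names = FALSE)
  }

  if ("simulate" %in% stages) {
    clients <- read_survey_csv(pth("clients.csv"), spec)
    fac_spec_cols <- c(spec$stages[[1L]]$id_col, spec$strata_cols,
                       spec$domain_col, spec$weight_col)
    facilities <- utils::read.csv(pth("facilities.csv"),
                                  stringsAsFactors = FALSE)
    indicators <- grep("^ind_", names(clients), value = TRUE)
    sim_cfg <- simulation_config(
      R = config$R, mode = "cluster_resample",
      resample_strata_col = config$resample_strata_col,
      B = config$B, variance_methods = config$variance_methods,
      variance_domains = config$variance_domains,
      seed = seeds[["simulation"]])
    sim <- run_simulation(clients, spec, indicators, sim_cfg,
                          facilities = facilities)
    utils::write.csv(sim$truth, pth("truth.csv"), row.names = FALSE)
    utils::write.csv(sim$estimates, pth("estimates.csv"), row.names = FALSE)
    if (!is.null(sim$variance_results)) {
      utils::write.csv(sim$variance_results, pth("variance.csv"),
                       row.names = FALSE)
    }
  }

  if ("metrics" %in% stages) {
    sim <- .read_sim_result(out_dir, config)
    wm <- weighting_metrics(sim, B_m = config$B_m,
                            seed = seeds[["metrics"]])
    utils::write.csv(wm, pth("weighting_metrics.csv"), row.names = FALSE)
    if (!is.null(sim$variance_results)) {
      cm <- coverage_metrics(sim)
      utils::write.csv(cm, pth("coverage_metrics.csv"), row.names = FALSE)
    }
  }

  if ("report" %in% stages) {
    if (!file.exists(pth("weighting_metrics.csv"))) {
      stop("report stage needs weighting_metrics.csv in ", out_dir,
           "; run the metrics stage first", call. = FALSE)
    }
    wm <- utils::read.csv(pth("weighting_metrics.csv"),
                          stringsAsFactors = FALSE)
    cm <- if (file.exists(pth("coverage_metrics.csv"))) {
      utils::read.csv(pth("coverage_metrics.csv"), stringsAsFactors = FALSE)
    } else NULL
    render_report(wm, cm, out_dir)
  }

  manifest <- list(
    package = "svysim",
    version = as.character(utils::packageVersion("svysim")),
    master_seed = as.integer(seed),
    derived_seeds = as.list(seeds),
    stages = stages,
    config = unclass(config),
    files = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE,
                                             pattern = "\\.(csv|yaml)$"))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

.read_sim_result <- function(out_dir, config) {
  pth <- function(f) file.path(out_dir, f)
  for (f in c("truth.csv", "estimates.csv")) {
    if (!file.exists(pth(f))) {
      stop("metrics stage needs ", f, " in ", out_dir,
           "; run the simulate stage first", call. = FALSE)
    }
  }
  structure(list(
    truth = utils::read.csv(pth("truth.csv"), stringsAsFactors = FALSE),
    estimates = utils::read.csv(pth("estimates.csv"),
                                stringsAsFactors = FALSE),
    variance_results = if (file.exists(pth("variance.csv"))) {
      utils::read.csv(pth("variance.csv"), stringsAsFactors = FALSE)
    } else NULL,
    config = config, n_failed = NA_integer_),
    class = "simulation_result")
}

#' Render report tables from computed metrics
#'
#' Writes the comparison tables of a run: the national weighting comparison
#' (one row per indicator: truth, mean estimates, bias difference with CI,
#' variances, variance log-ratio and ratio, MSEs, MSE log-ratio -- the
#' 15-column layout of the published comparisons), per-domain weighting
#' tables, a coverage matrix with good/fair/poor band labels, and a CI
#' length matrix flagging the smallest and largest method per row with
#' percent-information columns comparing the bootstrap against each
#' linearization method.
#'
#' @param weighting a [weighting_metrics()] table.
#' @param coverage a [coverage_metrics()] table, or `NULL`.
#' @param out_dir output directory.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(weighting, coverage, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  pth <- function(f) file.path(out_dir, f)

  nat <- weighting[weighting$domain == "national", , drop = FALSE]
  utils::write.csv(nat, pth("report_weighting_national.csv"),
                   row.names = FALSE)
  written <- c(written, pth("report_weighting_national.csv"))
  reg <- weighting[weighting$domain != "national", , drop = FALSE]
  if (nrow(reg)) {
    utils::write.csv(reg, pth("report_weighting_by_domain.csv"),
                     row.names = FALSE)
    written <- c(written, pth("report_weighting_by_domain.csv"))
  }

  if (!is.null(coverage) && nrow(coverage)) {
    methods <- sort(unique(coverage$method))
    cells <- unique(coverage[, c("indicator", "domain")])
    cov_w <- len_w <- cells
    for (m in methods) {
      sub <- coverage[coverage$method == m, , drop = FALSE]
      i <- match(.path_key(cells$indicator, cells$domain),
                 .path_key(sub$indicator, sub$domain))
      cov_w[[paste0("coverage_", m)]] <- sub$coverage[i]
      cov_w[[paste0("band_", m)]] <- sub$band[i]
      len_w[[paste0("len_", m)]] <- sub$avg_ci_length[i]
    }
    lens <- as.matrix(len_w[, paste0("len_", methods), drop = FALSE])
    len_w$smallest_method <- methods[apply(lens, 1L, which.min)]
    len_w$largest_method <- methods[apply(lens, 1L, which.max)]
    if (all(c("bootstrap", "svy1") %in% methods)) {
      len_w$info_bootstrap_vs_svy1 <- information_ratio(
        len_w$len_bootstrap, len_w$len_svy1)
    }
    if (all(c("bootstrap", "svy3") %in% methods)) {
      len_w$info_bootstrap_vs_svy3 <- information_ratio(
        len_w$len_bootstrap, len_w$len_svy3)
    }
    utils::write.csv(cov_w, pth("report_coverage_matrix.csv"),
                     row.names = FALSE)
    utils::write.csv(len_w, pth("report_ci_length_matrix.csv"),
                     row.names = FALSE)
    written <- c(written, pth("report_coverage_matrix.csv"),
                 pth("report_ci_length_matrix.csv"))
  }
  invisible(written)
}
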