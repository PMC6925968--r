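#' Describe one sampling stage of a survey design
#'
#' A stage is identified by the column holding the sampling-unit id at that
#' level (facility, provider, client; or enumeration area, household, woman).
#' If the number of units available for sampling within the enclosing group
#' is recorded in the data, `fpc_col` names that column and without-replacement
#' finite population corrections become available at the stage; when `fpc_col`
#' is `NULL` the stage is treated as sampled with replacement.
#'
#' @param id_col column name of the sampling-unit identifier.
#' @param fpc_col optional column name holding the population count of units
#'   at this stage within the enclosing unit (or stratum, for the first stage).
#' @return A `stage_spec` object.
#' @seealso [design_spec()]
#' @export
stage_spec <- function(id_col, fpc_col = NULL) {
  stopifnot(is.character(id_col), length(id_col) == 1L, nzchar(id_col))
  if (!is.null(fpc_col)) {
    stopifnot(is.character(fpc_col), length(fpc_col) == 1L, nzchar(fpc_col))
  }
  structure(list(id_col = id_col, fpc_col = fpc_col), class = "stage_spec")
}

#' Create a survey design specification
#'
#' The design specification is the shared vocabulary between the survey table
#' and every estimation routine: it names the nested sampling-unit id columns
#' (outermost first), the columns whose cross-classification defines the
#' sampling strata, the reporting-domain column, and the ultimate-unit design
#' weight column (inverse inclusion probabilities composed across stages).
#'
#' @param stages list of [stage_spec()] objects (1 to 3 entries, outermost
#'   first), or bare lists with `id_col`/`fpc_col` entries.
#' @param strata_cols character vector of stratum-defining columns (e.g.
#'   region and facility type).
#' @param domain_col column defining reporting domains (e.g. region); the
#'   pseudo-domain `"national"` always covers all rows.
#' @param weight_col name of the design-weight column.
#' @param notes free text carried along for provenance.
#' @return A validated `design_spec` object.
#' @examples
#' spec <- design_spec(
#'   stages = list(stage_spec("facility_id", "fpc_facility"),
#'                 stage_spec("provider_id", "fpc_provider"),
#'                 stage_spec("client_id", "fpc_client")),
#'   strata_cols = c("region", "facility_type"),
#'   domain_col = "region", weight_col = "weight")
#' @export
design_spec <- function(stages, strata_cols, domain_col, weight_col,
                        notes = "") {
  if (inherits(stages, "stage_spec")) stages <- list(stages)
  stages <- lapply(stages, function(s) {
    if (inherits(s, "stage_spec")) s else stage_spec(s$id_col, s$fpc_col)
  })
  spec <- structure(
    list(stages = stages,
         strata_cols = as.character(strata_cols),
         domain_col = as.character(domain_col),
         weight_col = as.character(weight_col),
         notes = as.character(notes)),
    class = "design_spec")
  validate_design_spec(spec)
}

validate_design_spec <- function(spec) {
  if (length(spec$stages) < 1L) {
    stop("design_spec: at least one sampling stage is required", call. = FALSE)
  }
  ids <- stage_id_cols(spec)
  if (anyDuplicated(ids)) {
    stop("design_spec: stage id columns must be distinct: ",
         paste(ids[duplicated(ids)], collapse = ", "), call. = FALSE)
  }
  if (length(spec$strata_cols) < 1L || !all(nzchar(spec$strata_cols))) {
    stop("design_spec: strata_cols must be a nonempty set of column names",
         call. = FALSE)
  }
  if (length(spec$weight_col) != 1L || !nzchar(spec$weight_col)) {
    stop("design_spec: weight_col is required", call. = FALSE)
  }
  if (length(spec$domain_col) != 1L || !nzchar(spec$domain_col)) {
    stop("design_spec: domain_col is required", call. = FALSE)
  }
  invisible(spec)
}

stage_id_cols <- function(spec) {
  vapply(spec$stages, function(s) s$id_col, character(1))
}

stage_fpc_cols <- function(spec) {
  lapply(spec$stages, function(s) s$fpc_col)
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>", length(x$stages), "stage(s)\n")
  for (i in seq_along(x$stages)) {
    s <- x$stages[[i]]
    cat(sprintf("  stage %d: id = %s%s\n", i, s$id_col,
                if (is.null(s$fpc_col)) " (with replacement)"
                else paste0(", fpc = ", s$fpc_col)))
  }
  cat("  strata :", paste(x$strata_cols, collapse = " x "), "\n")
  cat("  domain :", x$domain_col, "\n")
  cat("  weight :", x$weight_col, "\n")
  invisible(x)
}

#' Read or write a design specification as YAML
#'
#' The on-disk form is a small YAML (or JSON, which YAML subsumes) mapping
#' with keys `stages` (list of `id_col`/`fpc_col`), `strata_cols`,
#' `domain_col`, `weight_col` and optional `notes`.
#'
#' @param path file path.
#' @return `read_design_spec()` returns a `design_spec`;
#'   `write_design_spec()` returns `path` invisibly.
#' @export
read_design_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  design_spec(
    stages = lapply(cfg$stages, function(s) stage_spec(s$id_col, s$fpc_col)),
    strata_cols = cfg$strata_cols,
    domain_col = cfg$domain_col,
    weight_col = cfg$weight_col,
    notes = cfg$notes %||% "")
}

#' @rdname read_design_spec
#' @param spec a `design_spec`.
#' @export
write_design_spec <- function(spec, path) {
  validate_design_spec(spec)
  yaml::write_yaml(
    list(stages = lapply(spec$stages, function(s) {
           out <- list(id_col = s$id_col)
           if (!is.null(s$fpc_col)) out$fpc_col <- s$fpc_col
           out
         }),
         strata_cols = spec$strata_cols,
         domain_col = spec$domain_col,
         weight_col = spec$weight_col,
         notes = spec$notes),
    path)
  invisible(path)
}
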