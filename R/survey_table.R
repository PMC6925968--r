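# Survey microdata: validation, CSV I/O, and the facility/client merge.
#
# A survey table is a plain data.frame of ultimate-unit rows (clients or
# women) carrying stage id columns, strata columns, a domain column, one or
# more positive weight columns, binary indicator columns prefixed "ind_",
# and optional population-count columns prefixed "fpc_".

strata_key <- function(table, spec) {
  do.call(.path_key, lapply(spec$strata_cols,
                            function(cl) as.character(table[[cl]])))
}

#' Validate a survey table against a design specification
#'
#' Checks that all design columns are present, weights are strictly positive,
#' indicator columns (prefix `ind_`) contain only 0, 1 or missing, stage ids
#' are consistently nested (an inner-stage id maps to exactly one outer-stage
#' id), the stratum is constant within a primary sampling unit, and -- when
#' `check_fpc` -- population counts are no smaller than the number of sampled
#' units they refer to.
#'
#' @param table data.frame of ultimate-unit rows.
#' @param spec a [design_spec()].
#' @param check_nesting,check_fpc logical; individual check toggles
#'   (resampled-with-replacement tables legitimately violate the fpc check).
#' @return `table`, invisibly; errors describe the offending column, row or id.
#' @export
validate_survey_table <- function(table, spec, check_nesting = TRUE,
                                  check_fpc = TRUE) {
  validate_design_spec(spec)
  needed <- unique(c(stage_id_cols(spec), spec$strata_cols, spec$domain_col,
                     spec$weight_col))
  absent <- setdiff(needed, names(table))
  if (length(absent)) {
    stop("survey table is missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(table) == 0L) return(invisible(table))

  w <- table[[spec$weight_col]]
  bad <- which(!is.finite(w) | w <= 0)
  if (length(bad)) {
    stop("nonpositive or missing weight in column '", spec$weight_col,
         "' at row ", bad[1L], call. = FALSE)
  }
  for (cl in grep("^ind_", names(table), value = TRUE)) {
    v <- table[[cl]]
    if (!all(is.na(v) | v %in% c(0, 1))) {
      stop("indicator column '", cl, "' contains values outside {0, 1, NA}",
           call. = FALSE)
    }
  }

  ids <- stage_id_cols(spec)
  if (check_nesting && length(ids) > 1L) {
    for (k in 2:length(ids)) {
      inner <- as.character(table[[ids[k]]])
      outer <- as.character(table[[ids[k - 1L]]])
      pairs <- !duplicated(.path_key(inner, outer))
      if (anyDuplicated(inner[pairs])) {
        off <- inner[pairs][duplicated(inner[pairs])][1L]
        stop("inconsistent nesting: '", ids[k], "' id '", off,
             "' appears under more than one '", ids[k - 1L], "'",
             call. = FALSE)
      }
    }
    # stratum constant within PSU
    psu <- as.character(table[[ids[1L]]])
    st <- strata_key(table, spec)
    pairs <- !duplicated(.path_key(psu, st))
    if (anyDuplicated(psu[pairs])) {
      off <- psu[pairs][duplicated(psu[pairs])][1L]
      stop("primary sampling unit '", off, "' spans more than one stratum",
           call. = FALSE)
    }
  }

  if (check_fpc) {
    fpcs <- stage_fpc_cols(spec)
    parent <- strata_key(table, spec)
    for (k in seq_along(ids)) {
      fcol <- fpcs[[k]]
      uid <- as.character(table[[ids[k]]])
      if (!is.null(fcol) && fcol %in% names(table)) {
        f <- table[[fcol]]
        if (any(!is.na(f) & f <= 0)) {
          stop("fpc column '", fcol, "' contains nonpositive counts",
               call. = FALSE)
        }
        first <- !duplicated(.path_key(parent, uid))
        n_units <- rowsum(as.numeric(first[first]), parent[first])
        fpar <- rowsum(f[first], parent[first]) / as.vector(n_units)  # mean
        short <- as.vector(fpar) + 1e-9 < as.vector(n_units)
        if (any(short, na.rm = TRUE)) {
          stop("fpc column '", fcol, "' is smaller than the number of ",
               "sampled units in at least one group", call. = FALSE)
        }
      }
      parent <- .path_key(parent, uid)
    }
  }
  invisible(table)
}

#' Read / write survey microdata CSV
#'
#' CSV I/O that round-trips exactly: numeric columns are written with 17
#' significant digits so re-reading reproduces the same doubles bit for bit,
#' missing cells are written as empty strings, and all id / strata / domain
#' columns are read back as character (ids are opaque; no ordering semantics).
#'
#' @param path file path of an RFC-4180 CSV with a header row.
#' @param spec a [design_spec()] naming the design columns.
#' @param validate run [validate_survey_table()] on the result?
#' @return `read_survey_csv()` returns a validated data.frame;
#'   `write_survey_csv()` returns `path` invisibly.
#' @export
read_survey_csv <- function(path, spec, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        check.names = FALSE)
  char_cols <- unique(c(stage_id_cols(spec), spec$strata_cols,
                        spec$domain_col))
  absent <- setdiff(c(char_cols, spec$weight_col), names(df))
  if (length(absent)) {
    stop("CSV is missing required column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  for (cl in names(df)) {
    if (cl %in% char_cols) {
      df[[cl]] <- as.character(df[[cl]])
    } else if (is.numeric(df[[cl]])) {
      df[[cl]] <- as.double(df[[cl]])  # uniform double storage
    }
  }
  if (validate) validate_survey_table(df, spec)
  df
}

#' @rdname read_survey_csv
#' @param table data.frame to write.
#' @export
write_survey_csv <- function(table, path) {
  out <- table
  for (cl in names(out)) {
    if (is.numeric(out[[cl]])) {
      x <- out[[cl]]
      s <- sprintf("%.17g", x)
      s[is.na(x)] <- NA_character_
      out[[cl]] <- s
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}

# copy counter for a facility id vector that may contain duplicates:
# k-th occurrence of an id gets copy index k
.facility_copies <- function(fid) {
  stats::ave(seq_along(fid), fid, FUN = seq_along)
}

#' Merge (possibly resampled) facilities with their client rows
#'
#' Produces one client row per (facility copy, client of that facility).  A
#' facility drawn k times contributes its clients k times; every copy gets a
#' distinct `"#k"` suffix appended to *all* stage id columns so that copies
#' are treated as distinct clusters by downstream variance estimators (a
#' provider id repeated under two facility copies would otherwise break the
#' nesting invariant).
#'
#' @param facilities facility-level table whose first-stage id column may
#'   contain repeats (with-replacement resampling).
#' @param clients client-level survey table; every client's facility id must
#'   appear in `facilities`.
#' @param spec a [design_spec()]; its first stage identifies the facility id.
#' @return A client-level data.frame with suffixed stage ids.  Original
#'   weights are carried unchanged.
#' @export
merge_clients_to_facilities <- function(facilities, clients, spec) {
  psu <- spec$stages[[1L]]$id_col
  fid <- as.character(facilities[[psu]])
  cid <- as.character(clients[[psu]])
  orphan <- setdiff(unique(cid), fid)
  if (length(orphan)) {
    stop("client rows reference facilities absent from the facility table: ",
         orphan[1L], call. = FALSE)
  }
  copy <- .facility_copies(fid)
  idx_by_fac <- split(seq_len(nrow(clients)), cid)
  rows <- idx_by_fac[fid]                       # NULL for client-less facilities
  out <- clients[unlist(rows, use.names = FALSE), , drop = FALSE]
  if (nrow(out)) {
    copy_rep <- rep(copy, vapply(rows, length, integer(1)))
    for (cl in stage_id_cols(spec)) {
      if (cl %in% names(out)) {
        out[[cl]] <- paste0(out[[cl]], "#", copy_rep)
      }
    }
  }
  rownames(out) <- NULL
  out
}
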