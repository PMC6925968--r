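# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive n child seeds from a master seed without disturbing the caller's
# RNG stream.  Child seeds stay below 2^31 - 1 (R integers are 32-bit).
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

# key separator for composite grouping keys; ids are opaque strings but the
# unit separator control character is vanishingly unlikely to occur in them
.SEP <- "\x1f"

.path_key <- function(...) do.call(paste, c(list(...), sep = .SEP))

svysim_log <- function(...) {
  if (isTRUE(getOption("svysim.verbose", FALSE))) {
    message("[svysim] ", ...)
  }
  invisible(NULL)
}
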