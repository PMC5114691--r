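# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed when `seed` is supplied, otherwise use the
# current RNG stream. All exported stochastic functions funnel through this so
# "same seed => identical output" holds everywhere.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), expr)
  }
}

# Derive a bounded child seed from a master seed; NULL propagates NULL so
# unseeded calls stay unseeded.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1L))
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("`%s` is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

BASES <- c("A", "T", "C", "G")          # sync column order
BASES_LEX <- c("A", "C", "G", "T")      # lexicographic tie-break order
SYNC_COUNT_COLS <- c("A", "T", "C", "G", "N", "del")
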