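# Internal helpers shared across modules.

# Abort with a consistent class so callers can condition on package errors.
cre_abort <- function(msg, class = "cregrammar_error") {
  rlang::abort(msg, class = class)
}

# Check that `x` is a data frame containing the named columns.
check_columns <- function(x, cols, what = deparse(substitute(x))) {
  if (!is.data.frame(x)) {
    cre_abort(sprintf("`%s` must be a data frame.", what))
  }
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    cre_abort(sprintf(
      "`%s` is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

# Derive a deterministic sub-seed for a named simulation stage, so each
# generator is a pure function of (config, seed) yet stages stay decoupled.
# Kept below 2^31 - 1 to stay a valid R integer.
stage_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 1009 + offs) %% .Machine$integer.max)
}

# Peak tibbles: chrom, start, end (0-based half-open), summit offset from start.
check_peaks <- function(peaks, what = "peaks") {
  check_columns(peaks, c("chrom", "start", "end"), what)
  bad <- which(!(peaks$start >= 0 & peaks$start < peaks$end))
  if (length(bad) > 0) {
    cre_abort(sprintf(
      "`%s` has malformed interval(s) at row(s) %s: need 0 <= start < end.",
      what, paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  if ("summit" %in% names(peaks)) {
    bad <- which(!(peaks$summit >= 0 & peaks$summit < peaks$end - peaks$start))
    if (length(bad) > 0) {
      cre_abort(sprintf(
        "`%s` has summit(s) outside the interval at row(s) %s.",
        what, paste(utils::head(bad, 5), collapse = ", ")
      ))
    }
  }
  invisible(peaks)
}

# Default summit: interval midpoint (offset from start).
midpoint_summit <- function(start, end) {
  as.integer(floor((end - start) / 2))
}
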