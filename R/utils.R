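# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((abs(as.integer(seed)) %% 1000003L) * 2069L + as.integer(h) + 17L)
}

# Total length covered by the union of closed integer intervals.
# starts/ends are 1-based inclusive; ends may be < starts (reverse strand).
#' @keywords internal
#' @noRd
interval_union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  lo <- pmin(starts, ends)
  hi <- pmax(starts, ends)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  total <- 0L
  cur_lo <- lo[1L]; cur_hi <- hi[1L]
  for (i in seq_along(lo)[-1L]) {
    if (lo[i] <= cur_hi + 1L) {
      cur_hi <- max(cur_hi, hi[i])
    } else {
      total <- total + (cur_hi - cur_lo + 1L)
      cur_lo <- lo[i]; cur_hi <- hi[i]
    }
  }
  total + (cur_hi - cur_lo + 1L)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
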