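# internal helpers shared across modules

# centred running mean with shrinking window at the edges (partial windows
# averaged over the bases actually covered); k is forced odd
running_mean <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || length(x) <= 1L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# maximal runs of TRUE in a logical vector -> tibble(start_idx, end_idx) (inclusive)
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start_idx = starts[keep], end_idx = ends[keep])
}

stopf <- function(fmt, ..., class = "methocc_error") {
  rlang::abort(sprintf(fmt, ...), class = class)
}

format_error <- function(fmt, ...) {
  rlang::abort(sprintf(fmt, ...), class = c("methocc_format_error", "methocc_error"))
}

assert_interval_tbl <- function(x, arg = "intervals") {
  need <- c("chrom", "start", "end")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stopf("`%s` must be a data frame with columns chrom, start, end", arg)
  }
  bad <- which(x$start >= x$end | x$start < 0)
  if (length(bad) > 0) {
    stopf("`%s` contains invalid intervals (start >= end or start < 0), first at row %d",
          arg, bad[1])
  }
  invisible(x)
}

# reverse complement for plain character strings (A/C/G/T/N)
rev_comp <- function(s) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", s))
}

# weighted overlap of an interval [start, end) with a window partition of
# fixed width w starting at 0: returns indices and overlap widths
window_overlaps <- function(start, end, w, n_windows) {
  i0 <- max(0L, as.integer(start %/% w))
  i1 <- min(n_windows - 1L, as.integer((end - 1L) %/% w))
  if (i1 < i0) return(list(idx = integer(0), weight = numeric(0)))
  idx <- i0:i1
  ws <- idx * w
  we <- ws + w
  weight <- pmin(end, we) - pmax(start, ws)
  list(idx = idx + 1L, weight = weight)
}
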