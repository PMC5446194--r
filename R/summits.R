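#' Call summits of ChIP enrichment over Input
#'
#' A deliberately simple peak caller standing in for MACS-style summit
#' detection: per fine window, enrichment
#' `e = log2((chip + psi) / (input * r + psi))` with `r` the
#' ChIP/Input library-size ratio; `e` is smoothed by a running mean of the
#' given bandwidth; candidate peaks are maximal runs of smoothed `e` above
#' `threshold`; each peak is kept if its summed ChIP count clears a Poisson
#' upper-tail test against the library-scaled Input expectation at
#' `p_thresh`. The summit is the window of maximal smoothed enrichment
#' within the peak (leftmost on ties). The contract of this caller is
#' summit position, not score, agreement with full peak callers.
#'
#' @param chip,input `coverage_windows` tibbles on identical fine
#'   partitions (window width at most 50 bp recommended).
#' @param bandwidth Smoothing bandwidth, bp; must be at least the window
#'   width.
#' @param threshold Enrichment threshold (log2 units) defining candidate
#'   runs.
#' @param pseudocount Pseudocount in count units.
#' @param p_thresh Poisson upper-tail p-value cutoff.
#' @return A `summit_set` tibble: `chrom`, `pos` (summit, 0-based),
#'   `score` (smoothed enrichment), `peak_start`, `peak_end`, `p_value`.
#' @export
call_summits <- function(chip, input, bandwidth = 200L, threshold = 1,
                         pseudocount = 0.5, p_thresh = 1e-5) {
  assert_same_partition(chip, input)
  w <- chip$end[1] - chip$start[1]
  if (bandwidth < w) stopf("bandwidth must be at least the window width (%d bp)", w)
  r <- attr(chip, "library_size") / attr(input, "library_size")
  mean_input <- mean(input$count)
  out <- lapply(split(seq_len(nrow(chip)), chip$chrom), function(idx) {
    e <- log2((chip$count[idx] + pseudocount) /
                (input$count[idx] * r + pseudocount))
    es <- running_mean(e, bandwidth / w)
    runs <- true_runs(es > threshold)
    if (nrow(runs) == 0) return(NULL)
    res <- lapply(seq_len(nrow(runs)), function(j) {
      ii <- runs$start_idx[j]:runs$end_idx[j]
      chip_sum <- sum(chip$count[idx][ii])
      lambda <- r * max(sum(input$count[idx][ii]), mean_input * length(ii))
      p <- ppois(chip_sum - 1, lambda, lower.tail = FALSE)
      if (p >= p_thresh) return(NULL)
      peak_apex <- ii[which.max(es[ii])]        # which.max takes the leftmost tie
      tibble::tibble(
        chrom = chip$chrom[idx][1],
        pos = chip$start[idx][peak_apex] + w %/% 2L,
        score = es[peak_apex],
        peak_start = chip$start[idx][ii[1]],
        peak_end = chip$end[idx][ii[length(ii)]],
        p_value = p)
    })
    dplyr::bind_rows(res)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), pos = integer(), score = double(),
                          peak_start = integer(), peak_end = integer(),
                          p_value = double())
  }
  class(out) <- c("summit_set", class(out))
  out
}

#' Sample random anchor positions as a negative control
#'
#' Draws positions uniformly over the non-excluded, non-gap (non-`N`)
#' portion of the genome, reproducibly for a given seed.
#'
#' @param genome A `genome_seq`.
#' @param n Number of positions.
#' @param seed Integer seed.
#' @param exclusion Optional interval tibble to avoid.
#' @return Tibble with `chrom`, `pos` (0-based).
#' @export
sample_random_regions <- function(genome, n, seed, exclusion = NULL) {
  if (n < 1) stopf("n must be at least 1")
  lens <- as.numeric(genome$lengths)
  total <- sum(lens)
  if (!is.null(exclusion) && nrow(exclusion) > 0) {
    excl_len <- sum(pmin(exclusion$end,
                         lens[match(exclusion$chrom, names(genome$seq))]) -
                      pmax(exclusion$start, 0))
    if (excl_len >= total) stopf("exclusion set covers the whole genome")
  }
  set.seed(seed)
  chroms <- names(genome$seq)
  acc <- list(); got <- 0L; tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > 200L) stopf("could not place %d positions; exclusion too dense", n)
    m <- max(2L * (n - got), 100L)
    ci <- sample.int(length(chroms), m, replace = TRUE, prob = lens / total)
    pos <- floor(runif(m) * lens[ci])
    ok <- !in_intervals(chroms[ci], pos, exclusion %||%
                          tibble::tibble(chrom = character(), start = integer(),
                                         end = integer()))
    base <- stringi::stri_sub(genome$seq[ci[ok]], pos[ok] + 1L, pos[ok] + 1L)
    keep <- which(ok)[base != "N"]
    if (length(keep) > 0) {
      take <- head(keep, n - got)
      acc[[length(acc) + 1L]] <- tibble::tibble(chrom = chroms[ci[take]],
                                                pos = as.integer(pos[take]))
      got <- got + length(take)
    }
  }
  dplyr::bind_rows(acc)
}
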