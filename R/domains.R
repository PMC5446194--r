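#' Multiscale segmentation of occupancy into enriched/depleted domains
#'
#' A simplified multiscale scheme: for each scale `s` the ChIP and Input
#' window counts are mean-smoothed with a window of `w0 * 2^s` base pairs
#' (`w0` = the track's window width), the enrichment score is
#' `log2((chip_s + psi)/(input_s * r + psi))` with `r` the library-size
#' ratio, candidate segments are maximal runs with `|score| >=
#' score_threshold` of one sign, and each candidate is kept if a two-sided
#' binomial test of its summed raw ChIP count against the library-scaled
#' Input expectation is below `p_thresh`. The reported score is the
#' segment mean. Segments carry a scale index but no cross-scale pruning:
#' all scales are reported.
#'
#' @param chip,input `coverage_windows` tibbles on identical partitions.
#' @param scales Integer vector of scale indices (smoothing doublings),
#'   e.g. `0:8`.
#' @param score_threshold Minimum `|score|` (log2 units) for candidate
#'   runs.
#' @param p_thresh Binomial p-value cutoff (default 1e-6).
#' @param pseudocount Pseudocount in count units.
#' @return A `segment_set` tibble: `chrom`, `start`, `end`, `scale_index`,
#'   `scale_bp`, `enrichment_score`, `p_value`, `label`, `n_windows`.
#'   Attribute `n_candidates` counts candidate runs over all scales (the
#'   null-calibration denominator).
#' @export
multiscale_segments <- function(chip, input, scales = 0:8,
                                score_threshold = 0.3, p_thresh = 1e-6,
                                pseudocount = 0.5) {
  assert_same_partition(chip, input)
  if (length(scales) == 0) stopf("empty scale list")
  if (any(scales < 0)) stopf("scale indices must be >= 0")
  w0 <- chip$end[1] - chip$start[1]
  r <- attr(chip, "library_size") / attr(input, "library_size")
  p0 <- r / (1 + r)
  n_candidates <- 0L
  segs <- list()
  chrom_idx <- split(seq_len(nrow(chip)), chip$chrom)
  for (s in sort(unique(as.integer(scales)))) {
    k <- 2L^s
    for (idx in chrom_idx) {
      cc <- chip$count[idx]; ic <- input$count[idx]
      cs <- running_mean(cc, k)
      is <- running_mean(ic, k)
      score <- log2((cs + pseudocount) / (is * r + pseudocount))
      for (sgn in c(1, -1)) {
        runs <- true_runs(sgn * score >= score_threshold)
        n_candidates <- n_candidates + nrow(runs)
        if (nrow(runs) == 0) next
        res <- lapply(seq_len(nrow(runs)), function(j) {
          ii <- runs$start_idx[j]:runs$end_idx[j]
          C <- sum(cc[ii]); I <- sum(ic[ii])
          if (C + I == 0) return(NULL)
          p <- binom.test(C, C + I, p = p0)$p.value
          if (p >= p_thresh) return(NULL)
          tibble::tibble(
            chrom = chip$chrom[idx][1],
            start = chip$start[idx][ii[1]],
            end = chip$end[idx][ii[length(ii)]],
            scale_index = s, scale_bp = w0 * k,
            enrichment_score = mean(score[ii]),
            p_value = p,
            label = if (sgn > 0) "enriched" else "depleted",
            n_windows = length(ii))
        })
        segs[[length(segs) + 1L]] <- dplyr::bind_rows(res)
      }
    }
  }
  out <- dplyr::bind_rows(segs)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          scale_index = integer(), scale_bp = integer(),
                          enrichment_score = double(), p_value = double(),
                          label = character(), n_windows = integer())
  }
  attr(out, "n_candidates") <- n_candidates
  attr(out, "base_window") <- w0
  class(out) <- c("segment_set", class(out))
  out
}

#' Annotate segments with methylation densities and GC fraction
#'
#' Adds the mCG and mCAC methylation densities (per kb), their sum, and
#' the GC base fraction to each segment.
#'
#' @param segments A `segment_set` (or any interval tibble).
#' @param sites Methylation site tibble with `level` and `covered`.
#' @param genome A `genome_seq`.
#' @return The segments with columns `mcg_density`, `mcac_density`,
#'   `combined_density` (per kb) and `gc_fraction` appended.
#' @export
annotate_segments <- function(segments, sites, genome) {
  if (nrow(segments) == 0) {
    segments$mcg_density <- numeric(0); segments$mcac_density <- numeric(0)
    segments$combined_density <- numeric(0); segments$gc_fraction <- numeric(0)
    return(segments)
  }
  mcg <- region_methylation(sites, segments, "CG")$density_per_kb
  mcac <- region_methylation(sites, segments, "CAC")$density_per_kb
  gc <- vapply(seq_len(nrow(segments)), function(i) {
    s <- stringi::stri_sub(genome$seq[[segments$chrom[i]]],
                           segments$start[i] + 1L, segments$end[i])
    stringi::stri_count_charclass(s, "[CG]") / nchar(s)
  }, numeric(1))
  segments$mcg_density <- mcg
  segments$mcac_density <- mcac
  segments$combined_density <- mcg + mcac
  segments$gc_fraction <- gc
  segments
}

#' Summarise segments on a scale-by-score grid
#'
#' Bins segments by scale index and enrichment score and reports, per
#' populated cell, the segment count, the median segment length and the
#' mean of each annotation column present. Cells without segments are
#' absent from the output, not zero-filled.
#'
#' @param segments A `segment_set`, optionally annotated.
#' @param score_breaks Breakpoints for the enrichment-score axis.
#' @return A `scale_score_summary` tibble: `scale_index`, `scale_bp`,
#'   `score_bin` (factor), `n`, `median_length`, and `mean_<annotation>`
#'   columns.
#' @export
scale_score_summary <- function(segments,
                                score_breaks = seq(-4, 4, by = 0.5)) {
  if (nrow(segments) == 0) stopf("no segments to summarise")
  sb <- c(-Inf, score_breaks, Inf)
  seg <- dplyr::mutate(segments,
                       score_bin = cut(.data$enrichment_score, breaks = sb),
                       seg_length = .data$end - .data$start)
  ann <- intersect(c("mcg_density", "mcac_density", "combined_density",
                     "gc_fraction"), names(seg))
  out <- dplyr::summarise(
    dplyr::group_by(seg, .data$scale_index, .data$scale_bp, .data$score_bin),
    n = dplyr::n(),
    median_length = median(.data$seg_length),
    dplyr::across(dplyr::all_of(ann), mean, .names = "mean_{.col}"),
    .groups = "drop")
  class(out) <- c("scale_score_summary", class(out))
  out
}

#' Overlap of short depleted segments with CpG islands
#'
#' Computes the fraction of short (scale below `scale_cutoff_bp`) depleted
#' segments overlapping a CpG island, with an empirical p-value from
#' `n_shuffle` position-shuffled segment sets (shuffling preserves each
#' segment's length and chromosome).
#'
#' @param segments A `segment_set`.
#' @param cgis CpG-island interval tibble.
#' @param genome A `genome_seq` (for shuffle bounds).
#' @param scale_cutoff_bp Segments with `scale_bp` strictly below this are
#'   "short".
#' @param n_shuffle Number of shuffles (values below 100 warn).
#' @param seed Seed for the shuffles.
#' @return List: `observed_fraction`, `p_value`, `n_segments`,
#'   `shuffled_fractions`.
#' @export
overlap_with_cgis <- function(segments, cgis, genome, scale_cutoff_bp = 2000,
                              n_shuffle = 1000L, seed = 1L) {
  if (nrow(segments) == 0 || nrow(cgis) == 0) stopf("need non-empty segments and CGIs")
  if (n_shuffle < 100) rlang::warn("fewer than 100 shuffles: empirical p is coarse")
  short <- segments[segments$label == "depleted" &
                      segments$scale_bp < scale_cutoff_bp, ]
  if (nrow(short) == 0) {
    return(list(observed_fraction = NA_real_, p_value = NA_real_,
                n_segments = 0L, shuffled_fractions = numeric(0)))
  }
  overlap_frac <- function(st, en, chrom) {
    hits <- logical(length(st))
    for (nm in unique(chrom)) {
      sel <- chrom == nm
      iv <- cgis[cgis$chrom == nm, ]
      if (nrow(iv) == 0) next
      o <- order(iv$start)
      ivs <- iv$start[o]; ive <- iv$end[o]
      # overlap iff some island with start < en and end > st
      i <- findInterval(en[sel] - 0.5, ivs)       # islands starting before en
      # check the closest candidate island ending after st
      ends_cum <- cummax(ive)
      hits[sel] <- i > 0 & ends_cum[pmax(i, 1L)] > st[sel]
    }
    mean(hits)
  }
  obs <- overlap_frac(short$start, short$end, short$chrom)
  lens_g <- genome$lengths
  seg_len <- short$end - short$start
  set.seed(seed)
  max_start <- as.numeric(lens_g[short$chrom]) - seg_len
  shuf <- vapply(seq_len(n_shuffle), function(b) {
    ns <- floor(runif(nrow(short)) * max_start)
    overlap_frac(ns, ns + seg_len, short$chrom)
  }, numeric(1))
  list(observed_fraction = obs,
       p_value = (1 + sum(shuf >= obs)) / (n_shuffle + 1),
       n_segments = nrow(short),
       shuffled_fractions = shuf)
}
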