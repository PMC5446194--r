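#' Bin shifted fragments into fixed-width genome windows
#'
#' Partitions each chromosome into windows of width `w` (trailing partial
#' window dropped) and assigns each fragment to the window containing its
#' shifted 5' position: `start + shift` for plus-strand fragments and
#' `end - 1 - shift` for minus-strand fragments (fragments without strand
#' are treated as plus). Fragments whose shifted position falls off the
#' partition are dropped and counted in a loss tally. RPKM is
#' `count / (library_size/1e6) / (w/1e3)` with `library_size` the total of
#' assigned fragments.
#'
#' @param fragments Tibble with `chrom`, `start`, `end` and optionally
#'   `strand`.
#' @param genome A `genome_seq` (provides chromosome lengths).
#' @param w Window width, bp.
#' @param shift Shift applied to fragment 5' ends, bp. The full
#'   fragment-length shift used in the source protocol (134 bp) and the
#'   conventional half-fragment shift are both just values of this
#'   argument.
#' @return A `coverage_windows` tibble: `chrom`, `start`, `end`, `count`,
#'   `rpkm`, with attributes `library_size`, `window`, `shift`, `n_lost`.
#' @export
bin_coverage <- function(fragments, genome, w, shift = 0L) {
  if (w <= 0) stopf("window width must be positive")
  unknown <- setdiff(unique(fragments$chrom), names(genome$seq))
  if (length(unknown) > 0) stopf("fragments on unknown chromosome '%s'", unknown[1])
  strand <- if ("strand" %in% names(fragments)) fragments$strand else
    rep("+", nrow(fragments))
  anchor <- ifelse(strand == "-", fragments$end - 1L - shift,
                   fragments$start + shift)
  res <- lapply(names(genome$seq), function(nm) {
    n_win <- as.integer(genome$lengths[[nm]] %/% w)
    sel <- fragments$chrom == nm
    a <- anchor[sel]
    ok <- a >= 0 & a < n_win * w
    counts <- tabulate(a[ok] %/% w + 1L, nbins = n_win)
    list(tbl = tibble::tibble(chrom = nm,
                              start = (seq_len(n_win) - 1L) * w,
                              end = seq_len(n_win) * w,
                              count = counts),
         lost = sum(!ok))
  })
  out <- dplyr::bind_rows(lapply(res, `[[`, "tbl"))
  lib <- sum(out$count)
  out$rpkm <- out$count / (lib / 1e6) / (w / 1e3)
  attr(out, "library_size") <- lib
  attr(out, "window") <- as.integer(w)
  attr(out, "shift") <- as.integer(shift)
  attr(out, "n_lost") <- sum(vapply(res, `[[`, numeric(1), "lost"))
  class(out) <- c("coverage_windows", class(out))
  out
}

assert_same_partition <- function(a, b) {
  if (nrow(a) != nrow(b) || !all(a$chrom == b$chrom) ||
      !all(a$start == b$start) || !all(a$end == b$end)) {
    stopf("ChIP and Input tracks are on different window partitions")
  }
}

#' Input-corrected occupancy: per-window log2(ChIP/Input)
#'
#' Computes `log2((chip_rpkm + psi) / (input_rpkm + psi))` over a shared
#' window partition. The pseudocount keeps the ratio finite on empty
#' windows.
#'
#' @param chip,input `coverage_windows` tibbles on identical partitions.
#' @param pseudocount Pseudocount `psi` in RPKM units (default 0.5).
#' @return An `occupancy_track` tibble: `chrom`, `start`, `end`,
#'   `chip_rpkm`, `input_rpkm`, `log2_ratio`; attribute `pseudocount`.
#' @export
log2_ratio <- function(chip, input, pseudocount = 0.5) {
  assert_same_partition(chip, input)
  out <- tibble::tibble(
    chrom = chip$chrom, start = chip$start, end = chip$end,
    chip_rpkm = chip$rpkm, input_rpkm = input$rpkm,
    log2_ratio = log2((chip$rpkm + pseudocount) / (input$rpkm + pseudocount)))
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("occupancy_track", class(out))
  out
}

#' Fit the Input-predictability linear model
#'
#' Ordinary least squares of ChIP signal on Input signal over genome
#' windows (the model under which most of the ChIP variance is explained by
#' sequence/composition bias alone). Accepts `coverage_windows` tibbles
#' (RPKM is used) or bare numeric vectors.
#'
#' @param chip,input `coverage_windows` tibbles or numeric vectors of equal
#'   length.
#' @return An `input_fit` object: slope, intercept, `r_squared`, the
#'   per-window data with residuals, and empty outlier labels (see
#'   [partition_outliers()]).
#' @examples
#' f <- fit_input_model(c(1, 3, 2), c(1, 2, 3))
#' glance(f)
#' @export
fit_input_model <- function(chip, input) {
  y <- if (is.data.frame(chip)) chip$rpkm else as.numeric(chip)
  x <- if (is.data.frame(input)) input$rpkm else as.numeric(input)
  if (length(x) != length(y)) stopf("chip and input must have equal length")
  if (length(x) < 3) stopf("need at least 3 windows to fit")
  if (var(x) == 0) stopf("degenerate fit: Input signal has zero variance")
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - (intercept + slope * x)
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  data <- tibble::tibble(input = x, chip = y, residual = resid,
                         label = factor(rep("neutral", length(x)),
                                        levels = c("depleted", "neutral", "enriched")))
  if (is.data.frame(chip) && all(c("chrom", "start", "end") %in% names(chip))) {
    data <- dplyr::bind_cols(chip[, c("chrom", "start", "end")], data)
  }
  structure(list(slope = slope, intercept = intercept,
                 r_squared = 1 - ss_res / ss_tot,
                 data = data, partitioned = FALSE,
                 neutral_r_squared = NA_real_),
            class = "input_fit")
}

#' @export
print.input_fit <- function(x, ...) {
  cat("<input_fit> ChIP ~ Input over", nrow(x$data), "windows\n")
  cat(sprintf("  slope %.4g, intercept %.4g, R^2 %.4f\n",
              x$slope, x$intercept, x$r_squared))
  if (x$partitioned) {
    tab <- table(x$data$label)
    cat(sprintf("  labels: %d depleted / %d neutral / %d enriched; neutral R^2 %.4f\n",
                tab[["depleted"]], tab[["neutral"]], tab[["enriched"]],
                x$neutral_r_squared))
  }
  invisible(x)
}

#' Partition windows into enriched / depleted / neutral outlier classes
#'
#' Labels windows whose ChIP signal deviates from the Input prediction.
#' Quantile mode labels the lowest `q_low` residual fraction depleted and
#' the highest `q_high` fraction enriched (defaults reproduce the reported
#' 4.1% depleted / 1.7% enriched window fractions); z-score mode uses
#' standardized-residual cutoffs `|z| > z_cut`. The linear model is then
#' refit on neutral windows only, giving `neutral_r_squared`.
#'
#' @param fit An `input_fit` from [fit_input_model()].
#' @param mode `"quantile"` or `"zscore"`.
#' @param q_low,q_high Quantile-mode tail fractions.
#' @param z_cut Z-score-mode cutoff.
#' @return The `input_fit` with per-window labels and `neutral_r_squared`
#'   filled in.
#' @export
partition_outliers <- function(fit, mode = c("quantile", "zscore"),
                               q_low = 0.041, q_high = 0.017, z_cut = 2) {
  mode <- match.arg(mode)
  if (q_low + q_high >= 1) stopf("q_low + q_high must be below 1")
  r <- fit$data$residual
  n <- length(r)
  lab <- rep("neutral", n)
  if (mode == "quantile") {
    o <- order(r)
    n_dep <- floor(q_low * n + 1e-9)
    n_enr <- floor(q_high * n + 1e-9)
    if (n_dep > 0) lab[o[seq_len(n_dep)]] <- "depleted"
    if (n_enr > 0) lab[o[n - seq_len(n_enr) + 1L]] <- "enriched"
  } else {
    s <- sd(r)
    if (s > 0) {
      z <- r / s
      lab[z < -z_cut] <- "depleted"
      lab[z > z_cut] <- "enriched"
    }
  }
  fit$data$label <- factor(lab, levels = c("depleted", "neutral", "enriched"))
  neutral <- fit$data$label == "neutral"
  fit$neutral_r_squared <- if (sum(neutral) >= 3 &&
                               var(fit$data$input[neutral]) > 0) {
    fit_input_model(fit$data$chip[neutral], fit$data$input[neutral])$r_squared
  } else NA_real_
  fit$partitioned <- TRUE
  fit
}

# maximal A/T runs of length >= run_min starting within +/- flank of pos
# (0-based); local window extraction keeps maximality exact at its edges
has_at_run <- function(seq_str, pos, flank = 13L, run_min = 4L) {
  n <- nchar(seq_str)
  vapply(pos, function(p) {
    lo <- max(0L, p - flank - 1L)              # one extra base for maximality
    hi <- min(n - 1L, p + flank + run_min - 1L)
    sub <- stringi::stri_sub(seq_str, lo + 1L, hi + 1L)
    at <- strsplit(chartr("ACGTN", "10010", sub), "", fixed = TRUE)[[1]] == "1"
    r <- rle(at)
    ends <- cumsum(r$lengths)
    starts <- lo + ends - r$lengths            # 0-based run starts
    runs <- r$values & r$lengths >= run_min
    # a run flush with the left edge of the window may extend leftwards:
    # only trust it if we included the extra base (lo < p - flank)
    ok_start <- starts >= p - flank & starts <= p + flank
    # runs touching the right window edge have length >= run_min already
    any(runs & ok_start & (starts > lo | lo == 0L))
  }, logical(1))
}

#' Compare MeCP2-style occupancy at sites with and without AT-run flanks
#'
#' Tests whether methylated sites flanked by a run of `run_min` (default 4)
#' or more consecutive A/T bases starting within `flank` bp (default 13)
#' show different occupancy than sites lacking such a run. Only isolated
#' sites (no other supplied site within `isolation_radius`) enter the
#' comparison. The group difference is accompanied by a bootstrap 95%
#' confidence interval.
#'
#' @param sites Tibble of methylated-site positions: `chrom`, `pos`
#'   (0-based).
#' @param genome A `genome_seq`.
#' @param occupancy An `occupancy_track`; each site takes the value of its
#'   containing window (sites outside the partition are dropped).
#' @param isolation_radius Sites with a neighbour within this distance are
#'   excluded (bp).
#' @param flank,run_min AT-run rule parameters (bp, bases).
#' @param n_boot Bootstrap replicates for the CI.
#' @return List with `groups` (tibble: `has_at_run`, `n`, `mean_signal`),
#'   `difference`, `ci_lower`, `ci_upper`, `n_isolated`.
#' @export
at_flank_analysis <- function(sites, genome, occupancy,
                              isolation_radius = 50L, flank = 13L,
                              run_min = 4L, n_boot = 1000L) {
  iso <- dplyr::bind_rows(lapply(split(sites, sites$chrom), function(s) {
    p <- sort(s$pos)
    gap_ok <- c(TRUE, diff(p) > isolation_radius) &
      c(diff(p) > isolation_radius, TRUE)
    tibble::tibble(chrom = s$chrom[1], pos = p[gap_ok])
  }))
  if (nrow(iso) == 0) stopf("no isolated sites at radius %d", isolation_radius)
  w <- occupancy$end[1] - occupancy$start[1]
  flag <- logical(nrow(iso)); sig <- rep(NA_real_, nrow(iso))
  for (nm in unique(iso$chrom)) {
    sel <- iso$chrom == nm
    flag[sel] <- has_at_run(genome$seq[[nm]], iso$pos[sel], flank, run_min)
    occ <- occupancy[occupancy$chrom == nm, ]
    idx <- iso$pos[sel] %/% w + 1L
    idx[idx > nrow(occ)] <- NA_integer_
    sig[sel] <- occ$log2_ratio[idx]
  }
  keep <- !is.na(sig)
  flag <- flag[keep]; sig <- sig[keep]
  groups <- tibble::tibble(
    has_at_run = c(FALSE, TRUE),
    n = c(sum(!flag), sum(flag)),
    mean_signal = c(mean(sig[!flag]), mean(sig[flag])))
  diff_obs <- groups$mean_signal[2] - groups$mean_signal[1]
  boot <- replicate(n_boot, {
    a <- sig[flag][sample.int(sum(flag), replace = TRUE)]
    b <- sig[!flag][sample.int(sum(!flag), replace = TRUE)]
    mean(a) - mean(b)
  })
  ci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(groups = groups, difference = diff_obs,
       ci_lower = ci[1], ci_upper = ci[2], n_isolated = sum(keep))
}
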