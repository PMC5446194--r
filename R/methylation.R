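#' Classify cytosine contexts on both strands of a genome
#'
#' Emits one record per cytosine: every `C` on the plus strand and every `G`
#' on the plus strand (a `C` on the minus strand). The di-nucleotide context
#' is the cytosine plus the next base read 5'->3' on the cytosine's strand;
#' the tri-nucleotide context adds one more base. Contexts that run past the
#' chromosome end or contain `N` are `NA` at the affected rank (the
#' di-context may be defined while the tri-context is not).
#'
#' @param genome A `genome_seq` object.
#' @return A tibble of site skeletons: `chrom`, `pos` (0-based genome
#'   coordinate of the cytosine's base), `strand`, `di_context`,
#'   `tri_context`.
#' @examples
#' g <- simulate_genome(sim_config(n_chroms = 1, chrom_length = 2000))$genome
#' head(classify_contexts(g))
#' @export
classify_contexts <- function(genome) {
  # integer base codes: A=1 C=2 G=3 T=4, N/other = NA; contexts come from
  # small lookup tables indexed by the codes, avoiding per-site string work
  di_tab <- c("CA", "CC", "CG", "CT")
  tri_tab <- as.vector(outer(di_tab, c("A", "C", "G", "T"), paste0))
  res <- lapply(names(genome$seq), function(nm) {
    s <- genome$seq[[nm]]
    n <- nchar(s)
    code <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
    # plus strand: C at i, context read rightwards
    ip <- which(code == 2L)
    nx1 <- code[ip + 1L]            # out-of-range indexing yields NA
    nx2 <- code[ip + 2L]
    di_p <- di_tab[nx1]
    tri_p <- ifelse(is.na(di_p), NA_character_, tri_tab[(nx2 - 1L) * 4L + nx1])
    # minus strand: G at i is a C on the minus strand; context reads
    # leftwards in plus coordinates, complemented (complement code = 5 - code)
    im <- which(code == 3L)
    pv1 <- rep(NA_integer_, length(im)); ok1 <- im - 1L >= 1L
    pv1[ok1] <- code[im[ok1] - 1L]
    pv2 <- rep(NA_integer_, length(im)); okk <- im - 2L >= 1L
    pv2[okk] <- code[im[okk] - 2L]
    c1 <- 5L - pv1; c2 <- 5L - pv2
    di_m <- di_tab[c1]
    tri_m <- ifelse(is.na(di_m), NA_character_, tri_tab[(c2 - 1L) * 4L + c1])
    pos <- c(ip, im) - 1L
    o <- order(pos)
    tibble::tibble(
      chrom = nm,
      pos = pos[o],
      strand = rep(c("+", "-"), c(length(ip), length(im)))[o],
      di_context = c(di_p, di_m)[o],
      tri_context = c(tri_p, tri_m)[o]
    )
  })
  dplyr::bind_rows(res)
}

#' Attach basecall counts from a cytosine report to site skeletons
#'
#' Joins report counts onto classified sites. Report positions are 1-based
#' (file convention) and are shifted to the internal 0-based convention
#' here. Sites absent from the report are retained with zero coverage and
#' flagged uncovered; report records at positions that are not cytosines in
#' the skeleton set raise an error.
#'
#' @param skeletons Tibble from [classify_contexts()].
#' @param report Tibble from [read_cytosine_report()] (1-based `pos`).
#' @return Tibble of methylation sites: skeleton columns plus
#'   `count_modified`, `count_total`, `level` (`NA` when uncovered) and
#'   `covered`.
#' @export
attach_calls <- function(skeletons, report) {
  rep0 <- dplyr::transmute(report,
    chrom = .data$chrom, pos = .data$pos - 1L, strand = .data$strand,
    count_modified = .data$count_modified,
    count_total = .data$count_modified + .data$count_unmodified)
  key_sk <- paste(skeletons$chrom, skeletons$pos, skeletons$strand)
  key_rp <- paste(rep0$chrom, rep0$pos, rep0$strand)
  missing <- !(key_rp %in% key_sk)
  if (any(missing)) {
    i <- which(missing)[1]
    stopf("report record at %s:%d(%s) is not a cytosine in the genome",
          rep0$chrom[i], rep0$pos[i] + 1L, rep0$strand[i])
  }
  out <- dplyr::left_join(skeletons, rep0, by = c("chrom", "pos", "strand"))
  out$count_modified[is.na(out$count_modified)] <- 0L
  out$count_total[is.na(out$count_total)] <- 0L
  out$covered <- out$count_total > 0L
  out$level <- ifelse(out$covered, out$count_modified / out$count_total, NA_real_)
  out
}

match_context <- function(sites, context) {
  if (nchar(context) == 2) sites$di_context == context
  else sites$tri_context == context
}

#' Region methylation statistics
#'
#' For each region and a cytosine context (di- such as `"CG"` or tri- such
#' as `"CAC"`), computes the covered-site count `N_CX`, the unweighted mean
#' methylation level `m'_CX` and the methylation density
#' `N_CX * m'_CX / L` (stored per bp; also reported per kb, the plotting
#' unit). Regions are 0-based half-open. Sites with zero coverage are
#' excluded.
#'
#' @param sites Methylation site tibble from [attach_calls()] (or a
#'   simulated one), with `level` and `covered`.
#' @param regions Tibble with `chrom`, `start`, `end` (one row per region).
#' @param context Context label, e.g. `"CG"`, `"CA"`, `"CAC"`.
#' @param min_coverage Minimum reads for a site to enter the mean
#'   (default 1).
#' @return Tibble with one row per region: `chrom`, `start`, `end`,
#'   `context`, `n_sites`, `mean_level`, `density` (per bp),
#'   `density_per_kb`.
#' @export
region_methylation <- function(sites, regions, context, min_coverage = 1L) {
  assert_interval_tbl(regions, "regions")
  if (any(regions$end <= regions$start)) stopf("empty region supplied")
  keep <- which(match_context(sites, context) & sites$covered &
                  sites$count_total >= min_coverage)
  sub <- sites[keep, c("chrom", "pos", "level")]
  res <- lapply(split(seq_len(nrow(regions)), regions$chrom), function(ridx) {
    chrom <- regions$chrom[ridx[1]]
    sc <- sub[sub$chrom == chrom, ]
    o <- order(sc$pos)
    pos <- sc$pos[o]; lev <- sc$level[o]
    cslev <- cumsum(c(0, lev))
    lo <- findInterval(regions$start[ridx] - 0.5, pos) + 1L
    hi <- findInterval(regions$end[ridx] - 0.5, pos)
    n <- pmax(hi - lo + 1L, 0L)
    sum_lev <- ifelse(n > 0, cslev[hi + 1L] - cslev[lo], 0)
    L <- regions$end[ridx] - regions$start[ridx]
    tibble::tibble(
      .row = ridx,
      chrom = chrom,
      start = regions$start[ridx], end = regions$end[ridx],
      context = context,
      n_sites = n,
      mean_level = ifelse(n > 0, sum_lev / n, NA_real_),
      density = ifelse(n > 0, sum_lev / L, 0),
      density_per_kb = ifelse(n > 0, sum_lev / L, 0) * 1000
    )
  })
  out <- dplyr::bind_rows(res)
  out <- out[order(out$.row), ]
  out$.row <- NULL
  out
}

#' Genome-wide context frequency and methylation tables
#'
#' Produces the three genome-level summaries: the fraction of all cytosines
#' in each di-nucleotide context; the modified-cytosine context fractions;
#' and the mean methylation level per tri-nucleotide context. Modified
#' fractions default to expected-count weighting (each covered site
#' contributes its level); a binary mode counts sites with level at or
#' above `binary_threshold` instead.
#'
#' @param sites Methylation site tibble (skeletons are enough for
#'   `context_freq`; levels are needed for the other two tables).
#' @param mode `"weighted"` (default) or `"binary"` for the modified-context
#'   table.
#' @param binary_threshold Level cutoff for binary mode.
#' @return List of tibbles `context_freq`, `modified_freq`,
#'   `tri_mean_level`; the fraction column of each frequency table sums
#'   to 1.
#' @export
genome_context_frequencies <- function(sites, mode = c("weighted", "binary"),
                                       binary_threshold = 0.5) {
  mode <- match.arg(mode)
  ok <- !is.na(sites$di_context)
  cf <- dplyr::count(sites[ok, ], .data$di_context, name = "n")
  cf$fraction <- cf$n / sum(cf$n)
  has_level <- "level" %in% names(sites)
  if (has_level) {
    cov <- sites[ok & sites$covered %||% FALSE, ]
    cov$.w <- if (mode == "weighted") cov$level
              else as.numeric(cov$level >= binary_threshold)
    mf <- dplyr::summarise(dplyr::group_by(cov, .data$di_context),
                           weight = sum(.data$.w), .groups = "drop")
    tot <- sum(mf$weight)
    mf$fraction <- if (tot > 0) mf$weight / tot else 0
    tri <- cov[!is.na(cov$tri_context), ]
    tm <- dplyr::summarise(dplyr::group_by(tri, .data$tri_context),
                           n_sites = dplyr::n(),
                           mean_level = mean(.data$level), .groups = "drop")
  } else {
    mf <- tibble::tibble(di_context = character(), weight = double(),
                         fraction = double())
    tm <- tibble::tibble(tri_context = character(), n_sites = integer(),
                         mean_level = double())
  }
  list(context_freq = cf, modified_freq = mf, tri_mean_level = tm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve 5mC and 5hmC from paired bisulfite and TAB measurements
#'
#' Bisulfite sequencing reads 5mC + 5hmC together while TAB sequencing
#' reads 5hmC alone, so true 5mC is the (clamped-at-zero) difference of the
#' two levels at a site. Sites present in `bs` but absent from `tab` get
#' `mc = bs` and `hmc = NA`.
#'
#' @param bs Site tibble with `chrom`, `pos`, `strand`, `level` (BS
#'   channel).
#' @param tab Site tibble with the same identity columns and `level` (TAB
#'   channel), or `NULL` if no TAB data exist.
#' @return Tibble with `chrom`, `pos`, `strand`, `mc_level`, `hmc_level`,
#'   `clamped`; the number of clamp events is attached as attribute
#'   `n_clamped`.
#' @export
resolve_modification_levels <- function(bs, tab = NULL) {
  base <- bs[, c("chrom", "pos", "strand")]
  base$bs_level <- bs$level
  if (is.null(tab) || nrow(tab) == 0) {
    out <- dplyr::mutate(base, mc_level = .data$bs_level, hmc_level = NA_real_,
                         clamped = FALSE)
  } else {
    key_bs <- paste(bs$chrom, bs$pos, bs$strand)
    key_tab <- paste(tab$chrom, tab$pos, tab$strand)
    orphan <- !(key_tab %in% key_bs)
    if (any(orphan)) {
      i <- which(orphan)[1]
      stopf("TAB site %s:%d(%s) has no matching BS site",
            tab$chrom[i], tab$pos[i], tab$strand[i])
    }
    tb <- dplyr::transmute(tab, chrom = .data$chrom, pos = .data$pos,
                           strand = .data$strand, tab_level = .data$level)
    out <- dplyr::left_join(base, tb, by = c("chrom", "pos", "strand"))
    out <- dplyr::mutate(out,
      hmc_level = .data$tab_level,
      clamped = !is.na(.data$tab_level) & .data$bs_level < .data$tab_level,
      mc_level = dplyr::if_else(is.na(.data$tab_level), .data$bs_level,
                                pmax(0, .data$bs_level - .data$tab_level)))
  }
  out <- out[, c("chrom", "pos", "strand", "mc_level", "hmc_level", "clamped")]
  attr(out, "n_clamped") <- sum(out$clamped)
  out
}

#' Estimate the bisulfite non-conversion rate from unmethylated spike-in
#'
#' Pools modified and total basecalls over all covered spike-in sites on an
#' unmethylated control sequence (e.g. lambda phage DNA); the apparent
#' methylation there is the non-conversion rate. An exact binomial 95%
#' confidence interval accompanies the estimate.
#'
#' @param spike Tibble of spike-in sites with `count_modified` and either
#'   `count_total` or `count_unmodified`.
#' @return One-row tibble: `rate`, `ci_lower`, `ci_upper`, `n_sites`,
#'   `total_calls`.
#' @export
estimate_conversion_rate <- function(spike) {
  tot <- if ("count_total" %in% names(spike)) spike$count_total
         else spike$count_modified + spike$count_unmodified
  keep <- tot > 0
  if (sum(tot[keep]) == 0 || !any(keep)) stopf("no covered spike-in sites")
  x <- sum(spike$count_modified[keep])
  n <- sum(tot[keep])
  ci <- binom.test(x, n)$conf.int
  tibble::tibble(rate = x / n, ci_lower = ci[1], ci_upper = ci[2],
                 n_sites = sum(keep), total_calls = n)
}
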