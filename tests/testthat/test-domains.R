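test_that("identical tracks produce no segments at any scale", {
  set.seed(5)
  counts <- rpois(2000, 50)
  cw <- make_coverage_windows(counts, w = 1000)
  segs <- multiscale_segments(cw, cw, scales = 0:6)
  expect_equal(nrow(segs), 0L)
  expect_error(multiscale_segments(cw, cw, scales = integer(0)), "empty")
})

test_that("swapping tracks negates scores and swaps labels", {
  set.seed(9)
  n <- 2000
  lam <- rep(50, n); lam[500:560] <- 100; lam[1200:1400] <- 25
  a <- rpois(n, lam); b <- rpois(n, 50)
  # equalise library sizes so r = 1 exactly
  while (sum(a) != sum(b)) {
    if (sum(a) > sum(b)) b[1] <- b[1] + 1L else a[1] <- a[1] + 1L
  }
  chip <- make_coverage_windows(a, w = 1000)
  input <- make_coverage_windows(b, w = 1000)
  s1 <- multiscale_segments(chip, input, scales = 0:5, pseudocount = 0)
  s2 <- multiscale_segments(input, chip, scales = 0:5, pseudocount = 0)
  expect_equal(nrow(s1), nrow(s2))
  key <- function(s) s[order(s$scale_index, s$start), ]
  s1 <- key(s1); s2 <- key(s2)
  expect_equal(s1$start, s2$start)
  expect_equal(s1$enrichment_score, -s2$enrichment_score)
  expect_equal(s1$label, ifelse(s2$label == "enriched", "depleted", "enriched"))
})

test_that("segments within one scale never overlap", {
  set.seed(13)
  lam <- rep(50, 3000)
  for (a in seq(100, 2800, by = 250)) lam[a:(a + 30)] <- sample(c(80, 30), 1)
  chip <- make_coverage_windows(rpois(3000, lam), w = 1000)
  input <- make_coverage_windows(rpois(3000, 50), w = 1000)
  segs <- multiscale_segments(chip, input, scales = 0:6, p_thresh = 1e-3)
  for (s in unique(segs$scale_index)) {
    ss <- segs[segs$scale_index == s, ]
    ss <- ss[order(ss$start), ]
    if (nrow(ss) > 1) expect_true(all(ss$start[-1] >= ss$end[-nrow(ss)]))
  }
})

test_that("planted enriched and depleted domains are recovered with sign", {
  tr <- make_domain_tracks(seed = 1, fold = 1.5)
  segs <- multiscale_segments(tr$chip, tr$input, scales = 0:7)
  s6 <- segs[segs$scale_bp == 64000 & segs$label == "enriched", ]
  expect_equal(nrow(s6), 1L)
  expect_gte(interval_jaccard(c(s6$start, s6$end), tr$domain), 0.7)

  dep <- make_domain_tracks(seed = 2, fold = 0.5)
  sd6 <- multiscale_segments(dep$chip, dep$input, scales = 0:7)
  sd6 <- sd6[sd6$label == "depleted", ]
  expect_gt(nrow(sd6), 0)
  cover <- any(sd6$start <= dep$domain[1] + 5000 & sd6$end >= dep$domain[2] - 5000)
  expect_true(cover)
  expect_true(all(sd6$enrichment_score < 0))
})

test_that("annotation attaches densities and GC, with additivity", {
  g <- methocc:::new_genome_seq(c(chr1 = strrep("CGTA", 2500)))
  segs <- tibble::tibble(chrom = "chr1", start = c(0L, 5000L), end = c(1000L, 6000L),
                         scale_index = 0L, scale_bp = 1000L,
                         enrichment_score = c(1, -1), p_value = 1e-9,
                         label = c("enriched", "depleted"), n_windows = 1L)
  # fully methylated CG-only methylome in the first segment, nothing elsewhere
  sk <- classify_contexts(g)
  sites <- dplyr::mutate(sk, count_modified = 10L, count_total = 10L,
                         level = ifelse(di_context == "CG" & pos < 1000, 1, 0),
                         covered = TRUE)
  ann <- annotate_segments(segs, sites, g)
  expect_equal(ann$combined_density[1], ann$mcg_density[1])
  expect_gt(ann$mcg_density[1], 0)
  expect_equal(ann$gc_fraction, c(0.5, 0.5))

  uncov <- dplyr::mutate(sites, covered = FALSE, level = NA_real_)
  ann0 <- annotate_segments(segs, uncov, g)
  expect_equal(ann0$mcg_density, c(0, 0))
  expect_equal(ann0$combined_density, c(0, 0))
})

test_that("scale-by-score summary populates only occupied cells", {
  seg1 <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L,
                         scale_index = 3L, scale_bp = 8000L,
                         enrichment_score = 0.7, p_value = 1e-9,
                         label = "enriched", n_windows = 10L)
  s <- scale_score_summary(seg1)
  expect_equal(nrow(s), 1L)
  expect_equal(s$n, 1L)
  expect_equal(s$median_length, 10000)

  segs <- dplyr::bind_rows(seg1, dplyr::mutate(seg1, start = 20000L,
                                               end = 30000L,
                                               enrichment_score = -1.2,
                                               label = "depleted"))
  s2 <- scale_score_summary(segs)
  expect_true(all(s2$median_length == 10000))
  expect_error(scale_score_summary(seg1[0, ]), "no segments")
})

test_that("scale columns track planted domain lengths within a factor 2", {
  # one domain per track: the unpruned caller reports a long domain at many
  # scales, so each planted length is scored at its own nearest scale
  near_median <- function(seed, n_windows, target) {
    tr <- make_domain_tracks(seed = seed, domain_windows = n_windows)
    segs <- multiscale_segments(tr$chip, tr$input, scales = 0:8)
    sc_all <- sort(unique(segs$scale_bp))
    sc <- sc_all[which.min(abs(sc_all - target))]
    ss <- segs[segs$scale_bp == sc & segs$label == "enriched", ]
    median(ss$end - ss$start)
  }
  m20 <- near_median(17, 20L, 2e4)
  expect_gt(m20, 1e4); expect_lt(m20, 4e4)
  m200 <- near_median(18, 200L, 2e5)
  expect_gt(m200, 1e5); expect_lt(m200, 4e5)
})

test_that("CGI overlap statistic hits its bounds on degenerate inputs", {
  cgis <- tibble::tibble(chrom = "chr1", start = c(1000L, 9000L),
                         end = c(1600L, 9600L))
  segs <- tibble::tibble(chrom = "chr1", start = cgis$start, end = cgis$end,
                         scale_index = 0L, scale_bp = 600L,
                         enrichment_score = -2, p_value = 1e-9,
                         label = "depleted", n_windows = 1L)
  g <- methocc:::new_genome_seq(c(chr1 = strrep("A", 100000)))
  ov <- overlap_with_cgis(segs, cgis, g, scale_cutoff_bp = 2000, n_shuffle = 200)
  expect_equal(ov$observed_fraction, 1)
  expect_lte(ov$p_value, 1 / 200 + 1e-9)

  far <- dplyr::mutate(cgis, chrom = "chr9")
  ov0 <- overlap_with_cgis(segs, far, g, scale_cutoff_bp = 2000, n_shuffle = 100)
  expect_equal(ov0$observed_fraction, 0)
  expect_warning(overlap_with_cgis(segs, cgis, g, n_shuffle = 50), "coarse")
})
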