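toy_counts <- function(m, len = 200L) {
  dplyr::bind_cols(tibble::tibble(gene_id = sprintf("g%03d", seq_len(nrow(m))),
                                  length = len),
                   tibble::as_tibble(m))
}

test_that("median-of-ratios size factors match hand calculation and DESeq2", {
  m <- matrix(c(10, 20, 40, 20, 40, 80), ncol = 2,
              dimnames = list(NULL, c("s1", "s2")))
  sf <- size_factors(toy_counts(m))
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-5)

  same <- size_factors(toy_counts(cbind(s1 = c(5, 50, 500), s2 = c(5, 50, 500))))
  expect_equal(same$size_factor, c(1, 1))

  # an all-zero gene is excluded and leaves the result unchanged
  m0 <- rbind(m, c(0, 0))
  expect_equal(size_factors(toy_counts(m0))$size_factor, sf$size_factor)

  skip_if_not_installed("DESeq2")
  set.seed(1)
  big <- matrix(rnbinom(4000, mu = 80, size = 10), ncol = 4,
                dimnames = list(NULL, paste0("s", 1:4)))
  ours <- size_factors(toy_counts(big))$size_factor
  ref <- unname(DESeq2::estimateSizeFactorsForMatrix(big))
  expect_equal(ours, ref, tolerance = 1e-5)
})

test_that("the global-scale correction rescales one condition only", {
  sf <- tibble::tibble(sample = c("WT_1", "KO_1"), size_factor = c(1, 1))
  smp <- tibble::tibble(sample = c("WT_1", "KO_1"), condition = c("WT", "KO"))
  out <- apply_global_scale(sf, smp, "KO", 1.15)
  expect_equal(out$size_factor, c(1, 1.15))
  expect_equal(apply_global_scale(sf, smp, "KO", 1)$size_factor, c(1, 1))
  expect_error(apply_global_scale(sf, smp, "KO", 0), "positive")
})

test_that("the NB test is exact on duplicated groups and scale-invariant", {
  set.seed(4)
  base <- matrix(rnbinom(600 * 3, mu = 100, size = 20), ncol = 3)
  m <- cbind(base, base)
  colnames(m) <- c(paste0("WT_", 1:3), paste0("KO_", 1:3))
  cnt <- toy_counts(m)
  smp <- tibble::tibble(sample = colnames(m),
                        condition = rep(c("WT", "KO"), each = 3))
  unit <- tibble::tibble(sample = colnames(m), size_factor = 1)
  de <- nb_test(cnt, smp, unit)
  expect_true(all(de$log2fc[de$base_mean > 0] == 0))

  # multiplying one sample's counts by c and its factor by c changes nothing
  set.seed(5)
  m2 <- matrix(rnbinom(600 * 6, mu = 200, size = 20), ncol = 6,
               dimnames = list(NULL, colnames(m)))
  c2 <- toy_counts(m2)
  de1 <- nb_test(c2, smp, unit)
  m3 <- m2; m3[, 2] <- m3[, 2] * 3L
  f3 <- dplyr::mutate(unit, size_factor = ifelse(sample == "WT_2", 3, 1))
  de2 <- nb_test(toy_counts(m3), smp, f3)
  expect_equal(de1$log2fc, de2$log2fc, tolerance = 1e-9)
  # p-values may move slightly: the Poisson part of the variance genuinely
  # depends on the rescaled sample's depth
  expect_equal(de1$p_value, de2$p_value, tolerance = 0.05)

  expect_error(nb_test(c2, dplyr::mutate(smp, condition = "WT"), unit),
               "replicates")
})

test_that("BH adjustment is monotone in p-value rank", {
  set.seed(6)
  cfg <- sim_config(seed = 6, coupling_alpha = 0, global_scale_ko = 1,
                    n_genes = 500L)
  ex <- simulate_expression(make_flat_genes(500), list(windows = NULL), cfg)
  de <- nb_test(ex$counts, ex$samples, size_factors(ex$counts))
  ok <- !is.na(de$padj)
  o <- order(de$p_value[ok])
  expect_true(all(diff(de$padj[ok][o]) >= -1e-12))
  expect_true(all(de$padj[ok] >= de$p_value[ok] - 1e-12))
})

test_that("TPM columns sum to one million and drive the low filter", {
  m <- cbind(s1 = c(100L, 300L, 2L), s2 = c(80L, 350L, 1L))
  cnt <- toy_counts(m, len = c(1000L, 3000L, 500L))
  tpm <- compute_tpm(cnt)
  expect_equal(colSums(as.matrix(tpm[, -1])), c(s1 = 1e6, s2 = 1e6),
               tolerance = 1e-6)
})

test_that("gene classes follow the threshold rules and partition the genes", {
  res <- tibble::tibble(
    gene_id = paste0("g", 1:5),
    base_mean = c(50, 40, 30, 20, 10),
    log2fc = c(1.2, -0.8, 0.005, 0.4, 2),
    lfc_se = 0.1, stat = 1,
    p_value = c(1e-4, 1e-3, 0.9, 0.2, 1e-5),
    padj = NA_real_)
  class(res) <- c("nb_de", class(res))
  tpm <- tibble::tibble(gene_id = res$gene_id,
                        s1 = c(50, 20, 9, 7, 3), s2 = c(60, 25, 8, 6, 4))
  cls <- classify_genes(res, tpm)
  expect_equal(as.character(cls$class),
               c("up", "down", "unchanged", "other", "filtered"))
  expect_true(all(table(cls$class) >= 0))
  expect_equal(sum(table(cls$class)), nrow(res))   # exactly one class each
  expect_true(is.na(cls$padj[5]))                  # filtered: no adjustment
})

test_that("gene occupancy averages the track with clipping flags", {
  tr <- log2_ratio(make_coverage_windows(rep(8L, 50), w = 1000),
                   make_coverage_windows(rep(8L, 50), w = 1000))
  tr$log2_ratio <- 1.5                      # uniform value
  genes <- tibble::tibble(chrom = "chr1", start = c(0L, 20000L),
                          end = c(4000L, 30000L), gene_id = c("gA", "gB"))
  go <- gene_occupancy(genes, tr, flank = 10000)
  expect_equal(go$occupancy_body, c(1.5, 1.5))
  expect_equal(go$occupancy_flanked, c(1.5, 1.5))
  expect_equal(go$clipped, c(TRUE, FALSE))

  # non-uniform check against a direct weighted mean
  set.seed(2)
  tr$log2_ratio <- rnorm(50)
  go2 <- gene_occupancy(tibble::tibble(chrom = "chr1", start = 1500L,
                                       end = 3500L, gene_id = "gC"), tr,
                        flank = 0)
  manual <- (0.5 * tr$log2_ratio[2] + tr$log2_ratio[3] +
               0.5 * tr$log2_ratio[4]) / 2
  expect_equal(go2$occupancy_body, manual, tolerance = 1e-12)
})

test_that("rolling and grouped curves obey their counting rules", {
  d <- tibble::tibble(occ = c(2, 1, 3), dens = c(2, 1, 3))
  rc <- rolling_density(d, occ, dens, window = 2, step = 1)
  expect_equal(rc$mean_value, c(1.5, 2.5))

  d480 <- tibble::tibble(occ = rnorm(480), dens = rnorm(480))
  expect_equal(nrow(rolling_density(d480, occ, dens)), 2L)
  expect_error(rolling_density(d480[1:100, ], occ, dens), "at least")

  dc <- tibble::tibble(occ = rnorm(500), dens = 7)
  expect_true(all(rolling_density(dc, occ, dens, 100, 50)$mean_value == 7))

  w <- tibble::tibble(occ = rnorm(2500), dens = rnorm(2500))
  expect_equal(nrow(window_group_curve(w, occ, dens, group = 1000)), 2L)
  ident <- window_group_curve(d, occ, dens, group = 1)
  expect_equal(ident$mean_value, sort(d$dens))
})

test_that("grouped density rises with occupancy under planted coupling", {
  cfg <- sim_config(seed = 19, n_chroms = 1L, chrom_length = 2e6,
                    cgi_count = 20L, domain_length_range = c(5e4, 1e5),
                    beta_occupancy = 0.15, coverage_depth = 100)
  gs <- simulate_genome(cfg)
  ms <- simulate_methylome(gs$genome, gs$cgis, gs$truth, cfg)
  ch <- simulate_chip_experiment(gs$genome, ms, gs$truth, cfg)
  cw <- bin_coverage(ch$chip, gs$genome, 1000, 67)
  iw <- bin_coverage(ch$input, gs$genome, 1000, 67)
  occ <- log2_ratio(cw, iw)
  dens <- region_methylation(ms, occ[, c("chrom", "start", "end")], "CG")$density_per_kb +
    region_methylation(ms, occ[, c("chrom", "start", "end")], "CAC")$density_per_kb
  curve <- window_group_curve(tibble::tibble(occ = occ$log2_ratio, dens = dens),
                              occ, dens, group = 200)
  expect_gt(cor(curve$group, curve$mean_value, method = "spearman"), 0.8)
})

test_that("domain overlap categorises containment and partial overlap", {
  segs <- tibble::tibble(chrom = "chr1", start = c(1000L, 8000L),
                         end = c(5000L, 12000L),
                         label = c("enriched", "depleted"))
  genes <- tibble::tibble(
    gene_id = c("in_e", "strad", "in_d", "none"),
    chrom = "chr1",
    start = c(2000L, 4000L, 9000L, 20000L),
    end = c(3000L, 6000L, 10000L, 21000L),
    class = factor(c("up", "up", "down", "unchanged"),
                   levels = c("up", "down", "unchanged", "other", "filtered")))
  ov <- domain_overlap(genes, segs)
  got <- setNames(as.character(ov$assignments$category), ov$assignments$gene_id)
  expect_equal(unname(got["in_e"]), "inside_enriched")
  expect_equal(unname(got["strad"]), "overlapping_enriched")
  expect_equal(unname(got["in_d"]), "inside_depleted")
  expect_equal(unname(got["none"]), "neither")
  pr <- ov$proportions
  up_tot <- sum(pr$proportion[pr$class == "up"])
  expect_equal(up_tot, 1)
})

test_that("occupancy-expression statistics recover rank correlations", {
  go <- tibble::tibble(gene_id = paste0("g", 1:3),
                       occupancy_flanked = c(1, 2, 3))
  mk <- function(lfc) {
    r <- tibble::tibble(gene_id = paste0("g", 1:3), base_mean = 10,
                        log2fc = lfc, lfc_se = 0.1, stat = 1,
                        p_value = 0.5, padj = 0.5,
                        class = factor("unchanged",
                                       levels = c("up", "down", "unchanged",
                                                  "other", "filtered")))
    class(r) <- c("nb_de", class(r)); r
  }
  expect_error(occupancy_expression_stats(go, mk(c(1, 2, 3))), "at least 10")

  go10 <- tibble::tibble(gene_id = paste0("g", 1:10),
                         occupancy_flanked = 1:10)
  r10 <- mk(c(1, 2, 3))[rep(1, 10), ]
  r10$gene_id <- paste0("g", 1:10)
  r10$log2fc <- (1:10) / 10
  st <- occupancy_expression_stats(go10, r10)
  expect_equal(st$rho_ko, 1)

  # worked rank example: occupancies (1,2,3), log2FC (0.3, 0.1, 0.2) -> -0.5
  expect_equal(cor(c(1, 2, 3), c(0.3, 0.1, 0.2), method = "spearman"), -0.5)
  r10$log2fc <- rep(c(0.3, 0.1, 0.2), length.out = 10)
  st2 <- occupancy_expression_stats(go10[1:10, ], r10)
  expect_true(is.list(st2))
})
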