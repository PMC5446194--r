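test_that("context classification reads di/tri contexts off both strands", {
  g <- methocc:::new_genome_seq(c(chr1 = "ACACG"))
  sk <- classify_contexts(g)
  plus <- sk[sk$strand == "+", ]
  expect_equal(plus$pos, c(1L, 3L))
  expect_equal(plus$di_context, c("CA", "CG"))
  expect_equal(plus$tri_context, c("CAC", NA))

  g2 <- methocc:::new_genome_seq(c(chr1 = "ACGT"))
  sk2 <- classify_contexts(g2)
  expect_equal(nrow(sk2), 2L)             # palindromic CG: one site per strand
  expect_equal(sort(sk2$di_context), c("CG", "CG"))

  # N interrupts the affected rank only
  g3 <- methocc:::new_genome_seq(c(chr1 = "CANG"))
  sk3 <- classify_contexts(g3)
  p0 <- sk3[sk3$pos == 0L & sk3$strand == "+", ]
  expect_equal(p0$di_context, "CA")
  expect_true(is.na(p0$tri_context))
})

test_that("context multiset is invariant under reverse complement", {
  skip_if_not_installed("Biostrings")
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    a <- classify_contexts(methocc:::new_genome_seq(c(x = s)))
    b <- classify_contexts(methocc:::new_genome_seq(c(x = rc)))
    expect_equal(sort(table(a$di_context)), sort(table(b$di_context)))
    expect_equal(sort(table(a$tri_context)), sort(table(b$tri_context)))
    # strand closure: + strand contexts of s equal - strand contexts of rc
    expect_equal(table(a$di_context[a$strand == "+"]),
                 table(b$di_context[b$strand == "-"]))
  }
})

test_that("attach_calls joins counts, flags uncovered, rejects non-cytosines", {
  g <- methocc:::new_genome_seq(c(chr1 = "ACACG"))
  sk <- classify_contexts(g)
  rp <- tibble::tibble(chrom = "chr1", pos = 2L, strand = "+",   # 1-based
                       count_modified = 3L, count_unmodified = 1L,
                       di_context = "CA", tri_context = "CAC")
  sites <- attach_calls(sk, rp)
  hit <- sites[sites$pos == 1L & sites$strand == "+", ]
  expect_equal(hit$level, 0.75)
  expect_true(all(!sites$covered[sites$pos != 1L]))
  expect_true(all(is.na(sites$level[!sites$covered])))

  bad <- dplyr::mutate(rp, pos = 1L)       # position 0 is an A
  expect_error(attach_calls(sk, bad), "not a cytosine")
})

test_that("region methylation matches the brute-force oracle", {
  # worked example: L=1000, 4 CAC sites with levels 0.5, 1, 0, 0.5
  sites <- tibble::tibble(chrom = "chr1", pos = c(10L, 200L, 500L, 900L),
                          strand = "+", di_context = "CA", tri_context = "CAC",
                          count_modified = 1L, count_total = 2L,
                          level = c(0.5, 1, 0, 0.5), covered = TRUE)
  rm <- region_methylation(sites, tibble::tibble(chrom = "chr1", start = 0L,
                                                 end = 1000L), "CAC")
  expect_equal(rm$n_sites, 4L)
  expect_equal(rm$mean_level, 0.5)
  expect_equal(rm$density_per_kb, 2.0)

  # all levels 1: density per kb = N / L * 1000
  s7 <- dplyr::mutate(sites[rep(1, 7), ], pos = as.integer(seq(0, 600, 100)),
                      level = 1)
  rm7 <- region_methylation(s7, tibble::tibble(chrom = "chr1", start = 0L,
                                               end = 700L), "CAC")
  expect_equal(rm7$density_per_kb, 10)

  # empty context: density 0, mean NA
  rm0 <- region_methylation(sites, tibble::tibble(chrom = "chr1", start = 0L,
                                                  end = 1000L), "CG")
  expect_equal(rm0$density, 0)
  expect_true(is.na(rm0$mean_level))

  expect_error(region_methylation(sites,
    tibble::tibble(chrom = "chr1", start = 5L, end = 5L), "CAC"))

  # randomised oracle: brute-force per-site loop, 200 (region, context) pairs
  set.seed(42)
  cfg <- sim_config(seed = 8, n_chroms = 1L, chrom_length = 20000,
                    cgi_count = 2L, domain_length_range = c(5e3, 1e4))
  gs <- simulate_genome(cfg)
  ms <- simulate_methylome(gs$genome, gs$cgis, gs$truth, cfg)
  for (i in 1:200) {
    a <- sample.int(19000, 1)
    b <- a + sample.int(900, 1)
    ctx <- sample(c("CG", "CA", "CC", "CT", "CAC", "CAG", "CTC"), 1)
    got <- region_methylation(ms, tibble::tibble(chrom = "chr1", start = a,
                                                 end = b), ctx)
    inr <- ms$covered & ms$pos >= a & ms$pos < b &
      (if (nchar(ctx) == 2) ms$di_context else ms$tri_context) %in% ctx
    n <- sum(inr)
    expect_equal(got$n_sites, n)
    if (n > 0) {
      expect_equal(got$mean_level, sum(ms$level[inr]) / n, tolerance = 1e-12)
      expect_equal(got$density, sum(ms$level[inr]) / (b - a), tolerance = 1e-12)
      expect_lte(got$density, n / (b - a) + 1e-12)
    } else {
      expect_equal(got$density, 0)
    }
  }
})

test_that("genome context frequency tables are consistent", {
  g <- methocc:::new_genome_seq(c(chr1 = "ACGT"))
  sk <- classify_contexts(g)
  cf <- genome_context_frequencies(sk)$context_freq
  expect_equal(cf$di_context, "CG")
  expect_equal(cf$fraction, 1)

  sites <- dplyr::mutate(sk, count_modified = 0L, count_total = 10L,
                         level = 0, covered = TRUE)
  tabs <- genome_context_frequencies(sites)
  expect_true(all(tabs$modified_freq$weight == 0))
  expect_true(all(tabs$tri_mean_level$mean_level == 0))

  # fractions sum to one on a simulated methylome, and CAC leads the CAX/CCX/CTX set
  cfg <- sim_config(seed = 3, n_chroms = 1L, chrom_length = 3e5,
                    cgi_count = 5L, domain_length_range = c(5e4, 1e5))
  gs <- simulate_genome(cfg)
  ms <- simulate_methylome(gs$genome, gs$cgis, gs$truth, cfg)
  tabs <- genome_context_frequencies(ms)
  expect_equal(sum(tabs$context_freq$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(tabs$modified_freq$fraction), 1, tolerance = 1e-9)
  tri <- tabs$tri_mean_level
  ch <- tri[substr(tri$tri_context, 2, 2) != "G", ]
  expect_equal(ch$tri_context[which.max(ch$mean_level)], "CAC")
})

test_that("BS/TAB subtraction resolves mC and hmC with clamping", {
  bs <- tibble::tibble(chrom = "chr1", pos = c(1L, 2L, 3L), strand = "+",
                       level = c(0.8, 0.2, 0.6))
  tab <- tibble::tibble(chrom = "chr1", pos = c(1L, 2L), strand = "+",
                        level = c(0.3, 0.3))
  res <- resolve_modification_levels(bs, tab)
  expect_equal(res$mc_level, c(0.5, 0.0, 0.6))
  expect_equal(res$hmc_level, c(0.3, 0.3, NA))
  expect_equal(res$clamped, c(FALSE, TRUE, FALSE))
  expect_equal(attr(res, "n_clamped"), 1L)

  res2 <- resolve_modification_levels(bs, NULL)
  expect_equal(res2$mc_level, bs$level)
  expect_true(all(is.na(res2$hmc_level)))

  orphan <- tibble::tibble(chrom = "chr1", pos = 99L, strand = "+", level = 0.1)
  expect_error(resolve_modification_levels(bs, orphan), "no matching")
})

test_that("spike-in conversion-rate estimate pools calls with exact CI", {
  spike <- tibble::tibble(count_modified = c(3L, 2L), count_total = c(600L, 400L))
  est <- estimate_conversion_rate(spike)
  expect_equal(est$rate, 0.005)
  expect_equal(est$total_calls, 1000L)

  zero <- tibble::tibble(count_modified = 0L, count_total = 0L)
  expect_error(estimate_conversion_rate(zero))

  none <- tibble::tibble(count_modified = 0L, count_total = 1000L)
  est0 <- estimate_conversion_rate(none)
  expect_equal(est0$rate, 0)
  # exact binomial upper bound sits at the rule-of-three scale (~3/n)
  expect_gt(est0$ci_upper, 0.003)
  expect_lt(est0$ci_upper, 0.004)
})
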