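# shared fixture builders; everything is generated in code at test time

# wrap a count vector into a coverage_windows tibble on one chromosome
make_coverage_windows <- function(counts, w = 1000L, chrom = "chr1") {
  n <- length(counts)
  tb <- tibble::tibble(chrom = chrom, start = (seq_len(n) - 1L) * w,
                       end = seq_len(n) * w, count = as.integer(counts),
                       rpkm = counts / (sum(counts) / 1e6) / (w / 1e3))
  attr(tb, "library_size") <- sum(counts)
  attr(tb, "window") <- as.integer(w)
  attr(tb, "shift") <- 0L
  class(tb) <- c("coverage_windows", class(tb))
  tb
}

# flat gene table for expression-only simulations
make_flat_genes <- function(n, len = 200L) {
  tibble::tibble(chrom = "chr1", start = 0L, end = len,
                 gene_id = sprintf("g%05d", seq_len(n)),
                 score = 0, strand = "+", length = len)
}

# methylome with dense planted mCAC clusters (CAC-repeat motifs) plus a
# ChIP/Input pair enriched over the clusters, for summit-locality checks
make_summit_fixture <- function(seed, n_clusters = 80L, chrom_length = 1e6,
                                bg_level = 0.08, cluster_level = 0.9,
                                w = 20L, input_lambda = 2, fold = 6) {
  set.seed(seed)
  cfg <- sim_config(seed = seed, n_chroms = 1L, chrom_length = chrom_length,
                    cgi_count = 0L, domain_length_range = c(5e4, 1e5))
  gs <- simulate_genome(cfg)
  centers <- as.integer(seq(10000, chrom_length - 10000, length.out = n_clusters))
  s <- gs$genome$seq[["chr1"]]
  for (c0 in centers) stringi::stri_sub(s, c0 - 20, c0 + 21) <- strrep("CAC", 14)
  genome <- methocc:::new_genome_seq(c(chr1 = s))
  sk <- classify_contexts(genome)
  clust <- tibble::tibble(chrom = "chr1", start = centers - 21L, end = centers + 21L)
  p <- rep(0.001, nrow(sk))
  cac <- which(sk$tri_context == "CAC")
  p[cac] <- bg_level
  incl <- methocc:::in_intervals(sk$chrom[cac], sk$pos[cac], clust)
  p[cac[incl]] <- cluster_level
  depth <- rpois(nrow(sk), 30)
  mod <- rbinom(nrow(sk), depth, p)
  sites <- sk
  sites$count_modified <- mod
  sites$count_total <- depth
  sites$covered <- depth > 0
  sites$level <- ifelse(depth > 0, mod / depth, NA_real_)
  n_win <- as.integer(chrom_length %/% w)
  wst <- (seq_len(n_win) - 1L) * w
  enr <- tibble::tibble(chrom = "chr1", start = centers - 50L, end = centers + 50L)
  in_cl <- methocc:::in_intervals(rep("chr1", n_win), wst + w %/% 2L, enr)
  chip <- make_coverage_windows(rpois(n_win, ifelse(in_cl, fold * input_lambda,
                                                    input_lambda)), w = w)
  input <- make_coverage_windows(rpois(n_win, input_lambda), w = w)
  list(genome = genome, sites = sites, chip = chip, input = input,
       centers = centers, clusters = clust)
}

# ChIP/Input window pair with one planted fold-change domain, Poisson counts
make_domain_tracks <- function(seed, n_win = 5000L, w = 1000L, depth = 100,
                               domain_windows = 50L, fold = 1.5) {
  set.seed(seed)
  a <- sample.int(n_win - domain_windows, 1L)
  lam_chip <- rep(depth, n_win)
  lam_chip[a:(a + domain_windows - 1L)] <- depth * fold
  list(chip = make_coverage_windows(rpois(n_win, lam_chip), w = w),
       input = make_coverage_windows(rpois(n_win, depth), w = w),
       domain = c((a - 1L) * w, (a - 1L + domain_windows) * w))
}

# base-pair Jaccard of two intervals given as c(start, end)
interval_jaccard <- function(x, y) {
  inter <- max(0, min(x[2], y[2]) - max(x[1], y[1]))
  inter / ((x[2] - x[1]) + (y[2] - y[1]) - inter)
}
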