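#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the generative model with defaults at "desk
#' scale" (two 5 Mb chromosomes). The generator emulates a CG-depleted
#' genome with unmethylated CpG islands, high mCG outside islands,
#' domain-structured mCAC, Input coverage with a GC composition bias, ChIP
#' coverage coupled to the combined mCG+mCAC density, and negative-binomial
#' expression counts whose knockout fold changes couple to occupancy on top
#' of a global 0.85 library-scale effect.
#'
#' @param seed Integer seed; every stage derives its stream from it.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param cgi_count,cgi_length CpG islands planted per chromosome and their
#'   length (bp).
#' @param domain_length_range Range (bp) of planted mCAC domain lengths.
#' @param frac_high_domains Fraction of domains labelled high-mCAC.
#' @param mcg_level_out,mcg_level_cgi Mean CG methylation outside/inside
#'   CpG islands.
#' @param mcac_level_high,mcac_level_low Mean CAC methylation in high/low
#'   domains (defaults give a genome mean near the ~12% seen in neurons).
#' @param other_ch_level Mean methylation at remaining CH contexts.
#' @param nonconversion Global bisulfite non-conversion rate.
#' @param read_depth Mean per-site basecall depth (Poisson).
#' @param coverage_depth Mean fragments per window in the Input library.
#' @param chip_window Window width (bp) at which ChIP/Input intensities are
#'   defined.
#' @param gc_bias_strength Logistic slope of the Input composition bias on
#'   window GC fraction (0 = unbiased).
#' @param beta_occupancy ChIP log-intensity units per combined
#'   (mCG+mCAC) site density (sites per kb).
#' @param fragment_length Fixed fragment length (bp) for simulated reads.
#' @param global_scale_ko Global multiplier on all KO expression means
#'   (default 0.85: total RNA per cell 15% lower than WT).
#' @param n_genes Number of genes to place.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene length
#'   parameters.
#' @param nb_dispersion Negative-binomial dispersion of counts.
#' @param coupling_alpha log2 fold change per occupancy unit for coupled
#'   genes.
#' @param frac_coupled_genes Fraction of genes whose fold change couples to
#'   occupancy.
#' @param n_replicates Replicates per condition (WT, KO, OE).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline expression.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length = 5e6,
                       cgi_count = 50L, cgi_length = 1000L,
                       domain_length_range = c(5e4, 2e5),
                       frac_high_domains = 0.5,
                       mcg_level_out = 0.8, mcg_level_cgi = 0.05,
                       mcac_level_high = 0.2, mcac_level_low = 0.05,
                       other_ch_level = 0.01,
                       nonconversion = 0.005,
                       read_depth = 30,
                       coverage_depth = 50,
                       chip_window = 1000L,
                       gc_bias_strength = 2,
                       beta_occupancy = 0.15,
                       fragment_length = 134L,
                       global_scale_ko = 0.85,
                       n_genes = 2000L,
                       gene_length_meanlog = log(5e3), gene_length_sdlog = 0.5,
                       nb_dispersion = 0.05,
                       coupling_alpha = 1.0,
                       frac_coupled_genes = 0.5,
                       n_replicates = 3L,
                       baseline_meanlog = log(200), baseline_sdlog = 1) {
  cfg <- as.list(environment())
  fr <- c(cfg$frac_high_domains, cfg$mcg_level_out, cfg$mcg_level_cgi,
          cfg$mcac_level_high, cfg$mcac_level_low, cfg$other_ch_level,
          cfg$nonconversion, cfg$frac_coupled_genes)
  if (any(fr < 0 | fr > 1)) stopf("fractions must lie in [0, 1]")
  if (cfg$chrom_length <= 0 || cfg$cgi_length <= 0 || cfg$chip_window <= 0) {
    stopf("lengths must be positive")
  }
  if (cfg$chrom_length < max(cfg$domain_length_range)) {
    stopf("chrom_length must be at least the maximum domain length")
  }
  if (cfg$coverage_depth <= 0) stopf("coverage_depth must be positive")
  if (cfg$global_scale_ko <= 0) stopf("global_scale_ko must be positive")
  structure(cfg, class = "sim_config")
}

# stage-offset seeding: each generator stage has its own stream so changing
# one stage's parameters does not perturb the others
stage_seed <- function(config, stage) {
  set.seed((config$seed + 7919L * stage) %% .Machine$integer.max)
}

# membership of positions in a set of disjoint intervals (single chromosome)
in_intervals_1 <- function(pos, starts, ends) {
  if (length(starts) == 0) return(rep(FALSE, length(pos)))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  i <- findInterval(pos, starts)
  i > 0 & pos < ends[pmax(i, 1L)]
}

# membership for a tibble of positions against a tibble of intervals
in_intervals <- function(chrom, pos, intervals) {
  out <- rep(FALSE, length(pos))
  for (cn in unique(intervals$chrom)) {
    sel <- chrom == cn
    if (!any(sel)) next
    iv <- intervals[intervals$chrom == cn, ]
    out[sel] <- in_intervals_1(pos[sel], iv$start, iv$end)
  }
  out
}

#' Simulate a CG-depleted genome with CpG islands and planted domains
#'
#' Draws i.i.d. bases, plants GC-rich CpG islands (one per equal-width
#' slot, so islands never overlap), suppresses CG dinucleotides outside the
#' islands to emulate genome-wide CG depletion, and tiles each chromosome
#' with high/low mCAC domains drawn from `domain_length_range`.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (`genome_seq`), `cgis` (interval tibble) and
#'   `truth` (list carrying the `domains` tibble with `label` high/low).
#' @export
simulate_genome <- function(config) {
  stage_seed(config, 1L)
  bases <- c("A", "C", "G", "T")
  base_probs <- c(0.3, 0.2, 0.2, 0.3)
  # CGI composition mirrors real islands: ~65% GC with CpG obs/exp ~0.65
  # (below), rather than maximal CG density
  cgi_probs <- c(0.175, 0.325, 0.325, 0.175)
  draw_codes <- function(n, probs) {
    findInterval(runif(n), cumsum(probs)[-4]) + 1L
  }
  seqs <- character(config$n_chroms)
  cgis <- list(); domains <- list()
  for (k in seq_len(config$n_chroms)) {
    n <- as.integer(config$chrom_length)
    b <- draw_codes(n, base_probs)        # A=1 C=2 G=3 T=4
    # CpG islands: one per slot
    cg_start <- integer(0)
    if (config$cgi_count > 0) {
      slot <- n %/% config$cgi_count
      if (slot <= config$cgi_length) stopf("too many CGIs for the chromosome length")
      off <- sample.int(slot - config$cgi_length, config$cgi_count, replace = TRUE)
      cg_start <- (seq_len(config$cgi_count) - 1L) * slot + off
      for (s in cg_start) {
        b[(s + 1L):(s + config$cgi_length)] <- draw_codes(config$cgi_length, cgi_probs)
      }
    }
    # CG dinucleotide suppression: strong outside islands (genome-wide CG
    # depletion), mild inside (CpG obs/exp ~0.65 in real islands)
    in_cgi <- rep(FALSE, n)
    for (s in cg_start) in_cgi[(s + 1L):(s + config$cgi_length)] <- TRUE
    is_cg <- which(b[-n] == 2L & b[-1L] == 3L)
    inside <- in_cgi[is_cg] | in_cgi[is_cg + 1L]
    p_sup <- ifelse(inside, 0.35, 0.8)
    hit <- is_cg[runif(length(is_cg)) < p_sup]
    if (length(hit) > 0) {
      b[hit + 1L] <- c(1L, 4L)[1L + (runif(length(hit)) < 0.5)]
    }
    seqs[k] <- stringi::stri_flatten(bases[b])
    nm <- paste0("chr", k)
    if (length(cg_start) > 0) {
      cgis[[k]] <- tibble::tibble(chrom = nm, start = cg_start,
                                  end = cg_start + config$cgi_length)
    }
    # domain tiling
    lens <- integer(0)
    while (sum(lens) < n) {
      lens <- c(lens, sample.int(diff(config$domain_length_range) + 1L,
                                 1L) + config$domain_length_range[1] - 1L)
    }
    ends <- pmin(cumsum(lens), n)
    starts <- c(0L, head(ends, -1L))
    keep <- starts < ends
    domains[[k]] <- tibble::tibble(
      chrom = nm, start = as.integer(starts[keep]), end = as.integer(ends[keep]),
      label = ifelse(runif(sum(keep)) < config$frac_high_domains, "high", "low"))
  }
  genome <- new_genome_seq(setNames(seqs, paste0("chr", seq_len(config$n_chroms))))
  list(genome = genome,
       cgis = dplyr::bind_rows(cgis),
       truth = list(domains = dplyr::bind_rows(domains)))
}

#' Simulate a bisulfite (and optionally TAB) methylome
#'
#' Assigns each cytosine a true methylation probability by context and
#' compartment -- CG sites use the island/non-island levels, CAC sites the
#' high/low domain levels, other CH contexts a near-zero background -- then
#' draws Poisson per-site depths and binomial modified-basecall counts,
#' with a global non-conversion floor.
#'
#' @param genome A `genome_seq`.
#' @param cgis CpG-island interval tibble.
#' @param truth Truth list from [simulate_genome()] (needs `domains`).
#' @param config A [sim_config()].
#' @param tab Also draw an independent TAB (hmC-only) channel? If `TRUE`,
#'   hmC truth is a low level at CG sites.
#' @return A methylation site tibble (as from [attach_calls()]) with an
#'   extra `true_level` column; if `tab = TRUE`, a list with elements `bs`
#'   and `tab`.
#' @export
simulate_methylome <- function(genome, cgis, truth, config, tab = FALSE) {
  sk <- classify_contexts(genome)
  stage_seed(config, 2L)
  p <- rep(config$other_ch_level, nrow(sk))
  is_cg <- which(sk$di_context == "CG")
  in_cgi <- if (!is.null(cgis) && nrow(cgis) > 0) {
    in_intervals(sk$chrom[is_cg], sk$pos[is_cg], cgis)
  } else rep(FALSE, length(is_cg))
  p[is_cg] <- config$mcg_level_out
  p[is_cg[in_cgi]] <- config$mcg_level_cgi
  is_cac <- which(sk$tri_context == "CAC")
  high <- in_intervals(sk$chrom[is_cac], sk$pos[is_cac],
                       truth$domains[truth$domains$label == "high", ])
  p[is_cac] <- config$mcac_level_low
  p[is_cac[high]] <- config$mcac_level_high
  draw_channel <- function(prob) {
    depth <- rpois(nrow(sk), config$read_depth)
    p_eff <- config$nonconversion + (1 - config$nonconversion) * prob
    mod <- rbinom(nrow(sk), depth, p_eff)
    lev <- mod / depth
    lev[depth == 0L] <- NA_real_
    out <- sk
    out$count_modified <- mod
    out$count_total <- depth
    out$covered <- depth > 0L
    out$level <- lev
    out$true_level <- prob
    out
  }
  bs <- draw_channel(p)
  if (!tab) return(bs)
  p_h <- ifelse(is_cg, 0.05, 0.005)
  list(bs = bs, tab = draw_channel(p_h))
}

# expected window-level intensities shared by the ChIP generator and the
# expression truth: returns windows with gc fraction, combined true
# methylation density (per kb) and Input/ChIP Poisson intensities
expected_window_intensities <- function(genome, methylome, config) {
  w <- as.integer(config$chip_window)
  res <- lapply(names(genome$seq), function(nm) {
    n_win <- as.integer(genome$lengths[[nm]] %/% w)
    if (n_win == 0) return(NULL)
    m <- methylome[methylome$chrom == nm, ]
    widx <- m$pos %/% w + 1L
    keep <- widx <= n_win
    cg_gc <- tabulate(widx[keep], nbins = n_win)     # every site is a C or G base
    rel <- keep & (!is.na(m$di_context) & m$di_context == "CG" |
                     !is.na(m$tri_context) & m$tri_context == "CAC")
    dens <- numeric(n_win)
    agg <- rowsum(m$true_level[rel], widx[rel])
    dens[as.integer(rownames(agg))] <- agg[, 1]
    tibble::tibble(chrom = nm,
                   start = (seq_len(n_win) - 1L) * w,
                   end = seq_len(n_win) * w,
                   gc_fraction = cg_gc / w,
                   density_per_kb = dens / w * 1000)
  })
  win <- dplyr::bind_rows(res)
  gbar <- mean(win$gc_fraction)
  bias <- stats::plogis(config$gc_bias_strength * (win$gc_fraction - gbar))
  bias <- bias / mean(bias)
  win$input_intensity <- config$coverage_depth * bias
  dbar <- mean(win$density_per_kb)
  win$chip_intensity <- win$input_intensity *
    exp(config$beta_occupancy * (win$density_per_kb - dbar))
  win
}

#' Simulate a ChIP/Input fragment experiment
#'
#' Window-level Input intensity is the mean depth modulated by a logistic
#' composition bias on GC fraction; ChIP intensity multiplies it by
#' `exp(beta_occupancy * (combined mCG+mCAC density - genome mean))`.
#' Fragment counts per window are Poisson; each fragment is a fixed-length
#' interval whose shifted 5' position falls uniformly in its window, so
#' that [bin_coverage()] with `shift = fragment_length/2` reassigns it
#' exactly.
#'
#' @param genome A `genome_seq`.
#' @param methylome Site tibble from [simulate_methylome()] (needs
#'   `true_level`).
#' @param truth Truth list (augmented and returned).
#' @param config A [sim_config()].
#' @return List with `chip` and `input` fragment tibbles (`chrom`, `start`,
#'   `end`, `strand`), `windows` (expected intensities) and `truth`
#'   (with `fragment_length`, `shift`, `windows` recorded).
#' @export
simulate_chip_experiment <- function(genome, methylome, truth, config) {
  win <- expected_window_intensities(genome, methylome, config)
  stage_seed(config, 3L)
  shift <- as.integer(config$fragment_length %/% 2L)
  flen <- as.integer(config$fragment_length)
  draw_track <- function(intensity) {
    counts <- rpois(nrow(win), intensity)
    idx <- rep.int(seq_len(nrow(win)), counts)
    anchor <- win$start[idx] + floor(runif(length(idx)) * (win$end[idx] - win$start[idx]))
    strand <- ifelse(runif(length(idx)) < 0.5, "+", "-")
    start <- ifelse(strand == "+", anchor - shift, anchor + shift - flen + 1L)
    tibble::tibble(chrom = win$chrom[idx],
                   start = as.integer(start),
                   end = as.integer(start + flen),
                   strand = strand)
  }
  truth$windows <- win
  truth$fragment_length <- flen
  truth$shift <- shift
  list(chip = draw_track(win$chip_intensity),
       input = draw_track(win$input_intensity),
       windows = win, truth = truth)
}

#' Place genes on a simulated genome
#'
#' Gene lengths are log-normal; starts are uniform with the whole body kept
#' inside its chromosome. Strand is random. Genes carry their full span as
#' exonic length (the generator does not model introns).
#'
#' @param genome A `genome_seq`.
#' @param config A [sim_config()].
#' @return Interval tibble with `gene_id`, `strand` and `length`.
#' @export
simulate_genes <- function(genome, config) {
  stage_seed(config, 4L)
  chroms <- names(genome$seq)
  lens <- as.numeric(genome$lengths[chroms])
  chrom <- sample(chroms, config$n_genes, replace = TRUE, prob = lens / sum(lens))
  glen <- pmax(200L, as.integer(round(stats::rlnorm(
    config$n_genes, config$gene_length_meanlog, config$gene_length_sdlog))))
  max_start <- lens[match(chrom, chroms)] - glen
  if (any(max_start < 1)) stopf("gene longer than its chromosome; reduce lengths")
  start <- as.integer(floor(runif(config$n_genes) * max_start))
  tibble::tibble(chrom = chrom, start = start, end = start + glen,
                 gene_id = sprintf("gene%05d", seq_len(config$n_genes)),
                 score = 0, strand = sample(c("+", "-"), config$n_genes, TRUE),
                 length = glen)
}

#' Simulate WT/KO/OE expression counts coupled to occupancy
#'
#' Baseline expression is log-normal. For a coupled fraction of genes the
#' knockout log2 fold change equals `coupling_alpha` times the gene's true
#' occupancy (mean expected log2 ChIP/Input over the gene body), and the
#' overexpression fold change is its negative. All KO expectations are then
#' multiplied by `global_scale_ko` (default 0.85, the global RNA
#' reduction), and counts are drawn negative-binomial.
#'
#' @param genes Gene tibble from [simulate_genes()].
#' @param truth Truth list carrying `windows` (from
#'   [simulate_chip_experiment()]); when absent, occupancy is taken as 0
#'   for every gene and only the global scale acts.
#' @param config A [sim_config()].
#' @return List with `counts` (tibble: `gene_id`, `length`, one column per
#'   sample), `samples` (tibble: `sample`, `condition`) and `truth_genes`
#'   (per-gene occupancy, coupling flag and pre-scaling true fold
#'   changes).
#' @export
simulate_expression <- function(genes, truth, config) {
  stage_seed(config, 5L)
  n <- nrow(genes)
  occ <- if (!is.null(truth$windows)) {
    gene_occupancy_truth(genes, truth$windows)
  } else rep(0, n)
  coupled <- runif(n) < config$frac_coupled_genes
  occ_c <- occ - mean(occ)
  lfc_ko <- ifelse(coupled, config$coupling_alpha * occ_c, 0)
  lfc_oe <- -lfc_ko
  q <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  reps <- config$n_replicates
  samples <- tibble::tibble(
    sample = c(paste0("WT_", seq_len(reps)), paste0("KO_", seq_len(reps)),
               paste0("OE_", seq_len(reps))),
    condition = rep(c("WT", "KO", "OE"), each = reps))
  mu <- cbind(
    matrix(q, n, reps),
    matrix(q * 2^lfc_ko * config$global_scale_ko, n, reps),
    matrix(q * 2^lfc_oe, n, reps))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                   nrow = n)
  colnames(counts) <- samples$sample
  counts_tbl <- dplyr::bind_cols(
    tibble::tibble(gene_id = genes$gene_id, length = genes$length),
    tibble::as_tibble(counts))
  truth_genes <- tibble::tibble(
    gene_id = genes$gene_id, occupancy = occ_c, coupled = coupled,
    true_lfc_ko = lfc_ko, true_lfc_oe = lfc_oe)
  list(counts = counts_tbl, samples = samples, truth_genes = truth_genes,
       global_scale = config$global_scale_ko)
}

# true occupancy (expected log2 ChIP/Input) per gene body, window-weighted
gene_occupancy_truth <- function(genes, windows) {
  lr <- log2(windows$chip_intensity / windows$input_intensity)
  vapply(seq_len(nrow(genes)), function(i) {
    sel <- windows$chrom == genes$chrom[i] &
      windows$end > genes$start[i] & windows$start < genes$end[i]
    if (!any(sel)) return(0)
    wgt <- pmin(windows$end[sel], genes$end[i]) - pmax(windows$start[sel], genes$start[i])
    sum(lr[sel] * wgt) / sum(wgt)
  }, numeric(1))
}

#' Run the full synthetic experiment
#'
#' Chains [simulate_genome()], [simulate_methylome()],
#' [simulate_chip_experiment()], [simulate_genes()] and
#' [simulate_expression()] under one configuration and collects every
#' ground-truth record needed for parameter recovery.
#'
#' @param config A [sim_config()].
#' @param tab Also simulate the TAB channel?
#' @return List with `genome`, `cgis`, `sites` (BS methylome; plus
#'   `sites_tab` when requested), `chip`, `input`, `windows`, `genes`,
#'   `expression` and `truth`.
#' @export
simulate_experiment <- function(config = sim_config(), tab = FALSE) {
  gen <- simulate_genome(config)
  meth <- simulate_methylome(gen$genome, gen$cgis, gen$truth, config, tab = tab)
  sites <- if (tab) meth$bs else meth
  chip <- simulate_chip_experiment(gen$genome, sites, gen$truth, config)
  genes <- simulate_genes(gen$genome, config)
  expr <- simulate_expression(genes, chip$truth, config)
  out <- list(genome = gen$genome, cgis = gen$cgis, sites = sites,
              chip = chip$chip, input = chip$input, windows = chip$windows,
              genes = genes, expression = expr, truth = chip$truth)
  if (tab) out$sites_tab <- meth$tab
  out$truth$genes <- expr$truth_genes
  out$truth$global_scale <- expr$global_scale
  out
}
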