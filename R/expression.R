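counts_matrix_of <- function(counts) {
  num <- setdiff(names(counts), c("gene_id", "length"))
  m <- as.matrix(counts[, num])
  rownames(m) <- counts$gene_id
  m
}

#' Transcripts per million
#'
#' Length-normalised rates rescaled so each sample column sums to 1e6.
#' Exonic lengths are used when available (the `length` column); genes are
#' rows.
#'
#' @param counts Counts tibble with `gene_id`, `length` and one column per
#'   sample.
#' @return Tibble with `gene_id` and one TPM column per sample.
#' @export
compute_tpm <- function(counts) {
  m <- counts_matrix_of(counts)
  rate <- m / counts$length
  tpm <- sweep(rate, 2, colSums(rate), `/`) * 1e6
  dplyr::bind_cols(tibble::tibble(gene_id = counts$gene_id),
                   tibble::as_tibble(tpm))
}

#' Median-of-ratios size factors
#'
#' The standard size-factor procedure: per-gene geometric means across
#' samples (genes with any zero count are excluded), then the per-sample
#' median of count-to-geometric-mean ratios.
#'
#' @param counts Counts tibble (`gene_id`, `length`, sample columns).
#' @return Tibble with `sample` and `size_factor`.
#' @export
size_factors <- function(counts) {
  m <- counts_matrix_of(counts)
  if (ncol(m) < 2) stopf("need at least 2 samples")
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) stopf("no gene with all-positive counts")
  lg <- rowMeans(log(m[pos, , drop = FALSE]))
  sf <- apply(m[pos, , drop = FALSE], 2, function(col) median(exp(log(col) - lg)))
  tibble::tibble(sample = colnames(m), size_factor = unname(sf))
}

#' Apply a global library-scale correction to size factors
#'
#' Multiplies the size factors of one condition's samples by a constant.
#' The canonical use is the KO correction: total RNA per cell in the
#' knockout is ~15% lower than WT, so KO size factors are multiplied by
#' 1.15 to stop the global reduction masquerading as thousands of
#' down-regulated genes.
#'
#' @param factors Tibble from [size_factors()].
#' @param samples Tibble with `sample`, `condition`.
#' @param condition Condition whose factors are scaled (default `"KO"`).
#' @param multiplier Positive multiplier (default 1.15).
#' @return The factors tibble with the targeted samples rescaled.
#' @export
apply_global_scale <- function(factors, samples, condition = "KO",
                               multiplier = 1.15) {
  if (multiplier <= 0) stopf("multiplier must be positive")
  target <- samples$sample[samples$condition == condition]
  factors$size_factor <- factors$size_factor *
    ifelse(factors$sample %in% target, multiplier, 1)
  factors
}

#' Moderated negative-binomial Wald test for differential expression
#'
#' Self-contained two-group NB test with size-factor offsets: group means
#' are count sums over scaled library sizes; per-gene moment dispersions
#' are shrunk toward a fitted `a + b/mean` trend (weight `shrink_weight`)
#' and floored; the Wald statistic on the log fold change is referred to
#' the normal distribution, and p-values are BH-adjusted over tested
#' genes.
#'
#' @param counts Counts tibble (`gene_id`, `length`, sample columns).
#' @param samples Tibble with `sample`, `condition`.
#' @param factors Size-factor tibble (possibly globally rescaled).
#' @param contrast Character pair `c(test, reference)`, e.g.
#'   `c("KO", "WT")`: positive log2FC means higher in the test condition.
#' @param shrink_weight Weight of the dispersion trend in shrinkage.
#' @param dispersion_floor Lower bound on the working dispersion.
#' @return An `nb_de` tibble: `gene_id`, `base_mean`, `log2fc`, `lfc_se`,
#'   `stat`, `p_value`, `padj`. Genes with zero counts in both groups get
#'   `NA` statistics and are excluded from the BH adjustment.
#' @export
nb_test <- function(counts, samples, factors, contrast = c("KO", "WT"),
                    shrink_weight = 0.7, dispersion_floor = 1e-8) {
  m <- counts_matrix_of(counts)
  sf <- factors$size_factor[match(colnames(m), factors$sample)]
  cond <- samples$condition[match(colnames(m), samples$sample)]
  for (cn in contrast) {
    if (sum(cond == cn, na.rm = TRUE) < 2) {
      stopf("condition '%s' needs at least 2 replicates", cn)
    }
  }
  grp <- lapply(contrast, function(cn) which(cond == cn))
  names(grp) <- c("A", "B")
  # group mean of normalised counts: exactly invariant to rescaling a
  # sample's counts and size factor together
  y <- sweep(m, 2, sf, `/`)
  q <- vapply(grp, function(j) rowMeans(y[, j, drop = FALSE]),
              numeric(nrow(m)))
  # moment dispersion from within-group variances of normalised counts:
  # Var(K/s) = q * mean(1/s) + alpha * q^2
  disp_num <- 0; disp_den <- 0
  for (g in c("A", "B")) {
    j <- grp[[g]]
    v <- apply(y[, j, drop = FALSE], 1, var)
    qg <- q[, g]
    w <- length(j) - 1
    disp_num <- disp_num + w * (v - qg * mean(1 / sf[j]))
    disp_den <- disp_den + w * qg^2
  }
  alpha_raw <- ifelse(disp_den > 0, pmax(disp_num / disp_den, 0), NA_real_)
  qbar <- rowMeans(q)
  # dispersion trend alpha ~ a + b / mean, least squares on informative genes
  okt <- is.finite(alpha_raw) & qbar > 0
  trend <- if (sum(okt) >= 10) {
    ft <- lm(alpha_raw[okt] ~ I(1 / qbar[okt]))
    pmax(coef(ft)[1] + coef(ft)[2] / qbar, 0)
  } else rep(mean(alpha_raw[okt], na.rm = TRUE), length(qbar))
  alpha <- pmax((1 - shrink_weight) * ifelse(is.na(alpha_raw), trend, alpha_raw) +
                  shrink_weight * trend, dispersion_floor)
  tested <- q[, "A"] + q[, "B"] > 0
  eps <- 1e-8
  l2fc <- log2((q[, "A"] + eps) / (q[, "B"] + eps))
  # Var(mean_j K_j/s_j) = (q/n^2) sum(1/s_j) + alpha q^2 / n, so on the log
  # scale Var(log q) = sum(1/s_j)/(n^2 q) + alpha/n
  var_ln <- vapply(c("A", "B"), function(g) {
    j <- grp[[g]]
    n_g <- length(j)
    qg <- pmax(q[, g], eps)
    sum(1 / sf[j]) / (n_g^2 * qg) + alpha / n_g
  }, numeric(nrow(m)))
  se_ln <- sqrt(rowSums(var_ln))
  stat <- (l2fc * log(2)) / se_ln
  p <- 2 * pnorm(-abs(stat))
  p[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[tested] <- p.adjust(p[tested], method = "BH")
  out <- tibble::tibble(
    gene_id = counts$gene_id,
    base_mean = rowMeans(y),
    log2fc = ifelse(tested, l2fc, NA_real_),
    lfc_se = ifelse(tested, se_ln / log(2), NA_real_),
    stat = ifelse(tested, stat, NA_real_),
    p_value = p, padj = padj)
  attr(out, "contrast") <- contrast
  class(out) <- c("nb_de", class(out))
  out
}

#' Classify genes by differential-expression outcome
#'
#' Applies the threshold rules: `filtered` when TPM is below `tpm_min` in
#' every sample; `up`/`down` when `padj < padj_de` with the corresponding
#' fold-change sign; `unchanged` when `padj > padj_unchanged` and
#' `|log2FC| < lfc_unchanged`; `other` otherwise. Every gene receives
#' exactly one class. The BH adjustment is recomputed over genes passing
#' the TPM filter only.
#'
#' @param results An `nb_de` tibble.
#' @param tpm TPM tibble from [compute_tpm()].
#' @param padj_de,padj_unchanged,lfc_unchanged,tpm_min Threshold
#'   parameters (defaults 0.05, 0.5, 0.01, 5).
#' @return The results tibble with `padj` recomputed over unfiltered genes
#'   and a `class` column.
#' @export
classify_genes <- function(results, tpm, padj_de = 0.05, padj_unchanged = 0.5,
                           lfc_unchanged = 0.01, tpm_min = 5) {
  tm <- as.matrix(tpm[, setdiff(names(tpm), "gene_id")])
  low <- rowSums(tm >= tpm_min) == 0
  low <- low[match(results$gene_id, tpm$gene_id)]
  keep <- !low & !is.na(results$p_value)
  results$padj <- NA_real_
  results$padj[keep] <- p.adjust(results$p_value[keep], method = "BH")
  cls <- rep("other", nrow(results))
  cls[low] <- "filtered"
  up <- keep & results$padj < padj_de & results$log2fc > 0
  dn <- keep & results$padj < padj_de & results$log2fc < 0
  un <- keep & results$padj > padj_unchanged & abs(results$log2fc) < lfc_unchanged
  cls[up] <- "up"; cls[dn] <- "down"; cls[un & !up & !dn] <- "unchanged"
  results$class <- factor(cls, levels = c("up", "down", "unchanged", "other",
                                          "filtered"))
  results
}

#' Mean occupancy over gene bodies and flanked bodies
#'
#' Window-weighted mean of the log2(ChIP/Input) track over each gene body
#' and over the body extended by `flank` bp on both sides (the default,
#' reflecting that differential binding extends past transcription start
#' and end sites). Flanks truncated at chromosome ends set the `clipped`
#' flag.
#'
#' @param genes Interval tibble with `gene_id`.
#' @param occupancy An `occupancy_track`.
#' @param flank Flank size, bp (default 1e5).
#' @return Tibble: `gene_id`, `occupancy_body`, `occupancy_flanked`,
#'   `clipped`.
#' @export
gene_occupancy <- function(genes, occupancy, flank = 1e5) {
  out <- tibble::tibble(gene_id = genes$gene_id,
                        occupancy_body = NA_real_,
                        occupancy_flanked = NA_real_,
                        clipped = FALSE)
  for (nm in unique(genes$chrom)) {
    sel <- which(genes$chrom == nm)
    tr <- occupancy[occupancy$chrom == nm, ]
    if (nrow(tr) == 0) next
    o <- order(tr$start)
    Fx <- step_integral_fun(tr$start[o], tr$end[o], tr$log2_ratio[o])
    lo_lim <- min(tr$start); hi_lim <- max(tr$end)
    mean_over <- function(a, b) {
      a <- pmax(a, lo_lim); b <- pmin(b, hi_lim)
      ifelse(b > a, (Fx(b) - Fx(a)) / (b - a), NA_real_)
    }
    out$occupancy_body[sel] <- mean_over(genes$start[sel], genes$end[sel])
    fa <- genes$start[sel] - flank; fb <- genes$end[sel] + flank
    out$occupancy_flanked[sel] <- mean_over(fa, fb)
    out$clipped[sel] <- fa < lo_lim | fb > hi_lim
  }
  out
}

#' Rolling-mean curve over occupancy-ranked genes
#'
#' Sorts rows by an ordering column (stable: ties keep their original
#' order) and returns the mean of a value column over rolling subsets of
#' `window` rows advanced by `step` rows (defaults 400 and 80, the
#' gene-level plotting convention).
#'
#' @param data A data frame.
#' @param order_by,value Column names (tidy-eval) for the ranking variable
#'   and the averaged variable.
#' @param window,step Subset size and step, rows.
#' @return Tibble: `point`, `mean_rank_var`, `mean_value` with one row per
#'   rolling subset.
#' @export
rolling_density <- function(data, order_by, value, window = 400L, step = 80L) {
  ob <- dplyr::pull(data, {{ order_by }})
  vv <- dplyr::pull(data, {{ value }})
  n <- length(ob)
  if (n < window) stopf("need at least %d rows, got %d", window, n)
  o <- order(ob)                       # order() is stable for ties
  ob <- ob[o]; vv <- vv[o]
  n_pts <- (n - window) %/% step + 1L
  starts <- (seq_len(n_pts) - 1L) * step + 1L
  cs_v <- cumsum(c(0, vv)); cs_o <- cumsum(c(0, ob))
  tibble::tibble(
    point = seq_len(n_pts),
    mean_rank_var = (cs_o[starts + window] - cs_o[starts]) / window,
    mean_value = (cs_v[starts + window] - cs_v[starts]) / window)
}

#' Group-mean curve over occupancy-ranked windows
#'
#' Sorts rows by the ordering column and averages the value column over
#' consecutive non-overlapping groups of `group` rows (default 1000, the
#' genome-window plotting convention); a trailing partial group is
#' dropped.
#'
#' @inheritParams rolling_density
#' @param group Group size, rows.
#' @return Tibble: `group`, `mean_rank_var`, `mean_value`.
#' @export
window_group_curve <- function(data, order_by, value, group = 1000L) {
  ob <- dplyr::pull(data, {{ order_by }})
  vv <- dplyr::pull(data, {{ value }})
  n <- length(ob)
  if (n < group) stopf("need at least %d rows, got %d", group, n)
  o <- order(ob)
  ob <- ob[o]; vv <- vv[o]
  n_grp <- n %/% group
  idx <- rep(seq_len(n_grp), each = group)
  used <- seq_len(n_grp * group)
  tibble::tibble(
    group = seq_len(n_grp),
    mean_rank_var = as.numeric(tapply(ob[used], idx, mean)),
    mean_value = as.numeric(tapply(vv[used], idx, mean)))
}

#' Overlap of classified genes with enriched/depleted domains
#'
#' Assigns each gene one of `inside_enriched`, `overlapping_enriched`,
#' `inside_depleted`, `overlapping_depleted` or `neither` by gene-body
#' overlap with labelled segments (inside = fully contained; enriched
#' takes precedence when a gene touches both label sets), and tabulates
#' proportions per expression class.
#'
#' @param genes Classified gene tibble: `gene_id`, `chrom`, `start`,
#'   `end`, `class`.
#' @param segments A labelled `segment_set`.
#' @return List: `assignments` (per-gene tibble) and `proportions`
#'   (class-by-category proportion tibble).
#' @export
domain_overlap <- function(genes, segments) {
  categorise <- function(g_start, g_end, segs) {
    if (nrow(segs) == 0) return(list(inside = FALSE, partial = FALSE))
    hit <- segs$start < g_end & segs$end > g_start
    list(inside = any(hit & segs$start <= g_start & segs$end >= g_end),
         partial = any(hit))
  }
  cats <- character(nrow(genes))
  for (nm in unique(genes$chrom)) {
    sel <- which(genes$chrom == nm)
    enr <- segments[segments$chrom == nm & segments$label == "enriched", ]
    dep <- segments[segments$chrom == nm & segments$label == "depleted", ]
    for (i in sel) {
      e <- categorise(genes$start[i], genes$end[i], enr)
      d <- categorise(genes$start[i], genes$end[i], dep)
      cats[i] <- if (e$inside) "inside_enriched"
        else if (e$partial) "overlapping_enriched"
        else if (d$inside) "inside_depleted"
        else if (d$partial) "overlapping_depleted"
        else "neither"
    }
  }
  lev <- c("inside_enriched", "overlapping_enriched", "inside_depleted",
           "overlapping_depleted", "neither")
  assignments <- dplyr::bind_cols(genes[, c("gene_id", "class")],
                                  tibble::tibble(category = factor(cats, lev)))
  proportions <- dplyr::mutate(
    dplyr::count(assignments, .data$class, .data$category, .drop = FALSE),
    proportion = .data$n / pmax(stats::ave(.data$n, .data$class, FUN = sum), 1))
  list(assignments = assignments, proportions = tibble::as_tibble(proportions))
}

#' Occupancy-expression statistics bundle
#'
#' Spearman rank correlation (average-rank ties) between gene occupancy
#' and log2 fold change for the KO and OE contrasts; per-occupancy-bin
#' fractions of up/down/unchanged genes; and a rank-sum comparison of gene
#' length between up-regulated and unchanged genes when lengths are
#' available.
#'
#' @param gene_occ Tibble from [gene_occupancy()].
#' @param results_ko Classified `nb_de` tibble for KO vs WT.
#' @param results_oe Optional classified `nb_de` tibble for OE vs WT.
#' @param genes Optional gene tibble with `length` for the length test.
#' @param occupancy_col Which occupancy column to use.
#' @param n_bins Number of occupancy bins for the class-fraction table.
#' @return List: `rho_ko`, `rho_oe`, `bin_fractions`,
#'   `length_test_p`, `n`.
#' @export
occupancy_expression_stats <- function(gene_occ, results_ko,
                                       results_oe = NULL, genes = NULL,
                                       occupancy_col = "occupancy_flanked",
                                       n_bins = 5L) {
  occ <- gene_occ[[occupancy_col]]
  names(occ) <- gene_occ$gene_id
  pair <- function(res) {
    x <- occ[res$gene_id]
    ok <- !is.na(x) & !is.na(res$log2fc)
    if (sum(ok) < 10) stopf("need at least 10 genes with occupancy and log2FC")
    cor(x[ok], res$log2fc[ok], method = "spearman")
  }
  rho_ko <- pair(results_ko)
  rho_oe <- if (!is.null(results_oe)) pair(results_oe) else NA_real_
  has_class <- "class" %in% names(results_ko)
  x <- occ[results_ko$gene_id]
  ok <- if (has_class) {
    !is.na(x) & !is.na(results_ko$class) &
      results_ko$class %in% c("up", "down", "unchanged")
  } else rep(FALSE, nrow(results_ko))
  bin_fractions <- NULL
  if (sum(ok) >= n_bins) {
    br <- quantile(x[ok], probs = seq(0, 1, length.out = n_bins + 1))
    bin <- cut(x[ok], breaks = unique(br), include.lowest = TRUE)
    tab <- table(bin, droplevels(factor(results_ko$class[ok])))
    bin_fractions <- tibble::as_tibble(prop.table(tab, margin = 1),
                                       .name_repair = "minimal")
    names(bin_fractions) <- c("occupancy_bin", "class", "fraction")
  }
  length_test_p <- NA_real_
  if (!is.null(genes) && "length" %in% names(genes) && has_class) {
    len <- genes$length[match(results_ko$gene_id, genes$gene_id)]
    up <- results_ko$class == "up"; un <- results_ko$class == "unchanged"
    if (sum(up, na.rm = TRUE) >= 3 && sum(un, na.rm = TRUE) >= 3) {
      length_test_p <- wilcox.test(len[which(up)], len[which(un)])$p.value
    }
  }
  list(rho_ko = unname(rho_ko), rho_oe = unname(rho_oe),
       bin_fractions = bin_fractions, length_test_p = length_test_p,
       n = sum(!is.na(occ)))
}
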