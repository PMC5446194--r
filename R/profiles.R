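# piecewise-constant track integral: F(x) = integral of the step function
# from 0 to x; windows assumed sorted, non-overlapping; value 0 in gaps
step_integral_fun <- function(starts, ends, values) {
  cum <- cumsum(c(0, values * (ends - starts)))
  function(x) {
    i <- findInterval(x, starts)
    base <- cum[i + 1L]
    # subtract the part of window i beyond x (if x falls inside window i)
    inside <- i > 0 & x < ends[pmax(i, 1L)]
    adj <- numeric(length(x))
    adj[inside] <- (ends[i[inside]] - x[inside]) * values[i[inside]]
    base - adj
  }
}

#' Anchored meta-profile matrix
#'
#' Builds the per-anchor, per-bin signal matrix around a set of anchor
#' positions (summits, TSSs, random controls, CGI midpoints): `flank` bp on
#' each side at `bin` bp resolution. Two signal modes are supported:
#' a piecewise-constant track (tibble with `chrom`, `start`, `end` and a
#' value column, e.g. an `occupancy_track`), where each bin takes the
#' length-weighted mean of overlapping windows; or methylation sites
#' (tibble with `pos` and `level`), where each bin carries the methylation
#' density per kb of the chosen `context`. Anchors whose full flank does
#' not fit on the chromosome are dropped and tallied. Minus-strand anchors
#' have their rows reversed so downstream is always rightward.
#'
#' @param anchors Tibble with `chrom`, `pos` and optionally `strand`.
#' @param signal Track tibble or methylation site tibble (see above).
#' @param flank Flank size, bp; must be divisible by `bin`.
#' @param bin Bin width, bp.
#' @param context Context label when `signal` is a site tibble.
#' @param value_col Value column for track mode (default `log2_ratio`,
#'   falling back to `value`).
#' @param chrom_lengths Named lengths used for the drop rule; inferred from
#'   the signal extent when absent.
#' @return A `profile_matrix` object: list with `values` (matrix, one row
#'   per retained anchor), `aggregate` (per-bin column means), `bin_mid`
#'   (bp offsets of bin midpoints from the anchor), `n_dropped`, `flank`,
#'   `bin`.
#' @export
profile_matrix <- function(anchors, signal, flank, bin, context = NULL,
                           value_col = NULL, chrom_lengths = NULL) {
  if (flank %% bin != 0) stopf("flank must be divisible by bin")
  n_bins <- as.integer(2L * flank / bin)
  site_mode <- is.null(value_col) && all(c("pos", "level") %in% names(signal))
  if (site_mode && !is.null(context)) {
    signal <- signal[which(match_context(signal, context) &
                             (signal$covered %||% TRUE)), ]
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- if (site_mode) {
      tapply(signal$pos, signal$chrom, max) + 1L
    } else {
      tapply(signal$end, signal$chrom, max)
    }
  }
  vcol <- if (!site_mode) {
    value_col %||% (if ("log2_ratio" %in% names(signal)) "log2_ratio" else "value")
  }
  strand <- if ("strand" %in% names(anchors)) anchors$strand else
    rep("+", nrow(anchors))
  rows <- vector("list", length(unique(anchors$chrom)))
  mats <- list(); dropped <- 0L
  for (nm in unique(anchors$chrom)) {
    sel <- which(anchors$chrom == nm)
    clen <- if (nm %in% names(chrom_lengths)) chrom_lengths[[nm]] else NA
    if (is.na(clen)) { dropped <- dropped + length(sel); next }
    pos <- anchors$pos[sel]
    ok <- pos - flank >= 0 & pos + flank <= clen
    dropped <- dropped + sum(!ok)
    sel <- sel[ok]; pos <- pos[ok]
    if (length(sel) == 0) next
    # edges: (n_bins + 1) per anchor
    edges <- outer(pos - flank, seq.int(0L, n_bins) * bin, `+`)
    sc <- signal[signal$chrom == nm, ]
    if (site_mode) {
      o <- order(sc$pos)
      spos <- sc$pos[o]
      cslev <- cumsum(c(0, sc$level[o]))
      Fx <- function(x) cslev[findInterval(x - 0.5, spos) + 1L]
    } else {
      o <- order(sc$start)
      Fx <- step_integral_fun(sc$start[o], sc$end[o], sc[[vcol]][o])
    }
    Fe <- matrix(Fx(as.vector(edges)), nrow = length(pos))
    m <- Fe[, -1L, drop = FALSE] - Fe[, -(n_bins + 1L), drop = FALSE]
    m <- if (site_mode) m / bin * 1000 else m / bin
    rev_rows <- strand[sel] == "-"
    if (any(rev_rows)) m[rev_rows, ] <- m[rev_rows, n_bins:1L, drop = FALSE]
    mats[[length(mats) + 1L]] <- m
  }
  if (length(mats) == 0) stopf("no anchors retained (all dropped at the flanks)")
  values <- do.call(rbind, mats)
  structure(list(values = values,
                 aggregate = colMeans(values),
                 bin_mid = seq.int(-flank + bin %/% 2L, flank - bin %/% 2L, by = bin),
                 n_dropped = dropped, flank = flank, bin = bin,
                 mode = if (site_mode) "density" else "track"),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("<profile_matrix> ", nrow(x$values), " anchors x ", ncol(x$values),
      " bins (", x$bin, " bp, +/-", x$flank, " bp), ", x$n_dropped,
      " dropped; mode=", x$mode, "\n", sep = "")
  invisible(x)
}
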