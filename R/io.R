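#' Read a FASTA file into a genome object
#'
#' Parses a (plain-text, uncompressed) FASTA file into a `genome_seq` object:
#' a named list of upper-case sequences over the alphabet `{A,C,G,T,N}` with
#' per-chromosome lengths. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A `genome_seq` object: list with elements `seq` (named character
#'   vector of sequences) and `lengths` (named integer vector, bp).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), tf)
#' g <- read_fasta(tf)
#' g$lengths
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) format_error("empty FASTA file: %s", path)
  hdr <- startsWith(lines, ">")
  if (!hdr[1]) format_error("line 1: expected FASTA header starting with '>'")
  names_raw <- sub("^>", "", lines[hdr])
  names_raw <- sub("\\s.*$", "", names_raw)
  if (any(names_raw == "")) {
    format_error("line %d: empty FASTA header", which(hdr)[names_raw == ""][1])
  }
  if (anyDuplicated(names_raw)) {
    dup <- names_raw[duplicated(names_raw)][1]
    format_error("line %d: duplicate sequence name '%s'",
                 which(hdr)[which(names_raw == dup)[2]], dup)
  }
  seq_lines <- toupper(lines)
  bad <- !hdr & grepl("[^ACGTN]", seq_lines)
  if (any(bad)) {
    format_error("line %d: illegal character in sequence (alphabet is A,C,G,T,N)",
                 which(bad)[1])
  }
  grp <- cumsum(hdr)
  seqs <- vapply(split(seq_lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  # records with no sequence lines are empty strings
  out <- setNames(character(length(names_raw)), names_raw)
  out[as.integer(names(seqs))] <- seqs
  if (any(nchar(out) == 0)) {
    format_error("record '%s' has no sequence", names_raw[nchar(out) == 0][1])
  }
  new_genome_seq(out)
}

new_genome_seq <- function(seqs) {
  structure(list(seq = seqs,
                 lengths = setNames(nchar(seqs), names(seqs))),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("<genome_seq> ", length(x$seq), " sequence(s), ",
      format(sum(as.numeric(x$lengths)), big.mark = ","), " bp total\n", sep = "")
  for (nm in utils::head(names(x$seq), 10)) {
    cat("  ", nm, ": ", format(x$lengths[[nm]], big.mark = ","), " bp\n", sep = "")
  }
  invisible(x)
}

#' Write a genome object to FASTA
#'
#' @param genome A `genome_seq` object.
#' @param path Output path.
#' @param width Line width for wrapping sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(genome$seq)) {
    writeLines(paste0(">", nm), con)
    s <- genome$seq[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(stringi::stri_sub(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' Supports BED3, BED6 and BED12 dialects. Coordinates are BED-native
#' (0-based, half-open) and kept that way internally. Missing strand is
#' recorded as `"."`. For BED12, block (exon) sizes are retained so callers
#' can compute exonic lengths.
#'
#' @param path Path to a tab-separated BED file.
#' @param dialect One of `"BED3"`, `"BED6"`, `"BED12"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` and, for BED12, list-columns `block_sizes` and `block_starts`.
#' @export
read_intervals <- function(path, dialect = c("BED3", "BED6", "BED12")) {
  dialect <- match.arg(dialect)
  ncol_needed <- c(BED3 = 3L, BED6 = 6L, BED12 = 12L)[[dialect]]
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          name = character(), score = double(), strand = character()))
  }
  if (ncol(raw) < ncol_needed) {
    format_error("%s requires %d columns, found %d", dialect, ncol_needed, ncol(raw))
  }
  out <- tibble::tibble(
    chrom = raw[[1]],
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    name = if (ncol_needed >= 6) raw[[4]] else NA_character_,
    score = if (ncol_needed >= 6) suppressWarnings(as.double(raw[[5]])) else NA_real_,
    strand = if (ncol_needed >= 6) raw[[6]] else "."
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    format_error("non-numeric start/end at line %d",
                 which(is.na(out$start) | is.na(out$end))[1])
  }
  bad <- which(out$start >= out$end | out$start < 0)
  if (length(bad) > 0) {
    format_error("invalid interval (start >= end) at line %d", bad[1])
  }
  if (!all(out$strand %in% c("+", "-", "."))) {
    format_error("invalid strand at line %d",
                 which(!out$strand %in% c("+", "-", "."))[1])
  }
  if (dialect == "BED12") {
    split_ints <- function(x) lapply(strsplit(x, ",", fixed = TRUE),
                                     function(v) as.integer(v[v != ""]))
    out$block_count <- as.integer(raw[[10]])
    out$block_sizes <- split_ints(raw[[11]])
    out$block_starts <- split_ints(raw[[12]])
    nb <- lengths(out$block_sizes)
    if (any(nb != out$block_count)) {
      format_error("blockCount disagrees with blockSizes at line %d",
                   which(nb != out$block_count)[1])
    }
  }
  out
}

#' Write intervals to a BED file
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  assert_interval_tbl(intervals)
  has6 <- all(c("name", "score", "strand") %in% names(intervals))
  cols <- if (has6) {
    data.frame(intervals$chrom, intervals$start, intervals$end,
               ifelse(is.na(intervals$name), ".", intervals$name),
               ifelse(is.na(intervals$score), 0, intervals$score),
               intervals$strand)
  } else {
    data.frame(intervals$chrom, intervals$start, intervals$end)
  }
  readr::write_tsv(cols, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a per-cytosine methylation report
#'
#' Reads a Bismark-style cytosine report: tab-separated with columns chrom,
#' position (1-based), strand, modified basecall count, unmodified basecall
#' count, di-nucleotide context and tri-nucleotide context. Positions stay
#' 1-based on read; conversion to the package's internal 0-based convention
#' is done by callers (see [attach_calls()]).
#'
#' @param path Path to the report.
#' @return A tibble with columns `chrom`, `pos` (1-based), `strand`,
#'   `count_modified`, `count_unmodified`, `di_context`, `tri_context`.
#' @export
read_cytosine_report <- function(path) {
  raw <- readr::read_tsv(
    path, col_names = c("chrom", "pos", "strand", "count_modified",
                        "count_unmodified", "di_context", "tri_context"),
    col_types = "ciciicc", progress = FALSE)
  if (nrow(raw) == 0) {
    rlang::warn(sprintf("empty cytosine report: %s", path))
    return(raw)
  }
  if (any(raw$count_modified < 0 | raw$count_unmodified < 0, na.rm = TRUE)) {
    format_error("negative basecall count at line %d",
                 which(raw$count_modified < 0 | raw$count_unmodified < 0)[1])
  }
  if (!all(raw$strand %in% c("+", "-"))) {
    format_error("cytosine records require strand + or -, bad value at line %d",
                 which(!raw$strand %in% c("+", "-"))[1])
  }
  ok_tri <- is.na(raw$tri_context) |
    substr(raw$tri_context, 1, 2) == raw$di_context
  if (!all(ok_tri)) {
    format_error("tri_context disagrees with di_context at line %d", which(!ok_tri)[1])
  }
  raw
}

#' Write a per-cytosine methylation report
#'
#' Inverse of [read_cytosine_report()]; `pos` must already be 1-based.
#'
#' @param report Tibble in the cytosine-report layout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(report, path) {
  readr::write_tsv(report[, c("chrom", "pos", "strand", "count_modified",
                              "count_unmodified", "di_context", "tri_context")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a per-interval signal track as bedGraph
#'
#' Values are rendered with six significant digits so that a write/read
#' round trip reproduces them within 1e-5. Intervals must be sorted and
#' non-overlapping within each chromosome.
#'
#' @param track Tibble with columns `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  assert_interval_tbl(track, "track")
  if (!"value" %in% names(track)) stopf("`track` needs a `value` column")
  by_chrom <- split(seq_len(nrow(track)), track$chrom)
  for (idx in by_chrom) {
    s <- track$start[idx]; e <- track$end[idx]
    if (is.unsorted(s, strictly = FALSE)) stopf("bedGraph intervals must be sorted")
    if (length(idx) > 1 && any(s[-1] < e[-length(e)])) {
      stopf("bedGraph intervals must not overlap")
    }
  }
  val <- vapply(signif(track$value, 6), format, character(1),
                trim = TRUE, scientific = FALSE)
  writeLines(paste(track$chrom, track$start, track$end, val, sep = "\t"), path)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path Path to a bedGraph file.
#' @return Tibble with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                  col_types = "ciid", progress = FALSE)
}
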