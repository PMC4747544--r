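#' GC fraction of a nucleotide sequence
#'
#' `(G + C) / (A + C + G + T)`, case-insensitive; `N` is excluded from the
#' denominator. A sequence with no A/C/G/T (e.g. all N) returns `NA`.
#'
#' @param sequence character vector of sequences over `A C G T N` (either
#'   case), or a `Biostrings::DNAStringSet`.
#' @return GC fraction per sequence (`NA` where undefined).
#' @export
gc_content <- function(sequence) {
  if (inherits(sequence, "DNAStringSet") || inherits(sequence, "DNAString"))
    sequence <- as.character(sequence)
  sequence <- toupper(sequence)
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) stop("illegal character in sequence: only A, C, G, T, N allowed")
  counts <- Biostrings::letterFrequency(Biostrings::DNAStringSet(sequence),
                                        c("A", "C", "G", "T"))
  denom <- rowSums(counts)
  gc <- (counts[, "G"] + counts[, "C"]) / denom
  gc[denom == 0] <- NA_real_
  unname(gc)
}

#' Parse a repeat-element table
#'
#' Reads either a UCSC rmsk-style tab-separated table (with or without the
#' leading `bin` column; columns `genoName`, `genoStart`, `genoEnd`,
#' `strand`, `repName`, `repClass`, `repFamily` among the standard layout)
#' or RepeatMasker `.out` output (whitespace-aligned, two header lines,
#' `class/family` combined in one field). The format is auto-detected.
#' Coordinates are normalized to 0-based half-open; malformed lines
#' (including `end <= start`) are skipped with a message.
#'
#' @param source file path.
#' @param format `"auto"`, `"rmsk"` or `"out"`.
#' @return Data frame with `chrom`, `start`, `end`, `strand`, `name`,
#'   `class`, `family`; skipped-line count as attribute `"n_skipped"`.
#' @export
parse_repeat_table <- function(source, format = c("auto", "rmsk", "out")) {
  format <- match.arg(format)
  lines <- readLines(source, warn = FALSE)
  if (format == "auto") {
    head_txt <- paste(utils::head(lines, 3), collapse = "\n")
    format <- if (grepl("\\bSW\\b.*\\bperc\\b|^\\s*score\\s+div", head_txt) ||
                  !any(grepl("\t", utils::head(lines[nzchar(lines)], 3))))
      "out" else "rmsk"
  }
  n_skipped <- 0L
  rows <- list()
  if (format == "out") {
    body <- lines[nzchar(trimws(lines))]
    body <- body[!grepl("^\\s*(SW|score|perc)", body)]
    for (ln in body) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 11) { n_skipped <- n_skipped + 1L; next }
      start1 <- suppressWarnings(as.numeric(f[6]))
      end1 <- suppressWarnings(as.numeric(f[7]))
      if (is.na(start1) || is.na(end1) || end1 < start1) {
        n_skipped <- n_skipped + 1L; next
      }
      cf <- strsplit(f[11], "/", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = f[5], start = start1 - 1, end = end1,
        strand = if (f[9] == "C") "-" else f[9], name = f[10],
        class = cf[1], family = if (length(cf) > 1) cf[2] else cf[1],
        stringsAsFactors = FALSE)
    }
  } else {
    body <- lines[nzchar(lines) & !grepl("^#", lines)]
    for (ln in body) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      # UCSC layout is 17 columns with a leading bin; tolerate 16 without
      off <- if (length(f) >= 17) 1L else 0L
      if (length(f) < 13 + off) { n_skipped <- n_skipped + 1L; next }
      start0 <- suppressWarnings(as.numeric(f[6 + off]))
      end0 <- suppressWarnings(as.numeric(f[7 + off]))
      if (is.na(start0) || is.na(end0) || end0 <= start0) {
        n_skipped <- n_skipped + 1L; next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = f[5 + off], start = start0, end = end0,
        strand = f[9 + off], name = f[10 + off], class = f[11 + off],
        family = f[12 + off], stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0) message(n_skipped, " malformed repeat line(s) skipped")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               strand = character(0), name = character(0),
               class = character(0), family = character(0))
  bad <- out$class == "" | out$family == ""
  if (any(bad)) {
    n_skipped <- n_skipped + sum(bad)
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Annotate bins with GC content and repeat elements
#'
#' Computes the GC fraction of each bin from the region sequence, classifies
#' bins as hotspot (`BF >= bf_threshold`) or neutral, lists the repeat
#' elements overlapping each bin, and tallies element classes separately for
#' the hotspot and neutral bin sets. An element spanning several bins of one
#' class is counted once for that class (distinct elements per set);
#' percentages are floored to whole percent.
#'
#' @param track a [bin_track()] (or data frame with `start`, `end`, `bf`).
#' @param elements repeat-element data frame from [parse_repeat_table()]
#'   (0-based half-open coordinates).
#' @param sequence region sequence as a single character string /
#'   `DNAString(Set)` starting at the first bin's position, or NULL to skip
#'   GC.
#' @param chrom chromosome of the track; elements on other chromosomes are
#'   an error.
#' @param bf_threshold hotspot classification threshold; default 100.
#' @return List of class `"bin_annotation"`: `bins` (per-bin GC, class,
#'   element count), `elements` (input rows plus bin-set membership), and
#'   `class_tally` (per-class distinct-element counts and floored
#'   percentages for each set).
#' @export
annotate_bins <- function(track, elements, sequence = NULL, chrom = NULL,
                          bf_threshold = 100) {
  chrom <- chrom %||% attr(track, "chrom") %||% "region"
  if (nrow(elements) && !any(elements$chrom == chrom))
    stop("chromosome mismatch: no element on ", chrom)
  elements <- elements[elements$chrom == chrom, , drop = FALSE]
  nb <- nrow(track)
  gc <- rep(NA_real_, nb)
  if (!is.null(sequence)) {
    if (inherits(sequence, "DNAStringSet")) sequence <- as.character(sequence)[1]
    sequence <- as.character(sequence)
    offs <- track$start - track$start[1]
    seqs <- substring(sequence, offs + 1, offs + (track$end - track$start))
    ok <- nchar(seqs) > 0
    gc[ok] <- gc_content(seqs[ok])
  }
  bf_class <- ifelse(track$bf >= bf_threshold, "hotspot", "neutral")
  # half-open bin [start, end) vs 0-based half-open element [s, e):
  # overlap iff s < bin_end - 1 + 1 and e > bin_start - 1 (1-based algebra
  # handled via IRanges on closed integer intervals)
  bins_ir <- IRanges::IRanges(start = track$start, end = track$end - 1)
  n_el <- integer(nb)
  el_hot <- el_neu <- logical(nrow(elements))
  if (nrow(elements)) {
    el_ir <- IRanges::IRanges(start = elements$start + 1, end = elements$end)
    ov <- IRanges::findOverlaps(bins_ir, el_ir)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    n_el <- tabulate(qh, nbins = nb)
    el_hot <- seq_len(nrow(elements)) %in% sh[bf_class[qh] == "hotspot"]
    el_neu <- seq_len(nrow(elements)) %in% sh[bf_class[qh] == "neutral"]
  }
  elements$in_hotspot_bins <- el_hot
  elements$in_neutral_bins <- el_neu
  classes <- sort(unique(elements$class))
  tally <- data.frame(
    class = classes,
    hotspot_n = vapply(classes, function(cl)
      sum(elements$class == cl & el_hot), integer(1)),
    neutral_n = vapply(classes, function(cl)
      sum(elements$class == cl & el_neu), integer(1)))
  tally$hotspot_pct <- floor(100 * tally$hotspot_n / max(1, sum(tally$hotspot_n)))
  tally$neutral_pct <- floor(100 * tally$neutral_n / max(1, sum(tally$neutral_n)))
  structure(list(bins = data.frame(start = track$start, end = track$end,
                                   gc = gc, bf = track$bf,
                                   bf_class = bf_class, n_elements = n_el),
                 elements = elements, class_tally = tally),
            class = "bin_annotation")
}

#' @export
print.bin_annotation <- function(x, ...) {
  nh <- sum(x$bins$bf_class == "hotspot")
  cat(sprintf("bin annotation: %d bins (%d hotspot, %d neutral), %d elements\n",
              nrow(x$bins), nh, nrow(x$bins) - nh, nrow(x$elements)))
  print(x$class_tally, row.names = FALSE)
  invisible(x)
}

#' Correlation between GC content and Bayes factor
#'
#' Pearson correlation of per-bin GC fraction against `log10(BF)`, with a
#' two-sided p-value; bins with undefined GC are excluded.
#'
#' @param gc per-bin GC fractions.
#' @param bf per-bin Bayes factors (`> 0`).
#' @return The `stats::cor.test` result.
#' @export
correlate_gc_bf <- function(gc, bf) {
  stopifnot(length(gc) == length(bf))
  ok <- !is.na(gc) & !is.na(bf)
  gc <- gc[ok]; lbf <- log10(bf[ok])
  if (length(gc) < 3) stop("at least 3 bins with defined GC are required")
  if (stats::var(gc) == 0 || stats::var(lbf) == 0)
    stop(errorCondition("zero variance: correlation undefined",
                        class = c("rhomap_degenerate", "error")))
  stats::cor.test(gc, lbf, method = "pearson")
}

#' Welch t-test of GC content between bin classes
#'
#' @param hot GC values of hotspot bins (`BF >= 100`).
#' @param neutral GC values of neutral bins.
#' @return The `stats::t.test` (Welch) result.
#' @export
ttest_gc <- function(hot, neutral) {
  hot <- hot[!is.na(hot)]; neutral <- neutral[!is.na(neutral)]
  if (length(hot) < 2 || length(neutral) < 2)
    stop("each bin class needs at least 2 GC values")
  stats::t.test(hot, neutral, var.equal = FALSE)
}

#' Read region sequences from FASTA
#'
#' @param path FASTA file.
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_region_fasta <- function(path) Biostrings::readDNAStringSet(path)
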