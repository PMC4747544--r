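# Table-style reporting: per-region and per-hotspot summary arithmetic with
# the conventions used in array-based regional recombination surveys
# (region size = end - start; mean inter-SNP distance truncated to whole bp;
# means rounded at the precision the summaries are printed at).

#' Per-region summary table
#'
#' From per-region marker counts, coordinates, mean rates and bin counts,
#' computes region size (`end - start`), mean inter-SNP distance
#' (`size / (n_snps - 1)`, truncated to integer bp) and appends `Mean` and
#' `Total` rows (means rounded to the printed precision; rho to whole
#' units).
#'
#' @param regions data frame with columns `chr`, `n_snps`, `start`, `end`,
#'   `mean_rho`, `bins_lt100`, `bins_ge100`.
#' @return Data frame of class `"region_summary"` with computed columns and
#'   the two summary rows.
#' @export
region_summary <- function(regions) {
  need <- c("chr", "n_snps", "start", "end", "mean_rho", "bins_lt100",
            "bins_ge100")
  stopifnot(all(need %in% names(regions)))
  r <- regions
  r$size <- r$end - r$start
  r$mean_inter_snp <- trunc(r$size / (r$n_snps - 1))
  r$bins_total <- r$bins_lt100 + r$bins_ge100
  mean_row <- data.frame(
    chr = "Mean", n_snps = round(mean(r$n_snps)), start = NA, end = NA,
    mean_rho = round(mean(r$mean_rho)),
    bins_lt100 = round(mean(r$bins_lt100)),
    bins_ge100 = round(mean(r$bins_ge100)),
    size = round(mean(r$size)),
    mean_inter_snp = round(mean(r$mean_inter_snp)),
    bins_total = round(mean(r$bins_total)))
  total_row <- data.frame(
    chr = "Total", n_snps = sum(r$n_snps), start = NA, end = NA,
    mean_rho = NA, bins_lt100 = sum(r$bins_lt100),
    bins_ge100 = sum(r$bins_ge100), size = sum(r$size),
    mean_inter_snp = NA, bins_total = sum(r$bins_total))
  out <- rbind(r[names(mean_row)], mean_row, total_row)
  rownames(out) <- NULL
  class(out) <- c("region_summary", "data.frame")
  out
}

#' Per-hotspot summary table
#'
#' Computes size in kb from the call coordinates and appends a `Mean` row
#' (size and GC to 2 decimals, bin count to whole bins, PP and BF to 2
#' decimals).
#'
#' @param hotspots data frame with columns `chr`, `start`, `end`, `n_bins`,
#'   `mean_pp`, `mean_bf` and optionally `mean_gc`.
#' @return Data frame of class `"hotspot_summary"`.
#' @export
hotspot_summary <- function(hotspots) {
  h <- hotspots
  h$size_kb <- (h$end - h$start) / 1000
  has_gc <- "mean_gc" %in% names(h)
  mean_row <- data.frame(
    chr = "Mean", start = NA, end = NA,
    n_bins = round(mean(h$n_bins)), mean_pp = round(mean(h$mean_pp), 2),
    mean_bf = round(mean(h$mean_bf), 2),
    size_kb = round(mean(h$size_kb), 2))
  if (has_gc) mean_row$mean_gc <- round(mean(h$mean_gc), 2)
  cols <- c("chr", "start", "end", "size_kb", "n_bins", "mean_pp", "mean_bf",
            if (has_gc) "mean_gc")
  out <- rbind(h[cols], mean_row[cols])
  rownames(out) <- NULL
  class(out) <- c("hotspot_summary", "data.frame")
  out
}

#' Gaps between consecutive hotspots on one chromosome
#'
#' Gap = next hotspot's start minus the previous hotspot's end.
#'
#' @param hotspots data frame with `chr`, `start`, `end`.
#' @return Data frame with `chr` and `gap` (bp) per consecutive pair.
#' @export
hotspot_gaps <- function(hotspots) {
  out <- lapply(split(hotspots, hotspots$chr), function(h) {
    h <- h[order(h$start), , drop = FALSE]
    if (nrow(h) < 2) return(NULL)
    data.frame(chr = h$chr[-1], gap = h$start[-1] - h$end[-nrow(h)])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(chr = character(0), gap = numeric(0))
  rownames(out) <- NULL
  out
}

#' Bundled summaries of a published cat regional recombination survey
#'
#' Region-level and hotspot-level summary tables from a published array-based
#' survey of fine-scale recombination in ten genomic regions of the domestic
#' cat (22 individuals, 701 SNPs), bundled as the package's worked example:
#' per-region marker counts, assembly coordinates, mean population-scaled
#' rates and bin classifications; the four called hotspots with their mean
#' posterior probability, Bayes factor and GC content; and the 22 repeat and
#' variation elements within the hotspot intervals.
#'
#' @return `cat_region_table()`: per-region data frame; `cat_hotspot_table()`:
#'   per-hotspot data frame; `cat_hotspot_elements()`: element data frame
#'   with `class` and `family`.
#' @export
cat_region_table <- function() {
  utils::read.table(system.file("extdata", "cat_regions.tsv",
                                package = "rhomap"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname cat_region_table
#' @export
cat_hotspot_table <- function() {
  utils::read.table(system.file("extdata", "cat_hotspots.tsv",
                                package = "rhomap"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname cat_region_table
#' @export
cat_hotspot_elements <- function() {
  utils::read.table(system.file("extdata", "cat_hotspot_elements.tsv",
                                package = "rhomap"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
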