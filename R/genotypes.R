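#' SNP genotype container
#'
#' Builds the genotype object used throughout the package: biallelic SNP
#' calls (0/1/2 copies of the alternate allele, `NA` = missing) for a set of
#' individuals at ordered positions on one chromosome. Per-marker call rate
#' and minor allele frequency are computed from the non-missing calls.
#'
#' @param calls integer matrix, markers in rows, individuals in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param positions integer vector of 1-based bp positions, strictly
#'   increasing after sorting; duplicates are an error.
#' @param chrom single chromosome label.
#' @param ref,alt optional allele labels per marker.
#' @param samples individual identifiers; defaults to column names or `ind1..`.
#' @param region length-2 vector `c(start, end)` in bp; defaults to the
#'   marker span.
#' @param unique_mapping logical per marker: mapped to a single chromosomal
#'   location. Defaults to `TRUE`.
#' @param haplotypes optional 0/1 matrix with markers in rows and `2 *
#'   ncol(calls)` haplotype columns; column pairs `(2i-1, 2i)` must sum to the
#'   genotype calls of individual `i`.
#' @return An object of class `"genotypes"`.
#' @export
genotype_matrix <- function(calls, positions, chrom = "chr", ref = NULL,
                            alt = NULL, samples = NULL, region = NULL,
                            unique_mapping = TRUE, haplotypes = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  k <- nrow(calls)
  if (length(positions) != k)
    stop("length(positions) must equal nrow(calls)")
  if (anyDuplicated(positions))
    stop("duplicate marker positions are not allowed")
  if (is.unsorted(positions)) {
    warning("marker positions were not sorted; sorting")
    o <- order(positions)
    positions <- positions[o]
    calls <- calls[o, , drop = FALSE]
    if (!is.null(ref)) ref <- ref[o]
    if (!is.null(alt)) alt <- alt[o]
    if (length(unique_mapping) == k) unique_mapping <- unique_mapping[o]
    if (!is.null(haplotypes)) haplotypes <- haplotypes[o, , drop = FALSE]
  }
  if (any(!calls %in% c(0L, 1L, 2L, NA)))
    stop("genotype calls must be 0, 1, 2 or NA")
  if (is.null(samples)) {
    samples <- colnames(calls)
    if (is.null(samples)) samples <- paste0("ind", seq_len(ncol(calls)))
  }
  if (is.null(region)) region <- c(min(positions), max(positions))
  if (region[1] > min(positions) || region[2] < max(positions))
    stop("markers fall outside the stated region")
  unique_mapping <- rep_len(as.logical(unique_mapping), k)
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    if (!all(dim(haplotypes) == c(k, 2L * ncol(calls))))
      stop("haplotype matrix must be k x 2n")
    gsum <- haplotypes[, seq(1, ncol(haplotypes), 2), drop = FALSE] +
      haplotypes[, seq(2, ncol(haplotypes), 2), drop = FALSE]
    ok <- is.na(gsum) | is.na(calls) | gsum == calls
    if (!all(ok)) stop("haplotype pair sums do not reproduce the genotype calls")
  }
  g <- structure(list(
    chrom = as.character(chrom)[1],
    markers = data.frame(
      pos = as.integer(positions),
      ref = if (is.null(ref)) rep("A", k) else as.character(ref),
      alt = if (is.null(alt)) rep("G", k) else as.character(alt),
      unique_mapping = unique_mapping,
      stringsAsFactors = FALSE
    ),
    calls = unname(calls),
    samples = as.character(samples),
    region = as.numeric(region),
    haplotypes = haplotypes
  ), class = "genotypes")
  g$markers$call_rate <- marker_call_rate(g)
  g$markers$maf <- marker_maf(g)
  g
}

marker_call_rate <- function(g) rowMeans(!is.na(g$calls))

# MAF from non-missing calls only
marker_maf <- function(g) {
  nn <- rowSums(!is.na(g$calls))
  af <- rowSums(g$calls, na.rm = TRUE) / (2 * pmax(nn, 1L))
  af[nn == 0] <- NA_real_
  pmin(af, 1 - af)
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("SNP genotypes: %d markers x %d individuals on %s [%s-%s]\n",
              nrow(x$calls), ncol(x$calls), x$chrom,
              format(x$region[1], big.mark = ","),
              format(x$region[2], big.mark = ",")))
  cat(sprintf("  call rate %.2f-%.2f, MAF %.2f-%.2f, %s\n",
              min(x$markers$call_rate), max(x$markers$call_rate),
              min(x$markers$maf, na.rm = TRUE), max(x$markers$maf, na.rm = TRUE),
              if (is.null(x$haplotypes)) "unphased" else "phased"))
  invisible(x)
}

#' Marker table of a genotype object
#'
#' @param g a `"genotypes"` object.
#' @return Data frame of per-marker position, alleles, mapping flag, call
#'   rate and minor allele frequency, plus the inter-marker distances
#'   `d[i] = pos[i+1] - pos[i]` as attribute `"distances"`.
#' @export
marker_set <- function(g) {
  m <- g$markers
  attr(m, "chrom") <- g$chrom
  attr(m, "region") <- g$region
  attr(m, "distances") <- diff(m$pos)
  m
}

#' Read SNP genotypes from VCF or TSV
#'
#' The TSV dialect has a header line with columns `chrom`, `pos`, `ref`,
#' `alt`, then one column per individual coded 0/1/2/NA (copies of the
#' alternate allele). VCF input is restricted to biallelic SNVs; other
#' records are skipped with a message. An unsorted file is sorted with a
#' warning; duplicated positions are an error.
#'
#' @param source path to a `.vcf` or TSV genotype file.
#' @param region optional `c(start, end)` in 1-based bp; markers outside are
#'   dropped.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return A [genotype_matrix()] object.
#' @export
read_genotypes <- function(source, region = NULL,
                           format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", source, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") g <- read_genotypes_vcf(source) else g <- read_genotypes_tsv(source)
  if (!is.null(region)) {
    keep <- g$markers$pos >= region[1] & g$markers$pos <= region[2]
    if (!any(keep)) stop("no markers inside the requested region")
    g <- subset_markers(g, which(keep))
    g$region <- as.numeric(region)
  }
  g
}

read_genotypes_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(d)))
    stop("TSV genotype file must have columns chrom, pos, ref, alt, <samples>")
  multi <- grepl(",", d$alt, fixed = TRUE)
  if (any(multi)) {
    message(sum(multi), " non-biallelic record(s) skipped")
    d <- d[!multi, , drop = FALSE]
  }
  chrom <- unique(d$chrom)
  if (length(chrom) != 1) stop("TSV file must contain a single chromosome")
  gcols <- setdiff(names(d), need)
  if (length(gcols) == 0) stop("no sample columns found")
  calls <- as.matrix(d[, gcols, drop = FALSE])
  genotype_matrix(calls, d$pos, chrom = chrom, ref = d$ref, alt = d$alt,
                  samples = gcols)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  fx <- vcfR::getFIX(vcf)
  snv <- nchar(fx[, "REF"]) == 1 & nchar(fx[, "ALT"]) == 1 & !is.na(fx[, "ALT"])
  keep <- bi & snv
  if (any(!keep)) message(sum(!keep), " non-biallelic record(s) skipped")
  if (!any(keep)) stop("no biallelic SNVs in VCF")
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  fx <- fx[keep, , drop = FALSE]
  chrom <- unique(fx[, "CHROM"])
  if (length(chrom) != 1) stop("VCF must contain a single chromosome")
  alt_count <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
    vapply(a, function(al) {
      if (length(al) == 0 || any(al == ".") || any(is.na(al))) return(NA_integer_)
      sum(al != "0")
    }, integer(1))
  }
  calls <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  for (j in seq_len(ncol(gt))) calls[, j] <- alt_count(gt[, j])
  genotype_matrix(calls, as.integer(fx[, "POS"]), chrom = chrom,
                  ref = fx[, "REF"], alt = fx[, "ALT"], samples = colnames(gt))
}

subset_markers <- function(g, idx) {
  genotype_matrix(g$calls[idx, , drop = FALSE], g$markers$pos[idx],
                  chrom = g$chrom, ref = g$markers$ref[idx],
                  alt = g$markers$alt[idx], samples = g$samples,
                  region = g$region,
                  unique_mapping = g$markers$unique_mapping[idx],
                  haplotypes = if (is.null(g$haplotypes)) NULL else
                    g$haplotypes[idx, , drop = FALSE])
}

#' Filter markers on mapping, call rate and minor allele frequency
#'
#' Retains markers that (i) map to a single chromosomal location, (ii) have a
#' genotype call success rate at or above `min_call_rate` and (iii) have a
#' sample minor allele frequency at or above `min_maf`. Both thresholds are
#' inclusive. Removal counts are attributed in that order, so each removed
#' marker is counted once.
#'
#' @param g a `"genotypes"` object.
#' @param min_call_rate,min_maf thresholds in `[0, 1]`; defaults 0.8 and 0.1.
#' @return The filtered `"genotypes"` object with a `"filter_report"`
#'   attribute: list with `n_in`, `n_out`, and per-criterion removal counts.
#' @export
apply_filters <- function(g, min_call_rate = 0.8, min_maf = 0.1) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1, min_maf >= 0, min_maf <= 1)
  m <- g$markers
  fail_map <- !m$unique_mapping
  fail_cr <- !fail_map & m$call_rate < min_call_rate
  fail_maf <- !fail_map & !fail_cr & (is.na(m$maf) | m$maf < min_maf)
  keep <- !(fail_map | fail_cr | fail_maf)
  if (!any(keep))
    stop(errorCondition("all markers removed by filtering; region unusable",
                        class = c("rhomap_empty_region", "error")))
  out <- subset_markers(g, which(keep))
  attr(out, "filter_report") <- list(
    n_in = nrow(m), n_out = sum(keep),
    removed = c(unique_mapping = sum(fail_map), call_rate = sum(fail_cr),
                maf = sum(fail_maf)))
  out
}

#' Partition markers into contiguous blocks
#'
#' Splits `k` ordered markers into contiguous blocks of `block_size` with the
#' remainder in the final block; a remainder smaller than `min_remainder` is
#' merged into the preceding block, since a near-empty block carries no
#' recombination information.
#'
#' @param x a `"genotypes"` object, a [marker_set()] data frame, or a marker
#'   count.
#' @param block_size target markers per block; default 20.
#' @param min_remainder smallest remainder kept as its own block; default 5.
#' @return List with `sizes` (block sizes) and `assignments` (block index per
#'   marker), class `"block_partition"`.
#' @export
partition_blocks <- function(x, block_size = 20, min_remainder = 5) {
  k <- if (is.numeric(x) && length(x) == 1) as.integer(x)
       else if (inherits(x, "genotypes")) nrow(x$calls)
       else nrow(x)
  if (k < 2) stop("at least 2 markers are required")
  nfull <- k %/% block_size
  rem <- k %% block_size
  if (nfull == 0) sizes <- k
  else {
    sizes <- rep(block_size, nfull)
    if (rem >= min_remainder) sizes <- c(sizes, rem)
    else if (rem > 0) sizes[nfull] <- sizes[nfull] + rem
  }
  structure(list(sizes = sizes,
                 assignments = rep(seq_along(sizes), sizes)),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat("block partition:", paste(x$sizes, collapse = ", "), "markers\n")
  invisible(x)
}

#' Resolve unphased genotypes to haplotypes by random phase assignment
#'
#' Heterozygous calls are assigned a uniformly random phase under the given
#' seed. This is a documented stand-in for statistical phasing: linkage
#' information between heterozygous markers is destroyed in expectation, which
#' weakens but does not bias two-locus recombination signal.
#'
#' @param g a `"genotypes"` object.
#' @param seed integer seed for the phase assignment.
#' @return `g` with a `haplotypes` matrix (columns `2i-1`, `2i` are the two
#'   haplotypes of individual `i`; missing genotypes give `NA` haplotypes).
#' @export
phase_genotypes <- function(g, seed = 1) {
  if (!is.null(g$haplotypes)) return(g)
  k <- nrow(g$calls); n <- ncol(g$calls)
  set.seed(seed)
  h <- matrix(NA_integer_, k, 2 * n)
  for (j in seq_len(n)) {
    cj <- g$calls[, j]
    a <- ifelse(cj == 2L, 1L, 0L)
    b <- a
    het <- which(!is.na(cj) & cj == 1L)
    if (length(het)) {
      flip <- stats::runif(length(het)) < 0.5
      a[het] <- as.integer(flip)
      b[het] <- 1L - as.integer(flip)
    }
    h[, 2 * j - 1] <- a
    h[, 2 * j] <- b
  }
  message("unphased genotypes resolved by random phase assignment (seed ",
          seed, "); between-marker phase is not informative")
  g$haplotypes <- h
  g
}

#' Write genotypes in the package TSV dialect
#'
#' @param g a `"genotypes"` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(g, path) {
  d <- data.frame(chrom = g$chrom, pos = g$markers$pos, ref = g$markers$ref,
                  alt = g$markers$alt, stringsAsFactors = FALSE)
  calls <- g$calls
  colnames(calls) <- g$samples
  utils::write.table(cbind(d, calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write genotypes as minimal VCF 4.2
#'
#' @inheritParams write_genotypes_tsv
#' @export
write_genotypes_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", g$chrom, ">"),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples), collapse = "\t")), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (i in seq_len(nrow(g$calls))) {
    gt <- gt_code[as.character(g$calls[i, ])]
    gt[is.na(gt)] <- "./."
    writeLines(paste(c(g$chrom, g$markers$pos[i], ".", g$markers$ref[i],
                       g$markers$alt[i], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}
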