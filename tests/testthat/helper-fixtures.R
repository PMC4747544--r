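# Shared fixtures and small utilities, all generated in code.

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# simple 3-marker TSV genotype file (positions 100, 200, 300; 4 individuals)
tsv3_path <- function() {
  write_tsv_fixture(c(
    "chrom\tpos\tref\talt\ts1\ts2\ts3\ts4",
    "chr1\t100\tA\tG\t0\t1\t2\t1",
    "chr1\t200\tC\tT\t1\t1\t0\t2",
    "chr1\t300\tG\tA\t2\t0\t1\t1"))
}

# VCF with 5 records, one of them triallelic
vcf5_path <- function() {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t./.\t0/0",
    "chr1\t300\t.\tG\tA,C\t.\tPASS\t.\tGT\t1/2\t0/1\t0/0",
    "chr1\t400\t.\tT\tC\t.\tPASS\t.\tGT\t1/1\t0/1\t0/1",
    "chr1\t500\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1"), path)
  path
}

# fraction of marker pairs displaying all four gametes
four_gamete_pairs <- function(h) {
  S <- ncol(h)
  if (S < 2) return(integer(0))
  out <- matrix(FALSE, S, S)
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    a <- h[, i]; b <- h[, j]
    out[i, j] <- all(c(any(a == 0 & b == 0), any(a == 0 & b == 1),
                       any(a == 1 & b == 0), any(a == 1 & b == 1)))
  }
  out
}

pair_r2 <- function(h, i, j) {
  a <- h[, i]; b <- h[, j]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

# memoized shared lookup tables (built once per test session)
.fixture_env <- new.env()
shared_table <- function(n, reps = 3000, seed = 7) {
  key <- paste0("tab_", n, "_", reps, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- two_locus_table(n, reps = reps, seed = seed)
  .fixture_env[[key]]
}
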