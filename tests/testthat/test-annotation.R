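test_that("GC content follows the N-exclusion rule and rejects bad characters", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("NNGG"), 1.0)
  expect_equal(gc_content("atgc"), 0.5)
  expect_true(is.na(gc_content("NNNN")))
  expect_error(gc_content("ATXG"), "illegal character")
  expect_equal(gc_content(c("ATGC", "GGGG")), c(0.5, 1))
})

test_that("GC of a concatenation is the base-weighted mean of the parts", {
  set.seed(3)
  parts <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), sample(20:60, 1), TRUE),
          collapse = ""), character(1))
  whole <- paste(parts, collapse = "")
  gcs <- gc_content(parts)
  w <- vapply(parts, function(s)
    sum(strsplit(s, "")[[1]] != "N"), numeric(1))
  expect_equal(gc_content(whole), sum(gcs * w) / sum(w), tolerance = 1e-12)
})

test_that("GC agrees with the ape reference implementation", {
  set.seed(8)
  s <- paste(sample(c("a", "c", "g", "t"), 400, TRUE), collapse = "")
  ref <- ape::GC.content(ape::as.DNAbin(strsplit(s, "")[[1]]))
  expect_equal(gc_content(s), ref, tolerance = 1e-12)
})

rmsk_fixture <- function() {
  write_tsv_fixture(c(
    paste(c(607, 239, 310, 0, 0, "chrT", 1200, 1450, -98000, "+", "L2a",
            "LINE", "L2", 300, 550, -100, 1), collapse = "\t"),
    paste(c(608, 500, 120, 5, 2, "chrT", 2600, 2800, -97000, "-", "MIRb",
            "SINE", "MIR", 10, 210, -40, 2), collapse = "\t")))
}

out_fixture <- function() {
  path <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query     position in queryateien    matching  repeat",
    "score   div. del. ins.  sequence  begin end (left)   repeat  class/family  begin end (left) ID",
    "",
    "  607   23.9 31.0  0.0  chrT  1201 1450 (98000) +  L2a   LINE/L2    300 550 (100)  1",
    "  500   12.0  0.5  0.2  chrT  2601 2800 (97000) C  MIRb  SINE/MIR    10 210 (40)   2"), path)
  path
}

test_that("rmsk and .out repeat tables parse to the same elements", {
  r1 <- parse_repeat_table(rmsk_fixture())
  expect_equal(nrow(r1), 2)
  expect_equal(r1$class, c("LINE", "SINE"))
  expect_equal(r1$family, c("L2", "MIR"))
  expect_equal(r1$name, c("L2a", "MIRb"))
  expect_equal(r1$start, c(1200, 2600))
  r2 <- parse_repeat_table(out_fixture())
  expect_equal(r2[c("chrom", "start", "end", "name", "class", "family")],
               r1[c("chrom", "start", "end", "name", "class", "family")])
  expect_equal(r2$strand, c("+", "-"))
})

test_that("malformed repeat lines are skipped and counted", {
  p <- write_tsv_fixture(c(
    paste(c(607, 239, 310, 0, 0, "chrT", 1450, 1200, -98000, "+", "L2a",
            "LINE", "L2", 300, 550, -100, 1), collapse = "\t"),  # end < start
    paste(c(608, 500, 120, 5, 2, "chrT", 2600, 2800, -97000, "-", "MIRb",
            "SINE", "MIR", 10, 210, -40, 2), collapse = "\t")))
  expect_message(r <- parse_repeat_table(p), "1 malformed")
  expect_equal(nrow(r), 1)
  expect_equal(attr(r, "n_skipped"), 1L)
})

# a bin track whose hotspot bins reproduce the bundled cat survey hotspot
# intervals, mapped onto one synthetic coordinate system
cat_like_annotation <- function(elements_shuffled = FALSE) {
  hs <- cat_hotspot_table()
  # synthetic chromosome: concatenate the four hotspot intervals with 1-kb
  # neutral spacers
  widths <- hs$end - hs$start
  starts <- cumsum(c(1000, head(widths + 1000, -1)))
  region <- c(1, max(starts + widths) + 1000)
  track <- bin_probability(list(data.frame(start = 1, end = 2,
                                           multiplier = 1)),
                           region, bin_width = 200)
  track$q <- 0.01
  track$bf <- 1
  for (i in seq_along(starts)) {
    hot <- track$start >= starts[i] & track$end <= starts[i] + widths[i]
    track$bf[hot] <- 500
  }
  # place each catalogued element inside its hotspot interval
  el <- cat_hotspot_elements()
  hs_of <- match(el$hotspot, c("A2", "D1", "E2a", "E2b"))
  n_in <- ave(seq_len(nrow(el)), hs_of, FUN = seq_along)
  el_df <- data.frame(chrom = "synth", start = starts[hs_of] + n_in * 90,
                      end = starts[hs_of] + n_in * 90 + 80,
                      strand = "+", name = el$name, class = el$class,
                      family = el$family)
  if (elements_shuffled) el_df <- el_df[sample.int(nrow(el_df)), ]
  annotate_bins(track, el_df, chrom = "synth")
}

test_that("element tallies reproduce the survey proportions (SINE 40%, LINE 27%)", {
  ann <- cat_like_annotation()
  tal <- ann$class_tally
  expect_equal(sum(tal$hotspot_n), 22)
  expect_equal(tal$hotspot_pct[tal$class == "SINE"], 40)
  expect_equal(tal$hotspot_pct[tal$class == "LINE"], 27)
  expect_equal(tal$hotspot_n[tal$class == "SINE"], 9)
  expect_equal(tal$hotspot_n[tal$class == "LINE"], 6)
})

test_that("tallies are invariant to element order and empty input gives zeros", {
  set.seed(14)
  a1 <- cat_like_annotation()
  a2 <- cat_like_annotation(elements_shuffled = TRUE)
  t1 <- a1$class_tally[order(a1$class_tally$class), ]
  t2 <- a2$class_tally[order(a2$class_tally$class), ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1, t2)
  track <- data.frame(start = c(1, 201), end = c(201, 401), bf = c(1, 500))
  empty <- annotate_bins(track,
                         data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0), strand = character(0),
                                    name = character(0), class = character(0),
                                    family = character(0)),
                         chrom = "synth")
  expect_equal(nrow(empty$class_tally), 0)
  expect_true(all(empty$bins$n_elements == 0))
})

test_that("an element spanning several bins of a class is counted once per set", {
  track <- data.frame(start = c(1, 201, 401, 601),
                      end = c(201, 401, 601, 801),
                      bf = c(500, 500, 1, 1))
  el <- data.frame(chrom = "c", start = 50, end = 700, strand = "+",
                   name = "L2a", class = "LINE", family = "L2")
  ann <- annotate_bins(track, el, chrom = "c")
  # overlaps two hotspot bins and two neutral bins but counts once per set
  expect_equal(ann$class_tally$hotspot_n, 1L)
  expect_equal(ann$class_tally$neutral_n, 1L)
  expect_equal(sum(ann$bins$n_elements), 4)
})

test_that("per-bin GC is computed from the region sequence", {
  track <- data.frame(start = c(1, 201), end = c(201, 401), bf = c(1, 1))
  seqs <- paste0(paste(rep("AT", 100), collapse = ""),
                 paste(rep("GC", 100), collapse = ""))
  ann <- annotate_bins(track,
                       data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0), strand = character(0),
                                  name = character(0), class = character(0),
                                  family = character(0)),
                       sequence = seqs, chrom = "c")
  expect_equal(ann$bins$gc, c(0, 1))
})

test_that("GC/BF correlation behaves on exact, inverted and degenerate input", {
  bf <- c(10, 50, 100, 500, 1000)
  r <- correlate_gc_bf(log10(bf), bf)
  expect_equal(unname(r$estimate), 1)
  r2 <- correlate_gc_bf(-log10(bf), bf)
  expect_equal(unname(r2$estimate), -1)
  expect_error(correlate_gc_bf(rep(0.4, 5), bf), class = "rhomap_degenerate")
  # affine rescaling leaves the correlation magnitude unchanged
  set.seed(2)
  gc <- stats::runif(30, 0.3, 0.6)
  bfr <- stats::rlnorm(30, 2, 1)
  r3 <- correlate_gc_bf(gc, bfr)
  r4 <- correlate_gc_bf(0.2 + 3 * gc, bfr)
  expect_equal(unname(r3$estimate), unname(r4$estimate), tolerance = 1e-12)
})

test_that("Welch t-test gives t = 0 for identical groups and detects shifts", {
  g <- c(0.3, 0.35, 0.4, 0.45)
  r <- ttest_gc(g, g)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)
  set.seed(6)
  hot <- c(0.3, 0.3, 0.3, 0.3) + stats::rnorm(4, 0, 1e-3)
  neu <- c(0.5, 0.5, 0.5, 0.5) + stats::rnorm(4, 0, 1e-3)
  expect_lt(ttest_gc(hot, neu)$p.value, 0.01)
  # equal-variance equal-size groups: Welch df equals the pooled 2n - 2
  a <- c(0.3, 0.4, 0.5); b <- c(0.5, 0.6, 0.7)
  expect_equal(unname(ttest_gc(a, b)$parameter), 4, tolerance = 1e-9)
  expect_error(ttest_gc(0.4, c(0.3, 0.5)), "at least 2")
})
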