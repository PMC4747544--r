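#' Per-bin hotspot probability from posterior samples
#'
#' Tiles the region with `bin_width`-bp half-open bins starting at the region
#' start (a final partial bin is kept and flagged) and computes, per bin, the
#' fraction of samples in which any hotspot interval overlaps the bin
#' (nonempty intersection of half-open intervals).
#'
#' @param samples a `"rhomap_fit"`, or a list of hotspot interval data frames
#'   (`start`, `end` in absolute bp).
#' @param region `c(start, end)` in bp; taken from the fit when omitted.
#' @param bin_width bin width in bp; default 200.
#' @return Data frame with `start`, `end` (half-open bp) and `p`; attribute
#'   `"n_samples"`; the last row may be a flagged partial bin (attribute
#'   `"partial_last"`).
#' @export
bin_probability <- function(samples, region = NULL, bin_width = 200) {
  if (inherits(samples, "rhomap_fit")) {
    if (is.null(region)) region <- samples$region
    samples <- samples$hotspots
  }
  if (is.null(region)) stop("region is required")
  if (length(samples) == 0) stop("at least one sample is required")
  L <- region[2] - region[1]
  nb <- ceiling(L / bin_width)
  starts <- region[1] + (seq_len(nb) - 1) * bin_width
  ends <- pmin(starts + bin_width, region[2])
  hits <- integer(nb)
  for (s in samples) {
    if (is.null(s) || nrow(s) == 0) next
    covered <- rep(FALSE, nb)
    for (i in seq_len(nrow(s))) {
      lo <- floor((s$start[i] - region[1]) / bin_width) + 1
      hi <- ceiling((s$end[i] - region[1]) / bin_width)
      if (hi < 1 || lo > nb) next
      covered[max(1, lo):min(nb, hi)] <- TRUE
    }
    hits <- hits + covered
  }
  out <- data.frame(start = starts, end = ends, p = hits / length(samples))
  attr(out, "n_samples") <- length(samples)
  attr(out, "partial_last") <- (ends[nb] - starts[nb]) < bin_width
  out
}

#' Bayes factor for hotspot presence in a bin
#'
#' `BF = [p / (1 - p)] / [q / (1 - q)]`, the posterior odds of a hotspot
#' covering the bin divided by the prior odds. Probabilities are clamped to
#' `[eps, 1 - eps]` with `eps = 1 / (2 * n_samples)` (and
#' `1 / (2 * n_prior_samples)` for q), so empirical 0 and 1 stay finite.
#'
#' @param p posterior bin probability (vectorized).
#' @param q prior bin probability.
#' @param n_samples posterior sample count behind `p`.
#' @param n_prior_samples prior sample count behind `q`; defaults to
#'   `n_samples`.
#' @return Bayes factors, `>= 0`.
#' @export
bayes_factor <- function(p, q, n_samples, n_prior_samples = n_samples) {
  stopifnot(n_samples >= 1, all(p >= 0 & p <= 1, na.rm = TRUE),
            all(q >= 0 & q <= 1, na.rm = TRUE))
  eps_p <- 1 / (2 * n_samples)
  eps_q <- 1 / (2 * n_prior_samples)
  pc <- pmin(pmax(p, eps_p), 1 - eps_p)
  qc <- pmin(pmax(q, eps_q), 1 - eps_q)
  (pc / (1 - pc)) / (qc / (1 - qc))
}

#' Binned posterior/prior probabilities and Bayes factors
#'
#' @param fit a `"rhomap_fit"` from data.
#' @param prior_fit a `"rhomap_fit"` from the matching prior-only chain
#'   (see [prior_chain()]).
#' @param bin_width bin width in bp.
#' @return Data frame of class `"bin_track"`: `start`, `end`, `p`, `q`, `bf`.
#' @export
bin_track <- function(fit, prior_fit, bin_width = 200) {
  stopifnot(inherits(fit, "rhomap_fit"), inherits(prior_fit, "rhomap_fit"))
  if (!isTRUE(all.equal(fit$region, prior_fit$region)))
    stop("posterior and prior chains cover different regions")
  post <- bin_probability(fit, bin_width = bin_width)
  pri <- bin_probability(prior_fit, bin_width = bin_width)
  out <- data.frame(start = post$start, end = post$end, p = post$p, q = pri$p)
  out$bf <- bayes_factor(out$p, out$q, attr(post, "n_samples"),
                         attr(pri, "n_samples"))
  attr(out, "n_samples") <- attr(post, "n_samples")
  attr(out, "n_prior_samples") <- attr(pri, "n_samples")
  attr(out, "partial_last") <- attr(post, "partial_last")
  attr(out, "chrom") <- fit$chrom
  class(out) <- c("bin_track", "data.frame")
  out
}

#' Call hotspots as runs of consecutive high-Bayes-factor bins
#'
#' A hotspot is a maximal run of at least `min_consecutive` consecutive bins
#' with `BF >= bf_threshold`; reported start/end are the outer coordinates of
#' the member bins. All other bins are "neutral".
#'
#' @param track a [bin_track()] (or data frame with `start`, `end`, `p`,
#'   `bf`).
#' @param bf_threshold Bayes-factor threshold; default 100.
#' @param min_consecutive minimum run length; default 2.
#' @return Data frame of class `"hotspot_calls"`: `start`, `end`, `size`
#'   (bp), `n_bins`, `mean_pp`, `mean_bf`; zero rows when nothing qualifies.
#' @export
call_hotspots <- function(track, bf_threshold = 100, min_consecutive = 2) {
  hot <- track$bf >= bf_threshold
  r <- rle(hot)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1
  sel <- which(r$values & r$lengths >= min_consecutive)
  out <- data.frame(start = track$start[starts_i[sel]],
                    end = track$end[ends_i[sel]],
                    n_bins = r$lengths[sel],
                    mean_pp = vapply(sel, function(i)
                      mean(track$p[starts_i[i]:ends_i[i]]), numeric(1)),
                    mean_bf = vapply(sel, function(i)
                      mean(track$bf[starts_i[i]:ends_i[i]]), numeric(1)))
  out$size <- out$end - out$start
  out <- out[, c("start", "end", "size", "n_bins", "mean_pp", "mean_bf")]
  class(out) <- c("hotspot_calls", "data.frame")
  out
}

#' Length-weighted mean population recombination rate
#'
#' `mean rho = sum(rho_i * d_i) / sum(d_i)` over the k-1 inter-marker
#' intervals; the numerator (in rho units, with d in Mb) is the total
#' population-scaled recombination rate of the region and the denominator is
#' the region length in Mb.
#'
#' @param rho_per_interval rho per Mb for each inter-marker interval.
#' @param d inter-marker distances in bp (`d[i] = pos[i+1] - pos[i]`).
#' @return List of class `"rate_summary"`: `mean_rho_per_mb`, `total_rho`,
#'   `region_length_mb`.
#' @export
mean_rho <- function(rho_per_interval, d) {
  if (length(rho_per_interval) != length(d))
    stop("rho_per_interval and d must have equal length (k - 1 values)")
  if (any(d <= 0)) stop("all inter-marker distances must be positive")
  total <- sum(rho_per_interval * d) / 1e6
  len_mb <- sum(d) / 1e6
  structure(list(mean_rho_per_mb = total / len_mb, total_rho = total,
                 region_length_mb = len_mb), class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("mean rho: %.4g /Mb (total rho %.4g over %.4g Mb)\n",
              x$mean_rho_per_mb, x$total_rho, x$region_length_mb))
  invisible(x)
}

#' Convert a population-scaled rate to cM/Mb
#'
#' `c = rho / (ploidy_factor * N_e)` recombinations per Mb per generation,
#' reported as cM/Mb (x 100).
#'
#' @param rho_per_mb population-scaled rate per Mb.
#' @param n_e effective population size.
#' @param ploidy_factor 4 for the nuclear genome of a diploid.
#' @return Rate in cM/Mb.
#' @export
rho_to_cm_per_mb <- function(rho_per_mb, n_e, ploidy_factor = 4) {
  stopifnot(n_e > 0)
  100 * rho_per_mb / (ploidy_factor * n_e)
}

#' @rdname rho_to_cm_per_mb
#' @param cm_per_mb rate in cM/Mb.
#' @export
cm_per_mb_to_rho <- function(cm_per_mb, n_e, ploidy_factor = 4) {
  stopifnot(n_e > 0)
  cm_per_mb / 100 * ploidy_factor * n_e
}

#' Write a bin track as BED-graph-style TSV
#'
#' BED output is 0-based half-open; the TSV report keeps 1-based inclusive
#' coordinates.
#'
#' @param track a [bin_track()].
#' @param path output path.
#' @param chrom chromosome label; defaults to the track's.
#' @return `path`, invisibly.
#' @export
write_bin_track <- function(track, path, chrom = NULL) {
  chrom <- chrom %||% attr(track, "chrom") %||% "region"
  d <- data.frame(chrom = chrom, start = as.integer(track$start - 1),
                  end = as.integer(track$end - 1), p = track$p, q = track$q,
                  bf = track$bf)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write hotspot calls as BED and TSV
#'
#' @param calls a [call_hotspots()] result.
#' @param path output path stem; writes `<path>.bed` (0-based half-open) and
#'   `<path>.tsv` (1-based, Table-style columns).
#' @param chrom chromosome label.
#' @return `path`, invisibly.
#' @export
write_hotspot_calls <- function(calls, path, chrom = "region") {
  bed <- data.frame(chrom = rep(chrom, nrow(calls)),
                    start = as.integer(calls$start - 1),
                    end = as.integer(calls$end - 1),
                    name = sprintf("hotspot%d", seq_len(nrow(calls))),
                    score = round(calls$mean_bf, 2))
  utils::write.table(bed, paste0(path, ".bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tsv <- data.frame(chrom = rep(chrom, nrow(calls)), start = calls$start,
                    end = calls$end, size_kb = calls$size / 1000,
                    n_bins = calls$n_bins, mean_pp = round(calls$mean_pp, 2),
                    mean_bf = round(calls$mean_bf, 2))
  utils::write.table(tsv, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
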