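#' Population model for coalescent simulation
#'
#' @param theta population-scaled mutation rate per site, `4 * N_e * mu`.
#'   Computed from `n_e` and `mu` when missing.
#' @param n_e diploid effective population size.
#' @param mu mutation rate per site per generation.
#' @param ploidy_factor 4 for autosomes.
#' @return Object of class `"population_model"`.
#' @export
population_model <- function(theta = NULL, n_e = NULL, mu = NULL,
                             ploidy_factor = 4) {
  if (is.null(theta)) {
    if (is.null(n_e) || is.null(mu))
      stop("give theta, or both n_e and mu")
    theta <- ploidy_factor * n_e * mu
  } else if (!is.null(n_e) && !is.null(mu) &&
             abs(theta - ploidy_factor * n_e * mu) > 1e-12 * theta) {
    stop("theta inconsistent with ploidy_factor * n_e * mu")
  }
  if (theta <= 0) stop("theta must be positive")
  structure(list(theta = theta, n_e = n_e, mu = mu,
                 ploidy_factor = ploidy_factor), class = "population_model")
}

#' Background-plus-hotspot recombination rate map
#'
#' The local rate at position x (in rho = 4\*Ne\*c per Mb) is
#' `background * (1 + sum_h (multiplier_h - 1))` over hotspots containing x,
#' i.e. a single hotspot elevates the background by its multiplier and
#' overlapping hotspots act additively on the excess.
#'
#' @param region_length region length in bp (positions run 0..region_length).
#' @param background_per_mb background rho per Mb, `>= 0`.
#' @param hotspots data frame with columns `start`, `end` (bp offsets,
#'   half-open) and `multiplier` (`>= 1`), or NULL.
#' @return Object of class `"rate_map"`.
#' @export
rate_map <- function(region_length, background_per_mb, hotspots = NULL) {
  if (region_length <= 0) stop("zero-length region")
  if (background_per_mb < 0) stop("background rate must be >= 0")
  if (is.null(hotspots))
    hotspots <- data.frame(start = numeric(0), end = numeric(0),
                           multiplier = numeric(0))
  stopifnot(all(c("start", "end", "multiplier") %in% names(hotspots)))
  if (nrow(hotspots)) {
    if (any(hotspots$end <= hotspots$start)) stop("hotspot end must exceed start")
    if (any(hotspots$start < 0 | hotspots$end > region_length))
      stop("hotspot intervals must lie within the region")
    if (any(!is.finite(hotspots$multiplier)) || any(hotspots$multiplier < 1))
      stop("hotspot multipliers must be finite and >= 1")
    hotspots <- hotspots[order(hotspots$start), , drop = FALSE]
  }
  structure(list(region_length = region_length,
                 background_per_mb = background_per_mb,
                 hotspots = hotspots), class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("rate map: %s bp, background %.3g rho/Mb, %d hotspot(s)\n",
              format(x$region_length, big.mark = ","), x$background_per_mb,
              nrow(x$hotspots)))
  invisible(x)
}

#' Local rate of a rate map
#'
#' @param map a [rate_map()].
#' @param x positions in bp (offsets from region start).
#' @return rho per Mb at each position.
#' @export
rho_at <- function(map, x) {
  r <- rep(map$background_per_mb, length(x))
  h <- map$hotspots
  for (i in seq_len(nrow(h)))
    r <- r + map$background_per_mb * (h$multiplier[i] - 1) *
      (x >= h$start[i] & x < h$end[i])
  r
}

#' Integrated rho between two positions
#'
#' @param map a [rate_map()].
#' @param a,b positions in bp, `a <= b`; vectors recycle.
#' @return total rho (4\*Ne\*c) accumulated over `[a, b)`.
#' @export
rho_integral <- function(map, a, b) {
  per_bp <- map$background_per_mb / 1e6
  out <- per_bp * (b - a)
  h <- map$hotspots
  for (i in seq_len(nrow(h))) {
    ov <- pmax(0, pmin(b, h$end[i]) - pmax(a, h$start[i]))
    out <- out + per_bp * (h$multiplier[i] - 1) * ov
  }
  out
}

# piecewise-constant (breaks, per-bp rates) representation for the simulator
map_pieces <- function(map) {
  L <- map$region_length
  brk <- sort(unique(c(0, L, map$hotspots$start, map$hotspots$end)))
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  list(breaks = brk, rates = rho_at(map, mid) / 1e6)
}

#' Simulate haplotypes under the coalescent with recombination
#'
#' Hudson-style back-in-time simulation of the ancestral recombination graph
#' for `n` haplotypes under a non-uniform recombination map, with
#' infinite-sites mutations dropped on ancestral material at rate theta/2 per
#' site per lineage (time in units of 2N generations). Recombination
#' breakpoints are placed by inverse-CDF on the cumulative rate map, so
#' breakpoint density is proportional to the local rate. Crossing-over only;
#' no gene conversion.
#'
#' @param pop a [population_model()].
#' @param map a [rate_map()].
#' @param n number of haplotypes (2 per diploid individual), `2..64`.
#' @param seed integer seed.
#' @return Object of class `"sim_sample"`: list with `haplotypes` (n x S 0/1
#'   matrix), `positions` (bp, 1-based), `map`, `theta`, `seed`.
#' @export
simulate_haplotypes <- function(pop, map, n, seed) {
  stopifnot(inherits(pop, "population_model"), inherits(map, "rate_map"))
  if (n < 2) stop("n must be at least 2")
  pieces <- map_pieces(map)
  set.seed(seed)
  res <- .cpp_sim_arg(as.integer(n), map$region_length, pieces$breaks,
                      pieces$rates, pop$theta)
  structure(list(haplotypes = res$haplotypes, positions = res$positions,
                 map = map, theta = pop$theta, seed = seed),
            class = "sim_sample")
}

#' @export
print.sim_sample <- function(x, ...) {
  cat(sprintf("simulated sample: %d haplotypes, %d segregating sites over %s bp (seed %d)\n",
              nrow(x$haplotypes), length(x$positions),
              format(x$map$region_length, big.mark = ","), x$seed))
  invisible(x)
}

#' Ascertain array-like markers from a simulated sample
#'
#' Emulates SNP-array ascertainment: sites below the sample MAF threshold are
#' dropped and the remainder thinned uniformly at random to a target marker
#' density; haplotypes are then paired (1,2), (3,4), ... into diploid
#' genotypes.
#'
#' @param s a `"sim_sample"`.
#' @param min_maf sample minor allele frequency threshold (inclusive keep).
#' @param target_density markers per Mb after thinning, or NULL to keep all.
#' @param seed integer seed for the thinning draw.
#' @param chrom chromosome label for the resulting genotypes.
#' @return A [genotype_matrix()] with phased haplotypes attached.
#' @export
ascertain_markers <- function(s, min_maf = 0.1, target_density = NULL,
                              seed = 1, chrom = "sim") {
  if (length(s$positions) == 0) stop("sample contains no segregating sites")
  n <- nrow(s$haplotypes)
  daf <- colMeans(s$haplotypes)
  keep <- which(pmin(daf, 1 - daf) >= min_maf)
  if (length(keep) == 0)
    stop(errorCondition("no site survives the MAF threshold",
                        class = c("rhomap_empty_region", "error")))
  if (!is.null(target_density)) {
    target <- max(2L, round(target_density * s$map$region_length / 1e6))
    if (target < length(keep)) {
      set.seed(seed)
      keep <- sort(sample(keep, target))
    }
  }
  h <- t(s$haplotypes[, keep, drop = FALSE])  # markers x haplotypes
  calls <- h[, seq(1, n, 2), drop = FALSE] + h[, seq(2, n, 2), drop = FALSE]
  genotype_matrix(calls, s$positions[keep], chrom = chrom,
                  region = c(1, s$map$region_length), haplotypes = h)
}

#' Set genotype calls to missing at random
#'
#' Each call is independently set to missing with probability `missing_rate`;
#' used to exercise the call-rate filter. Phase information is dropped.
#'
#' @param g a `"genotypes"` object.
#' @param missing_rate probability in `[0, 1)`.
#' @param seed integer seed.
#' @return Degraded `"genotypes"` object.
#' @export
degrade_genotypes <- function(g, missing_rate, seed = 1) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (missing_rate == 0) return(g)
  set.seed(seed)
  calls <- g$calls
  calls[stats::runif(length(calls)) < missing_rate] <- NA_integer_
  genotype_matrix(calls, g$markers$pos, chrom = g$chrom, ref = g$markers$ref,
                  alt = g$markers$alt, samples = g$samples, region = g$region,
                  unique_mapping = g$markers$unique_mapping)
}

#' Default simulation preset emulating a dense-array regional survey
#'
#' Conditions: 22 diploid individuals (44 haplotypes), an 850 kb region,
#' markers thinned to about 70 per region with sample MAF >= 0.1, and a
#' background rate of 100 rho/Mb unless overridden.
#'
#' @param seed integer seed.
#' @param background_per_mb background rho per Mb.
#' @param hotspots hotspot data frame as in [rate_map()].
#' @param theta per-site theta.
#' @param region_length region length in bp.
#' @param n_haplotypes haplotype count.
#' @param markers_per_mb target marker density (per Mb).
#' @return A phased [genotype_matrix()] with attribute `"truth"` holding the
#'   generating [rate_map()].
#' @export
simulate_region_preset <- function(seed = 1, background_per_mb = 100,
                                   hotspots = NULL, theta = 0.001,
                                   region_length = 850000,
                                   n_haplotypes = 44,
                                   markers_per_mb = 70 / 0.85) {
  map <- rate_map(region_length, background_per_mb, hotspots)
  s <- simulate_haplotypes(population_model(theta = theta), map,
                           n = n_haplotypes, seed = seed)
  g <- ascertain_markers(s, min_maf = 0.1, target_density = markers_per_mb,
                         seed = seed + 1)
  attr(g, "truth") <- map
  g
}

#' Write a rate map as BED plus JSON sidecar
#'
#' Hotspot intervals go to a 0-based half-open BED file; the background rate,
#' multipliers and theta go to `<path>.json`.
#'
#' @param map a [rate_map()].
#' @param path BED output path.
#' @param chrom chromosome label.
#' @param theta optional per-site theta recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_rate_map_bed <- function(map, path, chrom = "sim", theta = NULL) {
  h <- map$hotspots
  bed <- data.frame(chrom = rep(chrom, nrow(h)),
                    start = as.integer(h$start), end = as.integer(h$end),
                    name = sprintf("hotspot_x%.3g", h$multiplier))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(region_length = map$region_length,
         background_per_mb = map$background_per_mb,
         multipliers = h$multiplier, theta = theta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
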