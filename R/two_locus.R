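# Two-locus composite likelihood engine.
#
# The sampling distribution of two-locus haplotype-count configurations
# (n00, n01, n10, n11) for n haplotypes is estimated by Monte Carlo from the
# two-locus structured coalescent at each node of a rho grid, conditional on
# one mutation per locus placed proportionally to marginal-tree branch
# length (the low-theta limit appropriate for ascertained biallelic SNPs;
# the conditional distribution is then theta-free). Configurations are
# folded to a canonical form that is invariant to allele relabelling at
# either locus and to locus exchange, matching what unpolarized genotype
# data can distinguish.

# canonical fold: minimum over the 8-element group generated by allele swaps
# at each locus and locus exchange. x is a length-4 vector or 4-col matrix.
fold_config <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  variants <- list(
    x[, c(1, 2, 3, 4), drop = FALSE],
    x[, c(3, 4, 1, 2), drop = FALSE],           # swap alleles at locus A
    x[, c(2, 1, 4, 3), drop = FALSE],           # swap alleles at locus B
    x[, c(4, 3, 2, 1), drop = FALSE],           # both
    x[, c(1, 3, 2, 4), drop = FALSE],           # exchange loci
    x[, c(2, 4, 1, 3), drop = FALSE],
    x[, c(3, 1, 4, 2), drop = FALSE],
    x[, c(4, 2, 3, 1), drop = FALSE])
  keys <- vapply(variants, function(v)
    sprintf("%03d%03d%03d%03d", v[, 1], v[, 2], v[, 3], v[, 4]),
    character(nrow(x)))
  if (is.null(dim(keys))) keys <- matrix(keys, nrow = 1)
  best <- apply(keys, 1, which.min)
  out <- t(vapply(seq_len(nrow(x)), function(i) variants[[best[i]]][i, ],
                  numeric(4)))
  list(config = out, key = keys[cbind(seq_len(nrow(x)), best)])
}

# all canonical configurations with both loci segregating, for n haplotypes
enumerate_configs <- function(n) {
  grid <- expand.grid(n00 = 0:n, n01 = 0:n, n10 = 0:n)
  grid$n11 <- n - grid$n00 - grid$n01 - grid$n10
  grid <- grid[grid$n11 >= 0, ]
  nA <- grid$n10 + grid$n11
  nB <- grid$n01 + grid$n11
  grid <- grid[nA > 0 & nA < n & nB > 0 & nB < n, ]
  f <- fold_config(as.matrix(grid))
  keep <- !duplicated(f$key)
  m <- f$config[keep, , drop = FALSE]
  o <- order(f$key[keep])
  structure(m[o, , drop = FALSE], keys = sort(f$key[keep]))
}

#' Default rho grid for two-locus lookup tables
#'
#' Exact node at 0, then approximately geometric up to 1000; pairwise rho
#' above the last node is clamped during likelihood evaluation.
#'
#' @return Numeric vector of grid nodes.
#' @export
default_rho_grid <- function() c(0, 0.5, 1, 2, 4, 8, 16, 32, 64, 128, 256, 512, 1000)

#' Build a Monte-Carlo two-locus configuration lookup table
#'
#' For each grid rho, simulates `reps` two-locus ancestral recombination
#' graphs for `n` haplotypes and draws `placements` mutation placements per
#' graph, tabulating canonical haplotype-count configurations. The raw
#' empirical probabilities at each rho sum to 1 over the canonical
#' configuration space; smoothing is applied only at likelihood lookup.
#'
#' With the default (Rao-Blackwellized) method each replicate graph
#' contributes its exact conditional configuration distribution, integrating
#' the mutation placement analytically; the naive method draws `placements`
#' configurations per graph and is kept as an independent estimator of the
#' same distribution.
#'
#' @param n haplotype count (2..64).
#' @param grid rho grid; first node must be 0.
#' @param reps ancestral recombination graphs per grid node. Production
#'   tables want at least 1e4 effective draws per node.
#' @param method `"rao-blackwell"` (default) or `"naive"`.
#' @param placements mutation placements per graph (naive method only).
#' @param seed integer seed.
#' @param theta_marker per-marker theta; recorded for provenance. The
#'   configuration distribution conditional on one mutation per locus does
#'   not depend on it.
#' @param alpha add-alpha smoothing weight used at lookup time.
#' @return Object of class `"two_locus_table"`.
#' @export
two_locus_table <- function(n, grid = default_rho_grid(), reps = 2000,
                            method = c("rao-blackwell", "naive"),
                            placements = 5, seed = 1, theta_marker = NULL,
                            alpha = 0.5) {
  method <- match.arg(method)
  if (length(grid) == 0) stop("empty rho grid")
  if (grid[1] != 0 || is.unsorted(grid, strictly = TRUE))
    stop("grid must start at 0 and increase")
  cfg <- enumerate_configs(n)
  keys <- attr(cfg, "keys")
  set.seed(seed)
  if (method == "rao-blackwell") {
    counts <- .cpp_two_locus_table(as.integer(n), grid, as.integer(reps),
                                   cfg)
    reps_total <- reps
  } else {
    counts <- matrix(0, nrow(cfg), length(grid))
    for (gi in seq_along(grid)) {
      raw <- .cpp_two_locus_configs(as.integer(n), grid[gi], as.integer(reps),
                                    as.integer(placements))
      key <- fold_config(raw)$key
      counts[, gi] <- as.numeric(table(factor(key, levels = keys)))
    }
    reps_total <- reps * placements
  }
  colnames(counts) <- paste0("rho", grid)
  structure(list(n = n, grid = grid, configs = cfg, keys = keys,
                 counts = counts, reps_total = reps_total,
                 alpha = alpha, theta_marker = theta_marker, seed = seed,
                 method = method),
            class = "two_locus_table")
}

#' @export
print.two_locus_table <- function(x, ...) {
  cat(sprintf("two-locus table: n = %d, %d configs, %d grid nodes (rho 0-%g), %g draws/node\n",
              x$n, nrow(x$configs), length(x$grid), max(x$grid), x$reps_total))
  invisible(x)
}

#' Raw configuration probabilities at one grid node
#'
#' @param table a [two_locus_table()].
#' @param rho a grid node value.
#' @return Named numeric vector of empirical probabilities (sums to 1).
#' @export
config_probability <- function(table, rho) {
  gi <- match(rho, table$grid)
  if (is.na(gi)) stop("rho is not a grid node")
  p <- table$counts[, gi] / table$reps_total
  names(p) <- table$keys
  p
}

# smoothed log-probability matrix (configs x grid)
table_logprob <- function(table) {
  M <- nrow(table$configs)
  log((table$counts + table$alpha) / (table$reps_total + table$alpha * M))
}

#' Project a lookup table to a smaller sample size
#'
#' Exact multivariate-hypergeometric downsampling: by the sampling
#' consistency of the coalescent, the configuration distribution for a
#' subsample of `m` of `n` haplotypes is the hypergeometric projection of
#' the size-n distribution, renormalized to configurations still segregating
#' at both loci.
#'
#' @param table a [two_locus_table()] at size n.
#' @param m target haplotype count, `2 <= m < n`.
#' @return A `"two_locus_table"` at size m (counts are expected counts).
#' @export
downsample_table <- function(table, m) {
  n <- table$n
  stopifnot(m >= 2, m < n)
  cfg_m <- enumerate_configs(m)
  keys_m <- attr(cfg_m, "keys")
  counts_m <- matrix(0, nrow(cfg_m), length(table$grid),
                     dimnames = list(NULL, colnames(table$counts)))
  lden <- lchoose(n, m)
  for (ci in seq_len(nrow(table$configs))) {
    src <- table$configs[ci, ]
    w <- table$counts[ci, ]
    if (all(w == 0)) next
    for (k00 in max(0, m - sum(src[2:4])):min(src[1], m)) {
      for (k01 in max(0, m - k00 - src[3] - src[4]):min(src[2], m - k00)) {
        for (k10 in max(0, m - k00 - k01 - src[4]):min(src[3], m - k00 - k01)) {
          k11 <- m - k00 - k01 - k10
          if (k11 > src[4]) next
          kA <- k10 + k11; kB <- k01 + k11
          if (kA == 0 || kA == m || kB == 0 || kB == m) next
          pr <- exp(lchoose(src[1], k00) + lchoose(src[2], k01) +
                    lchoose(src[3], k10) + lchoose(src[4], k11) - lden)
          key <- fold_config(c(k00, k01, k10, k11))$key
          ri <- match(key, keys_m)
          counts_m[ri, ] <- counts_m[ri, ] + pr * w
        }
      }
    }
  }
  # renormalize: condition on segregating in the subsample
  tot <- colSums(counts_m)
  tot[tot == 0] <- 1
  counts_m <- sweep(counts_m, 2, table$reps_total / tot, `*`)
  structure(list(n = m, grid = table$grid, configs = cfg_m, keys = keys_m,
                 counts = counts_m, reps_total = table$reps_total,
                 alpha = table$alpha, theta_marker = table$theta_marker,
                 seed = table$seed), class = "two_locus_table")
}

#' Save / load a lookup table with a parameter fingerprint
#'
#' Tables are cached as plain TSV plus a JSON header keyed by
#' (n, grid, reps, seed), so a cached table is never reused for different
#' parameters.
#'
#' @param table a [two_locus_table()].
#' @param dir cache directory.
#' @return The cache file path ([write_table_cache()]) or the table
#'   ([read_table_cache()]; NULL on a fingerprint miss).
#' @export
write_table_cache <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- paste0("tlt_n", table$n, "_r", table$reps_total, "_s", table$seed,
               "_g", length(table$grid))
  path <- file.path(dir, paste0(fp, ".tsv"))
  utils::write.table(cbind(as.data.frame(table$configs), table$counts),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(table[c("n", "grid", "reps_total", "alpha", "seed")],
                       file.path(dir, paste0(fp, ".json")), digits = NA)
  path
}

#' @rdname write_table_cache
#' @param n,reps_total,seed,grid fingerprint parameters of the wanted table.
#' @export
read_table_cache <- function(dir, n, reps_total, seed, grid = default_rho_grid()) {
  fp <- paste0("tlt_n", n, "_r", reps_total, "_s", seed, "_g", length(grid))
  path <- file.path(dir, paste0(fp, ".tsv"))
  meta_path <- file.path(dir, paste0(fp, ".json"))
  if (!file.exists(path) || !file.exists(meta_path)) return(NULL)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!isTRUE(all.equal(meta$grid, grid))) return(NULL)
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  cfg <- as.matrix(d[, 1:4])
  keys <- sprintf("%03d%03d%03d%03d", cfg[, 1], cfg[, 2], cfg[, 3], cfg[, 4])
  structure(list(n = n, grid = grid, configs = unname(cfg), keys = keys,
                 counts = as.matrix(d[, -(1:4), drop = FALSE]),
                 reps_total = reps_total, alpha = meta$alpha, seed = seed,
                 theta_marker = NULL), class = "two_locus_table")
}

# Pair engine: per marker pair within span, the observed canonical config's
# smoothed log-probability across the rho grid, conditioned on the marker
# ascertainment class (both loci at sample MAF >= maf_condition) so that the
# MAF filter applied to the data does not bias rho: intermediate-frequency
# configurations are relatively likelier at low rho, and an unconditioned
# likelihood systematically prefers too little recombination. Pairs with
# missing calls use complete haplotypes only, against the hypergeometric-
# projected table.
build_pair_engine <- function(g, table, max_pair_span = 1e5,
                              maf_condition = 0.1) {
  if (is.null(g$haplotypes))
    stop("haplotypes are required; call phase_genotypes() first")
  pos <- g$markers$pos
  k <- length(pos)
  if (k < 2)
    return(structure(list(x1 = numeric(0), x2 = numeric(0),
                          logP = matrix(0, 0, length(table$grid)),
                          grid = table$grid, n_pairs = 0L, n_skipped = 0L),
                     class = "pair_engine"))
  ij <- which(outer(pos, pos, function(a, b) b - a) > 0 &
              outer(pos, pos, function(a, b) b - a) <= max_pair_span,
              arr.ind = TRUE)
  tables <- list()
  tables[[as.character(table$n)]] <- table
  lp_cache <- list()  # per sample size: smoothed logP minus MAF-class normalizer
  pair_logprob <- function(tb, m) {
    mm <- as.character(m)
    if (!is.null(lp_cache[[mm]])) return(lp_cache[[mm]])
    lp <- table_logprob(tb)
    if (!is.null(maf_condition)) {
      nA <- tb$configs[, 3] + tb$configs[, 4]
      nB <- tb$configs[, 2] + tb$configs[, 4]
      minc <- ceiling(maf_condition * m)
      in_class <- pmin(nA, m - nA) >= minc & pmin(nB, m - nB) >= minc
      norm <- log(colSums(exp(lp[in_class, , drop = FALSE])))
      lp <- sweep(lp, 2, norm, `-`)
    }
    lp_cache[[mm]] <<- lp
    lp
  }
  logps <- list()
  x1 <- x2 <- numeric(0)
  n_skipped <- 0L
  for (r in seq_len(nrow(ij))) {
    i <- ij[r, 1]; j <- ij[r, 2]
    hi <- g$haplotypes[i, ]; hj <- g$haplotypes[j, ]
    ok <- !is.na(hi) & !is.na(hj)
    m <- sum(ok)
    if (m < 2 || m > table$n) { n_skipped <- n_skipped + 1L; next }
    a <- hi[ok]; b <- hj[ok]
    cfgv <- c(sum(a == 0 & b == 0), sum(a == 0 & b == 1),
              sum(a == 1 & b == 0), sum(a == 1 & b == 1))
    nA <- cfgv[3] + cfgv[4]; nB <- cfgv[2] + cfgv[4]
    if (nA == 0 || nA == m || nB == 0 || nB == m) { n_skipped <- n_skipped + 1L; next }
    key <- fold_config(cfgv)$key
    mm <- as.character(m)
    if (is.null(tables[[mm]])) tables[[mm]] <- downsample_table(table, m)
    tb <- tables[[mm]]
    ri <- match(key, tb$keys)
    logps[[length(logps) + 1L]] <- pair_logprob(tb, m)[ri, ]
    x1 <- c(x1, pos[i]); x2 <- c(x2, pos[j])
  }
  logP <- if (length(logps)) do.call(rbind, logps) else
    matrix(0, 0, length(table$grid))
  structure(list(x1 = x1, x2 = x2, logP = logP, grid = table$grid,
                 n_pairs = length(x1), n_skipped = n_skipped),
            class = "pair_engine")
}

# evaluate composite log-likelihood for a state on a prebuilt engine;
# positions in engine are absolute bp, hotspots absolute [start, end) bp
engine_loglik <- function(engine, background_per_mb, hs_start = numeric(0),
                          hs_end = numeric(0), hs_mult = numeric(0)) {
  if (engine$n_pairs == 0) return(structure(0, n_clamped = 0L))
  v <- .cpp_pair_loglik(engine$logP, engine$grid, engine$x1, engine$x2,
                        background_per_mb / 1e6, hs_start, hs_end, hs_mult)
  structure(v[1], n_clamped = as.integer(v[2]))
}

#' Composite log-likelihood of a model state
#'
#' Sum over marker pairs within `max_pair_span` of the log probability of the
#' pair's observed two-locus configuration, interpolated from the lookup
#' table at the pairwise rho implied by integrating the state's rate map
#' between the two markers (linear interpolation of log-probability between
#' grid nodes; pairwise rho beyond the grid is clamped to the last node and
#' counted in attribute `"n_clamped"`).
#'
#' @param g a phased `"genotypes"` object.
#' @param state list with `background_per_mb` and a `hotspots` data frame
#'   (`start`, `end` in absolute bp, `multiplier`).
#' @param table a [two_locus_table()] for (at least) the sample's haplotype
#'   count.
#' @param max_pair_span only pairs closer than this many bp enter the sum.
#' @param maf_condition pair probabilities are conditioned on both loci
#'   passing this sample-MAF threshold, matching the marker ascertainment;
#'   `NULL` disables the conditioning.
#' @return Log-likelihood (0 when no usable pair exists), with attribute
#'   `"n_clamped"`.
#' @export
composite_loglik <- function(g, state, table, max_pair_span = 1e5,
                             maf_condition = 0.1) {
  engine <- build_pair_engine(g, table, max_pair_span, maf_condition)
  h <- state$hotspots
  if (is.null(h)) h <- data.frame(start = numeric(0), end = numeric(0),
                                  multiplier = numeric(0))
  ll <- engine_loglik(engine, state$background_per_mb,
                      h$start, h$end, h$multiplier)
  n_cl <- attr(ll, "n_clamped")
  if (n_cl > 0) message(n_cl, " pair rho value(s) clamped to the grid maximum")
  ll
}
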