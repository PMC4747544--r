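test_that("configuration probabilities are normalized and rho=0 forbids four gametes", {
  tab <- shared_table(8, reps = 1500, seed = 21)
  for (rho in c(0, 1, 64, 1000)) {
    p <- config_probability(tab, rho)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  fourg <- apply(tab$configs, 1, function(cf) all(cf > 0))
  p0 <- config_probability(tab, 0)
  expect_true(all(p0[fourg] == 0))
  # at rho = 1000 four-gamete configurations do arise
  expect_gt(sum(config_probability(tab, 1000)[fourg]), 0)
})

test_that("the joint configuration factorizes at large rho", {
  n <- 8
  set.seed(31)
  raw0 <- rhomap:::.cpp_two_locus_configs(n, 0, 4000L, 1L)
  rawI <- rhomap:::.cpp_two_locus_configs(n, 1000, 4000L, 1L)
  D2 <- function(cf) {
    pA <- (cf[, 3] + cf[, 4]) / n
    pB <- (cf[, 2] + cf[, 4]) / n
    (cf[, 4] / n - pA * pB)^2
  }
  # under factorization, E[D^2 | margins] is the hypergeometric floor
  # pA qA pB qB / (n - 1); at rho = 0 D^2 sits far above it
  floor_indep <- function(cf) {
    pA <- (cf[, 3] + cf[, 4]) / n
    pB <- (cf[, 2] + cf[, 4]) / n
    pA * (1 - pA) * pB * (1 - pB) / (n - 1)
  }
  expect_equal(mean(D2(rawI)), mean(floor_indep(rawI)), tolerance = 0.1)
  expect_gt(mean(D2(raw0)), 2 * mean(floor_indep(raw0)))
  # minor-allele counts at the two loci become independent
  nA <- pmin(rawI[, 3] + rawI[, 4], n - rawI[, 3] - rawI[, 4])
  nB <- pmin(rawI[, 2] + rawI[, 4], n - rawI[, 2] - rawI[, 4])
  expect_gt(suppressWarnings(stats::chisq.test(table(nA, nB)))$p.value, 0.001)
})

test_that("the Rao-Blackwellized and naive estimators target the same distribution", {
  t_rb <- two_locus_table(6, grid = c(0, 4, 1000), reps = 3000, seed = 4)
  t_nv <- two_locus_table(6, grid = c(0, 4, 1000), reps = 3000,
                          method = "naive", placements = 4, seed = 5)
  for (rho in c(0, 4, 1000)) {
    p1 <- config_probability(t_rb, rho)
    p2 <- config_probability(t_nv, rho)
    expect_lt(max(abs(p1 - p2)), 0.02)
  }
})

test_that("hypergeometric downsampling matches a directly built table", {
  t8 <- shared_table(8, reps = 1500, seed = 21)
  t4d <- downsample_table(t8, 4)
  t4 <- two_locus_table(4, reps = 4000, seed = 9)
  for (rho in c(0, 8, 1000)) {
    p1 <- config_probability(t4d, rho)
    p2 <- config_probability(t4, rho)
    expect_lt(max(abs(p1 - p2)), 0.025)
  }
})

test_that("a single-marker region has zero composite log-likelihood", {
  g <- genotype_matrix(matrix(c(0L, 1L), 1, 2), positions = 100,
                       haplotypes = matrix(c(0L, 0L, 1L, 0L), 1, 4))
  tab <- two_locus_table(4, reps = 200, seed = 1)
  ll <- composite_loglik(g, list(background_per_mb = 50, hotspots = NULL), tab)
  expect_equal(as.numeric(ll), 0)
})

test_that("composite log-likelihood equals a hand-computed sum over pairs", {
  # 4 haplotypes x 3 markers, fully phased, no missingness
  h <- rbind(c(0L, 0L, 1L, 1L),
             c(0L, 1L, 1L, 0L),
             c(1L, 0L, 0L, 1L))
  calls <- h[, c(1, 3)] + h[, c(2, 4)]
  pos <- c(1000, 26000, 51000)
  g <- genotype_matrix(calls, positions = pos, haplotypes = h,
                       region = c(1000, 51000))
  tab <- two_locus_table(4, reps = 3000, seed = 13)
  b <- 37  # rho per Mb; pairwise rho off the grid nodes
  ll <- as.numeric(composite_loglik(g, list(background_per_mb = b,
                                            hotspots = NULL), tab,
                                    maf_condition = NULL))
  # independent evaluation: canonical fold, smoothing, linear interpolation
  M <- nrow(tab$configs)
  smooth_lp <- log((tab$counts + tab$alpha) / (tab$reps_total + tab$alpha * M))
  interp <- function(lp_row, rho) {
    gr <- tab$grid
    if (rho >= max(gr)) return(lp_row[length(gr)])
    i <- findInterval(rho, gr)
    w <- (rho - gr[i]) / (gr[i + 1] - gr[i])
    (1 - w) * lp_row[i] + w * lp_row[i + 1]
  }
  expected <- 0
  for (pr in list(c(1, 2), c(2, 3), c(1, 3))) {
    a <- h[pr[1], ]; bb <- h[pr[2], ]
    cf <- c(sum(a == 0 & bb == 0), sum(a == 0 & bb == 1),
            sum(a == 1 & bb == 0), sum(a == 1 & bb == 1))
    key <- oracle_fold_key(cf)
    keys_tab <- sprintf("%03d_%03d_%03d_%03d", tab$configs[, 1],
                        tab$configs[, 2], tab$configs[, 3], tab$configs[, 4])
    ri <- match(key, keys_tab)
    rho_pair <- b / 1e6 * (pos[pr[2]] - pos[pr[1]])
    expected <- expected + interp(smooth_lp[ri, ], rho_pair)
  }
  expect_equal(ll, unname(expected), tolerance = 1e-10)
})

test_that("a pairwise rho on a grid node uses the stored value exactly", {
  h <- rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 1L, 0L))
  g <- genotype_matrix(h[, c(1, 3)] + h[, c(2, 4)], positions = c(1, 50001),
                       haplotypes = h, region = c(1, 50001))
  tab <- two_locus_table(4, reps = 2000, seed = 17)
  b <- 0.5 * 1e6 / 50000  # pairwise rho exactly 0.5, the second grid node
  ll <- as.numeric(composite_loglik(g, list(background_per_mb = b,
                                            hotspots = NULL), tab,
                                    maf_condition = NULL))
  cf <- c(sum(h[1, ] == 0 & h[2, ] == 0), sum(h[1, ] == 0 & h[2, ] == 1),
          sum(h[1, ] == 1 & h[2, ] == 0), sum(h[1, ] == 1 & h[2, ] == 1))
  keys_tab <- sprintf("%03d_%03d_%03d_%03d", tab$configs[, 1],
                      tab$configs[, 2], tab$configs[, 3], tab$configs[, 4])
  ri <- match(oracle_fold_key(cf), keys_tab)
  M <- nrow(tab$configs)
  expect_equal(ll, unname(log((tab$counts[ri, 2] + tab$alpha) /
                              (tab$reps_total + tab$alpha * M))),
               tolerance = 1e-12)
})

test_that("pairwise rho beyond the grid is clamped and counted", {
  h <- rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 1L, 0L))
  g <- genotype_matrix(h[, c(1, 3)] + h[, c(2, 4)], positions = c(1, 90001),
                       haplotypes = h, region = c(1, 90001))
  tab <- two_locus_table(4, reps = 500, seed = 2)
  expect_message(
    ll <- composite_loglik(g, list(background_per_mb = 2e4, hotspots = NULL),
                           tab, maf_condition = NULL),
    "clamped")
  expect_equal(attr(ll, "n_clamped"), 1L)
})

test_that("table caching round-trips and rejects fingerprint mismatches", {
  dir <- tempfile("cache")
  tab <- two_locus_table(4, reps = 300, seed = 6)
  write_table_cache(tab, dir)
  back <- read_table_cache(dir, 4, tab$reps_total, 6)
  expect_equal(back$counts, tab$counts, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_null(read_table_cache(dir, 4, tab$reps_total, 7))
})

test_that("composite likelihood prefers the generating background to a 10x one", {
  n <- 30
  tab <- shared_table(30, reps = 2000, seed = 33)
  hits <- 0
  reps <- 12
  for (r in seq_len(reps)) {
    g <- simulate_region_preset(seed = 600 + r, background_per_mb = 50,
                                theta = 0.004, region_length = 100000,
                                n_haplotypes = n, markers_per_mb = 400)
    ll_true <- as.numeric(suppressMessages(composite_loglik(
      g, list(background_per_mb = 50, hotspots = NULL), tab)))
    ll_mis <- as.numeric(suppressMessages(composite_loglik(
      g, list(background_per_mb = 500, hotspots = NULL), tab)))
    hits <- hits + (ll_true > ll_mis)
  }
  expect_gte(hits, round(0.95 * reps) - 1)
})
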