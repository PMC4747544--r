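test_that("the prior-only chain recovers the Poisson hotspot process", {
  # expected count Lambda = 1 over a 1-Mb region at rate 1 per Mb
  pf <- prior_chain(c(0, 1e6), prior = prior_spec(hotspot_rate_per_mb = 1),
                    chain = chain_settings(iterations = 40000, seed = 5,
                                           target_samples = 2000))
  k <- pf$trace$n_hotspots
  ess <- compute_ess(as.numeric(k >= 1))
  p_occ <- mean(k >= 1)
  expected <- 1 - exp(-1)
  se <- sqrt(expected * (1 - expected) / ess)
  expect_lt(abs(p_occ - expected), 3 * se)
  # mean width recovers the Uniform(500, 5000) prior mean
  w_all <- unlist(lapply(pf$hotspots, function(h)
    if (nrow(h)) h$end - h$start else numeric(0)))
  # clipping at the edges shortens a small fraction of intervals
  expect_lt(abs(mean(w_all) - 2750), 120)
})

test_that("prior bin occupancy is flat over interior bins", {
  pf <- prior_chain(c(0, 4e5),
                    prior = prior_spec(hotspot_rate_per_mb = 5),
                    chain = chain_settings(iterations = 40000, seed = 8,
                                           target_samples = 2000))
  bp <- bin_probability(pf, bin_width = 10000)
  # interior = further than half the maximum width from either edge
  interior <- bp$start >= 2500 & bp$end <= 4e5 - 2500
  q <- bp$p[interior]
  # translation invariance: no interior trend; compare halves
  half <- seq_along(q) <= length(q) / 2
  expect_lt(abs(mean(q[half]) - mean(q[!half])), 0.1 * mean(q))
})

test_that("zero hotspot intensity yields zero hotspots everywhere", {
  pf <- prior_chain(c(0, 1e6), prior = prior_spec(hotspot_rate_per_mb = 0),
                    chain = chain_settings(iterations = 4000, seed = 2))
  expect_true(all(pf$trace$n_hotspots == 0))
  bp <- bin_probability(pf, bin_width = 10000)
  expect_true(all(bp$p == 0))
})

test_that("birth and death acceptance terms are exact inverses", {
  prior <- prior_spec(hotspot_rate_per_mb = 2)
  L <- 5e5
  Lambda <- 2 * L / 1e6
  s0 <- list(theta = 1e-3, background = 100,
             hs = data.frame(center = numeric(0), width = numeric(0),
                             lambda = numeric(0)))
  h <- data.frame(center = 2e5, width = 2000, lambda = 30)
  s1 <- list(theta = 1e-3, background = 100, hs = h)
  lp0 <- rhomap:::log_prior(s0, prior, L)
  lp1 <- rhomap:::log_prior(s1, prior, L)
  # Janossy form: adding one hotspot changes the log prior by
  # log(Lambda) + log p(center) + log p(width) + log p(lambda)
  expected <- log(Lambda) - log(L) - log(5000 - 500) -
    log(30) - log(log(500 / 5))
  expect_equal(lp1 - lp0, expected, tolerance = 1e-12)
  # forced proposal pair: birth Hastings log(Lambda/(K+1)) is the exact
  # negative of the death Hastings log((K+1)/Lambda)
  expect_equal(log(Lambda / 1), -log(1 / Lambda), tolerance = 1e-12)
})

test_that("prior densities integrate against sampled histograms", {
  pf <- prior_chain(c(0, 1e6),
                    prior = prior_spec(hotspot_rate_per_mb = 2,
                                       background_mean = 100),
                    chain = chain_settings(iterations = 40000, seed = 12,
                                           target_samples = 2000))
  b <- pf$trace$background
  ess_b <- compute_ess(b)
  expect_lt(abs(mean(b) - 100), 3 * stats::sd(b) / sqrt(ess_b))
  th <- log(pf$trace$theta)
  ess_t <- compute_ess(th)
  expect_lt(abs(mean(th) - mean(log(c(1e-4, 1e-2)))),
            3 * stats::sd(th) / sqrt(ess_t))
  lam <- unlist(lapply(pf$hotspots, function(h) h$multiplier))
  expect_lt(abs(mean(log(lam)) - mean(log(c(5, 500)))),
            4 * stats::sd(log(lam)) / sqrt(length(lam) / 4))
})

test_that("non-finite initialization aborts with a diagnostic", {
  g <- suppressMessages(phase_genotypes(read_genotypes(tsv3_path())))
  bad_prior <- prior_spec(theta_range = c(1e-9, 1e-8))  # init theta outside?
  # init theta is the geometric mid of the range, so force failure through
  # a degenerate region instead
  g$region <- c(100, 100)
  expect_error(infer_rhomap(g, likelihood = "constant"), "degenerate")
})

test_that("chains are reproducible under the seed and consistent across seeds", {
  tab <- shared_table(30, reps = 2000, seed = 33)
  g <- simulate_region_preset(seed = 77, background_per_mb = 80,
                              theta = 0.003, region_length = 100000,
                              n_haplotypes = 30, markers_per_mb = 400)
  prior <- prior_spec(hotspot_rate_per_mb = 0)  # unimodal background-only
  f1 <- infer_rhomap(g, prior, chain_settings(iterations = 8000, seed = 41),
                     table = tab)
  f2 <- infer_rhomap(g, prior, chain_settings(iterations = 8000, seed = 41),
                     table = tab)
  expect_identical(f1$trace, f2$trace)
  f3 <- infer_rhomap(g, prior, chain_settings(iterations = 8000, seed = 42),
                     table = tab)
  m1 <- mean(f1$trace$background); m3 <- mean(f3$trace$background)
  se1 <- stats::sd(f1$trace$background) / sqrt(f1$ess["background"])
  se3 <- stats::sd(f3$trace$background) / sqrt(f3$ess["background"])
  expect_lt(abs(m1 - m3), 3 * sqrt(se1^2 + se3^2) + 0.05 * m1)
})

test_that("acceptance bookkeeping covers every proposed move", {
  pf <- prior_chain(c(0, 2e5), chain = chain_settings(iterations = 3000,
                                                      seed = 3))
  a <- pf$acceptance
  expect_setequal(a$move, c("add", "remove", "move", "resize", "intensity",
                            "background", "theta"))
  expect_true(all(a$accepted <= a$proposed))
  expect_true(all(a$rate >= 0 & a$rate <= 1, na.rm = TRUE))
})

test_that("ESS matches closed forms for iid and AR(1) traces", {
  set.seed(101)
  x <- stats::rnorm(1000)
  expect_gt(compute_ess(x), 800)
  expect_lte(compute_ess(x), 1200)
  # AR(1), phi = 0.9: ESS ~ N (1 - phi) / (1 + phi)
  phi <- 0.9; N <- 10000
  ar <- as.numeric(stats::arima.sim(list(ar = phi), N))
  target <- N * (1 - phi) / (1 + phi)
  expect_lt(abs(compute_ess(ar) - target), 0.3 * target)
  expect_warning(e <- compute_ess(rep(1, 50)), "constant")
  expect_equal(e, 50)
  expect_error(compute_ess(1:5), "too short")
})

test_that("fit methods expose coefficients, predictions and simulations", {
  tab <- shared_table(30, reps = 2000, seed = 33)
  g <- simulate_region_preset(seed = 90, background_per_mb = 60,
                              theta = 0.003, region_length = 100000,
                              n_haplotypes = 30, markers_per_mb = 300)
  fit <- infer_rhomap(g, prior_spec(), chain_settings(iterations = 4000,
                                                      seed = 19), table = tab)
  cf <- coef(fit)
  expect_named(cf, c("background_rho_per_mb", "theta_per_site",
                     "mean_n_hotspots"))
  pr <- predict(fit, c(25000, 75000))
  expect_equal(nrow(pr), 2)
  expect_true(all(pr$rho_per_mb >= 0))
  s <- summary(fit)
  expect_s3_class(s, "summary.rhomap_fit")
  expect_output(print(s), "acceptance")
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "sim_sample")
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})
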