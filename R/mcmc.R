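#' Prior specification for the hotspot model
#'
#' Hotspots arrive as a homogeneous marked Poisson process along the region:
#' count ~ Poisson(`hotspot_rate_per_mb` x region length in Mb), centers
#' uniform on the region, widths uniform on `width_range_bp`, intensity
#' multipliers log-uniform on `intensity_range`. The background rho/Mb is
#' exponential with mean `background_mean`, and theta per site is log-uniform
#' on `theta_range`. All densities are proper with explicit bounds.
#'
#' @param hotspot_rate_per_mb expected hotspot count per Mb.
#' @param width_range_bp hotspot width bounds in bp.
#' @param intensity_range multiplier bounds (log-uniform).
#' @param background_mean mean of the exponential background prior (rho/Mb).
#' @param theta_range per-site theta bounds (log-uniform).
#' @return Object of class `"prior_spec"`.
#' @export
prior_spec <- function(hotspot_rate_per_mb = 1,
                       width_range_bp = c(500, 5000),
                       intensity_range = c(5, 500),
                       background_mean = 100,
                       theta_range = c(1e-4, 1e-2)) {
  stopifnot(hotspot_rate_per_mb >= 0, length(width_range_bp) == 2,
            width_range_bp[1] < width_range_bp[2],
            intensity_range[1] < intensity_range[2], intensity_range[1] > 0,
            background_mean > 0, theta_range[1] < theta_range[2],
            theta_range[1] > 0)
  structure(list(hotspot_rate_per_mb = hotspot_rate_per_mb,
                 width_range_bp = width_range_bp,
                 intensity_range = intensity_range,
                 background_mean = background_mean,
                 theta_range = theta_range), class = "prior_spec")
}

#' MCMC chain settings
#'
#' @param iterations total Metropolis-Hastings iterations.
#' @param burnin_frac fraction discarded as burn-in (first part of the
#'   chain); default 0.5.
#' @param thin thinning interval; default retains about `target_samples`
#'   post-burn-in samples.
#' @param target_samples retained sample count used to derive `thin`.
#' @param seed integer seed.
#' @param move_weights named proposal weights for the seven move types.
#' @param move_sd center-shift proposal sd (bp).
#' @param move_jump_prob probability that a center move redraws the center
#'   uniformly over the region instead of a local shift; lets hotspots
#'   relocate between well-separated likelihood modes.
#' @param resize_sd width-perturbation proposal sd (bp).
#' @param intensity_sd,background_sd,theta_sd log-scale random-walk sds.
#' @return Object of class `"chain_settings"`.
#' @export
chain_settings <- function(iterations = 20000, burnin_frac = 0.5, thin = NULL,
                           target_samples = 2000, seed = 1,
                           move_weights = c(add = 0.15, remove = 0.15,
                                            move = 0.2, resize = 0.15,
                                            intensity = 0.15,
                                            background = 0.1, theta = 0.1),
                           move_sd = 2000, move_jump_prob = 0.25,
                           resize_sd = 500,
                           intensity_sd = 0.4, background_sd = 0.25,
                           theta_sd = 0.4) {
  stopifnot(iterations > 0, burnin_frac > 0, burnin_frac < 1)
  keep <- floor(iterations * (1 - burnin_frac))
  if (is.null(thin)) thin <- max(1L, floor(keep / target_samples))
  mw <- move_weights / sum(move_weights)
  structure(list(iterations = as.integer(iterations),
                 burnin_frac = burnin_frac, thin = as.integer(thin),
                 seed = as.integer(seed), move_weights = mw,
                 move_sd = move_sd, move_jump_prob = move_jump_prob,
                 resize_sd = resize_sd,
                 intensity_sd = intensity_sd, background_sd = background_sd,
                 theta_sd = theta_sd), class = "chain_settings")
}

# log prior density of a state (Janossy form for the hotspot point process:
# exp(-Lambda) Lambda^K prod_i p(center_i) p(width_i) p(lambda_i))
log_prior <- function(state, prior, L_bp) {
  L_mb <- L_bp / 1e6
  Lambda <- prior$hotspot_rate_per_mb * L_mb
  K <- nrow(state$hs)
  lp <- stats::dexp(state$background, 1 / prior$background_mean, log = TRUE)
  tr <- prior$theta_range
  if (state$theta < tr[1] || state$theta > tr[2]) return(-Inf)
  lp <- lp - log(state$theta) - log(log(tr[2] / tr[1]))
  if (Lambda == 0 && K > 0) return(-Inf)
  if (Lambda > 0) lp <- lp - Lambda + K * log(Lambda)
  if (K > 0) {
    wr <- prior$width_range_bp; ir <- prior$intensity_range
    if (any(state$hs$center < 0 | state$hs$center > L_bp) ||
        any(state$hs$width < wr[1] | state$hs$width > wr[2]) ||
        any(state$hs$lambda < ir[1] | state$hs$lambda > ir[2])) return(-Inf)
    lp <- lp + K * (-log(L_bp) - log(wr[2] - wr[1])) +
      sum(-log(state$hs$lambda)) - K * log(log(ir[2] / ir[1]))
  }
  lp
}

# hotspot data frame (absolute, clipped, half-open) from internal (center,
# width) offsets
hs_intervals <- function(hs, region_start, L_bp) {
  if (nrow(hs) == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      multiplier = numeric(0)))
  data.frame(start = region_start + pmax(0, hs$center - hs$width / 2),
             end = region_start + pmin(L_bp, hs$center + hs$width / 2),
             multiplier = hs$lambda)
}

draw_hotspot_prior <- function(prior, L_bp) {
  data.frame(center = stats::runif(1, 0, L_bp),
             width = stats::runif(1, prior$width_range_bp[1],
                                  prior$width_range_bp[2]),
             lambda = exp(stats::runif(1, log(prior$intensity_range[1]),
                                       log(prior$intensity_range[2]))))
}

#' Fit the background-plus-hotspot recombination model by reversible-jump MCMC
#'
#' Metropolis-Hastings over (theta, background rho/Mb, hotspot set) with
#' birth/death (from/to the prior), center-move, width-resize, intensity,
#' background and theta moves. The likelihood is the two-locus composite
#' likelihood from `table`; with `likelihood = "constant"` the sampler
#' targets the prior, which is how the per-bin prior hotspot probabilities
#' for Bayes factors are obtained.
#'
#' @param g a `"genotypes"` object; phased haplotypes are required for the
#'   composite likelihood (see [phase_genotypes()]).
#' @param prior a [prior_spec()].
#' @param chain a [chain_settings()].
#' @param table a [two_locus_table()]; not needed in constant mode.
#' @param max_pair_span composite-likelihood pair span cap in bp.
#' @param maf_condition ascertainment MAF threshold the pair likelihood is
#'   conditioned on (see [composite_loglik()]).
#' @param likelihood `"composite"` or `"constant"` (prior-only chain).
#' @return Object of class `"rhomap_fit"`: retained samples (`trace` data
#'   frame with theta, background, hotspot count, log posterior; `hotspots`
#'   list of interval data frames per sample), acceptance rates per move
#'   type, effective sample sizes, and the inputs needed to reproduce the
#'   run.
#' @export
infer_rhomap <- function(g, prior = prior_spec(), chain = chain_settings(),
                         table = NULL, max_pair_span = 1e5,
                         maf_condition = 0.1,
                         likelihood = c("composite", "constant")) {
  likelihood <- match.arg(likelihood)
  region <- g$region
  region_start <- region[1]
  L_bp <- region[2] - region[1]
  if (L_bp <= 0) stop("degenerate region")
  if (likelihood == "composite") {
    if (is.null(table)) stop("a two_locus_table is required for composite likelihood")
    engine <- build_pair_engine(g, table, max_pair_span, maf_condition)
    llfun <- function(state) {
      iv <- hs_intervals(state$hs, region_start, L_bp)
      engine_loglik(engine, state$background, iv$start, iv$end, iv$multiplier)
    }
  } else {
    engine <- NULL
    llfun <- function(state) structure(0, n_clamped = 0L)
  }

  set.seed(chain$seed)
  state <- list(theta = sqrt(prod(prior$theta_range)),
                background = prior$background_mean,
                hs = data.frame(center = numeric(0), width = numeric(0),
                                lambda = numeric(0)))
  cur_ll <- as.numeric(llfun(state))
  cur_lp <- log_prior(state, prior, L_bp)
  if (!is.finite(cur_ll + cur_lp))
    stop("non-finite posterior at initialization: ll = ", cur_ll,
         ", log prior = ", cur_lp)

  Lambda <- prior$hotspot_rate_per_mb * L_bp / 1e6
  mv_names <- names(chain$move_weights)
  proposed <- accepted <- stats::setNames(integer(length(mv_names)), mv_names)
  burn <- floor(chain$iterations * chain$burnin_frac)
  keep_at <- seq(burn + chain$thin, chain$iterations, by = chain$thin)
  n_keep <- length(keep_at)
  tr_theta <- tr_b <- tr_lpost <- numeric(n_keep)
  tr_k <- integer(n_keep)
  hs_samples <- vector("list", n_keep)
  ki <- 0L
  n_clamp_tot <- 0L

  for (it in seq_len(chain$iterations)) {
    mv <- sample(mv_names, 1, prob = chain$move_weights)
    K <- nrow(state$hs)
    prop <- state
    log_hastings <- 0
    feasible <- TRUE
    if (mv == "add") {
      prop$hs <- rbind(state$hs, draw_hotspot_prior(prior, L_bp))
      log_hastings <- log(Lambda) - log(K + 1)
    } else if (mv == "remove") {
      if (K == 0) feasible <- FALSE
      else {
        i <- sample.int(K, 1)
        prop$hs <- state$hs[-i, , drop = FALSE]
        log_hastings <- log(K) - log(Lambda)
      }
    } else if (mv == "move") {
      if (K == 0) feasible <- FALSE
      else {
        i <- sample.int(K, 1)
        # mixture kernel: local shift, or a uniform redraw of the center
        # (independence proposal; uniform-to-uniform Hastings ratio is 1)
        prop$hs$center[i] <- if (stats::runif(1) < chain$move_jump_prob)
          stats::runif(1, 0, L_bp)
        else state$hs$center[i] + stats::rnorm(1, 0, chain$move_sd)
      }
    } else if (mv == "resize") {
      if (K == 0) feasible <- FALSE
      else {
        i <- sample.int(K, 1)
        prop$hs$width[i] <- state$hs$width[i] + stats::rnorm(1, 0, chain$resize_sd)
      }
    } else if (mv == "intensity") {
      if (K == 0) feasible <- FALSE
      else {
        i <- sample.int(K, 1)
        prop$hs$lambda[i] <- state$hs$lambda[i] * exp(stats::rnorm(1, 0, chain$intensity_sd))
      }
    } else if (mv == "background") {
      prop$background <- state$background * exp(stats::rnorm(1, 0, chain$background_sd))
      # log-scale walk: include the Jacobian via the extra log(b) term
      log_hastings <- log(prop$background) - log(state$background)
    } else if (mv == "theta") {
      prop$theta <- state$theta * exp(stats::rnorm(1, 0, chain$theta_sd))
      log_hastings <- log(prop$theta) - log(state$theta)
    }
    if (feasible) {
      proposed[mv] <- proposed[mv] + 1L
      prop_lp <- log_prior(prop, prior, L_bp)
      if (is.finite(prop_lp)) {
        prop_ll <- llfun(prop)
        n_clamp_tot <- n_clamp_tot + attr(prop_ll, "n_clamped")
        prop_ll <- as.numeric(prop_ll)
        # birth/death Hastings terms already include the prior count and
        # parameter densities (birth draws from the prior), so compare the
        # remaining prior factors only for within-model moves
        if (mv %in% c("add", "remove")) {
          log_alpha <- (prop_ll - cur_ll) + log_hastings
        } else {
          log_alpha <- (prop_ll - cur_ll) + (prop_lp - cur_lp) + log_hastings
        }
        if (log(stats::runif(1)) < log_alpha) {
          state <- prop; cur_ll <- prop_ll; cur_lp <- prop_lp
          accepted[mv] <- accepted[mv] + 1L
        }
      }
    }
    if (ki < n_keep && it == keep_at[ki + 1L]) {
      ki <- ki + 1L
      tr_theta[ki] <- state$theta
      tr_b[ki] <- state$background
      tr_k[ki] <- nrow(state$hs)
      tr_lpost[ki] <- cur_ll + cur_lp
      hs_samples[[ki]] <- hs_intervals(state$hs, region_start, L_bp)
    }
  }

  trace <- data.frame(iteration = keep_at, theta = tr_theta,
                      background = tr_b, n_hotspots = tr_k,
                      log_posterior = tr_lpost)
  ess <- c(theta = suppressWarnings(compute_ess(tr_theta)),
           background = suppressWarnings(compute_ess(tr_b)),
           n_hotspots = suppressWarnings(compute_ess(as.numeric(tr_k))))
  structure(list(trace = trace, hotspots = hs_samples,
                 acceptance = data.frame(move = mv_names,
                                         proposed = as.integer(proposed),
                                         accepted = as.integer(accepted),
                                         rate = ifelse(proposed > 0,
                                                       accepted / pmax(proposed, 1L),
                                                       NA_real_)),
                 ess = ess, prior = prior, chain = chain, region = region,
                 chrom = g$chrom, markers = g$markers$pos,
                 n_haplotypes = 2L * length(g$samples),
                 likelihood = likelihood, n_clamped = n_clamp_tot,
                 call = match.call()),
            class = "rhomap_fit")
}

#' Prior-only chain for Bayes-factor calibration
#'
#' Runs the identical sampler with a constant likelihood while keeping the
#' same region, sample size and marker positions, giving the per-bin prior
#' hotspot probabilities q_j.
#'
#' @param x a `"genotypes"` object, or a length-2 region `c(start, end)`.
#' @param n sample size carried along for provenance (unused by the
#'   constant-likelihood sampler); taken from `x` when it is a genotype
#'   object.
#' @param prior a [prior_spec()].
#' @param chain a [chain_settings()].
#' @return A `"rhomap_fit"` from the prior.
#' @export
prior_chain <- function(x, n = NULL, prior = prior_spec(),
                        chain = chain_settings()) {
  if (!inherits(x, "genotypes")) {
    stopifnot(length(x) == 2, x[2] > x[1])
    x <- structure(list(chrom = "region", region = as.numeric(x),
                        markers = data.frame(pos = as.numeric(x)),
                        samples = character(max(1, n %||% 2) / 2),
                        calls = matrix(integer(0), 0, 0)),
                   class = "genotypes")
  }
  infer_rhomap(x, prior = prior, chain = chain, likelihood = "constant")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Effective sample size by the initial-positive-sequence estimator
#'
#' Geyer's initial positive sequence: the integrated autocorrelation time is
#' `-1 + 2 * sum Gamma_m` over successive autocorrelation pair sums
#' `Gamma_m = rho_{2m} + rho_{2m+1}`, truncated before the first negative
#' pair sum; ESS = length / max(tau, 1), capped at the trace length.
#'
#' @param trace numeric vector, length at least 10.
#' @return Effective sample size.
#' @export
compute_ess <- function(trace) {
  N <- length(trace)
  if (N < 10) stop("trace too short for ESS estimation")
  if (stats::var(trace) == 0) {
    warning("constant trace; ESS defined as the trace length")
    return(N)
  }
  rho <- as.numeric(stats::acf(trace, lag.max = N - 1, plot = FALSE,
                               demean = TRUE)$acf)
  m_max <- floor((N - 1) / 2)
  tau <- -1
  for (m in 0:m_max) {
    gam <- rho[2 * m + 1] + if (2 * m + 2 <= N) rho[2 * m + 2] else 0
    if (gam <= 0) break
    tau <- tau + 2 * gam
  }
  min(N, N / max(tau, 1))
}
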