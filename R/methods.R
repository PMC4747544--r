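#' @export
print.rhomap_fit <- function(x, ...) {
  cat(sprintf("rhomap fit (%s likelihood): %s [%s-%s], %d markers, %d samples\n",
              x$likelihood, x$chrom,
              format(x$region[1], big.mark = ","),
              format(x$region[2], big.mark = ","),
              length(x$markers), nrow(x$trace)))
  cat(sprintf("  posterior mean background %.4g rho/Mb, E[hotspots] %.2f, theta %.3g\n",
              mean(x$trace$background), mean(x$trace$n_hotspots),
              mean(x$trace$theta)))
  invisible(x)
}

#' @export
summary.rhomap_fit <- function(object, ...) {
  qs <- function(v) stats::quantile(v, c(0.025, 0.5, 0.975))
  s <- list(
    n_samples = nrow(object$trace),
    likelihood = object$likelihood,
    region = object$region,
    params = rbind(background = c(mean = mean(object$trace$background),
                                  qs(object$trace$background)),
                   theta = c(mean = mean(object$trace$theta),
                             qs(object$trace$theta)),
                   n_hotspots = c(mean = mean(object$trace$n_hotspots),
                                  qs(object$trace$n_hotspots))),
    ess = object$ess,
    acceptance = object$acceptance,
    n_clamped = object$n_clamped)
  class(s) <- "summary.rhomap_fit"
  s
}

#' @export
print.summary.rhomap_fit <- function(x, ...) {
  cat(sprintf("rhomap fit summary (%s likelihood, %d retained samples)\n",
              x$likelihood, x$n_samples))
  print(round(x$params, 5))
  cat("effective sample sizes:\n")
  print(round(x$ess, 1))
  cat("acceptance rates:\n")
  print(transform(x$acceptance, rate = round(rate, 3)), row.names = FALSE)
  if (x$n_clamped > 0)
    cat(sprintf("%d pairwise rho evaluations clamped to the grid maximum\n",
                x$n_clamped))
  invisible(x)
}

#' @export
coef.rhomap_fit <- function(object, ...) {
  c(background_rho_per_mb = mean(object$trace$background),
    theta_per_site = mean(object$trace$theta),
    mean_n_hotspots = mean(object$trace$n_hotspots))
}

#' Posterior mean local recombination rate
#'
#' @param object a `"rhomap_fit"`.
#' @param positions bp positions (absolute); defaults to midpoints of the
#'   inter-marker intervals.
#' @param ... unused.
#' @return Data frame with `pos`, `rho_per_mb` (posterior mean total rate)
#'   and `background_per_mb` (posterior mean background).
#' @export
predict.rhomap_fit <- function(object, positions = NULL, ...) {
  if (is.null(positions)) {
    p <- object$markers
    positions <- if (length(p) >= 2) (p[-1] + p[-length(p)]) / 2
                 else mean(object$region)
  }
  n <- nrow(object$trace)
  tot <- numeric(length(positions))
  for (s in seq_len(n)) {
    b <- object$trace$background[s]
    r <- rep(b, length(positions))
    h <- object$hotspots[[s]]
    for (i in seq_len(nrow(h)))
      r <- r + b * (h$multiplier[i] - 1) *
        (positions >= h$start[i] & positions < h$end[i])
    tot <- tot + r
  }
  data.frame(pos = positions, rho_per_mb = tot / n,
             background_per_mb = mean(object$trace$background))
}

#' Plot a fitted recombination map
#'
#' Top panel: posterior mean total rate (solid) and background (dashed)
#' along the region with a marker rug. Lower panels, when a prior chain is
#' supplied: per-bin posterior hotspot probability and log10 Bayes factor
#' with the calling threshold.
#'
#' @param x a `"rhomap_fit"`.
#' @param prior_fit optional matching [prior_chain()] fit.
#' @param bin_width bin width for the probability/Bayes-factor panels.
#' @param bf_threshold threshold line in the Bayes-factor panel.
#' @param ... passed to `plot`.
#' @export
plot.rhomap_fit <- function(x, prior_fit = NULL, bin_width = 200,
                            bf_threshold = 100, ...) {
  grid_pos <- seq(x$region[1], x$region[2], length.out = 400)
  pr <- predict(x, grid_pos)
  npan <- if (is.null(prior_fit)) 1 else 3
  op <- graphics::par(mfrow = c(npan, 1), mar = c(3.5, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(pr$pos / 1e6, pr$rho_per_mb, type = "l", xlab = "position (Mb)",
       ylab = expression(rho / Mb), ...)
  graphics::abline(h = pr$background_per_mb[1], lty = 2)
  graphics::rug(x$markers / 1e6)
  if (!is.null(prior_fit)) {
    tr <- bin_track(x, prior_fit, bin_width = bin_width)
    mid <- (tr$start + tr$end) / 2e6
    plot(mid, tr$p, type = "h", xlab = "position (Mb)",
         ylab = "P(hotspot)", ylim = c(0, 1))
    plot(mid, log10(tr$bf), type = "h", xlab = "position (Mb)",
         ylab = expression(log[10] ~ BF))
    graphics::abline(h = log10(bf_threshold), lty = 3)
  }
  invisible(x)
}

#' Simulate genotype data from the fitted posterior
#'
#' Draws a posterior sample of the rate map and simulates haplotypes from
#' the coalescent with recombination under it (a posterior predictive draw
#' of new data for the fitted region).
#'
#' @param object a `"rhomap_fit"`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param n_haplotypes haplotypes per dataset; defaults to the fitted
#'   sample's.
#' @param ... unused.
#' @return List of `"sim_sample"` objects.
#' @export
simulate.rhomap_fit <- function(object, nsim = 1, seed = 1,
                                n_haplotypes = NULL, ...) {
  n <- n_haplotypes %||% object$n_haplotypes
  L <- object$region[2] - object$region[1]
  set.seed(seed)
  idx <- sample.int(nrow(object$trace), nsim, replace = TRUE)
  lapply(seq_len(nsim), function(s) {
    i <- idx[s]
    h <- object$hotspots[[i]]
    hs <- if (nrow(h)) data.frame(start = h$start - object$region[1],
                                  end = h$end - object$region[1],
                                  multiplier = h$multiplier) else NULL
    map <- rate_map(L, object$trace$background[i], hs)
    simulate_haplotypes(population_model(theta = object$trace$theta[i]),
                        map, n = n, seed = seed + s)
  })
}
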