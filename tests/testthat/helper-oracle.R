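# Independent pure-R two-locus coalescent oracle. Code path shares nothing
# with the package's C++ engine: its own event loop, its own descendant-set
# bookkeeping, its own canonical fold. Mutation placement is integrated
# analytically (each replicate graph contributes its full conditional
# configuration distribution), so a few thousand replicates match the
# precision of millions of naive draws.

oracle_fold_key <- function(cf) {
  perms <- rbind(c(1, 2, 3, 4), c(3, 4, 1, 2), c(2, 1, 4, 3), c(4, 3, 2, 1),
                 c(1, 3, 2, 4), c(2, 4, 1, 3), c(3, 1, 4, 2), c(4, 2, 3, 1))
  keys <- apply(perms, 1, function(p) sprintf("%03d_%03d_%03d_%03d",
                                              cf[p[1]], cf[p[2]], cf[p[3]], cf[p[4]]))
  min(keys)
}

# one two-locus ARG for n haplotypes at recombination rho; returns branch
# exposure weights per descendant-set bitmask for each locus
oracle_two_locus_arg <- function(n, rho) {
  lin <- cbind(dA = bitwShiftL(1L, 0:(n - 1)), dB = bitwShiftL(1L, 0:(n - 1)))
  full <- bitwShiftL(1L, n) - 1L
  expA <- numeric(0); expB <- numeric(0)
  add_exp <- function(acc, masks, dt) {
    for (m in masks[masks > 0L]) {
      key <- as.character(m)
      acc[key] <- (if (is.na(acc[key])) 0 else acc[key]) + dt
    }
    acc
  }
  repeat {
    k <- nrow(lin)
    if (k == 0) break
    both <- lin[, 1] > 0L & lin[, 2] > 0L
    coal <- k * (k - 1) / 2
    rec <- rho / 2 * sum(both)
    tot <- coal + rec
    if (tot <= 0) break
    dt <- stats::rexp(1) / tot
    expA <- add_exp(expA, lin[, 1], dt)
    expB <- add_exp(expB, lin[, 2], dt)
    if (stats::runif(1) * tot < coal) {
      pick <- sample.int(k, 2)
      dA <- bitwOr(lin[pick[1], 1], lin[pick[2], 1])
      dB <- bitwOr(lin[pick[1], 2], lin[pick[2], 2])
      if (dA == full) dA <- 0L
      if (dB == full) dB <- 0L
      lin <- lin[-pick, , drop = FALSE]
      if (dA > 0L || dB > 0L) lin <- rbind(lin, c(dA, dB))
    } else {
      wb <- which(both)
      li <- if (length(wb) == 1) wb else sample(wb, 1)
      newrow <- c(0L, lin[li, 2])
      lin[li, 2] <- 0L
      lin <- rbind(lin, newrow)
    }
  }
  list(expA = expA, expB = expB)
}

# Rao-Blackwellized configuration distribution: named probability vector
# over canonical keys (both loci segregating by construction)
oracle_config_dist <- function(n, rho, reps) {
  acc <- new.env(parent = emptyenv())
  for (r in seq_len(reps)) {
    arg <- oracle_two_locus_arg(n, rho)
    pA <- arg$expA / sum(arg$expA)
    pB <- arg$expB / sum(arg$expB)
    mA <- as.integer(names(pA)); mB <- as.integer(names(pB))
    for (i in seq_along(mA)) for (j in seq_along(mB)) {
      n11 <- sum(bitwAnd(bitwAnd(mA[i], mB[j]), bitwShiftL(1L, 0:(n - 1))) > 0L)
      nA <- sum(bitwAnd(mA[i], bitwShiftL(1L, 0:(n - 1))) > 0L)
      nB <- sum(bitwAnd(mB[j], bitwShiftL(1L, 0:(n - 1))) > 0L)
      cf <- c(n - nA - nB + n11, nB - n11, nA - n11, n11)
      key <- oracle_fold_key(cf)
      acc[[key]] <- (acc[[key]] %||% 0) + unname(pA[i] * pB[j])
    }
  }
  out <- unlist(as.list(acc)) / reps
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# oracle log-likelihood of observed pair configs (list of length-4 vectors)
# at pairwise rho values, from per-rho oracle distributions with a small
# floor for never-seen configurations
oracle_pair_loglik <- function(configs, rhos, n, reps, floor_p = NULL) {
  if (is.null(floor_p)) floor_p <- 1 / (10 * reps)
  ll <- 0
  for (i in seq_along(configs)) {
    d <- oracle_config_dist(n, rhos[i], reps)
    p <- d[oracle_fold_key(configs[[i]])]
    ll <- ll + log(max(if (is.na(p)) 0 else p, floor_p))
  }
  ll
}
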