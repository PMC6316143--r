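# Bayesian inference of the Homo-Pan speciation time tau and ancestral
# population-mutation parameter theta under the multispecies coalescent.
#
# Model, per locus i with x_i mismatches over L_i sites between the pair:
#   h_i  = tau + t_i,     t_i ~ Exp(mean theta/2)   (coalescent height, s/s)
#   x_i | h_i ~ Binomial(L_i, p(2 h_i)),  p(d) = (3/4)(1 - exp(-4d/3))  (JC69)
# priors: theta ~ G(2, 200); tau ~ Uniform(0, tau_max) with tau_max the mean
# of the root-age prior fitted to the Homo-Pongo d_T/2 distribution.
# Sampling: Metropolis-within-Gibbs over (tau, theta, h_1..h_n) with a joint
# translation move on (tau, h) to decorrelate tau from the latent heights.

# JC69 mismatch probability at coalescent height h (pairwise distance 2h).
.p_mismatch <- function(h) 0.75 * (-expm1(-8 * h / 3))

# Binomial log-likelihood without the combinatorial constant (MCMC internal).
.ll_pair <- function(h, x, L) {
  p <- pmin(pmax(.p_mismatch(h), 1e-300), 1 - 1e-15)
  x * log(p) + (L - x) * log1p(-p)
}

#' Pairwise sufficient statistics of a locus
#'
#' Counts the sites at which the two chosen taxa differ. Under JC69 the
#' mismatch count and the alignment length are sufficient for the pairwise
#' distance, so the coalescent sampler consumes only `(x, L)` per locus.
#'
#' @param aln a [locus_alignment()].
#' @param pair two taxon names (default Homo, Pan).
#' @return named integer vector `c(x = differences, L = sites)`.
#' @export
locus_stats <- function(aln, pair = c("Homo", "Pan")) {
  stopifnot(inherits(aln, "locus_alignment"), all(pair %in% aln$taxa))
  c(x = sum(aln$seqs[pair[1], ] != aln$seqs[pair[2], ]),
    L = ncol(aln$seqs))
}

#' @rdname locus_stats
#' @param loci list of [locus_alignment()] (or manifest / FASTA directory).
#' @return `pair_counts` returns a data frame with columns `locus_id`, `x`,
#'   `L`.
#' @export
pair_counts <- function(loci, pair = c("Homo", "Pan")) {
  loci <- .as_locus_list(loci)
  s <- t(vapply(loci, locus_stats, integer(2), pair = pair))
  data.frame(locus_id = vapply(loci, `[[`, character(1), "locus_id"),
             x = s[, "x"], L = s[, "L"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Simulate per-locus pair counts directly
#'
#' Shortcut generator for the two-lineage reduction: draws coalescent heights
#' `h_i = tau + Exp(mean theta/2)` and mismatch counts
#' `x_i ~ Binomial(L, p(2 h_i))` under JC69. Statistically identical to
#' simulating full alignments and reducing them with [pair_counts()], and
#' much faster for large replicate studies.
#'
#' @param n_loci number of loci.
#' @param L sites per locus.
#' @param tau,theta true speciation time and ancestral theta (s/s).
#' @param seed optional integer seed.
#' @return data frame with columns `x`, `L` and the latent truth `h`;
#'   `attr(, "truth")` records `(tau, theta)`.
#' @export
simulate_pair_counts <- function(n_loci, L, tau, theta, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- rcoal_pair(n_loci, tau, theta)
  x <- stats::rbinom(n_loci, L, .p_mismatch(h))
  out <- data.frame(x = x, L = L, h = h)
  attr(out, "truth") <- c(tau = tau, theta = theta)
  out
}

#' Model specification for the coalescent sampler
#'
#' @param theta_prior [gamma_prior()] on the ancestral theta; default
#'   `G(2, 200)`, a broad prior covering empirically reported theta values.
#' @param root_prior [gamma_prior()] on the root (Homo-Pongo) speciation
#'   time; default `G(16.7, 1264)` with mean 0.0132 s/s. Its mean sets the
#'   upper bound of the uniform prior on tau.
#' @param tau_max upper bound of the Uniform(0, tau_max) prior on the
#'   Homo-Pan speciation time; defaults to `root_prior$mean`.
#' @return object of class `msc_model_spec`.
#' @export
msc_model_spec <- function(theta_prior = gamma_prior(2, 200),
                           root_prior = gamma_prior(16.7, 1264),
                           tau_max = NULL) {
  stopifnot(inherits(theta_prior, "gamma_prior"),
            inherits(root_prior, "gamma_prior"))
  if (is.null(tau_max)) tau_max <- root_prior$mean
  if (!is.finite(tau_max) || tau_max <= 0) stop("tau_max must be positive")
  structure(list(theta_prior = theta_prior, root_prior = root_prior,
                 tau_max = tau_max),
            class = "msc_model_spec")
}

#' Joint log-posterior of the augmented coalescent model
#'
#' Evaluates `log p(tau, theta, h | x, L)` up to the normalizing constant:
#' the gamma log-prior on theta, the uniform log-prior on tau, exponential
#' log-densities of the latent height excesses `h_i - tau` (mean `theta/2`),
#' and binomial JC69 log-likelihoods of the mismatch counts (including the
#' combinatorial constant). Returns `-Inf` outside the support
#' (`h_i < tau`, non-positive parameters, `tau > tau_max`).
#'
#' @param tau,theta parameter values (s/s).
#' @param h vector of latent per-locus coalescent heights (s/s).
#' @param x,L integer vectors of per-locus mismatch counts and lengths.
#' @param spec an [msc_model_spec()].
#' @return log-posterior value (scalar).
#' @export
msc_log_posterior <- function(tau, theta, h, x, L, spec = msc_model_spec()) {
  if (!is.finite(tau) || !is.finite(theta) || tau <= 0 || theta <= 0 ||
      tau >= spec$tau_max || any(h < tau))
    return(-Inf)
  sum(stats::dexp(h - tau, rate = 2 / theta, log = TRUE)) +
    sum(stats::dbinom(x, L, .p_mismatch(h), log = TRUE)) +
    stats::dgamma(theta, spec$theta_prior$shape, spec$theta_prior$rate,
                  log = TRUE) +
    stats::dunif(tau, 0, spec$tau_max, log = TRUE)
}

# One MCMC chain. Returns matrix of retained (tau, theta) samples plus
# acceptance diagnostics. All proposals are random walks; step sizes adapt
# toward 20-50% acceptance during burn-in only.
.msc_chain <- function(x, L, spec, n_samples, thin, burnin, seed,
                       prior_only = FALSE) {
  set.seed(seed)
  n <- length(x)
  a_th <- spec$theta_prior$shape; b_th <- spec$theta_prior$rate
  tau_max <- spec$tau_max

  if (prior_only) {
    theta <- stats::rgamma(1, a_th, b_th)
    tau <- stats::runif(1, 0, tau_max)
    h <- tau + stats::rexp(n, 2 / theta)
  } else {
    p0 <- pmin((x + 0.5) / (L + 1), 0.74)
    h <- pmax(jc69_distance(p0) / 2, 1e-8)
    tau <- max(min(0.8 * min(h), 0.9 * tau_max), 1e-8)
    theta <- max(2 * (mean(h) - tau), 1e-5)
  }
  ll <- if (prior_only) numeric(n) else .ll_pair(h, x, L)

  s_h <- max(theta / 2, 1e-5); s_t <- s_h / 2; s_q <- 0.5; s_s <- s_h / 4
  acc <- c(h = 0, tau = 0, shift = 0, theta = 0); trials <- acc
  n_iter <- burnin + n_samples * thin
  out <- matrix(NA_real_, n_samples, 2,
                dimnames = list(NULL, c("tau", "theta")))
  kept <- 0L

  for (it in seq_len(n_iter)) {
    # latent heights, one vectorized sweep
    h_new <- h + stats::runif(n, -s_h, s_h)
    ok <- h_new > tau
    ll_new <- ll
    if (any(ok)) ll_new[ok] <- if (prior_only) 0 else
      .ll_pair(h_new[ok], x[ok], L[ok])
    logr <- (ll_new - ll) - (2 / theta) * (h_new - h)
    take <- ok & log(stats::runif(n)) < logr
    h[take] <- h_new[take]; ll[take] <- ll_new[take]
    acc["h"] <- acc["h"] + mean(take); trials["h"] <- trials["h"] + 1

    # tau random walk (heights fixed)
    tau_new <- tau + stats::runif(1, -s_t, s_t)
    if (tau_new > 0 && tau_new < tau_max && tau_new <= min(h)) {
      logr <- (2 / theta) * n * (tau_new - tau)
      if (log(stats::runif(1)) < logr) { tau <- tau_new; acc["tau"] <- acc["tau"] + 1 }
    }
    trials["tau"] <- trials["tau"] + 1

    # joint translation of (tau, h): exponential terms cancel exactly
    d <- stats::runif(1, -s_s, s_s)
    tau_new <- tau + d
    if (tau_new > 0 && tau_new < tau_max) {
      ll_new <- if (prior_only) numeric(n) else .ll_pair(h + d, x, L)
      if (log(stats::runif(1)) < sum(ll_new - ll)) {
        tau <- tau_new; h <- h + d; ll <- ll_new
        acc["shift"] <- acc["shift"] + 1
      }
    }
    trials["shift"] <- trials["shift"] + 1

    # theta on the log scale (conjugate-free MH)
    theta_new <- theta * exp(stats::runif(1, -s_q, s_q))
    S <- sum(h - tau)
    logr <- n * log(theta / theta_new) - 2 * S * (1 / theta_new - 1 / theta) +
      stats::dgamma(theta_new, a_th, b_th, log = TRUE) -
      stats::dgamma(theta, a_th, b_th, log = TRUE) +
      log(theta_new / theta)            # Jacobian of the log-scale walk
    if (log(stats::runif(1)) < logr) { theta <- theta_new; acc["theta"] <- acc["theta"] + 1 }
    trials["theta"] <- trials["theta"] + 1

    # step-size adaptation, burn-in only, in blocks of 100 sweeps
    if (it <= burnin && it %% 100 == 0) {
      rates <- acc / trials
      tune <- function(s, r) if (r > 0.5) s * 1.3 else if (r < 0.2) s * 0.7 else s
      s_h <- tune(s_h, rates["h"]); s_t <- tune(s_t, rates["tau"])
      s_s <- tune(s_s, rates["shift"]); s_q <- tune(s_q, rates["theta"])
      acc[] <- 0; trials[] <- 0
    }

    if (it > burnin && (it - burnin) %% thin == 0) {
      kept <- kept + 1L
      out[kept, ] <- c(tau, theta)
    }
  }
  list(samples = out, acceptance = acc / pmax(trials, 1),
       steps = c(h = s_h, tau = s_t, shift = s_s, theta = s_q))
}

# Effective sample size by Geyer's initial positive sequence on the
# autocorrelation function.
.ess <- function(v) {
  n <- length(v)
  if (n < 4 || stats::var(v) == 0) return(n)
  rho <- as.numeric(stats::acf(v, lag.max = min(n - 2, 1000),
                               plot = FALSE)$acf)[-1]
  s <- 0
  for (k in seq(1, length(rho) - 1, by = 2)) {
    g <- rho[k] + rho[k + 1]
    if (is.na(g) || g <= 0) break
    s <- s + g
  }
  max(1, min(n, n / (1 + 2 * s)))
}

#' Fit the multispecies-coalescent model for the Homo-Pan pair
#'
#' Draws from the joint posterior of the Homo-Pan speciation time `tau`
#' (= d_1/2) and the ancestral population-mutation parameter `theta`, with
#' one latent coalescent height per locus, by Metropolis-within-Gibbs MCMC
#' (see [msc_log_posterior()] for the model). Multiple independent chains are
#' run from over-dispersed starting points; burn-in is discarded, proposal
#' step sizes are tuned during burn-in only, and the chains' `tau` means are
#' checked against each other (a discrepancy beyond two combined Monte-Carlo
#' standard errors raises a convergence warning, as does an effective sample
#' size below `min_ess`).
#'
#' @param x per-locus data: a data frame with columns `x` (mismatches) and
#'   `L` (sites), a list of [locus_alignment()], a [generate_dataset()]
#'   manifest, or a directory of FASTA files.
#' @param spec an [msc_model_spec()].
#' @param n_samples retained samples per chain (default 2000).
#' @param thin sampling interval in sweeps (default 50).
#' @param n_chains number of independent chains (default 2).
#' @param burnin_frac burn-in, as a fraction of the post-burn-in generations
#'   (default 0.1).
#' @param seed integer seed; per-chain seeds are derived deterministically.
#' @param pair taxa used when `x` holds alignments.
#' @param prior_only logical; `TRUE` switches the likelihood off so the
#'   sampler targets the prior (a sampler-correctness diagnostic).
#' @param min_ess minimum acceptable effective sample size for `tau`.
#' @return An object of class `msc_fit` with components `samples` (list of
#'   per-chain matrices with columns `tau`, `theta`), `summary` (per-parameter
#'   posterior mean, sd, 95% equal-tailed interval, ESS; includes the derived
#'   mean coalescent height `half_dT = tau + theta/2`), `diagnostics`,
#'   `spec`, `data`, `seed` and `call`.
#' @examples
#' d <- simulate_pair_counts(200, 500, tau = 0.00473, theta = 0.00304,
#'                           seed = 1)
#' fit <- fit_msc(d, n_samples = 300, thin = 5, seed = 1)
#' coef(fit)
#' @export
fit_msc <- function(x, spec = msc_model_spec(), n_samples = 2000, thin = 50,
                    n_chains = 2, burnin_frac = 0.1, seed = NULL,
                    pair = c("Homo", "Pan"), prior_only = FALSE,
                    min_ess = 100) {
  cl <- match.call()
  if (!is.data.frame(x)) x <- pair_counts(x, pair = pair)
  stopifnot(all(c("x", "L") %in% names(x)))
  if (nrow(x) < 1) stop("need at least one locus")
  if (any(x$x < 0 | x$x > x$L | x$L < 1)) stop("invalid per-locus counts")
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)
  burnin <- ceiling(burnin_frac * n_samples * thin)

  chains <- lapply(seq_len(n_chains), function(ch)
    .msc_chain(x$x, x$L, spec, n_samples, thin, burnin,
               seed = .locus_seed(seed, 1000L + ch), prior_only = prior_only))
  samples <- lapply(chains, `[[`, "samples")

  pooled <- do.call(rbind, samples)
  pooled <- cbind(pooled, half_dT = pooled[, "tau"] + pooled[, "theta"] / 2)
  summ <- t(apply(pooled, 2, function(v)
    c(mean = mean(v), sd = stats::sd(v),
      q2.5 = unname(stats::quantile(v, 0.025)),
      q97.5 = unname(stats::quantile(v, 0.975)))))
  ess_chain <- vapply(samples, function(s) .ess(s[, "tau"]), numeric(1))
  summ <- cbind(summ, ess = c(
    sum(vapply(samples, function(s) .ess(s[, "tau"]), numeric(1))),
    sum(vapply(samples, function(s) .ess(s[, "theta"]), numeric(1))),
    sum(vapply(samples, function(s)
      .ess(s[, "tau"] + s[, "theta"] / 2), numeric(1)))))

  # between-chain agreement on tau, in combined Monte-Carlo standard errors
  diag <- list(ess_tau_per_chain = ess_chain,
               acceptance = lapply(chains, `[[`, "acceptance"))
  if (n_chains >= 2) {
    m <- vapply(samples, function(s) mean(s[, "tau"]), numeric(1))
    mcse <- vapply(seq_along(samples), function(i)
      stats::sd(samples[[i]][, "tau"]) / sqrt(ess_chain[i]), numeric(1))
    disc <- abs(max(m) - min(m)) / sqrt(sum(mcse^2))
    diag$tau_chain_discrepancy_se <- disc
    if (is.finite(disc) && disc > 2)
      warning(sprintf(
        "chains disagree on tau (|mean difference| = %.1f combined MC s.e.)",
        disc))
  }
  if (sum(vapply(samples, function(s) .ess(s[, "tau"]), numeric(1))) < min_ess)
    warning("effective sample size for tau below min_ess; lengthen the run")

  structure(list(samples = samples, summary = summ, diagnostics = diag,
                 spec = spec, data = x, seed = seed, thin = thin,
                 n_chains = n_chains, prior_only = prior_only, call = cl),
            class = "msc_fit")
}

#' @export
print.msc_fit <- function(x, digits = 4, ...) {
  cat("Multispecies-coalescent fit (Homo-Pan pair)\n")
  cat(sprintf("  %d loci, %s sites; %d chains x %d samples (thin %d)%s\n",
              nrow(x$data), format(sum(x$data$L), big.mark = ",", scientific = FALSE),
              x$n_chains, nrow(x$samples[[1]]), x$thin,
              if (x$prior_only) " [prior only]" else ""))
  s <- x$summary
  for (p in rownames(s))
    cat(sprintf("  %-8s %.*g +- %.2g  [%.*g, %.*g]\n", p, digits,
                s[p, "mean"], s[p, "sd"], digits, s[p, "q2.5"], digits,
                s[p, "q97.5"]))
  invisible(x)
}

#' @export
summary.msc_fit <- function(object, ...) {
  structure(list(summary = object$summary,
                 diagnostics = object$diagnostics,
                 n_loci = nrow(object$data),
                 total_sites = sum(object$data$L),
                 n_chains = object$n_chains,
                 prior_only = object$prior_only),
            class = "summary.msc_fit")
}

#' @export
print.summary.msc_fit <- function(x, ...) {
  cat("Posterior summary (pooled chains)\n")
  print(round(x$summary, 7))
  cat(sprintf("\n%d loci, %s sites, %d chains\n", x$n_loci,
              format(x$total_sites, big.mark = ","), x$n_chains))
  if (!is.null(x$diagnostics$tau_chain_discrepancy_se))
    cat(sprintf("between-chain tau discrepancy: %.2f combined MC s.e.\n",
                x$diagnostics$tau_chain_discrepancy_se))
  invisible(x)
}

#' @export
coef.msc_fit <- function(object, ...) {
  stats::setNames(object$summary[c("tau", "theta"), "mean"],
                  c("tau", "theta"))
}

#' @export
plot.msc_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (p in c("tau", "theta")) {
    cols <- grDevices::hcl.colors(length(x$samples), "Dark 2")
    graphics::matplot(sapply(x$samples, function(s) s[, p]), type = "l",
                      lty = 1, col = cols, xlab = "sample", ylab = p,
                      main = paste("trace:", p))
    pooled <- unlist(lapply(x$samples, function(s) s[, p]))
    graphics::plot(stats::density(pooled), main = paste("posterior:", p),
                   xlab = paste(p, "(subst/site)"))
  }
  invisible(x)
}

#' @export
simulate.msc_fit <- function(object, nsim = 1, seed = NULL, n_loci = NULL,
                             L = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_loci)) n_loci <- nrow(object$data)
  if (is.null(L)) L <- round(mean(object$data$L))
  pooled <- do.call(rbind, object$samples)
  idx <- sample.int(nrow(pooled), nsim, replace = TRUE)
  lapply(seq_len(nsim), function(i)
    simulate_pair_counts(n_loci, L, tau = pooled[idx[i], "tau"],
                         theta = pooled[idx[i], "theta"]))
}

#' Deterministic grid-integration posterior (cross-check)
#'
#' Computes the marginal posterior of `(tau, theta)` on a rectangular grid by
#' numerically integrating the latent coalescent height out of each locus's
#' likelihood (substituting `u = exp(-2 t / theta)` turns the exponential
#' mixture into a uniform integral over (0, 1], evaluated by midpoint
#' quadrature). Intended as an independent deterministic oracle for
#' [fit_msc()] on small datasets; cost grows as
#' `n_tau * n_theta * n_quad * n_loci`.
#'
#' @inheritParams msc_log_posterior
#' @param tau_grid,theta_grid grid values; sensible data-driven defaults are
#'   derived from the pooled JC69 half-distance when omitted.
#' @param n_quad midpoint quadrature points for the latent-height integral.
#' @return list with the grids, the joint log-posterior matrix (`tau` rows),
#'   and marginal `mean`, `sd`, `q2.5`, `q97.5` for both parameters.
#' @export
msc_posterior_grid <- function(x, L = NULL, spec = msc_model_spec(),
                               tau_grid = NULL, theta_grid = NULL,
                               n_quad = 400) {
  if (is.data.frame(x)) { L <- x$L; x <- x$x }
  stopifnot(length(x) == length(L), length(x) >= 1)
  m <- jc69_distance(min(sum(x) / sum(L), 0.74)) / 2
  if (is.null(tau_grid))
    tau_grid <- seq(max(m / 20, 1e-6), min(spec$tau_max * 0.999, 2 * m),
                    length.out = 120)
  if (is.null(theta_grid))
    theta_grid <- seq(max(m / 50, 1e-6), 4 * max(m, spec$theta_prior$mean),
                      length.out = 120)
  u <- (seq_len(n_quad) - 0.5) / n_quad

  lp <- matrix(NA_real_, length(tau_grid), length(theta_grid))
  for (j in seq_along(theta_grid)) {
    th <- theta_grid[j]
    tq <- -(th / 2) * log(u)            # quadrature nodes for h - tau
    for (i in seq_along(tau_grid)) {
      ta <- tau_grid[i]
      if (ta >= spec$tau_max) { lp[i, j] <- -Inf; next }
      hh <- ta + tq
      ll <- vapply(seq_along(x), function(k) {
        v <- .ll_pair(hh, x[k], L[k])
        mx <- max(v)
        mx + log(mean(exp(v - mx)))
      }, numeric(1))
      lp[i, j] <- sum(ll) +
        stats::dgamma(th, spec$theta_prior$shape, spec$theta_prior$rate,
                      log = TRUE)
    }
  }
  w <- exp(lp - max(lp[is.finite(lp)]))
  w <- w / sum(w)
  marg <- function(grid, wt) {
    mu <- sum(grid * wt)
    sdv <- sqrt(max(sum(grid^2 * wt) - mu^2, 0))
    cw <- cumsum(wt)
    c(mean = mu, sd = sdv,
      q2.5 = grid[which(cw >= 0.025)[1]],
      q97.5 = grid[which(cw >= 0.975)[1]])
  }
  list(tau_grid = tau_grid, theta_grid = theta_grid, log_posterior = lp,
       tau = marg(tau_grid, rowSums(w)), theta = marg(theta_grid, colSums(w)))
}
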