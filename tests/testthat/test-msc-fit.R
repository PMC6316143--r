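test_that("pair sufficient statistics agree with brute force", {
  g <- simulate_genealogy(species_tree_params(), seed = 15)
  a <- simulate_alignment(g, subst_model(), L = 137, seed = 15)
  s <- locus_stats(a)
  brute <- sum(vapply(seq_len(137), function(j)
    a$seqs["Homo", j] != a$seqs["Pan", j], logical(1)))
  expect_identical(unname(s["x"]), brute)
  expect_identical(unname(s["L"]), 137L)

  same <- locus_alignment(matrix("C", 4, 100, dimnames = list(TAXA, NULL)))
  expect_identical(unname(locus_stats(same)), c(0L, 100L))
  s2 <- same$seqs; s2["Pan", ] <- "T"
  expect_identical(unname(locus_stats(locus_alignment(s2))["x"]), 100L)
})

test_that("log posterior equals a term-by-term textbook composition", {
  set.seed(25)
  d <- simulate_pair_counts(5, 500, TAU_TRUE, THETA_TRUE)
  spec <- msc_model_spec()
  tau <- 0.004; theta <- 0.003
  h <- tau + rexp(5, 2 / theta)
  oracle <- dgamma(theta, 2, 200, log = TRUE) +
    dunif(tau, 0, spec$tau_max, log = TRUE) +
    sum(vapply(1:5, function(i) {
      p <- 0.75 * (1 - exp(-4 * (2 * h[i]) / 3))
      dexp(h[i] - tau, rate = 2 / theta, log = TRUE) +
        dbinom(d$x[i], d$L[i], p, log = TRUE)
    }, numeric(1)))
  expect_equal(msc_log_posterior(tau, theta, h, d$x, d$L, spec), oracle,
               tolerance = 1e-10)

  expect_identical(msc_log_posterior(tau, theta, c(h[-5], tau - 1e-6),
                                     d$x, d$L, spec), -Inf)
  expect_identical(msc_log_posterior(-1, theta, h, d$x, d$L, spec), -Inf)
  expect_identical(msc_log_posterior(tau, 0, h, d$x, d$L, spec), -Inf)
  expect_identical(msc_log_posterior(spec$tau_max * 1.01, theta,
                                     h + spec$tau_max, d$x, d$L, spec), -Inf)
})

test_that("with theta pinned near zero the posterior peaks at the pooled
           half-distance", {
  set.seed(35)
  d <- simulate_pair_counts(50, 2000, TAU_TRUE, 1e-8)
  pooled_half <- jc69_distance(sum(d$x) / sum(d$L)) / 2
  taus <- seq(0.003, 0.007, length.out = 401)
  lp <- vapply(taus, function(ta)
    msc_log_posterior(ta, 1e-6, rep(ta + 1e-9, 50), d$x, d$L), numeric(1))
  expect_lt(abs(taus[which.max(lp)] - pooled_half), 2e-5)
})

test_that("prior-only sampling reproduces the priors", {
  d <- simulate_pair_counts(5, 500, TAU_TRUE, THETA_TRUE, seed = 45)
  pf <- suppressWarnings(fit_msc(d, n_samples = 500, thin = 100, seed = 46,
                                 prior_only = TRUE))
  th <- unlist(lapply(pf$samples, function(s) s[, "theta"]))
  ta <- unlist(lapply(pf$samples, function(s) s[, "tau"]))
  expect_gt(suppressWarnings(
    stats::ks.test(th, stats::pgamma, 2, 200))$p.value, 0.01)
  expect_gt(suppressWarnings(
    stats::ks.test(ta, stats::punif, 0, msc_model_spec()$tau_max))$p.value,
    0.01)
})

test_that("fixed seeds give bit-identical chains", {
  d <- simulate_pair_counts(30, 400, TAU_TRUE, THETA_TRUE, seed = 55)
  f1 <- suppressWarnings(fit_msc(d, n_samples = 100, thin = 5, seed = 7))
  f2 <- suppressWarnings(fit_msc(d, n_samples = 100, thin = 5, seed = 7))
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$summary, f2$summary)
})

test_that("the posterior recovers the truth and matches the pooled
           half-distance identity", {
  d <- simulate_pair_counts(500, 1000, TAU_TRUE, THETA_TRUE, seed = 65)
  fit <- fit_msc(d, n_samples = 500, thin = 20, seed = 66)
  s <- fit$summary
  expect_true(s["tau", "q2.5"] <= TAU_TRUE && TAU_TRUE <= s["tau", "q97.5"])
  expect_true(all(unlist(lapply(fit$samples, function(m) m > 0))))
  expect_true(s["tau", "mean"] >= s["tau", "q2.5"] &&
                s["tau", "mean"] <= s["tau", "q97.5"])

  # E[d_T/2] = tau + theta/2 tracks the empirical pooled half-distance
  pooled_half <- jc69_distance(sum(d$x) / sum(d$L)) / 2
  expect_lt(abs(s["half_dT", "mean"] - pooled_half), 3 * s["half_dT", "sd"])

  # posterior-predictive simulation has the fitted shape
  pp <- simulate(fit, nsim = 2, seed = 1, n_loci = 40, L = 250)
  expect_length(pp, 2)
  expect_identical(dim(pp[[1]]), c(40L, 3L))
  expect_true(all(pp[[1]]$x <= 250))

  expect_identical(unname(coef(fit)),
                   unname(s[c("tau", "theta"), "mean"]))
})

test_that("degenerate MCMC inputs are rejected and poor runs warn", {
  expect_error(fit_msc(data.frame(x = integer(), L = integer())),
               "at least one locus")
  expect_error(fit_msc(data.frame(x = 5, L = 2)), "invalid")
  d <- simulate_pair_counts(20, 200, TAU_TRUE, THETA_TRUE, seed = 75)
  expect_warning(fit_msc(d, n_samples = 30, thin = 1, seed = 76,
                         min_ess = 1000), "effective sample size")
})
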