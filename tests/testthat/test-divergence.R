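test_that("JC69 ML distance equals the closed-form inversion", {
  L <- 100000L
  x <- 621L                              # mismatch fraction 0.00621
  a <- rep("A", L); b <- a; b[seq_len(x)] <- "G"
  d <- ml_distance(a, b, pair = c("Homo", "Pan"))
  p <- x / L
  expect_identical(d$d_t, -0.75 * log1p(-4 * p / 3))
  expect_identical(round_half_up(d$d_t, 5), 0.00624)
  expect_identical(d$half_dt, d$d_t / 2)
  expect_identical(d$n_sites, L)

  expect_identical(ml_distance(a, a)$d_t, 0)
  b80 <- a; b80[seq_len(0.8 * L)] <- "C"
  expect_warning(ds <- ml_distance(a, b80), "saturated")
  expect_identical(ds$d_t, Inf)
  expect_error(ml_distance(a, b[-1]), "length")
})

test_that("half_dT is monotone in the mismatch fraction below saturation", {
  p <- seq(0, 0.74, by = 0.01)
  expect_true(all(diff(jc69_distance(p)) > 0))
  expect_equal(jc69_mismatch(jc69_distance(0.3)), 0.3, tolerance = 1e-12)
})

test_that("supermatrix pooling equals the sufficient-statistic estimate", {
  loci <- small_loci(n = 5, L = 300, seed = 61)
  pooled <- supermatrix_distance(loci, c("Homo", "Pan"))
  x <- sum(vapply(loci, function(l)
    sum(l$seqs["Homo", ] != l$seqs["Pan", ]), numeric(1)))
  n <- sum(vapply(loci, function(l) ncol(l$seqs), numeric(1)))
  expect_identical(pooled$d_t, jc69_distance(x / n))
  expect_identical(pooled$n_sites, as.integer(n))

  sm <- concat_loci(loci)
  expect_identical(ncol(sm$seqs), 5L * 300L)
  # concatenating copies of one locus reproduces its estimate
  same <- concat_loci(list(loci[[1]], loci[[1]], loci[[1]]))
  one <- ml_distance(loci[[1]]$seqs["Homo", ], loci[[1]]$seqs["Pan", ])
  expect_equal(supermatrix_distance(list(same), c("Homo", "Pan"))$d_t,
               one$d_t, tolerance = 1e-12)
})

test_that("GTR distance optimization agrees with JC69 on JC-like input and
           recovers simulated GTR+G+I distances", {
  a <- rep(c("A", "C", "G", "T"), 2500); b <- a
  set.seed(71); flip <- sample(10000, 150)
  b[flip] <- c(A = "C", C = "G", G = "T", T = "A")[a[flip]]
  jc <- ml_distance(a, b)
  gtr_eq <- subst_model("GTR")            # equal rates/frequencies
  expect_equal(ml_distance(a, b, gtr_eq)$d_t, jc$d_t, tolerance = 1e-4)

  m <- subst_model("GTR", base_freq = c(0.3, 0.2, 0.2, 0.3),
                   rates = c(1, 4, 1, 1, 4, 1), gamma_shape = 0.8,
                   p_inv = 0.2)
  g <- simulate_genealogy(clock_params(), seed = 72)   # H-P distance 0.0125
  al <- simulate_alignment(g, m, L = 40000, seed = 72)
  d <- ml_distance(al$seqs["Homo", ], al$seqs["Pan", ], m)
  expect_lt(abs(d$d_t - 0.0125), 3 * d$se)
})

test_that("per-locus half-distances drop saturated loci with a warning", {
  loci <- small_loci(n = 4, L = 200, seed = 81)
  v <- per_locus_half_dt(loci, c("Homo", "Pongo"))
  expect_length(v, 4)
  expect_true(all(is.finite(v) & v > 0))

  sat <- loci
  s <- sat[[1]]$seqs
  s["Pongo", ] <- c(A = "C", C = "G", G = "T", T = "A")[s["Homo", ]]
  sat[[1]] <- locus_alignment(s, "sat")
  expect_warning(v2 <- per_locus_half_dt(sat, c("Homo", "Pongo")),
                 "saturated")
  expect_length(v2, 3)
})

test_that("gamma prior fitting is a consistent MLE that preserves the mean", {
  set.seed(91)
  v <- rgamma(1e5, 5, 400)
  f <- fit_gamma_prior(v)
  se <- attr(f, "se")
  expect_lt(abs(f$shape - 5), 3 * se["shape"])
  expect_lt(abs(f$rate - 400), 3 * se["rate"])
  # the gamma MLE matches the sample mean (exact for the score equations)
  expect_equal(f$mean, mean(v), tolerance = 1e-2)

  expect_error(fit_gamma_prior(rep(0.01, 50)), "variance")
  expect_error(fit_gamma_prior(c(1, 2, 3)), "at least 10")
  expect_error(fit_gamma_prior(c(rep(1, 10), -1)), "positive")
  expect_error(gamma_prior(-1, 2), "positive")
})
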