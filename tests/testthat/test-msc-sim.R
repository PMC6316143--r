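test_that("zero-theta genealogies collapse to the species tree", {
  p0 <- clock_params()
  for (s in 1:5) {
    g <- simulate_genealogy(p0, seed = s)
    expect_identical(g$t_hc, p0$tau_hc)
    expect_true(g$hc_sister)
    expect_equal(g$heights, c(p0$tau_hc, p0$tau_hcg, p0$tau_root))
    expect_true(ape::is.ultrametric(g$tree))
  }
})

test_that("Homo-Pan coalescent height averages tau + theta/2", {
  set.seed(101)
  h <- rcoal_pair(10000, TAU_TRUE, THETA_TRUE)
  se <- sd(h) / sqrt(length(h))
  expect_lt(abs(mean(h) - (TAU_TRUE + THETA_TRUE / 2)), 3 * se)
  expect_true(all(h >= TAU_TRUE))
  expect_identical(rcoal_pair(5, 0.01, 0), rep(0.01, 5))

  # same expectation through the full 4-taxon sampler when the HC ancestor
  # is deep enough that the pair always coalesces inside it
  deep <- species_tree_params(tau_hc = TAU_TRUE, tau_hcg = 1, tau_root = 2,
                              theta_hc = THETA_TRUE, theta_hcg = 0,
                              theta_root = 0)
  set.seed(202)
  t_hc <- vapply(seq_len(3000), function(i)
    simulate_genealogy(deep)$t_hc, numeric(1))
  se <- sd(t_hc) / sqrt(length(t_hc))
  expect_lt(abs(mean(t_hc) - (TAU_TRUE + THETA_TRUE / 2)), 3 * se)
})

test_that("incomplete lineage sorting gives 2/3 discordance when coalescence
           escapes into a deep common ancestor", {
  # huge thetas: the pair virtually never coalesces before reaching the HCG
  # ancestor, where the three possible first pairings are equally likely
  p <- species_tree_params(tau_hc = 1e-4, tau_hcg = 2e-4, tau_root = 50,
                           theta_hc = 100, theta_hcg = 100, theta_root = 100)
  set.seed(303)
  sis <- vapply(seq_len(3000), function(i)
    simulate_genealogy(p)$hc_sister, logical(1))
  se <- sqrt(1 / 3 * 2 / 3 / length(sis))
  expect_lt(abs(mean(!sis) - 2 / 3), 3 * se)
})

test_that("sequence evolution reproduces the JC69 mismatch probability", {
  g <- simulate_genealogy(clock_params(), seed = 7)   # H-P distance 0.0125
  a <- simulate_alignment(g, subst_model(), L = 20000, seed = 7)
  p_hat <- mean(a$seqs["Homo", ] != a$seqs["Pan", ])
  p_exp <- jc69_mismatch(2 * g$t_hc)
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 20000))
})

test_that("a zero-length genealogy yields identical sequences", {
  tr0 <- ape::read.tree(text = "((Homo:0,Pan:0):0,(Gorilla:0,Pongo:0):0);")
  a <- simulate_alignment(tr0, subst_model(), L = 50, seed = 1)
  expect_true(all(apply(a$seqs, 2, function(co) length(unique(co)) == 1)))
})

test_that("gamma and invariant site-rate mixtures are honoured", {
  m <- subst_model("GTR", gamma_shape = 0.4, p_inv = 0.4)
  g <- simulate_genealogy(species_tree_params(), seed = 11)
  a <- simulate_alignment(g, m, L = 5000, seed = 11)
  const <- mean(apply(a$seqs, 2, function(co) length(unique(co)) == 1))
  # at least the invariant fraction of columns must be constant
  expect_gt(const, 0.4)
  # rate mixture is scaled to mean one (the +I convention)
  mix <- coalrate:::.rate_mixture(m)
  expect_equal(sum(mix$rates * mix$weights), 1, tolerance = 1e-10)
})

test_that("datasets are byte-reproducible and loci individually regenerable", {
  p <- species_tree_params()
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  m1 <- generate_dataset(p, subst_model(), n_loci = 3, L = 100, seed = 9,
                         out_dir = d1)
  m2 <- generate_dataset(p, subst_model(), n_loci = 3, L = 100, seed = 9,
                         out_dir = d2)
  for (f in basename(m1$loci$file))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  # locus 2 can be rebuilt alone from its recorded substream seed
  set.seed(m1$loci$seed[2])
  g <- simulate_genealogy(p, locus_id = m1$loci$locus_id[2])
  a <- simulate_alignment(g, subst_model(), L = 100)
  expect_identical(a$seqs, read_locus_fasta(m1$loci$file[2])$seqs)
  expect_equal(g$t_hc, m1$loci$t_hc[2])
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("degenerate simulation inputs are rejected", {
  expect_error(generate_dataset(species_tree_params(), n_loci = 0, seed = 1),
               "n_loci")
  expect_error(species_tree_params(tau_hc = 0.01, tau_hcg = 0.005),
               "tau_hc < tau_hcg")
  expect_error(species_tree_params(theta_hc = -1), "non-negative")
  expect_error(subst_model("GTR", base_freq = c(1, 1, 1, 1)), "summing to 1")
  expect_error(subst_model(p_inv = 1), "p_inv")
  expect_error(simulate_alignment(simulate_genealogy(species_tree_params(),
                                                     seed = 1),
                                  subst_model(), L = 0), "L must be")
  expect_error(locus_alignment(matrix("N", 2, 2,
                                      dimnames = list(c("a", "b"), NULL))),
               "alphabet")
})
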