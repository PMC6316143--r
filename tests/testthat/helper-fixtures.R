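# Shared fixtures. The clock-true parameter set has zero ancestral thetas,
# so every genealogy is exactly ultrametric with heights (0.00625, 0.008,
# 0.013) -- the mean coalescent heights of the great-ape comparison.

clock_params <- function() species_tree_params(
  tau_hc = 0.00625, tau_hcg = 0.008, tau_root = 0.013,
  theta_hc = 0, theta_hcg = 0, theta_root = 0)

# Study-condition truth for the Homo-Pan pair: speciation time 0.00473 s/s,
# ancestral theta 0.00304 s/s, so the mean coalescent height is 0.00625.
TAU_TRUE <- 0.00473
THETA_TRUE <- 0.00304

derive_seed <- function(seed, i) coalrate:::.locus_seed(seed, i)

small_loci <- function(n = 6, L = 200, seed = 5,
                       params = species_tree_params()) {
  generate_dataset(params, subst_model(), n_loci = n, L = L, seed = seed,
                   out_dir = NULL)$alignments
}

# Null distribution of the clock LRT on clock-true loci; computed once per
# test run and shared between the calibration and distribution checks.
.batch_cache <- new.env(parent = emptyenv())
lrt_null_batch <- function(n = 1000, L = 5000) {
  key <- sprintf("lrt_%d_%d", n, L)
  if (is.null(.batch_cache[[key]])) {
    p0 <- clock_params()
    .batch_cache[[key]] <- t(vapply(seq_len(n), function(i) {
      g <- simulate_genealogy(p0, seed = derive_seed(1000, i))
      a <- simulate_alignment(g, subst_model(), L, seed = derive_seed(1001, i))
      r <- clock_lrt(a)
      c(LR = r$LR, p = r$p_value)
    }, numeric(2)))
  }
  .batch_cache[[key]]
}
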