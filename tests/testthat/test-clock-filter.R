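test_that("pruning likelihood is exact in the stationary limit and invariant
           to site order", {
  tr0 <- ape::read.tree(text = "((Homo:0,Pan:0):0,(Gorilla:0,Pongo:0):0);")
  one <- locus_alignment(matrix("A", 4, 1, dimnames = list(TAXA, NULL)))
  expect_equal(tree_loglik(one, tr0), log(0.25), tolerance = 1e-10)

  g <- simulate_genealogy(species_tree_params(), seed = 9)
  a <- simulate_alignment(g, subst_model(), L = 200, seed = 9)
  perm <- locus_alignment(a$seqs[, sample(ncol(a$seqs))], "perm")
  expect_equal(tree_loglik(a, g$tree), tree_loglik(perm, g$tree),
               tolerance = 1e-9)

  expect_error(tree_loglik(one, ape::read.tree(text = "((a:1,b:1):1,c:1);")),
               "taxa")
})

test_that("identical sequences drive all branch lengths and heights to zero", {
  a <- locus_alignment(matrix(rep(c("A", "C", "G", "T"), each = 4), 4, 100,
                              dimnames = list(TAXA, NULL))[, rep(1:4, 25)])
  expect_lt(max(fit_free(a)$branch_lengths), 1e-6)
  cl <- fit_clock(a)
  expect_lt(max(cl$heights), 1e-6)
  r <- clock_lrt(a)
  expect_equal(r$LR, 0, tolerance = 1e-4)
  expect_equal(r$p_value, 1, tolerance = 1e-4)
  expect_true(r$keep)
})

test_that("free and clock fits are properly nested", {
  loci <- small_loci(n = 12, L = 400, seed = 21)
  for (a in loci) {
    r <- clock_lrt(a)
    expect_gte(r$lnL_free, r$lnL_clock - 1e-6)
    expect_gte(r$LR, 0)
    expect_identical(r$df, 2L)
    expect_identical(r$keep, r$p_value >= 0.05)
  }
})

test_that("clock heights are consistently estimated on a long locus", {
  g <- simulate_genealogy(clock_params(), seed = 31)
  a <- simulate_alignment(g, subst_model(), L = 1e5, seed = 31)
  h <- fit_clock(a)$heights
  # large-sample s.e. of a JC69 height from the pairwise distance error
  se_h <- function(d, L) {
    p <- jc69_mismatch(d)
    sqrt(p * (1 - p) / L) / (1 - 4 * p / 3) / 2
  }
  expect_lt(abs(h["h_hc"] - 0.00625), 3 * se_h(0.0125, 1e5))
  expect_lt(abs(h["h_root"] - 0.013), 3 * se_h(0.026, 1e5))
  expect_true(all(diff(h) >= -1e-12))
})

test_that("gross rate heterogeneity is rejected with high power", {
  for (s in c(41, 42, 43)) {
    g <- simulate_genealogy(clock_params(), seed = s)
    tr <- g$tree
    homo_edge <- which(tr$edge[, 2] == which(tr$tip.label == "Homo"))
    tr$edge.length[homo_edge] <- tr$edge.length[homo_edge] * 10
    a <- simulate_alignment(tr, subst_model(), L = 2000, seed = s)
    expect_lt(clock_lrt(a)$p_value, 0.01)
  }
})

test_that("filtering is idempotent and reports every locus", {
  loci <- lapply(1:10, function(i) {
    g <- simulate_genealogy(clock_params(), seed = derive_seed(51, i),
                            locus_id = sprintf("locus_%02d", i))
    simulate_alignment(g, subst_model(), L = 500, seed = derive_seed(52, i))
  })
  f <- file.path(tempdir(), "clock_report.tsv")
  r1 <- filter_loci(loci, report_file = f)
  expect_identical(nrow(r1$report), 10L)
  expect_true(file.exists(f))
  expect_identical(names(utils::read.delim(f)),
                   c("locus_id", "lnL_free", "lnL_clock", "LR", "df",
                     "p_value", "keep"))
  r2 <- filter_loci(r1$kept)
  expect_identical(length(r2$kept), length(r1$kept))
  unlink(f)
})

test_that("the null LR statistic follows chi-square with 2 df", {
  batch <- lrt_null_batch()
  expect_true(all(batch[, "LR"] >= 0))
  ks <- suppressWarnings(stats::ks.test(batch[, "LR"], stats::pchisq, df = 2))
  expect_gt(ks$p.value, 0.01)
})
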