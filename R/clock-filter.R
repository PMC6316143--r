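# Molecular-clock likelihood ratio test on the fixed 4-taxon topology.
# Loci whose rate heterogeneity rejects a strict clock are removed before any
# divergence is interpreted as time: the coalescent decomposition d_T = d_1 +
# theta reads heights as ages only when rates are homogeneous across lineages.

.as_phyDat <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (ncol(aln$seqs) == 0) stop("zero-length alignment")
  phangorn::phyDat(aln$seqs, type = "DNA")
}

# Map a subst_model onto phangorn::pml() arguments.
.pml_args <- function(model) {
  list(bf = model$base_freq, Q = model$rates,
       k = if (is.null(model$gamma_shape)) 1L else model$gamma_ncat,
       shape = if (is.null(model$gamma_shape)) 1 else model$gamma_shape,
       inv = model$p_inv)
}

.pml_fit <- function(tree, dat, model) {
  a <- .pml_args(model)
  phangorn::pml(tree, dat, bf = a$bf, Q = a$Q, k = a$k, shape = a$shape,
                inv = a$inv)
}

# JC69-corrected pairwise distance matrix used only to seed the optimizers.
.start_heights <- function(aln) {
  d <- function(i, j) {
    p <- mean(aln$seqs[i, ] != aln$seqs[j, ])
    jc69_distance(min(p, 0.7))          # cap away from saturation for starts
  }
  h_hc <- d("Homo", "Pan") / 2
  h_hcg <- mean(c(d("Homo", "Gorilla"), d("Pan", "Gorilla"))) / 2
  h_root <- mean(c(d("Homo", "Pongo"), d("Pan", "Pongo"),
                   d("Gorilla", "Pongo"))) / 2
  eps <- 1e-7
  h_hc <- max(h_hc, eps)
  h_hcg <- max(h_hcg, h_hc + eps)
  h_root <- max(h_root, h_hcg + eps)
  c(h_hc = h_hc, h_hcg = h_hcg, h_root = h_root)
}

# Rooted ultrametric (((Homo,Pan),Gorilla),Pongo) tree from node heights.
.clock_tree <- function(h) {
  txt <- sprintf("(((Homo:%.12f,Pan:%.12f):%.12f,Gorilla:%.12f):%.12f,Pongo:%.12f);",
                 h[1], h[1], h[2] - h[1], h[2], h[3] - h[2], h[3])
  ape::read.tree(text = txt)
}

.node_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth) - depth
  mrca <- function(tips) ape::getMRCA(tree, tips)
  c(h_hc = h[mrca(c("Homo", "Pan"))],
    h_hcg = h[mrca(c("Homo", "Pan", "Gorilla"))],
    h_root = h[mrca(c("Homo", "Pan", "Gorilla", "Pongo"))])
}

#' Felsenstein pruning log-likelihood of an alignment on a tree
#'
#' Evaluates the phylogenetic log-likelihood of a fixed tree (branch lengths
#' in substitutions/site) under the substitution model, with site patterns
#' compressed before pruning.
#'
#' @param aln a [locus_alignment()]; taxa must match the tree's tip labels.
#' @param tree an [ape::phylo] with branch lengths.
#' @param model a [subst_model()].
#' @return The log-likelihood (numeric scalar).
#' @export
tree_loglik <- function(aln, tree, model = subst_model()) {
  if (!setequal(tree$tip.label, aln$taxa))
    stop("alignment taxa do not match tree tips")
  fit <- .pml_fit(tree, .as_phyDat(aln), model)
  ll <- as.numeric(stats::logLik(fit))
  if (!is.finite(ll)) stop("non-finite log-likelihood")
  ll
}

#' Maximum-likelihood branch lengths without a clock
#'
#' Maximizes the log-likelihood over the five free branch lengths of the
#' unrooted 4-taxon tree ((Homo,Pan),Gorilla,Pongo). The default start is the
#' JC69 distance-based tree; supply `start` to begin elsewhere (e.g. from the
#' clock optimum, which guarantees the nesting inequality by construction).
#'
#' @param aln a [locus_alignment()].
#' @param model a [subst_model()].
#' @param start optional unrooted starting [ape::phylo].
#' @return list with `lnL`, the fitted `tree`, and `branch_lengths`.
#' @export
fit_free <- function(aln, model = subst_model(), start = NULL) {
  dat <- .as_phyDat(aln)
  if (is.null(start)) start <- ape::unroot(.clock_tree(.start_heights(aln)))
  start$edge.length <- pmax(start$edge.length, 1e-9)
  fit <- .pml_fit(start, dat, model)
  fit <- phangorn::optim.pml(fit, optEdge = TRUE,
                             control = phangorn::pml.control(trace = 0,
                                                             epsilon = 1e-9))
  list(lnL = as.numeric(stats::logLik(fit)), tree = fit$tree,
       branch_lengths = fit$tree$edge.length)
}

#' Maximum-likelihood strict-clock fit
#'
#' Maximizes the log-likelihood over the three node heights of the rooted
#' ultrametric tree (((Homo,Pan),Gorilla),Pongo) with Pongo as outgroup,
#' subject to `0 <= h_HC <= h_HCG <= h_root`.
#'
#' @inheritParams fit_free
#' @return list with `lnL`, fitted node `heights` (h_hc, h_hcg, h_root) and
#'   the ultrametric `tree`.
#' @export
fit_clock <- function(aln, model = subst_model()) {
  dat <- .as_phyDat(aln)
  start <- .clock_tree(.start_heights(aln))
  fit <- .pml_fit(start, dat, model)
  fit <- phangorn::optim.pml(fit, optEdge = TRUE, optRooted = TRUE,
                             control = phangorn::pml.control(trace = 0,
                                                             epsilon = 1e-9))
  list(lnL = as.numeric(stats::logLik(fit)),
       heights = .node_heights(fit$tree), tree = fit$tree)
}

#' Likelihood ratio test of the molecular clock
#'
#' Compares the strict-clock fit (3 node heights) against the free fit (5
#' branch lengths) of the fixed 4-taxon topology. Twice the log-likelihood
#' difference is referred to a chi-square distribution with 2 degrees of
#' freedom (5 - 3 parameters); a locus is kept when the clock is *not*
#' rejected at level `alpha`. The free optimization is started from the clock
#' optimum, which enforces `lnL_free >= lnL_clock` up to optimizer tolerance.
#'
#' @inheritParams fit_free
#' @param alpha significance level of the test (default 0.05).
#' @return An object of class `clock_test`: list with `locus_id`, `lnL_free`,
#'   `lnL_clock`, `LR`, `df`, `p_value`, `keep`, and the fitted clock
#'   `heights`.
#' @examples
#' g <- simulate_genealogy(species_tree_params(), seed = 3)
#' a <- simulate_alignment(g, subst_model(), L = 500, seed = 3)
#' clock_lrt(a)
#' @export
clock_lrt <- function(aln, model = subst_model(), alpha = 0.05) {
  clock <- fit_clock(aln, model)
  free <- fit_free(aln, model, start = ape::unroot(clock$tree))
  lr <- max(0, 2 * (free$lnL - clock$lnL))
  df <- 2L
  p <- stats::pchisq(lr, df = df, lower.tail = FALSE)
  structure(list(locus_id = aln$locus_id, lnL_free = free$lnL,
                 lnL_clock = clock$lnL, LR = lr, df = df, p_value = p,
                 keep = p >= alpha, heights = clock$heights, alpha = alpha),
            class = "clock_test")
}

#' @export
print.clock_test <- function(x, ...) {
  cat(sprintf("Clock LRT %s: LR = %.4f (df = %d), p = %.4f -> %s\n",
              x$locus_id, x$LR, x$df, x$p_value,
              if (x$keep) "keep (clock not rejected)" else "reject"))
  invisible(x)
}

#' Filter loci by the molecular-clock LRT
#'
#' Runs [clock_lrt()] on every locus and retains those failing to reject the
#' clock at level `alpha`, mirroring the pre-filtering applied to genome-wide
#' segment collections before coalescent-time estimation.
#'
#' @param loci list of [locus_alignment()] (or a directory of FASTA files, or
#'   a manifest from [generate_dataset()]).
#' @param model a [subst_model()].
#' @param alpha significance level.
#' @param report_file optional path for a tab-separated per-locus report
#'   (locus_id, lnL_free, lnL_clock, LR, df, p_value, keep).
#' @return list with `kept` (the retained alignments) and `report` (a data
#'   frame, one row per input locus).
#' @export
filter_loci <- function(loci, model = subst_model(), alpha = 0.05,
                        report_file = NULL) {
  loci <- .as_locus_list(loci)
  tests <- lapply(loci, clock_lrt, model = model, alpha = alpha)
  report <- data.frame(
    locus_id = vapply(tests, `[[`, character(1), "locus_id"),
    lnL_free = vapply(tests, `[[`, numeric(1), "lnL_free"),
    lnL_clock = vapply(tests, `[[`, numeric(1), "lnL_clock"),
    LR = vapply(tests, `[[`, numeric(1), "LR"),
    df = vapply(tests, `[[`, integer(1), "df"),
    p_value = vapply(tests, `[[`, numeric(1), "p_value"),
    keep = vapply(tests, `[[`, logical(1), "keep"),
    stringsAsFactors = FALSE)
  if (!is.null(report_file))
    utils::write.table(report, report_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(kept = loci[report$keep], report = report)
}

# Accept a list of alignments, a manifest, or a FASTA directory.
.as_locus_list <- function(loci) {
  if (is.character(loci) && length(loci) == 1) return(read_loci(loci))
  if (is.list(loci) && !is.null(loci$alignments)) return(loci$alignments)
  if (inherits(loci, "locus_alignment")) return(list(loci))
  stopifnot(is.list(loci), all(vapply(loci, inherits, logical(1),
                                      "locus_alignment")))
  loci
}
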