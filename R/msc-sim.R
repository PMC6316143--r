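# Multispecies-coalescent simulation on the fixed great-ape species tree
# (((Homo,Pan),Gorilla),Pongo). All times are expected substitutions/site.

TAXA <- c("Homo", "Pan", "Gorilla", "Pongo")

#' Species-tree parameters for the great-ape multispecies coalescent
#'
#' Bundles the speciation times and ancestral population-mutation parameters
#' of the fixed rooted topology (((Homo,Pan),Gorilla),Pongo). All quantities
#' are in expected substitutions per site: speciation times `tau` are node
#' ages, and each `theta = 4 * Ne * mu` equals the expected pairwise diversity
#' within the corresponding ancestral population. Sampled (tip) species carry
#' `theta = 0` by default, i.e. one haploid sequence per species.
#'
#' @param tau_hc Homo-Pan speciation time (s/s). Default 0.00473, the
#'   Homo-Pan speciation time estimated from great-ape genomes.
#' @param tau_hcg Homo-Pan-Gorilla speciation time (s/s); must exceed
#'   `tau_hc`.
#' @param tau_root root (Pongo split) speciation time (s/s); must exceed
#'   `tau_hcg`.
#' @param theta_hc,theta_hcg,theta_root population-mutation parameters of the
#'   three ancestral populations (s/s, non-negative). The default
#'   `theta_hc = 0.00304` makes the mean Homo-Pan coalescent height
#'   `tau_hc + theta_hc/2 = 0.00625`.
#' @param theta_tips theta of the four sampled species; default 0 (a single
#'   sequence per species never coalesces within its own population, so the
#'   value is irrelevant unless you add sequences).
#'
#' @return An object of class `species_tree_params`.
#' @examples
#' species_tree_params()
#' @export
species_tree_params <- function(tau_hc = 0.00473, tau_hcg = 0.0065,
                                tau_root = 0.012, theta_hc = 0.00304,
                                theta_hcg = 0.003, theta_root = 0.002,
                                theta_tips = 0) {
  p <- list(tau_hc = tau_hc, tau_hcg = tau_hcg, tau_root = tau_root,
            theta_hc = theta_hc, theta_hcg = theta_hcg,
            theta_root = theta_root, theta_tips = theta_tips)
  vals <- unlist(p)
  if (any(!is.finite(vals))) stop("all parameters must be finite")
  if (any(vals < 0)) stop("all parameters must be non-negative")
  if (!(p$tau_hc > 0 && p$tau_hc < p$tau_hcg && p$tau_hcg < p$tau_root))
    stop("speciation times must satisfy 0 < tau_hc < tau_hcg < tau_root")
  structure(p, class = "species_tree_params")
}

#' @export
print.species_tree_params <- function(x, ...) {
  cat("Species tree (((Homo,Pan),Gorilla),Pongo), times in subst/site\n")
  cat(sprintf("  tau:   HC %.6g  HCG %.6g  root %.6g\n",
              x$tau_hc, x$tau_hcg, x$tau_root))
  cat(sprintf("  theta: HC %.6g  HCG %.6g  root %.6g  (tips %.6g)\n",
              x$theta_hc, x$theta_hcg, x$theta_root, x$theta_tips))
  invisible(x)
}

#' Substitution model specification
#'
#' Describes the nucleotide substitution process used for sequence simulation,
#' likelihood computation and distance estimation. JC69 is the default
#' throughout (closed-form distances, the model used by the coalescent
#' sampler); GTR with discrete-gamma rate variation and a proportion of
#' invariant sites (GTR+G+I) is available to mirror model-test choices made on
#' real supermatrices.
#'
#' @param model one of "JC69", "HKY85", "GTR".
#' @param base_freq equilibrium base frequencies (A, C, G, T); must sum to 1.
#' @param rates six exchangeability parameters in the order
#'   AC, AG, AT, CG, CT, GT (ignored for JC69; for HKY85 supply `kappa`
#'   instead).
#' @param kappa transition/transversion ratio for HKY85.
#' @param gamma_shape shape of the discrete-gamma distribution of site rates;
#'   `NULL` disables rate variation.
#' @param gamma_ncat number of discrete gamma categories (default 4).
#' @param p_inv proportion of invariant sites in `[0, 1)`.
#'
#' @return An object of class `subst_model`.
#' @examples
#' subst_model()                                  # JC69
#' subst_model("GTR", rates = c(1, 4, 1, 1, 4, 1), gamma_shape = 0.5,
#'             p_inv = 0.2)
#' @export
subst_model <- function(model = c("JC69", "HKY85", "GTR"),
                        base_freq = rep(0.25, 4), rates = rep(1, 6),
                        kappa = 2, gamma_shape = NULL, gamma_ncat = 4L,
                        p_inv = 0) {
  model <- match.arg(model)
  if (model == "JC69") {
    base_freq <- rep(0.25, 4)
    rates <- rep(1, 6)
  }
  if (model == "HKY85") rates <- c(1, kappa, 1, 1, kappa, 1)
  if (length(base_freq) != 4 || any(base_freq <= 0) ||
      abs(sum(base_freq) - 1) > 1e-8)
    stop("base_freq must be 4 positive values summing to 1")
  if (length(rates) != 6 || any(!is.finite(rates)) || any(rates <= 0))
    stop("rates must be 6 positive exchangeabilities")
  if (!is.null(gamma_shape) && (!is.finite(gamma_shape) || gamma_shape <= 0))
    stop("gamma_shape must be positive")
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must lie in [0, 1)")
  structure(list(model = model, base_freq = base_freq, rates = rates,
                 gamma_shape = gamma_shape, gamma_ncat = as.integer(gamma_ncat),
                 p_inv = p_inv),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  g <- if (is.null(x$gamma_shape)) "none"
       else sprintf("shape %.3g, %d categories", x$gamma_shape, x$gamma_ncat)
  cat(sprintf("%s model; gamma rate variation: %s; p_inv = %.3g\n",
              x$model, g, x$p_inv))
  invisible(x)
}

#' Pairwise coalescent heights in a single ancestral population
#'
#' Draws gene-tree heights for a pair of lineages that enter an ancestral
#' population at speciation time `tau`: the waiting time to coalescence is
#' exponential with mean `theta / 2` (in substitutions/site), so the height is
#' `tau + Exp(mean theta/2)`. With `theta = 0` the pair coalesces instantly at
#' `tau`. The expectation is `tau + theta/2`, the mean coalescent (gene
#' divergence) time the multispecies coalescent predicts for the pair.
#'
#' @param n number of independent genealogies.
#' @param tau speciation time (s/s).
#' @param theta ancestral population-mutation parameter (s/s).
#' @return numeric vector of `n` coalescent heights (s/s).
#' @examples
#' set.seed(1)
#' mean(rcoal_pair(1e4, 0.00473, 0.00304))  # ~ 0.00625
#' @export
rcoal_pair <- function(n, tau, theta) {
  if (!is.finite(tau) || tau < 0 || !is.finite(theta) || theta < 0)
    stop("tau and theta must be finite and non-negative")
  if (theta == 0) return(rep(tau, n))
  tau + stats::rexp(n, rate = 2 / theta)
}

# Run the coalescent among `lin` lineages inside one population on
# [t_start, t_end) with parameter theta. Returns updated lineage list and
# merge records. A lineage is list(label=<newick>, height=<node age>).
.coalesce_in_pop <- function(lin, theta, t_start, t_end, merges) {
  t <- t_start
  while (length(lin) >= 2) {
    k <- length(lin)
    wait <- if (theta == 0) 0 else stats::rexp(1, rate = k * (k - 1) / theta)
    if (t + wait >= t_end) break
    t <- t + wait
    pair <- sample.int(k, 2)
    a <- lin[[pair[1]]]; b <- lin[[pair[2]]]
    node <- list(
      label = sprintf("(%s:%.10f,%s:%.10f)", a$label, t - a$height,
                      b$label, t - b$height),
      height = t,
      tips = c(a$tips, b$tips))
    merges[[length(merges) + 1L]] <-
      list(tips = node$tips, height = t)
    lin <- c(lin[-pair], list(node))
  }
  list(lin = lin, merges = merges)
}

#' Simulate one gene genealogy under the multispecies coalescent
#'
#' Samples a 4-tip gene tree on the fixed species tree: the Homo and Pan
#' lineages enter the HC ancestral population at `tau_hc`, any uncoalesced
#' lineages (incomplete lineage sorting) carry over into the HCG ancestor at
#' `tau_hcg` together with Gorilla, and all remaining lineages join Pongo in
#' the root population at `tau_root`, where coalescence is guaranteed. Within
#' a population holding `k` lineages the next coalescence waits an
#' exponential time with rate `k (k - 1) / theta` (substitutions/site units),
#' so a pair coalescing in the HC ancestor has height
#' `tau_hc + Exp(mean theta_hc / 2)`.
#'
#' @param params a [species_tree_params()] object.
#' @param seed optional integer seed (set just before sampling).
#' @param locus_id identifier stored on the genealogy.
#' @return An object of class `gene_genealogy`: a list with the realized
#'   `tree` (an [ape::phylo] with branch lengths in s/s), `t_hc` (height of
#'   the Homo-Pan most recent common ancestor), `hc_sister` (logical, TRUE
#'   when Homo and Pan are sisters in the gene tree), `hc_in_hc_ancestor`
#'   (TRUE when their lineages coalesced before `tau_hcg`), `heights` (all
#'   coalescence heights, root-ward order) and `locus_id`.
#' @examples
#' g <- simulate_genealogy(species_tree_params(), seed = 1)
#' g$t_hc >= 0.00473
#' @export
simulate_genealogy <- function(params, seed = NULL, locus_id = "locus_1") {
  stopifnot(inherits(params, "species_tree_params"))
  if (!is.null(seed)) set.seed(seed)
  tip <- function(name) list(label = name, height = 0, tips = name)
  merges <- list()

  # Homo + Pan in the HC ancestor
  st <- .coalesce_in_pop(list(tip("Homo"), tip("Pan")), params$theta_hc,
                         params$tau_hc, params$tau_hcg, merges)
  # survivors + Gorilla in the HCG ancestor
  st <- .coalesce_in_pop(c(st$lin, list(tip("Gorilla"))), params$theta_hcg,
                         params$tau_hcg, params$tau_root, st$merges)
  # survivors + Pongo in the root population (no upper bound)
  st <- .coalesce_in_pop(c(st$lin, list(tip("Pongo"))), params$theta_root,
                         params$tau_root, Inf, st$merges)
  root <- st$lin[[1]]

  heights <- vapply(st$merges, `[[`, numeric(1), "height")
  hc_node <- Filter(function(m) all(c("Homo", "Pan") %in% m$tips), st$merges)
  t_hc <- hc_node[[1]]$height  # first (lowest) node containing both
  hc_sister <- any(vapply(st$merges, function(m)
    setequal(m$tips, c("Homo", "Pan")), logical(1)))
  tree <- ape::read.tree(text = paste0(root$label, ";"))

  structure(list(locus_id = locus_id, tree = tree, t_hc = t_hc,
                 hc_sister = hc_sister,
                 hc_in_hc_ancestor = hc_sister && t_hc < params$tau_hcg,
                 heights = sort(heights)),
            class = "gene_genealogy")
}

#' @export
print.gene_genealogy <- function(x, ...) {
  cat(sprintf("Gene genealogy %s: t_HC = %.6g s/s, %s\n", x$locus_id, x$t_hc,
              if (x$hc_sister) "Homo-Pan sisters"
              else "discordant topology (ILS)"))
  invisible(x)
}

#' A single simulated locus alignment
#'
#' Thin constructor validating the container used throughout: a character
#' matrix of aligned sequences over {A,C,G,T}, one row per taxon.
#'
#' @param seqs character matrix (rows = taxa, columns = sites), entries in
#'   A, C, G, T; rownames are taxon labels.
#' @param locus_id locus identifier.
#' @return An object of class `locus_alignment`.
#' @export
locus_alignment <- function(seqs, locus_id = "locus_1") {
  if (!is.matrix(seqs) || !is.character(seqs)) stop("seqs must be a character matrix")
  if (is.null(rownames(seqs))) stop("seqs must have taxon rownames")
  seqs[] <- toupper(seqs)
  if (!all(seqs %in% c("A", "C", "G", "T")))
    stop("alphabet restricted to A, C, G, T (no gaps in simulated data)")
  structure(list(locus_id = locus_id, taxa = rownames(seqs), seqs = seqs),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("Locus %s: %d taxa x %d sites\n", x$locus_id, nrow(x$seqs),
              ncol(x$seqs)))
  invisible(x)
}

# Draw per-site rate multipliers from the invariant + discrete-gamma mixture;
# variable-site rates are rescaled by 1/(1 - p_inv) so the mixture mean is 1
# (the standard +I convention, matching .rate_mixture and pml).
.site_rates <- function(model, L) {
  r <- rep(1, L)
  if (!is.null(model$gamma_shape)) {
    cats <- phangorn::discrete.gamma(model$gamma_shape, model$gamma_ncat)
    r <- cats[sample.int(model$gamma_ncat, L, replace = TRUE)]
  }
  if (model$p_inv > 0) {
    r <- r / (1 - model$p_inv)
    r[stats::runif(L) < model$p_inv] <- 0
  }
  r
}

#' Evolve sequences along a gene genealogy
#'
#' Simulates a gap-free alignment by evolving each site independently down
#' the genealogy under the substitution model; site-specific rate multipliers
#' are drawn from the invariant/discrete-gamma mixture. Branch lengths are in
#' expected substitutions/site, so a rate-1 site at distance `d` differs with
#' the model's transition probabilities at `d`.
#'
#' @param genealogy a `gene_genealogy` or an [ape::phylo] with branch lengths
#'   in s/s.
#' @param model a [subst_model()].
#' @param L alignment length (sites).
#' @param seed optional integer seed.
#' @param locus_id identifier for the resulting alignment (defaults to the
#'   genealogy's).
#' @return A [locus_alignment()].
#' @examples
#' g <- simulate_genealogy(species_tree_params(), seed = 1)
#' simulate_alignment(g, subst_model(), L = 100, seed = 1)
#' @export
simulate_alignment <- function(genealogy, model = subst_model(), L,
                               seed = NULL, locus_id = NULL) {
  tree <- if (inherits(genealogy, "gene_genealogy")) genealogy$tree else genealogy
  if (!inherits(tree, "phylo")) stop("genealogy must be a gene_genealogy or phylo")
  if (!inherits(model, "subst_model")) stop("model must be a subst_model")
  L <- as.integer(L)
  if (L < 1) stop("L must be >= 1")
  if (is.null(locus_id))
    locus_id <- if (inherits(genealogy, "gene_genealogy")) genealogy$locus_id
                else "locus_1"
  if (!is.null(seed)) set.seed(seed)

  rates <- .site_rates(model, L)
  seqs <- matrix(NA_character_, length(tree$tip.label), L,
                 dimnames = list(tree$tip.label, NULL))
  for (r in unique(rates)) {
    idx <- which(rates == r)
    if (r == 0) {                       # invariant: one stationary base/site
      base <- sample(c("a", "c", "g", "t"), length(idx), replace = TRUE,
                     prob = model$base_freq)
      seqs[, idx] <- matrix(base, nrow(seqs), length(idx), byrow = TRUE)
    } else {
      sim <- as.character(phangorn::simSeq(tree, l = length(idx),
                                           Q = model$rates,
                                           bf = model$base_freq, rate = r))
      seqs[, idx] <- sim[rownames(seqs), , drop = FALSE]
    }
  }
  locus_alignment(toupper(seqs), locus_id = locus_id)
}

#' Bookkeeping for a multi-locus sampling design
#'
#' Records the size of a locus-sampling design; `total_sites` is the length
#' of the supermatrix the loci concatenate to. The default is the genome-wide
#' design the simulator emulates: 15,744 loci of 5,000 bp, a supermatrix of
#' 78,720,000 bp.
#'
#' @param n_loci number of loci.
#' @param L sites per locus.
#' @return list with `n_loci`, `L` and `total_sites`.
#' @examples
#' dataset_design()$total_sites
#' @export
dataset_design <- function(n_loci = 15744, L = 5000) {
  n_loci <- as.integer(n_loci); L <- as.integer(L)
  if (is.na(n_loci) || n_loci < 1) stop("n_loci must be >= 1")
  if (is.na(L) || L < 1) stop("L must be >= 1")
  list(n_loci = n_loci, L = L,
       total_sites = as.numeric(n_loci) * as.numeric(L))
}

# Deterministic per-locus substream seed from (seed, locus index); keeps the
# derived seed inside the 32-bit integer range.
.locus_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 2654435769 * as.numeric(i)) %% 2147483647)
}

#' Generate a reproducible multi-locus dataset
#'
#' Simulates `n_loci` independent gene genealogies under the multispecies
#' coalescent, evolves a `L`-bp alignment along each, writes one FASTA file
#' per locus plus a JSON manifest holding the seed, the true parameters and
#' every per-locus genealogy summary. The dataset is a pure function of
#' `(seed, params, model, n_loci, L)`: per-locus seeds are derived
#' deterministically from the dataset seed and the locus index, so any locus
#' can be regenerated individually.
#'
#' @param params a [species_tree_params()].
#' @param model a [subst_model()].
#' @param n_loci number of loci (default 15744, the genome-wide sampling
#'   design this generator emulates).
#' @param L sites per locus (default 5000).
#' @param seed integer dataset seed.
#' @param out_dir output directory; created if missing. `NULL` keeps
#'   everything in memory (no files written).
#' @return Invisibly, the manifest: a list with the configuration and a
#'   `loci` data frame (locus_id, file, seed, t_hc, hc_sister); when
#'   `out_dir = NULL` it also carries the alignments in `$alignments`.
#' @examples
#' m <- generate_dataset(species_tree_params(), subst_model(), n_loci = 3,
#'                       L = 100, seed = 1, out_dir = NULL)
#' sapply(m$alignments, function(a) ncol(a$seqs))
#' @export
generate_dataset <- function(params, model = subst_model(), n_loci = 15744,
                             L = 5000, seed = 1, out_dir = NULL) {
  stopifnot(inherits(params, "species_tree_params"),
            inherits(model, "subst_model"))
  n_loci <- as.integer(n_loci)
  if (is.na(n_loci) || n_loci < 1) stop("n_loci must be >= 1")
  write_files <- !is.null(out_dir)
  if (write_files && !dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)

  ids <- sprintf("locus_%06d", seq_len(n_loci))
  files <- if (write_files) file.path(out_dir, paste0(ids, ".fasta"))
           else rep(NA_character_, n_loci)
  seeds <- vapply(seq_len(n_loci), function(i) .locus_seed(seed, i), integer(1))
  t_hc <- numeric(n_loci); hc_sister <- logical(n_loci)
  alns <- if (write_files) NULL else vector("list", n_loci)

  for (i in seq_len(n_loci)) {
    set.seed(seeds[i])
    g <- simulate_genealogy(params, locus_id = ids[i])
    a <- simulate_alignment(g, model, L = L)
    t_hc[i] <- g$t_hc; hc_sister[i] <- g$hc_sister
    if (write_files) write_locus_fasta(a, files[i]) else alns[[i]] <- a
  }

  manifest <- list(
    seed = seed, n_loci = n_loci, L = L,
    total_sites = dataset_design(n_loci, L)$total_sites,
    params = unclass(params), model = unclass(model),
    loci = data.frame(locus_id = ids, file = files, seed = seeds,
                      t_hc = t_hc, hc_sister = hc_sister,
                      stringsAsFactors = FALSE))
  if (!write_files) manifest$alignments <- stats::setNames(alns, ids)
  if (write_files)
    jsonlite::write_json(manifest[names(manifest) != "alignments"],
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write / read locus alignments as FASTA
#'
#' @param aln a [locus_alignment()].
#' @param file path to a FASTA file.
#' @return `write_locus_fasta` returns `file` invisibly; `read_locus_fasta`
#'   returns a [locus_alignment()]; `read_loci` returns a named list of them
#'   (one per `*.fasta` in `dir`, sorted).
#' @export
write_locus_fasta <- function(aln, file) {
  stopifnot(inherits(aln, "locus_alignment"))
  ape::write.FASTA(ape::as.DNAbin(aln$seqs), file)
  invisible(file)
}

#' @rdname write_locus_fasta
#' @export
read_locus_fasta <- function(file) {
  bin <- ape::read.FASTA(file)
  m <- toupper(do.call(rbind, as.character(bin)))
  locus_alignment(m, locus_id = sub("\\.fasta$", "", basename(file)))
}

#' @rdname write_locus_fasta
#' @param dir directory containing per-locus FASTA files.
#' @export
read_loci <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (length(files) == 0) stop("no .fasta files in ", dir)
  loci <- lapply(files, read_locus_fasta)
  stats::setNames(loci, vapply(loci, `[[`, character(1), "locus_id"))
}

#' Concatenate loci into a supermatrix
#'
#' Column-binds equal-taxon alignments into one supermatrix alignment, the
#' standard preparation for pooled distance estimation on many loci.
#'
#' @param loci list of [locus_alignment()] objects (or a manifest from
#'   [generate_dataset()] run with `out_dir = NULL`).
#' @param file optional path; when given the supermatrix is also written as
#'   FASTA.
#' @return A [locus_alignment()] with `locus_id = "supermatrix"`.
#' @export
concat_loci <- function(loci, file = NULL) {
  if (is.list(loci) && !is.null(loci$alignments)) loci <- loci$alignments
  stopifnot(length(loci) >= 1)
  taxa <- loci[[1]]$taxa
  ok <- vapply(loci, function(a) identical(sort(a$taxa), sort(taxa)), logical(1))
  if (!all(ok)) stop("all loci must contain the same taxa")
  seqs <- do.call(cbind, lapply(loci, function(a) a$seqs[taxa, , drop = FALSE]))
  out <- locus_alignment(seqs, locus_id = "supermatrix")
  if (!is.null(file)) write_locus_fasta(out, file)
  out
}
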