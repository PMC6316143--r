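# Maximum-likelihood pairwise genetic distances. Under a clock the total
# pairwise distance d_T between two species is twice the mean coalescent
# height, so half_dT = d_T/2 estimates the mean gene divergence time; the
# multispecies coalescent decomposes it as d_T/2 = tau + theta/2.

#' JC69 distance from a mismatch fraction
#'
#' Closed-form maximum-likelihood inversion `d = -(3/4) log(1 - 4p/3)` of the
#' JC69 mismatch probability `p = (3/4)(1 - exp(-4d/3))`. Saturated inputs
#' (`p >= 3/4`) map to `Inf`.
#'
#' @param p proportion of differing sites (vectorized).
#' @return distance(s) in expected substitutions/site.
#' @examples
#' jc69_distance(0.00621)
#' jc69_mismatch(jc69_distance(0.1))  # = 0.1
#' @export
jc69_distance <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  ifelse(p >= 0.75, Inf, -0.75 * log1p(-4 * p / 3))
}

#' @rdname jc69_distance
#' @param d distance in substitutions/site.
#' @export
jc69_mismatch <- function(d) 0.75 * (-expm1(-4 * d / 3))

# GTR rate matrix scaled to one expected substitution per site per unit time.
.gtr_Q <- function(rates, bf) {
  Q <- matrix(0, 4, 4)
  Q[lower.tri(Q)] <- rates
  Q <- Q + t(Q)
  Q <- Q * rep(bf, each = 4)            # q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  Q / sum(-diag(Q) * bf)
}

# Transition probability matrix exp(Q d) via symmetric eigendecomposition.
.gtr_pmat <- function(Q, bf, d) {
  s <- sqrt(bf)
  B <- (Q * rep(s, 4)) / rep(s, each = 4)   # diag(s) Q diag(1/s), symmetric
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  V <- e$vectors
  P <- (V %*% (t(V) * exp(e$values * d))) * rep(1 / s, 4) * rep(s, each = 4)
  pmax(P, 0)
}

# Mixture of site-rate multipliers implied by a subst_model (+G, +I); gamma
# categories are rescaled so the mixture mean is 1 (standard +I convention).
.rate_mixture <- function(model) {
  if (is.null(model$gamma_shape)) {
    r <- 1; w <- 1
  } else {
    r <- phangorn::discrete.gamma(model$gamma_shape, model$gamma_ncat)
    w <- rep(1 / model$gamma_ncat, model$gamma_ncat)
  }
  if (model$p_inv > 0) {
    r <- c(0, r / (1 - model$p_inv))
    w <- c(model$p_inv, w * (1 - model$p_inv))
  }
  list(rates = r, weights = w)
}

.pair_loglik_gtr <- function(counts, model, d) {
  mix <- .rate_mixture(model)
  Q <- .gtr_Q(model$rates, model$base_freq)
  M <- matrix(0, 4, 4)
  for (k in seq_along(mix$rates))
    M <- M + mix$weights[k] * .gtr_pmat(Q, model$base_freq, mix$rates[k] * d)
  sum(counts * log(pmax(model$base_freq * M, 1e-300)))
}

.pattern_counts <- function(a, b) {
  bases <- c("A", "C", "G", "T")
  table(factor(a, bases), factor(b, bases))
}

#' Maximum-likelihood pairwise distance
#'
#' Estimates the total genetic distance `d_T` between two aligned gap-free
#' sequences. Under JC69 the estimate is the closed-form inversion of the
#' mismatch fraction with its standard large-sample error; under GTR (+G+I)
#' the distance maximizes the pairwise likelihood by one-dimensional
#' optimization with the model's exchangeabilities, base frequencies and rate
#' mixture held fixed. `half_dT = d_T/2` is the implied mean coalescent
#' height. Saturated JC69 inputs (mismatch fraction >= 3/4) are flagged with
#' an infinite distance and a warning.
#'
#' @param seq_a,seq_b equal-length character vectors over A, C, G, T (rows of
#'   a [locus_alignment()] `$seqs` matrix).
#' @param model a [subst_model()].
#' @param pair label for the comparison, e.g. `c("Homo", "Pan")`.
#' @return An object of class `divergence_summary`: list with `pair`, `d_t`,
#'   `half_dt = d_t/2`, `se`, `n_sites`, `mismatch`.
#' @examples
#' a <- rep("A", 1000); b <- a; b[1:6] <- "C"
#' ml_distance(a, b)
#' @export
ml_distance <- function(seq_a, seq_b, model = subst_model(),
                        pair = c("A", "B")) {
  if (length(seq_a) != length(seq_b)) stop("sequences differ in length")
  n <- length(seq_a)
  if (n == 0) stop("zero-length sequences")
  p <- mean(seq_a != seq_b)
  if (model$model == "JC69" && is.null(model$gamma_shape) &&
      model$p_inv == 0) {
    d <- jc69_distance(p)
    if (!is.finite(d)) warning("saturated pair (mismatch fraction >= 3/4)")
    se <- if (is.finite(d) && p > 0)
      sqrt(p * (1 - p) / n) / (1 - 4 * p / 3) else if (p == 0) 0 else NA_real_
  } else {
    counts <- .pattern_counts(seq_a, seq_b)
    f <- function(d) .pair_loglik_gtr(counts, model, d)
    opt <- stats::optimize(f, c(1e-9, 3), maximum = TRUE, tol = 1e-10)
    d <- opt$maximum
    eps <- max(1e-6, d * 1e-3)          # curvature-based standard error
    h <- (f(d + eps) - 2 * opt$objective + f(d - eps)) / eps^2
    se <- if (h < 0) sqrt(-1 / h) else NA_real_
  }
  structure(list(pair = pair, d_t = d, half_dt = d / 2, se = se,
                 n_sites = n, mismatch = p, model = model$model),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf("%s-%s ML distance (%s): d_T = %.6g  d_T/2 = %.6g  (s.e. %.3g, %s sites)\n",
              x$pair[1], x$pair[2], x$model, x$d_t, x$half_dt, x$se,
              format(x$n_sites, big.mark = ",")))
  invisible(x)
}

#' Pooled distance on a concatenated supermatrix
#'
#' Concatenates the chosen pair's sequences across loci and estimates one
#' pooled ML distance. Under JC69 the mismatch count is the sufficient
#' statistic, so the pooled estimate equals the estimate from the
#' length-weighted pattern counts.
#'
#' @param loci list of [locus_alignment()] (or manifest / FASTA directory).
#' @param pair two taxon names, e.g. `c("Homo", "Pan")`.
#' @param model a [subst_model()].
#' @return A `divergence_summary` for the pooled comparison.
#' @export
supermatrix_distance <- function(loci, pair = c("Homo", "Pan"),
                                 model = subst_model()) {
  loci <- .as_locus_list(loci)
  a <- unlist(lapply(loci, function(l) l$seqs[pair[1], ]))
  b <- unlist(lapply(loci, function(l) l$seqs[pair[2], ]))
  ml_distance(a, b, model, pair = pair)
}

#' Per-locus mean coalescent heights d_T/2
#'
#' One ML half-distance per locus for the chosen pair; saturated loci are
#' dropped with a warning. The Homo-Pongo distribution of these values is
#' what the root speciation-time prior is fitted to.
#'
#' @inheritParams supermatrix_distance
#' @return named numeric vector of `d_T/2` values (s/s).
#' @export
per_locus_half_dt <- function(loci, pair = c("Homo", "Pongo"),
                              model = subst_model()) {
  loci <- .as_locus_list(loci)
  v <- vapply(loci, function(l)
    suppressWarnings(
      ml_distance(l$seqs[pair[1], ], l$seqs[pair[2], ], model,
                  pair = pair)$half_dt),
    numeric(1))
  names(v) <- vapply(loci, `[[`, character(1), "locus_id")
  if (any(!is.finite(v))) {
    warning(sum(!is.finite(v)), " saturated locus/loci dropped")
    v <- v[is.finite(v)]
  }
  v
}

#' Gamma prior specification
#'
#' Shape/rate gamma density `G(shape, rate)` with mean `shape/rate`, the form
#' used for the theta prior and for the root speciation-time prior.
#'
#' @param shape,rate positive gamma parameters (rate parameterization).
#' @return An object of class `gamma_prior`.
#' @examples
#' gamma_prior(16.7, 1264)   # mean ~ 0.0132 s/s
#' @export
gamma_prior <- function(shape, rate) {
  if (!is.finite(shape) || shape <= 0 || !is.finite(rate) || rate <= 0)
    stop("shape and rate must be positive")
  structure(list(shape = shape, rate = rate, mean = shape / rate),
            class = "gamma_prior")
}

#' @export
print.gamma_prior <- function(x, ...) {
  cat(sprintf("Gamma prior G(shape = %.4g, rate = %.4g), mean = %.4g\n",
              x$shape, x$rate, x$mean))
  invisible(x)
}

#' Fit a gamma prior to per-locus half-distances
#'
#' Maximum-likelihood gamma fit (shape/rate parameterization) to a sample of
#' positive values, used to turn the per-locus Homo-Pongo `d_T/2`
#' distribution into the prior on the root speciation time.
#'
#' @param values numeric vector of at least 10 positive values with non-zero
#'   variance.
#' @return A [gamma_prior()] carrying the standard errors of the estimates in
#'   `attr(, "se")`.
#' @examples
#' set.seed(1)
#' fit_gamma_prior(rgamma(1000, 16.7, 1264))
#' @export
fit_gamma_prior <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 10) stop("need at least 10 values")
  if (any(!is.finite(values) | values <= 0))
    stop("all values must be positive and finite")
  if (stats::var(values) == 0)
    stop("degenerate sample: variance is zero, gamma fit undefined")
  # fit on mean-scaled values for conditioning; Gamma(shape, rate) rescales
  # exactly: v = m * w with w ~ Gamma(shape, rate_w) gives rate = rate_w / m
  m <- mean(values)
  fit <- MASS::fitdistr(values / m, "gamma", lower = c(1e-10, 1e-10))
  out <- gamma_prior(unname(fit$estimate["shape"]),
                     unname(fit$estimate["rate"]) / m)
  attr(out, "se") <- c(shape = unname(fit$sd["shape"]),
                       rate = unname(fit$sd["rate"]) / m)
  out
}
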