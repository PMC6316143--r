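---
title: "Speciation-time calibration of phylogenetic mutation rates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speciation-time calibration of phylogenetic mutation rates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalrate)
```

## The problem

A fossil that dates a speciation event dates the time of complete genetic
isolation, τ. The genetic divergence observed between two genomes, however,
reflects the *coalescent* age of each locus, which predates the speciation
by the time the two lineages spent as segregating variation in the ancestral
population. Under the multispecies coalescent (MSC) the total pairwise
distance decomposes as

$$ d_T = d_1 + \theta, \qquad d_1 = 2\mu\tau, \qquad \theta = 4 N_e \mu, $$

so under a molecular clock the mean coalescent age across loci is
$d_T/2 = \tau + \theta/2$ while the speciation age is $d_1/2 = \tau$ (all in
expected substitutions per site, s/s). For humans and chimpanzees the two
differ by roughly a third of τ, enough to decide whether a fossil-calibrated
phylogenetic mutation rate does or does not overlap the rates measured
directly in pedigrees. `coalrate` implements the full chain — simulation,
clock filtering, distance estimation, Bayesian inference of (τ, θ), and
calibration — so that each step of that argument can be exercised and tested
on data with known truth.

Everything upstream of calibration works in s/s; the mutation rate µ never
appears as a separate parameter. Absolute time enters only at the last step,
through the fossil age in years.

## The simulator and what it emulates

`generate_dataset()` emulates a genome-wide collection of well-separated
orthologous segments from the four great apes: independent loci, one
haploid sequence per species, no recombination within a locus, no gaps, and
clock-like evolution. The fixed species tree is
(((Homo,Pan),Gorilla),Pongo), and each locus's genealogy is drawn by the
standard MSC recursion: within an ancestral population holding $k$ lineages
the next coalescence waits $\mathrm{Exp}(k(k-1)/\theta)$ in s/s time, and
uncoalesced lineages carry over into the parent population (incomplete
lineage sorting arises naturally in the Homo–Pan–Gorilla ancestor).
Sequences then evolve site-independently along the genealogy.

The default parameters are the study conditions the package is built
around, in s/s:

| parameter | default | why |
|---|---|---|
| `tau_hc` | 0.00473 | Homo–Pan speciation time estimated from great-ape genomes |
| `theta_hc` | 0.00304 | makes the mean Homo–Pan coalescent height `tau_hc + theta_hc/2 = 0.00625`, the genome-wide Homo–Pan half-distance |
| `tau_hcg`, `theta_hcg` | 0.0065, 0.003 | Homo–Gorilla mean height ≈ 0.008, the observed half-distance scale |
| `tau_root`, `theta_root` | 0.012, 0.002 | Homo–Pongo mean height ≈ 0.013, the observed half-distance scale |
| `theta_tips` | 0 | one sequence per species; within-species coalescence cannot occur |
| `n_loci`, `L` | 15,744 × 5,000 bp | the genome-wide sampling design (supermatrix of 78,720,000 bp); tests and examples use reduced sizes |

The substitution model defaults to JC69, which keeps the pairwise likelihood
closed-form and matches the model under which (τ, θ) are inferred; GTR with
discrete-gamma rate variation (4 categories, the common convention) and a
proportion of invariant sites is available for simulation, likelihood and
distance estimation. With `+I`, variable-site rates are rescaled by
$1/(1-p_{inv})$ so the mixture mean is 1 and branch lengths keep their
meaning as expected substitutions per site.

Reproducibility: a dataset is a pure function of `(seed, params, model,
n_loci, L)`. Per-locus seeds are derived deterministically from the dataset
seed and the locus index, so any locus can be regenerated on its own; the
manifest records them along with each true genealogy.

What the simulator does **not** emulate — alignment error, gaps and missing
data, selection and mutation-rate variation along the genome, recombination
within loci, post-speciation gene flow — bounds what passing tests show:
they demonstrate that the estimators are correct under the model, not that
the model captures every feature of real genomes. Gene flow in particular
would shrink the mean coalescent age toward the speciation time, so its
omission is conservative for the package's central inequality.

## Clock filtering

Interpreting $d_T/2$ as an age requires rate homogeneity across lineages, so
loci are pre-filtered by a likelihood ratio test: the strict-clock fit (3
node heights of the rooted ultrametric tree, Pongo as outgroup) against the
free fit (5 branch lengths of the unrooted tree), with
$2(\ell_{free}-\ell_{clock})$ referred to $\chi^2_2$ — four taxa give
$5-3=2$ degrees of freedom. Loci are kept when the clock is *not* rejected
at α = 0.05.

Both fits use Felsenstein pruning with site-pattern compression (via
`phangorn`). Optimization starts from a JC69 distance-based tree; the free
fit is started from the clock optimum, which makes the nesting inequality
$\ell_{free} \ge \ell_{clock}$ hold by construction. We verified that
distance-based and clock-based starting points reach the same free optimum
to ~1e-13 on this 4-taxon problem, so no random restarts are performed; the
likelihood surface for a fixed 4-taxon topology is effectively unimodal from
a consistent start. Under clock-true simulation the empirical LR
distribution is checked against $\chi^2_2$ (Kolmogorov–Smirnov) and the
rejection rate against the nominal 5% at 1,000 loci of 5,000 bp, the study's
locus length; shorter loci (~1,000 bp) leave so few informative sites at
great-ape divergences that the asymptotic reference becomes visibly rough.

## Distances and the root prior

`ml_distance()` computes pairwise ML distances: the closed-form inversion
$d = -\tfrac34\log(1-\tfrac43 p)$ under JC69 (mismatch fractions ≥ 3/4 are
flagged saturated and dropped with a warning downstream), or a
one-dimensional likelihood optimization over $d$ under GTR+Γ+I with model
parameters held fixed. Distances are computed pairwise rather than through
full-tree branch lengths; on clock-passing loci half the pairwise distance
*is* the node age, and under JC69 the pooled supermatrix estimate equals the
estimate from summed mismatch counts (the sufficient statistic), which the
tests assert exactly.

The prior for the root (Homo–Pongo) age is obtained by fitting a gamma
density (shape/rate, so the mean is α/β) to the per-locus Homo–Pongo
$d_T/2$ values by maximum likelihood (`MASS::fitdistr`, on mean-scaled
values for numerical conditioning — the gamma family is closed under
rescaling, so the fit is exact). The default `G(16.7, 1264)` has mean
0.0132 s/s, the Homo–Pongo half-distance scale.

## Bayesian inference of (τ, θ)

Inference targets the Homo–Pan pair: the estimand the calibration needs is
$\tau_{HC}$ (and $\theta_{HC}$, which separates $d_T/2$ from τ). Gorilla
and Pongo serve the clock filter and the root prior. The model for locus $i$
with $x_i$ mismatches over $L_i$ sites:

$$ h_i = \tau + t_i,\quad t_i \sim \mathrm{Exp}(\text{mean } \theta/2),
   \qquad x_i \mid h_i \sim \mathrm{Binomial}\!\big(L_i,\; p(2h_i)\big), $$

with $p(d) = \tfrac34(1-e^{-4d/3})$ the JC69 mismatch probability. Priors:
$\theta \sim G(2, 200)$ (a broad default covering empirical θ values) and
$\tau \sim \mathrm{Uniform}(0, m_{root})$ with $m_{root}$ the fitted
root-prior mean (0.013 s/s by default). The uniform bound is a deliberate
approximation to hierarchical internal-node priors conditioned on a root
age: the data dominate τ by orders of magnitude in any realistic multi-locus
setting, so the prior's only load-bearing feature is its support.

The sampler is Metropolis-within-Gibbs with four move types per sweep: a
vectorized random-walk update of all latent heights, a random walk on τ, a
joint translation of (τ, h) — which decorrelates τ from the heights and is
the move that makes mixing fast, since the exponential terms cancel exactly —
and a log-scale walk on θ. Step sizes adapt toward 20–50% acceptance during
burn-in only (diminishing adaptation is unnecessary because adaptation
stops), with burn-in at 10% of the post-burn-in generations. Defaults are
desk-scale: 2 chains × 2,000 retained samples at thinning 50; the
genome-scale convention of 20,000 samples every 1,000th generation is one
argument away. Two independent chains are compared on their τ means (a
discrepancy beyond 2 combined Monte-Carlo standard errors warns), effective
sample sizes are computed by Geyer's initial-positive-sequence estimator,
and a fixed seed yields bit-identical chains.

Correctness is checked three independent ways: (i) `msc_log_posterior()` is
asserted against a term-by-term composition of textbook densities; (ii) with
the likelihood switched off (`prior_only = TRUE`) the marginals must
reproduce the priors (KS test); (iii) on small datasets the MCMC means must
match `msc_posterior_grid()`, a deterministic 2-D grid integration that
eliminates the latent heights by quadrature — the substitution
$u = e^{-2t/\theta}$ turns the exponential mixture into a uniform integral
over $(0,1]$, evaluated by midpoint rule, which is exact enough at a few
hundred nodes because the integrand is smooth and bounded. Parameter
recovery is asserted at the study conditions: the 95% interval covers
τ = 0.00473 in ≥ 17 of 20 replicates of 500 loci × 1,000 bp, and the
posterior mean of $\tau + \theta/2$ tracks the pooled empirical
half-distance.

## Calibration conventions

`yearly_rate()` divides a genetic age by the fossil age;
`generational_rate()` multiplies by g. Uncertainty is propagated as
$d \pm n_{sd} \cdot sd$ with $n_{sd} = 2$ by default (±1 sd is available via
the argument; the two conventions give visibly different yearly-rate
intervals at the fourth decimal). Report tables round half-away-from-zero —
yearly rates to 3 decimals and generational rates to 2 on the 10⁻⁸ scale —
and always keep the unrounded values in separate columns. Note one
consequence of reporting unrounded values: the generation time required to
reach the envelope *minimum* (0.89 × 10⁻⁸) at a 5.7-Ma split evaluates to
10.73 → 10.7 years; we report the arithmetic as computed rather than forcing
any particular printed convention.

The pedigree envelope defaults to 0.89–1.75 × 10⁻⁸ s/s/generation, the
minimum and maximum of published whole-genome trio and
ancestral-recombination-density estimates; it is a configuration value, not
something the package recomputes. Default grids span 3.5–15 Ma and 10–30
years. Two identities are asserted on every pipeline run: $\mu_g = \mu_y
\cdot g$ exactly, and the coalescent-calibrated rate is at least the
speciation-calibrated one whenever θ > 0 — the package's central inequality.

## Numerical choices and degenerate inputs

- θ = 0 populations coalesce lineages instantly at the population's base
  (the zero-variance limit), so clock-true datasets with exact heights can
  be simulated by setting all θ to 0.
- Saturated distances are `Inf`, never `NaN`; downstream consumers drop them
  with a warning and a count.
- Optimizer starting trees floor heights at 1e-7 s/s and branch lengths at
  1e-9 to avoid zero-length pathologies; identical sequences still recover
  all-zero branch lengths to < 1e-6.
- The LR statistic is floored at 0 (optimizer noise can make it -1e-9).
- Degenerate gamma fits (zero variance), empty datasets, invalid counts,
  non-positive priors and unordered speciation times are rejected with
  errors, not warnings.

## Problem sizes

The shipped tests run at reduced scale, chosen so the full suite exercises
every statistical property in a few minutes on one CPU: 1,000 loci × 5,000
bp for the LRT null distribution, 20 replicates of 500 loci × 1,000 bp for
posterior coverage, 5-locus datasets for the grid-integration cross-check,
and 40–100 loci for end-to-end pipeline runs. All of them scale up by
changing arguments, not code.

## Known limitations

- Inference is JC69-based on the pairwise reduction; multiple-hit
  corrections beyond JC69 affect great-ape distances in the fourth decimal
  but are not propagated into the posterior.
- The full 4-taxon gene-tree topology MCMC is out of scope; incomplete
  lineage sorting is simulated but the posterior conditions on the Homo–Pan
  pair's counts only.
- No gene flow after speciation, no recombination within loci, one sequence
  per species.
- The clock LRT's asymptotic reference degrades below ~1,000 bp at great-ape
  divergences; filter calibration is only asserted at 5,000 bp.
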