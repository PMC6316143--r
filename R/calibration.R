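# Conversion of speciation-time estimates (substitutions/site) into absolute
# yearly and per-generation mutation rates via fossil calibration. The key
# point: the fossil age belongs to the speciation time tau = d_1/2, not to
# the older mean coalescent time d_T/2 = tau + theta/2; calibrating d_T/2
# overestimates the rate whenever ancestral theta > 0.

#' Round half away from zero
#'
#' Fixed-precision rounding used for report tables (R's `round()` rounds half
#' to even). Unrounded values are always stored alongside rounded ones.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  trunc(abs(x) * m + 0.5) * sign(x) / m
}

#' Yearly mutation rate from a calibrated divergence
#'
#' `mu_y = d_half / T_fossil`: a genetic age in substitutions/site divided by
#' the absolute calibration age in years. Pass the speciation time `d_1/2`
#' for a speciation-calibrated rate or the mean coalescent time `d_T/2` for
#' the (upwardly biased) coalescent-calibrated rate.
#'
#' @param d_half genetic age (s/s), vectorized.
#' @param t_fossil calibration age in years (e.g. `7e6`).
#' @return rate in substitutions/site/year.
#' @examples
#' yearly_rate(0.00473, 7e6) * 1e8   # 0.0676 on the 1e-8 scale
#' @export
yearly_rate <- function(d_half, t_fossil) {
  if (any(d_half < 0) || any(t_fossil <= 0))
    stop("d_half must be >= 0 and t_fossil > 0")
  d_half / t_fossil
}

#' Per-generation mutation rate
#'
#' `mu_g = mu_y * g`, the yearly rate accumulated over one generation of `g`
#' years — the quantity directly comparable to pedigree (parent-offspring
#' trio) mutation-rate estimates.
#'
#' @param mu_y yearly rate (s/s/y).
#' @param g generation time in years.
#' @return rate in substitutions/site/generation.
#' @export
generational_rate <- function(mu_y, g) {
  if (any(mu_y < 0) || any(g < 0)) stop("rates and generation times must be >= 0")
  mu_y * g
}

#' Point-plus-interval rate estimate
#'
#' Propagates the posterior uncertainty of the genetic age as
#' `d_half +- n_sd * d_sd` through the calibration, giving low/point/high
#' values for both the yearly and the per-generation rate.
#'
#' @param d_half genetic age point estimate (s/s).
#' @param d_sd its posterior standard deviation (s/s).
#' @param t_fossil calibration age (years).
#' @param g generation time (years).
#' @param n_sd half-width of the propagated band in posterior standard
#'   deviations (default 2).
#' @param calibration label recording whether `d_half` is a speciation
#'   (`d_1/2`) or coalescent (`d_T/2`) age.
#' @return An object of class `rate_estimate`: list with `mu_y` and `mu_g`
#'   (each `c(low, point, high)`) plus the provenance fields.
#' @examples
#' rate_estimate(0.00473, 0.00004, t_fossil = 7e6, g = 20)
#' @export
rate_estimate <- function(d_half, d_sd = 0, t_fossil = 7e6, g = 20,
                          n_sd = 2, calibration = c("speciation",
                                                    "coalescent")) {
  calibration <- match.arg(calibration)
  stopifnot(d_half >= 0, d_sd >= 0, t_fossil > 0, g >= 0)
  d_half <- unname(d_half); d_sd <- unname(d_sd)
  dd <- c(low = d_half - n_sd * d_sd, point = d_half,
          high = d_half + n_sd * d_sd)
  mu_y <- yearly_rate(pmax(dd, 0), t_fossil)
  structure(list(mu_y = mu_y, mu_g = generational_rate(mu_y, g),
                 d_half = d_half, d_sd = d_sd, n_sd = n_sd,
                 t_fossil = t_fossil, g = g, calibration = calibration),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s-calibrated rate (T_fossil = %.3g Ma, g = %.3g y, +-%g sd):\n",
              x$calibration, x$t_fossil / 1e6, x$g, x$n_sd))
  cat(sprintf("  mu_y = %.3f x 10^-8 s/s/y   [%.3f, %.3f]\n",
              x$mu_y["point"] * 1e8, x$mu_y["low"] * 1e8, x$mu_y["high"] * 1e8))
  cat(sprintf("  mu_g = %.2f x 10^-8 s/s/g   [%.2f, %.2f]\n",
              x$mu_g["point"] * 1e8, x$mu_g["low"] * 1e8, x$mu_g["high"] * 1e8))
  invisible(x)
}

#' Generational-rate table over a set of generation times
#'
#' One row per generation time, with the `+- n_sd` posterior band and
#' half-away-from-zero rounding to 2 decimals on the 1e-8 scale (yearly rates
#' to 3 decimals); unrounded values are kept in their own columns.
#'
#' @inheritParams rate_estimate
#' @param g vector of generation times (default `c(15, 20, 26.3)` years).
#' @return data frame with columns `g`, `mu_y_low/point/high`,
#'   `mu_g_low/point/high` (unrounded, s/s/y and s/s/g) and rounded display
#'   columns `mu_y_1e8`, `mu_g_low_1e8`, `mu_g_high_1e8`.
#' @export
rate_table <- function(d_half, d_sd = 0, t_fossil = 7e6,
                       g = c(15, 20, 26.3), n_sd = 2) {
  rows <- lapply(g, function(gi) {
    r <- rate_estimate(d_half, d_sd, t_fossil, gi, n_sd)
    data.frame(g = gi,
               mu_y_low = r$mu_y["low"], mu_y = r$mu_y["point"],
               mu_y_high = r$mu_y["high"],
               mu_g_low = r$mu_g["low"], mu_g = r$mu_g["point"],
               mu_g_high = r$mu_g["high"], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$mu_y_1e8 <- round_half_up(out$mu_y * 1e8, 3)
  out$mu_g_low_1e8 <- round_half_up(out$mu_g_low * 1e8, 2)
  out$mu_g_high_1e8 <- round_half_up(out$mu_g_high * 1e8, 2)
  out
}

#' Generational rates over a fossil-age x generation-time grid
#'
#' Evaluates `mu_g = (d_half / T_fossil) * g` over the Cartesian grid and
#' classifies each cell against the pedigree-rate envelope (the range of
#' whole-genome de novo rates reported by trio studies, default
#' `0.89e-8` to `1.75e-8` s/s/g).
#'
#' @inheritParams rate_estimate
#' @param t_fossil_grid fossil calibration ages in years (default 3.5-15 Ma).
#' @param g_grid generation times in years (default 10-30).
#' @param envelope `c(min, max)` pedigree rates in s/s/g.
#' @return An object of class `rate_grid`: a long-format data frame with
#'   columns `t_fossil`, `g`, `mu_y`, `mu_g`, `mu_g_low`, `mu_g_high`,
#'   `inside_envelope`; the inputs are kept as attributes.
#' @examples
#' gr <- rate_grid(0.00473, 0.00004)
#' mean(gr$inside_envelope)
#' @export
rate_grid <- function(d_half, d_sd = 0,
                      t_fossil_grid = seq(3.5e6, 15e6, by = 0.5e6),
                      g_grid = seq(10, 30, by = 1),
                      envelope = c(0.89e-8, 1.75e-8), n_sd = 2) {
  stopifnot(length(envelope) == 2, envelope[1] <= envelope[2],
            all(t_fossil_grid > 0), all(g_grid > 0),
            !is.unsorted(t_fossil_grid), !is.unsorted(g_grid))
  grid <- expand.grid(t_fossil = t_fossil_grid, g = g_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$mu_y <- yearly_rate(d_half, grid$t_fossil)
  grid$mu_g <- generational_rate(grid$mu_y, grid$g)
  grid$mu_g_low <- pmax(d_half - n_sd * d_sd, 0) / grid$t_fossil * grid$g
  grid$mu_g_high <- (d_half + n_sd * d_sd) / grid$t_fossil * grid$g
  grid$inside_envelope <- grid$mu_g >= envelope[1] & grid$mu_g <= envelope[2]
  structure(grid, class = c("rate_grid", "data.frame"),
            d_half = d_half, d_sd = d_sd, envelope = envelope, n_sd = n_sd)
}

#' @export
print.rate_grid <- function(x, ...) {
  env <- attr(x, "envelope")
  cat(sprintf(
    "Rate grid: %d fossil ages x %d generation times (d_half = %.5g s/s)\n",
    length(unique(x$t_fossil)), length(unique(x$g)), attr(x, "d_half")))
  cat(sprintf("  pedigree envelope [%.2f, %.2f] x 10^-8 s/s/g; %.0f%% of cells inside\n",
              env[1] * 1e8, env[2] * 1e8, 100 * mean(x$inside_envelope)))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ... ", nrow(x) - 4, " more rows\n")
  invisible(x)
}

#' @export
plot.rate_grid <- function(x, g_show = NULL, ...) {
  env <- attr(x, "envelope")
  gs <- sort(unique(x$g))
  if (is.null(g_show)) g_show <- gs[round(seq(1, length(gs), length.out = 5))]
  ts <- sort(unique(x$t_fossil))
  M <- sapply(g_show, function(gi) x$mu_g[x$g == gi][order(x$t_fossil[x$g == gi])])
  graphics::matplot(ts / 1e6, M * 1e8, type = "l", lty = 1,
                    col = grDevices::hcl.colors(length(g_show), "Zissou 1"),
                    xlab = "fossil calibration age (Ma)",
                    ylab = expression(mu[g] ~ (10^-8 ~ "s/s/g")), ...)
  graphics::polygon(c(range(ts / 1e6), rev(range(ts / 1e6))),
                    c(env[1], env[1], env[2], env[2]) * 1e8,
                    col = grDevices::adjustcolor("steelblue", 0.2),
                    border = NA)
  graphics::legend("topright", legend = paste("g =", g_show, "y"), lty = 1,
                   col = grDevices::hcl.colors(length(g_show), "Zissou 1"),
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Generation time required to hit a target pedigree rate
#'
#' Inverts the calibration: `g = mu_g_target * T_fossil / d_half`, the
#' ancestral generation time at which the speciation-calibrated phylogenetic
#' rate equals a given pedigree rate.
#'
#' @param mu_g_target target per-generation rate (s/s/g).
#' @param t_fossil calibration age (years).
#' @param d_half speciation-time estimate (s/s).
#' @return generation time in years (unrounded).
#' @examples
#' required_generation_time(1.75e-8, 7.3e6, 0.00473)   # ~27.0 years
#' @export
required_generation_time <- function(mu_g_target, t_fossil, d_half) {
  stopifnot(mu_g_target >= 0, t_fossil > 0, d_half > 0)
  mu_g_target * t_fossil / d_half
}
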