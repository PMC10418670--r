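## Semiempirical double-differential inelastic cross-section model: the
## angular distribution of inelastically scattered electrons follows the
## elastic DCS attenuated by a linear function of the fractional energy
## transfer,
##     d2sigma / dOmega dDE  ~  (dsigma/dOmega)_el * (1 - k * DE / E),
## with a single dimensionless weight k calibrated from measured angular
## distributions (k = 1.3 for 1M5NI at E = 97 eV, DE = 30 eV).

#' Semiempirical DDCS model
#'
#' @param elastic_dcs Elastic DCS provider, a function `(E, theta_deg) ->
#'   dcs` in 1e-20 m^2/sr, vectorized over `theta_deg`.
#' @param k Dimensionless energy-loss weight (> 0); default 1.3, the value
#'   calibrated for 1M5NI.
#' @return An object of class `ddcs_model`.
#' @examples
#' m <- ddcs_model(make_toy_dcs())
#' ddcs_shape(m, E = 97, dE = 30, theta_deg = 40)
#' @export
ddcs_model <- function(elastic_dcs, k = 1.3) {
  stopifnot(is.function(elastic_dcs), length(k) == 1, k > 0)
  structure(list(elastic_dcs = elastic_dcs, k = k), class = "ddcs_model")
}

#' @export
print.ddcs_model <- function(x, ...) {
  cat("<ddcs_model> k =", x$k, "\n")
  invisible(x)
}

## the energy-loss attenuation factor, clamped at zero where k dE > E
loss_factor <- function(model, E, dE) {
  pmax(0, 1 - model$k * dE / E)
}

#' Unnormalized DDCS shape
#'
#' Evaluates `elastic_dcs(E, theta) * max(0, 1 - k dE / E)`. The clamp at
#' zero covers `k dE > E`, where the linear attenuation would go negative;
#' the model is silent there and the shape is taken as zero.
#'
#' @param model A [ddcs_model()].
#' @param E Incident energy, eV.
#' @param dE Transferred energy, eV, in `(0, E]`.
#' @param theta_deg Scattering angle(s), degrees, in `[0, 180]`.
#' @return Relative intensity (unnormalized), vectorized over `theta_deg`.
#' @export
ddcs_shape <- function(model, E, dE, theta_deg) {
  stopifnot(inherits(model, "ddcs_model"))
  if (length(dE) != 1 || dE <= 0 || dE > E)
    stop("domain error: need 0 < dE <= E (dE = ", dE, ", E = ", E, ")")
  if (any(theta_deg < 0 | theta_deg > 180))
    stop("domain error: theta must lie in [0, 180] degrees")
  model$elastic_dcs(E, theta_deg) * loss_factor(model, E, dE)
}

#' Normalize the DDCS to a channel integral cross-section
#'
#' The model gives a proportionality only; the constant is fixed by
#' requiring the double integral over solid angle and transferred energy to
#' equal the channel's integral cross-section at that incident energy -
#' the same closure rule that ties the channel tables to the reference
#' TCS. Transferred energy is treated as binned: `dE_grid` gives bin
#' centres and `dE_width` the widths (defaults to the grid spacing).
#'
#' @param model A [ddcs_model()].
#' @param E Incident energy, eV.
#' @param sigma_ch Channel ICS at `E`, 1e-20 m^2 (>= 0).
#' @param dE_grid Transferred-energy bin centres, eV, within `(0, E]`.
#' @param dE_width Bin widths, eV; default from grid spacing.
#' @param n_mu Number of cos(theta) quadrature nodes (trapezoid) for the
#'   angular integral.
#' @return List of class `ddcs_table`: `dE_grid`, `dE_width`, `theta_deg`,
#'   `values` (matrix, rows = dE bins, cols = angles, 1e-20 m^2 / sr / eV),
#'   and `norm` (the normalization constant applied to the shape).
#' @export
ddcs_normalize <- function(model, E, sigma_ch, dE_grid,
                           dE_width = NULL, n_mu = 721) {
  stopifnot(inherits(model, "ddcs_model"), sigma_ch >= 0)
  if (any(dE_grid <= 0 | dE_grid > E))
    stop("domain error: dE grid must lie in (0, E]")
  if (is.null(dE_width)) {
    if (length(dE_grid) == 1)
      stop("dE_width required for a single-bin grid")
    mid <- (dE_grid[-1] + dE_grid[-length(dE_grid)]) / 2
    dE_width <- diff(c(2 * dE_grid[1] - mid[1], mid,
                       2 * dE_grid[length(dE_grid)] - mid[length(mid)]))
  }
  stopifnot(length(dE_width) == length(dE_grid), all(dE_width > 0))
  mu <- seq(-1, 1, length.out = n_mu)
  theta_deg <- acos(mu) * 180 / pi
  ang <- model$elastic_dcs(E, theta_deg)           # angular part, on mu grid
  wmu <- rep(2 / (n_mu - 1), n_mu); wmu[c(1, n_mu)] <- wmu[1] / 2  # trapezoid
  ang_int <- 2 * pi * sum(ang * wmu)
  fac <- loss_factor(model, E, dE_grid)
  total <- ang_int * sum(fac * dE_width)
  if (sigma_ch == 0) {
    vals <- matrix(0, length(dE_grid), n_mu)
  } else {
    if (total <= 0)
      stop("normalization error: DDCS shape is identically zero ",
           "(all transferred energies clamped) but sigma_ch > 0")
    vals <- (sigma_ch / total) * outer(fac, ang)
  }
  structure(list(dE_grid = dE_grid, dE_width = dE_width,
                 theta_deg = theta_deg, mu = mu, values = vals,
                 norm = if (sigma_ch == 0) 0 else sigma_ch / total,
                 E = E, sigma_ch = sigma_ch),
            class = "ddcs_table")
}

#' Integrate a normalized DDCS table back to its ICS
#'
#' @param table A `ddcs_table` from [ddcs_normalize()].
#' @return The double integral over solid angle and the dE bins, 1e-20 m^2.
#' @export
ddcs_integral <- function(table) {
  n_mu <- length(table$mu)
  wmu <- rep(2 / (n_mu - 1), n_mu); wmu[c(1, n_mu)] <- wmu[1] / 2
  2 * pi * sum(table$dE_width * (table$values %*% wmu))
}

## Build an inverse-CDF sampler of mu = cos(theta) for a weight function
## w(mu) tabulated on a fine mu grid (piecewise-linear density).
make_mu_sampler <- function(mu, w) {
  stopifnot(length(mu) == length(w), all(w >= 0))
  if (sum(w) <= 0) stop("cannot sample from an identically-zero density")
  seg <- (w[-1] + w[-length(w)]) / 2 * diff(mu)   # trapezoid cell masses
  cdf <- c(0, cumsum(seg)) / sum(seg)
  function(u) {
    i <- findInterval(u, cdf, rightmost.closed = TRUE)
    i[i < 1] <- 1; i[i > length(seg)] <- length(seg)
    t <- (u - cdf[i]) / (cdf[i + 1] - cdf[i])
    mu[i] + t * (mu[i + 1] - mu[i])
  }
}

#' Sample polar deflection angles from the DDCS angular profile
#'
#' Draws `theta` by inverse-CDF sampling over `mu = cos(theta)` from the
#' normalized angular profile of the model at `(E, dE)`. Because the
#' energy-loss attenuation is angle-independent, the angular profile is
#' that of the elastic DCS at `E`; the draw is still conditioned on a
#' valid `(E, dE)` pair. Azimuth is uniform and drawn by the caller.
#'
#' @param model A [ddcs_model()].
#' @param E Incident energy, eV.
#' @param dE Transferred energy, eV, in `(0, E]`.
#' @param n Number of draws.
#' @param n_mu Resolution of the tabulated inverse CDF.
#' @return Numeric vector of polar angles, degrees.
#' @examples
#' m <- ddcs_model(make_toy_dcs())
#' set.seed(1); summary(sample_deflection(m, 97, 30, 1000))
#' @export
sample_deflection <- function(model, E, dE, n = 1, n_mu = 513) {
  stopifnot(inherits(model, "ddcs_model"))
  if (dE <= 0 || dE > E)
    stop("domain error: need 0 < dE <= E (dE = ", dE, ", E = ", E, ")")
  mu <- seq(-1, 1, length.out = n_mu)
  w <- model$elastic_dcs(E, acos(mu) * 180 / pi)
  smp <- make_mu_sampler(mu, w)
  acos(smp(stats::runif(n))) * 180 / pi
}

#' Estimate the energy-loss weight k from angular-distribution data
#'
#' Fits measured intensities against `c * elastic_dcs(E, theta) *
#' (1 - k dE / E)` by weighted least squares over the free pair `(c, k)`.
#' The model is linear in `(a, b) = (c, -c k)`, so the fit is a weighted
#' linear regression on the two regressors `dcs` and `dcs * dE / E`;
#' `k = -b / a` and its standard error follows from the delta method. The
#' estimate is invariant under rescaling all intensities by a constant.
#'
#' Identifiability requires data at two or more distinct transferred
#' energies: with the overall scale free and a single `dE`, `c` and `k`
#' enter only through the product `c (1 - k dE / E)`, the two regressors
#' are collinear, and no angular measurement can separate them (at
#' `dE = 0` the attenuation factor is 1 for every k, the limiting case of
#' the same degeneracy). Supply `dE` as a vector parallel to the data -
#' e.g. intensities collected in several energy-loss bins around the
#' representative measurement condition.
#'
#' @param theta_deg Measurement angles (>= 3 distinct values).
#' @param intensity Measured relative intensities.
#' @param uncertainty Measurement uncertainties (1 sigma); weights are
#'   `1 / uncertainty^2`.
#' @param E Incident energy, eV.
#' @param dE Transferred energy per data point, eV; either a vector
#'   parallel to `theta_deg` or a scalar (which is an identifiability
#'   error - see above). At least two distinct positive values required.
#' @param elastic_dcs DCS provider `(E, theta_deg) -> value`.
#' @return List with `k`, `se` (standard error), `c` (scale), and `fit`
#'   (the underlying `lm` object).
#' @examples
#' set.seed(7)
#' th <- rep(seq(10, 170, 10), 3)
#' dE <- rep(c(15, 30, 45), each = 17)
#' d <- make_angular_data(th, E = 97, dE = dE, k = 1.3)
#' estimate_k(d$theta_deg, d$intensity, d$uncertainty, E = 97, dE = dE,
#'            elastic_dcs = make_toy_dcs())$k
#' @export
estimate_k <- function(theta_deg, intensity, uncertainty, E, dE,
                       elastic_dcs) {
  if (any(dE <= 0))
    stop("k is unidentifiable at dE = 0: the attenuation factor is 1 ",
         "for every k")
  dE <- rep_len(dE, length(theta_deg))
  if (length(unique(dE)) < 2)
    stop("k is unidentifiable from a single transferred energy with a ",
         "free overall scale; supply data at >= 2 distinct dE values")
  if (length(unique(theta_deg)) < 3)
    stop("need at least 3 distinct angles")
  stopifnot(length(intensity) == length(theta_deg),
            length(uncertainty) == length(theta_deg),
            all(uncertainty > 0))
  x1 <- elastic_dcs(E, theta_deg)
  x2 <- x1 * dE / E
  fit <- stats::lm(intensity ~ 0 + x1 + x2, weights = 1 / uncertainty^2)
  a <- stats::coef(fit)[["x1"]]
  b <- stats::coef(fit)[["x2"]]
  V <- stats::vcov(fit)
  k <- -b / a
  ## delta method on k = -b/a
  g <- c(b / a^2, -1 / a)
  se <- sqrt(drop(t(g) %*% V %*% g))
  list(k = k, se = se, c = a, fit = fit)
}
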