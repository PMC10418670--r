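## Packaged data fixtures and synthetic-input generators. The packaged CSVs
## under inst/extdata reproduce the published 1M5NI tables verbatim; the
## generators build inputs with known ground truth for testing the
## assembly, DDCS and fragmentation machinery.

#' Path of a packaged fixture
#'
#' Known ids: `"1m5ni_recommended"`, `"1m5ni_tcs_reference"` (directories of
#' channel CSVs), `"1m5ni_anion_br"`, `"1m5ni_cation_67eV"` (single CSVs).
#' @param id Fixture id.
#' @return Filesystem path.
#' @export
xs_fixture_path <- function(id) {
  file <- switch(id,
    "1m5ni_recommended" = "1m5ni_recommended",
    "1m5ni_tcs_reference" = "1m5ni_tcs_reference",
    "1m5ni_anion_br" = "1m5ni_anion_br.csv",
    "1m5ni_cation_67eV" = "1m5ni_cation_67eV.csv",
    stop("unknown fixture id: ", id))
  path <- system.file("extdata", file, package = "xs1m5ni")
  if (!nzchar(path)) stop("fixture not installed: ", id)
  path
}

#' Packaged anion branching-ratio table (DEA to 1M5NI)
#'
#' Branching ratios anchored at the two incident energies with printed
#' values, 3.1 and 4.7 eV: NO2- 58% at 3.1 eV; NO2- 35%, CN- 21%, CNO- 10%
#' at 4.7 eV. The five minor fragment channels (which individually stay
#' below 10%) share the residual probability equally; their unprinted
#' individual ratios are a documented package assumption.
#' @return A [branching_table()].
#' @export
anion_branching_1m5ni <- function() {
  read_branching_csv(xs_fixture_path("1m5ni_anion_br"))
}

#' Packaged cation relative intensities at 67 eV (1M5NI)
#'
#' Relative intensities of the cationic species formed by 67 eV electron
#' impact, parent ion (127 u) normalized to 1.
#' @return A [cation_table()].
#' @export
cation_intensities_1m5ni <- function() {
  read_cation_csv(xs_fixture_path("1m5ni_cation_67eV"))
}

#' All packaged 1M5NI tables
#'
#' @return List with elements `recommended` (a [xs_set()] of the recommended
#'   integral cross-sections, 0.1-1000 eV, with the printed SUM column as
#'   its reference TCS), `tcs` (a [xs_set()] holding the measured TCS and
#'   its missing-angle-corrected reference, 1-300 eV), `anion_br` (a
#'   [branching_table()]) and `cation` (a [cation_table()]).
#' @examples
#' pk <- packaged_tables()
#' interpolate_xs(pk$recommended$tables$elastic, 0.2)  # 214
#' @export
packaged_tables <- function() {
  list(recommended = load_xs_set("1m5ni_recommended"),
       tcs = load_xs_set("1m5ni_tcs_reference"),
       anion_br = anion_branching_1m5ni(),
       cation = cation_intensities_1m5ni())
}

#' Screened-Coulomb toy elastic DCS provider
#'
#' Builds a forward-peaked differential elastic cross-section of
#' screened-Rutherford shape, `dcs(E, theta) ~ 1 / (1 - cos(theta) + 2
#' eta(E))^2`, normalized at each energy so the solid-angle integral equals
#' the integral elastic cross-section supplied by `ics` (a function of E or
#' a constant). This is an explicitly synthetic stand-in for tabulated
#' elastic DCS - convenient, positive and normalizable - not measured or
#' calculated physics for any particular molecule.
#'
#' The screening parameter `eta` controls forward peaking: small `eta`
#' means strong forward peaking. `eta` may be a constant or a function of
#' energy; it must be > 0.
#'
#' @param ics Function of E (eV) returning the target ICS in 1e-20 m^2, or
#'   a single number.
#' @param eta Screening parameter (> 0), constant or function of E.
#' @return A function `(E, theta_deg) -> dcs` in 1e-20 m^2/sr, vectorized
#'   over `theta_deg`.
#' @examples
#' dcs <- make_toy_dcs(ics = 50, eta = 0.05)
#' dcs(100, c(0, 30, 90, 180))
#' @export
make_toy_dcs <- function(ics = 50, eta = 0.05) {
  ics_f <- if (is.function(ics)) ics else function(E) ics
  eta_f <- if (is.function(eta)) eta else function(E) eta
  function(E, theta_deg) {
    et <- eta_f(E)
    if (!is.finite(et) || et <= 0)
      stop("invalid screening parameter eta = ", et)
    mu <- cos(theta_deg * pi / 180)
    ## analytic normalization: Int dOmega (1 - mu + 2 eta)^-2
    ##   = 2 pi * [1 / (2 eta) - 1 / (2 + 2 eta)]
    norm <- 2 * pi * (1 / (2 * et) - 1 / (2 + 2 * et))
    ics_f(E) / norm / (1 - mu + 2 * et)^2
  }
}

#' Synthetic low-energy cross-section curve with known resonances
#'
#' Builds a smooth decaying background `a + b / E` plus Lorentzian
#' resonance peaks, sampled on a grid - the kind of curve a fixed-nuclei
#' elastic calculation produces when resonances ride on a smooth elastic
#' cross-section. The true decomposition is retained so extraction code
#' can be checked against ground truth.
#'
#' @param grid Energy grid, eV (strictly increasing).
#' @param background_a,background_b Background parameters of `a + b / E`
#'   (both >= 0), 1e-20 m^2 and 1e-20 m^2 eV.
#' @param peaks Data frame with columns `center` (eV), `width` (full width
#'   at half maximum, eV) and `area` (1e-20 m^2 eV); may have zero rows.
#' @return A [channel_table()] (channel `"elastic"`) with attribute
#'   `"truth"`: a list with `background` and `resonant` value vectors on
#'   `grid` and the `peaks` data frame.
#' @examples
#' g <- exp(seq(log(0.5), log(12), length.out = 60))
#' curve <- make_resonance_curve(g, peaks = data.frame(
#'   center = 2, width = 0.4, area = 8))
#' @export
make_resonance_curve <- function(grid, background_a = 40, background_b = 20,
                                 peaks = data.frame(center = numeric(),
                                                    width = numeric(),
                                                    area = numeric())) {
  stopifnot(all(diff(grid) > 0), background_a >= 0, background_b >= 0)
  bg <- background_a + background_b / grid
  res <- numeric(length(grid))
  for (i in seq_len(nrow(peaks))) {
    g2 <- peaks$width[i] / 2
    res <- res + peaks$area[i] / pi * g2 / ((grid - peaks$center[i])^2 + g2^2)
  }
  tab <- channel_table("elastic", grid, bg + res,
                       provenance = "synthetic: smooth background + Lorentzian peaks")
  attr(tab, "truth") <- list(background = bg, resonant = res, peaks = peaks)
  tab
}

#' Synthetic angular-distribution data for k-estimation
#'
#' Generates intensity measurements `c * dcs(E, theta) * (1 - k dE / E)`
#' with multiplicative Gaussian noise, for testing the recovery of the
#' energy-loss weight k from angular data.
#'
#' @param theta_deg Measurement angles.
#' @param E Incident energy, eV.
#' @param dE Transferred energy, eV; scalar or vector parallel to
#'   `theta_deg` (data spanning several energy-loss bins is what makes k
#'   estimable when the overall scale is free).
#' @param k True energy-loss weight.
#' @param elastic_dcs DCS provider `(E, theta_deg) -> value`.
#' @param scale Overall scale factor c.
#' @param noise Relative (fractional) Gaussian noise level.
#' @return Data frame with `theta_deg`, `intensity`, `uncertainty`.
#' @export
make_angular_data <- function(theta_deg, E, dE, k = 1.3,
                              elastic_dcs = make_toy_dcs(),
                              scale = 1, noise = 0.05) {
  mu_true <- scale * elastic_dcs(E, theta_deg) * (1 - k * dE / E)
  sd <- pmax(noise * abs(mu_true), 1e-12)
  data.frame(theta_deg = theta_deg,
             intensity = stats::rnorm(length(theta_deg), mu_true, sd),
             uncertainty = sd)
}
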