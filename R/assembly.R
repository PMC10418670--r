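## Self-consistency engine: the operations used to assemble a recommended
## channel-resolved cross-section set from a reference TCS, calculated
## elastic data and measured fragment statistics.

#' Detector acceptance geometry for the missing-angle correction
#'
#' Transmission-beam TCS measurements cannot distinguish electrons
#' elastically scattered into a narrow forward cone (and, for magnetically
#' confined beams, a backward cone) from unscattered ones, so the measured
#' TCS misses that flux. The geometry records the forward cutoff angle and
#' an optional backward cutoff.
#'
#' @param theta_acc Forward acceptance half-angle, degrees, in `[0, 90)`.
#' @param theta_back Optional backward cutoff, degrees, in `(90, 180]`:
#'   scattering at angles above it is also missed.
#' @return An object of class `acceptance_geometry`.
#' @export
acceptance_geometry <- function(theta_acc, theta_back = NULL) {
  stopifnot(length(theta_acc) == 1, theta_acc >= 0, theta_acc < 90)
  if (!is.null(theta_back))
    stopifnot(length(theta_back) == 1, theta_back > 90, theta_back <= 180)
  structure(list(theta_acc = theta_acc, theta_back = theta_back),
            class = "acceptance_geometry")
}

#' Missing-angle correction from an elastic DCS
#'
#' Integrates the differential elastic cross-section over the detector's
#' acceptance cone(s) to quantify the elastic flux a transmission
#' measurement misses:
#' \deqn{\Delta\sigma = 2\pi \int_0^{\theta_{acc}} \frac{d\sigma}{d\Omega}(\theta)\, \sin\theta \, d\theta}
#' plus the analogous backward integral when a backward cutoff is set. The
#' caller adds the result to the measured TCS to form the corrected
#' reference value.
#'
#' @param dcs Function `theta_deg -> dcs` (1e-20 m^2/sr), the elastic DCS at
#'   one incident energy; must be non-negative on `[0, 180]`.
#' @param geometry An [acceptance_geometry()].
#' @param rel.tol Quadrature relative tolerance.
#' @return Correction in 1e-20 m^2.
#' @examples
#' iso <- function(theta) rep(50 / (4 * pi), length(theta))
#' missing_angle_correction(iso, acceptance_geometry(90 - 1e-9))  # ~25
#' @export
missing_angle_correction <- function(dcs, geometry, rel.tol = 1e-10) {
  stopifnot(inherits(geometry, "acceptance_geometry"))
  probe <- seq(0, 180, by = 1)
  if (any(dcs(probe) < 0))
    stop("input error: negative DCS values on [0, 180] degrees")
  integrand <- function(theta_rad) dcs(theta_rad * 180 / pi) * sin(theta_rad)
  total <- 0
  if (geometry$theta_acc > 0)
    total <- total + 2 * pi * stats::integrate(
      integrand, 0, geometry$theta_acc * pi / 180,
      rel.tol = rel.tol, abs.tol = 0)$value
  if (!is.null(geometry$theta_back))
    total <- total + 2 * pi * stats::integrate(
      integrand, geometry$theta_back * pi / 180, pi,
      rel.tol = rel.tol, abs.tol = 0)$value
  total
}

#' Total inelastic cross-section by subtraction from the reference TCS
#'
#' The total inelastic cross-section is obtained by subtracting the pure
#' integral elastic cross-section from the corrected reference TCS,
#' pointwise on a common grid. Small negative differences are expected
#' from measurement noise wherever the channels nearly exhaust the TCS;
#' they are clamped to zero and reported via a warning rather than
#' rejected.
#'
#' @param reference Reference TCS [channel_table()] (measured TCS + missing
#'   angle correction).
#' @param elastic Elastic [channel_table()].
#' @param grid Evaluation grid, eV; defaults to the portion of the
#'   reference grid covered by both tables.
#' @param label Channel label carried by the output table. The inelastic
#'   total is not itself one of the enumerated physical channels (it is
#'   subsequently partitioned), so the label is a carrier only; default
#'   `"electronic"`.
#' @return A [channel_table()] holding the pointwise difference, clamped
#'   at zero.
#' @export
derive_total_inelastic <- function(reference, elastic, grid = NULL,
                                   label = "electronic") {
  stopifnot(inherits(reference, "channel_table"),
            inherits(elastic, "channel_table"))
  lo <- max(min(reference$energies), min(elastic$energies))
  hi <- min(max(reference$energies), max(elastic$energies))
  if (lo > hi)
    stop("range error: reference and elastic energy spans are disjoint")
  if (is.null(grid))
    grid <- reference$energies[reference$energies >= lo &
                               reference$energies <= hi]
  if (length(grid) == 0) stop("range error: empty common grid")
  if (any(grid < lo | grid > hi))
    stop("range error: grid extends beyond the common span [",
         lo, ", ", hi, "] eV")
  diff <- interpolate_xs(reference, grid) - interpolate_xs(elastic, grid)
  neg <- diff < 0
  if (any(neg)) {
    warning("elastic exceeds reference at ", sum(neg), " energies (",
            paste(utils::head(grid[neg], 5), collapse = ", "),
            if (sum(neg) > 5) ", ..." else "",
            " eV); clamped to 0")
    diff[neg] <- 0
  }
  channel_table(label, grid, diff,
                provenance = "reference TCS minus integral elastic")
}

#' Extract attachment resonances from a low-energy cross-section curve
#'
#' A fixed-nuclei elastic calculation at low energy produces a curve that
#' is the smooth elastic cross-section plus sharp resonant structures -
#' transient anion states. This routine splits the curve into a smooth
#' background (the pure elastic part) and a resonant excess (the electron
#' attachment cross-section) by iteratively-clipped smooth fitting:
#'
#' 1. fit a low-rank smoothing spline through the curve in log-log
#'    coordinates;
#' 2. discard points lying more than `band` times the local residual
#'    spread above the fit (peaks only pull the curve up);
#' 3. refit on the surviving points, and repeat until the retained point
#'    set is stable or `max_iter` is reached.
#'
#' The attachment curve is `max(curve - background, 0)`. Local maxima of
#' the attachment are reported as peaks; any peak centred above
#' `pseudo_cutoff` (default 10 eV) is treated as a pseudo-resonance - an
#' artifact of omitting inelastic channels from the elastic calculation -
#' flagged, and removed from the attachment curve.
#'
#' @param curve A [channel_table()] covering the low-energy region, with at
#'   least 6 grid points.
#' @param pseudo_cutoff Energy (eV) above which peaks are flagged as
#'   pseudo-resonances and zeroed (default 10).
#' @param band Core-detection band in units of the residual spread
#'   (default 2).
#' @param max_iter Maximum clipping iterations (default 20).
#' @param df Effective degrees of freedom of the background spline
#'   (default 8).
#' @param floor_log Floor on the residual-spread estimate used for core
#'   detection, in log units (default 0.01, i.e. ~1% of the local value).
#'   Prevents runaway clipping on noiseless curves, and sets the minimum
#'   relative peak height the extraction will react to.
#' @details Peak cores are grid runs more than `band` spreads above the
#'   fit; each core is expanded outward while the residual stays above
#'   `-spread/2` (to the wing's crossing of the background), and the
#'   expanded runs are excluded from the refit. The two outermost grid
#'   points on each side always stay in the fit so the spline is anchored
#'   at the edges; attachment is reported only inside detected runs, so a
#'   smooth curve yields an identically zero attachment.
#' @return A list of class `resonance_decomposition`: `background` and
#'   `attachment` ([channel_table()]s on the input grid), `peaks` (data
#'   frame with `center_eV`, `height`, `area`, `flagged_pseudo`), and
#'   `input` (the curve).
#' @examples
#' g <- exp(seq(log(0.5), log(12), length.out = 80))
#' cur <- make_resonance_curve(g, peaks = data.frame(
#'   center = 2, width = 0.4, area = 8))
#' dec <- extract_resonances(cur)
#' dec$peaks
#' @export
extract_resonances <- function(curve, pseudo_cutoff = 10, band = 2,
                               max_iter = 20, df = 8, floor_log = 0.01) {
  stopifnot(inherits(curve, "channel_table"))
  E <- curve$energies
  y <- curve$values
  n <- length(E)
  if (n < 6) stop("insufficient data: need at least 6 grid points, got ", n)
  if (any(y <= 0)) stop("curve values must be positive for log-log fitting")
  lx <- log(E); ly <- log(y)
  keep <- rep(TRUE, n)
  fit_vals <- ly
  runsets <- list()
  for (iter in seq_len(max_iter)) {
    dfit <- max(2, min(df, sum(keep) - 2))
    sp <- stats::smooth.spline(lx[keep], ly[keep], df = dfit)
    fit_vals <- stats::predict(sp, lx)$y
    resid <- ly - fit_vals
    spread_raw <- stats::mad(resid[keep], center = 0)
    spread_core <- max(spread_raw, floor_log)
    texp <- -0.5 * spread_raw
    core <- resid > band * spread_core
    new_keep <- rep(TRUE, n)
    runsets <- list()
    if (any(core)) {
      runs <- rle(core)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (r in which(runs$values)) {
        i0 <- starts[r]; i1 <- ends[r]
        while (i0 > 3 && resid[i0 - 1] > texp) i0 <- i0 - 1L
        while (i1 < n - 2 && resid[i1 + 1] > texp) i1 <- i1 + 1L
        new_keep[max(i0, 3):min(i1, n - 2)] <- FALSE
        runsets[[length(runsets) + 1L]] <- i0:i1
      }
    }
    if (sum(new_keep) < df + 2) break
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  bg <- exp(fit_vals)
  att <- numeric(n)
  for (seg in runsets) att[seg] <- pmax(y[seg] - bg[seg], 0)

  peaks <- data.frame(center_eV = numeric(), height = numeric(),
                      area = numeric(), flagged_pseudo = logical())
  for (seg in runsets) {
    imax <- seg[which.max(att[seg])]
    area <- if (length(seg) > 1)
      sum(diff(E[seg]) * (att[seg[-length(seg)]] + att[seg[-1]]) / 2)
    else 0
    flag <- E[imax] > pseudo_cutoff
    peaks <- rbind(peaks, data.frame(
      center_eV = E[imax], height = att[imax], area = area,
      flagged_pseudo = flag))
    if (flag) att[seg] <- 0
  }
  structure(list(
    input = curve,
    background = channel_table("elastic", E, bg,
                               provenance = "smooth background (pure elastic)"),
    attachment = channel_table("attachment", E, att,
                               threshold = 0,
                               provenance = "resonant excess over smooth background"),
    peaks = peaks),
    class = "resonance_decomposition")
}

#' @export
print.resonance_decomposition <- function(x, ...) {
  cat("<resonance_decomposition>", nrow(x$peaks), "peak(s)\n")
  if (nrow(x$peaks)) print(x$peaks)
  invisible(x)
}

#' Threshold-constrained partition specification
#'
#' Describes how the inelastic residual (total inelastic minus ionization
#' minus attachment) is split between vibrational and electronic
#' excitation: per-energy anchor weights `w_e(E)` give the electronic
#' fraction of the residual, interpolated linearly in log E between
#' anchors, held at the boundary values outside, and forced to 0 below the
#' electronic threshold.
#'
#' @param vib_threshold Vibrational opening energy, eV.
#' @param elec_threshold Electronic opening energy, eV (> `vib_threshold`).
#' @param anchor_E Anchor energies, eV.
#' @param anchor_w Electronic fractions at the anchors, in `[0, 1]`; must
#'   be 0 for anchors below `elec_threshold`.
#' @return An object of class `partition_spec`.
#' @export
partition_spec <- function(vib_threshold, elec_threshold, anchor_E, anchor_w) {
  stopifnot(vib_threshold < elec_threshold, length(anchor_E) == length(anchor_w))
  if (any(anchor_w < 0 | anchor_w > 1))
    stop("spec error: anchor weights must lie in [0, 1]")
  if (any(anchor_w[anchor_E < elec_threshold] > 0))
    stop("spec error: nonzero electronic weight below the electronic threshold")
  o <- order(anchor_E)
  structure(list(vib_threshold = vib_threshold,
                 elec_threshold = elec_threshold,
                 anchor_E = anchor_E[o], anchor_w = anchor_w[o]),
            class = "partition_spec")
}

partition_weight <- function(spec, E) {
  w <- stats::approx(log(spec$anchor_E), spec$anchor_w, xout = log(E),
                     rule = 2)$y
  w[E < spec$elec_threshold] <- 0
  w
}

#' Partition the inelastic residual into vibrational and electronic parts
#'
#' Splits the residual pointwise: `electronic = w_e(E) * residual`,
#' `vibrational = residual - electronic`. The split conserves the residual
#' exactly at every grid energy, keeps both parts non-negative, and
#' respects the channel thresholds (electronic weight 0 below the
#' electronic threshold; everything below the vibrational threshold is
#' zero by construction of the residual).
#'
#' @param residual A [channel_table()] of the inelastic residual (>= 0).
#' @param spec A [partition_spec()].
#' @return List with `vibrational` and `electronic` [channel_table()]s on
#'   the residual grid.
#' @export
partition_inelastic <- function(residual, spec) {
  stopifnot(inherits(residual, "channel_table"),
            inherits(spec, "partition_spec"))
  E <- residual$energies
  w <- partition_weight(spec, E)
  elec <- w * residual$values
  vib <- residual$values - elec
  list(
    vibrational = channel_table("vibrational", E, vib,
                                threshold = spec$vib_threshold,
                                provenance = "residual minus electronic share"),
    electronic = channel_table("electronic", E, elec,
                               threshold = spec$elec_threshold,
                               provenance = "anchored electronic share of residual"))
}

#' Calibrate partition weights from a recommended set
#'
#' Reads the electronic fraction of (vibrational + electronic) off an
#' existing recommended set at every grid energy where that sum is
#' positive, yielding a [partition_spec()] that reproduces the set's own
#' split. Thresholds default to the tabulated opening energies.
#'
#' @param set A [xs_set()] with vibrational and electronic tables.
#' @return A [partition_spec()].
#' @examples
#' spec <- calibrate_partition(load_xs_set("1m5ni_recommended"))
#' @export
calibrate_partition <- function(set) {
  stopifnot(inherits(set, "xs_set"))
  vib <- set$tables$vibrational
  elec <- set$tables$electronic
  if (is.null(vib) || is.null(elec))
    stop("set must contain vibrational and electronic tables")
  E <- sort(union(vib$energies, elec$energies))
  v <- interpolate_xs(vib, E)
  e <- interpolate_xs(elec, E)
  tot <- v + e
  use <- tot > 0
  partition_spec(vib$threshold, elec$threshold,
                 anchor_E = E[use], anchor_w = (e / tot)[use])
}
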