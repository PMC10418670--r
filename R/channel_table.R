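#' @keywords internal
"_PACKAGE"

## Channel labels recognised throughout the package. "rotational" is carried
## as a side channel and is never part of closure sums.
XS_CHANNELS <- c("elastic", "attachment", "vibrational", "electronic",
                 "ionization", "tcs_experimental", "tcs_reference",
                 "rotational")

## Channels that enter the open-channel sum against the reference TCS.
XS_SUM_CHANNELS <- c("elastic", "attachment", "vibrational", "electronic",
                     "ionization")

#' Energy-gridded integral cross-section table for one scattering channel
#'
#' A `channel_table` holds one scattering channel of a molecule: a strictly
#' increasing impact-energy grid (eV) and the integral cross-section at each
#' grid point, in units of 1e-20 m^2 (identical to Angstrom^2). The channel
#' `threshold` is the opening energy; grid values below it must be zero.
#'
#' Zeros on the grid are legitimate: they encode "channel closed or
#' negligible" where a published table leaves a cell blank. The `provenance`
#' string is free text recording where the numbers come from and how zeros
#' are to be read.
#'
#' @param channel One of `"elastic"`, `"attachment"`, `"vibrational"`,
#'   `"electronic"`, `"ionization"`, `"tcs_experimental"`, `"tcs_reference"`,
#'   `"rotational"`.
#' @param energies Strictly increasing numeric vector of impact energies, eV,
#'   all positive.
#' @param values Cross-sections at `energies`, 1e-20 m^2, all non-negative.
#' @param threshold Channel opening energy in eV (0 for elastic and TCS
#'   channels). Values at grid points below `threshold` must be 0.
#' @param provenance Optional free-text note.
#'
#' @return An object of class `channel_table`.
#' @examples
#' tab <- channel_table("elastic", c(1, 10, 100), c(90, 70, 46))
#' interpolate_xs(tab, 10)
#' @export
channel_table <- function(channel, energies, values, threshold = 0,
                          provenance = NULL) {
  channel <- match.arg(channel, XS_CHANNELS)
  energies <- as.numeric(energies)
  values <- as.numeric(values)
  if (length(energies) != length(values))
    stop("channel '", channel, "': energies and values differ in length (",
         length(energies), " vs ", length(values), ")")
  if (length(energies) == 0)
    stop("channel '", channel, "': empty table")
  if (anyNA(energies) || anyNA(values))
    stop("channel '", channel, "': NA entries are not allowed")
  if (any(energies <= 0))
    stop("channel '", channel, "': energies must all be > 0")
  if (any(diff(energies) <= 0)) {
    bad <- which(diff(energies) <= 0)[1] + 1L
    stop("channel '", channel, "': energies not strictly increasing at row ",
         bad, " (", energies[bad - 1L], " then ", energies[bad], ")")
  }
  if (any(values < 0)) {
    bad <- which(values < 0)[1]
    stop("channel '", channel, "': negative cross-section at row ", bad,
         " (E = ", energies[bad], " eV)")
  }
  if (threshold < 0) stop("threshold must be >= 0")
  below <- energies < threshold
  if (any(values[below] != 0))
    stop("channel '", channel, "': nonzero value below threshold ",
         threshold, " eV")
  structure(
    list(channel = channel, energies = energies, values = values,
         threshold = threshold, provenance = provenance),
    class = "channel_table")
}

#' @export
print.channel_table <- function(x, ...) {
  cat("<channel_table> ", x$channel,
      sprintf(": %d points, %g-%g eV, threshold %g eV\n",
              length(x$energies), min(x$energies), max(x$energies),
              x$threshold))
  if (!is.null(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Evaluate a channel table at arbitrary impact energies
#'
#' Returns the tabulated cross-section at `E`. At a grid point the stored
#' value is returned exactly. Between grid points the default is log-log
#' linear interpolation (cross-sections are positive, smooth and span
#' decades); where either bracketing value is zero - a closed or omitted
#' cell - the interpolation falls back to linear-linear, which handles the
#' channel switching on or off without taking logs of zero.
#' `method = "linear"` forces linear-linear throughout, useful for sub-eV
#' resonant structure on coarse grids.
#'
#' Below the channel threshold the result is 0. Energies outside the
#' tabulated span (and at or above threshold) raise an error: the library
#' never extrapolates.
#'
#' @param table A [channel_table()].
#' @param E Numeric vector of impact energies, eV.
#' @param method `"loglog"` (default) or `"linear"`.
#' @return Numeric vector of cross-sections, 1e-20 m^2.
#' @examples
#' tab <- channel_table("elastic", c(20, 30), c(54.9, 46.8))
#' interpolate_xs(tab, sqrt(20 * 30))  # log-log midpoint
#' @export
interpolate_xs <- function(table, E, method = c("loglog", "linear")) {
  stopifnot(inherits(table, "channel_table"))
  method <- match.arg(method)
  E <- as.numeric(E)
  out <- numeric(length(E))
  below <- E < table$threshold
  eg <- table$energies
  vg <- table$values
  inside <- !below & E >= eg[1] & E <= eg[length(eg)]
  if (any(!below & !inside)) {
    bad <- E[!below & !inside][1]
    stop(sprintf(
      "energy %g eV outside tabulated span [%g, %g] for channel '%s'; no extrapolation",
      bad, eg[1], eg[length(eg)], table$channel))
  }
  if (!any(inside)) return(out)
  Ei <- E[inside]
  res <- numeric(length(Ei))
  ## exact grid hits: return stored value bit-for-bit
  hit <- match(Ei, eg)
  ok <- !is.na(hit)
  res[ok] <- vg[hit[ok]]
  if (any(!ok)) {
    Em <- Ei[!ok]
    i0 <- findInterval(Em, eg)
    i1 <- i0 + 1L
    x0 <- eg[i0]; x1 <- eg[i1]
    y0 <- vg[i0]; y1 <- vg[i1]
    v <- numeric(length(Em))
    uselog <- method == "loglog" & y0 > 0 & y1 > 0
    if (any(uselog)) {
      t <- (log(Em[uselog]) - log(x0[uselog])) /
           (log(x1[uselog]) - log(x0[uselog]))
      v[uselog] <- exp((1 - t) * log(y0[uselog]) + t * log(y1[uselog]))
    }
    if (any(!uselog)) {
      t <- (Em[!uselog] - x0[!uselog]) / (x1[!uselog] - x0[!uselog])
      v[!uselog] <- (1 - t) * y0[!uselog] + t * y1[!uselog]
    }
    res[!ok] <- v
  }
  out[inside] <- res
  out
}

#' Restrict a channel table to an energy window
#'
#' @param table A [channel_table()].
#' @param lo,hi Window bounds in eV (inclusive).
#' @return A [channel_table()] with the grid restricted to `[lo, hi]`.
#' @export
clip_channel <- function(table, lo = -Inf, hi = Inf) {
  stopifnot(inherits(table, "channel_table"))
  keep <- table$energies >= lo & table$energies <= hi
  if (!any(keep)) stop("no grid points left in [", lo, ", ", hi, "]")
  channel_table(table$channel, table$energies[keep], table$values[keep],
                threshold = table$threshold, provenance = table$provenance)
}
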