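## Fragmentation statistics: dissociative-electron-attachment anion
## branching ratios (anchored at measured energies) and electron-impact
## cation relative intensities.

#' Energy-indexed fragment branching table
#'
#' Discrete probability tables for fragment species, one row of
#' probabilities per anchored incident energy. Probabilities at each energy
#' must sum to 1 (within 1e-9). Between anchors the probabilities are
#' linearly interpolated in energy and renormalized; outside the anchored
#' window the nearest anchor is used (the measurements exist only inside
#' the resonant window, so no energy extrapolation is attempted).
#'
#' @param energies Increasing numeric vector of anchored incident energies, eV.
#' @param species Character vector of fragment labels (unique).
#' @param mass_u Fragment masses, u (> 0), parallel to `species`.
#' @param probs Matrix `length(energies) x length(species)` of probabilities.
#' @return An object of class `branching_table`.
#' @examples
#' bt <- branching_table(c(3.1, 4.7), c("A", "B"), c(46, 26),
#'                       rbind(c(0.6, 0.4), c(0.3, 0.7)))
#' branching_at(bt, 3.9)
#' @export
branching_table <- function(energies, species, mass_u, probs) {
  energies <- as.numeric(energies)
  probs <- as.matrix(probs)
  if (length(species) == 0) stop("configuration error: empty species list")
  if (anyDuplicated(species)) stop("duplicate species label")
  if (any(mass_u <= 0)) stop("fragment masses must be > 0")
  if (length(mass_u) != length(species))
    stop("species and mass_u differ in length")
  if (any(diff(energies) <= 0)) stop("energies must be strictly increasing")
  if (nrow(probs) != length(energies) || ncol(probs) != length(species))
    stop("probs must be length(energies) x length(species)")
  if (any(probs < 0)) stop("negative probability")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-9))
    stop("probabilities must sum to 1 at each energy (off by ",
         format(max(abs(rs - 1))), ")")
  colnames(probs) <- species
  structure(list(energies = energies, species = species,
                 mass_u = stats::setNames(as.numeric(mass_u), species),
                 probs = probs),
            class = "branching_table")
}

#' @export
print.branching_table <- function(x, ...) {
  cat("<branching_table>", length(x$species), "species anchored at",
      paste(x$energies, collapse = ", "), "eV\n")
  print(round(x$probs, 4))
  invisible(x)
}

#' Branching probabilities at an incident energy
#'
#' @param table A [branching_table()].
#' @param E Incident electron energy, eV.
#' @return Named probability vector (sums to 1).
#' @export
branching_at <- function(table, E) {
  stopifnot(inherits(table, "branching_table"), length(E) == 1)
  eg <- table$energies
  if (E <= eg[1]) {
    p <- table$probs[1, ]
  } else if (E >= eg[length(eg)]) {
    p <- table$probs[length(eg), ]
  } else {
    i <- findInterval(E, eg)
    t <- (E - eg[i]) / (eg[i + 1] - eg[i])
    p <- (1 - t) * table$probs[i, ] + t * table$probs[i + 1, ]
  }
  p / sum(p)
}

#' Sample anion fragment species from a DEA branching table
#'
#' Draws fragment species from the categorical distribution at incident
#' energy `E` (interpolated between anchors, nearest anchor outside the
#' anchored window).
#'
#' @param table A [branching_table()].
#' @param E Incident electron energy, eV.
#' @param n Number of draws.
#' @return Character vector of species labels of length `n`.
#' @examples
#' bt <- anion_branching_1m5ni()
#' table(sample_anion(bt, 3.1, 1000))
#' @export
sample_anion <- function(table, E, n = 1) {
  p <- branching_at(table, E)
  sample(table$species, n, replace = TRUE, prob = p)
}

#' Default anion kinetic-energy scales (eV)
#'
#' Mean kinetic energies for the exponential (zero-mode) fragment KE draw.
#' These are package configuration, not measured parameters: the
#' measurements give distribution shapes (all peaking near 0 eV, CN-
#' distinctly broader than NO2-), not tabulated moments. The defaults keep
#' that ordering: CN- 0.2 eV, everything else 0.05 eV.
#' @return Named numeric vector of mean KEs, eV.
#' @export
default_anion_ke_means <- function() {
  c("NO2-" = 0.05, "CN-" = 0.2, "CNO-" = 0.05, "C2N2Hx-" = 0.05,
    "C3N2Hx-" = 0.05, "C4N2Hx-" = 0.05, "M-NO" = 0.05, "M-OH/CH3" = 0.05)
}

#' Sample anion fragment kinetic energies and emission directions
#'
#' Fragment kinetic energies are drawn from an exponential distribution
#' with a species-specific mean - a zero-mode decaying shape consistent
#' with KE distributions that all peak near 0 eV. Emission directions are
#' isotropic (the measured fragment momentum images are highly isotropic).
#'
#' @param species Character vector of species labels.
#' @param ke_means Named vector of mean KEs, eV; see
#'   [default_anion_ke_means()]. Unlisted species fall back to 0.05 eV.
#' @param directions If `TRUE`, also return isotropic unit vectors.
#' @return If `directions = FALSE`, numeric vector of kinetic energies, eV;
#'   otherwise a data frame with `ke_eV`, `ux`, `uy`, `uz`.
#' @export
sample_anion_ke <- function(species, ke_means = default_anion_ke_means(),
                            directions = FALSE) {
  mu <- ke_means[species]
  mu[is.na(mu)] <- 0.05
  ke <- stats::rexp(length(species), rate = 1 / mu)
  if (!directions) return(unname(ke))
  u <- isotropic_directions(length(species))
  data.frame(ke_eV = ke, ux = u[, 1], uy = u[, 2], uz = u[, 3])
}

## uniform directions on the unit sphere
isotropic_directions <- function(n) {
  mu <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - mu^2)
  cbind(s * cos(phi), s * sin(phi), mu)
}

#' Cation relative-intensity table
#'
#' Relative intensities of the cationic species observed after
#' electron-impact ionization, normalized so the parent ion has intensity 1.
#' Intensities are treated as energy-independent (they were measured at a
#' single incident energy, 67 eV) - a documented limitation.
#'
#' @param species Character vector of labels (unique).
#' @param mass_u Fragment masses, u (> 0).
#' @param relative_intensity Positive intensities; the parent (heaviest
#'   species by default, or `parent` if given) must have intensity 1.
#' @param parent Label of the parent ion; defaults to the heaviest species.
#' @return An object of class `cation_table`.
#' @export
cation_table <- function(species, mass_u, relative_intensity, parent = NULL) {
  if (anyDuplicated(species)) stop("duplicate species label")
  if (any(mass_u <= 0)) stop("fragment masses must be > 0")
  if (any(relative_intensity <= 0)) stop("intensities must be > 0")
  if (is.null(parent)) parent <- species[which.max(mass_u)]
  if (!parent %in% species) stop("parent species not in table")
  if (relative_intensity[species == parent] != 1)
    stop("parent intensity must be 1")
  structure(list(species = species,
                 mass_u = stats::setNames(as.numeric(mass_u), species),
                 intensity = stats::setNames(as.numeric(relative_intensity),
                                             species),
                 parent = parent),
            class = "cation_table")
}

#' @export
print.cation_table <- function(x, ...) {
  cat("<cation_table>", length(x$species), "species, parent", x$parent,
      sprintf("(%g u)\n", x$mass_u[x$parent]))
  invisible(x)
}

#' Sample cation species from a relative-intensity table
#'
#' Species are drawn with probability intensity / sum(intensities); the
#' draw is invariant under rescaling all intensities by a constant.
#'
#' @param table A [cation_table()].
#' @param n Number of draws.
#' @return Character vector of species labels.
#' @examples
#' ct <- cation_intensities_1m5ni()
#' head(sample_cation(ct, 5))
#' @export
sample_cation <- function(table, n = 1) {
  stopifnot(inherits(table, "cation_table"))
  sample(table$species, n, replace = TRUE,
         prob = table$intensity / sum(table$intensity))
}

#' Read a branching table from CSV
#'
#' Schema: columns `energy_eV,species,mass_u,probability`, one row per
#' (energy, species) pair.
#' @param path CSV path.
#' @return A [branching_table()].
#' @export
read_branching_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("energy_eV", "species", "mass_u", "probability")
  if (!all(need %in% names(df)))
    stop("schema error in ", path, ": need columns ",
         paste(need, collapse = ","))
  energies <- sort(unique(df$energy_eV))
  species <- unique(df$species)
  mass <- df$mass_u[match(species, df$species)]
  probs <- matrix(0, length(energies), length(species))
  for (i in seq_along(energies)) {
    sub <- df[df$energy_eV == energies[i], ]
    probs[i, match(sub$species, species)] <- sub$probability
  }
  branching_table(energies, species, mass, probs)
}

#' Read a cation intensity table from CSV
#'
#' Schema: columns `species,mass_u,relative_intensity`.
#' @param path CSV path.
#' @return A [cation_table()].
#' @export
read_cation_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("species", "mass_u", "relative_intensity")
  if (!all(need %in% names(df)))
    stop("schema error in ", path, ": need columns ",
         paste(need, collapse = ","))
  cation_table(df$species, df$mass_u, df$relative_intensity)
}
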