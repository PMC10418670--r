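## Event-by-event Monte Carlo electron transport through 1M5NI vapor,
## driven entirely by a cross-section set (free paths and channel choice),
## the semiempirical DDCS model (inelastic deflections), and the
## fragmentation samplers (anion / cation products).

#' Transport configuration
#'
#' Collects the run parameters of the track-structure simulator. Several
#' conventions are package choices, not measured physics, and are flagged
#' as such in the parameter docs.
#'
#' @param density_m3 Target number density, m^-3 (> 0). Default 1e25
#'   (a convenient low-pressure vapor value).
#' @param E0_eV Primary electron energy, eV.
#' @param cutoff_eV Tracking cutoff, eV: electrons below it deposit their
#'   residual energy locally ("thermalized") and stop. Default 0.1, the
#'   floor of the packaged data set; must not be below the set's lowest
#'   tabulated energy.
#' @param ionization_eV Ionization energy used for secondary-electron
#'   bookkeeping. Assumption, not a measured value for 1M5NI: default
#'   placeholder 9.0 eV.
#' @param vibrational_loss_eV Energy lost per vibrational collision, eV.
#'   Package convention (fixed quantum): default 0.15.
#' @param electronic_loss_eV Energy lost per electronic-excitation
#'   collision, eV. Package convention (threshold value): default 4.0.
#' @param max_events Per-electron event cap; an electron exceeding it is
#'   truncated and its track flagged. Default 10000.
#' @param channels Channels open to the simulation; removing entries
#'   disables processes (e.g. a pure elastic random walk).
#' @param collect_events Keep the full per-event record (`TRUE`) or only
#'   track summaries (`FALSE`, cheaper for large runs).
#' @return An object of class `transport_config`.
#' @export
transport_config <- function(density_m3 = 1e25, E0_eV = 100,
                             cutoff_eV = 0.1, ionization_eV = 9.0,
                             vibrational_loss_eV = 0.15,
                             electronic_loss_eV = 4.0,
                             max_events = 10000,
                             channels = c("elastic", "attachment",
                                          "vibrational", "electronic",
                                          "ionization"),
                             collect_events = TRUE) {
  stopifnot(density_m3 > 0, E0_eV > 0, cutoff_eV > 0,
            ionization_eV > 0, vibrational_loss_eV > 0,
            electronic_loss_eV > 0, max_events >= 1)
  channels <- match.arg(channels, XS_SUM_CHANNELS, several.ok = TRUE)
  structure(list(density_m3 = density_m3, E0_eV = E0_eV,
                 cutoff_eV = cutoff_eV, ionization_eV = ionization_eV,
                 vibrational_loss_eV = vibrational_loss_eV,
                 electronic_loss_eV = electronic_loss_eV,
                 max_events = max_events, channels = channels,
                 collect_events = collect_events),
            class = "transport_config")
}

## per-channel cross-sections open at E, restricted to enabled channels
channel_sigmas <- function(set, E, channels = XS_SUM_CHANNELS) {
  present <- intersect(channels, names(set$tables))
  vapply(present, function(ch) interpolate_xs(set$tables[[ch]], E),
         numeric(1))
}

#' Sample exponential free path lengths
#'
#' Free paths follow exponential attenuation with mean `1 / (n sigma_tot)`,
#' where `sigma_tot` is the open-channel sum of the set at `E` (converted
#' from 1e-20 m^2 to m^2).
#'
#' @param E Electron energy, eV (within the set's tabulated span).
#' @param set A [xs_set()].
#' @param config A [transport_config()] (supplies the number density and
#'   the enabled channels).
#' @param n Number of draws.
#' @return Path lengths in metres.
#' @export
step_free_path <- function(E, set, config, n = 1) {
  sig <- sum(channel_sigmas(set, E, config$channels)) * 1e-20
  if (sig <= 0) stop("total cross-section is zero at E = ", E, " eV")
  -log(stats::runif(n)) / (config$density_m3 * sig)
}

#' Sample the collision channel at an energy
#'
#' Channels are drawn with probability proportional to their
#' cross-sections at `E` - the same open-channel weights whose sum closes
#' to the reference TCS.
#'
#' @param E Electron energy, eV.
#' @param set A [xs_set()].
#' @param n Number of draws.
#' @param channels Channels to consider (default: the five summed
#'   scattering channels).
#' @return Character vector of channel labels.
#' @examples
#' set <- load_xs_set("1m5ni_recommended")
#' set.seed(1); table(choose_channel(2, set, 1000))
#' @export
choose_channel <- function(E, set, n = 1,
                           channels = c("elastic", "attachment",
                                        "vibrational", "electronic",
                                        "ionization")) {
  sig <- channel_sigmas(set, E, channels)
  tot <- sum(sig)
  if (tot <= 0) stop("internal error: all channels zero at E = ", E, " eV")
  if (length(sig) == 1) return(rep(names(sig), n))
  sample(names(sig), n, replace = TRUE, prob = sig / tot)
}

## inverse-CDF sample of the ionization energy loss: density ~ 1/dE^2 on
## [IP, (E + IP)/2] (binary-encounter-like tail; the faster of the two
## outgoing electrons is called the primary, hence the upper limit)
sample_ionization_loss <- function(E, IP, n = 1) {
  a <- IP
  b <- (E + IP) / 2
  if (b <= a) return(rep(a, n))
  u <- stats::runif(n)
  1 / (1 / a - u * (1 / a - 1 / b))
}

## rotate unit vector `d` by polar angle theta (deg) about itself with
## azimuth phi (deg); returns the new unit vector
deflect_direction <- function(d, theta_deg, phi_deg) {
  ct <- cos(theta_deg * pi / 180); st <- sin(theta_deg * pi / 180)
  cp <- cos(phi_deg * pi / 180); sp <- sin(phi_deg * pi / 180)
  ## orthonormal frame (u, v, d)
  if (abs(d[3]) < 0.99) a <- c(0, 0, 1) else a <- c(1, 0, 0)
  u <- c(d[2] * a[3] - d[3] * a[2],
         d[3] * a[1] - d[1] * a[3],
         d[1] * a[2] - d[2] * a[1])
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  out <- ct * d + st * (cp * u + sp * v)
  out / sqrt(sum(out^2))
}

#' Bundle the sampling models the simulator needs
#'
#' Builds the model set used by [apply_collision()] and
#' [simulate_tracks()]: the elastic-DCS angular sampler (tabulated inverse
#' CDFs on a log energy grid for speed), the DDCS energy-loss weight k,
#' and the fragmentation tables. If no elastic DCS table or provider is
#' supplied, the screened-Coulomb toy shape normalized to the set's
#' elastic ICS is used as a documented fallback and stamped into the run
#' metadata (`fallback_dcs = TRUE`).
#'
#' @param set A [xs_set()].
#' @param elastic_dcs Optional DCS provider `(E, theta_deg) -> value`.
#' @param k Energy-loss weight of the DDCS model; default 1.3.
#' @param anion_br A [branching_table()]; default the packaged 1M5NI table.
#' @param cation A [cation_table()]; default the packaged 67 eV table.
#' @param ke_means Anion KE means, eV; see [default_anion_ke_means()].
#' @param n_E,n_mu Resolution of the cached angular inverse-CDF tables.
#' @return An object of class `transport_models`.
#' @export
transport_models <- function(set, elastic_dcs = NULL, k = 1.3,
                             anion_br = anion_branching_1m5ni(),
                             cation = cation_intensities_1m5ni(),
                             ke_means = default_anion_ke_means(),
                             n_E = 48, n_mu = 257) {
  fallback <- is.null(elastic_dcs)
  if (fallback) {
    el <- set$tables$elastic
    span <- range(el$energies)
    ics <- function(E) interpolate_xs(el, pmin(pmax(E, span[1]), span[2]))
    elastic_dcs <- make_toy_dcs(ics = ics, eta = 0.05)
  }
  el <- set$tables$elastic
  Egrid <- exp(seq(log(min(el$energies)), log(max(el$energies)),
                   length.out = n_E))
  mu <- seq(-1, 1, length.out = n_mu)
  th <- acos(mu) * 180 / pi
  samplers <- lapply(Egrid, function(E)
    make_mu_sampler(mu, elastic_dcs(E, th)))
  sample_angle <- function(E) {
    i <- which.min(abs(log(E) - log(Egrid)))   # nearest log-energy node
    acos(samplers[[i]](stats::runif(1))) * 180 / pi
  }
  structure(list(elastic_dcs = elastic_dcs, k = k,
                 ddcs = ddcs_model(elastic_dcs, k = k),
                 sample_angle = sample_angle,
                 anion_br = anion_br, cation = cation,
                 ke_means = ke_means, fallback_dcs = fallback),
            class = "transport_models")
}

#' Apply one collision to an electron state
#'
#' Implements the channel semantics of the simulator:
#' \describe{
#'   \item{elastic}{deflection drawn from the elastic DCS; energy unchanged
#'     (target recoil neglected).}
#'   \item{vibrational / electronic}{fixed channel energy loss subtracted;
#'     deflection drawn from the DDCS angular profile at `(E, dE)`.}
#'   \item{ionization}{total loss drawn from the binary-encounter-like
#'     `1/dE^2` spectrum on `[IP, (E+IP)/2]`; a secondary electron with
#'     kinetic energy `dE - IP` is spawned isotropically, the cation
#'     species is sampled from the intensity table, and the primary is
#'     deflected via the DDCS.}
#'   \item{attachment}{the electron is captured (track ends); the anion
#'     species and its kinetic energy are sampled from the branching
#'     table and KE model. The electron's remaining energy is booked as
#'     deposited.}
#' }
#' A loss that would push the electron's energy negative is truncated at
#' the available energy with a warning.
#'
#' @param state List with `E` (eV), `dir` (unit 3-vector), `pos` (m).
#' @param channel One of the five scattering channels.
#' @param models A [transport_models()].
#' @param config A [transport_config()].
#' @return List with `electron` (updated state, or `NULL` if the electron
#'   terminated), `secondary` (spawned electron state or `NULL`), and
#'   `event` (named list: energies, channel, deflection, deposit, product).
#' @export
apply_collision <- function(state, channel, models, config) {
  E <- state$E
  phi <- stats::runif(1, 0, 360)
  theta <- 0
  deposit <- 0
  secondary <- NULL
  product <- NA_character_
  product_ke <- NA_real_
  E_after <- E

  truncate_loss <- function(dE) {
    if (dE > E) {
      warning("energy loss ", dE, " eV exceeds available ", E,
              " eV; truncated")
      E
    } else dE
  }

  if (channel == "elastic") {
    theta <- models$sample_angle(E)
  } else if (channel == "vibrational") {
    dE <- truncate_loss(config$vibrational_loss_eV)
    theta <- models$sample_angle(E)      # DDCS angular profile at (E, dE)
    deposit <- dE
    E_after <- E - dE
  } else if (channel == "electronic") {
    dE <- truncate_loss(config$electronic_loss_eV)
    theta <- models$sample_angle(E)
    deposit <- dE
    E_after <- E - dE
  } else if (channel == "ionization") {
    dE <- truncate_loss(sample_ionization_loss(E, config$ionization_eV))
    ke2 <- max(0, dE - config$ionization_eV)
    deposit <- dE - ke2                  # the binding energy stays local
    E_after <- E - dE
    theta <- models$sample_angle(E)
    u2 <- isotropic_directions(1)
    secondary <- list(E = ke2, dir = as.numeric(u2), pos = state$pos)
    product <- sample_cation(models$cation, 1)
  } else if (channel == "attachment") {
    product <- sample_anion(models$anion_br, E, 1)
    product_ke <- sample_anion_ke(product, models$ke_means)
    deposit <- E                         # electron captured
    E_after <- 0
  } else stop("unknown channel: ", channel)

  electron <- NULL
  if (channel != "attachment") {
    dir2 <- deflect_direction(state$dir, theta, phi)
    electron <- list(E = E_after, dir = dir2, pos = state$pos)
  }
  list(electron = electron, secondary = secondary,
       event = list(E_before = E, E_after = E_after, channel = channel,
                    theta_deg = theta, phi_deg = phi, deposit = deposit,
                    secondary_ke = if (is.null(secondary)) 0 else secondary$E,
                    product = product, product_ke = product_ke))
}

## growable event buffer (amortized O(1) appends)
new_event_buffer <- function(init = 1024L) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$num <- matrix(NA_real_, init, 10)
  colnames(env$num) <- c("x", "y", "z", "E_before", "E_after",
                         "theta_deg", "phi_deg", "deposit",
                         "secondary_ke", "product_ke")
  env$chr <- matrix(NA_character_, init, 2)
  colnames(env$chr) <- c("channel", "product")
  env$int <- matrix(NA_integer_, init, 3)
  colnames(env$int) <- c("track", "electron", "event")
  env
}
push_event <- function(buf, ints, nums, chrs) {
  if (buf$n == nrow(buf$num)) {
    buf$num <- rbind(buf$num, matrix(NA_real_, buf$n, ncol(buf$num)))
    buf$chr <- rbind(buf$chr, matrix(NA_character_, buf$n, ncol(buf$chr)))
    buf$int <- rbind(buf$int, matrix(NA_integer_, buf$n, ncol(buf$int)))
  }
  buf$n <- buf$n + 1L
  buf$num[buf$n, ] <- nums
  buf$chr[buf$n, ] <- chrs
  buf$int[buf$n, ] <- ints
}
buffer_to_df <- function(buf) {
  if (buf$n == 0L) return(NULL)
  i <- seq_len(buf$n)
  cbind(as.data.frame(buf$int[i, , drop = FALSE]),
        as.data.frame(buf$num[i, , drop = FALSE]),
        as.data.frame(buf$chr[i, , drop = FALSE]))
}

#' Run event-by-event electron track simulations
#'
#' Simulates `n_primaries` full cascades: each primary starts at the
#' origin moving along +z with energy `config$E0_eV`; secondaries from
#' ionization are pushed on a stack and transported identically. Tracking
#' stops on attachment (capture), at the energy cutoff (local deposition
#' of the residual), or at the per-electron event cap (flagged as
#' truncated). With a fixed seed the event stream is reproducible.
#'
#' Energy is audited per cascade: the primary energy must equal the sum of
#' all deposits plus the residual energies of all terminated electrons
#' (secondary kinetic energy is handed over, not lost), to 1e-6 relative.
#'
#' @param set A [xs_set()] (must span `[cutoff, E0]`).
#' @param config A [transport_config()].
#' @param models A [transport_models()]; built with defaults if `NULL`.
#' @param n_primaries Number of primary electrons.
#' @return List of class `track_run`: `summary` (one row per primary:
#'   event/channel counts, path length, deposited and residual energy,
#'   secondaries, closure error), `events` (data frame, or `NULL` when
#'   `collect_events = FALSE`), `fragments` (named product counts),
#'   `config`, `fallback_dcs`.
#' @examples
#' set <- load_xs_set("1m5ni_recommended")
#' cfg <- transport_config(E0_eV = 50, cutoff_eV = 1, max_events = 200)
#' set.seed(1)
#' run <- simulate_tracks(set, cfg, n_primaries = 3)
#' run$summary[, c("E0_eV", "n_events", "deposited_eV", "closure_rel")]
#' @export
simulate_tracks <- function(set, config, models = NULL, n_primaries = 1) {
  stopifnot(inherits(set, "xs_set"), inherits(config, "transport_config"))
  el_span <- range(set$tables$elastic$energies)
  if (config$cutoff_eV < el_span[1])
    stop("cutoff ", config$cutoff_eV, " eV is below the data floor ",
         el_span[1], " eV")
  if (config$E0_eV > el_span[2])
    stop("primary energy exceeds the tabulated span; no extrapolation")
  if (is.null(models)) models <- transport_models(set)

  buf <- if (config$collect_events) new_event_buffer() else NULL
  frag_counts <- integer(0)
  chs <- config$channels
  sum_rows <- vector("list", n_primaries)

  for (tr in seq_len(n_primaries)) {
    stack <- list(list(E = config$E0_eV, dir = c(0, 0, 1),
                       pos = c(0, 0, 0)))
    electron_id <- 0L
    deposited <- 0; residual <- 0; path <- 0
    counts <- stats::setNames(integer(length(chs)), chs)
    n_sec <- 0L; truncated <- FALSE; n_events_track <- 0L

    while (length(stack) > 0) {
      st <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      electron_id <- electron_id + 1L
      ev <- 0L
      repeat {
        if (st$E < config$cutoff_eV) { residual <- residual + st$E; break }
        if (ev >= config$max_events) {
          truncated <- TRUE; residual <- residual + st$E; break
        }
        s <- step_free_path(st$E, set, config, 1)
        st$pos <- st$pos + s * st$dir
        path <- path + s
        ch <- choose_channel(st$E, set, 1, channels = chs)
        out <- apply_collision(st, ch, models, config)
        ev <- ev + 1L
        n_events_track <- n_events_track + 1L
        counts[ch] <- counts[ch] + 1L
        deposited <- deposited + out$event$deposit
        if (!is.na(out$event$product)) {
          frag_counts[out$event$product] <-
            (if (is.na(frag_counts[out$event$product]))
               0L else frag_counts[out$event$product]) + 1L
        }
        if (!is.null(buf))
          push_event(buf,
                     ints = c(tr, electron_id, ev),
                     nums = c(st$pos, out$event$E_before, out$event$E_after,
                              out$event$theta_deg, out$event$phi_deg,
                              out$event$deposit, out$event$secondary_ke,
                              out$event$product_ke),
                     chrs = c(out$event$channel, out$event$product))
        if (!is.null(out$secondary)) {
          n_sec <- n_sec + 1L
          stack[[length(stack) + 1L]] <- out$secondary
        }
        if (is.null(out$electron)) break
        st <- out$electron
      }
    }
    closure <- abs(config$E0_eV - deposited - residual) / config$E0_eV
    sum_rows[[tr]] <- data.frame(
      track = tr, E0_eV = config$E0_eV, n_events = n_events_track,
      path_length_m = path, deposited_eV = deposited,
      residual_eV = residual, n_secondaries = n_sec,
      n_elastic = unname(counts["elastic"] %||% 0L),
      n_attachment = unname(counts["attachment"] %||% 0L),
      n_vibrational = unname(counts["vibrational"] %||% 0L),
      n_electronic = unname(counts["electronic"] %||% 0L),
      n_ionization = unname(counts["ionization"] %||% 0L),
      truncated = truncated, closure_rel = closure)
  }
  summary <- do.call(rbind, sum_rows)
  rownames(summary) <- NULL
  structure(list(summary = summary,
                 events = if (is.null(buf)) NULL else buffer_to_df(buf),
                 fragments = frag_counts, config = config,
                 fallback_dcs = isTRUE(models$fallback_dcs)),
            class = "track_run")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' @export
print.track_run <- function(x, ...) {
  s <- x$summary
  cat("<track_run>", nrow(s), "primaries at", s$E0_eV[1], "eV\n")
  cat(sprintf("  events %d, secondaries %d, deposited %.1f eV/track, max closure err %.2g\n",
              sum(s$n_events), sum(s$n_secondaries),
              mean(s$deposited_eV), max(s$closure_rel)))
  if (x$fallback_dcs)
    cat("  [elastic angular sampling used the toy screened-Coulomb fallback]\n")
  invisible(x)
}

#' Write the event stream as JSON Lines
#'
#' One JSON object per collision event, with the track/electron/event
#' indices, position (m), energies (eV), channel, deflection angles and
#' any product.
#'
#' @param run A `track_run` from [simulate_tracks()] with collected events.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(run, path) {
  stopifnot(inherits(run, "track_run"))
  if (is.null(run$events)) stop("run has no collected events")
  con <- file(path, "w")
  on.exit(close(con))
  ev <- run$events
  for (i in seq_len(nrow(ev)))
    writeLines(jsonlite::toJSON(as.list(ev[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  invisible(path)
}
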