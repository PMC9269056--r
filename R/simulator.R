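# Monte Carlo coincidence simulator: back-to-back 511 keV photon pairs from
# a source, geometric acceptance on two planar heads, angle-dependent crystal
# stopping, single Compton scatter in an attenuating phantom body, Gaussian
# energy and positioning blur, random coincidences, and dead-time thinning.

E511 <- 511

# Path length (mm) from points `p` (n x 3, assumed inside or outside the
# medium) to the exit of the cylinder (axis along X) along unit directions
# `v`. Returns 0 where the forward ray misses the medium.
cylinder_path_length <- function(p, v, medium) {
  py <- p[, 2] - medium$center[2]
  pz <- p[, 3] - medium$center[3]
  px <- p[, 1] - medium$center[1]
  a <- v[, 2]^2 + v[, 3]^2
  b <- 2 * (py * v[, 2] + pz * v[, 3])
  cc <- py^2 + pz^2 - medium$radius^2
  disc <- b^2 - 4 * a * cc
  t1 <- rep(0, nrow(p)); t2 <- rep(0, nrow(p))
  ok <- disc > 0 & a > 0
  sq <- sqrt(pmax(disc, 0))
  t1[ok] <- ((-b - sq) / (2 * a))[ok]
  t2[ok] <- ((-b + sq) / (2 * a))[ok]
  # axial ray (a == 0): inside the disc for all t
  ax <- !ok & cc < 0
  t1[ax] <- -Inf; t2[ax] <- Inf
  # clip to the x-slab |x| <= length/2
  hx <- medium$length / 2
  with_x <- abs(v[, 1]) > 1e-12
  xs1 <- ifelse(with_x, (-hx - px) / v[, 1], -Inf)
  xs2 <- ifelse(with_x, (hx - px) / v[, 1], Inf)
  xin <- !with_x & abs(px) <= hx
  xs1[xin] <- -Inf; xs2[xin] <- Inf
  xs_lo <- pmin(xs1, xs2); xs_hi <- pmax(xs1, xs2)
  miss_x <- !with_x & !xin
  lo <- pmax(pmax(t1, xs_lo), 0)
  hi <- pmin(t2, xs_hi)
  len <- pmax(hi - lo, 0)
  len[miss_x | (!ok & !ax)] <- 0
  len
}

#' Sample Compton scattering angles from the Klein-Nishina distribution
#'
#' Draws `n` values of `cos(theta)` from the Klein-Nishina differential
#' cross-section at the given photon energy, via a tabulated inverse CDF.
#' Uses the current RNG stream unless `seed` is given.
#'
#' @param n number of samples.
#' @param energy_kev incident photon energy in keV.
#' @param seed optional integer seed.
#' @return Numeric vector of `cos(theta)` in `[-1, 1]`.
#' @export
sample_klein_nishina <- function(n, energy_kev = E511, seed = NULL) {
  k <- energy_kev / E511
  ct <- seq(-1, 1, length.out = 2048L)
  ratio <- 1 / (1 + k * (1 - ct))          # E'/E
  pdf <- ratio^2 * (ratio + 1 / ratio - (1 - ct^2))
  cdf <- cumsum(pdf); cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  with_seed(seed, {
    u <- runif(n)
    approx(cdf, ct, xout = u, ties = "ordered")$y
  })
}

#' Compton-scattered photon energy
#'
#' `E' = E / (1 + (E/511)(1 - cos(theta)))` in keV.
#'
#' @param energy_kev incident energy in keV.
#' @param cos_theta cosine of the scattering angle.
#' @return Scattered photon energy in keV.
#' @export
compton_energy <- function(energy_kev, cos_theta) {
  energy_kev / (1 + (energy_kev / E511) * (1 - cos_theta))
}

# Rotate unit vectors `v` (n x 3) by polar angle acos(ct) about themselves
# with azimuth `phi`: returns new unit directions.
rotate_directions <- function(v, ct, phi) {
  st <- sqrt(pmax(0, 1 - ct^2))
  # orthonormal frame (e1, e2, v)
  small <- abs(v[, 3]) > 0.9
  ref <- cbind(ifelse(small, 1, 0), 0, ifelse(small, 0, 1))
  e1 <- cbind(ref[, 2] * v[, 3] - ref[, 3] * v[, 2],
              ref[, 3] * v[, 1] - ref[, 1] * v[, 3],
              ref[, 1] * v[, 2] - ref[, 2] * v[, 1])
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(v[, 2] * e1[, 3] - v[, 3] * e1[, 2],
              v[, 3] * e1[, 1] - v[, 1] * e1[, 3],
              v[, 1] * e1[, 2] - v[, 2] * e1[, 1])
  v * ct + (e1 * cos(phi) + e2 * sin(phi)) * st
}

#' Single Compton scatter of a photon crossing an attenuating medium
#'
#' Samples one possible interaction of a 511 keV (or other energy) photon on
#' its path through `medium`: with probability `1 - exp(-mu * L)` the photon
#' Compton-scatters once (interaction point from a truncated exponential,
#' scattering angle from the Klein-Nishina distribution, outgoing energy from
#' the Compton formula); otherwise it is unscattered. Scattered photons are
#' not attenuated again (single-scatter model).
#'
#' @param point length-3 photon origin (mm).
#' @param direction length-3 direction (normalized internally).
#' @param medium an [attenuation_medium()].
#' @param energy_kev incident energy in keV.
#' @param seed optional integer seed.
#' @return A list with `status` (`"unscattered"` or `"scattered"`),
#'   `direction`, `energy_kev`, and for scattered photons `cos_theta` and
#'   `scatter_point`.
#' @export
compton_single_scatter <- function(point, direction, medium,
                                   energy_kev = E511, seed = NULL) {
  v <- as.numeric(direction); v <- v / sqrt(sum(v^2))
  p <- matrix(as.numeric(point), ncol = 3)
  L <- cylinder_path_length(p, matrix(v, ncol = 3), medium)
  mu <- medium$mu_511 / 10   # 1/mm
  with_seed(seed, {
    p_int <- 1 - exp(-mu * L)
    if (runif(1) >= p_int)
      return(list(status = "unscattered", direction = v,
                  energy_kev = energy_kev))
    s <- -log(1 - runif(1) * p_int) / mu
    ct <- sample_klein_nishina(1L, energy_kev)
    phi <- runif(1, 0, 2 * pi)
    w <- rotate_directions(matrix(v, ncol = 3), ct, phi)[1, ]
    list(status = "scattered", direction = w,
         energy_kev = compton_energy(energy_kev, ct),
         cos_theta = ct, scatter_point = as.numeric(point) + s * v)
  })
}

# Vectorized single-photon transport: origins `p`, unit dirs `v`, returns a
# list with head index (1 = z+, 2 = z-, NA = lost), blurred endpoint coords,
# observed energy, detected flag and scattered flag.
transport_photons <- function(p, v, geom, response, windows, medium = NULL) {
  n <- nrow(p)
  scattered <- rep(FALSE, n)
  energy <- rep(E511, n)
  if (!is.null(medium)) {
    mu <- medium$mu_511 / 10
    L <- cylinder_path_length(p, v, medium)
    p_int <- 1 - exp(-mu * L)
    sc <- runif(n) < p_int
    if (any(sc)) {
      s <- -log(1 - runif(sum(sc)) * p_int[sc]) / mu
      p[sc, ] <- p[sc, , drop = FALSE] + s * v[sc, , drop = FALSE]
      ct <- sample_klein_nishina(sum(sc))
      phi <- runif(sum(sc), 0, 2 * pi)
      v[sc, ] <- rotate_directions(v[sc, , drop = FALSE], ct, phi)
      energy[sc] <- compton_energy(E511, ct)
      scattered <- sc
    }
  }
  h <- geom$separation / 2
  vz <- v[, 3]
  head <- ifelse(vz > 0, 1L, ifelse(vz < 0, 2L, NA_integer_))
  tz <- ifelse(head == 1L, (h - p[, 3]) / vz, (-h - p[, 3]) / vz)
  valid <- !is.na(head) & tz > 0
  x <- p[, 1] + tz * v[, 1]
  y <- p[, 2] + tz * v[, 2]
  inside <- valid & in_sensing_area(x, y, geom)
  pdet <- photon_detection_prob(abs(vz), response, geom)
  detected <- inside & (runif(n) < pdet)
  # energy blur: fractional FWHM scales as 1/sqrt(E)
  sig <- response$energy_resolution_fwhm / 2.3548 * sqrt(E511 * energy)
  e_obs <- energy + rnorm(n, 0, sig)
  in_window <- e_obs >= windows$energy_low & e_obs <= windows$energy_high
  # positioning blur, clamped into the sensing area
  if (response$positioning_fwhm > 0) {
    sp <- response$positioning_fwhm / 2.3548
    x <- x + rnorm(n, 0, sp)
    y <- y + rnorm(n, 0, sp)
    hx <- geom$head_size_x / 2; hy <- geom$head_size_y / 2
    eps <- 1e-9
    x <- pmin(pmax(x, -hx), hx - eps)
    y <- pmin(pmax(y, -hy), hy - eps)
  }
  list(head = head, x = x, y = y, energy = e_obs,
       accepted = detected & in_window, scattered = scattered)
}

#' Simulate a coincidence acquisition
#'
#' Generates a list-mode set of coincidence events for `source` viewed by the
#' two planar heads over `duration` seconds. The number of decays is Poisson
#' with mean equal to the time-integral of the decaying activity; each
#' positron-producing decay emits a back-to-back photon pair isotropically.
#' Each photon must intercept a sensing area, survive single-Compton
#' attenuation in the phantom body (if the source carries a `medium`),
#' survive the angle-dependent crystal-stopping Bernoulli thinning, and fall
#' inside the energy window after Gaussian energy blur. Random coincidences
#' are added at the rate `2 tau S_A S_B` from the measured singles rates, and
#' the configured dead-time model thins the merged prompt stream.
#'
#' @param source a `source_spec`.
#' @param geom a [build_detector()] geometry.
#' @param response a [detector_response()].
#' @param windows an [acquisition_windows()].
#' @param duration requested acquisition duration in seconds.
#' @param seed integer seed (reproducible stream for the whole acquisition).
#' @param include_randoms add accidental coincidences (default `TRUE`).
#' @param max_decays cap on simulated decays; when the expected number of
#'   decays exceeds the cap the acquisition is truncated to the equivalent
#'   shorter duration (recorded in the returned set) so that rates remain
#'   unbiased.
#' @param t0_min time offset of the acquisition start since the source
#'   reference time, in minutes (activity is decayed to this point).
#' @return A [listmode_set()].
#' @export
simulate_acquisition <- function(source, geom, response,
                                 windows = acquisition_windows(),
                                 duration = 60, seed = NULL,
                                 include_randoms = TRUE,
                                 max_decays = 5e6, t0_min = 0) {
  if (duration <= 0) stop_domain("duration must be > 0")
  a0_bq <- decay_activity(source, t0_min) * 1000
  lam <- log(2) / (source$isotope$half_life * 60)  # 1/s
  # expected decays in [0, T]
  exp_decays <- function(T) a0_bq * (1 - exp(-lam * T)) / lam
  dur <- duration
  if (is.finite(max_decays) && a0_bq > 0 && exp_decays(duration) > max_decays) {
    dur <- -log(1 - max_decays * lam / a0_bq) / lam
  }
  with_seed(seed, {
    br <- source$isotope$positron_branching_ratio
    mean_pairs <- exp_decays(dur) * br
    n <- if (mean_pairs > 0 && response$eta > 0) rpois(1, mean_pairs) else 0L
    if (n == 0) {
      return(listmode_set(empty_events(), windows, geom, dur,
                          meta = acquisition_meta(source, t0_min, dur, seed)))
    }
    # decay-weighted emission times
    u <- runif(n)
    t <- if (lam * dur > 1e-9) -log(1 - u * (1 - exp(-lam * dur))) / lam
         else u * dur
    pts <- sample_emission_points(source, n)
    cz <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    sz <- sqrt(pmax(0, 1 - cz^2))
    v <- cbind(sz * cos(phi), sz * sin(phi), cz)
    medium <- source$medium
    ph1 <- transport_photons(pts, v, geom, response, windows, medium)
    ph2 <- transport_photons(pts, -v, geom, response, windows, medium)
    coin <- ph1$accepted & ph2$accepted & !is.na(ph1$head) &
      !is.na(ph2$head) & ph1$head != ph2$head
    a_is_1 <- ph1$head == 1L
    ev <- data.frame(
      x1 = ifelse(a_is_1, ph1$x, ph2$x)[coin],
      y1 = ifelse(a_is_1, ph1$y, ph2$y)[coin],
      x2 = ifelse(a_is_1, ph2$x, ph1$x)[coin],
      y2 = ifelse(a_is_1, ph2$y, ph1$y)[coin],
      e1 = ifelse(a_is_1, ph1$energy, ph2$energy)[coin],
      e2 = ifelse(a_is_1, ph2$energy, ph1$energy)[coin],
      t = t[coin],
      label = ifelse((ph1$scattered | ph2$scattered)[coin], "scatter", "true")
    )
    singles <- list(
      a = list(n = sum(ph1$accepted & ph1$head == 1L, na.rm = TRUE) +
                 sum(ph2$accepted & ph2$head == 1L, na.rm = TRUE)),
      b = list(n = sum(ph1$accepted & ph1$head == 2L, na.rm = TRUE) +
                 sum(ph2$accepted & ph2$head == 2L, na.rm = TRUE)))
    rate_a <- singles$a$n / dur
    rate_b <- singles$b$n / dur
    if (include_randoms && nrow(ev) > 0) {
      # endpoint pools for the two heads, from detected singles
      pool_a <- rbind(
        cbind(ph1$x, ph1$y, ph1$energy)[ph1$accepted & ph1$head == 1L, , drop = FALSE],
        cbind(ph2$x, ph2$y, ph2$energy)[ph2$accepted & ph2$head == 1L, , drop = FALSE])
      pool_b <- rbind(
        cbind(ph1$x, ph1$y, ph1$energy)[ph1$accepted & ph1$head == 2L, , drop = FALSE],
        cbind(ph2$x, ph2$y, ph2$energy)[ph2$accepted & ph2$head == 2L, , drop = FALSE])
      rnd <- generate_randoms(rate_a, rate_b, windows$timing_window_ns, dur,
                              geom = geom,
                              endpoint_pool_a = pool_a,
                              endpoint_pool_b = pool_b)
      ev <- rbind(ev, rnd)
    }
    ev <- ev[order(ev$t), , drop = FALSE]
    rownames(ev) <- NULL
    meta <- acquisition_meta(source, t0_min, dur, seed)
    meta$singles_rate_a <- rate_a
    meta$singles_rate_b <- rate_b
    set <- listmode_set(ev, windows, geom, dur, meta = meta)
    if (response$dead_time_tau_us > 0) set <- apply_dead_time(set, response)
    set
  })
}

acquisition_meta <- function(source, t0_min, dur, seed) {
  a_mid <- decay_activity(source, t0_min + dur / 2 / 60)
  meta <- list(source_kind = source$kind,
               isotope = source$isotope$name,
               frame_start_min = t0_min,
               activity_start_kbq = decay_activity(source, t0_min),
               activity_mid_kbq = a_mid,
               seed = seed)
  if (!is.null(source$reporting_volume_ml))
    meta$concentration_kbq_ml <- a_mid / source$reporting_volume_ml
  meta
}

#' Generate random (accidental) coincidences
#'
#' Accidental coincidences arise when unrelated single photons on the two
#' heads fall within the coincidence timing window; their rate is
#' `2 * tau * S_A * S_B`. Endpoints are drawn from the supplied singles
#' endpoint pools (or uniformly over the sensing areas), times uniformly
#' over the acquisition.
#'
#' @param singles_rate_a,singles_rate_b singles rates on the two heads (cps).
#' @param timing_window_ns coincidence window in ns.
#' @param duration acquisition duration in s.
#' @param seed optional integer seed (`NULL`: current RNG stream).
#' @param geom geometry, used when no endpoint pool is given.
#' @param endpoint_pool_a,endpoint_pool_b optional matrices with columns
#'   (x, y, energy) from which endpoints are resampled.
#' @return A data frame of events with `label = "random"`.
#' @export
generate_randoms <- function(singles_rate_a, singles_rate_b, timing_window_ns,
                             duration, seed = NULL, geom = NULL,
                             endpoint_pool_a = NULL, endpoint_pool_b = NULL) {
  if (singles_rate_a < 0 || singles_rate_b < 0)
    stop_domain("singles rates must be >= 0")
  rate <- 2 * timing_window_ns * 1e-9 * singles_rate_a * singles_rate_b
  with_seed(seed, {
    n <- rpois(1, rate * duration)
    if (n == 0) return(empty_events())
    draw <- function(pool) {
      if (!is.null(pool) && nrow(pool) > 0) {
        pool[sample.int(nrow(pool), n, replace = TRUE), , drop = FALSE]
      } else {
        if (is.null(geom)) stop_domain("geom required without endpoint pools")
        cbind(runif(n, -geom$head_size_x / 2, geom$head_size_x / 2),
              runif(n, -geom$head_size_y / 2, geom$head_size_y / 2),
              rep(E511, n))
      }
    }
    pa <- draw(endpoint_pool_a)
    pb <- draw(endpoint_pool_b)
    data.frame(x1 = pa[, 1], y1 = pa[, 2], x2 = pb[, 1], y2 = pb[, 2],
               e1 = pa[, 3], e2 = pb[, 3],
               t = sort(runif(n, 0, duration)), label = "random")
  })
}

#' Apply dead-time thinning to a time-sorted event stream
#'
#' Paralyzable model: an event is recorded only if no other event (recorded
#' or not) occurred within the preceding `tau`; the observed rate for a
#' Poisson stream of true rate `n` is `m = n exp(-n tau)`. The
#' non-paralyzable model only extends dead time after recorded events.
#'
#' @param x a [listmode_set()] or a data frame of events with column `t`
#'   (seconds), time-sorted.
#' @param response a [detector_response()]; `dead_time_tau_us` and
#'   `dead_time_model` are used.
#' @return Object of the same type with dead events removed.
#' @export
apply_dead_time <- function(x, response) {
  ev <- if (inherits(x, "listmode_set")) x$events else x
  if (is.unsorted(ev$t)) stop_domain("events must be time-sorted")
  tau <- response$dead_time_tau_us * 1e-6
  if (tau > 0 && nrow(ev) > 0) {
    keep <- if (response$dead_time_model == "paralyzable") {
      c(TRUE, diff(ev$t) > tau)
    } else {
      cpp_nonparalyzable_keep(ev$t, tau)
    }
    ev <- ev[keep, , drop = FALSE]
    rownames(ev) <- NULL
  }
  if (inherits(x, "listmode_set")) {
    x$events <- ev
    x
  } else ev
}

#' Simulate the decaying count-rate acquisition series
#'
#' Repeats acquisitions of `phantom` every `frame_interval` minutes from
#' t = 0 until the source has decayed through `stop_half_lives` half-lives,
#' or until `max_total_events` events have been collected, whichever comes
#' first. Activity decays continuously; each frame records the activity and
#' concentration at its own midpoint.
#'
#' @param phantom a `source_spec` (normally [nu4_scatter_phantom()]).
#' @param geom,response,windows as in [simulate_acquisition()].
#' @param frame_interval minutes between frame starts (default 15).
#' @param stop_half_lives stop once this many half-lives have elapsed.
#' @param frame_duration per-frame acquisition length in seconds.
#' @param max_decays_per_frame cap on simulated decays per frame; frames at
#'   high activity are truncated to an equivalent shorter duration so rates
#'   stay unbiased while the simulation stays tractable.
#' @param max_total_events stop rule on accumulated events (default 29e6).
#' @param seed integer seed; each frame derives its own sub-seed.
#' @return A list of [listmode_set()] frames, with a `frames` attribute
#'   summarizing start time, activity, concentration and event counts.
#' @export
simulate_decay_series <- function(phantom, geom, response,
                                  windows = acquisition_windows(),
                                  frame_interval = 15, stop_half_lives = 10,
                                  frame_duration = 60,
                                  max_decays_per_frame = 5e5,
                                  max_total_events = 29e6, seed = 1L) {
  if (frame_interval <= 0) stop_domain("frame_interval must be > 0")
  stop_min <- stop_half_lives * phantom$isotope$half_life
  starts <- seq(0, stop_min, by = frame_interval)
  starts <- starts[starts < stop_min]
  frames <- vector("list", length(starts))
  total <- 0
  for (i in seq_along(starts)) {
    fr <- simulate_acquisition(phantom, geom, response, windows,
                               duration = frame_duration,
                               seed = seed + i - 1L,
                               max_decays = max_decays_per_frame,
                               t0_min = starts[i])
    frames[[i]] <- fr
    total <- total + nrow(fr$events)
    if (total >= max_total_events) {
      frames <- frames[seq_len(i)]
      break
    }
  }
  summ <- do.call(rbind, lapply(frames, function(f) {
    data.frame(start_min = f$meta$frame_start_min,
               duration_s = f$duration,
               activity_mid_kbq = f$meta$activity_mid_kbq,
               concentration_kbq_ml = f$meta$concentration_kbq_ml %||% NA_real_,
               n_events = nrow(f$events))
  }))
  attr(frames, "frames") <- summ
  frames
}

#' Simulate the NEMA point-source sensitivity scan
#'
#' Steps a point source along the X axis at the midplane and acquires a
#' fixed number of decays at each position (the equivalent of a fixed-length
#' acquisition at the source's calibrated activity).
#'
#' @param geom a [build_detector()] geometry (separation 60 mm for the
#'   reference protocol).
#' @param response a calibrated [detector_response()].
#' @param windows an [acquisition_windows()].
#' @param source the point source to move (default the 89.9 kBq Na-22
#'   source).
#' @param step step size along X in mm (default 2).
#' @param span full scan span in mm (default 224, i.e. 113 positions).
#' @param n_decays decays per position.
#' @param seed integer seed; each position derives its own sub-seed.
#' @return A list of [listmode_set()] acquisitions with positions stored in
#'   their metadata, plus a `positions` attribute.
#' @export
simulate_sensitivity_scan <- function(geom, response,
                                      windows = acquisition_windows(),
                                      source = point_source(),
                                      step = 2, span = 224,
                                      n_decays = 1e5, seed = 1L) {
  positions <- seq(-span / 2, span / 2, by = step)
  duration <- n_decays / (source$activity_at_start * 1000)
  acqs <- vector("list", length(positions))
  for (i in seq_along(positions)) {
    src <- source
    src$position <- c(positions[i], 0, 0)
    acq <- simulate_acquisition(src, geom, response, windows,
                                duration = duration, seed = seed + i - 1L,
                                include_randoms = FALSE, max_decays = Inf)
    acq$meta$position_mm <- positions[i]
    acqs[[i]] <- acq
  }
  attr(acqs, "positions") <- positions
  acqs
}
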