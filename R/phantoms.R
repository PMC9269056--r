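#' Isotope specification
#'
#' @param name isotope label.
#' @param half_life half-life in minutes.
#' @param positron_branching_ratio fraction of decays emitting a positron,
#'   in (0, 1].
#' @return An object of class `isotope_spec`.
#' @export
isotope_spec <- function(name, half_life, positron_branching_ratio) {
  if (half_life <= 0) stop_validation("half_life must be > 0")
  if (positron_branching_ratio <= 0 || positron_branching_ratio > 1)
    stop_validation("positron_branching_ratio must be in (0, 1]")
  structure(list(name = name, half_life = half_life,
                 positron_branching_ratio = positron_branching_ratio),
            class = "isotope_spec")
}

#' Reference isotopes
#'
#' `F18` (half-life 109.77 min, branching ratio 0.9686) and `NA22`
#' (half-life 2.6018 years, branching ratio 0.9060).
#' @rdname isotopes
#' @export
F18 <- NULL
#' @rdname isotopes
#' @export
NA22 <- NULL

.onLoad <- function(libname, pkgname) {
  ns <- asNamespace(pkgname)
  assign("F18", isotope_spec("F-18", 109.77, 0.9686), envir = ns)
  assign("NA22", isotope_spec("Na-22", 2.6018 * 365.25 * 24 * 60, 0.9060),
         envir = ns)
}

#' Attenuating medium (cylinder)
#'
#' A homogeneous attenuating cylinder with its axis along X, used for the
#' scatter phantom body. Default values describe high-density polyethylene
#' (HDPE, 0.98 g/cm^3) with a 511 keV linear attenuation coefficient of
#' 0.0967 1/cm.
#'
#' @param radius,length cylinder radius and length in mm.
#' @param center length-3 center of the cylinder in mm.
#' @param density g/cm^3 (metadata).
#' @param mu_511 linear attenuation coefficient at 511 keV in 1/cm.
#' @return An object of class `attenuation_medium`.
#' @export
attenuation_medium <- function(radius = 25, length = 150, center = c(0, 0, 0),
                               density = 0.98, mu_511 = 0.0967) {
  if (mu_511 < 0) stop_validation("mu_511 must be >= 0")
  structure(list(radius = radius, length = length, center = center,
                 density = density, mu_511 = mu_511),
            class = "attenuation_medium")
}

new_source_spec <- function(kind, isotope, activity_kbq, fields) {
  if (activity_kbq < 0) stop_validation("activity must be >= 0")
  structure(c(list(kind = kind, isotope = isotope,
                   activity_at_start = activity_kbq), fields),
            class = "source_spec")
}

#' Point source
#'
#' A small spherical source, by default the 0.3 mm diameter Na-22 source of
#' calibrated activity 89.9 kBq used for the resolution and sensitivity
#' protocols. The acrylic carrier cube is geometric support only; no
#' attenuation is modeled for the point source.
#'
#' @param position length-3 source center in mm.
#' @param activity_kbq activity in kBq.
#' @param isotope an [isotope_spec()].
#' @param diameter source diameter in mm.
#' @return A `source_spec` of kind `"point"`.
#' @export
point_source <- function(position = c(0, 0, 0), activity_kbq = 89.9,
                         isotope = NA22, diameter = 0.3) {
  new_source_spec("point", isotope, activity_kbq,
                  list(position = as.numeric(position), diameter = diameter))
}

#' NU-4 rat-sized scatter phantom
#'
#' HDPE cylinder (50 mm diameter x 150 mm, axis along X) with a line-source
#' cavity of 3.5 mm diameter and 142 mm fillable length, offset 17.5 mm
#' radially from the cylinder axis. The offset is placed along +Y (in the
#' detector plane). The volume used for activity-concentration reporting is
#' the nominal 300 mL phantom volume, not the geometric cylinder volume.
#'
#' @param activity_kbq line-source activity in kBq (default 51 MBq).
#' @param isotope an [isotope_spec()] (default F-18).
#' @param offset radial offset of the cavity from the cylinder axis in mm.
#' @param cavity_diameter line-source cavity diameter in mm.
#' @param line_length fillable line length in mm.
#' @param reporting_volume_ml volume (mL) used to convert activity to
#'   concentration.
#' @return A `source_spec` of kind `"line_in_cylinder"` with an attached
#'   `medium` ([attenuation_medium()]).
#' @export
nu4_scatter_phantom <- function(activity_kbq = 51e3, isotope = F18,
                                offset = 17.5, cavity_diameter = 3.5,
                                line_length = 142,
                                reporting_volume_ml = 300) {
  medium <- attenuation_medium(radius = 25, length = 150)
  if (offset + cavity_diameter / 2 > medium$radius)
    stop_validation("line cavity must lie fully inside the cylinder")
  new_source_spec("line_in_cylinder", isotope, activity_kbq,
                  list(offset = offset, cavity_diameter = cavity_diameter,
                       line_length = line_length,
                       reporting_volume_ml = reporting_volume_ml,
                       medium = medium))
}

#' Micro hotspot (Derenzo-type) phantom
#'
#' Six 60-degree sectors of parallel rods (axes along Z), one rod diameter
#' per sector, with center-to-center spacing twice the rod diameter. Rods in
#' each sector form a triangular lattice growing outward from `r_inner`.
#'
#' @param diameters rod diameters in mm, positive and strictly descending.
#'   The default set spans 2.4 mm down to 0.75 mm and includes the 1.7 mm
#'   and 1.35 mm sectors used for the resolvability assessment.
#' @param activity_kbq total activity in kBq (default 1 MBq).
#' @param isotope an [isotope_spec()].
#' @param r_inner,r_outer radial extent of the rod region in mm.
#' @param rod_length active rod length along Z in mm.
#' @return A `source_spec` of kind `"rod_sectors"`; `$rods` is a data frame
#'   with columns `x`, `y`, `diameter`, `sector`.
#' @export
micro_hotspot_phantom <- function(diameters = c(2.4, 2.0, 1.7, 1.35, 1.0, 0.75),
                                  activity_kbq = 1e3, isotope = F18,
                                  r_inner = 5, r_outer = 13.5,
                                  rod_length = 10) {
  if (any(diameters <= 0)) stop_domain("diameters must be positive")
  if (is.unsorted(rev(diameters), strictly = TRUE))
    stop_domain("diameters must be strictly descending")
  ns <- length(diameters)
  sector_width <- 2 * pi / ns
  rods <- list()
  for (k in seq_len(ns)) {
    d <- diameters[k]
    s <- 2 * d                      # center-to-center spacing
    phi <- (k - 1) * sector_width + sector_width / 2
    u <- c(cos(phi), sin(phi))      # sector bisector
    v <- c(-sin(phi), cos(phi))
    hrow <- s * sqrt(3) / 2
    pts <- NULL
    j <- 0
    repeat {
      r <- r_inner + j * hrow
      if (r + d / 2 > r_outer) break
      off <- (seq_len(j + 1) - 1 - j / 2) * s
      pts <- rbind(pts, cbind(r * u[1] + off * v[1], r * u[2] + off * v[2]))
      j <- j + 1
    }
    if (!is.null(pts))
      rods[[k]] <- data.frame(x = pts[, 1], y = pts[, 2], diameter = d,
                              sector = k)
  }
  rods <- do.call(rbind, rods)
  # pairwise overlap check
  if (nrow(rods) > 1) {
    dd <- as.matrix(dist(rods[, c("x", "y")]))
    lim <- outer(rods$diameter, rods$diameter, "+") / 2
    diag(dd) <- Inf
    if (any(dd < lim - 1e-9)) stop_validation("rod layout contains overlapping rods")
  }
  new_source_spec("rod_sectors", isotope, activity_kbq,
                  list(rods = rods, rod_length = rod_length,
                       r_outer = r_outer))
}

#' Uniform flood source
#'
#' A thin uniform planar activity distribution at the midplane covering the
#' sensing area, used for flood calibration acquisitions.
#'
#' @param geom a [build_detector()] geometry.
#' @param activity_kbq activity in kBq.
#' @param isotope an [isotope_spec()].
#' @return A `source_spec` of kind `"flood"`.
#' @export
flood_source <- function(geom, activity_kbq = 1e3, isotope = F18) {
  new_source_spec("flood", isotope, activity_kbq,
                  list(extent_x = geom$head_size_x, extent_y = geom$head_size_y))
}

#' @export
print.source_spec <- function(x, ...) {
  cat(sprintf("source_spec kind=%s isotope=%s activity=%.4g kBq\n",
              x$kind, x$isotope$name, x$activity_at_start))
  invisible(x)
}

#' Radioactive decay of a source
#'
#' @param spec a `source_spec`.
#' @param elapsed elapsed time in minutes (>= 0).
#' @return Activity in kBq: `A0 * 2^(-elapsed / half_life)`.
#' @export
decay_activity <- function(spec, elapsed) {
  if (any(elapsed < 0)) stop_domain("elapsed time must be >= 0")
  spec$activity_at_start * 2^(-elapsed / spec$isotope$half_life)
}

#' Activity concentration of a phantom
#'
#' Activity divided by the phantom's reporting volume (300 mL for the NU-4
#' rat scatter phantom, matching the convention used for count-rate
#' reporting).
#'
#' @param spec a `source_spec` with a `reporting_volume_ml` field.
#' @param activity_kbq activity in kBq (defaults to the start activity).
#' @return Concentration in kBq/mL.
#' @export
activity_concentration <- function(spec, activity_kbq = spec$activity_at_start) {
  vol <- spec$reporting_volume_ml
  if (is.null(vol)) stop_domain("source kind '", spec$kind,
                                "' has no reporting volume")
  activity_kbq / vol
}

#' Sample emission points from a source
#'
#' Uniform sampling over the source's spatial support; deterministic given
#' `seed`.
#'
#' @param spec a `source_spec`.
#' @param n number of points (>= 1).
#' @param seed integer seed (or `NULL` to use the current RNG stream).
#' @return An `n` x 3 matrix of points (mm).
#' @export
sample_emission_points <- function(spec, n, seed = NULL) {
  if (n < 1) stop_domain("n must be >= 1")
  n <- as.integer(n)
  with_seed(seed, switch(spec$kind,
    point = {
      r <- (spec$diameter / 2) * runif(n)^(1 / 3)
      cz <- runif(n, -1, 1)
      phi <- runif(n, 0, 2 * pi)
      sz <- sqrt(pmax(0, 1 - cz^2))
      sweep(cbind(r * sz * cos(phi), r * sz * sin(phi), r * cz), 2,
            spec$position, "+")
    },
    line_in_cylinder = {
      rr <- (spec$cavity_diameter / 2) * sqrt(runif(n))
      th <- runif(n, 0, 2 * pi)
      cbind(runif(n, -spec$line_length / 2, spec$line_length / 2),
            spec$offset + rr * cos(th),
            rr * sin(th))
    },
    rod_sectors = {
      rods <- spec$rods
      w <- rods$diameter^2   # area-proportional
      idx <- sample.int(nrow(rods), n, replace = TRUE, prob = w)
      rr <- (rods$diameter[idx] / 2) * sqrt(runif(n))
      th <- runif(n, 0, 2 * pi)
      cbind(rods$x[idx] + rr * cos(th),
            rods$y[idx] + rr * sin(th),
            runif(n, -spec$rod_length / 2, spec$rod_length / 2))
    },
    flood = cbind(runif(n, -spec$extent_x / 2, spec$extent_x / 2),
                  runif(n, -spec$extent_y / 2, spec$extent_y / 2),
                  rep(0, n)),
    stop_domain("unsupported source kind: ", spec$kind)
  ))
}
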