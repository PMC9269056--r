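#' Build a dual-head planar detector geometry
#'
#' Constructs and validates the geometry of a PET camera made of two opposed
#' planar detector heads. Each head tiles `modules_nx` x `modules_ny` square
#' sensor modules of pitch `module_pitch`; tiling is seamless, so the head
#' sensing area is `module_pitch * modules_nx` by `module_pitch * modules_ny`.
#' The heads face each other across a gap of `separation` along Z, with the
#' origin midway between them (heads at z = +/- separation/2).
#'
#' When `head_size_x`/`head_size_y` are supplied explicitly they must agree
#' with the tiled size to within 1e-9 mm; otherwise they are derived.
#' Sensing-area membership uses half-open intervals `[-L/2, L/2)` so bin
#' membership at the edge is unambiguous.
#'
#' @param separation head-to-head gap along Z in mm (60, 80 or 89 for the
#'   acquisition protocols modeled here).
#' @param module_pitch module pitch in mm (default 57.66).
#' @param modules_nx,modules_ny number of modules tiled along X and Y.
#' @param crystal_pitch crystal pixel pitch in mm (default 2.32).
#' @param crystals_per_module crystals per module side (default 24).
#' @param crystal_thickness crystal depth in mm (default 13).
#' @param housing_offset distance from housing edge to imaging area in mm;
#'   metadata only, it does not clip the sensing area.
#' @param head_size_x,head_size_y optional explicit head sensing extents in
#'   mm; validated against the tiled size.
#' @return An object of class `detector_geometry`.
#' @examples
#' geom <- build_detector(separation = 60)
#' geom$head_size_x  # 230.64
#' @export
build_detector <- function(separation = 60,
                           module_pitch = 57.66,
                           modules_nx = 4L,
                           modules_ny = 3L,
                           crystal_pitch = 2.32,
                           crystals_per_module = 24L,
                           crystal_thickness = 13,
                           housing_offset = 4,
                           head_size_x = NULL,
                           head_size_y = NULL) {
  if (separation <= 0) stop_validation("separation must be > 0, got ", separation)
  if (module_pitch <= 0 || crystal_pitch <= 0 || crystal_thickness <= 0)
    stop_validation("all pitches and thicknesses must be > 0")
  if (modules_nx < 1 || modules_ny < 1 || crystals_per_module < 1)
    stop_validation("module and crystal counts must be positive")

  derived_x <- module_pitch * modules_nx
  derived_y <- module_pitch * modules_ny
  if (!is.null(head_size_x) && abs(head_size_x - derived_x) > 1e-9)
    stop_validation("head_size_x (", head_size_x, " mm) inconsistent with ",
                    "module_pitch x modules_nx (", derived_x, " mm)")
  if (!is.null(head_size_y) && abs(head_size_y - derived_y) > 1e-9)
    stop_validation("head_size_y (", head_size_y, " mm) inconsistent with ",
                    "module_pitch x modules_ny (", derived_y, " mm)")
  crystal_side <- crystal_pitch * crystals_per_module
  if (crystal_side > module_pitch + 1e-9)
    stop_validation("crystal array side (", crystal_side,
                    " mm) exceeds module pitch (", module_pitch, " mm)")

  structure(list(
    head_size_x = derived_x,
    head_size_y = derived_y,
    separation = separation,
    module_pitch = module_pitch,
    modules_nx = as.integer(modules_nx),
    modules_ny = as.integer(modules_ny),
    crystal_pitch = crystal_pitch,
    crystals_per_module = as.integer(crystals_per_module),
    crystal_thickness = crystal_thickness,
    housing_offset = housing_offset
  ), class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat("Dual-head planar detector geometry\n")
  cat(sprintf("  sensing area : %.2f x %.2f mm (%d x %d modules, pitch %.2f mm)\n",
              x$head_size_x, x$head_size_y, x$modules_nx, x$modules_ny,
              x$module_pitch))
  cat(sprintf("  separation   : %g mm (heads at z = +/- %g)\n",
              x$separation, x$separation / 2))
  cat(sprintf("  crystals     : %d x %d per module, %.2f mm pitch, %g mm thick\n",
              x$crystals_per_module, x$crystals_per_module, x$crystal_pitch,
              x$crystal_thickness))
  invisible(x)
}

# TRUE for (x, y) inside the half-open sensing area [-L/2, L/2).
in_sensing_area <- function(x, y, geom) {
  hx <- geom$head_size_x / 2
  hy <- geom$head_size_y / 2
  x >= -hx & x < hx & y >= -hy & y < hy
}

#' Solid angle of a centered rectangle
#'
#' Closed-form solid angle subtended by an `a` x `b` rectangle at a point on
#' its central axis at perpendicular distance `d`.
#'
#' @param a,b rectangle side lengths (mm).
#' @param d perpendicular distance from the point to the rectangle plane (mm).
#' @return Solid angle in steradians.
#' @export
rect_solid_angle <- function(a, b, d) {
  al <- a / (2 * d)
  be <- b / (2 * d)
  4 * atan(al * be / sqrt(1 + al^2 + be^2))
}

# Integral of dtx dty / (1 + tx^2 + ty^2)^(3/2) over the box
# [x1,x2] x [y1,y2] in tangent coordinates t = (dx/|dz|, dy/|dz|);
# equals the solid angle of the corresponding off-axis planar region.
box_solid_angle <- function(x1, x2, y1, y2) {
  f <- function(a, b) atan(a * b / sqrt(1 + a^2 + b^2))
  f(x2, y2) - f(x1, y2) - f(x2, y1) + f(x1, y1)
}

#' Analytic pair geometric acceptance
#'
#' Probability that both annihilation photons of a back-to-back pair emitted
#' isotropically from `point` intercept the sensing areas of the two heads,
#' from the closed-form solid angle of the admissible direction set. No
#' crystal-stopping weighting is applied; this is the purely geometric
#' acceptance used as an analytic cross-check of [pair_geometric_acceptance()]
#' and as the MLEM sensitivity image.
#'
#' @param point numeric length-3 `c(x, y, z)` in mm, or an n x 3 matrix of
#'   points; all points must lie strictly between the head planes.
#' @param geom a [build_detector()] geometry.
#' @return Acceptance probability in `[0, 1]` (vector for a matrix input).
#' @export
pair_acceptance_analytic <- function(point, geom) {
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  h <- geom$separation / 2
  if (any(abs(p[, 3]) >= h))
    stop_domain("points must lie strictly between the head planes")
  hx <- geom$head_size_x / 2
  hy <- geom$head_size_y / 2
  da <- h - p[, 3]  # distance to head A (z = +h)
  db <- h + p[, 3]  # distance to head B (z = -h)
  # Photon along +z hits A at p + da*t; partner hits B at p - db*t.
  ival <- function(lo1, hi1, lo2, hi2) {
    lo <- pmax(lo1, lo2)
    hi <- pmin(hi1, hi2)
    cbind(lo, pmax(lo, hi))
  }
  tx <- ival((-hx - p[, 1]) / da, (hx - p[, 1]) / da,
             (p[, 1] - hx) / db, (p[, 1] + hx) / db)
  ty <- ival((-hy - p[, 2]) / da, (hy - p[, 2]) / da,
             (p[, 2] - hy) / db, (p[, 2] + hy) / db)
  om <- box_solid_angle(tx[, 1], tx[, 2], ty[, 1], ty[, 2])
  # Both hemispheres contribute equally: 2 * omega / (4 pi).
  as.numeric(om / (2 * pi))
}

# Obliquity-weighted acceptance integral at a single point:
#   (1/2pi) * int eff(theta)^2 dOmega over the admissible direction set,
# with eff(theta) = 1 - exp(-sigma_t / cos(theta)) the Beer-Lambert
# interaction probability of a crystal with attenuation sigma_t = mu * depth
# at normal incidence. Used to calibrate the per-photon efficiency scale.
pair_acceptance_weighted <- function(point, geom, sigma_t, n_grid = 400L) {
  p <- as.numeric(point)
  h <- geom$separation / 2
  if (abs(p[3]) >= h) stop_domain("point must lie strictly between the head planes")
  hx <- geom$head_size_x / 2
  hy <- geom$head_size_y / 2
  da <- h - p[3]
  db <- h + p[3]
  txl <- max((-hx - p[1]) / da, (p[1] - hx) / db)
  txh <- min((hx - p[1]) / da, (p[1] + hx) / db)
  tyl <- max((-hy - p[2]) / da, (p[2] - hy) / db)
  tyh <- min((hy - p[2]) / da, (p[2] + hy) / db)
  if (txh <= txl || tyh <= tyl) return(0)
  tx <- seq(txl, txh, length.out = n_grid)
  ty <- seq(tyl, tyh, length.out = n_grid)
  r2 <- 1 + outer(tx^2, ty^2, "+")
  integrand <- r2^(-1.5)
  if (sigma_t > 0 && is.finite(sigma_t)) {
    cost <- 1 / sqrt(r2)           # cos(theta) of the direction
    integrand <- integrand * (1 - exp(-sigma_t / cost))^2
  }
  # trapezoid weights
  wx <- rep(1, n_grid); wx[c(1, n_grid)] <- 0.5
  wy <- rep(1, n_grid); wy[c(1, n_grid)] <- 0.5
  dxy <- (tx[2] - tx[1]) * (ty[2] - ty[1])
  sum(integrand * outer(wx, wy)) * dxy / (2 * pi)
}

#' Head-plane intercepts of a line of response
#'
#' For a back-to-back photon pair emitted from `point` along `direction`,
#' returns the (x, y) intercepts of the two photons on the two head planes,
#' or a miss when either intercept falls outside the sensing area (or the
#' direction is parallel to the heads).
#'
#' @param point numeric length-3 emission point (mm), strictly between the
#'   head planes.
#' @param direction numeric length-3 direction (need not be normalized).
#' @param geom a [build_detector()] geometry.
#' @return A list with `hit` (logical), and when `hit` is `TRUE`, `head_a`
#'   and `head_b`, the `(x, y)` intercepts on the z = +sep/2 and z = -sep/2
#'   planes.
#' @export
lor_head_intercepts <- function(point, direction, geom) {
  p <- as.numeric(point)
  d <- as.numeric(direction)
  if (all(d == 0)) stop_domain("direction must be non-zero")
  h <- geom$separation / 2
  if (abs(p[3]) >= h)
    stop_domain("emission point must lie strictly between the head planes")
  if (d[3] == 0) return(list(hit = FALSE))
  d <- d / sqrt(sum(d^2))
  if (d[3] < 0) d <- -d  # photon 1 is the one moving toward head A
  ta <- (h - p[3]) / d[3]
  tb <- (-h - p[3]) / (-d[3])
  a <- p[1:2] + ta * d[1:2]
  b <- p[1:2] - tb * d[1:2]
  if (!in_sensing_area(a[1], a[2], geom) || !in_sensing_area(b[1], b[2], geom))
    return(list(hit = FALSE))
  list(hit = TRUE, head_a = a, head_b = b)
}

#' Monte Carlo pair geometric acceptance
#'
#' Estimates, by isotropic direction sampling, the probability that both
#' annihilation photons from `point` intercept the two sensing areas.
#' Deterministic given `seed`.
#'
#' @inheritParams pair_acceptance_analytic
#' @param n_samples number of sampled directions (>= 1).
#' @param seed integer seed.
#' @return Acceptance estimate in `[0, 1]`.
#' @export
pair_geometric_acceptance <- function(point, geom, n_samples = 1e5, seed = 1L) {
  if (n_samples < 1) stop_domain("n_samples must be >= 1")
  p <- as.numeric(point)
  h <- geom$separation / 2
  if (abs(p[3]) >= h) {
    # Point outside the gap in z sees no LOR at all; points wildly outside
    # the XY extent are handled by the intercept test below.
    stop_domain("point must lie strictly between the head planes")
  }
  with_seed(seed, {
    n <- as.integer(n_samples)
    cz <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    sz <- sqrt(pmax(0, 1 - cz^2))
    dx <- sz * cos(phi); dy <- sz * sin(phi); dz <- cz
    ok <- dz != 0
    # fold: photon 1 toward head A
    s <- sign(dz)
    dx <- dx * s; dy <- dy * s; dz <- abs(dz)
    ta <- (h - p[3]) / dz
    tb <- (h + p[3]) / dz
    ax <- p[1] + ta * dx; ay <- p[2] + ta * dy
    bx <- p[1] - tb * dx; by <- p[2] - tb * dy
    hit <- ok & in_sensing_area(ax, ay, geom) & in_sensing_area(bx, by, geom)
    mean(hit)
  })
}
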