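#' Conical cercus segment
#'
#' Constructs the geometric domain of the modeled cercus segment: a right
#' circular cone frustum, together with its flattened (filet) representation.
#' The flattened sheet puts axial position on the x axis (0 at the base) and
#' the circumferential position on the y axis; the sheet is cut along the
#' medial lineage restriction line, so the lateral line runs along y = 0 and
#' the two sheet edges are the same (medial) line. The sheet height tapers
#' linearly from `base_height_flat` at the base to `tip_height_flat` at the
#' far end of the segment.
#'
#' Defaults describe the basal segment of a typical adult cercus: 5.2 mm
#' long, 0.54 mm diameter at the base narrowing to 0.26 mm, with the
#' flattened sheet tapering from 1.7 mm down to 0.8 mm.
#'
#' @param axial_length segment length along the cone axis, mm.
#' @param base_radius,tip_radius cone radii at the base and at the far end,
#'   mm; `base_radius > tip_radius > 0`.
#' @param base_height_flat,tip_height_flat heights of the flattened sheet at
#'   the two ends, mm. These should equal the local circumferences
#'   (2*pi*radius); a discrepancy beyond 3% triggers a warning, not an
#'   error, since published filet measurements are approximate.
#'
#' @return An object of class `cone_domain`.
#' @examples
#' dom <- cone_domain()
#' local_height(dom, c(0, 2.6, 5.2))
#' @export
cone_domain <- function(axial_length = 5.2,
                        base_radius = 0.27,
                        tip_radius = 0.13,
                        base_height_flat = 1.7,
                        tip_height_flat = 0.8) {
  stopifnot(is.numeric(axial_length), length(axial_length) == 1L,
            is.finite(axial_length), axial_length > 0,
            is.numeric(base_radius), is.numeric(tip_radius),
            base_radius > tip_radius, tip_radius > 0)
  for (side in list(c(base_height_flat, base_radius, "base"),
                    c(tip_height_flat, tip_radius, "tip"))) {
    h <- as.numeric(side[[1]]); r <- as.numeric(side[[2]])
    rel <- abs(h - 2 * pi * r) / (2 * pi * r)
    if (rel > 0.03) {
      warning(sprintf(
        "flattened height at the %s (%.3f mm) differs from the local circumference (%.3f mm) by %.1f%%",
        side[[3]], h, 2 * pi * r, 100 * rel))
    }
  }
  slope <- (base_radius - tip_radius) / axial_length   # dr/dx, > 0
  k <- sqrt(1 + slope^2)                               # slant per unit axial
  structure(list(
    axial_length = axial_length,
    base_radius = base_radius,
    tip_radius = tip_radius,
    base_height_flat = base_height_flat,
    tip_height_flat = tip_height_flat,
    apex_axial = axial_length * base_radius / (base_radius - tip_radius),
    slant_factor = k,
    sin_half_angle = slope / k
  ), class = "cone_domain")
}

#' @export
print.cone_domain <- function(x, ...) {
  cat(sprintf(
    "cone frustum: %.3g mm long, radius %.3g -> %.3g mm (flat sheet %.3g -> %.3g mm)\n",
    x$axial_length, x$base_radius, x$tip_radius,
    x$base_height_flat, x$tip_height_flat))
  invisible(x)
}

check_axial <- function(domain, axial) {
  if (any(!is.finite(axial)) ||
      any(axial < -1e-9) || any(axial > domain$axial_length + 1e-9)) {
    stop("axial coordinate outside [0, ", domain$axial_length, "] mm",
         call. = FALSE)
  }
  pmin(pmax(axial, 0), domain$axial_length)
}

#' Height of the flattened sheet at an axial position
#'
#' Linear interpolation between the base and tip heights of the flattened
#' trapezoid.
#'
#' @param domain a [cone_domain()].
#' @param axial axial position(s), mm, in `[0, axial_length]`.
#' @return Height(s) in mm.
#' @export
local_height <- function(domain, axial) {
  axial <- check_axial(domain, axial)
  f <- axial / domain$axial_length
  domain$base_height_flat + f * (domain$tip_height_flat - domain$base_height_flat)
}

#' Cone radius at an axial position
#' @inheritParams local_height
#' @return Radius/radii in mm.
#' @export
local_radius <- function(domain, axial) {
  axial <- check_axial(domain, axial)
  f <- axial / domain$axial_length
  domain$base_radius + f * (domain$tip_radius - domain$base_radius)
}

#' Area of the modeled surface
#'
#' Area of the flattened trapezoid (axial length times mean sheet height),
#' used as the region area in Ripley's K/L and for uniform-density sampling.
#'
#' @param domain a [cone_domain()].
#' @return Area in mm^2.
#' @export
surface_area <- function(domain) {
  domain$axial_length *
    (domain$base_height_flat + domain$tip_height_flat) / 2
}

#' Canonicalize circumferential coordinates and angles
#'
#' The circumferential coordinate is a signed fraction: 0 on the lateral
#' lineage restriction line, +1 and -1 both on the medial line (the same
#' physical points; the canonical range is `(-1, 1]`). Angles are degrees in
#' `(-180, 180]`, with 0 pointing toward the cercus tip along the +axial
#' direction of the flattened sheet.
#'
#' @param u circumferential fractions (any real).
#' @return Values wrapped into `(-1, 1]`.
#' @export
wrap_circum <- function(u) {
  w <- u %% 2
  w[w > 1] <- w[w > 1] - 2
  w
}

#' @rdname wrap_circum
#' @param theta angles in degrees (any real).
#' @return `wrap_angle`: values wrapped into `(-180, 180]`.
#' @export
wrap_angle <- function(theta) {
  w <- theta %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Embed surface points in 3-D
#'
#' Maps flattened surface coordinates onto the cone in a fixed frame: the
#' first axis is the cone axis pointing from base to tip, the second axis
#' points radially outward through the lateral restriction line
#' (`circum = 0`), and the third completes a right-handed frame. The azimuth
#' around the axis is `pi * circum`, so `circum = +1` and `circum = -1` map
#' to the same point on the medial line.
#'
#' @param domain a [cone_domain()].
#' @param axial,circum surface coordinates (recycled to a common length).
#'   `circum` may be unwrapped (outside `(-1, 1]`); only its azimuth matters.
#' @return An `n x 3` matrix of points in mm.
#' @export
cone_to_3d <- function(domain, axial, circum) {
  n <- max(length(axial), length(circum))
  axial <- rep_len(axial, n); circum <- rep_len(circum, n)
  r <- local_radius(domain, axial)
  phi <- pi * circum
  cbind(axial, r * cos(phi), r * sin(phi), deparse.level = 0)
}

## Unrolled-cone polar coordinates: the frustum unrolls to an annular
## sector about the apex.  rho is the slant distance from the apex, and one
## full turn of azimuth maps to an unrolled angle of 2*pi*sin_half_angle.
unroll_rho <- function(domain, axial) {
  (domain$apex_axial - axial) * domain$slant_factor
}

#' Exact geodesic distance on the cone
#'
#' The frustum is a developable surface: cutting it along a generator and
#' unrolling it into a planar annular sector is an isometry, so the geodesic
#' between two surface points is the straight chord between their unrolled
#' images. The chord is evaluated for both circumferential winding
#' directions and the shorter one is returned. Because the default domain
#' unrolls to a very narrow sector (under 10 degrees for a full turn),
#' chords never leave the sector and the construction is always valid.
#'
#' This closed form is the distance kernel used throughout the package; the
#' stepwise [geodesic_numeric()] reproduces the discretized evaluation used
#' in the original simulations and is checked against this oracle.
#'
#' @param domain a [cone_domain()].
#' @param axial1,circum1,axial2,circum2 coordinates of the two point sets,
#'   recycled to a common length.
#' @return Geodesic distance(s), mm.
#' @examples
#' dom <- cone_domain()
#' geodesic_analytic(dom, 1, 0, 2, 0)  # a generator: the slant length
#' @export
geodesic_analytic <- function(domain, axial1, circum1, axial2, circum2) {
  n <- max(length(axial1), length(circum1), length(axial2), length(circum2))
  axial1 <- rep_len(axial1, n); circum1 <- rep_len(circum1, n)
  axial2 <- rep_len(axial2, n); circum2 <- rep_len(circum2, n)
  rho1 <- unroll_rho(domain, check_axial(domain, axial1))
  rho2 <- unroll_rho(domain, check_axial(domain, axial2))
  du <- abs(circum1 - circum2) %% 2
  du <- pmin(du, 2 - du)                       # shorter winding
  psi <- pi * domain$sin_half_angle * du       # unrolled angle between them
  sqrt((rho1 - rho2)^2 + 4 * rho1 * rho2 * sin(psi / 2)^2)
}

#' Stepwise geodesic distance on the cone
#'
#' Discretizes the straight segment between the two points in
#' (axial, unwrapped circumferential fraction) parameter space into `steps`
#' equal increments, maps every node onto the cone with [cone_to_3d()], and
#' sums the Euclidean chord lengths. Both circumferential windings are
#' evaluated and the shorter polyline is returned. With the default 100
#' steps this agrees with [geodesic_analytic()] to well under 1% on the
#' default domain.
#'
#' @inheritParams geodesic_analytic
#' @param steps number of discrete steps (>= 1).
#' @return Geodesic distance(s), mm.
#' @export
geodesic_numeric <- function(domain, axial1, circum1, axial2, circum2,
                             steps = 100L) {
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 1L) stop("steps must be >= 1", call. = FALSE)
  n <- max(length(axial1), length(circum1), length(axial2), length(circum2))
  axial1 <- rep_len(axial1, n); circum1 <- rep_len(circum1, n)
  axial2 <- rep_len(axial2, n); circum2 <- rep_len(circum2, n)
  check_axial(domain, axial1); check_axial(domain, axial2)
  tt <- seq(0, 1, length.out = steps + 1L)
  polyline <- function(x1, u1, x2, u2) {
    pts <- cone_to_3d(domain, x1 + tt * (x2 - x1), u1 + tt * (u2 - u1))
    sum(sqrt(rowSums(diff(pts)^2)))
  }
  vapply(seq_len(n), function(i) {
    du <- circum2[i] - circum1[i]
    # the two winding directions, as unwrapped circumferential spans
    spans <- if (du == 0) 0 else c(du %% 2, du %% 2 - 2)
    min(vapply(spans, function(s)
      polyline(axial1[i], circum1[i], axial2[i], circum1[i] + s),
      numeric(1)))
  }, numeric(1))
}

#' Pairwise geodesic distance matrix
#'
#' All pairwise exact geodesic distances between surface points, computed
#' from the unrolled-cone chord formula.
#'
#' @param domain a [cone_domain()].
#' @param axial,circum coordinate vectors of equal length n.
#' @return A symmetric `n x n` matrix, mm, zero diagonal.
#' @export
geodesic_matrix <- function(domain, axial, circum) {
  stopifnot(length(axial) == length(circum))
  rho <- unroll_rho(domain, check_axial(domain, axial))
  du <- abs(outer(circum, circum, "-")) %% 2
  du <- pmin(du, 2 - du)
  psi <- pi * domain$sin_half_angle * du
  d <- sqrt(outer(rho, rho, "-")^2 + 4 * outer(rho, rho) * sin(psi / 2)^2)
  diag(d) <- 0
  d
}
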