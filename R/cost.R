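#' Hair configurations
#'
#' A hair configuration is an ordered set of filiform hairs on a cone
#' domain: each hair has a surface position (`axial` mm, `circum` signed
#' fraction in `(-1, 1]`) and an excitatory movement direction `theta`
#' (degrees in `(-180, 180]`, 0 pointing toward the cercus tip in the
#' flattened sheet). Stored as a data frame with the domain attached.
#'
#' @param axial,circum,theta numeric vectors of equal length.
#' @param domain a [cone_domain()].
#' @return An object of classes `hair_config` and `data.frame`.
#' @export
hair_config <- function(axial, circum, theta, domain = cone_domain()) {
  stopifnot(inherits(domain, "cone_domain"),
            length(axial) == length(circum),
            length(axial) == length(theta))
  check_axial(domain, axial)
  df <- data.frame(axial = as.numeric(axial),
                   circum = wrap_circum(as.numeric(circum)),
                   theta = wrap_angle(as.numeric(theta)))
  structure(df, domain = domain, class = c("hair_config", "data.frame"))
}

#' @export
print.hair_config <- function(x, ...) {
  cat(sprintf("hair_config: %d hairs on a %.3g mm cercus segment\n",
              nrow(x), attr(x, "domain")$axial_length))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' @export
#' @rdname hair_config
#' @param x a `hair_config`.
n_hairs <- function(x) nrow(x)

config_domain <- function(config) attr(config, "domain")

#' Spacing decay length along the cercus
#'
#' The spacing morphogen's characteristic decay length, interpolated
#' linearly from `lambda_base` at the cercus base to `lambda_tip` at the
#' end of the modeled segment. The gradient reproduces the observed axial
#' density gradient: a longer decay length near the tip spreads hairs
#' further apart there.
#'
#' @param params a [model_params()].
#' @param domain a [cone_domain()].
#' @param axial axial position(s), mm.
#' @return Decay length(s), mm.
#' @export
lambda_s <- function(params, domain, axial) {
  axial <- check_axial(domain, axial)
  params$lambda_base +
    (params$lambda_tip - params$lambda_base) * axial / domain$axial_length
}

#' Spacing (inhibition) cost between two hairs
#'
#' The spacing morphogen diffuses from each hair socket with first-order
#' decay, so its normalized concentration at geodesic distance r is
#' `exp(-r / lambda)`, with lambda evaluated at the midpoint axial
#' coordinate of the pair (keeping the term symmetric while letting the
#' decay length vary along the cercus). The inhibition acts over a finite
#' range: hairs farther apart than `spacing_range * lambda` (one decay
#' length by default) contribute nothing, so each hair effectively
#' interacts with its first neighbour shell of roughly six hairs, and the
#' per-hair spacing cost sits in the 6 * exp(-0.3) ~ 4.4 regime.
#'
#' @param params a [model_params()].
#' @param domain a [cone_domain()].
#' @param axial1,circum1,axial2,circum2 coordinates of the two hairs
#'   (vectorized).
#' @return Cost(s) in `[0, 1]`.
#' @export
pair_cost <- function(params, domain, axial1, circum1, axial2, circum2) {
  r <- geodesic_analytic(domain, axial1, circum1, axial2, circum2)
  lam <- lambda_s(params, domain, (axial1 + axial2) / 2)
  ifelse(r < params$spacing_range * lam, exp(-r / lam), 0)
}

# TRUE for hairs strictly inside the ventral half (hairs exactly on the
# lateral line, circum == 0, or the medial line, circum == 1, are on the
# compartment boundary and belong to neither half)
ventral_mask <- function(params, circum) {
  s <- sign(circum)
  s[circum == 1] <- 0
  s == params$ventral_sign
}

#' Movement-direction morphogen response
#'
#' The direction morphogen is released from both lineage restriction lines
#' and decays exponentially (decay constant `lambda_m` in fractional-distance
#' units). Its two-source concentration profile is rescaled to sit at 1 on
#' both restriction lines and 0 midway between them:
#' `raw(x) = exp(-x/lambda_m) + exp(-(1-x)/lambda_m)`, then
#' `norm(x) = (raw(x) - raw(0.5)) / (raw(0) - raw(0.5))`. The angular
#' response of the target cells saturates at high concentration
#' (first-order receptor occupancy), which is modeled by clipping:
#' `m(x) = min(1, norm(x) / m_saturation)`. The saturated plateau around
#' each restriction line is what gives the arrays their wide bands of
#' longitudinally moving hairs.
#'
#' @param params a [model_params()].
#' @param x fractional distance from the medial restriction line, in
#'   `[0, 1]` (0 = medial line, 1 = lateral line).
#' @return Normalized response(s) in `[0, 1]`: 1 on both lines, 0 midway.
#' @export
m_concentration <- function(params, x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("fractional distance x must lie in [0, 1]", call. = FALSE)
  }
  raw <- function(z) exp(-z / params$lambda_m) + exp(-(1 - z) / params$lambda_m)
  norm <- (raw(x) - raw(0.5)) / (raw(0) - raw(0.5))
  pmin(1, norm / params$m_saturation)
}

#' Movement axis prescribed by the morphogen field
#'
#' High response (on either restriction line) prescribes a longitudinal
#' movement axis (0 degrees, equivalently +/-180); low response (midway
#' between the lines) prescribes a transverse axis (+/-90). The prescribed
#' axis is `90 * (1 - m)` degrees, interpreted modulo 180 (an axis, not a
#' signed direction). Note that under the weighted [angle_cost()] the
#' cost-minimizing axis snaps to the nearer of 0 and 90 (the longitudinal
#' band is `m > 1/2`, the transverse band `m < 1/2`); this function gives
#' the graded axis the response interpolates through.
#'
#' @param params a [model_params()].
#' @param circum circumferential fraction(s) in `(-1, 1]` (0 lateral,
#'   +/-1 medial). The field does not vary axially.
#' @return Prescribed axis in degrees, in `[0, 90]`.
#' @export
prescribed_angle <- function(params, circum) {
  x_m <- 1 - abs(wrap_circum(circum))   # fractional distance from medial line
  90 * (1 - m_concentration(params, x_m))
}

#' Alignment cost of a single hair
#'
#' The direction morphogen penalizes deviation from the longitudinal axis
#' where its response is high and from the transverse axis where it is low,
#' weighting the two sine terms by the local response:
#' `c1 * (1 - a_star * V) * (m * |sin(theta - 0)| + (1 - m) * |sin(theta - 90)|)`.
#' Both terms are sines of an angle difference, so a 180-degree flip is
#' never penalized (the morphogen sets the movement axis only, not which
#' direction along it excites the neuron) and the bracket never exceeds 1.
#' On the restriction lines (`m = 1`) the cost reduces to `c1 * |sin(theta)|`
#' and midway between them (`m = 0`) to `c1 * |cos(theta)|`; in the
#' transition zones the minimum over theta is `c1 * min(m, 1 - m) > 0`, an
#' irreducible residue.
#'
#' `V` is 1 for hairs moving at a positive angle (`theta` in (0, 180))
#' while located in the ventral half (`sign(circum) == ventral_sign`):
#' their alignment cost is lowered by the fraction `a_star`, favouring
#' positive movement directions on the ventral surface. (The density shift
#' itself comes from the matching ventral weight on the spacing term; see
#' [hair_cost()].)
#'
#' @param params a [model_params()].
#' @param theta movement direction(s), degrees.
#' @param circum circumferential fraction(s).
#' @return Cost(s) in `[0, c1]`.
#' @export
angle_cost <- function(params, theta, circum) {
  theta <- wrap_angle(theta)
  circum <- wrap_circum(circum)
  m <- m_concentration(params, 1 - abs(circum))
  v <- as.numeric(theta > 0 & theta < 180 &
                    sign(circum) == params$ventral_sign)
  th <- theta * pi / 180
  params$c1 * (1 - params$a_star * v) *
    (m * abs(sin(th)) + (1 - m) * abs(cos(th)))
}

#' Cost contributions of one hair and of the whole array
#'
#' The cost of hair i is the sum of its spacing interactions with every
#' other hair, scaled by the ventral correction, plus its own alignment
#' term:
#' `E_i = (1 - a_star * W_i) * sum_{j != i} pair_cost(i, j) + angle_cost(i)`,
#' where `W_i` is 1 for hairs in the ventral half. Lowering the spacing
#' cost of ventral hairs lets the ventral hemi-cone pack them slightly
#' denser, reproducing the observed ventral/dorsal density ratio of about
#' 1.22 at `a_star = 0.1`.
#' The total cost is the literal sum of `E_i` over all hairs, so each
#' unordered pair contributes twice (once in `E_i`, once in `E_j`, each
#' side carrying its own hair's ventral weight); the greedy optimizer is
#' unaffected by this double counting.
#'
#' @param params a [model_params()].
#' @param config a [hair_config()].
#' @param i hair index (1-based).
#' @return `hair_cost`: the scalar `E_i`; `total_cost`: the scalar `E`.
#' @export
hair_cost <- function(params, config, i) {
  n <- nrow(config)
  if (length(i) != 1L || is.na(i) || i < 1L || i > n) {
    stop("hair index out of range", call. = FALSE)
  }
  dom <- config_domain(config)
  j <- setdiff(seq_len(n), i)
  pc <- if (length(j) == 0) 0 else
    sum(pair_cost(params, dom,
                  config$axial[i], config$circum[i],
                  config$axial[j], config$circum[j]))
  w <- 1 - params$a_star * ventral_mask(params, config$circum[i])
  w * pc + angle_cost(params, config$theta[i], config$circum[i])
}

#' @rdname hair_cost
#' @export
total_cost <- function(params, config) {
  n <- nrow(config)
  if (n == 0L) return(0)
  dom <- config_domain(config)
  ang <- sum(angle_cost(params, config$theta, config$circum))
  if (n == 1L) return(ang)
  d <- geodesic_matrix(dom, config$axial, config$circum)
  lam_mid <- lambda_s(params, dom, outer(config$axial, config$axial, "+") / 2)
  pm <- ifelse(d < params$spacing_range * lam_mid, exp(-d / lam_mid), 0)
  diag(pm) <- 0
  w <- 1 - params$a_star * ventral_mask(params, config$circum)
  sum(w * rowSums(pm)) + ang
}

#' Incremental cost change for a single-hair move
#'
#' Change in the total cost when hair `i` is relocated to
#' (`new_axial`, `new_circum`) and rotated to `new_theta`, evaluated
#' incrementally: the change in the hair's alignment term, in its own
#' ventrally weighted spacing sum, and in every other hair's weighted pair
#' term with it (each pair appears in both hairs' `E_i`). Agrees with
#' recomputing [total_cost()] to floating-point accuracy, at O(N) instead
#' of O(N^2) cost.
#'
#' @param params a [model_params()].
#' @param config a [hair_config()].
#' @param i index of the hair to move.
#' @param new_axial,new_circum,new_theta proposed position and direction.
#' @return The scalar change `E_after - E_before`.
#' @export
delta_cost_move <- function(params, config, i, new_axial, new_circum,
                            new_theta) {
  n <- nrow(config)
  if (length(i) != 1L || is.na(i) || i < 1L || i > n) {
    stop("hair index out of range", call. = FALSE)
  }
  dom <- config_domain(config)
  check_axial(dom, new_axial)
  new_circum <- wrap_circum(new_circum)
  d_ang <- angle_cost(params, new_theta, new_circum) -
    angle_cost(params, config$theta[i], config$circum[i])
  j <- setdiff(seq_len(n), i)
  if (length(j) == 0L) return(d_ang)
  f_old <- pair_cost(params, dom,
                     config$axial[i], config$circum[i],
                     config$axial[j], config$circum[j])
  f_new <- pair_cost(params, dom,
                     new_axial, new_circum,
                     config$axial[j], config$circum[j])
  w_old <- 1 - params$a_star * ventral_mask(params, config$circum[i])
  w_new <- 1 - params$a_star * ventral_mask(params, new_circum)
  w_j <- 1 - params$a_star * ventral_mask(params, config$circum[j])
  d_ang + (w_new * sum(f_new) - w_old * sum(f_old)) +
    sum(w_j * (f_new - f_old))
}
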