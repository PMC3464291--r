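#' Model parameters
#'
#' Collects every constant of the two-morphogen cost model and of the Monte
#' Carlo search. Defaults are the values used for the reference simulations:
#' 300 hairs, spacing/alignment balance `c1 = 10`, ventral correction
#' `a_star = 0.1`, `1e5` proposals, and a spacing decay length rising
#' linearly from 0.2 mm at the cercus base to 0.4 mm at the end of the
#' segment.
#'
#' @param n_hairs number of hairs in the array (fixed during optimization).
#' @param c1 weight of the alignment term relative to the spacing term
#'   (dimensionless, >= 0). At `c1 = 10` a misalignment above roughly 5
#'   degrees dominates the six-neighbour spacing term.
#' @param a_star ventral correction in `[0, 1)`: the alignment cost of a
#'   hair moving at a positive angle while located in the ventral half is
#'   multiplied by `1 - a_star`, which biases hair accumulation ventrally.
#' @param p_iterations number of Monte Carlo proposals P (accepted or not).
#' @param lambda_base,lambda_tip decay length of the spacing morphogen at
#'   the base and at the end of the domain, mm; interpolated linearly along
#'   the axis (about half the local inter-hair distance).
#' @param spacing_range range of the spacing interaction in units of the
#'   local decay length: hairs farther apart than
#'   `spacing_range * lambda` do not interact. At the default of 1 each
#'   hair interacts with its first neighbour shell (about six hairs), and
#'   the per-hair spacing cost sits near the 6 * exp(-0.3) ~ 4.4 regime
#'   that balances against the alignment term at c1 = 10.
#' @param lambda_m decay constant of the movement-direction morphogen, in
#'   units of fractional distance between the restriction lines.
#' @param m_saturation fraction of the on-line concentration at which the
#'   angular response to the direction morphogen saturates (receptor
#'   saturation); the normalized concentration is clipped at
#'   `norm / m_saturation`. Controls the width of the longitudinal bands.
#' @param ventral_sign +1 or -1: which sign of the circumferential
#'   coordinate is the ventral half.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @param log_stride record the running cost every `log_stride` proposals.
#'
#' @return An object of class `model_params`.
#' @export
model_params <- function(n_hairs = 300L,
                         c1 = 10,
                         a_star = 0.1,
                         p_iterations = 1e5,
                         lambda_base = 0.2,
                         lambda_tip = 0.4,
                         spacing_range = 1,
                         lambda_m = 0.2,
                         m_saturation = 0.4,
                         ventral_sign = 1L,
                         seed = NULL,
                         log_stride = 100L) {
  n_hairs <- as.integer(n_hairs)
  p_iterations <- as.numeric(p_iterations)
  stopifnot(n_hairs >= 0L,
            is.numeric(c1), length(c1) == 1L, c1 >= 0,
            is.numeric(a_star), a_star >= 0, a_star < 1,
            p_iterations >= 0, p_iterations == floor(p_iterations),
            lambda_base > 0, lambda_tip > 0, spacing_range > 0,
            lambda_m > 0,
            m_saturation > 0, m_saturation <= 1,
            ventral_sign %in% c(-1, 1),
            log_stride >= 1)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(!is.na(seed))
  }
  structure(list(
    n_hairs = n_hairs, c1 = c1, a_star = a_star,
    p_iterations = p_iterations,
    lambda_base = lambda_base, lambda_tip = lambda_tip,
    spacing_range = spacing_range,
    lambda_m = lambda_m, m_saturation = m_saturation,
    ventral_sign = as.integer(ventral_sign),
    seed = seed,
    log_stride = as.integer(log_stride)
  ), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "model_params: N=%d, c1=%g, a*=%g, P=%g, lambda %g->%g mm, lambda_m=%g, ventral=%+d%s\n",
    x$n_hairs, x$c1, x$a_star, x$p_iterations,
    x$lambda_base, x$lambda_tip, x$lambda_m, x$ventral_sign,
    if (is.null(x$seed)) "" else sprintf(", seed=%d", x$seed)))
  invisible(x)
}
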