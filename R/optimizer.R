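#' Sample hair positions uniformly over the surface
#'
#' Draws positions uniformly per unit area of the flattened trapezoid:
#' axial positions are drawn with density proportional to the local sheet
#' height (inverse-CDF of the trapezoid profile), circumferential fractions
#' uniformly over (-1, 1). Uses R's RNG stream.
#'
#' @param n number of points.
#' @param domain a [cone_domain()].
#' @return A list with numeric vectors `axial` and `circum`.
#' @export
sample_positions <- function(n, domain) {
  q <- runif(n)
  h0 <- domain$base_height_flat
  h1 <- domain$tip_height_flat
  L <- domain$axial_length
  cc <- (h1 - h0) / L
  I <- L * (h0 + h1) / 2
  axial <- if (abs(cc) < 1e-12) q * L else
    (-h0 + sqrt(h0^2 + 2 * cc * q * I)) / cc
  axial <- pmin(pmax(axial, 0), L)
  list(axial = axial, circum = runif(n, -1, 1))
}

#' Random initial hair array
#'
#' The starting state of the Monte Carlo search: `n_hairs` hairs placed
#' uniformly at random over the surface, each with a movement direction
#' drawn uniformly over the full circle.
#'
#' @param params a [model_params()] (only `n_hairs` is used here).
#' @param domain a [cone_domain()].
#' @return A [hair_config()].
#' @export
initialize_hairs <- function(params, domain = cone_domain()) {
  pos <- sample_positions(params$n_hairs, domain)
  hair_config(pos$axial, pos$circum,
              runif(params$n_hairs, -180, 180), domain)
}

#' Propose a single-hair move
#'
#' One Monte Carlo proposal: a uniformly chosen hair is assigned a fresh
#' position drawn exactly as in [initialize_hairs()] (a global re-draw, not
#' a local perturbation) and its direction is rotated by an increment
#' uniform over (-180, 180].
#'
#' @param config a non-empty [hair_config()].
#' @return A list with `index`, `axial`, `circum`, `theta`.
#' @export
propose_move <- function(config) {
  n <- nrow(config)
  if (n == 0L) stop("cannot propose a move on an empty configuration",
                    call. = FALSE)
  idx <- sample.int(n, 1L)
  pos <- sample_positions(1L, config_domain(config))
  list(index = idx, axial = pos$axial, circum = pos$circum,
       theta = wrap_angle(config$theta[idx] + runif(1, -180, 180)))
}

#' Run the greedy Monte Carlo search
#'
#' Seeds `n_hairs` hairs uniformly at random, then performs exactly
#' `p_iterations` proposals (each a global relocation plus rotation of one
#' random hair), accepting a proposal if and only if it strictly decreases
#' the total cost. P counts proposals, accepted or not; the choice of P
#' regulates how much of the initial randomness survives in the final
#' array (small P leaves it nearly random, very large P approaches the
#' fully ordered optimum).
#'
#' Given a `seed` in `params`, the run is fully deterministic.
#'
#' @param params a [model_params()].
#' @param domain a [cone_domain()].
#' @return An object of class `run_record`: a list with `initial_config`,
#'   `final_config`, `cost_trace` (data frame of proposal index and running
#'   total cost at `log_stride` intervals), `accepted_count`, `e_initial`,
#'   `e_final`, `params`, and `domain`.
#' @examples
#' rec <- run_model(model_params(n_hairs = 40, p_iterations = 500, seed = 1),
#'                  cone_domain())
#' rec$e_initial; rec$e_final
#' @export
run_model <- function(params, domain = cone_domain()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  init <- initialize_hairs(params, domain)
  res <- .mc_run(init$axial, init$circum, init$theta,
                 unclass(domain), unclass(params),
                 params$p_iterations, params$log_stride)
  final <- hair_config(res$axial, res$circum, res$theta, domain)
  structure(list(
    initial_config = init,
    final_config = final,
    cost_trace = data.frame(proposal = res$trace_proposal,
                            cost = res$trace_cost),
    accepted_count = res$accepted,
    e_initial = res$e_initial,
    e_final = res$e_final,
    e_final_recomputed = res$e_final_recomputed,
    params = params,
    domain = domain
  ), class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf(
    "run_record: N=%d, P=%g, accepted %d moves, cost %.2f -> %.2f\n",
    nrow(x$final_config), x$params$p_iterations,
    as.integer(x$accepted_count), x$e_initial, x$e_final))
  invisible(x)
}
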