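# Shared fixtures: the default cercus segment and small parameter sets used
# across the test files. Heavier simulations set their own seeds locally.

default_domain <- function() cone_domain()

quick_params <- function(...) {
  model_params(n_hairs = 20L, p_iterations = 500, ...)
}

# random surface points on a domain, using the current RNG state
random_points <- function(n, domain = default_domain()) {
  list(axial = runif(n, 0, domain$axial_length),
       circum = runif(n, -1, 1))
}

# solve for the circumferential offset at fixed axial position that puts two
# hairs at a prescribed geodesic distance
circum_offset_at_distance <- function(domain, axial, dist) {
  stats::uniroot(function(du) {
    geodesic_analytic(domain, axial, 0, axial, du) - dist
  }, c(1e-9, 1), tol = 1e-13)$root
}
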