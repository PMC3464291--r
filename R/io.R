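#' Read and write hair tables
#'
#' A hair table is a tab-separated text file with a header and one row per
#' hair: `axial_mm`, `circum_frac` (signed fraction in (-1, 1]), and
#' `theta_deg` (degrees in (-180, 180]). Writing and re-reading a
#' configuration reproduces it to better than 1e-9.
#'
#' @param config a [hair_config()].
#' @param path file path.
#' @export
write_hair_table <- function(config, path) {
  df <- data.frame(axial_mm = config$axial,
                   circum_frac = config$circum,
                   theta_deg = config$theta)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hair_table
#' @param domain the [cone_domain()] the positions live on.
#' @return `read_hair_table`: a validated [hair_config()].
#' @export
read_hair_table <- function(path, domain = cone_domain()) {
  if (!file.exists(path)) stop("hair table not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = TRUE)
  needed <- c("axial_mm", "circum_frac", "theta_deg")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("hair table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(hair_config(numeric(0), numeric(0), numeric(0), domain))
  }
  num <- lapply(df[needed], function(col) suppressWarnings(as.numeric(col)))
  for (col in needed) {
    bad <- which(!is.finite(num[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value in column %s at row %d", col, bad[1]),
           call. = FALSE)
    }
  }
  bad <- which(num$axial_mm < 0 | num$axial_mm > domain$axial_length)
  if (length(bad) > 0) {
    stop(sprintf("axial_mm out of [0, %g] at row %d",
                 domain$axial_length, bad[1]), call. = FALSE)
  }
  bad <- which(num$circum_frac < -1 | num$circum_frac > 1)
  if (length(bad) > 0) {
    stop(sprintf("circum_frac out of [-1, 1] at row %d", bad[1]),
         call. = FALSE)
  }
  bad <- which(num$theta_deg < -180 | num$theta_deg > 180)
  if (length(bad) > 0) {
    stop(sprintf("theta_deg out of [-180, 180] at row %d", bad[1]),
         call. = FALSE)
  }
  # boundary values (-1, -180) are canonicalized by the constructor
  hair_config(num$axial_mm, num$circum_frac, num$theta_deg, domain)
}

config_keys <- function() {
  list(domain = c("axial_length", "base_radius", "tip_radius",
                  "base_height_flat", "tip_height_flat"),
       params = c("n_hairs", "c1", "a_star", "p_iterations",
                  "lambda_base", "lambda_tip", "spacing_range",
                  "lambda_m", "m_saturation",
                  "ventral_sign", "seed", "log_stride"),
       other = c("out_hairs", "out_trace", "out_prefix", "log_level",
                 "cercus_rotation", "smooth_window", "min_prominence_frac",
                 "ripley_radii"))
}

#' Read a run configuration file
#'
#' A flat YAML file whose keys are the fields of [model_params()] and
#' [cone_domain()], plus optional output paths and statistics options
#' (`out_hairs`, `out_trace`, `out_prefix`, `log_level`, `cercus_rotation`,
#' `smooth_window`, `min_prominence_frac`, `ripley_radii`). Every model key
#' is optional and defaults to the standard value; unknown keys are
#' rejected by name.
#'
#' @param path YAML file path.
#' @return A list with elements `domain` (a `cone_domain`), `params`
#'   (a `model_params`), and `options` (everything else).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  keys <- config_keys()
  unknown <- setdiff(names(raw), unlist(keys))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  domain <- do.call(cone_domain, raw[intersect(names(raw), keys$domain)])
  params <- do.call(model_params, raw[intersect(names(raw), keys$params)])
  list(domain = domain, params = params,
       options = raw[intersect(names(raw), keys$other)])
}

#' Fixture generators for validating the spatial statistics
#'
#' `poisson_hairs` draws a homogeneous Poisson-style pattern: `n` hairs
#' uniform per unit area with uniform random directions — the null pattern
#' for which Ripley's L tracks the diagonal. `clustered_hairs` draws
#' uniform parent points and scatters `offspring_per_parent` hairs around
#' each with isotropic Gaussian displacements of scale `cluster_sd` mm in
#' the flattened plane (wrapped circumferentially, clamped axially) — a
#' positive control for spatial clustering. `vonmises_mixture_hairs` places
#' hairs uniformly but draws directions from an equal-weight von Mises
#' mixture — a fixture with a known number of angular peaks.
#'
#' @param n,n_parents,offspring_per_parent counts.
#' @param cluster_sd offspring displacement scale, mm.
#' @param modes mixture mode directions, degrees.
#' @param kappa von Mises concentration.
#' @param domain a [cone_domain()].
#' @return A [hair_config()].
#' @export
poisson_hairs <- function(n, domain = cone_domain()) {
  pos <- sample_positions(n, domain)
  hair_config(pos$axial, pos$circum, runif(n, -180, 180), domain)
}

#' @rdname poisson_hairs
#' @export
clustered_hairs <- function(n_parents, offspring_per_parent, cluster_sd,
                            domain = cone_domain()) {
  stopifnot(n_parents >= 1, offspring_per_parent >= 1, cluster_sd >= 0)
  par <- sample_positions(n_parents, domain)
  n <- n_parents * offspring_per_parent
  px <- rep(par$axial, each = offspring_per_parent)
  pu <- rep(par$circum, each = offspring_per_parent)
  x <- pmin(pmax(px + rnorm(n, 0, cluster_sd), 0), domain$axial_length)
  # displace in flattened y, then wrap around the local circumference
  y <- pu * local_height(domain, px) / 2 + rnorm(n, 0, cluster_sd)
  u <- wrap_circum(2 * y / local_height(domain, x))
  hair_config(x, u, runif(n, -180, 180), domain)
}

#' @rdname poisson_hairs
#' @export
vonmises_mixture_hairs <- function(n, modes = c(-120, -30, 60, 150),
                                   kappa = 20, domain = cone_domain()) {
  pos <- sample_positions(n, domain)
  mu <- sample(modes, n, replace = TRUE)
  theta <- wrap_angle(mu + rvonmises(n, kappa) * 180 / pi)
  hair_config(pos$axial, pos$circum, theta, domain)
}

# von Mises deviates about zero (radians), Best & Fisher rejection sampler.
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    z <- cos(pi * runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(runif(1) - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

#' Write assessment outputs as plain text
#'
#' Tab-separated writers for the Ripley curve (`radius_mm`, `diameter_mm`,
#' `L_mm`, `poisson_ref_mm`), an angle histogram (`bin_start_deg`,
#' `bin_end_deg`, `count`), and a flat `key<TAB>value` summary file.
#'
#' @param curve a `ripley_curve`.
#' @param hist an `angle_histogram`.
#' @param summary a named list of scalars.
#' @param path output file path.
#' @export
write_ripley <- function(curve, path) {
  df <- data.frame(radius_mm = curve$radius, diameter_mm = curve$diameter,
                   L_mm = curve$l, poisson_ref_mm = curve$poisson_ref)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ripley
#' @export
write_histogram <- function(hist, path) {
  e <- hist$bin_edges
  df <- data.frame(bin_start_deg = e[-length(e)], bin_end_deg = e[-1],
                   count = hist$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ripley
#' @export
write_summary <- function(summary, path) {
  stopifnot(length(names(summary)) == length(summary))
  lines <- paste(names(summary), vapply(summary, format, character(1)),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
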