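#' Ripley's L function on the cercus surface
#'
#' Spatial autocorrelation of the hair positions for a series of circular
#' search-window radii, using on-cone geodesic distances:
#' `K(s) = A * sum_i sum_{j!=i} 1[r_ij < s] / (N * (N - 1))` and
#' `L(s) = sqrt(K(s) / pi)`, with `A` the area of the flattened trapezoid.
#' No edge correction is applied (the circumferential direction has no
#' boundary at all; only the two axial ends truncate windows). For a
#' homogeneous Poisson pattern `L(s)` tracks the diagonal `L = s`; values
#' above it indicate clustering, values below indicate segregation
#' (regular spacing).
#'
#' Published curves of this statistic are usually plotted against window
#' *diameter*; the returned object carries both columns to keep the factor
#' of two explicit.
#'
#' @param config a [hair_config()] with at least two hairs.
#' @param radii positive, strictly increasing window radii, mm.
#' @return An object of class `ripley_curve`: a data frame with columns
#'   `radius`, `diameter`, `l`, and `poisson_ref` (= `radius`), with the
#'   point count and area as attributes.
#' @export
ripley_l <- function(config, radii) {
  n <- nrow(config)
  if (n < 2L) stop("Ripley's L is undefined for fewer than 2 hairs",
                   call. = FALSE)
  if (any(radii <= 0) || is.unsorted(radii, strictly = TRUE)) {
    stop("radii must be positive and strictly increasing", call. = FALSE)
  }
  dom <- config_domain(config)
  d <- geodesic_matrix(dom, config$axial, config$circum)
  pd <- d[upper.tri(d)]
  a <- surface_area(dom)
  k <- vapply(radii, function(s) a * 2 * sum(pd < s) / (n * (n - 1)),
              numeric(1))
  out <- data.frame(radius = radii, diameter = 2 * radii,
                    l = sqrt(k / pi), poisson_ref = radii)
  structure(out, n_points = n, area = a,
            class = c("ripley_curve", "data.frame"))
}

#' Ventral/dorsal hair density ratio
#'
#' Ratio of hair counts in the ventral circumferential half
#' (`sign(circum) == ventral_sign`) to the dorsal half. Hairs lying exactly
#' on a restriction line (`circum` of 0 or 1) belong to neither half and
#' are excluded. The measured value on real cerci is about 1.22.
#'
#' @param config a [hair_config()].
#' @param ventral_sign +1 or -1.
#' @return The scalar ratio.
#' @export
ventral_dorsal_ratio <- function(config, ventral_sign = 1) {
  stopifnot(ventral_sign %in% c(-1, 1))
  s <- sign(config$circum)
  s[config$circum == 1] <- 0      # on the medial line: neither half
  nv <- sum(s == ventral_sign)
  nd <- sum(s == -ventral_sign)
  if (nd == 0L) stop("no hairs in the dorsal half; ratio undefined",
                     call. = FALSE)
  nv / nd
}

angle_histogram <- function(theta, frame) {
  edges <- seq(-180, 180, by = 5)
  theta <- wrap_angle(theta)
  # bins are (a, b]; theta = -180 cannot occur after wrapping
  idx <- ceiling((theta + 180) / 5)
  idx[idx < 1L] <- 1L
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts, frame = frame),
            class = "angle_histogram")
}

#' @export
print.angle_histogram <- function(x, ...) {
  cat(sprintf("angle_histogram (%s frame): %d hairs in %d bins of 5 degrees\n",
              x$frame, sum(x$counts), length(x$counts)))
  invisible(x)
}

#' Movement-direction histogram in the flattened frame
#'
#' Bins the hairs' movement directions into 5-degree bins over
#' (-180, 180], as measured directly on the flattened (filet) sheet.
#'
#' @param config a [hair_config()].
#' @return An object of class `angle_histogram` with fields `bin_edges`
#'   (degrees), `counts`, and `frame`.
#' @export
flattened_histogram <- function(config) {
  angle_histogram(config$theta, "flattened")
}

#' Transform movement directions to body-centric coordinates
#'
#' Re-expresses each hair's movement direction in the coordinate frame of
#' the cricket's body. The flattened-frame direction is mapped to a unit
#' tangent vector on the cone (axial component `cos(theta)` along the cone
#' axis, azimuthal component `sin(theta)`), projected onto the horizontal
#' plane (the cercus axis is horizontal, with the lateral line in the
#' horizontal plane), converted to an azimuth with 0 degrees pointing
#' directly anterior, and finally corrected for the cercus being rotated
#' `cercus_rotation` degrees out from the body axis. With the default 30
#' degree offset, hairs on the lateral line moving at 0 or 180 degrees in
#' the flattened frame map to approximately -30 and 150 degrees.
#'
#' Hairs whose movement axis projects onto the horizontal plane with
#' near-zero length (transverse movement exactly on a restriction line) are
#' excluded with a warning.
#'
#' @param config a [hair_config()].
#' @param cercus_rotation outward rotation of the cercus from the body
#'   axis, degrees (default 30).
#' @return An `angle_histogram` (`frame = "body_centric"`); the per-hair
#'   transformed angles are attached as attribute `"angles"` and the number
#'   of excluded hairs as attribute `"n_excluded"`.
#' @export
to_body_frame <- function(config, cercus_rotation = 30) {
  phi <- pi * config$circum
  th <- config$theta * pi / 180
  vx <- cos(th)                  # along the cone axis, toward the tip
  vy <- -sin(th) * sin(phi)      # horizontal component of the azimuthal part
  len <- sqrt(vx^2 + vy^2)
  bad <- len < 1e-6
  if (any(bad)) {
    warning(sum(bad), " hair(s) with a vertical movement axis excluded ",
            "from the body-frame histogram")
  }
  az <- atan2(vy[!bad], vx[!bad]) * 180 / pi
  body <- wrap_angle(az - cercus_rotation)
  h <- angle_histogram(body, "body_centric")
  attr(h, "angles") <- body
  attr(h, "n_excluded") <- sum(bad)
  h
}

#' Count peaks in a circular angle histogram
#'
#' Smooths the binned counts with a centered circular moving average and
#' counts circular local maxima whose prominence (height above the higher
#' of the two flanking saddles, walking each way until a taller bar is
#' met) is at least `min_prominence_frac` of the total count. A run of
#' equal smoothed values that stands above both of its neighbours (a
#' flat-topped peak, common when a sharp 2-bin peak is averaged) counts as
#' a single peak; perfectly uniform counts have no peaks.
#'
#' @param hist an `angle_histogram`.
#' @param smooth_window width of the circular moving average, bins (odd).
#' @param min_prominence_frac minimum peak prominence as a fraction of the
#'   total hair count.
#' @return Integer number of peaks.
#' @export
count_peaks <- function(hist, smooth_window = 3L, min_prominence_frac = 0.05) {
  y <- hist$counts
  b <- length(y)
  if (b == 0L || sum(y) == 0) stop("empty histogram", call. = FALSE)
  w <- as.integer(smooth_window)
  stopifnot(w >= 1L, w %% 2L == 1L)
  half <- (w - 1L) %/% 2L
  ext <- c(utils::tail(y, half), y, utils::head(y, half))
  sm <- vapply(seq_len(b), function(i) mean(ext[i:(i + w - 1L)]), numeric(1))
  nxt <- c(2:b, 1L); prv <- c(b, 1:(b - 1L))
  thresh <- min_prominence_frac * sum(y)
  n_peaks <- 0L
  seen <- rep(FALSE, b)
  for (i in seq_len(b)) {
    if (seen[i]) next
    # extend the run of bins tied with sm[i] in both directions
    right <- i
    while (sm[nxt[right]] == sm[i] && nxt[right] != i) right <- nxt[right]
    left <- i
    while (sm[prv[left]] == sm[i] && prv[left] != i) left <- prv[left]
    run <- if (left <= right) left:right else c(left:b, seq_len(right))
    seen[run] <- TRUE
    if (nxt[right] == left) next            # all bins equal: no peaks
    if (sm[i] <= sm[nxt[right]] || sm[i] <= sm[prv[left]]) next
    walk <- function(from, step) {
      lo <- sm[i]; j <- from
      for (k in seq_len(b)) {
        j <- if (step > 0) nxt[j] else prv[j]
        if (sm[j] > sm[i]) return(lo)
        lo <- min(lo, sm[j])
      }
      lo                                    # global maximum: base at minimum
    }
    if (sm[i] - max(walk(right, 1L), walk(left, -1L)) >= thresh) {
      n_peaks <- n_peaks + 1L
    }
  }
  n_peaks
}

#' Alignment and spacing summaries of a configuration
#'
#' `mean_misalignment` is the mean of `|sin(theta - theta_opt)|` over the
#' hairs, where `theta_opt` is the cost-minimizing movement axis at each
#' hair's position (longitudinal in the high-response bands, transverse in
#' the low-response band): 0 for perfect alignment, about 0.64 for uniform
#' random directions. `mean_nn_distance` is the mean geodesic distance to
#' the nearest neighbour, mm. Both are used to characterize how the balance
#' parameter `c1` trades alignment against spacing.
#'
#' @param params a [model_params()].
#' @param config a [hair_config()].
#' @return A scalar.
#' @export
mean_misalignment <- function(params, config) {
  m <- m_concentration(params, 1 - abs(config$circum))
  th_opt <- ifelse(m >= 0.5, 0, 90)
  mean(abs(sin((config$theta - th_opt) * pi / 180)))
}

#' @rdname mean_misalignment
#' @export
mean_nn_distance <- function(config) {
  n <- nrow(config)
  if (n < 2L) stop("need at least 2 hairs", call. = FALSE)
  d <- geodesic_matrix(config_domain(config), config$axial, config$circum)
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}
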