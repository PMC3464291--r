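test_that("Ripley's L matches hand-computed values for two points", {
  dom <- default_domain()
  a <- surface_area(dom)
  expect_equal(a, 6.5)
  du <- circum_offset_at_distance(dom, 2, 0.2)
  cfg <- hair_config(c(2, 2), c(0, du), c(0, 0), dom)
  # window smaller than the pair distance: no neighbours, L = 0
  # window larger: K = A, L = sqrt(A / pi)
  rl <- ripley_l(cfg, c(0.1, 0.5))
  expect_equal(rl$l, c(0, sqrt(a / pi)))
  expect_equal(rl$diameter, 2 * rl$radius)
  expect_equal(rl$poisson_ref, rl$radius)
  expect_error(ripley_l(hair_config(1, 0, 0, dom), c(0.1)), "2 hairs")
  expect_error(ripley_l(cfg, c(0.5, 0.1)), "increasing")
})

test_that("L is zero below the minimum spacing and non-decreasing", {
  set.seed(31)
  cfg <- poisson_hairs(100)
  rl <- ripley_l(cfg, seq(0.05, 1, by = 0.05))
  expect_true(all(diff(rl$l) >= 0))
  d <- geodesic_matrix(attr(cfg, "domain"), cfg$axial, cfg$circum)
  rmin <- min(d[upper.tri(d)])
  expect_equal(ripley_l(cfg, rmin * 0.9)$l, 0)
})

test_that("homogeneous Poisson patterns track the diagonal", {
  set.seed(12)
  radii <- seq(0.15, 0.75, by = 0.05)       # window diameters 0.3-1.5 mm
  L <- vapply(1:20, function(i) ripley_l(poisson_hairs(300), radii)$l,
              numeric(length(radii)))
  dev <- abs(rowMeans(L) - radii) / radii
  expect_lt(max(dev), 0.10)
})

test_that("clustered fixtures push L above the diagonal", {
  set.seed(13)
  devs <- vapply(1:5, function(i) {
    cfg <- clustered_hairs(30, 10, cluster_sd = 0.02)
    rl <- ripley_l(cfg, c(0.1, 0.15, 0.2, 0.3, 0.5))
    min(rl$l - rl$radius)
  }, numeric(1))
  expect_true(all(devs > 0))
})

test_that("ventral/dorsal ratio counts halves and excludes boundaries", {
  dom <- default_domain()
  cfg <- hair_config(c(1, 2, 3, 4), c(0.5, -0.5, 0.3, -0.3), rep(0, 4), dom)
  expect_equal(ventral_dorsal_ratio(cfg), 1)
  expect_equal(ventral_dorsal_ratio(cfg, ventral_sign = -1), 1)
  # hairs exactly on a restriction line belong to neither half
  cfg2 <- hair_config(c(1, 2, 3, 4), c(0, 1, 0.5, -0.5), rep(0, 4), dom)
  expect_equal(ventral_dorsal_ratio(cfg2), 1)
  cfg3 <- hair_config(c(1, 2), c(0.2, 0.4), c(0, 0), dom)
  expect_error(ventral_dorsal_ratio(cfg3), "dorsal")
})

test_that("flattened histograms use 5-degree bins over (-180, 180]", {
  dom <- default_domain()
  cfg <- hair_config(rep(1, 7), rep(0.3, 7), rep(0, 7), dom)
  h <- flattened_histogram(cfg)
  expect_equal(length(h$counts), 72L)
  expect_equal(sum(h$counts), 7)
  nz <- which(h$counts > 0)
  expect_length(nz, 1)
  # the single occupied bin is (-5, 0]
  expect_equal(h$bin_edges[nz], -5)
  expect_equal(h$bin_edges[nz + 1], 0)
  expect_identical(h$frame, "flattened")
})

test_that("uniform random directions produce no dominant bins", {
  set.seed(17)
  exceed <- vapply(1:20, function(i) {
    h <- flattened_histogram(poisson_hairs(300))
    any(h$counts > 3 * mean(h$counts))
  }, logical(1))
  # a bin above 3x the mean is a rare fluctuation; most seeds show none
  expect_lte(sum(exceed), 2)
})

test_that("body-frame transform reproduces the lateral-line anchors", {
  dom <- default_domain()
  cfg <- hair_config(c(1, 1), c(0, 0), c(0, 180), dom)
  h <- to_body_frame(cfg)
  ang <- attr(h, "angles")
  expect_equal(ang, c(-30, 150))
  expect_identical(h$frame, "body_centric")
  # no cercus rotation: the wrap alone maps theta = 0 to straight ahead
  h0 <- to_body_frame(hair_config(1, 0, 0, dom), cercus_rotation = 0)
  expect_equal(attr(h0, "angles"), 0)
  # medial-line hairs moving longitudinally land on the same anchors
  hm <- to_body_frame(hair_config(1, 1, 0, dom))
  expect_equal(attr(hm, "angles"), -30)
})

test_that("transverse movement exactly on a line is flagged and excluded", {
  dom <- default_domain()
  cfg <- hair_config(c(1, 2, 3), c(0, 0.5, 0), c(90, 90, 45), dom)
  expect_warning(h <- to_body_frame(cfg), "vertical")
  expect_equal(attr(h, "n_excluded"), 1L)
  expect_equal(sum(h$counts), 2)
})

test_that("transverse hairs map to exactly +/-90 before the offset", {
  dom <- default_domain()
  u <- c(0.2, 0.5, 0.9, -0.2, -0.5, -0.9)
  cfg <- hair_config(rep(1, 6), u, rep(90, 6), dom)
  ang <- attr(to_body_frame(cfg, cercus_rotation = 0), "angles")
  expect_equal(ang, ifelse(u > 0, -90, 90))
})

test_that("peak counting finds the constructed number of modes", {
  dom <- default_domain()
  set.seed(41)
  one <- vonmises_mixture_hairs(300, modes = 20, kappa = 20)
  expect_equal(count_peaks(flattened_histogram(one)), 1L)
  # kappa = 20 spreads each of the four modes over ~10 bins, so a mode's
  # smoothed prominence is ~0.04 of the total count; lower the threshold
  # accordingly for this broad fixture
  four <- vonmises_mixture_hairs(300, modes = c(-120, -30, 60, 150),
                                 kappa = 20)
  expect_equal(count_peaks(flattened_histogram(four),
                           min_prominence_frac = 0.03), 4L)
  # tighter modes clear the default prominence threshold
  four_tight <- vonmises_mixture_hairs(300, modes = c(-120, -30, 60, 150),
                                       kappa = 80)
  expect_equal(count_peaks(flattened_histogram(four_tight)), 4L)
  # perfectly uniform counts: no local maximum at all
  flat <- structure(list(bin_edges = seq(-180, 180, 5),
                         counts = rep(4L, 72), frame = "flattened"),
                    class = "angle_histogram")
  expect_equal(count_peaks(flat), 0L)
})

test_that("flat-topped peaks from tied smoothed bins count once", {
  # a sharp 2-bin peak smooths into two exactly tied bins; it is one peak
  counts <- rep(0L, 72)
  counts[20:21] <- c(30L, 30L)
  counts[50] <- 40L
  h <- structure(list(bin_edges = seq(-180, 180, 5), counts = counts,
                      frame = "flattened"), class = "angle_histogram")
  expect_equal(count_peaks(h), 2L)
  # prominence filter: a shoulder below the threshold is not a peak
  counts[40] <- 3L
  h$counts <- counts
  expect_equal(count_peaks(h), 2L)
})

test_that("alignment and spacing summaries behave at the extremes", {
  dom <- default_domain()
  p <- model_params()
  aligned <- hair_config(c(1, 2), c(0.05, -0.05), c(0, 180), dom)
  expect_equal(mean_misalignment(p, aligned), 0, tolerance = 1e-12)
  worst <- hair_config(c(1, 2), c(0.05, -0.05), c(90, -90), dom)
  expect_equal(mean_misalignment(p, worst), 1, tolerance = 1e-12)
  du <- circum_offset_at_distance(dom, 2, 0.15)
  cfg <- hair_config(c(2, 2, 2), c(0, du, 2 * du), c(0, 0, 0), dom)
  expect_equal(mean_nn_distance(cfg), 0.15, tolerance = 1e-6)
  expect_error(mean_nn_distance(hair_config(1, 0, 0, dom)), "2 hairs")
})
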