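test_that("spacing decay length interpolates 0.2 -> 0.4 mm along the axis", {
  p <- model_params(); dom <- default_domain()
  expect_equal(lambda_s(p, dom, 0), 0.2)
  expect_equal(lambda_s(p, dom, 5.2), 0.4)
  expect_equal(lambda_s(p, dom, 2.6), 0.3)
  expect_error(lambda_s(p, dom, 6), "axial")
})

test_that("pair cost is the exponential of the scaled geodesic distance", {
  p <- model_params(); dom <- default_domain()
  # coincident hairs: full inhibition
  expect_equal(pair_cost(p, dom, 1, 0.2, 1, 0.2), 1)
  # a pair placed exactly at r = 0.3 * lambda on the base circle
  du <- circum_offset_at_distance(dom, 0, 0.3 * 0.2)
  expect_equal(pair_cost(p, dom, 0, 0, 0, du), exp(-0.3), tolerance = 1e-9)
  # symmetric in the two hairs
  expect_equal(pair_cost(p, dom, 0.5, -0.3, 3.1, 0.7),
               pair_cost(p, dom, 3.1, 0.7, 0.5, -0.3))
  # beyond the interaction range the inhibition is negligible (< 5e-5)
  expect_lt(pair_cost(p, dom, 0, 0, 5.2, 0), 5e-5)
  expect_identical(pair_cost(p, dom, 0, 0, 5.2, 0), 0)
})

test_that("pair costs lie in [0, 1] and are positive within range", {
  p <- model_params(); dom <- default_domain()
  set.seed(19)
  a <- random_points(200); b <- random_points(200)
  pc <- pair_cost(p, dom, a$axial, a$circum, b$axial, b$circum)
  expect_true(all(pc >= 0 & pc <= 1))
  r <- geodesic_analytic(dom, a$axial, a$circum, b$axial, b$circum)
  lam <- lambda_s(p, dom, (a$axial + b$axial) / 2)
  expect_true(all((pc > 0) == (r < p$spacing_range * lam)))
})

test_that("morphogen-M response is 1 on both lines and 0 midway", {
  p <- model_params()
  expect_equal(m_concentration(p, 0), 1)
  expect_equal(m_concentration(p, 1), 1)
  expect_equal(m_concentration(p, 0.5), 0)
  x <- seq(0, 1, by = 0.01)
  m <- m_concentration(p, x)
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m, rev(m))                       # symmetric about the middle
  expect_error(m_concentration(p, -0.01), "\\[0, 1\\]")
  expect_error(m_concentration(p, 1.2), "\\[0, 1\\]")
})

test_that("prescribed axis is longitudinal on the lines, transverse midway", {
  p <- model_params()
  expect_equal(prescribed_angle(p, 0), 0)        # lateral line
  expect_equal(prescribed_angle(p, 1), 0)        # medial line
  expect_equal(prescribed_angle(p, -1), 0)
  expect_equal(prescribed_angle(p, 0.5), 90)     # midway between the lines
  expect_equal(prescribed_angle(p, -0.5), 90)
})

test_that("alignment cost honours the sine form and the ventral discount", {
  p <- model_params()
  # circum = 0.9 is inside the saturated longitudinal band (m = 1), so the
  # cost there is exactly c1 * (1 - a*V) * |sin(theta)|
  expect_equal(angle_cost(p, 0, 0.9), 0)
  expect_equal(angle_cost(p, 180, 0.9), 0)       # 180-degree flip free
  expect_equal(angle_cost(p, 90, -0.9), 10)      # dorsal: full weight
  expect_equal(angle_cost(p, 90, 0.9), 9)        # ventral positive: -10%
  # transverse optimum midway between the lines
  expect_equal(angle_cost(model_params(a_star = 0), 90, 0.5), 0)
  expect_equal(angle_cost(model_params(a_star = 0), -90, 0.5), 0)
  expect_equal(angle_cost(model_params(a_star = 0), 0, 0.5), 10)
})

test_that("alignment cost is bounded by c1 and 180-degree periodic", {
  p <- model_params()
  set.seed(23)
  th <- runif(300, -180, 180); u <- runif(300, -1, 1)
  ac <- angle_cost(p, th, u)
  expect_true(all(ac >= 0 & ac <= p$c1))
  # on the dorsal half V is always 0, so a flip changes nothing
  ud <- -abs(u)
  expect_equal(angle_cost(p, th, ud), angle_cost(p, th + 180, ud),
               tolerance = 1e-12)
  # with a_star = 0 the flip invariance holds everywhere
  p0 <- model_params(a_star = 0)
  expect_equal(angle_cost(p0, th, u), angle_cost(p0, th + 180, u),
               tolerance = 1e-12)
})

test_that("per-hair cost combines neighbour inhibition and alignment", {
  p <- model_params(); dom <- default_domain()
  # a single aligned hair on the lateral line costs nothing
  solo <- hair_config(2, 0, 0, dom)
  expect_equal(hair_cost(p, solo, 1), 0)
  expect_equal(total_cost(p, solo), 0)
  # two aligned hairs on the base circle at r = 0.3 * lambda: each pays one
  # pair term e^-0.3, the total counts the pair twice
  du <- circum_offset_at_distance(dom, 0, 0.3 * 0.2)
  pair <- hair_config(c(0, 0), c(0, du), c(0, 0), dom)
  # hair 2 sits just off the lateral line, inside the ventral half: its
  # spacing term carries the ventral weight (1 - a_star)
  expect_equal(hair_cost(p, pair, 1), exp(-0.3), tolerance = 1e-6)
  expect_equal(hair_cost(p, pair, 2), 0.9 * exp(-0.3), tolerance = 1e-6)
  expect_equal(total_cost(p, pair), 1.9 * exp(-0.3), tolerance = 1e-6)
  # with the correction off the double-count is exact
  p0 <- model_params(a_star = 0)
  expect_equal(total_cost(p0, pair), 2 * exp(-0.3), tolerance = 1e-6)
  expect_error(hair_cost(p, pair, 3), "index")
})

test_that("six coincident neighbours at r = 0.3 lambda cost about 4.4", {
  p <- model_params(); dom <- default_domain()
  du <- circum_offset_at_distance(dom, 2.6, 0.3 * lambda_s(p, dom, 2.6))
  cfg <- hair_config(rep(2.6, 7), c(0, rep(-du, 6)), rep(0, 7), dom)
  expect_equal(hair_cost(p, cfg, 1), 6 * exp(-0.3), tolerance = 1e-6)
})

test_that("empty and single-hair totals follow the definition", {
  p <- model_params(); dom <- default_domain()
  expect_equal(total_cost(p, hair_config(numeric(0), numeric(0),
                                         numeric(0), dom)), 0)
  expect_equal(total_cost(p, hair_config(2, -0.9, 90, dom)), 10)
})

test_that("incremental move evaluation matches brute-force recomputation", {
  dom <- default_domain()
  p <- model_params(n_hairs = 20L)
  set.seed(101)
  pos <- sample_positions(20, dom)
  cfg <- hair_config(pos$axial, pos$circum, runif(20, -180, 180), dom)
  base <- total_cost(p, cfg)
  for (k in 1:1000) {
    i <- sample.int(20, 1)
    np <- sample_positions(1, dom)
    nt <- runif(1, -180, 180)
    dlt <- delta_cost_move(p, cfg, i, np$axial, np$circum, nt)
    cfg2 <- cfg
    cfg2$axial[i] <- np$axial; cfg2$circum[i] <- np$circum
    cfg2$theta[i] <- wrap_angle(nt)
    full <- total_cost(p, cfg2) - base
    expect_equal(dlt, full, tolerance = 1e-9)
    # keep walking: accept every 3rd move so states vary
    if (k %% 3 == 0) { cfg <- cfg2; base <- base + full }
  }
  # the null move changes nothing
  expect_equal(delta_cost_move(p, cfg, 1, cfg$axial[1], cfg$circum[1],
                               cfg$theta[1]), 0)
})

test_that("moving an isolated aligned hair to a transverse angle costs c1", {
  p <- model_params(); dom <- default_domain()
  solo <- hair_config(2, 0, 0, dom)
  expect_equal(delta_cost_move(p, solo, 1, 2, 0, 90), 10)
})
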