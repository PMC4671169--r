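test_that("tendon line is the tangent to the scaled centroid curve", {
  p <- paper_profile()
  for (spec in list(bic(), bra())) {
    for (a in c(0.5, 1, 1.7)) {
      tl <- tendon_line(p, spec, a)
      scale <- spec$phi * sqrt(a)
      # passes through the scaled junction point
      expect_equal(tl$slope * spec$beta + tl$intercept,
                   scale * radius_at(p, spec$beta))
      # value and first derivative match the belly curve at beta
      expect_equal(tl$slope * spec$beta + tl$intercept,
                   mtu_height(p, spec, a, spec$beta))
      fd <- fd_deriv(function(x) scale * radius_at(p, x), spec$beta)
      expect_equal(tl$slope, fd, tolerance = 1e-6)
    }
  }
  expect_equal(tendon_line(p, bic(), 1)$slope, 1.5 * radius_slope_at(p, 1.1))
  expect_equal(tendon_line(p, bic(), 1)$slope, 0.5473132, tolerance = 1e-6)
  expect_equal(tendon_line(p, bra(), 1)$slope, 0.2427843, tolerance = 1e-6)
})

test_that("tendon slope scales exactly as sqrt(alpha)", {
  p <- paper_profile()
  for (spec in list(bic(), bra())) {
    s1 <- tendon_line(p, spec, 1)$slope
    for (a in default_alpha_grid())
      expect_equal(tendon_line(p, spec, a)$slope / s1, sqrt(a))
  }
})

test_that("MTU height is piecewise and continuous at the MT junction", {
  p <- paper_profile()
  expect_equal(mtu_height(p, bic(), 1, 7.3), 1.5 * sqrt(22 / pi))
  expect_equal(mtu_height(p, bra(), 1, 0.69), 0.9373844, tolerance = 1e-6)
  eps <- 1e-9
  for (spec in list(bic(), bra())) {
    below <- mtu_height(p, spec, 1.3, spec$beta - eps)
    above <- mtu_height(p, spec, 1.3, spec$beta + eps)
    expect_equal(below, above, tolerance = 1e-6)
  }
  # distal of the junction the curve is the straight tendon line
  tl <- tendon_line(p, bic(), 1)
  expect_equal(mtu_height(p, bic(), 1, 0.2), tl$slope * 0.2 + tl$intercept)
  expect_error(mtu_height(p, bic(), 1, 11.3), "belly end")
})

test_that("moment arms reproduce the published three-condition cells", {
  p <- paper_profile()
  expect_equal(round2(moment_arm(p, bic(), 0.5)), 1.63)
  expect_equal(round2(moment_arm(p, bic(), 1)), 2.17)
  expect_equal(round2(moment_arm(p, bic(), 2)), 2.76)
  expect_equal(round2(moment_arm(p, bra(), 0.5)), 0.54)
  expect_equal(round2(moment_arm(p, bra(), 1)), 0.75)
  expect_equal(round2(moment_arm(p, bra(), 2)), 1.03)
  # full-precision anchors
  expect_equal(moment_arm(p, bic(), 1), 2.165288, tolerance = 1e-6)
  expect_equal(moment_arm(p, bra(), 2), 1.029427, tolerance = 1e-6)
})

test_that("moment arm is bounded by the insertion distance and increasing in alpha", {
  p <- paper_profile()
  for (spec in list(bic(), bra())) {
    grid_ma <- vapply(default_alpha_grid(),
                      function(a) moment_arm(p, spec, a), 0)
    expect_true(all(diff(grid_ma) > 0))
    expect_true(all(grid_ma > 0 & grid_ma < spec$gamma))
    set.seed(7)
    draws <- sort(stats::runif(1000, 0.5, 2))
    rand_ma <- vapply(draws, function(a) moment_arm(p, spec, a), 0)
    expect_true(all(diff(rand_ma) > 0))
    expect_true(all(rand_ma < spec$gamma))
    # alpha -> 0+ limit: slope and hence MA vanish
    expect_lt(suppressWarnings(moment_arm(p, spec, 1e-10)), 1e-4)
  }
})

test_that("moment arm ignores pennation and warns outside the modelled alpha range", {
  p <- paper_profile()
  tweaked <- muscle_spec("BIC", beta = 1.1, gamma = 4.51, phi = 1.5,
                         theta_p0 = 42)
  expect_equal(moment_arm(p, tweaked, 1.4), moment_arm(p, bic(), 1.4))
  expect_warning(moment_arm(p, bic(), 2.5), "outside the modelled interval")
  expect_warning(moment_arm(p, bic(), 0.3), "outside the modelled interval")
  expect_error(moment_arm(p, bic(), 0), "positive")
})

test_that("the literal unscaled tangent slope makes the moment arm alpha-invariant", {
  p <- paper_profile()
  ma_lit <- vapply(c(0.5, 1, 2),
                   function(a) moment_arm(p, bic(), a, literal_eq3 = TRUE), 0)
  expect_equal(ma_lit, rep(ma_lit[1], 3))
  # and it cannot reproduce the published alpha-dependent cells
  expect_false(isTRUE(all.equal(round2(ma_lit[3]), 2.76)))
})

test_that("muscle spec validation enforces geometric invariants", {
  expect_error(muscle_spec("m", beta = 0, gamma = 1, phi = 1, theta_p0 = 10),
               "beta")
  expect_error(muscle_spec("m", beta = 12, gamma = 1, phi = 1, theta_p0 = 10),
               "beta")
  expect_error(muscle_spec("m", beta = 1, gamma = -1, phi = 1, theta_p0 = 10),
               "gamma")
  expect_error(muscle_spec("m", beta = 1, gamma = 1, phi = 0, theta_p0 = 10),
               "phi")
  expect_error(muscle_spec("m", beta = 1, gamma = 1, phi = 1, theta_p0 = 90),
               "theta_p0")
})
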