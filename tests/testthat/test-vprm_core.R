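test_that("EVI matches the standard formulation and masks bad denominators", {
  g <- mk_grid(2, 2)
  red <- mk_field(0.1, g); blue <- mk_field(0.05, g)
  nir <- mk_field(0.4, g)
  evi <- compute_evi(red, nir, blue)
  expect_equal(evi$values[1, 1, 1], 0.75 / 1.625, tolerance = 1e-12)

  expect_equal(compute_evi(red, mk_field(0.1, g), blue)$values[1, 1, 1], 0)

  # denominator <= 0 masks the cell
  bad_blue <- mk_field(0.5, g)  # den = 0.4 + 0.6 - 3.75 + 1 < 0
  expect_true(all(is.na(compute_evi(red, nir, bad_blue)$values)))

  other <- mk_field(0.1, mk_grid(3, 3))
  expect_error(compute_evi(other, nir, blue), "not on the same grid")
})

test_that("LSWI is the NIR/SWIR normalized difference with range endpoints", {
  g <- mk_grid(2, 2)
  nir <- mk_field(0.4, g)
  expect_equal(compute_lswi(nir, mk_field(0.2, g))$values[1, 1, 1],
               1 / 3, tolerance = 1e-12)
  expect_equal(compute_lswi(nir, mk_field(0.4, g))$values[1, 1, 1], 0)
  expect_equal(compute_lswi(nir, mk_field(0, g))$values[1, 1, 1], 1)
  expect_equal(compute_lswi(mk_field(0, g), nir)$values[1, 1, 1], -1)
  expect_true(is.na(compute_lswi(mk_field(0, g), mk_field(0, g))$values[1]))
})

test_that("temperature scalar peaks at the optimum and is clamped outside limits", {
  expect_equal(t_scale(20), 1)
  expect_equal(t_scale(10), 350 / 450, tolerance = 1e-12)
  expect_equal(t_scale(50), 0)
  expect_equal(t_scale(-5), 0)
  expect_equal(t_scale(c(0, 45)), c(0, 0))  # ties at the limits -> absent
  sweep <- t_scale(seq(-20, 60, by = 0.25))
  expect_true(all(sweep >= 0 & sweep <= 1))
  expect_equal(sum(sweep == 1), 1)  # only at t_opt
  expect_error(temperature_limits(t_opt = 50, t_max = 45), "t_min < t_opt")
})

test_that("phenology scalar honours class conventions", {
  expect_equal(p_scale(-0.8, "EvergreenForest"), 1)
  expect_equal(p_scale(0.2, "DeciduousForest"), 0.6)
  expect_equal(p_scale(0.2, "Other"), 0)
  expect_equal(p_scale(-0.5, "Cropland", is_max_greenness = TRUE), 1)
  expect_error(p_scale(0, "Tundra"), "unknown vegetation class")
  lswi <- seq(-1, 0.5, by = 0.1)
  ps <- p_scale(lswi, rep("Grassland", length(lswi)))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("water scalar is the LSWI ratio with masked degenerate maxima", {
  expect_equal(w_scale(0.3, 0.3), 1)
  expect_equal(w_scale(0, 0.5), 2 / 3, tolerance = 1e-12)
  expect_equal(w_scale(-1, 0.5), 0)
  expect_true(is.na(w_scale(0, -1)))
  expect_true(all(w_scale(seq(-1, 0.4, by = 0.1), 0.4) >= 0))
  expect_true(all(w_scale(seq(-1, 0.4, by = 0.1), 0.4) <= 1))
})

test_that("annual LSWI maximum is taken per cell over non-missing composites", {
  g <- mk_grid(2, 2)
  v <- array(NA_real_, dim = c(3, 2, 2))
  v[1, , ] <- -0.1; v[2, , ] <- 0.4; v[3, , ] <- 0.2
  v[, 2, 2] <- NA
  f <- mk_field(v, g)
  mx <- lswi_max_by_cell(f)
  expect_equal(mx[1, 1], 0.4)
  expect_true(is.na(mx[2, 2]))
  expect_equal(lswi_max_by_cell(mk_field(array(0.3, c(3, 2, 2)), g))[1, 1], 0.3)
})

test_that("GPP reproduces the light-use-efficiency closed form", {
  g <- mk_grid(2, 2)
  vm <- uniform_map("EvergreenForest", g)
  params <- vprm_param_table("tropical")
  evi <- mk_field(0.5, g)
  t20 <- mk_field(20, g)
  # Evergreen: Pscale = 1 (class rule), Wscale = 1 (no lswi), Tscale(20) = 1
  gpp <- gpp_vprm(evi, t20, mk_field(501, g), vm, params)
  expect_equal(gpp$values[1, 1, 1], 0.21 * 0.5 * 501 * 0.5, tolerance = 1e-12)
  expect_true(all(gpp_vprm(evi, t20, mk_field(0, g), vm, params)$values == 0))
})

test_that("GPP is monotone in radiation and saturates at the algebraic limit", {
  g <- mk_grid(2, 2)
  vm <- uniform_map("EvergreenForest", g)
  params <- vprm_param_table("tropical")
  evi <- mk_field(0.5, g)
  t20 <- mk_field(20, g)
  sw <- seq(0, 5000, by = 250)
  gvals <- vapply(sw, function(s)
    gpp_vprm(evi, t20, mk_field(s, g), vm, params)$values[1, 1, 1], 0)
  expect_true(all(diff(gvals) >= 0))
  lim <- 0.21 * 1 * 1 * 1 * 0.5 * 501
  at_inf <- gpp_vprm(evi, t20, mk_field(1e6 * 501, g), vm, params)$values[1, 1, 1]
  expect_lt(abs(at_inf - lim) / lim, 1e-3)
})

test_that("tropical and european sets differ only through lambda and swdown0", {
  # under constant radiation the radiation response collapses to a per-class
  # constant, so the two sets' outputs are exactly proportional per class
  # (shared scalars and drivers; |lambda| ratio constant per class)
  scn <- noiseless_scene(seed = 3)
  sw_const <- gridded_field(array(800, dim = dim(scn$swdown$values)),
                            scn$grid, scn$swdown$times, scn$swdown$units,
                            "swdown")
  g_trop <- gpp_vprm(scn$evi, scn$t_air, sw_const, scn$vegmap,
                     vprm_param_table("tropical"), lswi = scn$lswi)
  g_eur <- gpp_vprm(scn$evi, scn$t_air, sw_const, scn$vegmap,
                    vprm_param_table("european"), lswi = scn$lswi)
  nt <- dim(g_trop$values)[1]
  cls <- class_array(scn$vegmap, nt)
  for (cl in c("Grassland", "EvergreenForest", "Cropland", "Savanna")) {
    a <- g_trop$values[cls == cl]
    b <- g_eur$values[cls == cl]
    expect_true(all(b >= 0))  # |lambda| convention: uptake magnitude
    expect_equal(cor(a, b), 1, tolerance = 1e-9)
  }
  # Savanna carries identical magnitudes in both sets (only the sign flips)
  expect_equal(g_eur$values[cls == "Savanna"],
               g_trop$values[cls == "Savanna"], tolerance = 1e-12)
  # with spatially varying radiation the two sets still agree on where GPP
  # is zero
  g_eur2 <- gpp_vprm(scn$evi, scn$t_air, scn$swdown, scn$vegmap,
                     vprm_param_table("european"), lswi = scn$lswi)
  expect_identical(g_eur2$values == 0, scn$gpp_vprm$values == 0)
})

test_that("respiration is the clamped linear temperature response", {
  g <- mk_grid(2, 2)
  vm <- uniform_map("Grassland", g)
  params <- vprm_param_table("tropical")
  expect_equal(reco_vprm(mk_field(20, g), vm, params)$values[1, 1, 1],
               0.52, tolerance = 1e-12)
  # clamp at the threshold: cold air falls back to alpha * t_thresh + beta
  expect_equal(reco_vprm(mk_field(-10, g), vm, params)$values[1, 1, 1], 0)
  lim5 <- temperature_limits(t_thresh = 5)
  expect_equal(reco_vprm(mk_field(-10, g), vm, params, lim5)$values[1, 1, 1],
               0.026 * 5, tolerance = 1e-12)
  expect_true(all(reco_vprm(mk_field(20, g), uniform_map("Other", g),
                            params)$values == 0))
  half <- veg_map(matrix(c("Grassland", "Savanna"), 2, 2), g)
  missing_savanna <- params[params$class != "Savanna", ]
  expect_error(reco_vprm(mk_field(20, g), half, missing_savanna), "Savanna")
})
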