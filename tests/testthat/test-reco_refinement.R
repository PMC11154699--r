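test_that("noiseless coefficients are recovered to machine precision", {
  scn <- noiseless_scene(seed = 41)
  params <- vprm_param_table("tropical")
  # SM-only truth: reco = 0.5e4 * SM + 0.9 * B
  b <- reco_vprm(scn$t_air, scn$vegmap, params)
  ref_sm <- gridded_field(5000 * scn$sm$values + 0.9 * b$values, scn$grid,
                          scn$t_air$times, "umol CO2 m-2 s-1", "ref")
  fit <- fit_reco_params("SM", sm = scn$sm, t_air = scn$t_air,
                         reco_ref = ref_sm, vegmap = scn$vegmap,
                         params = params)
  expect_equal(fit$nu, rep(5000, nrow(fit)), tolerance = 1e-6)
  expect_equal(fit$kappa, rep(0.9, nrow(fit)), tolerance = 1e-6)
  expect_true(all(is.na(fit$tau)))

  # the scene's own truth-based reference, joint SMST fit
  fit3 <- fit_reco_params("SMST", sm = scn$sm, st = scn$st,
                          t_air = scn$t_air, reco_ref = scn$reco_ref,
                          vegmap = scn$vegmap, params = params)
  expect_equal(fit3$nu, rep(scn$truth$nu0, nrow(fit3)), tolerance = 1e-6)
  expect_equal(fit3$tau, rep(scn$truth$tau0, nrow(fit3)), tolerance = 1e-6)
  expect_equal(fit3$kappa, rep(scn$truth$kappa0, nrow(fit3)),
               tolerance = 1e-6)

  # identity model: reference equal to the baseline gives kappa 1, nu 0
  fit_b <- fit_reco_params("SM", sm = scn$sm, t_air = scn$t_air,
                           reco_ref = b, vegmap = scn$vegmap, params = params)
  expect_equal(fit_b$kappa, rep(1, nrow(fit_b)), tolerance = 1e-8)
  expect_equal(fit_b$nu, rep(0, nrow(fit_b)), tolerance = 1e-5)
})

test_that("noisy coefficients land within three standard errors", {
  scn <- generate_scene(scene_config(seed = 43))  # 20 x 20 x 46, sd 0.1
  params <- vprm_param_table("tropical")
  fit <- fit_reco_params("SMST", sm = scn$sm, st = scn$st,
                         t_air = scn$t_air, reco_ref = scn$reco_ref,
                         vegmap = scn$vegmap, params = params)
  expect_true(all(fit$n >= 1500))
  b <- reco_vprm(scn$t_air, scn$vegmap, params)
  nt <- dim(b$values)[1]
  cls <- class_array(scn$vegmap, nt)
  for (k in seq_len(nrow(fit))) {
    sel <- cls == fit$class[k]
    # independent route: stats::lm on the extracted per-class samples
    d <- data.frame(y = scn$reco_ref$values[sel], st = scn$st$values[sel],
                    sm = scn$sm$values[sel], b = b$values[sel])
    m <- lm(y ~ 0 + st + sm + b, data = d)
    se <- coef(summary(m))[, "Std. Error"]
    expect_equal(unname(coef(m)[["sm"]]), fit$nu[k], tolerance = 1e-9)
    expect_lt(abs(fit$nu[k] - scn$truth$nu0), 3 * se[["sm"]])
    expect_lt(abs(fit$tau[k] - scn$truth$tau0), 3 * se[["st"]])
    expect_lt(abs(fit$kappa[k] - scn$truth$kappa0), 3 * se[["b"]])
  }
})

test_that("degenerate designs are rejected or omitted with named predictors", {
  g <- mk_grid(2, 2)
  vm <- uniform_map("Grassland", g)
  params <- vprm_param_table("tropical")
  t_air <- mk_field(20, g, n_time = 4)
  # soil moisture proportional to the baseline term -> collinear
  sm <- mk_field(0.2, g, n_time = 4)
  ref <- mk_field(1, g, n_time = 4)
  expect_warning(
    expect_error(fit_reco_params("SM", sm = sm, t_air = t_air,
                                 reco_ref = ref, vegmap = vm,
                                 params = params),
                 "no class"),
    "collinear")
  expect_error(fit_reco_params("SM", t_air = t_air, reco_ref = ref,
                               vegmap = vm, params = params), "needs sm")
  expect_error(fit_reco_params("nope", sm = sm, t_air = t_air,
                               reco_ref = ref, vegmap = vm, params = params),
               "unknown experiment")
})

test_that("prediction evaluates the experiment formulas with floors and zeros", {
  g <- mk_grid(2, 2)
  vm <- uniform_map("Grassland", g)
  params <- data.frame(class = "Grassland", alpha = 0.1, beta = 0)
  t_air <- mk_field(20, g)     # baseline B = 2
  st <- mk_field(300, g)
  sm <- mk_field(0.0002, g)
  tab <- data.frame(class = "Grassland", experiment = "SMST",
                    nu = 5000, tau = 0.01, kappa = 0.5)
  out <- predict_reco("SMST", tab, sm = sm, st = st, t_air = t_air,
                      vegmap = vm, vprm_params = params)
  expect_equal(out$values[1, 1, 1], 3 + 1 + 1, tolerance = 1e-12)

  # nu = 0, kappa = 1 degenerates to the unrefined baseline
  degen <- data.frame(class = "Grassland", experiment = "SM", nu = 0, kappa = 1)
  out_sm <- predict_reco("SM", degen, sm = sm, t_air = t_air, vegmap = vm,
                         vprm_params = params)
  expect_equal(out_sm$values,
               reco_vprm(t_air, vm, params)$values, tolerance = 1e-12)

  zero <- data.frame(class = "Grassland", experiment = "ST", tau = 0, kappa = 0)
  expect_true(all(predict_reco("ST", zero, st = st, t_air = t_air,
                               vegmap = vm, vprm_params = params)$values == 0))
  expect_error(predict_reco("SMST", degen, sm = sm, st = st, t_air = t_air,
                            vegmap = vm, vprm_params = params),
               "no rows for experiment")
})

test_that("forcing a coefficient to zero collapses SMST onto the single-predictor model", {
  scn <- noiseless_scene(seed = 47)
  params <- vprm_param_table("tropical")
  fit_st <- fit_reco_params("ST", st = scn$st, t_air = scn$t_air,
                            reco_ref = scn$reco_ref, vegmap = scn$vegmap,
                            params = params)
  tab <- fit_st
  tab$experiment <- "SMST"
  tab$nu <- 0
  p_a <- predict_reco("SMST", tab, sm = scn$sm, st = scn$st,
                      t_air = scn$t_air, vegmap = scn$vegmap,
                      vprm_params = params)
  p_b <- predict_reco("ST", fit_st, st = scn$st, t_air = scn$t_air,
                      vegmap = scn$vegmap, vprm_params = params)
  expect_equal(p_a$values, p_b$values, tolerance = 1e-12)
})

test_that("fitted models never beat nesting order on the fitting sample", {
  scn <- generate_scene(scene_config(n_lat = 10, n_lon = 16, seed = 53))
  params <- vprm_param_table("tropical")
  base <- reco_vprm(scn$t_air, scn$vegmap, params)
  fits <- lapply(c("SM", "ST", "SMST"), function(ex)
    fit_reco_params(ex, sm = scn$sm, st = scn$st, t_air = scn$t_air,
                    reco_ref = scn$reco_ref, vegmap = scn$vegmap,
                    params = params))
  preds <- Map(function(ex, f)
    predict_reco(ex, f, sm = scn$sm, st = scn$st, t_air = scn$t_air,
                 vegmap = scn$vegmap, vprm_params = params),
    c("SM", "ST", "SMST"), fits)
  nt <- dim(base$values)[1]
  cls <- class_array(scn$vegmap, nt)
  rmse_for <- function(pred, sel)
    sqrt(mean((pred$values[sel] - scn$reco_ref$values[sel])^2))
  for (cl in veg_classes(TRUE)) {
    sel <- cls == cl
    r <- vapply(preds, rmse_for, 0, sel = sel)
    r_base <- rmse_for(base, sel)
    expect_lte(r[["SMST"]], r[["SM"]] + 1e-9)
    expect_lte(r[["SMST"]], r[["ST"]] + 1e-9)
    expect_lte(r[["SM"]], r_base + 1e-9)
  }
})
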