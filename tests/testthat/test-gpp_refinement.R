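test_that("ratio estimator matches hand arithmetic", {
  g <- mk_grid(2, 2)
  vm <- uniform_map("Grassland", g)
  # single usable pair (sif = 6, vprm = 2): eta = 12/2, epsilon = 6 - 12
  sif <- mk_field(array(c(6, NA, NA, NA), c(1, 2, 2)), g)
  vprm <- mk_field(array(c(2, NA, NA, NA), c(1, 2, 2)), g)
  fit <- fit_eta(sif, vprm, vm)
  expect_equal(fit$eta, 6)
  expect_equal(fit$epsilon, -6)
  expect_equal(fit$n, 1)
})

test_that("constant VPRM GPP makes the ratio estimator the mean SIF GPP", {
  g <- mk_grid(3, 3)
  vm <- uniform_map("Cropland", g)
  set.seed(2)
  sifv <- array(runif(2 * 9, 1, 5), c(2, 3, 3))
  fit <- fit_eta(mk_field(sifv, g, n_time = 2), mk_field(3, g, n_time = 2), vm)
  expect_equal(fit$eta, mean(sifv), tolerance = 1e-12)
})

test_that("indicator-like identical fields give eta 1 and epsilon 0", {
  g <- mk_grid(2, 2)
  vm <- uniform_map("Savanna", g)
  v <- mk_field(array(c(0, 1, 1, 0), c(1, 2, 2)), g)
  fit <- fit_eta(v, v, vm)
  expect_equal(fit$eta, 1)
  expect_equal(fit$epsilon, 0)
})

test_that("centered slope variant recovers an exact affine relation", {
  scn <- noiseless_scene(seed = 23)
  fit <- fit_eta(scn$gpp_sif_ref, scn$gpp_vprm, scn$vegmap,
                 estimator = "slope")
  for (k in seq_len(nrow(fit))) {
    cl <- fit$class[k]
    expect_equal(fit$eta[k], unname(scn$truth$eta0[[cl]]), tolerance = 1e-9)
    expect_equal(fit$epsilon[k], unname(scn$truth$eps0[[cl]]),
                 tolerance = 1e-8)
  }
})

test_that("fitting is invariant to sample traversal order", {
  scn <- noiseless_scene(seed = 29)
  f1 <- fit_eta(scn$gpp_sif_ref, scn$gpp_vprm, scn$vegmap)
  rev_time <- function(f) gridded_field(f$values[rev(seq_len(dim(f$values)[1])), , ,
                                                 drop = FALSE],
                                        f$grid, f$times, f$units, f$name)
  f2 <- fit_eta(rev_time(scn$gpp_sif_ref), rev_time(scn$gpp_vprm), scn$vegmap)
  expect_equal(f1$eta, f2$eta, tolerance = 1e-12)
  expect_equal(f1$epsilon, f2$epsilon, tolerance = 1e-12)
})

test_that("refinement is mean-unbiased per class on the fitting sample", {
  scn <- generate_scene(scene_config(n_lat = 10, n_lon = 16, seed = 31))
  # a deliberately biased 'SIF GPP': scaled + shifted VPRM GPP plus noise,
  # kept strictly positive so the non-negativity floor never binds
  set.seed(1)
  sif_gpp <- gridded_field(
    1.8 * scn$gpp_vprm$values + 0.7 +
      rnorm(length(scn$gpp_vprm$values), sd = 0.1),
    scn$grid, scn$gpp_vprm$times, scn$gpp_vprm$units, "gpp_sif")
  fit <- fit_eta(sif_gpp, scn$gpp_vprm, scn$vegmap, estimator = "slope")
  refined <- apply_refinement(scn$gpp_vprm, scn$vegmap, fit)
  nt <- dim(refined$values)[1]
  cls <- class_array(scn$vegmap, nt)
  for (cl in fit$class) {
    sel <- cls == cl
    expect_equal(mean(refined$values[sel]), mean(sif_gpp$values[sel]),
                 tolerance = 1e-9)
  }
  # the mean-residual intercept makes any estimator mean-unbiased before the
  # non-negativity floor, including the ratio estimator
  fit_lit <- fit_eta(sif_gpp, scn$gpp_vprm, scn$vegmap)
  for (k in seq_len(nrow(fit_lit))) {
    sel <- cls == fit_lit$class[k]
    lin <- fit_lit$eta[k] * scn$gpp_vprm$values[sel] + fit_lit$epsilon[k]
    expect_equal(mean(lin), mean(sif_gpp$values[sel]), tolerance = 1e-9)
  }
})

test_that("applying refinement honours identity, scaling and masks", {
  g <- mk_grid(2, 2)
  vm <- uniform_map("DeciduousForest", g)
  gpp <- mk_field(array(c(3, 3, NA, 3), c(1, 2, 2)), g)
  ident <- data.frame(class = "DeciduousForest", eta = 1, epsilon = 0)
  expect_equal(apply_refinement(gpp, vm, ident)$values, gpp$values)
  # packaged deciduous TROPOSIF-side factor: eta = 2.4 (no intercept column)
  tab <- gpp_refinement_table()
  tab <- tab[tab$product == "troposif", ]
  out <- apply_refinement(gpp, vm, tab)
  expect_equal(out$values[1, 1, 1], 7.2, tolerance = 1e-12)
  expect_true(is.na(out$values[1, 1, 2]))
  expect_error(apply_refinement(gpp, vm, ident[0, ]), "DeciduousForest")
})
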