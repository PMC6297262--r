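test_that("warp handles identity, integer shifts, and label contracts", {
  g <- test_geometry()
  p <- base_phantom_cached()
  idf <- identity_field(g)
  expect_equal(warp(p$volume, idf, "linear")$data, p$volume$data, tolerance = 1e-12)
  expect_identical(warp(p$labels, idf)$labels, p$labels$labels)
  # integer-voxel translation moves a delta by exactly that many voxels
  delta <- image_volume(array(0, g$dim), g$spacing)
  delta$data[20, 20, 10] <- 1
  u <- array(0, c(g$dim, 3))
  u[, , , 1] <- 3 * g$spacing[1]  # phi(x) = x + 3 voxels: samples 3 right
  tf <- displacement_field(u, g$spacing)
  shifted <- warp(delta, tf, "linear")
  expect_equal(shifted$data[17, 20, 10], 1)
  expect_equal(sum(shifted$data), 1)
  # labels must use nearest-neighbour
  expect_error(warp(p$labels, idf, "linear"), "nearest")
  # geometry mismatch rejected
  small <- identity_field(list(dim = c(8L, 8L, 8L), spacing = g$spacing,
                               origin = c(0, 0, 0)))
  expect_error(warp(p$volume, small), "geometry")
})

test_that("field composition is exact for translations and inverts cleanly", {
  g <- test_geometry()
  tr <- function(v) {
    u <- array(0, c(g$dim, 3))
    for (c in 1:3) u[, , , c] <- v[c]
    displacement_field(u, g$spacing)
  }
  f <- tr(c(0.25, -0.1, 0.5)); h <- tr(c(-0.05, 0.3, 0.2))
  comp <- compose_fields(f, h)
  expect_equal(comp$u[, , , 1], array(0.2, g$dim), tolerance = 1e-12)
  expect_equal(comp$u[, , , 2], array(0.2, g$dim), tolerance = 1e-12)
  expect_equal(comp$u[, , , 3], array(0.7, g$dim), tolerance = 1e-12)
  # compose(identity, g) = g
  idf <- identity_field(g)
  expect_equal(compose_fields(idf, h)$u, h$u, tolerance = 1e-12)
  # pure translation inverts to its negation
  inv <- invert_field(f, tol = 1e-6)
  expect_lt(max(abs(inv$u[5:60, 5:60, 3:30, ] + f$u[5:60, 5:60, 3:30, ])), 1e-5)
  expect_true(all(invert_field(idf)$u == 0))
})

test_that("analytic warp inverts and composes toward identity", {
  g <- test_geometry()
  cen <- roi_center("ventricles")
  f <- make_analytic_warp(analytic_warp_spec(cen, 2.1, 3.26, 1.5), g)
  inv <- invert_field(f, tol = 0.02)
  comp <- compose_fields(f, inv)
  res_vox <- sqrt((comp$u[, , , 1] / g$spacing[1])^2 +
                    (comp$u[, , , 2] / g$spacing[2])^2 +
                    (comp$u[, , , 3] / g$spacing[3])^2)
  expect_lt(mean(res_vox), 0.1)
  expect_lt(max(res_vox[5:60, 5:60, 3:30]), 0.5)
})

test_that("nonrigid registration recovers an analytic expansion and stays diffeomorphic", {
  g <- test_geometry()
  p <- base_phantom_cached()
  cen <- roi_center("ventricles")
  pullback <- make_analytic_warp(analytic_warp_spec(cen, 2.1, 3.26, 1 / 1.5), g)
  moving <- warp(p$volume, pullback, "linear")
  fld <- register_nonrigid(p$volume, moving)
  # masked MSD at least halved
  msd <- attr(fld, "msd")
  expect_lt(msd["final"], 0.5 * msd["initial"])
  # mean log-Jacobian in the inner ball within 15% of ln 1.5
  lj <- log_jacobian(fld)
  w <- jacmorph:::world_coords(g)
  r <- sqrt((w$x - cen[1])^2 + (w$y - cen[2])^2 + (w$z - cen[3])^2)
  expect_lt(abs(mean(lj$values[r < 1.8]) - log(1.5)), 0.15 * log(1.5))
  # diffeomorphism contract
  expect_gt(min(exp(lj$values)), 0)
  # moving = fixed: no displacement
  fld0 <- register_nonrigid(p$volume, p$volume)
  expect_lt(max(abs(fld0$u)) / min(g$spacing), 0.1)
  # contrast-scale invariance
  mv2 <- moving; mv2$data <- moving$data * 2
  fld2 <- register_nonrigid(p$volume, mv2)
  dvox <- sqrt((fld2$u[, , , 1] - fld$u[, , , 1])^2 +
                 (fld2$u[, , , 2] - fld$u[, , , 2])^2 +
                 (fld2$u[, , , 3] - fld$u[, , , 3])^2) / min(g$spacing)
  expect_lt(mean(dvox), 0.2)
})

test_that("degenerate registration inputs are rejected", {
  g <- test_geometry()
  p <- base_phantom_cached()
  flat <- image_volume(array(0, g$dim), g$spacing)
  expect_error(register_nonrigid(p$volume, flat), "contrast")
  m1 <- p$volume; m1$mask <- array(FALSE, g$dim); m1$mask[1:5, 1:5, 1:2] <- TRUE
  m2 <- p$volume; m2$mask <- array(FALSE, g$dim); m2$mask[60:64, 60:64, 30:32] <- TRUE
  expect_error(register_nonrigid(m1, m2), "overlap")
})

test_that("groupwise template is unbiased and centred between two warped phantoms", {
  g <- test_geometry()
  p <- base_phantom_cached()
  # identical inputs -> template equals input, fields vanish
  gw0 <- build_groupwise_template(list(p$volume, p$volume),
                                  light_reg(), n_outer_iter = 1)
  expect_lt(max(abs(gw0$fields[[1]]$u)) / min(g$spacing), 0.1)
  expect_equal(gw0$template$data, p$volume$data, tolerance = 0.02 * max(p$volume$data))
  # two phantoms related by a known warp: template sits between them
  cen <- roi_center("ventricles")
  pullback <- make_analytic_warp(analytic_warp_spec(cen, 2.1, 3.26, 1 / 1.6), g)
  v2 <- warp(p$volume, pullback, "linear")
  gw <- build_groupwise_template(list(p$volume, v2), light_reg(), n_outer_iter = 2)
  mean_u <- (gw$fields[[1]]$u + gw$fields[[2]]$u) / 2
  expect_lt(max(abs(mean_u)) / min(g$spacing), 0.1)  # unbiasedness
  w <- jacmorph:::world_coords(g)
  r <- sqrt((w$x - cen[1])^2 + (w$y - cen[2])^2 + (w$z - cen[3])^2)
  lj1 <- mean(log_jacobian(gw$fields[[1]])$values[r < 1.8])
  lj2 <- mean(log_jacobian(gw$fields[[2]])$values[r < 1.8])
  expect_lt(lj1 * lj2, 0)                    # opposite signs
  expect_lt(abs(lj1 + lj2), 0.25 * max(abs(lj1), abs(lj2)))  # roughly half each
})

test_that("groupwise template of a jittered cohort is sharper than the naive mean", {
  g <- test_geometry()
  p <- base_phantom_cached()
  jits <- lapply(1:6, function(i) make_jitter_field(g, 2, seed = i * 13))
  vols <- lapply(jits, function(j) warp(p$volume, j, "linear"))
  ge <- function(x) {
    gr <- jacmorph:::gradient3(x, g$spacing)
    mean(gr[[1]]^2 + gr[[2]]^2 + gr[[3]]^2)
  }
  naive <- Reduce(`+`, lapply(vols, `[[`, "data")) / length(vols)
  gw <- build_groupwise_template(vols, reg_params(iterations = c(30, 20, 15)),
                                 n_outer_iter = 2)
  expect_gt(ge(gw$template$data), ge(naive))
  # unbiasedness at scale
  mean_u <- Reduce(`+`, lapply(gw$fields, `[[`, "u")) / length(vols)
  expect_lt(max(abs(mean_u)) / min(g$spacing), 0.1)
})

test_that("template construction is insensitive to input order", {
  g <- test_geometry()
  p <- base_phantom_cached()
  vols <- lapply(1:3, function(i)
    warp(p$volume, make_jitter_field(g, 2, seed = i * 31), "linear"))
  gw_a <- build_groupwise_template(vols, light_reg(), n_outer_iter = 1)
  gw_b <- build_groupwise_template(rev(vols), light_reg(), n_outer_iter = 1)
  rel <- sqrt(mean((gw_a$template$data - gw_b$template$data)^2)) /
    sqrt(mean(gw_a$template$data^2))
  expect_lt(rel, 0.01)
})
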