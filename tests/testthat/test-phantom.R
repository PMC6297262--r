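test_that("base phantom places all layout ROIs, bilaterally symmetric", {
  p <- base_phantom_cached()
  lay <- default_roi_layout()
  expect_setequal(p$labels$lut$name, lay$name)
  expect_true(all(c("ventricles", "csf_above_frontal", "central_thalamus",
                    "superior_colliculus", "inferior_colliculus") %in%
                    p$labels$lut$name))
  counts <- tabulate(p$labels$labels[p$labels$labels > 0], nbins = nrow(lay))
  expect_true(all(counts > 0))
  # bilateral label symmetry about the central sagittal (first-axis) plane
  lab <- p$labels$labels
  mirrored <- lab[rev(seq_len(dim(lab)[1])), , ]
  expect_identical(lab, mirrored)
  # T2-like contrast: CSF bright, tissue intermediate, background near zero
  csf_ids <- which(lay$tissue_class == "csf")
  expect_gt(mean(p$volume$data[lab %in% csf_ids]),
            mean(p$volume$data[p$volume$mask & lab == 0]))
  expect_lt(mean(p$volume$data[!p$volume$mask]), 5)
})

test_that("degenerate and invalid layouts are handled", {
  g <- test_geometry()
  empty <- make_base_phantom(g, default_roi_layout()[0, ])
  expect_true(all(empty$labels$labels == 0L))
  expect_gt(sum(empty$volume$mask), 0)
  # same layout twice -> identical label grids regardless of seed
  a <- make_base_phantom(g, seed = 1)
  b <- make_base_phantom(g, seed = 99)
  expect_identical(a$labels$labels, b$labels$labels)
  # overlapping regions rejected with a diagnostic naming the ROI
  lay <- default_roi_layout()
  lay$x[lay$name == "infralimbic"] <- lay$x[lay$name == "prelimbic"]
  lay$y[lay$name == "infralimbic"] <- lay$y[lay$name == "prelimbic"]
  lay$z[lay$name == "infralimbic"] <- lay$z[lay$name == "prelimbic"]
  expect_error(make_base_phantom(g, lay), "overlap")
  # region outside the envelope rejected
  lay2 <- default_roi_layout()
  lay2$z[1] <- 100
  expect_error(make_base_phantom(g, lay2), "grid|envelope")
})

test_that("analytic warp scales the inner ball by the prescribed volume ratio", {
  # fine isotropic grid so central differences probe the analytic gradient
  gg <- list(dim = c(40L, 40L, 40L), spacing = c(0.2, 0.2, 0.2), origin = c(0, 0, 0))
  cen <- c(4, 4, 4)
  spec <- analytic_warp_spec(cen, 2, 3.2, 1.8735)
  f <- make_analytic_warp(spec, gg)
  jd <- log_jacobian(f)
  w <- jacmorph:::world_coords(gg)
  r <- sqrt((w$x - cen[1])^2 + (w$y - cen[2])^2 + (w$z - cen[3])^2)
  inner <- r < spec$inner_radius - 0.25
  expect_lt(max(abs(exp(jd$values[inner]) - 1.8735)), 1e-6)
  # compact support: displacement exactly zero beyond the outer radius
  umag <- sqrt(f$u[, , , 1]^2 + f$u[, , , 2]^2 + f$u[, , , 3]^2)
  expect_true(all(umag[r >= spec$outer_radius] == 0))
  # identity ratio -> zero displacement everywhere
  f1 <- make_analytic_warp(analytic_warp_spec(cen, 2, 3.2, 1), gg)
  expect_true(all(f1$u == 0))
  # invalid specs rejected
  expect_error(analytic_warp_spec(cen, 2, 3.2, -1), "volume_ratio")
  expect_error(analytic_warp_spec(cen, 3.2, 2, 1.5), "inner_radius")
  # strong expansion across a narrow annulus folds the Hermite profile
  expect_error(make_analytic_warp(analytic_warp_spec(cen, 2, 2.2, 8), gg),
               "fold|increasing")
})

test_that("finite-difference log-Jacobian of the analytic warp matches closed form", {
  gg <- list(dim = c(36L, 36L, 36L), spacing = c(0.2, 0.2, 0.2), origin = c(0, 0, 0))
  cen <- c(3.6, 3.6, 3.6)
  for (ratio in c(0.7, 1.2, 1.8735)) {
    f <- make_analytic_warp(analytic_warp_spec(cen, 1.8, 3.0, ratio), gg)
    lj <- log_jacobian(f)
    w <- jacmorph:::world_coords(gg)
    r <- sqrt((w$x - cen[1])^2 + (w$y - cen[2])^2 + (w$z - cen[3])^2)
    inner <- r < 1.5
    expect_lt(max(abs(lj$values[inner] - log(ratio))), 1e-3)
  }
})

test_that("acquisition artifacts: unit-mean bias, seeded determinism, no-op case", {
  p <- base_phantom_cached()
  expect_identical(add_acquisition_artifacts(p$volume, 0, 0, seed = 1), p$volume)
  b <- add_acquisition_artifacts(p$volume, 0, 0.2, seed = 5)
  ratio <- b$data[p$volume$mask] / p$volume$data[p$volume$mask]
  keep <- p$volume$data[p$volume$mask] > 10
  expect_lt(abs(mean(ratio[keep]) - 1), 0.01)
  expect_gt(diff(range(ratio[keep])), 0.1)
  a1 <- add_acquisition_artifacts(p$volume, 4, 0.1, seed = 7)
  a2 <- add_acquisition_artifacts(p$volume, 4, 0.1, seed = 7)
  expect_identical(a1$data, a2$data)
  a3 <- add_acquisition_artifacts(p$volume, 4, 0.1, seed = 8)
  expect_false(identical(a1$data, a3$data))
})

test_that("simulate_cohort writes deterministic scans and voxel-count ground truth", {
  g <- test_geometry()
  cfg <- list(n_etoh = 2, n_con = 2, geometry = g)
  eff <- rbind(effect_spec("ventricles", 1, "EtOH", 1.87),
               effect_spec("ventricles", 2, "EtOH", 1 / 1.87))
  d1 <- withr::local_tempdir()
  man <- simulate_cohort(cfg, eff, list(noise_sigma = 2, bias_amplitude = 0.05),
                         seed = 11, outdir = d1)
  expect_equal(nrow(man$subjects), 4)
  expect_true(all(file.exists(unlist(man$subjects[, c("scan1", "scan2", "scan3")]))))
  # ground truth: EtOH ventricle ratio near 1.87 at interval 1, controls near 1
  tr <- man$truth
  vr <- tr[tr$roi == "ventricles" & tr$interval == 1, ]
  etoh <- man$subjects$subject[man$subjects$group == "EtOH"]
  expect_true(all(abs(vr$true_ratio[vr$subject %in% etoh] - 1.87) < 0.05 * 1.87))
  expect_true(all(abs(vr$true_ratio[!vr$subject %in% etoh] - 1) < 0.02))
  # reversal brings the ventricles back near baseline volume
  vr2 <- tr[tr$roi == "ventricles" & tr$interval == 2 & tr$subject %in% etoh, ]
  expect_true(all(abs(vr2$true_ratio - 1 / 1.87) < 0.05))
  # ROIs without effects stay at ratio 1 exactly up to label resampling
  other <- tr[tr$roi %in% c("inferior_colliculus", "prelimbic"), ]
  expect_true(all(abs(other$true_ratio - 1) < 0.02))
  # byte-identical rerun under the same seed
  d2 <- withr::local_tempdir()
  simulate_cohort(cfg, eff, list(noise_sigma = 2, bias_amplitude = 0.05),
                  seed = 11, outdir = d2)
  f1 <- file.path(d1, "sub-S01_t2.nii"); f2 <- file.path(d2, "sub-S01_t2.nii")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # unknown effect ROI rejected with its name
  expect_error(simulate_cohort(cfg, effect_spec("nonexistent_roi", 1, "EtOH", 2),
                               seed = 1, outdir = withr::local_tempdir()),
               "nonexistent_roi")
})

test_that("null cohort scans differ across timepoints only by artifacts", {
  g <- test_geometry()
  d <- withr::local_tempdir()
  man <- simulate_cohort(list(n_etoh = 1, n_con = 1, geometry = g),
                         effects = NULL,
                         list(noise_sigma = 0, bias_amplitude = 0),
                         seed = 3, outdir = d)
  s1 <- read_volume(man$subjects$scan1[1])
  s2 <- read_volume(man$subjects$scan2[1])
  expect_equal(s1$data, s2$data, tolerance = 1e-6)
  expect_true(all(man$truth$true_ratio == 1))
})
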