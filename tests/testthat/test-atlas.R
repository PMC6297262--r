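test_that("atlas loads from files with verified ROI volumes and validation", {
  p <- base_phantom_cached()
  d <- withr::local_tempdir()
  write_volume(p$labels, file.path(d, "labels.nii"))
  write.csv(p$labels$lut, file.path(d, "lut.csv"), row.names = FALSE)
  lay <- default_roi_layout()
  write.csv(data.frame(name = lay$name, tissue_class = lay$tissue_class),
            file.path(d, "tissue.csv"), row.names = FALSE)
  atl <- load_atlas(file.path(d, "labels.nii"), file.path(d, "lut.csv"),
                    file.path(d, "tissue.csv"))
  # ROI volumes equal the generator's voxel counts exactly
  counts <- tabulate(p$labels$labels[p$labels$labels > 0], nbins = nrow(lay))
  expect_equal(atl$roi_table$roi_vol, counts)
  expect_equal(atl$roi_table$tissue_class[atl$roi_table$name == "ventricles"], "csf")
  # lut id with no voxels warns; grid label missing from lut rejects
  lut_extra <- rbind(p$labels$lut, data.frame(id = 99L, name = "ghost"))
  write.csv(lut_extra, file.path(d, "lut2.csv"), row.names = FALSE)
  expect_warning(load_atlas(file.path(d, "labels.nii"), file.path(d, "lut2.csv")),
                 "ghost")
  lut_short <- p$labels$lut[-1, ]
  write.csv(lut_short, file.path(d, "lut3.csv"), row.names = FALSE)
  expect_error(load_atlas(file.path(d, "labels.nii"), file.path(d, "lut3.csv")),
               "missing from lut")
  # duplicate ROI names rejected
  lut_dup <- p$labels$lut; lut_dup$name[2] <- lut_dup$name[1]
  write.csv(lut_dup, file.path(d, "lut4.csv"), row.names = FALSE)
  expect_error(load_atlas(file.path(d, "labels.nii"), file.path(d, "lut4.csv")),
               "duplicate")
})

test_that("cluster masks transform to atlas space with mirroring", {
  p <- base_phantom_cached()
  g <- test_geometry()
  atl <- atlas_from_labels(p$labels)
  # a cluster covering the right ventricle
  lab <- p$labels$labels
  vid <- p$labels$lut$id[p$labels$lut$name == "ventricles"]
  right <- jacmorph:::right_hemisphere_mask(g$dim, 1)
  cs <- structure(list(clusters = list(which(lab == vid & right)),
                       sizes = sum(lab == vid & right), peak_t = 5,
                       direction = "expand", dim = g$dim, comparison = "test"),
                  class = "cluster_set")
  idf <- identity_field(g)
  m <- map_clusters_to_atlas(cs, idf, mirror = TRUE)
  # mirrored mask covers both ventricle copies
  expect_true(all(m[lab == vid]))
  tab <- roi_overlap_table(m, NULL, atl, 1)
  vrow <- tab[tab$roi == "ventricles", ]
  expect_equal(vrow$expand_vol, sum(lab == vid))
  expect_equal(vrow$expand_pct, 100)
  # without mirroring only half the ROI overlaps
  m1 <- map_clusters_to_atlas(cs, idf, mirror = FALSE)
  tab1 <- roi_overlap_table(m1, NULL, atl, 1)
  expect_equal(tab1[tab1$roi == "ventricles", "expand_pct"], 50)
  # empty cluster set gives an all-zero mask
  cs0 <- structure(list(clusters = list(), sizes = integer(0), peak_t = numeric(0),
                        direction = "expand", dim = g$dim, comparison = "t"),
                   class = "cluster_set")
  expect_false(any(map_clusters_to_atlas(cs0, idf)))
  # mask accounting: per-ROI counts sum to the mask total
  tab_all <- roi_overlap_table(m, m1, atl, 1)
  expect_equal(sum(tab_all$expand_vol), sum(m))
  expect_equal(sum(tab_all$shrink_vol), sum(m1))
})

test_that("percentage and overall arithmetic reproduce the printed table cells", {
  fx <- printed_overlap_fixture()
  for (i in seq_len(nrow(fx))) {
    r <- fx[i, ]
    row1 <- roi_overlap_row(r$roi, r$roi_vol, r$e1, r$s1, interval = 1,
                            tissue_class = r$tissue_class)
    row2 <- roi_overlap_row(r$roi, r$roi_vol, r$e2, r$s2, interval = 2,
                            tissue_class = r$tissue_class)
    if (!is.na(r$e1_pct)) expect_equal(row1$expand_pct, r$e1_pct)
    if (!is.na(r$s1_pct)) expect_equal(row1$shrink_pct, r$s1_pct)
    if (!is.na(r$e2_pct)) expect_equal(row2$expand_pct, r$e2_pct)
    if (!is.na(r$s2_pct)) expect_equal(row2$shrink_pct, r$s2_pct)
    expect_equal(overall_change(row1, row2), r$overall)
  }
  # boundary percentages
  expect_equal(roi_overlap_row("x", 100, 0)$expand_pct, 0)
  expect_equal(roi_overlap_row("x", 100, 100)$expand_pct, 100)
  expect_error(overall_change(roi_overlap_row("a", 10), roi_overlap_row("b", 10)),
               "different ROIs")
})

test_that("pattern classification follows the 10% decision table", {
  mk <- function(roi_vol, e1, s1, e2, s2, tc = "tissue") {
    list(r1 = roi_overlap_row("r", roi_vol, e1, s1, 1, tc),
         r2 = roi_overlap_row("r", roi_vol, e2, s2, 2, tc))
  }
  cl <- function(x, tc = "tissue") classify_pattern(x$r1, x$r2, tissue_class = tc)
  # ventricular pattern: 87% expansion then 87% shrinkage
  expect_equal(cl(mk(253, 221, 0, 0, 220), "csf"), "reversible_expansion")
  # central thalamus: 20.66% shrinkage then 25.30% expansion
  expect_equal(cl(mk(656, 0, 139, 164, 0))
               , "reversible_shrinkage")
  # superior colliculus: 16.45% shrinkage, nothing at interval 2
  expect_equal(cl(mk(1635, 0, 272, 0, 0)), "enduring_shrinkage")
  # prelimbic: expansion both intervals, no opposing change
  expect_equal(cl(mk(1205, 91 * 2, 0, 98 * 2, 0)), "enduring_expansion")
  # CSF class expansion gets the fluid label
  expect_equal(cl(mk(483, 76, 0, 0, 0), "csf"), "enduring_fluid_expansion")
  expect_equal(cl(mk(1000, 0, 0, 0, 0)), "below_threshold")
  expect_equal(cl(mk(1000, 5, 5, 5, 5)), "below_threshold")
  # shrinkage only at interval 2 is not covered by the named patterns
  expect_equal(cl(mk(1000, 0, 0, 0, 500)), "mixed")
  # threshold monotonicity: raising tau never resurrects below_threshold
  x <- mk(1000, 150, 0, 0, 120)
  expect_equal(classify_pattern(x$r1, x$r2, threshold_pct = 10), "reversible_expansion")
  expect_equal(classify_pattern(x$r1, x$r2, threshold_pct = 20), "below_threshold")
})

test_that("combined family table carries patterns and pre-rounding overall", {
  atlv <- base_phantom_cached()$labels
  atl <- atlas_from_labels(atlv, tissue_class = c(ventricles = "csf"))
  g <- test_geometry()
  lab <- atlv$labels
  vid <- atlv$lut$id[atlv$lut$name == "ventricles"]
  vent <- lab == vid
  t1 <- roi_overlap_table(vent, NULL, atl, 1)
  t2 <- roi_overlap_table(NULL, vent, atl, 2)
  comb <- combine_interval_tables(t1, t2)
  vrow <- comb[comb$roi == "ventricles", ]
  expect_equal(vrow$pattern, "reversible_expansion")
  expect_equal(vrow$overall_pct, 0)
  expect_true(all(comb$pattern[comb$roi != "ventricles"] == "below_threshold"))
})
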