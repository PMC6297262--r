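# Published-style ROI overlap fixture: per-ROI voxel volumes and overlap
# counts for the two scan intervals, with the percentage and net-change
# cells they imply. Columns: e1/s1 = interval-1 expand/shrink overlap
# voxels, e2/s2 = interval-2; *_pct are the printed 2-decimal values.
printed_overlap_fixture <- function() {
  rows <- list(
    # family, roi, roi_vol, e1, s1, e2, s2, e1_pct, s1_pct, e2_pct, s2_pct, overall
    list("between", "Ventricles",           253,   221, 0,    0,   220, 87.35, NA,   NA,    86.96,  0.40, "csf"),
    list("between", "Prelimbic",            1205,  91,  0,    98,  0,   7.55,  NA,   8.13,  NA,    15.68, "tissue"),
    list("between", "Infralimbic",          342,   0,   0,    60,  0,   NA,    NA,   17.54, NA,    17.54, "tissue"),
    list("between", "CSF above frontal",    483,   76,  0,    0,   0,   15.73, NA,   NA,    NA,    15.73, "csf"),
    list("between", "Cingulate",            2328,  56,  0,    21,  0,   2.41,  NA,   0.90,  NA,     3.31, "tissue"),
    list("between", "Corpus callosum",      6408,  143, 0,    0,   453, 2.23,  NA,   NA,    7.07,  -4.84, "white"),
    list("between", "Temporal association", 597,   0,   0,    0,   2,   NA,    NA,   NA,    0.34,  -0.34, "tissue"),
    list("between", "Thalamus (vpl/vpm)",   487,   0,   3,    0,   0,   NA,    0.62, NA,    NA,    -0.62, "tissue"),
    list("between", "Pontine reticular",    1013,  0,   37,   0,   0,   NA,    3.65, NA,    NA,    -3.65, "tissue"),
    list("between", "Cerebellum",           11619, 0,   335,  0,   0,   NA,    2.88, NA,    NA,    -2.88, "tissue"),
    list("between", "Unlabeled",            94035, 878, 4233, 1640, 585, 0.93, 4.50, 1.74,  0.62,  -2.45, "none"),
    list("within",  "Ventricles",           253,   248, 0,    0,   225, 98.02, NA,   NA,    88.93,  9.09, "csf")
  )
  do.call(rbind, lapply(rows, function(r)
    data.frame(family = r[[1]], roi = r[[2]], roi_vol = r[[3]],
               e1 = r[[4]], s1 = r[[5]], e2 = r[[6]], s2 = r[[7]],
               e1_pct = r[[8]], s1_pct = r[[9]], e2_pct = r[[10]],
               s2_pct = r[[11]], overall = r[[12]], tissue_class = r[[13]],
               stringsAsFactors = FALSE)))
}
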