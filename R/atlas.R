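#' Load a label atlas
#'
#' Reads an integer label volume, its id-to-name lookup table, and a
#' tissue class per ROI (tissue / CSF / white matter), and verifies the
#' per-ROI voxel volumes against the label grid. Lookup ids absent from
#' the grid produce a warning; grid labels absent from the lookup are an
#' error.
#'
#' @param label_volume_file NIfTI-1 file with the integer label grid.
#' @param lut_file delimited text (columns `id`, `name`).
#' @param tissue_class_file delimited text (columns `name`,
#'   `tissue_class`); ROIs not listed default to `"tissue"`.
#' @param intensity_file optional NIfTI-1 intensity image in atlas space
#'   (used as the registration target when mapping clusters to the atlas).
#' @return an `atlas`: list with `labels` (a [label_volume()]),
#'   `roi_table` (data.frame `id`, `name`, `tissue_class`, `roi_vol`),
#'   and optionally `intensity` (an [image_volume()]).
#' @export
load_atlas <- function(label_volume_file, lut_file, tissue_class_file = NULL,
                       intensity_file = NULL) {
  lut <- as_lut(read.csv(lut_file, stringsAsFactors = FALSE))
  lv <- read_label_volume(label_volume_file, lut)
  present <- setdiff(unique(as.integer(lv$labels)), 0L)
  absent <- setdiff(lut$id, present)
  if (length(absent) > 0)
    warning("lut ids missing from the label grid: ",
            paste(lut$name[lut$id %in% absent], collapse = ", "))
  tc <- rep("tissue", nrow(lut))
  if (!is.null(tissue_class_file)) {
    tt <- read.csv(tissue_class_file, stringsAsFactors = FALSE)
    idx <- match(lut$name, tt$name)
    tc[!is.na(idx)] <- tt$tissue_class[idx[!is.na(idx)]]
  }
  counts <- tabulate(lv$labels[lv$labels > 0], nbins = max(lut$id))
  roi_table <- data.frame(id = lut$id, name = lut$name, tissue_class = tc,
                          roi_vol = counts[lut$id], stringsAsFactors = FALSE)
  out <- list(labels = lv, roi_table = roi_table)
  if (!is.null(intensity_file)) out$intensity <- read_volume(intensity_file)
  structure(out, class = "atlas")
}

#' Build an atlas object from in-memory phantom pieces
#' @param labels a [label_volume()].
#' @param tissue_class named character vector (ROI name -> class) or NULL.
#' @param intensity optional [image_volume()] in the same space.
#' @rdname load_atlas
#' @export
atlas_from_labels <- function(labels, tissue_class = NULL, intensity = NULL) {
  lut <- labels$lut
  tc <- rep("tissue", nrow(lut))
  if (!is.null(tissue_class)) {
    idx <- match(lut$name, names(tissue_class))
    tc[!is.na(idx)] <- unname(tissue_class[idx[!is.na(idx)]])
  }
  counts <- tabulate(labels$labels[labels$labels > 0], nbins = max(lut$id, 1))
  roi_table <- data.frame(id = lut$id, name = lut$name, tissue_class = tc,
                          roi_vol = counts[lut$id], stringsAsFactors = FALSE)
  structure(list(labels = labels, roi_table = roi_table, intensity = intensity),
            class = "atlas")
}

#' Map cluster masks into atlas space
#'
#' Reflects each direction's cluster union mask across the mid-sagittal
#' plane (bilateral reporting: statistics are computed on one hemisphere
#' of bilaterally averaged maps) and carries it through the
#' template-to-atlas deformation with nearest-neighbour interpolation.
#'
#' @param clusters a `cluster_set` on the template grid.
#' @param template_to_atlas `displacement_field` on the atlas grid whose
#'   transform maps atlas-grid positions into template coordinates.
#' @param mirror reflect the mask to both hemispheres before warping
#'   (default TRUE).
#' @param midplane_axis axis of the left-right direction.
#' @return logical array on the atlas grid.
#' @export
map_clusters_to_atlas <- function(clusters, template_to_atlas, mirror = TRUE,
                                  midplane_axis = 1) {
  m <- cluster_union_mask(clusters)
  if (mirror) m <- m | mirror_array(m, midplane_axis)
  gf <- geometry_of_field(template_to_atlas)
  if (!identical(dim(m), gf$dim))
    stop("cluster grid does not match the template-to-atlas field grid")
  w <- cpp_warp_disp(m + 0, template_to_atlas$u, template_to_atlas$spacing, TRUE, 0)
  array(w > 0.5, gf$dim)
}

#' Per-ROI overlap table for one interval
#'
#' Counts, for every atlas ROI, the voxels overlapped by the expansion
#' and shrinkage cluster masks and expresses them as percentages of the
#' ROI volume (`100 * vol / roi_vol`, reported to 2 decimals, half-up).
#' Voxels outside all ROIs accumulate under an `"Unlabeled"` row.
#'
#' @param expand_mask,shrink_mask logical arrays on the atlas grid (NULL
#'   for none).
#' @param atlas an `atlas`.
#' @param interval 1 (baseline to binge) or 2 (binge to recovery).
#' @return data.frame with columns `roi`, `tissue_class`, `roi_vol`,
#'   `interval`, `expand_vol`, `expand_pct`, `shrink_vol`, `shrink_pct`.
#' @export
roi_overlap_table <- function(expand_mask, shrink_mask, atlas, interval) {
  rt <- atlas$roi_table
  lab <- atlas$labels$labels
  unl_vol <- sum(lab == 0L)
  count_in <- function(mask, id) {
    if (is.null(mask)) return(0L)
    if (id == 0L) sum(mask & lab == 0L) else sum(mask & lab == id)
  }
  rows <- rbind(
    data.frame(roi = rt$name, tissue_class = rt$tissue_class, roi_vol = rt$roi_vol,
               stringsAsFactors = FALSE),
    data.frame(roi = "Unlabeled", tissue_class = "none", roi_vol = unl_vol,
               stringsAsFactors = FALSE))
  ids <- c(rt$id, 0L)
  rows$interval <- as.integer(interval)
  rows$expand_vol <- vapply(ids, function(id) count_in(expand_mask, id), integer(1))
  rows$shrink_vol <- vapply(ids, function(id) count_in(shrink_mask, id), integer(1))
  rows$expand_pct <- ifelse(rows$roi_vol > 0,
                            round_half_up(100 * rows$expand_vol / rows$roi_vol, 2), NA_real_)
  rows$shrink_pct <- ifelse(rows$roi_vol > 0,
                            round_half_up(100 * rows$shrink_vol / rows$roi_vol, 2), NA_real_)
  rows[, c("roi", "tissue_class", "roi_vol", "interval",
           "expand_vol", "expand_pct", "shrink_vol", "shrink_pct")]
}

#' Single-ROI overlap row from raw counts
#'
#' The arithmetic core of [roi_overlap_table()], exposed for working
#' directly from printed volume counts: percentages are
#' `100 * vol / roi_vol` rounded half-up to 2 decimals.
#'
#' @param roi ROI name.
#' @param roi_vol ROI volume in voxels (> 0).
#' @param expand_vol,shrink_vol overlap voxel counts.
#' @param interval 1 or 2.
#' @param tissue_class tissue class label.
#' @return one-row data.frame in the [roi_overlap_table()] layout.
#' @export
roi_overlap_row <- function(roi, roi_vol, expand_vol = 0, shrink_vol = 0,
                            interval = 1, tissue_class = "tissue") {
  stopifnot(roi_vol > 0, expand_vol >= 0, shrink_vol >= 0)
  data.frame(roi = roi, tissue_class = tissue_class, roi_vol = roi_vol,
             interval = as.integer(interval),
             expand_vol = expand_vol,
             expand_pct = round_half_up(100 * expand_vol / roi_vol, 2),
             shrink_vol = shrink_vol,
             shrink_pct = round_half_up(100 * shrink_vol / roi_vol, 2),
             stringsAsFactors = FALSE)
}

#' Net overall change across the two intervals
#'
#' Signed percentage `100 * (e1 - s1 + e2 - s2) / roi_vol` computed from
#' the raw voxel counts and rounded last, so a large expansion followed
#' by an almost equal shrinkage yields the small net value the unrounded
#' arithmetic implies.
#'
#' @param row_interval1,row_interval2 rows from [roi_overlap_table()] for
#'   the same ROI.
#' @return signed percent (numeric, 2 decimals).
#' @export
overall_change <- function(row_interval1, row_interval2) {
  if (!identical(row_interval1$roi, row_interval2$roi))
    stop("rows refer to different ROIs: ", row_interval1$roi, " vs ", row_interval2$roi)
  if (row_interval1$roi_vol <= 0) return(NA_real_)
  net <- row_interval1$expand_vol - row_interval1$shrink_vol +
    row_interval2$expand_vol - row_interval2$shrink_vol
  round_half_up(100 * net / row_interval1$roi_vol, 2)
}

#' Classify the temporal pattern of an ROI's change
#'
#' Applies the 10%-of-ROI relevance threshold to the two intervals'
#' unrounded overlap percentages and assigns one label:
#' * `reversible_expansion` - expansion in interval 1 and shrinkage in
#'   interval 2, both at or above threshold (the ventricular pattern);
#' * `reversible_shrinkage` - shrinkage then expansion (the thalamic
#'   pattern);
#' * `enduring_shrinkage` - interval-1 shrinkage without interval-2
#'   recovery (the collicular pattern);
#' * `enduring_expansion` / `enduring_fluid_expansion` - expansion in
#'   either interval with no opposing change at threshold, the latter
#'   for CSF-class ROIs;
#' * `below_threshold` - nothing reaches threshold;
#' * `mixed` - any remaining combination.
#'
#' @inheritParams overall_change
#' @param tissue_class tissue class of the ROI (`"csf"` selects the fluid
#'   label); defaults to the class stored in the rows.
#' @param threshold_pct relevance threshold (percent of ROI volume).
#' @return character pattern label.
#' @export
classify_pattern <- function(row_interval1, row_interval2,
                             tissue_class = row_interval1$tissue_class,
                             threshold_pct = 10) {
  if (!identical(row_interval1$roi, row_interval2$roi))
    stop("rows refer to different ROIs")
  if (row_interval1$roi_vol <= 0) return("below_threshold")
  tau <- threshold_pct
  e1 <- 100 * row_interval1$expand_vol / row_interval1$roi_vol
  s1 <- 100 * row_interval1$shrink_vol / row_interval1$roi_vol
  e2 <- 100 * row_interval2$expand_vol / row_interval2$roi_vol
  s2 <- 100 * row_interval2$shrink_vol / row_interval2$roi_vol
  is_csf <- identical(tolower(tissue_class), "csf")
  if (e1 >= tau && s2 >= tau) return("reversible_expansion")
  if (s1 >= tau && e2 >= tau) return("reversible_shrinkage")
  if (s1 >= tau && e2 < tau) return("enduring_shrinkage")
  if ((e1 >= tau || e2 >= tau) && s1 < tau && s2 < tau)
    return(if (is_csf) "enduring_fluid_expansion" else "enduring_expansion")
  if (e1 < tau && s1 < tau && e2 < tau && s2 < tau) return("below_threshold")
  "mixed"
}

#' Combine two interval tables into a full report table
#'
#' Joins the interval-1 and interval-2 overlap tables of one comparison
#' family, appends the pre-rounding `overall_pct` and the pattern label.
#'
#' @param tab1,tab2 data.frames from [roi_overlap_table()] for intervals
#'   1 and 2.
#' @param threshold_pct pattern threshold.
#' @return data.frame in printed-table column order.
#' @export
combine_interval_tables <- function(tab1, tab2, threshold_pct = 10) {
  stopifnot(identical(tab1$roi, tab2$roi))
  out <- data.frame(roi = tab1$roi, tissue_class = tab1$tissue_class,
                    roi_vol = tab1$roi_vol,
                    expand_vol_1 = tab1$expand_vol, expand_pct_1 = tab1$expand_pct,
                    shrink_vol_1 = tab1$shrink_vol, shrink_pct_1 = tab1$shrink_pct,
                    expand_vol_2 = tab2$expand_vol, expand_pct_2 = tab2$expand_pct,
                    shrink_vol_2 = tab2$shrink_vol, shrink_pct_2 = tab2$shrink_pct,
                    stringsAsFactors = FALSE)
  out$overall_pct <- vapply(seq_len(nrow(out)), function(i)
    overall_change(tab1[i, ], tab2[i, ]), numeric(1))
  out$pattern <- vapply(seq_len(nrow(out)), function(i)
    classify_pattern(tab1[i, ], tab2[i, ], threshold_pct = threshold_pct),
    character(1))
  out
}
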