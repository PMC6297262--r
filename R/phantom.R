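#' Phantom geometry
#'
#' Default acquisition-like grid: 160 x 160 in-plane matrix at 0.2 mm
#' in-plane resolution, 32 slices. Through-plane spacing is exposed as a
#' knob (default 1 mm). A 64 x 64 x 32 grid at the same spacing is used
#' throughout the test-suite for speed.
#'
#' @param dim integer length-3 grid shape.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return geometry list with `dim`, `spacing`, `origin`.
#' @export
phantom_geometry <- function(dim = c(160L, 160L, 32L), spacing = c(0.2, 0.2, 1.0)) {
  stopifnot(length(dim) == 3, all(dim > 0), length(spacing) == 3, all(spacing > 0))
  list(dim = as.integer(dim), spacing = as.numeric(spacing), origin = c(0, 0, 0))
}

#' Default ROI layout for the phantom brain
#'
#' Places compact ellipsoidal compartments inside an ellipsoidal brain
#' envelope, mirror-symmetric about the central sagittal (first-axis)
#' plane: prelimbic and infralimbic cortex, nucleus accumbens, lateral
#' ventricles, central and VPL/VPM thalamus, anterior pretectal nuclei,
#' superior and inferior colliculi, and a midline CSF pool above the
#' frontal regions. Positions and semi-axes are in mm relative to the
#' grid centre; CSF compartments are bright on the T2-like contrast.
#'
#' @return data.frame with one row per ROI: `name`, centre offsets
#'   `x`,`y`,`z`, semi-axes `sx`,`sy`,`sz`, `bilateral`, `intensity`,
#'   `tissue_class`.
#' @export
default_roi_layout <- function() {
  data.frame(
    name = c("prelimbic", "infralimbic", "csf_above_frontal", "accumbens",
             "ventricles", "central_thalamus", "vpl_vpm_thalamus",
             "anterior_pretectal", "superior_colliculus", "inferior_colliculus"),
    x  = c(1.2, 1.2, 0.0, 2.2, 2.8, 1.5, 3.8, 1.5, 1.8, 1.8),
    y  = c(1.5, -1.5, 0.5, -1.0, 1.0, 1.2, 1.0, -1.2, 1.8, 1.5),
    z  = c(8.8, 8.8, 11.4, 6.0, 2.0, -2.0, -2.0, -5.0, -7.5, -11.0),
    sx = c(0.9, 0.7, 1.6, 0.9, 0.9, 1.0, 0.7, 0.6, 1.1, 1.0),
    sy = c(1.2, 0.9, 0.8, 0.9, 1.1, 1.1, 0.8, 0.7, 1.0, 1.0),
    sz = c(1.6, 1.3, 0.9, 1.4, 1.4, 1.8, 1.2, 1.0, 1.6, 1.3),
    bilateral = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    intensity = c(120, 115, 180, 125, 185, 130, 120, 125, 135, 130),
    tissue_class = c("tissue", "tissue", "csf", "tissue", "csf", "tissue",
                     "tissue", "tissue", "tissue", "tissue"),
    stringsAsFactors = FALSE
  )
}

# Envelope semi-axes (mm) for a given geometry: a brain-shaped ellipsoid
# filling most of the grid.
envelope_semiaxes <- function(geom) {
  ext <- geom$dim * geom$spacing
  c(0.45 * ext[1], 0.45 * ext[2], 0.45 * ext[3])
}

roi_centers_mm <- function(layout_row, geom) {
  ctr <- grid_center_mm(geom)
  base <- ctr + c(layout_row$x, layout_row$y, layout_row$z)
  if (!layout_row$bilateral) return(list(base))
  mirr <- base
  # mirror about the central sagittal plane of the grid (first axis)
  mirr[1] <- 2 * ctr[1] - base[1]
  list(base, mirr)
}

#' Build the base phantom anatomy
#'
#' Generates a T2-like intensity volume (CSF bright, tissue intermediate,
#' background near zero) with a matching integer label map. Bilateral ROIs
#' are mirror-symmetric about the central sagittal plane. Layout regions
#' that overlap one another or leave the brain envelope are rejected.
#'
#' @param geometry from [phantom_geometry()].
#' @param roi_layout data.frame as from [default_roi_layout()]; an empty
#'   (zero-row) layout yields a brain envelope only.
#' @param seed reserved for optional texture; the label map is a pure
#'   function of geometry and layout.
#' @param tissue_intensity,smooth_sigma_vox appearance parameters.
#' @return list with `volume` (an [image_volume()] carrying the envelope
#'   mask) and `labels` (a [label_volume()]; layout metadata attached as
#'   attribute `"layout"`).
#' @export
make_base_phantom <- function(geometry, roi_layout = default_roi_layout(), seed = 1L,
                              tissue_intensity = 100, smooth_sigma_vox = c(0.7, 0.7, 0.35)) {
  geom <- geometry
  w <- world_coords(geom)
  ctr <- grid_center_mm(geom)
  env <- envelope_semiaxes(geom)
  envelope <- ((w$x - ctr[1]) / env[1])^2 + ((w$y - ctr[2]) / env[2])^2 +
    ((w$z - ctr[3]) / env[3])^2 <= 1
  vol <- array(0, geom$dim)
  vol[envelope] <- tissue_intensity
  labels <- array(0L, geom$dim)
  if (nrow(roi_layout) > 0) {
    for (r in seq_len(nrow(roi_layout))) {
      row <- roi_layout[r, ]
      id <- r
      for (cen in roi_centers_mm(row, geom)) {
        semi <- c(row$sx, row$sy, row$sz)
        wmax <- geom$origin + (geom$dim - 1) * geom$spacing
        if (any(cen - semi < geom$origin) || any(cen + semi > wmax))
          stop(sprintf("ROI '%s' exits the grid", row$name))
        inside <- ((w$x - cen[1]) / row$sx)^2 + ((w$y - cen[2]) / row$sy)^2 +
          ((w$z - cen[3]) / row$sz)^2 <= 1
        if (any(inside & !envelope))
          stop(sprintf("ROI '%s' exits the brain envelope", row$name))
        if (any(labels[inside] != 0L)) {
          hit <- unique(labels[inside])
          hit <- hit[hit != 0L]
          stop(sprintf("ROI '%s' overlaps ROI(s): %s", row$name,
                       paste(roi_layout$name[hit], collapse = ", ")))
        }
        labels[inside] <- id
        vol[inside] <- row$intensity
      }
    }
  }
  vol <- cpp_gauss_smooth(vol, smooth_sigma_vox)
  iv <- image_volume(vol, spacing = geom$spacing, origin = geom$origin, mask = envelope)
  lut <- if (nrow(roi_layout) > 0) {
    data.frame(id = seq_len(nrow(roi_layout)), name = roi_layout$name,
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = integer(0), name = character(0), stringsAsFactors = FALSE)
  }
  lv <- label_volume(labels, lut = lut, spacing = geom$spacing, origin = geom$origin)
  attr(lv, "layout") <- roi_layout
  list(volume = iv, labels = lv)
}

#' Analytic radial warp with exactly known Jacobian
#'
#' A compactly supported radial transform about `center`: the ball of
#' `inner_radius` is scaled uniformly by `volume_ratio^(1/3)` (so the local
#' volume ratio there is exactly `volume_ratio`), and the radial map blends
#' C1-smoothly (cubic Hermite in radius) to the identity at `outer_radius`.
#' Monotonicity of the radial profile is verified numerically on 1024
#' samples before the field is emitted, so the transform is fold-free.
#'
#' @param center world-mm 3-vector.
#' @param inner_radius,outer_radius mm, `0 < inner < outer`.
#' @param volume_ratio dimensionless local volume multiplier (> 0; 1 = no
#'   change).
#' @return an `analytic_warp` specification.
#' @export
analytic_warp_spec <- function(center, inner_radius, outer_radius, volume_ratio) {
  stopifnot(length(center) == 3)
  if (!(inner_radius > 0 && outer_radius > inner_radius))
    stop("require 0 < inner_radius < outer_radius")
  if (!(volume_ratio > 0)) stop("volume_ratio must be > 0")
  structure(list(center = as.numeric(center), inner_radius = inner_radius,
                 outer_radius = outer_radius, volume_ratio = volume_ratio),
            class = "analytic_warp")
}

# Radial profile f(r): s*r inside a, identity beyond b, Hermite in between.
radial_profile <- function(r, a, b, s) {
  out <- r
  out[r <= a] <- s * r[r <= a]
  mid <- r > a & r < b
  if (any(mid)) {
    t <- (r[mid] - a) / (b - a)
    h00 <- 2 * t^3 - 3 * t^2 + 1
    h10 <- t^3 - 2 * t^2 + t
    h01 <- -2 * t^3 + 3 * t^2
    h11 <- t^3 - t^2
    out[mid] <- h00 * (s * a) + h10 * (b - a) * s + h01 * b + h11 * (b - a) * 1
  }
  out
}

#' @rdname analytic_warp_spec
#' @param spec an `analytic_warp`.
#' @param geometry grid geometry the field is sampled on.
#' @export
make_analytic_warp <- function(spec, geometry) {
  stopifnot(inherits(spec, "analytic_warp"))
  a <- spec$inner_radius; b <- spec$outer_radius
  s <- spec$volume_ratio^(1 / 3)
  if (spec$volume_ratio == 1)
    return(identity_field(geometry))
  rs <- seq(a, b, length.out = 1024)
  fr <- radial_profile(rs, a, b, s)
  if (any(diff(fr) <= 0))
    stop(sprintf("radial profile is not strictly increasing for volume_ratio %.4g (would fold)",
                 spec$volume_ratio))
  w <- world_coords(geometry)
  dx <- w$x - spec$center[1]; dy <- w$y - spec$center[2]; dz <- w$z - spec$center[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  scale <- array(0, geometry$dim)
  act <- r < b & r > 0
  scale[act] <- radial_profile(r[act], a, b, s) / r[act] - 1
  u <- array(0, c(geometry$dim, 3))
  u[, , , 1] <- scale * dx
  u[, , , 2] <- scale * dy
  u[, , , 3] <- scale * dz
  displacement_field(u, spacing = geometry$spacing, origin = geometry$origin)
}

#' Acquisition artifacts: multiplicative bias and additive noise
#'
#' Multiplies the image by a smooth low-order-polynomial bias field with
#' unit mean over the brain mask, then adds zero-mean Gaussian noise.
#' Deterministic given `seed`.
#'
#' @param vol an [image_volume()] (its mask, or `data > 1e-6`, defines the
#'   brain for bias normalisation).
#' @param noise_sigma additive noise standard deviation (intensity units).
#' @param bias_amplitude peak relative amplitude of the bias modulation.
#' @param seed integer RNG seed.
#' @return an [image_volume()] with artifacts applied.
#' @export
add_acquisition_artifacts <- function(vol, noise_sigma, bias_amplitude, seed) {
  stopifnot(noise_sigma >= 0, bias_amplitude >= 0)
  if (noise_sigma == 0 && bias_amplitude == 0) return(vol)
  geom <- geometry_of(vol)
  mask <- if (!is.null(vol$mask)) vol$mask else vol$data > 1e-6
  out <- vol
  with_seed(as.integer(seed), {
    data <- vol$data
    if (bias_amplitude > 0) {
      w <- world_coords(geom)
      ctr <- grid_center_mm(geom)
      ext <- geom$dim * geom$spacing / 2
      xn <- (w$x - ctr[1]) / ext[1]; yn <- (w$y - ctr[2]) / ext[2]
      zn <- (w$z - ctr[3]) / ext[3]
      basis <- list(xn, yn, zn, xn * yn, xn * zn, yn * zn, xn^2, yn^2, zn^2)
      cf <- rnorm(length(basis))
      q <- Reduce(`+`, Map(`*`, basis, as.list(cf)))
      q <- q - mean(q[mask])
      q <- q / max(abs(q[mask]))
      bias <- 1 + bias_amplitude * q
      bias <- bias / mean(bias[mask])
      data <- data * bias
    }
    if (noise_sigma > 0)
      data <- data + array(rnorm(length(data), sd = noise_sigma), dim(data))
    out$data <- data
  })
  out
}

#' Smooth random per-subject jitter field
#'
#' Anatomical variability surrogate: white noise smoothed to a coarse
#' scale and rescaled so the maximum displacement magnitude is `max_vox`
#' voxels (measured per-axis in voxel units). Fixed per subject across
#' timepoints.
#'
#' @param geometry grid geometry.
#' @param max_vox maximum displacement in voxel units (default 2).
#' @param seed integer seed.
#' @return a `displacement_field`.
#' @export
make_jitter_field <- function(geometry, max_vox = 2, seed = 1L) {
  geom <- geometry
  u <- with_seed(as.integer(seed), array(rnorm(prod(geom$dim) * 3), c(geom$dim, 3)))
  u <- cpp_gauss_smooth(u, c(8, 8, 4))
  # magnitude in voxel units
  mag <- sqrt((u[, , , 1])^2 + (u[, , , 2])^2 + (u[, , , 3])^2)
  u <- u * (max_vox / max(mag, 1e-12))
  for (c in 1:3) u[, , , c] <- u[, , , c] * geom$spacing[c]
  displacement_field(u, spacing = geom$spacing, origin = geom$origin)
}

#' Effect specification
#'
#' Encodes a per-ROI, per-interval, per-group local volume change: the
#' named ROI's local volume is multiplied by `volume_ratio` over the
#' interval (1 = baseline to binge, 2 = binge to recovery).
#'
#' @param roi ROI name (must exist in the phantom layout).
#' @param interval 1 or 2.
#' @param group `"EtOH"` or `"Con"`.
#' @param volume_ratio dimensionless multiplier (> 0).
#' @export
effect_spec <- function(roi, interval, group, volume_ratio) {
  stopifnot(interval %in% c(1, 2), group %in% c("EtOH", "Con"), volume_ratio > 0)
  data.frame(roi = roi, interval = as.integer(interval), group = group,
             volume_ratio = volume_ratio, stringsAsFactors = FALSE)
}

# Volume (in fine-grid cells) of each ROI after pulling the label map
# through `field`, measured on a supersampled grid so that sub-voxel
# (especially sub-slice) boundary motion is resolved.
measure_label_counts <- function(field, labels, n_roi, upsample = c(2L, 2L, 4L)) {
  g <- geometry_of_field(field)
  fd <- g$dim * upsample
  fs <- g$spacing / upsample
  # fine-grid voxel centres in coarse-grid voxel units
  xi <- ((seq_len(fd[1]) - 0.5) / upsample[1]) - 0.5
  yi <- ((seq_len(fd[2]) - 0.5) / upsample[2]) - 0.5
  zi <- ((seq_len(fd[3]) - 0.5) / upsample[3]) - 0.5
  xs <- rep(xi, times = fd[2] * fd[3])
  ys <- rep(rep(yi, each = fd[1]), times = fd[3])
  zs <- rep(zi, each = fd[1] * fd[2])
  px <- xs + cpp_sample(field$u[, , , 1], xs, ys, zs, FALSE, 1L, 0) / g$spacing[1]
  py <- ys + cpp_sample(field$u[, , , 2], xs, ys, zs, FALSE, 1L, 0) / g$spacing[2]
  pz <- zs + cpp_sample(field$u[, , , 3], xs, ys, zs, FALSE, 1L, 0) / g$spacing[3]
  lab <- cpp_sample(labels + 0.0, px, py, pz, TRUE, 0L, 0)
  tabulate(as.integer(lab), nbins = n_roi)
}

# Pullback field implementing all effects of one (group, interval):
# an analytic warp of ratio 1/volume_ratio at each affected ROI centre
# (both mirror centres for bilateral ROIs), composed sequentially.
effect_pullback <- function(effects, layout, geom) {
  fld <- NULL
  for (r in seq_len(nrow(effects))) {
    e <- effects[r, ]
    row <- layout[layout$name == e$roi, ]
    # the inner ball must contain the ROI's *preimage* under the pullback,
    # which for an expansion is the ROI enlarged by volume_ratio^(1/3)
    inner <- (max(row$sx, row$sy, row$sz) + 0.4) * max(e$volume_ratio, 1)^(1 / 3)
    outer <- inner * 1.5
    for (cen in roi_centers_mm(row, geom)) {
      spec <- analytic_warp_spec(cen, inner, outer, 1 / e$volume_ratio)
      wf <- make_analytic_warp(spec, geom)
      fld <- if (is.null(fld)) wf else compose_fields(fld, wf)
    }
  }
  if (is.null(fld)) identity_field(geom) else fld
}

#' Simulate a longitudinal phantom cohort
#'
#' Generates a three-timepoint scan series per subject: a per-subject
#' smooth jitter warp (fixed across timepoints) models anatomical
#' variability; group- and interval-specific effect warps change ROI
#' volumes by prescribed ratios; acquisition artifacts are applied
#' independently per scan. All scans are written as uncompressed NIfTI-1,
#' the cohort manifest and analytic ground-truth ROI volume ratios as CSV,
#' and the clean base anatomy as template/atlas files.
#'
#' @param config list: `n_etoh`, `n_con`, `geometry`, optional
#'   `roi_layout` and `jitter_max_vox` (default 2).
#' @param effects data.frame of [effect_spec()] rows (possibly 0-row).
#' @param artifact_params list with `noise_sigma`, `bias_amplitude`.
#' @param seed integer master seed; all per-subject and per-scan seeds are
#'   derived from it.
#' @param outdir output directory (created if needed).
#' @return invisibly, the cohort manifest: list with `subjects`
#'   (data.frame: subject, group, scan1..3 paths), `truth` (data.frame),
#'   `geometry`, `seed`, and file paths (`manifest`, `truth_file`,
#'   `template`, `template_mask`, `atlas_labels`, `atlas_lut`,
#'   `atlas_tissue`).
#' @export
simulate_cohort <- function(config, effects = NULL, artifact_params = list(noise_sigma = 4, bias_amplitude = 0.1),
                            seed = 1L, outdir) {
  geom <- config$geometry
  layout <- config$roi_layout
  if (is.null(layout)) layout <- default_roi_layout()
  jitter_max <- if (is.null(config$jitter_max_vox)) 2 else config$jitter_max_vox
  if (is.null(effects)) effects <- effect_spec("ventricles", 1, "EtOH", 1)[0, ]
  bad <- setdiff(unique(effects$roi), layout$name)
  if (length(bad) > 0)
    stop("effect ROIs missing from layout: ", paste(bad, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  base <- make_base_phantom(geom, layout, seed = seed)
  write_volume(base$volume, file.path(outdir, "template.nii"))
  maskvol <- image_volume(base$volume$mask + 0, geom$spacing, geom$origin)
  write_volume(maskvol, file.path(outdir, "template_mask.nii"))
  write_volume(base$labels, file.path(outdir, "atlas_labels.nii"))
  write.csv(base$labels$lut, file.path(outdir, "atlas_lut.csv"), row.names = FALSE)
  write.csv(data.frame(name = layout$name, tissue_class = layout$tissue_class,
                       stringsAsFactors = FALSE),
            file.path(outdir, "atlas_tissue.csv"), row.names = FALSE)

  # pullback fields per group and cumulative timepoint
  groups <- c("EtOH", "Con")
  pull <- list()
  for (g in groups) {
    c1 <- effect_pullback(effects[effects$group == g & effects$interval == 1, , drop = FALSE],
                          layout, geom)
    c2 <- effect_pullback(effects[effects$group == g & effects$interval == 2, , drop = FALSE],
                          layout, geom)
    pull[[g]] <- list(identity_field(geom), c1, compose_fields(c1, c2))
  }

  ids <- sprintf("S%02d", seq_len(config$n_etoh + config$n_con))
  grp <- c(rep("EtOH", config$n_etoh), rep("Con", config$n_con))
  rows <- list()
  truth <- list()
  for (si in seq_along(ids)) {
    jit <- make_jitter_field(geom, max_vox = jitter_max,
                             seed = child_seed(seed, "jitter", si))
    paths <- character(3)
    counts <- matrix(0, nrow = nrow(layout), ncol = 3)
    for (tp in 1:3) {
      m <- compose_fields(pull[[grp[si]]][[tp]], jit)
      ivol <- warp(base$volume, m, "linear")
      counts[, tp] <- measure_label_counts(m, base$labels$labels, nrow(layout))
      ivol$mask <- NULL  # raw scans carry no mask; stripping recovers it
      scan <- add_acquisition_artifacts(ivol, artifact_params$noise_sigma,
                                        artifact_params$bias_amplitude,
                                        seed = child_seed(seed, "scan", si, tp))
      paths[tp] <- file.path(outdir, sprintf("sub-%s_t%d.nii", ids[si], tp))
      write_volume(scan, paths[tp])
    }
    rows[[si]] <- data.frame(subject = ids[si], group = grp[si],
                             scan1 = paths[1], scan2 = paths[2], scan3 = paths[3],
                             stringsAsFactors = FALSE)
    for (iv in 1:2) {
      truth[[length(truth) + 1]] <- data.frame(
        subject = ids[si], roi = layout$name, interval = iv,
        true_ratio = counts[, iv + 1] / pmax(counts[, iv], 1),
        stringsAsFactors = FALSE)
    }
  }
  subjects <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)
  write.csv(subjects, file.path(outdir, "manifest.csv"), row.names = FALSE)
  write.csv(truth, file.path(outdir, "truth.csv"), row.names = FALSE)
  invisible(list(subjects = subjects, truth = truth, geometry = geom, seed = seed,
                 manifest = file.path(outdir, "manifest.csv"),
                 truth_file = file.path(outdir, "truth.csv"),
                 template = file.path(outdir, "template.nii"),
                 template_mask = file.path(outdir, "template_mask.nii"),
                 atlas_labels = file.path(outdir, "atlas_labels.nii"),
                 atlas_lut = file.path(outdir, "atlas_lut.csv"),
                 atlas_tissue = file.path(outdir, "atlas_tissue.csv")))
}
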