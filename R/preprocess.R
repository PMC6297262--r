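#' Edge-preserving denoising
#'
#' Non-local-means patch averaging (patch radius 1, search radius 2). The
#' filter bandwidth is tied to a noise estimate taken from the background
#' (voxels outside the brain mask, or the darkest decile when no mask is
#' present) and scaled by `strength`; `strength = 0` returns the input
#' unchanged.
#'
#' @param vol an [image_volume()].
#' @param strength non-negative bandwidth multiplier (default 1).
#' @param patch_radius,search_radius NLM window radii in voxels.
#' @return the denoised [image_volume()].
#' @export
denoise <- function(vol, strength = 1, patch_radius = 1, search_radius = 2) {
  stopifnot(strength >= 0)
  if (strength == 0) return(vol)
  sigma <- estimate_noise_sigma(vol)
  if (sigma <= 0) return(vol)
  out <- vol
  out$data <- cpp_nlm(vol$data, h = strength * 2 * sigma,
                      pr = as.integer(patch_radius), sr = as.integer(search_radius))
  out
}

# Background-based noise estimate: sd of high-pass residuals in the
# darkest region (robust to the anatomy itself).
estimate_noise_sigma <- function(vol) {
  bg <- if (!is.null(vol$mask)) !vol$mask else
    vol$data < quantile(vol$data, 0.1, names = FALSE)
  if (sum(bg) < 100) bg <- array(TRUE, dim(vol$data))
  smoothed <- cpp_gauss_smooth(vol$data, c(1, 1, 1))
  stats::mad(vol$data[bg] - smoothed[bg])
}

#' Bias-field estimation and correction
#'
#' Estimates a smooth multiplicative inhomogeneity field by low-order
#' polynomial regression of log-intensity within the brain mask, divides
#' it out, and returns both the corrected image and the field. The field
#' has unit mean over the mask and is strictly positive, so
#' `corrected * field` reconstructs the input exactly.
#'
#' @param vol an [image_volume()]; its mask (or the whole grid) defines
#'   the fit support. Fewer than 100 mask voxels is rejected as
#'   underdetermined.
#' @param order total polynomial degree of the log-domain fit (default 3).
#' @return list with `corrected` ([image_volume()]) and `field` (3D array).
#' @export
correct_bias <- function(vol, order = 3) {
  mask <- mask_or_all(vol)
  if (sum(mask) < 100) stop("bias correction needs >= 100 mask voxels")
  geom <- geometry_of(vol)
  w <- world_coords(geom)
  ctr <- grid_center_mm(geom)
  ext <- geom$dim * geom$spacing / 2
  xn <- (w$x - ctr[1]) / ext[1]; yn <- (w$y - ctr[2]) / ext[2]
  zn <- (w$z - ctr[3]) / ext[3]
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j))
    cols[[length(cols) + 1]] <- xn^i * yn^j * zn^k
  midx <- which(mask)
  # a smooth low-order field is fully determined by a modest subsample
  if (length(midx) > 40000) midx <- midx[seq(1, length(midx), length.out = 40000)]
  X <- vapply(cols, function(cc) cc[midx], numeric(length(midx)))
  eps <- 1e-6 * max(vol$data)
  y <- log(pmax(vol$data[midx], eps))
  pos <- vol$data[midx] > 0
  # anatomy (distinct tissue classes) is not in the polynomial span;
  # iteratively reweighted least squares treats it as outliers so the fit
  # follows the smooth inhomogeneity, not the structures
  wts <- as.numeric(pos)
  coefs <- NULL
  for (pass in 1:4) {
    fit <- lm.wfit(X, y, w = wts)
    coefs <- fit$coefficients
    r <- y - X %*% coefs
    s <- median(abs(r[pos])) / 0.6745
    if (s <= 0) break
    wts <- as.numeric(pos) * pmax(1 - (r / (3 * s))^2, 0)^2  # Tukey biweight
  }
  full <- Reduce(`+`, Map(`*`, cols, as.list(coefs)))
  # remove the constant so the field carries shape, not brightness
  field <- exp(full - mean(full[mask]))
  field <- field / mean(field[mask])
  field <- pmax(field, 0.05)
  out <- vol
  out$data <- vol$data / field
  list(corrected = out, field = field)
}

#' Skull stripping by template-mask propagation
#'
#' Aligns the template to the scan (rigid initialisation followed by
#' dense diffeomorphic registration), carries the template's brain mask
#' through the resulting deformation with nearest-neighbour interpolation,
#' zeroes everything outside it, and attaches the propagated mask to the
#' output. Never adds voxels outside the warped template mask.
#'
#' @param vol the scan to strip (an [image_volume()]).
#' @param template template [image_volume()].
#' @param template_mask logical array, the template's brain mask (defaults
#'   to the template's own mask).
#' @param params [reg_params()] for the dense registration.
#' @return the masked [image_volume()].
#' @export
skull_strip <- function(vol, template, template_mask = template$mask,
                        params = reg_params()) {
  if (is.null(template_mask)) stop("template must provide a brain mask")
  if (max(abs(vol$data)) == 0) stop("cannot skull strip: scan has no contrast")
  ra <- rigid_align(template, vol)
  tmpl_r <- ra$resampled
  mask_r <- apply_rigid(image_volume(template_mask + 0, template$spacing, template$origin),
                        ra$transform, vol, nearest = TRUE)
  tmpl_r$mask <- array(mask_r$data > 0.5, dim(vol$data))
  fld <- register_nonrigid(vol, tmpl_r, params)
  warped_mask <- cpp_warp_disp(tmpl_r$mask + 0, fld$u, fld$spacing, TRUE, 0)
  out <- vol
  out$mask <- array(warped_mask > 0.5, dim(vol$data))
  out$data[!out$mask] <- 0
  out
}

#' Rigid (6 degrees of freedom) intensity-driven alignment
#'
#' Maximises normalised cross-correlation over rotations and translations
#' with multi-resolution coordinate descent from several starting
#' orientations. Rotations are about the volume centre.
#'
#' @param moving,fixed skull-stripped [image_volume()]s.
#' @param multi_start list of initial rotation vectors (radians, about
#'   x/y/z); defaults to the identity plus half-turns about each axis.
#' @return list with `resampled` (moving resampled on the fixed grid),
#'   and `transform` (list `rotation` 3x3, `translation` mm, `center` mm).
#' @export
rigid_align <- function(moving, fixed,
                        multi_start = list(c(0, 0, 0), c(pi, 0, 0), c(0, pi, 0), c(0, 0, pi))) {
  if (max(abs(moving$data)) == 0 || max(abs(fixed$data)) == 0)
    stop("cannot align: a volume has no contrast")
  pyr_f <- list(fixed); pyr_m <- list(moving)
  for (l in 1:2) {
    pyr_f[[l + 1]] <- downsample_volume(pyr_f[[l]])
    pyr_m[[l + 1]] <- downsample_volume(pyr_m[[l]])
  }
  ctr <- grid_center_mm(geometry_of(fixed))
  # per level: fixed masked sample positions (world mm) and values
  level_ctx <- lapply(1:3, function(l) {
    f <- pyr_f[[l]]
    gm <- geometry_of(pyr_m[[l]])
    fm <- mask_or_all(f)
    w <- world_coords(geometry_of(f))
    pts <- cbind(w$x[fm], w$y[fm], w$z[fm])
    fvals <- f$data[fm]
    # the NCC surface is smooth; ~20k samples locate its optimum as well
    # as the full voxel set at a fraction of the cost
    if (nrow(pts) > 20000) {
      keep <- seq(1, nrow(pts), length.out = 20000)
      pts <- pts[keep, , drop = FALSE]
      fvals <- fvals[keep]
    }
    list(pts = pts, fvals = fvals,
         morigin = gm$origin, mspacing = gm$spacing, mdata = pyr_m[[l]]$data)
  })
  ncc_at <- function(par, ctx) {
    R <- rot_matrix(par[1:3])
    q <- sweep(ctx$pts, 2, ctr) %*% t(R)
    q <- sweep(q, 2, ctr + par[4:6], `+`)
    b <- cpp_sample(ctx$mdata,
                    (q[, 1] - ctx$morigin[1]) / ctx$mspacing[1],
                    (q[, 2] - ctx$morigin[2]) / ctx$mspacing[2],
                    (q[, 3] - ctx$morigin[3]) / ctx$mspacing[3], FALSE, 0L, 0)
    if (sd(b) < 1e-12) return(-1)
    suppressWarnings(cor(ctx$fvals, b))
  }
  descend <- function(par, ctx, steps, min_steps) {
    val <- ncc_at(par, ctx)
    while (any(steps > min_steps)) {
      improved <- FALSE
      for (i in seq_along(par)) {
        for (sgn in c(1, -1)) {
          cand <- par; cand[i] <- cand[i] + sgn * steps[i]
          v <- ncc_at(cand, ctx)
          if (v > val + 1e-9) { par <- cand; val <- v; improved <- TRUE; break }
        }
      }
      if (!improved) steps <- steps / 2
    }
    list(par = par, val = val)
  }
  # coarsest level: try each starting orientation
  sp3 <- pyr_f[[3]]$spacing
  coarse <- lapply(multi_start, function(rot)
    descend(c(rot, 0, 0, 0), level_ctx[[3]],
            steps = c(rep(0.1, 3), rep(2 * max(sp3), 3)),
            min_steps = c(rep(0.01, 3), rep(0.2 * min(sp3), 3))))
  par <- coarse[[which.max(vapply(coarse, `[[`, numeric(1), "val"))]]$par
  for (l in 2:1) {
    spl <- pyr_f[[l]]$spacing
    par <- descend(par, level_ctx[[l]],
                   steps = c(rep(0.02, 3), rep(min(spl), 3)),
                   min_steps = c(rep(0.002, 3), rep(0.1 * min(spl), 3)))$par
  }
  tr <- par_to_transform(par, fixed)
  list(resampled = apply_rigid(moving, tr, fixed, nearest = FALSE), transform = tr)
}

#' Serialize a rigid transform as a plain-text 4 x 4 matrix
#'
#' The homogeneous matrix maps world coordinates:
#' `y = R (x - c) + c + t`, folded into a single affine.
#'
#' @param transform list with `rotation`, `translation`, `center` (as
#'   returned by [rigid_align()]).
#' @param path text file path.
#' @export
write_rigid_transform <- function(transform, path) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$center + transform$translation -
    transform$rotation %*% transform$center
  writeLines(apply(m, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), con = path)
  invisible(path)
}

#' @rdname write_rigid_transform
#' @export
read_rigid_transform <- function(path) {
  m <- matrix(scan(path, quiet = TRUE), 4, 4, byrow = TRUE)
  R <- m[1:3, 1:3]
  if (abs(det(R) - 1) > 1e-6) stop("not a proper rotation (det != +1)")
  list(rotation = R, translation = as.numeric(m[1:3, 4]), center = c(0, 0, 0))
}

rot_matrix <- function(ang) {
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]), 0, -sin(ang[1]), cos(ang[1])), 3)
  Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0, sin(ang[2]), 0, cos(ang[2])), 3)
  Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

par_to_transform <- function(par, fixed) {
  list(rotation = rot_matrix(par[1:3]), translation = par[4:6],
       center = grid_center_mm(geometry_of(fixed)))
}

# Resample `moving` on the fixed grid through a rigid transform: the
# sample point for fixed-grid position x is R (x - c) + c + t.
apply_rigid <- function(moving, transform, fixed, nearest = FALSE) {
  gf <- geometry_of(fixed)
  gm <- geometry_of(moving)
  w <- world_coords(gf)
  pts <- cbind(as.vector(w$x), as.vector(w$y), as.vector(w$z))
  ctr <- matrix(transform$center, nrow(pts), 3, byrow = TRUE)
  q <- (pts - ctr) %*% t(transform$rotation) + ctr +
    matrix(transform$translation, nrow(pts), 3, byrow = TRUE)
  xs <- (q[, 1] - gm$origin[1]) / gm$spacing[1]
  ys <- (q[, 2] - gm$origin[2]) / gm$spacing[2]
  zs <- (q[, 3] - gm$origin[3]) / gm$spacing[3]
  out_data <- array(cpp_sample(moving$data, xs, ys, zs, nearest, 0L, 0), gf$dim)
  out <- image_volume(out_data, gf$spacing, gf$origin)
  if (!is.null(moving$mask)) {
    m <- array(cpp_sample(moving$mask + 0, xs, ys, zs, TRUE, 0L, 0), gf$dim)
    out$mask <- m > 0.5
  }
  out
}

#' Monotone histogram matching
#'
#' Maps the source intensity distribution onto the reference distribution
#' within the brain masks by exact quantile matching: each masked source
#' voxel is replaced by the reference quantile at its own (mid-rank)
#' cumulative probability. The map is monotone, so the rank order of
#' source voxels is preserved. Used to match the earlier scan of an
#' interval to the later one before non-rigid registration.
#'
#' @param source,reference [image_volume()]s masked to the brain.
#' @return the matched [image_volume()] (background left unchanged).
#' @export
match_intensity <- function(source, reference) {
  smask <- mask_or_all(source)
  rmask <- mask_or_all(reference)
  sv <- source$data[smask]
  if (max(sv) - min(sv) < 1e-12)
    stop("histogram matching undefined for a constant source image")
  pr <- (rank(sv, ties.method = "average") - 1) / max(length(sv) - 1, 1)
  matched <- quantile(reference$data[rmask], probs = pr, names = FALSE, type = 7)
  out <- source
  out$data[smask] <- matched
  out
}
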