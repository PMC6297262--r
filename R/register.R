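#' Registration parameters
#'
#' Controls the dense diffeomorphic (demons-type) registration: a stationary
#' velocity field is updated from the intensity-difference force, smoothed
#' (fluid-like regularisation, `sigma_update_mm`), accumulated, smoothed
#' again (diffusion-like regularisation, `sigma_total_mm`), and
#' exponentiated by scaling-and-squaring to guarantee a positive-Jacobian
#' transform.
#'
#' @param levels number of multi-resolution levels (>= 1).
#' @param iterations iterations per level, coarsest first (recycled).
#' @param sigma_update_mm Gaussian sigma (mm) applied to each update force.
#' @param sigma_total_mm Gaussian sigma (mm) applied to the accumulated
#'   velocity field.
#' @param step step length multiplying the demons force.
#' @param tol relative mean-squared-difference improvement below which a
#'   level stops early.
#' @param max_step_vox cap on the per-iteration force magnitude, in voxels.
#' @param histogram_match match the moving image's intensity distribution
#'   to the fixed image before registration (the intensity-difference
#'   force assumes comparable intensities).
#' @return a `reg_params` list.
#' @export
reg_params <- function(levels = 3, iterations = c(40, 30, 30),
                       sigma_update_mm = 0.5, sigma_total_mm = 0.15,
                       step = 1.0, tol = 1e-4, max_step_vox = 0.8,
                       histogram_match = FALSE) {
  stopifnot(levels >= 1, sigma_update_mm >= 0, sigma_total_mm >= 0)
  list(levels = as.integer(levels),
       iterations = rep_len(as.integer(iterations), levels),
       sigma_update_mm = sigma_update_mm, sigma_total_mm = sigma_total_mm,
       step = step, tol = tol, max_step_vox = max_step_vox,
       histogram_match = isTRUE(histogram_match))
}

# Median of the foreground (above 10% of the robust maximum) within the
# mask: a tissue-level intensity scale that ignores how much background
# the mask happens to include.
foreground_scale <- function(data, mask) {
  v <- abs(data[mask])
  hi <- quantile(v, 0.99, names = FALSE)
  fg <- v > 0.1 * hi
  if (!any(fg)) return(max(hi, 1e-12))
  median(v[fg])
}

# Central-difference spatial gradient (world mm) of a 3D array.
gradient3 <- function(a, spacing) {
  d <- dim(a)
  g <- vector("list", 3)
  for (ax in 1:3) {
    hi <- a; lo <- a
    n <- d[ax]
    idx_hi <- c(2:n, n)
    idx_lo <- c(1, 1:(n - 1))
    if (ax == 1) { hi <- a[idx_hi, , , drop = FALSE]; lo <- a[idx_lo, , , drop = FALSE] }
    if (ax == 2) { hi <- a[, idx_hi, , drop = FALSE]; lo <- a[, idx_lo, , drop = FALSE] }
    if (ax == 3) { hi <- a[, , idx_hi, drop = FALSE]; lo <- a[, , idx_lo, drop = FALSE] }
    den <- array(2 * spacing[ax], d)
    if (ax == 1) { den[1, , ] <- spacing[ax]; den[n, , ] <- spacing[ax] }
    if (ax == 2) { den[, 1, ] <- spacing[ax]; den[, n, ] <- spacing[ax] }
    if (ax == 3) { den[, , 1] <- spacing[ax]; den[, , n] <- spacing[ax] }
    g[[ax]] <- (hi - lo) / den
  }
  g
}

downsample_volume <- function(vol) {
  out <- vol
  out$data <- cpp_downsample2(vol$data)
  out$spacing <- vol$spacing * 2
  out$affine <- affine_from(out$spacing, vol$origin)
  if (!is.null(vol$mask))
    out$mask <- array(cpp_downsample2(vol$mask + 0) > 0.25, dim(out$data))
  out
}

# Resample a per-component field array onto a finer grid (voxel-centre
# aligned), keeping displacement values in mm.
upsample_field_arr <- function(u, dim_to) {
  dfrom <- dim(u)[1:3]
  w <- expand_grid_coords(dim_to, dfrom)
  out <- array(0, c(dim_to, 3))
  for (c in 1:3) {
    out[, , , c] <- array(cpp_sample(u[, , , c], w$x, w$y, w$z, FALSE, 1L, 0),
                          dim_to)
  }
  out
}

expand_grid_coords <- function(dim_to, dim_from) {
  sc <- dim_from / dim_to
  xi <- (seq_len(dim_to[1]) - 0.5) * sc[1] - 0.5
  yi <- (seq_len(dim_to[2]) - 0.5) * sc[2] - 0.5
  zi <- (seq_len(dim_to[3]) - 0.5) * sc[3] - 0.5
  list(x = rep(xi, times = dim_to[2] * dim_to[3]),
       y = rep(rep(yi, each = dim_to[1]), times = dim_to[3]),
       z = rep(zi, each = dim_to[1] * dim_to[2]))
}

exp_velocity <- function(v, spacing) {
  maxvox <- max(abs(v[, , , 1]) / spacing[1], abs(v[, , , 2]) / spacing[2],
                abs(v[, , , 3]) / spacing[3])
  n_sq <- max(2L, ceiling(log2(max(maxvox, 1e-9) / 0.4)))
  cpp_exp_disp(v, spacing, n_sq)
}

#' Dense non-rigid diffeomorphic registration
#'
#' Registers `moving` to `fixed` with a multi-resolution log-domain
#' demons scheme and returns the displacement field on the fixed grid
#' (`phi(x) = x + u(x)` maps fixed-grid positions into the moving image).
#' The transform is the exponential of a smoothed stationary velocity
#' field, so the diffeomorphism contract (`det grad phi > 0` everywhere)
#' is enforced; a field violating it is never emitted.
#'
#' With the fixed image being the earlier scan of an interval and the
#' moving image the later one, `det grad phi` is the local (later / earlier)
#' volume ratio, so positive log-Jacobian means expansion over the interval.
#'
#' @param fixed,moving [image_volume()]s in the same world frame (rigidly
#'   pre-aligned), intensity-comparable (see [match_intensity()]).
#' @param params a [reg_params()] list.
#' @return a `displacement_field` with attributes `trace` (per-iteration
#'   masked mean-squared difference) and `msd` (initial/final).
#' @export
register_nonrigid <- function(fixed, moving, params = reg_params()) {
  if (!same_geometry(fixed, moving))
    stop("fixed and moving must share grid geometry")
  fmask <- mask_or_all(fixed)
  mmask <- mask_or_all(moving)
  if (!any(fmask & mmask)) stop("fixed and moving masks do not overlap")
  if (max(abs(fixed$data)) == 0 || max(abs(moving$data)) == 0)
    stop("cannot register: an input volume has no contrast")
  # contrast-scale invariance: normalise each image by its own foreground
  # median (the tissue level), which tracks a global intensity rescaling
  # exactly and is insensitive to focal volume changes
  fscale <- foreground_scale(fixed$data, fmask)
  mscale <- foreground_scale(moving$data, mmask)
  fvol <- fixed; fvol$data <- fixed$data / max(fscale, 1e-12)
  mvol <- moving; mvol$data <- moving$data / max(mscale, 1e-12)
  fvol$mask <- fmask; mvol$mask <- mmask
  if (params$histogram_match) mvol <- match_intensity(mvol, fvol)

  pyr_f <- list(fvol); pyr_m <- list(mvol)
  for (l in seq_len(params$levels - 1)) {
    pyr_f[[l + 1]] <- downsample_volume(pyr_f[[l]])
    pyr_m[[l + 1]] <- downsample_volume(pyr_m[[l]])
  }
  pyr_f <- rev(pyr_f); pyr_m <- rev(pyr_m)  # coarsest first

  v <- NULL
  trace <- numeric(0)
  umask <- fmask | mmask
  msd0 <- mean((fvol$data - mvol$data)[umask]^2)  # full-resolution baseline
  for (l in seq_len(params$levels)) {
    f <- pyr_f[[l]]; m <- pyr_m[[l]]
    sp <- f$spacing
    d <- dim(f$data)
    v <- if (is.null(v)) array(0, c(d, 3)) else upsample_field_arr(v, d)
    mask <- f$mask | m$mask
    K2 <- mean(sp)^2
    cap <- params$max_step_vox * min(sp)
    best <- Inf; stall <- 0L
    for (it in seq_len(params$iterations[l])) {
      u <- exp_velocity(v, sp)
      warped <- cpp_warp_disp(m$data, u, sp, FALSE, 0)
      # the Thirion force is scale-free in diff, so tiny residuals in flat
      # regions would otherwise still push ~sqrt(K2)/2; floor them out
      force <- cpp_demons_force(f$data, warped, mask, sp, K2, cap, 1e-4)
      msd <- attr(force, "msd")
      trace <- c(trace, msd)
      if (msd < best * (1 - params$tol)) { best <- msd; stall <- 0L } else stall <- stall + 1L
      if (stall >= 5L) break
      force <- smooth_field_arr(force, sp, params$sigma_update_mm, min_vox = 0.8)
      v <- smooth_field_arr(v + params$step * force, sp, params$sigma_total_mm,
                            min_vox = 0.3)
    }
  }
  u <- exp_velocity(v, fixed$spacing)
  # the exponential is fold-free in the continuum, but the discrete
  # determinant can still dip; re-smooth the velocity until it does not
  for (try in 1:3) {
    if (min(cpp_jacobian_det(u, fixed$spacing)) > 0) break
    v <- smooth_field_arr(v, fixed$spacing, params$sigma_total_mm, min_vox = 0.6 * try)
    u <- exp_velocity(v, fixed$spacing)
  }
  jdet <- cpp_jacobian_det(u, fixed$spacing)
  if (min(jdet) <= 0) {
    bad <- which(jdet <= 0)
    stop(sprintf("registration produced %d non-positive-Jacobian voxel(s) (first index %d)",
                 length(bad), bad[1]))
  }
  out <- displacement_field(u, spacing = fixed$spacing, origin = fixed$origin)
  attr(out, "trace") <- trace
  attr(out, "msd") <- c(initial = msd0, final = best)
  out
}

#' Group-wise unbiased template construction
#'
#' Iteratively registers every subject to an evolving mean image,
#' subtracts the mean displacement field from each subject's field each
#' outer iteration (unbiasing), and averages the warped images into the
#' new template. After the final iteration the per-subject fields have
#' zero mean displacement by construction.
#'
#' @param volumes list of >= 2 preprocessed, rigidly co-aligned
#'   [image_volume()]s.
#' @param params a [reg_params()] list used for each pairwise registration.
#' @param n_outer_iter outer (template-update) iterations.
#' @return a `groupwise_result`: list with `template` (an `image_volume`),
#'   `fields` (per subject, template grid to subject coordinates), and
#'   `trace` (RMS template change per iteration).
#' @export
build_groupwise_template <- function(volumes, params = reg_params(), n_outer_iter = 5) {
  n <- length(volumes)
  if (n < 2) stop("group-wise template needs at least 2 volumes")
  g1 <- geometry_of(volumes[[1]])
  for (i in seq_len(n)) {
    if (!same_geometry(volumes[[i]], volumes[[1]]))
      stop("all volumes must share grid geometry")
  }
  datas <- lapply(volumes, function(v) v$data)
  masks <- lapply(volumes, mask_or_all)
  tmpl_data <- Reduce(`+`, datas) / n
  tmpl_mask <- Reduce(`+`, masks) / n > 0.5
  template <- image_volume(tmpl_data, g1$spacing, g1$origin, mask = tmpl_mask)
  fields <- NULL
  trace <- numeric(0)
  for (outer in seq_len(n_outer_iter)) {
    fields <- vector("list", n)
    for (i in seq_len(n)) {
      fields[[i]] <- tryCatch(register_nonrigid(template, volumes[[i]], params),
                              error = function(e) stop(sprintf(
                                "group-wise registration failed for subject %d: %s",
                                i, conditionMessage(e))))
    }
    mean_u <- Reduce(`+`, lapply(fields, `[[`, "u")) / n
    warped_data <- vector("list", n)
    warped_mask <- vector("list", n)
    for (i in seq_len(n)) {
      fields[[i]]$u <- fields[[i]]$u - mean_u
      # cubic resampling keeps the evolving template sharp
      warped_data[[i]] <- cpp_warp_disp_cubic(datas[[i]], fields[[i]]$u, g1$spacing, 0)
      warped_mask[[i]] <- cpp_warp_disp(masks[[i]] + 0, fields[[i]]$u, g1$spacing, TRUE, 0)
    }
    new_data <- Reduce(`+`, warped_data) / n
    new_mask <- Reduce(`+`, warped_mask) / n > 0.5
    trace <- c(trace, sqrt(mean((new_data - template$data)^2)))
    template <- image_volume(new_data, g1$spacing, g1$origin, mask = new_mask)
  }
  structure(list(template = template, fields = fields, trace = trace),
            class = "groupwise_result")
}
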