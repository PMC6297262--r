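#' Dense displacement fields
#'
#' A `displacement_field` stores a per-voxel 3-vector displacement `u`
#' (mm, world frame) on the fixed image grid; the associated transform is
#' `phi(x) = x + u(x)`. All registration output is carried in this form.
#' The diffeomorphism contract requires `det(grad phi) > 0` at every
#' interior voxel.
#'
#' @param u 4D numeric array `[nx, ny, nz, 3]`, displacements in mm.
#' @param spacing voxel spacing (mm) of the fixed grid.
#' @param origin world position of voxel (0, 0, 0).
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(u, spacing, origin = c(0, 0, 0)) {
  u <- unclass(u)
  attr_keep <- dim(u)
  for (a in setdiff(names(attributes(u)), "dim")) attr(u, a) <- NULL
  if (length(dim(u)) != 4 || dim(u)[4] != 3)
    stop("u must be a 4D array with 3 components in the 4th dimension")
  if (!all(is.finite(u))) stop("displacement field contains non-finite values")
  structure(list(u = u, spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "displacement_field")
}

#' @rdname displacement_field
#' @param geom geometry list (`dim`, `spacing`, `origin`).
#' @export
identity_field <- function(geom) {
  displacement_field(array(0, c(geom$dim, 3)), spacing = geom$spacing,
                     origin = geom$origin)
}

#' @export
print.displacement_field <- function(x, ...) {
  mx <- max(abs(x$u))
  cat("<displacement_field> ", paste(dim(x$u)[1:3], collapse = " x "),
      " @ ", paste(signif(x$spacing, 3), collapse = " x "), " mm; max |u| = ",
      signif(mx, 4), " mm\n", sep = "")
  invisible(x)
}

geometry_of_field <- function(f) list(dim = dim(f$u)[1:3], spacing = f$spacing,
                                      origin = f$origin)

field_compatible <- function(f, x, tol = 1e-6) {
  g <- geometry_of(x)
  gf <- geometry_of_field(f)
  identical(g$dim, gf$dim) && max(abs(g$spacing - gf$spacing)) < tol
}

#' Warp a volume by a displacement field
#'
#' Samples the input at `phi(x) = x + u(x)`: linear interpolation for
#' intensity volumes, nearest-neighbour for label volumes and masks.
#' Samples falling outside the input domain map to 0 / background.
#'
#' @param vol an `image_volume` or `label_volume`.
#' @param field a `displacement_field` on the output grid.
#' @param interpolation `"linear"` or `"nearest"`; label volumes require
#'   `"nearest"`.
#' @return warped volume of the same type.
#' @export
warp <- function(vol, field, interpolation = if (inherits(vol, "label_volume")) "nearest" else "linear") {
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  if (!field_compatible(field, vol))
    stop("field geometry does not match the volume grid")
  if (inherits(vol, "label_volume")) {
    if (interpolation != "nearest")
      stop("label volumes must be warped with nearest-neighbour interpolation")
    arr <- cpp_warp_disp(vol$labels + 0.0, field$u, field$spacing, TRUE, 0)
    out <- vol
    storage.mode(arr) <- "integer"
    out$labels <- arr
    return(out)
  }
  out <- vol
  out$data <- cpp_warp_disp(vol$data, field$u, field$spacing, FALSE, 0)
  if (!is.null(vol$mask)) {
    m <- cpp_warp_disp(vol$mask + 0.0, field$u, field$spacing, TRUE, 0)
    out$mask <- array(m > 0.5, dim(vol$data))
  }
  out
}

#' Compose two displacement fields
#'
#' Returns the field of `phi_f o phi_g`, i.e. applying `g` first:
#' `u(x) = u_g(x) + u_f(x + u_g(x))`.
#'
#' @param f,g `displacement_field`s on compatible grids.
#' @return a `displacement_field`.
#' @export
compose_fields <- function(f, g) {
  if (!identical(dim(f$u), dim(g$u)) || max(abs(f$spacing - g$spacing)) > 1e-6)
    stop("cannot compose fields with mismatched geometry")
  u <- cpp_compose_disp(f$u, g$u, g$spacing)
  displacement_field(u, spacing = g$spacing, origin = g$origin)
}

#' Invert a displacement field
#'
#' Fixed-point iteration for the inverse transform:
#' `u_inv(x) <- -u(x + u_inv(x))`, stopped when the mean composition
#' residual `mean |phi o phi_inv - id|` falls below `tol` (in voxels).
#'
#' @param field a `displacement_field` satisfying the diffeomorphism contract.
#' @param tol mean residual tolerance in voxel units.
#' @param max_iter maximum fixed-point iterations.
#' @return the inverse `displacement_field`.
#' @export
invert_field <- function(field, tol = 0.05, max_iter = 50) {
  geom <- geometry_of_field(field)
  uinv <- array(0, dim(field$u))
  sp <- field$spacing
  for (it in seq_len(max_iter)) {
    comp <- cpp_compose_disp(field$u, uinv, sp)  # phi o phi_inv - id
    uinv_new <- uinv - comp
    # damped update for stability on large deformations
    uinv <- uinv + 0.8 * (uinv_new - uinv)
    res <- mean(sqrt((comp[, , , 1] / sp[1])^2 + (comp[, , , 2] / sp[2])^2 +
                       (comp[, , , 3] / sp[3])^2))
    if (res < tol)
      return(displacement_field(uinv, spacing = sp, origin = field$origin))
  }
  stop(sprintf("field inversion did not converge in %d iterations (residual %.4f voxels)",
               max_iter, res))
}

#' Minimum Jacobian determinant of a field
#' @keywords internal
min_jacobian <- function(field) min(cpp_jacobian_det(field$u, field$spacing))

# Smooth each component of a field with a Gaussian of sigma_mm (world mm).
# `min_vox` floors the kernel width in voxel units per axis, so strongly
# anisotropic grids (thick slices) still get through-plane regularisation.
smooth_field_arr <- function(u, spacing, sigma_mm, min_vox = 0) {
  sv <- pmax(sigma_mm / spacing, min_vox)
  if (all(sv <= 0)) return(u)
  cpp_gauss_smooth(u, sv)
}
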