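#' Log-Jacobian determinant maps
#'
#' Converts a displacement field into a per-voxel natural-log local
#' volume-ratio map: `values = ln det(grad phi)` with `phi(x) = x + u(x)`.
#' The gradient uses spacing-aware central differences (one-sided at the
#' grid boundary), which is exact for affine transforms. A field with any
#' non-positive determinant violates the diffeomorphism contract and is
#' rejected.
#'
#' @param field a `displacement_field`.
#' @param provenance optional list (e.g. subject, interval) carried along.
#' @return a `log_jacobian_map`: list with `values` (3D array), `spacing`,
#'   `origin`, `provenance`.
#' @export
log_jacobian <- function(field, provenance = NULL) {
  det <- cpp_jacobian_det(field$u, field$spacing)
  if (min(det) <= 0) {
    bad <- which(det <= 0)
    stop(sprintf("non-positive Jacobian determinant at %d voxel(s) (first index %d)",
                 length(bad), bad[1]))
  }
  structure(list(values = log(det), spacing = field$spacing, origin = field$origin,
                 provenance = provenance),
            class = "log_jacobian_map")
}

#' @export
print.log_jacobian_map <- function(x, ...) {
  cat("<log_jacobian_map> ", paste(dim(x$values), collapse = " x "),
      "; range [", signif(min(x$values), 4), ", ", signif(max(x$values), 4), "]\n",
      sep = "")
  invisible(x)
}

#' Bilateral averaging about the central sagittal plane
#'
#' Averages each voxel with its mirror image across the centre of the
#' chosen axis (`mirror(i) = N - 1 - i`, 0-based), producing a
#' mirror-symmetric map; for odd-sized axes the central slice is
#' unchanged. Applying the operation twice equals applying it once.
#'
#' @param map a `log_jacobian_map`.
#' @param midplane_axis axis index (1..3) of the left-right direction.
#' @return the bilaterally averaged `log_jacobian_map`.
#' @export
bilateral_average <- function(map, midplane_axis = 1) {
  if (!(midplane_axis %in% 1:3)) stop("midplane_axis must be 1, 2, or 3")
  v <- map$values
  m <- mirror_array(v, midplane_axis)
  map$values <- (v + m) / 2
  map
}

mirror_array <- function(a, axis) {
  n <- dim(a)[axis]
  idx <- rev(seq_len(n))
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

#' Transport a Jacobian map into template space
#'
#' Resamples the scalar map through the subject-to-template deformation
#' with linear interpolation. Values are transported unchanged - no
#' Jacobian modulation is applied - following standard Jacobian-map
#' practice, so group tests in template space remain interpretable as
#' tests on the subject-space log volume ratios.
#'
#' @param map a `log_jacobian_map` on the subject grid.
#' @param subject_to_template `displacement_field` from the group-wise
#'   registration (template grid to subject coordinates).
#' @return a `log_jacobian_map` on the template grid.
#' @export
to_template_space <- function(map, subject_to_template) {
  gf <- geometry_of_field(subject_to_template)
  if (!identical(dim(map$values), gf$dim) ||
      max(abs(map$spacing - gf$spacing)) > 1e-6)
    stop("map and field geometry mismatch")
  out <- map
  out$values <- cpp_warp_disp(map$values, subject_to_template$u,
                              subject_to_template$spacing, FALSE, 0)
  out$spacing <- gf$spacing
  out$origin <- gf$origin
  out
}
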