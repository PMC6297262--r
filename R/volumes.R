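#' Image and label volume containers
#'
#' `image_volume()` wraps a 3D scalar grid together with its voxel spacing
#' (mm), a grid-index-to-world affine, and an optional brain mask.
#' `label_volume()` holds an integer label grid plus a lookup table mapping
#' label ids to ROI names (background is 0). These are the units of all
#' image I/O in the package.
#'
#' World coordinates are `affine %*% c(i, j, k, 1)` for 0-based voxel
#' indices; by default the affine is `diag(spacing)` with an optional
#' translation, i.e. axis-aligned grids.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, mm per voxel along each axis (all > 0).
#' @param origin numeric length-3, world position (mm) of voxel (0, 0, 0).
#' @param mask optional logical array of the same shape (brain mask).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0), mask = NULL) {
  data <- as_array3d(data)
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3, all(is.finite(spacing)))
  if (any(spacing <= 0)) stop("all spacing components must be > 0")
  if (!is.null(mask)) {
    mask <- array(as.logical(mask), dim(data))
    if (!identical(dim(mask), dim(data))) stop("mask and data must share the grid shape")
  }
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin),
                 affine = affine_from(spacing, origin), mask = mask),
            class = "image_volume")
}

#' @param labels 3D integer array of label ids (0 = background).
#' @param lut named integer vector or data.frame with columns `id`, `name`.
#' @rdname image_volume
#' @export
label_volume <- function(labels, lut, spacing, origin = c(0, 0, 0)) {
  labels <- as_array3d(labels)
  storage.mode(labels) <- "integer"
  lut <- as_lut(lut)
  present <- setdiff(unique(as.integer(labels)), 0L)
  missing <- setdiff(present, lut$id)
  if (length(missing) > 0)
    stop("label ids present in grid but missing from lut: ", paste(missing, collapse = ", "))
  structure(list(labels = labels, lut = lut, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 affine = affine_from(spacing, origin)),
            class = "label_volume")
}

as_lut <- function(lut) {
  if (is.data.frame(lut)) {
    stopifnot(all(c("id", "name") %in% names(lut)))
    lut <- data.frame(id = as.integer(lut$id), name = as.character(lut$name),
                      stringsAsFactors = FALSE)
  } else {
    lut <- data.frame(id = as.integer(lut), name = names(lut), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(lut$id)) stop("duplicate label ids in lut")
  if (anyDuplicated(lut$name)) stop("duplicate ROI names in lut")
  lut
}

as_array3d <- function(x) {
  x <- unclass(x)
  attr_names <- setdiff(names(attributes(x)), "dim")
  for (a in attr_names) attr(x, a) <- NULL
  if (length(dim(x)) != 3) stop("expected a 3D array")
  x
}

affine_from <- function(spacing, origin) {
  a <- diag(4)
  a[1:3, 1:3] <- diag(spacing, 3)
  a[1:3, 4] <- origin
  a
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " @ ", paste(signif(x$spacing, 3), collapse = " x "), " mm",
      if (!is.null(x$mask)) sprintf("  [mask: %d voxels]", sum(x$mask)) else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "),
      " @ ", paste(signif(x$spacing, 3), collapse = " x "), " mm; ",
      nrow(x$lut), " ROIs\n", sep = "")
  invisible(x)
}

geometry_of <- function(x) {
  d <- if (inherits(x, "label_volume")) dim(x$labels) else dim(x$data)
  list(dim = d, spacing = x$spacing, origin = x$origin)
}

same_geometry <- function(a, b, tol = 1e-6) {
  ga <- geometry_of(a); gb <- geometry_of(b)
  identical(ga$dim, gb$dim) &&
    max(abs(ga$spacing - gb$spacing)) < tol &&
    max(abs(ga$origin - gb$origin)) < tol
}

voxel_volume_mm3 <- function(x) prod(x$spacing)

#' World coordinate arrays of a grid
#'
#' Returns the world-mm coordinates of every voxel centre as three arrays
#' shaped like the grid.
#' @param geom list with `dim`, `spacing`, `origin` (as from a volume).
#' @keywords internal
world_coords <- function(geom) {
  d <- geom$dim; s <- geom$spacing; o <- geom$origin
  xi <- o[1] + s[1] * (seq_len(d[1]) - 1)
  yi <- o[2] + s[2] * (seq_len(d[2]) - 1)
  zi <- o[3] + s[3] * (seq_len(d[3]) - 1)
  list(x = array(rep(xi, times = d[2] * d[3]), d),
       y = array(rep(rep(yi, each = d[1]), times = d[3]), d),
       z = array(rep(zi, each = d[1] * d[2]), d))
}

grid_center_mm <- function(geom) geom$origin + (geom$dim - 1) / 2 * geom$spacing

#' Read and write volumes as NIfTI-1
#'
#' Volumes round-trip through NIfTI-1 via the RNifti package. Files ending
#' in `.nii` are written uncompressed, which keeps repeated writes
#' byte-identical.
#'
#' @param vol an `image_volume`, `label_volume`, or `displacement_field`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns an `image_volume`.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "label_volume")) {
    arr <- vol$labels
    storage.mode(arr) <- "integer"
  } else if (inherits(vol, "displacement_field")) {
    arr <- vol$u
  } else {
    arr <- vol$data
  }
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(vol$spacing, rep(1, nd - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  if (length(dim(arr)) == 4) {
    f <- displacement_field(arr, spacing = sp)
    return(f)
  }
  image_volume(arr, spacing = sp)
}

#' @rdname write_volume
#' @param lut lookup table (see [label_volume()]).
#' @export
read_label_volume <- function(path, lut) {
  img <- RNifti::readNifti(path)
  label_volume(round(as.array(img)), lut = lut, spacing = RNifti::pixdim(img)[1:3])
}

mask_or_all <- function(vol) {
  if (!is.null(vol$mask)) vol$mask else array(TRUE, dim(vol$data))
}

#' Run code with a fixed RNG seed
#' @keywords internal
with_seed <- function(seed, code) withr::with_seed(seed, code)

# Deterministic child seed derivation, kept below 2^31; string parts are
# hashed by code point.
child_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
    h <- (h * 1000003 + (v %% 2147483647)) %% 2147483629
  }
  as.integer(h %% 2147483587) + 1L
}

round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
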