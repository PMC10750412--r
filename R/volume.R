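#' Voxel volumes with physical spacing
#'
#' A voxel volume is a 3-D grid of values together with its physical voxel
#' spacing (mm per voxel along x, y, z) and the physical position of the
#' first voxel's corner (origin, mm). Two subclasses are used throughout the
#' package: `scalar_volume` holds real intensities (CT Hounsfield units or
#' network output probabilities); `binary_volume` holds occupancy in \{0, 1\},
#' 1 marking bone tissue. Grid axes are (x, y, z) with z the craniocaudal
#' (head-to-foot) axis; indices reported by operations such as
#' [crop_below_plane()] are 0-based.
#'
#' @param values Numeric 3-D array.
#' @param spacing Numeric length-3, mm per voxel; all components > 0.
#' @param origin Numeric length-3, mm.
#' @return An object of class `scalar_volume` or `binary_volume` (both
#'   inheriting `voxel_volume`): a list with elements `values`, `spacing`,
#'   `origin`.
#' @examples
#' v <- binary_volume(array(0:1, c(2, 2, 2)))
#' n_ones(v)
#' @export
scalar_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new_volume(values, spacing, origin, binary = FALSE)
}

#' @rdname scalar_volume
#' @export
binary_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new_volume(values, spacing, origin, binary = TRUE)
}

new_volume <- function(values, spacing, origin, binary) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  if (any(dim(values) < 1L)) stop("all three dims must be >= 1", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm/voxel)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  if (binary) {
    if (anyNA(values) || !all(values == 0 | values == 1))
      stop("binary volume values must all be 0 or 1", call. = FALSE)
    storage.mode(values) <- "integer"
  } else {
    storage.mode(values) <- "double"
  }
  structure(
    list(values = values, spacing = spacing, origin = origin),
    class = c(if (binary) "binary_volume" else "scalar_volume", "voxel_volume")
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  kind <- if (is_binary_volume(x)) "binary" else "scalar"
  cat(sprintf("<%s volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              kind, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  if (is_binary_volume(x)) {
    cat(sprintf("  occupancy: %d voxels (%.2f%%)\n", n_ones(x),
                100 * n_ones(x) / prod(d)))
  } else {
    cat(sprintf("  intensity range: [%.4g, %.4g]\n",
                min(x$values), max(x$values)))
  }
  invisible(x)
}

#' @rdname scalar_volume
#' @param x Object to test.
#' @export
is_binary_volume <- function(x) inherits(x, "binary_volume")

#' @rdname scalar_volume
#' @param v A `voxel_volume`.
#' @export
n_ones <- function(v) {
  stopifnot(inherits(v, "voxel_volume"))
  sum(v$values != 0)
}

#' @rdname scalar_volume
#' @export
vol_dims <- function(v) dim(v$values)

# physical coordinates of voxel centers along one axis (0-based index i ->
# origin + (i + 0.5) * spacing)
axis_centers <- function(v, axis) {
  n <- dim(v$values)[axis]
  v$origin[axis] + (seq_len(n) - 0.5) * v$spacing[axis]
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("volumes have different dims", call. = FALSE)
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("volumes have different spacing", call. = FALSE)
  invisible(TRUE)
}

# voxel-center coordinate matrix (n x 3) of occupied voxels; lattice units
# (0-based indices) or mm
occupied_coords <- function(v, in_mm = FALSE) {
  idx <- which(v$values != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0, 3))
  co <- idx - 1
  if (in_mm) {
    co <- sweep(sweep(co + 0.5, 2, v$spacing, `*`), 2, v$origin, `+`)
  }
  storage.mode(co) <- "double"
  unname(co)
}
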