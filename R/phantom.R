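#' Specify a synthetic cranial-vault phantom
#'
#' Phantoms are closed ellipsoidal bone shells of finite thickness, with the
#' right half scaled by `1 + asymmetry` (human skulls are asymmetric about
#' the sagittal plane) and everything below a horizontal base plane removed,
#' mimicking skull models normalized to the region above the Frankfort
#' horizontal plane. They stand in for patient CT data so the whole pipeline
#' is trainable and testable without any clinical volumes.
#'
#' Defaults describe an adult-sized vault (outer semi-axes 72 x 88 x 60 mm,
#' 6 mm bone thickness) on a desk-scale 64 x 64 x 48 grid with 3 x 3 x 4 mm
#' voxels (192 mm extent per axis).
#'
#' @param outer_semi_axes Outer ellipsoid semi-axes (a, b, c), mm.
#' @param shell_thickness Bone thickness, mm; `0 < thickness < min(a, b, c)`.
#' @param asymmetry Fractional right-side enlargement, in `[0, 0.5)`.
#' @param base_plane_fraction Fraction of the grid height below which bone is
#'   removed, in `[0, 1)`.
#' @param dims Grid dims (x, y, z).
#' @param spacing Voxel size, mm.
#' @param seed Integer recorded with the spec (phantom geometry is analytic
#'   and deterministic; the seed identifies the draw that produced the spec).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_semi_axes = c(72, 88, 60),
                         shell_thickness = 6,
                         asymmetry = 0.05,
                         base_plane_fraction = 0.25,
                         dims = c(64L, 64L, 48L),
                         spacing = c(3, 3, 4),
                         seed = 0L) {
  if (shell_thickness <= 0 || shell_thickness >= min(outer_semi_axes))
    stop("`shell_thickness` must be in (0, min(outer_semi_axes))")
  if (asymmetry < 0 || asymmetry >= 0.5)
    stop("`asymmetry` must be in [0, 0.5)")
  if (base_plane_fraction < 0 || base_plane_fraction >= 1)
    stop("`base_plane_fraction` must be in [0, 1)")
  structure(list(outer_semi_axes = as.numeric(outer_semi_axes),
                 shell_thickness = as.numeric(shell_thickness),
                 asymmetry = as.numeric(asymmetry),
                 base_plane_fraction = as.numeric(base_plane_fraction),
                 dims = as.integer(dims), spacing = as.numeric(spacing),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a cranial-vault phantom
#'
#' Voxelizes the double-ellipsoid shell implied by a [phantom_spec()]: a
#' voxel is bone when its center lies inside the outer ellipsoid and outside
#' the inner one (outer semi-axes minus the shell thickness). The shell is
#' evaluated about the grid center; for `asymmetry = 0` and even dims the
#' result is exactly mirror-symmetric about the midsagittal plane.
#'
#' @param spec A [phantom_spec()].
#' @return A [binary_volume()].
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  sp <- spec$spacing
  half <- d * sp / 2
  a_right <- spec$outer_semi_axes[1] * (1 + spec$asymmetry)
  lim <- c(a_right, spec$outer_semi_axes[2:3])
  for (ax in 1:3) {
    if (lim[ax] > half[ax])
      stop("shell exceeds grid bounds along axis ", c("x", "y", "z")[ax],
           " (", round(lim[ax], 1), " mm > ", round(half[ax], 1), " mm)")
  }
  cx <- (seq_len(d[1]) - 0.5) * sp[1] - half[1]
  cy <- (seq_len(d[2]) - 0.5) * sp[2] - half[2]
  cz <- (seq_len(d[3]) - 0.5) * sp[3] - half[3]
  ax_out <- ifelse(cx >= 0, a_right, spec$outer_semi_axes[1])
  inner <- pmax(spec$outer_semi_axes - spec$shell_thickness, 1e-6)
  ax_in <- ifelse(cx >= 0, inner[1] * (1 + spec$asymmetry), inner[1])
  xo2 <- (cx / ax_out)^2
  xi2 <- (cx / ax_in)^2
  yo2 <- (cy / spec$outer_semi_axes[2])^2
  yi2 <- (cy / inner[2])^2
  zo2 <- (cz / spec$outer_semi_axes[3])^2
  zi2 <- (cz / inner[3])^2
  out3 <- outer(outer(xo2, yo2, `+`), zo2, `+`)
  in3 <- outer(outer(xi2, yi2, `+`), zi2, `+`)
  vals <- array(as.integer(out3 <= 1 & in3 > 1), dim = d)
  vol <- binary_volume(vals, sp)
  crop_below_plane(vol, as.integer(floor(spec$base_plane_fraction * d[3])))
}

#' Generate a dataset of paired high/low-resolution phantoms
#'
#' Draws `n` phantom specs with parameters uniform over `spec_ranges` and
#' returns, for each, the intact shell at full grid resolution together with
#' its 4x block-majority down-sampled companion — the two volumetric
#' resolutions every training pair is normalized to.
#'
#' @param n Number of phantoms (>= 1).
#' @param spec_ranges Named list of `c(min, max)` ranges overriding the
#'   [phantom_spec()] defaults; recognised names: `outer_a`, `outer_b`,
#'   `outer_c`, `shell_thickness`, `asymmetry`. Fixed-value entries may be
#'   given as a single number.
#' @param seed RNG seed; output is reproducible per seed.
#' @param dims,spacing Grid geometry passed to [phantom_spec()].
#' @param base_plane_fraction Crop fraction passed to [phantom_spec()].
#' @return A list of `n` elements, each
#'   `list(intact_high, intact_low, spec)`.
#' @export
generate_dataset <- function(n, spec_ranges = list(), seed = 1L,
                             dims = c(64L, 64L, 48L), spacing = c(3, 3, 4),
                             base_plane_fraction = 0.25) {
  if (n < 1) stop("`n` must be >= 1")
  defaults <- list(outer_a = c(64, 76), outer_b = c(80, 92),
                   outer_c = c(52, 64), shell_thickness = c(5, 8),
                   asymmetry = c(0, 0.1))
  ranges <- modifyList(defaults, spec_ranges)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) == 1L) r <- c(r, r)
    if (length(r) != 2L || r[1] > r[2])
      stop("invalid range for '", nm, "'")
    ranges[[nm]] <- r
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  draw <- function(r) runif(1, r[1], r[2])
  lapply(seq_len(n), function(i) {
    spec <- phantom_spec(
      outer_semi_axes = c(draw(ranges$outer_a), draw(ranges$outer_b),
                          draw(ranges$outer_c)),
      shell_thickness = draw(ranges$shell_thickness),
      asymmetry = draw(ranges$asymmetry),
      base_plane_fraction = base_plane_fraction,
      dims = dims, spacing = spacing, seed = seed + i
    )
    high <- generate_phantom(spec)
    list(intact_high = high, intact_low = downsample_binary(high, 4L),
         spec = spec)
  })
}
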