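#' Parametric defect-mask specification
#'
#' A mask spec describes one synthetic craniectomy defect as a union of one
#' or two analytic solids. Four families are supported: `elliptical_cylinder`
#' (one cylinder of elliptical cross-section), `mixed_elliptical_cylinder`
#' (union of two elliptical cylinders with independent axis directions),
#' `ellipsoid`, and `hybrid_ellipsoid` (union of an ellipsoid and an
#' elliptical cylinder sharing its center).
#'
#' Each component is a list with fields `kind` (`"cylinder"` or
#' `"ellipsoid"`), `center` (mm), and for cylinders `semi_axes` (in-plane
#' semi-axes, mm), `half_height` (mm) and `axis` (unit direction); for
#' ellipsoids `semi_axes` is length 3. The mask's nominal diameter is twice
#' its largest in-plane semi-axis.
#'
#' @param family One of the four family names.
#' @param components List of component solids (see Details).
#' @return An object of class `mask_spec`.
#' @export
mask_spec <- function(family = c("elliptical_cylinder",
                                 "mixed_elliptical_cylinder",
                                 "ellipsoid", "hybrid_ellipsoid"),
                      components) {
  family <- match.arg(family)
  if (length(components) < 1L || length(components) > 2L)
    stop("a mask has 1 or 2 components")
  for (cm in components) {
    if (!cm$kind %in% c("cylinder", "ellipsoid")) stop("unknown component kind")
    if (any(cm$semi_axes <= 0)) stop("every semi-axis must be > 0")
    if (cm$kind == "cylinder" && cm$half_height <= 0)
      stop("cylinder half_height must be > 0")
  }
  structure(list(family = family, components = components),
            class = "mask_spec")
}

#' @rdname mask_spec
#' @param spec A `mask_spec`.
#' @return `mask_max_diameter()`: the largest in-plane defect diameter in mm.
#' @export
mask_max_diameter <- function(spec) {
  stopifnot(inherits(spec, "mask_spec"))
  2 * max(vapply(spec$components, function(cm)
    max(cm$semi_axes[seq_len(min(2L, length(cm$semi_axes)))],
        if (cm$kind == "ellipsoid") cm$semi_axes else 0), numeric(1)))
}

# random unit vector, mildly biased away from the horizontal plane so
# cylinder axes tend to pierce the vault like real craniectomy cuts
random_axis <- function() {
  v <- c(rnorm(2, 0, 0.6), rnorm(1, 1, 0.4))
  v / sqrt(sum(v^2))
}

#' Sample a random defect-mask specification
#'
#' Family is chosen uniformly among `families`; the mask's largest in-plane
#' diameter is uniform over `diameter_range_mm` (default 60-120 mm, the
#' clinically representative craniectomy range) and its center is uniform
#' over the upper-skull region of the template grid (the top
#' `1 - upper_fraction` of the z extent). Draws come from R's global RNG, so
#' a fixed `set.seed()` reproduces the spec sequence exactly.
#'
#' @param template A `voxel_volume` giving the grid the mask will be applied
#'   to (its physical bounds locate the sampled centers).
#' @param diameter_range_mm `c(min, max)` nominal diameter, mm.
#' @param families Character vector of enabled mask families.
#' @param upper_fraction Lower bound of the center-sampling region as a
#'   fraction of the z extent (default 0.5: upper half).
#' @return A [mask_spec()].
#' @export
sample_mask_spec <- function(template, diameter_range_mm = c(60, 120),
                             families = c("elliptical_cylinder",
                                          "mixed_elliptical_cylinder",
                                          "ellipsoid", "hybrid_ellipsoid"),
                             upper_fraction = 0.5) {
  if (length(families) < 1L) stop("`families` must name at least one family")
  families <- match.arg(families, several.ok = TRUE)
  if (diameter_range_mm[1] > diameter_range_mm[2] ||
      any(diameter_range_mm <= 0))
    stop("invalid `diameter_range_mm`")
  d <- vol_dims(template)
  ext <- d * template$spacing
  lo <- template$origin
  center <- c(runif(1, lo[1] + 0.2 * ext[1], lo[1] + 0.8 * ext[1]),
              runif(1, lo[2] + 0.2 * ext[2], lo[2] + 0.8 * ext[2]),
              runif(1, lo[3] + upper_fraction * ext[3], lo[3] + ext[3]))
  family <- families[sample.int(length(families), 1L)]
  dmax <- runif(1, diameter_range_mm[1], diameter_range_mm[2])
  r1 <- dmax / 2
  r2 <- r1 * runif(1, 0.6, 1)
  hh <- runif(1, 40, 90) # tall enough to punch through the vault
  cyl <- function(ctr, ra, rb) list(kind = "cylinder", center = ctr,
                                    semi_axes = c(ra, rb), half_height = hh,
                                    axis = random_axis())
  ell <- function(ctr, ra, rb) list(kind = "ellipsoid", center = ctr,
                                    semi_axes = c(ra, rb,
                                                  r1 * runif(1, 0.6, 1)))
  comps <- switch(family,
    elliptical_cylinder = list(cyl(center, r1, r2)),
    mixed_elliptical_cylinder = {
      # second cylinder strictly smaller so the union's max diameter is r1*2
      off <- center + runif(3, -0.2, 0.2) * r1
      list(cyl(center, r1, r2), cyl(off, r1 * runif(1, 0.5, 0.9),
                                    r2 * runif(1, 0.5, 0.9)))
    },
    ellipsoid = list(ell(center, r1, r2)),
    hybrid_ellipsoid = list(ell(center, r1, r2),
                            cyl(center, r1 * runif(1, 0.5, 0.9),
                                r2 * runif(1, 0.5, 0.9)))
  )
  mask_spec(family, comps)
}

# orthonormal frame completing unit vector u
complete_frame <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  list(v = v, w = c(u[2] * v[3] - u[3] * v[2],
                    u[3] * v[1] - u[1] * v[3],
                    u[1] * v[2] - u[2] * v[1]))
}

#' Rasterize a defect mask onto a grid
#'
#' A voxel is inside the mask when its center lies inside the union of the
#' spec's component solids.
#'
#' @param spec A [mask_spec()].
#' @param grid_template A `voxel_volume` defining dims, spacing and origin.
#' @return A [binary_volume()]; carries attribute `empty_mask = TRUE` when
#'   the mask misses the grid entirely.
#' @export
rasterize_mask <- function(spec, grid_template) {
  stopifnot(inherits(spec, "mask_spec"),
            inherits(grid_template, "voxel_volume"))
  d <- vol_dims(grid_template)
  cx <- axis_centers(grid_template, 1)
  cy <- axis_centers(grid_template, 2)
  cz <- axis_centers(grid_template, 3)
  px <- rep(cx, times = d[2] * d[3])
  py <- rep(rep(cy, each = d[1]), times = d[3])
  pz <- rep(cz, each = d[1] * d[2])
  inside <- rep(FALSE, prod(d))
  for (cm in spec$components) {
    rx <- px - cm$center[1]; ry <- py - cm$center[2]; rz <- pz - cm$center[3]
    if (cm$kind == "ellipsoid") {
      q <- (rx / cm$semi_axes[1])^2 + (ry / cm$semi_axes[2])^2 +
        (rz / cm$semi_axes[3])^2
      inside <- inside | (q <= 1)
    } else {
      u <- cm$axis
      fr <- complete_frame(u)
      t <- rx * u[1] + ry * u[2] + rz * u[3]
      a <- (rx * fr$v[1] + ry * fr$v[2] + rz * fr$v[3]) / cm$semi_axes[1]
      b <- (rx * fr$w[1] + ry * fr$w[2] + rz * fr$w[3]) / cm$semi_axes[2]
      inside <- inside | (a^2 + b^2 <= 1 & abs(t) <= cm$half_height)
    }
  }
  out <- binary_volume(array(as.integer(inside), dim = d),
                       grid_template$spacing, grid_template$origin)
  if (n_ones(out) == 0L) {
    warning("mask lies entirely outside the grid")
    attr(out, "empty_mask") <- TRUE
  }
  out
}

#' Apply a defect mask to an intact skull
#'
#' Boolean subtraction: the defective skull is the intact bone outside the
#' mask; the removed bone inside the mask is the ground-truth (ideal)
#' implant. By construction the two parts are disjoint and their union is
#' the intact skull.
#'
#' @param intact,mask `binary_volume`s on the same grid.
#' @return An object of class `defect_pair`: list with `defective`,
#'   `implant_truth`, and `mask`.
#' @export
apply_defect <- function(intact, mask) {
  stopifnot(is_binary_volume(intact), is_binary_volume(mask))
  check_same_grid(intact, mask)
  defective <- intact
  defective$values <- array(as.integer(intact$values & !mask$values),
                            dim = vol_dims(intact))
  implant <- intact
  implant$values <- array(as.integer(intact$values & mask$values),
                          dim = vol_dims(intact))
  structure(list(defective = defective, implant_truth = implant, mask = mask),
            class = "defect_pair")
}

#' @export
print.defect_pair <- function(x, ...) {
  cat(sprintf("<defect pair> defective %d voxels | implant %d voxels\n",
              n_ones(x$defective), n_ones(x$implant_truth)))
  invisible(x)
}

#' Rotation augmentation about the craniocaudal axis
#'
#' Returns `2 * per_side + 1` variants of the input rotated by
#' `k * interval_deg` degrees, `k = -per_side .. per_side`, about the grid
#' center of the axial plane. Nearest-neighbour resampling keeps volumes
#' binary; the `k = 0` member is the unrotated input itself. Defaults (2
#' degrees, three variants per side) give seven variants per skull.
#'
#' @param volume A `binary_volume`.
#' @param interval_deg Rotation step in degrees (> 0).
#' @param per_side Number of variants on each side of zero.
#' @return List of `binary_volume`s, ordered by angle.
#' @export
rotate_augment <- function(volume, interval_deg = 2, per_side = 3L) {
  stopifnot(is_binary_volume(volume))
  if (interval_deg <= 0) stop("`interval_deg` must be > 0")
  angles <- (-per_side:per_side) * interval_deg
  lapply(angles, function(a) rotate_z(volume, a))
}

# nearest-neighbour rotation of all axial slices by `deg` about grid center
rotate_z <- function(volume, deg) {
  if (deg == 0) return(volume)
  d <- vol_dims(volume)
  th <- deg * pi / 180
  ctr <- (d[1:2] + 1) / 2
  ij <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  # inverse map: source position of each target voxel
  dx <- ij$i - ctr[1]
  dy <- ij$j - ctr[2]
  si <- round(cos(th) * dx + sin(th) * dy + ctr[1])
  sj <- round(-sin(th) * dx + cos(th) * dy + ctr[2])
  ok <- si >= 1 & si <= d[1] & sj >= 1 & sj <= d[2]
  out <- array(0L, dim = d)
  src <- cbind(si[ok], sj[ok])
  tgt <- cbind(ij$i[ok], ij$j[ok])
  for (k in seq_len(d[3])) {
    slice <- volume$values[, , k]
    dst <- array(0L, dim = d[1:2])
    dst[tgt] <- slice[src]
    out[, , k] <- dst
  }
  binary_volume(out, volume$spacing, volume$origin)
}

#' Is a defect usable for training?
#'
#' A defect pair is in range when the removed part is a real defect (at
#' least `min_fraction` of the intact skull's bone — a mask that merely
#' grazes the outer table does not emulate a craniectomy), lies entirely at
#' or above the horizontal plane index, and does not break the remaining
#' skull into more than two large connected pieces (6-connectivity; "large"
#' meaning at least 5% of the remaining bone). Out-of-range defects are
#' discarded during dataset construction.
#'
#' @param pair A [apply_defect()] result.
#' @param plane_index 0-based craniocaudal plane index.
#' @param min_fraction Minimum removed fraction of the intact bone.
#' @return `TRUE` or `FALSE`.
#' @export
is_defect_in_range <- function(pair, plane_index, min_fraction = 0.01) {
  stopifnot(inherits(pair, "defect_pair"))
  imp <- pair$implant_truth
  n_bone <- n_ones(imp) + n_ones(pair$defective)
  if (n_ones(imp) == 0L || n_ones(imp) < min_fraction * n_bone)
    return(FALSE)
  zmin <- min(which(apply(imp$values, 3, sum) > 0)) - 1L # 0-based
  if (zmin < plane_index) return(FALSE)
  lab <- cf_label_components(pair$defective$values)
  if (max(lab) == 0L) return(FALSE)
  sizes <- tabulate(lab[lab > 0])
  n_large <- sum(sizes >= 0.05 * sum(sizes))
  n_large <= 2L
}

#' Generate defect pairs for one intact skull
#'
#' Draws mask specs with [sample_mask_spec()], rasterizes and applies them,
#' and keeps only in-range defects until `n` pairs are collected (25 by
#' default, the number of defect variations injected into each complete
#' skull model). Deterministic given the RNG state.
#'
#' @param intact A `binary_volume`.
#' @param n Number of pairs to emit.
#' @param plane_index 0-based plane used by [is_defect_in_range()].
#' @param diameter_range_mm,families Passed to [sample_mask_spec()].
#' @param min_fraction Minimum removed fraction, see [is_defect_in_range()].
#' @param max_tries Attempt budget before giving up.
#' @return List of `n` `defect_pair`s.
#' @export
generate_defect_pairs <- function(intact, n = 25L, plane_index = 0L,
                                  diameter_range_mm = c(60, 120),
                                  families = c("elliptical_cylinder",
                                               "mixed_elliptical_cylinder",
                                               "ellipsoid",
                                               "hybrid_ellipsoid"),
                                  min_fraction = 0.01,
                                  max_tries = 40L * n) {
  stopifnot(is_binary_volume(intact))
  out <- vector("list", n)
  got <- 0L
  for (t in seq_len(max_tries)) {
    spec <- sample_mask_spec(intact, diameter_range_mm, families)
    mask <- suppressWarnings(rasterize_mask(spec, intact))
    pair <- apply_defect(intact, mask)
    if (is_defect_in_range(pair, plane_index, min_fraction)) {
      got <- got + 1L
      out[[got]] <- pair
      if (got == n) return(out)
    }
  }
  stop("could not generate ", n, " in-range defects in ", max_tries,
       " attempts")
}
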