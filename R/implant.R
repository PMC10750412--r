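#' Uniformly scale a binary volume about its occupancy centroid
#'
#' Nearest-neighbour resampling under a uniform scaling; used to enlarge the
#' defective skull (to 102% by default elsewhere) before Boolean
#' subtraction, which buys fitting tolerance and suppresses mismatch noise
#' outside the defect area. `factor = 1` is the identity.
#'
#' @param volume A `binary_volume`.
#' @param factor Positive scale factor.
#' @return A `binary_volume` on the same grid.
#' @export
scale_volume <- function(volume, factor = 1.02) {
  stopifnot(is_binary_volume(volume))
  if (factor <= 0) stop("`factor` must be > 0")
  if (factor == 1 || n_ones(volume) == 0L) return(volume)
  d <- vol_dims(volume)
  occ <- which(volume$values != 0, arr.ind = TRUE)
  ctr <- colMeans(occ)
  if (factor > 1) {
    # bounding box of the scaled occupancy must stay inside the grid
    lo <- ctr + (apply(occ, 2, min) - ctr) * factor
    hi <- ctr + (apply(occ, 2, max) - ctr) * factor
    if (any(lo < 0.5) || any(hi > d + 0.5))
      stop("scaled shape exceeds the grid; pad the volume before scaling")
  }
  ax <- lapply(1:3, function(k) ctr[k] + (seq_len(d[k]) - ctr[k]) / factor)
  si <- pmin(pmax(round(ax[[1]]), 1L), d[1])
  sj <- pmin(pmax(round(ax[[2]]), 1L), d[2])
  sk <- pmin(pmax(round(ax[[3]]), 1L), d[3])
  vals <- volume$values[si, sj, sk]
  # tolerance scaling must be extensive: nearest-neighbour sampling alone
  # can drop thin-structure voxels, so growing keeps the original occupancy
  if (factor > 1) vals <- vals | volume$values
  binary_volume(array(as.integer(vals), dim = d), volume$spacing,
                volume$origin)
}

#' Extract the implant by Boolean subtraction
#'
#' The implant is the completed skull minus the (optionally tolerance-
#' scaled) defective skull: `completed AND NOT scale(defective, s)`. With a
#' perfect completion and `tolerance_scale = 1` this recovers the
#' ground-truth implant exactly; scales above 1 can only shrink the result.
#'
#' @param completed,defective `binary_volume`s on the same grid.
#' @param tolerance_scale Scale applied to the defective model first
#'   (default 1.02).
#' @return A `binary_volume`.
#' @export
extract_implant <- function(completed, defective, tolerance_scale = 1.02) {
  stopifnot(is_binary_volume(completed), is_binary_volume(defective))
  check_same_grid(completed, defective)
  grown <- scale_volume(defective, tolerance_scale)
  out <- completed
  out$values <- array(as.integer(completed$values & !grown$values),
                      dim = vol_dims(completed))
  out
}

ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  keep <- g$x^2 + g$y^2 + g$z^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

#' Clean an extracted implant
#'
#' Morphological opening (erosion then dilation with a voxel ball of the
#' given radius) removes small and thin noise attached to the implant;
#' connected-component analysis then keeps only the largest
#' `keep_components` 6-connected pieces, discarding isolated specks.
#' Idempotent at fixed parameters.
#'
#' @param implant A `binary_volume`.
#' @param opening_radius Ball radius in voxels (0 skips the opening).
#' @param keep_components Number of largest components to keep.
#' @return A `binary_volume` (possibly empty).
#' @export
postprocess_implant <- function(implant, opening_radius = 1,
                                keep_components = 1L) {
  stopifnot(is_binary_volume(implant))
  if (opening_radius < 0) stop("`opening_radius` must be >= 0")
  vals <- implant$values
  if (opening_radius > 0 && sum(vals) > 0) {
    off <- ball_offsets(opening_radius)
    vals <- cf_binary_morph(vals, off, TRUE)   # erosion
    vals <- cf_binary_morph(vals, off, FALSE)  # dilation
  }
  if (sum(vals) > 0 && keep_components >= 1L) {
    lab <- cf_label_components(vals)
    sizes <- tabulate(lab[lab > 0])
    keep <- order(sizes, decreasing = TRUE)[seq_len(min(keep_components,
                                                        length(sizes)))]
    vals <- array(as.integer(lab %in% keep & lab > 0), dim = dim(vals))
  }
  binary_volume(vals, implant$spacing, implant$origin)
}

#' Export a binary volume as an STL surface mesh
#'
#' Writes the closed triangle surface of the volume's 0.5 iso-level under
#' nearest-neighbour interpolation — the exact boundary between bone and
#' background voxels — as binary STL, with vertex coordinates in mm
#' (spacing- and origin-aware). The mesh encloses precisely the occupied
#' voxels, so its signed volume equals the voxel volume; every boundary
#' quad is split into two triangles with outward normals.
#'
#' @param volume A non-empty `binary_volume`.
#' @param path Output `.stl` path.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(volume, path) {
  stopifnot(is_binary_volume(volume))
  if (n_ones(volume) == 0L) stop("cannot mesh an empty volume")
  v <- volume$values
  d <- dim(v)
  sp <- volume$spacing
  or <- volume$origin
  # pad so boundary faces at the grid edge are emitted
  pad <- array(0L, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  tris <- list()
  # face template: for each of 6 directions, the 4 corner offsets (voxel
  # corner coordinates, in units of voxels relative to the voxel's lower
  # corner), ordered counter-clockwise seen from outside
  faces <- list(
    list(dir = c(1, 0, 0),  q = rbind(c(1,0,0), c(1,1,0), c(1,1,1), c(1,0,1))),
    list(dir = c(-1, 0, 0), q = rbind(c(0,0,0), c(0,0,1), c(0,1,1), c(0,1,0))),
    list(dir = c(0, 1, 0),  q = rbind(c(0,1,0), c(0,1,1), c(1,1,1), c(1,1,0))),
    list(dir = c(0, -1, 0), q = rbind(c(0,0,0), c(1,0,0), c(1,0,1), c(0,0,1))),
    list(dir = c(0, 0, 1),  q = rbind(c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))),
    list(dir = c(0, 0, -1), q = rbind(c(0,0,0), c(0,1,0), c(1,1,0), c(1,0,0)))
  )
  occ <- which(v != 0, arr.ind = TRUE)
  for (f in faces) {
    nb <- pad[cbind(occ[, 1] + 1 + f$dir[1], occ[, 2] + 1 + f$dir[2],
                    occ[, 3] + 1 + f$dir[3])]
    expose <- occ[nb == 0L, , drop = FALSE]
    if (nrow(expose) == 0L) next
    corner <- sweep(expose - 1, 2, sp, `*`)
    corner <- sweep(corner, 2, or, `+`)
    q <- sweep(f$q, 2, sp, `*`)
    for (tr in list(c(1, 2, 3), c(1, 3, 4))) {
      v1 <- sweep(corner, 2, q[tr[1], ], `+`)
      v2 <- sweep(corner, 2, q[tr[2], ], `+`)
      v3 <- sweep(corner, 2, q[tr[3], ], `+`)
      tris[[length(tris) + 1L]] <- cbind(
        matrix(rep(f$dir, each = nrow(v1)), ncol = 3), v1, v2, v3)
    }
  }
  tri <- do.call(rbind, tris)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- raw(80)
  txt <- charToRaw("craniofill voxel iso-surface")
  hdr[seq_along(txt)] <- txt
  writeBin(hdr, con)
  writeBin(as.integer(nrow(tri)), con, size = 4, endian = "little")
  floats <- writeBin(as.numeric(t(tri)), raw(), size = 4, endian = "little")
  recs <- rbind(matrix(floats, nrow = 48L),
                matrix(as.raw(0), nrow = 2L, ncol = nrow(tri)))
  writeBin(as.raw(recs), con)
  invisible(path)
}
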