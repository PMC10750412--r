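#' Voxel overlap counts
#'
#' True/false positive and false negative voxel counts between a predicted
#' skull model P and its ground truth G (1 = bone tissue).
#'
#' @param P,G `binary_volume`s with equal dims.
#' @return List with `n_tp`, `n_fp`, `n_fn`.
#' @export
overlap_counts <- function(P, G) {
  stopifnot(is_binary_volume(P), is_binary_volume(G))
  if (!identical(vol_dims(P), vol_dims(G))) stop("dim mismatch")
  p <- P$values != 0
  g <- G$values != 0
  list(n_tp = sum(p & g), n_fp = sum(p & !g), n_fn = sum(!p & g))
}

#' Sorensen-Dice index
#'
#' `2 N_TP / (2 N_TP + N_FP + N_FN) x 100%`: the volumetric overlap between
#' a predicted model and its ground truth, in percent. Symmetric in its
#' arguments; 100 for identical models, 0 for disjoint non-empty ones.
#'
#' @param P,G `binary_volume`s with equal dims; at least one non-empty.
#' @return Percentage in `[0, 100]`.
#' @export
sdi <- function(P, G) {
  oc <- overlap_counts(P, G)
  denom <- 2 * oc$n_tp + oc$n_fp + oc$n_fn
  if (denom == 0) stop("SDI undefined: both volumes are empty")
  200 * oc$n_tp / denom
}

#' Directed Hausdorff distance
#'
#' The largest distance from any bone voxel center in `G` to the closest
#' bone voxel center in `P` (the directed form; use
#' [hausdorff_distance()] for the symmetric variant). Computed in lattice
#' (index) units by default — one HD unit then corresponds to a physical
#' distance between the smallest spacing component and the norm of the
#' spacing vector, see [hd_unit_range()] — or in mm over spacing-scaled
#' voxel centers with `in_mm = TRUE`.
#'
#' @param G,P Non-empty `binary_volume`s on compatible grids.
#' @param in_mm Use physical voxel-center coordinates.
#' @return Non-negative distance.
#' @export
directed_hausdorff <- function(G, P, in_mm = FALSE) {
  stopifnot(is_binary_volume(G), is_binary_volume(P))
  cg <- occupied_coords(G, in_mm)
  cp <- occupied_coords(P, in_mm)
  if (nrow(cg) == 0L || nrow(cp) == 0L)
    stop("directed Hausdorff distance needs non-empty voxel sets")
  cf_directed_hausdorff(cg, cp)
}

#' @rdname directed_hausdorff
#' @export
hausdorff_distance <- function(G, P, in_mm = FALSE) {
  max(directed_hausdorff(G, P, in_mm), directed_hausdorff(P, G, in_mm))
}

#' Physical span of one Hausdorff lattice unit
#'
#' On an anisotropic grid a unit step in lattice units covers between the
#' smallest spacing component (two voxels adjacent along the finest axis)
#' and the Euclidean norm of the spacing vector (diagonal neighbours).
#'
#' @param spacing Numeric length-3 voxel size, mm.
#' @return `c(min_mm, max_mm)`.
#' @examples
#' hd_unit_range(c(0.45, 0.45, 0.8)) # 0.45 .. 1.0223 mm
#' @export
hd_unit_range <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers")
  c(min(spacing), sqrt(sum(spacing^2)))
}

#' Select the CVAI measurement plane
#'
#' The measurement plane M is the axial slice, parallel to the Frankfort
#' horizontal plane, that intersects the implant the most: the craniocaudal
#' index maximizing the implant's in-slice voxel count (ties resolved to
#' the inferior-most slice).
#'
#' @param implant A non-empty `binary_volume`.
#' @param frankfort_index Optional 0-based lower bound; slices below it are
#'   ignored.
#' @return 0-based slice index.
#' @export
select_measurement_plane <- function(implant, frankfort_index = 0L) {
  stopifnot(is_binary_volume(implant))
  if (n_ones(implant) == 0L) stop("empty implant")
  counts <- apply(implant$values, 3, sum)
  if (frankfort_index > 0) counts[seq_len(frankfort_index)] <- -1
  which.max(counts) - 1L # ties: which.max takes the first (inferior-most)
}

#' Measure the CVAI diagonal lengths
#'
#' Casts four rays in the measurement plane from the midline point O at
#' +/-60 degrees from the anterior Y direction — A (anterior-left),
#' B (anterior-right), C (posterior-right), D (posterior-left), so AC and
#' BD are straight diagonal lines through O — and returns the distance from
#' O to the outermost skull-boundary crossing of each ray, in mm. Occupancy
#' along the rays is sampled with bilinear interpolation at sub-voxel steps;
#' the boundary is the 0.5 level.
#'
#' O defaults to the midsagittal axis (grid center x) at the y centroid of
#' the in-plane skull cross-section.
#'
#' @param skull A `binary_volume`.
#' @param plane_index 0-based axial slice (see
#'   [select_measurement_plane()]).
#' @param O Optional `c(x, y)` in mm overriding the default.
#' @return An object of class `cvai_measurement`: list with `plane_index`,
#'   `O`, the four `points` (mm) and `lengths` (`AO`, `BO`, `CO`, `DO`, mm).
#' @export
cvai_diagonals <- function(skull, plane_index, O = NULL) {
  stopifnot(is_binary_volume(skull))
  d <- vol_dims(skull)
  if (plane_index < 0 || plane_index >= d[3]) stop("plane index out of bounds")
  slice <- skull$values[, , plane_index + 1L]
  if (sum(slice) == 0L) stop("skull slice at plane ", plane_index, " is empty")
  cx <- axis_centers(skull, 1)
  cy <- axis_centers(skull, 2)
  if (is.null(O)) {
    occ <- which(slice != 0, arr.ind = TRUE)
    O <- c(skull$origin[1] + d[1] * skull$spacing[1] / 2, # midsagittal x
           mean(cy[occ[, 2]]))
  }
  s60 <- sin(pi / 3)
  c60 <- cos(pi / 3)
  dirs <- list(A = c(-s60, c60), B = c(s60, c60),
               C = c(s60, -c60), D = c(-s60, -c60))
  lens <- vapply(names(dirs), function(nm) {
    r <- ray_outermost_crossing(slice, cx, cy, O, dirs[[nm]],
                                step = min(skull$spacing[1:2]) / 10)
    if (is.na(r)) stop("ray ", nm, " does not cross the skull contour")
    r
  }, numeric(1))
  pts <- lapply(names(dirs), function(nm) O + lens[[nm]] * dirs[[nm]])
  names(pts) <- names(dirs)
  structure(list(plane_index = plane_index, O = O, points = pts,
                 lengths = c(AO = lens[["A"]], BO = lens[["B"]],
                             CO = lens[["C"]], DO = lens[["D"]])),
            class = "cvai_measurement")
}

#' @export
print.cvai_measurement <- function(x, ...) {
  cat(sprintf("<CVAI measurement> plane z = %d, O = (%.1f, %.1f) mm\n",
              x$plane_index, x$O[1], x$O[2]))
  cat(sprintf("  AO %.2f | BO %.2f | CO %.2f | DO %.2f mm\n",
              x$lengths["AO"], x$lengths["BO"], x$lengths["CO"],
              x$lengths["DO"]))
  idx <- cvai_indices(x$lengths["AO"], x$lengths["BO"], x$lengths["CO"],
                      x$lengths["DO"])
  cat(sprintf("  ACVAI %.2f%% | PCVAI %.2f%%\n", idx[["acvai"]],
              idx[["pcvai"]]))
  invisible(x)
}

# farthest point along a ray (bilinear occupancy >= 0.5), with linear
# refinement of the final crossing; NA when the ray never enters the contour
ray_outermost_crossing <- function(slice, cx, cy, O, dir, step) {
  nx <- length(cx); ny <- length(cy)
  tmax <- sqrt((cx[nx] - cx[1])^2 + (cy[ny] - cy[1])^2)
  ts <- seq(0, tmax, by = step)
  px <- O[1] + ts * dir[1]
  py <- O[2] + ts * dir[2]
  v <- bilinear_sample(slice, cx, cy, px, py)
  inside <- which(v >= 0.5)
  if (length(inside) == 0L) return(NA_real_)
  i <- max(inside)
  if (i == length(ts)) return(ts[i])
  # refine between the last inside sample and the next outside one
  f <- (0.5 - v[i]) / (v[i + 1] - v[i])
  ts[i] + f * step
}

bilinear_sample <- function(slice, cx, cy, px, py) {
  nx <- length(cx); ny <- length(cy)
  sx <- cx[2] - cx[1]; sy <- cy[2] - cy[1]
  gx <- (px - cx[1]) / sx
  gy <- (py - cy[1]) / sy
  i0 <- floor(gx); j0 <- floor(gy)
  fx <- gx - i0; fy <- gy - j0
  gv <- function(i, j) {
    ok <- i >= 0 & i < nx & j >= 0 & j < ny
    out <- numeric(length(i))
    out[ok] <- slice[cbind(i[ok] + 1, j[ok] + 1)]
    out
  }
  gv(i0, j0) * (1 - fx) * (1 - fy) + gv(i0 + 1, j0) * fx * (1 - fy) +
    gv(i0, j0 + 1) * (1 - fx) * fy + gv(i0 + 1, j0 + 1) * fx * fy
}

#' Cranial vault asymmetry indices
#'
#' `ACVAI = |AO - BO| / AO x 100%` (anterior) and
#' `PCVAI = |CO - DO| / DO x 100%` (posterior), from the diagonal lengths
#' measured by [cvai_diagonals()]. A perfectly symmetric reconstruction
#' scores 0% on both. Magnitudes are reported; the signed values (negative
#' when the second length of a pair is larger) are kept in the `"signed"`
#' attribute.
#'
#' @param AO,BO,CO,DO Diagonal lengths in mm; `AO` and `DO` must be > 0.
#' @return Named numeric `c(acvai, pcvai)`, percent.
#' @examples
#' cvai_indices(71.05, 72.63, 83.70, 85.53) # 2.22 / 2.14
#' @export
cvai_indices <- function(AO, BO, CO, DO) {
  if (AO <= 0 || DO <= 0) stop("AO and DO must be positive")
  signed <- c(acvai = (AO - BO) / AO * 100, pcvai = (CO - DO) / DO * 100)
  structure(abs(signed), signed = signed)
}

#' Full reconstruction metrics report
#'
#' Convenience wrapper computing SDI, directed Hausdorff (both lattice and
#' mm) and, when an implant is supplied, the CVAI indices on its measurement
#' plane.
#'
#' @param pred,truth `binary_volume`s to compare.
#' @param skull Optional reconstructed skull for the CVAI measurement.
#' @param implant Optional implant used to select the measurement plane.
#' @return List of metric values.
#' @export
metrics_report <- function(pred, truth, skull = NULL, implant = NULL) {
  rep <- list(
    sdi = sdi(pred, truth),
    hd = directed_hausdorff(truth, pred),
    hd_mm = directed_hausdorff(truth, pred, in_mm = TRUE),
    hd_unit_range_mm = hd_unit_range(pred$spacing)
  )
  if (!is.null(skull) && !is.null(implant)) {
    pl <- select_measurement_plane(implant)
    meas <- cvai_diagonals(skull, pl)
    idx <- cvai_indices(meas$lengths[["AO"]], meas$lengths[["BO"]],
                        meas$lengths[["CO"]], meas$lengths[["DO"]])
    rep$cvai <- list(plane_index = pl, lengths = as.list(meas$lengths),
                     acvai = idx[["acvai"]], pcvai = idx[["pcvai"]])
  }
  rep
}
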