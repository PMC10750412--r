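#' Read a skull volume from disk
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`), NRRD (`.nrrd`), and a raw
#' uint8 dialect (any other extension) consisting of an x-fastest byte grid
#' plus a JSON sidecar `<path>.json` holding `dims`, `spacing` and `origin`.
#' Files whose values are all 0/1 are returned as [binary_volume()], anything
#' else as [scalar_volume()].
#'
#' @param path File to read.
#' @param format One of `"auto"`, `"nifti"`, `"nrrd"`, `"raw"`.
#' @return A `voxel_volume`.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, format = c("auto", "nifti", "nrrd", "raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (format == "auto") format <- guess_format(path)
  switch(format,
    nifti = read_nifti_volume(path),
    nrrd = read_nrrd_volume(path),
    raw = read_raw_volume(path)
  )
}

#' Write a skull volume to disk
#'
#' The inverse of [read_volume()]: the written file round-trips to equal
#' values and spacing. Binary volumes are stored with a 1-byte-per-voxel
#' payload in the raw-uint8 and NIfTI dialects.
#'
#' @param volume A `voxel_volume`.
#' @param path Output file; the parent directory must exist.
#' @param format One of `"auto"`, `"nifti"`, `"nrrd"`, `"raw"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = c("auto", "nifti", "nrrd", "raw")) {
  if (!inherits(volume, "voxel_volume")) stop("`volume` must be a voxel_volume")
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unsupported format name", call. = FALSE))
  if (format == "auto") format <- guess_format(path)
  if (!dir.exists(dirname(path)))
    stop("parent directory '", dirname(path), "' does not exist")
  switch(format,
    nifti = write_nifti_volume(volume, path),
    nrrd = write_nrrd_volume(volume, path),
    raw = write_raw_volume(volume, path)
  )
  invisible(path)
}

guess_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.nrrd$", low)) return("nrrd")
  "raw"
}

as_read_volume <- function(values, spacing, origin) {
  if (!anyNA(values) && all(values == 0 | values == 1))
    binary_volume(values, spacing, origin)
  else
    scalar_volume(values, spacing, origin)
}

# ---- NIfTI (via RNifti) ----------------------------------------------------

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- as.numeric(RNifti::pixdim(img))[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else
    as.numeric(xf[1:3, 4]) - 0.5 * spacing
  vals <- array(as.numeric(img), dim = dim(img)[1:3])
  as_read_volume(vals, spacing, origin)
}

write_nifti_volume <- function(volume, path) {
  vals <- volume$values
  storage.mode(vals) <- if (is_binary_volume(volume)) "integer" else "double"
  attr(vals, "pixdim") <- volume$spacing
  nii <- RNifti::asNifti(vals,
                         datatype = if (is_binary_volume(volume)) "uint8" else "double")
  m <- diag(4)
  m[1:3, 1:3] <- diag(volume$spacing)
  m[1:3, 4] <- volume$origin + 0.5 * volume$spacing
  RNifti::sform(nii) <- structure(m, code = 2L)
  RNifti::qform(nii) <- structure(m, code = 2L)
  RNifti::writeNifti(nii, path)
}

# ---- NRRD (minimal reader/writer: raw and gzip encodings) ------------------

read_nrrd_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000", magic)) stop("'", path, "' is not an NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("NRRD header ended without a blank line")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3-D NRRD volumes are supported")
  type <- fields[["type"]]
  enc <- tolower(fields[["encoding"]] %||% "raw")
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- parse_nrrd_vectors(fields[["space directions"]])
    spacing <- vapply(vecs, function(v) sqrt(sum(v^2)), numeric(1))
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vectors(fields[["space origin"]])[[1]]
  payload <- readBin(con, "raw", n = file.size(path))
  if (enc == "gzip") payload <- memDecompress(payload, type = "gzip")
  else if (enc != "raw") stop("unsupported NRRD encoding '", enc, "'")
  n <- prod(sizes)
  vals <- switch(type,
    uint8 = , uchar = as.numeric(readBin(payload, "integer", n = n, size = 1,
                                         signed = FALSE)),
    int16 = , short = as.numeric(readBin(payload, "integer", n = n, size = 2,
                                         endian = "little")),
    int32 = , int = as.numeric(readBin(payload, "integer", n = n, size = 4,
                                       endian = "little")),
    float = as.numeric(readBin(payload, "double", n = n, size = 4,
                               endian = "little")),
    double = readBin(payload, "double", n = n, size = 8, endian = "little"),
    stop("unsupported NRRD type '", type, "'")
  )
  if (length(vals) < n) stop("NRRD payload shorter than declared sizes")
  as_read_volume(array(vals[seq_len(n)], dim = sizes), spacing, origin)
}

parse_nrrd_vectors <- function(txt) {
  m <- regmatches(txt, gregexpr("\\(([^)]*)\\)", txt))[[1]]
  lapply(m, function(v)
    as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
}

write_nrrd_volume <- function(volume, path) {
  binary <- is_binary_volume(volume)
  d <- vol_dims(volume)
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", if (binary) "uint8" else "double"),
    "dimension: 3",
    "space dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            volume$spacing[1], volume$spacing[2], volume$spacing[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            volume$origin[1], volume$origin[2], volume$origin[3]),
    "encoding: raw",
    "endian: little",
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (binary) writeBin(as.raw(volume$values), con)
  else writeBin(as.numeric(volume$values), con, size = 8, endian = "little")
}

# ---- raw uint8 + JSON sidecar ----------------------------------------------

raw_sidecar_path <- function(path) paste0(path, ".json")

read_raw_volume <- function(path) {
  side <- raw_sidecar_path(path)
  if (!file.exists(side))
    stop("raw volume '", path, "' has no JSON sidecar '", side,
         "' declaring dims/spacing")
  meta <- jsonlite::fromJSON(side)
  if (is.null(meta$dims) || is.null(meta$spacing))
    stop("raw sidecar must declare `dims` and `spacing`")
  dims <- as.integer(meta$dims)
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) != prod(dims))
    stop("raw payload has ", length(bytes), " bytes but dims declare ",
         prod(dims))
  vals <- array(as.numeric(as.integer(bytes)), dim = dims)
  as_read_volume(vals, as.numeric(meta$spacing),
                 as.numeric(meta$origin %||% c(0, 0, 0)))
}

write_raw_volume <- function(volume, path) {
  vals <- volume$values
  if (anyNA(vals) || any(vals < 0 | vals > 255 | vals != floor(vals)))
    stop("raw-uint8 dialect requires integer values in [0, 255]")
  writeBin(as.raw(vals), path)
  jsonlite::write_json(
    list(dims = vol_dims(volume), spacing = volume$spacing,
         origin = volume$origin),
    raw_sidecar_path(path), auto_unbox = FALSE, digits = NA
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- binarization, resampling, cropping ------------------------------------

#' Extract bone tissue by Hounsfield windowing
#'
#' Voxels whose CT intensity lies inside the closed window `[lo, hi]` become
#' bone (1); everything else becomes background (0). The default window is
#' the interval typically enclosing cranial bone on the scanners this
#' workflow targets; per-patient adjustment is expected because bone density
#' varies with acquisition conditions.
#'
#' @param volume A `scalar_volume` of CT intensities.
#' @param lo,hi Window endpoints (HU), inclusive; `lo <= hi`.
#' @return A [binary_volume()] on the same grid.
#' @export
binarize_hounsfield <- function(volume, lo = 1200, hi = 1817) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (lo > hi) stop("`lo` must be <= `hi`")
  bad <- sum(!is.finite(volume$values))
  if (bad > 0)
    stop("volume has ", bad, " non-finite intensities; clean before windowing")
  vals <- array(as.integer(volume$values >= lo & volume$values <= hi),
                dim = vol_dims(volume))
  binary_volume(vals, volume$spacing, volume$origin)
}

# Lanczos-3 kernel
lanczos3 <- function(x) {
  out <- numeric(length(x))
  core <- abs(x) < 3 & x != 0
  out[x == 0] <- 1
  xs <- x[core]
  out[core] <- (sin(pi * xs) / (pi * xs)) * (sin(pi * xs / 3) / (pi * xs / 3))
  out
}

# n_new x n_old row-normalized resampling matrix along one axis.
# Output sample i (0-based) reads the continuous position
# (i + 0.5) * n_old / n_new - 0.5 so the physical extent is preserved;
# samples beyond the ends are clamped to the edge slices.
resample_weights <- function(n_old, n_new, method) {
  W <- matrix(0, n_new, n_old)
  scale <- n_old / n_new
  pos <- (seq_len(n_new) - 0.5) * scale - 0.5
  for (i in seq_len(n_new)) {
    x <- pos[i]
    if (method == "nearest") {
      j <- min(max(round(x), 0), n_old - 1)
      W[i, j + 1] <- 1
    } else if (method == "linear") {
      j0 <- floor(x)
      f <- x - j0
      ja <- min(max(j0, 0), n_old - 1)
      jb <- min(max(j0 + 1, 0), n_old - 1)
      W[i, ja + 1] <- W[i, ja + 1] + (1 - f)
      W[i, jb + 1] <- W[i, jb + 1] + f
    } else { # lanczos, a = 3
      js <- seq(floor(x) - 2, floor(x) + 3)
      w <- lanczos3(x - js)
      js <- pmin(pmax(js, 0), n_old - 1) # clamp to edge values
      for (q in seq_along(js)) W[i, js[q] + 1] <- W[i, js[q] + 1] + w[q]
    }
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

#' Resample a volume along the craniocaudal axis
#'
#' Changes only the number of z slices, rescaling the z spacing so the
#' physical extent is preserved. CT series have varying slice intervals, so
#' volumes are brought to a common slice count before any learning. Lanczos
#' (order 3, edge-clamped) is the default interpolator; binary input is
#' interpolated as reals and re-binarized at 0.5.
#'
#' @param volume A `voxel_volume`.
#' @param target_slices New z extent (>= 1).
#' @param method `"lanczos"`, `"nearest"` or `"linear"`.
#' @return A volume with identical planar dims and `target_slices` slices.
#' @export
resample_craniocaudal <- function(volume, target_slices,
                                  method = c("lanczos", "nearest", "linear")) {
  stopifnot(inherits(volume, "voxel_volume"))
  method <- match.arg(method)
  if (length(target_slices) != 1L || target_slices < 1)
    stop("`target_slices` must be a positive count")
  d <- vol_dims(volume)
  W <- resample_weights(d[3], as.integer(target_slices), method)
  flat <- matrix(as.numeric(volume$values), d[1] * d[2], d[3])
  out <- array(flat %*% t(W), dim = c(d[1], d[2], as.integer(target_slices)))
  spacing <- volume$spacing
  spacing[3] <- spacing[3] * d[3] / target_slices
  if (is_binary_volume(volume)) {
    binary_volume(array(as.integer(out >= 0.5), dim = dim(out)),
                  spacing, volume$origin)
  } else {
    scalar_volume(out, spacing, volume$origin)
  }
}

#' Down-sample a binary volume by block majority
#'
#' Each output voxel summarizes a `factor`^3 block of the input; it becomes
#' bone when at least half of the block is bone (ties count as bone). The
#' default factor of 4 maps the native 512 x 512 x 384 grid to the
#' 128 x 128 x 96 grid used by the completion network.
#'
#' @param volume A `binary_volume` whose dims are divisible by `factor`.
#' @param factor Integer block edge (default 4).
#' @return A `binary_volume` with dims `dims / factor` and spacing
#'   `spacing * factor`.
#' @export
downsample_binary <- function(volume, factor = 4L) {
  if (!is_binary_volume(volume)) stop("`volume` must be a binary_volume")
  factor <- as.integer(factor)
  d <- vol_dims(volume)
  if (any(d %% factor != 0))
    stop("dims (", paste(d, collapse = "x"), ") not divisible by ", factor,
         "; pad or crop the volume first")
  dd <- d %/% factor
  a <- array(volume$values, dim = c(factor, dd[1], factor, dd[2], factor, dd[3]))
  block <- apply(a, c(2, 4, 6), sum)
  vals <- array(as.integer(2L * block >= factor^3), dim = dd)
  binary_volume(vals, volume$spacing * factor, volume$origin)
}

#' Zero all voxels below a horizontal plane
#'
#' Removes bone below the given craniocaudal slice, emulating the standard
#' normalization that keeps only tissue above the Frankfort horizontal plane.
#' The plane index is 0-based and supplied per volume (no automatic landmark
#' detection); `plane_index = 0` is a no-op.
#'
#' @param volume A `voxel_volume`.
#' @param plane_index Integer in `[0, dim_z]`; voxels with z index (0-based)
#'   strictly below it are zeroed.
#' @return A volume with unchanged dims.
#' @export
crop_below_plane <- function(volume, plane_index) {
  stopifnot(inherits(volume, "voxel_volume"))
  d <- vol_dims(volume)
  if (plane_index < 0 || plane_index > d[3])
    stop("`plane_index` must be in [0, ", d[3], "]")
  if (plane_index > 0) {
    volume$values[, , seq_len(plane_index)] <- 0L
  }
  volume
}
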