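test_that("read/write round-trips values and spacing for every format", {
  set.seed(1)
  for (fmt in c("raw", "nrrd", "nifti")) {
    for (rep in 1:3) {
      v <- random_binary_vol(spacing = c(0.45, 0.45, 0.8))
      ext <- switch(fmt, raw = ".bin", nrrd = ".nrrd", nifti = ".nii.gz")
      path <- tempfile(fileext = ext)
      write_volume(v, path, fmt)
      r <- read_volume(path, fmt)
      expect_true(is_binary_volume(r), info = fmt)
      expect_identical(r$values, v$values, info = fmt)
      expect_equal(r$spacing, v$spacing, tolerance = 1e-6, info = fmt)
    }
    # scalar round-trip (raw dialect needs integers in [0, 255])
    sv <- scalar_volume(array(sample(0:255, 64, TRUE), c(4, 4, 4)),
                        spacing = c(1, 2, 3))
    path <- tempfile(fileext = switch(fmt, raw = ".bin", nrrd = ".nrrd",
                                      nifti = ".nii"))
    write_volume(sv, path, fmt)
    r <- read_volume(path, fmt)
    expect_equal(as.numeric(r$values), as.numeric(sv$values), info = fmt)
    expect_equal(r$spacing, sv$spacing, tolerance = 1e-6, info = fmt)
  }
})

test_that("NRRD stores the reference CT voxel size", {
  v <- random_binary_vol(spacing = c(0.45, 0.45, 0.8))
  path <- tempfile(fileext = ".nrrd")
  write_volume(v, path)
  expect_equal(read_volume(path)$spacing, c(0.45, 0.45, 0.8),
               tolerance = 1e-9)
})

test_that("raw dialect is x-fastest with a JSON sidecar", {
  # hand-built reference: byte value encodes its own (i, j, k) index
  bytes <- as.raw(0:63)
  path <- tempfile(fileext = ".bin")
  writeBin(bytes, path)
  jsonlite::write_json(list(dims = c(4L, 4L, 4L), spacing = c(1, 1, 1),
                            origin = c(0, 0, 0)),
                       paste0(path, ".json"))
  v <- read_volume(path)
  expect_equal(dim(v$values), c(4L, 4L, 4L))
  ref <- array(0:63, c(4, 4, 4)) # R arrays are first-index fastest
  expect_equal(as.numeric(v$values), as.numeric(ref))
  expect_equal(v$values[2, 1, 1], 1) # x moves first
  expect_equal(v$values[1, 2, 1], 4)
  expect_equal(v$values[1, 1, 2], 16)
})

test_that("all-zero volumes and uint8 payloads write correctly", {
  z <- binary_volume(array(0L, c(4, 4, 4)))
  path <- tempfile(fileext = ".bin")
  write_volume(z, path)
  expect_true(file.exists(path))
  expect_equal(file.size(path), 64) # 1 byte per voxel
  expect_equal(sum(read_volume(path)$values), 0)
})

test_that("unsupported formats and unreadable files error", {
  v <- random_binary_vol()
  expect_error(write_volume(v, tempfile(), "hdf5"), "unsupported format")
  expect_error(read_volume(tempfile(fileext = ".nrrd")), "no such file")
  # raw without sidecar is a format error
  p <- tempfile(fileext = ".bin")
  writeBin(as.raw(0:7), p)
  expect_error(read_volume(p), "sidecar")
})

test_that("Hounsfield windowing is inclusive and matches a brute-force scan", {
  sv <- scalar_volume(array(c(1000, 1200, 1817, 2000, 500, 1500, 1199, 1818),
                            c(2, 2, 2)))
  b <- binarize_hounsfield(sv, 1200, 1817)
  expect_equal(as.numeric(b$values),
               c(0, 1, 1, 0, 0, 1, 0, 0))
  # all below the window
  low <- scalar_volume(array(runif(27, 0, 100), c(3, 3, 3)))
  expect_equal(sum(binarize_hounsfield(low, 1200, 1817)$values), 0)
  # random volume against an independent scan
  set.seed(2)
  rv <- scalar_volume(array(runif(4 * 5 * 6, 800, 2200), c(4, 5, 6)))
  b <- binarize_hounsfield(rv, 1200, 1817)
  expect_equal(sum(b$values),
               sum(rv$values >= 1200 & rv$values <= 1817))
  # monotonicity: raising lo never adds bone
  n_prev <- Inf
  for (lo in c(900, 1100, 1300, 1500)) {
    n <- sum(binarize_hounsfield(rv, lo, 1817)$values)
    expect_lte(n, n_prev)
    n_prev <- n
  }
  bad <- scalar_volume(array(c(NaN, 1:7), c(2, 2, 2)))
  bad$values[1] <- NA
  expect_error(binarize_hounsfield(bad), "non-finite")
})

test_that("craniocaudal resampling preserves planar dims, extent and constants", {
  set.seed(3)
  sv <- scalar_volume(array(runif(6 * 5 * 8), c(6, 5, 8)), c(1, 1, 2))
  # identity resampling reproduces node values
  id <- resample_craniocaudal(sv, 8, "lanczos")
  expect_lt(max(abs(id$values - sv$values)), 1e-9)
  # constants are fixed points
  cv <- scalar_volume(array(3.7, c(4, 4, 6)))
  for (m in c("lanczos", "nearest", "linear")) {
    r <- resample_craniocaudal(cv, 9, m)
    expect_equal(dim(r$values)[1:2], c(4L, 4L))
    expect_lt(max(abs(r$values - 3.7)), 1e-12)
    # physical extent preserved
    expect_equal(dim(r$values)[3] * r$spacing[3], 6 * cv$spacing[3])
  }
  # linear ramp along z, 2x upsampling, interior within 1%
  nz <- 16
  ramp <- scalar_volume(array(rep(seq_len(nz), each = 4), c(2, 2, nz)))
  up <- resample_craniocaudal(ramp, 2 * nz, "lanczos")
  pos <- ((seq_len(2 * nz) - 0.5) * 0.5 - 0.5) + 1 # analytic ramp value
  interior <- 7:(2 * nz - 6)
  rel <- abs(up$values[1, 1, interior] - pos[interior]) / pos[interior]
  expect_lt(max(rel), 0.01)
  # binary volumes stay binary
  bv <- random_binary_vol(c(4, 4, 10))
  rb <- resample_craniocaudal(bv, 25)
  expect_true(is_binary_volume(rb))
  expect_error(resample_craniocaudal(bv, 0), "positive")
})

test_that("block-majority downsampling summarizes factor^3 blocks", {
  ones <- binary_volume(array(1L, c(8, 8, 8)))
  d <- downsample_binary(ones, 2)
  expect_equal(dim(d$values), c(4L, 4L, 4L))
  expect_equal(sum(d$values), 64)
  expect_equal(d$spacing, 2 * ones$spacing)
  # single voxel: occupancy 1/8 is below majority
  lone <- binary_volume(array(0L, c(8, 8, 8)))
  lone$values[3, 3, 3] <- 1L
  expect_equal(sum(downsample_binary(lone, 2)$values), 0)
  # ties (exactly half the block) count as bone
  half <- binary_volume(array(rep(c(1L, 0L), 4), c(2, 2, 2)))
  expect_equal(sum(downsample_binary(half, 2)$values), 1)
  # factor 4 gives the reference 4x grid reduction
  big <- random_binary_vol(c(32, 32, 16))
  expect_equal(dim(downsample_binary(big, 4)$values), c(8L, 8L, 4L))
  expect_error(downsample_binary(random_binary_vol(c(6, 6, 6)), 4),
               "divisible")
})

test_that("down-then-up never escapes the (factor-1)-voxel dilation", {
  set.seed(4)
  f <- 2L
  for (rep in 1:5) {
    v <- random_binary_vol(c(8, 8, 8), p = 0.4)
    d <- downsample_binary(v, f)
    up <- array(0L, dim = c(8, 8, 8))
    for (i in 1:8) for (j in 1:8) for (k in 1:8)
      up[i, j, k] <- d$values[ceiling(i / f), ceiling(j / f), ceiling(k / f)]
    # every up voxel must be within Chebyshev distance (f-1) of an original 1
    occ <- which(up == 1, arr.ind = TRUE)
    orig <- which(v$values == 1, arr.ind = TRUE)
    ok <- apply(occ, 1, function(p) {
      any(apply(abs(t(orig) - p), 2, max) <= f - 1)
    })
    expect_true(all(ok))
  }
})

test_that("cropping below a plane zeroes inferior slices only", {
  v <- toy_phantom(crop = 0)
  expect_identical(crop_below_plane(v, 0)$values, v$values)
  expect_equal(sum(crop_below_plane(v, vol_dims(v)[3])$values), 0)
  mid <- vol_dims(v)[3] %/% 2
  cr <- crop_below_plane(v, mid)
  # brute-force: ones at or above the plane (0-based z >= mid)
  expect_equal(sum(cr$values), sum(v$values[, , (mid + 1):vol_dims(v)[3]]))
  expect_equal(dim(cr$values), vol_dims(v))
  expect_error(crop_below_plane(v, -1), "plane_index")
})
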