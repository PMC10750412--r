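test_that("mask sampling respects the diameter range and is reproducible", {
  ph <- toy_phantom()
  # collapsed range: every draw has exactly that diameter
  set.seed(1)
  for (i in 1:10) {
    sp <- sample_mask_spec(ph, diameter_range_mm = c(80, 80))
    expect_equal(mask_max_diameter(sp), 80)
  }
  # fixed seed reproduces the spec sequence
  set.seed(9)
  a <- replicate(5, sample_mask_spec(ph), simplify = FALSE)
  set.seed(9)
  b <- replicate(5, sample_mask_spec(ph), simplify = FALSE)
  expect_identical(a, b)
  expect_error(sample_mask_spec(ph, families = character(0)), "family")
  expect_error(sample_mask_spec(ph, diameter_range_mm = c(120, 60)),
               "diameter_range")
})

test_that("rasterized solids match their analytic volumes within 5%", {
  grid <- binary_volume(array(0L, c(64, 64, 64)))
  ctr <- c(32, 32, 32)
  # ellipsoid
  ell <- mask_spec("ellipsoid", list(list(kind = "ellipsoid", center = ctr,
                                          semi_axes = c(12, 9, 7))))
  m <- rasterize_mask(ell, grid)
  expect_lt(abs(n_ones(m) - 4 / 3 * pi * 12 * 9 * 7) /
              (4 / 3 * pi * 12 * 9 * 7), 0.05)
  # z-aligned elliptical cylinder
  cyl <- mask_spec("elliptical_cylinder",
                   list(list(kind = "cylinder", center = ctr,
                             semi_axes = c(10, 6), half_height = 11,
                             axis = c(0, 0, 1))))
  m <- rasterize_mask(cyl, grid)
  expect_lt(abs(n_ones(m) - pi * 10 * 6 * 22) / (pi * 10 * 6 * 22), 0.05)
  # degenerate: semi-axes below half a voxel leave at most a 1-voxel line
  thin <- mask_spec("elliptical_cylinder",
                    list(list(kind = "cylinder", center = ctr,
                              semi_axes = c(0.3, 0.3), half_height = 10,
                              axis = c(0, 0, 1))))
  expect_lte(n_ones(suppressWarnings(rasterize_mask(thin, grid))), 21)
  # entirely outside the grid flags an empty mask
  far <- mask_spec("ellipsoid", list(list(kind = "ellipsoid",
                                          center = c(500, 500, 500),
                                          semi_axes = c(5, 5, 5))))
  expect_warning(m <- rasterize_mask(far, grid), "outside")
  expect_true(isTRUE(attr(m, "empty_mask")))
})

test_that("rasterization is monotone in the semi-axes", {
  grid <- binary_volume(array(0L, c(32, 32, 32)))
  set.seed(3)
  for (rep in 1:5) {
    ax <- runif(3, 3, 8)
    small <- mask_spec("ellipsoid", list(list(kind = "ellipsoid",
                                              center = c(16, 16, 16),
                                              semi_axes = ax)))
    big <- mask_spec("ellipsoid", list(list(kind = "ellipsoid",
                                            center = c(16, 16, 16),
                                            semi_axes = ax + runif(3, 0, 4))))
    ms <- rasterize_mask(small, grid)$values
    mb <- rasterize_mask(big, grid)$values
    expect_true(all(mb[ms == 1] == 1))
  }
})

test_that("Boolean defect application conserves the intact skull", {
  ph <- toy_phantom()
  # empty mask: identity
  none <- binary_volume(array(0L, vol_dims(ph)), ph$spacing, ph$origin)
  pr <- apply_defect(ph, none)
  expect_identical(pr$defective$values, ph$values)
  expect_equal(n_ones(pr$implant_truth), 0)
  # total mask: everything becomes implant
  all1 <- binary_volume(array(1L, vol_dims(ph)), ph$spacing, ph$origin)
  pr <- apply_defect(ph, all1)
  expect_equal(n_ones(pr$defective), 0)
  expect_identical(pr$implant_truth$values, ph$values)
  # conservation and disjointness over random masks (property)
  set.seed(4)
  for (rep in 1:20) {
    mask <- suppressWarnings(rasterize_mask(sample_mask_spec(ph), ph))
    pr <- apply_defect(ph, mask)
    expect_equal(n_ones(pr$defective) + n_ones(pr$implant_truth), n_ones(ph))
    expect_equal(sum(pr$defective$values & pr$implant_truth$values), 0)
    expect_identical(array(as.integer(pr$defective$values |
                                        pr$implant_truth$values),
                           vol_dims(ph)),
                     ph$values)
  }
  expect_error(apply_defect(ph, random_binary_vol(c(4, 4, 4))), "dims")
})

test_that("rotation augmentation yields 2*per_side + 1 binary variants", {
  ph <- toy_phantom()
  vars <- rotate_augment(ph)
  expect_length(vars, 7)
  expect_identical(vars[[4]]$values, ph$values) # k = 0 is exact
  expect_length(rotate_augment(ph, per_side = 2L), 5)
  # rotational invariance on a z-symmetric annular cylinder
  d <- c(32L, 32L, 8L)
  ctr <- (d[1:2] + 1) / 2
  ann <- array(0L, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    r <- sqrt((i - ctr[1])^2 + (j - ctr[2])^2)
    if (r >= 8 && r <= 12) ann[i, j, ] <- 1L
  }
  annv <- binary_volume(ann)
  for (v in rotate_augment(annv)) {
    expect_lt(abs(n_ones(v) - n_ones(annv)) / n_ones(annv), 0.02)
    expect_true(is_binary_volume(v))
  }
  expect_error(rotate_augment(ph, interval_deg = 0), "interval_deg")
})

test_that("out-of-range defects are detected", {
  ph <- toy_phantom()
  d <- vol_dims(ph)
  none <- binary_volume(array(0L, d), ph$spacing, ph$origin)
  expect_false(is_defect_in_range(apply_defect(ph, none), 0L))
  # defect strictly in the top half passes a mid-height plane
  top <- array(0L, d)
  top[, , (d[3] - 5):d[3]] <- 1L
  topv <- binary_volume(top, ph$spacing, ph$origin)
  pr <- apply_defect(ph, topv)
  expect_true(is_defect_in_range(pr, d[3] %/% 2))
  # defect straddling the plane fails
  strad <- array(0L, d)
  strad[, , (d[3] %/% 2 - 2):d[3]] <- 1L
  pr2 <- apply_defect(ph, binary_volume(strad, ph$spacing, ph$origin))
  expect_false(is_defect_in_range(pr2, d[3] %/% 2))
  # a mask that merely grazes a few voxels is not a craniectomy defect
  occ <- which(ph$values == 1, arr.ind = TRUE)
  occ <- occ[order(occ[, 3], decreasing = TRUE)[1:2], , drop = FALSE]
  graze <- array(0L, d)
  graze[occ] <- 1L
  pr3 <- apply_defect(ph, binary_volume(graze, ph$spacing, ph$origin))
  expect_false(is_defect_in_range(pr3, 0L))
  expect_true(is_defect_in_range(pr3, 0L, min_fraction = 0))
})

test_that("the generator emits the configured number of defect pairs", {
  ph <- toy_phantom()
  set.seed(5)
  pairs <- generate_defect_pairs(ph, n = 5L)
  expect_length(pairs, 5)
  for (pr in pairs) {
    expect_s3_class(pr, "defect_pair")
    expect_gt(n_ones(pr$implant_truth), 0)
    expect_equal(n_ones(pr$defective) + n_ones(pr$implant_truth), n_ones(ph))
  }
})
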