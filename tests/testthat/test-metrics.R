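vol_from_voxels <- function(dims, voxels) {
  a <- array(0L, dims)
  for (v in voxels) a[v[1] + 1, v[2] + 1, v[3] + 1] <- 1L
  binary_volume(a)
}

test_that("overlap counts enumerate TP/FP/FN voxels", {
  g <- random_binary_vol(c(5, 5, 5), p = 0.4)
  oc <- overlap_counts(g, g)
  expect_equal(oc, list(n_tp = n_ones(g), n_fp = 0L, n_fn = 0L))
  p2 <- vol_from_voxels(c(4, 4, 4), list(c(0, 0, 0), c(1, 0, 0)))
  g2 <- vol_from_voxels(c(4, 4, 4), list(c(2, 2, 2), c(3, 3, 3), c(0, 3, 0)))
  expect_equal(overlap_counts(p2, g2), list(n_tp = 0L, n_fp = 2L, n_fn = 3L))
  p3 <- vol_from_voxels(c(4, 4, 4), list(c(0, 0, 0), c(1, 1, 1)))
  g3 <- vol_from_voxels(c(4, 4, 4), list(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(overlap_counts(p3, g3), list(n_tp = 1L, n_fp = 1L, n_fn = 1L))
  expect_error(overlap_counts(p3, random_binary_vol(c(3, 3, 3))), "mismatch")
})

test_that("SDI matches its definition, is symmetric and bounded", {
  g <- random_binary_vol(c(6, 6, 6), p = 0.3)
  expect_equal(sdi(g, g), 100)
  p <- vol_from_voxels(c(4, 4, 4), list(c(0, 0, 0)))
  q <- vol_from_voxels(c(4, 4, 4), list(c(3, 3, 3)))
  expect_equal(sdi(p, q), 0)
  p3 <- vol_from_voxels(c(4, 4, 4), list(c(0, 0, 0), c(1, 1, 1)))
  g3 <- vol_from_voxels(c(4, 4, 4), list(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(sdi(p3, g3), 50)
  set.seed(1)
  for (rep in 1:10) {
    a <- random_binary_vol(c(5, 5, 5), p = 0.4)
    b <- random_binary_vol(c(5, 5, 5), p = 0.4)
    expect_equal(sdi(a, b), sdi(b, a))
    expect_gte(sdi(a, b), 0)
    expect_lte(sdi(a, b), 100)
    expect_equal(sdi(a, b), brute_sdi(a, b))
  }
  empty <- binary_volume(array(0L, c(3, 3, 3)))
  expect_error(sdi(empty, empty), "empty")
})

test_that("directed Hausdorff matches hand cases and the brute-force oracle", {
  g <- random_binary_vol(c(5, 5, 5), p = 0.4)
  expect_equal(directed_hausdorff(g, g), 0)
  a <- vol_from_voxels(c(5, 5, 5), list(c(0, 0, 0)))
  b <- vol_from_voxels(c(5, 5, 5), list(c(2, 0, 0)))
  expect_equal(directed_hausdorff(a, b), 2)
  c2 <- vol_from_voxels(c(5, 5, 5), list(c(0, 0, 0), c(1, 1, 1)))
  d2 <- vol_from_voxels(c(5, 5, 5), list(c(0, 0, 0)))
  expect_equal(directed_hausdorff(c2, d2), sqrt(3), tolerance = 1e-12)
  # directionality: every voxel of d2 is in c2, so the reverse is 0
  expect_equal(directed_hausdorff(d2, c2), 0)
  expect_equal(hausdorff_distance(c2, d2), sqrt(3), tolerance = 1e-12)
  set.seed(2)
  for (rep in 1:10) {
    G <- random_binary_vol(c(6, 6, 6), p = 0.2)
    P <- random_binary_vol(c(6, 6, 6), p = 0.2)
    if (n_ones(G) == 0 || n_ones(P) == 0) next
    expect_equal(directed_hausdorff(G, P), brute_directed_hausdorff(G, P))
    # zero iff containment
    expect_equal(directed_hausdorff(G, P) == 0,
                 all(P$values[G$values == 1] == 1))
  }
  # mm mode scales by voxel spacing
  am <- vol_from_voxels(c(5, 5, 5), list(c(0, 0, 0)))
  bm <- vol_from_voxels(c(5, 5, 5), list(c(0, 0, 2)))
  am$spacing <- bm$spacing <- c(0.45, 0.45, 0.8)
  expect_equal(directed_hausdorff(am, bm, in_mm = TRUE), 1.6)
  empty <- binary_volume(array(0L, c(3, 3, 3)))
  expect_error(directed_hausdorff(empty, a), "non-empty")
})

test_that("HD unit range spans nearest to diagonal neighbour distances", {
  expect_equal(round(hd_unit_range(c(0.45, 0.45, 0.8)), 4), c(0.45, 1.0223))
  expect_equal(hd_unit_range(c(1, 1, 1)), c(1, sqrt(3)))
  expect_equal(hd_unit_range(c(2, 2, 2)), 2 * hd_unit_range(c(1, 1, 1)))
  expect_error(hd_unit_range(c(0, 1, 1)), "positive")
})

test_that("the measurement plane maximizes implant intersection", {
  d <- c(6L, 6L, 4L)
  one_slice <- array(0L, d)
  one_slice[2:4, 2:4, 3] <- 1L
  expect_equal(select_measurement_plane(binary_volume(one_slice)), 2L)
  counts <- array(0L, c(8, 8, 4))
  counts[1:3, 1, 1] <- 1L  # slice 0: 3 voxels
  counts[1:7, 1, 2] <- 1L  # slice 1: 7
  counts[1:7, 2, 3] <- 1L  # slice 2: 7 (tie -> inferior-most wins)
  counts[1, 1, 4] <- 1L    # slice 3: 1
  expect_equal(select_measurement_plane(binary_volume(counts)), 1L)
  expect_error(select_measurement_plane(binary_volume(array(0L, c(2, 2, 2)))),
               "empty")
})

test_that("CVAI diagonals recover analytic radii on circle and ellipse", {
  d <- c(64L, 64L, 4L)
  mk_ring <- function(a, b) {
    arr <- array(0L, d)
    ctr <- (d[1:2] + 1) / 2
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      q <- ((i - ctr[1]) / a)^2 + ((j - ctr[2]) / b)^2
      qi <- ((i - ctr[1]) / (a - 3))^2 + ((j - ctr[2]) / (b - 3))^2
      if (q <= 1 && qi > 1) arr[i, j, ] <- 1L
    }
    binary_volume(arr)
  }
  # circular annulus: all four radii equal r
  ring <- mk_ring(20, 20)
  m <- cvai_diagonals(ring, 1L)
  expect_true(all(abs(m$lengths - 20) < 1))
  idx <- cvai_indices(m$lengths[["AO"]], m$lengths[["BO"]],
                      m$lengths[["CO"]], m$lengths[["DO"]])
  expect_lt(max(idx), 1.5)
  # ellipse: compare to the polar radius at 60 degrees from the y axis
  ell <- mk_ring(26, 18)
  me <- cvai_diagonals(ell, 1L)
  th <- pi / 3 # from the y axis
  r_analytic <- 1 / sqrt((sin(th) / 26)^2 + (cos(th) / 18)^2)
  expect_true(all(abs(me$lengths - r_analytic) < 1))
  # mirroring the slice left-right swaps A<->B and C<->D: use a ring whose
  # right half is wider than its left half
  asym <- binary_volume(array(0L, d))
  ctr <- (d[1:2] + 1) / 2
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    a <- if (i >= ctr[1]) 28 else 22
    q <- ((i - ctr[1]) / a)^2 + ((j - ctr[2]) / 18)^2
    qi <- ((i - ctr[1]) / (a - 3))^2 + ((j - ctr[2]) / 15)^2
    if (q <= 1 && qi > 1) asym$values[i, j, ] <- 1L
  }
  ma <- cvai_diagonals(asym, 1L, O = c(32, 32))
  mirror <- asym
  mirror$values <- asym$values[rev(seq_len(d[1])), , ]
  mm <- cvai_diagonals(mirror, 1L, O = c(32, 32))
  expect_equal(ma$lengths[["AO"]], mm$lengths[["BO"]], tolerance = 0.05)
  expect_equal(ma$lengths[["CO"]], mm$lengths[["DO"]], tolerance = 0.05)
  expect_gt(ma$lengths[["BO"]], ma$lengths[["AO"]]) # right side is wider
})

test_that("CVAI indices follow their defining ratios", {
  expect_equal(as.numeric(cvai_indices(50, 50, 60, 60)), c(0, 0))
  expect_equal(round(as.numeric(cvai_indices(71.05, 72.63, 83.70, 85.53)), 2),
               c(2.22, 2.14))
  expect_equal(as.numeric(cvai_indices(100, 98, 50, 50))[1], 2.00)
  sg <- attr(cvai_indices(71.05, 72.63, 83.70, 85.53), "signed")
  expect_lt(sg[["acvai"]], 0) # BO longer than AO: signed value retained
  expect_error(cvai_indices(0, 1, 1, 1), "positive")
})

test_that("metrics_report bundles the metric suite", {
  ph <- toy_phantom()
  rep <- metrics_report(ph, ph)
  expect_equal(rep$sdi, 100)
  expect_equal(rep$hd, 0)
  expect_equal(round(rep$hd_unit_range_mm, 4), round(hd_unit_range(ph$spacing), 4))
})
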