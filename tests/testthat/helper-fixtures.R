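# Shared fixtures and independent brute-force oracles.

random_binary_vol <- function(dims = c(8L, 8L, 8L), p = 0.3,
                              spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  binary_volume(array(rbinom(prod(dims), 1, p), dim = dims), spacing, origin)
}

# small connected vault phantom on a 32^3-ish grid, shells thick enough to
# stay 6-connected at the coarse voxel size
toy_phantom <- function(dims = c(32L, 32L, 24L), spacing = c(6, 6, 8),
                        thickness = 12, asymmetry = 0.05, crop = 0.25) {
  generate_phantom(phantom_spec(shell_thickness = thickness,
                                asymmetry = asymmetry,
                                base_plane_fraction = crop,
                                dims = dims, spacing = spacing))
}

# exhaustive all-pairs directed Hausdorff (lattice units)
brute_directed_hausdorff <- function(G, P) {
  cg <- which(G$values != 0, arr.ind = TRUE) - 1
  cp <- which(P$values != 0, arr.ind = TRUE) - 1
  dmins <- apply(cg, 1, function(g) {
    min(sqrt(colSums((t(cp) - g)^2)))
  })
  max(dmins)
}

brute_sdi <- function(P, G) {
  p <- P$values != 0
  g <- G$values != 0
  200 * sum(p & g) / (2 * sum(p & g) + sum(p & !g) + sum(!p & g))
}

# parse a binary STL back into a triangle array (n x 3 x 3 vertices)
read_stl_tris <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  tris <- array(NA_real_, dim = c(n, 3, 3))
  for (i in seq_len(n)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "raw", n = 2)
    tris[i, , ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
  }
  tris
}

# signed volume enclosed by a triangle mesh (divergence theorem)
mesh_volume <- function(tris) {
  v <- 0
  for (i in seq_len(dim(tris)[1])) {
    a <- tris[i, 1, ]; b <- tris[i, 2, ]; c <- tris[i, 3, ]
    v <- v + sum(a * c(b[2] * c[3] - b[3] * c[2],
                       b[3] * c[1] - b[1] * c[3],
                       b[1] * c[2] - b[2] * c[1])) / 6
  }
  v
}

# every edge must appear in exactly two triangles (opposite orientation)
mesh_watertight <- function(tris) {
  edges <- character(0)
  for (i in seq_len(dim(tris)[1])) {
    vs <- round(tris[i, , ], 9)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      key <- paste(c(vs[e[1], ], vs[e[2], ]), collapse = ",")
      edges <- c(edges, key)
    }
  }
  # undirected edge key: sort the two endpoint strings
  undir <- vapply(strsplit(edges, ","), function(x) {
    a <- paste(x[1:3], collapse = ",")
    b <- paste(x[4:6], collapse = ",")
    paste(sort(c(a, b)), collapse = "|")
  }, character(1))
  all(table(undir) == 2L)
}
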