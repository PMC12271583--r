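# Independent oracles and tiny fixture builders used across the suite.
# Everything here is deliberately naive (loops, direct arithmetic) and shares
# no code path with the implementation it checks.

# floor-arithmetic oracle for the coordinate->index transform, one point at
# a time
oracle_point_to_ijk <- function(x, y, z, origin, voxel) {
  origin <- unname(origin); voxel <- unname(voxel)
  c(i = floor((unname(z) - origin[3]) / voxel[3]),
    j = floor((unname(y) - origin[2]) / voxel[2]),
    k = floor((unname(x) - origin[1]) / voxel[1]))
}

# brute-force lattice enumeration of in-bounds voxels whose center lies
# within `radius` of a point, excluding the point's own floor voxel;
# returns the 0-based index triples
oracle_neighbor_set <- function(point, dims_ijk, origin, voxel, radius) {
  own <- oracle_point_to_ijk(point[1], point[2], point[3], origin, voxel)
  out <- matrix(numeric(0), ncol = 3)
  for (i in 0:(dims_ijk[1] - 1)) {
    cz <- origin[3] + (i + 0.5) * voxel[3]
    for (j in 0:(dims_ijk[2] - 1)) {
      cy <- origin[2] + (j + 0.5) * voxel[2]
      for (k in 0:(dims_ijk[3] - 1)) {
        cx <- origin[1] + (k + 0.5) * voxel[1]
        d2 <- (cx - point[1])^2 + (cy - point[2])^2 + (cz - point[3])^2
        if (d2 <= radius^2 && !(i == own["i"] && j == own["j"] && k == own["k"])) {
          out <- rbind(out, c(i, j, k))
        }
      }
    }
  }
  out
}

# naive separable DFT (explicit DFT matrix per axis) -- independent of
# stats::fft
naive_dft3 <- function(x) {
  arr <- array(as.complex(x), dim(x))
  for (pass in 1:3) {
    n <- dim(arr)[1]
    W <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
    arr <- apply(arr, c(2, 3), function(v) W %*% v)
    arr <- aperm(arr, c(2, 3, 1))
  }
  arr
}

# naive shell-by-shell FSC built on naive_dft3 with explicit loops
oracle_fsc <- function(va, vb, voxel, shell_width) {
  fa <- naive_dft3(va)
  fb <- naive_dft3(vb)
  d <- dim(va)
  signed_freq <- function(idx0, n) {
    f <- idx0
    if (f > n / 2) f <- f - n
    f / (n * voxel)
  }
  shells <- list()
  for (i in 0:(d[1] - 1)) {
    for (j in 0:(d[2] - 1)) {
      for (k in 0:(d[3] - 1)) {
        r <- sqrt(signed_freq(i, d[1])^2 + signed_freq(j, d[2])^2 +
                    signed_freq(k, d[3])^2)
        if (r == 0) next
        s <- ceiling(r / shell_width - 1e-12)
        if ((s - 0.5) * shell_width > 1 / (2 * voxel) + 1e-12) next
        key <- as.character(s)
        a <- fa[i + 1, j + 1, k + 1]
        b <- fb[i + 1, j + 1, k + 1]
        prev <- shells[[key]]
        if (is.null(prev)) prev <- c(0, 0, 0)
        shells[[key]] <- prev +
          c(Re(a * Conj(b)), Mod(a)^2, Mod(b)^2)
      }
    }
  }
  s_ids <- sort(as.integer(names(shells)))
  vapply(as.character(s_ids), function(key) {
    v <- shells[[key]]
    v[1] / sqrt(v[2] * v[3])
  }, numeric(1))
}

# raw MRC writer with arbitrary axis correspondence and start indices,
# independent of write_mrc; `values` is the canonical (z, y, x) array
write_mrc_raw <- function(values, path, origin = c(0, 0, 0), voxel = c(1, 1, 1),
                          mapcrs = 1:3, nstart = c(0L, 0L, 0L),
                          origin_rec = origin) {
  a_xyz <- aperm(values, c(3, 2, 1)) # (x, y, z) phys order
  arr <- aperm(a_xyz, mapcrs) # stored (col, row, sec)
  n_xyz <- dim(a_xyz)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(dim(arr))
  wi(2L)
  wi(nstart)
  wi(n_xyz)
  wf(n_xyz * voxel)
  wf(c(90, 90, 90))
  wi(mapcrs)
  wf(c(min(values), max(values), mean(values)))
  wi(1L); wi(0L)
  writeBin(raw(100L), con)
  wf(origin_rec)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)
  wf(stats::sd(values))
  wi(0L)
  writeBin(raw(800L), con)
  writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  invisible(path)
}

# small deterministic random grid
random_grid <- function(dims_ijk = c(8, 7, 6), origin = c(0, 0, 0),
                        voxel = 1, seed = 42) {
  withr::with_seed(seed, {
    voxel_grid(array(rnorm(prod(dims_ijk)), dims_ijk), origin, voxel)
  })
}

# one-atom structure table at a coordinate
one_atom <- function(x, y, z, name = "CA", element = "C",
                     res_name = "ALA", is_hetero = FALSE) {
  tibble::tibble(
    model = 1L, serial = 1L, name = name, alt_loc = "", res_name = res_name,
    chain = "A", res_seq = 1L, i_code = "", x = x, y = y, z = z,
    occupancy = 1, b_factor = 0, element = element, is_hetero = is_hetero
  )
}
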