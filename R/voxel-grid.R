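#' Voxel grid objects
#'
#' A `voxel_grid` is the universal in-memory representation of a cryo-EM
#' density map: a 3-D scalar field together with its physical placement. The
#' value array is indexed `[i, j, k]` where `i` runs along z (sections), `j`
#' along y (rows) and `k` along x (columns) -- the canonical section/row/column
#' layout of deposited maps. `origin` and `voxel` are physical quantities in
#' Angstrom, stored per x/y/z axis.
#'
#' Grid indices throughout the package are **0-based**, matching the index
#' convention of map files and of the coordinate-to-index transform (see
#' [coords_to_indices()]); they are converted to R's 1-based subscripts only at
#' array-access time.
#'
#' @param values numeric 3-D array, indexed `[i (z), j (y), k (x)]`.
#' @param origin numeric length-3, physical origin in Angstrom, order (x, y, z).
#' @param voxel numeric length-3 (or scalar, recycled), voxel edge lengths in
#'   Angstrom, order (x, y, z). All components must be strictly positive.
#'
#' @return An object of class `voxel_grid` with elements `values`, `origin`
#'   (named x/y/z) and `voxel` (named x/y/z).
#' @examples
#' g <- voxel_grid(array(0, c(4, 5, 6)), origin = c(0, 0, 0), voxel = 1)
#' dim(g$values) # (n_i, n_j, n_k) = (4, 5, 6): 6 voxels along x
#' @export
voxel_grid <- function(values, origin = c(0, 0, 0), voxel = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  if (length(voxel) == 1L) voxel <- rep(voxel, 3L)
  origin <- as.numeric(origin)
  voxel <- as.numeric(voxel)
  if (length(origin) != 3L || length(voxel) != 3L) {
    stop("`origin` and `voxel` must have length 3", call. = FALSE)
  }
  if (any(!is.finite(origin)) || any(!is.finite(voxel))) {
    stop("`origin` and `voxel` must be finite", call. = FALSE)
  }
  if (any(voxel <= 0)) {
    stop("all voxel sizes must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("grid values must all be finite", call. = FALSE)
  }
  names(origin) <- names(voxel) <- c("x", "y", "z")
  structure(
    list(values = values, origin = origin, voxel = voxel),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d (i=z, j=y, k=x)\n  voxel  (x,y,z): %s A\n  origin (x,y,z): %s A\n  values: [%.4g, %.4g], mean %.4g\n",
    d[1], d[2], d[3],
    paste(format(x$voxel, digits = 4), collapse = ", "),
    paste(format(x$origin, digits = 4), collapse = ", "),
    min(x$values), max(x$values), mean(x$values)
  ))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

#' Grid dimensions in physical-axis order
#'
#' @param grid a [voxel_grid()].
#' @return Integer length-3, number of voxels along (x, y, z); the reverse of
#'   `dim(grid$values)`.
#' @export
grid_dims_xyz <- function(grid) rev(dim(grid$values))

#' Physical extent of a grid
#'
#' The grid covers the half-open box `[origin, origin + n * voxel)` per axis.
#'
#' @inheritParams grid_dims_xyz
#' @return A 2 x 3 matrix, rows `min`/`max`, columns x/y/z, in Angstrom.
#' @export
grid_extent <- function(grid) {
  n <- grid_dims_xyz(grid)
  rbind(min = grid$origin, max = grid$origin + n * grid$voxel)
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

stopifnot_grid <- function(grid) {
  if (!is_voxel_grid(grid)) stop("expected a `voxel_grid`", call. = FALSE)
  invisible(grid)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$voxel - b$voxel) < tol)
}

as_xyz_matrix <- function(points) {
  if (is.data.frame(points)) {
    points <- as.matrix(points[, c("x", "y", "z")])
  } else if (is.null(dim(points))) {
    points <- matrix(as.numeric(points), ncol = 3L)
  }
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must have columns x, y, z", call. = FALSE)
  points
}

as_ijk_matrix <- function(idx) {
  if (is.data.frame(idx)) {
    idx <- as.matrix(idx[, c("i", "j", "k")])
  } else if (is.null(dim(idx))) {
    idx <- matrix(idx, ncol = 3L)
  }
  if (ncol(idx) != 3L) stop("indices must have columns i, j, k", call. = FALSE)
  idx
}

#' Map physical coordinates to grid indices
#'
#' Converts atomic coordinates (x, y, z) in Angstrom to 0-based grid indices
#' (i, j, k) by per-axis floor division: `i = floor((z - origin_z) / voxel_z)`,
#' `j = floor((y - origin_y) / voxel_y)`, `k = floor((x - origin_x) / voxel_x)`.
#' The axis pairing is i<->z, j<->y, k<->x. Points falling outside the grid are
#' not an error: they are flagged by `in_bounds = FALSE`.
#'
#' @param points coordinates: a data frame with columns `x`, `y`, `z`, an
#'   n x 3 matrix, or a length-3 vector (one point). Angstrom.
#' @param grid a [voxel_grid()].
#' @return A tibble with integer columns `i`, `j`, `k` (0-based) and logical
#'   `in_bounds`.
#' @examples
#' g <- voxel_grid(array(0, c(10, 10, 10)), origin = c(4, 0, 4), voxel = c(1.2, 1, 1.2))
#' coords_to_indices(c(x = 5, y = 2, z = 10.7), g) # i = floor(6.7 / 1.2) = 5
#' @export
coords_to_indices <- function(points, grid) {
  stopifnot_grid(grid)
  pts <- as_xyz_matrix(points)
  if (any(!is.finite(pts))) stop("coordinates must be finite", call. = FALSE)
  i <- as.integer(floor((pts[, 3] - grid$origin[["z"]]) / grid$voxel[["z"]]))
  j <- as.integer(floor((pts[, 2] - grid$origin[["y"]]) / grid$voxel[["y"]]))
  k <- as.integer(floor((pts[, 1] - grid$origin[["x"]]) / grid$voxel[["x"]]))
  tibble::tibble(i = i, j = j, k = k,
                 in_bounds = in_bounds(cbind(i, j, k), grid))
}

#' Map grid indices to physical coordinates (voxel centers)
#'
#' Inverse of [coords_to_indices()] under the voxel-center convention: index
#' (i, j, k) maps to `origin + (index + 0.5) * voxel` on the paired physical
#' axis (i->z, j->y, k->x). With the floor-based forward transform this makes
#' the round trip exact for every in-bounds index.
#'
#' @param idx indices: a data frame with columns `i`, `j`, `k`, an n x 3
#'   matrix, or a length-3 vector. 0-based.
#' @inheritParams coords_to_indices
#' @return A tibble with columns `x`, `y`, `z` (Angstrom, voxel centers).
#' @export
indices_to_coords <- function(idx, grid) {
  stopifnot_grid(grid)
  m <- as_ijk_matrix(idx)
  if (!all(in_bounds(m, grid))) {
    stop("index out of grid bounds", call. = FALSE)
  }
  tibble::tibble(
    x = grid$origin[["x"]] + (m[, 3] + 0.5) * grid$voxel[["x"]],
    y = grid$origin[["y"]] + (m[, 2] + 0.5) * grid$voxel[["y"]],
    z = grid$origin[["z"]] + (m[, 1] + 0.5) * grid$voxel[["z"]]
  )
}

#' Test whether indices lie inside a grid
#'
#' Half-open bounds: component c is valid iff `0 <= c < dim`.
#'
#' @inheritParams indices_to_coords
#' @return Logical vector, one element per index triple.
#' @export
in_bounds <- function(idx, grid) {
  stopifnot_grid(grid)
  m <- as_ijk_matrix(idx)
  d <- dim(grid$values)
  m[, 1] >= 0 & m[, 1] < d[1] &
    m[, 2] >= 0 & m[, 2] < d[2] &
    m[, 3] >= 0 & m[, 3] < d[3]
}

# Trilinear interpolation of grid values at physical points; points outside
# the grid's physical extent return `outside`. Sample positions between the
# boundary voxel center and the extent edge are clamped to the edge value.
trilinear_sample <- function(grid, points, outside = 0) {
  pts <- as_xyz_matrix(points)
  d <- dim(grid$values)
  ext <- grid_extent(grid)
  inside <- pts[, 1] >= ext["min", "x"] & pts[, 1] <= ext["max", "x"] &
    pts[, 2] >= ext["min", "y"] & pts[, 2] <= ext["max", "y"] &
    pts[, 3] >= ext["min", "z"] & pts[, 3] <= ext["max", "z"]

  # continuous 0-based index of each point relative to voxel centers,
  # in array-axis order (i=z, j=y, k=x)
  t_i <- (pts[, 3] - grid$origin[["z"]]) / grid$voxel[["z"]] - 0.5
  t_j <- (pts[, 2] - grid$origin[["y"]]) / grid$voxel[["y"]] - 0.5
  t_k <- (pts[, 1] - grid$origin[["x"]]) / grid$voxel[["x"]] - 0.5

  interp_axis <- function(t, n) {
    lo <- floor(t)
    fr <- t - lo
    lo_c <- pmin(pmax(lo, 0), n - 1)
    hi_c <- pmin(pmax(lo + 1, 0), n - 1)
    list(lo = lo_c, hi = hi_c, fr = fr)
  }
  ai <- interp_axis(t_i, d[1])
  aj <- interp_axis(t_j, d[2])
  ak <- interp_axis(t_k, d[3])

  v <- numeric(nrow(pts))
  for (ci in 0:1) {
    for (cj in 0:1) {
      for (ck in 0:1) {
        ii <- if (ci == 0) ai$lo else ai$hi
        jj <- if (cj == 0) aj$lo else aj$hi
        kk <- if (ck == 0) ak$lo else ak$hi
        w <- (if (ci == 0) 1 - ai$fr else ai$fr) *
          (if (cj == 0) 1 - aj$fr else aj$fr) *
          (if (ck == 0) 1 - ak$fr else ak$fr)
        v <- v + w * grid$values[cbind(ii + 1L, jj + 1L, kk + 1L)]
      }
    }
  }
  v[!inside] <- outside
  v
}

#' Resample a map to a standard voxel size
#'
#' Standardizes a density map to a common (isotropic) voxel size by trilinear
#' interpolation, the preprocessing applied to every experimental map before
#' label generation. The output grid keeps the input origin; its dimensions
#' per axis are `ceiling(extent / target)` so the whole input extent is
#' covered. Values are interpolated at output voxel centers; sample points
#' outside the input extent are set to 0 (solvent level).
#'
#' @inheritParams grid_dims_xyz
#' @param target target voxel edge length in Angstrom (scalar, isotropic).
#'   Default 1.0, the standardization used for the dataset.
#' @return A [voxel_grid()] with voxel `(target, target, target)`.
#' @export
resample_to_voxel_size <- function(grid, target = 1.0) {
  stopifnot_grid(grid)
  if (!is.numeric(target) || length(target) != 1L || !is.finite(target) ||
      target <= 0) {
    stop("`target` voxel size must be a positive number", call. = FALSE)
  }
  n_in <- grid_dims_xyz(grid)
  extent <- n_in * grid$voxel
  n_out <- pmax(1L, as.integer(ceiling(extent / target - 1e-9)))
  # output voxel centers along each physical axis
  cx <- grid$origin[["x"]] + (seq_len(n_out[1]) - 0.5) * target
  cy <- grid$origin[["y"]] + (seq_len(n_out[2]) - 0.5) * target
  cz <- grid$origin[["z"]] + (seq_len(n_out[3]) - 0.5) * target
  # array order (i=z, j=y, k=x): i varies fastest in the expansion
  pts <- cbind(
    x = rep(cx, each = n_out[3] * n_out[2]),
    y = rep(rep(cy, each = n_out[3]), times = n_out[1]),
    z = rep(cz, times = n_out[1] * n_out[2])
  )
  vals <- trilinear_sample(grid, pts, outside = 0)
  voxel_grid(array(vals, dim = c(n_out[3], n_out[2], n_out[1])),
             origin = grid$origin, voxel = rep(target, 3))
}
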