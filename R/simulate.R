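#' Gaussian simulation kernel
#'
#' Parameters of the real-space convolution kernel used to turn atomic
#' coordinates into an idealized, noise-free density map (the pdb2vol-style
#' approach). Each atom contributes an isotropic Gaussian whose full width at
#' half maximum equals the nominal `resolution`, i.e.
#' `sigma = resolution / (2 * sqrt(2 * log(2)))`. The kernel is truncated at
#' `cutoff * sigma` and renormalized so the truncated kernel has exactly unit
#' integral (the radial mass factor `pchisq(cutoff^2, 3)` is divided out).
#'
#' @param resolution nominal map resolution in Angstrom (> 0). Default 2.0,
#'   the fixture-scale default; for real entries pass the reported resolution.
#' @param cutoff truncation radius in units of sigma (>= 2). Default 4.
#' @param amplitude_mode `"uniform"` (every atom weight 1, default) or
#'   `"element"` (weight = atomic number, a crude element weighting).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(resolution = 2.0, cutoff = 4,
                        amplitude_mode = c("uniform", "element")) {
  amplitude_mode <- match.arg(amplitude_mode)
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      !is.finite(resolution) || resolution <= 0) {
    stop("`resolution` must be a positive number (Angstrom)", call. = FALSE)
  }
  if (!is.numeric(cutoff) || cutoff < 2) {
    stop("`cutoff` must be >= 2 (units of sigma)", call. = FALSE)
  }
  sigma <- resolution / (2 * sqrt(2 * log(2)))
  structure(
    list(resolution = resolution, sigma = sigma, cutoff = cutoff,
         amplitude_mode = amplitude_mode),
    class = "kernel_spec"
  )
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf(
    "<kernel_spec> resolution %.3g A (sigma %.4g A, FWHM = resolution), cutoff %g sigma, %s weights\n",
    x$resolution, x$sigma, x$cutoff, x$amplitude_mode))
  invisible(x)
}

.element_weights <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

atom_weights <- function(structure, kernel) {
  if (kernel$amplitude_mode == "uniform") return(rep(1, nrow(structure)))
  w <- .element_weights[toupper(structure$element)]
  w[is.na(w)] <- 6 # unknown elements weighted as carbon
  unname(w)
}

#' Empty grid bounding a structure
#'
#' Builds the auto grid on which a simulated map is generated when no
#' experimental grid is supplied: per axis, the origin is the minimum atom
#' coordinate minus `pad`, snapped down to an integer multiple of `voxel`,
#' and the dimensions cover the maximum coordinate plus `pad`.
#'
#' @param structure an atom tibble ([read_assembly()] schema).
#' @param voxel voxel edge length in Angstrom (default 1, the standardized
#'   size).
#' @param pad padding in Angstrom around the structure (default 5).
#' @return An all-zero [voxel_grid()] containing every atom.
#' @export
bounding_grid <- function(structure, voxel = 1.0, pad = 5.0) {
  if (!is.data.frame(structure) || nrow(structure) == 0L) {
    stop("`structure` must be a non-empty atom table", call. = FALSE)
  }
  lo <- c(min(structure$x), min(structure$y), min(structure$z)) - pad
  hi <- c(max(structure$x), max(structure$y), max(structure$z)) + pad
  origin <- floor(lo / voxel) * voxel
  n_xyz <- as.integer(ceiling((hi - origin) / voxel))
  voxel_grid(array(0, dim = rev(n_xyz)), origin = origin, voxel = voxel)
}

#' Simulate an idealized density map from atomic coordinates
#'
#' Real-space convolution of the atomic model with a truncated Gaussian
#' kernel: the value at a voxel is the sum over atoms of
#' `w_a * G(|center(v) - r_a|; sigma)` where `G` is the unit-integral
#' truncated Gaussian of [kernel_spec()]. This produces the noise-free
#' reference density that label maps copy from. Deterministic.
#'
#' @param structure an atom tibble.
#' @param target a [voxel_grid()] defining the output geometry (its values
#'   are ignored), or `NULL` to use [bounding_grid()].
#' @param kernel a [kernel_spec()].
#' @param voxel,pad passed to [bounding_grid()] when `target` is `NULL`.
#' @return A [voxel_grid()] with the simulated density.
#' @export
simulate_map <- function(structure, target = NULL, kernel = kernel_spec(),
                         voxel = 1.0, pad = 5.0) {
  if (!is.data.frame(structure) || nrow(structure) == 0L) {
    stop("`structure` must be a non-empty atom table", call. = FALSE)
  }
  if (is.null(target)) target <- bounding_grid(structure, voxel, pad)
  stopifnot_grid(target)
  sigma <- kernel$sigma
  if (sigma < max(target$voxel) / 2) {
    warning("kernel sigma (", signif(sigma, 3),
            " A) is under half the voxel size: kernel is undersampled",
            call. = FALSE)
  }
  r_cut <- kernel$cutoff * sigma
  # unit-integral truncated Gaussian: renormalize by the enclosed radial mass
  amp <- (2 * pi * sigma^2)^(-1.5) / stats::pchisq(kernel$cutoff^2, df = 3)
  w <- atom_weights(structure, kernel)

  d <- dim(target$values)
  vals <- array(0, dim = d)
  vx <- target$voxel
  org <- target$origin
  for (a in seq_len(nrow(structure))) {
    # continuous 0-based center index per array axis (i=z, j=y, k=x)
    ti <- (structure$z[a] - org[["z"]]) / vx[["z"]] - 0.5
    tj <- (structure$y[a] - org[["y"]]) / vx[["y"]] - 0.5
    tk <- (structure$x[a] - org[["x"]]) / vx[["x"]] - 0.5
    ri <- max(0L, ceiling(ti - r_cut / vx[["z"]])):min(d[1] - 1L, floor(ti + r_cut / vx[["z"]]))
    rj <- max(0L, ceiling(tj - r_cut / vx[["y"]])):min(d[2] - 1L, floor(tj + r_cut / vx[["y"]]))
    rk <- max(0L, ceiling(tk - r_cut / vx[["x"]])):min(d[3] - 1L, floor(tk + r_cut / vx[["x"]]))
    if (ri[1] > ri[length(ri)] || rj[1] > rj[length(rj)] || rk[1] > rk[length(rk)]) next
    d2i <- ((ri - ti) * vx[["z"]])^2
    d2j <- ((rj - tj) * vx[["y"]])^2
    d2k <- ((rk - tk) * vx[["x"]])^2
    d2 <- outer(outer(d2i, d2j, "+"), d2k, "+")
    g <- w[a] * amp * exp(-d2 / (2 * sigma^2))
    g[d2 > r_cut^2] <- 0
    vals[ri + 1L, rj + 1L, rk + 1L] <-
      vals[ri + 1L, rj + 1L, rk + 1L] + g
  }
  voxel_grid(vals, origin = org, voxel = vx)
}

#' Sample a map at physical points
#'
#' Looks up density values at arbitrary coordinates, either by nearest voxel
#' (the floor-index voxel of [coords_to_indices()]) or by trilinear
#' interpolation. Points outside the map extent return 0. This is the
#' cross-grid lookup used when a simulated map does not share the
#' experimental grid.
#'
#' @param map a [voxel_grid()].
#' @param points coordinates (data frame with `x`,`y`,`z`, matrix, or
#'   length-3 vector).
#' @param mode `"nearest"` or `"trilinear"`.
#' @return Numeric vector of density values.
#' @export
sample_at <- function(map, points, mode = c("nearest", "trilinear")) {
  mode <- match.arg(mode)
  stopifnot_grid(map)
  pts <- as_xyz_matrix(points)
  if (mode == "trilinear") return(trilinear_sample(map, pts, outside = 0))
  idx <- coords_to_indices(pts, map)
  v <- numeric(nrow(pts))
  ok <- idx$in_bounds
  v[ok] <- map$values[cbind(idx$i[ok] + 1L, idx$j[ok] + 1L, idx$k[ok] + 1L)]
  v
}
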