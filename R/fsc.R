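#' Fourier Shell Correlation curves
#'
#' Constructs an `fsc_curve` from per-shell frequencies and correlations --
#' mostly useful for building synthetic curves in analyses and tests;
#' [compute_fsc()] builds curves from maps.
#'
#' @param freq spatial frequencies at shell centers, 1/Angstrom, ascending.
#' @param fsc per-shell correlations in \[-1, 1\].
#' @param n_voxels optional per-shell Fourier voxel counts.
#' @param nyquist optional Nyquist frequency (1/(2 voxel)) of the source
#'   grids; used by [resolution_at()] when a curve never drops below the
#'   threshold.
#' @return A tibble of class `fsc_curve` with columns `freq`, `fsc`,
#'   `n_voxels`.
#' @export
fsc_curve <- function(freq, fsc, n_voxels = NA_integer_, nyquist = NULL) {
  stopifnot(length(freq) == length(fsc), !is.unsorted(freq))
  out <- tibble::tibble(freq = as.numeric(freq), fsc = as.numeric(fsc),
                        n_voxels = n_voxels)
  class(out) <- c("fsc_curve", class(out))
  attr(out, "nyquist") <- nyquist %||% max(freq)
  out
}

#' Compute the Fourier Shell Correlation between two maps
#'
#' Correlates the discrete Fourier transforms of two aligned maps in shells
#' of constant spatial frequency:
#' `FSC(s) = Re(sum(F_a * Conj(F_b))) / sqrt(sum|F_a|^2 * sum|F_b|^2)` over
#' the Fourier voxels whose radial frequency falls in shell `s`. No mask is
#' applied. The DC term is excluded from the first shell; shells beyond the
#' Nyquist frequency (box corners) are discarded. Requires isotropic voxels
#' (the dataset standardizes to 1 Angstrom isotropic).
#'
#' @param map_a,map_b [voxel_grid()]s with identical dims, voxel and origin.
#' @param shell_width shell width in 1/Angstrom; default one Fourier voxel,
#'   `1 / (max(dim) * voxel)`.
#' @return An [fsc_curve()].
#' @export
compute_fsc <- function(map_a, map_b, shell_width = NULL) {
  stopifnot_grid(map_a); stopifnot_grid(map_b)
  if (!same_geometry(map_a, map_b)) {
    stop("maps must share dims, voxel size and origin", call. = FALSE)
  }
  vx <- map_a$voxel
  if (max(vx) - min(vx) > 1e-6 * max(vx)) {
    stop("anisotropic voxels are not supported for FSC", call. = FALSE)
  }
  voxel <- vx[[1]]
  d <- dim(map_a$values)
  nyq <- 1 / (2 * voxel)
  if (is.null(shell_width)) shell_width <- 1 / (max(d) * voxel)

  fa <- stats::fft(map_a$values)
  fb <- stats::fft(map_b$values)

  fftfreq <- function(n) {
    f <- 0:(n - 1)
    f[f > n / 2] <- f[f > n / 2] - n
    f / (n * voxel)
  }
  # radial frequency per Fourier voxel; array axes are (z, y, x)
  fz2 <- fftfreq(d[1])^2
  fy2 <- fftfreq(d[2])^2
  fx2 <- fftfreq(d[3])^2
  r <- sqrt(outer(outer(fz2, fy2, "+"), fx2, "+"))

  shell <- ceiling(r / shell_width - 1e-12)
  shell[1, 1, 1] <- 0L # DC excluded
  keep <- shell >= 1 & (shell - 0.5) * shell_width <= nyq + 1e-12
  s <- as.integer(shell[keep])
  cross <- Re(fa[keep] * Conj(fb[keep]))
  pa <- Mod(fa[keep])^2
  pb <- Mod(fb[keep])^2

  num <- rowsum(cross, s)
  den <- sqrt(rowsum(pa, s) * rowsum(pb, s))
  counts <- as.integer(table(s))
  sh <- sort(unique(s))
  corr <- as.numeric(num / pmax(den, .Machine$double.xmin))
  fsc_curve(freq = (sh - 0.5) * shell_width, fsc = corr,
            n_voxels = counts, nyquist = nyq)
}

#' Resolution at an FSC threshold
#'
#' Finds the first shell pair where the correlation crosses from at or above
#' the threshold to below it, linearly interpolates the crossing frequency,
#' and reports `1 / frequency` in Angstrom. A curve that never drops below
#' the threshold is resolved to the Nyquist limit (`2 * voxel` when the
#' curve came from maps, `1 / max(freq)` for bare curves); a curve below the
#' threshold from the first shell returns `Inf`.
#'
#' @param curve an [fsc_curve()].
#' @param threshold FSC threshold, conventionally 0.5 (map-model, stringent)
#'   or 0.143.
#' @return Resolution in Angstrom (possibly `Inf`).
#' @examples
#' resolution_at(fsc_curve(c(0.20, 0.25), c(0.8, 0.2)), 0.5) # 1/0.225
#' @export
resolution_at <- function(curve, threshold = 0.5) {
  stopifnot(nrow(curve) > 0)
  f <- curve$freq
  v <- curve$fsc
  if (v[1] < threshold) return(Inf)
  below <- which(v < threshold)
  cross <- below[below > 1][1]
  if (is.na(cross)) {
    return(1 / (attr(curve, "nyquist") %||% max(f)))
  }
  i0 <- cross - 1L
  fr <- f[i0] + (v[i0] - threshold) / (v[i0] - v[cross]) * (f[cross] - f[i0])
  1 / fr
}

#' Unmasked map-model FSC
#'
#' Validates a density map against its atomic model: a model map is
#' simulated on the experimental grid with the given kernel, both maps are
#' intensity-normalized (zero mean, unit variance; normalization cancels in
#' FSC but guards the numerics), and the unmasked FSC curve plus the
#' threshold resolution are returned. Low resolution values indicate maps
#' whose fine atomic detail agrees with the model.
#'
#' @param map the experimental (or label) [voxel_grid()].
#' @param structure an atom tibble.
#' @param kernel a [kernel_spec()]; for real entries use the reported
#'   resolution.
#' @param threshold FSC threshold (default 0.5).
#' @param shell_width passed to [compute_fsc()].
#' @return A list of class `map_model_fsc`: `curve` ([fsc_curve()]),
#'   `resolution` (Angstrom), `threshold`.
#' @export
map_model_fsc <- function(map, structure, kernel = kernel_spec(),
                          threshold = 0.5, shell_width = NULL) {
  stopifnot_grid(map)
  ext <- grid_extent(map)
  inside <- structure$x >= ext["min", "x"] & structure$x <= ext["max", "x"] &
    structure$y >= ext["min", "y"] & structure$y <= ext["max", "y"] &
    structure$z >= ext["min", "z"] & structure$z <= ext["max", "z"]
  if (!any(inside)) {
    stop("structure does not overlap the map extent", call. = FALSE)
  }
  model_map <- simulate_map(structure, target = map, kernel = kernel)
  normalize <- function(g) {
    v <- g$values
    s <- stats::sd(as.vector(v))
    if (s == 0) stop("map has zero variance", call. = FALSE)
    voxel_grid((v - mean(v)) / s, g$origin, g$voxel)
  }
  curve <- compute_fsc(normalize(map), normalize(model_map),
                       shell_width = shell_width)
  out <- list(curve = curve, resolution = resolution_at(curve, threshold),
              threshold = threshold, kernel = kernel)
  class(out) <- "map_model_fsc"
  out
}

#' @export
print.map_model_fsc <- function(x, ...) {
  cat(sprintf(
    "<map_model_fsc> unmasked, %d shells; FSC-%g resolution: %.3f A\n",
    nrow(x$curve), x$threshold, x$resolution))
  invisible(x)
}

#' @rdname map_model_fsc
#' @param x a `map_model_fsc` object.
#' @param ... unused.
#' @export
tidy.map_model_fsc <- function(x, ...) tibble::as_tibble(x$curve)

#' @rdname map_model_fsc
#' @export
glance.map_model_fsc <- function(x, ...) {
  tibble::tibble(
    resolution = x$resolution, threshold = x$threshold,
    n_shells = nrow(x$curve), nyquist = attr(x$curve, "nyquist"),
    kernel_resolution = x$kernel$resolution
  )
}

#' @export
tidy.fsc_curve <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "fsc_curve")
  out
}

#' Plot an FSC curve
#'
#' @param object an [fsc_curve()].
#' @param thresholds FSC thresholds drawn as horizontal reference lines.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fsc_curve <- function(object, thresholds = c(0.5, 0.143), ...) {
  df <- tidy.fsc_curve(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$fsc)) +
    ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "spatial frequency (1/Å)",
                  y = "Fourier shell correlation") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.map_model_fsc <- function(object, ...) {
  autoplot.fsc_curve(object$curve, thresholds = object$threshold, ...) +
    ggplot2::geom_vline(xintercept = 1 / object$resolution,
                        linetype = "dotted", colour = "firebrick")
}

#' Relative improvement between two mean resolutions
#'
#' The dataset-level summary statistic: the percent reduction of a mean
#' FSC resolution after labeling, `100 * (before - after) / before`.
#'
#' @param mean_before,mean_after mean resolutions in Angstrom;
#'   `mean_before` must be positive.
#' @return Percent improvement (positive when `after` is better, i.e.
#'   smaller).
#' @examples
#' improvement_percent(4.01, 3.33) # ~17.0
#' @export
improvement_percent <- function(mean_before, mean_after) {
  if (!is.numeric(mean_before) || any(mean_before <= 0)) {
    stop("`mean_before` must be positive", call. = FALSE)
  }
  100 * (mean_before - mean_after) / mean_before
}

#' Aggregate FSC resolutions over a manifest
#'
#' Computes the dataset-level means and improvement statistic from a
#' manifest table with one row per entry and before/after resolution
#' columns.
#'
#' @param manifest data frame with numeric columns `resolution_before` and
#'   `resolution_after` (Angstrom).
#' @return A one-row tibble: `n`, `mean_before`, `mean_after`,
#'   `improvement_percent`.
#' @export
summarize_manifest <- function(manifest) {
  stopifnot(all(c("resolution_before", "resolution_after") %in%
                  names(manifest)))
  b <- mean(manifest$resolution_before)
  a <- mean(manifest$resolution_after)
  tibble::tibble(
    n = nrow(manifest), mean_before = b, mean_after = a,
    improvement_percent = improvement_percent(b, a)
  )
}
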