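#' Ideal poly-alanine helix fixture
#'
#' Builds a deterministic synthetic structure for desk-scale testing: an
#' ideal alpha-helix with per-residue rise 1.5 Angstrom, twist 100 degrees
#' and C-alpha radius 2.3 Angstrom from the helix axis (textbook values,
#' giving the canonical ~3.8 Angstrom consecutive C-alpha distance). Each
#' residue carries N, CA, C, O and CB at fixed ideal offsets from its
#' C-alpha, expressed in the local radial/tangential/axial frame so the
#' geometry is helix-symmetric. The helix axis runs along z through
#' (x, y) = (0, 0).
#'
#' @param n_res number of residues (>= 1).
#' @param chain_id chain identifier (default "A").
#' @return An atom tibble in the [read_assembly()] schema
#'   (5 atoms per residue).
#' @export
make_helix <- function(n_res, chain_id = "A") {
  if (!is.numeric(n_res) || length(n_res) != 1L || n_res < 1) {
    stop("`n_res` must be a positive count", call. = FALSE)
  }
  n_res <- as.integer(n_res)
  rise <- 1.5; twist <- 100 * pi / 180; radius <- 2.3

  # offsets from CA in the local frame (radial, tangential, axial), Angstrom
  offsets <- rbind(
    N  = c(-0.521, -1.240, -0.600),
    CA = c(0, 0, 0),
    C  = c(0.550, 1.250, 0.550),
    O  = c(1.450, 1.650, -0.200),
    CB = c(1.200, -0.600, 0.750)
  )
  elements <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")

  rows <- lapply(seq_len(n_res) - 1L, function(r) {
    th <- r * twist
    e_r <- c(cos(th), sin(th), 0)
    e_t <- c(-sin(th), cos(th), 0)
    e_z <- c(0, 0, 1)
    ca <- radius * e_r + c(0, 0, r * rise)
    xyz <- t(apply(offsets, 1, function(o) {
      ca + o[1] * e_r + o[2] * e_t + o[3] * e_z
    }))
    data.frame(
      model = 1L, serial = NA_integer_, name = rownames(offsets),
      alt_loc = "", res_name = "ALA", chain = chain_id,
      res_seq = r + 1L, i_code = "",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = 1, b_factor = 0, element = unname(elements),
      is_hetero = FALSE, stringsAsFactors = FALSE
    )
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out$serial <- seq_len(nrow(out))
  attr(out, "source_id") <- "helix"
  out
}

#' Noise model for synthetic experimental maps
#'
#' Parameters of the noise layered onto a clean simulated map to emulate an
#' experimental reconstruction. White Gaussian noise stands in for the
#' random background (shot/digital) noise stages; randomly placed Gaussian
#' blobs stand in for structural noise -- spurious density with defined
#' shape.
#'
#' @param gaussian_sigma standard deviation of the white noise, in density
#'   units (>= 0).
#' @param blob_count number of structural-noise blobs (>= 0).
#' @param blob_sigma blob width in Angstrom.
#' @param blob_amplitude blob peak height in density units.
#' @param seed integer RNG seed; every draw is reproducible per seed.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(gaussian_sigma = 0.05, blob_count = 3L,
                       blob_sigma = 2.0, blob_amplitude = 0.1, seed = 1L) {
  stopifnot(gaussian_sigma >= 0, blob_count >= 0, blob_sigma > 0)
  out <- list(gaussian_sigma = gaussian_sigma,
              blob_count = as.integer(blob_count),
              blob_sigma = blob_sigma, blob_amplitude = blob_amplitude,
              seed = as.integer(seed))
  class(out) <- "noise_spec"
  out
}

#' Corrupt a clean map with synthetic noise
#'
#' Adds seeded white Gaussian noise plus `blob_count` randomly placed
#' Gaussian blobs to a clean map, preserving the grid geometry. Blob
#' centers are drawn uniformly over the map extent; when `avoid_box` is
#' given (a 2 x 3 min/max matrix, e.g. the structure's bounding box), up to
#' 20 redraws per blob try to place it outside that box, mimicking
#' off-particle structural noise.
#'
#' @param clean a [voxel_grid()].
#' @param noise a [noise_spec()].
#' @param avoid_box optional 2 x 3 matrix (rows min/max, columns x/y/z).
#' @return A [voxel_grid()] with the same geometry.
#' @export
make_noisy_map <- function(clean, noise = noise_spec(), avoid_box = NULL) {
  stopifnot_grid(clean)
  withr::with_seed(noise$seed, {
    v <- clean$values
    if (noise$blob_count > 0) {
      ext <- grid_extent(clean)
      blob_kernel <- kernel_spec(
        resolution = noise$blob_sigma * 2 * sqrt(2 * log(2)),
        cutoff = 4)
      centers <- matrix(NA_real_, noise$blob_count, 3)
      for (b in seq_len(noise$blob_count)) {
        for (try in 1:20) {
          p <- stats::runif(3, ext["min", ], ext["max", ])
          outside <- is.null(avoid_box) ||
            any(p < avoid_box[1, ] | p > avoid_box[2, ])
          if (outside) break
        }
        centers[b, ] <- p
      }
      blob_structure <- tibble::tibble(
        name = "X", element = "C", res_name = "UNK", is_hetero = TRUE,
        x = centers[, 1], y = centers[, 2], z = centers[, 3]
      )
      blob_map <- simulate_map(blob_structure, target = clean,
                               kernel = blob_kernel)
      # rescale unit-mass blobs to the requested peak amplitude
      peak <- (2 * pi * blob_kernel$sigma^2)^(-1.5)
      v <- v + blob_map$values * (noise$blob_amplitude / peak)
    }
    if (noise$gaussian_sigma > 0) {
      v <- v + stats::rnorm(length(v), sd = noise$gaussian_sigma)
    }
    voxel_grid(v, clean$origin, clean$voxel)
  })
}

#' Write a complete desk-scale fixture bundle
#'
#' Generates everything one pipeline run needs, with no downloads: an ideal
#' helix assembly (`toy.pdb`), its clean simulated map at a 2 Angstrom
#' kernel on a 1 Angstrom bounding grid with 5 Angstrom padding
#' (`toy_situs_simulated.mrc`), a noise-corrupted "experimental" version
#' (`toy_experimental.mrc`), and a one-row metadata CSV
#' (`toy_metadata.csv`) consumable by [curate_records()].
#'
#' @param out_dir output directory (created if needed).
#' @param n_res helix length in residues (default 20).
#' @param seed integer seed driving the noise draws.
#' @param noise a [noise_spec()]; its seed is overridden by `seed`.
#' @param resolution simulation kernel resolution in Angstrom (default 2).
#' @return Named character vector of the four file paths, invisibly.
#' @export
make_fixture_bundle <- function(out_dir, n_res = 20L, seed = 1L,
                                noise = noise_spec(), resolution = 2.0) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  helix <- make_helix(n_res)
  clean <- simulate_map(helix, kernel = kernel_spec(resolution))
  noise$seed <- as.integer(seed)
  bbox <- rbind(min = c(min(helix$x), min(helix$y), min(helix$z)),
                max = c(max(helix$x), max(helix$y), max(helix$z)))
  noisy <- make_noisy_map(clean, noise, avoid_box = bbox)

  paths <- c(
    pdb = file.path(out_dir, "toy.pdb"),
    simulated = file.path(out_dir, "toy_situs_simulated.mrc"),
    experimental = file.path(out_dir, "toy_experimental.mrc"),
    metadata = file.path(out_dir, "toy_metadata.csv")
  )
  write_pdb(helix, paths[["pdb"]])
  write_mrc(clean, paths[["simulated"]])
  write_mrc(noisy, paths[["experimental"]])
  utils::write.csv(
    data.frame(emdb_id = "EMD-TOY1", pdb_id = "toy",
               resolution = resolution, has_assembly = TRUE,
               resolution_method = "FSC 0.143"),
    paths[["metadata"]], row.names = FALSE)
  invisible(paths)
}
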