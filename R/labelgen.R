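#' Voxels neighboring an atomic coordinate
#'
#' Enumerates the in-bounds 0-based grid indices whose voxel **center** lies
#' within `radius` of the given point, excluding the point's own floor index
#' (the "direct" voxel). These are the voxels that receive neighbor labels:
#' the float-to-integer index conversion loses sub-voxel accuracy, and
#' labeling the surrounding sphere compensates for it while adding local
#' structural context.
#'
#' @param atom_point length-3 coordinate (x, y, z) in Angstrom, or a 1-row
#'   data frame / matrix.
#' @param grid a [voxel_grid()].
#' @param radius neighborhood radius in Angstrom (default 6, chosen from the
#'   electron-density falloff in high-resolution maps; configurable).
#' @return A tibble of 0-based indices `i`, `j`, `k`.
#' @export
neighbor_indices <- function(atom_point, grid, radius = 6.0) {
  stopifnot_grid(grid)
  if (!is.numeric(radius) || radius <= 0) {
    stop("`radius` must be positive", call. = FALSE)
  }
  p <- as_xyz_matrix(atom_point)
  if (nrow(p) != 1L) stop("one point at a time", call. = FALSE)
  d <- dim(grid$values)
  vx <- grid$voxel
  org <- grid$origin
  ti <- (p[, 3] - org[["z"]]) / vx[["z"]] - 0.5
  tj <- (p[, 2] - org[["y"]]) / vx[["y"]] - 0.5
  tk <- (p[, 1] - org[["x"]]) / vx[["x"]] - 0.5
  lo <- c(max(0, ceiling(ti - radius / vx[["z"]])),
          max(0, ceiling(tj - radius / vx[["y"]])),
          max(0, ceiling(tk - radius / vx[["x"]])))
  hi <- c(min(d[1] - 1, floor(ti + radius / vx[["z"]])),
          min(d[2] - 1, floor(tj + radius / vx[["y"]])),
          min(d[3] - 1, floor(tk + radius / vx[["x"]])))
  if (any(hi < lo)) {
    return(tibble::tibble(i = integer(), j = integer(), k = integer()))
  }
  ri <- lo[1]:hi[1]; rj <- lo[2]:hi[2]; rk <- lo[3]:hi[3]
  d2 <- outer(outer(((ri - ti) * vx[["z"]])^2,
                    ((rj - tj) * vx[["y"]])^2, "+"),
              ((rk - tk) * vx[["x"]])^2, "+")
  sel <- which(d2 <= radius^2, arr.ind = TRUE)
  i <- as.integer(ri[sel[, 1]]); j <- as.integer(rj[sel[, 2]])
  k <- as.integer(rk[sel[, 3]])
  own <- coords_to_indices(p, grid)
  drop <- i == own$i & j == own$j & k == own$k
  tibble::tibble(i = i[!drop], j = j[!drop], k = k[!drop])
}

#' Generate the three voxel-aligned label maps
#'
#' The core labeling procedure. Three zero-initialized grids matching the
#' experimental grid are filled atom by atom:
#'
#' * each atom's coordinate is converted to a grid index by
#'   [coords_to_indices()] against the experimental grid;
#' * the atom contributes labels only when that index is in-bounds **and**
#'   the atomic position falls inside the simulated map's physical extent
#'   (dual validation, so labels mark regions present in both maps);
#' * **classification**: the direct voxel gets 1, every neighbor voxel
#'   (within `radius`, see [neighbor_indices()]) gets 2 unless already 1 --
#'   the direct label has precedence;
#' * **atom_type**: the direct voxel gets the [classify_atoms()] code;
#'   neighbors are left untouched, since their chemical identity is
#'   ambiguous. When atoms collide on a voxel the last writer wins, except
#'   that class 0 never overwrites a nonzero class;
#' * **regression**: every labeled voxel (direct or neighbor) receives the
#'   simulated density at that voxel -- copied by index when the grids are
#'   aligned, else trilinear-sampled at the voxel center. Background stays 0.
#'
#' @param structure an atom tibble ([read_assembly()] schema).
#' @param experimental the (resampled) experimental [voxel_grid()]; defines
#'   the geometry of all outputs.
#' @param simulated the simulated density [voxel_grid()] (any geometry).
#' @param radius neighborhood radius in Angstrom, default 6.
#' @return A `label_map_set`: list with `regression`, `classification`,
#'   `atom_type` (all [voxel_grid()]s aligned to `experimental`) and
#'   `radius`.
#' @export
generate_labels <- function(structure, experimental, simulated,
                            radius = 6.0) {
  if (!is.data.frame(structure) || nrow(structure) == 0L) {
    stop("`structure` must be a non-empty atom table", call. = FALSE)
  }
  stopifnot_grid(experimental)
  stopifnot_grid(simulated)
  d <- dim(experimental$values)
  cls <- array(0L, dim = d)
  atype <- array(0L, dim = d)

  ext_sim <- grid_extent(simulated)
  overlap <- all(ext_sim["max", ] > experimental$origin) &&
    all(ext_sim["min", ] < grid_extent(experimental)["max", ])
  if (!overlap) {
    warning("experimental and simulated extents do not overlap: ",
            "label maps are all zero", call. = FALSE)
  }

  codes <- classify_atoms(structure)
  idx <- coords_to_indices(structure, experimental)
  inside_sim <- structure$x >= ext_sim["min", "x"] &
    structure$x <= ext_sim["max", "x"] &
    structure$y >= ext_sim["min", "y"] &
    structure$y <= ext_sim["max", "y"] &
    structure$z >= ext_sim["min", "z"] &
    structure$z <= ext_sim["max", "z"]
  valid <- idx$in_bounds & inside_sim

  for (a in which(valid)) {
    nb <- neighbor_indices(c(structure$x[a], structure$y[a], structure$z[a]),
                           experimental, radius)
    if (nrow(nb)) {
      lin <- cbind(nb$i + 1L, nb$j + 1L, nb$k + 1L)
      cur <- cls[lin]
      cls[lin[cur != 1L, , drop = FALSE]] <- 2L
    }
    own <- cbind(idx$i[a] + 1L, idx$j[a] + 1L, idx$k[a] + 1L)
    cls[own] <- 1L
    if (codes[a] != 0L || atype[own] == 0L) atype[own] <- codes[a]
  }

  reg <- array(0, dim = d)
  support <- which(cls > 0L)
  if (length(support)) {
    if (same_geometry(experimental, simulated)) {
      reg[support] <- simulated$values[support]
    } else {
      sub <- arrayInd(support, d)
      centers <- indices_to_coords(
        cbind(i = sub[, 1] - 1L, j = sub[, 2] - 1L, k = sub[, 3] - 1L),
        experimental)
      reg[support] <- trilinear_sample(simulated, centers, outside = 0)
    }
  }

  out <- list(
    regression = voxel_grid(reg, experimental$origin, experimental$voxel),
    classification = voxel_grid(cls + 0, experimental$origin,
                                experimental$voxel),
    atom_type = voxel_grid(atype + 0, experimental$origin,
                           experimental$voxel),
    radius = radius
  )
  class(out) <- "label_map_set"
  out
}

#' @export
print.label_map_set <- function(x, ...) {
  cat(sprintf(
    "<label_map_set> %s voxels, radius %g A\n  classification: %d direct (1), %d neighbor (2)\n  atom_type codes present: %s\n  regression support: %d voxels, max %.4g\n",
    paste(dim(x$classification$values), collapse = " x "), x$radius,
    sum(x$classification$values == 1), sum(x$classification$values == 2),
    paste(sort(unique(as.vector(x$atom_type$values))), collapse = ", "),
    sum(x$regression$values != 0), max(x$regression$values)
  ))
  invisible(x)
}

#' Summary counts for a label map set
#'
#' @param x a `label_map_set`.
#' @param ... unused.
#' @return A one-row tibble: voxel totals, direct/neighbor counts, per-class
#'   atom-type counts and regression support size.
#' @export
glance.label_map_set <- function(x, ...) {
  cls <- x$classification$values
  at <- x$atom_type$values
  tibble::tibble(
    n_voxels = length(cls),
    n_direct = sum(cls == 1),
    n_neighbor = sum(cls == 2),
    n_background = sum(cls == 0),
    n_atom_type_nonzero = sum(at != 0),
    n_regression_support = sum(x$regression$values != 0),
    radius = x$radius
  )
}

#' Run the full per-entry labeling pipeline
#'
#' Reproduces one complete data record from an experimental map and its
#' biological assembly: read both inputs, resample the experimental map to
#' the standard voxel size, simulate the idealized map on the aligned grid,
#' generate the three label maps, and write the five MRC outputs with the
#' dataset naming convention (`<id>.mrc`, `<id>_situs_simulated.mrc`,
#' `<id>_regression_situs.mrc`, `<id>_classification_situs.mrc`,
#' `<id>_classification_types_situs.mrc`) plus a plain-text provenance
#' sidecar (`<id>_provenance.txt`) recording inputs, parameters and output
#' checksums. Reruns are byte-identical.
#'
#' @param experimental_map_path path to the experimental MRC map.
#' @param assembly_path path to the PDB / .pdb1 assembly.
#' @param out_dir output directory (created if needed).
#' @param config a [run_config()].
#' @return Invisibly, a named character vector of output paths.
#' @export
run_record <- function(experimental_map_path, assembly_path, out_dir,
                       config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  id <- config$id %||% sub("\\.(pdb1?|ent)$", "", basename(assembly_path))

  exp_raw <- stage("read_mrc",
                   read_mrc(experimental_map_path,
                            origin_dialect = config$origin_dialect))
  structure <- stage("read_assembly",
                     read_assembly(assembly_path,
                                   include_hetero = config$include_hetero))
  exp_std <- stage("resample",
                   resample_to_voxel_size(exp_raw, config$voxel_target))
  kern <- kernel_spec(config$kernel_resolution, config$kernel_cutoff)
  sim <- stage("simulate", simulate_map(structure, target = exp_std,
                                        kernel = kern))
  labels <- stage("generate_labels",
                  generate_labels(structure, exp_std, sim,
                                  radius = config$neighbor_radius))

  paths <- c(
    experimental = file.path(out_dir, paste0(id, ".mrc")),
    simulated = file.path(out_dir, paste0(id, "_situs_simulated.mrc")),
    regression = file.path(out_dir, paste0(id, "_regression_situs.mrc")),
    classification = file.path(out_dir,
                               paste0(id, "_classification_situs.mrc")),
    atom_type = file.path(out_dir,
                          paste0(id, "_classification_types_situs.mrc"))
  )
  label_mode <- if (identical(config$label_storage, "int8")) 0L else 2L
  stage("write_mrc", {
    write_mrc(exp_std, paths[["experimental"]])
    write_mrc(sim, paths[["simulated"]])
    write_mrc(labels$regression, paths[["regression"]])
    write_mrc(labels$classification, paths[["classification"]], mode = label_mode)
    write_mrc(labels$atom_type, paths[["atom_type"]], mode = label_mode)
  })

  prov <- file.path(out_dir, paste0(id, "_provenance.txt"))
  md5 <- tools::md5sum(paths)
  writeLines(c(
    paste0("id: ", id),
    paste0("experimental_map: ", basename(experimental_map_path)),
    paste0("assembly: ", basename(assembly_path)),
    paste0("package: cryolabel ",
           as.character(utils::packageVersion("cryolabel"))),
    paste0("voxel_target_A: ", config$voxel_target),
    paste0("neighbor_radius_A: ", config$neighbor_radius),
    paste0("kernel_resolution_A: ", config$kernel_resolution),
    paste0("kernel_cutoff_sigma: ", config$kernel_cutoff),
    paste0("origin_dialect: ", config$origin_dialect),
    paste0("label_storage: ", config$label_storage),
    paste0("md5_", names(paths), ": ", unname(md5))
  ), prov)
  invisible(c(paths, provenance = prov))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' Collects the tunable parameters of [run_record()] and the command-line
#' interface. Flags override values loaded from a YAML config file (see
#' [load_run_config()]).
#'
#' @param voxel_target standard voxel size in Angstrom (default 1.0).
#' @param neighbor_radius neighborhood labeling radius in Angstrom
#'   (default 6.0).
#' @param kernel_resolution simulation kernel nominal resolution in Angstrom
#'   (default 2.0; for real entries use the reported map resolution).
#' @param kernel_cutoff kernel truncation in sigmas (default 4).
#' @param origin_dialect MRC origin rule: `"auto"`, `"header"` or `"nstart"`.
#' @param include_hetero include HETATM atoms (default `TRUE`).
#' @param label_storage `"float32"` (mode-2 MRC, dataset-compatible, default)
#'   or `"int8"` (mode-0) for the two integer label maps.
#' @param seed integer seed for the stochastic fixture generators.
#' @param id optional record identifier overriding the assembly file stem in
#'   output names.
#' @return A list of class `run_config`.
#' @export
run_config <- function(voxel_target = 1.0, neighbor_radius = 6.0,
                       kernel_resolution = 2.0, kernel_cutoff = 4,
                       origin_dialect = "auto", include_hetero = TRUE,
                       label_storage = "float32", seed = 1L, id = NULL) {
  stopifnot(voxel_target > 0, neighbor_radius > 0, kernel_resolution > 0)
  structure(list(
    voxel_target = voxel_target, neighbor_radius = neighbor_radius,
    kernel_resolution = kernel_resolution, kernel_cutoff = kernel_cutoff,
    origin_dialect = origin_dialect, include_hetero = include_hetero,
    label_storage = label_storage, seed = as.integer(seed), id = id
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @param overrides named list of values taking precedence over the file.
#' @return A [run_config()].
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals[names(overrides)] <- overrides
  do.call(run_config, vals[names(vals) %in% names(formals(run_config))])
}
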