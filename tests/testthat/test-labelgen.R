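test_that("neighbor voxels match brute-force lattice enumeration (interior)", {
  g <- voxel_grid(array(0, c(41, 41, 41)), origin = c(0, 0, 0), voxel = 1)
  p <- c(20.5, 20.5, 20.5) # center voxel's center
  nb <- neighbor_indices(p, g, radius = 6)
  # integer offsets with squared norm <= 36, minus the atom's own voxel
  offsets <- expand.grid(-6:6, -6:6, -6:6)
  n_expect <- sum(rowSums(offsets^2) <= 36) - 1L
  expect_equal(nrow(nb), n_expect)
  ref <- oracle_neighbor_set(p, c(41, 41, 41), c(0, 0, 0), c(1, 1, 1), 6)
  expect_equal(nrow(nb), nrow(ref))
  expect_setequal(paste(nb$i, nb$j, nb$k), paste(ref[, 1], ref[, 2], ref[, 3]))
})

test_that("neighbor sets clip at grid boundaries and off-center points", {
  g <- voxel_grid(array(0, c(15, 15, 15)), origin = c(0, 0, 0), voxel = 1)
  for (p in list(c(1.5, 7.5, 7.5), c(7.2, 0.9, 13.8), c(3.3, 4.4, 5.5))) {
    nb <- neighbor_indices(p, g, radius = 6)
    ref <- oracle_neighbor_set(c(p[1], p[2], p[3]), c(15, 15, 15),
                               c(0, 0, 0), c(1, 1, 1), 6)
    expect_setequal(paste(nb$i, nb$j, nb$k),
                    paste(ref[, 1], ref[, 2], ref[, 3]))
  }
  # boundary atom has strictly fewer neighbors than an interior one
  interior <- nrow(neighbor_indices(c(7.5, 7.5, 7.5), g, 6))
  clipped <- nrow(neighbor_indices(c(1.5, 7.5, 7.5), g, 6))
  expect_lt(clipped, interior)
})

test_that("a tiny radius around a voxel center labels no neighbors", {
  g <- voxel_grid(array(0, c(9, 9, 9)), voxel = 1)
  expect_equal(nrow(neighbor_indices(c(4.5, 4.5, 4.5), g, radius = 0.4)), 0L)
  expect_error(neighbor_indices(c(1, 1, 1), g, radius = -1), "positive")
})

test_that("a single interior atom produces the minimal label pattern", {
  s <- one_atom(10.2, 9.7, 10.9)
  g <- bounding_grid(s, voxel = 1, pad = 8)
  sim <- simulate_map(s, g, kernel_spec(2.0))
  lab <- generate_labels(s, g, sim, radius = 6)
  cls <- lab$classification$values
  expect_equal(sum(cls == 1), 1L)
  own <- coords_to_indices(s, g)
  expect_equal(cls[own$i + 1, own$j + 1, own$k + 1], 1)
  expect_equal(lab$atom_type$values[own$i + 1, own$j + 1, own$k + 1], 1) # CA
  expect_equal(lab$regression$values[own$i + 1, own$j + 1, own$k + 1],
               sim$values[own$i + 1, own$j + 1, own$k + 1])
  expect_equal(sum(cls == 2), nrow(neighbor_indices(s, g, 6)))
})

test_that("atoms outside the simulated extent contribute nothing (dual validation)", {
  s <- one_atom(10, 10, 10)
  exp_g <- voxel_grid(array(0, c(30, 30, 30)), origin = c(0, 0, 0), voxel = 1)
  # simulated map far away: atom is inside experimental but outside simulated
  sim_far <- voxel_grid(array(0, c(5, 5, 5)), origin = c(100, 100, 100),
                        voxel = 1)
  expect_warning(lab <- generate_labels(s, exp_g, sim_far), "overlap")
  expect_true(all(lab$classification$values == 0))
  expect_true(all(lab$regression$values == 0))
  expect_true(all(lab$atom_type$values == 0))
})

test_that("direct labels take precedence over neighbor labels", {
  s <- dplyr::bind_rows(one_atom(10.5, 10.5, 10.5),
                        one_atom(12.5, 10.5, 10.5, name = "N", element = "N"))
  g <- bounding_grid(s, voxel = 1, pad = 8)
  sim <- simulate_map(s, g, kernel_spec(2.0))
  lab <- generate_labels(s, g, sim)
  idx <- coords_to_indices(s, g)
  # each atom's voxel is inside the other's 6 A neighborhood yet stays 1
  for (a in 1:2) {
    expect_equal(lab$classification$values[idx$i[a] + 1, idx$j[a] + 1,
                                           idx$k[a] + 1], 1)
  }
  expect_equal(lab$atom_type$values[idx$i[2] + 1, idx$j[2] + 1, idx$k[2] + 1],
               5) # nitrogen
})

test_that("atom-type collisions: last writer wins but 0 never clobbers", {
  # two atoms mapping to the same voxel: CA (class 1) then side-chain CG (0)
  s <- dplyr::bind_rows(one_atom(10.2, 10.2, 10.2),
                        one_atom(10.8, 10.8, 10.8, name = "CG"))
  g <- voxel_grid(array(0, c(21, 21, 21)), voxel = 1)
  sim <- simulate_map(s, g, kernel_spec(2.0))
  lab <- generate_labels(s, g, sim)
  own <- coords_to_indices(s[1, ], g)
  expect_equal(lab$atom_type$values[own$i + 1, own$j + 1, own$k + 1], 1)
  # reversed order: nonzero class overwrites the earlier zero
  lab2 <- generate_labels(s[2:1, ], g, sim)
  expect_equal(lab2$atom_type$values[own$i + 1, own$j + 1, own$k + 1], 1)
  # nonzero-vs-nonzero: the later atom wins
  s3 <- dplyr::bind_rows(one_atom(10.2, 10.2, 10.2),
                         one_atom(10.8, 10.8, 10.8, name = "CB"))
  lab3 <- generate_labels(s3, g, sim)
  expect_equal(lab3$atom_type$values[own$i + 1, own$j + 1, own$k + 1], 2)
})

test_that("regression equals simulated masked by the labeled support", {
  h <- make_helix(8)
  g <- bounding_grid(h)
  sim <- simulate_map(h, g, kernel_spec(2.0))
  lab <- generate_labels(h, g, sim)
  support <- lab$classification$values > 0
  expect_identical(lab$regression$values, sim$values * support)
})

test_that("cross-grid regression values are trilinear samples of the simulated map", {
  s <- one_atom(10.3, 10.3, 10.3)
  exp_g <- voxel_grid(array(0, c(25, 25, 25)), origin = c(0, 0, 0), voxel = 1)
  # simulated on its own, offset, finer grid
  sim_g <- bounding_grid(s, voxel = 0.8, pad = 7)
  sim <- simulate_map(s, sim_g, kernel_spec(2.0))
  lab <- generate_labels(s, exp_g, sim, radius = 3)
  nz <- which(lab$regression$values != 0, arr.ind = TRUE)
  expect_gt(nrow(nz), 0)
  centers <- indices_to_coords(
    cbind(i = nz[, 1] - 1L, j = nz[, 2] - 1L, k = nz[, 3] - 1L), exp_g)
  expect_equal(lab$regression$values[nz],
               sample_at(sim, centers, "trilinear"))
})

test_that("labeled set grows monotonically with the radius", {
  h <- make_helix(5)
  g <- bounding_grid(h)
  sim <- simulate_map(h, g, kernel_spec(2.0))
  labeled <- lapply(c(2, 4, 6), function(r) {
    which(generate_labels(h, g, sim, radius = r)$classification$values > 0)
  })
  expect_true(all(labeled[[1]] %in% labeled[[2]]))
  expect_true(all(labeled[[2]] %in% labeled[[3]]))
})

test_that("run_record writes the aligned five-map record with provenance", {
  td <- withr::local_tempdir()
  bundle <- make_fixture_bundle(file.path(td, "fix"), n_res = 8, seed = 3)
  out <- run_record(bundle[["experimental"]], bundle[["pdb"]],
                    file.path(td, "rec"), run_config())
  expect_true(all(file.exists(out)))
  mrcs <- out[names(out) != "provenance"]
  grids <- lapply(mrcs, read_mrc)
  ref <- grids$experimental
  for (g in grids) {
    expect_equal(dim(g$values), dim(ref$values))
    expect_equal(g$origin, ref$origin, tolerance = 1e-6)
    expect_equal(unname(g$voxel), c(1, 1, 1), tolerance = 1e-6)
  }
  # label value sets
  expect_true(all(grids$classification$values %in% c(0, 1, 2)))
  expect_true(all(grids$atom_type$values %in% 0:5))
  # every dual-validated atom yields a direct label: >= distinct atom voxels
  s <- read_assembly(bundle[["pdb"]])
  idx <- coords_to_indices(s, ref)
  n_distinct <- nrow(unique(idx[idx$in_bounds, c("i", "j", "k")]))
  expect_gte(sum(grids$classification$values == 1), n_distinct)
  prov <- readLines(out[["provenance"]])
  expect_true(any(grepl("^md5_regression:", prov)))
  expect_true(any(grepl("neighbor_radius_A: 6", prov)))
})

test_that("stage failures name the failing stage", {
  expect_error(run_record("nope.mrc", "nope.pdb", tempfile()),
               "\\[read_mrc\\]")
})
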