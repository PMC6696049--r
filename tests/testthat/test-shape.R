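as_grid <- function(spec, occ, scope = "whole", n_sources = 1L) {
  structure(list(spec = spec, occupied = occ, scope = scope,
                 n_sources = n_sources), class = "twn_grid")
}

test_that("voxelized sphere volume matches the analytic volume", {
  lig <- new_ligand(data.frame(element = "C", x = 0, y = 0, z = 0))
  g <- voxelize_ligand(lig, spacing = 0.5)
  vox_vol <- sum(g$occupied) * 0.5^3
  expect_equal(vox_vol, 4 / 3 * pi * 1.7^3, tolerance = 0.15)

  w <- new_frame(matrix(0, 1, 3), matrix(c(0.9572, 0, 0), 1, 3),
                 matrix(c(-0.24, 0.927, 0), 1, 3))
  one_water <- voxelize_twn(
    data.frame(frame = 1L, members = I(list(1L))), w,
    grid_from_atoms(matrix(0, 1, 3), padding = 3), water_radius = 1.4)
  expect_equal(sum(one_water$occupied) * 0.5^3, 4 / 3 * pi * 1.4^3,
               tolerance = 0.15)
})

test_that("region grids are subsets of the whole-ligand grid", {
  lig <- make_toy_ligand()$ligand
  gspec <- grid_from_atoms(ligand_coords(lig))
  whole <- voxelize_ligand(lig, "whole", gspec)
  for (sc in c("head", "linker", "tail", "Lprime")) {
    part <- voxelize_ligand(lig, sc, gspec)
    expect_true(all(!part$occupied | whole$occupied))
  }
  expect_error(voxelize_ligand(lig, "nothing"), "label|atoms")
})

test_that("similarity limits: identity 100, disjoint 0, half-coverage 50", {
  spec <- grid_spec(c(0, 0, 0), 1, c(4, 4, 4))
  ligocc <- array(FALSE, c(4, 4, 4))
  ligocc[1:32] <- TRUE
  lig <- as_grid(spec, ligocc)

  expect_equal(shape_similarity(lig, lig)$percent, 100)

  empty <- as_grid(spec, array(FALSE, c(4, 4, 4)))
  expect_equal(shape_similarity(lig, empty)$percent, 0)

  half <- array(FALSE, c(4, 4, 4))
  half[1:16] <- TRUE
  expect_equal(shape_similarity(lig, as_grid(spec, half))$percent, 50)

  expect_error(shape_similarity(empty, lig), "no occupied")
  other <- as_grid(grid_spec(c(1, 0, 0), 1, c(4, 4, 4)), ligocc)
  expect_error(shape_similarity(lig, other), "congruent")

  # tanimoto: half-coverage twn entirely inside lig -> 16/32
  s <- shape_similarity(lig, as_grid(spec, half), mode = "tanimoto")
  expect_equal(s$percent, 50)
  full <- as_grid(spec, array(TRUE, c(4, 4, 4)))
  expect_equal(shape_similarity(lig, full, mode = "tanimoto")$percent, 50)
  expect_equal(shape_similarity(lig, full, mode = "coverage")$percent, 100)
})

test_that("adding rings never decreases coverage", {
  plan <- data.frame(size = c(3, 4, 5, 3),
                     region = c("head", "linker", "head", "linker"),
                     lprime = c(FALSE, TRUE, FALSE, TRUE),
                     offset = 1.8, frame = 1:4)
  sc <- plant_scene(plant_spec(plan, n_frames = 4, seed = 6))
  rep <- occupancy_report(sc$frames, sc$ligand)
  gspec <- grid_from_atoms(ligand_coords(sc$ligand))
  lig <- voxelize_ligand(sc$ligand, "whole", gspec)
  pcts <- vapply(seq_len(nrow(rep$rings)), function(k) {
    tw <- voxelize_twn(rep$rings[seq_len(k), ], sc$frames, gspec)
    shape_similarity(lig, tw)$percent
  }, numeric(1))
  expect_true(all(diff(pcts) >= 0))
  expect_gt(pcts[length(pcts)], 0)
})

test_that("voxelizing a duplicated ring is idempotent", {
  ring <- make_ring(4, center = c(2, 2, 0))
  fr1 <- bind_waters(list(ring), index = 1L)
  fr2 <- bind_waters(list(ring), index = 2L)
  gspec <- grid_spec(c(-3, -3, -3), 0.5, c(20, 20, 20))
  single <- voxelize_twn(data.frame(frame = 1L, members = I(list(1:4))),
                         list(fr1), gspec)
  doubled <- voxelize_twn(
    data.frame(frame = c(1L, 2L), members = I(list(1:4, 1:4))),
    list(fr1, fr2), gspec)
  expect_identical(single$occupied, doubled$occupied)
  none <- voxelize_twn(data.frame(frame = integer(0),
                                  members = I(list()))[0, ],
                       list(fr1), gspec)
  expect_equal(sum(none$occupied), 0L)
})

test_that("proximal-ring extraction uses an inclusive 2 A cutoff", {
  lig <- make_toy_ligand()$ligand
  mk <- function(d) data.frame(frame = 1L, size = 3L, region = "head",
                               lprime = FALSE, distance = d,
                               members = I(list(1:3)), resids = "1,2,3",
                               cx = 0, cy = d, cz = 0)
  # ligand heavy atom at origin; centers at 1.5 / 2.0 / 2.5 A
  rings <- rbind(mk(1.5), mk(2.0), mk(2.5))
  kept <- proximal_rings(rings, lig, com_cutoff = 2.0)
  expect_equal(kept$cy, c(1.5, 2.0))
})

test_that("joint rotation of ligand and waters barely changes coverage", {
  plan <- data.frame(size = c(4, 5), region = c("head", "linker"),
                     lprime = c(FALSE, TRUE), offset = 1.8, frame = 1:2)
  sc <- plant_scene(plant_spec(plan, n_frames = 2, seed = 10))
  rep <- occupancy_report(sc$frames, sc$ligand)
  score <- function(frames, lig, rings) {
    gspec <- grid_from_atoms(ligand_coords(lig))
    shape_similarity(voxelize_ligand(lig, "whole", gspec),
                     voxelize_twn(rings, frames, gspec))$percent
  }
  p0 <- score(sc$frames, sc$ligand, rep$rings)

  set.seed(2)
  R <- rand_rotation()
  frames_r <- lapply(sc$frames, transform_frame, rotation = R)
  at <- sc$ligand$atoms
  at[, c("x", "y", "z")] <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  lig_r <- new_ligand(at)
  rep_r <- occupancy_report(frames_r, lig_r)
  p1 <- score(frames_r, lig_r, rep_r$rings)
  expect_lt(abs(p1 - p0), 3)
})

test_that("grids export to OpenDX text", {
  lig <- new_ligand(data.frame(element = "C", x = 0, y = 0, z = 0))
  g <- voxelize_ligand(lig, spacing = 1)
  path <- tempfile(fileext = ".dx")
  write_dx(g, path)
  lines <- readLines(path)
  expect_match(lines[1], "gridpositions")
  counts <- as.integer(strsplit(sub(".*counts ", "", lines[1]), " ")[[1]])
  expect_equal(prod(counts), prod(g$spec$dims))
})
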