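test_that("generated rings are found as exactly one ring of the right size", {
  for (s in 3:6) {
    fr <- make_ring(s)
    rings <- enumerate_rings(hbond_graph(fr))
    expect_length(rings, 1)
    expect_equal(length(rings[[1]]), s)
  }
  expect_error(make_ring(7), "size")
  expect_error(make_ring(2), "size")
})

test_that("ring generation self-check rejects non-bonding geometry", {
  expect_error(make_ring(4, o_o_distance = 4.5), "self-check")
})

test_that("planted ring geometry is invariant to placement", {
  set.seed(17)
  for (k in 1:5) {
    ctr <- stats::rnorm(3, sd = 20)
    nrm <- stats::rnorm(3)
    fr <- make_ring(sample(3:6, 1), center = ctr, normal = nrm)
    expect_equal(colMeans(fr$o), ctr, tolerance = 1e-9)
    rings <- enumerate_rings(hbond_graph(fr))
    expect_length(rings, 1)
  }
})

test_that("random boxes are reproducible and respect the O-O floor", {
  f1 <- make_box(40, box = 25, seed = 31)
  f2 <- make_box(40, box = 25, seed = 31)
  expect_identical(f1$o, f2$o)
  expect_identical(f1$h1, f2$h1)
  f3 <- make_box(40, box = 25, seed = 32)
  expect_false(identical(f1$o, f3$o))

  empty <- make_box(0, box = 10)
  expect_equal(n_waters(empty), 0L)

  for (seed in 1:40) {
    fr <- make_box(30, box = 20, min_oo = 2.6, seed = seed)
    d <- as.matrix(dist(fr$o))
    # minimum-image distances in the periodic box
    for (dim in 1:3) {
      dd <- outer(fr$o[, dim], fr$o[, dim], `-`)
      dd <- dd - round(dd / 20) * 20
      if (dim == 1) mind2 <- dd^2 else mind2 <- mind2 + dd^2
    }
    diag(mind2) <- Inf
    expect_gte(sqrt(min(mind2)), 2.6)
  }
})

test_that("box generation seeding does not disturb the global RNG", {
  set.seed(123)
  before <- .Random.seed
  invisible(make_box(10, box = 20, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("the toy ligand has the documented region layout", {
  toy <- make_toy_ligand()
  at <- toy$ligand$atoms
  expect_equal(nrow(at), 12L)
  expect_equal(sum(at$region == "head"), 4L)
  expect_equal(sum(at$region == "linker"), 4L)
  expect_equal(sum(at$region == "tail"), 4L)
  expect_equal(sum(at$lprime), 1L)
  expect_true(all(at$region[at$lprime] == "linker"))

  # annotation round-trips through the ligand reader
  ligf <- tempfile(fileext = ".pdb")
  annf <- tempfile(fileext = ".tsv")
  write_ligand_pdb(toy$ligand, ligf)
  write_region_annotation(toy$ligand, annf)
  back <- read_ligand(ligf, regions = annf)
  expect_equal(back$atoms$region, at$region)
  expect_equal(back$atoms$lprime, at$lprime)
})

test_that("planted scenes recover counts, sizes, regions and percentages", {
  plan <- data.frame(size = rep(c(3L, 4L, 5L, 6L), 3),
                     region = rep(c("head", "linker", "tail"), each = 4))
  sc <- plant_scene(plant_spec(plan, n_frames = 6, noise_waters = 10,
                               seed = 44))
  rep <- occupancy_report(sc$frames, sc$ligand)
  expect_equal(rep$n_rings, nrow(plan))
  expect_equal(unname(rep$counts[c("head", "linker", "tail")]),
               unname(sc$truth$counts))
  expect_equal(unname(rep$percent), unname(sc$truth$percent))
  expect_equal(sort(rep$rings$size), sort(plan$size))
  expect_equal(rep$lprime_fraction, sc$truth$lprime_fraction)
})

test_that("scene invariants are enforced at generation time", {
  plan <- data.frame(size = rep(3L, 3), region = "head", frame = 1L)
  expect_error(plant_spec(plan, n_frames = 1), "at most 2")
  expect_error(plant_spec(data.frame(size = 8, region = "head")), "\\[3, 6\\]")
  expect_error(plant_spec(data.frame(size = 3, region = "middle")), "region")
})

test_that("fixtures survive a GRO and PDB round trip", {
  plan <- data.frame(size = c(3, 5), region = c("head", "linker"))
  sc <- plant_scene(plant_spec(plan, n_frames = 1, noise_waters = 6,
                               seed = 2))
  fr <- sc$frames[[1]]
  rep0 <- occupancy_report(list(fr), sc$ligand)

  for (ext in c(".gro", ".pdb")) {
    f <- tempfile(fileext = ext)
    suppressWarnings(write_frames(fr, f))
    back <- suppressWarnings(read_frames(f))
    expect_length(back, 1)
    expect_equal(n_waters(back[[1]]), n_waters(fr))
    tol <- if (ext == ".gro") 0.011 else 0.0011  # format precision
    expect_lt(max(abs(back[[1]]$o - fr$o)), tol)
    rep1 <- occupancy_report(back, sc$ligand)
    expect_equal(rep1$percent, rep0$percent)
    expect_equal(rep1$n_rings, rep0$n_rings)
  }
})
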