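# A minimal labelled ligand for assignment tests: head at +x, linker (with
# one L' atom) at -x.
tiny_ligand <- function() {
  new_ligand(data.frame(
    element = c("C", "C", "O", "C"),
    x = c(1, 2.5, -1, -2.5), y = 0, z = 0,
    region = c("head", "head", "linker", "linker"),
    lprime = c(FALSE, FALSE, TRUE, FALSE)
  ))
}

test_that("site sphere keeps and drops waters exactly at the boundary", {
  dvals <- c(24.9, 25.0, 25.1)
  o <- cbind(dvals, 0, 0)
  fr <- new_frame(o, o + matrix(c(0.9572, 0, 0), 3, 3, byrow = TRUE),
                  o + matrix(c(-0.24, 0.927, 0), 3, 3, byrow = TRUE))
  sub <- select_site_waters(fr, site_spec(center = c(0, 0, 0), radius = 25))
  expect_equal(attr(sub, "index_map"), c(1L, 2L))  # <= convention
  expect_equal(n_waters(sub), 2L)
})

test_that("empty site selection warns and returns an empty frame", {
  fr <- make_box(5, box = 30, seed = 4)
  expect_warning(
    sub <- select_site_waters(fr, site_spec(center = c(500, 500, 500),
                                            radius = 0.1)),
    "no waters"
  )
  expect_equal(n_waters(sub), 0L)
})

test_that("site selection preserves water order and records the index map", {
  fr <- make_box(40, box = 30, seed = 8)
  ctr <- colMeans(fr$o)
  sub <- select_site_waters(fr, site_spec(center = ctr, radius = 10))
  imap <- attr(sub, "index_map")
  expect_false(is.unsorted(imap))
  expect_equal(sub$o, fr$o[imap, , drop = FALSE])
  expect_equal(sub$resid, fr$resid[imap])
})

test_that("rings are assigned to the nearest labelled region within cutoff", {
  lig <- tiny_ligand()
  near_head <- make_ring(3, center = c(2, 2, 0))      # 1 A off atom 2.5
  a <- assign_ring(1:3, near_head, lig, cutoff = 5)
  expect_equal(a$region, "head")
  expect_false(a$lprime)

  far <- make_ring(3, center = c(0, 40, 0))
  a2 <- assign_ring(1:3, far, lig, cutoff = 5)
  expect_equal(a2$region, "unassigned")

  unlabeled <- new_ligand(data.frame(element = "C", x = 0, y = 0, z = 0))
  expect_error(assign_ring(1:3, near_head, unlabeled), "no labelled")
})

test_that("exact assignment ties resolve by L' > linker > head priority", {
  lig <- tiny_ligand()
  # ring centered at the origin: equidistant (1 A) to head atom at +1 and
  # the L' linker atom at -1
  ring <- make_ring(3, center = c(0, 0, 0))
  a <- assign_ring(1:3, ring, lig, cutoff = 5)
  expect_equal(a$region, "linker")
  expect_true(a$lprime)
})

test_that("occupancy report reproduces planted percentages", {
  plan <- data.frame(size = c(3, 4, 3, 5),
                     region = c("head", "head", "head", "linker"),
                     frame = 1:4)
  sc <- plant_scene(plant_spec(plan, n_frames = 4, noise_waters = 8,
                               seed = 21))
  rep <- occupancy_report(sc$frames, sc$ligand)
  expect_equal(rep$n_rings, 4L)
  expect_equal(unname(rep$percent), c(75, 25, 0))
  expect_equal(sum(rep$percent), 100, tolerance = 0.1)
  expect_false(rep$no_assigned_rings)
  expect_equal(rep$counts[["unassigned"]], 0L)
})

test_that("all-L' scenes give a 100% linker and 100% L' fraction", {
  plan <- data.frame(size = rep(3, 4), region = "linker",
                     lprime = TRUE, frame = 1:4)
  sc <- plant_scene(plant_spec(plan, n_frames = 4, seed = 3))
  rep <- occupancy_report(sc$frames, sc$ligand)
  expect_equal(unname(rep$percent), c(0, 100, 0))
  expect_equal(rep$lprime_fraction, 100)
})

test_that("a ring-bearing scene far from the ligand is flagged unassigned", {
  ring <- make_ring(4, center = c(400, 400, 400))
  fr <- bind_waters(list(ring), index = 1L)
  lig <- tiny_ligand()
  rep <- occupancy_report(list(fr), lig,
                          site = site_spec(center = c(400, 400, 400),
                                           radius = 25))
  expect_true(rep$no_assigned_rings)
  expect_equal(rep$counts[["unassigned"]], 1L)
  expect_equal(unname(rep$percent), c(0, 0, 0))
})

test_that("raising the assignment cutoff never unassigns rings", {
  plan <- data.frame(size = c(3, 4, 5, 3), region = c("head", "linker",
                                                      "head", "tail"))
  sc <- plant_scene(plant_spec(plan, n_frames = 4, seed = 5))
  n_assigned <- function(cut) {
    r <- occupancy_report(sc$frames, sc$ligand, assign_cutoff = cut)
    sum(r$counts[c("head", "linker", "tail")])
  }
  counts <- vapply(c(3, 4, 5, 6, 7), n_assigned, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("percentages are invariant under frame reordering and rigid motion", {
  plan <- data.frame(size = c(3, 4, 3), region = c("head", "linker", "head"),
                     frame = 1:3)
  sc <- plant_scene(plant_spec(plan, n_frames = 3, noise_waters = 5,
                               seed = 12))
  rep0 <- occupancy_report(sc$frames, sc$ligand)
  rep_rev <- occupancy_report(rev(sc$frames), sc$ligand)
  expect_equal(rep_rev$percent, rep0$percent)
  expect_equal(rep_rev$lprime_fraction, rep0$lprime_fraction)

  set.seed(99)
  R <- rand_rotation()
  t <- c(5, -3, 11)
  frames_t <- lapply(sc$frames, transform_frame, rotation = R,
                     translation = t)
  at <- sc$ligand$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at[, c("x", "y", "z")] <- sweep(xyz, 2, t, `+`)
  lig_t <- new_ligand(at, name = sc$ligand$name)
  rep_t <- occupancy_report(frames_t, lig_t)
  expect_equal(rep_t$percent, rep0$percent, tolerance = 1e-9)
  expect_equal(rep_t$counts, rep0$counts)
})

test_that("report serialises to TSV and JSON", {
  plan <- data.frame(size = 3, region = "head")
  sc <- plant_scene(plant_spec(plan, n_frames = 1, seed = 1))
  rep <- occupancy_report(sc$frames, sc$ligand)
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  write_occupancy(rep, tsv)
  write_occupancy(rep, js)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$region, "head")
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$percent$head, 100)
})
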