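test_that("canonical H-bond dimer reproduces the frozen golden energy", {
  d <- canonical_dimer(2.8)
  e <- pair_energy(d$a, d$b)
  expect_equal(e, GOLDEN_DIMER_ENERGY, tolerance = 1e-9)
  expect_lt(e, -2.25)
  expect_true(is_hbonded(d$a, d$b))
  # and the in-test oracle agrees with the frozen value too
  expect_equal(oracle_pair_energy(d$a, d$b), GOLDEN_DIMER_ENERGY,
               tolerance = 1e-9)
})

test_that("pair energy is symmetric and matches the 9-pair oracle", {
  set.seed(11)
  for (k in 1:100) {
    d <- rand_dimer()
    e_ab <- pair_energy(d$a, d$b)
    expect_lt(abs(e_ab - pair_energy(d$b, d$a)), 1e-10)
    expect_lt(abs(e_ab - oracle_pair_energy(d$a, d$b)), 1e-10)
  }
})

test_that("pair energy is invariant under rigid motion of both waters", {
  set.seed(23)
  for (k in 1:25) {
    d <- rand_dimer()
    e0 <- pair_energy(d$a, d$b)
    R <- rand_rotation()
    t <- stats::rnorm(3, sd = 10)
    e1 <- pair_energy(rotate_water(d$a, R, t), rotate_water(d$b, R, t))
    expect_equal(e0, e1, tolerance = 1e-8)
  }
})

test_that("pair energy decays at long range (dipole-dipole limit)", {
  set.seed(5)
  for (k in 1:10) {
    d <- canonical_dimer(30)
    R <- rand_rotation()
    d$b <- rotate_water(rotate_water(d$b, diag(3), -d$b$o), R, d$b$o)
    expect_lt(abs(pair_energy(d$a, d$b)), 0.2)
  }
})

test_that("energy is monotone non-decreasing beyond the potential minimum", {
  roo <- seq(2.5, 8, by = 0.05)
  e <- vapply(roo, function(r) {
    d <- canonical_dimer(r)
    pair_energy(d$a, d$b)
  }, numeric(1))
  imin <- which.min(e)
  expect_true(all(diff(e[imin:length(e)]) >= -1e-12))
  # the default criterion sits near the minimum of the pair-energy curve
  expect_lt(e[imin], -2.25)
})

test_that("H-bond threshold comparison is inclusive at exact equality", {
  d <- canonical_dimer(2.8)
  e <- pair_energy(d$a, d$b)
  at <- potential_params(hbond_threshold = e)
  below <- potential_params(hbond_threshold = e - 1e-9)
  expect_true(is_hbonded(d$a, d$b, at))
  expect_false(is_hbonded(d$a, d$b, below))
  far <- canonical_dimer(6)   # weakly interacting
  expect_false(is_hbonded(far$a, far$b))
})

test_that("degenerate inputs are rejected", {
  d <- canonical_dimer(0.05)
  expect_error(pair_energy(d$a, d$b), "overlap")
  w <- canonical_dimer(2.8)$a
  broken <- w
  broken$h2 <- NULL
  expect_error(pair_energy(w, broken), "missing")
  expect_error(potential_params(hbond_threshold = 1), "negative")
  expect_error(potential_params(q_O = -0.8, q_H = 0.3), "neutral")
})

test_that("minimum image: energy uses the nearest periodic image", {
  d <- canonical_dimer(2.8)
  box <- c(20, 20, 20)
  shifted <- d$b
  shifted$o <- shifted$o + c(20, -40, 20)
  shifted$h1 <- shifted$h1 + c(20, -40, 20)
  shifted$h2 <- shifted$h2 + c(20, -40, 20)
  expect_equal(pair_energy(d$a, shifted, box = box),
               pair_energy(d$a, d$b), tolerance = 1e-10)
  expect_equal(pair_energy(d$a, shifted, box = box),
               oracle_pair_energy(d$a, shifted, box = box),
               tolerance = 1e-10)
})

test_that("H-bond graph finds planted bonds and ignores distant waters", {
  d <- canonical_dimer(2.8)
  far <- rotate_water(d$a, diag(3), c(20, 0, 0))
  fr <- new_frame(rbind(d$a$o, d$b$o, far$o),
                  rbind(d$a$h1, d$b$h1, far$h1),
                  rbind(d$a$h2, d$b$h2, far$h2))
  g <- hbond_graph(fr)
  expect_equal(g$n, 3L)
  expect_equal(g$edges, matrix(c(1L, 2L), 1, 2))
})

test_that("empty and edgeless frames yield valid graphs", {
  empty <- new_frame(matrix(numeric(0), 0, 3), matrix(numeric(0), 0, 3),
                     matrix(numeric(0), 0, 3))
  g <- hbond_graph(empty)
  expect_equal(g$n, 0L)
  expect_equal(nrow(g$edges), 0L)
  sparse <- make_box(8, box = 40, min_oo = 12, seed = 2)
  g2 <- hbond_graph(sparse)
  expect_equal(g2$n, 8L)
  expect_equal(nrow(g2$edges), 0L)
})

test_that("cell-list graph equals the exhaustive graph on boxed fixtures", {
  for (seed in 1:5) {
    fr <- make_box(80, box = 25, seed = seed)
    expect_identical(hbond_graph(fr, method = "cell")$edges,
                     hbond_graph(fr, method = "exhaustive")$edges)
  }
})

test_that("graph is invariant under whole-frame lattice translation", {
  fr <- make_box(60, box = 22, seed = 9)
  g0 <- hbond_graph(fr)
  shift <- c(22, -44, 22)
  fr2 <- new_frame(sweep(fr$o, 2, shift, `+`), sweep(fr$h1, 2, shift, `+`),
                   sweep(fr$h2, 2, shift, `+`), box = fr$box)
  expect_identical(hbond_graph(fr2)$edges, g0$edges)
})
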