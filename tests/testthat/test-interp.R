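# The planted-intermediate fixture: a 4-atom chain with a six-fold
# torsional potential (minima every 60 degrees). Endpoints minimized near
# 30 and 150 degrees leave a distinct basin near 90 degrees between them.
planted_chain <- function(phi) {
  make_torsion_chain(4, dihedrals = phi)$geometry
}
planted_params <- torsion_params(amplitude = 1, mult = 6, rep_a = 0.01)
planted_model <- torsion_chain_potential(planted_params)

test_that("pair selection filters by threshold and subsamples reproducibly", {
  set.seed(23)
  geoms <- lapply(1:5, function(i) rand_geometry(5))
  pd <- pairwise(geoms)
  allp <- pd$M[upper.tri(pd$M)]
  expect_identical(nrow(select_pairs(geoms, min_distance = max(allp) + 1)), 0L)
  # threshold placed so that exactly 4 pairs lie above it
  thr <- sort(allp, decreasing = TRUE)[5]
  got <- select_pairs(geoms, min_distance = thr)
  expect_identical(nrow(got), 4L)
  want <- which(pd$M > thr & upper.tri(pd$M), arr.ind = TRUE)
  expect_setequal(paste(got$i, got$j), paste(want[, 1], want[, 2]))
  s1 <- select_pairs(geoms, min_distance = 0, max_pairs = 3, seed = 9)
  s2 <- select_pairs(geoms, min_distance = 0, max_pairs = 3, seed = 9)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 3L)
  expect_true(all(s1$distance > 0))
})

test_that("degenerate interpolation between a minimum and itself returns its own basin", {
  lj <- lj_potential()
  a <- local_minimize(lj, make_lj_cluster(5, seed = 4))
  res <- interpolate_ff(a$geometry, a$geometry, lj)
  expect_equal(res$record$energy, a$energy, tolerance = 1e-8)
  expect_identical(res$record$provenance, "interpolation")
})

test_that("stage-1 interpolants realize the blended distance matrix on trimer pairs", {
  set.seed(24)
  lj <- lj_potential()
  for (i in 1:5) {
    a <- rand_geometry(3, spread = 1.5)
    b <- rand_geometry(3, spread = 1.5)
    res <- interpolate_ff(a, b, lj, lambda = 0.5)
    expect_lt(res$stage1_max_dev, 1e-4)
  }
})

test_that("midpoint interpolation lands in a planted intermediate basin", {
  a <- local_minimize(planted_model, planted_chain(35))
  b <- local_minimize(planted_model, planted_chain(145))
  quad <- list(1:4)
  expect_equal(abs(dihedral_angles(a$geometry, quad)), 30, tolerance = 2)
  expect_equal(abs(dihedral_angles(b$geometry, quad)), 150, tolerance = 2)
  res <- interpolate_ff(a$geometry, b$geometry, planted_model, lambda = 0.5)
  expect_equal(abs(dihedral_angles(res$record$geometry, quad)), 90,
               tolerance = 2)
})

test_that("interpolation-factor verification has exact endpoints and swap symmetry", {
  set.seed(25)
  a <- rand_geometry(4); b <- rand_geometry(4)
  ep <- verify_eq_interp(a, b, a, lambda = 1)
  expect_equal(ep$d_ac, 0)
  expect_equal(ep$d_bc, ep$d_ab)
  expect_equal(ep$dev_ac, 0); expect_equal(ep$dev_bc, 0, tolerance = 1e-12)
  cc <- rand_geometry(4)
  f <- verify_eq_interp(a, b, cc, lambda = 0.3)
  r <- verify_eq_interp(b, a, cc, lambda = 0.7)
  expect_equal(f$dev_ac, r$dev_bc, tolerance = 1e-12)
  expect_equal(f$dev_bc, r$dev_ac, tolerance = 1e-12)
})

test_that("stage-1 midpoints satisfy the interpolation-factor relation within 5 percent", {
  set.seed(26)
  lj <- lj_potential()
  for (i in 1:5) {
    a <- rand_geometry(3, spread = 1.5)
    b <- rand_geometry(3, spread = 1.5)
    res <- interpolate_ff(a, b, lj, lambda = 0.5)
    v <- verify_eq_interp(a, b, res$stage1_geometry, lambda = 0.5)
    expect_lte(v$dev_ac, 0.05 * v$d_ab)
    expect_lte(v$dev_bc, 0.05 * v$d_ab)
  }
})

test_that("interpolation-relation deviations shrink as the endpoints approach", {
  set.seed(27)
  lj <- lj_potential()
  a <- rand_geometry(6, spread = 1.5)
  dirn <- matrix(stats::runif(18, -1, 1), 6, 3)
  dev_at <- function(t) {
    b <- a; b$coords <- a$coords + t * dirn
    res <- interpolate_ff(a, b, lj, lambda = 0.5)
    v <- verify_eq_interp(a, b, res$stage1_geometry, lambda = 0.5)
    max(v$dev_ac, v$dev_bc)
  }
  devs <- vapply(c(1.5, 0.75, 0.3), dev_at, numeric(1))
  expect_lt(devs[3], devs[1] + 1e-12)
})

test_that("constrained Monte Carlo keeps every record inside both radii", {
  a <- local_minimize(planted_model, planted_chain(35))$geometry
  b <- local_minimize(planted_model, planted_chain(145))$geometry
  d_ab <- dm_similarity(a, b)
  cfg <- bh_config(thermal_energy = 0.5, n_steps = 120, dihedral_step = 30,
                   min_interatomic = 0.5, interaction_radius = 10,
                   energy_tol = 1e-5, similarity_tol = 0.05, seed = 6)
  topo <- make_torsion_chain(4)$topology
  expect_error(
    mc_constrained_sample(a, b, planted_model, cfg, d_ab / 4, d_ab / 4),
    "infeasible")
  res <- mc_constrained_sample(a, b, planted_model, cfg,
                               radius_a = 0.8 * d_ab, radius_b = 0.8 * d_ab,
                               topology = topo)
  for (rec in res$library$records) {
    expect_lte(dm_similarity(rec$geometry, a), 0.8 * d_ab)
    expect_lte(dm_similarity(rec$geometry, b), 0.8 * d_ab)
  }
})

test_that("infinite radii reduce the constrained sampler to plain basin-hopping", {
  a <- local_minimize(planted_model, planted_chain(35))$geometry
  b <- local_minimize(planted_model, planted_chain(145))$geometry
  cfg <- bh_config(thermal_energy = 0.5, n_steps = 80, dihedral_step = 30,
                   min_interatomic = 0.5, interaction_radius = 10,
                   energy_tol = 1e-5, similarity_tol = 0.05, seed = 12)
  topo <- make_torsion_chain(4)$topology
  free <- mc_constrained_sample(a, b, planted_model, cfg, Inf, Inf,
                                topology = topo)
  plain <- run_bh(planted_model, a, cfg, topology = topo)
  expect_equal(library_energies(free$library), library_energies(plain$library))
  expect_equal(free$log$decision, plain$log$decision)
})

test_that("the constrained sampler finds the planted intermediate within 200 steps", {
  a <- local_minimize(planted_model, planted_chain(35))$geometry
  b <- local_minimize(planted_model, planted_chain(145))$geometry
  d_ab <- dm_similarity(a, b)
  cfg <- bh_config(thermal_energy = 1, n_steps = 200, dihedral_step = 60,
                   min_interatomic = 0.5, interaction_radius = 10,
                   energy_tol = 1e-5, similarity_tol = 0.05, seed = 31)
  topo <- make_torsion_chain(4)$topology
  res <- mc_constrained_sample(a, b, planted_model, cfg,
                               radius_a = d_ab, radius_b = d_ab,
                               topology = topo)
  phis <- vapply(res$library$records, function(r)
    abs(dihedral_angles(r$geometry, list(1:4))), numeric(1))
  expect_true(any(abs(phis - 90) < 5))
})

test_that("TS-guess export writes an ordered 3-frame file and validates atom order", {
  set.seed(28)
  a <- rand_geometry(5, c("C", "C", "O", "H", "H"))
  b <- rand_geometry(5, c("C", "C", "O", "H", "H"))
  cc <- rand_geometry(5, c("C", "C", "O", "H", "H"))
  path <- withr::local_tempfile(fileext = ".xyz")
  ts_guess_export(a, cc, b, path)
  frames <- read_xyz(path)
  expect_length(frames, 3L)
  expect_match(frames[[1]]$label, "reactant")
  expect_match(frames[[2]]$label, "ts_guess")
  expect_match(frames[[3]]$label, "product")
  expect_lt(max(abs(frames[[1]]$coords - a$coords)), 1e-6)
  expect_lt(max(abs(frames[[2]]$coords - cc$coords)), 1e-6)
  expect_lt(max(abs(frames[[3]]$coords - b$coords)), 1e-6)
  bad <- rand_geometry(5, c("O", "C", "C", "H", "H"))
  expect_error(ts_guess_export(a, bad, b, path), "element order")
})
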