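test_that("perturbation respects null moves, bond rigidity and determinism", {
  ch <- make_torsion_chain(6, seed = 2)
  cfg0 <- bh_config(dihedral_step = 0, rigid_rot_step = 0,
                    translation_step = 0)
  same <- perturb(ch$geometry, cfg0, ch$topology)
  expect_equal(same$coords, ch$geometry$coords)
  cfg <- bh_config(dihedral_step = 25)
  set.seed(1)
  moved <- perturb(ch$geometry, cfg, ch$topology)
  bl <- function(g) sqrt(rowSums((g$coords[1:5, ] - g$coords[2:6, ])^2))
  expect_lt(max(abs(bl(moved) - bl(ch$geometry))), 1e-9)
  expect_gt(max(abs(moved$coords - ch$geometry$coords)), 1e-4)
  set.seed(77); a <- perturb(ch$geometry, cfg, ch$topology)
  set.seed(77); b <- perturb(ch$geometry, cfg, ch$topology)
  expect_identical(a$coords, b$coords)
})

test_that("rigid moiety moves preserve the moiety's internal distances exactly", {
  g <- make_lj_cluster(8, seed = 5)
  topo <- list(moieties = list(1:4, 5:8))
  cfg <- bh_config(rigid_rot_step = 30, translation_step = 1)
  set.seed(3)
  moved <- perturb(g, cfg, topo)
  for (idx in topo$moieties) {
    expect_lt(max(abs(distance_matrix(moved$coords[idx, ]) -
                        distance_matrix(g$coords[idx, ]))), 1e-9)
  }
  expect_gt(dm_similarity(moved, g), 1e-3)   # relative arrangement changed
})

test_that("screening rejects clashes and dissociation with informative reasons", {
  cfg <- bh_config(min_interatomic = 0.8, interaction_radius = 15)
  clash <- geometry(c("X", "X"), rbind(c(0, 0, 0), c(0.3, 0, 0)))
  s1 <- screen(clash, cfg)
  expect_false(s1$accept)
  expect_match(s1$reason, "clash.*1-2")
  far <- geometry(rep("X", 3),
                  rbind(c(0, 0, 0), c(1, 0, 0), c(50, 0, 0)))
  s2 <- screen(far, cfg)
  expect_false(s2$accept)
  expect_match(s2$reason, "dissociation")
  ok <- make_lj_cluster(5, seed = 2)
  expect_true(screen(ok, cfg)$accept)
  # bonded pairs are exempt from the clash rule
  chain <- make_torsion_chain(5, seed = 1)
  cfgb <- bh_config(min_interatomic = 1.05)
  expect_true(screen(chain$geometry, cfgb, chain$topology)$accept)
})

test_that("acceptance implements definite GM replacement and the Metropolis window", {
  cfg <- bh_config(thermal_energy = 1)
  set.seed(1)
  expect_identical(accept_step(-10, -5, -9, cfg), "replace_gm")
  expect_identical(accept_step(-5, -5, -9, cfg), "accept")
  expect_identical(accept_step(-6, -5, -9, cfg), "accept")
  # uphill by exactly kT: long-run acceptance frequency e^-1
  set.seed(42)
  acc <- sum(vapply(1:1e5, function(i)
    accept_step(1, 0, -100, cfg) == "accept", logical(1)))
  expect_equal(acc / 1e5, exp(-1), tolerance = 0.01 / exp(-1))
})

test_that("uniqueness registration needs both energy- and geometry-near to deduplicate", {
  cfg <- bh_config(energy_tol = 1e-3, similarity_tol = 1)
  g <- make_lj_cluster(4, seed = 1)
  lib <- minima_library()
  lib <- register_unique(lib, minimum_record(g, -5), cfg)$library
  r <- register_unique(lib, minimum_record(g, -5), cfg)
  expect_false(r$added)
  # energy-distinct duplicates in geometry are still unique
  r2 <- register_unique(lib, minimum_record(g, -5 + 2e-3), cfg)
  expect_true(r2$added)
  lib <- r2$library
  expect_equal(lib$e_low, -5)
  # geometry-distinct at equal energy is unique
  g2 <- make_lj_cluster(4, seed = 9)
  r3 <- register_unique(lib, minimum_record(g2, -5), cfg)
  expect_true(r3$added)
})

test_that("a planted set with three near-duplicates registers as seven minima", {
  cfg <- bh_config(energy_tol = 0.01, similarity_tol = 0.5)
  set.seed(8)
  base <- lapply(1:7, function(i) make_lj_cluster(4, seed = 100 + i))
  energies <- seq(-10, -4, by = 1)
  lib <- minima_library()
  for (i in 1:7)
    lib <- register_unique(lib, minimum_record(base[[i]], energies[i]),
                           cfg)$library
  # three near-duplicates: tiny coordinate jitter + energy inside tolerance
  for (i in c(1, 3, 5)) {
    gg <- base[[i]]
    gg$coords <- gg$coords + 1e-4
    lib <- register_unique(lib, minimum_record(gg, energies[i] + 1e-3),
                           cfg)$library
  }
  expect_length(lib, 7L)
})

test_that("basin-hopping runs are reproducible, track E_low monotonically and re-minimize idempotently", {
  lj <- lj_potential()
  cfg <- bh_config(thermal_energy = 0.5, n_steps = 60,
                   translation_step = 0.35, min_interatomic = 0.5,
                   interaction_radius = 10, similarity_tol = 50, seed = 7)
  start <- make_lj_cluster(6, seed = 7)
  r1 <- run_bh(lj, start, cfg)
  r2 <- run_bh(lj, start, cfg)
  expect_equal(r1$log, r2$log)
  expect_equal(library_energies(r1$library), library_energies(r2$library))
  expect_false(is.unsorted(rev(r1$log$e_low)))     # non-increasing
  expect_equal(r1$library$e_low, min(library_energies(r1$library)))
  for (rec in r1$library$records) {
    again <- local_minimize(lj, rec$geometry)
    expect_lt(abs(again$energy - rec$energy), 1e-6)
  }
})

test_that("zero-step runs register exactly the minimized start", {
  lj <- lj_potential()
  cfg <- bh_config(n_steps = 0, min_interatomic = 0.5,
                   interaction_radius = 10, seed = 3)
  r <- run_bh(lj, make_lj_cluster(5, seed = 3), cfg)
  expect_length(r$library, 1L)
  expect_identical(nrow(r$log), 0L)
  expect_equal(r$library$records[[1]]$energy, r$library$e_low)
})

test_that("higher thermal energy tolerates larger uphill accepted moves", {
  lj <- lj_potential()
  mean_uphill <- function(te, seed) {
    cfg <- bh_config(thermal_energy = te, n_steps = 250,
                     translation_step = 0.4, min_interatomic = 0.5,
                     interaction_radius = 10, similarity_tol = 50,
                     seed = seed)
    r <- run_bh(lj, make_lj_cluster(6, seed = seed), cfg)
    acc <- r$log[r$log$decision %in% c("accept", "replace_gm"), ]
    de <- diff(acc$energy)
    mean(pmax(de, 0))
  }
  lo <- mean(vapply(1:3, function(s) mean_uphill(0.2, s), numeric(1)))
  hi <- mean(vapply(1:3, function(s) mean_uphill(2.0, s), numeric(1)))
  expect_lt(lo, hi)
})
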