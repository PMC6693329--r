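test_that("XYZ round trip preserves symbols, coordinates, labels and energies", {
  path <- withr::local_tempfile(fileext = ".xyz")
  g1 <- geometry(c("O", "H", "H"),
                 rbind(c(0, 0, 0.1173), c(0, 0.7572, -0.4692),
                       c(0, -0.7572, -0.4692)),
                 label = "water", energy = -76.4)
  g2 <- rand_geometry(5, elements = c("C", "C", "N", "H", "H"))
  write_xyz(list(g1, g2), path)
  back <- read_xyz(path)
  expect_length(back, 2L)
  expect_identical(back[[1]]$elements, g1$elements)
  expect_identical(back[[2]]$elements, g2$elements)
  expect_lt(max(abs(back[[1]]$coords - g1$coords)), 1e-6)
  expect_lt(max(abs(back[[2]]$coords - g2$coords)), 1e-6)
  expect_match(back[[1]]$label, "water")
  expect_equal(back[[1]]$energy, -76.4)
})

test_that("XYZ parser reports malformed input with line numbers", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "bad coords", "H 0 0 0", "H 0 0 zz"), path)
  expect_error(read_xyz(path), "line 4.*non-numeric")
  writeLines(c("notanumber", "c", "H 0 0 0"), path)
  expect_error(read_xyz(path), "line 1.*malformed")
  writeLines(c("1", "c", "Qq 0 0 0"), path)
  expect_error(read_xyz(path), "unknown element")
})

test_that("distance matrix reproduces ruler and triangle geometries and is rigid-motion invariant", {
  ruler <- geometry(rep("X", 3), cbind(c(0, 1, 2), 0, 0))
  D <- distance_matrix(ruler)
  expect_equal(sort(D[upper.tri(D)]), c(1, 1, 2))
  tri <- geometry(rep("X", 3),
                  rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)))
  expect_equal(unname(distance_matrix(tri)[upper.tri(diag(3))]),
               rep(1, 3), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:5) {
    g <- rand_geometry(6)
    expect_lt(max(abs(distance_matrix(rand_rigid(g)) - distance_matrix(g))),
              1e-10)
  }
})

test_that("distance-matrix similarity matches hand-enumerated pairs and its axioms", {
  a <- geometry(rep("X", 3), cbind(c(0, 1, 2), 0, 0))
  b <- geometry(rep("X", 3), cbind(c(0, 1, 3), 0, 0))
  # pairs (1,2): |1-1|; (1,3): |2-3|; (2,3): |1-2|
  expect_equal(dm_similarity(a, b), 2)
  expect_equal(dm_similarity(a, a), 0)
  expect_equal(dm_similarity(a, b), dm_similarity(b, a))
  expect_error(dm_similarity(a, rand_geometry(4)), "different numbers")
})

test_that("element-constrained assignment never exceeds identity and tracks the exhaustive optimum", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    els <- sample(c("C", "O", "H"), n, replace = TRUE)
    a <- rand_geometry(n, els)
    b <- rand_geometry(n, sample(els))  # same composition, shuffled listing
    d_id <- dm_similarity(a, b)
    d_as <- dm_similarity(a, b, mapping = "assignment")
    expect_lte(d_as, d_id + 1e-12)
    # value realized by the mapping itself vs the exhaustive optimum
    p <- element_constrained_mapping(a, b)
    da <- distance_matrix(a); db <- distance_matrix(b)
    d_map <- sum(abs(da - db[p, p])[upper.tri(da)])
    best <- brute_force_mapping_value(a, b)
    expect_lte(d_map, best * 1.05 + 1e-9)
    expect_gte(d_map, best - 1e-9)
  }
})

test_that("element-constrained mapping recovers relabelings and respects element identity", {
  set.seed(21)
  a <- rand_geometry(6, c("C", "C", "O", "H", "H", "H"))
  rev_idx <- rev(seq_len(6))
  b <- geometry(a$elements[rev_idx], a$coords[rev_idx, ])
  p <- element_constrained_mapping(a, b)
  expect_identical(b$elements[p], a$elements)
  expect_equal(dm_similarity(a, b, mapping = "assignment"), 0, tolerance = 1e-9)
  w1 <- geometry(c("O", "H", "H"), rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  w2 <- geometry(c("H", "O", "H"), rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)))
  p2 <- element_constrained_mapping(w1, w2)
  expect_identical(w2$elements[p2], w1$elements)
  expect_error(element_constrained_mapping(w1, rand_geometry(3)),
               "composition")
})

test_that("mass-weighted vector has the analytic values and invariances", {
  single <- geometry("C", matrix(c(3, -1, 2), 1, 3))
  expect_equal(unclass(mass_weighted_vector(single)), 0,
               ignore_attr = TRUE)
  diat <- geometry(c("O", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)))
  v <- mass_weighted_vector(diat)
  expect_equal(as.numeric(v), rep(atomic_mass("O") * 0.6, 2))
  set.seed(5)
  g <- rand_geometry(7, sample(c("C", "N", "H"), 7, replace = TRUE))
  shifted <- transform_geometry(g, translation = c(12, -4, 7))
  expect_equal(as.numeric(mass_weighted_vector(shifted)),
               as.numeric(mass_weighted_vector(g)), tolerance = 1e-10)
  rot <- rand_rigid(g)
  expect_equal(as.numeric(mass_weighted_vector(rot)),
               as.numeric(mass_weighted_vector(g)), tolerance = 1e-8)
})

test_that("cosine distance evaluates analytically and stays in range", {
  expect_equal(cosine_distance(c(1, 1), c(1, 0)), acos(1 / sqrt(2)) / pi)
  expect_equal(cosine_distance(c(1, 1), c(1, 0)), 0.25)
  expect_equal(cosine_distance(c(2, 3, 4), c(2, 3, 4)), 0)
  expect_error(cosine_distance(c(0, 0), c(1, 0)), "zero-norm")
  set.seed(6)
  for (i in 1:20) {
    ra <- stats::runif(5); rb <- stats::runif(5)
    d <- cosine_distance(ra, rb)
    expect_gte(d, 0); expect_lte(d, 0.5)  # nonnegative vectors
  }
})

test_that("sorted mass-weighted vectors make the cosine metric relabeling-invariant", {
  set.seed(9)
  g <- rand_geometry(8, sample(c("C", "O", "H"), 8, replace = TRUE))
  idx <- sample(8)
  gp <- geometry(g$elements[idx], g$coords[idx, ])
  expect_equal(cosine_distance(mass_weighted_vector(g, sorted = TRUE),
                               mass_weighted_vector(gp, sorted = TRUE)), 0,
               tolerance = 1e-12)
})

test_that("container sizes scale quadratically (matrix) and linearly (vector)", {
  g10 <- rand_geometry(10)
  g20 <- rand_geometry(20)
  expect_identical(dim(distance_matrix(g10)), c(10L, 10L))
  expect_identical(dim(distance_matrix(g20)), c(20L, 20L))
  expect_length(mass_weighted_vector(g10), 10L)
  expect_length(mass_weighted_vector(g20), 20L)
})

test_that("distance tables round-trip through the labelled text format", {
  M <- distance_matrix(rand_geometry(4))
  dimnames(M) <- list(letters[1:4], letters[1:4])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distmat(M, path)
  back <- read_distmat(path)
  expect_equal(back, M, tolerance = 1e-10)
})
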