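# Shared test utilities: random geometries, random rigid motions, and
# brute-force oracles kept deliberately independent of the package
# implementations they check.

rand_geometry <- function(n, elements = NULL, spread = 3) {
  if (is.null(elements)) elements <- rep("X", n)
  geometry(elements, matrix(stats::runif(3 * n, -spread, spread), n, 3))
}

rand_rigid <- function(g) {
  axis <- stats::rnorm(3)
  ang <- stats::runif(1, 0, 360)
  shift <- stats::rnorm(3, sd = 5)
  transform_geometry(g, rotation_matrix(axis, ang), shift)
}

# exhaustive element-preserving permutation minimum of the
# distance-matrix similarity (feasible for n <= 6)
brute_force_mapping_value <- function(a, b) {
  da <- distance_matrix(a)
  db <- distance_matrix(b)
  n <- nrow(da)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  groups <- split(seq_len(n), a$elements)
  # cartesian product of per-element permutations of b's same-element atoms
  bgroups <- split(seq_len(n), b$elements)
  best <- Inf
  combine <- function(gi, p) {
    if (gi > length(groups)) {
      dd <- sum(abs(da - db[p, p])[upper.tri(da)])
      if (dd < best) best <<- dd
      return(invisible())
    }
    ia <- groups[[gi]]
    for (q in perms(bgroups[[names(groups)[gi]]])) {
      p2 <- p
      p2[ia] <- q
      combine(gi + 1L, p2)
    }
  }
  combine(1L, integer(n))
  best
}

# literal recursive WPGMA: repeatedly merge the nearest pair and average
# member distances, tracking flat member sets (not the package's
# matrix-shrinking loop)
wpgma_oracle <- function(M) {
  m <- nrow(M)
  clusters <- lapply(seq_len(m), identity)   # member leaf sets
  d <- function(ci, cj) {
    # recursive arithmetic-mean distance between two cluster trees
    if (length(ci) == 1L && length(cj) == 1L) return(M[ci[[1]], cj[[1]]])
    if (length(cj) > 1L && length(ci) == 1L) return(d(cj, ci))
    (d(ci[[1]], cj) + d(ci[[2]], cj)) / 2
  }
  heights <- numeric(m - 1L)
  pairs <- list()
  trees <- lapply(seq_len(m), function(i) i)
  ids <- -seq_len(m)
  for (s in seq_len(m - 1L)) {
    k <- length(trees)
    bi <- bj <- NA; bmin <- Inf
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      dij <- d(trees[[i]], trees[[j]])
      if (dij < bmin) { bmin <- dij; bi <- i; bj <- j }
    }
    heights[s] <- bmin
    pairs[[s]] <- sort(c(ids[bi], ids[bj]))
    newtree <- list(trees[[bi]], trees[[bj]])
    keep <- setdiff(seq_len(k), c(bi, bj))
    trees <- c(trees[keep], list(newtree))
    ids <- c(ids[keep], s)
  }
  list(heights = heights, pairs = pairs)
}

lj13_cfg <- function(seed) {
  bh_config(thermal_energy = 0.5, n_steps = 500, translation_step = 0.35,
            min_interatomic = 0.5, interaction_radius = 10,
            energy_tol = 1e-5, similarity_tol = 50, seed = seed)
}
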