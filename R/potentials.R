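# Pluggable model potentials with analytic gradients, plus a local
# minimizer. Every model is a "bh_potential": list(name, energy, gradient,
# units) where energy/gradient accept a bh_geometry or a bare n x 3
# coordinate matrix (the fast path used inside minimization loops).

#' Construct a potential-model object
#'
#' @param name model name.
#' @param energy function(geometry-or-coords) -> scalar.
#' @param gradient function(geometry-or-coords) -> n x 3 matrix
#'   (d energy / d coords).
#' @param units declared energy unit (free text).
#' @return object of class \code{"bh_potential"}.
#' @export
potential_model <- function(name, energy, gradient, units = "model") {
  structure(list(name = name, energy = energy, gradient = gradient,
                 units = units), class = "bh_potential")
}

#' @export
print.bh_potential <- function(x, ...) {
  cat(sprintf("<bh_potential> %s (units: %s)\n", x$name, x$units))
  invisible(x)
}

.pair_idx <- function(n) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = ut[, 1], j = ut[, 2])
}

# ----------------------------------------------------------- Lennard-Jones

#' Lennard-Jones cluster energy
#'
#' Pairwise-additive 4 eps ((sigma/r)^12 - (sigma/r)^6). The dimer minimum
#' sits at r = 2^(1/6) sigma with energy -eps. Reduced units
#' (eps = sigma = 1) are the default, the standard convention for
#' basin-hopping benchmarks.
#'
#' @param g geometry or n x 3 coordinate matrix (n >= 2).
#' @param epsilon well depth.
#' @param sigma zero-crossing distance.
#' @return scalar energy.
#' @export
lj_energy <- function(g, epsilon = 1, sigma = 1) {
  x <- .coords_of(g)
  r <- stats::dist(x)
  if (any(r < 1e-8 * sigma)) stop("coincident atoms: LJ energy overflows")
  s6 <- (sigma / r)^6
  sum(4 * epsilon * (s6^2 - s6))
}

.lj_gradient <- function(x, epsilon, sigma) {
  n <- nrow(x)
  px <- .pair_idx(n)
  d <- x[px$i, , drop = FALSE] - x[px$j, , drop = FALSE]
  r2 <- rowSums(d^2)
  s6 <- (sigma^2 / r2)^3
  # dE/dr * 1/r = -24 eps (2 s12 - s6) / r^2
  f <- -24 * epsilon * (2 * s6^2 - s6) / r2
  gmat <- matrix(0, n, 3)
  for (k in 1:3) {
    gk <- f * d[, k]
    gmat[, k] <- tapply(c(gk, -gk), c(px$i, px$j), sum)[as.character(1:n)]
  }
  gmat
}

#' Lennard-Jones potential model
#'
#' @param epsilon,sigma LJ parameters (reduced units by default).
#' @return a \code{"bh_potential"}.
#' @export
lj_potential <- function(epsilon = 1, sigma = 1) {
  potential_model(
    name = sprintf("lj(eps=%g, sigma=%g)", epsilon, sigma),
    energy = function(g) lj_energy(g, epsilon, sigma),
    gradient = function(g) .lj_gradient(.coords_of(g), epsilon, sigma),
    units = "epsilon"
  )
}

# ------------------------------------------------------- internal coords

.angle_val <- function(u, v) {
  c_ <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, c_)))
}

.dihedral_val <- function(x, q) {
  b1 <- x[q[2], ] - x[q[1], ]
  b2 <- x[q[3], ] - x[q[2], ]
  b3 <- x[q[4], ] - x[q[3], ]
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  -atan2(sum(m1 * n2), sum(n1 * n2))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angles of a geometry
#'
#' @param g geometry or coordinate matrix.
#' @param quads list of length-4 integer vectors (atom indices).
#' @return numeric vector of dihedral angles in degrees, in (-180, 180].
#' @export
dihedral_angles <- function(g, quads) {
  x <- .coords_of(g)
  vapply(quads, function(q) .dihedral_val(x, q) * 180 / pi, numeric(1))
}

# analytic gradient of one dihedral wrt the four atom positions
# (Blondel-Karplus formulation, matching .dihedral_val's sign convention)
.dihedral_grad <- function(x, q) {
  b1 <- x[q[2], ] - x[q[1], ]
  b2 <- x[q[3], ] - x[q[2], ]
  b3 <- x[q[4], ] - x[q[3], ]
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  b2n <- sqrt(sum(b2^2))
  g1 <- -b2n / sum(n1^2) * n1
  g4 <- b2n / sum(n2^2) * n2
  t1 <- sum(b1 * b2) / (sum(n1^2) * b2n)
  t2 <- sum(b3 * b2) / (sum(n2^2) * b2n)
  g2 <- -g1 + t1 * n1 + t2 * n2
  g3 <- -t1 * n1 - t2 * n2 - g4
  rbind(g1, g2, g3, g4)
}

# analytic gradient of the angle at (i, j, k) wrt the three positions
.angle_grad <- function(x, i, j, k) {
  u <- x[i, ] - x[j, ]; v <- x[k, ] - x[j, ]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  uh <- u / nu; vh <- v / nv
  c_ <- min(1, max(-1, sum(uh * vh)))
  s_ <- sqrt(max(1e-12, 1 - c_^2))
  gi <- (c_ * uh - vh) / (nu * s_)
  gk <- (c_ * vh - uh) / (nv * s_)
  rbind(gi, -(gi + gk), gk)
}

# ---------------------------------------------------------- torsion chain

#' Parameters of the toy torsional chain potential
#'
#' A linear chain (atom i bonded to i+1) whose conformational energy is a
#' cosine series in each dihedral plus a soft-sphere repulsion between
#' nonbonded atoms (|i - j| >= 3). Stiff harmonic bond-length and
#' bond-angle restraints anchor the chain to unit bonds and tetrahedral
#' angles so that unconstrained Cartesian minimization is well posed; on
#' that manifold (which the chain generator produces exactly) they
#' contribute zero and the energy is a function of the dihedral angles and
#' nonbonded distances only.
#'
#' @param amplitude torsion amplitude k (scalar or per-dihedral vector);
#'   each dihedral contributes k (1 + cos(mult * phi + phase)).
#' @param mult cosine multiplicity (default 3: minima at 60, 180, 300 deg).
#' @param phase phase offset in degrees.
#' @param rep_a soft-sphere repulsion prefactor A in A (sigma/r)^12.
#' @param rep_sigma soft-sphere diameter (Angstrom).
#' @param bond_k,angle_k harmonic restraint force constants.
#' @param r0 equilibrium bond length (Angstrom).
#' @param theta0 equilibrium angle (radians; default tetrahedral).
#' @return parameter list.
#' @export
torsion_params <- function(amplitude = 1, mult = 3, phase = 0,
                           rep_a = 0.05, rep_sigma = 1.0,
                           bond_k = 100, angle_k = 100,
                           r0 = 1, theta0 = acos(-1 / 3)) {
  list(amplitude = amplitude, mult = mult, phase = phase,
       rep_a = rep_a, rep_sigma = rep_sigma, bond_k = bond_k,
       angle_k = angle_k, r0 = r0, theta0 = theta0)
}

.chain_topology <- function(n) {
  if (n < 2L) stop("chain needs >= 2 atoms")
  dih <- if (n >= 4L) lapply(seq_len(n - 3L), function(i) i:(i + 3L)) else list()
  structure(list(
    bonds = cbind(seq_len(n - 1L), seq(2L, n)),
    angles = if (n >= 3L) lapply(seq_len(n - 2L), function(i) i:(i + 2L)) else list(),
    dihedrals = dih,
    n_atoms = n
  ), class = "bh_topology")
}

#' Torsional-chain energy
#'
#' @param g geometry or coordinate matrix (chain order = atom order).
#' @param params from \code{\link{torsion_params}}.
#' @param components if TRUE, return the named term decomposition.
#' @return scalar energy (or named vector when \code{components = TRUE}).
#' @export
torsion_chain_energy <- function(g, params = torsion_params(),
                                 components = FALSE) {
  x <- .coords_of(g)
  n <- nrow(x)
  if (n < 4L) stop("chain has no dihedral (need >= 4 atoms)")
  top <- .chain_topology(n)
  bl <- sqrt(rowSums((x[top$bonds[, 1], , drop = FALSE] -
                        x[top$bonds[, 2], , drop = FALSE])^2))
  e_bond <- sum(params$bond_k * (bl - params$r0)^2)
  e_ang <- sum(vapply(top$angles, function(a) {
    th <- .angle_val(x[a[1], ] - x[a[2], ], x[a[3], ] - x[a[2], ])
    params$angle_k * (th - params$theta0)^2
  }, numeric(1)))
  amp <- rep_len(params$amplitude, length(top$dihedrals))
  ph <- params$phase * pi / 180
  e_tor <- sum(vapply(seq_along(top$dihedrals), function(t) {
    phi <- .dihedral_val(x, top$dihedrals[[t]])
    amp[t] * (1 + cos(params$mult * phi + ph))
  }, numeric(1)))
  e_rep <- 0
  px <- .pair_idx(n)
  nb <- (px$j - px$i) >= 3L
  if (any(nb)) {
    r <- sqrt(rowSums((x[px$i[nb], , drop = FALSE] -
                         x[px$j[nb], , drop = FALSE])^2))
    e_rep <- sum(params$rep_a * (params$rep_sigma / r)^12)
  }
  if (components)
    c(bond = e_bond, angle = e_ang, torsion = e_tor, repulsion = e_rep)
  else e_bond + e_ang + e_tor + e_rep
}

.torsion_chain_gradient <- function(x, params) {
  n <- nrow(x)
  top <- .chain_topology(n)
  gmat <- matrix(0, n, 3)
  for (b in seq_len(nrow(top$bonds))) {
    i <- top$bonds[b, 1]; j <- top$bonds[b, 2]
    d <- x[i, ] - x[j, ]; r <- sqrt(sum(d^2))
    f <- 2 * params$bond_k * (r - params$r0) / r
    gmat[i, ] <- gmat[i, ] + f * d
    gmat[j, ] <- gmat[j, ] - f * d
  }
  for (a in top$angles) {
    th <- .angle_val(x[a[1], ] - x[a[2], ], x[a[3], ] - x[a[2], ])
    dg <- .angle_grad(x, a[1], a[2], a[3])
    f <- 2 * params$angle_k * (th - params$theta0)
    gmat[a, ] <- gmat[a, ] + f * dg
  }
  amp <- rep_len(params$amplitude, length(top$dihedrals))
  ph <- params$phase * pi / 180
  for (t in seq_along(top$dihedrals)) {
    q <- top$dihedrals[[t]]
    phi <- .dihedral_val(x, q)
    f <- -amp[t] * params$mult * sin(params$mult * phi + ph)
    gmat[q, ] <- gmat[q, ] + f * .dihedral_grad(x, q)
  }
  px <- .pair_idx(n)
  nb <- which((px$j - px$i) >= 3L)
  for (k in nb) {
    i <- px$i[k]; j <- px$j[k]
    d <- x[i, ] - x[j, ]; r2 <- sum(d^2)
    s12 <- (params$rep_sigma^2 / r2)^6
    f <- -12 * params$rep_a * s12 / r2
    gmat[i, ] <- gmat[i, ] + f * d
    gmat[j, ] <- gmat[j, ] - f * d
  }
  gmat
}

#' Torsional-chain potential model
#'
#' @param params from \code{\link{torsion_params}}.
#' @return a \code{"bh_potential"}.
#' @export
torsion_chain_potential <- function(params = torsion_params()) {
  potential_model(
    name = "torsion_chain",
    energy = function(g) torsion_chain_energy(g, params),
    gradient = function(g) .torsion_chain_gradient(.coords_of(g), params),
    units = "model"
  )
}

# --------------------------------------------------- artificial force field

#' Build the interpolation force field between two distance matrices
#'
#' Target distances rbar_ij = lambda D_A,ij + (1 - lambda) D_B,ij; the
#' field is a collection of harmonic terms with force constants inversely
#' proportional to rbar_ij:
#' V = chi sum_{i<j} (D_ij - rbar_ij)^2 / rbar_ij >= 0, zero iff the
#' geometry realizes rbar exactly.
#'
#' @param da,db endpoint distance matrices (equal dimension).
#' @param lambda interpolation factor in [0, 1] (1 returns D_A).
#' @param chi positive scale constant that facilitates optimization.
#' @return a \code{"bh_potential"} with extra fields \code{rbar},
#'   \code{chi}, \code{lambda}.
#' @export
artificial_ff <- function(da, db, lambda, chi = 1) {
  if (!all(dim(da) == dim(db))) stop("distance matrices differ in dimension")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (chi <= 0) stop("chi must be positive")
  rbar <- lambda * da + (1 - lambda) * db
  if (any(rbar[upper.tri(rbar)] <= 0))
    stop("ill-posed target: rbar has a non-positive off-diagonal entry")
  n <- nrow(rbar)
  px <- .pair_idx(n)
  rb <- rbar[upper.tri(rbar)]
  energy <- function(g) {
    x <- .coords_of(g)
    d <- sqrt(rowSums((x[px$i, , drop = FALSE] - x[px$j, , drop = FALSE])^2))
    chi * sum((d - rb)^2 / rb)
  }
  gradient <- function(g) {
    x <- .coords_of(g)
    dv <- x[px$i, , drop = FALSE] - x[px$j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    f <- chi * 2 * (d - rb) / (rb * d)
    gmat <- matrix(0, n, 3)
    for (k in 1:3) {
      gk <- f * dv[, k]
      gmat[, k] <- tapply(c(gk, -gk), c(px$i, px$j), sum)[as.character(1:n)]
    }
    gmat
  }
  m <- potential_model(sprintf("artificial_ff(lambda=%g, chi=%g)", lambda, chi),
                       energy, gradient, units = "chi Angstrom")
  m$rbar <- rbar; m$chi <- chi; m$lambda <- lambda
  m
}

#' Evaluate the artificial force field
#'
#' @param ff model from \code{\link{artificial_ff}}.
#' @param g geometry or coordinate matrix of matching dimension.
#' @return scalar V >= 0.
#' @export
artificial_ff_energy <- function(ff, g) {
  if (nrow(.coords_of(g)) != nrow(ff$rbar))
    stop("geometry dimension does not match force field")
  ff$energy(g)
}

# ------------------------------------------------------- local minimizer

#' Central-difference gradient of a potential model
#'
#' Testing utility for the model contract: every potential's analytic
#' gradient must agree with this within small relative error.
#'
#' @param model a \code{"bh_potential"}.
#' @param g geometry or coordinate matrix.
#' @param h step (Angstrom).
#' @return n x 3 finite-difference gradient.
#' @export
fd_gradient <- function(model, g, h = 1e-5) {
  x <- .coords_of(g)
  gmat <- matrix(0, nrow(x), 3)
  for (i in seq_len(nrow(x))) for (k in 1:3) {
    xp <- x; xp[i, k] <- xp[i, k] + h
    xm <- x; xm[i, k] <- xm[i, k] - h
    gmat[i, k] <- (model$energy(xp) - model$energy(xm)) / (2 * h)
  }
  gmat
}

#' Locally minimize a geometry on a model potential
#'
#' Quasi-Newton (L-BFGS-B) minimization with the model's analytic
#' gradient, restarted until the gradient max-norm falls below \code{tol}
#' or the iteration budget is exhausted.
#'
#' @param model a \code{"bh_potential"}.
#' @param g starting \code{bh_geometry}.
#' @param tol convergence threshold on the gradient max-norm
#'   (model units per Angstrom).
#' @param max_iter total iteration budget.
#' @return list with \code{geometry} (energy field filled in),
#'   \code{energy}, \code{converged}, \code{grad_norm}, \code{iterations}.
#' @export
local_minimize <- function(model, g, tol = 1e-6, max_iter = 2000) {
  x0 <- as.vector(.coords_of(g))
  nr <- length(x0) / 3
  fn <- function(x) {
    v <- tryCatch(model$energy(matrix(x, ncol = 3)), error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  gr <- function(x) {
    v <- tryCatch(as.vector(model$gradient(matrix(x, ncol = 3))),
                  error = function(e) rep(0, length(x)))
    v[!is.finite(v)] <- 0
    v
  }
  x <- x0
  used <- 0L
  grad_norm <- Inf
  for (round in 1:6) {
    budget <- max_iter - used
    if (budget <= 0) break
    res <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = budget, factr = 10,
                                       pgtol = tol / 10))
    x <- res$par
    used <- used + res$counts[1]
    grad_norm <- max(abs(gr(x)))
    if (grad_norm <= tol) break
  }
  e <- fn(x)
  if (!is.finite(e) || e >= 1e10)
    stop("divergence: non-finite energy at minimizer candidate")
  out <- g
  out$coords <- matrix(x, ncol = 3)
  out$energy <- e
  list(geometry = out, energy = e, converged = grad_norm <= tol,
       grad_norm = grad_norm, iterations = as.integer(used))
}
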