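# Seeded synthetic-data generators: every pipeline stage is testable with
# no external data and no electronic-structure engine. All generators are
# pure functions of their parameters and seed.

#' Random Lennard-Jones cluster start
#'
#' n atoms placed uniformly in a cube, rejection-resampled so no pair is
#' closer than \code{min_sep} (0.7 sigma by default).
#'
#' @param n atom count (>= 2).
#' @param seed RNG seed.
#' @param box cube side length (sigma units); default scales as n^(1/3).
#' @param min_sep minimum pair separation during placement.
#' @return a \code{bh_geometry} of pseudo-element \code{"X"} atoms.
#' @export
make_lj_cluster <- function(n, seed = 1L, box = NULL, min_sep = 0.7) {
  stopifnot(n >= 2)
  if (is.null(box)) box <- max(2, 1.4 * n^(1 / 3))
  set.seed(seed)
  x <- matrix(NA_real_, n, 3)
  x[1, ] <- stats::runif(3, 0, box)
  for (i in 2:n) {
    for (try in 1:10000) {
      cand <- stats::runif(3, 0, box)
      d2 <- rowSums(sweep(x[seq_len(i - 1L), , drop = FALSE], 2, cand)^2)
      if (all(d2 >= min_sep^2)) { x[i, ] <- cand; break }
    }
    if (anyNA(x[i, ])) stop("could not place atom ", i, "; box too small")
  }
  geometry(rep("X", n), x, label = sprintf("lj%d seed=%d", n, seed))
}

# place atom D given A, B, C and internals (r, theta, phi): standard
# NeRF construction
.place_atom <- function(A, B, C, r, theta, phi) {
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A; ab <- ab / sqrt(sum(ab^2))
  n <- .cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d <- r * c(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Random torsional chain
#'
#' Linear chain with unit bonds and tetrahedral angles; dihedrals drawn
#' uniformly on [0, 360). Returns the geometry together with its topology
#' (bonds, angles, rotatable dihedrals) for the move set.
#'
#' @param n_atoms chain length (>= 4).
#' @param seed RNG seed.
#' @param dihedrals optional explicit dihedral angles (degrees, length
#'   \code{n_atoms - 3}) overriding the random draw.
#' @param r0 bond length; \code{theta0} bond angle (radians).
#' @return list with \code{geometry} (a \code{bh_geometry}) and
#'   \code{topology}.
#' @export
make_torsion_chain <- function(n_atoms, seed = 1L, dihedrals = NULL,
                               r0 = 1, theta0 = acos(-1 / 3)) {
  stopifnot(n_atoms >= 4)
  set.seed(seed)
  if (is.null(dihedrals)) dihedrals <- stats::runif(n_atoms - 3L, 0, 360)
  stopifnot(length(dihedrals) == n_atoms - 3L)
  x <- matrix(0, n_atoms, 3)
  x[2, ] <- c(r0, 0, 0)
  x[3, ] <- x[2, ] + r0 * c(-cos(theta0), sin(theta0), 0)
  for (i in seq(4L, n_atoms)) {
    x[i, ] <- .place_atom(x[i - 3L, ], x[i - 2L, ], x[i - 1L, ],
                          r0, theta0, dihedrals[i - 3L] * pi / 180)
  }
  list(geometry = geometry(rep("X", n_atoms), x,
                           label = sprintf("chain%d seed=%d", n_atoms, seed)),
       topology = .chain_topology(n_atoms))
}

#' Idealized difluoroethene-like isomer set
#'
#' Three planar C2H2F2 isomers (cis-1,2, trans-1,2, 1,1) built from
#' idealized bond lengths (C=C 1.33, C-F 1.35, C-H 1.08 Angstrom) and
#' 120-degree sp2 angles. These support qualitative clustering checks
#' (the two 1,2 isomers are geometrically closer to each other than to
#' the 1,1 isomer); they are idealized constructions, not optimized
#' geometries.
#'
#' @return named list of three \code{bh_geometry} objects
#'   (\code{cis}, \code{trans}, \code{geminal}).
#' @export
make_difluoroethene_set <- function() {
  cc <- 1.33 / 2; cf <- 1.35; ch <- 1.08
  up_l <- c(-0.5, sin(2 * pi / 3)); up_r <- c(0.5, sin(2 * pi / 3))
  dn_l <- c(-0.5, -sin(2 * pi / 3)); dn_r <- c(0.5, -sin(2 * pi / 3))
  c1 <- c(-cc, 0); c2 <- c(cc, 0)
  pl <- function(p) c(p, 0)  # embed in z = 0 plane
  els <- c("C", "C", "F", "F", "H", "H")
  cis <- geometry(els, rbind(pl(c1), pl(c2),
                             pl(c1 + cf * up_l), pl(c2 + cf * up_r),
                             pl(c1 + ch * dn_l), pl(c2 + ch * dn_r)),
                  label = "cis-1,2-difluoroethene (idealized)")
  trans <- geometry(els, rbind(pl(c1), pl(c2),
                               pl(c1 + cf * up_l), pl(c2 + cf * dn_r),
                               pl(c1 + ch * dn_l), pl(c2 + ch * up_r)),
                    label = "trans-1,2-difluoroethene (idealized)")
  geminal <- geometry(els, rbind(pl(c1), pl(c2),
                                 pl(c1 + cf * up_l), pl(c1 + cf * dn_l),
                                 pl(c2 + ch * up_r), pl(c2 + ch * dn_r)),
                      label = "1,1-difluoroethene (idealized)")
  list(cis = cis, trans = trans, geminal = geminal)
}

#' Synthetic spectra set with a planted carrier
#'
#' Random stick spectra for \code{n_isomers} isomers; one isomer is
#' designated the carrier and its fully processed spectrum, perturbed by
#' multiplicative Gaussian intensity noise and re-normalized per region,
#' becomes the "experiment". Unscaled line positions are drawn so that
#' the scaled lines stay inside the region grids.
#'
#' @param n_isomers number of candidate isomers.
#' @param lines_per_region stick lines per isomer per region.
#' @param regions from \code{\link{spectral_regions}}.
#' @param noise multiplicative noise level (0.05 = 5 percent).
#' @param fwhm Lorentzian FWHM used to process the planted experiment.
#' @param seed RNG seed.
#' @return list: \code{spectra} (list of \code{"bh_lines"}),
#'   \code{experiment} (a \code{"bh_grid"}), \code{carrier} (label),
#'   \code{carrier_index}.
#' @export
make_spectra_set <- function(n_isomers = 10, lines_per_region = 10,
                             regions = spectral_regions(), noise = 0.05,
                             fwhm = 15, seed = 1L) {
  stopifnot(n_isomers >= 1, lines_per_region >= 1)
  set.seed(seed)
  spectra <- lapply(seq_len(n_isomers), function(i) {
    fr <- unlist(lapply(seq_len(nrow(regions)), function(r) {
      lo <- min(regions$hi[r], regions$lo[r] / regions$scale_factor[r])
      stats::runif(lines_per_region, lo, regions$hi[r])
    }))
    line_spectrum(fr, stats::runif(length(fr), 0.1, 1),
                  label = sprintf("isomer%02d", i))
  })
  carrier_index <- sample.int(n_isomers, 1)
  proc <- process_spectrum(spectra[[carrier_index]], regions, fwhm)
  inten <- proc$intensity * (1 + noise * stats::rnorm(length(proc$intensity)))
  inten <- pmax(inten, 0)
  ends <- cumsum(proc$regions$n)
  starts <- c(1, utils::head(ends, -1) + 1)
  for (r in seq_along(ends)) {
    idx <- starts[r]:ends[r]
    mx <- max(inten[idx])
    if (mx > 0) inten[idx] <- inten[idx] / mx
  }
  experiment <- proc
  experiment$intensity <- inten
  experiment$label <- "experiment"
  list(spectra = spectra, experiment = experiment,
       carrier = spectra[[carrier_index]]$label,
       carrier_index = carrier_index)
}

#' Analytic two-state conformer ensemble
#'
#' Two conformers: a compact reference (dG_rel = 0 at all T) and an
#' entropy-favoured extended conformer with dG(T) = dH - T dS, giving a
#' closed-form population crossover at T = dH / dS. The defaults place
#' the crossover at 420 K with CCS values 148 and 160 Angstrom^2.
#'
#' @param dH enthalpy difference extended - compact (kJ/mol, > 0).
#' @param dS entropy difference (J/mol/K, != 0).
#' @param omegas length-2 CCS vector (compact, extended; Angstrom^2).
#' @param temperatures ensemble temperature grid (K).
#' @return a \code{"bh_ensemble"}; the closed-form crossover is in
#'   attribute \code{"T_cross"}.
#' @export
make_two_state_ensemble <- function(dH = 10.5, dS = 25,
                                    omegas = c(148, 160),
                                    temperatures = seq(300, 800, by = 10)) {
  stopifnot(dS != 0, length(omegas) == 2)
  ens <- conformer_ensemble(labels = c("compact", "extended"),
                            ccs = omegas, dH = c(0, dH), dS = c(0, dS),
                            temperatures = temperatures)
  attr(ens, "T_cross") <- dH * 1000 / dS
  ens
}
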