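# Ensemble ion mobility: Boltzmann conformer populations versus
# temperature, Gibbs-energy crossover, a projection-approximation CCS
# estimator, the Mason-Schamp low-field mobility and Boltzmann-weighted
# CCS(T) curves.

.R_GAS <- 8.314462618      # J mol^-1 K^-1
.KB <- 1.380649e-23        # J K^-1
.E_CHARGE <- 1.602176634e-19  # C
.AMU <- 1.66053906660e-27  # kg

#' Construct a conformer ensemble
#'
#' Per-conformer relative Gibbs energies and collision cross sections.
#' Thermochemistry can be analytic (\code{dH} kJ/mol and \code{dS}
#' J/mol/K giving dG(T) = dH - T dS) or tabulated (long table
#' \code{conformer, T, dG_rel} in kJ/mol, linearly interpolated in T).
#' Exactly one conformer must be the reference (dG_rel = 0 at the
#' reference temperature).
#'
#' @param labels conformer labels.
#' @param ccs per-conformer collision cross sections (Angstrom^2, > 0).
#' @param dH,dS analytic thermochemistry (kJ/mol; J/mol/K).
#' @param dG_table long data.frame (conformer, T, dG_rel) alternative.
#' @param temperatures ensemble temperature grid (K), default
#'   300-800 K in 10 K steps.
#' @param reference_T temperature at which the reference conformer is
#'   checked (K).
#' @return object of class \code{"bh_ensemble"}.
#' @export
conformer_ensemble <- function(labels, ccs, dH = NULL, dS = NULL,
                               dG_table = NULL,
                               temperatures = seq(300, 800, by = 10),
                               reference_T = 300) {
  labels <- as.character(labels)
  m <- length(labels)
  stopifnot(length(ccs) == m, all(ccs > 0),
            all(temperatures > 0), !is.unsorted(temperatures))
  if (is.null(dG_table)) {
    stopifnot(length(dH) == m, length(dS) == m)
    dG_fun <- function(Tk)
      dH - Tk * dS / 1000   # kJ/mol
  } else {
    tab <- as.data.frame(dG_table)
    names(tab)[1:3] <- c("conformer", "T", "dG_rel")
    dG_fun <- function(Tk) {
      vapply(labels, function(lb) {
        sub <- tab[tab$conformer == lb, , drop = FALSE]
        if (Tk < min(sub$T) || Tk > max(sub$T))
          stop(sprintf("T = %g K outside tabulated range for %s", Tk, lb))
        stats::approx(sub$T, sub$dG_rel, xout = Tk)$y
      }, numeric(1))
    }
  }
  g_ref <- dG_fun(reference_T)
  if (abs(min(g_ref)) > 1e-9)
    stop("the reference conformer (dG_rel = 0 at the reference temperature) is missing")
  structure(list(labels = labels, ccs = as.numeric(ccs), dG = dG_fun,
                 temperatures = as.numeric(temperatures),
                 reference = labels[which.min(abs(g_ref))],
                 dH = dH, dS = dS),
            class = "bh_ensemble")
}

#' @export
print.bh_ensemble <- function(x, ...) {
  cat(sprintf("<bh_ensemble> %d conformers (ref: %s), T grid %g-%g K\n",
              length(x$labels), x$reference, min(x$temperatures),
              max(x$temperatures)))
  invisible(x)
}

#' Boltzmann populations of an ensemble at temperature T
#'
#' Relative populations N_i = exp(-dG_rel,i / RT) with the reference
#' conformer at 1 (molar Gibbs energies, so the gas constant R is used),
#' returned normalized to fractions summing to 1.
#'
#' @param ens a \code{"bh_ensemble"}.
#' @param T temperature (K).
#' @return named numeric vector of fractions.
#' @export
populations <- function(ens, T) {
  dG <- ens$dG(T)                       # kJ/mol
  rel <- exp(-dG * 1000 / (.R_GAS * T))
  out <- rel / sum(rel)
  names(out) <- ens$labels
  out
}

#' Gibbs-energy crossover temperature of two conformers
#'
#' With analytic thermochemistry, the dG(T) curves of two conformers
#' cross at T = ddH / ddS; their populations are equal there.
#'
#' @param ens a \code{"bh_ensemble"} built from \code{dH}/\code{dS}.
#' @param c1,c2 conformer labels or indices.
#' @return crossover temperature (K).
#' @export
crossover_temperature <- function(ens, c1 = 1, c2 = 2) {
  if (is.null(ens$dH)) stop("analytic dH/dS thermochemistry required")
  i <- if (is.character(c1)) match(c1, ens$labels) else c1
  j <- if (is.character(c2)) match(c2, ens$labels) else c2
  ddH <- ens$dH[i] - ens$dH[j]          # kJ/mol
  ddS <- ens$dS[i] - ens$dS[j]          # J/mol/K
  if (abs(ddS) < 1e-12)
    stop("no crossover: the two conformers have equal entropy")
  Tc <- ddH * 1000 / ddS
  if (Tc <= 0) stop("no physical crossover (negative temperature)")
  Tc
}

# Bondi-style van der Waals radii (Angstrom) for the projection stand-in.
.vdw_radii <- c(H = 1.10, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98,
                X = 1.00)

#' Projection-approximation collision cross section
#'
#' Orientationally averaged projected area of the union of atom-centred
#' disks (radius = element van der Waals radius + probe radius),
#' estimated by seeded Monte Carlo over uniform random orientations and
#' sample points. This is a geometric stand-in, not a trajectory-method
#' CCS: it ignores long-range ion-neutral interactions and scattering,
#' so absolute values are not comparable with trajectory-method results.
#'
#' @param g a \code{bh_geometry}.
#' @param radii named element-radius table (Angstrom).
#' @param probe probe (buffer-gas) radius added to every atom (Angstrom).
#' @param n_orientations number of random orientations.
#' @param n_rays Monte Carlo sample points per orientation.
#' @param seed RNG seed.
#' @return scalar CCS (Angstrom^2) with attribute \code{"se"} (standard
#'   error over orientations).
#' @export
pa_ccs <- function(g, radii = NULL, probe = 1.0, n_orientations = 300,
                   n_rays = 2000, seed = 1L) {
  stopifnot(n_orientations > 0, n_rays > 0)
  rt <- .vdw_radii
  if (!is.null(radii)) rt[names(radii)] <- radii
  r <- rt[g$elements]
  if (anyNA(r))
    stop("no radius tabulated for element(s): ",
         paste(unique(g$elements[is.na(r)]), collapse = ", "))
  r <- unname(r) + probe
  x <- sweep(g$coords, 2, colMeans(g$coords))
  set.seed(seed)
  areas <- numeric(n_orientations)
  for (o in seq_len(n_orientations)) {
    # uniform random rotation via normalized quaternion
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    R <- .quat_to_rot(q)
    p <- x %*% t(R)
    px <- p[, 1]; py <- p[, 2]
    xlim <- range(px) + c(-1, 1) * max(r)
    ylim <- range(py) + c(-1, 1) * max(r)
    sx <- stats::runif(n_rays, xlim[1], xlim[2])
    sy <- stats::runif(n_rays, ylim[1], ylim[2])
    inside <- rep(FALSE, n_rays)
    for (a in seq_along(px)) {
      inside <- inside | ((sx - px[a])^2 + (sy - py[a])^2 <= r[a]^2)
    }
    areas[o] <- mean(inside) * diff(xlim) * diff(ylim)
  }
  est <- mean(areas)
  attr(est, "se") <- stats::sd(areas) / sqrt(n_orientations)
  est
}

.quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Ion-mobility experiment parameters
#'
#' @param m_ion ion mass (u).
#' @param m_gas buffer-gas mass (u; 28.0062 for N2).
#' @param z integer charge state (>= 1).
#' @param temperature temperature (K).
#' @param N gas number density (m^-3); if missing, derived from
#'   \code{pressure} via the ideal gas law.
#' @param pressure gas pressure (Pa), used only when \code{N} is missing.
#' @return parameter list of class \code{"bh_mobility_params"}.
#' @export
mobility_params <- function(m_ion, m_gas = 28.0062, z = 1L,
                            temperature = 298, N = NULL,
                            pressure = 101325) {
  stopifnot(m_ion > 0, m_gas > 0, z >= 1, temperature > 0)
  if (is.null(N)) N <- pressure / (.KB * temperature)
  stopifnot(N > 0)
  structure(list(m_ion = m_ion, m_gas = m_gas, z = as.integer(z),
                 temperature = temperature, N = N),
            class = "bh_mobility_params")
}

#' Mason-Schamp low-field ion mobility
#'
#' K = (3/16) (z e / N) sqrt(2 pi / (mu k_B T)) / Omega with reduced mass
#' 1/mu = 1/m_ion + 1/m_gas. SI units internally; the CCS is supplied in
#' Angstrom^2 and converted.
#'
#' @param p a \code{\link{mobility_params}}.
#' @param omega collision cross section (Angstrom^2, > 0).
#' @return mobility K (m^2 V^-1 s^-1).
#' @export
mason_schamp <- function(p, omega) {
  if (omega <= 0) stop("CCS must be positive")
  mu <- 1 / (1 / (p$m_ion * .AMU) + 1 / (p$m_gas * .AMU))
  omega_m2 <- omega * 1e-20
  (3 / 16) * (p$z * .E_CHARGE / p$N) *
    sqrt(2 * pi / (mu * .KB * p$temperature)) / omega_m2
}

#' Boltzmann-weighted CCS versus temperature
#'
#' Omega_B(T) = sum_i f_i(T) Omega_i with f the normalized Boltzmann
#' fractions; always bounded by the ensemble's min and max CCS.
#'
#' @param ens a \code{"bh_ensemble"}.
#' @param temperatures evaluation grid (K), default the ensemble grid.
#' @return data.frame (T, ccs) of class \code{"bh_ccs_curve"}.
#' @export
weighted_ccs_curve <- function(ens, temperatures = ens$temperatures) {
  ccs <- vapply(temperatures, function(Tk)
    sum(populations(ens, Tk) * ens$ccs), numeric(1))
  structure(data.frame(T = temperatures, ccs = ccs),
            class = c("bh_ccs_curve", "data.frame"))
}

#' @export
plot.bh_ccs_curve <- function(x, ...) {
  plot(x$T, x$ccs, type = "l", xlab = "T (K)",
       ylab = expression(Omega[B] ~ (ring(A)^2)), ...)
  invisible(x)
}
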