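# The basin-hopping loop: perturbation moves, pre-optimization screening,
# dual acceptance criteria (definite GM replacement + Metropolis window),
# and uniqueness registration of local minima.

#' Basin-hopping run configuration
#'
#' The "pre-defined energy window" of the conditional acceptance step is a
#' Metropolis criterion exp(-dE / thermal_energy), so \code{thermal_energy}
#' is the k_B T of the acceptance distribution in model energy units.
#' Default move ranges are the dihedral / rigid-rotation / translation
#' amplitudes used for the protonated-dimer search (5 deg, 5 deg, 0.5 A);
#' the uniqueness thresholds default to dE >= 1e-5 and 50.0 A on the
#' distance-matrix similarity.
#'
#' @param thermal_energy acceptance-window k_B T (model units, > 0).
#' @param n_steps number of basin-hopping steps (>= 0).
#' @param dihedral_step max dihedral move, degrees.
#' @param rigid_rot_step max rigid body-axis rotation per moiety, degrees.
#' @param translation_step max Cartesian translation, Angstrom.
#' @param min_interatomic screening threshold: reject candidates with a
#'   nonbonded pair closer than this (Angstrom).
#' @param interaction_radius dissociation guard: reject candidates with an
#'   atom farther than this from the centre of mass (Angstrom).
#' @param energy_tol uniqueness energy threshold dE.
#' @param similarity_tol uniqueness distance-matrix threshold (Angstrom).
#' @param seed RNG seed for the run.
#' @param min_tol,min_max_iter tolerances handed to
#'   \code{\link{local_minimize}}.
#' @return object of class \code{"bh_config"}.
#' @export
bh_config <- function(thermal_energy = 0.5, n_steps = 100,
                      dihedral_step = 5, rigid_rot_step = 5,
                      translation_step = 0.5, min_interatomic = 0.8,
                      interaction_radius = 15, energy_tol = 1e-5,
                      similarity_tol = 50, seed = 1L,
                      min_tol = 1e-6, min_max_iter = 2000) {
  stopifnot(thermal_energy > 0, n_steps >= 0, dihedral_step >= 0,
            rigid_rot_step >= 0, translation_step >= 0)
  structure(list(thermal_energy = thermal_energy, n_steps = as.integer(n_steps),
                 dihedral_step = dihedral_step, rigid_rot_step = rigid_rot_step,
                 translation_step = translation_step,
                 min_interatomic = min_interatomic,
                 interaction_radius = interaction_radius,
                 energy_tol = energy_tol, similarity_tol = similarity_tol,
                 seed = as.integer(seed), min_tol = min_tol,
                 min_max_iter = as.integer(min_max_iter)),
            class = "bh_config")
}

# rotate the tail atoms (> pivot position in chain order) about the
# bond axis j -> k by `angle` degrees
.rotate_dihedral <- function(x, j, k, moved, angle) {
  axis <- x[k, ] - x[j, ]
  R <- rotation_matrix(axis, angle)
  piv <- x[k, ]
  x[moved, ] <- sweep(sweep(x[moved, , drop = FALSE], 2, piv) %*% t(R), 2,
                      piv, "+")
  x
}

#' Randomly perturb a geometry
#'
#' The move set is resolved from the topology: chains get uniform dihedral
#' twists of up to \code{dihedral_step} degrees per rotatable dihedral
#' (bonded distances are preserved exactly, up to rounding); topologies
#' with \code{moieties} additionally give each movable moiety a rigid
#' rotation of up to \code{rigid_rot_step} degrees about each body-fixed
#' axis and a translation of up to \code{translation_step} Angstrom per
#' direction. With no topology every atom is translated independently
#' (the standard cluster move).
#'
#' Randomness comes from the R session RNG; seed it (or use
#' \code{\link{run_bh}}, which seeds from its config) for reproducibility.
#'
#' @param g a \code{bh_geometry}.
#' @param cfg a \code{\link{bh_config}}.
#' @param topology \code{NULL}, or a list with \code{dihedrals} (length-4
#'   index vectors, chain convention: atoms after the third move) and/or
#'   \code{moieties} (list of atom-index vectors moved rigidly).
#' @return perturbed \code{bh_geometry}.
#' @export
perturb <- function(g, cfg, topology = NULL) {
  x <- g$coords
  n <- nrow(x)
  moved_any <- FALSE
  if (!is.null(topology) && length(topology$dihedrals)) {
    for (q in topology$dihedrals) {
      if (cfg$dihedral_step > 0) {
        ang <- stats::runif(1, -cfg$dihedral_step, cfg$dihedral_step)
        x <- .rotate_dihedral(x, q[2], q[3], (q[3] + 1L):n, ang)
      }
    }
    moved_any <- TRUE
  }
  if (!is.null(topology) && length(topology$moieties)) {
    for (idx in topology$moieties) {
      sub <- x[idx, , drop = FALSE]
      cen <- colMeans(sub)
      if (cfg$rigid_rot_step > 0) {
        for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
          ang <- stats::runif(1, -cfg$rigid_rot_step, cfg$rigid_rot_step)
          sub <- sweep(sweep(sub, 2, cen) %*% t(rotation_matrix(ax, ang)),
                       2, cen, "+")
        }
      }
      if (cfg$translation_step > 0)
        sub <- sweep(sub, 2,
                     stats::runif(3, -cfg$translation_step,
                                  cfg$translation_step), "+")
      x[idx, ] <- sub
    }
    moved_any <- TRUE
  }
  if (!moved_any) {
    if (is.null(topology) || (is.null(topology$dihedrals) &&
                              is.null(topology$moieties))) {
      if (cfg$translation_step > 0)
        x <- x + matrix(stats::runif(3 * n, -cfg$translation_step,
                                     cfg$translation_step), n, 3)
    } else {
      stop("topology has no movable degrees of freedom")
    }
  }
  g$coords <- x
  g
}

#' Screen a candidate geometry before optimization
#'
#' Rejects structures with a nonbonded interatomic distance below
#' \code{min_interatomic} (clash) or an atom farther than
#' \code{interaction_radius} from the centre of mass (dissociation guard).
#'
#' @param g a \code{bh_geometry}.
#' @param cfg a \code{\link{bh_config}}.
#' @param topology optional topology; bonded pairs are exempt from the
#'   clash rule.
#' @return list with \code{accept} (logical) and \code{reason} (string
#'   naming the violated rule and atom pair, or \code{"ok"}).
#' @export
screen <- function(g, cfg, topology = NULL) {
  x <- g$coords
  n <- nrow(x)
  if (n >= 2L) {
    D <- distance_matrix(x)
    bonded <- matrix(FALSE, n, n)
    if (!is.null(topology) && !is.null(topology$bonds)) {
      b <- topology$bonds
      bonded[cbind(b[, 1], b[, 2])] <- TRUE
      bonded[cbind(b[, 2], b[, 1])] <- TRUE
    }
    viol <- which(upper.tri(D) & D < cfg$min_interatomic & !bonded,
                  arr.ind = TRUE)
    if (nrow(viol)) {
      return(list(accept = FALSE,
                  reason = sprintf("clash: atoms %d-%d at %.3f A < %.3f A",
                                   viol[1, 1], viol[1, 2],
                                   D[viol[1, 1], viol[1, 2]],
                                   cfg$min_interatomic)))
    }
  }
  com <- colSums(x * g$masses) / sum(g$masses)
  rc <- sqrt(rowSums(sweep(x, 2, com)^2))
  if (any(rc > cfg$interaction_radius)) {
    i <- which.max(rc)
    return(list(accept = FALSE,
                reason = sprintf("dissociation: atom %d at %.2f A > %.2f A from COM",
                                 i, rc[i], cfg$interaction_radius)))
  }
  list(accept = TRUE, reason = "ok")
}

#' Basin-hopping acceptance decision
#'
#' Two criteria, mirroring the general BH procedure: a new minimum below
#' the current global minimum replaces it unconditionally
#' (\code{"replace_gm"}); otherwise the move is accepted with Metropolis
#' probability min(1, exp(-(e_new - e_current) / thermal_energy)), so
#' downhill moves are always accepted.
#'
#' @param e_new energy of the newly minimized structure.
#' @param e_current energy of the current accepted structure.
#' @param e_low current global-minimum energy.
#' @param cfg a \code{\link{bh_config}}.
#' @return one of \code{"replace_gm"}, \code{"accept"}, \code{"reject"}.
#' @export
accept_step <- function(e_new, e_current, e_low, cfg) {
  stopifnot(is.finite(e_new), is.finite(e_current), !is.nan(e_low))
  if (e_new < e_low) return("replace_gm")
  if (e_new <= e_current) return("accept")
  p <- exp(-(e_new - e_current) / cfg$thermal_energy)
  if (stats::runif(1) < p) "accept" else "reject"
}

#' Create a minimum record
#'
#' @param geometry converged \code{bh_geometry}.
#' @param energy its minimized energy.
#' @param step_found basin-hopping step index (0 = the start structure).
#' @param provenance \code{"bh"} or \code{"interpolation"}.
#' @return object of class \code{"bh_minimum"}.
#' @export
minimum_record <- function(geometry, energy, step_found = 0L,
                           provenance = c("bh", "interpolation")) {
  provenance <- match.arg(provenance)
  structure(list(geometry = geometry, energy = energy,
                 step_found = as.integer(step_found),
                 provenance = provenance),
            class = "bh_minimum")
}

#' Create an empty minima library
#'
#' Ordered registry of deduplicated local minima with the running
#' global-minimum energy \code{e_low}.
#'
#' @return object of class \code{"bh_minima"}.
#' @export
minima_library <- function() {
  structure(list(records = list(), e_low = Inf), class = "bh_minima")
}

#' @export
length.bh_minima <- function(x) length(x$records)

#' @export
print.bh_minima <- function(x, ...) {
  cat(sprintf("<bh_minima> %d unique minima; E_low = %s\n", length(x),
              if (is.finite(x$e_low)) sprintf("%.8g", x$e_low) else "none"))
  invisible(x)
}

#' Energies stored in a minima library
#' @param lib a \code{bh_minima}.
#' @return numeric vector, in registration order.
#' @export
library_energies <- function(lib) {
  vapply(lib$records, function(r) r$energy, numeric(1))
}

#' Register a minimum if it is unique
#'
#' A candidate is a duplicate of a stored record only when it is close in
#' BOTH senses: |dE| < \code{energy_tol} AND distance-matrix similarity <
#' \code{similarity_tol}. It is added iff no stored record duplicates it,
#' and \code{e_low} is updated.
#'
#' @param lib a \code{bh_minima}.
#' @param rec a \code{\link{minimum_record}}.
#' @param cfg a \code{\link{bh_config}} supplying the two thresholds.
#' @return list with the updated \code{library} and logical \code{added}.
#' @export
register_unique <- function(lib, rec, cfg) {
  dup <- FALSE
  for (r in lib$records) {
    if (abs(r$energy - rec$energy) < cfg$energy_tol &&
        dm_similarity(r$geometry, rec$geometry) < cfg$similarity_tol) {
      dup <- TRUE
      break
    }
  }
  if (!dup) {
    lib$records[[length(lib$records) + 1L]] <- rec
    lib$e_low <- min(lib$e_low, rec$energy)
  }
  list(library = lib, added = !dup)
}

#' Run a basin-hopping search
#'
#' Executes \code{n_steps} of perturb -> screen -> local minimization ->
#' acceptance -> uniqueness registration, from a locally minimized start.
#' Every converged minimized structure is offered to the library
#' (acceptance only steers the walker); screened-out candidates consume a
#' step and are logged with the violated rule. Fully reproducible under
#' the config seed.
#'
#' @param model a \code{"bh_potential"}.
#' @param start starting \code{bh_geometry}; must pass screening after
#'   initial minimization.
#' @param cfg a \code{\link{bh_config}}.
#' @param topology optional move-set/bond topology (see
#'   \code{\link{perturb}}).
#' @param constraint optional predicate \code{function(geometry)}; a
#'   minimized candidate failing it is rejected before the acceptance
#'   step and never registered (used by the similarity-constrained
#'   Monte Carlo sampler). With no constraint the loop is the plain
#'   basin-hopping algorithm.
#' @return object of class \code{"bh_result"}: \code{library}
#'   (\code{bh_minima}), \code{log} (one row per step: energy, decision,
#'   reason, running \code{e_low}), \code{config}, \code{model_name}.
#' @export
run_bh <- function(model, start, cfg, topology = NULL, constraint = NULL) {
  set.seed(cfg$seed)
  m0 <- local_minimize(model, start, tol = cfg$min_tol,
                       max_iter = cfg$min_max_iter)
  sc0 <- screen(m0$geometry, cfg, topology)
  if (!sc0$accept)
    stop("initial structure fails screening after minimization: ", sc0$reason)
  lib <- minima_library()
  if (is.null(constraint) || isTRUE(constraint(m0$geometry)))
    lib <- register_unique(lib, minimum_record(m0$geometry, m0$energy, 0L,
                                               "bh"), cfg)$library
  current <- m0$geometry
  e_current <- m0$energy
  log <- vector("list", cfg$n_steps)
  for (step in seq_len(cfg$n_steps)) {
    cand <- perturb(current, cfg, topology)
    sc <- screen(cand, cfg, topology)
    if (!sc$accept) {
      log[[step]] <- data.frame(step = step, energy = NA_real_,
                                decision = "screened_out", reason = sc$reason,
                                e_low = lib$e_low)
      next
    }
    mm <- tryCatch(local_minimize(model, cand, tol = cfg$min_tol,
                                  max_iter = cfg$min_max_iter),
                   error = function(e) NULL)
    if (is.null(mm) || !mm$converged) {
      log[[step]] <- data.frame(step = step, energy = NA_real_,
                                decision = "minimization_failed",
                                reason = "local minimization did not converge",
                                e_low = lib$e_low)
      next
    }
    if (!is.null(constraint) && !isTRUE(constraint(mm$geometry))) {
      log[[step]] <- data.frame(step = step, energy = mm$energy,
                                decision = "constraint_reject",
                                reason = "outside similarity constraint",
                                e_low = lib$e_low)
      next
    }
    decision <- accept_step(mm$energy, e_current, lib$e_low, cfg)
    lib <- register_unique(lib, minimum_record(mm$geometry, mm$energy,
                                               step, "bh"), cfg)$library
    if (decision != "reject") {
      current <- mm$geometry
      e_current <- mm$energy
    }
    log[[step]] <- data.frame(step = step, energy = mm$energy,
                              decision = decision, reason = "ok",
                              e_low = lib$e_low)
  }
  structure(list(library = lib,
                 log = if (cfg$n_steps) do.call(rbind, log) else
                   data.frame(step = integer(), energy = numeric(),
                              decision = character(), reason = character(),
                              e_low = numeric()),
                 config = cfg, model_name = model$name),
            class = "bh_result")
}

#' @export
print.bh_result <- function(x, ...) {
  cat(sprintf("<bh_result> %s: %d steps, %d unique minima, E_low = %.8g\n",
              x$model_name, nrow(x$log), length(x$library), x$library$e_low))
  invisible(x)
}

#' @export
summary.bh_result <- function(object, ...) {
  dec <- table(object$log$decision)
  cat(sprintf("Basin-hopping run on %s\n", object$model_name))
  cat(sprintf("  steps: %d   unique minima: %d   E_low: %.8g\n",
              nrow(object$log), length(object$library),
              object$library$e_low))
  for (nm in names(dec)) cat(sprintf("  %-20s %d\n", nm, dec[[nm]]))
  invisible(object)
}

#' Export a minima library as multi-frame XYZ
#'
#' One frame per record, energies written as \code{E=} tokens in the
#' comment lines.
#'
#' @param lib a \code{bh_minima}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_library_xyz <- function(lib, path) {
  geoms <- lapply(seq_along(lib$records), function(i) {
    r <- lib$records[[i]]
    g <- r$geometry
    g$label <- sprintf("minimum %d provenance=%s step=%d", i, r$provenance,
                       r$step_found)
    g$energy <- r$energy
    g
  })
  write_xyz(geoms, path)
}
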