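# Intermediate-geometry generation between known minima: candidate-pair
# selection, two-stage artificial-force-field interpolation, the
# similarity-constrained Monte Carlo sampler, interpolation-factor
# verification and transition-state guess export.

.geom_of <- function(x) if (inherits(x, "bh_minimum")) x$geometry else x

#' Optimal rigid superposition (Kabsch)
#'
#' Rotates and translates \code{mov} onto \code{ref} minimizing the RMSD
#' of corresponding atoms (proper rotation only; no reflection).
#'
#' @param ref,mov geometries with corresponding atom order.
#' @return \code{mov} superposed onto \code{ref}.
#' @export
align_onto <- function(ref, mov) {
  P <- .coords_of(mov); Q <- .coords_of(ref)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  out <- if (inherits(mov, "bh_geometry")) mov else ref
  out$coords <- sweep(Pc %*% R, 2, cq, "+")
  out
}

#' Select candidate pairs for structural interpolation
#'
#' Pairs of library records whose distance-matrix similarity exceeds
#' \code{min_distance} are interpolation candidates; at most
#' \code{max_pairs} of them are kept, sampled uniformly without
#' replacement under the seed.
#'
#' @param lib a \code{bh_minima} (or list of geometries).
#' @param min_distance candidacy threshold (Angstrom; the worked usage is
#'   150.0 A for a ~28-atom dimer).
#' @param max_pairs cap on returned pairs.
#' @param seed RNG seed for the subsample.
#' @param pd optional precomputed \code{"bh_pairwise"} (dm metric) to
#'   avoid recomputation.
#' @return data.frame with columns \code{i}, \code{j}, \code{distance};
#'   zero rows when nothing is eligible.
#' @export
select_pairs <- function(lib, min_distance, max_pairs = Inf, seed = 1L,
                         pd = NULL) {
  if (is.null(pd)) pd <- pairwise(lib, metric = "dm")
  M <- pd$M
  ut <- which(upper.tri(M), arr.ind = TRUE)
  keep <- M[ut] > min_distance
  out <- data.frame(i = ut[keep, 1], j = ut[keep, 2], distance = M[ut][keep])
  if (nrow(out) > max_pairs) {
    set.seed(seed)
    out <- out[sort(sample.int(nrow(out), max_pairs)), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Two-stage artificial-force-field interpolation
#'
#' Stage 1 minimizes the interpolation force field (target distances
#' rbar = lambda D_A + (1 - lambda) D_B) starting from the
#' Kabsch-superposed Cartesian blend lambda A + (1 - lambda) B, driving
#' the structure toward a realization of rbar. Stage 2 re-minimizes the
#' stage-1 structure on the real model potential, yielding a candidate
#' intermediate minimum with provenance \code{"interpolation"}.
#'
#' @param a,b endpoint geometries or \code{bh_minimum} records of the same
#'   composition.
#' @param model the real \code{"bh_potential"}.
#' @param lambda interpolation factor (default 0.5, the midpoint).
#' @param chi artificial-force-field scale constant.
#' @param tol,max_iter minimization controls (both stages).
#' @return object of class \code{"bh_interp"}: \code{record} (the stage-2
#'   \code{bh_minimum}), \code{stage1_geometry}, \code{stage1_value}
#'   (residual V at the stage-1 minimum), \code{stage1_max_dev} (max
#'   |D_C,ij - rbar_ij|, Angstrom), \code{lambda}, \code{converged}.
#' @export
interpolate_ff <- function(a, b, model, lambda = 0.5, chi = 1,
                           tol = 1e-6, max_iter = 2000) {
  ga <- .geom_of(a); gb <- .geom_of(b)
  if (!identical(sort(ga$elements), sort(gb$elements)))
    stop("endpoints differ in composition")
  ff <- artificial_ff(distance_matrix(ga), distance_matrix(gb), lambda, chi)
  gb_al <- align_onto(ga, gb)
  start <- ga
  start$coords <- lambda * ga$coords + (1 - lambda) * gb_al$coords
  s1 <- local_minimize(ff, start, tol = tol, max_iter = max_iter)
  if (!s1$converged)
    stop(sprintf(paste0("interpolation failure: stage-1 force field did not ",
                        "converge (grad norm %.3g, residual %.3g)"),
                 s1$grad_norm, s1$energy))
  dev <- max(abs(distance_matrix(s1$geometry) - ff$rbar))
  s2 <- local_minimize(model, s1$geometry, tol = tol, max_iter = max_iter)
  structure(list(
    record = minimum_record(s2$geometry, s2$energy, 0L, "interpolation"),
    stage1_geometry = s1$geometry, stage1_value = s1$energy,
    stage1_max_dev = dev, lambda = lambda, converged = s2$converged),
    class = "bh_interp")
}

#' @export
print.bh_interp <- function(x, ...) {
  cat(sprintf(paste0("<bh_interp> lambda = %.3g, stage-1 residual %.3g ",
                     "(max dev %.3g A), final E = %.8g\n"),
              x$lambda, x$stage1_value, x$stage1_max_dev, x$record$energy))
  invisible(x)
}

#' Augment a minima library by pairwise interpolation
#'
#' Applies \code{\link{interpolate_ff}} to the selected candidate pairs
#' and registers each interpolated minimum with the same uniqueness
#' thresholds used during the basin-hopping run. The input library is
#' never shrunk; only additions are possible.
#'
#' @param lib a \code{bh_minima}.
#' @param model the real \code{"bh_potential"}.
#' @param cfg \code{\link{bh_config}} carrying the uniqueness thresholds.
#' @param min_distance interpolation candidacy threshold (Angstrom).
#' @param max_pairs cap on interpolated pairs.
#' @param lambda,chi interpolation parameters.
#' @param seed seed for pair subsampling.
#' @return list: \code{library} (augmented \code{bh_minima}),
#'   \code{report} (one row per attempted pair: indices, lambda, stage-1
#'   residual, final energy, whether a new unique minimum was added).
#' @export
augment_library <- function(lib, model, cfg, min_distance, max_pairs = 300,
                            lambda = 0.5, chi = 1, seed = 1L) {
  pairs <- select_pairs(lib, min_distance, max_pairs, seed)
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    res <- tryCatch(
      interpolate_ff(lib$records[[i]], lib$records[[j]], model,
                     lambda = lambda, chi = chi, tol = cfg$min_tol,
                     max_iter = cfg$min_max_iter),
      error = function(e) NULL)
    if (is.null(res)) {
      rows[[k]] <- data.frame(i = i, j = j, lambda = lambda,
                              stage1_residual = NA_real_,
                              final_energy = NA_real_, added = FALSE,
                              status = "failed")
      next
    }
    reg <- register_unique(lib, res$record, cfg)
    lib <- reg$library
    rows[[k]] <- data.frame(i = i, j = j, lambda = lambda,
                            stage1_residual = res$stage1_value,
                            final_energy = res$record$energy,
                            added = reg$added, status = "ok")
  }
  list(library = lib,
       report = if (length(rows)) do.call(rbind, rows) else
         data.frame(i = integer(), j = integer(), lambda = numeric(),
                    stage1_residual = numeric(), final_energy = numeric(),
                    added = logical(), status = character()))
}

#' Similarity-constrained Monte Carlo sampling between two minima
#'
#' A basin-hopping loop whose acceptance additionally rejects any
#' minimized structure farther (distance-matrix similarity) than
#' \code{radius_a} from A or \code{radius_b} from B, constraining the
#' search to the lens-shaped region between the two minima. The walk
#' starts from A; with infinite radii the loop reduces exactly to plain
#' basin-hopping from A.
#'
#' @param a,b endpoint geometries or \code{bh_minimum} records.
#' @param model a \code{"bh_potential"}.
#' @param cfg a \code{\link{bh_config}}.
#' @param radius_a,radius_b constraint radii (Angstrom); each must be at
#'   least half the A-B separation or the constrained region is empty.
#' @param topology optional move-set topology.
#' @return a \code{"bh_result"} whose library contains only conforming
#'   records.
#' @export
mc_constrained_sample <- function(a, b, model, cfg, radius_a, radius_b,
                                  topology = NULL) {
  ga <- .geom_of(a); gb <- .geom_of(b)
  d_ab <- dm_similarity(ga, gb)
  if (radius_a < d_ab / 2 || radius_b < d_ab / 2)
    stop(sprintf("infeasible constraint radii: need >= d(A,B)/2 = %.4g A",
                 d_ab / 2))
  constraint <- function(g) {
    dm_similarity(g, ga) <= radius_a && dm_similarity(g, gb) <= radius_b
  }
  run_bh(model, ga, cfg, topology = topology, constraint = constraint)
}

#' Verify the interpolation-factor relation for a candidate intermediate
#'
#' For an interpolant C built toward target distances
#' rbar = lambda D_A + (1 - lambda) D_B, an exact realization satisfies
#' d(A,C) = (1 - lambda) d(A,B) and d(B,C) = lambda d(A,B) in the
#' distance-matrix metric. The report gives the three pairwise distances
#' and the two deviations from that relation.
#'
#' @param a,b,c geometries of identical composition.
#' @param lambda interpolation factor used to build C.
#' @param metric \code{"dm"} or \code{"cosine"}.
#' @param sorted sorted-vector convention for the cosine metric.
#' @return list: \code{d_ab}, \code{d_ac}, \code{d_bc}, \code{dev_ac}
#'   = |(1 - lambda) d(A,B) - d(A,C)|, \code{dev_bc}
#'   = |lambda d(A,B) - d(B,C)|.
#' @export
verify_eq_interp <- function(a, b, c, lambda, metric = c("dm", "cosine"),
                             sorted = FALSE) {
  metric <- match.arg(metric)
  dfun <- if (metric == "dm") {
    function(x, y) dm_similarity(x, y)
  } else {
    function(x, y) cosine_distance(mass_weighted_vector(x, sorted),
                                   mass_weighted_vector(y, sorted))
  }
  d_ab <- dfun(a, b); d_ac <- dfun(a, c); d_bc <- dfun(b, c)
  list(d_ab = d_ab, d_ac = d_ac, d_bc = d_bc,
       dev_ac = abs((1 - lambda) * d_ab - d_ac),
       dev_bc = abs(lambda * d_ab - d_bc))
}

#' Export a transition-state guess triple as 3-frame XYZ
#'
#' Writes reactant, guess and product (in that order) with identical atom
#' ordering, the input format expected by synchronous-transit TS searches
#' (e.g. QST3).
#'
#' @param a reactant geometry.
#' @param c guess (interpolated) geometry.
#' @param b product geometry.
#' @param path output path.
#' @return invisibly, the path.
#' @export
ts_guess_export <- function(a, c, b, path) {
  ga <- .geom_of(a); gc <- .geom_of(c); gb <- .geom_of(b)
  if (!identical(ga$elements, gc$elements) ||
      !identical(gc$elements, gb$elements))
    stop("export error: element order differs between frames")
  ga$label <- "reactant"; gc$label <- "ts_guess"; gb$label <- "product"
  write_xyz(list(ga, gc, gb), path)
}
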