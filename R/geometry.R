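# Molecular geometry container, XYZ I/O and similarity functions.

# Most-abundant-isotope masses (u), 4 decimal places. "X" is a generic
# unit-mass model particle used by the toy potentials.
.atomic_masses <- c(
  H = 1.0078, D = 2.0141, He = 4.0026, Li = 7.0160, Be = 9.0122,
  B = 11.0093, C = 12.0000, N = 14.0031, O = 15.9949, F = 18.9984,
  Ne = 19.9924, Na = 22.9898, Mg = 23.9850, Al = 26.9815, Si = 27.9769,
  P = 30.9738, S = 31.9721, Cl = 34.9689, Ar = 39.9624, K = 38.9637,
  Ca = 39.9626, Fe = 55.9349, Ni = 57.9353, Cu = 62.9296, Zn = 63.9291,
  Br = 78.9183, I = 126.9045, X = 1.0000
)

#' Look up atomic masses by element symbol
#'
#' Masses are most-abundant-isotope values in unified atomic mass units.
#' The pseudo-element \code{"X"} (mass 1) is available for model particles
#' such as reduced-unit Lennard-Jones atoms.
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of masses (u).
#' @export
atomic_mass <- function(elements) {
  m <- .atomic_masses[elements]
  if (anyNA(m)) {
    bad <- unique(elements[is.na(m)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

#' Construct a molecular geometry
#'
#' The basic unit consumed by every similarity and potential operation:
#' labelled atoms with masses and Cartesian coordinates in Angstrom.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param label free-text label (stored in the XYZ comment line).
#' @param energy optional scalar energy in model-potential units.
#' @return an object of class \code{"bh_geometry"} with fields
#'   \code{elements}, \code{masses}, \code{coords}, \code{label},
#'   \code{energy}.
#' @export
geometry <- function(elements, coords, label = "", energy = NULL) {
  elements <- as.character(elements)
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- length(elements)
  if (n < 1L) stop("geometry needs at least one atom")
  if (nrow(coords) != n) stop("elements and coords differ in length")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  masses <- atomic_mass(elements)
  structure(
    list(elements = elements, masses = masses, coords = coords,
         label = as.character(label)[1],
         energy = if (is.null(energy)) NA_real_ else as.numeric(energy)[1]),
    class = "bh_geometry"
  )
}

#' @export
print.bh_geometry <- function(x, ...) {
  cat(sprintf("<bh_geometry> %d atoms (%s)", n_atoms(x),
              paste(unique(x$elements), collapse = ",")))
  if (nzchar(x$label)) cat(" label:", x$label)
  if (is.finite(x$energy)) cat(sprintf("  E = %.8g", x$energy))
  cat("\n")
  invisible(x)
}

#' Number of atoms in a geometry
#' @param g a \code{bh_geometry}.
#' @return integer atom count.
#' @export
n_atoms <- function(g) length(g$elements)

# Accept a geometry or a bare n x 3 coordinate matrix (fast path used by
# the potential models during minimization).
.coords_of <- function(g) {
  if (inherits(g, "bh_geometry")) g$coords else matrix(g, ncol = 3)
}

#' Apply a rigid rotation and/or translation to a geometry
#'
#' @param g a \code{bh_geometry}.
#' @param rotation 3 x 3 rotation matrix, or \code{NULL}.
#' @param translation length-3 shift vector (Angstrom).
#' @return transformed \code{bh_geometry}.
#' @export
transform_geometry <- function(g, rotation = NULL, translation = c(0, 0, 0)) {
  xyz <- g$coords
  if (!is.null(rotation)) xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, as.numeric(translation), "+")
  g$coords <- xyz
  g
}

#' Rotation matrix about an axis
#'
#' @param axis length-3 axis vector (normalized internally).
#' @param angle rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %*% t(u))
}

# ---------------------------------------------------------------- XYZ I/O

#' Read a (multi-frame) XYZ file
#'
#' Standard XYZ: an atom-count line, a comment line, then one
#' \code{symbol x y z} record per atom; frames may repeat. The comment line
#' is stored as the geometry label; a token \code{E=<float>} in the comment
#' is parsed into the \code{energy} field.
#'
#' @param path path to an XYZ file.
#' @return list of \code{bh_geometry}, in file order.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop(sprintf("line %d: malformed atom count '%s'", i, lines[i]))
    if (i + 1L + n > length(lines))
      stop(sprintf("line %d: frame of %d atoms truncated", i, n))
    comment <- lines[i + 1L]
    elements <- character(n)
    coords <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      ln <- i + 1L + k
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(tok) < 4L)
        stop(sprintf("line %d: expected 'symbol x y z'", ln))
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(xyz))
        stop(sprintf("line %d: non-numeric coordinate", ln))
      elements[k] <- tok[1]
      coords[k, ] <- xyz
    }
    energy <- NULL
    m <- regmatches(comment, regexpr("E=\\s*[-+0-9.eE]+", comment))
    if (length(m) == 1L && nzchar(m))
      energy <- as.numeric(sub("E=\\s*", "", m))
    out[[length(out) + 1L]] <- geometry(elements, coords,
                                        label = comment, energy = energy)
    i <- i + 2L + n
  }
  out
}

#' Write geometries to a (multi-frame) XYZ file
#'
#' Coordinates are written with 8 decimal places so that a write/read
#' round trip preserves them far below 1e-6 Angstrom. If a geometry has a
#' finite energy and its label carries no \code{E=} token, one is appended
#' to the comment line.
#'
#' @param geometries a \code{bh_geometry} or list of them.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_xyz <- function(geometries, path) {
  if (inherits(geometries, "bh_geometry")) geometries <- list(geometries)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in geometries) {
    comment <- g$label
    if (is.finite(g$energy) && !grepl("E=", comment, fixed = TRUE))
      comment <- trimws(paste(comment, sprintf("E=%.10g", g$energy)))
    writeLines(as.character(n_atoms(g)), con)
    writeLines(comment, con)
    writeLines(sprintf("%-3s %16.8f %16.8f %16.8f",
                       g$elements, g$coords[, 1], g$coords[, 2],
                       g$coords[, 3]), con)
  }
  invisible(path)
}

# ------------------------------------------------- similarity functions

#' Interatomic (Euclidean) distance matrix representation
#'
#' The collection of all interatomic distances: a symmetric matrix with a
#' zero diagonal, invariant under rigid rotation and translation of the
#' geometry (but not under atom relabelling).
#'
#' @param g a \code{bh_geometry} or n x 3 coordinate matrix.
#' @return symmetric n x n numeric matrix of distances (Angstrom).
#' @export
distance_matrix <- function(g) {
  as.matrix(stats::dist(.coords_of(g)))
}

#' Distance-matrix similarity index
#'
#' Sum over unique atom pairs of the absolute difference between the two
#' interatomic distance matrices, in Angstrom. Zero iff the matrices agree;
#' symmetric; non-negative. With \code{mapping = "assignment"} the atoms of
#' \code{b} are relabelled by an element-constrained assignment (see
#' \code{\link{element_constrained_mapping}}) before comparison, and the
#' smaller of the remapped and identity values is returned.
#'
#' @param a,b geometries, or (for \code{mapping = "identity"}) distance
#'   matrices.
#' @param mapping \code{"identity"} or \code{"assignment"}.
#' @return scalar similarity index (Angstrom).
#' @export
dm_similarity <- function(a, b, mapping = c("identity", "assignment")) {
  mapping <- match.arg(mapping)
  da <- if (is.matrix(a) && !inherits(a, "bh_geometry")) a else distance_matrix(a)
  db <- if (is.matrix(b) && !inherits(b, "bh_geometry")) b else distance_matrix(b)
  if (!all(dim(da) == dim(db)))
    stop("structures have different numbers of atoms")
  d_id <- sum(abs(da - db)[upper.tri(da)])
  if (mapping == "identity") return(d_id)
  if (!inherits(a, "bh_geometry") || !inherits(b, "bh_geometry"))
    stop("mapping = 'assignment' requires geometries, not matrices")
  p <- element_constrained_mapping(a, b)
  db_p <- db[p, p]
  d_map <- sum(abs(da - db_p)[upper.tri(da)])
  min(d_id, d_map)
}

#' Mass-weighted centre-of-mass distance vector
#'
#' Entry i is \eqn{m_i |r_i - R_{COM}|} (u Angstrom). Translation- and
#' rotation-invariant; with \code{sorted = TRUE} the entries are sorted
#' ascending, adding permutational invariance for cross-provenance
#' comparisons.
#'
#' @param g a \code{bh_geometry}.
#' @param sorted sort entries ascending before use?
#' @return numeric vector of length \code{n_atoms(g)} with attribute
#'   \code{"sorted"}.
#' @export
mass_weighted_vector <- function(g, sorted = FALSE) {
  com <- colSums(g$coords * g$masses) / sum(g$masses)
  r <- sqrt(rowSums(sweep(g$coords, 2, com)^2))
  v <- g$masses * r
  if (sorted) v <- sort(v)
  attr(v, "sorted") <- sorted
  v
}

#' Cosine distance between mass-weighted vectors
#'
#' \eqn{d = \arccos(s)/\pi} where s is the cosine similarity of the two
#' vectors. For the non-negative mass-weighted vectors this lies in
#' [0, 0.5]; it is zero iff the vectors are parallel.
#'
#' @param ra,rb numeric vectors (e.g. from
#'   \code{\link{mass_weighted_vector}}), equal length, nonzero.
#' @return scalar in [0, 1].
#' @export
cosine_distance <- function(ra, rb) {
  ra <- as.numeric(ra); rb <- as.numeric(rb)
  if (length(ra) != length(rb)) stop("vectors differ in length")
  na <- sqrt(sum(ra^2)); nb <- sqrt(sum(rb^2))
  if (na == 0 || nb == 0) stop("zero-norm vector has no direction")
  s <- sum(ra * rb) / (na * nb)
  s <- min(1, max(-1, s))  # clamp rounding noise
  acos(s) / pi
}

.perm_list <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in .perm_list(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

#' Element-constrained atom mapping between two geometries
#'
#' Finds a permutation p of the atoms of \code{b}, mapping each atom of
#' \code{b} to an atom of \code{a} of the same element, minimizing the
#' distance-matrix similarity index. When the number of element-preserving
#' permutations is small (at most 5040) the minimum is found exactly by
#' enumeration; larger systems use a heuristic: within each element, atoms
#' are first matched by rank of their mass-weighted centre-of-mass
#' distances (the exact solution of the per-element scalar assignment),
#' then refined by element-preserving pair swaps until no swap lowers the
#' index. The heuristic is not guaranteed to reach the global optimum.
#'
#' @param a,b geometries of identical element composition.
#' @return integer permutation p such that atom \code{p[i]} of \code{b}
#'   corresponds to atom i of \code{a}.
#' @export
element_constrained_mapping <- function(a, b) {
  if (!identical(sort(a$elements), sort(b$elements)))
    stop("geometries differ in element composition")
  n <- n_atoms(a)
  da <- distance_matrix(a)
  db <- distance_matrix(b)
  score <- function(p) sum(abs(da - db[p, p])[upper.tri(da)])
  groups_a <- split(seq_len(n), a$elements)
  groups_b <- split(seq_len(n), b$elements)
  n_maps <- prod(factorial(lengths(groups_a)))
  if (n_maps <= 5040) {
    best_p <- NULL; best <- Inf
    recurse <- function(gi, p) {
      if (gi > length(groups_a)) {
        s <- score(p)
        if (s < best) { best <<- s; best_p <<- p }
        return(invisible())
      }
      ia <- groups_a[[gi]]
      for (q in .perm_list(groups_b[[names(groups_a)[gi]]])) {
        p[ia] <- q
        recurse(gi + 1L, p)
      }
    }
    recurse(1L, integer(n))
    return(best_p)
  }
  ra <- mass_weighted_vector(a)
  rb <- mass_weighted_vector(b)
  p <- integer(n)
  for (el in names(groups_a)) {
    ia <- groups_a[[el]]
    ib <- groups_b[[el]]
    # rank-matching minimizes sum |ra - rb| over per-element assignments
    p[ia[order(ra[ia])]] <- ib[order(rb[ib])]
  }
  best <- score(p)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (el in names(groups_a)) {
      ia <- groups_a[[el]]
      if (length(ia) < 2L) next
      for (u in seq_along(ia)[-length(ia)]) for (v in seq((u + 1), length(ia))) {
        q <- p
        q[c(ia[u], ia[v])] <- q[c(ia[v], ia[u])]
        sq <- score(q)
        if (sq < best - 1e-12) {
          p <- q; best <- sq; improved <- TRUE
        }
      }
    }
  }
  p
}

# ------------------------------------------ distance-matrix table export

#' Write / read a labelled square distance table
#'
#' Plain whitespace-delimited square table with a header row of labels.
#'
#' @param M symmetric numeric matrix.
#' @param path file path.
#' @param labels column/row labels (defaults to existing dimnames).
#' @return \code{write_distmat}: invisibly the path; \code{read_distmat}:
#'   a labelled symmetric matrix.
#' @export
write_distmat <- function(M, path, labels = NULL) {
  if (is.null(labels)) labels <- colnames(M)
  if (is.null(labels)) labels <- paste0("s", seq_len(ncol(M)))
  dimnames(M) <- list(labels, labels)
  utils::write.table(M, path, quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_distmat
#' @export
read_distmat <- function(path) {
  M <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1,
                                   check.names = FALSE))
  storage.mode(M) <- "double"
  M
}
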