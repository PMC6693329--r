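# Pairwise distances over minima libraries, agglomerative clustering
# (hand-rolled WPGMA with a fixed tie rule; Ward via Lance-Williams on the
# raw distance matrix), dendrogram/Newick export and 2D multidimensional
# scaling by stress majorization.

.as_geometry_list <- function(x) {
  if (inherits(x, "bh_minima")) lapply(x$records, `[[`, "geometry")
  else if (inherits(x, "bh_geometry")) list(x)
  else x
}

#' Pairwise distance matrix over a set of minima
#'
#' Applies one of the two similarity functions across all record pairs of
#' a minima library (or plain list of geometries).
#'
#' @param lib a \code{bh_minima} or list of \code{bh_geometry} of
#'   identical composition.
#' @param metric \code{"dm"} (distance-matrix index, Angstrom) or
#'   \code{"cosine"} (mass-weighted cosine distance).
#' @param mapping atom-mapping policy for the dm metric.
#' @param sorted sort mass-weighted vectors before the cosine metric?
#'   Defaults to TRUE (cross-provenance convention); use FALSE when atom
#'   identity is tracked through a single run.
#' @param labels record labels (defaults to \code{s1, s2, ...}).
#' @return object of class \code{"bh_pairwise"}: list(M, labels, metric).
#' @export
pairwise <- function(lib, metric = c("dm", "cosine"),
                     mapping = c("identity", "assignment"),
                     sorted = TRUE, labels = NULL) {
  metric <- match.arg(metric)
  mapping <- match.arg(mapping)
  geoms <- .as_geometry_list(lib)
  m <- length(geoms)
  comp <- lapply(geoms, function(g) sort(g$elements))
  if (m > 1L && !all(vapply(comp[-1], identical, logical(1), comp[[1]])))
    stop("records have mixed element compositions")
  if (is.null(labels)) labels <- paste0("s", seq_len(m))
  M <- matrix(0, m, m, dimnames = list(labels, labels))
  if (metric == "cosine")
    vecs <- lapply(geoms, mass_weighted_vector, sorted = sorted)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) for (j in seq((i + 1L), m)) {
      M[i, j] <- M[j, i] <- if (metric == "dm")
        dm_similarity(geoms[[i]], geoms[[j]], mapping = mapping)
      else cosine_distance(vecs[[i]], vecs[[j]])
    }
  }
  structure(list(M = M, labels = labels, metric = metric),
            class = "bh_pairwise")
}

#' Wrap an existing symmetric matrix as pairwise distances
#'
#' For distance matrices obtained outside the package (e.g. a published
#' table).
#'
#' @param M symmetric matrix with zero diagonal.
#' @param labels leaf labels.
#' @param metric metric tag.
#' @return a \code{"bh_pairwise"}.
#' @export
as_pairwise <- function(M, labels = colnames(M), metric = "dm") {
  M <- as.matrix(M)
  if (!isSymmetric(unname(M), tol = 1e-12)) stop("matrix is not symmetric")
  if (any(diag(M) != 0)) stop("diagonal must be zero")
  if (any(M < 0)) stop("negative distances")
  if (is.null(labels)) labels <- paste0("s", seq_len(ncol(M)))
  dimnames(M) <- list(labels, labels)
  structure(list(M = M, labels = labels, metric = metric),
            class = "bh_pairwise")
}

#' @export
print.bh_pairwise <- function(x, ...) {
  cat(sprintf("<bh_pairwise> %d x %d, metric = %s\n", nrow(x$M), ncol(x$M),
              x$metric))
  invisible(x)
}

.pd_matrix <- function(pd) {
  if (inherits(pd, "bh_pairwise")) pd$M
  else if (inherits(pd, "dist")) as.matrix(pd)
  else as.matrix(pd)
}

# leaf ordering for an hclust-style merge matrix
.merge_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' WPGMA agglomerative clustering
#'
#' Weighted pair-group method with arithmetic mean: at each iteration the
#' two nearest groups P and Q merge, and the distance of the merged group
#' to any other group R is (d(P,R) + d(Q,R)) / 2. Ties in the
#' nearest-pair search are broken by the lowest (i, j) index pair in the
#' current matrix, so the linkage is deterministic.
#'
#' @param pd a \code{"bh_pairwise"} (or bare symmetric matrix).
#' @return an hclust-compatible object of class
#'   \code{c("bh_linkage", "hclust")} with \code{method = "wpgma"}.
#' @export
wpgma <- function(pd) {
  M <- .pd_matrix(pd)
  labels <- colnames(M)
  if (is.null(labels)) labels <- paste0("s", seq_len(ncol(M)))
  m <- nrow(M)
  if (m < 2L) stop("need at least two records to cluster")
  id <- -seq_len(m)          # hclust node ids of current rows
  cur <- M
  merge <- matrix(0L, m - 1L, 2L)
  height <- numeric(m - 1L)
  for (s in seq_len(m - 1L)) {
    k <- nrow(cur)
    best <- c(NA, NA); bmin <- Inf
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      if (cur[i, j] < bmin - 0) {   # strict <: first (lexicographic) wins ties
        bmin <- cur[i, j]; best <- c(i, j)
      }
    }
    i <- best[1]; j <- best[2]
    a <- id[i]; b <- id[j]
    # hclust convention: singletons (negative) before clusters, else by value
    pr <- if ((a < 0) == (b < 0)) sort(c(a, b)) else c(min(a, b), max(a, b))
    merge[s, ] <- pr
    height[s] <- bmin
    if (k > 2L) {
      rest <- setdiff(seq_len(k), c(i, j))
      newd <- (cur[i, rest] + cur[j, rest]) / 2
      cur <- rbind(cbind(cur[rest, rest, drop = FALSE], newd),
                   c(newd, 0))
      id <- c(id[rest], s)
    }
  }
  structure(list(merge = merge, height = height,
                 order = .merge_order(merge), labels = labels,
                 method = "wpgma",
                 dist.method = if (inherits(pd, "bh_pairwise")) pd$metric else NA,
                 call = match.call()),
            class = c("bh_linkage", "hclust"))
}

#' Ward minimum-variance clustering
#'
#' Lance-Williams Ward update applied to the raw distance matrix (the
#' classical \code{"ward.D"} scheme), merging at each step the pair of
#' clusters giving the minimum increase in total within-cluster variance.
#' The distance-matrix similarity index is not exactly Euclidean; the raw
#' matrix is clustered as-is, which is the intended field usage.
#'
#' @param pd a \code{"bh_pairwise"} (or bare symmetric matrix).
#' @return an hclust-compatible object of class
#'   \code{c("bh_linkage", "hclust")} with \code{method = "ward"}.
#' @export
ward <- function(pd) {
  M <- .pd_matrix(pd)
  if (nrow(M) < 2L) stop("need at least two records to cluster")
  hc <- stats::hclust(stats::as.dist(M), method = "ward.D")
  hc$method <- "ward"
  hc$dist.method <- if (inherits(pd, "bh_pairwise")) pd$metric else NA
  class(hc) <- c("bh_linkage", "hclust")
  hc
}

#' Cut a linkage into groups
#'
#' @param linkage a \code{"bh_linkage"}.
#' @param k desired number of groups (1 <= k <= leaves), or
#' @param height cut height.
#' @return named integer vector: label -> group id.
#' @export
cut_groups <- function(linkage, k = NULL, height = NULL) {
  m <- length(linkage$labels)
  if (!is.null(k) && (k < 1 || k > m)) stop("k must lie in [1, ", m, "]")
  stats::cutree(linkage, k = k, h = height)
}

#' Flat merge table of a linkage
#'
#' One row per merge: the two members (negative = leaf index, positive =
#' earlier merge id), the merge distance, and the new group id.
#'
#' @param linkage a \code{"bh_linkage"}.
#' @return data.frame with columns \code{member_a}, \code{member_b},
#'   \code{distance}, \code{group_id}.
#' @export
linkage_table <- function(linkage) {
  data.frame(member_a = linkage$merge[, 1], member_b = linkage$merge[, 2],
             distance = linkage$height,
             group_id = seq_along(linkage$height))
}

#' Export a linkage as a Newick tree
#'
#' Branch lengths derive from the merge heights (ultrametric dendrogram).
#'
#' @param linkage a \code{"bh_linkage"}.
#' @param path output path, or \code{NULL} to return the Newick string.
#' @return the Newick string (invisibly when written to file).
#' @export
linkage_newick <- function(linkage, path = NULL) {
  hc <- linkage
  class(hc) <- "hclust"
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

# ------------------------------------------------------------------- MDS

#' Raw stress of a 2D embedding
#'
#' Sum over pairs of squared differences between embedded Euclidean
#' distances and the target distances.
#'
#' @param points m x 2 coordinate matrix.
#' @param pd the target \code{"bh_pairwise"} (or matrix).
#' @return scalar stress >= 0.
#' @export
mds_stress <- function(points, pd) {
  M <- .pd_matrix(pd)
  d <- as.matrix(stats::dist(points))
  sum(((d - M)[upper.tri(M)])^2)
}

#' 2D multidimensional scaling of a distance matrix
#'
#' Classical (eigendecomposition) initialization refined by iterative
#' stress majorization (SMACOF/Guttman transform) of the raw squared-error
#' stress. Deterministic given the seed (the seed only matters when the
#' classical start is degenerate and random jitter is needed).
#'
#' @param pd a \code{"bh_pairwise"} (or bare symmetric matrix), m >= 3.
#' @param seed RNG seed.
#' @param max_iter majorization iteration cap.
#' @param tol relative stress-change stopping threshold.
#' @return object of class \code{"bh_mds"}: \code{points} (m x 2, rows
#'   named by labels), \code{stress}, \code{iterations}.
#' @export
mds2d <- function(pd, seed = 1L, max_iter = 500L, tol = 1e-12) {
  M <- .pd_matrix(pd)
  m <- nrow(M)
  if (m < 3L) stop("MDS needs at least three records")
  labels <- colnames(M)
  set.seed(seed)
  X <- suppressWarnings(stats::cmdscale(M, k = 2))
  if (ncol(X) < 2L)
    X <- cbind(X, matrix(stats::rnorm(m * (2 - ncol(X)), sd = 1e-3), m))
  if (all(abs(X) < 1e-12)) X <- matrix(stats::rnorm(2 * m, sd = 1e-3), m, 2)
  s_old <- mds_stress(X, M)
  iters <- 0L
  for (it in seq_len(max_iter)) {
    D <- as.matrix(stats::dist(X))
    B <- matrix(0, m, m)
    nz <- D > 1e-12
    B[nz] <- -M[nz] / D[nz]
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / m
    s_new <- mds_stress(X, M)
    iters <- it
    if (s_old - s_new <= tol * max(s_old, 1e-300)) { s_old <- s_new; break }
    s_old <- s_new
  }
  rownames(X) <- labels
  colnames(X) <- c("x", "y")
  structure(list(points = X, stress = s_old, iterations = iters),
            class = "bh_mds")
}

#' @export
print.bh_mds <- function(x, ...) {
  cat(sprintf("<bh_mds> %d points, stress = %.6g (%d iterations)\n",
              nrow(x$points), x$stress, x$iterations))
  invisible(x)
}

#' @export
plot.bh_mds <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  plot(x$points, col = col, pch = 19,
       xlab = "MDS 1", ylab = "MDS 2", ...)
  if (!is.null(rownames(x$points)))
    graphics::text(x$points, labels = rownames(x$points), pos = 3, cex = 0.7)
  invisible(x)
}
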