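# IR spectral-matching pipeline: frequency scaling, Lorentzian
# broadening onto a regular grid, per-region max normalization, region
# concatenation, Euclidean comparison and scaled-similarity ranking.

#' Construct a stick (line) spectrum
#'
#' @param frequency line positions (cm^-1, > 0).
#' @param intensity non-negative line intensities (arbitrary units).
#' @param label isomer label.
#' @return object of class \code{"bh_lines"}.
#' @export
line_spectrum <- function(frequency, intensity, label = "") {
  stopifnot(length(frequency) == length(intensity),
            all(frequency > 0), all(is.finite(intensity)),
            all(intensity >= 0))
  structure(list(frequency = as.numeric(frequency),
                 intensity = as.numeric(intensity),
                 label = as.character(label)[1]),
            class = "bh_lines")
}

#' @export
print.bh_lines <- function(x, ...) {
  cat(sprintf("<bh_lines> %s: %d lines, %.0f-%.0f cm^-1\n", x$label,
              length(x$frequency), min(x$frequency), max(x$frequency)))
  invisible(x)
}

#' Spectral region table
#'
#' Each region has grid bounds, a harmonic frequency scale factor and a
#' grid step. The default is the two-window fingerprint/hydride-stretch
#' setup: 1000-1900 cm^-1 scaled by 0.9679 and 3200-3800 cm^-1 scaled by
#' 0.95, on a 2 cm^-1 grid.
#'
#' @param lo,hi region bounds (cm^-1).
#' @param scale_factor harmonic scale factor per region (0, 1.2].
#' @param grid_step grid spacing (cm^-1).
#' @return data.frame with one row per region, ordered by \code{lo}.
#' @export
spectral_regions <- function(lo = c(1000, 3200), hi = c(1900, 3800),
                             scale_factor = c(0.9679, 0.95), grid_step = 2) {
  stopifnot(length(lo) == length(hi), all(lo < hi),
            all(scale_factor > 0), all(scale_factor <= 1.2),
            all(grid_step > 0))
  out <- data.frame(lo = lo, hi = hi,
                    scale_factor = rep_len(scale_factor, length(lo)),
                    grid_step = rep_len(grid_step, length(lo)))
  out <- out[order(out$lo), , drop = FALSE]
  if (nrow(out) > 1L && any(out$lo[-1] < out$hi[-nrow(out)]))
    stop("regions overlap")
  rownames(out) <- NULL
  out
}

#' Scale line frequencies by region
#'
#' Region assignment uses the unscaled frequency; each line's frequency
#' is multiplied by its region's scale factor and intensities are kept.
#' Lines falling outside every region are dropped with a warning; the
#' number dropped is recorded in attribute \code{"dropped"}.
#'
#' @param s a \code{"bh_lines"}.
#' @param regions from \code{\link{spectral_regions}}.
#' @return scaled \code{"bh_lines"}.
#' @export
scale_lines <- function(s, regions = spectral_regions()) {
  reg_of <- rep(NA_integer_, length(s$frequency))
  for (r in seq_len(nrow(regions))) {
    inr <- s$frequency >= regions$lo[r] & s$frequency <= regions$hi[r]
    reg_of[inr] <- r
  }
  dropped <- sum(is.na(reg_of))
  if (dropped > 0)
    warning(sprintf("%d line(s) outside all regions dropped (%s)",
                    dropped, s$label))
  keep <- !is.na(reg_of)
  out <- line_spectrum(s$frequency[keep] * regions$scale_factor[reg_of[keep]],
                       s$intensity[keep], s$label)
  attr(out, "dropped") <- dropped
  out
}

.region_grid <- function(region) seq(region$lo, region$hi, by = region$grid_step)

#' Lorentzian broadening of a line spectrum onto one region grid
#'
#' Each line contributes a Lorentzian of unit peak height scaled by its
#' intensity: I(nu) = sum_k A_k gamma^2 / ((nu - nu_k)^2 + gamma^2) with
#' gamma = fwhm / 2, evaluated on the region grid and then max-normalized
#' to 1 (only relative shape matters downstream).
#'
#' @param s a \code{"bh_lines"} (already frequency-scaled).
#' @param fwhm full width at half maximum (cm^-1, default 15).
#' @param region single-row region data.frame (grid bounds + step).
#' @return object of class \code{"bh_grid"} with one region; empty region
#'   (no lines, all-zero intensity) is marked, not an error.
#' @export
broaden <- function(s, fwhm = 15, region) {
  stopifnot(fwhm > 0, nrow(region) == 1L)
  grid <- .region_grid(region)
  gam <- fwhm / 2
  inten <- numeric(length(grid))
  for (k in seq_along(s$frequency))
    inten <- inten + s$intensity[k] * gam^2 /
      ((grid - s$frequency[k])^2 + gam^2)
  has_lines <- any(s$frequency >= region$lo & s$frequency <= region$hi)
  mx <- max(inten)
  empty <- !has_lines || mx <= 0
  if (mx > 0) inten <- inten / mx
  structure(list(grid = grid, intensity = inten,
                 regions = data.frame(lo = region$lo, hi = region$hi,
                                      n = length(grid), empty = empty),
                 label = s$label),
            class = "bh_grid")
}

#' @export
print.bh_grid <- function(x, ...) {
  cat(sprintf("<bh_grid> %s: %d points in %d region(s)\n", x$label,
              length(x$grid), nrow(x$regions)))
  invisible(x)
}

#' Concatenate per-region grid spectra
#'
#' Regions are ordered by frequency and must not overlap; each region
#' keeps its own normalization (no renormalization across regions).
#'
#' @param parts list of one-region \code{"bh_grid"} objects.
#' @return combined \code{"bh_grid"}.
#' @export
concat_regions <- function(parts) {
  stopifnot(length(parts) >= 1L)
  los <- vapply(parts, function(p) p$regions$lo[1], numeric(1))
  parts <- parts[order(los)]
  reg <- do.call(rbind, lapply(parts, `[[`, "regions"))
  if (nrow(reg) > 1L && any(reg$lo[-1] < reg$hi[-nrow(reg)]))
    stop("regions overlap; cannot concatenate")
  structure(list(grid = unlist(lapply(parts, `[[`, "grid")),
                 intensity = unlist(lapply(parts, `[[`, "intensity")),
                 regions = reg, label = parts[[1]]$label),
            class = "bh_grid")
}

#' Full per-isomer processing pipeline
#'
#' scale -> per-region Lorentzian broadening -> concatenation.
#'
#' @param s a \code{"bh_lines"} (unscaled computed spectrum).
#' @param regions from \code{\link{spectral_regions}}.
#' @param fwhm Lorentzian FWHM (cm^-1).
#' @return a \code{"bh_grid"} over all regions.
#' @export
process_spectrum <- function(s, regions = spectral_regions(), fwhm = 15) {
  sc <- suppressWarnings(scale_lines(s, regions))
  parts <- lapply(seq_len(nrow(regions)), function(r)
    broaden(sc, fwhm, regions[r, , drop = FALSE]))
  concat_regions(parts)
}

#' Euclidean distance between two grid spectra
#'
#' @param a,b \code{"bh_grid"} objects on identical grids.
#' @return scalar distance.
#' @export
euclid <- function(a, b) {
  if (length(a$grid) != length(b$grid) ||
      any(abs(a$grid - b$grid) > 1e-9))
    stop("grid mismatch: spectra are not on the same frequency grid")
  sqrt(sum((a$intensity - b$intensity)^2))
}

#' Scaled similarity scores from a set of Euclidean distances
#'
#' score_i = 1 - (d_i - d_min) / max_j(d_j - d_min). The best-matching
#' isomer scores exactly 1 and the worst exactly 0; scores are invariant
#' under affine rescaling of the distances.
#'
#' @param distances numeric vector of per-isomer Euclidean distances
#'   (>= 2 values, not all equal).
#' @return numeric vector of scores in [0, 1], same names/order.
#' @export
scaled_similarity <- function(distances) {
  d <- as.numeric(distances)
  if (length(d) < 2L) stop("need at least two isomers")
  rng <- max(d) - min(d)
  if (rng <= 0) stop("degenerate set: all distances equal, scores undefined")
  out <- 1 - (d - min(d)) / rng
  names(out) <- names(distances)
  out
}

#' Resample a grid spectrum onto a target grid (linear interpolation)
#'
#' @param gs a \code{"bh_grid"}.
#' @param target a \code{"bh_grid"} supplying the target grid/regions.
#' @return \code{gs} resampled onto \code{target}'s grid.
#' @export
resample_onto <- function(gs, target) {
  inten <- stats::approx(gs$grid, gs$intensity, xout = target$grid,
                         rule = 2)$y
  structure(list(grid = target$grid, intensity = inten,
                 regions = target$regions, label = gs$label),
            class = "bh_grid")
}

#' Rank candidate spectral carriers against an experimental spectrum
#'
#' Runs the full pipeline per isomer (scale -> broaden -> concatenate),
#' resamples onto the experiment's grid if needed, computes Euclidean
#' distances and scaled similarity scores, and returns the report sorted
#' by score (best first).
#'
#' @param computed list of \code{"bh_lines"} (unscaled computed spectra).
#' @param experiment a \code{"bh_grid"} (digitized, normalized
#'   experimental spectrum) or two-column table (frequency, intensity)
#'   which is gridded per region.
#' @param regions from \code{\link{spectral_regions}}.
#' @param fwhm Lorentzian FWHM (cm^-1).
#' @return data.frame (isomer, d_euc, score, rank), sorted by rank.
#' @export
rank_carriers <- function(computed, experiment,
                          regions = spectral_regions(), fwhm = 15) {
  if (!inherits(experiment, "bh_grid")) {
    tab <- as.data.frame(experiment)
    ls <- line_spectrum(tab[[1]], pmax(tab[[2]], 0), "experiment")
    parts <- lapply(seq_len(nrow(regions)), function(r) {
      region <- regions[r, , drop = FALSE]
      grid <- .region_grid(region)
      keep <- ls$frequency >= region$lo & ls$frequency <= region$hi
      inten <- stats::approx(ls$frequency[keep], ls$intensity[keep],
                             xout = grid, rule = 2)$y
      mx <- max(inten)
      structure(list(grid = grid, intensity = if (mx > 0) inten / mx else inten,
                     regions = data.frame(lo = region$lo, hi = region$hi,
                                          n = length(grid), empty = mx <= 0),
                     label = "experiment"),
                class = "bh_grid")
    })
    experiment <- concat_regions(parts)
  }
  labels <- vapply(seq_along(computed), function(i) {
    lb <- computed[[i]]$label
    if (nzchar(lb)) lb else paste0("isomer", i)
  }, character(1))
  d <- vapply(computed, function(s) {
    gs <- process_spectrum(s, regions, fwhm)
    if (length(gs$grid) != length(experiment$grid) ||
        any(abs(gs$grid - experiment$grid) > 1e-9))
      gs <- resample_onto(gs, experiment)
    euclid(gs, experiment)
  }, numeric(1))
  score <- scaled_similarity(d)
  out <- data.frame(isomer = labels, d_euc = d, score = score)
  out <- out[order(-out$score, out$d_euc), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Read a two-column spectrum table
#'
#' Whitespace- or comma-delimited (frequency cm^-1, intensity), with or
#' without a header.
#'
#' @param path file path.
#' @return data.frame with columns \code{frequency}, \code{intensity}.
#' @export
read_spectrum_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  header <- !grepl("^[-+0-9.eE \t,]+$", first)
  tab <- utils::read.table(path, header = header, sep = sep)
  out <- data.frame(frequency = as.numeric(tab[[1]]),
                    intensity = as.numeric(tab[[2]]))
  out
}
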