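#' Default DBSCAN neighbour radius for a window size
#'
#' The neighbour radius defaults to the diagonal of the sliding window,
#' rounded up to the next micrometre, so that diagonally adjacent window
#' centers are always neighbours: 142 um for the default 100 um window.
#'
#' @param window_side window side length in um.
#' @return Radius in um.
#' @export
default_eps <- function(window_side) {
  if (window_side <= 0) stop("`window_side` must be > 0", call. = FALSE)
  ceiling(window_side * sqrt(2))
}

#' DBSCAN density clustering of points
#'
#' Standard DBSCAN: a core point has at least `min_size` neighbours within
#' `eps` (itself included); clusters are the connected components of core
#' points under the eps-neighbour relation, border points join the first
#' core cluster that reaches them in scan order, and the rest is noise.
#'
#' @param x,y point coordinates.
#' @param eps neighbour radius (same units as the coordinates).
#' @param min_size minimum neighbourhood size for a core point.
#' @return Integer cluster labels (0 = noise), in input order.
#' @export
dbscan_points <- function(x, y, eps, min_size) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  if (eps <= 0) stop("`eps` must be > 0", call. = FALSE)
  if (min_size < 1) stop("`min_size` must be >= 1", call. = FALSE)
  d <- as.matrix(stats::dist(cbind(x, y)))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nb) >= min_size
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue) > 0L) {
      j <- queue[1L]; queue <- queue[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Cluster flagged outlier windows into proximal regions
#'
#' Runs DBSCAN on the centers of outlier windows, separately per section;
#' surviving clusters are the proximal activation regions, while noise
#' windows stay distal. Cluster ids are unique across sections.
#'
#' @param flags data frame with `section_id`, `x_um`, `y_um`, `is_outlier`.
#' @param eps neighbour radius in um (default [default_eps()] of 100 um).
#' @param min_size minimum cluster size.
#' @return The input with an added integer `proximal_id` column (0 = not in
#'   a proximal cluster).
#' @export
cluster_proximal <- function(flags, eps = default_eps(100), min_size = 5) {
  flags$proximal_id <- 0L
  offset <- 0L
  for (sec in unique(flags$section_id)) {
    sel <- which(flags$section_id == sec & flags$is_outlier)
    if (length(sel) == 0L) next
    lab <- dbscan_points(flags$x_um[sel], flags$y_um[sel], eps, min_size)
    lab[lab > 0L] <- lab[lab > 0L] + offset
    offset <- offset + max(0L, max(lab))
    flags$proximal_id[sel] <- lab
  }
  flags
}

#' Elbow threshold of a sorted intensity curve
#'
#' Sorts the values ascending, scales rank to `[0, 1]`, and finds the point
#' of maximum perpendicular distance to the chord joining the first and last
#' points (the elbow). For stability the procedure is repeated, dropping the
#' leading point each time until three points remain, and the modal elbow
#' (by identity in the sorted sequence) provides the threshold value. The
#' first-iteration maximum perpendicular magnitude must exceed
#' `magnitude_floor` (strictly) for the threshold to be considered usable:
#' a near-linear curve has no meaningful elbow.
#'
#' @param values numeric vector (integrated-density z-scores of proximal
#'   windows of one section).
#' @param magnitude_floor minimum first-iteration perpendicular magnitude.
#' @return List of class `gc_elbow`: `threshold_value`, `max_perp_magnitude`,
#'   `modal_index` (rank in the ascending sequence), `passes_floor`, `n`.
#' @export
elbow_threshold <- function(values, magnitude_floor = 0.5) {
  n <- length(values)
  if (n < 3L)
    return(structure(list(threshold_value = NA_real_, max_perp_magnitude = 0,
                          modal_index = NA_integer_, passes_floor = FALSE,
                          n = n), class = "gc_elbow"))
  v <- sort(values)
  elbow_of <- function(idx) {
    m <- length(idx)
    xx <- (seq_len(m) - 1) / (m - 1)
    yy <- v[idx]
    dx <- xx[m] - xx[1L]; dy <- yy[m] - yy[1L]
    len <- sqrt(dx^2 + dy^2)
    perp <- abs(dx * (yy - yy[1L]) - dy * (xx - xx[1L])) / len
    list(which = idx[which.max(perp)], mag = max(perp))
  }
  first <- elbow_of(seq_len(n))
  picks <- integer(0)
  start <- 1L
  while (n - start + 1L >= 3L) {
    picks <- c(picks, elbow_of(start:n)$which)
    start <- start + 1L
  }
  tab <- table(picks)
  modal <- as.integer(names(tab)[tab == max(tab)])
  modal <- min(modal)  # tie: smaller threshold, more inclusive focal set
  structure(list(threshold_value = v[modal],
                 max_perp_magnitude = first$mag,
                 modal_index = modal,
                 passes_floor = first$mag > magnitude_floor,
                 n = n),
            class = "gc_elbow")
}

#' @export
print.gc_elbow <- function(x, ...) {
  cat(sprintf("<elbow> n = %d, threshold = %s, |A1Bx|max = %.3f, usable = %s\n",
              x$n, format(x$threshold_value, digits = 4),
              x$max_perp_magnitude, x$passes_floor))
  invisible(x)
}

#' Identify focal sub-clusters inside proximal regions
#'
#' Per section, computes the elbow threshold of the proximal windows'
#' integrated-density z-scores; if the elbow magnitude clears the floor,
#' proximal windows with integrated density above the threshold are
#' re-clustered with DBSCAN (default radius 142 um, minimum size 5) to give
#' focal clusters — the hyperintense core of the activation region.
#'
#' @param flags output of [cluster_proximal()] with an `IntDen_z` column.
#' @param eps,min_size DBSCAN parameters for the focal pass.
#' @param magnitude_floor elbow magnitude floor.
#' @return The input with an added `focal_id` column (0 = not focal), plus
#'   attribute `elbows`: the per-section `gc_elbow` results.
#' @export
cluster_focal <- function(flags, eps = default_eps(100), min_size = 5,
                          magnitude_floor = 0.5) {
  flags$focal_id <- 0L
  elbows <- list()
  offset <- 0L
  for (sec in unique(flags$section_id)) {
    sel <- which(flags$section_id == sec & flags$proximal_id > 0L)
    el <- elbow_threshold(flags$IntDen_z[sel], magnitude_floor)
    elbows[[as.character(sec)]] <- el
    if (!el$passes_floor) next
    hot <- sel[flags$IntDen_z[sel] > el$threshold_value]
    if (length(hot) == 0L) next
    lab <- dbscan_points(flags$x_um[hot], flags$y_um[hot], eps, min_size)
    lab[lab > 0L] <- lab[lab > 0L] + offset
    offset <- offset + max(0L, max(lab))
    flags$focal_id[hot] <- lab
  }
  attr(flags, "elbows") <- elbows
  flags
}

#' Assign every test window a region label
#'
#' Completes the labeling into the three-way spatial taxonomy: `focal`
#' (inside a focal cluster, a subset of proximal), `proximal` (in a proximal
#' cluster but not focal) and `distal` (everything else — windows of typical
#' morphology).
#'
#' @param flags output of [cluster_focal()] (or [cluster_proximal()]).
#' @return The input with a `region` factor column.
#' @export
assign_regions <- function(flags) {
  if (is.null(flags$focal_id)) flags$focal_id <- 0L
  flags$region <- factor(ifelse(flags$focal_id > 0L, "focal",
                         ifelse(flags$proximal_id > 0L, "proximal", "distal")),
                         levels = c("distal", "proximal", "focal"))
  flags
}

# occupied-cell keys of the union of axis-aligned squares (side um) centered
# at (cx, cy), rasterized on a `cell`-um grid; exact when edges fall on cell
# boundaries (they do for origin-anchored windows when cell divides stride)
footprint_cells <- function(cx, cy, side, cell = side / 4) {
  if (length(cx) == 0L) return(integer(0))
  half <- side / 2
  per <- round(side / cell)
  keys <- integer(0)
  big <- 2^16
  for (i in seq_along(cx)) {
    ix0 <- round((cx[i] - half) / cell)
    iy0 <- round((cy[i] - half) / cell)
    gx <- ix0 + seq_len(per) - 1L
    gy <- iy0 + seq_len(per) - 1L
    keys <- c(keys, as.vector(outer(gx, gy * big, `+`)))
  }
  unique(keys)
}

#' Area of a cluster footprint
#'
#' Area of the union of the member windows' squares (overlaps counted once),
#' computed by exact grid rasterization.
#'
#' @param cx,cy member window centers in um.
#' @param side window side in um.
#' @param cell rasterization cell in um (must divide the window stride for
#'   exactness; default `side/4`).
#' @return Area in um^2.
#' @export
footprint_area <- function(cx, cy, side, cell = side / 4) {
  length(footprint_cells(cx, cy, side, cell)) * cell^2
}

#' Per-region cluster area fractions
#'
#' Fraction of the section's tissue area covered by proximal and focal
#' cluster footprints (union of member window squares, overlaps counted
#' once).
#'
#' @param flags labelled window table ([assign_regions()] output).
#' @param tissue_area section tissue area in um^2.
#' @param side window side in um.
#' @return Named numeric: `proximal` and `focal` fractions.
#' @export
cluster_area_fraction <- function(flags, tissue_area, side = 100) {
  if (tissue_area <= 0) stop("`tissue_area` must be > 0", call. = FALSE)
  prox <- flags$proximal_id > 0L
  foc <- flags$focal_id > 0L
  c(proximal = footprint_area(flags$x_um[prox], flags$y_um[prox], side) / tissue_area,
    focal = footprint_area(flags$x_um[foc], flags$y_um[foc], side) / tissue_area)
}

#' Overlap between two cluster footprints
#'
#' Intersection area of two footprints expressed as a fraction of each
#' footprint's own area — e.g. how much of the astrocyte activation area
#' lies inside the microglial activation area and vice versa.
#'
#' @param ax,ay window centers of footprint A (um).
#' @param bx,by window centers of footprint B (um).
#' @param side window side in um.
#' @param cell rasterization cell in um.
#' @return Named numeric: `frac_A_in_B`, `frac_B_in_A`.
#' @export
cluster_overlap <- function(ax, ay, bx, by, side = 100, cell = side / 4) {
  ca <- footprint_cells(ax, ay, side, cell)
  cb <- footprint_cells(bx, by, side, cell)
  inter <- length(intersect(ca, cb))
  c(frac_A_in_B = if (length(ca) > 0) inter / length(ca) else 0,
    frac_B_in_A = if (length(cb) > 0) inter / length(cb) else 0)
}

#' Intersection-over-union of two footprints
#'
#' @inheritParams cluster_overlap
#' @return IoU in `[0, 1]`.
#' @export
footprint_iou <- function(ax, ay, bx, by, side = 100, cell = side / 4) {
  ca <- footprint_cells(ax, ay, side, cell)
  cb <- footprint_cells(bx, by, side, cell)
  u <- length(union(ca, cb))
  if (u == 0L) return(0)
  length(intersect(ca, cb)) / u
}
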