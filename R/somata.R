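# IsoData (iterative intermeans) global threshold over the full histogram
isodata_threshold <- function(px) {
  v <- as.numeric(px)
  if (max(v) == min(v)) return(Inf)
  t <- mean(v)
  repeat {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < 1e-8) break
    t <- t_new
  }
  t
}

# chain-code perimeter of one labelled object (sqrt(2)-weighted diagonal
# steps); after the morphological opening in the segmentation chain the
# boundary is smooth enough that the uncorrected chain length tracks the
# true perimeter (validated on rendered disks)
contour_perimeter_px <- function(contour) {
  p <- rbind(contour, contour[1, , drop = FALSE])
  d <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  sum(d)
}

#' Segment cell somata
#'
#' Simplified soma-segmentation chain for counting cells and measuring soma
#' size, circularity and nearest-neighbour distance: morphological opening
#' (disk radius 2 px) to strip thin processes, a white top-hat to flatten
#' large-scale intensity structure, then a global IsoData threshold
#' (microglia) or a permissive Phansalkar local threshold (astrocyte soma
#' channel), connected components and a minimum-size filter (25 px for
#' microglia, 30 px for astrocytes).
#'
#' @param plane an [image_plane] preprocessed with `protocol = "soma"`.
#' @param protocol `"microglia"` or `"astrocyte"`.
#' @param min_px override the protocol's minimum component size in pixels.
#' @param tophat_radius radius (px) of the box element of the white top-hat.
#' @return Data frame with one row per soma: `cx, cy` (centroid, um),
#'   `area_um2`, `perimeter_um`, `circularity` (`4*pi*A/P^2`) and `nnd_um`
#'   (Euclidean nearest-neighbour distance between soma centers; with a
#'   single soma, the window-diagonal fallback is left to the caller and
#'   `nnd_um` is `NA`).
#' @export
segment_somata <- function(plane, protocol = c("microglia", "astrocyte"),
                           min_px = NULL, tophat_radius = 12L) {
  protocol <- match.arg(protocol)
  if (is.null(min_px)) min_px <- if (protocol == "microglia") 25L else 30L
  px <- plane$pixels
  empty <- data.frame(cx = numeric(0), cy = numeric(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), circularity = numeric(0),
                      nnd_um = numeric(0))
  if (max(px) <= 0) return(empty)
  img <- EBImage::Image(px / max(px))
  img <- EBImage::opening(img, EBImage::makeBrush(5L, "disc"))
  img <- EBImage::whiteTopHat(img, EBImage::makeBrush(2L * tophat_radius + 1L, "box"))
  dat <- EBImage::imageData(img)
  if (protocol == "microglia") {
    t <- isodata_threshold(dat)
    # contrast guard: a threshold inside the background-noise band means the
    # section has no somata to segment
    if (!is.finite(t) ||
        t < stats::median(dat) + 4 * stats::mad(dat) + 1e-12)
      return(empty)
    fg <- dat > t
  } else {
    fg <- local_threshold(image_plane(dat, scale = plane$scale),
                          threshold_config(radius = 60, k = 0.15, r = 0.5))
  }
  if (!any(fg)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(as.numeric(fg), dim = dim(fg)))
  sizes <- tabulate(EBImage::imageData(lab))
  keep <- which(sizes >= min_px)
  if (length(keep) == 0L) return(empty)
  labd <- EBImage::imageData(lab)
  labd[!(labd %in% keep)] <- 0
  # relabel compactly so ocontour/moments line up
  relab <- match(labd, c(0, keep)) - 1
  lab2 <- EBImage::Image(relab, dim = dim(labd))
  mom <- EBImage::computeFeatures.moment(lab2)
  contours <- EBImage::ocontour(lab2)
  s <- plane$scale
  n <- nrow(mom)
  area_px <- sizes[keep]
  perim_px <- vapply(seq_len(n), function(k) contour_perimeter_px(contours[[k]]),
                     numeric(1))
  out <- data.frame(cx = mom[, "m.cx"] / s, cy = mom[, "m.cy"] / s,
                    area_um2 = area_px / s^2,
                    perimeter_um = perim_px / s,
                    circularity = 4 * pi * area_px / pmax(perim_px, 1e-9)^2,
                    nnd_um = NA_real_)
  if (n >= 2L) {
    d <- as.matrix(stats::dist(cbind(out$cx, out$cy)))
    diag(d) <- Inf
    out$nnd_um <- apply(d, 1, min)
  }
  rownames(out) <- NULL
  out
}
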