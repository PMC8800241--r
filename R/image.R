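#' Single-channel image plane
#'
#' Container for one immunofluorescence channel of one section: a nonnegative
#' intensity matrix plus the pixel scale that converts pixel indices to
#' micrometres. The matrix is indexed `[x, y]` (column-major x fastest), the
#' same orientation EBImage uses, so pixel `(i, j)` sits at
#' `((i - 0.5)/scale, (j - 0.5)/scale)` um.
#'
#' @param pixels numeric matrix of nonnegative intensities, indexed `[x, y]`.
#' @param scale pixels per micrometre (default 1.5, i.e. 20x magnification).
#' @param channel label for the stain, e.g. `"IBA1"`, `"GFAP"`, `"S100B"`.
#' @param tissue_mask optional logical matrix of the same shape; `FALSE`
#'   pixels are outside the tissue region of interest.
#' @return An object of class `image_plane`.
#' @export
image_plane <- function(pixels, scale = 1.5, channel = "IBA1", tissue_mask = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (anyNA(pixels) || any(pixels < 0))
    stop("`pixels` must be nonnegative and free of NA", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("`scale` must be a single positive number (px/um)", call. = FALSE)
  if (!is.null(tissue_mask)) {
    if (!identical(dim(tissue_mask), dim(pixels)))
      stop("`tissue_mask` shape must match `pixels`", call. = FALSE)
    tissue_mask <- matrix(as.logical(tissue_mask), nrow(pixels), ncol(pixels))
  }
  structure(list(pixels = pixels, scale = scale, channel = channel,
                 tissue_mask = tissue_mask),
            class = "image_plane")
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %d x %d px (%.1f x %.1f um), channel %s, scale %.3g px/um%s\n",
              nrow(x$pixels), ncol(x$pixels),
              nrow(x$pixels) / x$scale, ncol(x$pixels) / x$scale,
              x$channel, x$scale,
              if (is.null(x$tissue_mask)) "" else ", with tissue mask"))
  invisible(x)
}

#' Maximum-intensity projection of a z-stack
#'
#' Collapses a list of planes (one per z-slice) into a single plane by taking
#' the per-pixel maximum, the usual reduction applied to confocal z-stacks
#' before 2-D morphometry.
#'
#' @param zstack list of [image_plane] objects with identical shapes and scales.
#' @return A single [image_plane].
#' @export
project_max <- function(zstack) {
  if (inherits(zstack, "image_plane")) zstack <- list(zstack)
  if (length(zstack) < 1L) stop("need at least one plane", call. = FALSE)
  ref <- zstack[[1L]]
  px <- ref$pixels
  for (p in zstack[-1L]) {
    if (!identical(dim(p$pixels), dim(px)))
      stop("z-stack planes have mismatched shapes", call. = FALSE)
    if (p$scale != ref$scale)
      stop("z-stack planes have mismatched scales", call. = FALSE)
    px <- pmax(px, p$pixels)
  }
  image_plane(px, scale = ref$scale, channel = ref$channel,
              tissue_mask = ref$tissue_mask)
}

# Grayscale opening computed on a downsampled copy: the fast approximation of
# rolling-ball background estimation for large radii.
rolling_background <- function(px, radius) {
  shrink <- max(1L, as.integer(round(radius / 10)))
  top <- max(px)          # EBImage grayscale morphology clamps above 1
  px <- px / top
  img <- EBImage::Image(px)
  if (shrink > 1L) {
    small <- EBImage::resize(img, w = max(3L, ceiling(nrow(px) / shrink)),
                             h = max(3L, ceiling(ncol(px) / shrink)))
    r_small <- max(1L, as.integer(round(radius / shrink)))
    bg <- EBImage::opening(small, EBImage::makeBrush(2L * r_small + 1L, "disc"))
    bg <- EBImage::resize(bg, w = nrow(px), h = ncol(px))
  } else {
    bg <- EBImage::opening(img, EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc"))
  }
  pmin(EBImage::imageData(bg), px) * top
}

#' Preprocess a plane for feature extraction
#'
#' Applies the standard cleanup chain: rolling-ball background subtraction
#' (radius 50 px), a 3x3 median despeckle, and, for the astrocyte branching
#' protocol, a saturated-percentile contrast stretch so faint distal processes
#' survive thresholding. Pixels outside the tissue mask are cleared.
#'
#' @param plane an [image_plane].
#' @param protocol `"microglia"`, `"astrocyte_branching"` or `"soma"`.
#' @param background_radius rolling-ball radius in pixels.
#' @param saturation fraction of pixels saturated by the contrast stretch
#'   (astrocyte branching protocol only).
#' @return The preprocessed [image_plane].
#' @export
preprocess_plane <- function(plane,
                             protocol = c("microglia", "astrocyte_branching", "soma"),
                             background_radius = 50,
                             saturation = 0.0035) {
  protocol <- match.arg(protocol)
  px <- plane$pixels
  if (max(px) > 0) {
    px <- px - rolling_background(px, background_radius)
    px[px < 0] <- 0
    top <- max(px)
    if (top > 0) {
      px <- EBImage::imageData(EBImage::medianFilter(EBImage::Image(px / top), 1L)) * top
    }
    if (protocol == "astrocyte_branching" && max(px) > 0) {
      hi <- stats::quantile(px[px > 0], 1 - saturation, names = FALSE)
      if (hi > 0) px <- pmin(px, hi) / hi * max(px)
    }
  }
  if (!is.null(plane$tissue_mask)) px[!plane$tissue_mask] <- 0
  image_plane(px, scale = plane$scale, channel = plane$channel,
              tissue_mask = plane$tissue_mask)
}

#' Local threshold configuration
#'
#' Parameters of the Phansalkar local adaptive threshold used to binarize the
#' stain channel before skeleton and area measurements.
#'
#' @param method currently only `"phansalkar"`.
#' @param radius neighbourhood radius in pixels (default 60).
#' @param k sensitivity coefficient on the local standard deviation.
#' @param r normalisation constant for the local standard deviation.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(method = "phansalkar", radius = 60, k = 0.25, r = 0.5) {
  method <- match.arg(method, "phansalkar")
  if (radius < 1) stop("`radius` must be >= 1", call. = FALSE)
  structure(list(method = method, radius = as.integer(radius), k = k, r = r),
            class = "threshold_config")
}

#' Phansalkar local adaptive threshold
#'
#' Binarizes an intensity image with the Phansalkar rule, designed for stained
#' images with low-contrast foreground: a pixel with normalised intensity
#' `v` is foreground iff `v > m * (1 + p*exp(-q*m) + k*(s/r - 1))` where `m`
#' and `s` are the local mean and standard deviation in a disk neighbourhood
#' and `p = 2`, `q = 10`. Intensities are normalised to `[0, 1]` by the image
#' maximum before evaluation.
#'
#' @param plane an [image_plane].
#' @param cfg a [threshold_config].
#' @return Logical matrix (same shape as the plane) of foreground pixels.
#' @export
local_threshold <- function(plane, cfg = threshold_config()) {
  px <- plane$pixels
  top <- max(px)
  if (top <= 0) return(matrix(FALSE, nrow(px), ncol(px)))
  v <- px / top
  # the neighbourhood cannot exceed the image
  radius <- min(cfg$radius, (min(dim(px)) - 1L) %/% 2L)
  brush <- EBImage::makeBrush(2L * radius + 1L, "disc")
  brush <- brush / sum(brush)
  m <- EBImage::imageData(EBImage::filter2(EBImage::Image(v), brush, boundary = "replicate"))
  m2 <- EBImage::imageData(EBImage::filter2(EBImage::Image(v * v), brush, boundary = "replicate"))
  s <- sqrt(pmax(m2 - m * m, 0))
  thr <- m * (1 + 2 * exp(-10 * m) + cfg$k * (s / cfg$r - 1))
  # a pixel with no local contrast (s = 0, as in a uniform image) is never
  # foreground: there is nothing to segment locally
  v > thr & s > 1e-6
}

#' Window-level intensity features
#'
#' Measures the classic ImageJ intensity triple over the thresholded
#' foreground inside one window: `Mean` (mean intensity of foreground
#' pixels), `IntDen` (mean times foreground pixel count) and `Area`
#' (foreground area in um^2).
#'
#' @param plane an [image_plane].
#' @param mask logical foreground matrix from [local_threshold()].
#' @param window numeric vector `c(x0, y0, x1, y1)` in um.
#' @return Named numeric vector `c(mean, integrated_density, area_um2)`;
#'   all zero when the window has no foreground.
#' @export
intensity_features <- function(plane, mask, window) {
  idx <- window_px_index(plane, window)
  fg <- mask[idx$xs, idx$ys, drop = FALSE]
  n <- sum(fg)
  if (n == 0L)
    return(c(mean = 0, integrated_density = 0, area_um2 = 0))
  vals <- plane$pixels[idx$xs, idx$ys, drop = FALSE][fg]
  m <- mean(vals)
  c(mean = m, integrated_density = m * n, area_um2 = n / plane$scale^2)
}

# pixel index ranges covered by a um-coordinate window
window_px_index <- function(plane, window) {
  s <- plane$scale
  xs <- (floor(window[1] * s) + 1L):min(nrow(plane$pixels), ceiling(window[3] * s))
  ys <- (floor(window[2] * s) + 1L):min(ncol(plane$pixels), ceiling(window[4] * s))
  list(xs = xs, ys = ys)
}

#' Pearson colocalization of two channels
#'
#' Pixel-wise Pearson correlation between two channels inside a region of
#' interest, the standard colocalization statistic for double-labelled
#' sections.
#'
#' @param planeA,planeB [image_plane] objects of identical shape.
#' @param roi optional logical matrix selecting pixels; default all pixels.
#' @return List with `R` (correlation), `n_pixels` and `roi` label.
#' @export
pearson_coloc <- function(planeA, planeB, roi = NULL) {
  if (!identical(dim(planeA$pixels), dim(planeB$pixels)))
    stop("channel shapes differ", call. = FALSE)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(planeA$pixels), ncol(planeA$pixels))
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  a <- planeA$pixels[roi]; b <- planeB$pixels[roi]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant channel inside ROI: correlation undefined", call. = FALSE)
  list(R = stats::cor(a, b), n_pixels = length(a), roi = "roi")
}
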