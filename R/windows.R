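#' Sliding-window specification
#'
#' Geometry of the sliding window used for feature extraction: a square of
#' `side` um translated across the section with fractional `overlap` between
#' successive positions (default 100 um windows at 50% overlap).
#'
#' @param side window side length in um.
#' @param overlap fraction of overlap between adjacent windows, in `[0, 1)`.
#' @param min_tissue_fraction drop windows whose tissue-mask coverage is below
#'   this fraction (default 0: keep all windows; off-tissue pixels are cleared
#'   during preprocessing instead).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(side = 100, overlap = 0.5, min_tissue_fraction = 0) {
  if (side <= 0) stop("`side` must be positive", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)", call. = FALSE)
  if (min_tissue_fraction < 0 || min_tissue_fraction > 1)
    stop("`min_tissue_fraction` must be in [0, 1]", call. = FALSE)
  structure(list(side = side, overlap = overlap,
                 min_tissue_fraction = min_tissue_fraction),
            class = "window_spec")
}

#' Enumerate sliding-window positions over a plane
#'
#' Lays an axis-aligned grid of square windows over the section, anchored at
#' the image origin with stride `side * (1 - overlap)`. Windows that would
#' extend past the image edge are dropped, as are windows with insufficient
#' tissue coverage when a mask and `min_tissue_fraction > 0` are supplied.
#'
#' @param plane an [image_plane].
#' @param spec a [window_spec].
#' @return Data frame with one row per window: `x0, y0, x1, y1` (bounds, um)
#'   and `cx, cy` (center, um). Empty (with a warning) when the image is
#'   smaller than one window.
#' @export
enumerate_windows <- function(plane, spec = window_spec()) {
  Lx <- nrow(plane$pixels) / plane$scale
  Ly <- ncol(plane$pixels) / plane$scale
  side <- spec$side
  stride <- side * (1 - spec$overlap)
  tol <- 1e-9
  if (Lx + tol < side || Ly + tol < side) {
    warning("image smaller than one window; no windows enumerated")
    return(data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), cx = numeric(0), cy = numeric(0)))
  }
  nx <- floor((Lx - side) / stride + tol) + 1
  ny <- floor((Ly - side) / stride + tol) + 1
  x0 <- rep((seq_len(nx) - 1) * stride, times = ny)
  y0 <- rep((seq_len(ny) - 1) * stride, each = nx)
  win <- data.frame(x0 = x0, y0 = y0, x1 = x0 + side, y1 = y0 + side,
                    cx = x0 + side / 2, cy = y0 + side / 2)
  if (!is.null(plane$tissue_mask) && spec$min_tissue_fraction > 0) {
    keep <- vapply(seq_len(nrow(win)), function(i) {
      idx <- window_px_index(plane, as.numeric(win[i, c("x0", "y0", "x1", "y1")]))
      mean(plane$tissue_mask[idx$xs, idx$ys]) >= spec$min_tissue_fraction
    }, logical(1))
    win <- win[keep, , drop = FALSE]
    rownames(win) <- NULL
  }
  win
}
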