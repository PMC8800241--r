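#' Feature-table column schema
#'
#' The per-window feature table is the central exchange format: one row per
#' sliding-window position with spatial coordinates and the morphometric
#' features. `feature_columns()` returns the model features of each stain
#' set: 13 for microglia (intensity, fractal dimension, soma and branch
#' morphometry) and 7 for astrocytes (intensity and branch measures only,
#' since GFAP labels processes rather than whole cells).
#'
#' @param feature_set `"microglia"` or `"astrocyte"`.
#' @return Character vector of model feature column names.
#' @export
feature_columns <- function(feature_set = c("microglia", "astrocyte")) {
  feature_set <- match.arg(feature_set)
  if (feature_set == "microglia")
    c("Area", "Mean", "FracDim", "NumCells", "MeanNND", "MeanSomaArea",
      "MeanSomaCirc", "NumBranches", "BranchLength", "NumJunctions",
      "NumTriplePoints", "NumEndPoints", "Perimeter")
  else
    c("Area", "Mean", "NumJunctions", "NumEndPoints", "NumSlabPixels",
      "NumTriplePoints", "Perimeter")
}

# full CSV schema (module boundary; drop-in compatible with externally
# produced window tables)
feature_table_schema <- function() {
  c("section_id", "group", "x_um", "y_um",
    "Area", "Mean", "IntDen", "FracDim", "NumCells", "MeanNND",
    "MeanSomaArea", "MeanSomaCirc", "NumBranches", "BranchLength",
    "NumJunctions", "NumTriplePoints", "NumEndPoints", "NumSlabPixels",
    "Perimeter")
}

#' Extract the per-window morphometric feature table from image planes
#'
#' Runs the full window-level extraction: preprocessing, Phansalkar
#' thresholding, per-window intensity features (Mean, IntDen, Area),
#' box-counting fractal dimension, skeleton branch statistics, foreground
#' perimeter, and soma-derived features (count, mean nearest-neighbour
#' distance, mean soma area and circularity) from somata whose centroid falls
#' inside the window. Windows without somata report zero for the soma
#' features so that every window remains classifiable; a section with exactly
#' one soma uses the window diagonal as its nearest-neighbour distance.
#'
#' @param planes named list of [image_plane] objects. The microglia set needs
#'   one element (any name; the first is used). The astrocyte set needs a
#'   `branching` plane (GFAP-like) and, only if soma features are wanted, a
#'   `soma` plane (S100B-like).
#' @param spec a [window_spec].
#' @param cfg a [threshold_config].
#' @param feature_set `"microglia"` or `"astrocyte"`.
#' @param section_id,group row labels (`group` is `"control"` or `"test"`).
#' @param preprocessed set `TRUE` when `planes` have already been passed
#'   through [preprocess_plane()].
#' @return Data frame in the feature-table schema, one row per window, with
#'   attributes `feature_set` and `window_side`. Columns not in the chosen
#'   feature set (beyond Mean/IntDen, always kept) are `NA`.
#' @export
build_feature_table <- function(planes, spec = window_spec(),
                                cfg = threshold_config(),
                                feature_set = c("microglia", "astrocyte"),
                                section_id = "S1", group = "test",
                                preprocessed = FALSE) {
  feature_set <- match.arg(feature_set)
  if (inherits(planes, "image_plane")) planes <- list(planes)
  if (feature_set == "microglia") {
    if (length(planes) < 1L) stop("microglia set needs one channel", call. = FALSE)
    raw <- planes[[1L]]
    main <- if (preprocessed) raw else preprocess_plane(raw, "microglia")
    soma_plane <- if (preprocessed) raw else preprocess_plane(raw, "soma")
    somata <- segment_somata(soma_plane, "microglia")
    want_soma <- TRUE
  } else {
    if (is.null(planes$branching))
      stop("astrocyte set needs a `branching` channel", call. = FALSE)
    raw <- planes$branching
    main <- if (preprocessed) raw else preprocess_plane(raw, "astrocyte_branching")
    want_soma <- !is.null(planes$soma)
    somata <- if (want_soma) {
      sp <- if (preprocessed) planes$soma else preprocess_plane(planes$soma, "soma")
      segment_somata(sp, "astrocyte")
    } else NULL
  }
  win <- enumerate_windows(main, spec)
  mask <- local_threshold(main, cfg)
  scale <- main$scale
  n <- nrow(win)
  out <- as.data.frame(matrix(NA_real_, n, length(feature_table_schema()) - 4L))
  names(out) <- feature_table_schema()[-(1:4)]
  out <- cbind(data.frame(section_id = rep(section_id, n),
                          group = rep(group, n),
                          x_um = win$cx, y_um = win$cy,
                          stringsAsFactors = FALSE), out)
  single_soma_nnd <- spec$side * sqrt(2)
  for (i in seq_len(n)) {
    rect <- as.numeric(win[i, c("x0", "y0", "x1", "y1")])
    idx <- window_px_index(main, rect)
    mwin <- mask[idx$xs, idx$ys, drop = FALSE]
    iv <- intensity_features(main, mask, rect)
    out$Mean[i] <- iv[["mean"]]
    out$IntDen[i] <- iv[["integrated_density"]]
    out$Area[i] <- iv[["area_um2"]]
    sk <- skeleton_stats(mwin, scale)
    out$NumBranches[i] <- sk$n_branches
    out$BranchLength[i] <- sk$total_branch_length
    out$NumJunctions[i] <- sk$n_junctions
    out$NumTriplePoints[i] <- sk$n_triple_points
    out$NumEndPoints[i] <- sk$n_end_points
    out$NumSlabPixels[i] <- sk$n_slab_pixels
    out$Perimeter[i] <- mask_perimeter(mwin, scale)
    if (feature_set == "microglia")
      out$FracDim[i] <- fractal_dimension(mwin)
    if (want_soma) {
      inside <- somata$cx >= rect[1] & somata$cx < rect[3] &
                somata$cy >= rect[2] & somata$cy < rect[4]
      k <- sum(inside)
      out$NumCells[i] <- k
      if (k > 0L) {
        sub <- somata[inside, , drop = FALSE]
        nnd <- sub$nnd_um
        nnd[is.na(nnd)] <- single_soma_nnd
        out$MeanNND[i] <- mean(nnd)
        out$MeanSomaArea[i] <- mean(sub$area_um2)
        out$MeanSomaCirc[i] <- mean(sub$circularity)
      } else {
        out$MeanNND[i] <- 0
        out$MeanSomaArea[i] <- 0
        out$MeanSomaCirc[i] <- 0
      }
    }
  }
  keep_na <- setdiff(names(out)[-(1:4)],
                     union(feature_columns(feature_set), c("Mean", "IntDen")))
  if (feature_set == "astrocyte" && want_soma)
    keep_na <- setdiff(keep_na, c("NumCells", "MeanNND", "MeanSomaArea", "MeanSomaCirc"))
  for (cn in setdiff(names(out)[-(1:4)], keep_na))
    if (anyNA(out[[cn]])) out[[cn]][is.na(out[[cn]])] <- 0
  attr(out, "feature_set") <- feature_set
  attr(out, "window_side") <- spec$side
  out
}
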