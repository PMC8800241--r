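#' Fit an activation-detection model on control tissue
#'
#' The core estimator: given a per-window feature table from control tissue
#' only, fits (1) a z-score normalizer, (2) a PCA projection retaining 99% of
#' variance, and (3) a one-class SVM over the retained PC scores. The fitted
#' model defines "typical" glial morphology; applying it to test tissue with
#' [predict.gliaclust()] flags morphological outlier windows and segments
#' them into proximal and focal activation clusters.
#'
#' @param control control feature table (data frame in the feature-table
#'   schema; see [build_feature_table()] / [read_feature_csv()]).
#' @param feature_set `"microglia"` (13 features) or `"astrocyte"` (7);
#'   defaults to the table's `feature_set` attribute.
#' @param nu one-class SVM nu: upper bound on the fraction of control
#'   windows outside the boundary.
#' @param gamma RBF kernel parameter.
#' @param variance_target PCA cumulative variance fraction to retain.
#' @param intensity_floor mean-intensity z-score floor; flagged outliers at
#'   or below it are demoted (suppresses hypointense artefacts).
#' @param window_side sliding-window side in um (defaults to the table's
#'   `window_side` attribute, else 100).
#' @return An object of class `gliaclust`.
#' @seealso [predict.gliaclust()], [tune_gliaclust()]
#' @export
gliaclust <- function(control, feature_set = NULL, nu = 0.1, gamma = 0.1,
                      variance_target = 0.99, intensity_floor = -1,
                      window_side = NULL) {
  if (is.null(feature_set))
    feature_set <- attr(control, "feature_set") %||% "microglia"
  feature_set <- match.arg(feature_set, c("microglia", "astrocyte"))
  if (is.null(window_side))
    window_side <- attr(control, "window_side") %||% 100
  control <- control[order(control$section_id, control$y_um, control$x_um), ]
  feats <- feature_columns(feature_set)
  norm <- fit_normalizer(control, union(feats, intersect(c("Mean", "IntDen"),
                                                         names(control))))
  z <- apply_normalizer(norm, control)
  proj <- fit_projection(z, intersect(feats, norm$features), variance_target)
  scores <- apply_projection(proj, z)
  svm <- fit_ocsvm(scores, nu = nu, gamma = gamma)
  structure(list(normalizer = norm, projection = proj, svm = svm,
                 feature_set = feature_set,
                 nu = nu, gamma = gamma,
                 variance_target = variance_target,
                 intensity_floor = intensity_floor,
                 window_side = window_side,
                 n_train = nrow(control),
                 train_sections = unique(control$section_id)),
            class = "gliaclust")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gliaclust <- function(x, ...) {
  cat(sprintf("Glial activation model (%s feature set)\n", x$feature_set))
  cat(sprintf("  trained on %d control windows from %d section(s)\n",
              x$n_train, length(x$train_sections)))
  cat(sprintf("  PCA: %d of %d components (>= %.0f%% variance)\n",
              x$projection$n_retained, length(x$projection$var_fraction),
              100 * x$variance_target))
  cat(sprintf("  one-class SVM: nu = %g, gamma = %g, %d support vectors\n",
              x$nu, x$gamma, nrow(x$svm$sv)))
  cat(sprintf("  intensity floor: z > %g\n", x$intensity_floor))
  invisible(x)
}

#' @export
summary.gliaclust <- function(object, ...) {
  print(object)
  vf <- object$projection$var_fraction
  cat("  cumulative variance by component:\n   ",
      paste(sprintf("%.3f", cumsum(vf)[seq_len(min(10, length(vf)))]),
            collapse = " "), "\n")
  invisible(object)
}

#' Classify test windows into distal, proximal and focal regions
#'
#' Applies a fitted model to a test feature table: windows are z-scored and
#' projected with the control-fitted transforms, scored by the one-class
#' SVM, floor-filtered, and the surviving outliers are DBSCAN-clustered into
#' proximal regions (per section). If `focal = TRUE`, a per-section elbow
#' threshold on integrated density selects hyperintense proximal windows,
#' which are re-clustered into focal sub-clusters.
#'
#' @param object a fitted [gliaclust] model.
#' @param newdata test feature table.
#' @param eps DBSCAN neighbour radius in um; default [default_eps()] of the
#'   model's window side.
#' @param min_size DBSCAN minimum cluster size for the proximal pass.
#' @param focal evaluate focal sub-clusters?
#' @param focal_eps,focal_min_size DBSCAN parameters for the focal pass.
#' @param magnitude_floor elbow magnitude floor for focal evaluation.
#' @param ... unused.
#' @return Object of class `gliaclust_labels`: a data frame with one row per
#'   test window (`section_id`, `x_um`, `y_um`, `Mean_z`, `IntDen_z`,
#'   `decision`, `is_outlier`, `proximal_id`, `focal_id`, `region`) plus
#'   attributes `elbows`, `params` and `window_side`.
#' @export
predict.gliaclust <- function(object, newdata, eps = NULL, min_size = 5,
                              focal = TRUE, focal_eps = NULL,
                              focal_min_size = 5, magnitude_floor = 0.5, ...) {
  if (is.null(eps)) eps <- default_eps(object$window_side)
  if (is.null(focal_eps)) focal_eps <- default_eps(object$window_side)
  newdata <- newdata[order(newdata$section_id, newdata$y_um, newdata$x_um), ]
  z <- apply_normalizer(object$normalizer, newdata)
  scores <- apply_projection(object$projection, z)
  flags <- predict_outliers(object$svm, scores)
  flags <- intensity_floor_filter(flags, object$intensity_floor)
  flags <- cluster_proximal(flags, eps = eps, min_size = min_size)
  if (focal) {
    flags <- cluster_focal(flags, eps = focal_eps, min_size = focal_min_size,
                           magnitude_floor = magnitude_floor)
  } else {
    flags$focal_id <- 0L
  }
  elbows <- attr(flags, "elbows")
  flags <- assign_regions(flags)
  rownames(flags) <- NULL
  structure(flags,
            class = c("gliaclust_labels", "data.frame"),
            elbows = elbows,
            window_side = object$window_side,
            params = list(eps = eps, min_size = min_size,
                          focal_eps = focal_eps,
                          focal_min_size = focal_min_size,
                          magnitude_floor = magnitude_floor,
                          nu = object$nu, gamma = object$gamma))
}

#' @export
print.gliaclust_labels <- function(x, ...) {
  tb <- table(x$region)
  cat(sprintf("Window labeling: %d windows in %d section(s)\n",
              nrow(x), length(unique(x$section_id))))
  cat(sprintf("  distal %d | proximal %d | focal %d\n",
              tb[["distal"]], tb[["proximal"]], tb[["focal"]]))
  cat(sprintf("  proximal clusters: %d, focal clusters: %d\n",
              length(setdiff(unique(x$proximal_id), 0L)),
              length(setdiff(unique(x$focal_id), 0L))))
  invisible(x)
}

#' Per-section summary of a window labeling
#'
#' @param object a `gliaclust_labels` object.
#' @param tissue_area optional named vector of per-section tissue areas
#'   (um^2) for area fractions; defaults to the bounding extent of the
#'   windows.
#' @param ... unused.
#' @return Data frame with per-section window counts per region, cluster
#'   counts and footprint area fractions.
#' @export
summary.gliaclust_labels <- function(object, tissue_area = NULL, ...) {
  side <- attr(object, "window_side")
  secs <- unique(object$section_id)
  rows <- lapply(secs, function(sec) {
    d <- object[object$section_id == sec, ]
    ta <- if (!is.null(tissue_area)) tissue_area[[as.character(sec)]]
          else (diff(range(d$x_um)) + side) * (diff(range(d$y_um)) + side)
    fr <- cluster_area_fraction(d, ta, side)
    data.frame(section_id = sec,
               n_windows = nrow(d),
               n_distal = sum(d$region == "distal"),
               n_proximal = sum(d$region == "proximal"),
               n_focal = sum(d$region == "focal"),
               n_proximal_clusters = length(setdiff(unique(d$proximal_id), 0L)),
               n_focal_clusters = length(setdiff(unique(d$focal_id), 0L)),
               proximal_area_fraction = fr[["proximal"]],
               focal_area_fraction = fr[["focal"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Map of the window labeling
#'
#' Draws each section's window grid coloured by region (grey distal, orange
#' proximal, red focal), the usual way these spatial labelings are displayed.
#'
#' @param x a `gliaclust_labels` object.
#' @param sections which sections to draw (default all).
#' @param ... passed to [graphics::plot()].
#' @export
plot.gliaclust_labels <- function(x, sections = NULL, ...) {
  if (is.null(sections)) sections <- unique(x$section_id)
  cols <- c(distal = "grey80", proximal = "darkorange", focal = "red3")
  side <- attr(x, "window_side")
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(sections)),
                       mar = c(2, 2, 2, 1))
  on.exit(graphics::par(old))
  for (sec in sections) {
    d <- x[x$section_id == sec, ]
    graphics::plot(d$x_um, d$y_um, pch = 15,
                   cex = 0.8, col = cols[as.character(d$region)],
                   asp = 1, xlab = "x (um)", ylab = "y (um)",
                   main = as.character(sec), ...)
  }
  invisible(x)
}
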