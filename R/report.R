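#' Per-region feature summary with fold changes against control
#'
#' Summarizes each morphometric feature by region — control, the whole test
#' tissue (the conventional whole-ROI comparison), distal, proximal and
#' focal — as mean, sd and n, plus the fold change of each region mean over
#' the control mean.
#'
#' @param test_table test feature table.
#' @param labeling `gliaclust_labels` for the test table.
#' @param control_table control feature table.
#' @param features feature columns to summarize (default: the model features
#'   of the table's feature set, plus `IntDen`).
#' @return Data frame with columns `region`, `feature`, `mean`, `sd`, `n`,
#'   `fold_change` (NA where the control mean is 0 or the region is empty).
#' @export
region_summary <- function(test_table, labeling, control_table,
                           features = NULL) {
  if (is.null(features)) {
    fs <- attr(test_table, "feature_set") %||% "microglia"
    features <- union(feature_columns(fs), "IntDen")
  }
  key <- function(d) paste(d$section_id, d$x_um, d$y_um)
  reg <- labeling$region[match(key(test_table), key(labeling))]
  if (anyNA(reg)) stop("labeling does not cover the test table", call. = FALSE)
  groups <- list(control = control_table,
                 test_all = test_table,
                 distal = test_table[reg == "distal", , drop = FALSE],
                 proximal = test_table[reg == "proximal", , drop = FALSE],
                 focal = test_table[reg == "focal", , drop = FALSE])
  ctrl_mean <- vapply(features, function(f) mean(control_table[[f]]), numeric(1))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    data.frame(region = g, feature = features,
               mean = if (nrow(d)) vapply(features, function(f) mean(d[[f]]), numeric(1)) else NA_real_,
               sd = if (nrow(d)) vapply(features, function(f) stats::sd(d[[f]]), numeric(1)) else NA_real_,
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  out$fold_change <- ifelse(ctrl_mean[out$feature] != 0 & !is.na(out$mean),
                            out$mean / ctrl_mean[out$feature], NA_real_)
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares fit with R-squared
#'
#' Simple linear regression used for the package's validation correlations
#' (e.g. automated versus true cell counts).
#'
#' @param x,y numeric vectors, `n >= 3`.
#' @return List: `slope`, `intercept`, `r_squared`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y))
    stop("need matched x, y with n >= 3", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero-variance x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot)
}
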