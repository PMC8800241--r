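#' Fit a z-score normalizer on control (training) windows
#'
#' Computes per-feature mean and standard deviation on the training table
#' only; both training and test windows are later standardized with these
#' statistics, so test windows are expressed as deviations from control
#' tissue. Zero-variance features are dropped with a warning.
#'
#' @param train feature table (data frame).
#' @param features feature columns to include; defaults to every numeric
#'   feature column present in the schema (model features plus `IntDen`,
#'   which downstream focal thresholding needs in z units).
#' @return Object of class `gc_normalizer` with `mu`, `sd` and `features`.
#' @export
fit_normalizer <- function(train, features = NULL) {
  if (is.null(features))
    features <- intersect(feature_table_schema()[-(1:4)], names(train))
  features <- features[vapply(train[features], function(x) !all(is.na(x)), logical(1))]
  if (nrow(train) < 2L) stop("need >= 2 training rows", call. = FALSE)
  mu <- vapply(train[features], mean, numeric(1))
  s <- vapply(train[features], stats::sd, numeric(1))
  bad <- s <= 0 | !is.finite(s)
  if (any(bad)) {
    warning("dropping zero-variance feature(s): ",
            paste(features[bad], collapse = ", "))
    features <- features[!bad]; mu <- mu[!bad]; s <- s[!bad]
  }
  structure(list(mu = mu, sd = s, features = features), class = "gc_normalizer")
}

#' Apply a fitted normalizer
#'
#' Standardizes each feature as `z = (x - mu)/s` using the training-set
#' statistics stored in the model; the table's non-feature columns are kept.
#'
#' @param model a `gc_normalizer`.
#' @param table feature table containing the model's feature columns.
#' @return The table with the model's feature columns replaced by z-scores.
#' @export
apply_normalizer <- function(model, table) {
  missing <- setdiff(model$features, names(table))
  if (length(missing) > 0L)
    stop("table lacks feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  for (f in model$features)
    table[[f]] <- (table[[f]] - model$mu[[f]]) / model$sd[[f]]
  table
}

#' Fit a PCA projection on z-scored control windows
#'
#' Eigendecomposition of the training covariance, retaining the smallest
#' number of leading components whose cumulative variance fraction reaches
#' `variance_target` (default 0.99). Loading signs are fixed by making the
#' largest-magnitude entry of each component positive, so fits are
#' deterministic.
#'
#' @param train_z z-scored training table.
#' @param features model feature columns to project.
#' @param variance_target cumulative variance fraction to retain.
#' @return Object of class `gc_projection` with orthonormal `loadings`
#'   (rows = components), `var_fraction`, `n_retained` and `features`.
#' @export
fit_projection <- function(train_z, features, variance_target = 0.99) {
  x <- as.matrix(train_z[features])
  if (nrow(x) < 2L) stop("need >= 2 rows", call. = FALSE)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(vf) >= variance_target - 1e-12)[1L]
  rot <- t(pc$rotation)
  flip <- apply(rot, 1L, function(r) sign(r[which.max(abs(r))]))
  rot <- rot * flip
  structure(list(loadings = rot, var_fraction = vf,
                 n_retained = as.integer(k),
                 variance_target = variance_target, features = features),
            class = "gc_projection")
}

#' Project a z-scored table onto the retained principal components
#'
#' Returns the PC scores of the retained components, keeping the table's
#' identifying columns and the raw-feature z-scores of `Mean` and `IntDen`
#' alongside (the intensity floor and the focal elbow operate on those, not
#' on PC scores).
#'
#' @param model a `gc_projection`.
#' @param z_table z-scored feature table.
#' @return Data frame with `section_id`, `x_um`, `y_um`, `Mean_z`,
#'   `IntDen_z` and score columns `PC1..PCk`.
#' @export
apply_projection <- function(model, z_table) {
  missing <- setdiff(model$features, names(z_table))
  if (length(missing) > 0L)
    stop("table lacks feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  x <- as.matrix(z_table[model$features])
  sc <- x %*% t(model$loadings[seq_len(model$n_retained), , drop = FALSE])
  colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
  out <- data.frame(section_id = z_table$section_id,
                    x_um = z_table$x_um, y_um = z_table$y_um,
                    Mean_z = if ("Mean" %in% names(z_table)) z_table$Mean else NA_real_,
                    IntDen_z = if ("IntDen" %in% names(z_table)) z_table$IntDen else NA_real_,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(sc))
}
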