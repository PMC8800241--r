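# numeric columns are written with 17 significant digits so that
# write-then-read reproduces doubles bit-identically
format_full <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- NA_character_
    out
  } else x
}

#' Read and write per-window feature tables
#'
#' The feature CSV is the module boundary between feature extraction and the
#' model: one row per window with the schema columns (`section_id`, `group`,
#' `x_um`, `y_um`, then the feature columns). Tables produced by external
#' window-measurement scripts can be dropped in as long as they follow the
#' schema. Round-trips are lossless (doubles written at full precision).
#'
#' @param table feature table.
#' @param path CSV file path.
#' @param feature_set,window_side stored as attributes on read.
#' @return `read_feature_csv` returns the table; `write_feature_csv` returns
#'   the path invisibly.
#' @export
write_feature_csv <- function(table, path) {
  out <- as.data.frame(lapply(table, format_full), stringsAsFactors = FALSE)
  names(out) <- names(table)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path, feature_set = "microglia", window_side = 100) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("section_id", "x_um", "y_um")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L)
    stop("feature CSV lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (cn in intersect(feature_table_schema()[-(1:2)], names(tab))) {
    if (!is.numeric(tab[[cn]]) && !all(is.na(tab[[cn]])))
      stop(sprintf("feature CSV column `%s` is not numeric", cn), call. = FALSE)
    tab[[cn]] <- as.double(tab[[cn]])
  }
  attr(tab, "feature_set") <- feature_set
  attr(tab, "window_side") <- window_side
  tab
}

#' Write a window labeling as CSV
#'
#' Columns: `section_id`, `x_um`, `y_um`, `region`, `cluster_id` (the focal
#' cluster id for focal windows, else the proximal cluster id, else 0).
#'
#' @param labeling a `gliaclust_labels` object.
#' @param path CSV file path.
#' @export
write_labels_csv <- function(labeling, path) {
  cluster_id <- ifelse(labeling$focal_id > 0L, labeling$focal_id,
                       labeling$proximal_id)
  out <- data.frame(section_id = labeling$section_id,
                    x_um = format_full(labeling$x_um),
                    y_um = format_full(labeling$y_um),
                    region = as.character(labeling$region),
                    cluster_id = cluster_id)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export cluster footprints as GeoJSON
#'
#' Writes a FeatureCollection with one MultiPolygon feature per cluster
#' (member window squares, um coordinates) with `section_id`, `region` and
#' `cluster_id` properties.
#'
#' @param labeling a `gliaclust_labels` object.
#' @param path output path.
#' @export
write_geojson <- function(labeling, path) {
  side <- attr(labeling, "window_side") %||% 100
  h <- side / 2
  feats <- list()
  for (kind in c("proximal", "focal")) {
    idcol <- paste0(kind, "_id")
    for (id in setdiff(unique(labeling[[idcol]]), 0L)) {
      d <- labeling[labeling[[idcol]] == id, ]
      polys <- lapply(seq_len(nrow(d)), function(i) {
        x <- d$x_um[i]; y <- d$y_um[i]
        list(list(list(x - h, y - h), list(x + h, y - h), list(x + h, y + h),
                  list(x - h, y + h), list(x - h, y - h)))
      })
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(section_id = as.character(d$section_id[1L]),
                          region = kind, cluster_id = id),
        geometry = list(type = "MultiPolygon", coordinates = polys))
    }
  }
  doc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a TIFF channel as an image plane
#'
#' Reads a single-channel grayscale TIFF (multi-page files are treated as a
#' z-stack and max-projected).
#'
#' @param path TIFF path.
#' @param scale pixels per um.
#' @param channel channel label.
#' @return An [image_plane].
#' @export
read_tiff_plane <- function(path, scale = 1.5, channel = "IBA1") {
  img <- tiff::readTIFF(path, all = TRUE)
  planes <- lapply(img, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    image_plane(t(m), scale = scale, channel = channel)  # rows are y in TIFF
  })
  project_max(planes)
}

#' @rdname read_tiff_plane
#' @param plane an [image_plane] to write (intensities clipped to `[0, 1]`).
#' @export
write_tiff_plane <- function(plane, path) {
  m <- t(plane$pixels)
  m[m > 1] <- 1
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' Validates the fields against the model invariants and fails with a
#' message naming the offending field.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  chk <- function(field, ok, why) {
    if (!is.null(cfg[[field]]) && !all(ok(cfg[[field]])))
      stop(sprintf("config field `%s` invalid: %s", field, why), call. = FALSE)
  }
  chk("nu", function(v) v > 0 & v <= 1, "nu must be in (0, 1]")
  chk("gamma", function(v) v > 0, "gamma must be > 0")
  chk("min_size", function(v) v >= 1, "min_size must be >= 1")
  chk("eps", function(v) v > 0, "eps must be > 0")
  chk("window_side", function(v) v > 0, "window side must be > 0")
  chk("overlap", function(v) v >= 0 & v < 1, "overlap must be in [0, 1)")
  cfg
}

#' Persist and restore a fitted model as JSON
#'
#' Stores the normalizer statistics, PCA loadings and the one-class SVM
#' decision function (support vectors, coefficients, offset) so that a model
#' trained in one run can score new sections in another.
#'
#' @param model a [gliaclust] model.
#' @param path JSON path.
#' @export
write_model_json <- function(model, path) {
  doc <- list(
    feature_set = model$feature_set,
    nu = model$nu, gamma = model$gamma,
    variance_target = model$variance_target,
    intensity_floor = model$intensity_floor,
    window_side = model$window_side,
    n_train = model$n_train,
    normalizer = list(mu = as.list(model$normalizer$mu),
                      sd = as.list(model$normalizer$sd),
                      features = model$normalizer$features),
    projection = list(loadings = model$projection$loadings,
                      var_fraction = model$projection$var_fraction,
                      n_retained = model$projection$n_retained,
                      variance_target = model$projection$variance_target,
                      features = model$projection$features),
    svm = list(sv = model$svm$sv, coefs = model$svm$coefs,
               rho = model$svm$rho, dim = model$svm$dim,
               n_train = model$svm$n_train))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  norm <- structure(list(mu = unlist(doc$normalizer$mu),
                         sd = unlist(doc$normalizer$sd),
                         features = doc$normalizer$features),
                    class = "gc_normalizer")
  proj <- structure(list(loadings = as.matrix(doc$projection$loadings),
                         var_fraction = doc$projection$var_fraction,
                         n_retained = as.integer(doc$projection$n_retained),
                         variance_target = doc$projection$variance_target,
                         features = doc$projection$features),
                    class = "gc_projection")
  colnames(proj$loadings) <- proj$features
  svm <- structure(list(sv = as.matrix(doc$svm$sv),
                        coefs = as.numeric(doc$svm$coefs),
                        rho = as.numeric(doc$svm$rho),
                        nu = doc$nu, gamma = doc$gamma,
                        n_train = as.integer(doc$svm$n_train),
                        dim = as.integer(doc$svm$dim)),
                   class = "gc_ocsvm")
  structure(list(normalizer = norm, projection = proj, svm = svm,
                 feature_set = doc$feature_set,
                 nu = doc$nu, gamma = doc$gamma,
                 variance_target = doc$variance_target,
                 intensity_floor = doc$intensity_floor,
                 window_side = doc$window_side,
                 n_train = as.integer(doc$n_train),
                 train_sections = NULL),
            class = "gliaclust")
}

#' Write a run log
#'
#' Records versions, the seed and the parameters of a run as JSON, so every
#' result can be traced back to its inputs.
#'
#' @param path output path.
#' @param seed RNG seed used.
#' @param params named list of parameters.
#' @export
write_run_log <- function(path, seed = NA, params = list()) {
  doc <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              r_version = R.version.string,
              package_version = as.character(utils::packageVersion("gliaclust")),
              seed = seed, params = params)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
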