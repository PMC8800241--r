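#' Cross-validation folds over control sections
#'
#' Partitions control sections (the folding unit — windows within a section
#' are spatially correlated, so window-level folds would leak) into up to
#' `k` balanced folds after a seeded shuffle. With fewer sections than `k`
#' this degrades gracefully to leave-one-section-out.
#'
#' @param sections character/factor vector of section ids (unique or not).
#' @param k target number of folds (default 10).
#' @param seed RNG seed for the shuffle.
#' @return Named integer vector: fold index per unique section.
#' @export
make_folds <- function(sections, k = 10, seed = 1) {
  secs <- unique(as.character(sections))
  if (length(secs) < 2L) stop("need >= 2 sections", call. = FALSE)
  k <- min(k, length(secs))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  secs <- sample(secs)
  folds <- rep(seq_len(k), length.out = length(secs))
  stats::setNames(folds, secs)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Default hyperparameter grid
#'
#' @return List with `nu`, `gamma` and `min_size` candidate vectors.
#' @export
default_grid <- function() {
  list(nu = c(0.02, 0.05, 0.1, 0.15, 0.2),
       gamma = c(0.01, 0.05, 0.1, 0.5, 1, 5),
       min_size = c(5, 10, 15, 20, 30))
}

# proximal footprint area (um^2) and cluster count of a labeling
labeling_yield <- function(flags, side) {
  prox <- flags$proximal_id > 0L
  list(n_clusters = length(setdiff(unique(flags$proximal_id), 0L)),
       area = footprint_area(flags$x_um[prox], flags$y_um[prox], side))
}

#' Two-stage hyperparameter search under a zero-false-positive constraint
#'
#' Stage 1 (feasibility): for every (nu, gamma, min_size) combination,
#' cross-validate over control sections — fit the full model on the training
#' folds and run the proximal pipeline on each held-out control section. A
#' combination is feasible only if no held-out control section yields any
#' proximal cluster. Stage 2 (selection): among feasible combinations,
#' retrain on all control sections, predict the test table, and pick the
#' combination maximizing the total proximal footprint area in test tissue
#' (ties broken toward larger nu, then gamma, then min_size).
#'
#' @param control control feature table (>= 2 sections).
#' @param test test feature table.
#' @param grid list with `nu`, `gamma`, `min_size` vectors
#'   (default [default_grid()]).
#' @param k CV fold count (default 10; degrades to leave-one-section-out).
#' @param seed fold-shuffle seed.
#' @param eps DBSCAN radius in um (default from the window side).
#' @param feature_set passed to [gliaclust()].
#' @param variance_target,intensity_floor passed to [gliaclust()].
#' @return Object of class `gliaclust_tuning`: `results` (one row per
#'   combination: feasibility, control cluster count/area, test area),
#'   `best` (selected parameters), `model` (final model at `best`) and
#'   `labels` (test labeling at `best`).
#' @export
tune_gliaclust <- function(control, test, grid = default_grid(), k = 10,
                           seed = 1, eps = NULL, feature_set = NULL,
                           variance_target = 0.99, intensity_floor = -1) {
  if (is.null(feature_set))
    feature_set <- attr(control, "feature_set") %||% "microglia"
  side <- attr(control, "window_side") %||% 100
  if (is.null(eps)) eps <- default_eps(side)
  folds <- make_folds(control$section_id, k = k, seed = seed)
  res <- expand.grid(nu = grid$nu, gamma = grid$gamma, min_size = grid$min_size,
                     KEEP.OUT.ATTRS = FALSE)
  res$feasible <- TRUE
  res$control_clusters <- 0L
  res$control_area <- 0
  res$test_area <- NA_real_
  # stage 1: OC-SVM fits depend on (nu, gamma, fold) only; min_size reuses flags
  for (f in sort(unique(folds))) {
    held <- names(folds)[folds == f]
    tr <- control[!(control$section_id %in% held), , drop = FALSE]
    te <- control[control$section_id %in% held, , drop = FALSE]
    attr(tr, "feature_set") <- feature_set; attr(tr, "window_side") <- side
    for (nu in grid$nu) for (gamma in grid$gamma) {
      fit <- gliaclust(tr, feature_set = feature_set, nu = nu, gamma = gamma,
                       variance_target = variance_target,
                       intensity_floor = intensity_floor, window_side = side)
      for (ms in grid$min_size) {
        lab <- predict(fit, te, eps = eps, min_size = ms, focal = FALSE)
        y <- labeling_yield(lab, side)
        i <- which(res$nu == nu & res$gamma == gamma & res$min_size == ms)
        if (y$n_clusters > 0L) {
          res$feasible[i] <- FALSE
          res$control_clusters[i] <- res$control_clusters[i] + y$n_clusters
          res$control_area[i] <- res$control_area[i] + y$area
        }
      }
    }
  }
  # stage 2: evaluate feasible combinations on the test table
  feas <- which(res$feasible)
  if (length(feas) == 0L)
    stop("no feasible hyperparameters: every grid combination produced ",
         "clusters in held-out control sections; widen the grid ",
         "(larger min_size or smaller nu)", call. = FALSE)
  final_fits <- list()
  for (i in feas) {
    key <- paste(res$nu[i], res$gamma[i])
    if (is.null(final_fits[[key]]))
      final_fits[[key]] <- gliaclust(control, feature_set = feature_set,
                                     nu = res$nu[i], gamma = res$gamma[i],
                                     variance_target = variance_target,
                                     intensity_floor = intensity_floor,
                                     window_side = side)
    lab <- predict(final_fits[[key]], test, eps = eps,
                   min_size = res$min_size[i], focal = FALSE)
    res$test_area[i] <- labeling_yield(lab, side)$area
  }
  ord <- feas[order(-res$test_area[feas], -res$nu[feas], -res$gamma[feas],
                    -res$min_size[feas])]
  best_i <- ord[1L]
  best <- res[best_i, c("nu", "gamma", "min_size")]
  model <- final_fits[[paste(best$nu, best$gamma)]]
  labels <- predict(model, test, eps = eps, min_size = best$min_size)
  structure(list(results = res, best = best, model = model, labels = labels,
                 eps = eps, k = length(unique(folds)), seed = seed),
            class = "gliaclust_tuning")
}

#' @export
print.gliaclust_tuning <- function(x, ...) {
  cat(sprintf("Hyperparameter search: %d combinations, %d feasible (%d-fold CV)\n",
              nrow(x$results), sum(x$results$feasible), x$k))
  cat(sprintf("  selected: nu = %g, gamma = %g, min_size = %d (test area %.3g um^2)\n",
              x$best$nu, x$best$gamma, as.integer(x$best$min_size),
              x$results$test_area[x$results$nu == x$best$nu &
                                  x$results$gamma == x$best$gamma &
                                  x$results$min_size == x$best$min_size]))
  invisible(x)
}
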