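#' Fit a one-class SVM on control PC scores
#'
#' Trains a nu-parameterised one-class support vector machine with an RBF
#' kernel on control windows only. `nu` upper-bounds the fraction of training
#' windows allowed outside the decision boundary (and so sets how much of
#' control tissue may be called atypical); `gamma` is the RBF width. Rows
#' should be pre-sorted (the pipeline sorts by section, y, x) so fits are
#' reproducible regardless of input order.
#'
#' @param train_scores data frame or matrix of PC score columns (`PC*`).
#' @param nu fraction in (0, 1].
#' @param gamma RBF kernel parameter, > 0.
#' @return Object of class `gc_ocsvm` wrapping the fitted machine.
#' @export
fit_ocsvm <- function(train_scores, nu = 0.1, gamma = 0.1) {
  if (nu <= 0 || nu > 1) stop("`nu` must be in (0, 1]", call. = FALSE)
  if (gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  x <- score_matrix(train_scores)
  if (nrow(x) < 10L) stop("need >= 10 training rows", call. = FALSE)
  if (all(apply(x, 2L, function(c) max(c) - min(c) == 0)))
    stop("degenerate training set: all rows identical", call. = FALSE)
  fit <- e1071::svm(x, y = NULL, type = "one-classification",
                    kernel = "radial", nu = nu, gamma = gamma,
                    scale = FALSE, tolerance = 1e-4)
  # keep only the decision-function representation: support vectors, their
  # dual coefficients and the offset (rho); makes models serializable
  structure(list(sv = unname(as.matrix(fit$SV)),
                 coefs = as.numeric(fit$coefs),
                 rho = as.numeric(fit$rho),
                 nu = nu, gamma = gamma,
                 n_train = nrow(x), dim = ncol(x)),
            class = "gc_ocsvm")
}

# RBF decision function: positive inside the boundary
ocsvm_decision <- function(model, x) {
  sv <- model$sv
  # squared distances between rows of x and sv
  d2 <- outer(rowSums(x^2), rowSums(sv^2), `+`) - 2 * x %*% t(sv)
  d2[d2 < 0] <- 0
  as.numeric(exp(-model$gamma * d2) %*% model$coefs) - model$rho
}

score_matrix <- function(scores) {
  if (is.matrix(scores)) return(scores)
  pc <- grep("^PC[0-9]+$", names(scores), value = TRUE)
  if (length(pc) == 0L) stop("no PC score columns found", call. = FALSE)
  as.matrix(scores[pc])
}

#' Flag outlier windows with a trained one-class SVM
#'
#' Evaluates the decision function on test windows; a strictly negative
#' decision value marks the window as a morphological outlier (ties at zero
#' count as inliers).
#'
#' @param model a `gc_ocsvm`.
#' @param test_scores data frame with PC columns and, if available, `Mean_z`
#'   (carried into the flags for the intensity floor).
#' @return Data frame of flags: input identifier columns plus `decision` and
#'   `is_outlier`.
#' @export
predict_outliers <- function(model, test_scores) {
  x <- score_matrix(test_scores)
  if (ncol(x) != model$dim)
    stop(sprintf("score dimensionality %d does not match model (%d)",
                 ncol(x), model$dim), call. = FALSE)
  if (nrow(x) == 0L) {
    out <- as.data.frame(test_scores)
    out$decision <- numeric(0); out$is_outlier <- logical(0)
    return(out)
  }
  dv <- ocsvm_decision(model, x)
  out <- as.data.frame(test_scores)
  out$decision <- as.numeric(dv)
  out$is_outlier <- out$decision < 0
  out
}

#' Demote hypointense outliers
#'
#' One-class outliers can be either hyperintense (activation) or hypointense
#' (tissue edges, staining dropouts). The floor filter demotes any outlier
#' whose raw mean-intensity z-score is at or below `floor_z` (default -1)
#' back to non-outlier; it never promotes.
#'
#' @param flags output of [predict_outliers()] with a `Mean_z` column.
#' @param floor_z intensity floor in z units.
#' @return The flags with `is_outlier` updated.
#' @export
intensity_floor_filter <- function(flags, floor_z = -1) {
  if (!"Mean_z" %in% names(flags))
    stop("flags lack `Mean_z`", call. = FALSE)
  flags$is_outlier <- flags$is_outlier & flags$Mean_z > floor_z
  flags
}
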