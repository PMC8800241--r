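# shift a logical/numeric matrix by (dx, dy), zero/FALSE fill
shift_mat <- function(m, dx, dy) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(if (is.logical(m)) FALSE else 0, nx, ny)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  out[xs, ys] <- m[xs - dx, ys - dy, drop = FALSE]
  out
}

# neighbours in the Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
zs_offsets <- list(c(0, -1), c(1, -1), c(1, 0), c(1, 1),
                   c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))

#' Morphological thinning to a one-pixel skeleton
#'
#' Zhang-Suen iterative thinning: erodes a binary shape to its 1-px-wide
#' medial skeleton while preserving connectivity, the standard precursor to
#' branch statistics on ramified cells.
#'
#' @param mask logical matrix.
#' @return Logical matrix of the same shape containing the skeleton.
#' @export
thin_mask <- function(mask) {
  m <- mask
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- lapply(zs_offsets, function(o) shift_mat(m, -o[1], -o[2]))
      # nb[[k]] is TRUE where the P(k+1) neighbour of the pixel is set
      B <- Reduce(`+`, nb)
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) {
        nxt <- if (k == 8) 1 else k + 1
        A <- A + (!nb[[k]] & nb[[nxt]])
      }
      if (step == 1) {
        c3 <- !(nb[[1]] & nb[[3]] & nb[[5]])   # P2*P4*P6 == 0
        c4 <- !(nb[[3]] & nb[[5]] & nb[[7]])   # P4*P6*P8 == 0
      } else {
        c3 <- !(nb[[1]] & nb[[3]] & nb[[7]])   # P2*P4*P8 == 0
        c4 <- !(nb[[1]] & nb[[5]] & nb[[7]])   # P2*P6*P8 == 0
      }
      kill <- m & B >= 2 & B <= 6 & A == 1 & c3 & c4
      if (any(kill)) {
        m[kill] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# connected components of TRUE pixels under 8-connectivity
label_components8 <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(lab)
  nx <- nrow(mask)
  pos <- seq_along(idx)
  lut <- integer(length(mask)); lut[idx] <- pos
  edges <- NULL
  for (o in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    nb <- idx + o[1] + o[2] * nx
    i <- (idx - 1L) %% nx + 1L
    j <- (idx - 1L) %/% nx + 1L
    ok <- i + o[1] >= 1L & i + o[1] <= nx & j + o[2] >= 1L & j + o[2] <= ncol(mask)
    ok[ok] <- mask[nb[ok]]
    if (any(ok)) edges <- rbind(edges, cbind(pos[ok], lut[nb[ok]]))
  }
  if (is.null(edges)) {
    lab[idx] <- pos
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    lab[idx] <- igraph::components(g)$membership
  }
  lab
}

#' Skeleton branch statistics of a binary window
#'
#' Thins the foreground to a skeleton and classifies skeleton pixels by their
#' 8-connected skeleton-neighbour count: end points (1 neighbour), slab
#' pixels (2), junctions (3 or more, of which triple points have exactly 3).
#' Branches are connected components of slab pixels after junction removal;
#' branch length sums orthogonal steps as 1 px and diagonal steps as
#' `sqrt(2)` px, converted to um.
#'
#' @param mask logical matrix (one window of thresholded foreground).
#' @param scale pixels per um.
#' @return List: `n_branches`, `total_branch_length` (um), `n_junctions`,
#'   `n_triple_points`, `n_end_points`, `n_slab_pixels`.
#' @export
skeleton_stats <- function(mask, scale = 1.5) {
  empty <- list(n_branches = 0L, total_branch_length = 0,
                n_junctions = 0L, n_triple_points = 0L,
                n_end_points = 0L, n_slab_pixels = 0L)
  if (!any(mask)) return(empty)
  sk <- thin_mask(mask)
  if (!any(sk)) return(empty)
  nb <- Reduce(`+`, lapply(zs_offsets, function(o) shift_mat(sk, o[1], o[2])))
  nb[!sk] <- 0L
  ends <- sk & nb == 1
  slab <- sk & nb == 2
  junc <- sk & nb >= 3
  lab <- label_components8(slab)
  n_branches <- max(lab)
  len_px <- 0
  if (any(slab)) {
    nx <- nrow(slab)
    idx <- which(slab)
    i <- (idx - 1L) %% nx + 1L
    j <- (idx - 1L) %/% nx + 1L
    for (o in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
      ok <- i + o[1] >= 1L & i + o[1] <= nx & j + o[2] >= 1L & j + o[2] <= ncol(slab)
      nbidx <- idx[ok] + o[1] + o[2] * nx
      hit <- slab[nbidx]
      w <- if (o[1] != 0 && o[2] != 0) sqrt(2) else 1
      len_px <- len_px + w * sum(hit)
    }
  }
  list(n_branches = as.integer(n_branches),
       total_branch_length = len_px / scale,
       n_junctions = as.integer(sum(junc)),
       n_triple_points = as.integer(sum(junc & nb == 3)),
       n_end_points = as.integer(sum(ends)),
       n_slab_pixels = as.integer(sum(slab)))
}

#' Box-counting fractal dimension of a binary window
#'
#' Counts occupied boxes at box sizes 2, 3, 4, 6, 8, 12, 16, 32 and 64 px
#' (sizes exceeding the window are skipped) and returns the slope of the
#' least-squares fit of `log N(eps)` against `log(1/eps)` -- the box-counting
#' estimate of the fractal dimension D, an index of morphological complexity
#' between 1 (a smooth curve) and 2 (a filled plane).
#'
#' @param mask logical matrix.
#' @param box_sizes box side lengths in px.
#' @return The dimension D; 0 for an empty mask.
#' @export
fractal_dimension <- function(mask, box_sizes = c(2, 3, 4, 6, 8, 12, 16, 32, 64)) {
  idx <- which(mask)
  if (length(idx) == 0L) return(0)
  nx <- nrow(mask); ny <- ncol(mask)
  i <- (idx - 1L) %% nx + 1L
  j <- (idx - 1L) %/% nx + 1L
  eps <- box_sizes[box_sizes <= min(nx, ny)]
  if (length(eps) < 2L) eps <- box_sizes[1:2]
  counts <- vapply(eps, function(e) {
    bx <- (i - 1L) %/% as.integer(e)
    by <- (j - 1L) %/% as.integer(e)
    length(unique(bx * (ny %/% e + 2L) + by))
  }, numeric(1))
  stats::coef(stats::lm(log(counts) ~ I(log(1 / eps))))[[2]]
}

#' Foreground boundary length of a binary window
#'
#' Crofton-corrected boundary estimate: counts exposed pixel edges (4-adjacent
#' foreground/background pairs, image border included) and multiplies by
#' pi/4, which corrects the Manhattan overestimate for isotropically oriented
#' boundaries; result converted to um.
#'
#' @param mask logical matrix.
#' @param scale pixels per um.
#' @return Boundary length in um.
#' @export
mask_perimeter <- function(mask, scale = 1.5) {
  if (!any(mask)) return(0)
  exposed <- 0L
  for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    exposed <- exposed + sum(mask & !shift_mat(mask, o[1], o[2]))
  }
  (pi / 4) * exposed / scale
}
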