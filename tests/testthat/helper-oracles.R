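# Independent oracles and fixture builders used across the suite.

# Naive reference DBSCAN: core points from the full distance matrix, clusters
# as connected components of the core-core eps graph, border points attached
# to a neighbouring core's cluster. Written independently of the package's
# implementation.
oracle_dbscan <- function(x, y, eps, min_size) {
  n <- length(x)
  d <- as.matrix(dist(cbind(x, y)))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_size
  lab <- integer(n)
  cl <- 0L
  for (i in which(core)) {
    if (lab[i] != 0L) next
    cl <- cl + 1L
    comp <- i
    repeat {
      grow <- unique(unlist(nb[comp]))
      grow <- grow[core[grow] & !(grow %in% comp)]
      if (length(grow) == 0L) break
      comp <- c(comp, grow)
    }
    lab[comp] <- cl
  }
  border <- which(!core & lab == 0L)
  for (i in border) {
    cn <- nb[[i]][core[nb[[i]]]]
    if (length(cn) > 0L) lab[i] <- lab[cn[1L]]
  }
  list(labels = lab, core = core)
}

# Compare a DBSCAN labelling against the oracle up to (a) label permutation
# and (b) the inherent ambiguity of border-point assignment: noise sets must
# match, core points must induce the same partition, and every border point
# must carry the label of one of its core neighbours.
dbscan_equivalent <- function(labels, x, y, eps, min_size) {
  ora <- oracle_dbscan(x, y, eps, min_size)
  if (!identical(labels == 0L, ora$labels == 0L)) return(FALSE)
  core <- ora$core
  # same partition over core points
  if (any(core)) {
    a <- labels[core]; b <- ora$labels[core]
    if (length(unique(a)) != length(unique(b))) return(FALSE)
    if (any(tapply(b, a, function(v) length(unique(v))) != 1L)) return(FALSE)
  }
  d <- as.matrix(dist(cbind(x, y)))
  for (i in which(!core & labels != 0L)) {
    cn <- which(core & d[i, ] <= eps)
    if (!(labels[i] %in% labels[cn])) return(FALSE)
  }
  TRUE
}

# a "Y" skeleton mask: three straight 20-px arms meeting at one point
y_mask <- function(n = 60) {
  m <- matrix(FALSE, n, n)
  cx <- n %/% 2
  m[cx, (n %/% 2):(n %/% 2 + 20)] <- TRUE
  for (k in 0:20) {
    m[cx - k, n %/% 2 - k] <- TRUE
    m[cx + k, n %/% 2 - k] <- TRUE
  }
  m
}

disk_mask <- function(r, n = 2 * r + 10) {
  c0 <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
}

# direct per-pixel evaluation of the Phansalkar rule with a clamped-index
# disk neighbourhood (independent of the package's convolution path; the
# disk shape itself comes from the same standard brush constructor)
oracle_phansalkar <- function(px, radius, k, r) {
  top <- max(px)
  v <- px / top
  nx <- nrow(v); ny <- ncol(v)
  brush <- EBImage::makeBrush(2L * radius + 1L, "disc")
  off <- which(brush > 0, arr.ind = TRUE) - radius - 1L
  off <- data.frame(dx = off[, 1L], dy = off[, 2L])
  out <- matrix(FALSE, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    xi <- pmin(pmax(i + off$dx, 1L), nx)
    yj <- pmin(pmax(j + off$dy, 1L), ny)
    vals <- v[cbind(xi, yj)]
    m <- mean(vals); s <- sqrt(max(mean(vals^2) - m^2, 0))
    out[i, j] <- v[i, j] > m * (1 + 2 * exp(-10 * m) + k * (s / r - 1)) &&
      s > 1e-6
  }
  out
}

# hockey-stick curve: n points, flat segment then a linear rise starting at
# rank fraction f, with slope ratio `ratio` and additive noise
hockey_values <- function(n, f, ratio = 20, noise = 0.05, seed = 1) {
  set.seed(seed)
  nb <- round(n * f)
  flat <- seq(0, 1, length.out = nb)
  rise <- 1 + seq_len(n - nb) * ratio / (n - nb)
  c(flat, rise) + rnorm(n, 0, noise)
}

# small synthetic study (fewer windows) for fast tuning tests
small_feature_spec <- function(...) {
  synth_feature_spec(n_control = 3, n_test = 2, grid_nx = 14, grid_ny = 14,
                     region = c(4, 4, 9, 9), core = c(6, 6, 7, 7), ...)
}
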