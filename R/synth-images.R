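#' Specification for the image-level tissue renderer
#'
#' Defines a rendered synthetic section: cell somata placed by a hard-core
#' Poisson process (somata do not overlap), ramified cells drawn as random
#' trees of thin strokes growing out of a soma disk, and — inside an
#' optional circular activation region — ameboid cells with enlarged,
#' brighter somata and stunted processes, at locally increased density. A
#' paired soma-only channel (disks only) is rendered for astrocyte-mode
#' tests.
#'
#' @param section_um section side length in um (square sections).
#' @param scale pixels per um.
#' @param density cell density per mm^2.
#' @param soma_radius_um soma radius of a ramified cell (um).
#' @param soma_intensity peak soma intensity of a ramified cell, in `[0,1]`.
#' @param n_primary range (2-vector) of primary branches per ramified cell.
#' @param branch_depth branching generations of a ramified cell.
#' @param branch_len_um mean branch segment length (um).
#' @param activation optional circle `c(cx, cy, r)` in um: the activation
#'   region.
#' @param core optional circle `c(cx, cy, r)` in um: the focal core (must
#'   lie within the activation region).
#' @param ameboid_soma_mult,ameboid_intensity_mult,ameboid_density_mult
#'   soma-radius, intensity and density multipliers inside the activation
#'   region (the density multiplier emulates the reduced nearest-neighbour
#'   distance of activated cells).
#' @param noise_sd additive Gaussian background noise sd.
#' @param min_spacing_um hard-core minimum distance between cell centers.
#' @return Object of class `synth_tissue_spec`.
#' @export
synth_tissue_spec <- function(section_um = 300, scale = 1.5, density = 200,
                              soma_radius_um = 3.5, soma_intensity = 0.65,
                              n_primary = c(3, 5), branch_depth = 2,
                              branch_len_um = 10,
                              activation = NULL, core = NULL,
                              ameboid_soma_mult = 1.5,
                              ameboid_intensity_mult = 1.5,
                              ameboid_density_mult = 1.4,
                              noise_sd = 0.02,
                              min_spacing_um = 14) {
  stopifnot(section_um > 0, scale > 0, density > 0)
  structure(as.list(environment()), class = "synth_tissue_spec")
}

# stamp a filled disk into px (matrix [x, y]); returns modified matrix
stamp_disk <- function(px, cx, cy, r, value) {
  nx <- nrow(px); ny <- ncol(px)
  xs <- max(1L, floor(cx - r)):min(nx, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(ny, ceiling(cy + r))
  if (length(xs) == 0L || length(ys) == 0L) return(px)
  dd <- outer((xs - cx)^2, (ys - cy)^2, `+`)
  sub <- px[xs, ys, drop = FALSE]
  sub[dd <= r^2] <- pmax(sub[dd <= r^2], value)
  px[xs, ys] <- sub
  px
}

# stamp a 1-px stroke from (x0,y0) to (x1,y1) (pixel coords)
stamp_stroke <- function(px, x0, y0, x1, y1, value) {
  n <- max(2L, ceiling(sqrt((x1 - x0)^2 + (y1 - y0)^2) / 0.4))
  xs <- round(seq(x0, x1, length.out = n))
  ys <- round(seq(y0, y1, length.out = n))
  ok <- xs >= 1 & xs <= nrow(px) & ys >= 1 & ys <= ncol(px)
  idx <- cbind(xs[ok], ys[ok])
  px[idx] <- pmax(px[idx], value)
  px
}

# recursive random tree of strokes from (x, y) at pixel scale
draw_tree <- function(px, x, y, angle, depth, seg_px, value) {
  if (depth < 1L) return(px)
  x1 <- x + seg_px * stats::runif(1, 0.7, 1.3) * cos(angle)
  y1 <- y + seg_px * stats::runif(1, 0.7, 1.3) * sin(angle)
  px <- stamp_stroke(px, x, y, x1, y1, value)
  for (kid in seq_len(stats::rbinom(1, 2, 0.8))) {
    px <- draw_tree(px, x1, y1, angle + stats::runif(1, -0.9, 0.9),
                    depth - 1L, seg_px * 0.8, value * 0.85)
  }
  px
}

#' Render a synthetic tissue section
#'
#' @param spec a [synth_tissue_spec].
#' @param seed RNG seed.
#' @return List: `plane` (the branching/intensity channel, an
#'   [image_plane]), `soma_plane` (soma disks only) and `truth` — data frame
#'   of true cells (`x_um`, `y_um`, `type`) plus the activation geometry.
#' @export
render_section <- function(spec = synth_tissue_spec(), seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  L <- spec$section_um
  npx <- round(L * spec$scale)
  # hard-core Poisson cell placement, with extra intensity inside activation
  n_base <- stats::rpois(1, spec$density * L^2 / 1e6)
  pts <- cbind(stats::runif(n_base, 0, L), stats::runif(n_base, 0, L))
  if (!is.null(spec$activation)) {
    a <- spec$activation
    extra_rate <- spec$density * (spec$ameboid_density_mult - 1) * pi * a[3]^2 / 1e6
    n_extra <- stats::rpois(1, max(0, extra_rate))
    if (n_extra > 0) {
      th <- stats::runif(n_extra, 0, 2 * pi)
      rr <- a[3] * sqrt(stats::runif(n_extra))
      pts <- rbind(pts, cbind(a[1] + rr * cos(th), a[2] + rr * sin(th)))
    }
  }
  # hard-core thinning in arrival order
  keep <- rep(TRUE, nrow(pts))
  if (nrow(pts) > 1L) {
    d <- as.matrix(stats::dist(pts))
    for (i in seq_len(nrow(pts))[-1L]) {
      prev <- which(keep[seq_len(i - 1L)])
      if (length(prev) > 0L && min(d[i, prev]) < spec$min_spacing_um)
        keep[i] <- FALSE
    }
  }
  pts <- pts[keep, , drop = FALSE]
  activated <- if (is.null(spec$activation)) rep(FALSE, nrow(pts)) else
    (pts[, 1] - spec$activation[1])^2 + (pts[, 2] - spec$activation[2])^2 <=
      spec$activation[3]^2
  px <- matrix(0, npx, npx)
  soma_px <- matrix(0, npx, npx)
  s <- spec$scale
  if (nrow(pts) > 0L) for (i in seq_len(nrow(pts))) {
    cx <- pts[i, 1] * s; cy <- pts[i, 2] * s
    amb <- activated[i]
    r <- spec$soma_radius_um * s * (if (amb) spec$ameboid_soma_mult else 1) *
         stats::runif(1, 0.85, 1.15)
    val <- spec$soma_intensity * (if (amb) spec$ameboid_intensity_mult else 1) *
           stats::runif(1, 0.9, 1.1)
    val <- min(val, 1)
    px <- stamp_disk(px, cx, cy, r, val)
    soma_px <- stamp_disk(soma_px, cx, cy, r, val)
    n_prim <- sample(spec$n_primary[1]:spec$n_primary[2], 1L)
    depth <- if (amb) 1L else spec$branch_depth
    seg <- spec$branch_len_um * s * (if (amb) 0.4 else 1)
    for (b in seq_len(n_prim)) {
      ang <- 2 * pi * b / n_prim + stats::runif(1, -0.4, 0.4)
      px <- draw_tree(px, cx + r * cos(ang), cy + r * sin(ang),
                      ang, depth, seg, val * 0.55)
    }
  }
  blur <- function(m) EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = 0.7))
  px <- blur(px) + stats::rnorm(npx * npx, 0, spec$noise_sd)
  px[px < 0] <- 0; px[px > 1] <- 1
  soma_px <- blur(soma_px)
  soma_px[soma_px < 0] <- 0
  truth <- data.frame(x_um = pts[, 1], y_um = pts[, 2],
                      type = ifelse(activated, "ameboid", "ramified"),
                      stringsAsFactors = FALSE)
  list(plane = image_plane(px, scale = s, channel = "IBA1"),
       soma_plane = image_plane(soma_px, scale = s, channel = "S100B"),
       truth = list(cells = truth, activation = spec$activation,
                    core = spec$core))
}
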