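#' Specification for the feature-level synthetic generator
#'
#' Defines the study conditions emulated by the feature-level generator:
#' control sections whose window features are Gaussian around ramified-cell
#' values (with a between-section random effect emulating staining
#' variability), and test sections carrying an implanted rectangular
#' activation region whose windows have their feature means multiplied by
#' proximal fold changes, with an optional brighter focal core. Default
#' effect directions and magnitudes follow the morphology of activated
#' microglia: higher intensity, area and soma size, fewer/shorter branches,
#' smaller nearest-neighbour distance.
#'
#' @param n_control,n_test numbers of control and test sections.
#' @param grid_nx,grid_ny window-grid dimensions per section.
#' @param side,overlap window geometry (um, fraction).
#' @param scale pixels per um (used to keep `IntDen = Mean * Area * scale^2`
#'   internally consistent).
#' @param mean,sd named per-feature control means and standard deviations.
#' @param proximal,focal named per-feature fold-change multipliers.
#' @param region activation rectangle in 0-based window indices
#'   `c(ix0, iy0, ix1, iy1)`, inclusive.
#' @param core focal-core rectangle (same convention) or `NULL` for none.
#' @param section_effect_sd between-section random effect, as a fraction of
#'   each feature's sd.
#' @param latent_sd sd of the per-window latent activation intensity that
#'   scales all effects jointly (induces feature correlation).
#' @param edge_taper,edge_width activation decays toward the lesion rim:
#'   windows at the rim express `edge_taper` of the full effect, rising
#'   linearly to 1 over `edge_width` window steps into the region (the core
#'   always expresses the full focal effect). Emulates the graded border of
#'   real activation fields.
#' @return Object of class `synth_feature_spec`.
#' @export
synth_feature_spec <- function(n_control = 4, n_test = 4,
                               grid_nx = 28, grid_ny = 28,
                               side = 100, overlap = 0.5, scale = 1.5,
                               mean = NULL, sd = NULL,
                               proximal = NULL, focal = NULL,
                               region = c(9, 9, 18, 18),
                               core = c(13, 13, 15, 15),
                               section_effect_sd = 0.1,
                               latent_sd = 0.15,
                               edge_taper = 0.35, edge_width = 2) {
  base_mean <- c(Area = 2500, Mean = 40, FracDim = 1.45, NumCells = 4,
                 MeanNND = 45, MeanSomaArea = 40, MeanSomaCirc = 0.75,
                 NumBranches = 60, BranchLength = 450, NumJunctions = 25,
                 NumTriplePoints = 22, NumEndPoints = 35, Perimeter = 1800,
                 NumSlabPixels = 500)
  base_sd <- c(Area = 350, Mean = 4, FracDim = 0.05, NumCells = 1.2,
               MeanNND = 7, MeanSomaArea = 5, MeanSomaCirc = 0.05,
               NumBranches = 8, BranchLength = 60, NumJunctions = 4,
               NumTriplePoints = 3.5, NumEndPoints = 5, Perimeter = 220,
               NumSlabPixels = 70)
  prox_mult <- c(Area = 1.4, Mean = 1.4, FracDim = 0.97, NumCells = 1.35,
                 MeanNND = 0.85, MeanSomaArea = 1.2, MeanSomaCirc = 1.08,
                 NumBranches = 0.7, BranchLength = 0.75, NumJunctions = 0.7,
                 NumTriplePoints = 0.7, NumEndPoints = 0.75, Perimeter = 1.1,
                 NumSlabPixels = 0.8)
  focal_mult <- c(Area = 2.0, Mean = 1.8, FracDim = 0.94, NumCells = 1.6,
                  MeanNND = 0.65, MeanSomaArea = 1.4, MeanSomaCirc = 1.15,
                  NumBranches = 0.55, BranchLength = 0.6, NumJunctions = 0.55,
                  NumTriplePoints = 0.55, NumEndPoints = 0.6, Perimeter = 1.2,
                  NumSlabPixels = 0.65)
  if (!is.null(mean)) base_mean[names(mean)] <- mean
  if (!is.null(sd)) base_sd[names(sd)] <- sd
  if (!is.null(proximal)) prox_mult[names(proximal)] <- proximal
  if (!is.null(focal)) focal_mult[names(focal)] <- focal
  stopifnot(all(prox_mult > 0), all(focal_mult > 0))
  if (region[1] < 0 || region[3] >= grid_nx || region[2] < 0 || region[4] >= grid_ny)
    stop("activation region outside window grid", call. = FALSE)
  if (!is.null(core) &&
      (core[1] < region[1] || core[3] > region[3] ||
       core[2] < region[2] || core[4] > region[4]))
    stop("focal core must lie inside the activation region", call. = FALSE)
  structure(list(n_control = n_control, n_test = n_test,
                 grid_nx = grid_nx, grid_ny = grid_ny,
                 side = side, overlap = overlap, scale = scale,
                 mean = base_mean, sd = base_sd,
                 proximal = prox_mult, focal = focal_mult,
                 region = region, core = core,
                 section_effect_sd = section_effect_sd,
                 latent_sd = latent_sd,
                 edge_taper = edge_taper, edge_width = edge_width),
            class = "synth_feature_spec")
}

#' Generate synthetic control and test feature tables with ground truth
#'
#' Draws per-window features from the spec's Gaussians: control windows from
#' the base distribution plus a between-section random effect; test windows
#' inside the implanted region have their means scaled by the proximal (or,
#' in the core, focal) multipliers, modulated by a shared per-window latent
#' activation intensity so that features co-vary. `IntDen` is computed from
#' the realized `Mean` and `Area` so its defining identity holds exactly.
#'
#' @param spec a [synth_feature_spec].
#' @param seed RNG seed (generation is fully reproducible).
#' @return List: `control` and `test` feature tables, and `truth` — a data
#'   frame of per-window true regions for the test sections plus the implant
#'   rectangles in um.
#' @export
generate_feature_table <- function(spec = synth_feature_spec(), seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  stride <- spec$side * (1 - spec$overlap)
  cx <- spec$side / 2 + (seq_len(spec$grid_nx) - 1) * stride
  cy <- spec$side / 2 + (seq_len(spec$grid_ny) - 1) * stride
  grid <- expand.grid(ix = seq_len(spec$grid_nx) - 1L,
                      iy = seq_len(spec$grid_ny) - 1L)
  feats <- names(spec$mean)
  n_win <- nrow(grid)

  make_section <- function(sec_id, group, implant) {
    eff <- stats::rnorm(length(feats), 0, spec$section_effect_sd * spec$sd)
    names(eff) <- feats
    region_lab <- rep("control", n_win)
    strength <- rep(0, n_win)
    if (implant) {
      r <- spec$region
      inR <- grid$ix >= r[1] & grid$ix <= r[3] & grid$iy >= r[2] & grid$iy <= r[4]
      region_lab[inR] <- "proximal"
      # graded lesion edge: depth (in window steps) to the region boundary
      depth <- pmin(grid$ix - r[1], r[3] - grid$ix,
                    grid$iy - r[2], r[4] - grid$iy)
      strength[inR] <- spec$edge_taper + (1 - spec$edge_taper) *
        pmin(1, depth[inR] / spec$edge_width)
      if (!is.null(spec$core)) {
        k <- spec$core
        inC <- grid$ix >= k[1] & grid$ix <= k[3] & grid$iy >= k[2] & grid$iy <= k[4]
        region_lab[inC] <- "focal"
        strength[inC] <- 1
      }
    }
    latent <- stats::rnorm(n_win, 1, spec$latent_sd)
    tab <- data.frame(section_id = sec_id, group = group,
                      x_um = cx[grid$ix + 1L], y_um = cy[grid$iy + 1L],
                      stringsAsFactors = FALSE)
    for (f in feats) {
      mult <- rep(1, n_win)
      mult[region_lab == "proximal"] <- spec$proximal[[f]]
      mult[region_lab == "focal"] <- spec$focal[[f]]
      m <- spec$mean[[f]] * (1 + (mult - 1) * latent * strength) + eff[[f]]
      tab[[f]] <- pmax(0, stats::rnorm(n_win, m, spec$sd[[f]]))
    }
    tab$IntDen <- tab$Mean * tab$Area * spec$scale^2
    tab$true_region <- region_lab
    tab
  }

  ctrl <- do.call(rbind, lapply(seq_len(spec$n_control), function(i)
    make_section(sprintf("ctrl_%02d", i), "control", FALSE)))
  test <- do.call(rbind, lapply(seq_len(spec$n_test), function(i)
    make_section(sprintf("test_%02d", i), "test", TRUE)))

  truth <- test[c("section_id", "x_um", "y_um", "true_region")]
  ctrl$true_region <- NULL
  test$true_region <- NULL
  schema_order <- intersect(feature_table_schema(), names(ctrl))
  ctrl <- ctrl[schema_order]
  test <- test[schema_order]
  for (tb in c("ctrl", "test")) {
    t2 <- get(tb)
    attr(t2, "feature_set") <- "microglia"
    attr(t2, "window_side") <- spec$side
    assign(tb, t2)
  }
  r <- spec$region
  region_um <- c(x0 = r[1] * stride, y0 = r[2] * stride,
                 x1 = r[3] * stride + spec$side, y1 = r[4] * stride + spec$side)
  core_um <- if (is.null(spec$core)) NULL else
    c(x0 = spec$core[1] * stride, y0 = spec$core[2] * stride,
      x1 = spec$core[3] * stride + spec$side, y1 = spec$core[4] * stride + spec$side)
  list(control = ctrl, test = test,
       truth = list(windows = truth, region_um = region_um, core_um = core_um))
}
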