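truth_labeling <- function(gen) {
  # a labeling built from the generator's ground truth, for summaries
  tw <- gen$truth$windows
  lab <- data.frame(section_id = tw$section_id, x_um = tw$x_um, y_um = tw$y_um,
                    region = factor(ifelse(tw$true_region == "control", "distal",
                                           tw$true_region),
                                    levels = c("distal", "proximal", "focal")),
                    proximal_id = as.integer(tw$true_region != "control"),
                    focal_id = as.integer(tw$true_region == "focal"))
  structure(lab, class = c("gliaclust_labels", "data.frame"), window_side = 100)
}

test_that("region summary reports means, counts and fold changes", {
  spec <- synth_feature_spec()
  gen <- generate_feature_table(spec, seed = 11)
  lab <- truth_labeling(gen)
  rs <- region_summary(gen$test, lab, gen$control)
  expect_setequal(unique(rs$region),
                  c("control", "test_all", "distal", "proximal", "focal"))
  # group sizes partition the test table
  n_regions <- rs$n[match(c("distal", "proximal", "focal"), rs$region)]
  expect_equal(sum(n_regions), nrow(gen$test))

  # control summarized against itself: all fold changes are 1
  all_distal <- truth_labeling(gen)
  all_distal$region[] <- "distal"; all_distal$proximal_id <- 0L; all_distal$focal_id <- 0L
  ctrl_lab <- all_distal
  ctrl_lab$section_id <- gen$control$section_id
  ctrl_lab$x_um <- gen$control$x_um; ctrl_lab$y_um <- gen$control$y_um
  rs0 <- region_summary(gen$control, ctrl_lab, gen$control)
  expect_equal(rs0$fold_change[rs0$region == "test_all"],
               rep(1, sum(rs0$region == "test_all")), tolerance = 1e-12)

  # proximal intensity fold change matches the generator's effective
  # multiplier (taper-weighted mean of the proximal strength profile)
  s <- spec$edge_taper; w <- spec$edge_width
  counts <- c(36, 28, 20, 12, 4)  # windows at depths 0..4 of the 10x10 region
  strengths <- pmin(1, (0:4) / w) * (1 - s) + s
  core_n <- 9
  interior <- counts * strengths
  eff <- (sum(interior) - core_n * 1) / (sum(counts) - core_n)
  expected_fold <- 1 + (spec$proximal[["Mean"]] - 1) * eff
  got <- rs$fold_change[rs$region == "proximal" & rs$feature == "Mean"]
  expect_lt(abs(got - expected_fold), 0.1)

  # an empty region keeps its row with n = 0
  none <- truth_labeling(gen)
  none$region[] <- "distal"; none$proximal_id <- 0L; none$focal_id <- 0L
  rs1 <- region_summary(gen$test, none, gen$control)
  expect_true(all(rs1$n[rs1$region %in% c("proximal", "focal")] == 0))
})

test_that("pixel colocalization behaves like a Pearson correlation", {
  set.seed(21)
  a <- image_plane(matrix(runif(10000), 100, 100))
  expect_equal(pearson_coloc(a, a)$R, 1)
  inv <- image_plane(1 - a$pixels)
  expect_equal(pearson_coloc(a, inv)$R, -1)
  b <- image_plane(matrix(runif(10000), 100, 100))
  expect_lt(abs(pearson_coloc(a, b)$R), 0.05)
  expect_equal(pearson_coloc(a, b)$R, pearson_coloc(b, a)$R)
  flat <- image_plane(matrix(1, 100, 100))
  expect_error(pearson_coloc(a, flat), "constant")
  roi <- matrix(FALSE, 100, 100)
  expect_error(pearson_coloc(a, b, roi), "empty")
})

test_that("linear fits recover exact and null relationships", {
  x <- 1:20
  f <- linear_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  f3 <- linear_fit(c(1, 2, 3), c(4, 6, 8))
  expect_equal(f3$r_squared, 1)

  set.seed(31)
  f0 <- linear_fit(rnorm(500), rnorm(500))
  expect_lt(f0$r_squared, 0.03)
  expect_error(linear_fit(rep(1, 10), rnorm(10)), "zero-variance")
  expect_error(linear_fit(1:2, 1:2), "n >= 3")
})

test_that("feature tables round-trip through CSV bit-identically", {
  gen <- generate_feature_table(small_feature_spec(), seed = 12)
  path <- tempfile(fileext = ".csv")
  write_feature_csv(gen$control, path)
  back <- read_feature_csv(path)
  for (cn in names(gen$control)) {
    expect_identical(back[[cn]], gen$control[[cn]], label = cn)
  }
  unlink(path)
  expect_error(read_feature_csv({
    p <- tempfile(); writeLines("a,b\n1,2", p); p
  }), "required column")
})

test_that("label CSV and GeoJSON exports carry the labeling", {
  gen <- generate_feature_table(small_feature_spec(), seed = 13)
  fit <- gliaclust(gen$control, nu = 0.05, gamma = 0.1)
  lab <- predict(fit, gen$test, min_size = 5)
  p1 <- tempfile(fileext = ".csv")
  write_labels_csv(lab, p1)
  got <- read.csv(p1)
  expect_identical(names(got), c("section_id", "x_um", "y_um", "region", "cluster_id"))
  expect_equal(nrow(got), nrow(lab))
  expect_setequal(unique(got$region), unique(as.character(lab$region)))
  unlink(p1)

  p2 <- tempfile(fileext = ".geojson")
  write_geojson(lab, p2)
  doc <- jsonlite::read_json(p2)
  expect_equal(doc$type, "FeatureCollection")
  n_clusters <- length(setdiff(unique(lab$proximal_id), 0L)) +
                length(setdiff(unique(lab$focal_id), 0L))
  expect_equal(length(doc$features), n_clusters)
  unlink(p2)
})

test_that("TIFF round trip preserves the image to quantization accuracy", {
  px <- matrix(runif(4000), 80, 50)
  pl <- image_plane(px, scale = 1.5)
  path <- tempfile(fileext = ".tif")
  write_tiff_plane(pl, path)
  back <- read_tiff_plane(path, scale = 1.5)
  expect_equal(dim(back$pixels), dim(px))
  expect_lt(max(abs(back$pixels - px)), 1 / 65535 + 1e-9)
  unlink(path)
})

test_that("configs are validated with named-field errors", {
  p <- tempfile(fileext = ".json")
  writeLines('{"nu": 0.1, "gamma": 0.5, "min_size": 5}', p)
  cfg <- read_config(p)
  expect_equal(cfg$nu, 0.1)
  writeLines('{"nu": 0}', p)
  expect_error(read_config(p), "nu")
  unlink(p)
  py <- tempfile(fileext = ".yaml")
  writeLines("nu: 0.05\ngamma: 1.0", py)
  expect_equal(read_config(py)$gamma, 1.0)
  unlink(py)
})
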