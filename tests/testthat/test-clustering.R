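test_that("default neighbour radius is the rounded-up window diagonal", {
  expect_equal(default_eps(100), 142)
  expect_equal(default_eps(50), 71)
  expect_error(default_eps(0), "> 0")
})

test_that("DBSCAN handles canonical window layouts", {
  # six windows on a stride-50 line: one cluster
  lab <- dbscan_points(seq(0, 250, by = 50), rep(0, 6), eps = 142, min_size = 5)
  expect_equal(lab, rep(1L, 6))
  # three windows cannot reach min_size 5
  expect_equal(dbscan_points(c(0, 50, 100), rep(0, 3), 142, 5), rep(0L, 3))
  # two groups 500 um apart form two clusters
  x <- c(seq(0, 250, 50), seq(800, 1050, 50))
  lab2 <- dbscan_points(x, rep(0, 12), 142, 5)
  expect_equal(length(setdiff(unique(lab2), 0L)), 2L)
  expect_true(all(lab2[1:6] == lab2[1]) && all(lab2[7:12] == lab2[7]))
  expect_equal(dbscan_points(numeric(0), numeric(0), 142, 5), integer(0))
})

test_that("DBSCAN agrees with a brute-force oracle on random point sets", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(10:60, 1)
    x <- runif(n, 0, 500); y <- runif(n, 0, 500)
    eps <- sample(c(60, 100, 142), 1)
    ms <- sample(c(2, 3, 5), 1)
    lab <- dbscan_points(x, y, eps, ms)
    expect_true(dbscan_equivalent(lab, x, y, eps, ms),
                label = sprintf("seed %d eps %g ms %d", seed, eps, ms))
  }
})

test_that("elbow detection finds hockey-stick breakpoints, rejects ramps", {
  # 80 near-zero points then 20 rising to 4: elbow at the breakpoint
  v <- c(rnorm(80, 0, 0.02), seq(0.2, 4, length.out = 20))
  el <- elbow_threshold(v)
  expect_true(el$passes_floor)
  expect_lt(abs(el$modal_index - 80), 3)
  expect_equal(el$threshold_value, sort(v)[el$modal_index])

  # a perfect linear ramp has no elbow
  ramp <- elbow_threshold(seq(0, 5, length.out = 60))
  expect_lt(ramp$max_perp_magnitude, 0.05)
  expect_false(ramp$passes_floor)

  # the floor comparison is strict: magnitude == floor does not pass
  el2 <- elbow_threshold(v, magnitude_floor = el$max_perp_magnitude)
  expect_false(el2$passes_floor)

  # fewer than three values: unusable result, not an error
  short <- elbow_threshold(c(1, 2))
  expect_false(short$passes_floor)
  expect_true(is.na(short$threshold_value))
})

test_that("modal elbow rank tracks the true breakpoint across noise levels", {
  for (f in c(0.6, 0.7, 0.8, 0.9)) {
    for (noise in c(0.01, 0.05, 0.1)) {
      v <- hockey_values(100, f, ratio = 20, noise = noise,
                         seed = round(1000 * f + 100 * noise))
      el <- elbow_threshold(v)
      expect_lt(abs(el$modal_index - 100 * f), 2.5,
                label = sprintf("f=%.1f noise=%.2f", f, noise))
    }
  }
})

test_that("region labels partition windows and focal stays inside proximal", {
  gen <- generate_feature_table(small_feature_spec(), seed = 4)
  fit <- gliaclust(gen$control, nu = 0.05, gamma = 0.1)
  lab <- predict(fit, gen$test, min_size = 5)
  expect_equal(nrow(lab), nrow(gen$test))
  expect_false(anyNA(lab$region))
  expect_true(all(lab$focal_id == 0L | lab$proximal_id > 0L))
  expect_true(all((lab$region == "focal") == (lab$focal_id > 0L)))
  expect_true(all((lab$region == "proximal") ==
                  (lab$proximal_id > 0L & lab$focal_id == 0L)))

  # without outliers everything stays distal
  lab0 <- predict(fit, gen$control[gen$control$section_id == "ctrl_01", ],
                  min_size = 500)
  expect_true(all(lab0$region == "distal"))
})

test_that("focal clustering respects the elbow floor and min size", {
  flags <- data.frame(section_id = "s",
                      x_um = seq(50, 1000, 50),
                      y_um = 50,
                      is_outlier = TRUE)
  flags <- cluster_proximal(flags, eps = 142, min_size = 5)
  expect_true(all(flags$proximal_id == 1L))
  # bimodal integrated density: the hot contiguous windows above the elbow
  # threshold form one focal cluster
  flags$IntDen_z <- c(seq(0.1, 0.2, length.out = 12), seq(6, 8, length.out = 8))
  el <- elbow_threshold(flags$IntDen_z)
  expect_true(el$passes_floor)
  out <- cluster_focal(flags, eps = 142, min_size = 5)
  hot <- flags$IntDen_z > el$threshold_value
  expect_equal(out$focal_id > 0L, hot)
  expect_equal(length(setdiff(unique(out$focal_id), 0L)), 1L)
  # impossible floor: no focal clusters regardless of the values
  out2 <- cluster_focal(flags, magnitude_floor = Inf)
  expect_true(all(out2$focal_id == 0L))
  # hot windows scattered too sparsely for min_size
  flags2 <- data.frame(section_id = "s",
                       x_um = c(seq(50, 600, 50), seq(2000, 16000, 2000)),
                       y_um = 50, is_outlier = TRUE,
                       IntDen_z = c(seq(0.1, 0.2, length.out = 12),
                                    seq(6, 8, length.out = 8)))
  flags2 <- cluster_proximal(flags2, eps = 20000, min_size = 5)
  expect_true(all(flags2$proximal_id == 1L))
  out3 <- cluster_focal(flags2, eps = 142, min_size = 5)
  expect_true(all(out3$focal_id == 0L))
})

test_that("footprint areas and overlaps follow polygon arithmetic", {
  # one 100 um window in a 1 mm^2 section covers 1%
  flags <- data.frame(section_id = "s", x_um = 50, y_um = 50,
                      is_outlier = TRUE, proximal_id = 1L, focal_id = 0L)
  fr <- cluster_area_fraction(flags, 1e6, side = 100)
  expect_equal(fr[["proximal"]], 0.01)
  expect_equal(fr[["focal"]], 0)

  # two windows overlapping 50%: union is 1.5 window areas
  expect_equal(footprint_area(c(50, 100), c(50, 50), side = 100), 1.5e4)

  # identical, disjoint, and half-contained footprints
  expect_equal(unname(cluster_overlap(c(50, 150), c(50, 50), c(50, 150), c(50, 50))),
               c(1, 1))
  expect_equal(unname(cluster_overlap(50, 50, 1050, 50)), c(0, 0))
  ov <- cluster_overlap(c(50, 150), c(50, 50), 50, 50)
  expect_equal(unname(ov), c(0.5, 1.0))

  iou <- footprint_iou(c(50, 150), c(50, 50), 50, 50)
  expect_equal(iou, 0.5)
  expect_error(cluster_area_fraction(flags, 0), "tissue_area")
})
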