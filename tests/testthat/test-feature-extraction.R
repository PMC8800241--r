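test_that("max projection reduces a z-stack per pixel", {
  a <- image_plane(matrix(runif(100), 10, 10))
  expect_equal(project_max(list(a))$pixels, a$pixels)

  zero <- image_plane(matrix(0, 10, 10))
  expect_equal(project_max(list(a, zero))$pixels, a$pixels)

  b <- image_plane(a$pixels + 0.5)  # b >= a elementwise
  expect_equal(project_max(list(a, b))$pixels, b$pixels)

  bad <- image_plane(matrix(0, 5, 5))
  expect_error(project_max(list(a, bad)), "mismatch")
})

test_that("window enumeration matches the closed-form grid count", {
  p1 <- image_plane(matrix(1, 150, 150), scale = 1.5)  # 100 x 100 um
  expect_equal(nrow(enumerate_windows(p1, window_spec())), 1L)

  p2 <- image_plane(matrix(1, 300, 150), scale = 1.5)  # 200 x 100 um
  w <- enumerate_windows(p2, window_spec())
  expect_equal(nrow(w), 3L)
  expect_equal(sort(w$cx), c(50, 100, 150))

  p3 <- image_plane(matrix(1, 300, 300), scale = 1.5)
  expect_equal(nrow(enumerate_windows(p3, window_spec(overlap = 0))), 4L)

  # property: floor((L - w)/stride) + 1 per axis
  set.seed(11)
  for (rep in 1:20) {
    npx <- sample(160:600, 2)
    side <- sample(c(50, 80, 100), 1)
    ov <- sample(c(0, 0.25, 0.5), 1)
    p <- image_plane(matrix(1, npx[1], npx[2]), scale = 1.5)
    L <- npx / 1.5
    stride <- side * (1 - ov)
    expected <- prod(floor((L - side) / stride + 1e-9) + 1)
    expect_equal(nrow(enumerate_windows(p, window_spec(side, ov))), expected)
  }

  tiny <- image_plane(matrix(1, 30, 30), scale = 1.5)
  expect_warning(w0 <- enumerate_windows(tiny, window_spec()), "smaller")
  expect_equal(nrow(w0), 0L)
})

test_that("preprocessing removes flat background and speckle, keeps spots", {
  const <- image_plane(matrix(5, 120, 120))
  expect_true(all(preprocess_plane(const, "microglia")$pixels == 0))

  spk <- matrix(0, 120, 120); spk[60, 60] <- 1
  expect_true(all(preprocess_plane(image_plane(spk), "microglia")$pixels == 0))

  # smooth gradient + two bright spots: spots survive, gradient is suppressed
  grad <- outer(seq(0, 0.3, length.out = 200), rep(1, 200))
  img <- grad
  img[80:83, 80:83] <- img[80:83, 80:83] + 1
  img[150:153, 150:153] <- img[150:153, 150:153] + 1
  out <- preprocess_plane(image_plane(img), "microglia")$pixels
  expect_gt(out[81, 81], 0.7)
  expect_gt(out[151, 151], 0.7)
  expect_lt(max(out[grad > 0.2 & img < 0.4]), 0.2)

  # tissue mask clearing
  msk <- matrix(TRUE, 120, 120); msk[1:60, ] <- FALSE
  pm <- image_plane(matrix(1, 120, 120) + matrix(runif(14400), 120, 120),
                    tissue_mask = msk)
  expect_true(all(preprocess_plane(pm, "microglia")$pixels[1:60, ] == 0))
})

test_that("Phansalkar threshold matches direct formula evaluation", {
  # all-zero image: nothing is foreground
  z <- image_plane(matrix(0, 32, 32))
  expect_false(any(local_threshold(z)))

  # uniform bright image: local mean equals pixel value, strict > fails
  u <- image_plane(matrix(7, 64, 64))
  expect_false(any(local_threshold(u)))

  # bright disk on black: package path vs direct per-pixel evaluation
  px <- matrix(0.05, 64, 64)
  px[disk_mask(12, 64)] <- 1
  cfg <- threshold_config(radius = 10)
  got <- local_threshold(image_plane(px), cfg)
  want <- oracle_phansalkar(px, 10, cfg$k, cfg$r)
  expect_gt(mean(got == want), 0.995)

  # behavioural check at the default radius 60 on a large instance
  big <- matrix(0.02, 180, 180)
  dm <- disk_mask(30, 180)
  big[dm] <- 0.9
  fg <- local_threshold(image_plane(big), threshold_config(radius = 60))
  expect_gt(mean(fg[dm]), 0.95)         # disk interior accepted
  expect_lt(mean(fg[!dm]), 0.02)        # background rejected
})

test_that("intensity features follow their definitions", {
  p <- image_plane(matrix(3, 150, 150), scale = 1.5)
  full <- matrix(TRUE, 150, 150)
  v <- intensity_features(p, full, c(0, 0, 100, 100))
  expect_equal(v[["mean"]], 3)
  expect_equal(v[["integrated_density"]], 3 * 150 * 150)
  expect_equal(v[["area_um2"]], 150 * 150 / 1.5^2)

  none <- matrix(FALSE, 150, 150)
  expect_equal(unname(intensity_features(p, none, c(0, 0, 100, 100))), c(0, 0, 0))

  # half foreground at intensities 10 and 20 -> mean 15
  px <- matrix(10, 100, 100); px[, 51:100] <- 20
  mask <- matrix(FALSE, 100, 100); mask[26:75, 26:75] <- TRUE
  p2 <- image_plane(px, scale = 1)
  v2 <- intensity_features(p2, mask, c(0, 0, 100, 100))
  expect_equal(v2[["mean"]], 15)
  expect_equal(v2[["integrated_density"]], 15 * sum(mask))
})

test_that("feature table has the schema, one row per window, consistent IntDen", {
  sec <- render_section(synth_tissue_spec(section_um = 200, density = 250),
                        seed = 5)
  ft <- build_feature_table(sec$plane, window_spec(), feature_set = "microglia",
                            section_id = "s", group = "control")
  w <- enumerate_windows(preprocess_plane(sec$plane, "microglia"), window_spec())
  expect_equal(nrow(ft), nrow(w))
  expect_identical(names(ft), feature_table_schema())
  feats <- feature_columns("microglia")
  expect_true(all(is.finite(as.matrix(ft[feats]))))
  # IntDen = Mean x foreground pixel count = Mean x Area x scale^2
  expect_equal(ft$IntDen, ft$Mean * ft$Area * 1.5^2, tolerance = 1e-10)

  # astrocyte set: 7 features populated, others empty unless soma channel given
  fa <- build_feature_table(list(branching = sec$plane), window_spec(),
                            feature_set = "astrocyte")
  expect_true(all(is.finite(as.matrix(fa[feature_columns("astrocyte")]))))
  expect_true(all(is.na(fa$FracDim)))
  expect_true(all(is.na(fa$NumCells)))
  expect_error(build_feature_table(list(soma = sec$soma_plane), window_spec(),
                                   feature_set = "astrocyte"), "branching")
})
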