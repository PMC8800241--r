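fake_table <- function(n, p = 4, seed = 1, sds = NULL) {
  set.seed(seed)
  feats <- feature_columns("microglia")[seq_len(p)]
  if (is.null(sds)) sds <- rep(1, p)
  tab <- data.frame(section_id = "s1", group = "control",
                    x_um = seq_len(n) * 50, y_um = 50)
  for (i in seq_along(feats)) tab[[feats[i]]] <- rnorm(n, 10, sds[i])
  tab
}

test_that("z-scoring uses training statistics only", {
  tr <- fake_table(40)
  nm <- fit_normalizer(tr)
  z <- apply_normalizer(nm, tr)
  for (f in nm$features) {
    expect_equal(mean(z[[f]]), 0, tolerance = 1e-9)
    expect_equal(sd(z[[f]]), 1, tolerance = 1e-9)
  }

  # a test row equal to the training mean maps to the zero vector
  te <- tr[1, ]
  for (f in nm$features) te[[f]] <- nm$mu[[f]]
  expect_true(all(abs(as.numeric(apply_normalizer(nm, te)[nm$features])) < 1e-12))

  # x = mu + s -> 1 and x = mu - s -> -1 (the intensity-floor boundary)
  for (f in nm$features) te[[f]] <- nm$mu[[f]] + nm$sd[[f]]
  expect_true(all(abs(as.numeric(apply_normalizer(nm, te)[nm$features]) - 1) < 1e-12))
  for (f in nm$features) te[[f]] <- nm$mu[[f]] - nm$sd[[f]]
  expect_true(all(abs(as.numeric(apply_normalizer(nm, te)[nm$features]) + 1) < 1e-12))

  # metamorphic: growing the test set leaves existing transforms unchanged
  te2 <- rbind(tr[1:5, ], fake_table(10, seed = 99))
  z1 <- apply_normalizer(nm, tr[1:5, ])
  z2 <- apply_normalizer(nm, te2)
  expect_equal(z2[1:5, nm$features], z1[nm$features])
})

test_that("normalizer rejects degenerate input and drops constant features", {
  expect_error(fit_normalizer(fake_table(1)), "2 training rows")
  tr <- fake_table(20)
  tr$Area <- 5  # constant
  expect_warning(nm <- fit_normalizer(tr), "zero-variance")
  expect_false("Area" %in% nm$features)
  expect_error(apply_normalizer(structure(list(mu = c(Qq = 0), sd = c(Qq = 1),
                                               features = "Qq"),
                                          class = "gc_normalizer"),
                                tr), "lacks")
})

test_that("PCA retains the minimal component count for the variance target", {
  # two isotropic features: nothing can be dropped at a 0.99 target
  tr <- fake_table(500, p = 2, seed = 3)
  nm <- fit_normalizer(tr)
  z <- apply_normalizer(nm, tr)
  pr <- fit_projection(z, nm$features, 0.99)
  expect_equal(pr$n_retained, 2L)

  # one dominant direction -> a single retained component
  tr2 <- fake_table(500, p = 2, seed = 4, sds = c(10, 0.1))
  nm2 <- fit_normalizer(tr2, features = feature_columns("microglia")[1:2])
  # dominant direction must survive standardization: scale feature 1 back up
  z2 <- tr2
  z2[[nm2$features[1]]] <- (z2[[nm2$features[1]]] - nm2$mu[1]) / nm2$sd[1] * 20
  z2[[nm2$features[2]]] <- (z2[[nm2$features[2]]] - nm2$mu[2]) / nm2$sd[2]
  pr2 <- fit_projection(z2, nm2$features, 0.99)
  expect_equal(pr2$n_retained, 1L)

  # minimal k equals brute-force cumulative-sum search, loadings orthonormal
  tr3 <- fake_table(300, p = 4, seed = 5, sds = c(5, 2, 1, 0.2))
  nm3 <- fit_normalizer(tr3)
  z3 <- apply_normalizer(nm3, tr3)
  for (target in c(0.5, 0.9, 0.99)) {
    pr3 <- fit_projection(z3, nm3$features, target)
    expect_equal(pr3$n_retained,
                 which(cumsum(pr3$var_fraction) >= target - 1e-12)[1])
  }
  pr3 <- fit_projection(z3, nm3$features, 0.99)
  g <- pr3$loadings %*% t(pr3$loadings)
  expect_equal(g, diag(nrow(g)), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("projection scores decorrelate training data and keep raw z columns", {
  tr <- fake_table(300, p = 4, seed = 6, sds = c(3, 2, 1, 0.5))
  tr$Mean <- rnorm(300, 50, 5); tr$IntDen <- tr$Mean * 100
  nm <- fit_normalizer(tr)
  z <- apply_normalizer(nm, tr)
  pr <- fit_projection(z, setdiff(nm$features, c("Mean", "IntDen")), 0.9999)
  sc <- apply_projection(pr, z)
  pcs <- as.matrix(sc[grep("^PC", names(sc))])
  cv <- cov(pcs)
  expect_equal(cv, diag(diag(cv)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(c("Mean_z", "IntDen_z", "section_id", "x_um", "y_um") %in% names(sc)))

  # zero z-vector projects to zero scores
  z0 <- z[1, ]
  for (f in pr$features) z0[[f]] <- 0
  expect_true(all(abs(as.matrix(apply_projection(pr, z0)[grep("^PC", names(sc))])) < 1e-12))

  # norm preservation when every component is retained
  pr_all <- fit_projection(z, pr$features, 1)
  sc_all <- apply_projection(pr_all, z)
  expect_equal(rowSums(as.matrix(sc_all[grep("^PC", names(sc_all))])^2),
               rowSums(as.matrix(z[pr$features])^2), tolerance = 1e-9)
})
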