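fake_profiles <- function(n, p = 31, seed = 1, f = NULL) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p)
  if (!is.null(f)) x <- f(x)
  df <- as.data.frame(x)
  names(df) <- encoding_parameter_names()[seq_len(p)]
  df$neuron_class <- rep(c("Ia", "Iun", "Ib", "II"), length.out = n)
  df$treatment <- rep(c("control", "cOIN"), each = ceiling(n / 2))[seq_len(n)]
  df
}

test_that("standardization centers, scales, imputes and drops constants", {
  df <- fake_profiles(30)
  df$baseline_rate <- 0                 # constant column
  df$peak_dynamic_rate[3] <- NA         # one missing flag
  expect_warning(std <- standardize_profiles(df), "baseline_rate")
  expect_true(all(abs(colMeans(std$x)) < 1e-10))
  expect_true(all(abs(apply(std$x, 2, stats::sd) - 1) < 0.05))
  expect_equal(unname(std$x[3, "peak_dynamic_rate"]), 0)  # mean-imputed post-scaling
  expect_equal(unname(std$imputed["peak_dynamic_rate"]), 1)
  expect_identical(std$dropped, "baseline_rate")
  # duplicated rows standardize identically
  df2 <- fake_profiles(10)
  std2 <- standardize_profiles(rbind(df2, df2))
  expect_equal(std2$x[1, ], std2$x[11, ])
})

test_that("rank-1 data loads everything on PC1", {
  df <- fake_profiles(40, f = function(x) {
    u <- x[, 1]
    outer(u, seq_len(ncol(x)) / ncol(x))
  })
  space <- fit_pca(standardize_profiles(df))
  expect_gt(space$explained_variance[1], 99.9)
})

test_that("isotropic data spreads variance evenly across the 31 PCs", {
  df <- fake_profiles(4000)
  space <- fit_pca(standardize_profiles(df))
  expect_equal(space$explained_variance,
               rep(100 / 31, 31), tolerance = 0.25)  # relative tolerance
  expect_true(all(diff(space$explained_variance) <= 1e-12))
  expect_lte(sum(space$explained_variance), 100 + 1e-9)
})

test_that("scores are centered, orthogonal, and reconstruct the data", {
  df <- fake_profiles(60, f = function(x) x %*% diag(seq(1, 4, length.out = ncol(x))))
  std <- standardize_profiles(df)
  space <- fit_pca(std)
  expect_true(all(abs(colMeans(space$scores)) < 1e-10))
  cc <- stats::cor(space$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-10)
  recon <- space$scores %*% t(space$rotation)
  expect_equal(unname(recon), unname(std$x), tolerance = 1e-10)
  expect_true(all(abs(space$loadings) <= 1 + 1e-8))
  # deterministic sign convention: refitting gives identical loadings
  expect_identical(space$loadings, fit_pca(std)$loadings)
  expect_error(fit_pca(std$x[1:2, ]), "at least 3")
})

test_that("group geometry returns centroids, shifts, and calibrated ellipses", {
  df <- fake_profiles(60)
  std <- standardize_profiles(df)
  space <- fit_pca(std)
  geom <- group_geometry(space)
  expect_true(all(c("PC1", "PC2", "n") %in% names(geom$centroids)))
  # identical groups: zero shift
  sc <- matrix(stats::rnorm(40), 20, 2)
  fake_space <- structure(list(scores = cbind(rbind(sc, sc), 0),
                               labels = NULL), class = "latent_space")
  g0 <- group_geometry(fake_space,
                       class_labels = rep("Ia", 40),
                       treatment_labels = rep(c("control", "cOIN"), each = 20))
  expect_equal(g0$shift_vectors$dPC1, 0, tolerance = 1e-12)
  expect_equal(g0$shift_vectors$dPC2, 0, tolerance = 1e-12)
  # translated group: shift vector equals the translation
  g2 <- group_geometry(structure(list(scores = cbind(rbind(sc, sweep(sc, 2, c(-2, 0))), 0),
                                      labels = NULL), class = "latent_space"),
                       class_labels = rep("Ia", 40),
                       treatment_labels = rep(c("control", "cOIN"), each = 20))
  expect_equal(g2$shift_vectors$dPC1, 2, tolerance = 1e-12)
  expect_equal(g2$shift_vectors$dPC2, 0, tolerance = 1e-12)
})

test_that("95% ellipse covers ~95% of a large bivariate normal sample", {
  set.seed(5)
  n <- 10000
  sigma <- matrix(c(2, 0.8, 0.8, 1), 2)
  ch <- chol(sigma)
  pts <- matrix(stats::rnorm(2 * n), n, 2) %*% ch
  space <- structure(list(scores = cbind(pts, 0), labels = NULL),
                     class = "latent_space")
  geom <- group_geometry(space, class_labels = rep("Ia", n),
                         treatment_labels = rep("control", n))
  b <- geom$ellipses[["Ia/control"]]
  # coverage oracle: Mahalanobis distance against the fitted boundary's cov
  s_hat <- stats::cov(pts)
  d2 <- stats::mahalanobis(pts, colMeans(pts), s_hat)
  inside <- d2 <= stats::qchisq(0.95, 2)
  expect_equal(mean(inside), 0.95, tolerance = 0.011)
  # boundary points sit at the chi-square radius
  db <- stats::mahalanobis(b, colMeans(pts), s_hat)
  expect_equal(unname(db), rep(stats::qchisq(0.95, 2), 100), tolerance = 0.05)
})

test_that("default phenotypes shift all muscle classes the same way along PC1", {
  st <- fast_ramp(2000)
  d <- simulate_muscle_force(st)
  rows <- list()
  i <- 0
  for (treatment in c("control", "cOIN")) {
    phen <- default_phenotypes(treatment)$neurons
    for (cls in c("Ia", "Iun", "Ib", "II")) {
      p <- phen[phen$neuron_class == cls, ]
      for (neuron in 1:6) {
        i <- i + 1
        trains <- lapply(1:2, function(tr)
          simulate_propriosensor_spikes(p, st, d, seed = 31 * i + tr))
        rows[[i]] <- compute_profile(trains, st, d)
      }
    }
  }
  profiles <- do.call(rbind, rows)
  space <- suppressWarnings(fit_pca(standardize_profiles(profiles)))
  geom <- group_geometry(space)
  expect_equal(nrow(geom$shift_vectors), 4)
  signs <- sign(geom$shift_vectors$dPC1)
  expect_true(all(signs == signs[1]))  # common PC1 half-plane
})
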