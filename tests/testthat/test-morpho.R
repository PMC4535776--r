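test_that("centroid size has the defining value and invariances", {
  sq <- matrix(c(-0.5, -0.5, 0.5, 0.5, -0.5, 0.5, -0.5, 0.5), 4, 2)
  expect_equal(centroid_size(sq), sqrt(2))

  x <- ref_shape()
  expect_equal(centroid_size(3 * x), 3 * centroid_size(x))
  expect_equal(centroid_size(sweep(x, 2, c(10, -4), "+")),
               centroid_size(x))
  expect_equal(centroid_size(rand_similarity(x, 0.7, 1, c(0, 0))),
               centroid_size(x))
  expect_error(centroid_size(matrix(1, 5, 2)), "degenerate")
})

test_that("GPA recovers identical shapes under arbitrary similarity transforms", {
  set.seed(61)
  x <- ref_shape()
  coords <- array(NA_real_, c(8, 14, 2))
  for (i in 1:8)
    coords[i, , ] <- rand_similarity(x, runif(1, -pi, pi),
                                     exp(runif(1, -1, 1)),
                                     runif(2, -10, 10))
  fit <- gpa(coords)
  expect_true(fit$converged)
  # all aligned configurations coincide with the mean to high precision
  expect_lt(max(abs(sweep(fit$aligned, c(2, 3), fit$mean_shape))), 1e-8)
  # full Procrustes: unit centroid size everywhere, mean centered
  for (i in 1:8) expect_equal(centroid_size(fit$aligned[i, , ]), 1)
  expect_equal(colMeans(fit$mean_shape), c(0, 0))
  expect_equal(centroid_size(fit$mean_shape), 1)
  # original sizes are reported untouched
  expect_equal(unname(fit$centroid_sizes[1]), centroid_size(coords[1, , ]))
})

test_that("two-shape GPA agrees with the closed-form ordinary Procrustes fit", {
  set.seed(62)
  x <- ref_shape()
  y <- x + matrix(rnorm(28, sd = 0.05), 14, 2)
  y <- rand_similarity(y, 1.1, 2.4, c(3, -1))
  coords <- array(NA_real_, c(2, 14, 2))
  coords[1, , ] <- x; coords[2, , ] <- y
  fit <- gpa(coords)
  # aligned difference should equal the direct OPA residual of y on x
  y_on_x <- opa_fit(y, x)
  x_unit <- opa_fit(x, x)
  d_gpa <- sqrt(sum((fit$aligned[2, , ] - fit$aligned[1, , ])^2))
  d_opa <- sqrt(sum((y_on_x - x_unit)^2))
  expect_equal(d_gpa, d_opa, tolerance = 1e-6)
})

test_that("two-shape alignment matches an independent Procrustes implementation", {
  set.seed(63)
  x <- ref_shape()
  y <- rand_similarity(x + matrix(rnorm(28, sd = 0.08), 14, 2),
                       -0.6, 0.7, c(5, 2))
  coords <- array(NA_real_, c(2, 14, 2))
  coords[1, , ] <- x; coords[2, , ] <- y
  fit <- gpa(coords)
  d_gpa <- sqrt(sum((fit$aligned[2, , ] - fit$aligned[1, , ])^2))
  # vegan's symmetric Procrustes residual is sin(rho) of the Procrustes
  # angle rho (it rescales optimally); the full-Procrustes chord distance
  # between unit-size shapes is 2 sin(rho / 2)
  pv <- vegan::procrustes(x, y, scale = TRUE, symmetric = TRUE)
  rho <- asin(min(1, sqrt(pv$ss)))
  expect_equal(d_gpa, 2 * sin(rho / 2), tolerance = 1e-6)
})

test_that("Procrustes residual sum never increases across GPA iterations and is order-invariant", {
  set.seed(64)
  sim <- simulate_landmarks(list(A = ref_shape()), 12, noise_sd = 0.08,
                            translation_range = 4, scale_range = 2,
                            seed = 65)
  fit <- gpa(sim$coords)
  rss <- function(f) sum(sweep(f$aligned, c(2, 3), f$mean_shape)^2)
  # permute input order: same mean shape up to rotation, same residual
  perm <- sample(dim(sim$coords)[1])
  fit2 <- gpa(sim$coords[perm, , ])
  expect_equal(rss(fit), rss(fit2), tolerance = 1e-8)
  m1 <- fit$mean_shape
  m2 <- fit2$mean_shape %*% islandmouse:::.opt_rotation(fit2$mean_shape,
                                                        fit$mean_shape)
  expect_equal(m1, m2, tolerance = 1e-6)
})

test_that("shape PCA conserves variance and reconstructs the data", {
  set.seed(66)
  sim <- simulate_landmarks(list(A = ref_shape()), 30, noise_sd = 0.05,
                            seed = 67)
  fit <- gpa(sim$coords)
  pca <- shape_pca(fit)
  X <- matrix(fit$aligned, nrow = 30)
  # total variance equals the trace of the covariance matrix
  expect_equal(sum(pca$eigenvalues), sum(diag(stats::cov(X))))
  expect_equal(sum(pca$variance_fraction), 1)
  # scores have zero mean; full reconstruction reproduces the data
  expect_lt(max(abs(colMeans(pca$scores))), 1e-12)
  rebuilt <- sweep(pca$scores %*% t(pca$loadings), 2, pca$center, "+")
  expect_equal(unname(rebuilt), unname(X), tolerance = 1e-10)
  # eigenvalues descending and non-negative
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
  expect_true(all(pca$eigenvalues >= -1e-12))
  # full-rank scores preserve pairwise Procrustes distances
  d_shape <- as.matrix(dist(X))
  d_score <- as.matrix(dist(pca$scores))
  expect_equal(unname(d_shape), unname(d_score), tolerance = 1e-10)
  expect_error(shape_pca(gpa(sim$coords[1:2, , ])), "at least 3")
})

test_that("PC1 recovers a simulated group-shape axis", {
  base <- ref_shape()
  stretch <- base
  stretch[, 1] <- stretch[, 1] * 1.25   # anterior-posterior elongation
  sim <- simulate_landmarks(list(A = base, B = stretch), 25,
                            noise_sd = 0.02, translation_range = 2,
                            scale_range = 1.5, seed = 68)
  fit <- gpa(sim$coords)
  pca <- shape_pca(fit)
  # the true between-group axis in aligned space
  ga <- apply(fit$aligned[sim$group == "A", , ], c(2, 3), mean)
  gb <- apply(fit$aligned[sim$group == "B", , ], c(2, 3), mean)
  axis <- as.vector(gb - ga)
  r <- abs(cor(pca$loadings[, 1], axis))
  expect_gt(r, 0.9)
  # and the groups separate along PC1
  expect_gt(abs(mean(pca$scores[sim$group == "A", 1]) -
                  mean(pca$scores[sim$group == "B", 1])),
            2 * (sd(pca$scores[sim$group == "A", 1]) +
                   sd(pca$scores[sim$group == "B", 1])))
})

test_that("group shape differences are antisymmetric and localize simulated effects", {
  base <- ref_shape()
  stretch <- base
  stretch[1:3, 1] <- stretch[1:3, 1] + 0.4   # effect on landmarks 1-3 only
  sim <- simulate_landmarks(list(A = base, B = stretch), 20,
                            noise_sd = 0.01, seed = 69)
  fit <- gpa(sim$coords)
  ab <- group_shape_difference(fit, sim$group, "A", "B")
  ba <- group_shape_difference(fit, sim$group, "B", "A")
  expect_equal(ab$displacement, -ba$displacement)
  expect_equal(unname(group_shape_difference(fit, sim$group, "A",
                                             "A")$displacement),
               matrix(0, 14, 2), tolerance = 1e-12)
  # displacement magnitude concentrated on the perturbed landmarks
  mag <- sqrt(rowSums(ab$displacement^2))
  expect_gt(min(mag[1:3]), max(mag[8:14]))
  expect_error(group_shape_difference(fit, sim$group, "A", "nope"),
               "empty group")
})

test_that("centroid size report summarizes groups and detects size shifts", {
  # hand-checkable medians on a 5-specimen toy set
  coords <- array(NA_real_, c(5, 14, 2))
  for (i in 1:5) coords[i, , ] <- i * ref_shape()
  grp <- c("a", "a", "a", "b", "b")
  rep1 <- centroid_size_report(coords, grp)
  expect_equal(unname(rep1$summary["a", "median"]),
               median(rep1$sizes[1:3]))
  expect_equal(unname(rep1$summary["b", "n"]), 2L)

  # identical groups: no significant difference
  set.seed(70)
  simn <- simulate_landmarks(list(A = ref_shape()), 30, noise_sd = 0.05,
                             scale_range = 1.3, seed = 71)
  grp0 <- rep(c("g1", "g2"), 15)
  rep0 <- centroid_size_report(simn$coords, grp0)
  expect_gt(rep0$tests$p_adjusted, 0.01)

  # a 1.2x scaled group at n = 15/group is detected at alpha = 0.001
  detections <- 0L
  for (s in 1:20) {
    simA <- simulate_landmarks(list(A = ref_shape()), 15, noise_sd = 0.03,
                               scale_range = 1.1, seed = 100 + s)
    simB <- simulate_landmarks(list(B = 1.2 * ref_shape()), 15,
                               noise_sd = 0.03, scale_range = 1.1,
                               seed = 200 + s)
    coords <- array(NA_real_, c(30, 14, 2))
    coords[1:15, , ] <- simA$coords
    coords[16:30, , ] <- simB$coords
    rp <- centroid_size_report(coords, rep(c("A", "B"), each = 15))
    if (rp$tests$p_adjusted < 0.001) detections <- detections + 1L
  }
  expect_gte(detections, 19L)   # power > 0.9 at alpha 0.001

  expect_warning(
    centroid_size_report(coords, c("solo", rep(c("A", "B"), c(14, 15)))),
    "excluded")
})
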