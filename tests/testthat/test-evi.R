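make_layers <- function(mats, polarity = "positive") {
  lapply(seq_along(mats), function(i) {
    list(spec = list(code = paste0("X", i), name = paste0("layer", i),
                     polarity = polarity),
         grid = eco_grid(mats[[i]]))
  })
}

test_that("correlation-matrix PCA has the expected algebraic structure", {
  m <- with_seed_local(17, matrix(stats::runif(64), 8, 8))
  layers <- make_layers(list(m, 1 - m))  # perfectly anti-correlated pair
  pca <- fit_pca(build_stack(layers))
  expect_equal(pca$contribution, c(100, 0), tolerance = 1e-9)
  expect_equal(sum(pca$eigenvalues), 2, tolerance = 1e-12)

  sc <- synth_known_evi_scene(24, 24, seed = 2)
  p2 <- fit_pca(sc$stack)
  expect_equal(sum(p2$eigenvalues), 13, tolerance = 1e-9)
  expect_equal(p2$cumulative[13], 100, tolerance = 1e-6)
  # score surfaces are pairwise uncorrelated
  S <- vapply(p2$scores, function(g) as.vector(g$values), numeric(24 * 24))
  cc <- stats::cor(S)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  # loadings orthonormal
  expect_equal(crossprod(p2$loadings), diag(13), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("full-component scores reconstruct the z-scored layers", {
  sc <- synth_known_evi_scene(20, 20, seed = 9)
  pca <- fit_pca(sc$stack)
  X <- vapply(sc$stack, function(l) as.vector(l$grid$values),
              numeric(400))
  Z <- scale(X)
  recon <- vapply(pca$scores, function(g) as.vector(g$values),
                  numeric(400)) %*% t(pca$loadings)
  expect_lt(max(abs(recon - Z)), 1e-8)
})

test_that("EVI matches an independent eigensolver up to the sign rule", {
  sc <- synth_known_evi_scene(16, 16, seed = 10)
  pca <- fit_pca(sc$stack)
  n <- select_components(pca)
  evi <- compute_evi(pca, n)

  # oracle: svd of the centered/scaled data matrix, same sign convention
  X <- vapply(sc$stack, function(l) as.vector(l$grid$values), numeric(256))
  Z <- scale(X)
  sv <- svd(Z)
  lam <- sv$d^2 / (nrow(Z) - 1)
  A <- sv$v
  A[, colSums(A) < 0] <- -A[, colSums(A) < 0]
  alpha <- lam / sum(lam)
  evi_oracle <- (Z %*% A[, 1:n]) %*% alpha[1:n]
  expect_lt(max(abs(as.vector(evi$values) - evi_oracle)), 1e-8)
})

test_that("component selection applies the cumulative-threshold rule", {
  expect_equal(select_components(c(60, 30, 10), 85), 2)
  expect_equal(select_components(c(86, 14), 85), 1)
  expect_equal(select_components(c(50, 20, 20, 10), 100), 4)
  expect_error(select_components(c(50, 50), 0), class = "ecovuln_usage_error")
})

test_that("published 2010 contribution rates retain six components at 85%", {
  tab <- utils::read.csv(system.file("extdata", "shenyang_pca_2010.csv",
                                     package = "ecovuln"))
  expect_equal(select_components(tab$contribution_rate, 85), 6)
  # the stored cumulative column is consistent with the rates
  expect_equal(cumsum(tab$contribution_rate), tab$cumulative_contribution_rate,
               tolerance = 1e-3)
})

test_that("EVI is the contribution-weighted sum of retained scores", {
  sc <- synth_known_evi_scene(16, 16, seed = 12)
  pca <- fit_pca(sc$stack)
  e1 <- compute_evi(pca, 1)
  expect_equal(e1$values,
               pca$contribution[1] / 100 * pca$scores[[1]]$values,
               tolerance = 1e-12)
  # hand case: alpha = (0.6, 0.4), scores (1, -0.5) at a cell -> 0.4
  fake <- structure(list(
    contribution = c(60, 40),
    scores = list(eco_grid(matrix(1, 1, 2)),
                  eco_grid(matrix(-0.5, 1, 2)))), class = "eco_pca")
  expect_equal(as.vector(compute_evi(fake, 2)$values), c(0.4, 0.4))
  expect_error(compute_evi(fake, 3), class = "ecovuln_usage_error")
})

test_that("natural-breaks grading yields ordered labeled classes", {
  sc <- synth_known_evi_scene(24, 24, seed = 3)
  pca <- fit_pca(sc$stack)
  evi <- compute_evi(pca, select_components(pca))
  cls <- classify_natural_breaks(evi, k = 5)
  expect_setequal(unname(cls$legend),
                  c("slight", "light", "medium", "heavy", "extreme"))
  # class label non-decreasing in EVI
  ord <- order(as.vector(evi$values))
  expect_true(all(diff(as.vector(cls$values)[ord]) >= 0))
  iv <- attr(cls, "intervals")
  expect_true(all(diff(as.vector(t(iv))) >= 0))  # contiguous increasing
  expect_error(classify_natural_breaks(eco_grid(matrix(c(1, 1, 2, 2), 2, 2))),
               class = "ecovuln_classification_error")
})

test_that("zonal shares agree with direct counting and sum to 100", {
  classes <- eco_catgrid(matrix(c(1L, 1L, 2L, 5L), 2, 2),
                         legend = c(`1` = "slight", `2` = "light",
                                    `5` = "extreme"))
  zones <- eco_catgrid(matrix(1L, 2, 2), legend = c(`1` = "districtA"))
  tab <- zonal_class_share(classes, zones)
  expect_equal(tab$percent[tab$class == "slight"], 50)
  expect_equal(tab$percent[tab$class == "light"], 25)
  expect_equal(tab$percent[tab$class == "extreme"], 25)

  z2 <- synth_zones(24, 24, 4, seed = 2)
  sc <- synth_known_evi_scene(24, 24, seed = 3)
  cls <- classify_natural_breaks(compute_evi(fit_pca(sc$stack), 3))
  t2 <- zonal_class_share(cls, z2)
  sums <- tapply(t2$percent, t2$zone, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("EVI summaries are plain statistics over unmasked cells", {
  expect_equal(evi_summary(eco_grid(matrix(0.3, 2, 2))),
               c(mean = 0.3, min = 0.3, max = 0.3))
  g <- irregular_grid(10, seed = 2)
  expect_equal(evi_summary(g)[["mean"]], mean(g$values), tolerance = 1e-12)
  expect_error(evi_summary(eco_grid(matrix(NA_real_, 2, 2))),
               class = "ecovuln_empty_domain_error")
})

test_that("EVI recovers a known latent composite", {
  sc <- synth_known_evi_scene(64, 64, seed = 20)
  pca <- fit_pca(sc$stack)
  evi <- compute_evi(pca, select_components(pca))
  r <- stats::cor(as.vector(evi$values), as.vector(sc$composite$values))
  expect_gt(abs(r), 0.9)
})
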