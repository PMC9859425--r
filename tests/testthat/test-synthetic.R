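test_that("gaussian fields are seeded, stationary and tunably smooth", {
  a <- gaussian_field(32, 32, 4, seed = 11)
  b <- gaussian_field(32, 32, 4, seed = 11)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values,
                         gaussian_field(32, 32, 4, seed = 12)$values))

  # white noise: neighboring cells essentially uncorrelated
  w <- gaussian_field(64, 64, 0, seed = 5)$values
  r_lag1 <- stats::cor(as.vector(w[-1, ]), as.vector(w[-64, ]))
  expect_lt(abs(r_lag1), 0.1)

  # smooth field: short-lag correlation dominates long-lag correlation
  s <- gaussian_field(64, 64, 8, seed = 5)$values
  r1 <- stats::cor(as.vector(s[-1, ]), as.vector(s[-64, ]))
  r16 <- stats::cor(as.vector(s[-(1:16), ]), as.vector(s[-(49:64), ]))
  expect_gt(r1, r16)
  expect_gt(r1, 0.5)
})

test_that("gaussian_field validates its domain", {
  expect_error(gaussian_field(1, 10), class = "ecovuln_usage_error")
  expect_error(gaussian_field(10, 10, correlation_length = -1),
               class = "ecovuln_usage_error")
})

test_that("indicator stack has the 13 canonical layers with their polarities", {
  out <- synth_indicator_stack(32, 32, seed = 4)
  expect_length(out$stack, 13)
  codes <- vapply(out$stack, function(l) l$spec$code, character(1))
  expect_identical(codes, paste0("X", 1:13))
  pol <- vapply(out$stack, function(l) l$spec$polarity, character(1))
  expect_identical(pol[5:8], rep("negative", 4))  # temp, precip, NDVI, abundance
  expect_identical(pol[13], "categorical")
  expect_identical(pol[c(1:4, 9:12)], rep("positive", 8))
  expect_silent(assert_aligned(lapply(out$stack, `[[`, "grid")))

  again <- synth_indicator_stack(32, 32, seed = 4)
  for (p in 1:13) {
    expect_identical(again$stack[[p]]$grid$values, out$stack[[p]]$grid$values)
  }
})

test_that("synthetic land use is six clumped categories", {
  lu <- synth_landuse(64, 64, seed = 9)
  expect_length(lu$legend, 6)
  expect_setequal(unname(lu$legend),
                  c("cropland", "woodland", "grassland", "waters",
                    "construction land", "bare land"))
  expect_true(all(as.character(lu$values) %in% names(lu$legend)))

  # clumping: the modal 4-connected patch must be larger than one cell;
  # census patches of the modal class by flood fill
  modal <- as.integer(names(which.max(table(lu$values))))
  mask <- lu$values == modal
  # largest patch size via simple two-pass labelling on the logical mask
  lab <- matrix(0L, 64, 64); nxt <- 0L
  for (r in 1:64) for (cc in 1:64) {
    if (!mask[r, cc]) next
    up <- if (r > 1) lab[r - 1, cc] else 0L
    lf <- if (cc > 1) lab[r, cc - 1] else 0L
    if (up == 0L && lf == 0L) { nxt <- nxt + 1L; lab[r, cc] <- nxt }
    else if (up == 0L) lab[r, cc] <- lf
    else if (lf == 0L || up == lf) lab[r, cc] <- up
    else { lab[r, cc] <- up; lab[lab == lf] <- up }
  }
  expect_gt(max(table(lab[lab > 0])), 1)
})

test_that("class series follow the generating Markov matrix", {
  P <- matrix(c(0.85, 0.15, 0.00,
                0.10, 0.80, 0.10,
                0.00, 0.25, 0.75), 3, 3, byrow = TRUE)
  out <- synth_class_series(128, 128, 3, P, epochs = 2, seed = 21)
  tm <- transition_matrix(out$maps[[1]], out$maps[[2]])
  expect_lt(max(abs(tm$prob - P)), 0.05)
  expect_identical(out$truth$true_transition, P)

  # identity dynamics freeze the map
  frozen <- synth_class_series(32, 32, 3, diag(3), epochs = 3, seed = 2)
  expect_identical(frozen$maps[[1]]$values, frozen$maps[[3]]$values)

  # seeded reproducibility
  again <- synth_class_series(128, 128, 3, P, epochs = 2, seed = 21)
  expect_identical(again$maps[[2]]$values, out$maps[[2]]$values)

  expect_error(synth_class_series(16, 16, 2, matrix(1, 2, 2), epochs = 2),
               class = "ecovuln_usage_error")
})

test_that("an absorbing class's share never decreases", {
  P <- matrix(c(1.0, 0.0, 0.0,
                0.2, 0.8, 0.0,
                0.0, 0.3, 0.7), 3, 3, byrow = TRUE)
  out <- synth_class_series(64, 64, 3, P, epochs = 5, seed = 13)
  share1 <- vapply(out$maps, function(mp) mean(mp$values == 1L), numeric(1))
  expect_true(all(diff(share1) >= 0))
})

test_that("known-EVI scenes expose their construction exactly", {
  sc <- synth_known_evi_scene(32, 32, seed = 6)
  recon <- Reduce(`+`, Map(function(l, w) w * l$grid$values,
                           sc$stack, as.list(sc$truth$latent_weights)))
  expect_lt(max(abs(recon - sc$composite$values)), 1e-10)

  flat <- synth_known_evi_scene(32, 32, seed = 6, weights = rep(0, 13))
  expect_equal(stats::sd(flat$composite$values), 0)
})

test_that("district partitions label every cell with a named zone", {
  z <- synth_zones(32, 32, n_zones = 5, seed = 3)
  expect_length(z$legend, 5)
  expect_false(anyNA(z$values))
  expect_setequal(sort(unique(as.vector(z$values))), 1:5)
})
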