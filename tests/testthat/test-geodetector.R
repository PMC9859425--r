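strata_from <- function(codes, nr, nc) {
  eco_catgrid(matrix(as.integer(codes), nr, nc))
}

test_that("q reproduces hand-computed and degenerate cases", {
  y <- eco_grid(matrix(c(1, 2, 3, 4), 1, 4))
  st <- strata_from(c(1, 1, 2, 2), 1, 4)
  qr <- factor_q(y, st, p_method = "none")
  # SST = 5, SSW = 0.5 + 0.5 (population variances) -> q = 0.8
  expect_equal(qr$q, 0.8, tolerance = 1e-12)
  expect_equal(qr$k, 2)

  # piecewise-constant response: q = 1
  yc <- eco_grid(matrix(c(7, 7, 3, 3), 1, 4))
  expect_equal(factor_q(yc, st, p_method = "none")$q, 1, tolerance = 1e-12)
  # a single stratum explains nothing
  one <- strata_from(rep(1, 4), 1, 4)
  expect_equal(factor_q(y, one, p_method = "none")$q, 0, tolerance = 1e-12)

  expect_error(factor_q(eco_grid(matrix(5, 2, 2)),
                        strata_from(c(1, 1, 2, 2), 2, 2), p_method = "none"),
               class = "ecovuln_zero_variance_error")
})

test_that("q agrees with an independent group-by oracle", {
  for (seed in c(7, 8, 9)) {
    n <- 10
    y <- irregular_grid(n, seed = seed)
    st <- strata_from(with_seed_local(seed + 50, sample(1:4, n * n, TRUE)),
                      n, n)
    got <- factor_q(y, st, p_method = "none")$q
    expect_equal(got, brute_q(as.vector(y$values), as.vector(st$values)),
                 tolerance = 1e-12)
  }
})

test_that("q is invariant under affine transformation of the response", {
  y <- irregular_grid(8, seed = 12)
  st <- strata_from(with_seed_local(60, sample(1:3, 64, TRUE)), 8, 8)
  q0 <- factor_q(y, st, p_method = "none")$q
  ya <- eco_grid(-4 * y$values + 2)
  expect_equal(factor_q(ya, st, p_method = "none")$q, q0, tolerance = 1e-12)
})

test_that("discretization produces valid strata by either method", {
  g <- irregular_grid(10, seed = 13)
  qs <- discretize_factor(g, k = 4, method = "quantile")
  sizes <- table(qs$values)
  expect_true(all(abs(sizes - 25) <= 1))
  js <- discretize_factor(g, k = 5, method = "jenks")
  expect_setequal(sort(unique(as.vector(js$values))), 1:5)
  # jenks strata on small data match the exhaustive oracle
  small <- eco_grid(matrix(c(1, 2, 3, 10, 11, 12, 30, 31, 32), 3, 3))
  ds <- discretize_factor(small, k = 3, method = "jenks")
  want <- brute_jenks(as.vector(small$values), 3)
  cl_want <- jenks_assign(as.vector(small$values), want$breaks)
  expect_identical(as.vector(ds$values), as.integer(cl_want))
  # categorical factors pass through untouched
  lu <- synth_landuse(16, 16, seed = 1)
  expect_identical(discretize_factor(lu), lu)
  expect_error(discretize_factor(eco_grid(matrix(c(1, 1, 2, 2), 2, 2)), k = 3),
               class = "ecovuln_classification_error")
})

test_that("interaction q refines both partitions and is categorized", {
  y <- irregular_grid(10, seed = 21)
  a <- strata_from(with_seed_local(61, sample(1:3, 100, TRUE)), 10, 10)
  b <- strata_from(with_seed_local(62, sample(1:4, 100, TRUE)), 10, 10)
  ir <- suppressWarnings(interaction_q(y, a, b))
  expect_gte(ir$q12, max(ir$q1, ir$q2) - 1e-12)
  expect_true(ir$category %in% c("nonlinear-weaken",
                                 "single-factor-nonlinear-weaken",
                                 "independent", "bifactor-enhance",
                                 "nonlinear-enhance"))
  # identical stratifications: overlay changes nothing
  ir2 <- interaction_q(y, a, a)
  expect_equal(ir2$q12, ir2$q1, tolerance = 1e-12)
  # overlay isolating every value is fully explanatory
  fine <- strata_from(1:16, 4, 4)
  y4 <- irregular_grid(4, seed = 22)
  ir3 <- suppressWarnings(interaction_q(y4, fine, fine))
  expect_equal(ir3$q12, 1, tolerance = 1e-12)
})

test_that("interaction categories implement the five-way rule", {
  expect_equal(interaction_category(0.3, 0.2, 0.6), "nonlinear-enhance")
  expect_equal(interaction_category(0.3, 0.2, 0.5), "independent")
  expect_equal(interaction_category(0.3, 0.2, 0.45), "bifactor-enhance")
  expect_equal(interaction_category(0.3, 0.2, 0.25),
               "single-factor-nonlinear-weaken")
  expect_equal(interaction_category(0.3, 0.2, 0.1), "nonlinear-weaken")
  expect_error(interaction_category(1.2, 0.2, 0.5),
               class = "ecovuln_domain_error")
})

test_that("significance machinery behaves across both methods", {
  y <- irregular_grid(8, seed = 25)
  st <- strata_from(with_seed_local(63, sample(1:4, 64, TRUE)), 8, 8)
  qr <- factor_q(y, st, p_method = "permutation", permutations = 199,
                 seed = 5)
  expect_gte(qr$p_value, 1 / 200)
  expect_lte(qr$p_value, 1)

  # noncentral-F p falls as the structure strengthens
  base <- matrix(rep(c(0, 1, 2, 3), each = 16), 8, 8)
  noise <- with_seed_local(64, matrix(stats::rnorm(64), 8, 8))
  stf <- strata_from(rep(c(1, 2, 3, 4), each = 16), 8, 8)
  p_weak <- factor_q(eco_grid(0.3 * base + noise), stf)$p_value
  p_strong <- factor_q(eco_grid(3 * base + noise), stf)$p_value
  expect_lte(p_strong, p_weak)

  # q rises with signal-to-noise
  q_weak <- factor_q(eco_grid(0.3 * base + noise), stf, p_method = "none")$q
  q_strong <- factor_q(eco_grid(3 * base + noise), stf, p_method = "none")$q
  expect_gt(q_strong, q_weak)
})
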