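two_maps <- function(codes_t, codes_t1, nr, nc, cell_size = 1000) {
  legend <- stats::setNames(paste0("c", sort(unique(c(codes_t, codes_t1)))),
                            sort(unique(c(codes_t, codes_t1))))
  list(t = eco_catgrid(matrix(as.integer(codes_t), nr, nc), legend = legend,
                       cell_size = cell_size),
       t1 = eco_catgrid(matrix(as.integer(codes_t1), nr, nc), legend = legend,
                        cell_size = cell_size))
}

test_that("transition matrices tally cell moves into areas and probabilities", {
  mp <- two_maps(c(1, 2, 1, 2), c(1, 2, 1, 2), 2, 2)
  tm <- transition_matrix(mp$t, mp$t1)
  expect_true(all(tm$area[row(tm$area) != col(tm$area)] == 0))
  expect_equal(unname(tm$prob), diag(2), ignore_attr = TRUE)

  toy <- two_maps(c(1, 2), c(2, 2), 1, 2, cell_size = 1000)
  tm2 <- transition_matrix(toy$t, toy$t1, cell_area = 1)
  expect_equal(unname(tm2$area), matrix(c(0, 0, 1, 1), 2, 2),
               ignore_attr = TRUE)
  expect_equal(unname(tm2$prob), matrix(c(0, 0, 1, 1), 2, 2),
               ignore_attr = TRUE)
})

test_that("markov projection conserves total area", {
  P <- matrix(c(0.7, 0.3, 0.1, 0.9), 2, 2, byrow = TRUE)
  areas <- c(100, 50)
  out <- markov_project(areas, P)
  expect_equal(sum(out), sum(areas), tolerance = 1e-9)
  expect_equal(markov_project(areas, diag(2)), areas, ignore_attr = TRUE)
  expect_error(markov_project(areas, matrix(c(0.5, 0.2, 0.5, 0.2), 2)),
               class = "ecovuln_usage_error")
})

test_that("published transfer matrix reproduces its own projections", {
  tm <- read_area_matrix(table8_path())
  areas_2020 <- rowSums(tm$area)
  proj_2025 <- markov_project(areas_2020, tm$prob)
  expect_equal(unname(proj_2025), unname(colSums(tm$area)), tolerance = 1e-9)
})

test_that("suitability surfaces reflect neighborhood composition", {
  m <- matrix(1L, 9, 9); m[, 6:9] <- 2L
  cm <- eco_catgrid(m)
  suit <- build_suitability(cm, window = 3)
  expect_equal(suit$grids[["1"]]$values[5, 2], 1)   # deep inside class 1
  expect_equal(suit$grids[["2"]]$values[5, 2], 0)   # class 2 absent there
  tot <- Reduce(`+`, lapply(suit$grids, `[[`, "values"))
  expect_true(all(abs(tot - 1) < 1e-12))            # frequencies partition 1
  # boundary cells see a mix
  expect_true(suit$grids[["2"]]$values[5, 5] > 0 &&
                suit$grids[["2"]]$values[5, 5] < 1)
  expect_error(build_suitability(cm, window = 4),
               class = "ecovuln_usage_error")
})

test_that("CA simulation honors demand, determinism and identity dynamics", {
  P <- matrix(c(0.85, 0.15, 0.00,
                0.05, 0.85, 0.10,
                0.00, 0.20, 0.80), 3, 3, byrow = TRUE)
  ser <- synth_class_series(128, 128, 3, P, epochs = 2, seed = 31)
  tm <- transition_matrix(ser$maps[[1]], ser$maps[[2]])
  sim <- ca_simulate(ser$maps[[1]], tm$prob, iterations = 5, seed = 8)
  proj <- markov_project(rowSums(tm$area), tm$prob)
  achieved_area <- sim$achieved * tm$cell_area
  expect_true(all(abs(achieved_area - proj) / pmax(proj, 1e-9) < 0.01))
  expect_equal(sum(achieved_area), sum(tm$area), tolerance = 1e-9)

  sim_again <- ca_simulate(ser$maps[[1]], tm$prob, iterations = 5, seed = 8)
  expect_identical(sim_again$map$values, sim$map$values)
  sim_one <- ca_simulate(ser$maps[[1]], tm$prob, iterations = 1, seed = 8)
  achieved_one <- sim_one$achieved * tm$cell_area
  expect_true(all(abs(achieved_one - proj) / pmax(proj, 1e-9) < 0.01))

  ident <- ca_simulate(ser$maps[[1]], diag(3), iterations = 5, seed = 99)
  expect_identical(ident$map$values, ser$maps[[1]]$values)
})

test_that("kappa implements chance-corrected agreement", {
  mp <- two_maps(rep(1:2, 8), rep(1:2, 8), 4, 4)
  expect_equal(kappa_agreement(mp$t, mp$t1)$kappa, 1)

  # confusion [[2,1],[1,2]] over 6 cells: p0 = 4/6, pc = 1/2 -> kappa = 1/3
  conf <- two_maps(c(1, 1, 1, 2, 2, 2), c(1, 1, 2, 1, 2, 2), 2, 3)
  k <- kappa_agreement(conf$t, conf$t1)
  expect_equal(unname(k$confusion), matrix(c(2, 1, 1, 2), 2),
               ignore_attr = TRUE)
  expect_equal(k$kappa, 1 / 3, tolerance = 1e-12)

  # agreement no better than chance scores zero
  zero <- two_maps(rep(1, 8), rep(1:2, 4), 2, 4)
  expect_equal(kappa_agreement(zero$t, zero$t1)$kappa, 0, tolerance = 1e-12)

  # symmetry
  expect_equal(kappa_agreement(conf$t1, conf$t)$kappa, k$kappa)
})

test_that("area-change tables mirror the published 2020/2025 comparison", {
  tm <- read_area_matrix(table8_path())
  tab <- area_change_table(tm)
  expect_equal(tab$change[tab$class == "light"], -193.175, tolerance = 1e-9)
  expect_equal(round(tab$pct_t1[tab$class == "light"], 2), 43.58)
  expect_equal(round(tab$area_t1[tab$class == "heavy"], 3), 697.002)
  expect_equal(round(tab$area_t1[tab$class == "extreme"], 3), 370.238)
  expect_equal(sum(tab$pct_t), 100, tolerance = 1e-9)
  expect_equal(sum(tab$pct_t1), 100, tolerance = 1e-9)

  same <- area_change_table(c(a = 10, b = 20), c(a = 10, b = 20))
  expect_true(all(same$change == 0))
})

test_that("transfer reports decompose gains and losses", {
  diag_tm <- transition_matrix(
    eco_catgrid(matrix(c(1L, 2L, 1L, 2L), 2, 2)),
    eco_catgrid(matrix(c(1L, 2L, 1L, 2L), 2, 2)), cell_area = 1)
  tr0 <- transfer_report(diag_tm)
  expect_true(all(tr0$decrease == 0) && all(tr0$increase == 0))

  tm <- read_area_matrix(table8_path())
  tr <- transfer_report(tm)
  expect_equal(unname(tr$decrease["light"]), 1098.928, tolerance = 1e-9)
  expect_equal(unname(tr$increase["medium"]), 274.106, tolerance = 1e-9)
  expect_equal(round(unname(tr$outflow_share["slight", "light"]), 2), 88.27)
})
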