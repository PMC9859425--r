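#' Binary contiguity weights for a masked grid
#'
#' Builds the binary adjacency structure over the unmasked cells of a grid:
#' rook neighbors share an edge, queen neighbors share an edge or a corner.
#' Masked cells are excluded from all neighbor lists.
#'
#' @param grid an `eco_grid` with at least 2 unmasked cells.
#' @param scheme `"rook"` (default) or `"queen"`.
#' @return An object of class `eco_weights`: `cells` (linear indices of the
#'   unmasked cells), directed edge lists `from`/`to` (positions within
#'   `cells`), `n`, `S0` (total number of directed links, i.e. the sum of
#'   the binary weight matrix) and `scheme`.
#' @export
build_weights <- function(grid, scheme = c("rook", "queen")) {
  scheme <- match.arg(scheme)
  mask <- grid_mask(grid)
  nr <- nrow(mask); nc <- ncol(mask)
  cells <- which(!mask)
  n <- length(cells)
  if (n < 2) {
    stop_ecovuln("need at least 2 unmasked cells", "ecovuln_degenerate_error")
  }
  rank <- integer(nr * nc)
  rank[cells] <- seq_len(n)
  offsets <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (scheme == "queen") {
    offsets <- c(offsets, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  r0 <- ((cells - 1) %% nr) + 1
  c0 <- ((cells - 1) %/% nr) + 1
  from <- integer(0); to <- integer(0)
  for (d in offsets) {
    r1 <- r0 + d[1]; c1 <- c0 + d[2]
    ok <- r1 >= 1 & r1 <= nr & c1 >= 1 & c1 <= nc
    tgt <- (c1[ok] - 1) * nr + r1[ok]
    keep <- !mask[tgt]
    from <- c(from, rank[cells[ok][keep]])
    to <- c(to, rank[tgt[keep]])
  }
  structure(list(cells = cells, from = from, to = to, n = n,
                 S0 = length(from), scheme = scheme, dim = c(nr, nc)),
            class = "eco_weights")
}

#' @export
print.eco_weights <- function(x, ...) {
  cat(sprintf("<eco_weights: %s contiguity, %d cells, S0 = %d>\n",
              x$scheme, x$n, x$S0))
  invisible(x)
}

neighbor_counts <- function(W) {
  d <- integer(W$n)
  tb <- table(W$from)
  d[as.integer(names(tb))] <- as.integer(tb)
  d
}

#' Global Moran's I with permutation inference
#'
#' The global spatial autocorrelation statistic with binary contiguity
#' weights,
#' `I = n / S0 * sum_ij W_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#' Values above 0 indicate spatial clustering of like values, values below 0
#' spatial alternation; the expectation under the randomization null is
#' `-1/(n-1)`. Significance is assessed by randomly relabeling the values
#' over the cells; the two-sided pseudo p-value is
#' `(#{|I*| >= |I|} + 1) / (permutations + 1)`.
#'
#' @param values an `eco_grid`, non-constant on unmasked cells.
#' @param W an `eco_weights` built on the same grid.
#' @param permutations number of random relabelings.
#' @param seed integer seed for the permutations.
#' @return An object of class `eco_moran`: `I`, `expected`, `p_value`,
#'   `z_score`, `n`, `S0`, `permutations`.
#' @export
global_morans_i <- function(values, W, permutations = 999, seed = 1) {
  x <- values$values[W$cells]
  if (anyNA(x)) {
    stop_ecovuln("weights and values disagree on the mask",
                 "ecovuln_usage_error")
  }
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom == 0) {
    stop_ecovuln("values are constant on unmasked cells",
                 "ecovuln_zero_variance_error")
  }
  I_obs <- (W$n / W$S0) * sum(z[W$from] * z[W$to]) / denom
  I_star <- if (permutations > 0) {
    with_seed(seed, vapply(seq_len(permutations), function(b) {
      zp <- z[sample.int(W$n)]
      (W$n / W$S0) * sum(zp[W$from] * zp[W$to]) / sum(zp^2)
    }, numeric(1)))
  } else numeric(0)
  p <- if (permutations > 0) {
    (sum(abs(I_star) >= abs(I_obs)) + 1) / (permutations + 1)
  } else NA_real_
  zsc <- if (permutations > 1) {
    (I_obs - mean(I_star)) / stats::sd(I_star)
  } else NA_real_
  structure(list(I = I_obs, expected = -1 / (W$n - 1), p_value = p,
                 z_score = zsc, n = W$n, S0 = W$S0,
                 permutations = permutations),
            class = "eco_moran")
}

#' @export
print.eco_moran <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (expected %.4f under the null)\n",
              x$I, x$expected))
  cat(sprintf("  n = %d, S0 = %d, permutation p = %.4g (%d permutations)\n",
              x$n, x$S0, x$p_value, x$permutations))
  invisible(x)
}

#' Local Moran's I (LISA) with conditional permutation
#'
#' Per-cell local autocorrelation,
#' `I_i = (x_i - xbar) / s^2 * sum_j w_ij (x_j - xbar)` with
#' `s^2 = sum_i (x_i - xbar)^2 / n` and binary weights, so that
#' `sum_i I_i = S0 * I` (the global statistic). Per-cell significance uses
#' conditional permutation: cell i's value is held fixed while its
#' neighbors' values are drawn without replacement from the remaining
#' cells. With `row_standardize = TRUE` the neighbor sum is replaced by the
#' neighbor mean (GeoDa-style weights); the additivity identity then no
#' longer holds.
#'
#' @inheritParams global_morans_i
#' @param row_standardize divide each cell's neighbor sum by its degree.
#' @return An object of class `eco_lisa`: `local_i` and `p_value` grids
#'   (`eco_grid`), plus `n`, `S0`, `permutations`, `row_standardize` and the
#'   weights' `cells`.
#' @export
local_morans_i <- function(values, W, permutations = 999, seed = 1,
                           row_standardize = FALSE) {
  x <- values$values[W$cells]
  if (anyNA(x)) {
    stop_ecovuln("weights and values disagree on the mask",
                 "ecovuln_usage_error")
  }
  z <- x - mean(x)
  s2 <- sum(z^2) / W$n
  if (s2 == 0) {
    stop_ecovuln("values are constant on unmasked cells",
                 "ecovuln_zero_variance_error")
  }
  deg <- neighbor_counts(W)
  lag_sum <- function(v) {
    out <- numeric(W$n)
    tmp <- rowsum(v, W$from)
    out[as.integer(rownames(tmp))] <- tmp
    out
  }
  scl <- if (row_standardize) ifelse(deg > 0, deg, 1) else rep(1, W$n)
  I_loc <- z * (lag_sum(z[W$to]) / scl) / s2
  counts <- integer(W$n)
  if (permutations > 0) {
    with_seed(seed, for (b in seq_len(permutations)) {
      perm <- sample.int(W$n)
      v_to <- perm[W$to]
      hit <- v_to == W$from        # a neighbor drew cell i's own value:
      v_to[hit] <- perm[W$from[hit]]  # swap in the unused value from slot i
      I_b <- z * (lag_sum(z[v_to]) / scl) / s2
      counts <- counts + (abs(I_b) >= abs(I_loc))
    })
  }
  p <- (counts + 1) / (permutations + 1)
  to_grid <- function(v) {
    m <- matrix(NA_real_, W$dim[1], W$dim[2])
    m[W$cells] <- v
    eco_grid(m, cell_size = values$cell_size, origin = values$origin,
             crs_label = values$crs_label)
  }
  structure(list(local_i = to_grid(I_loc), p_value = to_grid(p),
                 n = W$n, S0 = W$S0, permutations = permutations,
                 row_standardize = row_standardize, cells = W$cells),
            class = "eco_lisa")
}

#' @export
print.eco_lisa <- function(x, ...) {
  li <- x$local_i$values[x$cells]
  cat(sprintf("Local Moran's I over %d cells (sum = %.4f)\n", x$n, sum(li)))
  cat(sprintf("  %d cells with permutation p <= 0.05 (%d permutations)\n",
              sum(x$p_value$values[x$cells] <= 0.05), x$permutations))
  invisible(x)
}

#' LISA cluster categories
#'
#' Labels each significant cell (permutation p <= `alpha`) by the sign
#' pattern of its own deviation and its neighbors' mean deviation from the
#' global mean: high-high (HH), high-low (HL), low-high (LH), low-low (LL);
#' all other cells are non-significant (NN).
#'
#' @param lisa an `eco_lisa` computed on the same grid and weights.
#' @param values the `eco_grid` the LISA was computed on.
#' @param W the `eco_weights` used.
#' @param alpha significance level for the NN gate.
#' @return An `eco_catgrid` with legend `0 = NN, 1 = HH, 2 = HL, 3 = LH,
#'   4 = LL`.
#' @export
lisa_classify <- function(lisa, values, W, alpha = 0.05) {
  if (!identical(lisa$cells, W$cells) || lisa$n != W$n) {
    stop_ecovuln("lisa and weights were built on different grids",
                 "ecovuln_usage_error")
  }
  x <- values$values[W$cells]
  if (anyNA(x)) {
    stop_ecovuln("weights and values disagree on the mask",
                 "ecovuln_usage_error")
  }
  z <- x - mean(x)
  deg <- neighbor_counts(W)
  nb_sum <- numeric(W$n)
  tmp <- rowsum(z[W$to], W$from)
  nb_sum[as.integer(rownames(tmp))] <- tmp
  nb_mean_dev <- ifelse(deg > 0, nb_sum / pmax(deg, 1), 0)
  p <- lisa$p_value$values[W$cells]
  cat_code <- integer(W$n)  # 0 = NN
  sig <- p <= alpha & deg > 0
  cat_code[sig & z > 0 & nb_mean_dev > 0] <- 1L
  cat_code[sig & z > 0 & nb_mean_dev <= 0] <- 2L
  cat_code[sig & z <= 0 & nb_mean_dev > 0] <- 3L
  cat_code[sig & z <= 0 & nb_mean_dev <= 0] <- 4L
  m <- matrix(NA_integer_, W$dim[1], W$dim[2])
  m[W$cells] <- cat_code
  eco_catgrid(m, legend = c(`0` = "NN", `1` = "HH", `2` = "HL", `3` = "LH",
                            `4` = "LL"),
              cell_size = values$cell_size, origin = values$origin,
              crs_label = values$crs_label)
}
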