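#' Class-transition matrix between two epochs
#'
#' Tallies cell transitions between two aligned class maps into an
#' inter-class area matrix `A_ij` (area moving from class i to class j, in
#' km^2) and the row-stochastic probability matrix `P_ij = A_ij / sum_j
#' A_ij`. The diagonal holds persistence. Classes absent at the first epoch
#' get an identity row in P.
#'
#' @param map_t,map_t1 aligned `eco_catgrid`s over the same class universe.
#' @param cell_area area of one cell in km^2; defaults to the cell size
#'   squared converted from metres.
#' @return An object of class `eco_transition`: `area` (A, km^2), `prob`
#'   (P), `labels`, `cell_area`.
#' @export
transition_matrix <- function(map_t, map_t1,
                              cell_area = (map_t$cell_size / 1000)^2) {
  assert_aligned(list(t = map_t, t1 = map_t1))
  codes <- sort(unique(c(as.integer(names(map_t$legend)),
                         as.integer(names(map_t1$legend)))))
  labels <- map_t$legend[as.character(codes)]
  labels[is.na(labels)] <- map_t1$legend[as.character(codes)][is.na(labels)]
  ok <- !is.na(map_t$values) & !is.na(map_t1$values)
  f_t <- factor(map_t$values[ok], levels = codes)
  f_t1 <- factor(map_t1$values[ok], levels = codes)
  A <- unclass(table(f_t, f_t1)) * cell_area
  dimnames(A) <- list(from = labels, to = labels)
  new_transition(A, labels, cell_area)
}

new_transition <- function(A, labels, cell_area) {
  rs <- rowSums(A)
  P <- A / ifelse(rs > 0, rs, 1)
  P[rs == 0, ] <- 0
  diag(P)[rs == 0] <- 1  # absent classes persist by convention
  structure(list(area = A, prob = P, labels = labels,
                 cell_area = cell_area),
            class = "eco_transition")
}

#' Read a published inter-class area matrix from a text file
#'
#' Input format for entering a printed transfer table directly: a CSV whose
#' first column holds the class labels and whose remaining columns hold the
#' transferred areas (km^2) to each class, in the same order; empty cells or
#' dashes count as zero.
#'
#' @param path CSV file path.
#' @return An `eco_transition` built from the matrix.
#' @export
read_area_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  M[M %in% c("", "-", "—")] <- "0"
  A <- matrix(as.numeric(M), nrow(M), ncol(M))
  if (nrow(A) != ncol(A) || any(is.na(A)) || any(A < 0)) {
    stop_ecovuln("area matrix must be square and non-negative",
                 "ecovuln_format_error")
  }
  dimnames(A) <- list(from = labels, to = labels)
  new_transition(A, labels, cell_area = NA_real_)
}

#' @export
print.eco_transition <- function(x, ...) {
  cat("<eco_transition> area matrix (km^2):\n")
  print(round(x$area, 3))
  cat("row-stochastic P:\n")
  print(round(x$prob, 4))
  invisible(x)
}

#' Markov projection of class areas
#'
#' Projects per-class areas one step forward through a row-stochastic
#' transition matrix: `S_{t+1} = t(P) %*% S_t`. Total area is conserved.
#'
#' @param areas_t named non-negative per-class areas at time t.
#' @param P row-stochastic probability matrix (e.g. `tm$prob`).
#' @return Per-class areas at t+1.
#' @export
markov_project <- function(areas_t, P) {
  P <- as.matrix(P)
  if (any(P < -1e-12) || any(abs(rowSums(P) - 1) > 1e-6)) {
    stop_ecovuln("P must be row-stochastic", "ecovuln_usage_error")
  }
  if (any(areas_t < 0)) {
    stop_ecovuln("areas must be non-negative", "ecovuln_usage_error")
  }
  out <- as.numeric(t(P) %*% areas_t)
  names(out) <- colnames(P) %||% names(areas_t)
  out
}

#' Per-class suitability surfaces
#'
#' Builds one suitability grid per class. The base score is the local
#' neighborhood frequency of the class within a `window` x `window` moving
#' window (IDRISI-style contiguity filtering: cells deep inside a uniform
#' patch of class c score 1 for c, and with the frequency score alone the
#' per-class surfaces sum to 1 at every cell). When an EVI surface is
#' supplied, the frequency is blended (`blend` frequency, `1 - blend` EVI
#' term) with the closeness of the cell's EVI to the class's EVI-interval
#' midpoint, each closeness normalized to \[0, 1\] per class.
#'
#' @param class_map an `eco_catgrid` (five vulnerability levels or any
#'   class set).
#' @param evi optional aligned `eco_grid`; enables the EVI-proximity blend.
#'   Class interval midpoints are taken from the map's `intervals`
#'   attribute when present, else from per-class EVI means.
#' @param window odd window size >= 3.
#' @param blend weight of the neighborhood-frequency term when `evi` is
#'   supplied.
#' @return An object of class `eco_suitability`: list of `eco_grid`s named
#'   by class code, plus the codes.
#' @export
build_suitability <- function(class_map, evi = NULL, window = 5,
                              blend = 0.5) {
  if (window < 3 || window %% 2 == 0) {
    stop_ecovuln("'window' must be an odd integer >= 3", "ecovuln_usage_error")
  }
  codes <- sort(as.integer(names(class_map$legend)))
  h <- (window - 1) / 2
  valid <- !is.na(class_map$values)
  n_valid <- box_sum(matrix(as.numeric(valid), nrow(valid)), h)
  mids <- NULL
  if (!is.null(evi)) {
    iv <- attr(class_map, "intervals")
    mids <- if (!is.null(iv)) {
      stats::setNames(rowMeans(iv), codes)
    } else {
      vapply(codes, function(cd) {
        mean(evi$values[class_map$values == cd], na.rm = TRUE)
      }, numeric(1), USE.NAMES = FALSE) |>
        stats::setNames(codes)
    }
  }
  grids <- lapply(codes, function(cd) {
    ind <- matrix(as.numeric(class_map$values == cd & valid), nrow(valid))
    freq <- box_sum(ind, h) / pmax(n_valid, 1)
    s <- freq
    if (!is.null(evi)) {
      dist <- abs(evi$values - mids[as.character(cd)])
      mx <- max(dist, na.rm = TRUE)
      close <- if (mx > 0) 1 - dist / mx else matrix(1, nrow(dist), ncol(dist))
      s <- blend * freq + (1 - blend) * close
    }
    s[!valid] <- NA
    eco_grid(s, cell_size = class_map$cell_size, origin = class_map$origin,
             crs_label = class_map$crs_label)
  })
  names(grids) <- as.character(codes)
  structure(list(grids = grids, codes = codes, window = window,
                 blend = if (is.null(evi)) 1 else blend),
            class = "eco_suitability")
}

# moving-window sum with clipped edges, via integral images
box_sum <- function(M, h) {
  nr <- nrow(M); nc <- ncol(M)
  cs <- rbind(0, apply(M, 2, cumsum))
  r1 <- pmax(seq_len(nr) - h, 1)
  r2 <- pmin(seq_len(nr) + h, nr)
  R <- cs[r2 + 1, , drop = FALSE] - cs[r1, , drop = FALSE]
  cs2 <- cbind(0, t(apply(R, 1, cumsum)))
  c1 <- pmax(seq_len(nc) - h, 1)
  c2 <- pmin(seq_len(nc) + h, nc)
  cs2[, c2 + 1, drop = FALSE] - cs2[, c1, drop = FALSE]
}

#' CA-Markov simulation of a class map
#'
#' Couples Markov transition demand with cellular-automaton allocation: the
#' per-class transition demand implied by `P` applied to the starting map is
#' split evenly across `iterations` cycles, and in each cycle the demanded
#' i-to-j conversions are assigned to the class-i cells with the highest
#' suitability for class j. Suitability is recomputed every cycle from the
#' current map with the `window` x `window` contiguity filter (blended with
#' EVI proximity when `evi` is given), which keeps growth spatially
#' contiguous. Ties are broken by a seeded random jitter, so a given seed
#' always yields the same map; cells converted once are frozen for the rest
#' of the run (a cell takes at most one Markov step per simulated interval).
#'
#' @param map_t starting `eco_catgrid`.
#' @param P row-stochastic transition matrix over the map's class codes
#'   (rows/columns in ascending code order).
#' @param evi optional aligned `eco_grid` blended into suitability.
#' @param iterations number of CA cycles (>= 1).
#' @param window contiguity filter size (odd, >= 3).
#' @param seed integer seed for tie-breaking.
#' @param suitability optional `eco_suitability` used for the first cycle
#'   (the base-period suitability image set); later cycles recompute from
#'   the evolving map.
#' @return An object of class `eco_casim`: `map` (the simulated
#'   `eco_catgrid`), `iterations`, `window`, `seed`, `achieved` and
#'   `demanded` per-class cell counts.
#' @export
ca_simulate <- function(map_t, P, evi = NULL, iterations = 5, window = 5,
                        seed = 1, suitability = NULL) {
  if (iterations < 1) {
    stop_ecovuln("iterations must be >= 1", "ecovuln_usage_error")
  }
  P <- as.matrix(P)
  codes <- sort(as.integer(names(map_t$legend)))
  K <- length(codes)
  if (!all(dim(P) == K)) {
    stop_ecovuln("P dimensions must match the class universe",
                 "ecovuln_usage_error")
  }
  if (any(P < -1e-12) || any(abs(rowSums(P) - 1) > 1e-6)) {
    stop_ecovuln("P must be row-stochastic", "ecovuln_usage_error")
  }
  cur <- map_t$values
  valid_idx <- which(!is.na(cur))
  n0 <- vapply(codes, function(cd) sum(cur[valid_idx] == cd), integer(1))
  # integer demand per (from, to): largest-remainder rounding per row so the
  # row total exactly matches the class's starting cell count
  demand <- matrix(0L, K, K)
  for (i in seq_len(K)) demand[i, ] <- round_largest_remainder(n0[i] * P[i, ])
  done <- matrix(0L, K, K)
  frozen <- matrix(FALSE, nrow(cur), ncol(cur))
  jitter <- with_seed(seed, matrix(stats::runif(length(cur)), nrow(cur)))
  clipped <- FALSE
  for (it in seq_len(iterations)) {
    suit <- if (it == 1 && !is.null(suitability)) {
      suitability
    } else {
      build_suitability(
        eco_catgrid(cur, legend = map_t$legend, cell_size = map_t$cell_size,
                    origin = map_t$origin, crs_label = map_t$crs_label),
        evi = evi, window = window)
    }
    target <- matrix(pmin(round(demand * it / iterations), demand), K, K)
    pending <- target - done
    taken <- frozen
    ord <- order(pending, decreasing = TRUE)  # largest demands pick first
    for (o in ord) {
      need <- pending[o]
      if (need <= 0) next
      i <- ((o - 1) %% K) + 1
      j <- ((o - 1) %/% K) + 1
      if (i == j) { done[i, j] <- done[i, j] + need; next }
      cand <- which(cur == codes[i] & !taken & !is.na(cur))
      if (length(cand) < need) {
        clipped <- TRUE
        need <- length(cand)
      }
      if (!need) next
      sc <- suit$grids[[as.character(codes[j])]]$values[cand]
      pick <- cand[order(sc, jitter[cand], decreasing = TRUE)[seq_len(need)]]
      taken[pick] <- TRUE
      done[i, j] <- done[i, j] + length(pick)
      cur[pick] <- codes[j]
    }
    frozen <- taken | frozen
  }
  if (clipped) {
    warning("demanded transitions exceeded available source cells; clipped")
  }
  achieved <- vapply(codes, function(cd) sum(cur[valid_idx] == cd),
                     integer(1))
  out_map <- eco_catgrid(cur, legend = map_t$legend,
                         cell_size = map_t$cell_size, origin = map_t$origin,
                         crs_label = map_t$crs_label)
  structure(list(map = out_map, iterations = iterations, window = window,
                 seed = seed,
                 achieved = stats::setNames(achieved, codes),
                 demanded = stats::setNames(as.integer(colSums(demand)),
                                            codes)),
            class = "eco_casim")
}

round_largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- x - fl
  short <- round(sum(x)) - sum(fl)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    fl[bump] <- fl[bump] + 1
  }
  as.integer(fl)
}

#' @export
print.eco_casim <- function(x, ...) {
  cat(sprintf("<eco_casim: %d iteration(s), %dx%d filter, seed %d>\n",
              x$iterations, x$window, x$window, x$seed))
  print(rbind(demanded = x$demanded, achieved = x$achieved))
  invisible(x)
}

#' Kappa agreement between two class maps
#'
#' Chance-corrected agreement: `kappa = (p0 - pc) / (pp - pc)` with observed
#' agreement `p0`, chance agreement `pc` (sum over classes of the product of
#' row and column shares of the confusion matrix) and ideal agreement
#' `pp = 1`.
#'
#' @param reference,simulated aligned `eco_catgrid`s.
#' @return An object of class `eco_kappa`: `kappa`, `p0`, `pc`, `pp`,
#'   `confusion`.
#' @export
kappa_agreement <- function(reference, simulated) {
  assert_aligned(list(reference = reference, simulated = simulated))
  ok <- !is.na(reference$values) & !is.na(simulated$values)
  if (!any(ok)) {
    stop_ecovuln("no overlapping unmasked cells", "ecovuln_empty_domain_error")
  }
  codes <- sort(unique(c(reference$values[ok], simulated$values[ok])))
  conf <- unclass(table(factor(reference$values[ok], levels = codes),
                        factor(simulated$values[ok], levels = codes)))
  n <- sum(conf)
  p0 <- sum(diag(conf)) / n
  pc <- sum(rowSums(conf) * colSums(conf)) / n^2
  pp <- 1
  kap <- if (pp - pc == 0) 1 else (p0 - pc) / (pp - pc)
  structure(list(kappa = kap, p0 = p0, pc = pc, pp = pp, confusion = conf),
            class = "eco_kappa")
}

#' @export
print.eco_kappa <- function(x, ...) {
  cat(sprintf("Kappa = %.4f (p0 = %.4f, pc = %.4f)\n", x$kappa, x$p0, x$pc))
  invisible(x)
}

#' Per-class area change between two epochs
#'
#' Reports per-class areas, their shares of the total, and the absolute and
#' percentage-point change between two epochs. Accepts an `eco_transition`
#' (epoch areas are its row and column sums), two named per-class area
#' vectors, or two aligned class maps.
#'
#' @param a an `eco_transition`, a named area vector, or an `eco_catgrid`.
#' @param b second epoch (ignored when `a` is an `eco_transition`).
#' @param cell_area cell area in km^2 when maps are supplied.
#' @return A data.frame: `class`, `area_t`, `pct_t`, `area_t1`, `pct_t1`,
#'   `change`, `change_pct` (percentage points).
#' @export
area_change_table <- function(a, b = NULL, cell_area = NULL) {
  if (inherits(a, "eco_transition")) {
    areas_t <- rowSums(a$area)
    areas_t1 <- colSums(a$area)
    labels <- a$labels
  } else if (inherits(a, "eco_catgrid")) {
    stopifnot(inherits(b, "eco_catgrid"))
    ca <- cell_area %||% (a$cell_size / 1000)^2
    codes <- sort(unique(c(as.integer(names(a$legend)),
                           as.integer(names(b$legend)))))
    cnt <- function(m) vapply(codes, function(cd)
      sum(m$values == cd, na.rm = TRUE), numeric(1)) * ca
    areas_t <- cnt(a); areas_t1 <- cnt(b)
    labels <- a$legend[as.character(codes)]
  } else {
    areas_t <- a; areas_t1 <- b
    labels <- names(a) %||% paste0("class", seq_along(a))
  }
  tot_t <- sum(areas_t); tot_t1 <- sum(areas_t1)
  data.frame(
    class = as.character(labels),
    area_t = as.numeric(areas_t),
    pct_t = 100 * as.numeric(areas_t) / tot_t,
    area_t1 = as.numeric(areas_t1),
    pct_t1 = 100 * as.numeric(areas_t1) / tot_t1,
    change = as.numeric(areas_t1 - areas_t),
    change_pct = 100 * (as.numeric(areas_t1) / tot_t1 -
                          as.numeric(areas_t) / tot_t),
    stringsAsFactors = FALSE
  )
}

#' Transfer (gain/loss) report for a transition matrix
#'
#' Per-class Decrease (off-diagonal row sum: area transferred out) and
#' Increase (off-diagonal column sum: area transferred in), plus the share
#' of each destination within every class's outflow, in percent.
#'
#' @param tm an `eco_transition`.
#' @return A list with `decrease`, `increase` (named vectors, km^2) and
#'   `outflow_share` (matrix, percent of the source class's outflow going to
#'   each destination; `NA` row where a class lost nothing).
#' @export
transfer_report <- function(tm) {
  A <- tm$area
  off <- A; diag(off) <- 0
  decrease <- rowSums(off)
  increase <- colSums(off)
  share <- 100 * off / ifelse(decrease > 0, decrease, NA)
  diag(share) <- NA
  list(decrease = decrease, increase = increase, outflow_share = share)
}
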