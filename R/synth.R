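#' Stationary Gaussian random field on a grid
#'
#' Generates a zero-mean, unit-variance (in expectation) stationary random
#' field by circular FFT convolution of white noise with a Gaussian kernel of
#' the given correlation length; `correlation_length = 0` returns plain white
#' noise. Identical arguments always give an identical field, and the
#' caller's RNG state is left untouched.
#'
#' @param rows,cols grid dimensions, both at least 2.
#' @param correlation_length kernel scale in cells (>= 0).
#' @param seed integer seed.
#' @param cell_size,origin,crs_label passed to [eco_grid()].
#' @return An `eco_grid`.
#' @examples
#' g <- gaussian_field(32, 32, correlation_length = 4, seed = 1)
#' @export
gaussian_field <- function(rows, cols, correlation_length = 4, seed = 1,
                           cell_size = 90, origin = c(0, 0),
                           crs_label = "synthetic") {
  if (rows < 2 || cols < 2) {
    stop_ecovuln("rows and cols must be >= 2", "ecovuln_usage_error")
  }
  if (correlation_length < 0) {
    stop_ecovuln("correlation_length must be >= 0", "ecovuln_usage_error")
  }
  z <- with_seed(seed, matrix(stats::rnorm(rows * cols), rows, cols))
  if (correlation_length > 0) {
    # circular convolution keeps the field stationary; kernel normalized to
    # unit L2 norm so the output variance stays 1 in expectation
    dr <- pmin(0:(rows - 1), rows - 0:(rows - 1))
    dc <- pmin(0:(cols - 1), cols - 0:(cols - 1))
    k <- exp(-outer(dr^2, dc^2, "+") / (2 * correlation_length^2))
    k <- k / sqrt(sum(k^2))
    z <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) /
      (rows * cols)
  }
  eco_grid(z, cell_size = cell_size, origin = origin, crs_label = crs_label)
}

# kernel above is exp(-(dr^2 + dc^2)/(2L^2)) evaluated on the torus metric;
# note outer(dr^2, dc^2, "+") is the squared torus distance decomposition

#' Synthetic clumped land-use map
#'
#' Cuts a smooth Gaussian field into the six land-use categories (cropland,
#' woodland, grassland, waters, construction land, bare land), producing
#' spatially clumped patches rather than i.i.d. noise. When `base` is
#' supplied its field drives the category layout (higher values map to more
#' vulnerable categories per the 1-6 assignment scale), which couples the
#' land-use layer to a scene's latent vulnerability.
#'
#' @param rows,cols dimensions (>= 4).
#' @param seed integer seed.
#' @param base optional `eco_grid` used as the driving field.
#' @param prop length-6 category area proportions (waters, woodland,
#'   grassland, cropland, construction, bare), in increasing order of the
#'   vulnerability value assigned to each category.
#' @return An `eco_catgrid` with the 6-entry legend.
#' @export
synth_landuse <- function(rows, cols, seed = 1, base = NULL,
                          prop = c(0.06, 0.22, 0.17, 0.35, 0.15, 0.05)) {
  if (rows < 4 || cols < 4) {
    stop_ecovuln("rows and cols must be >= 4", "ecovuln_usage_error")
  }
  stopifnot(length(prop) == 6, all(prop > 0))
  f <- if (is.null(base)) {
    gaussian_field(rows, cols, correlation_length = max(3, rows / 12),
                   seed = seed + 101L)
  } else base
  # categories ordered by their vulnerability assignment value so the driving
  # field increases with assigned vulnerability: waters(1) < woodland(2) <
  # grassland(3) < cropland(4) < construction(5) < bare(6); legend codes are
  # chosen to coincide with that ordering
  qcut <- stats::quantile(f$values, probs = cumsum(prop / sum(prop)),
                          na.rm = TRUE, names = FALSE)
  lvl <- findInterval(f$values, qcut[-6], left.open = TRUE) + 1L
  codes <- matrix(pmin(lvl, 6L), rows, cols)
  legend <- c(`1` = "waters", `2` = "woodland", `3` = "grassland",
              `4` = "cropland", `5` = "construction land", `6` = "bare land")
  eco_catgrid(codes, legend = legend, cell_size = f$cell_size,
              origin = f$origin, crs_label = f$crs_label)
}

#' Synthetic 13-indicator SRP stack with recorded truth
#'
#' Builds the canonical 13-layer indicator stack (codes X1-X13) used by the
#' SRP vulnerability analysis: elevation, slope, landscape fragmentation,
#' soil erosion, mean annual temperature, annual precipitation, NDVI,
#' biological abundance, GDP per capita, economic density, population
#' density, nighttime light intensity and land-use type. Layers share latent
#' Gaussian fields (so a PCA over the stack has non-degenerate correlated
#' structure) and carry the canonical polarity flags: X5-X8 negative, X13
#' categorical, all others positive. X13 is a clumped land-use map coupled to
#' the latent vulnerability field.
#'
#' @param rows,cols dimensions (>= 16).
#' @param seed integer seed.
#' @param share amount of each continuous layer's variance carried by its
#'   latent field loading (per-layer loadings are drawn in `share` +/- 0.15).
#' @param latent optional `eco_grid` supplying the shared latent
#'   vulnerability field (e.g. an externally evolved time series); generated
#'   from the seed when absent.
#' @return A list with `stack` (see [build_stack()] input: list of layers,
#'   each a list with `spec` and `grid`) and `truth` (a `SyntheticTruth`
#'   record: seed, per-layer latent loadings, field parameters).
#' @export
synth_indicator_stack <- function(rows, cols, seed = 1, share = 0.75,
                                  latent = NULL) {
  if (rows < 16 || cols < 16) {
    stop_ecovuln("rows and cols must be >= 16", "ecovuln_usage_error")
  }
  specs <- indicator_specs()
  L <- max(4, rows / 10)
  latent <- latent %||%
    gaussian_field(rows, cols, correlation_length = L, seed = seed)
  load <- with_seed(seed + 1L,
                    stats::runif(12, max(0.05, share - 0.15),
                                 min(0.95, share + 0.15)))
  layers <- vector("list", 13)
  for (p in 1:12) {
    noise <- gaussian_field(rows, cols, correlation_length = max(2, L / 2),
                            seed = seed + 10L + p)
    c_p <- load[p]
    # negative-polarity indicators decrease where latent vulnerability is
    # high, so standardization flips them back into alignment
    sgn <- if (specs$polarity[p] == "negative") -1 else 1
    v <- sgn * c_p * latent$values + sqrt(1 - c_p^2) * noise$values
    layers[[p]] <- list(
      spec = list(code = specs$code[p], name = specs$name[p],
                  polarity = specs$polarity[p]),
      grid = eco_grid(v, cell_size = latent$cell_size)
    )
  }
  lu <- synth_landuse(rows, cols, seed = seed, base = latent)
  layers[[13]] <- list(
    spec = list(code = "X13", name = specs$name[13], polarity = "categorical"),
    grid = lu
  )
  truth <- list(seed = seed,
                field_params = list(correlation_length = L, variance = 1),
                latent_weights = c(load, NA),
                epoch_labels = character(0))
  list(stack = layers, truth = truth)
}

#' Synthetic district partition
#'
#' Splits the grid into `n_zones` contiguous districts by nearest-center
#' (Voronoi) assignment around seeded random centers, supporting
#' district-level zonal reporting of vulnerability class shares.
#'
#' @param rows,cols dimensions.
#' @param n_zones number of districts (>= 1).
#' @param seed integer seed.
#' @return An `eco_catgrid` whose legend labels are district names.
#' @export
synth_zones <- function(rows, cols, n_zones = 6, seed = 1) {
  if (n_zones < 1) stop_ecovuln("n_zones must be >= 1", "ecovuln_usage_error")
  ctr <- with_seed(seed + 900L,
                   cbind(stats::runif(n_zones, 1, rows),
                         stats::runif(n_zones, 1, cols)))
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  d2 <- vapply(seq_len(n_zones), function(z) {
    as.vector((rr - ctr[z, 1])^2 + (cc - ctr[z, 2])^2)
  }, numeric(rows * cols))
  codes <- matrix(max.col(-d2, ties.method = "first"), rows, cols)
  eco_catgrid(codes,
              legend = stats::setNames(paste0("district", seq_len(n_zones)),
                                       seq_len(n_zones)))
}

#' Multi-epoch class series from a known Markov matrix
#'
#' Simulates class maps across epochs: each cell's next class is drawn from
#' its current class's row of `true_transition`, using a spatially correlated
#' uniform field as the random draw so transitions form patches (the marginal
#' law at every cell is exactly the given row). The generating matrix is
#' recorded as ground truth for recovery tests.
#'
#' @param rows,cols dimensions.
#' @param n_classes number of classes (codes `1:n_classes`).
#' @param true_transition `n_classes` x `n_classes` row-stochastic matrix.
#' @param epochs number of maps to produce (>= 2).
#' @param seed integer seed.
#' @param correlation_length patchiness of the transition noise, in cells.
#' @return A list with `maps` (list of `eco_catgrid`) and `truth`
#'   (seed, `true_transition`, `epoch_labels`).
#' @export
synth_class_series <- function(rows, cols, n_classes = 5,
                               true_transition, epochs = 2, seed = 1,
                               correlation_length = 2) {
  if (epochs < 2) stop_ecovuln("epochs must be >= 2", "ecovuln_usage_error")
  P <- as.matrix(true_transition)
  if (!all(dim(P) == c(n_classes, n_classes)) ||
      any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9)) {
    stop_ecovuln("true_transition must be n_classes x n_classes row-stochastic",
                 "ecovuln_usage_error")
  }
  legend <- stats::setNames(paste0("class", seq_len(n_classes)),
                            as.character(seq_len(n_classes)))
  # initial map: clumped classes from a smooth field
  f0 <- gaussian_field(rows, cols, correlation_length = max(3, rows / 10),
                       seed = seed + 500L)
  q0 <- stats::quantile(f0$values, probs = seq_len(n_classes - 1) / n_classes,
                        names = FALSE)
  m <- matrix(findInterval(f0$values, q0) + 1L, rows, cols)
  maps <- vector("list", epochs)
  maps[[1]] <- eco_catgrid(m, legend = legend)
  cum <- t(apply(P, 1, cumsum))
  for (t in seq_len(epochs - 1)) {
    u_field <- gaussian_field(rows, cols,
                              correlation_length = correlation_length,
                              seed = seed + 1000L + t)
    u <- u_field$values
    nxt <- m
    for (cl in seq_len(n_classes)) {
      idx <- which(m == cl)
      if (!length(idx)) next
      # stratified draw: rank the correlated field within the class's own
      # cells, so realized transition frequencies match the generating row
      # to within rounding while the field decides which cells flip,
      # keeping transitions spatially clumped
      u_cl <- rank(u[idx], ties.method = "first") / (length(idx) + 1)
      nxt[idx] <- findInterval(u_cl, cum[cl, ], left.open = TRUE) + 1L
    }
    nxt[nxt > n_classes] <- n_classes  # guard against u == 1 edge
    m <- nxt
    maps[[t + 1]] <- eco_catgrid(m, legend = legend)
  }
  truth <- list(seed = seed, true_transition = P,
                epoch_labels = paste0("t", seq_len(epochs) - 1))
  list(maps = maps, truth = truth)
}

#' Scene with a known latent vulnerability composite
#'
#' Generates a 13-indicator stack whose continuous layers all load on one
#' latent vulnerability field, plus the latent composite defined as a known
#' positively weighted sum of the standardized layers. The recorded weights
#' make the scene a ground-truth target for EVI parameter-recovery tests:
#' the PCA-weighted EVI computed from the stack should correlate strongly
#' with the composite.
#'
#' @param rows,cols dimensions (>= 16).
#' @param seed integer seed.
#' @param weights optional length-13 non-negative weights over the
#'   standardized layers; default uses the latent loadings for the
#'   continuous layers and 0.5 for land use.
#' @return A list with `stack` (standardized [build_stack()] output),
#'   `composite` (an `eco_grid`), and `truth` (seed and the weights used).
#' @export
synth_known_evi_scene <- function(rows, cols, seed = 1, weights = NULL) {
  raw <- synth_indicator_stack(rows, cols, seed = seed, share = 0.8)
  layers <- raw$stack
  layers[[13]]$grid <- assign_landuse_vulnerability(layers[[13]]$grid)
  layers[[13]]$spec$polarity <- "positive"
  std <- build_stack(layers)
  w <- weights %||% c(raw$truth$latent_weights[1:12], 0.5)
  if (length(w) != 13 || any(w < 0)) {
    stop_ecovuln("weights must be 13 non-negative numbers",
                 "ecovuln_usage_error")
  }
  comp <- Reduce(`+`, Map(function(layer, wi) wi * layer$grid$values,
                          std, as.list(w)))
  truth <- list(seed = seed, latent_weights = w,
                field_params = raw$truth$field_params)
  list(stack = std, composite = eco_grid(comp), truth = truth)
}
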