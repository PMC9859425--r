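#' Canonical SRP indicator specification table
#'
#' The 13-indicator sensitivity-resilience-pressure evaluation system:
#' topography (elevation, slope), land surface (landscape fragmentation,
#' soil erosion), climate (mean annual temperature, annual precipitation),
#' vegetation and ecological vitality (NDVI, biological abundance), economy
#' (GDP per capita, economic density) and human activity (population
#' density, nighttime light intensity, land-use type). Polarity states
#' whether larger raw values mean higher vulnerability (`positive`) or lower
#' (`negative`); land use is a categorical variable assigned vulnerability
#' scores separately.
#'
#' @return A data.frame with columns `code`, `name`, `element`, `polarity`.
#' @export
indicator_specs <- function() {
  data.frame(
    code = paste0("X", 1:13),
    name = c("elevation", "slope", "landscape fragmentation", "soil erosion",
             "mean annual temperature", "annual precipitation", "NDVI",
             "biological abundance", "GDP per capita", "economic density",
             "population density", "nighttime light intensity",
             "land use type"),
    element = c("sensitivity", "sensitivity", "sensitivity", "sensitivity",
                "sensitivity", "sensitivity", "resilience", "resilience",
                "pressure", "pressure", "pressure", "pressure", "pressure"),
    polarity = c("positive", "positive", "positive", "positive",
                 "negative", "negative", "negative", "negative",
                 "positive", "positive", "positive", "positive",
                 "categorical"),
    stringsAsFactors = FALSE
  )
}

#' Polarity-aware min-max standardization
#'
#' Rescales a layer to \[0, 1\] by extreme-difference standardization:
#' `(a - amin) / (amax - amin)` for positive indicators (vulnerability rises
#' with the value) and `(amax - a) / (amax - amin)` for negative indicators
#' (vulnerability falls with the value). Extremes are taken over the
#' unmasked cells of the grid; the mask is preserved.
#'
#' @param grid an `eco_grid` with at least two distinct unmasked values.
#' @param polarity `"positive"` or `"negative"`.
#' @return A standardized `eco_grid` in \[0, 1\].
#' @examples
#' standardize(eco_grid(matrix(c(2, 4, 6, 4), 2, 2)), "positive")$values
#' @export
standardize <- function(grid, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  v <- grid$values
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) {
    stop_ecovuln("cannot standardize a constant (or empty) layer",
                 "ecovuln_degenerate_range_error")
  }
  out <- if (polarity == "positive") {
    (v - rng[1]) / (rng[2] - rng[1])
  } else {
    (rng[2] - v) / (rng[2] - rng[1])
  }
  eco_grid(out, cell_size = grid$cell_size, origin = grid$origin,
           crs_label = grid$crs_label)
}

#' Land-use vulnerability assignment
#'
#' Converts a six-category land-use map to the standard vulnerability score
#' scale: waters 1, woodland 2, grassland 3, cropland 4, construction land
#' 5, bare land 6. The resulting layer is treated as a positive-direction
#' indicator (higher score = more vulnerable) in downstream standardization.
#' Lookup is by legend label, so any coding of the six categories is
#' accepted.
#'
#' @param landuse an `eco_catgrid` whose legend labels are among the six
#'   categories above.
#' @return A continuous `eco_grid` of scores 1-6.
#' @export
assign_landuse_vulnerability <- function(landuse) {
  if (!is_catgrid(landuse)) {
    stop_ecovuln("'landuse' must be an eco_catgrid", "ecovuln_usage_error")
  }
  scores <- c("waters" = 1, "woodland" = 2, "grassland" = 3, "cropland" = 4,
              "construction land" = 5, "bare land" = 6)
  labels <- tolower(trimws(landuse$legend))
  unknown <- setdiff(labels, names(scores))
  if (length(unknown)) {
    stop_ecovuln(paste0("unknown land-use categories: ",
                        paste(unknown, collapse = ", ")),
                 "ecovuln_legend_error")
  }
  code_score <- stats::setNames(scores[labels], names(landuse$legend))
  out <- matrix(NA_real_, nrow(landuse$values), ncol(landuse$values))
  ok <- !is.na(landuse$values)
  out[ok] <- code_score[as.character(landuse$values[ok])]
  eco_grid(out, cell_size = landuse$cell_size, origin = landuse$origin,
           crs_label = landuse$crs_label)
}

#' Soil-erosion layer as a RUSLE factor product
#'
#' Composes the soil-erosion indicator as the cellwise product of the four
#' RUSLE factor grids: soil erodibility K, slope length-steepness LS,
#' rainfall erosivity R and vegetation cover C. The output mask is the union
#' of the input masks.
#'
#' @param K,LS,R,C aligned non-negative `eco_grid`s.
#' @return An `eco_grid` of K*LS*R*C.
#' @export
compose_rusle <- function(K, LS, R, C) {
  grids <- list(K = K, LS = LS, R = R, C = C)
  assert_aligned(grids)
  for (nm in names(grids)) {
    if (any(grids[[nm]]$values < 0, na.rm = TRUE)) {
      stop_ecovuln(sprintf("RUSLE factor %s has negative values", nm),
                   "ecovuln_domain_error")
    }
  }
  out <- K$values * LS$values * R$values * C$values
  eco_grid(out, cell_size = K$cell_size, origin = K$origin,
           crs_label = K$crs_label)
}

#' Landscape fragmentation as focal patch density
#'
#' A patch-density fragmentation surrogate: for each cell, the number of
#' distinct 4-connected patches of the focal cell's land-use class within a
#' `window` x `window` neighborhood, divided by the window area. A uniform
#' map scores the minimum `1/window^2` everywhere in the interior; highly
#' interleaved classes score close to the cell count of the focal class.
#' This is an explicit stand-in for landscape-metrics software output
#' (e.g. Fragstats patch density) and is invariant under relabeling of the
#' class codes.
#'
#' @param landuse an `eco_catgrid`.
#' @param window odd window size >= 3.
#' @return An `eco_grid` of patch densities.
#' @export
fragmentation_index <- function(landuse, window = 3) {
  if (window < 3 || window %% 2 == 0) {
    stop_ecovuln("'window' must be an odd integer >= 3", "ecovuln_usage_error")
  }
  m <- landuse$values
  nr <- nrow(m); nc <- ncol(m)
  h <- (window - 1) / 2
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (is.na(m[r, cc])) next
      rs <- max(1, r - h):min(nr, r + h)
      cs <- max(1, cc - h):min(nc, cc + h)
      w <- m[rs, cs, drop = FALSE]
      out[r, cc] <- count_patches(w == m[r, cc]) / (window * window)
    }
  }
  eco_grid(out, cell_size = landuse$cell_size, origin = landuse$origin,
           crs_label = landuse$crs_label)
}

# number of 4-connected components of TRUE cells in a small logical matrix
count_patches <- function(mask) {
  mask[is.na(mask)] <- FALSE
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  n <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (!mask[r, cc] || seen[r, cc]) next
      n <- n + 1L
      queue <- list(c(r, cc))
      seen[r, cc] <- TRUE
      while (length(queue)) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          rr <- p[1] + d[1]; c2 <- p[2] + d[2]
          if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc &&
              mask[rr, c2] && !seen[rr, c2]) {
            seen[rr, c2] <- TRUE
            queue[[length(queue) + 1L]] <- c(rr, c2)
          }
        }
      }
    }
  }
  n
}

#' Build a standardized indicator stack
#'
#' Standardizes every layer according to its polarity (the land-use layer
#' must already be converted to vulnerability scores via
#' [assign_landuse_vulnerability()] and is treated as positive-direction),
#' checks alignment, and propagates masks: a cell masked in any input layer
#' is masked in every output layer.
#'
#' @param layers list of layers, each a list with elements `spec` (list with
#'   `code`, `name`, `polarity`) and `grid` (an `eco_grid`).
#' @return A list of the same shape with standardized grids; class
#'   `eco_stack`.
#' @export
build_stack <- function(layers) {
  if (!length(layers)) {
    stop_ecovuln("'layers' must be non-empty", "ecovuln_usage_error")
  }
  codes <- vapply(layers, function(l) l$spec$code, character(1))
  if (anyDuplicated(codes)) {
    stop_ecovuln("indicator codes must be unique", "ecovuln_usage_error")
  }
  grids <- lapply(layers, `[[`, "grid")
  names(grids) <- codes
  assert_aligned(grids)
  if (any(vapply(layers, function(l) l$spec$polarity, character(1)) ==
          "categorical")) {
    stop_ecovuln(paste("categorical layers must be converted with",
                       "assign_landuse_vulnerability() before build_stack()"),
                 "ecovuln_usage_error")
  }
  union_mask <- Reduce(`|`, lapply(grids, grid_mask))
  out <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    g <- layers[[i]]$grid
    g$values[union_mask] <- NA
    pol <- layers[[i]]$spec$polarity
    out[[i]] <- list(spec = layers[[i]]$spec,
                     grid = standardize(g, pol))
  }
  names(out) <- codes
  structure(out, class = "eco_stack")
}

#' @export
print.eco_stack <- function(x, ...) {
  d <- grid_dim(x[[1]]$grid)
  cat(sprintf("<eco_stack: %d standardized layers, %d x %d>\n",
              length(x), d[1], d[2]))
  for (l in x) {
    cat(sprintf("  %-4s %-26s %s\n", l$spec$code, l$spec$name,
                l$spec$polarity))
  }
  invisible(x)
}
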