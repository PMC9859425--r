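#' Raster grid objects
#'
#' `eco_grid()` wraps a numeric matrix as a masked, georeferenced raster:
#' missing cells are `NA`, `cell_size` is the cell edge length in metres and
#' `origin` is the map coordinate of the upper-left corner of the upper-left
#' cell (rows increase southward, the standard north-up convention).
#' `eco_catgrid()` is the categorical counterpart holding integer class codes
#' plus a legend mapping each code to a label.
#'
#' @param values numeric (or integer for `eco_catgrid`) matrix; `NA` = nodata.
#' @param cell_size positive cell edge length in metres.
#' @param origin length-2 numeric, map x/y of the upper-left corner.
#' @param crs_label free-text coordinate system tag.
#' @param codes integer matrix of class codes; `NA` = nodata.
#' @param legend named character vector; names are the integer codes as
#'   strings, values the class labels. Every unmasked code must appear.
#'
#' @return An object of class `eco_grid` (and additionally `eco_catgrid` for
#'   the categorical constructor): a list with elements `values`, `cell_size`,
#'   `origin`, `crs_label` and, for categorical grids, `legend`.
#' @examples
#' g <- eco_grid(matrix(runif(9), 3, 3))
#' summary(g)
#' lu <- eco_catgrid(matrix(1L, 2, 2), legend = c(`1` = "waters"))
#' @export
eco_grid <- function(values, cell_size = 90, origin = c(0, 0),
                     crs_label = "synthetic") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_ecovuln("'values' must be a numeric matrix", "ecovuln_usage_error")
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop_ecovuln("'cell_size' must be a single positive number",
                 "ecovuln_usage_error")
  }
  if (any(is.infinite(values) | is.nan(values))) {
    stop_ecovuln("unmasked grid values must be finite (use NA for nodata)",
                 "ecovuln_usage_error")
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)[1:2], crs_label = as.character(crs_label)),
    class = "eco_grid"
  )
}

#' @rdname eco_grid
#' @export
eco_catgrid <- function(codes, legend, cell_size = 90, origin = c(0, 0),
                        crs_label = "synthetic") {
  if (!is.matrix(codes)) {
    stop_ecovuln("'codes' must be an integer matrix", "ecovuln_usage_error")
  }
  storage.mode(codes) <- "integer"
  present <- unique(codes[!is.na(codes)])
  if (missing(legend) || is.null(legend)) {
    legend <- stats::setNames(as.character(sort(present)),
                              as.character(sort(present)))
  }
  if (is.null(names(legend))) {
    stop_ecovuln("'legend' must be named by integer code",
                 "ecovuln_legend_error")
  }
  missing_codes <- setdiff(as.character(present), names(legend))
  if (length(missing_codes)) {
    stop_ecovuln(paste0("codes absent from legend: ",
                        paste(missing_codes, collapse = ", ")),
                 "ecovuln_legend_error")
  }
  g <- eco_grid(matrix(as.numeric(codes), nrow(codes), ncol(codes)),
                cell_size = cell_size, origin = origin, crs_label = crs_label)
  g$values <- codes
  g$legend <- vapply(legend, as.character, character(1))
  class(g) <- c("eco_catgrid", "eco_grid")
  g
}

is_catgrid <- function(x) inherits(x, "eco_catgrid")

grid_mask <- function(g) is.na(g$values)

grid_dim <- function(g) dim(g$values)

#' @export
print.eco_grid <- function(x, ...) {
  d <- dim(x$values)
  kind <- if (is_catgrid(x)) "categorical raster" else "raster"
  cat(sprintf("<eco_grid: %s %d x %d, cell %g m, origin (%g, %g)>\n",
              kind, d[1], d[2], x$cell_size, x$origin[1], x$origin[2]))
  n_na <- sum(is.na(x$values))
  cat(sprintf("  unmasked cells: %d (%d masked)\n",
              length(x$values) - n_na, n_na))
  if (is_catgrid(x)) {
    cat("  legend:", paste(sprintf("%s=%s", names(x$legend), x$legend),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.eco_grid <- function(object, ...) {
  v <- object$values[!is.na(object$values)]
  if (is_catgrid(object)) {
    tab <- table(factor(v, levels = as.integer(names(object$legend)),
                        labels = object$legend))
    print(tab)
    return(invisible(tab))
  }
  s <- c(mean = mean(v), min = min(v), max = max(v), sd = stats::sd(v),
         n = length(v))
  print(signif(s, 6))
  invisible(s)
}

#' @export
plot.eco_grid <- function(x, main = NULL, ...) {
  # image() draws column-major from bottom; transpose and flip for north-up
  z <- t(x$values[nrow(x$values):1, , drop = FALSE])
  graphics::image(z, main = main, axes = FALSE, useRaster = TRUE, ...)
  invisible(x)
}

#' Check that a set of grids shares one geometry
#'
#' Passes silently when every grid has the same dimensions, cell size and
#' origin; otherwise raises an alignment error naming the first offending
#' grid. All stack-level operations in the package require aligned inputs.
#'
#' @param grids a (optionally named) list of `eco_grid` objects.
#' @return Invisibly `TRUE` on success.
#' @export
assert_aligned <- function(grids) {
  if (!is.list(grids) || !length(grids)) {
    stop_ecovuln("'grids' must be a non-empty list", "ecovuln_usage_error")
  }
  ref <- grids[[1]]
  nm <- names(grids) %||% rep("", length(grids))
  for (i in seq_along(grids)) {
    g <- grids[[i]]
    label <- if (nzchar(nm[i])) nm[i] else sprintf("grid %d", i)
    if (!identical(grid_dim(g), grid_dim(ref))) {
      stop_ecovuln(sprintf("%s: shape mismatch", label),
                   "ecovuln_alignment_error")
    }
    if (!isTRUE(all.equal(g$cell_size, ref$cell_size))) {
      stop_ecovuln(sprintf("%s: cell_size mismatch", label),
                   "ecovuln_alignment_error")
    }
    if (!isTRUE(all.equal(g$origin, ref$origin))) {
      stop_ecovuln(sprintf("%s: origin mismatch", label),
                   "ecovuln_alignment_error")
    }
  }
  invisible(TRUE)
}

#' Aggregate a grid to coarser analysis cells
#'
#' Summarizes each `block` x `block` window of unmasked cells into one output
#' cell: the arithmetic mean for continuous grids (`how = "mean"`) or the
#' modal code for categorical grids (`how = "majority"`, ties broken by the
#' smallest code). Used e.g. to move an EVI surface onto 900 m analysis cells
#' before spatial autocorrelation. Trailing partial blocks are aggregated
#' over the cells present rather than dropped, so the study area never
#' shrinks; blocks with no unmasked cells are masked.
#'
#' @param grid an `eco_grid` or `eco_catgrid`.
#' @param block positive integer aggregation factor; `1` returns the input.
#' @param how `"mean"` (continuous only) or `"majority"` (categorical only).
#' @return A grid of the same kind with `cell_size * block` geometry.
#' @examples
#' g <- eco_grid(matrix(c(1, 3, 1, 3), 2, 2))
#' aggregate_blocks(g, 2, "mean")$values  # 2
#' @export
aggregate_blocks <- function(grid, block,
                             how = if (is_catgrid(grid)) "majority" else "mean") {
  how <- match.arg(how, c("mean", "majority"))
  if (!is.numeric(block) || length(block) != 1L || block < 1 ||
      block != round(block)) {
    stop_ecovuln("'block' must be a positive integer", "ecovuln_usage_error")
  }
  if (how == "mean" && is_catgrid(grid)) {
    stop_ecovuln("how='mean' applies to continuous grids only",
                 "ecovuln_usage_error")
  }
  if (how == "majority" && !is_catgrid(grid)) {
    stop_ecovuln("how='majority' applies to categorical grids only",
                 "ecovuln_usage_error")
  }
  if (block == 1) return(grid)
  d <- grid_dim(grid)
  ri <- ceiling(seq_len(d[1]) / block)
  ci <- ceiling(seq_len(d[2]) / block)
  out <- matrix(NA_real_, max(ri), max(ci))
  for (r in seq_len(max(ri))) {
    for (cc in seq_len(max(ci))) {
      v <- grid$values[ri == r, ci == cc]
      v <- v[!is.na(v)]
      if (!length(v)) next
      out[r, cc] <- if (how == "mean") {
        mean(v)
      } else {
        tab <- table(v)
        best <- tab == max(tab)
        min(as.numeric(names(tab)[best]))  # smallest-code tie-break
      }
    }
  }
  if (is_catgrid(grid)) {
    oc <- matrix(as.integer(out), nrow(out), ncol(out))
    eco_catgrid(oc, legend = grid$legend,
                cell_size = grid$cell_size * block, origin = grid$origin,
                crs_label = grid$crs_label)
  } else {
    eco_grid(out, cell_size = grid$cell_size * block, origin = grid$origin,
             crs_label = grid$crs_label)
  }
}
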