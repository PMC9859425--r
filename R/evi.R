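#' Principal component analysis of a standardized indicator stack
#'
#' Eigendecomposition of the correlation matrix (default) or covariance
#' matrix of the standardized layers over their shared unmasked cells.
#' Components are ordered by descending eigenvalue; each component's sign is
#' flipped so that the sum of its loadings is non-negative, making the
#' direction of downstream composite indices reproducible across eigen
#' solvers. Contribution rates are eigenvalue shares of total variance, in
#' percent; score grids hold each cell's projection onto each component.
#'
#' @param stack an `eco_stack` from [build_stack()] (or any list of layers
#'   with `spec`/`grid` elements), at least 2 layers.
#' @param use `"correlation"` (default) or `"covariance"`.
#' @return An object of class `eco_pca`: eigenvalues, `contribution` and
#'   `cumulative` rates (percent), orthonormal `loadings` (p x p, layers in
#'   rows), `scores` (list of score `eco_grid`s), layer `codes`, the cell
#'   `mask` used, and `centers`/`scales` of the layer z-scoring.
#' @seealso [select_components()], [compute_evi()]
#' @export
fit_pca <- function(stack, use = c("correlation", "covariance")) {
  use <- match.arg(use)
  if (length(stack) < 2) {
    stop_ecovuln("need at least 2 layers", "ecovuln_usage_error")
  }
  grids <- lapply(stack, `[[`, "grid")
  assert_aligned(grids)
  mask <- Reduce(`|`, lapply(grids, grid_mask))
  idx <- which(!mask)
  p <- length(stack)
  if (length(idx) < p + 1) {
    stop_ecovuln("need more unmasked cells than layers",
                 "ecovuln_usage_error")
  }
  X <- vapply(grids, function(g) g$values[idx], numeric(length(idx)))
  centers <- colMeans(X)
  scales <- if (use == "correlation") {
    apply(X, 2, stats::sd)
  } else {
    rep(1, p)
  }
  if (any(scales == 0)) {
    warning("constant layer(s) in PCA input; dropping their variance ",
            "contribution (zero eigenvalue retained at the tail)")
    scales[scales == 0] <- 1
  }
  Z <- sweep(sweep(X, 2, centers), 2, scales, "/")
  S <- if (use == "correlation") stats::cor(X) else stats::cov(X)
  eg <- eigen(S, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  A <- eg$vectors
  flip <- colSums(A) < 0
  A[, flip] <- -A[, flip]
  contribution <- 100 * lambda / sum(lambda)
  scores <- Z %*% A
  template <- grids[[1]]
  score_grids <- lapply(seq_len(p), function(kk) {
    v <- matrix(NA_real_, nrow(template$values), ncol(template$values))
    v[idx] <- scores[, kk]
    eco_grid(v, cell_size = template$cell_size, origin = template$origin,
             crs_label = template$crs_label)
  })
  codes <- vapply(stack, function(l) l$spec$code, character(1))
  rownames(A) <- codes
  structure(
    list(eigenvalues = lambda, contribution = contribution,
         cumulative = cumsum(contribution), loadings = A,
         scores = score_grids, codes = codes, mask = mask,
         centers = centers, scales = scales, use = use,
         sign_convention = "sum of loadings >= 0"),
    class = "eco_pca"
  )
}

#' @export
print.eco_pca <- function(x, ...) {
  cat(sprintf("<eco_pca: %d components (%s matrix)>\n",
              length(x$eigenvalues), x$use))
  tab <- data.frame(
    eigenvalue = round(x$eigenvalues, 3),
    contribution = round(x$contribution, 3),
    cumulative = round(x$cumulative, 3)
  )
  rownames(tab) <- paste0("PC", seq_len(nrow(tab)))
  print(utils::head(tab, 8))
  if (nrow(tab) > 8) cat("  ...\n")
  invisible(x)
}

#' @export
summary.eco_pca <- function(object, threshold = 85, ...) {
  n <- select_components(object, threshold)
  cat(sprintf("Retaining %d component(s) at the %.4g%% cumulative threshold\n",
              n, threshold))
  print(object)
  invisible(object)
}

#' Number of components at a cumulative-contribution threshold
#'
#' The smallest N whose cumulative contribution rate reaches `threshold`
#' percent; always at least 1. Accepts either an `eco_pca` object or a bare
#' vector of contribution rates in percent (e.g. a published table row).
#'
#' @param pca an `eco_pca` or numeric vector of contribution rates (%).
#' @param threshold percent in (0, 100].
#' @return Integer count N.
#' @examples
#' select_components(c(60, 30, 10), 85)  # 2
#' @export
select_components <- function(pca, threshold = 85) {
  if (threshold <= 0 || threshold > 100) {
    stop_ecovuln("'threshold' must be in (0, 100]", "ecovuln_usage_error")
  }
  rates <- if (inherits(pca, "eco_pca")) pca$contribution else as.numeric(pca)
  cum <- cumsum(rates)
  n <- which(cum >= threshold - 1e-9)[1]
  if (is.na(n)) n <- length(rates)
  max(1L, as.integer(n))
}

#' Ecological vulnerability index from retained components
#'
#' The EVI is the contribution-weighted sum of the first `n` principal
#' component score surfaces: `I_EV = sum_k alpha_k F_k`, with the weights
#' `alpha_k` taken as proportions (contribution percent / 100). Higher EVI
#' means a more vulnerable ecosystem.
#'
#' @param pca an `eco_pca`.
#' @param n number of retained components (<= available components);
#'   defaults to the 85% rule.
#' @return An `eco_grid` of EVI values.
#' @export
compute_evi <- function(pca, n = select_components(pca)) {
  if (n > length(pca$scores)) {
    stop_ecovuln("n exceeds the number of available components",
                 "ecovuln_usage_error")
  }
  alpha <- pca$contribution[seq_len(n)] / 100
  out <- Reduce(`+`, Map(function(g, a) a * g$values,
                         pca$scores[seq_len(n)], as.list(alpha)))
  g1 <- pca$scores[[1]]
  eco_grid(out, cell_size = g1$cell_size, origin = g1$origin,
           crs_label = g1$crs_label)
}

#' Five-level vulnerability grading by natural breaks
#'
#' Classifies an EVI surface into `k` ordered vulnerability levels with
#' Jenks natural-breaks optimization (class 1 = slight ... class 5 =
#' extreme for the default `k = 5`). Labels are attached as the legend and
#' the break values are kept on the result.
#'
#' @param evi an `eco_grid` of EVI values with >= `k` distinct unmasked
#'   values.
#' @param k number of classes.
#' @return An `eco_catgrid` with codes `1:k`, plus attributes `breaks`
#'   (interior break values) and `intervals` (k x 2 matrix of class ranges).
#' @export
classify_natural_breaks <- function(evi, k = 5) {
  v <- evi$values[!is.na(evi$values)]
  jb <- jenks_breaks(v, k = k)
  cl <- matrix(jenks_assign(evi$values, jb$breaks),
               nrow(evi$values), ncol(evi$values))
  labels <- if (k == 5) {
    c("slight", "light", "medium", "heavy", "extreme")
  } else {
    paste0("level", seq_len(k))
  }
  lower <- c(min(v), jb$breaks)
  upper <- c(jb$breaks, max(v))
  g <- eco_catgrid(cl, legend = stats::setNames(labels, seq_len(k)),
                   cell_size = evi$cell_size, origin = evi$origin,
                   crs_label = evi$crs_label)
  attr(g, "breaks") <- jb$breaks
  attr(g, "intervals") <- cbind(lower = lower, upper = upper)
  g
}

#' Zonal share of vulnerability classes
#'
#' Cross-tabulates a class map against a zone (district) map and reports the
#' percent of each zone's unmasked area in each class; shares per zone sum
#' to 100. Zones with no unmasked overlap are omitted with a warning.
#'
#' @param classes an `eco_catgrid` class map.
#' @param zones an `eco_catgrid` whose legend labels are zone names.
#' @return A data.frame with columns `zone`, `class`, `percent`.
#' @export
zonal_class_share <- function(classes, zones) {
  assert_aligned(list(classes = classes, zones = zones))
  ok <- !is.na(classes$values) & !is.na(zones$values)
  zl <- zones$legend[as.character(zones$values[ok])]
  cl <- classes$legend[as.character(classes$values[ok])]
  empty <- setdiff(zones$legend, unique(zl))
  if (length(empty)) {
    warning("zones with no unmasked cells omitted: ",
            paste(empty, collapse = ", "))
  }
  tab <- table(zone = zl, class = cl)
  shares <- 100 * prop.table(tab, margin = 1)
  df <- as.data.frame(shares, responseName = "percent",
                      stringsAsFactors = FALSE)
  df <- df[order(df$zone, df$class), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Summary statistics of an EVI surface
#'
#' @param evi an `eco_grid` with at least one unmasked cell.
#' @return Named numeric vector `mean`, `min`, `max`.
#' @export
evi_summary <- function(evi) {
  v <- evi$values[!is.na(evi$values)]
  if (!length(v)) {
    stop_ecovuln("all cells are masked", "ecovuln_empty_domain_error")
  }
  c(mean = mean(v), min = min(v), max = max(v))
}
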