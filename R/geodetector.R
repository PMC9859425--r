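#' Discretize a continuous driver into strata
#'
#' Turns a continuous factor grid into the categorical strata the
#' geographical detector requires, by Jenks natural breaks (default) or
#' sample quantiles. Categorical grids pass through unchanged (their codes
#' already are strata).
#'
#' @param grid an `eco_grid` (continuous) or `eco_catgrid` (returned as-is).
#' @param k number of strata.
#' @param method `"jenks"` or `"quantile"`.
#' @return An `eco_catgrid` of stratum codes `1:k`.
#' @export
discretize_factor <- function(grid, k = 5, method = c("jenks", "quantile")) {
  method <- match.arg(method)
  if (is_catgrid(grid)) return(grid)
  v <- grid$values
  vv <- v[!is.na(v)]
  if (length(unique(vv)) < k) {
    stop_ecovuln(sprintf("need >= %d distinct values for %d strata", k, k),
                 "ecovuln_classification_error")
  }
  breaks <- if (method == "jenks") {
    jenks_breaks(vv, k = k)$breaks
  } else {
    unique(stats::quantile(vv, probs = seq_len(k - 1) / k, names = FALSE,
                           type = 1))
  }
  cl <- matrix(findInterval(v, breaks, left.open = TRUE) + 1L,
               nrow(v), ncol(v))
  cl[is.na(v)] <- NA_integer_
  eco_catgrid(cl, legend = stats::setNames(paste0("stratum", seq_len(k)),
                                           seq_len(k)),
              cell_size = grid$cell_size, origin = grid$origin,
              crs_label = grid$crs_label)
}

#' Factor detector q-statistic
#'
#' The geographical-detector measure of how much of a response's spatial
#' variance a stratification explains:
#' `q = 1 - sum_h N_h sigma_h^2 / (N sigma^2)`, with population variances in
#' both the within-stratum and total terms so q is a pure variance ratio in
#' \[0, 1\]. `q = 1` means y is constant within every stratum; `q = 0` means
#' the strata explain nothing.
#'
#' @param y an `eco_grid` response (e.g. an EVI surface), non-constant.
#' @param strata an `eco_catgrid` of stratum codes, aligned with `y`.
#' @param p_method how to attach a p-value: `"noncentral_f"` (the standard
#'   geodetector transformation), `"permutation"`, or `"none"`.
#' @param permutations,seed used when `p_method = "permutation"`.
#' @return An object of class `eco_q`: `q`, `p_value`, `n`, `k`, and a
#'   per-stratum table of sizes, means and variances.
#' @export
factor_q <- function(y, strata, p_method = c("noncentral_f", "permutation",
                                             "none"),
                     permutations = 999, seed = 1) {
  p_method <- match.arg(p_method)
  assert_aligned(list(y = y, strata = strata))
  ok <- !is.na(y$values) & !is.na(strata$values)
  yy <- y$values[ok]
  hh <- strata$values[ok]
  qres <- q_statistic(yy, hh)
  qres$p_value <- switch(
    p_method,
    none = NA_real_,
    noncentral_f = q_ncf_p(qres, yy, hh),
    permutation = q_perm_p(qres, yy, hh, permutations, seed)
  )
  qres$p_method <- p_method
  class(qres) <- "eco_q"
  qres
}

# core q computation on bare vectors
q_statistic <- function(yy, hh) {
  n <- length(yy)
  if (n < 2 || stats::var(yy) == 0) {
    stop_ecovuln("response is constant (zero variance)",
                 "ecovuln_zero_variance_error")
  }
  pop_var <- function(v) mean((v - mean(v))^2)
  sizes <- tapply(yy, hh, length)
  if (any(sizes < 1)) {
    stop_ecovuln("empty stratum", "ecovuln_stratification_error")
  }
  means <- tapply(yy, hh, mean)
  vars <- tapply(yy, hh, pop_var)
  ssw <- sum(sizes * vars)
  sst <- n * pop_var(yy)
  list(q = 1 - ssw / sst, n = n, k = length(sizes),
       strata_table = data.frame(stratum = names(sizes),
                                 n = as.integer(sizes),
                                 mean = as.numeric(means),
                                 variance = as.numeric(vars)))
}

# noncentral-F significance transformation for the q statistic
q_ncf_p <- function(qres, yy, hh) {
  n <- qres$n; k <- qres$k
  if (k >= n) {
    stop_ecovuln("saturated strata (k = n): test undefined",
                 "ecovuln_undefined_test_error")
  }
  if (qres$q >= 1) return(0)
  Fv <- (n - k) / (k - 1) * qres$q / (1 - qres$q)
  sizes <- tapply(yy, hh, length)
  means <- tapply(yy, hh, mean)
  # noncentrality of the standard geodetector test:
  # lambda = [sum_h m_h^2 - (sum_h sqrt(N_h) m_h)^2 / N] / sigma^2
  lambda <- (sum(means^2) - sum(sqrt(sizes) * means)^2 / n) /
    mean((yy - mean(yy))^2)
  stats::pf(Fv, k - 1, n - k, ncp = max(lambda, 0), lower.tail = FALSE)
}

q_perm_p <- function(qres, yy, hh, permutations, seed) {
  q_star <- with_seed(seed, vapply(seq_len(permutations), function(b) {
    q_statistic(yy, hh[sample.int(length(hh))])$q
  }, numeric(1)))
  (sum(q_star >= qres$q) + 1) / (permutations + 1)
}

#' Significance of a q statistic
#'
#' Recomputes the p-value for a fitted [factor_q()] result by the
#' noncentral-F transformation or by permuting the stratum labels.
#'
#' @param y,strata the inputs the q was computed from.
#' @param qres an `eco_q`.
#' @param method `"noncentral_f"` or `"permutation"`.
#' @param permutations,seed permutation settings.
#' @return The p-value (also stored back on the returned `eco_q`).
#' @export
q_significance <- function(qres, y, strata,
                           method = c("noncentral_f", "permutation"),
                           permutations = 999, seed = 1) {
  method <- match.arg(method)
  ok <- !is.na(y$values) & !is.na(strata$values)
  yy <- y$values[ok]
  hh <- strata$values[ok]
  if (method == "noncentral_f") q_ncf_p(qres, yy, hh)
  else q_perm_p(qres, yy, hh, permutations, seed)
}

#' @export
print.eco_q <- function(x, ...) {
  cat(sprintf("GeoDetector q = %.4f (n = %d, k = %d strata)", x$q, x$n, x$k))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g [%s]", x$p_value,
                                     x$p_method))
  cat("\n")
  invisible(x)
}

#' Interaction detector
#'
#' Computes q for two factors and for their overlay (the Cartesian product
#' of their strata, keeping only combinations present in the data) and
#' classifies the interaction: the overlay refines both stratifications, so
#' `q12 >= max(q1, q2)` always.
#'
#' @param y response `eco_grid`.
#' @param strataA,strataB `eco_catgrid` stratifications of two factors.
#' @return An object of class `eco_interaction` with `q1`, `q2`, `q12` and
#'   `category`.
#' @export
interaction_q <- function(y, strataA, strataB) {
  assert_aligned(list(y = y, A = strataA, B = strataB))
  ok <- !is.na(y$values) & !is.na(strataA$values) & !is.na(strataB$values)
  yy <- y$values[ok]
  a <- strataA$values[ok]
  b <- strataB$values[ok]
  q1 <- q_statistic(yy, a)$q
  q2 <- q_statistic(yy, b)$q
  overlay <- paste(a, b, sep = ":")
  if (any(tapply(yy, overlay, length) == 1)) {
    warning("overlay contains singleton strata")
  }
  q12 <- q_statistic(yy, overlay)$q
  structure(list(q1 = q1, q2 = q2, q12 = q12,
                 category = interaction_category(q1, q2, q12)),
            class = "eco_interaction")
}

#' Interaction category rule
#'
#' Classifies a pairwise interaction from its single-factor and overlay q
#' values: `q12 < min(q1, q2)` nonlinear-weaken; `min <= q12 < max`
#' single-factor-nonlinear-weaken; `q12 = q1 + q2` (within `tol`)
#' independent; `q12 > q1 + q2` nonlinear-enhance; otherwise (between the
#' max and the sum) bifactor-enhance.
#'
#' @param q1,q2,q12 q values in \[0, 1\].
#' @param tol equality tolerance for the independent case.
#' @return One of `"nonlinear-weaken"`, `"single-factor-nonlinear-weaken"`,
#'   `"independent"`, `"bifactor-enhance"`, `"nonlinear-enhance"`.
#' @export
interaction_category <- function(q1, q2, q12, tol = 1e-6) {
  vals <- c(q1, q2, q12)
  if (any(!is.finite(vals)) || any(vals < -tol) || any(vals > 1 + tol)) {
    stop_ecovuln("q values must lie in [0, 1]", "ecovuln_domain_error")
  }
  if (abs(q12 - (q1 + q2)) <= tol) return("independent")
  if (q12 < min(q1, q2)) return("nonlinear-weaken")
  if (q12 < max(q1, q2)) return("single-factor-nonlinear-weaken")
  if (q12 > q1 + q2) return("nonlinear-enhance")
  "bifactor-enhance"
}

#' @export
print.eco_interaction <- function(x, ...) {
  cat(sprintf("q1 = %.4f, q2 = %.4f, q(1 ^ 2) = %.4f -> %s\n",
              x$q1, x$q2, x$q12, x$category))
  invisible(x)
}
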