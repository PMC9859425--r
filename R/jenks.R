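#' Jenks natural-breaks optimization
#'
#' Exact Fisher-Jenks dynamic programming: partitions sorted values into
#' `k` contiguous classes minimizing the total within-class sum of squared
#' deviations from class means. Returns the `k - 1` interior break values
#' (upper bounds of classes 1..k-1, taken as the largest value in each
#' class), so a value `v` belongs to class `findInterval(v, breaks) + 1`
#' with intervals closed on the right at the breaks.
#'
#' For very large inputs the optimization runs on a uniform sample of at
#' most `max_exact` values and all data are then assigned by the resulting
#' breaks; below that size the solution is exact on the full data.
#'
#' @param x numeric vector (NAs dropped), at least `k` distinct values.
#' @param k number of classes.
#' @param max_exact sample cap for the DP stage.
#' @param seed seed used only when sampling is triggered.
#' @return List with `breaks` (length `k - 1`), `ssd` (optimal within-class
#'   sum of squared deviations on the data used for the DP) and `k`.
#' @export
jenks_breaks <- function(x, k = 5, max_exact = 50000, seed = 1) {
  x <- x[!is.na(x)]
  if (length(unique(x)) < k) {
    stop_ecovuln(sprintf("need >= %d distinct values for %d classes", k, k),
                 "ecovuln_classification_error")
  }
  if (length(x) > max_exact) {
    xs <- with_seed(seed, sample(x, max_exact))
    if (length(unique(xs)) < k) {  # guard against sampling away rare values
      xs <- c(xs, unique(x))
    }
    x <- xs
  }
  # collapse to unique values with counts: optimal classes are contiguous in
  # sorted order and never split tied values (rle keeps exact doubles)
  runs <- rle(sort(x))
  u <- runs$values
  w <- as.numeric(runs$lengths)
  m <- length(u)
  cw0 <- c(0, cumsum(w))
  cwx0 <- c(0, cumsum(w * u))
  cwx20 <- c(0, cumsum(w * u^2))
  ssd_to <- function(i_vec, j) {  # within-SSD of u[i..j] for a vector of i
    W <- cw0[j + 1] - cw0[i_vec]
    S <- cwx0[j + 1] - cwx0[i_vec]
    S2 <- cwx20[j + 1] - cwx20[i_vec]
    pmax(S2 - S^2 / W, 0)
  }
  # DP over (class count, last index); start index vectorized
  cost <- matrix(Inf, k, m)
  back <- matrix(0L, k, m)
  cost[1, ] <- cwx20[-1] - cwx0[-1]^2 / cw0[-1]  # one class covering 1..j
  if (k > 1) {
    for (cl in 2:k) {
      for (j in cl:m) {
        i_vec <- cl:j
        v <- cost[cl - 1, i_vec - 1] + ssd_to(i_vec, j)
        arg <- which.min(v)
        cost[cl, j] <- v[arg]
        back[cl, j] <- i_vec[arg]
      }
    }
  }
  # recover class upper bounds
  bounds <- numeric(k)
  j <- m
  for (cl in k:1) {
    bounds[cl] <- u[j]
    j <- back[cl, j] - 1L
    if (cl == 1) break
  }
  list(breaks = bounds[-k], ssd = cost[k, m], k = k)
}

jenks_assign <- function(x, breaks) {
  cl <- findInterval(x, breaks, left.open = TRUE) + 1L
  cl[is.na(x)] <- NA_integer_
  cl
}
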