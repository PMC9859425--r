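# shared fixtures built in code

toy_grid <- function(values, ...) {
  eco_grid(matrix(values, nrow = sqrt(length(values))), ...)
}

# a full n x n grid with deterministic but irregular values
irregular_grid <- function(n, seed = 1) {
  eco_grid(with_seed_local(seed, matrix(stats::runif(n * n), n, n)))
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# brute-force global Moran's I: explicit double sum over all cell pairs
brute_moran <- function(values, scheme = "rook") {
  m <- values$values
  nr <- nrow(m); nc <- ncol(m)
  cells <- which(!is.na(m))
  x <- m[cells]
  n <- length(x)
  xbar <- mean(x)
  r <- ((cells - 1) %% nr) + 1
  cc <- ((cells - 1) %/% nr) + 1
  num <- 0; S0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dr <- abs(r[i] - r[j]); dc <- abs(cc[i] - cc[j])
      w <- if (scheme == "rook") (dr + dc == 1) else (max(dr, dc) == 1)
      if (w) {
        num <- num + (x[i] - xbar) * (x[j] - xbar)
        S0 <- S0 + 1
      }
    }
  }
  (n / S0) * num / sum((x - xbar)^2)
}

# exhaustive-search Jenks oracle for small vectors: tries every placement of
# k contiguous classes over the sorted values
brute_jenks <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf; best_breaks <- NULL
  splits <- utils::combn(n - 1, k - 1)
  for (s in seq_len(ncol(splits))) {
    cut_after <- splits[, s]
    starts <- c(1, cut_after + 1)
    ends <- c(cut_after, n)
    obj <- sum(vapply(seq_len(k), function(i) ssd(x[starts[i]:ends[i]]),
                      numeric(1)))
    if (obj < best - 1e-12) {
      best <- obj
      best_breaks <- x[cut_after]
    }
  }
  list(breaks = best_breaks, ssd = best)
}

# independent group-by computation of the geodetector variance ratio
brute_q <- function(y, strata) {
  pop_var <- function(v) mean((v - mean(v))^2)
  ssw <- sum(vapply(split(y, strata), function(v) length(v) * pop_var(v),
                    numeric(1)))
  1 - ssw / (length(y) * pop_var(y))
}

table8_path <- function() {
  system.file("extdata", "shenyang_transfer_2020_2025.csv",
              package = "ecovuln")
}
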