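# Independent brute-force oracles used across tests. These deliberately use
# plain double loops and textbook formulas, not the package's vectorized or
# compiled paths.

# prominent contacts by direct two-pass enumeration over strata
oracle_prominent <- function(map) {
  m <- unclass(map)
  n <- nrow(m)
  out <- NULL
  for (s in 2:(n - 1)) {
    vals <- c()
    for (i in 1:(n - s)) vals <- c(vals, m[i, i + s])
    mu <- mean(vals)
    sigma <- sqrt(sum((vals - mu)^2) / length(vals))
    for (i in 1:(n - s)) {
      p <- m[i, i + s]
      hit <- if (sigma == 0) FALSE else p >= mu + sigma
      if (hit) out <- rbind(out, c(i - 1, i + s - 1, p))
    }
  }
  if (is.null(out)) {
    return(data.frame(i = integer(0), j = integer(0), p = numeric(0)))
  }
  out <- as.data.frame(out)
  names(out) <- c("i", "j", "p")
  out[order(out$i, out$j), ]
}

# stratum-adjusted correlation by direct loops (no smoothing fast path)
oracle_scc <- function(a, b, h, max_stratum) {
  n <- nrow(a)
  smooth <- function(m) {
    if (h == 0) return(m)
    out <- m
    for (i in 1:n) {
      for (j in 1:n) {
        ii <- max(1, i - h):min(n, i + h)
        jj <- max(1, j - h):min(n, j + h)
        out[i, j] <- mean(m[ii, jj])
      }
    }
    out
  }
  a <- smooth(unclass(a)); b <- smooth(unclass(b))
  num <- 0; den <- 0
  for (s in 2:min(max_stratum, n - 1)) {
    va <- vb <- c()
    for (i in 1:(n - s)) { va <- c(va, a[i, i + s]); vb <- c(vb, b[i, i + s]) }
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
    w <- length(va) * stats::sd(va) * stats::sd(vb)
    num <- num + w * stats::cor(va, vb)
    den <- den + w
  }
  num / den
}

# contact frequency by direct loops
oracle_contact_map <- function(coords_list, cutoff) {
  n <- nrow(coords_list[[1]])
  m <- matrix(0, n, n)
  for (cfg in coords_list) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (sqrt(sum((cfg[i, ] - cfg[j, ])^2)) < cutoff) {
          m[i, j] <- m[i, j] + 1
          m[j, i] <- m[j, i] + 1
        }
      }
    }
  }
  m <- m / length(coords_list)
  diag(m) <- 1
  m
}

# small random conformation
random_coords <- function(n, seed, spread = 2) {
  withr::with_seed(seed, matrix(stats::rnorm(3 * n, sd = spread), n, 3))
}
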