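#' Stratum-adjusted correlation coefficient between two contact maps
#'
#' HiCRep-style similarity: both maps are optionally smoothed with a 2D mean
#' filter of half-width `h` (a `(2h+1) x (2h+1)` box, truncated at the map
#' edge), the Pearson correlation `rho_s` is computed within each genomic
#' separation stratum `s` in `[2, max_stratum]`, and the strata are combined
#' as `SCC = sum(w_s rho_s) / sum(w_s)` with weights
#' `w_s = N_s * sd_A(s) * sd_B(s)`. Strata with zero variance in either map
#' are skipped.
#'
#' @param map_a,map_b Two [contact_map()]s of equal dimension.
#' @param h Smoothing half-width (0 disables smoothing).
#' @param max_stratum Largest separation included; default
#'   `min(50, n_bins / 3)`.
#' @return A scalar in \[-1, 1\].
#' @export
scc <- function(map_a, map_b, h = 1L, max_stratum = NULL) {
  stopifnot(inherits(map_a, "contact_map"), inherits(map_b, "contact_map"))
  n <- n_bins(map_a)
  if (n != n_bins(map_b)) stop("maps must have equal dimensions", call. = FALSE)
  if (is.null(max_stratum)) max_stratum <- min(50L, n %/% 3L)
  if (max_stratum < 2) stop("max_stratum must be >= 2", call. = FALSE)
  a <- mean_filter_2d(unclass(map_a), h)
  b <- mean_filter_2d(unclass(map_b), h)
  num <- 0; den <- 0; used <- 0L
  for (s in 2:min(max_stratum, n - 1L)) {
    idx <- seq_len(n - s)
    va <- a[cbind(idx, idx + s)]
    vb <- b[cbind(idx, idx + s)]
    sda <- stats::sd(va); sdb <- stats::sd(vb)
    if (!is.finite(sda) || !is.finite(sdb) || sda == 0 || sdb == 0) next
    rho <- stats::cor(va, vb)
    w <- length(va) * sda * sdb
    num <- num + w * rho
    den <- den + w
    used <- used + 1L
  }
  if (used == 0L) stop("all strata skipped (zero variance)", call. = FALSE)
  num / den
}

# 2D mean filter with half-width h, box truncated at the edges.
mean_filter_2d <- function(m, h) {
  h <- as.integer(h)
  if (h <= 0) return(m)
  n <- nrow(m)
  # running sums along rows then columns via cumulative sums
  run_sum <- function(x, h) {
    n <- length(x)
    cs <- c(0, cumsum(x))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  m1 <- t(apply(m, 1L, run_sum, h = h))   # smooth along rows
  apply(m1, 2L, run_sum, h = h)           # then along columns
}

#' Kullback-Leibler divergence between binned distributions
#'
#' `KL(P || Q) = sum P ln(P / Q)` over the common grid, after additive
#' regularization of both distributions with `eps = 1e-10` and
#' renormalization (empty bins are inevitable in sampled histograms).
#'
#' @param p,q Numeric vectors of bin masses or densities on the same grid.
#' @param eps Regularization constant.
#' @return Non-negative scalar.
#' @export
kl_divergence <- function(p, q, eps = 1e-10) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  p <- p + eps; q <- q + eps
  p <- p / sum(p); q <- q / sum(q)
  sum(p * log(p / q))
}

#' Distance distribution of coarse-grained bead pairs
#'
#' Histogram of 3D distances pooled over all (configuration, pair) events of
#' the requested class on the blocked CG trace at scale `n_b`: `"bonded"`
#' pairs are successive CG beads, `"nonbonded"` pairs are separated by at
#' least 2 CG bonds, `"all"` includes every pair. Normalized to unit
#' integral; the range is auto-truncated at the last occupied bin.
#'
#' @param ensemble An [new_ensemble()].
#' @param n_b Beads per CG bead (1 keeps the fine-grained chain).
#' @param pairs Pair class.
#' @param bin_width Histogram bin width in sigma.
#' @return A tibble with columns `r` (bin centre) and `p` (density);
#'   attributes `bin_width` and `breaks`.
#' @export
distance_distribution <- function(ensemble, n_b = 1L,
                                  pairs = c("nonbonded", "bonded", "all"),
                                  bin_width = 0.1) {
  pairs <- match.arg(pairs)
  stopifnot(inherits(ensemble, "ensemble"), bin_width > 0)
  traces <- lapply(ensemble$coords, function(m) {
    suppressWarnings(cg_trace(m, n_b, mode = "blocked"))
  })
  n_cg <- nrow(traces[[1]])
  vals <- unlist(lapply(traces, function(tr) {
    d <- as.matrix(stats::dist(tr))
    sep <- abs(outer(seq_len(n_cg), seq_len(n_cg), "-"))
    keep <- switch(pairs,
                   bonded = sep == 1,
                   nonbonded = sep >= 2,
                   all = sep >= 1)
    d[keep & upper.tri(d)]
  }))
  r_max <- max(vals) + bin_width
  breaks <- seq(0, ceiling(r_max / bin_width) * bin_width, by = bin_width)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  last <- max(which(h$counts > 0))
  out <- tibble::tibble(r = h$mids[seq_len(last)],
                        p = h$density[seq_len(last)])
  attr(out, "bin_width") <- bin_width
  attr(out, "breaks") <- breaks[seq_len(last + 1L)]
  out
}

#' Compare radius-of-gyration distributions of fine- and coarse-grained
#' ensembles
#'
#' The fine-grained chains are reduced to their blocked CG trace at scale
#' `n_b` before measuring, so both sides measure the radius of gyration of
#' the same object (a chain of `floor(N / n_b)` centres).
#'
#' @param fg_ensemble Fine-grained [new_ensemble()].
#' @param cg_ensemble Coarse-grained [new_ensemble()] with `floor(N / n_b)`
#'   beads.
#' @param n_b Coarse-graining scale applied to the fine-grained side.
#' @return A one-row tibble: means, SDs, quartiles of both distributions,
#'   `rel_diff` (relative difference of means) and `cohens_d`.
#' @export
compare_rg_distributions <- function(fg_ensemble, cg_ensemble, n_b) {
  stopifnot(inherits(fg_ensemble, "ensemble"), inherits(cg_ensemble, "ensemble"))
  fg <- vapply(fg_ensemble$coords, function(m) {
    radius_of_gyration(suppressWarnings(cg_trace(m, n_b, mode = "blocked")))
  }, numeric(1))
  cg <- vapply(cg_ensemble$coords, radius_of_gyration, numeric(1))
  qs_fg <- stats::quantile(fg, c(0.25, 0.5, 0.75))
  qs_cg <- stats::quantile(cg, c(0.25, 0.5, 0.75))
  pooled_sd <- sqrt((stats::var(fg) + stats::var(cg)) / 2)
  tibble::tibble(mean_fg = mean(fg), mean_cg = mean(cg),
                 sd_fg = stats::sd(fg), sd_cg = stats::sd(cg),
                 q25_fg = qs_fg[[1]], q50_fg = qs_fg[[2]], q75_fg = qs_fg[[3]],
                 q25_cg = qs_cg[[1]], q50_cg = qs_cg[[2]], q75_cg = qs_cg[[3]],
                 rel_diff = (mean(cg) - mean(fg)) / mean(fg),
                 cohens_d = (mean(cg) - mean(fg)) / pooled_sd)
}
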