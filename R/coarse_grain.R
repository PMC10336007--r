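#' Radius of gyration of a set of points
#'
#' Root-mean-square distance of the points from their centroid, with equal
#' masses.
#'
#' @param coords M x 3 coordinate matrix (or a single 3-vector).
#' @return Non-negative scalar.
#' @export
radius_of_gyration <- function(coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, 1L)
  ctr <- colMeans(coords)
  sqrt(mean(rowSums((coords - matrix(ctr, nrow(coords), 3, byrow = TRUE))^2)))
}

#' Coarse-grained trace of a conformation
#'
#' `"blocked"` mode returns the centroids of consecutive disjoint blocks of
#' `n_b` beads (`floor(N / n_b)` centres; a trailing remainder is dropped
#' with a warning). `"sliding"` mode returns the centroid of every window
#' `[i, i + n_b)` and is used for per-genomic-position profiles.
#'
#' @param coords N x 3 coordinate matrix.
#' @param n_b Beads per coarse-grained bead.
#' @param mode `"blocked"` or `"sliding"`.
#' @return Matrix of CG-bead centres.
#' @export
cg_trace <- function(coords, n_b, mode = c("blocked", "sliding")) {
  mode <- match.arg(mode)
  n <- nrow(coords)
  stopifnot(n_b >= 1)
  if (n < n_b) stop("chain shorter than one window (N < n_b)", call. = FALSE)
  if (n_b == 1L) return(coords)
  if (mode == "blocked") {
    n_cg <- n %/% n_b
    if (n %% n_b != 0L) {
      warning(sprintf("dropping %d trailing bead(s) not filling a block",
                      n %% n_b))
    }
    grp <- rep(seq_len(n_cg), each = n_b)
    used <- seq_len(n_cg * n_b)
    out <- rowsum(coords[used, , drop = FALSE], grp) / n_b
    unname(out)
  } else {
    cs <- apply(rbind(0, coords), 2L, cumsum)
    starts <- seq_len(n - n_b + 1L)
    (cs[starts + n_b, , drop = FALSE] - cs[starts, , drop = FALSE]) / n_b
  }
}

# Sliding-window Rg values of one conformation via cumulative sums: O(N).
window_rg <- function(coords, n_b) {
  n <- nrow(coords)
  stopifnot(n >= n_b, n_b >= 1)
  cs <- apply(rbind(0, coords), 2L, cumsum)
  cs2 <- c(0, cumsum(rowSums(coords^2)))
  starts <- seq_len(n - n_b + 1L)
  sum2 <- cs2[starts + n_b] - cs2[starts]
  ctr2 <- rowSums((cs[starts + n_b, , drop = FALSE] -
                     cs[starts, , drop = FALSE])^2) / n_b^2
  sqrt(pmax(sum2 / n_b - ctr2, 0))
}

#' Radius-of-gyration profile along the chain
#'
#' For each sliding window of `n_b` beads, the ensemble mean and standard
#' deviation of the window radius of gyration.
#'
#' @param ensemble An [new_ensemble()].
#' @param n_b Window size in beads.
#' @return A tibble with columns `start` (0-based bead index of the window
#'   start), `mean`, `sd`, `n`.
#' @export
rg_profile <- function(ensemble, n_b) {
  stopifnot(inherits(ensemble, "ensemble"))
  vals <- vapply(ensemble$coords, window_rg, numeric(n_beads(ensemble) - n_b + 1L),
                 n_b = n_b)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  tibble::tibble(start = seq_len(nrow(vals)) - 1L,
                 mean = rowMeans(vals),
                 sd = apply(vals, 1L, stats::sd),
                 n = ncol(vals))
}

#' Bond lengths, bond angles and dihedrals of a CG trace
#'
#' `cg_bond_lengths` returns Euclidean distances of successive centres.
#' `cg_bond_angles` returns the angle `theta = pi - alpha` in degrees, where
#' `alpha = acos(l_hat_i . l_hat_{i+1})`: a straight chain gives 180 degrees
#' and a complete fold-back 0. `cg_dihedrals` returns the signed dihedral in
#' (-180, 180] degrees via the standard atan2 construction on three
#' successive bond vectors, with the trans (planar zigzag) arrangement at
#' 180 and cis at 0; the convention is right-handed. Angles adjacent to a
#' zero-length bond (coincident centroids of overlapping soft beads) and
#' dihedrals with a collinear triple are dropped with a warning.
#'
#' @param centers Matrix of CG-bead centres from [cg_trace()].
#' @return Numeric vector (lengths in sigma, angles in degrees).
#' @export
cg_bond_lengths <- function(centers) {
  stopifnot(nrow(centers) >= 2)
  bond_lengths(centers)
}

#' @rdname cg_bond_lengths
#' @export
cg_bond_angles <- function(centers) {
  stopifnot(nrow(centers) >= 3)
  b <- diff(centers)
  len <- sqrt(rowSums(b^2))
  n <- nrow(b)
  dotp <- rowSums(b[-n, , drop = FALSE] * b[-1L, , drop = FALSE])
  denom <- len[-n] * len[-1L]
  bad <- denom < 1e-12
  if (any(bad)) {
    warning(sprintf("%d angle(s) undefined (zero-length CG bond); excluded",
                    sum(bad)))
  }
  cosa <- pmin(pmax(dotp[!bad] / denom[!bad], -1), 1)
  180 - acos(cosa) * 180 / pi
}

#' @rdname cg_bond_lengths
#' @export
cg_dihedrals <- function(centers) {
  stopifnot(nrow(centers) >= 4)
  b <- diff(centers)
  n <- nrow(b)
  b1 <- b[seq_len(n - 2L), , drop = FALSE]
  b2 <- b[seq_len(n - 2L) + 1L, , drop = FALSE]
  b3 <- b[seq_len(n - 2L) + 2L, , drop = FALSE]
  cross <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  b2n <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(cross(n1, n2) * b2) / b2n
  bad <- rowSums(n1^2) < 1e-20 | rowSums(n2^2) < 1e-20
  if (any(bad)) {
    warning(sprintf("%d dihedral(s) undefined (collinear bond triple); excluded",
                    sum(bad)))
  }
  # phi = 0 for cis, 180 for trans, sign right-handed; atan2 is in (-180, 180]
  atan2(y[!bad], x[!bad]) * 180 / pi
}

#' Coarse-grained observables of an ensemble
#'
#' Applies the blocked (disjoint) partition at scale `n_b` to every
#' conformation and pools the per-bond / per-angle samples: blocked-window
#' radius of gyration `rg`, CG bond length `l_cg`, bond angle `theta`
#' (degrees) and dihedral `phi` (degrees).
#'
#' @param ensemble An [new_ensemble()].
#' @param n_b Beads per CG bead.
#' @return A tibble with columns `config`, `quantity`, `index`, `value`.
#' @export
cg_observables <- function(ensemble, n_b) {
  stopifnot(inherits(ensemble, "ensemble"))
  rows <- purrr::imap(ensemble$coords, function(m, c) {
    tr <- suppressWarnings(cg_trace(m, n_b, mode = "blocked"))
    n_cg <- nrow(tr)
    grp <- rep(seq_len(n_cg), each = n_b)
    rg <- vapply(seq_len(n_cg), function(k) {
      radius_of_gyration(m[which(grp == k), , drop = FALSE])
    }, numeric(1))
    out <- list(tibble::tibble(config = c, quantity = "rg",
                               index = seq_len(n_cg), value = rg))
    if (n_cg >= 2) {
      l <- cg_bond_lengths(tr)
      out <- c(out, list(tibble::tibble(config = c, quantity = "l_cg",
                                        index = seq_along(l), value = l)))
    }
    if (n_cg >= 3) {
      th <- suppressWarnings(cg_bond_angles(tr))
      out <- c(out, list(tibble::tibble(config = c, quantity = "theta",
                                        index = seq_along(th), value = th)))
    }
    if (n_cg >= 4) {
      ph <- suppressWarnings(cg_dihedrals(tr))
      out <- c(out, list(tibble::tibble(config = c, quantity = "phi",
                                        index = seq_along(ph), value = ph)))
    }
    dplyr::bind_rows(out)
  })
  res <- dplyr::bind_rows(rows)
  attr(res, "n_b") <- n_b
  res
}

#' Overlap parameter of coarse-grained beads
#'
#' `O = 2 <Rg> / <l_cg>`: values above 1 mean neighbouring CG beads
#' interpenetrate (the bond is shorter than the bead diameter `2 Rg`);
#' non-overlapping hard spheres give `O <= 1`.
#'
#' @param mean_rg Mean CG-bead radius of gyration.
#' @param mean_lcg Mean CG bond length (> 0).
#' @return Dimensionless scalar.
#' @export
overlap_parameter <- function(mean_rg, mean_lcg) {
  stopifnot(mean_lcg > 0)
  2 * mean_rg / mean_lcg
}

#' Effective stretching spring constant from bond-length fluctuations
#'
#' `K_cg = kBT / Var(l_cg)` with the population variance (distribution
#' moments, not a sample-corrected estimate). The value in kBT/sigma^2 is
#' returned; the value in kBT/l_cg^2 units (`K * <l_cg>^2`) is attached as
#' attribute `k_lcg2`.
#'
#' @param lengths Sample of CG bond lengths (>= 2 distinct values).
#' @return Spring constant in kBT/sigma^2 with attribute `k_lcg2`.
#' @export
spring_constant <- function(lengths) {
  stopifnot(length(lengths) >= 2)
  v <- mean(lengths^2) - mean(lengths)^2
  if (v <= 0) stop("rigid bond: zero variance of l_cg", call. = FALSE)
  structure(1 / v, k_lcg2 = mean(lengths)^2 / v)
}

#' Bond-angle distribution with sine-measure correction
#'
#' Histogram of angles on \[0, 180\] degrees normalized to unit integral
#' (density per degree), plus the corrected density
#' `P_tilde(theta) = P(theta) / sin(theta)` evaluated with the sine of the
#' bin centre. The two outermost bins are masked (`NA`) in `p_sin` because
#' `sin -> 0` there. For an ideal chain the corrected density is flat.
#'
#' @param angles Angles in degrees.
#' @param n_bins Number of equal-width bins over \[0, 180\].
#' @return A tibble with columns `theta` (bin centre, degrees), `p`
#'   (density per degree) and `p_sin`.
#' @export
angle_distribution <- function(angles, n_bins = 36L) {
  stopifnot(n_bins >= 4)
  breaks <- seq(0, 180, length.out = n_bins + 1L)
  h <- graphics::hist(angles, breaks = breaks, plot = FALSE)
  centers <- h$mids
  p <- h$density
  p_sin <- p / sin(centers * pi / 180)
  p_sin[c(1L, n_bins)] <- NA_real_
  tibble::tibble(theta = centers, p = p, p_sin = p_sin)
}

#' Histogram of dihedral angles
#'
#' @param phi Dihedral angles in degrees, in (-180, 180].
#' @param n_bins Number of equal-width bins over \[-180, 180\].
#' @return A tibble with columns `phi` (bin centre) and `p` (density per
#'   degree).
#' @export
dihedral_distribution <- function(phi, n_bins = 72L) {
  breaks <- seq(-180, 180, length.out = n_bins + 1L)
  h <- graphics::hist(phi, breaks = breaks, plot = FALSE)
  tibble::tibble(phi = h$mids, p = h$density)
}

#' Effective potential from a binned density
#'
#' Boltzmann inversion `V = -ln(density)` in kBT on occupied bins; empty or
#' masked bins are left `NA` (no extrapolation) and the minimum is shifted
#' to zero for reporting. For bond angles pass the sine-corrected density
#' `p_sin`; for bond lengths and dihedrals pass the plain density.
#'
#' @param dist A tibble whose first column is the grid (e.g. from
#'   [angle_distribution()] or [distance_distribution()]).
#' @param density Name of the density column to invert.
#' @return A tibble with the grid column and `v` (kBT, min 0); attribute
#'   `variable` records the grid column name.
#' @export
effective_potential <- function(dist, density = "p") {
  stopifnot(is.data.frame(dist), density %in% names(dist))
  grid_col <- names(dist)[1]
  d <- dist[[density]]
  if (all(is.na(d) | d <= 0)) stop("all bins empty", call. = FALSE)
  v <- ifelse(is.na(d) | d <= 0, NA_real_, -log(d))
  v <- v - min(v, na.rm = TRUE)
  out <- tibble::tibble(!!grid_col := dist[[grid_col]], v = v)
  attr(out, "variable") <- grid_col
  out
}

#' Two-Gaussian deconvolution of an angle distribution
#'
#' Nonlinear least squares of `w N(mu1, s1) + (1 - w) N(mu2, s2)` to the
#' binned density `P(theta)`, with multi-start over five fixed
#' initializations; the component means are ordered `mu1 < mu2` after the
#' fit. A residual norm above `poor_fit_threshold` (relative to the density
#' scale) sets `poor_fit = TRUE`.
#'
#' @param dist Tibble from [angle_distribution()] (columns `theta`, `p`).
#' @param poor_fit_threshold Relative residual norm flag level.
#' @return An object of class `angle_deconvolution` with components
#'   (mean, sd, weight), `residual` (RMS) and `poor_fit`; supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
deconvolute_two_gaussians <- function(dist, poor_fit_threshold = 0.15) {
  stopifnot(all(c("theta", "p") %in% names(dist)))
  d <- dist[!is.na(dist$p), ]
  if (sum(d$p > 0) < 20) stop("need >= 20 occupied bins", call. = FALSE)
  starts <- list(
    c(mu1 = 60, s1 = 10, mu2 = 110, s2 = 25, w = 0.5),
    c(mu1 = 45, s1 = 15, mu2 = 120, s2 = 30, w = 0.4),
    c(mu1 = 70, s1 = 20, mu2 = 130, s2 = 20, w = 0.5),
    c(mu1 = 30, s1 = 12, mu2 = 90, s2 = 35, w = 0.3),
    c(mu1 = 90, s1 = 30, mu2 = 140, s2 = 15, w = 0.6)
  )
  model <- function(par, x) {
    par["w"] * stats::dnorm(x, par["mu1"], par["s1"]) +
      (1 - par["w"]) * stats::dnorm(x, par["mu2"], par["s2"])
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st,
        fn = function(par) model(par, d$theta) - d$p,
        lower = c(0, 1, 0, 1, 0), upper = c(180, 90, 180, 90, 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("two-Gaussian fit failed from all starts", call. = FALSE)
  par <- best$fit$par
  comps <- data.frame(mean = c(par["mu1"], par["mu2"]),
                      sd = c(par["s1"], par["s2"]),
                      weight = c(par["w"], 1 - par["w"]))
  ord <- order(comps$mean)
  comps <- comps[ord, ]
  rownames(comps) <- NULL
  rms <- sqrt(best$rss / nrow(d))
  rel <- rms / max(d$p)
  structure(list(components = comps, residual = rms,
                 poor_fit = rel > poor_fit_threshold),
            class = "angle_deconvolution")
}

#' @export
print.angle_deconvolution <- function(x, ...) {
  cat("<angle_deconvolution>\n")
  print(x$components)
  cat(sprintf("RMS residual %.4g%s\n", x$residual,
              if (x$poor_fit) " (poor fit)" else ""))
  invisible(x)
}

#' Fit a cosine bending potential to an effective angle potential
#'
#' Least squares of `V(theta) = (k_b / 2) (1 + cos(theta - theta0)) + c`
#' over `(k_b, theta0, c)`. The additive offset absorbs the arbitrary zero
#' of a Boltzmann-inverted potential.
#'
#' @param potential Tibble from [effective_potential()] over angles
#'   (columns `theta`, `v`) with at least 10 finite points.
#' @return An object of class `stiffness_fit` with `k_b` (kBT), `theta0`
#'   (degrees), `offset` and `residual` (RMS); supports [generics::tidy()].
#' @export
fit_bending_stiffness <- function(potential) {
  stopifnot(all(c("theta", "v") %in% names(potential)))
  d <- potential[is.finite(potential$v), ]
  if (nrow(d) < 10) stop("need >= 10 finite potential points", call. = FALSE)
  model <- function(par, x) {
    par[1] / 2 * (1 + cos((x - par[2]) * pi / 180)) + par[3]
  }
  starts <- list(c(1, d$theta[which.min(d$v)], 0),
                 c(0.1, 90, mean(d$v)),
                 c(2, 60, 0))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st,
                         fn = function(par) model(par, d$theta) - d$v,
                         lower = c(0, -180, -Inf), upper = c(Inf, 360, Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("stiffness fit failed", call. = FALSE)
  par <- best$fit$par
  theta0 <- ((par[2] %% 360) + 360) %% 360
  if (theta0 > 180) theta0 <- 360 - theta0 # angle range is [0, 180]
  structure(list(k_b = par[1], theta0 = theta0, offset = par[3],
                 residual = sqrt(best$rss / nrow(d))),
            class = "stiffness_fit")
}

#' @export
print.stiffness_fit <- function(x, ...) {
  cat(sprintf("<stiffness_fit> k_b = %.4g kBT, theta0 = %.4g deg (RMS %.3g)\n",
              x$k_b, x$theta0, x$residual))
  invisible(x)
}

#' Additive bond-angle / dihedral energy surface
#'
#' Assuming independent theta and phi distributions, the joint effective
#' potential is the outer sum `V(theta, phi) = V(theta) + V(phi)` on the
#' tensor grid; cells where either factor is masked stay `NA`.
#'
#' @param v_theta Tibble (`theta`, `v`) from [effective_potential()].
#' @param v_phi Tibble (`phi`, `v`).
#' @return A tibble with columns `theta`, `phi`, `v`.
#' @export
angle_dihedral_energy_map <- function(v_theta, v_phi) {
  stopifnot(all(c("theta", "v") %in% names(v_theta)),
            all(c("phi", "v") %in% names(v_phi)))
  grid <- tidyr::expand_grid(theta = v_theta$theta, phi = v_phi$phi)
  grid$v <- v_theta$v[match(grid$theta, v_theta$theta)] +
    v_phi$v[match(grid$phi, v_phi$phi)]
  grid
}

#' Overlap fraction among non-bonded coarse-grained beads
#'
#' Fraction of (configuration, pair) events in which two CG-bead centres at
#' contour separation of at least 2 CG bonds are closer than `l_cg_ref`.
#'
#' @param ensemble An [new_ensemble()].
#' @param n_b Beads per CG bead (blocked partition).
#' @param l_cg_ref Reference length, typically the mean CG bond length.
#' @return A list with `aggregate` (overall fraction) and `per_pair`
#'   (tibble `i`, `j`, `fraction` over CG-bead indices, 0-based).
#' @export
nonbonded_overlap_fraction <- function(ensemble, n_b, l_cg_ref) {
  stopifnot(inherits(ensemble, "ensemble"), l_cg_ref > 0)
  traces <- lapply(ensemble$coords, function(m) {
    suppressWarnings(cg_trace(m, n_b, mode = "blocked"))
  })
  n_cg <- nrow(traces[[1]])
  if (n_cg < 3) stop("need at least 3 CG beads", call. = FALSE)
  counts <- contact_count_cpp(traces, l_cg_ref)
  ij <- which(upper.tri(counts), arr.ind = TRUE)
  sep_ok <- (ij[, 2] - ij[, 1]) >= 2
  ij <- ij[sep_ok, , drop = FALSE]
  frac <- counts[ij] / length(traces)
  list(aggregate = mean(frac),
       per_pair = tibble::tibble(i = ij[, 1] - 1L, j = ij[, 2] - 1L,
                                 fraction = frac))
}
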