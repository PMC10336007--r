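#' Tabulated pair potential
#'
#' A potential energy on a strictly increasing distance grid (sigma or
#' CG-bond-length units), zero at and beyond the cutoff. Used as the carrier
#' for iterative Boltzmann inversion iterates and for the `"tabulated"` pair
#' term of [force_field()] (cubic Hermite interpolation).
#'
#' @param r Strictly increasing grid.
#' @param v Potential values in kBT (finite).
#' @param cutoff Distance beyond which V = 0; defaults to the last grid
#'   point. Values at grid points past the cutoff are forced to zero.
#' @return An object of class `tabulated_potential`.
#' @export
tabulated_potential <- function(r, v, cutoff = max(r)) {
  stopifnot(length(r) == length(v), length(r) >= 2, all(diff(r) > 0),
            all(is.finite(v)))
  v[r >= cutoff] <- 0
  structure(list(r = r, v = v, cutoff = cutoff),
            class = "tabulated_potential")
}

#' @export
print.tabulated_potential <- function(x, ...) {
  cat(sprintf("<tabulated_potential> %d points on [%.3g, %.3g], cutoff %.3g\n",
              length(x$r), min(x$r), max(x$r), x$cutoff))
  invisible(x)
}

#' Write / read a tabulated potential as two-column TSV
#'
#' Columns `r_sigma` and `V_kBT`.
#'
#' @param potential A [tabulated_potential()].
#' @param path File path.
#' @return `path` invisibly; the reader returns a `tabulated_potential`.
#' @export
write_potential_tsv <- function(potential, path) {
  stopifnot(inherits(potential, "tabulated_potential"))
  utils::write.table(data.frame(r_sigma = potential$r, V_kBT = potential$v),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_potential_tsv
#' @export
read_potential_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  tabulated_potential(d$r_sigma, d$V_kBT)
}

#' One iterative Boltzmann inversion update
#'
#' `V'(r) = V(r) + alpha(r) kBT ln(P_i(r) / P_target(r))` with the damped,
#' short-range prefactor `alpha(r) = a exp(-r^2 / 2)`. Bins where either
#' distribution falls below `floor` leave the potential unchanged (no
#' extrapolation into unsampled regions). After the update the potential is
#' optionally smoothed with a 3-point moving average, reset to zero beyond
#' the cutoff, and shifted so that `V(cutoff) = 0`.
#'
#' @param potential Current [tabulated_potential()].
#' @param p_current,p_target Densities on the potential's grid.
#' @param prefactor Update amplitude `a`.
#' @param floor Regularization floor below which a bin is skipped.
#' @param smooth Apply the 3-point moving average.
#' @return The updated [tabulated_potential()].
#' @export
ibi_update <- function(potential, p_current, p_target, prefactor = 0.2,
                       floor = 1e-8, smooth = TRUE) {
  stopifnot(inherits(potential, "tabulated_potential"),
            length(p_current) == length(potential$r),
            length(p_target) == length(potential$r))
  r <- potential$r
  v <- potential$v
  ok <- p_current > floor & p_target > floor
  alpha <- prefactor * exp(-r^2 / 2)
  v[ok] <- v[ok] + alpha[ok] * log(p_current[ok] / p_target[ok])
  if (smooth) v <- smooth3(v)
  cut_idx <- which(r >= potential$cutoff)
  anchor <- if (length(cut_idx)) min(cut_idx) else length(r)
  v <- v - v[anchor]
  v[r >= potential$cutoff] <- 0
  tabulated_potential(r, v, cutoff = potential$cutoff)
}

smooth3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  out <- v
  out[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
  out
}

#' Coarse-grained polymer specification
#'
#' A bead-spring chain of `n_beads` CG beads with harmonic bonds whose rest
#' length and stiffness come from CG measurements (`l_cg`, `K_cg`), plus a
#' non-bonded term (tabulated or parametric soft form). Distances are
#' expressed in units of `l_cg` (so `bond_r0 = 1` by default) and energies
#' in kBT.
#'
#' @param n_beads Number of CG beads.
#' @param bond_r0 Harmonic bond rest length (l_cg units).
#' @param bond_k Harmonic bond stiffness (kBT / l_cg^2).
#' @param nonbonded A [tabulated_potential()], a [soft_potential()], or
#'   `NULL` for no non-bonded term.
#' @return A list of class `cg_polymer_spec`.
#' @export
cg_polymer_spec <- function(n_beads, bond_r0 = 1, bond_k = 7.5,
                            nonbonded = NULL) {
  stopifnot(n_beads >= 2, bond_r0 > 0, bond_k > 0)
  if (!is.null(nonbonded)) {
    stopifnot(inherits(nonbonded, "tabulated_potential") ||
                inherits(nonbonded, "soft_potential"))
  }
  structure(list(n_beads = as.integer(n_beads), bond_r0 = bond_r0,
                 bond_k = bond_k, nonbonded = nonbonded),
            class = "cg_polymer_spec")
}

# Force field for a CG chain with the given non-bonded tabulated term.
cg_force_field <- function(spec, tab = NULL) {
  if (is.null(tab)) {
    force_field(chain_k = spec$bond_k, chain_r0 = spec$bond_r0, pair = "none")
  } else {
    force_field(chain_k = spec$bond_k, chain_r0 = spec$bond_r0,
                pair = "tabulated", tabulated = tab)
  }
}

# Simulate a CG chain and return the non-bonded distance density on `breaks`.
sample_cg_distance_density <- function(spec, tab, n_chains, n_steps,
                                       samples_per_chain, dt, seed, breaks) {
  ff <- cg_force_field(spec, tab)
  samples <- list()
  for (c in seq_len(n_chains)) {
    chain_seed <- derive_seed(seed, c)
    init <- init_chain(spec$n_beads, seed = chain_seed, method = "saw")
    sample_every <- max(1L, n_steps %/% (2L * samples_per_chain + 2L))
    traj <- run_langevin(init, ff,
                         langevin_params(dt = dt, n_steps = n_steps,
                                         sample_every = sample_every,
                                         seed = chain_seed))
    keep <- traj$samples
    if (length(keep) > samples_per_chain) {
      keep <- keep[seq.int(length(keep) - samples_per_chain + 1L, length(keep))]
    }
    samples <- c(samples, keep)
  }
  counts <- pair_distance_hist_cpp(samples, 2L, breaks)
  dens <- counts / (sum(counts) * diff(breaks))
  list(density = dens, ensemble = new_ensemble(samples))
}

#' Iterative Boltzmann inversion of a non-bonded pair potential
#'
#' Starting from a flat potential `V = 0`, each iteration simulates the CG
#' bead-spring chain with the current tabulated non-bonded term, measures
#' the steady-state distance distribution `P_i(r)` over non-bonded pairs
#' (contour separation >= 2), applies [ibi_update()], and evaluates
#' convergence as `KL(P_target || P_i)`. The iterate with the best KL is
#' returned (the running minimum of the KL history is non-increasing by
#' construction).
#'
#' @param target Tibble (`r`, `p`) of the target non-bonded distance
#'   density, e.g. from [distance_distribution()]; it is re-binned onto the
#'   IBI grid.
#' @param spec A [cg_polymer_spec()].
#' @param grid Distance grid for the potential (bin centres).
#' @param max_iter Maximum iterations.
#' @param kl_tol Convergence tolerance on the KL divergence.
#' @param prefactor,smooth Passed to [ibi_update()].
#' @param n_chains,n_steps,samples_per_chain,dt Simulation effort per
#'   iteration.
#' @param seed Master seed (iteration streams derive from it).
#' @return An object of class `ibi_result`: `potential` (best iterate),
#'   `history` (tibble `iteration`, `kl`), `best_iteration`, `converged`,
#'   and the final sampled density `p_final`. Supports [generics::tidy()]
#'   and [generics::glance()].
#' @export
run_ibi <- function(target, spec, grid = seq(0.05, 3, by = 0.05),
                    max_iter = 30L, kl_tol = 0.01, prefactor = 0.2,
                    smooth = TRUE, n_chains = 8L, n_steps = 6000L,
                    samples_per_chain = 10L, dt = 0.01, seed = 1L) {
  stopifnot(inherits(spec, "cg_polymer_spec"), all(c("r", "p") %in% names(target)))
  dr <- grid[2] - grid[1]
  breaks <- c(grid - dr / 2, max(grid) + dr / 2)
  p_target <- rebin_density(target, grid)

  pot <- tabulated_potential(grid, rep(0, length(grid)))
  best <- NULL
  hist_iter <- integer(0); hist_kl <- numeric(0)
  p_final <- NULL
  for (it in seq_len(max_iter + 1L) - 1L) { # iteration 0 = flat potential
    sim <- sample_cg_distance_density(spec, pot, n_chains, n_steps,
                                      samples_per_chain, dt,
                                      derive_seed(seed, it + 1L), breaks)
    kl <- kl_divergence(p_target * dr, sim$density * dr)
    hist_iter <- c(hist_iter, it)
    hist_kl <- c(hist_kl, kl)
    if (is.null(best) || kl < best$kl) {
      best <- list(kl = kl, potential = pot, iteration = it,
                   density = sim$density)
    }
    if (kl < kl_tol || it == max_iter) { p_final <- sim$density; break }
    pot <- ibi_update(pot, sim$density, p_target, prefactor = prefactor,
                      smooth = smooth)
  }
  structure(list(potential = best$potential,
                 history = tibble::tibble(iteration = hist_iter, kl = hist_kl),
                 best_iteration = best$iteration,
                 best_kl = best$kl,
                 converged = best$kl < kl_tol,
                 p_target = p_target, p_final = best$density, grid = grid),
            class = "ibi_result")
}

# Re-bin a (r, p) density onto new bin centres by interpolation, then
# renormalize on the new grid.
rebin_density <- function(target, grid) {
  dr <- grid[2] - grid[1]
  p <- stats::approx(target$r, target$p, xout = grid, yleft = 0, yright = 0,
                     rule = 2)$y
  p[!is.finite(p) | p < 0] <- 0
  p / (sum(p) * dr)
}

#' @export
print.ibi_result <- function(x, ...) {
  cat(sprintf("<ibi_result> %d iterations, best KL %.4g at iteration %d%s\n",
              nrow(x$history), x$best_kl, x$best_iteration,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Parametric soft pair potential
#'
#' A bounded soft-core form with independently tunable softness and depth:
#' \deqn{V(r) = V_0 [1 - (r/r_m)^{\eta_1}]^{\eta_2} - \epsilon, \quad r < r_m}
#' \deqn{V(r) = (\epsilon/2) [\cos(\mu r^2 + \nu) - 1], \quad r_m \le r < r_c}
#' \deqn{V(r) = 0, \quad r \ge r_c.}
#' `V0` controls the height at the origin (where V(0) = V0 - eps), `r_m` is the
#' position of the minimum with depth `eps`, and `eta1`, `eta2` tune the
#' softness of the repulsive core. The phase parameters `mu`, `nu` are
#' solved by [solve_attractive_phase()] so the attractive branch meets
#' `-eps` at `r_m` and 0 at `r_c` with zero slope at both ends
#' (C1-continuous for `eta2 > 1`).
#'
#' @param v0 Repulsive height scale (kBT).
#' @param r_m Position of the minimum (sigma).
#' @param epsilon Depth of the minimum (kBT, >= 0).
#' @param eta1,eta2 Shape exponents (> 0; `eta2 >= 1` gives zero slope at
#'   `r_m` from the repulsive side).
#' @param r_c Cutoff (> `r_m`).
#' @return An object of class `soft_potential`.
#' @export
soft_potential <- function(v0, r_m, epsilon, eta1 = 2, eta2 = 2, r_c) {
  stopifnot(v0 >= 0, r_m > 0, epsilon >= 0, eta1 > 0, eta2 > 0, r_c > r_m)
  phase <- solve_attractive_phase(r_m, r_c)
  structure(list(v0 = v0, r_m = r_m, epsilon = epsilon, eta1 = eta1,
                 eta2 = eta2, mu = phase[["mu"]], nu = phase[["nu"]],
                 r_c = r_c),
            class = "soft_potential")
}

#' @export
print.soft_potential <- function(x, ...) {
  cat(sprintf(paste0("<soft_potential> V0 = %.4g, r_m = %.4g, eps = %.4g, ",
                     "eta1 = %.3g, eta2 = %.3g, r_c = %.4g\n"),
              x$v0, x$r_m, x$epsilon, x$eta1, x$eta2, x$r_c))
  invisible(x)
}

#' Solve the attractive-branch phase parameters
#'
#' Returns `mu = pi / (r_c^2 - r_m^2)` and `nu = pi - mu r_m^2`, the unique
#' solution for which `cos(mu r_m^2 + nu) = -1` (value `-eps` at the
#' minimum) and `cos(mu r_c^2 + nu) = 1` (value 0 at the cutoff); the cosine
#' argument passes through multiples of pi at both ends, so the branch also
#' has zero slope there.
#'
#' @param r_m Position of the minimum (0 < `r_m` < `r_c`).
#' @param r_c Cutoff.
#' @return Named numeric vector `c(mu, nu)`.
#' @export
solve_attractive_phase <- function(r_m, r_c) {
  if (!(r_m > 0 && r_c > r_m)) stop("need 0 < r_m < r_c", call. = FALSE)
  mu <- pi / (r_c^2 - r_m^2)
  c(mu = mu, nu = pi - mu * r_m^2)
}

#' Evaluate the soft potential
#'
#' @param params A [soft_potential()].
#' @param r Distances (vectorized).
#' @return Potential values in kBT.
#' @export
soft_potential_eval <- function(params, r) {
  stopifnot(inherits(params, "soft_potential"))
  v <- numeric(length(r))
  rep_reg <- r < params$r_m
  att <- r >= params$r_m & r < params$r_c
  v[rep_reg] <- params$v0 *
    (1 - (r[rep_reg] / params$r_m)^params$eta1)^params$eta2 - params$epsilon
  v[att] <- params$epsilon / 2 *
    (cos(params$mu * r[att]^2 + params$nu) - 1)
  v
}

#' Tabulate a soft potential on a grid
#'
#' @param params A [soft_potential()].
#' @param grid Distance grid.
#' @return A [tabulated_potential()] with cutoff `r_c`.
#' @export
tabulate_soft_potential <- function(params, grid = seq(0.05, 3, by = 0.05)) {
  tabulated_potential(grid, soft_potential_eval(params, grid),
                      cutoff = params$r_c)
}

#' Fit the parametric soft form to a tabulated potential
#'
#' `r_m` is taken from the tabulated argmin and `eps` from the tabulated
#' depth; `r_c` is the first zero crossing beyond `r_m` (linear
#' interpolation); `mu`, `nu` follow from [solve_attractive_phase()]; and
#' `V0`, `eta1`, `eta2` are fit by least squares on the repulsive branch
#' with `eta2 >= 1` enforced. A purely repulsive table (no negative values)
#' yields `eps = 0` and `r_c` at the first zero of the repulsive branch.
#'
#' @param tab A [tabulated_potential()] with an interior minimum.
#' @return An object of class `soft_potential_fit`: element `params` (a
#'   [soft_potential()]) and `residual` (RMS on the repulsive branch).
#'   Supports [generics::tidy()] and [generics::glance()].
#' @export
fit_soft_potential <- function(tab) {
  stopifnot(inherits(tab, "tabulated_potential"))
  r <- tab$r; v <- tab$v
  imin <- which.min(v)
  if (imin <= 1 || imin >= length(r)) {
    stop("tabulated potential has no interior minimum", call. = FALSE)
  }
  vmin <- v[imin]
  if (vmin < 0) {
    r_m <- r[imin]
    epsilon <- -vmin
    # first zero crossing (from below) beyond the minimum
    after <- seq(imin, length(r))
    cross <- after[which(v[after] < 0 & c(v[after[-1]], 0) >= 0)[1]]
    if (is.na(cross) || cross >= length(r)) {
      r_c <- tab$cutoff
    } else {
      r1 <- r[cross]; r2 <- r[cross + 1L]
      v1 <- v[cross]; v2 <- v[cross + 1L]
      r_c <- if (v2 == v1) r2 else r1 + (0 - v1) * (r2 - r1) / (v2 - v1)
    }
  } else {
    # purely repulsive: depth 0, cutoff at first (near-)zero of the branch
    epsilon <- 0
    below <- which(v <= 1e-10)
    r_c <- if (length(below)) r[min(below)] else tab$cutoff
    r_m <- r_c * (1 - 1e-6) # degenerate minimum collapses onto the cutoff
  }

  rep_idx <- which(r < r_m & is.finite(v))
  if (length(rep_idx) < 3) stop("too few repulsive-branch points", call. = FALSE)
  rr <- r[rep_idx]; vv <- v[rep_idx]
  model <- function(par) {
    base <- 1 - (rr / r_m)^par[2]
    par[1] * sign(base) * abs(base)^par[3] - epsilon - vv
  }
  start <- c(max(vv) + epsilon, 2, 2)
  fit <- minpack.lm::nls.lm(par = start, fn = model,
                            lower = c(1e-8, 1e-2, 1), upper = c(Inf, 50, 50),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  par <- fit$par
  params <- soft_potential(v0 = par[1], r_m = r_m, epsilon = epsilon,
                           eta1 = par[2], eta2 = par[3], r_c = r_c)
  structure(list(params = params,
                 residual = sqrt(mean(fit$fvec^2))),
            class = "soft_potential_fit")
}

#' @export
print.soft_potential_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("repulsive-branch RMS residual %.4g kBT\n", x$residual))
  invisible(x)
}

#' Softness and depth of a pair potential
#'
#' The force is `F(r) = -dV/dr`; its maximum over the repulsive region
#' (`r` below the minimum) is `F_max`, and `1 / F_max` measures how soft the
#' beads are (an infinitely hard core has softness 0). The depth `eps` is
#' the magnitude of the potential minimum.
#'
#' @param x A [soft_potential()] or [tabulated_potential()].
#' @param n_grid Evaluation grid size for the numerical derivative.
#' @return A tibble with columns `softness` (`1 / F_max`), `f_max` and
#'   `depth`.
#' @export
softness_and_depth <- function(x, n_grid = 2000L) {
  if (inherits(x, "soft_potential")) {
    grid <- seq(1e-4, x$r_c, length.out = n_grid)
    v <- soft_potential_eval(x, grid)
    depth <- x$epsilon
    r_min <- x$r_m
  } else if (inherits(x, "tabulated_potential")) {
    grid <- seq(min(x$r), max(x$r), length.out = n_grid)
    v <- stats::approx(x$r, x$v, xout = grid)$y
    depth <- max(0, -min(x$v))
    r_min <- grid[which.min(v)]
  } else {
    stop("x must be a soft_potential or tabulated_potential", call. = FALSE)
  }
  f <- -diff(v) / diff(grid)
  mids <- (grid[-1] + grid[-length(grid)]) / 2
  f_rep <- f[mids <= r_min]
  f_max <- max(f_rep)
  if (!is.finite(f_max) || f_max <= 0) {
    stop("no repulsive force found (F_max <= 0)", call. = FALSE)
  }
  tibble::tibble(softness = 1 / f_max, f_max = f_max, depth = depth)
}

#' Simulate a coarse-grained chain with the soft non-bonded potential
#'
#' Langevin sampling of the CG bead-spring chain defined by `spec`
#' (harmonic bonds at `l_cg`, `K_cg`) with its non-bonded term (parametric
#' soft form or tabulated). Output feeds [compare_rg_distributions()].
#'
#' @param spec A [cg_polymer_spec()].
#' @param n_samples Pooled conformations to return.
#' @param n_steps,samples_per_chain,dt Simulation effort.
#' @param seed Master seed.
#' @return An [new_ensemble()].
#' @export
simulate_cg_with_soft_potential <- function(spec, n_samples = 100L,
                                            n_steps = 8000L,
                                            samples_per_chain = 10L,
                                            dt = 0.01, seed = 1L) {
  stopifnot(inherits(spec, "cg_polymer_spec"))
  tab <- spec$nonbonded
  if (inherits(tab, "soft_potential")) tab <- tabulate_soft_potential(tab)
  ff <- cg_force_field(spec, tab)
  n_chains <- ceiling(n_samples / samples_per_chain)
  out <- list()
  for (c in seq_len(n_chains)) {
    chain_seed <- derive_seed(seed, c)
    init <- init_chain(spec$n_beads, seed = chain_seed, method = "saw")
    sample_every <- max(1L, n_steps %/% (2L * samples_per_chain + 2L))
    traj <- run_langevin(init, ff,
                         langevin_params(dt = dt, n_steps = n_steps,
                                         sample_every = sample_every,
                                         seed = chain_seed))
    keep <- traj$samples
    if (length(keep) > samples_per_chain) {
      keep <- keep[seq.int(length(keep) - samples_per_chain + 1L, length(keep))]
    }
    out <- c(out, keep)
  }
  if (length(out) > n_samples) out <- out[seq_len(n_samples)]
  new_ensemble(out, provenance = list(kind = "cg-soft", spec = spec,
                                      seed = seed))
}
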