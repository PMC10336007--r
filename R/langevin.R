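#' Langevin integrator parameters
#'
#' BAOAB discretization of Langevin dynamics with unit bead mass, in reduced
#' units. A warning is emitted when `dt` exceeds a tenth of the fastest bond
#' period, `dt > 0.1 / sqrt(k_max)`.
#'
#' @param dt Time step (reduced units).
#' @param friction Friction coefficient (1/time).
#' @param temperature Thermal energy kBT (default 1; 0 gives damped descent).
#' @param n_steps Number of integration steps.
#' @param sample_every Record a sample every this many steps.
#' @param seed Integer seed; trajectories are bitwise reproducible given the
#'   seed.
#' @return A list of class `langevin_params`.
#' @export
langevin_params <- function(dt = 0.005, friction = 1, temperature = 1,
                            n_steps = 10000L, sample_every = 100L, seed = 1L) {
  stopifnot(dt > 0, friction > 0, temperature >= 0, n_steps >= 1,
            sample_every >= 1)
  structure(list(dt = dt, friction = friction, temperature = temperature,
                 n_steps = as.integer(n_steps),
                 sample_every = as.integer(sample_every),
                 seed = as.integer(seed)),
            class = "langevin_params")
}

#' Run Langevin dynamics on a bead-spring chain
#'
#' Integrates the chain with the BAOAB scheme and records conformations,
#' radius of gyration and energies every `sample_every` steps. When
#' `burn_in = "auto"` the burn-in is located on the recorded Rg series with
#' [detect_equilibration()] and the returned samples start after it.
#'
#' @param coords Initial N x 3 coordinates.
#' @param ff A [force_field()].
#' @param params A [langevin_params()].
#' @param burn_in `"auto"`, or an integer number of recorded samples to
#'   discard, or `0` to keep everything.
#' @return A list of class `langevin_trajectory` with elements `samples`
#'   (list of N x 3 matrices after burn-in), `rg`, `epot`, `ekin` (full
#'   recorded series), `burn_in` (samples discarded), `equilibrated`
#'   (logical), and `n_capped`.
#' @export
run_langevin <- function(coords, ff, params, burn_in = "auto") {
  stopifnot(is.matrix(coords), ncol(coords) == 3, nrow(coords) >= 2,
            inherits(ff, "force_field"), inherits(params, "langevin_params"))
  a <- ff_engine_args(ff, nrow(coords))
  k_max <- max(ff$chain_k,
               if (!is.null(ff$constraint_bonds) &&
                   nrow(ff$constraint_bonds) > 0) ff$constraint_k else 0)
  if (params$dt > 0.1 / sqrt(k_max)) {
    warning(sprintf("dt = %.4g exceeds stability margin 0.1/sqrt(k_max) = %.4g",
                    params$dt, 0.1 / sqrt(k_max)))
  }
  res <- run_langevin_cpp(coords, a$chain_k, a$chain_r0, a$cbonds, a$cbond_k,
                          a$cbond_r0, a$pair_type, a$pair_eps, a$pair_sigma,
                          a$pair_rcut, a$tab_r, a$tab_v, a$tab_m,
                          params$dt, params$friction, params$temperature,
                          params$n_steps, params$sample_every, params$seed)
  n_rec <- length(res$rg)
  equilibrated <- TRUE
  if (identical(burn_in, "auto")) {
    window <- max(2L, n_rec %/% 10L)
    if (n_rec >= 2L * window) {
      bi <- detect_equilibration(res$rg, window)
      equilibrated <- attr(bi, "equilibrated")
      burn_in <- min(bi, n_rec - 1L)
    } else {
      burn_in <- 0L
    }
  }
  burn_in <- as.integer(burn_in)
  keep <- seq.int(burn_in + 1L, n_rec)
  n <- nrow(coords)
  samples <- lapply(keep, function(k) {
    matrix(res$samples[k + n_rec * (seq_len(n) - 1L + n * rep(0:2, each = n))],
           n, 3)
  })
  structure(list(samples = samples, rg = res$rg, epot = res$epot,
                 ekin = res$ekin, burn_in = burn_in,
                 equilibrated = equilibrated, n_capped = res$n_capped,
                 params = params),
            class = "langevin_trajectory")
}

#' Locate the burn-in of a scalar time series
#'
#' Splits the series into consecutive windows and returns the number of
#' leading samples to discard: the start of the first window whose mean
#' differs from the next window's mean by less than 2 percent (relative to
#' the current window mean). A constant series needs no burn-in (0); a series
#' that never stabilizes returns its full length with attribute
#' `equilibrated = FALSE`.
#'
#' @param series Numeric series (e.g. recorded Rg values).
#' @param window Window length; the series must be at least twice as long.
#' @param tol Relative change threshold between consecutive window means.
#' @return Integer number of samples to discard, with attribute
#'   `equilibrated`.
#' @export
detect_equilibration <- function(series, window, tol = 0.02) {
  stopifnot(window >= 1, length(series) >= 2 * window)
  n_win <- length(series) %/% window
  means <- vapply(seq_len(n_win), function(k) {
    mean(series[((k - 1L) * window + 1L):(k * window)])
  }, numeric(1))
  for (k in seq_len(n_win - 1L)) {
    ref <- max(abs(means[k]), .Machine$double.eps)
    if (abs(means[k + 1L] - means[k]) < tol * ref) {
      return(structure((k - 1L) * window, equilibrated = TRUE))
    }
  }
  structure(length(series), equilibrated = FALSE)
}

#' Initial chain configurations
#'
#' `"saw"` grows a random walk with unit steps, retrying any step that lands
#' within 0.8 sigma of a previous bead and falling back to a compact
#' serpentine lattice layout after 1000 failed retries; `"serpentine"` places
#' beads directly along a space-filling serpentine path on a unit cubic
#' lattice (a compact, bond-respecting start used for collapsed chains).
#'
#' @param n_beads Number of beads.
#' @param seed Integer seed.
#' @param method `"saw"` or `"serpentine"`.
#' @return N x 3 coordinate matrix.
#' @export
init_chain <- function(n_beads, seed = 1L, method = c("saw", "serpentine")) {
  method <- match.arg(method)
  stopifnot(n_beads >= 2)
  if (method == "serpentine") return(serpentine_coords(n_beads))
  withr::with_seed(seed, {
    x <- matrix(0, n_beads, 3)
    for (i in 2:n_beads) {
      placed <- FALSE
      for (try in seq_len(1000L)) {
        step <- stats::rnorm(3)
        step <- step / sqrt(sum(step^2))
        cand <- x[i - 1L, ] + step
        d2 <- rowSums((x[seq_len(i - 1L), , drop = FALSE] -
                         matrix(cand, i - 1L, 3, byrow = TRUE))^2)
        if (all(d2 > 0.64)) { x[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) return(serpentine_coords(n_beads))
    }
    x
  })
}

# Compact serpentine path on a unit cubic lattice, roughly cubical overall.
serpentine_coords <- function(n_beads) {
  side <- ceiling(n_beads^(1 / 3))
  x <- matrix(0, n_beads, 3)
  for (k in seq_len(n_beads)) {
    i <- (k - 1L) %% side
    j <- ((k - 1L) %/% side) %% side
    l <- (k - 1L) %/% (side * side)
    ii <- if (j %% 2L == 0L) i else side - 1L - i
    jj <- if (l %% 2L == 0L) j else side - 1L - j
    x[k, ] <- c(ii, jj, l)
  }
  x
}

#' Generate an equilibrated control ensemble
#'
#' The self-avoiding walk (`"saw"`) control is a chain with harmonic bonds
#' and the purely repulsive WCA pair term (`eps = 1`, `sigma_p = 1`); the
#' collapsed globule (`"globule"`) uses the attractive Lennard-Jones term at
#' `eps = 1` kBT with cutoff 2.5 sigma and starts from a compact serpentine
#' layout. Independent chains are run with per-chain seeds derived from
#' `seed`; each chain's burn-in is located with [detect_equilibration()] and
#' the post-burn-in samples are pooled. Chains that never equilibrate or
#' whose bonds stretch beyond `3 * chain_r0` are dropped with a warning.
#'
#' @param kind `"saw"` or `"globule"`.
#' @param n_beads Beads per chain (>= 50 for meaningful statistics).
#' @param n_samples Target number of pooled conformations.
#' @param n_steps Integration steps per chain.
#' @param samples_per_chain Post-burn-in samples kept per chain.
#' @param dt,friction Integrator settings.
#' @param seed Master seed.
#' @return An [new_ensemble()] with provenance.
#' @export
make_control_ensemble <- function(kind = c("saw", "globule"), n_beads = 300L,
                                  n_samples = 100L, n_steps = 30000L,
                                  samples_per_chain = 5L, dt = 0.005,
                                  friction = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (n_beads < 50) stop("need n_beads >= 50 for meaningful statistics",
                         call. = FALSE)
  ff <- switch(kind,
               saw = force_field(pair = "wca", pair_eps = 1, pair_sigma = 1),
               globule = force_field(pair = "lj", pair_eps = 1,
                                     pair_sigma = 1, pair_rcut = 2.5))
  n_chains <- ceiling(n_samples / samples_per_chain)
  # sample spacing: half the run reserved for burn-in headroom
  sample_every <- max(1L, n_steps %/% (2L * samples_per_chain + 2L))
  coords_out <- list()
  dropped <- 0L
  for (c in seq_len(n_chains)) {
    chain_seed <- derive_seed(seed, c)
    init <- init_chain(n_beads, seed = chain_seed,
                       method = if (kind == "saw") "saw" else "serpentine")
    traj <- run_langevin(init, ff,
                         langevin_params(dt = dt, friction = friction,
                                         n_steps = n_steps,
                                         sample_every = sample_every,
                                         seed = chain_seed))
    keep <- traj$samples
    if (length(keep) > samples_per_chain) {
      keep <- keep[seq.int(length(keep) - samples_per_chain + 1L, length(keep))]
    }
    ok <- traj$equilibrated &&
      all(vapply(keep, function(m) max(bond_lengths(m)) < 3 * ff$chain_r0,
                 logical(1)))
    if (!ok) { dropped <- dropped + 1L; next }
    coords_out <- c(coords_out, keep)
  }
  if (dropped > 0) {
    warning(sprintf("%d chain(s) dropped (not equilibrated or broken bonds)",
                    dropped))
  }
  if (!length(coords_out)) stop("no equilibrated chains produced", call. = FALSE)
  if (length(coords_out) > n_samples) coords_out <- coords_out[seq_len(n_samples)]
  new_ensemble(coords_out,
               provenance = list(kind = kind, n_beads = n_beads,
                                 n_steps = n_steps, dt = dt,
                                 friction = friction, seed = seed,
                                 force_field = ff))
}

bond_lengths <- function(coords) {
  d <- diff(coords)
  sqrt(rowSums(d^2))
}

# Deterministic per-stage/per-chain seed stream below 2^31.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 69621) %%
               2147483647)
}
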