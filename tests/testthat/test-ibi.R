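test_that("the IBI update has the stated fixed point and magnitude", {
  grid <- seq(0.2, 3, by = 0.2)
  pot <- tabulated_potential(grid, 0.5 * exp(-grid))
  p <- stats::dnorm(grid, 1.5, 0.5)
  same <- ibi_update(pot, p, p, smooth = FALSE)
  expect_equal(same$v, pot$v, tolerance = 1e-12) # ln(1) = 0 everywhere

  # flat potential, ratio e at r = 1: update is 0.2 exp(-1/2) ~ 0.1213
  grid2 <- seq(0.25, 3, by = 0.25)
  flat <- tabulated_potential(grid2, rep(0, length(grid2)))
  p_t <- rep(0.1, length(grid2))
  p_c <- p_t
  p_c[grid2 == 1] <- 0.1 * exp(1)
  up <- ibi_update(flat, p_c, p_t, smooth = FALSE)
  expect_equal(up$v[grid2 == 1], 0.2 * exp(-0.5), tolerance = 1e-12)
  expect_equal(up$v[grid2 == 2], 0, tolerance = 1e-12)

  # prefactor alpha(r) is 0.2 at r = 0
  expect_equal(0.2 * exp(-0^2 / 2), 0.2)

  # under-sampled bins leave the potential unchanged
  p_c2 <- p_t; p_c2[2] <- 0
  up2 <- ibi_update(flat, p_c2, p_t, smooth = FALSE)
  expect_equal(up2$v[2], 0)
})

test_that("attractive-branch phase solves all four boundary conditions", {
  ph <- solve_attractive_phase(1, sqrt(3))
  expect_equal(ph[["mu"]], pi / 2, tolerance = 1e-12)
  expect_equal(ph[["nu"]], pi / 2, tolerance = 1e-12)
  expect_equal(cos(ph[["mu"]] * 1 + ph[["nu"]]), -1, tolerance = 1e-12)

  for (seed in 1:20) {
    rm_rc <- withr::with_seed(seed, sort(stats::runif(2, 0.5, 3)))
    r_m <- rm_rc[1]; r_c <- rm_rc[2]
    ph <- solve_attractive_phase(r_m, r_c)
    mu <- ph[["mu"]]; nu <- ph[["nu"]]
    expect_equal(mu * (r_c^2 - r_m^2), pi, tolerance = 1e-12)
    branch <- function(r) 0.5 * (cos(mu * r^2 + nu) - 1) # in units of eps
    expect_equal(branch(r_m), -1, tolerance = 1e-10)
    expect_equal(branch(r_c), 0, tolerance = 1e-10)
    h <- 1e-6
    expect_lt(abs((branch(r_m + h) - branch(r_m)) / h), 1e-4)
    expect_lt(abs((branch(r_c) - branch(r_c - h)) / h), 1e-4)
  }
  expect_error(solve_attractive_phase(2, 1))
})

test_that("soft potential evaluates its printed piecewise form", {
  sp <- soft_potential(v0 = 4, r_m = 1, epsilon = 0.5, eta1 = 2, eta2 = 2,
                       r_c = 1.8)
  expect_equal(soft_potential_eval(sp, 0), 4 - 0.5)     # V0 - eps at origin
  expect_equal(soft_potential_eval(sp, 1), -0.5)        # -eps at the minimum
  expect_equal(soft_potential_eval(sp, 1.8), 0)         # 0 at the cutoff
  expect_equal(soft_potential_eval(sp, 2.5), 0)         # 0 beyond
  # C0/C1 matching at r_m
  h <- 1e-7
  expect_lt(abs(soft_potential_eval(sp, 1 - h) - soft_potential_eval(sp, 1 + h)),
            1e-6)
  slope_left <- (soft_potential_eval(sp, 1) - soft_potential_eval(sp, 1 - h)) / h
  expect_lt(abs(slope_left), 1e-5)
})

test_that("soft-potential fit round-trips the generating parameters", {
  sp <- soft_potential(v0 = 4, r_m = 1, epsilon = 0.5, eta1 = 2.5, eta2 = 2,
                       r_c = 1.8)
  tab <- tabulate_soft_potential(sp, grid = seq(0.02, 2.5, by = 0.02))
  fit <- fit_soft_potential(tab)
  p <- fit$params
  expect_lt(abs(p$r_m - 1), 0.01)
  expect_lt(abs(p$epsilon - 0.5), 0.005)
  expect_lt(abs(p$r_c - 1.8), 0.018)
  expect_lt(abs(p$v0 / 4 - 1), 0.05)
  expect_lt(abs(p$eta1 / 2.5 - 1), 0.05)
  expect_lt(abs(p$eta2 / 2 - 1), 0.05)
  # sup-norm of the re-tabulated fit
  re <- soft_potential_eval(p, tab$r)
  expect_lt(max(abs(re - tab$v)), 0.05)

  # purely repulsive table: depth 0
  grid <- seq(0.05, 1.5, by = 0.05)
  v_rep <- ifelse(grid < 1, (1 - grid)^2, 0)
  fit2 <- fit_soft_potential(tabulated_potential(grid, v_rep))
  expect_equal(fit2$params$epsilon, 0)
  expect_lt(abs(fit2$params$r_c - 1), 0.06)

  # noise-perturbed table still recovers the shape parameters roughly
  noisy <- tab
  noisy$v <- tab$v + withr::with_seed(3, stats::rnorm(length(tab$v), 0, 0.03))
  fit3 <- fit_soft_potential(tabulated_potential(noisy$r, noisy$v))
  expect_lt(abs(fit3$params$r_m - 1), 0.1)
  expect_lt(abs(fit3$params$v0 / 4 - 1), 0.12)
  expect_gt(fit3$residual, 0)
})

test_that("softness is the inverse maximal repulsive force", {
  grid <- seq(0.001, 1.5, by = 0.001)
  v <- ifelse(grid < 1, (grid - 1)^2, 0)
  sd1 <- softness_and_depth(tabulated_potential(grid, v))
  expect_equal(sd1$f_max, 2, tolerance = 0.01) # F = 2(1 - r), max 2 at r -> 0
  expect_equal(sd1$softness, 0.5, tolerance = 0.01)
  expect_equal(sd1$depth, 0)

  sd2 <- softness_and_depth(tabulated_potential(grid, 2 * v))
  expect_equal(sd2$softness, sd1$softness / 2, tolerance = 0.01)

  # depth does not affect softness (branch independence)
  a <- soft_potential(v0 = 3, r_m = 1, epsilon = 0.2, r_c = 1.8)
  b <- soft_potential(v0 = 3, r_m = 1, epsilon = 0.8, r_c = 1.8)
  expect_equal(softness_and_depth(a)$softness, softness_and_depth(b)$softness,
               tolerance = 1e-6)
  expect_equal(softness_and_depth(b)$depth, 0.8)
})

test_that("two tethered beads sample the Boltzmann distribution of the soft term", {
  sp <- soft_potential(v0 = 2, r_m = 1, epsilon = 0.6, eta1 = 2, eta2 = 2,
                       r_c = 1.8)
  tab <- tabulate_soft_potential(sp, grid = seq(0.02, 2.2, by = 0.02))
  k_tether <- 2
  ff <- force_field(chain_k = k_tether, chain_r0 = 1, pair = "tabulated",
                    tabulated = tab)
  traj <- run_langevin(rbind(c(0, 0, 0), c(1, 0, 0)), ff,
                       langevin_params(dt = 0.01, n_steps = 400000,
                                       sample_every = 20, seed = 23),
                       burn_in = 100)
  r <- vapply(traj$samples, function(m) sqrt(sum((m[2, ] - m[1, ])^2)),
              numeric(1))
  breaks <- seq(0, 3.2, by = 0.2)
  obs <- graphics::hist(r[r < 3.2], breaks = breaks, plot = FALSE)$counts
  obs <- obs / sum(obs)
  mids <- breaks[-1] - 0.1
  v_tot <- 0.5 * k_tether * (mids - 1)^2 + soft_potential_eval(sp, mids)
  expected <- mids^2 * exp(-v_tot)
  expected <- expected / sum(expected)
  expect_lt(max(abs(cumsum(obs) - cumsum(expected))), 0.02)
})

test_that("CG chain with harmonic bonds alone has Boltzmann bond statistics", {
  spec <- cg_polymer_spec(n_beads = 20, bond_r0 = 1, bond_k = 20)
  ens <- simulate_cg_with_soft_potential(spec, n_samples = 200,
                                         n_steps = 20000,
                                         samples_per_chain = 20, dt = 0.01,
                                         seed = 3)
  lens <- unlist(lapply(ens$coords, function(m) sqrt(rowSums(diff(m)^2))))
  expect_lt(abs(mean(lens) / (1 + 2 / 20) - 1), 0.05) # <l> = r0 + 2kBT/(k r0)
  expect_lt(abs(stats::var(lens) * 20 - 1), 0.1)      # Var = kBT / k

  same <- simulate_cg_with_soft_potential(spec, n_samples = 5,
                                          n_steps = 500,
                                          samples_per_chain = 5, dt = 0.01,
                                          seed = 9)
  again <- simulate_cg_with_soft_potential(spec, n_samples = 5,
                                           n_steps = 500,
                                           samples_per_chain = 5, dt = 0.01,
                                           seed = 9)
  expect_identical(same$coords, again$coords)
})

test_that("IBI recovers a known soft potential on a 50-bead CG chain", {
  truth <- soft_potential(v0 = 3, r_m = 1, epsilon = 0.4, eta1 = 2, eta2 = 2,
                          r_c = 1.8)
  spec_truth <- cg_polymer_spec(n_beads = 50, bond_r0 = 1, bond_k = 7.5,
                                nonbonded = truth)
  target_ens <- simulate_cg_with_soft_potential(spec_truth, n_samples = 150,
                                                n_steps = 12000,
                                                samples_per_chain = 15,
                                                dt = 0.01, seed = 41)
  target <- distance_distribution(target_ens, n_b = 1, pairs = "nonbonded",
                                  bin_width = 0.05)

  spec <- cg_polymer_spec(n_beads = 50, bond_r0 = 1, bond_k = 7.5)
  res <- run_ibi(target, spec, grid = seq(0.05, 3, by = 0.05),
                 max_iter = 30, kl_tol = 1e-5, seed = 51)
  expect_lt(res$best_kl, 0.05) # well converged within 30 iterations
  expect_lte(res$best_iteration, 30)

  # running minimum of the KL history is non-increasing by construction
  run_min <- cummin(tidy(res)$kl)
  expect_true(all(diff(run_min) <= 0))

  # the recovered potential tracks the truth over the attractive well,
  # where thermally accessible configurations actually sample distances;
  # the steep repulsive core (several kBT) is visited too rarely for any
  # structure-based inversion to pin it down at this effort
  pot <- res$potential
  sel <- pot$r >= 0.8 & pot$r <= 1.8
  v_true <- soft_potential_eval(truth, pot$r[sel])
  expect_lt(max(abs(pot$v[sel] - v_true)), 0.2)
  expect_lt(abs(pot$r[which.min(pot$v)] - truth$r_m), 0.15)
})

test_that("IBI at the trivial target converges immediately", {
  spec <- cg_polymer_spec(n_beads = 30, bond_r0 = 1, bond_k = 7.5)
  free_ens <- simulate_cg_with_soft_potential(spec, n_samples = 100,
                                              n_steps = 8000,
                                              samples_per_chain = 10,
                                              dt = 0.01, seed = 61)
  target <- distance_distribution(free_ens, n_b = 1, pairs = "nonbonded",
                                  bin_width = 0.05)
  res <- run_ibi(target, spec, max_iter = 5, kl_tol = 0.02, seed = 61)
  expect_true(res$converged)
  expect_lte(res$best_iteration, 1)
})

test_that("potential TSV round trip preserves the table", {
  tab <- tabulated_potential(seq(0.1, 2, by = 0.1),
                             exp(-seq(0.1, 2, by = 0.1)) - 0.1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_potential_tsv(tab, path)
  back <- read_potential_tsv(path)
  expect_equal(back$r, tab$r, tolerance = 1e-9)
  expect_equal(back$v, tab$v, tolerance = 1e-9)
})
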