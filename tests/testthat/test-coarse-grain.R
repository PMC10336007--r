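test_that("radius of gyration matches hand calculations", {
  expect_equal(radius_of_gyration(c(1, 2, 3)), 0)
  two <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_equal(radius_of_gyration(two), 1.5) # d / 2
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(radius_of_gyration(square), 1 / sqrt(2))
})

test_that("cg_trace computes blocked and sliding centroids", {
  x <- cbind(0:9, 0, 0) * 1.0
  expect_equal(cg_trace(x, 1), x)
  expect_equal(cg_trace(x, 10), rbind(colMeans(x)))
  expect_equal(cg_trace(x, 2)[, 1], c(0.5, 2.5, 4.5, 6.5, 8.5))
  slid <- cg_trace(x, 3, mode = "sliding")
  expect_equal(nrow(slid), 8)
  expect_equal(slid[, 1], 1:8)
  expect_warning(cg_trace(x, 4), "trailing")
  expect_error(cg_trace(x[1:2, ], 5), "N < n_b")
})

test_that("Rg variance decomposes across blocks exactly", {
  # Rg^2(chain) = Rg^2(CG trace) + mean within-block Rg^2, per conformation
  sets <- c(lapply(1:3, function(k) random_coords(60, seed = 330 + k)),
            sample_ideal_chain(60, 2, seed = 9)$coords)
  for (m in sets) {
    for (nb in c(2, 5, 10)) {
      tr <- cg_trace(m, nb)
      grp <- rep(seq_len(60 / nb), each = nb)
      within <- vapply(seq_len(60 / nb), function(k) {
        radius_of_gyration(m[grp == k, , drop = FALSE])^2
      }, numeric(1))
      expect_equal(radius_of_gyration(m)^2,
                   radius_of_gyration(tr)^2 + mean(within),
                   tolerance = 1e-10)
      # the CG-trace Rg is therefore never larger than the full-chain Rg
      expect_lte(radius_of_gyration(tr), radius_of_gyration(m))
    }
  }
})

test_that("rg_profile reflects ensemble structure", {
  fixed <- new_ensemble(rep(list(random_coords(30, seed = 77)), 5))
  prof <- rg_profile(fixed, 5)
  expect_equal(prof$sd, rep(0, nrow(prof)))
  expect_equal(nrow(prof), 26)

  e <- sample_ideal_chain(40, 50, seed = 3)
  prof2 <- rg_profile(e, 8)
  expect_equal(prof2$n, rep(50L, 33))
  expect_true(all(prof2$mean > 0))
})

test_that("bond geometry observables follow the stated conventions", {
  line <- cbind(0:4, 0, 0) * 2.0
  expect_equal(cg_bond_lengths(line), rep(2, 4))
  expect_equal(cg_bond_angles(line), rep(180, 3)) # collinear forward

  right <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(cg_bond_angles(right), 90)

  fold <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0) + 1e-13 * c(1, 1, 1))
  expect_equal(cg_bond_angles(fold), 0, tolerance = 1e-4)

  # straight chain of equal bonds: blocked l_cg = n_b * b exactly
  chain <- cbind(0:11, 0, 0) * 0.7
  expect_equal(cg_bond_lengths(cg_trace(chain, 3)), rep(3 * 0.7, 3))

  expect_warning(cg_bond_angles(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))),
                 "zero-length")
})

test_that("dihedrals use the right-handed atan2 convention", {
  trans <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(3, 1, 0))
  expect_equal(abs(cg_dihedrals(trans)), 180)

  cis <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(1, -1, 0))
  expect_equal(cg_dihedrals(cis), 0)

  twist <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  expect_equal(cg_dihedrals(twist), 90)
  # mirror image flips the sign
  mirror <- twist; mirror[, 3] <- -mirror[, 3]
  expect_equal(cg_dihedrals(mirror), -90)

  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_warning(out <- cg_dihedrals(collinear), "collinear")
  expect_length(out, 0)
})

test_that("overlap parameter and spring constant match hand values", {
  expect_equal(overlap_parameter(0.5, 1), 1)
  expect_equal(overlap_parameter(1.2, 2), 1.2)
  expect_error(overlap_parameter(1, 0))

  k <- spring_constant(c(1, 3)) # population variance 1
  expect_equal(as.numeric(k), 1)
  expect_equal(attr(k, "k_lcg2"), 4) # <l>^2 / var
  expect_error(spring_constant(rep(2, 10)), "rigid")

  lens <- withr::with_seed(10, stats::rnorm(10000, mean = 3, sd = 0.5))
  expect_lt(abs(as.numeric(spring_constant(lens)) / 4 - 1), 0.05)
})

test_that("angle distribution normalizes and inverts the sine correction", {
  dist <- angle_distribution(rep(90, 500))
  expect_equal(sum(dist$p > 0), 1L)
  expect_equal(dist$theta[which(dist$p > 0)], 87.5) # 5-degree default bins

  angles <- withr::with_seed(2, 180 / pi * acos(stats::runif(20000, -1, 1)))
  d <- angle_distribution(angles)
  expect_equal(sum(d$p) * 5, 1, tolerance = 1e-9) # unit integral
  expect_true(all(is.na(d$p_sin[c(1, 36)]))) # outermost bins masked
  # p_sin * sin, renormalized, recovers p
  recon <- d$p_sin * sin(d$theta * pi / 180)
  keep <- !is.na(recon)
  recon <- recon / (sum(recon[keep]) * 5)
  expect_equal(recon[keep], d$p[keep] / (sum(d$p[keep]) * 5),
               tolerance = 0.02)
})

test_that("effective potential inverts known densities", {
  flat <- tibble::tibble(theta = seq(2.5, 177.5, by = 5),
                         p = rep(1 / 175, 36))
  v <- effective_potential(flat)
  expect_equal(v$v, rep(0, 36))

  # Gaussian density: quadratic potential with curvature 1/s^2
  x <- seq(-3, 3, by = 0.05)
  s <- 0.7
  gauss <- tibble::tibble(x = x, p = stats::dnorm(x, 0, s))
  vg <- effective_potential(gauss)
  fit <- stats::lm(v ~ I(x^2), data = vg)
  expect_equal(stats::coef(fit)[[2]], 1 / (2 * s^2), tolerance = 0.02)

  two <- tibble::tibble(x = c(0, 1), p = c(0.8, 0.2))
  vt <- effective_potential(two)
  expect_equal(diff(vt$v), log(4))

  masked <- tibble::tibble(x = 1:3, p = c(0, 0.5, 0.5))
  vm <- effective_potential(masked)
  expect_true(is.na(vm$v[1]))
  expect_error(effective_potential(tibble::tibble(x = 1:2, p = c(0, 0))),
               "empty")
})

test_that("two-Gaussian deconvolution recovers a known mixture", {
  draws <- withr::with_seed(6, {
    pick <- stats::runif(10000) < 0.5
    ifelse(pick, stats::rnorm(10000, 60, 10), stats::rnorm(10000, 110, 25))
  })
  draws <- draws[draws >= 0 & draws <= 180]
  dec <- deconvolute_two_gaussians(angle_distribution(draws))
  td <- tidy(dec)
  expect_lt(abs(td$mean[1] - 60), 3)
  expect_lt(abs(td$mean[2] - 110), 3)
  expect_lt(abs(td$sd[2] / td$sd[1] - 2.5), 0.5) # width ratio within 20%
  expect_false(glance(dec)$poor_fit)

  # single-Gaussian input collapses to one dominant component
  single <- withr::with_seed(7, stats::rnorm(8000, 90, 15))
  dec1 <- deconvolute_two_gaussians(angle_distribution(single))
  td1 <- tidy(dec1)
  expect_true(max(td1$weight) > 0.9 || abs(diff(td1$mean)) < 5)

  flat <- withr::with_seed(8, stats::runif(8000, 0, 180))
  dec2 <- deconvolute_two_gaussians(angle_distribution(flat))
  expect_true(glance(dec2)$poor_fit)
})

test_that("bending-stiffness fit recovers the generating parameters", {
  theta <- seq(5, 175, by = 5)
  v_true <- 0.5 * 1 * (1 + cos((theta - 60) * pi / 180)) + 0.3
  fit <- fit_bending_stiffness(tibble::tibble(theta = theta, v = v_true))
  expect_lt(abs(fit$k_b - 1), 0.01)
  expect_lt(abs(fit$theta0 - 60), 0.5)

  flat <- fit_bending_stiffness(tibble::tibble(theta = theta,
                                               v = rep(0.2, length(theta))))
  expect_lt(flat$k_b, 0.01)

  # ideal-chain corrected density is flat, so the fitted stiffness is tiny
  e <- sample_ideal_chain(102, 100, seed = 15)
  angles <- unlist(lapply(e$coords, cg_bond_angles))
  pot <- effective_potential(angle_distribution(angles), density = "p_sin")
  fit2 <- fit_bending_stiffness(pot)
  expect_lt(fit2$k_b, 0.1)
})

test_that("angle-dihedral energy map is the masked outer sum", {
  vt <- tibble::tibble(theta = c(30, 60, 90), v = c(1, 0, 2))
  vp <- tibble::tibble(phi = c(-60, 60), v = c(0.5, NA))
  m <- angle_dihedral_energy_map(vt, vp)
  expect_equal(nrow(m), 6)
  expect_equal(m$v[m$theta == 90 & m$phi == -60], 2.5)
  expect_true(all(is.na(m$v[m$phi == 60])))
  best <- m[which.min(m$v), ]
  expect_equal(best$theta, 60) # argmin factorizes
  expect_equal(best$phi, -60)
})

test_that("nonbonded overlap fraction matches a brute-force loop", {
  coords <- lapply(1:10, function(k) random_coords(40, seed = 400 + k))
  ens <- new_ensemble(coords)
  got <- nonbonded_overlap_fraction(ens, n_b = 5, l_cg_ref = 2.5)
  # brute force
  hits <- 0; tot <- 0
  per <- list()
  for (m in coords) {
    tr <- cg_trace(m, 5)
    for (i in 1:6) {
      for (j in (i + 2):8) {
        d <- sqrt(sum((tr[i, ] - tr[j, ])^2))
        tot <- tot + 1
        hits <- hits + (d < 2.5)
      }
    }
  }
  expect_equal(got$aggregate, hits / tot, tolerance = 1e-12)
  expect_equal(sum(got$per_pair$fraction) * 10, hits)

  stretched <- new_ensemble(list(cbind(seq(0, 390, by = 10), 0, 0)))
  far <- nonbonded_overlap_fraction(stretched, n_b = 5, l_cg_ref = 2)
  expect_equal(far$aggregate, 0)
})

test_that("cg_observables pools blocked measurements per configuration", {
  e <- sample_ideal_chain(40, 6, seed = 44)
  obs <- cg_observables(e, 10)
  expect_setequal(unique(obs$quantity), c("rg", "l_cg", "theta", "phi"))
  expect_equal(sum(obs$quantity == "rg"), 6 * 4)
  expect_equal(sum(obs$quantity == "l_cg"), 6 * 3)
  expect_equal(sum(obs$quantity == "theta"), 6 * 2)
  expect_equal(sum(obs$quantity == "phi"), 6 * 1)
})
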