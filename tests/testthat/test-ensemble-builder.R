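make_prominent <- function(i, j, p) tibble::tibble(i = i, j = j, p = p)

test_that("step-1 bonds are Bernoulli draws with the map probability", {
  pr <- make_prominent(c(0L, 0L, 1L), c(2L, 5L, 9L), c(1, 0, 0.5))
  b <- assign_step1_bonds(pr, 1000, seed = 9)
  certain <- sum(b$i == 0 & b$j == 2)
  never <- sum(b$i == 0 & b$j == 5)
  half <- sum(b$i == 1 & b$j == 9)
  expect_equal(certain, 1000L)
  expect_equal(never, 0L)
  expect_gte(half, 438L) # within 4 binomial SD of 500
  expect_lte(half, 562L)

  expect_identical(assign_step1_bonds(pr, 50, seed = 1),
                   assign_step1_bonds(pr, 50, seed = 1))
})

test_that("step-1 bond counts are binomial across many pairs", {
  n_pairs <- 300L
  pr <- make_prominent(seq_len(n_pairs) - 1L, seq_len(n_pairs) + 50L,
                       rep(0.3, n_pairs))
  b <- assign_step1_bonds(pr, 100, seed = 21)
  counts <- as.integer(table(factor(b$i, levels = pr$i)))
  # chi-square goodness of fit against Binomial(100, 0.3)
  edges <- c(-Inf, 24, 27, 30, 33, 36, Inf)
  obs <- table(cut(counts, edges))
  pbin <- diff(stats::pbinom(c(-Inf, 24, 27, 30, 33, 36, Inf), 100, 0.3))
  chi <- suppressWarnings(stats::chisq.test(as.integer(obs), p = pbin))
  expect_gt(chi$p.value, 0.01)
})

test_that("step-2 bonds fill the distance-ranked quota exactly", {
  # pair (0, 5) with 10 configurations of engineered distances
  n <- 8
  base <- init_chain(n, seed = 2)
  dists <- c(3.1, 0.7, 2.2, 1.5, 4.0, 0.9, 2.8, 3.5, 1.1, 5.0)
  coords <- lapply(dists, function(d) {
    m <- base
    m[6, ] <- m[1, ] + c(d, 0, 0) # bead index 5 (0-based) at distance d
    m
  })
  ens <- new_ensemble(coords)
  m <- diag(n)
  m[1, 6] <- m[6, 1] <- 0.3
  cm <- suppressWarnings(contact_map(m))
  b2 <- assign_step2_bonds(ens, cm)
  sel <- b2[b2$i == 0 & b2$j == 5, ]
  expect_equal(sort(sel$config), sort(order(dists)[1:3])) # 3 smallest of 10

  # quota is exact for every pair of a random map
  cm2 <- generate_synthetic_map(synthetic_map_spec(n_bins = 20,
                                                   tad_boundaries = 10L,
                                                   noise_cv = 0.5, seed = 6))
  ens2 <- new_ensemble(lapply(1:40, function(k) random_coords(20, seed = k)))
  b <- assign_step2_bonds(ens2, cm2)
  tab <- dplyr::count(b, i, j)
  for (r in seq_len(nrow(tab))) {
    expect_equal(tab$n[r], round(cm2[tab$i[r] + 1, tab$j[r] + 1] * 40))
  }
})

test_that("step-2 distance ties go to the lower configuration index", {
  n <- 6
  base <- init_chain(n, seed = 4)
  coords <- lapply(c(2, 2, 2, 2), function(d) {
    m <- base
    m[5, ] <- m[1, ] + c(d, 0, 0)
    m
  })
  ens <- new_ensemble(coords)
  m <- diag(n); m[1, 5] <- m[5, 1] <- 0.5
  cm <- suppressWarnings(contact_map(m))
  b <- assign_step2_bonds(ens, cm)
  sel <- b[b$i == 0 & b$j == 4, ]
  expect_equal(sort(sel$config), 1:2) # quota 2, ties broken by index
})

test_that("step-2 quota skips step-1 duplicates but counts them", {
  n <- 8
  coords <- lapply(1:10, function(k) random_coords(n, seed = 100 + k))
  ens <- new_ensemble(coords)
  m <- diag(n); m[1, 4] <- m[4, 1] <- 0.5 # quota 5 of 10
  cm <- suppressWarnings(contact_map(m))
  dist03 <- vapply(coords, function(x) sqrt(sum((x[1, ] - x[4, ])^2)),
                   numeric(1))
  closest5 <- sort(order(dist03)[1:5])
  existing <- tibble::tibble(config = closest5[1:2], i = 0L, j = 3L, step = 1L)
  b <- assign_step2_bonds(ens, cm, existing = existing)
  sel <- b[b$i == 0 & b$j == 3, ]
  expect_equal(sort(sel$config), setdiff(closest5, closest5[1:2]))
})

test_that("ensemble contact map equals the brute-force oracle", {
  coords <- lapply(1:25, function(k) random_coords(12, seed = 200 + k))
  ens <- new_ensemble(coords)
  got <- ensemble_contact_map(ens, cutoff = 2)
  want <- oracle_contact_map(coords, 2)
  expect_equal(unclass(got), want, tolerance = 1e-12, ignore_attr = TRUE)

  one <- ensemble_contact_map(new_ensemble(coords[1]), cutoff = 2)
  expect_true(all(unclass(one) %in% c(0, 1)))

  same <- ensemble_contact_map(new_ensemble(rep(coords[3], 7)), cutoff = 2)
  expect_equal(unclass(same), oracle_contact_map(coords[3], 2),
               ignore_attr = TRUE)
})

test_that("build_ensemble is deterministic and respects a null map", {
  null_map <- contact_map(diag(30))
  e1 <- build_ensemble(null_map, n_configs = 4, n_steps_stage = 800,
                       sample_every = 40, seed = 5)
  e2 <- build_ensemble(null_map, n_configs = 4, n_steps_stage = 800,
                       sample_every = 40, seed = 5)
  expect_identical(e1$coords, e2$coords)
  # no contacts in the map -> no constraint springs anywhere
  expect_true(all(vapply(e1$bonds, nrow, integer(1)) == 0L))
})

test_that("TAD maps produce compact domains in the built ensemble", {
  cm <- generate_synthetic_map(
    synthetic_map_spec(n_bins = 60, tad_boundaries = c(20L, 40L)))
  ens <- suppressWarnings(build_ensemble(cm, n_configs = 20,
                                         n_steps_stage = 3000, seed = 3))
  block <- chromcg:::tad_block_index(60, c(20L, 40L))
  # intra-TAD pairs should be closer than inter-TAD pairs at equal separation
  seps <- c(8L, 12L, 16L)
  intra <- c(); inter <- c()
  for (m in ens$coords) {
    for (s in seps) {
      for (i in seq_len(60 - s)) {
        d <- sqrt(sum((m[i, ] - m[i + s, ])^2))
        if (block[i] == block[i + s]) intra <- c(intra, d) else inter <- c(inter, d)
      }
    }
  }
  expect_lt(mean(intra), mean(inter))

  recon <- ensemble_contact_map(ens, cutoff = 2)
  expect_gt(scc(cm, recon, h = 1), 0.8)
})
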