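#' Step-1 constraint bonds: Bernoulli draws on prominent contacts
#'
#' For every configuration, each prominent pair `(i, j)` is tied with a
#' harmonic constraint spring when an independent uniform draw `r_n`
#' satisfies `r_n < P_ij`. Draws are consumed in a fixed documented order
#' (configurations outer, pairs sorted by `(i, j)` inner), so the assignment
#' is deterministic given the seed.
#'
#' @param prominent Tibble of prominent contacts from
#'   [find_prominent_contacts()] (columns `i`, `j`, `p`).
#' @param n_configs Number of configurations.
#' @param seed Integer seed.
#' @return A tibble with columns `config` (1-based), `i`, `j` (0-based,
#'   `i < j`) and `step = 1L`.
#' @export
assign_step1_bonds <- function(prominent, n_configs, seed = 1L) {
  stopifnot(n_configs >= 1, all(c("i", "j", "p") %in% names(prominent)))
  pr <- prominent[order(prominent$i, prominent$j), ]
  out <- withr::with_seed(seed, {
    purrr::map(seq_len(n_configs), function(c) {
      u <- stats::runif(nrow(pr))
      sel <- u < pr$p
      tibble::tibble(config = c, i = pr$i[sel], j = pr$j[sel])
    })
  })
  res <- dplyr::bind_rows(out)
  res$step <- 1L
  res
}

#' Step-2 constraint bonds: distance-ranked quota filling
#'
#' For every pair `(i, j)` with `j - i >= 2` and `P_ij >= 1/n_configs`
#' (smaller probabilities round to a zero quota), the configurations are
#' ranked by the pair's current 3D distance `r_ij` (ascending; exact ties
#' resolved in favour of the lower configuration index) and the first
#' `round(P_ij * n_configs)` configurations (round-half-even) are bonded.
#' Configurations already carrying the bond from step 1 count toward the
#' quota but are not duplicated. Quotas are computed from a single snapshot
#' of the step-1-equilibrated distances, so pair processing order is
#' immaterial.
#'
#' @param ensemble Step-1-equilibrated [new_ensemble()] whose bead count
#'   matches the map.
#' @param map The input [contact_map()].
#' @param existing Step-1 bond tibble from [assign_step1_bonds()] (may be
#'   empty).
#' @return A tibble of newly added bonds with columns `config`, `i`, `j`,
#'   `step = 2L`.
#' @export
assign_step2_bonds <- function(ensemble, map, existing = NULL) {
  stopifnot(inherits(ensemble, "ensemble"), inherits(map, "contact_map"))
  n <- n_beads(ensemble)
  if (n != n_bins(map)) {
    stop("ensemble bead count (", n, ") does not match map bins (",
         n_bins(map), ")", call. = FALSE)
  }
  nc <- n_conformations(ensemble)
  m <- unclass(map)

  # distances per (pair, config); pairs in (i, j) column-major lower-tri
  # order as produced by dist()
  D <- vapply(ensemble$coords, function(x) as.numeric(stats::dist(x)),
              numeric(n * (n - 1) / 2))
  if (is.null(dim(D))) D <- matrix(D, ncol = nc)
  ij <- pair_index_table(n)

  existing_key <- character(0)
  if (!is.null(existing) && nrow(existing) > 0) {
    existing_key <- paste(existing$config, existing$i, existing$j)
  }

  keep <- (ij$j - ij$i) >= 2 & m[cbind(ij$i + 1L, ij$j + 1L)] >= 1 / nc
  rows <- which(keep)
  out_config <- integer(0); out_i <- integer(0); out_j <- integer(0)
  for (r in rows) {
    p <- m[ij$i[r] + 1L, ij$j[r] + 1L]
    quota <- round(p * nc) # round-half-even
    if (quota < 1) next
    ord <- order(D[r, ], seq_len(nc))
    chosen <- ord[seq_len(quota)]
    out_config <- c(out_config, chosen)
    out_i <- c(out_i, rep(ij$i[r], quota))
    out_j <- c(out_j, rep(ij$j[r], quota))
  }
  res <- tibble::tibble(config = out_config, i = out_i, j = out_j)
  if (length(existing_key)) {
    res <- res[!(paste(res$config, res$i, res$j) %in% existing_key), ]
  }
  res <- res[order(res$config, res$i, res$j), ]
  res$step <- 2L
  res
}

# 0-based (i, j) pairs in the order of dist()'s packed lower triangle.
pair_index_table <- function(n) {
  j <- sequence((n - 1):1, from = 2:n) - 1L
  i <- rep(1:(n - 1), times = (n - 1):1) - 1L
  list(i = i, j = j)
}

#' Build a fine-grained ensemble consistent with a contact map
#'
#' The two-step construction: (1) prominent contacts are bonded with
#' probability `P_ij` per configuration and each configuration is
#' equilibrated by Langevin dynamics; (2) using a snapshot of the step-1
#' distances, every pair gets constraint bonds in the `P_ij` fraction of
#' configurations where it is spatially closest, and the system is
#' equilibrated again. Per-configuration seeds derive from `seed`.
#' Configurations that fail the equilibration detector or break a chain bond
#' are excluded with a warning.
#'
#' @param map Input [contact_map()] (at most 5000 bins).
#' @param n_configs Number of configurations.
#' @param ff A [force_field()]; its `constraint_k`/`constraint_r0` set the
#'   constraint-spring stiffness and rest length.
#' @param n_steps_stage Integration steps per equilibration stage.
#' @param dt,friction,sample_every Integrator settings.
#' @param seed Master seed.
#' @return An [new_ensemble()]; element `bonds` holds each configuration's
#'   constraint bonds, and the provenance records seeds, stages and the bond
#'   tibbles.
#' @export
build_ensemble <- function(map, n_configs = 100L,
                           ff = force_field(pair = "wca"),
                           n_steps_stage = 6000L, dt = 0.002, friction = 1,
                           sample_every = 200L, seed = 1L) {
  stopifnot(inherits(map, "contact_map"), n_configs >= 1)
  n <- n_bins(map)
  if (n > 5000) stop("maps above 5000 bins are out of desk scale", call. = FALSE)

  prominent <- find_prominent_contacts(map)
  step1 <- assign_step1_bonds(prominent, n_configs, seed = derive_seed(seed, 1L))

  run_stage <- function(init_list, bonds_tbl, stage) {
    lapply(seq_len(n_configs), function(c) {
      b <- bonds_tbl[bonds_tbl$config == c, c("i", "j"), drop = FALSE]
      ffc <- ff
      ffc$constraint_bonds <- as_bond_matrix(as.matrix(b))
      traj <- run_langevin(init_list[[c]], ffc,
                           langevin_params(dt = dt, friction = friction,
                                           n_steps = n_steps_stage,
                                           sample_every = sample_every,
                                           seed = derive_seed(seed, stage * 100000L + c)),
                           burn_in = "auto")
      list(coords = traj$samples[[length(traj$samples)]],
           equilibrated = traj$equilibrated)
    })
  }

  init <- lapply(seq_len(n_configs), function(c) {
    init_chain(n, seed = derive_seed(seed, 50000L + c), method = "saw")
  })
  stage1 <- run_stage(init, step1, 1L)
  ens1 <- new_ensemble(lapply(stage1, `[[`, "coords"))

  step2 <- assign_step2_bonds(ens1, map, existing = step1)
  all_bonds <- dplyr::bind_rows(step1, step2)
  stage2 <- run_stage(ens1$coords, all_bonds, 2L)

  eq <- vapply(stage2, `[[`, logical(1), "equilibrated")
  coords <- lapply(stage2, `[[`, "coords")
  intact <- vapply(coords, function(m) max(bond_lengths(m)) < 3 * ff$chain_r0,
                   logical(1))
  ok <- eq & intact
  if (!all(ok)) {
    warning(sprintf("%d configuration(s) excluded (not equilibrated or broken bonds)",
                    sum(!ok)))
  }
  if (!any(ok)) stop("no configuration equilibrated", call. = FALSE)
  keep <- which(ok)
  bonds_list <- lapply(keep, function(c) {
    b <- all_bonds[all_bonds$config == c, c("i", "j"), drop = FALSE]
    as_bond_matrix(as.matrix(b))
  })
  new_ensemble(coords[keep], bonds = bonds_list,
               provenance = list(kind = "map-constrained",
                                 map_n_bins = n,
                                 resolution_bp = attr(map, "resolution_bp"),
                                 chrom = attr(map, "chrom"),
                                 start_bp = attr(map, "start_bp"),
                                 n_configs = n_configs, seed = seed,
                                 n_steps_stage = n_steps_stage, dt = dt,
                                 friction = friction, force_field = ff,
                                 step1_bonds = step1, step2_bonds = step2,
                                 excluded = sum(!ok)))
}

#' Recompute a contact map from an ensemble
#'
#' `P_ij` is the fraction of configurations in which beads `i` and `j` are
#' closer than `cutoff`; the diagonal is set to 1. The default cutoff of
#' 2 sigma exceeds the constraint-spring rest length, so bonded pairs
#' register as contacts.
#'
#' @param ensemble An [new_ensemble()].
#' @param cutoff Contact distance threshold in sigma.
#' @return A [contact_map()] (metadata taken from the ensemble provenance
#'   when available).
#' @export
ensemble_contact_map <- function(ensemble, cutoff = 2) {
  stopifnot(inherits(ensemble, "ensemble"), cutoff > 0)
  counts <- contact_count_cpp(ensemble$coords, cutoff)
  m <- counts / n_conformations(ensemble)
  diag(m) <- 1
  pv <- ensemble$provenance
  contact_map(m,
              resolution_bp = pv$resolution_bp %||% 200L,
              chrom = pv$chrom %||% "ens",
              start_bp = pv$start_bp %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
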