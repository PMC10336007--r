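#' Bead-spring force field
#'
#' Defines the potential energy of an N-bead chain: harmonic chain bonds
#' between successive beads, optional per-configuration harmonic constraint
#' bonds, and one non-bonded pair term applied to all bead pairs (including
#' chain neighbours): none, the purely repulsive Weeks-Chandler-Andersen
#' (WCA) form (Lennard-Jones truncated and shifted at its minimum
#' `2^(1/6) sigma_p`), truncated-and-shifted attractive Lennard-Jones, or a
#' tabulated potential (cubic Hermite interpolation of `V(r)`, force from the
#' interpolant's analytic derivative, zero beyond the grid).
#'
#' @param chain_k Chain-bond stiffness in kBT/sigma^2.
#' @param chain_r0 Chain-bond rest length in sigma.
#' @param pair Non-bonded pair term: `"none"`, `"wca"`, `"lj"`, `"tabulated"`.
#' @param pair_eps Pair energy scale epsilon in kBT.
#' @param pair_sigma Pair length scale in sigma.
#' @param pair_rcut Cutoff for `"lj"` (must exceed `pair_sigma`); the WCA
#'   cutoff is fixed at `2^(1/6) * pair_sigma`.
#' @param tabulated A [tabulated_potential()] for `pair = "tabulated"`.
#' @param constraint_bonds 2-column integer matrix of 0-based bead pairs to
#'   tie with harmonic constraint springs, or `NULL`.
#' @param constraint_k,constraint_r0 Constraint-spring stiffness and rest
#'   length.
#' @return A list of class `force_field`.
#' @export
force_field <- function(chain_k = 100, chain_r0 = 1,
                        pair = c("none", "wca", "lj", "tabulated"),
                        pair_eps = 1, pair_sigma = 1, pair_rcut = 2.5,
                        tabulated = NULL, constraint_bonds = NULL,
                        constraint_k = 50, constraint_r0 = 1) {
  pair <- match.arg(pair)
  stopifnot(chain_k > 0, chain_r0 > 0, constraint_k > 0, constraint_r0 > 0)
  if (pair == "lj" && pair_rcut <= pair_sigma) {
    stop("LJ cutoff must exceed pair_sigma", call. = FALSE)
  }
  if (pair == "tabulated") {
    stopifnot(inherits(tabulated, "tabulated_potential"))
  }
  if (!is.null(constraint_bonds)) {
    constraint_bonds <- as_bond_matrix(constraint_bonds)
  }
  structure(list(chain_k = chain_k, chain_r0 = chain_r0, pair = pair,
                 pair_eps = pair_eps, pair_sigma = pair_sigma,
                 pair_rcut = pair_rcut, tabulated = tabulated,
                 constraint_bonds = constraint_bonds,
                 constraint_k = constraint_k, constraint_r0 = constraint_r0),
            class = "force_field")
}

as_bond_matrix <- function(b) {
  b <- as.matrix(b)
  if (ncol(b) != 2) stop("constraint bonds must have two columns (i, j)",
                         call. = FALSE)
  storage.mode(b) <- "integer"
  dimnames(b) <- NULL
  if (nrow(b) > 0 && any(b[, 1] >= b[, 2])) {
    stop("constraint bonds must satisfy i < j (0-based)", call. = FALSE)
  }
  if (anyDuplicated(b)) stop("duplicate constraint bond", call. = FALSE)
  b
}

# Unpack a force_field into the argument list expected by the C++ engine.
ff_engine_args <- function(ff, n_beads) {
  cb <- ff$constraint_bonds
  if (is.null(cb)) cb <- matrix(integer(0), 0, 2)
  if (nrow(cb) > 0 && max(cb) >= n_beads) {
    stop("constraint bond index out of range", call. = FALSE)
  }
  pt <- match(ff$pair, c("none", "wca", "lj", "tabulated")) - 1L
  rcut <- switch(ff$pair,
                 wca = 2^(1 / 6) * ff$pair_sigma,
                 lj = ff$pair_rcut,
                 0)
  tab_r <- numeric(0); tab_v <- numeric(0); tab_m <- numeric(0)
  if (ff$pair == "tabulated") {
    tab_r <- ff$tabulated$r
    tab_v <- ff$tabulated$v
    tab_m <- hermite_slopes(tab_r, tab_v)
  }
  list(chain_k = ff$chain_k, chain_r0 = ff$chain_r0, cbonds = cb,
       cbond_k = rep(ff$constraint_k, nrow(cb)),
       cbond_r0 = rep(ff$constraint_r0, nrow(cb)),
       pair_type = pt, pair_eps = ff$pair_eps, pair_sigma = ff$pair_sigma,
       pair_rcut = rcut, tab_r = tab_r, tab_v = tab_v, tab_m = tab_m)
}

# Node slopes for cubic Hermite interpolation: central differences in the
# interior, one-sided at the ends.
hermite_slopes <- function(r, v) {
  n <- length(r)
  if (n < 2) return(numeric(n))
  m <- numeric(n)
  m[1] <- (v[2] - v[1]) / (r[2] - r[1])
  m[n] <- (v[n] - v[n - 1]) / (r[n] - r[n - 1])
  if (n > 2) {
    m[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (r[3:n] - r[1:(n - 2)])
  }
  m
}

#' Evaluate potential energy and forces of a conformation
#'
#' Forces are the exact negative gradient of the force field's potential
#' (pair forces of magnitude above 1e4 kBT/sigma, which can only arise from
#' near-coincident beads under a steep pair term, are capped at that value
#' with a warning).
#'
#' @param coords N x 3 coordinate matrix.
#' @param ff A [force_field()].
#' @return A list with `energy` (kBT) and `forces` (N x 3, kBT/sigma).
#' @export
evaluate_forces <- function(coords, ff) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, nrow(coords) >= 2,
            inherits(ff, "force_field"))
  a <- ff_engine_args(ff, nrow(coords))
  res <- eval_forces_cpp(coords, a$chain_k, a$chain_r0, a$cbonds, a$cbond_k,
                         a$cbond_r0, a$pair_type, a$pair_eps, a$pair_sigma,
                         a$pair_rcut, a$tab_r, a$tab_v, a$tab_m)
  if (res$n_capped > 0) {
    warning(sprintf("%d pair force(s) capped at 1e4 (near-overlapping beads)",
                    res$n_capped))
  }
  list(energy = res$energy, forces = res$forces)
}
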