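#' Sample an ideal (Gaussian) chain exactly
#'
#' Conformations of a phantom bead-spring chain are drawn directly from the
#' equilibrium distribution: each bond vector is an independent isotropic
#' Gaussian triple scaled so that the mean squared step length equals
#' `bond_length^2`. No dynamics is involved, so the control carries no
#' integrator error.
#'
#' @param n_beads Number of beads (>= 2).
#' @param n_samples Number of independent conformations.
#' @param bond_length Root-mean-square bond length `b`.
#' @param seed Integer seed.
#' @return An [new_ensemble()].
#' @examples
#' e <- sample_ideal_chain(50, 100, seed = 7)
#' mean(vapply(e$coords, radius_of_gyration, numeric(1)))
#' @export
sample_ideal_chain <- function(n_beads, n_samples, bond_length = 1, seed = 1L) {
  stopifnot(n_beads >= 2, n_samples >= 1, bond_length > 0)
  s <- bond_length / sqrt(3)
  coords <- withr::with_seed(seed, {
    lapply(seq_len(n_samples), function(k) {
      steps <- matrix(stats::rnorm(3L * (n_beads - 1L), sd = s),
                      n_beads - 1L, 3L)
      rbind(c(0, 0, 0), apply(steps, 2L, cumsum))
    })
  })
  new_ensemble(coords,
               provenance = list(kind = "ideal", n_beads = n_beads,
                                 bond_length = bond_length, seed = seed))
}
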