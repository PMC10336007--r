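#' Specification for a synthetic contact probability map
#'
#' Describes a map with the statistical structure of nucleosome-resolution
#' chromatin contact data: power-law decay of contact probability with
#' genomic separation, block-enriched TAD-like domains, and optional
#' multiplicative log-normal noise. The defaults generate the 200-bin,
#' three-domain, noise-free map used throughout the package's worked
#' examples and self-tests.
#'
#' @param n_bins Number of genomic bins.
#' @param decay_exponent Power-law exponent `gamma` of the baseline decay
#'   `P(s) = A * s^-gamma`.
#' @param amplitude Amplitude `A` in (0, 1].
#' @param tad_boundaries Strictly increasing 0-based bin indices in
#'   `[1, n_bins - 1]` delimiting TAD-like blocks; `k` boundaries give
#'   `k + 1` blocks.
#' @param tad_boost Multiplicative enrichment (>= 1) applied to intra-block
#'   entries.
#' @param noise_cv Coefficient of variation of symmetric multiplicative
#'   log-normal noise with unit median; 0 disables noise.
#' @param seed Integer seed for the noise draw.
#' @return A list of class `synthetic_map_spec`.
#' @export
synthetic_map_spec <- function(n_bins = 200L, decay_exponent = 1,
                               amplitude = 0.9,
                               tad_boundaries = c(67L, 133L),
                               tad_boost = 3, noise_cv = 0, seed = 1L) {
  stopifnot(n_bins >= 2, decay_exponent > 0, amplitude > 0, amplitude <= 1,
            tad_boost >= 1, noise_cv >= 0)
  tad_boundaries <- as.integer(tad_boundaries)
  if (length(tad_boundaries)) {
    stopifnot(all(diff(tad_boundaries) > 0),
              all(tad_boundaries >= 1L), all(tad_boundaries <= n_bins - 1L))
  }
  structure(list(n_bins = as.integer(n_bins), decay_exponent = decay_exponent,
                 amplitude = amplitude, tad_boundaries = tad_boundaries,
                 tad_boost = tad_boost, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "synthetic_map_spec")
}

#' Generate a synthetic contact probability map
#'
#' Entries are `P_ij = clip(A * s^-gamma * B_ij * eta_ij, 0, 1)` for
#' separation `s = |i - j| >= 1`, with unit diagonal. `B_ij` equals
#' `tad_boost` when bins `i` and `j` fall in the same TAD-like block and 1
#' otherwise; `eta_ij` is symmetric log-normal noise with unit median and
#' coefficient of variation `noise_cv`, drawn from the seeded generator. The
#' result is symmetric by construction and deterministic given the seed.
#'
#' @param spec A [synthetic_map_spec()].
#' @param resolution_bp,chrom,start_bp Genomic metadata for the output map.
#' @return A [contact_map()].
#' @examples
#' cm <- generate_synthetic_map(synthetic_map_spec(n_bins = 50))
#' contact_probability_curve(cm)
#' @export
generate_synthetic_map <- function(spec = synthetic_map_spec(),
                                   resolution_bp = 200L, chrom = "synth",
                                   start_bp = 0L) {
  stopifnot(inherits(spec, "synthetic_map_spec"))
  n <- spec$n_bins
  s <- abs(outer(seq_len(n), seq_len(n), "-"))
  base <- matrix(0, n, n)
  off <- s >= 1
  base[off] <- spec$amplitude * s[off]^(-spec$decay_exponent)

  block <- tad_block_index(n, spec$tad_boundaries)
  same <- outer(block, block, "==")
  boost <- matrix(1, n, n)
  boost[same] <- spec$tad_boost

  eta <- matrix(1, n, n)
  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    eta <- withr::with_seed(spec$seed, {
      e <- matrix(1, n, n)
      ut <- upper.tri(e)
      e[ut] <- exp(stats::rnorm(sum(ut), mean = 0, sd = sdlog)) # unit median
      e[lower.tri(e)] <- t(e)[lower.tri(e)]
      e
    })
  }

  m <- pmin(pmax(base * boost * eta, 0), 1)
  diag(m) <- 1
  contact_map(m, resolution_bp = resolution_bp, chrom = chrom,
              start_bp = start_bp)
}

# 0-based TAD block membership per bin (1-based bin position in, block id out)
tad_block_index <- function(n_bins, tad_boundaries) {
  findInterval(0:(n_bins - 1L), c(-1L, tad_boundaries))
}
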