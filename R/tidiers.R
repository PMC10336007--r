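#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an angle deconvolution
#'
#' @param x An `angle_deconvolution` from [deconvolute_two_gaussians()].
#' @param ... Unused.
#' @return One row per Gaussian component: `component`, `mean`, `sd`,
#'   `weight`.
#' @method tidy angle_deconvolution
#' @export
tidy.angle_deconvolution <- function(x, ...) {
  tibble::tibble(component = seq_len(nrow(x$components)),
                 mean = x$components$mean,
                 sd = x$components$sd,
                 weight = x$components$weight)
}

#' @rdname tidy.angle_deconvolution
#' @method glance angle_deconvolution
#' @export
glance.angle_deconvolution <- function(x, ...) {
  tibble::tibble(residual = x$residual, poor_fit = x$poor_fit)
}

#' Tidy a bending-stiffness fit
#'
#' @param x A `stiffness_fit` from [fit_bending_stiffness()].
#' @param ... Unused.
#' @return A tibble with `term` and `estimate` for `k_b` (kBT), `theta0`
#'   (degrees) and `offset`.
#' @method tidy stiffness_fit
#' @export
tidy.stiffness_fit <- function(x, ...) {
  tibble::tibble(term = c("k_b", "theta0", "offset"),
                 estimate = c(x$k_b, x$theta0, x$offset))
}

#' @rdname tidy.stiffness_fit
#' @method glance stiffness_fit
#' @export
glance.stiffness_fit <- function(x, ...) {
  tibble::tibble(k_b = x$k_b, theta0 = x$theta0, residual = x$residual)
}

#' Tidy a soft-potential fit
#'
#' @param x A `soft_potential_fit` from [fit_soft_potential()].
#' @param ... Unused.
#' @return A tibble with one row per parameter of the soft form.
#' @method tidy soft_potential_fit
#' @export
tidy.soft_potential_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(term = c("v0", "r_m", "epsilon", "eta1", "eta2", "mu", "nu",
                          "r_c"),
                 estimate = c(p$v0, p$r_m, p$epsilon, p$eta1, p$eta2, p$mu,
                              p$nu, p$r_c))
}

#' @rdname tidy.soft_potential_fit
#' @method glance soft_potential_fit
#' @export
glance.soft_potential_fit <- function(x, ...) {
  tibble::tibble(residual = x$residual, r_m = x$params$r_m,
                 epsilon = x$params$epsilon, r_c = x$params$r_c)
}

#' Tidy an iterative Boltzmann inversion result
#'
#' @param x An `ibi_result` from [run_ibi()].
#' @param ... Unused.
#' @return `tidy()`: the KL history (`iteration`, `kl`); `glance()`: one row
#'   with `best_iteration`, `best_kl`, `converged`.
#' @method tidy ibi_result
#' @export
tidy.ibi_result <- function(x, ...) x$history

#' @rdname tidy.ibi_result
#' @method glance ibi_result
#' @export
glance.ibi_result <- function(x, ...) {
  tibble::tibble(best_iteration = x$best_iteration, best_kl = x$best_kl,
                 converged = x$converged,
                 n_iterations = nrow(x$history))
}
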