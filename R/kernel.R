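#' Truncated bivariate-normal phage diffusion kernel
#'
#' Per-step phage movement is limited to the 3x3 neighborhood of a patch.
#' Movement weights come from a symmetric bivariate normal density of scale
#' `sigma` centered on the patch, integrated over the nine unit squares and
#' truncated there. With `F` the standard normal CDF, write
#' `A = 2 F(0.5/sigma) - 1` and `B = F(1.5/sigma) - F(0.5/sigma)`; the
#' unnormalized masses are `A^2` (stay), `A*B` (each of the 4 orthogonal
#' neighbors) and `B^2` (each of the 4 diagonal neighbors), normalized by
#' `A^2 + 4AB + 4B^2` so the nine weights sum to one.
#'
#' @param sigma Positive kernel scale.
#' @return An object of class `"diffusion_kernel"`: list with `sigma`,
#'   `w_center`, `w_orth`, `w_diag` (normalized weights), `norm` (the
#'   normalizer before division), and `leave_fraction = 1 - w_center`.
#' @examples
#' k <- diffusion_kernel(1)
#' k$w_center + 4 * k$w_orth + 4 * k$w_diag  # 1
#' @seealso [sigma_from_leave_fraction()]
#' @export
diffusion_kernel <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number")
  A <- 2 * stats::pnorm(0.5 / sigma) - 1
  B <- stats::pnorm(1.5 / sigma) - stats::pnorm(0.5 / sigma)
  norm <- A^2 + 4 * A * B + 4 * B^2
  structure(list(sigma = sigma,
                 w_center = A^2 / norm,
                 w_orth = A * B / norm,
                 w_diag = B^2 / norm,
                 norm = norm,
                 leave_fraction = 1 - A^2 / norm),
            class = "diffusion_kernel")
}

#' @export
print.diffusion_kernel <- function(x, ...) {
  cat(sprintf("3x3 diffusion kernel, sigma = %.6g\n", x$sigma))
  cat(sprintf("  stay %.6g | orthogonal 4 x %.6g | diagonal 4 x %.6g\n",
              x$w_center, x$w_orth, x$w_diag))
  cat(sprintf("  leave fraction %.6g\n", x$leave_fraction))
  invisible(x)
}

#' Kernel scale from the per-step leave fraction
#'
#' Inverts [diffusion_kernel()]: finds the `sigma` whose kernel scatters a
#' fraction `d` of a patch's phage to the eight neighbors each step. Runs are
#' usually reported by this leave fraction rather than by `sigma`. The leave
#' fraction increases monotonically with `sigma` toward its supremum 8/9 (the
#' uniform 3x3 kernel), so `d` must lie strictly in (0, 8/9).
#'
#' @param d Leave fraction, in (0, 8/9).
#' @param tol Convergence tolerance on the leave fraction (default 1e-12).
#' @return The kernel scale `sigma` with `1 - w_center(sigma) = d`.
#' @examples
#' sigma_from_leave_fraction(0.80466)  # ~1
#' @export
sigma_from_leave_fraction <- function(d, tol = 1e-12) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d <= 0 || d >= 8 / 9)
    stop("leave fraction 'd' must lie strictly in (0, 8/9)")
  f <- function(s) diffusion_kernel(s)$leave_fraction - d
  lo <- 1e-4
  hi <- 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-14)
  if (abs(f(r$root)) > max(tol, 1e-10))
    stop("root finding for sigma did not converge")
  r$root
}
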