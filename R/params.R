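# Parameter containers and validation for the segmentation flow.

#' Segmentation parameters
#'
#' Collects the weights and numerical constants of the two-phase energy
#' \deqn{E(c_1, c_2, \phi) = \lambda_1 F_1 + \lambda_2 F_2 + \mu L_g +
#' v A_g + \alpha P}
#' and its explicit time stepping. The defaults are the regime used
#' throughout: \eqn{\lambda_1 = \lambda_2 = 100}, \eqn{\mu = 200/225^2},
#' \eqn{v = 0}, \eqn{\alpha = 0.2/\tau}, \eqn{\tau = 1}, Heaviside/Dirac
#' width \eqn{\epsilon = 1.5}, binary initialization magnitude
#' \eqn{\rho = 4\epsilon} and intensity offset \eqn{\kappa = 1}.
#'
#' The stability condition \eqn{\tau\alpha < 1/4} for the signed-distance
#' penalty is enforced here: violating it is rejected immediately.
#'
#' The region (data) terms act on raw 0-255 intensities, so with
#' \eqn{\lambda = 100} they dominate the geometric terms by orders of
#' magnitude wherever the pixel intensity is far from a region mean. This
#' is what lets the small, isolated dark-seed initialization survive the
#' penalty's smoothing; the evolution confines \eqn{\phi} to
#' \eqn{[-\rho, \rho]} so these large forces saturate instead of producing
#' unbounded level-set magnitudes. See the methods vignette.
#'
#' @param lambda1,lambda2 positive weights of the inner/outer region terms.
#' @param mu nonnegative weight of the edge-weighted contour length.
#' @param v weight of the edge-weighted inner area (sign controls whether
#'   the contour is pushed to shrink or expand; 0 disables it).
#' @param tau time step of the explicit evolution.
#' @param alpha positive weight of the signed-distance penalty; default
#'   `0.2 / tau`. Must satisfy `tau * alpha < 1/4`.
#' @param eps width of the regularized Heaviside/Dirac pair (pixels).
#' @param eps_d small division guard inside gradient-magnitude roots.
#' @param rho magnitude of the binary initial level set; default `4 * eps`.
#' @param kappa intensity offset defining the seed set of darkest pixels at
#'   initialization; also the homogeneity scale at which a region stops
#'   being splittable.
#' @param min_split_contrast minimum difference between the two region
#'   means (gray levels) for a converged bisection to count as a new
#'   contour. A split whose sides differ by less than this -- about twice
#'   the residual noise spread left by denoising, 2\% of the 8-bit range --
#'   separates nothing topographically, so the recursion is declared
#'   stationary. Set to 0 to disable.
#' @param max_iters_per_pass safety cap on iterations within one pass.
#' @param stationary_window number of consecutive quiescent iterations
#'   required to declare a pass stationary.
#' @param stationary_tol an iteration is quiescent when the inside pixel
#'   set is unchanged and no pixel of \eqn{\phi} moved by more than this
#'   (level-set units), so a converged pass has a settled signed-distance
#'   profile, not just a frozen sign pattern.
#' @return an object of class `mpac_params` (a validated list).
#' @export
algo_params <- function(lambda1 = 100, lambda2 = 100, mu = 200 / 225^2,
                        v = 0, tau = 1, alpha = 0.2 / tau, eps = 1.5,
                        eps_d = 1e-8, rho = 4 * eps, kappa = 1,
                        min_split_contrast = 5,
                        max_iters_per_pass = 200L, stationary_window = 3L,
                        stationary_tol = 0.02) {
  check_positive_scalar(lambda1, "lambda1")
  check_positive_scalar(lambda2, "lambda2")
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu < 0) {
    stop_param("`mu` must be a nonnegative finite scalar")
  }
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
    stop_param("`v` must be a finite scalar")
  }
  check_positive_scalar(tau, "tau")
  check_positive_scalar(alpha, "alpha")
  check_positive_scalar(eps, "eps")
  check_positive_scalar(eps_d, "eps_d")
  check_positive_scalar(rho, "rho")
  check_positive_scalar(kappa, "kappa")
  if (!is.numeric(min_split_contrast) || length(min_split_contrast) != 1L ||
      !is.finite(min_split_contrast) || min_split_contrast < 0) {
    stop_param("`min_split_contrast` must be a nonnegative finite scalar")
  }
  check_positive_scalar(max_iters_per_pass, "max_iters_per_pass")
  check_positive_scalar(stationary_window, "stationary_window")
  check_positive_scalar(stationary_tol, "stationary_tol")
  if (tau * alpha >= 0.25) {
    stop_param(sprintf(
      "tau * alpha = %g violates the stability condition tau * alpha < 1/4 required for stable level set evolution",
      tau * alpha))
  }
  structure(list(
    lambda1 = lambda1, lambda2 = lambda2, mu = mu, v = v,
    tau = tau, alpha = alpha, eps = eps, eps_d = eps_d,
    rho = rho, kappa = kappa, min_split_contrast = min_split_contrast,
    max_iters_per_pass = as.integer(max_iters_per_pass),
    stationary_window = as.integer(stationary_window),
    stationary_tol = stationary_tol
  ), class = "mpac_params")
}

#' ROF denoising configuration
#'
#' @param lam fidelity weight (0-255 intensity scale).
#' @param n_iters descent iterations.
#' @param dt descent step.
#' @return an object of class `mpac_rof_config`.
#' @seealso [rof_denoise()]
#' @export
rof_config <- function(lam = 0.1, n_iters = 100L, dt = 0.1) {
  check_positive_scalar(lam, "lam")
  check_positive_scalar(n_iters, "n_iters")
  check_positive_scalar(dt, "dt")
  structure(list(lam = lam, n_iters = as.integer(n_iters), dt = dt),
            class = "mpac_rof_config")
}

#' @export
print.mpac_params <- function(x, ...) {
  cat("Multipass active contour parameters\n")
  cat(sprintf("  region weights  lambda1 = %g, lambda2 = %g\n",
              x$lambda1, x$lambda2))
  cat(sprintf("  length / area   mu = %g, v = %g\n", x$mu, x$v))
  cat(sprintf("  penalty         alpha = %g (tau * alpha = %g < 1/4)\n",
              x$alpha, x$tau * x$alpha))
  cat(sprintf("  stepping        tau = %g, max %d iters/pass, stationary window %d\n",
              x$tau, x$max_iters_per_pass, x$stationary_window))
  cat(sprintf("  regularization  eps = %g, eps_d = %g\n", x$eps, x$eps_d))
  cat(sprintf("  initialization  rho = %g, kappa = %g\n", x$rho, x$kappa))
  invisible(x)
}
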