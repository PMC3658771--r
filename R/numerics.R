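# Discrete operator toolbox for the level-set evolution: regularized
# Heaviside/Dirac pair, finite differences, normalized gradients, the
# curvature divergence and the 5-point Laplacian. All stencils use
# replicate-edge (Neumann) boundaries, the convention of the level-set
# literature, so nothing leaks through the image border.
#
# Coordinate convention throughout the package: the x axis runs along matrix
# rows (index i) and the y axis along columns (index j).

#' Regularized Heaviside function
#'
#' Smooth step \eqn{H_\epsilon(z) = \tfrac{1}{2}(1 + \tfrac{2}{\pi}
#' \arctan(z/\epsilon))}, used to weight the inside/outside of the zero
#' level set. Values are strictly inside (0, 1) and
#' \eqn{H_\epsilon(-z) = 1 - H_\epsilon(z)}.
#'
#' @param z numeric scalar, vector or matrix.
#' @param eps positive width of the regularization (default 1.5 pixels).
#' @return same shape as `z`.
#' @seealso [smooth_dirac()], its derivative.
#' @export
#' @examples
#' smooth_heaviside(0, 1.5)    # 0.5
#' smooth_heaviside(1.5, 1.5)  # 0.75
smooth_heaviside <- function(z, eps = 1.5) {
  check_positive_scalar(eps, "eps")
  0.5 * (1 + (2 / pi) * atan(z / eps))
}

#' Regularized Dirac delta
#'
#' \eqn{\delta_\epsilon(z) = \epsilon / (\pi (z^2 + \epsilon^2))}, the exact
#' derivative of [smooth_heaviside()]. Even, strictly positive, integrates
#' to 1 over the real line, with maximum \eqn{1/(\pi\epsilon)} at z = 0.
#'
#' @inheritParams smooth_heaviside
#' @return same shape as `z`.
#' @export
smooth_dirac <- function(z, eps = 1.5) {
  check_positive_scalar(eps, "eps")
  eps / (pi * (z^2 + eps^2))
}

# d/dz of smooth_dirac; needed by the exact gradient of the weighted
# length energy.
smooth_dirac_deriv <- function(z, eps = 1.5) {
  -2 * eps * z / (pi * (z^2 + eps^2)^2)
}

#' Finite differences on a 2-D grid
#'
#' Forward, backward or central differences along rows (`axis = "x"`) or
#' columns (`axis = "y"`), with replicate-edge boundaries, so e.g. the
#' forward x-difference on the last row is 0.
#'
#' @param field numeric matrix (at least 2x2).
#' @param axis "x" (rows) or "y" (columns).
#' @param scheme "forward", "backward" or "central".
#' @return matrix of the same shape.
#' @export
finite_differences <- function(field, axis = c("x", "y"),
                               scheme = c("forward", "backward", "central")) {
  axis <- tryCatch(match.arg(axis), error = function(e) stop_param(
    "`axis` must be one of \"x\", \"y\""))
  scheme <- tryCatch(match.arg(scheme), error = function(e) stop_param(
    "`scheme` must be one of \"forward\", \"backward\", \"central\""))
  check_field(field, "field", min_dim = 1L)
  if (length(field) < 2L) stop_param("`field` needs at least 2 entries")
  d <- if (axis == "x") c(1L, 0L) else c(0L, 1L)
  switch(scheme,
    forward  = shift_mat(field, d[1L], d[2L]) - field,
    backward = field - shift_mat(field, -d[1L], -d[2L]),
    central  = (shift_mat(field, d[1L], d[2L]) -
                  shift_mat(field, -d[1L], -d[2L])) / 2
  )
}

# Terse internal aliases used by the flow assembly (no re-validation).
fdxp <- function(m) shift_mat(m, 1L, 0L) - m
fdxm <- function(m) m - shift_mat(m, -1L, 0L)
fdxc <- function(m) (shift_mat(m, 1L, 0L) - shift_mat(m, -1L, 0L)) / 2
fdyp <- function(m) shift_mat(m, 0L, 1L) - m
fdym <- function(m) m - shift_mat(m, 0L, -1L)
fdyc <- function(m) (shift_mat(m, 0L, 1L) - shift_mat(m, 0L, -1L)) / 2

# Conservative divergence of a flux pair living on forward edges: backward
# differences with zero (no-flux) padding at the leading boundary. This is
# the exact discrete adjoint of the forward gradient, so flows assembled
# with it are exact negative gradients of their energies.
div_flux <- function(ax, ay) {
  axm <- shift_mat(ax, -1L, 0L)
  axm[1L, ] <- 0
  aym <- shift_mat(ay, 0L, -1L)
  aym[, 1L] <- 0
  (ax - axm) + (ay - aym)
}

#' Normalized gradient field
#'
#' Components of \eqn{\nabla\phi / |\nabla\phi|} with a small `eps_d` added
#' inside the square root of each denominator to prevent division by zero.
#' The pairing of difference schemes is the one used by the curvature
#' stencil: the x component divides the forward x-difference by
#' \eqn{\sqrt{(D_x^+\phi)^2 + (D_y^c\phi)^2 + \epsilon_d}} and the
#' y component mirrors it.
#'
#' @param field numeric matrix.
#' @param eps_d small positive division guard (default 1e-8).
#' @return list with matrices `nx` and `ny`.
#' @export
normalized_gradient <- function(field, eps_d = 1e-8) {
  check_field(field, "field", min_dim = 2L)
  check_positive_scalar(eps_d, "eps_d")
  ux <- fdxp(field)
  uy <- fdyp(field)
  uxc <- fdxc(field)
  uyc <- fdyc(field)
  list(nx = ux / sqrt(ux^2 + uyc^2 + eps_d),
       ny = uy / sqrt(uxc^2 + uy^2 + eps_d))
}

#' Curvature divergence
#'
#' Discrete \eqn{\mathrm{div}(\nabla\phi / |\nabla\phi|)}: backward
#' differences of the mixed forward/central normalized gradient of
#' [normalized_gradient()]. On a signed distance function of a disk this
#' recovers the analytic curvature \eqn{1/\rho} of the level set at
#' radius \eqn{\rho}.
#'
#' @inheritParams normalized_gradient
#' @return matrix of the same shape.
#' @export
curvature_divergence <- function(field, eps_d = 1e-8) {
  n <- normalized_gradient(field, eps_d)
  fdxm(n$nx) + fdym(n$ny)
}

#' Five-point Laplacian
#'
#' \eqn{\phi_{i+1,j} + \phi_{i-1,j} + \phi_{i,j+1} + \phi_{i,j-1} -
#' 4\phi_{i,j}} with replicate-edge boundaries.
#'
#' @param field numeric matrix (at least 3x3).
#' @return matrix of the same shape.
#' @export
laplacian <- function(field) {
  check_field(field, "field", min_dim = 3L)
  shift_mat(field, 1L, 0L) + shift_mat(field, -1L, 0L) +
    shift_mat(field, 0L, 1L) + shift_mat(field, 0L, -1L) - 4 * field
}
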