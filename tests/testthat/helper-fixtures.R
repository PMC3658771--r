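# Shared fixtures and independent oracles, all built in code.

# Signed distance function of a disk; pixel centers at 0-based integers.
disk_sdf <- function(n, radius, center = rep((n - 1) / 2, 2)) {
  ri <- matrix(0:(n - 1), n, n)
  ci <- matrix(0:(n - 1), n, n, byrow = TRUE)
  sqrt((ri - center[1])^2 + (ci - center[2])^2) - radius
}

# Independent brute-force energy oracle: naive double loop over pixels,
# recomputing every term from its defining formula (regularized Heaviside /
# Dirac written out, forward differences with replicate edges, eps_d inside
# the square root). Shares no code with total_energy().
naive_energy_oracle <- function(phi, image, g, mask, c1, c2, params) {
  nr <- nrow(phi); nc <- ncol(phi)
  H <- function(z) 0.5 * (1 + (2 / pi) * atan(z / params$eps))
  D <- function(z) params$eps / (pi * (z^2 + params$eps^2))
  e <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ip <- min(i + 1L, nr)
      jp <- min(j + 1L, nc)
      dx <- phi[ip, j] - phi[i, j]
      dy <- phi[i, jp] - phi[i, j]
      s <- sqrt(dx^2 + dy^2 + params$eps_d)
      e <- e +
        params$lambda1 * (image[i, j] - c1)^2 * H(-phi[i, j]) * mask[i, j] +
        params$lambda2 * (image[i, j] - c2)^2 * H(phi[i, j]) * mask[i, j] +
        params$mu * g[i, j] * D(phi[i, j]) * s +
        params$v * g[i, j] * H(-phi[i, j]) +
        params$alpha * 0.5 * (s - 1)^2
    }
  }
  e
}

# A random 16x16 configuration (image, phi, mask, g) for oracle checks.
random_config <- function(n = 16) {
  img <- matrix(stats::runif(n * n, 0, 255), n, n)
  list(image = img,
       phi = matrix(stats::runif(n * n, -8, 8), n, n),
       mask = matrix(rbinom(n * n, 1, 0.8), n, n),
       g = edge_indicator(img))
}

# Central finite difference of the energy wrt one pixel of phi.
energy_fd <- function(phi, image, g, mask, c1, c2, params, i, j, h = 1e-3) {
  pp <- phi; pp[i, j] <- pp[i, j] + h
  pm <- phi; pm[i, j] <- pm[i, j] - h
  (total_energy(pp, image, g, mask, c1, c2, params) -
     total_energy(pm, image, g, mask, c1, c2, params)) / (2 * h)
}

# Forward-difference gradient magnitude, for band measurements in tests.
grad_mag <- function(phi) {
  sqrt(finite_differences(phi, "x", "forward")^2 +
         finite_differences(phi, "y", "forward")^2)
}

# Small bright-square test image: side^2 square of intensity `hi` centered
# in an n x n field of `lo`.
square_image <- function(n = 64, side = 20, lo = 50, hi = 200) {
  img <- matrix(lo, n, n)
  a <- (n - side) %/% 2 + 1
  img[a:(a + side - 1), a:(a + side - 1)] <- hi
  img
}
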