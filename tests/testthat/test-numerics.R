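test_that("regularized Heaviside matches closed forms and its symmetry", {
  expect_equal(smooth_heaviside(0, 1.5), 0.5)
  expect_equal(smooth_heaviside(1.5, 1.5), 0.75)  # arctan(1) = pi/4
  expect_equal(smooth_heaviside(1e6, 1.5), 1, tolerance = 1e-5)
  set.seed(1)
  z <- stats::runif(1000, -50, 50)
  for (eps in c(0.5, 1.5, 4)) {
    h <- smooth_heaviside(z, eps)
    expect_true(all(h > 0 & h < 1))
    expect_equal(h + smooth_heaviside(-z, eps), rep(1, length(z)))
  }
  expect_error(smooth_heaviside(0, -1), class = "mpac_param_error")
})

test_that("regularized Dirac is the Heaviside derivative and integrates to one", {
  expect_equal(smooth_dirac(0, 1.5), 1 / (1.5 * pi))
  expect_equal(smooth_dirac(1.5, 1.5), 1 / (3 * pi))
  set.seed(2)
  z <- stats::runif(100, -20, 20)
  d <- smooth_dirac(z, 1.5)
  expect_true(all(d > 0))
  expect_equal(d, smooth_dirac(-z, 1.5))
  expect_true(all(d <= smooth_dirac(0, 1.5)))
  # finite-difference derivative of H matches delta
  h <- 1e-4
  fd <- (smooth_heaviside(z + h, 1.5) - smooth_heaviside(z - h, 1.5)) / (2 * h)
  expect_equal(fd, d, tolerance = 1e-6)
  # quadrature oracle: integral over [-100, 100] is ~1
  q <- stats::integrate(smooth_dirac, -100, 100, eps = 1.5)$value
  expect_equal(q, 1, tolerance = 1e-2)
  expect_error(smooth_dirac(0, 0), class = "mpac_param_error")
})

test_that("finite differences are exact on constants, planes and sequences", {
  const <- matrix(7, 5, 5)
  for (sch in c("forward", "backward", "central")) {
    for (ax in c("x", "y")) {
      expect_equal(finite_differences(const, ax, sch), matrix(0, 5, 5))
    }
  }
  # phi(i, j) = 3 i + 5 j on a 4x4 grid: every x scheme gives 3 inside
  ij <- expand.grid(i = 1:4, j = 1:4)
  lin <- matrix(3 * ij$i + 5 * ij$j, 4, 4)
  for (sch in c("forward", "backward", "central")) {
    expect_equal(finite_differences(lin, "x", sch)[2:3, 2:3],
                 matrix(3, 2, 2))
    expect_equal(finite_differences(lin, "y", sch)[2:3, 2:3],
                 matrix(5, 2, 2))
  }
  # sequence 0, 1, 4, 9 along x: forward differences 1, 3, 5, then 0 at
  # the replicate boundary
  col <- matrix(c(0, 1, 4, 9), 4, 1)
  expect_equal(as.vector(finite_differences(col, "x", "forward")),
               c(1, 3, 5, 0))
  expect_equal(as.vector(finite_differences(col, "x", "backward")),
               c(0, 1, 3, 5))
  expect_error(finite_differences(const, "z", "forward"),
               class = "mpac_param_error")
  expect_error(finite_differences(const, "x", "upwind"),
               class = "mpac_param_error")
})

test_that("normalized gradient has unit magnitude along slopes and bounded norm", {
  n <- 12
  xi <- matrix(1:n, n, n)
  yj <- matrix(1:n, n, n, byrow = TRUE)
  ng <- normalized_gradient(xi, 1e-8)
  expect_equal(ng$nx[2:(n - 2), 2:(n - 2)],
               matrix(1, n - 3, n - 3), tolerance = 1e-6)
  expect_equal(ng$ny[2:(n - 2), 2:(n - 2)],
               matrix(0, n - 3, n - 3), tolerance = 1e-6)
  ng0 <- normalized_gradient(matrix(4, n, n), 1e-8)
  expect_equal(ng0$nx, matrix(0, n, n))
  expect_equal(ng0$ny, matrix(0, n, n))
  ngd <- normalized_gradient(xi + yj, 1e-8)
  expect_equal(ngd$nx[2:(n - 2), 2:(n - 2)],
               matrix(1 / sqrt(2), n - 3, n - 3), tolerance = 1e-6)
  # each component is a ratio against a dominating root, so bounded by 1;
  # the pair uses mixed denominators, so only the sqrt(2) bound is exact
  set.seed(3)
  r <- matrix(stats::rnorm(n * n), n, n)
  ngr <- normalized_gradient(r, 1e-8)
  expect_true(all(abs(ngr$nx) <= 1 & abs(ngr$ny) <= 1))
  expect_true(all(ngr$nx^2 + ngr$ny^2 <= 2))
})

test_that("curvature divergence recovers 1/rho on disk signed distance fields", {
  phi <- disk_sdf(101, 20)
  k <- curvature_divergence(phi, 1e-8)
  r <- phi + 20
  on10 <- abs(r - 10) < 0.5
  expect_equal(mean(k[on10]), 0.1, tolerance = 0.02 / 0.1)
  # property over radii 10..30: curvature at the level set of radius rho
  for (rho in c(10, 20, 30)) {
    phi <- disk_sdf(101, rho)
    k <- curvature_divergence(phi, 1e-8)
    band <- abs(phi) < 0.5
    expect_equal(mean(k[band]), 1 / rho, tolerance = 0.1)
  }
  # planes and constants have zero curvature
  n <- 10
  plane <- matrix(1:n, n, n) + matrix(1:n, n, n, byrow = TRUE)
  expect_equal(curvature_divergence(plane, 1e-8)[3:8, 3:8],
               matrix(0, 6, 6), tolerance = 1e-4)
  expect_equal(curvature_divergence(matrix(2, n, n), 1e-8), matrix(0, n, n))
})

test_that("laplacian matches the 5-point stencil", {
  n <- 9
  plane <- matrix(3 * (1:n), n, n)
  expect_equal(laplacian(plane)[2:(n - 1), 2:(n - 1)], matrix(0, n - 2, n - 2))
  sq <- matrix((1:n)^2, n, n)
  expect_equal(laplacian(sq)[2:(n - 1), 2:(n - 1)], matrix(2, n - 2, n - 2))
  imp <- matrix(0, 5, 5)
  imp[3, 3] <- 1
  l <- laplacian(imp)
  expect_equal(l[3, 3], -4)
  expect_equal(l[2, 3], 1)
  expect_equal(l[3, 2], 1)
  expect_equal(l[4, 3], 1)
  expect_equal(l[3, 4], 1)
})

test_that("operators preserve shape and stay finite on random inputs", {
  set.seed(4)
  for (dims in list(c(5, 9), c(12, 7))) {
    m <- matrix(stats::rnorm(prod(dims), sd = 10), dims[1], dims[2])
    out <- list(finite_differences(m, "x", "central"),
                normalized_gradient(m)$nx,
                curvature_divergence(m),
                laplacian(m),
                smooth_heaviside(m),
                smooth_dirac(m))
    for (o in out) {
      expect_identical(dim(o), dim(m))
      expect_true(all(is.finite(o)))
    }
  }
})
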