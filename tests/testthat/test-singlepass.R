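test_that("initial level set seeds the darkest pixels of the base region", {
  n <- 8
  img <- matrix(100, n, n)
  img[3, 5] <- 10          # unique minimum
  img[6, 2] <- 10.5        # within kappa of it
  full <- matrix(1L, n, n)
  phi <- init_level_set(img, full, rho = 6, kappa = 1)
  expect_setequal(unique(as.vector(phi)), c(6, -6))
  expect_equal(phi[3, 5], 6)
  expect_equal(phi[6, 2], 6)
  expect_equal(sum(phi == 6), 2)

  # constant region: every pixel is within kappa of the minimum
  phi_c <- init_level_set(matrix(77, n, n), full, rho = 6, kappa = 1)
  expect_true(all(phi_c == 6))

  # masked bright square on dark background: outside-mask pixels and the
  # square's own darkest pixels get +rho, the rest of the square -rho
  img2 <- square_image(16, 6, 40, 200)
  img2[7, 7] <- 180  # darkest pixel of the square
  mask <- matrix(0L, 16, 16)
  mask[img2 > 100] <- 1L
  phi2 <- init_level_set(img2, mask, rho = 6, kappa = 1)
  expect_true(all(phi2[mask == 0] == 6))
  expect_equal(phi2[7, 7], 6)
  expect_true(all(phi2[mask == 1 & img2 == 200] == -6))

  expect_error(init_level_set(img, matrix(0L, n, n), 6, 1),
               class = "mpac_degenerate_error")
})

test_that("region means are Heaviside-weighted means restricted to the mask", {
  # phi identically -6: both sides weight every pixel equally, so both
  # means equal the global mean (9 pixels keep the residual outer weight
  # above the degeneracy threshold)
  img <- matrix(10 * (1:9), 3, 3)
  full3 <- matrix(1L, 3, 3)
  rm1 <- region_means(img, matrix(-6, 3, 3), full3, eps = 1.5)
  expect_equal(rm1$c1, 50)
  expect_equal(rm1$c2, 50)
  full <- matrix(1L, 2, 2)

  # [[0, 0], [100, 100]], phi negative exactly on the 100-row; hand-derived
  # smoothed weights H_eps(6) = h1, H_eps(-6) = 1 - h1
  img2 <- matrix(c(0, 100, 0, 100), 2, 2)
  phi2 <- matrix(c(6, -6, 6, -6), 2, 2)
  h1 <- 0.5 * (1 + (2 / pi) * atan(4))
  rm2 <- region_means(img2, phi2, full, eps = 1.5)
  expect_equal(rm2$c1, 100 * h1)        # 92.20 with these weights
  expect_equal(rm2$c2, 100 * (1 - h1))  # 7.80
  # binary-Heaviside oracle (c1 = 100, c2 = 0) brackets the smoothed means
  expect_true(rm2$c1 < 100 && rm2$c1 > 50)
  expect_true(rm2$c2 > 0 && rm2$c2 < 50)

  # mask excluding the bright row entirely: the restriction zeroes those
  # pixels, so both means collapse to the remaining value
  img3 <- matrix(0, 4, 4)
  img3[2, ] <- 100
  phi3 <- matrix(6, 4, 4)
  phi3[2, ] <- -6
  mask3 <- matrix(1L, 4, 4)
  mask3[2, ] <- 0L
  rm3 <- region_means(img3, phi3, mask3, eps = 1.5)
  expect_equal(rm3$c1, 0)
  expect_equal(rm3$c2, 0)

  # a tiny mask with phi strongly positive: weighted inner area under the
  # degeneracy threshold
  img4 <- matrix(50, 12, 12)
  mask4 <- matrix(0L, 12, 12)
  mask4[1:5, 1] <- 1L
  expect_error(region_means(img4, matrix(60, 12, 12), mask4, eps = 1.5),
               class = "mpac_degenerate_error")
})

test_that("gradient flow vanishes on equilibrium configurations", {
  p <- algo_params()
  phi <- disk_sdf(41, 12)
  img <- matrix(120, 41, 41)
  g <- edge_indicator(img)
  full <- matrix(1L, 41, 41)
  q <- gradient_flow(phi, img, g, full, 120, 120, p)
  # data terms vanish (c1 = c2 = I) and the penalty vanishes where
  # |grad phi| = 1; away from the distance function's center cusp and the
  # replicated border only a small curvature residue remains
  interior <- phi > -9 & row(phi) > 2 & row(phi) < 40 & col(phi) > 2 & col(phi) < 40
  expect_lt(max(abs(q[interior])), 0.05)
})

test_that("the signed-distance penalty diffuses toward unit gradient", {
  p <- algo_params()
  phi2 <- 2 * disk_sdf(41, 12)   # |grad phi| = 2 everywhere
  img <- matrix(120, 41, 41)
  g <- edge_indicator(img)
  full <- matrix(1L, 41, 41)
  q <- gradient_flow(phi2, img, g, full, 120, 120, p)
  p_energy <- function(phi) sum(0.5 * (grad_mag(phi) - 1)^2)
  # one explicit step strictly decreases the penalty energy
  expect_lt(p_energy(phi2 + p$tau * q), p_energy(phi2))
})

test_that("data forces push pixels toward the closer region mean", {
  p <- algo_params(mu = 1e-12)  # isolate the data term (mu = 0 allowed too)
  n <- 9
  img <- matrix(100, n, n)
  img[5, 5] <- 250
  g <- edge_indicator(img)
  full <- matrix(1L, n, n)
  phi <- matrix(6, n, n)  # flat, so penalty/length contributions are zero-ish
  # c1 = 240, c2 = 90: lambda1 (I - c1)^2 < lambda2 (I - c2)^2 at the pixel
  q <- gradient_flow(phi, img, g, full, 240, 90, p)
  expect_lt(q[5, 5], 0)   # driven inside (phi decreases)
  q2 <- gradient_flow(phi, img, g, full, 90, 240, p)
  expect_gt(q2[5, 5], 0)  # with means swapped it is driven outside
})

test_that("the flow is the exact negative gradient of the energy", {
  set.seed(20)
  p <- algo_params()
  cfg <- random_config(16)
  rm <- region_means(cfg$image, cfg$phi, cfg$mask, p$eps)
  q <- gradient_flow(cfg$phi, cfg$image, cfg$g, cfg$mask, rm$c1, rm$c2, p)
  for (rep in 1:10) {
    i <- sample(16, 1)
    j <- sample(16, 1)
    fd <- energy_fd(cfg$phi, cfg$image, cfg$g, cfg$mask, rm$c1, rm$c2, p, i, j)
    expect_equal(-q[i, j], fd, tolerance = 1e-4)
  }
})

test_that("total energy agrees with the naive pixel-loop oracle", {
  set.seed(21)
  p <- algo_params(v = 0.5)  # exercise the area term too
  for (rep in 1:5) {
    cfg <- random_config(12)
    c1 <- stats::runif(1, 0, 255)
    c2 <- stats::runif(1, 0, 255)
    e <- total_energy(cfg$phi, cfg$image, cfg$g, cfg$mask, c1, c2, p)
    o <- naive_energy_oracle(cfg$phi, cfg$image, cfg$g, cfg$mask, c1, c2, p)
    expect_equal(e, o, tolerance = 1e-12)
    expect_true(is.finite(e) && e >= 0)
  }
})

test_that("energy terms vanish individually on their null configurations", {
  phi <- disk_sdf(41, 12)
  img <- matrix(120, 41, 41)
  g <- edge_indicator(img)
  full <- matrix(1L, 41, 41)
  # with c1 = c2 = I both region terms are exactly zero
  p00 <- algo_params(mu = 0, alpha = 1e-15)
  expect_lt(total_energy(phi, img, g, full, 120, 120, p00), 1e-6)
  # on the signed distance field, with the penalty switched off, the
  # energy is the weighted length alone
  p <- algo_params(alpha = 1e-15)
  e <- total_energy(phi, img, g, full, 120, 120, p)
  lg <- sum(g * smooth_dirac(phi, p$eps) * grad_mag(phi))
  expect_equal(e, p$mu * lg, tolerance = 1e-4)

  # closed-form penalty: |grad phi| = 2 over N pixels -> P ~ N / 2
  pd <- algo_params()
  n <- 20
  phi2 <- 2 * matrix(1:n, n, n)
  e2 <- total_energy(phi2, matrix(0, n, n), matrix(1, n, n),
                     matrix(1L, n, n), 0, 0, pd)
  expect_equal(e2 / pd$alpha, n * n / 2, tolerance = 0.01)
})

test_that("a pass segments a bright square and reports its means", {
  img <- square_image(64, 20, 50, 200)
  g <- edge_indicator(img)
  full <- matrix(1L, 64, 64)
  pass <- evolve_pass(img, g, full, algo_params())
  truth <- matrix(0L, 64, 64)
  truth[img == 200] <- 1L
  expect_gte(region_agreement(pass$inner_mask, truth), 0.95)
  expect_equal(pass$c1, 200, tolerance = 0.01)
  expect_equal(pass$c2, 50, tolerance = 0.01)
  expect_true(pass$terminated_by %in% c("stationary", "max_iters"))
  # exact partition of the base region
  expect_true(all(pass$inner_mask + pass$outer_mask == full))
  # reruns are bit-identical: no randomness anywhere
  pass2 <- evolve_pass(img, g, full, algo_params())
  expect_identical(pass, pass2)
})

test_that("a constant image degenerates immediately", {
  img <- matrix(128, 32, 32)
  pass <- evolve_pass(img, edge_indicator(img), matrix(1L, 32, 32))
  expect_equal(pass$terminated_by, "degenerate_empty_inner")
  expect_equal(pass$n_iters, 0L)
  expect_equal(sum(pass$inner_mask), 0)
})

test_that("energy is non-increasing over a pass on a noise-free phantom", {
  img <- square_image(64, 20, 50, 200)
  pass <- evolve_pass(img, edge_indicator(img), matrix(1L, 64, 64))
  tr <- pass$energy_trace
  expect_gt(length(tr), 1)
  expect_lte(max(diff(tr)), 0.01 * tr[1])
})

test_that("the penalty restores a unit-gradient band where forcing is weak", {
  # deep passes split near-homogeneous regions: there the region forces are
  # comparable to the penalty and the level set anneals to a signed-
  # distance profile around its contour
  ph <- make_nested_phantom(phantom_spec(shape = c(64, 64),
                                         levels = c(50, 200),
                                         noise_frac = 0.05, seed = 3))
  res <- run_multipass(ph$image, algo_params(min_split_contrast = 0),
                       max_passes = 4)
  deep <- res$passes[-1]
  expect_gte(length(deep), 2)
  for (pass in deep) {
    band <- abs(pass$phi_final) < 3
    expect_gt(sum(band), 50)
    med <- stats::median(grad_mag(pass$phi_final)[band])
    expect_gte(med, 0.7)
    expect_lte(med, 1.3)
  }
})
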