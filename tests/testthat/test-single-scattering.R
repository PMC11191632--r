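test_that("Mueller matrix action on Stokes vectors has the exact circular limits", {
  el0 <- mueller_elements(1.195, pi * 11 * 1.33, 0)
  elp <- mueller_elements(1.195, pi * 11 * 1.33, pi)
  rcp <- stokes_vector(1, 0, 0, 1)
  s0 <- scatter_stokes(rcp, el0)
  sp <- scatter_stokes(rcp, elp)
  expect_equal(s0[["S3"]] / s0[["S0"]], 1, tolerance = 1e-12)
  expect_equal(sp[["S3"]] / sp[["S0"]], -1, tolerance = 1e-12)

  # unpolarized light picks up no circular component from a sphere
  unpol <- stokes_vector(1, 0, 0, 0)
  for (th in c(0.4, 1.3, 2.8)) {
    el <- mueller_elements(1.195, 10, th)
    expect_equal(scatter_stokes(unpol, el)[["S3"]], 0)
  }
})

test_that("scattering preserves the polarization bound", {
  set.seed(7)
  for (k in 1:50) {
    p <- runif(3, -0.6, 0.6)
    s_in <- stokes_vector(1, p[1], p[2], p[3])
    el <- mueller_elements(runif(1, 1.02, 1.8), runif(1, 0.5, 30), runif(1, 0, pi))
    s_out <- scatter_stokes(s_in, el)
    expect_lte(s_out[["S1"]]^2 + s_out[["S2"]]^2 + s_out[["S3"]]^2,
               s_out[["S0"]]^2 * (1 + 1e-9))
  }
})

test_that("Stokes rotations preserve S0, S3 and linear magnitude and compose to identity", {
  expect_equal(unclass(rotate_stokes(stokes_vector(1, 1, 0, 0), pi / 2)),
               c(S0 = 1, S1 = -1, S2 = 0, S3 = 0))
  set.seed(8)
  for (k in 1:25) {
    s <- stokes_vector(1, runif(1, -0.5, 0.5), runif(1, -0.5, 0.5), runif(1, -0.5, 0.5))
    psi <- runif(1, -pi, pi)
    r <- rotate_stokes(s, psi)
    expect_equal(r[["S0"]], s[["S0"]], tolerance = 1e-12)
    expect_equal(r[["S3"]], s[["S3"]], tolerance = 1e-12)
    expect_equal(r[["S1"]]^2 + r[["S2"]]^2, s[["S1"]]^2 + s[["S2"]]^2,
                 tolerance = 1e-12)
    back <- rotate_stokes(r, -psi)
    expect_equal(unclass(back), unclass(s), tolerance = 1e-12)
    expect_equal(unclass(rotate_stokes(s, pi)), unclass(s), tolerance = 1e-12)
  }
})

test_that("angular profile endpoints pin the degree of circular polarization", {
  prof <- angular_profile(optical_context(1000, 9))
  expect_equal(prof$s3[1], 1, tolerance = 1e-9)
  expect_equal(prof$s3[nrow(prof)], -1, tolerance = 1e-9)
  expect_true(all(prof$intensity >= 0))
  expect_true(all(abs(prof$s3) <= 1 + 1e-9))
})

test_that("forward scattering dominates and smaller X has larger backscatter fraction", {
  p11 <- angular_profile(optical_context(1000, 11))
  p9 <- angular_profile(optical_context(1000, 9))
  over10 <- p11$theta > 10 * pi / 180
  expect_true(all(p11$intensity[1] > p11$intensity[over10]))
  back_frac <- function(p) {
    w <- p$intensity * sin(p$theta)
    sum(w[p$theta >= pi / 2]) / sum(w)
  }
  expect_gt(back_frac(p9), back_frac(p11))
})

test_that("Rayleigh-regime profile matches the closed-form dipole pattern", {
  ctx <- optical_context(1000, 1e-2 / (pi * 1.33))  # x = 1e-2
  th <- seq(0, pi, length.out = 181)
  prof <- angular_profile(ctx, theta_grid = th)
  expect_equal(prof$s3, 2 * cos(th) / (1 + cos(th)^2), tolerance = 1e-4)
})

test_that("expected single-scattering S3 matches a brute-force Riemann sum", {
  m <- 1.195
  for (X in c(2, 9, 17)) {
    x <- pi * X * 1.33
    th <- seq(0, pi, length.out = 1e5 + 1)
    el <- mueller_elements(m, x, th)
    brute <- sum(el$M33 * sin(th)) / sum(el$M11 * sin(th))
    expect_equal(expected_s3_single(m, X), brute, tolerance = 1e-4,
                 label = sprintf("<S3> at X = %g", X))
  }
})

test_that("expected S3 lies in [-1, 1] and vanishes in the Rayleigh limit", {
  vals <- vapply(c(0.01, 0.005, 0.002), function(X) {
    expected_s3_single(1.195, X)
  }, numeric(1))
  expect_true(all(abs(vals) <= 1))
  expect_true(all(abs(vals) < 5e-4))
  expect_true(all(diff(abs(vals)) < 0))  # vanishes quadratically with X
  expect_lt(abs(expected_s3_single(1.195, 9)), 1)
})

test_that("forward-cone intensity fraction increases with X", {
  Xs <- seq(1, 30, 1)
  frac <- vapply(Xs, function(X) {
    x <- pi * X * 1.33
    th <- seq(0, pi, length.out = 2001)
    el <- mueller_elements(1.195, x, th)
    w <- el$M11 * sin(th)
    sum(w[th < 5 * pi / 180]) / sum(w)
  }, numeric(1))
  # resonance ripple sits on top of the trend; test the ripple-averaged curve
  sm <- stats::filter(frac, rep(1 / 5, 5), sides = 2)
  ok <- !is.na(sm)
  expect_gt(suppressWarnings(cor(Xs[ok], as.numeric(sm[ok]),
                                 method = "spearman")), 0.8)
})

test_that("minima detection handles degenerate and synthetic curves", {
  expect_error(find_depolarization_minima(data.frame(X = numeric(), s3 = numeric())),
               "empty")
  mono <- data.frame(X = seq(1, 10, 0.05), s3 = seq(1, 0.5, length.out = 181))
  expect_equal(nrow(find_depolarization_minima(mono)), 0L)

  xs <- seq(0, 20, 0.05)
  synth <- find_depolarization_minima(data.frame(X = xs, s3 = cos(xs) + xs / 100),
                                      smooth_window = 0)
  expect_equal(synth$X, c(pi, 3 * pi, 5 * pi), tolerance = 0.02)
})

test_that("minima locations are stable under 2x theta-grid refinement", {
  Xs <- seq(8, 13, 0.05)
  coarse <- vapply(Xs, function(X) expected_s3_single(1.195, X, max_refine = 0L),
                   numeric(1))
  fine <- vapply(Xs, function(X) expected_s3_single(1.195, X, max_refine = 1L),
                 numeric(1))
  m_c <- find_depolarization_minima(data.frame(X = Xs, s3 = coarse))
  m_f <- find_depolarization_minima(data.frame(X = Xs, s3 = fine))
  expect_equal(nrow(m_c), nrow(m_f))
  expect_true(all(abs(m_c$X - m_f$X) < 0.05))
})
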