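test_that("Riccati-Bessel functions match closed forms and half-integer Bessel oracle", {
  rb <- riccati_bessel(2, 5)
  expect_equal(rb$psi[1], sin(2) / 2 - cos(2), tolerance = 1e-12)

  # independent oracle: psi_n = x j_n = sqrt(pi x / 2) J_{n+1/2}(x),
  # chi-part from Y_{n+1/2}
  x <- 10
  n_max <- 12
  rb <- riccati_bessel(x, n_max)
  n <- seq_len(n_max)
  psi_oracle <- sqrt(pi * x / 2) * besselJ(x, n + 0.5)
  y_oracle <- sqrt(pi / (2 * x)) * besselY(x, n + 0.5)
  expect_equal(rb$psi, psi_oracle, tolerance = 1e-10)
  expect_equal(rb$xi, complex(real = psi_oracle, imaginary = x * y_oracle),
               tolerance = 1e-10)
})

test_that("xi_n - psi_n = i x y_n identity holds on a grid of arguments", {
  for (x in c(0.5, 1, 5, 20)) {
    n_max <- 8
    rb <- riccati_bessel(x, n_max)
    y <- sqrt(pi / (2 * x)) * besselY(x, seq_len(n_max) + 0.5)
    expect_equal(rb$xi - rb$psi, 1i * x * y, tolerance = 1e-9,
                 label = sprintf("xi - psi at x = %g", x))
  }
})

test_that("riccati_bessel rejects invalid arguments", {
  expect_error(riccati_bessel(NaN, 3))
  expect_error(riccati_bessel(0, 3))
})

test_that("Mie coefficients reach the Rayleigh closed form as x -> 0", {
  m <- 1.195
  x <- 1e-3
  co <- mie_coefficients(m, x, n_max = 3)
  a1_closed <- -2i / 3 * x^3 * (m^2 - 1) / (m^2 + 2)
  expect_lt(Mod(co$a[1] / a1_closed - 1), 1e-6)
})

test_that("index-matched sphere has zero coefficients, with a warning", {
  expect_warning(co <- mie_coefficients(1, 10), "index-matched")
  expect_true(all(co$a == 0) && all(co$b == 0))
})

test_that("Mie series agrees term-by-term with the direct Riccati-Bessel evaluation", {
  # non-recursive oracle: evaluate Eq. coefficients straight from the
  # Riccati-Bessel functions at x and m x
  m <- 1.195
  x <- pi * 9 * 1.33
  co <- mie_coefficients(m, x)
  rb_x <- riccati_bessel(x, co$n_max)
  rb_mx <- riccati_bessel(m * x, co$n_max)
  a_direct <- (m * rb_mx$psi * rb_x$dpsi - rb_x$psi * rb_mx$dpsi) /
              (m * rb_mx$psi * rb_x$dxi - rb_x$xi * rb_mx$dpsi)
  b_direct <- (rb_mx$psi * rb_x$dpsi - m * rb_x$psi * rb_mx$dpsi) /
              (rb_mx$psi * rb_x$dxi - m * rb_x$xi * rb_mx$dpsi)
  expect_equal(co$a, a_direct, tolerance = 1e-9)
  expect_equal(co$b, b_direct, tolerance = 1e-9)
})

test_that("Mie coefficients are passive and the series is converged", {
  for (x in c(0.5, 5, 37.6)) {
    co <- mie_coefficients(1.195, x)
    expect_true(all(Mod(co$a) <= 1 + 1e-12))
    expect_true(all(Mod(co$b) <= 1 + 1e-12))
    tail_mag <- Mod(co$a[co$n_max]) + Mod(co$b[co$n_max])
    expect_lt(tail_mag, 1e-10 * max(Mod(co$a) + Mod(co$b)))
  }
})

test_that("angular functions obey their recurrence seeds and polar limits", {
  ang <- angular_functions(0.7, 6)
  expect_equal(ang$pi_n[1, 1], 1)
  expect_equal(ang$tau_n[1, 1], cos(0.7))

  # theta = 0: pi_n = tau_n = n(n+1)/2; theta = pi: alternating signs
  n <- 1:10
  a0 <- angular_functions(0, 10)
  expect_equal(a0$pi_n[, 1], n * (n + 1) / 2)
  expect_equal(a0$tau_n[, 1], n * (n + 1) / 2)
  api <- angular_functions(pi, 10)
  expect_equal(api$pi_n[, 1], (-1)^(n + 1) * n * (n + 1) / 2)
  expect_equal(api$tau_n[, 1], -(-1)^(n + 1) * n * (n + 1) / 2)

  expect_error(angular_functions(-0.5, 4))
  expect_error(angular_functions(3.5, 4))
})

test_that("amplitude functions have the exact forward/backward symmetries", {
  m <- 1.195
  x <- 12.3
  co <- mie_coefficients(m, x)
  amp <- amplitude_functions(m, x, c(0, pi), coefficients = co)
  s_forward <- sum((2 * seq_len(co$n_max) + 1) * (co$a + co$b)) / 2
  expect_equal(amp$M1[1], s_forward, tolerance = 1e-12)
  expect_equal(amp$M2[1], s_forward, tolerance = 1e-12)
  expect_equal(amp$M1[2], -amp$M2[2], tolerance = 1e-10)
})

test_that("truncated amplitudes match an over-truncated direct sum", {
  m <- 1.195
  x <- 20
  th <- seq(0, pi, length.out = 181)
  amp <- amplitude_functions(m, x, th)
  co4 <- mie_coefficients(m, x, n_max = 4L * mie_n_max(x))
  amp4 <- amplitude_functions(m, x, th, coefficients = co4)
  expect_equal(Mod(amp$M1)^2, Mod(amp4$M1)^2, tolerance = 1e-8)
  expect_equal(Mod(amp$M2)^2, Mod(amp4$M2)^2, tolerance = 1e-8)
})

test_that("Mueller elements satisfy the pure-Mueller identity on random draws", {
  set.seed(42)
  for (k in 1:40) {
    m <- runif(1, 1.01, 2)
    x <- runif(1, 0.1, 40)
    th <- runif(25, 0, pi)
    el <- mueller_elements(m, x, th)
    expect_true(all(el$M11 >= 0))
    expect_equal(el$M11^2, el$M12^2 + el$M33^2 + el$M34^2,
                 tolerance = 1e-9)
    expect_true(all(abs(el$M12) <= el$M11 * (1 + 1e-12)))
    expect_true(all(abs(el$M33) <= el$M11 * (1 + 1e-12)))
    expect_true(all(abs(el$M34) <= el$M11 * (1 + 1e-12)))
  }
})

test_that("forward and backward Mueller limits hold for every (m, x)", {
  for (m in c(1.05, 1.195, 1.8)) for (x in c(0.3, 7, 46)) {
    el <- mueller_elements(m, x, c(0, pi))
    expect_equal(el$M33[1] / el$M11[1], 1, tolerance = 1e-12)
    expect_equal(el$M12[1], 0, tolerance = 1e-9 * el$M11[1])
    expect_equal(el$M33[2] / el$M11[2], -1, tolerance = 1e-10)
  }
})

test_that("Rayleigh limit reproduces the dipole circular-depolarization pattern", {
  th <- seq(0.05, pi - 0.05, length.out = 60)
  el <- mueller_elements(1.195, 1e-2, th)
  expect_equal(el$M33 / el$M11, 2 * cos(th) / (1 + cos(th)^2), tolerance = 1e-4)
})

test_that("results are stable when the truncation order is doubled", {
  m <- 1.195
  x <- 25
  th <- seq(0, pi, length.out = 91)
  e1 <- mueller_elements(m, x, th)
  e2 <- mueller_elements(m, x, th,
                         coefficients = mie_coefficients(m, x, 2L * mie_n_max(x)))
  expect_equal(e1$M11, e2$M11, tolerance = 1e-8)
  expect_equal(e1$M33, e2$M33, tolerance = 1e-8)
})

test_that("all elements vanish smoothly as m -> 1", {
  th <- c(0.3, 1.2, 2.4)
  norms <- vapply(c(1.1, 1.01, 1.001), function(m) {
    el <- mueller_elements(m, 5, th)
    max(abs(unlist(el[c("M11", "M12", "M33", "M34")])))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[3] / norms[1], 1e-3)
})

test_that("optical context derives m, x and X consistently", {
  ctx <- optical_context(1000, 9)
  expect_equal(ctx$m, 1.59 / 1.33)
  expect_equal(ctx$X, 9)
  expect_equal(ctx$x, pi * 9 * 1.33)
  expect_equal(ctx$X, ctx$x / (pi * ctx$n_medium))
  expect_error(optical_context(-500, 9))
  expect_error(optical_context(1000, 0))
})
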