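test_that("free-path sampling follows the exponential law", {
  expect_equal(-log(exp(-1)) / 6.96, 1 / 6.96)  # closed form anchor
  set.seed(1)
  s <- sample_step(6.96, 1e5)
  expect_true(all(s >= 0))
  expect_lt(abs(mean(s) - 1 / 6.96), 3 * sd(s) / sqrt(length(s)))
  expect_error(sample_step(0))
})

test_that("rejection sampler reproduces the polarized phase density", {
  tb <- phase_table(1.195, pi * 5 * 1.33)
  set.seed(4)
  ang <- rejection_sample_angles(stokes_vector(1, 0, 0, 1), table = tb, n = 1e5)

  # circular input: phi marginal uniform
  p_phi <- chisq.test(table(cut(ang$phi, seq(0, 2 * pi, length.out = 37))))$p.value
  expect_gt(p_phi, 0.01)

  # theta marginal matches the quadrature CDF of M11 sin(theta)
  cdf_fun <- approxfun(tb$theta, tb$cdf)
  p_th <- suppressWarnings(ks.test(ang$theta, cdf_fun))$p.value
  expect_gt(p_th, 0.01)

  # mean emitted s3 equals the quadrature expectation (dual route)
  el <- mueller_elements(1.195, pi * 5 * 1.33, ang$theta)
  s3 <- el$M33 / el$M11
  expect_lt(abs(mean(s3) - expected_s3_single(1.195, 5)),
            4 * sd(s3) / sqrt(length(s3)))
})

test_that("Rayleigh-regime sampler reproduces the dipole phase function", {
  tb <- phase_table(1.195, 0.01)
  set.seed(5)
  ang <- rejection_sample_angles(stokes_vector(1, 0, 0, 0), table = tb, n = 5e4)
  breaks <- seq(0, pi, length.out = 25)
  obs <- table(cut(ang$theta, breaks))
  dens <- function(th) (1 + cos(th)^2) * sin(th)
  p_expected <- vapply(seq_len(24), function(i) {
    integrate(dens, breaks[i], breaks[i + 1])$value
  }, numeric(1))
  p <- chisq.test(obs, p = p_expected / sum(p_expected))$p.value
  expect_gt(p, 0.01)
})

test_that("thin slab transmission is ballistic with S3 near +1", {
  res <- simulate_slab(make_fixture("thin_slab"))
  expect_gt(res$transmission$n_detected, 1000)
  expect_lt(abs(res$transmission$mean_s3 - 1), 1e-2)
})

test_that("photon weight is conserved exactly by the transport bookkeeping", {
  for (profile in c("smoke", "rayleigh")) {
    cons <- simulate_slab(make_fixture(profile))$conservation
    total <- cons$detected + cons$exited_outside_detectors +
      cons$lateral_escape + cons$absorbed + cons$roulette_kill -
      cons$roulette_gain
    expect_equal(total, cons$n_photons, tolerance = 1e-6)
  }
})

test_that("single-scattered photons in an optically thin slab carry the expected S3", {
  cfg <- make_fixture("thin_slab", photons = 1000000L,
                      slab = list(width_mm = 60, depth_mm = 6),
                      detectors = list(reflection = c(-3, 3),
                                       transmission = c(-3, 3),
                                       strip_half_mm = 3),
                      medium = list(diameter_um = 9, mu_s = 0.005 / 6, mu_a = 0))
  res <- simulate_slab(cfg, keep_records = TRUE)
  rec <- as.data.frame(res$records)
  r1 <- rec[rec$n_events == 1, ]
  expect_gt(nrow(r1), 2000)
  m1 <- weighted.mean(r1$S3, r1$weight)
  se <- sd(r1$S3) / sqrt(nrow(r1))
  expect_lt(abs(m1 - expected_s3_single(1.59 / 1.33, 9)), 3 * se + 0.003)
})

test_that("multiple scattering in the Rayleigh regime destroys circular polarization", {
  res <- simulate_slab(make_fixture("rayleigh"))
  expect_lt(abs(res$reflection$mean_s3), 0.2)
  expect_gt(res$reflection$n_events_mean, 10)
})

test_that("transmitted light at X = 11 is less depolarized than reflected", {
  cfg <- default_config(photons = 100000L, seed = 21L,
                        medium = list(diameter_um = 11))
  res <- simulate_slab(cfg)
  sep <- res$transmission$mean_s3 - res$reflection$mean_s3
  expect_gt(sep, 3 * sqrt(res$transmission$se^2 + res$reflection$se^2))
})

test_that("identical seeds give bit-identical simulations", {
  a <- simulate_slab(make_fixture("smoke"))
  b <- simulate_slab(make_fixture("smoke"))
  a$config <- b$config <- NULL
  expect_identical(a, b)
})

test_that("mean number of scattering events grows with the scattering coefficient", {
  ev <- vapply(c(2, 4, 6.86), function(mu) {
    simulate_slab(default_config(medium = list(mu_s = mu),
                                 photons = 5000L, seed = 3L))$reflection$n_events_mean
  }, numeric(1))
  expect_true(all(diff(ev) > 0))
})

test_that("standard error scales as 1/sqrt(N)", {
  se1 <- simulate_slab(default_config(photons = 10000L, seed = 5L))$reflection$se
  se4 <- simulate_slab(default_config(photons = 40000L, seed = 5L))$reflection$se
  expect_gt(se1 / se4, 2 * 0.7)
  expect_lt(se1 / se4, 2 * 1.3)
})

test_that("single photons report a definite fate", {
  st <- vapply(1:40, function(s) {
    propagate_photon(make_fixture("smoke"), seed = s)$status
  }, character(1))
  expect_true(all(st %in% c("detected", "exited", "escaped", "absorbed")))
  expect_gt(sum(st %in% c("detected", "exited")), 0)
})

test_that("detection records stay within physical bounds", {
  res <- simulate_slab(default_config(photons = 5000L), keep_records = TRUE)
  rec <- as.data.frame(res$records)
  expect_true(all(rec$phi_exit >= 0 & rec$phi_exit < pi / 2))
  expect_true(all(abs(rec$S3) <= 1 + 1e-9))
  expect_true(all(rec$weight > 0 & rec$weight <= 1 + 1e-9))
  expect_true(all(rec$n_events >= 0))
})

test_that("passage maps trace the banana and the transmission channel", {
  pm <- passage_probability_map(default_config(photons = 20000L,
                                               passage = list(enabled = TRUE)))
  mr <- pm$reflection
  peak <- which(mr == max(mr), arr.ind = TRUE)[1, ]
  z_frac <- peak[["row"]] / nrow(mr)
  x_mm <- -6 + (peak[["col"]] - 0.5) * 12 / ncol(mr)
  expect_lt(z_frac, 0.5)                 # upper half of the slab
  expect_true(x_mm > -1 && x_mm < 3)     # between source and detector strip

  mt <- pm$transmission
  expect_true(all(rowSums(mt) > 0))      # connected from source to far side
  expect_gt(sum(mt[nrow(mt), 55:66]), 0) # mass above the far window
})

test_that("no detected photons is an error with advice", {
  cfg <- default_config(photons = 5L, passage = list(enabled = TRUE),
                        detectors = list(reflection = c(5.5, 6),
                                         transmission = c(5.5, 6)))
  expect_error(passage_probability_map(cfg), "increase photons")
})
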