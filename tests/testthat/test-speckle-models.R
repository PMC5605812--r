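# Densities, samplers and the closed-form intensity SNR.

test_that("rayleigh density: direct values, boundary, domain errors", {
  expect_equal(rayleigh_pdf(1, d = 1), exp(-0.5), tolerance = 1e-12)
  expect_identical(rayleigh_pdf(0, d = 2), 0)
  expect_error(rayleigh_pdf(-0.1, d = 1), "amplitude")
  expect_error(rayleigh_pdf(1, d = 0), "must be > 0")
  for (d in c(0.1, 1, 5))
    expect_equal(integrate_pdf(function(a) rayleigh_pdf(a, d)), 1,
                 tolerance = 1e-6)
})

test_that("rician density: Rayleigh reduction, normalization, log-space stability", {
  a <- seq(0, 3, by = 0.1)
  expect_equal(rician_pdf(a, l = 0, g = 1.3), rayleigh_pdf(a, d = 1.3),
               tolerance = 1e-12)
  expect_equal(rician_pdf(1, l = 0, g = 1), exp(-0.5), tolerance = 1e-12)
  for (p in list(c(0.5, 0.15), c(0.6, 0.11)))
    expect_equal(integrate_pdf(function(a) rician_pdf(a, p[1], p[2])), 1,
                 tolerance = 1e-6)
  # a*l/g^2 ~ 4e5 would overflow a naive I0
  expect_true(is.finite(rician_pdf(10, l = 9.8, g = 0.015)))
  expect_error(rician_pdf(1, l = -0.1, g = 1), ">= 0")
})

test_that("k density: normalization, second moment, Rayleigh limit", {
  for (p in list(c(0.87, 7.48), c(1.92, 7.50)))
    expect_equal(integrate_pdf(function(a) k_pdf(a, p[1], p[2])), 1,
                 tolerance = 1e-6)
  # second moment = 2 sigma^2 with a = 2 sqrt(m / (2 sigma^2)), m = 2, sigma = 0.2
  m <- 2; sig <- 0.2; a_scale <- 2 * sqrt(m / (2 * sig^2))
  m2 <- integrate_pdf(function(a) a^2 * k_pdf(a, m, a_scale))
  expect_equal(m2, 2 * sig^2, tolerance = 1e-6)
  # m -> Inf: Rayleigh with matched second moment (2 sigma^2 = 4 m / a^2)
  m <- 500; sig <- 1 / sqrt(2); a_scale <- 2 * sqrt(m / (2 * sig^2))
  a <- seq(0.01, 4, length.out = 200)
  expect_lt(max(abs(k_pdf(a, m, a_scale) - rayleigh_pdf(a, sig))), 1e-2)
  expect_error(k_pdf(1, m = -1, a = 2), "must be > 0")
})

test_that("hk density: K identity at eps = 0, normalization, Rician limit", {
  # eps = 0 equals K with m = c, a = sqrt(2)/sigma
  sig <- 0.2; cc <- 2
  a <- seq(0.01, 2, length.out = 150)
  expect_lt(max(abs(hk_pdf(a, 0, sig, cc) - k_pdf(a, cc, sqrt(2) / sig))),
            1e-6)
  for (p in list(c(0.54, 0.16, 5.69), c(0.01, 0.17, 1.0)))
    expect_equal(integrate_pdf(function(a) hk_pdf(a, p[1], p[2], p[3])), 1,
                 tolerance = 1e-6)
  # c -> Inf with sigma^2 c fixed at g^2: Rician limit
  g <- 0.15; cc <- 200; sig <- g / sqrt(cc)
  a <- seq(0.01, 1.5, length.out = 100)
  expect_lt(max(abs(hk_pdf(a, 0.5, sig, cc) - rician_pdf(a, 0.5, g))), 1e-2)
  expect_error(hk_pdf(1, 0.5, 0, 2), "must be > 0")
  expect_error(hk_pdf(-1, 0.5, 0.2, 2), "amplitude")
})

test_that("hk density: literal Bessel-integral route agrees with the mixture route", {
  a <- seq(0.05, 1.5, length.out = 12)
  for (p in list(c(0.54, 0.16, 5.69), c(0.36, 0.16, 5.61), c(0, 0.2, 3)))
    expect_equal(hk_pdf(a, p[1], p[2], p[3], method = "bessel"),
                 hk_pdf(a, p[1], p[2], p[3], tol = 1e-9),
                 tolerance = 1e-6)
})

test_that("normalization holds across a dense parameter sample of all models", {
  set.seed(5)
  for (i in 1:4) {
    d <- runif(1, .1, 2)
    expect_equal(integrate_pdf(function(a) rayleigh_pdf(a, d)), 1,
                 tolerance = 1e-6)
    l <- runif(1, 0, 1); g <- runif(1, .1, .5)
    expect_equal(integrate_pdf(function(a) rician_pdf(a, l, g)), 1,
                 tolerance = 1e-6)
    m <- runif(1, .5, 20); asc <- runif(1, 2, 20)
    expect_equal(integrate_pdf(function(a) k_pdf(a, m, asc)), 1,
                 tolerance = 1e-6)
    e <- runif(1, 0, 1); s <- runif(1, .1, .4); cc <- runif(1, 1, 30)
    expect_equal(integrate_pdf(function(a) hk_pdf(a, e, s, cc)), 1,
                 tolerance = 1e-6)
  }
})

test_that("intensity SNR: published-value fixtures and the Rayleigh limit", {
  expect_equal(round(hk_intensity_snr(0.01, 0.17, 1.00), 2), 0.58)
  expect_equal(round(hk_intensity_snr(0.36, 0.16, 5.61), 2), 0.97)
  # eps = 0, c -> Inf: (2 s^2 c) / (2 s^2 sqrt(2c + c^2)) -> 1
  expect_equal(hk_intensity_snr(0, 0.3, 1e8), 1, tolerance = 1e-3)
  expect_error(hk_intensity_snr(0.1, -1, 2), "must be > 0")
})

test_that("samplers: moments, determinism, seed decoupling", {
  a <- speckle_sample("hk", hk_params(10, 0.01, 1), 1000, seed = 2)
  expect_lt(abs(mean(a) - 10), 0.01)  # coherent-dominated limit
  a <- speckle_sample("hk", hk_params(0.5, 0.2, 3), 20000, seed = 3)
  mi <- 0.5^2 + 2 * 0.2^2 * 3
  se <- sd(a^2) / sqrt(length(a))
  expect_lt(abs(mean(a^2) - mi), 3 * se)
  expect_identical(speckle_sample("k", k_params(2, 7), 50, seed = 9),
                   speckle_sample("k", k_params(2, 7), 50, seed = 9))
  expect_error(speckle_sample("hk", hk_params(-1, 0.2, 3), 10), ">= 0")
})

test_that("sampler-PDF KS consistency for all four models at n = 5000", {
  cases <- list(list("rayleigh", rayleigh_params(0.3)),
                list("rician", rician_params(0.6, 0.11)),
                list("k", k_params(2, 7.5)),
                list("hk", hk_params(0.36, 0.16, 5.61)))
  for (cs in cases) {
    a <- speckle_sample(cs[[1]], cs[[2]], 5000, seed = 7)
    F <- hkspeckle:::speckle_cdf_fun(cs[[1]], cs[[2]])
    p <- suppressWarnings(ks.test(a, F)$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("Monte-Carlo intensity SNR matches the closed form within 3%", {
  for (p in list(c(0.01, 0.17, 1), c(0.36, 0.16, 5.61), c(0.6, 0.11, 40.26),
                 c(0.54, 0.16, 5.69), c(0.69, 0.11, 14.02))) {
    a <- speckle_sample("hk", hk_params(p[1], p[2], p[3]), 1e5, seed = 13)
    expect_equal(mean(a^2) / sd(a^2), hk_intensity_snr(p[1], p[2], p[3]),
                 tolerance = 0.03)
  }
})
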