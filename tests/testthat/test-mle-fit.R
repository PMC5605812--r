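# Likelihood, BIC, Newton-Raphson fitting and OKRR model selection.

test_that("log-likelihood: raw, binned-weighted and binning-error forms", {
  expect_equal(log_likelihood(1, "rayleigh", rayleigh_params(1)), -0.5,
               tolerance = 1e-12)
  # one bin of 10 identical centers = 10x single-point value
  h <- amplitude_histogram(edges = c(0.95, 1.05), counts = 10L)
  expect_equal(log_likelihood(h, "rayleigh", rayleigh_params(1)),
               10 * log(rayleigh_pdf(1, 1)), tolerance = 1e-12)
  # raw vs 256-bin histogram on 1000 Rayleigh draws: < 0.5% difference
  a <- speckle_sample("rayleigh", rayleigh_params(0.2), 1000, seed = 21)
  ll_raw <- log_likelihood(a, "rayleigh", rayleigh_params(0.2))
  h <- amplitude_histogram(a, 256, range = c(0, max(a)))
  ll_bin <- log_likelihood(h, "rayleigh", rayleigh_params(0.2))
  expect_lt(abs(ll_raw - ll_bin) / abs(ll_raw), 0.005)
  expect_error(log_likelihood(numeric(0), "rayleigh", rayleigh_params(1)),
               "empty")
})

test_that("bic_value: arithmetic, m = 0, monotonicity in m", {
  expect_equal(bic_value(-50, 2, 100), 100 + 2 * log(100), tolerance = 1e-12)
  expect_equal(bic_value(-50, 0, 100), 100)
  b <- vapply(0:4, function(m) bic_value(-50, m, 100), 0)
  expect_true(all(diff(b) > 0))
})

test_that("rayleigh numeric MLE equals the closed form", {
  f <- fit_mle(c(1, 2, 3), "rayleigh")
  expect_equal(unname(f$par), sqrt(14 / 6), tolerance = 1e-6)
  a <- speckle_sample("rayleigh", rayleigh_params(0.31), 500, seed = 4)
  f <- fit_mle(a, "rayleigh", init = rayleigh_params(1))
  expect_equal(unname(f$par), sqrt(sum(a^2) / (2 * length(a))),
               tolerance = 1e-6)
  expect_true(f$converged)
})

test_that("converged fits are local optima of the binned likelihood", {
  a <- speckle_sample("k", k_params(2, 7.5), 3000, seed = 6)
  h <- amplitude_histogram(a, 256, range = c(0, max(a)))
  for (m in c("rayleigh", "rician", "k")) {
    f <- fit_mle(h, m)
    ll <- log_likelihood(h, m, f$par)
    for (i in seq_along(f$par)) for (s in c(-1, 1)) {
      p <- f$par
      p[i] <- p[i] * (1 + s * 0.01)
      info <- hkspeckle:::.model_info[[m]]
      p <- pmin(pmax(p, info$lower), info$upper)
      expect_lte(log_likelihood(h, m, p), ll + 1e-9)
    }
  }
})

test_that("K-model shape recovery within 15% at n = 5000", {
  a <- speckle_sample("k", k_params(2, 2 * sqrt(2 / 0.08)), 5000, seed = 8)
  h <- amplitude_histogram(a, 256, range = c(0, max(a)))
  f <- fit_mle(h, "k")
  expect_lt(abs(f$par[["m"]] - 2) / 2, 0.15)
})

test_that("HK parameter recovery: median relative bias under 10% in the identifiable regime", {
  # c <= 10, k = eps/sigma >= 0.3 (well-identified regime), 10 seeds, n = 5000
  truth <- c(epsilon = 0.5, sigma = 0.2, c = 4)  # k = 2.5
  est <- t(vapply(1:10, function(s) {
    a <- speckle_sample("hk", hk_params(truth[1], truth[2], truth[3]), 5000,
                        seed = s)
    h <- amplitude_histogram(a, 256, range = c(0, max(a)))
    fit_mle(h, "hk")$par
  }, numeric(3)))
  bias <- abs(apply(est, 2, median) - truth) / truth
  expect_true(all(bias < 0.10))
})

test_that("select_okrr: minimal BIC, tie-breaks, flagged non-convergence", {
  mk <- function(model, bic, conv = TRUE)
    structure(list(model = model, bic = bic, converged = conv),
              class = "fit_result")
  fits <- list(mk("rayleigh", 157), mk("rician", 200), mk("k", 180))
  expect_identical(select_okrr(fits)$model, "rayleigh")
  fits <- list(mk("rayleigh", 100), mk("rician", 100), mk("k", 100))
  expect_identical(select_okrr(fits)$model, "rayleigh")
  fits <- list(mk("rayleigh", 101), mk("rician", 100), mk("k", 100))
  expect_identical(select_okrr(fits)$model, "rician")
  expect_error(select_okrr(fits[1:2]), "exactly one")
})

test_that("OKRR selects the generating single model consistently", {
  # Rician truth (l = 0.6, g = 0.11): selected in >= 90% of 20 repetitions
  hits <- vapply(1:20, function(s) {
    a <- speckle_sample("rician", rician_params(0.6, 0.11), 2000, seed = s)
    h <- amplitude_histogram(a, 256, range = c(0, max(a)))
    fits <- lapply(c("rayleigh", "rician", "k"), function(m) fit_mle(h, m))
    select_okrr(fits)$model == "rician"
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("BIC prefers the true generating model in most repetitions", {
  # generator parameters sit well inside each family (HK away from its
  # Rician/K limits) so the truth is identifiable at n = 5000
  gens <- list(list("rayleigh", rayleigh_params(0.3)),
               list("rician", rician_params(0.6, 0.11)),
               list("k", k_params(1.5, 8)),
               list("hk", hk_params(0.5, 0.2, 3)))
  for (g in gens) {
    hits <- vapply(1:5, function(s) {
      a <- speckle_sample(g[[1]], g[[2]], 5000, seed = 100 + s)
      h <- amplitude_histogram(a, 256, range = c(0, max(a)))
      fits <- lapply(c("rayleigh", "rician", "k", "hk"),
                     function(m) fit_mle(h, m))
      bics <- vapply(fits, function(f) f$bic, 0)
      names(bics) <- c("rayleigh", "rician", "k", "hk")
      bics[[g[[1]]]] <= min(bics) + 1e-9
    }, TRUE)
    expect_gte(mean(hits), 0.8)
  }
})

test_that("compare_hk_okrr wires fits, labels and the relative difference", {
  expect_equal(rel_diff_pct(449, 421), 6.24, tolerance = 0.005)
  expect_equal(rel_diff_pct(159, 157), 1.26, tolerance = 0.005)
  expect_identical(rel_diff_pct(200, 200), 0)
  a <- hk_fixture_sample(600)
  h <- amplitude_histogram(a, 128, range = c(0, max(a)))
  cmp <- compare_hk_okrr(h)
  expect_s3_class(cmp, "model_comparison")
  expect_true(cmp$okrr_label %in% c("RA", "RI", "K"))
  expect_equal(cmp$rel_diff_pct,
               abs(cmp$hk$bic - cmp$okrr$bic) / abs(cmp$hk$bic) * 100)
})
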