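# HRF/OER model: photon and ion parameterizations, LQ application,
# hypoxic effective dose.

test_that("photon HRF has the anoxic, half-effect and normoxic limits", {
  p <- hypoxia_params()
  expect_equal(hrf_photon(0), p$m)                      # anoxic limit = m
  expect_equal(hrf_photon(1e9), 1, tolerance = 1e-6)    # fully oxygenated
  expect_equal(hrf_photon(p$K), (p$m + 1) / 2)          # midpoint at K
  expect_equal(round(hrf_photon(p$K), 2), 1.97)
  po2 <- seq(0, 21, by = 0.5)
  expect_true(all(diff(hrf_photon(po2)) < 0))
  expect_error(hrf_photon(-1), "non-negative")
})

test_that("ion HRF interpolates between the photon HRF and 1", {
  p <- hypoxia_params()
  for (po2 in c(0.05, 0.5, 2)) {
    expect_equal(hrf_ion(1e-9, po2), hrf_photon(po2), tolerance = 1e-6)
    expect_equal(hrf_ion(1e9, po2), 1, tolerance = 1e-4)
    # halfway point at RQE = a^(1/gamma)
    rq_half <- p$a^(1 / p$gamma)
    expect_equal(hrf_ion(rq_half, po2), (hrf_photon(po2) + 1) / 2,
                 tolerance = 1e-10)
    rq <- 10^seq(-1, 5, by = 0.25)
    h <- hrf_ion(rq, po2)
    expect_true(all(h >= 1 - 1e-12 & h <= p$m))
    expect_true(all(diff(h) < 0))          # decreasing in RQE
  }
  # decreasing in pO2 at fixed RQE (finite-difference grid)
  for (rq in c(1, 100, 1e4)) {
    h <- hrf_ion(rq, seq(0, 21, by = 0.7))
    expect_true(all(diff(h) < 1e-12))
  }
})

test_that("LQ-based HRF recovers a dose-modifying factor at any survival", {
  expect_equal(hrf_from_lq(0.1, 0.02, 0.1, 0.02, 0.1), 1)
  for (H in c(1.2, 1.9, 2.94)) {
    for (S in c(0.1, 0.37, 0.9)) {
      got <- hrf_from_lq(0.3 / H, 0.025 / H^2, 0.3, 0.025, S)
      expect_equal(got, H, tolerance = 1e-10)
    }
  }
  expect_error(hrf_from_lq(0.1, 0.02, 0.1, 0.02, 1.2), "survival")
})

test_that("HRF application to LQ round-trips through the LQ-based HRF", {
  p <- hypoxia_params()
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, 0.05, 1); b <- runif(1, 0.01, 0.05)
    rq <- 10^runif(1, 0, 4); po2 <- runif(1, 0, 5)
    hy <- apply_hrf(a, b, rq, po2, p)
    expect_equal(hy$alpha_h, a / hy$hrf)
    expect_equal(hy$beta_h, b / hy$hrf^2)
    back <- hrf_from_lq(hy$alpha_h, hy$beta_h, a, b, S = 0.37)
    expect_equal(back, hy$hrf, tolerance = 1e-10)
  }
  # fully oxygenated leaves LQ unchanged
  hy <- apply_hrf(0.3, 0.025, 50, 1e9, p)
  expect_equal(hy$alpha_h, 0.3, tolerance = 1e-4)
})

test_that("hypoxic effective dose obeys the model limits", {
  ph <- photon_lq(); p <- hypoxia_params()
  # all components at HRF = 1 (normoxia) equals the normoxic effective dose
  d <- c(1, 0.5); a <- c(0.2, 0.4); b <- c(0.025, 0.025); rq <- c(20, 300)
  expect_equal(d_oer_rbe(d, a, b, rq, pO2 = 1e9, ph, p),
               effective_dose(d, a, b, ph), tolerance = 1e-6)
  # anoxic low-RQE field at the linear-dose limit: iso-effect reduced m-fold
  dd <- 1e-4
  ratio <- effective_dose(dd, 0.3, 0.025, ph) /
    d_oer_rbe(dd, 0.3, 0.025, 1e-6, pO2 = 0, ph, p)
  expect_equal(ratio, p$m, tolerance = 1e-3)
  # anoxic voxel with extreme radiation quality: hypoxia has no effect
  expect_equal(d_oer_rbe(2, 0.5, 0.025, 1e9, pO2 = 0, ph, p),
               effective_dose(2, 0.5, 0.025, ph), tolerance = 1e-4)
  expect_error(d_oer_rbe(1, 0.3, 0.025, 10, pO2 = NULL), "required")
})

test_that("hypoxia never increases effect and delta is bounded by photon HRF", {
  ph <- photon_lq(); p <- hypoxia_params()
  set.seed(5)
  for (i in 1:25) {
    k <- sample(1:6, 1)
    d <- runif(k, 0.05, 2); a <- runif(k, 0.05, 1); b <- rep(0.025, k)
    rq <- 10^runif(k, 0, 4.5); po2 <- runif(1, 0.02, 20)
    dn <- effective_dose(d, a, b, ph)
    dh <- d_oer_rbe(d, a, b, rq, po2, ph, p)
    expect_lte(dh, dn + 1e-12)
    delta <- delta_oer(dn, dh)
    expect_gte(delta, 1 - 1e-12)
    expect_lte(delta, hrf_photon(po2, p) + 1e-9)
  }
  expect_true(is.na(delta_oer(1, 0)))
})
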