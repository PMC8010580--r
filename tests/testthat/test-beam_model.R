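# Beam physics: kinematics, effective charge, ranges, depth profiles.

test_that("relativistic kinematics matches the closed form", {
  expect_equal(beta_from_energy("proton", 0), 0)
  # beta = sqrt(1 - 1/gamma^2), gamma = 1 + T/931.494
  g <- 1 + 118.14 / 931.494
  expect_equal(beta_from_energy("proton", 118.14), sqrt(1 - 1 / g^2))
  expect_equal(round(beta_from_energy("proton", 118.14), 2), 0.46)
  expect_equal(round(beta_from_energy("carbon", 218.52), 2), 0.59)
  expect_error(beta_from_energy("proton", -1), "non-negative")
})

test_that("Barkas effective charge has the right limits", {
  expect_equal(zeff_barkas(6, 0.9999), 6, tolerance = 1e-6)
  expect_equal(zeff_barkas(1, 0.4), 1, tolerance = 1e-6)
  # direct evaluation: 6 (1 - exp(-125 * 0.02 * 6^(-2/3)))
  expect_equal(zeff_barkas(6, 0.02), 6 * (1 - exp(-125 * 0.02 * 6^(-2 / 3))))
  expect_equal(round(zeff_barkas(6, 0.02), 2), 3.19)
  expect_warning(zeff_barkas(2, 0), "stopped")
})

test_that("ranges are increasing, calibrated, and A/Z^2-scaled", {
  expect_equal(csda_range("proton", 150), 158, tolerance = 0.03)
  es <- seq(20, 400, length.out = 12)
  r <- csda_range("proton", es)
  expect_true(all(diff(r) > 0))
  # independent oracle: trapezoid integration of 1/S(E) on a fine grid
  eg <- seq(1, 150, length.out = 4000)
  inv <- 1 / stopping_power("proton", eg)
  r_oracle <- sum(diff(eg) * (inv[-1] + inv[-length(eg)]) / 2)
  expect_equal(csda_range("proton", 150), r_oracle, tolerance = 0.005)
  # A/Z^2 scaling between ions at equal energy per nucleon
  for (e in c(50, 118.51, 250)) {
    expect_equal(csda_range("helium", e), csda_range("proton", e),
                 tolerance = 0.02)
    expect_equal(csda_range("carbon", e), csda_range("proton", e) * 12 / 36,
                 tolerance = 0.02)
  }
  expect_error(csda_range("proton", 0.5), "calibrated window")
})

test_that("depth profiles satisfy their structural invariants", {
  for (spec in list(c("proton", 118.14), c("helium", 118.51),
                    c("carbon", 218.52))) {
    tb <- build_depth_profile(spec[1], as.numeric(spec[2]))
    expect_true(all(tb$dose_per_primary >= 0))
    pos <- tb$dose_per_primary > 0
    expect_equal(rowSums(tb$fraction[pos, ]), rep(1, sum(pos)),
                 tolerance = 1e-12)
    expect_true(tb$R80 > min(tb$depth) && tb$R80 < max(tb$depth))
    expect_true(all(diff(tb$sigma) >= 0))
    # primary track LET non-decreasing up to its maximum
    lp <- tb$let[, 1]
    expect_true(all(diff(lp[seq_len(which.max(lp))]) >= -1e-9))
  }
})

test_that("fragment tails behave as the beam model intends", {
  tp <- build_depth_profile("proton", 118.14)
  tc <- build_depth_profile("carbon", 218.52)
  beyond <- tp$depth > tp$R80 + 3 * tp$straggle_sigma
  expect_lt(max(tp$dose_per_primary[beyond]), 0.01 * max(tp$dose_per_primary))
  at20 <- stats::approx(tc$depth, tc$dose_per_primary, tc$R80 + 20)$y
  expect_gt(at20, 0)
  at10 <- stats::approx(tc$depth, tc$dose_per_primary, tc$R80 + 10)$y
  expect_gt(at10, 0)
})

test_that("proton depth dose conserves energy to 5%", {
  tp <- build_depth_profile("proton", 118.14)
  dz <- diff(tp$depth[1:2])
  integral <- sum(tp$dose_per_primary) * dz            # Gy mm^3
  expect_equal(integral, 118.14 * 1.602176634e-7, tolerance = 0.05)
})

test_that("entrance LET of a 118 MeV proton beam is 0.6-0.7 keV/um", {
  tp <- build_depth_profile("proton", 118.14)
  ent <- depth_letd(tp, 0.5)
  expect_gt(ent, 0.6)
  expect_lt(ent, 0.7)
})

test_that("depth LET_D equals the explicit weighted-mean oracle", {
  tb <- build_depth_profile("carbon", 200)
  i <- which.min(abs(tb$depth - 60))
  oracle <- sum(tb$fraction[i, ] * tb$let[i, ]) / sum(tb$fraction[i, ])
  expect_equal(depth_letd(tb, tb$depth[i]), oracle, tolerance = 1e-12)
  # brute-force random 10-component field
  set.seed(7)
  d <- runif(10); let <- runif(10, 1, 300)
  expect_equal(sum(d * let) / sum(d),
               weighted.mean(let, d), tolerance = 1e-12)
  expect_error(depth_letd(tb, max(tb$depth) + 5), "outside")
})

test_that("R80 inversion round-trips across the energy range", {
  for (ion in c("proton", "helium", "carbon")) {
    r80 <- vapply(c(60, 120, 250), function(e)
      build_depth_profile(ion, e)$R80, numeric(1))
    expect_true(all(diff(r80) > 0))
    e_star <- 150
    r <- build_depth_profile(ion, e_star)$R80
    expect_equal(energy_for_r80(ion, r), e_star, tolerance = 1e-3)
  }
  expect_error(energy_for_r80("proton", 1), "admissible")
})

test_that("lateral sigma grows with depth and is larger for protons", {
  z <- seq(0, 100, by = 5)
  sp <- lateral_sigma("proton", 118.14, z)
  sc <- lateral_sigma("carbon", 218.52, z)
  expect_true(all(diff(sp) >= 0))
  expect_true(all(diff(sc) >= 0))
  expect_equal(lateral_sigma("proton", 118.14, 0),
               ion_species("proton")$initial_spot_sigma)
  expect_gt(sp[length(z)], sc[length(z)])
})

test_that("beam library stores tables consistent with their R80", {
  lib <- build_beam_library("carbon", list(c(180, 220)))
  for (tb in lib$tables$carbon) {
    rebuilt <- build_depth_profile("carbon", tb$energy)
    expect_equal(tb$R80, rebuilt$R80, tolerance = 0.1)
  }
  d <- tempfile()
  paths <- write_beam_library(lib, d)
  expect_true(all(file.exists(file.path(d, c("carbon_180.0000.csv",
                                             "generation.json")))))
  df <- read.csv(file.path(d, "carbon_220.0000.csv"))
  expect_equal(df$dose_per_primary,
               lib$tables$carbon[["220.0000"]]$dose_per_primary,
               tolerance = 1e-6)
})
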