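# Spot placement, dose influence, optimizer contract, pruning.

test_that("spot placement follows the technique and spacing conventions", {
  scen <- tiny_scenario()
  sc <- plan_config("carbon", "sharc")
  spc <- place_spots(scen, sc)
  expect_length(unique(spc$angle_deg), 180)
  expect_equal(sort(unique(spc$angle_deg)), seq(0, 358, by = 2))
  expect_equal(diff(sort(unique(spc$u_mm)))[1], 2.4)
  sp <- place_spots(scen, plan_config("proton", "sharc"))
  expect_equal(diff(sort(unique(sp$u_mm)))[1], 4.8)
  # u grid covers the target projection plus one spacing of margin
  expect_gte(max(sp$u_mm), 30)
  s1 <- place_spots(scen, plan_config("carbon", "1f"))
  expect_equal(unique(s1$angle_deg), 90)
  expect_gt(length(unique(s1$energy_MeV_u)), 5)   # energy stack
  s2 <- place_spots(scen, plan_config("carbon", "2f"))
  expect_equal(sort(unique(s2$angle_deg)), c(0, 180))
})

test_that("subarc plans use 7 energies over 14-degree subarcs", {
  scen <- tiny_scenario()
  units <- hadronarc:::plan_beam_units(ion_species("carbon"), "sharc_subarc",
                                       plan_config("carbon", "sharc_subarc"))
  expect_length(unique(units$energy), 7)
  # all angles within one subarc share an energy
  first <- units[units$angle < 14, ]
  expect_length(unique(first$energy), 1)
  # R80 values span isocenter depth -6..+6 mm in 2 mm steps
  r80s <- vapply(sort(unique(units$energy)), function(e)
    build_depth_profile("carbon", e)$R80, numeric(1))
  expect_equal(sort(r80s), seq(94, 106, by = 2), tolerance = 0.01)
})

test_that("influence kernel matches the pencil-beam definition", {
  scen <- tiny_scenario()
  cfg <- plan_config("carbon", "sharc", energy = 200)
  spots <- place_spots(scen, cfg)
  inf <- compute_influence(scen, spots, cfg, n_sigma_bins = 1)
  # one central spot from angle 0
  w <- rep(0, nrow(spots))
  i0 <- which(spots$angle_deg == 0 & spots$u_mm == 0 & spots$v_mm == 0)
  w[i0] <- 1
  D <- inf$forward(w, "dose")
  tb <- inf$tables[[1]]
  # voxel on the spot axis near entrance: entrance dose with the binned
  # Gaussian normalization (single sigma bin -> sigma is the bin center)
  iax <- which(scen$xy[, 1] == scen$xy[which.min(abs(scen$xy[,1])),1][1] &
               scen$xy[, 2] > 90)
  iax <- iax[which.max(scen$xy[iax, 2])]
  fr <- hadronarc:::scenario_beam_frame(scen, 0)
  dep <- fr$depth[iax]; uoff <- fr$u[iax]
  sref <- mean(range(tb$sigma))
  iz <- which.min(abs(scen$zc))
  expected <- stats::approx(tb$depth, tb$dose_per_primary, dep)$y *
    exp(-(uoff^2 + scen$zc[iz]^2) / (2 * sref^2)) / (2 * pi * sref^2)
  expect_equal(unname(D[iax, iz]), unname(expected), tolerance = 1e-9)
})

test_that("laterally integrated spot dose matches the depth table", {
  scen <- build_scenario("A", voxel_size = 2, slab_half_height = 12)
  cfg <- plan_config("carbon", "sharc", energy = 200)
  spots <- place_spots(scen, cfg)
  inf <- compute_influence(scen, spots, cfg)
  w <- as.numeric(spots$angle_deg == 0 & spots$u_mm == 0 & spots$v_mm == 0)
  D <- inf$forward(w, "dose")
  total <- sum(D) * scen$voxel_size^3          # Gy mm^3 over the grid
  tb <- inf$tables[[1]]
  # central spot from angle 0 traverses the full 200 mm chord
  dz <- diff(tb$depth[1:2])
  keep <- tb$depth <= 200
  expected <- sum(tb$dose_per_primary[keep]) * dz
  expect_equal(total, expected, tolerance = 0.02)
})

test_that("opposed beams give mirror-symmetric influence", {
  scen <- tiny_scenario()
  cfg <- plan_config("carbon", "2f", energy = NULL)
  spots <- place_spots(scen, cfg)
  inf <- compute_influence(scen, spots, cfg)
  en <- sort(unique(spots$energy_MeV_u))[1]
  w <- as.numeric(spots$angle_deg == 0 & spots$u_mm == 0 &
                  spots$v_mm == 0 & spots$energy_MeV_u == en)
  w180 <- as.numeric(spots$angle_deg == 180 & spots$u_mm == 0 &
                     spots$v_mm == 0 & spots$energy_MeV_u == en)
  D0 <- inf$forward(w, "dose")
  D180 <- inf$forward(w180, "dose")
  # mirror in y: match each (x, y) to (x, -y)
  mirror <- match(
    paste(scen$xy[, 1], -scen$xy[, 2]),
    paste(scen$xy[, 1], scen$xy[, 2]))
  ok <- !is.na(mirror)
  expect_equal(D0[ok, ], D180[mirror[ok], ], tolerance = 1e-9)
})

test_that("optimizer recovers the single-spot optimum exactly", {
  # one spot, one voxel, physical mode: w* = target dose / unit influence
  A <- matrix(2.5e-4, 1, 1)
  b <- list(lo = 1.8, hi = 1.8, wt_lo = 1, wt_hi = 1)
  cfg <- plan_config("carbon", "sharc")
  fit <- optimize_weights(A, config = cfg, mode = "physical", bounds = b)
  expect_equal(fit$weights, 1.8 / 2.5e-4, tolerance = 1e-10)
  expect_true(all(diff(fit$trace) <= 0))
})

test_that("optimizer decreases the objective monotonically on fixtures", {
  set.seed(21)
  A <- matrix(runif(40 * 12, 0, 1e-4), 40, 12)
  lo <- rep(1, 40); hi <- rep(1.1, 40)
  b <- list(lo = lo, hi = hi, wt_lo = rep(1, 40), wt_hi = rep(1, 40))
  fit <- optimize_weights(A, config = plan_config(), mode = "physical",
                          bounds = b)
  expect_true(all(diff(fit$trace) <= 1e-12))
  expect_true(all(fit$weights >= 0))
  expect_lt(fit$trace[length(fit$trace)], fit$trace[1] / 10)
})

test_that("pruning enforces the minimum fluence invariant", {
  thr <- ion_species("carbon")$min_fluence_threshold
  plan <- list(weights = c(2 * thr, 3 * thr), config = plan_config("carbon"),
               spots = data.frame(weight = c(0, 0)), pruned = FALSE)
  class(plan) <- "sharc_plan"
  out <- prune_spots(plan)
  expect_equal(out$weights, c(2 * thr, 3 * thr))  # all above: unchanged
  expect_equal(out$n_pruned, 0L)
})
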