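# Histograms, Dx statistics, LET_D grids, TCP.

test_that("cumulative histograms match the sort-based oracle", {
  cv <- cumulative_histogram(rep(2, 100), bin_width = 0.01)
  expect_equal(cv$volume[1], 1)
  expect_equal(cv$volume[length(cv$volume)], 0)
  expect_true(all(diff(cv$volume) <= 0))
  # step function at the uniform value
  expect_equal(cv$volume[which.min(abs(cv$edges - 1.99))], 1)
  two <- cumulative_histogram(c(rep(1, 50), rep(3, 50)), bin_width = 0.01)
  expect_equal(two$volume[which.min(abs(two$edges - 2))], 0.5)
  set.seed(9)
  v <- rgamma(500, 2, 1)
  cv <- cumulative_histogram(v, bin_width = 0.005)
  oracle <- vapply(cv$edges, function(e) mean(v >= e - 0.005 * 1e-6),
                   numeric(1))
  expect_equal(cv$volume, oracle, tolerance = 1e-12)
  expect_error(cumulative_histogram(numeric(0)), "empty mask")
})

test_that("Dx inverts the cumulative curve", {
  u <- cumulative_histogram(rep(2.5, 64), bin_width = 0.01)
  for (x in c(2, 50, 95)) expect_equal(metric_dx(u, x), 2.5, tolerance = 0.011)
  two <- cumulative_histogram(c(rep(1, 50), rep(3, 50)), bin_width = 0.01)
  expect_equal(metric_dx(two, 2), 3, tolerance = 0.011)
  expect_equal(metric_dx(two, 95), 1, tolerance = 0.011)
  expect_gt(metric_dx(two, 10), metric_dx(two, 90))  # decreasing in x
})

test_that("TCP matches the closed-form Poisson model", {
  expect_equal(tcp(rep(0, 50)), 1)
  expect_equal(tcp(numeric(0)), 1)                 # empty product
  # uniform S = 0.5, n = 30, N = 1000 voxels of 1 mm^3
  p <- tcp_params(n_fractions = 30, cell_density = 1e4)
  expect_equal(tcp(rep(0.5, 1000), p, voxel_volume = 1),
               exp(-0.5^30 * 1e4 * 1000), tolerance = 1e-12)
  expect_equal(round(tcp(rep(0.5, 1000), p, 1), 4), 0.9907)
  # strictly increasing under uniform dose scaling (S decreases)
  alpha <- 0.3; D <- 2
  s_of <- function(s) exp(-alpha * s * D)
  tcps <- vapply(seq(0.5, 3, by = 0.25), function(s)
    tcp(rep(s_of(s), 200), p, 1), numeric(1))
  expect_true(all(diff(tcps) > 0))
})

test_that("TCP50 matches the uniform-survival algebraic inversion", {
  # uniform field: alpha_bar, D per voxel identical -> closed form
  scen <- build_scenario("A", voxel_size = 4, slab_half_height = 8)
  n_t <- sum(scen$target)
  vol <- 4^3
  alpha <- 0.25; D0 <- 1.2
  grids <- list(dose = matrix(D0, nrow(scen$target), ncol(scen$target)),
                alpha_bar = matrix(alpha, nrow(scen$target), ncol(scen$target)))
  pars <- tcp_params(n_fractions = 10, cell_density = 1e4)
  ph <- photon_lq()
  got <- tcp50(grids, scen, pars, hypoxic = FALSE, ph)
  # solve for the scale: n (alpha s D + beta_x (s D)^2) = -ln(ln 2 / (p V))
  f <- function(s) {
    nls <- alpha * s * D0 + ph$beta_x * (s * D0)^2
    exp(-pars$n_fractions * nls) * 1e4 * n_t * vol - log(2)
  }
  s50 <- uniroot(f, c(0.1, 10), tol = 1e-10)$root
  drbe <- (-ph$alpha_x + sqrt(ph$alpha_x^2 + 4 * ph$beta_x *
            (alpha * s50 * D0 + ph$beta_x * (s50 * D0)^2))) / (2 * ph$beta_x)
  expect_equal(got, pars$n_fractions * drbe, tolerance = 1e-3)
  # a plan against itself has zero shift
  expect_equal(got - tcp50(grids, scen, pars, FALSE, ph), 0)
})

test_that("LET_D grid equals the event-list oracle on a toy plan", {
  scen <- tiny_scenario()
  cfg <- plan_config("carbon", "sharc", energy = 200)
  spots <- place_spots(scen, cfg)
  inf <- compute_influence(scen, spots, cfg)
  set.seed(31)
  idx <- sample(which(spots$angle_deg %in% c(0, 90, 180)), 3)
  w <- rep(0, nrow(spots)); w[idx] <- c(1e6, 5e5, 2e6)
  D <- inf$forward(w, "dose")
  Dl <- inf$forward(w, "dose_letd")
  plan <- structure(list(influence = inf, weights = w,
                         config = cfg, scenario = scen), class = "sharc_plan")
  lg <- letd_grid(plan)
  manual <- ifelse(D > 0, Dl / D, NA_real_)
  expect_equal(lg, manual, tolerance = 1e-12)
  # single spot at the entrance reproduces the table's entrance LET_D
  w1 <- rep(0, nrow(spots))
  w1[which(spots$angle_deg == 0 & spots$u_mm == 0 & spots$v_mm == 0)] <- 1e6
  plan$weights <- w1
  lg1 <- letd_grid(plan)
  fr <- hadronarc:::scenario_beam_frame(scen, 0)
  iax <- which(!is.na(fr$depth) & abs(fr$u) <= 2.5 &
                 fr$depth > 0 & fr$depth < 8)
  iz <- which.min(abs(scen$zc))
  tb <- inf$tables[[1]]
  expect_equal(unname(lg1[iax[1], iz]),
               unname(depth_letd(tb, fr$depth[iax[1]])), tolerance = 0.02)
})

test_that("angular fluence map conserves total particles", {
  scen <- tiny_scenario()
  cfg <- plan_config("carbon", "sharc", energy = 200)
  spots <- place_spots(scen, cfg)
  set.seed(13)
  w <- runif(nrow(spots))
  plan <- structure(list(spots = spots, weights = w), class = "sharc_plan")
  am <- angular_fluence_map(plan)
  expect_equal(sum(am$particles), sum(w), tolerance = 1e-12)
  expect_equal(max(am$relative), 1)
  expect_equal(nrow(am), 180)
})

test_that("delta_oer volume histogram is degenerate under normoxia", {
  d_rbe <- matrix(runif(50, 1, 3), 10, 5)
  curve <- delta_oer_vh(d_rbe, d_rbe, matrix(TRUE, 10, 5))
  expect_equal(metric_dx(curve, 50), 1, tolerance = 0.002)
  expect_equal(attr(curve, "n_excluded"), 0)
  # zero-dose voxels excluded and counted
  d_oer <- d_rbe; d_oer[1, 1] <- 0
  curve2 <- delta_oer_vh(d_rbe, d_oer, matrix(TRUE, 10, 5))
  expect_equal(attr(curve2, "n_excluded"), 1)
})
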