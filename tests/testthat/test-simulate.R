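test_that("simulation config validates its inputs", {
  expect_error(simulation_config(), "seed")
  cfg <- simulation_config(seed = 1)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$prey_ratio, c(0.65, 0.21))
  expect_equal(cfg$prey_ratio_control, c(0.72, 0.17))
  expect_equal(cfg$predator_ratio, c(1.10, 0.12))
})

test_that("log-normal pipetting ratios match the requested moments", {
  set.seed(5)
  x <- grazefit:::rlnorm_moments(2e5, 0.65, 0.21)
  expect_equal(mean(x), 0.65, tolerance = 0.01)
  expect_equal(sd(x), 0.21, tolerance = 0.01)
  expect_true(all(x > 0))
})

test_that("Poisson subsample counting has the expected error structure", {
  set.seed(6)
  # density 25/mL in 3 mL: mean count 75, CV ~ 1/sqrt(75)
  cc <- simulate_counts(rep(25, 20000), 3)
  expect_equal(mean(cc$count), 75, tolerance = 0.02)
  expect_equal(sd(cc$count) / mean(cc$count), 1 / sqrt(75), tolerance = 0.05)
  expect_equal(cc$observed_density, cc$count / 3)
  # zero expectation -> zero count
  expect_equal(simulate_counts(0, 3)$count, 0L)
  # observed/true converges to 1 as counted volume grows
  rel_err <- vapply(c(1, 10, 100), function(v) {
    o <- simulate_counts(rep(1000, 500), v)$observed_density
    sd(o / 1000)
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))
})

test_that("well dynamics conserve prey mass and hold predators in NR-off mode", {
  cfg <- simulation_config(nr = NULL, seed = 1)
  dyn <- simulate_well_dynamics(5e4, 25, 0.1, cfg)
  # mass balance: P0 - Pt = ingested - grown, to ODE tolerance
  lhs <- 5e4 - dyn$pt
  rhs <- dyn$ingested_cum - dyn$grown_cum
  expect_equal(lhs, rhs, tolerance = 1e-6)
  # predator exactly constant when the NR is off
  expect_identical(dyn$rt, 25)
  # with zero prey growth, removal equals the ingestion integral
  dyn0 <- simulate_well_dynamics(5e4, 25, 0, cfg)
  expect_equal(5e4 - dyn0$pt, dyn0$ingested_cum, tolerance = 1e-6)
  expect_equal(dyn0$grown_cum, 0)
  # control well: pure exponential growth
  dyn_c <- simulate_well_dynamics(1e4, 0, -0.2, cfg)
  expect_equal(dyn_c$pt, 1e4 * exp(-0.2), tolerance = 1e-6)
})

test_that("lag phase freezes the dynamics for its duration", {
  cfg_full <- simulation_config(nr = NULL, seed = 1)
  cfg_lag <- simulation_config(nr = NULL, lag_hours = 12, seed = 1)
  d_full <- simulate_well_dynamics(2e4, 25, 0, cfg_full)
  d_lag <- simulate_well_dynamics(2e4, 25, 0, cfg_lag)
  # half the active time means strictly less depletion
  expect_gt(d_lag$pt, d_full$pt)
  # lag equal to the whole incubation: nothing happens
  cfg_all <- simulation_config(nr = NULL, lag_hours = 24, seed = 1)
  d_all <- simulate_well_dynamics(2e4, 25, 0, cfg_all)
  expect_equal(d_all$pt, 2e4)
})

test_that("simulated experiments are deterministic given seed and config", {
  plan <- demo_plan()
  cfg <- simulation_config(seed = 99)
  w1 <- simulate_experiment(plan, cfg)
  w2 <- simulate_experiment(plan, cfg)
  expect_identical(w1, w2)
  w3 <- simulate_experiment(plan, simulation_config(seed = 100))
  expect_false(identical(w1$P0, w3$P0))
})

test_that("simulated wells carry the designed structure and noise signature", {
  plan <- demo_plan()
  cfg <- simulation_config(seed = 7)
  w <- simulate_experiment(plan, cfg)
  expect_equal(nrow(w), nrow(plan))
  expect_true(all(is.na(w$R0[w$role == "control"])))
  expect_true(all(!is.na(w$R0[w$role == "experimental"])))
  # schema round-trips through CSV unchanged
  path <- tempfile(fileext = ".csv")
  write_wells(w, path)
  w_back <- read_wells(path)
  expect_equal(as.data.frame(w_back), as.data.frame(w[, names(w_back)]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # realized/target prey ratios center near the configured pipetting bias
  truth <- attr(w, "truth")
  ratio <- truth$P0_true / w$target_prey
  expect_lt(mean(ratio[w$role == "experimental"]), 1)
})

test_that("negative diluent effects reproduce the negative-grazing pathology", {
  # controls get more diluent than experimental wells; diluent depresses
  # prey growth, so controls decline faster -> negative g at low density
  plan <- demo_plan()
  cfg <- simulation_config(beta_flw = -0.5, sigma_mu = 0.02, seed = 13)
  w <- simulate_experiment(plan, cfg)
  ctl_flw <- mean(w$flw_fraction[w$role == "control"])
  exp_flw <- mean(w$flw_fraction[w$role == "experimental"])
  expect_gt(ctl_flw, exp_flw)
  rt <- well_rates(w, mu_strategy = "density_bins", bins = 3)
  low <- rt$density < median(rt$density)
  expect_true(any(rt$g[low] < 0))
  expect_true(any(grepl("negative_grazing", rt$flags)))
})

test_that("estimated ingestion gets noisier with prey density (heteroscedasticity)", {
  plan <- demo_plan()
  set.seed(17)
  est <- purrr::map_dfr(1:12, function(i) {
    cfg <- simulation_config(seed = 1000 + i)
    w <- simulate_experiment(plan, cfg)
    rt <- well_rates(w, mu_strategy = "uncorrected")
    tibble::tibble(density = rt$density, i_cells = rt$i_cells)
  })
  lo <- est$i_cells[est$density < stats::quantile(est$density, 1 / 3)]
  hi <- est$i_cells[est$density > stats::quantile(est$density, 2 / 3)]
  expect_gt(sd(hi), sd(lo))
})

test_that("recovery study is deterministic, tracks failures, and nails zero noise", {
  plan <- demo_plan()
  cfg0 <- simulation_config(
    sigma_mu = 0, prey_ratio = c(1, 0), prey_ratio_control = c(1, 0),
    predator_ratio = c(1, 0), nr = NULL, mu0 = 0, beta_flw = 0, seed = 500
  )
  # zero-noise replicates: only Poisson counting remains; damp it with big
  # uncapped subsample volumes so bias and RMSE collapse toward zero
  cfg0$count_vol_prey <- 1000
  cfg0$count_vol_pred <- 1000
  cfg0$max_count_prey <- Inf
  rs <- recovery_study(cfg0, 4, plan = plan,
                       candidates = list(FR3 = 3),
                       mu_strategy = "uncorrected", density_axis = "mean")
  expect_equal(rs$n_failed, 0L)
  imax_row <- rs$params[rs$params$param == "imax", ]
  expect_lt(abs(imax_row$relative_bias), 0.1)
  # and essentially no between-replicate scatter without noise
  expect_lt(sd(rs$estimates$imax) / mean(rs$estimates$imax), 0.02)
  rs2 <- recovery_study(cfg0, 4, plan = plan,
                        candidates = list(FR3 = 3),
                        mu_strategy = "uncorrected", density_axis = "mean")
  expect_identical(rs$estimates, rs2$estimates)
  # pairing rates with the initial instead of the time-averaged density
  # leaves the depletion bias in: the log-mean axis is the less biased one
  rs_init <- recovery_study(cfg0, 4, plan = plan,
                            candidates = list(FR3 = 3),
                            mu_strategy = "uncorrected",
                            density_axis = "initial")
  expect_gt(abs(rs_init$params$relative_bias[3]), abs(imax_row$relative_bias))
})

test_that("model selection frequencies behave at the truth's corners", {
  plan <- demo_plan()
  # type II truth: the theta = 1 candidate wins most replicates
  cfg2 <- simulation_config(
    fr = fr_params(a = 667 / 2e4, h = 1 / 667, theta = 1),
    nr = NULL, seed = 600
  )
  rs2 <- recovery_study(cfg2, 20, plan = plan,
                        candidates = list(FR2 = 1, FR3 = 2),
                        mu_strategy = "uncorrected")
  w2 <- rs2$wins$fraction[rs2$wins$model_id == "FR2"]
  expect_gte(w2, 0.8)
})
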