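test_that("AICc matches its closed form and collapses to AIC for large n", {
  # direct evaluation: n = 20, two model params + variance -> k = 3
  expect_equal(aicc(1, 20, 2), 20 * log(1 / 20) + 6 + 24 / 16,
               tolerance = 1e-12)
  # correction term vanishes as n grows
  aic <- function(rss, n, k) n * log(rss / n) + 2 * (k + 1)
  expect_equal(aicc(50, 1e6, 3), aic(50, 1e6, 3), tolerance = 1e-6)
  expect_error(aicc(0, 20, 2), "positive")
  expect_error(aicc(1, 5, 4), "undefined")
})

test_that("noiseless NR data are recovered to 1e-6 relative error", {
  truth <- nr_params(0.32, 1349, 5000)
  dat <- make_nr_data(truth, sd = 0, n = 20)
  fit <- fit_nr(dat, density_axis = "mean")
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_equal(unname(est["rmax"]), truth$rmax, tolerance = 1e-6)
  expect_equal(unname(est["pp"]), truth$p_prime, tolerance = 1e-6)
  expect_equal(unname(est["k2"]), truth$k2, tolerance = 1e-6)
})

test_that("NR parameters are recovered within 10% under Gaussian noise", {
  truth <- nr_params(0.32, 1349, 5000)
  set.seed(11)
  rmax_hat <- replicate(100, {
    dat <- make_nr_data(truth, sd = 0.03, n = 20)
    fit <- tryCatch(fit_nr(dat), error = function(e) NULL)
    if (is.null(fit)) NA_real_ else
      fit$params$estimate[fit$params$term == "rmax"]
  })
  expect_lt(mean(is.na(rmax_hat)), 0.1)
  expect_lt(abs(median(rmax_hat, na.rm = TRUE) - truth$rmax) / truth$rmax, 0.1)
})

test_that("NR fits on initial vs mean axes of the same wells are near-equivalent", {
  truth <- nr_params(0.32, 1349, 5000)
  set.seed(21)
  d0 <- density_grid(20)
  dat <- tibble::tibble(
    p_initial = d0,
    p_mean = log_mean_density(d0, d0 * exp(runif(20, -0.3, 0.05))),
    r = NA_real_
  )
  dat$r <- nr_predict(dat$p_mean, truth) + rnorm(20, 0, 0.02)
  f_mean <- fit_nr(dat, "mean")
  f_init <- fit_nr(dat, "initial")
  expect_lt(abs(f_mean$aicc - f_init$aicc), 6)
  rm_m <- f_mean$params$estimate[f_mean$params$term == "rmax"]
  rm_i <- f_init$params$estimate[f_init$params$term == "rmax"]
  expect_lt(abs(rm_m - rm_i) / rm_m, 0.15)
})

test_that("noiseless FR data (theta = 3) are recovered exactly", {
  truth <- fr_params(a = 667 / 2e4^3, h = 1 / 667, theta = 3)
  dat <- make_fr_data(truth, cv = 0, n = 20)
  fit <- fit_fr(dat, theta = 3, correction = "none")
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_equal(unname(est["a"]), truth$a, tolerance = 1e-6)
  expect_equal(unname(est["h"]), truth$h, tolerance = 1e-6)
  imax <- fit$derived$estimate[fit$derived$term == "imax"]
  expect_equal(imax, 667, tolerance = 1e-6)
})

test_that("free-theta fits recover the Hill exponent from clean data", {
  truth <- fr_params(a = 667 / 2e4^3, h = 1 / 667, theta = 3)
  dat <- make_fr_data(truth, cv = 0, n = 20)
  fit <- fit_fr(dat, theta = "free", correction = "none")
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_equal(unname(est["theta"]), 3, tolerance = 1e-4)
})

test_that("the true Hill exponent wins AICc at moderate noise", {
  truth <- fr_params(a = 667 / 2e4^3, h = 1 / 667, theta = 3)
  set.seed(31)
  wins <- replicate(40, {
    dat <- make_fr_data(truth, cv = 0.2, n = 20)
    fits <- lapply(c(1, 2, 3), function(th) {
      tryCatch(fit_fr(dat, theta = th, correction = "none"),
               error = function(e) NULL)
    })
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) < 2) return(NA_character_)
    rank_models(fits)$model_id[1L]
  })
  expect_gte(mean(wins == "FR3-theta=3", na.rm = TRUE), 0.8)
})

test_that("disk and Michaelis-Menten fits give identical curves and AICc", {
  truth <- fr_params(a = 667 / 2e4, h = 1 / 667, theta = 1)
  set.seed(41)
  dat <- make_fr_data(truth, cv = 0.15, n = 20)
  f_disk <- fit_fr(dat, theta = 1, correction = "none")
  f_mm <- fit_fr_mm(dat, correction = "none")
  expect_equal(f_disk$fitted, f_mm$fitted, tolerance = 1e-5)
  expect_equal(f_disk$aicc, f_mm$aicc, tolerance = 1e-5)
  # parameter mapping: imax = 1/h, k = 1/(a h)
  a <- f_disk$params$estimate[f_disk$params$term == "a"]
  h <- f_disk$params$estimate[f_disk$params$term == "h"]
  imax_mm <- f_mm$params$estimate[f_mm$params$term == "imax"]
  k_mm <- f_mm$params$estimate[f_mm$params$term == "k"]
  expect_equal(1 / h, imax_mm, tolerance = 1e-4)
  expect_equal(1 / (a * h), k_mm, tolerance = 1e-4)
})

test_that("log transform refuses non-positive ingestion rates", {
  dat <- make_fr_data(fr_params(3e-4, 1 / 800), cv = 0, n = 10)
  dat$i_cells[2] <- -1
  expect_error(fit_fr(dat, transform = "log"), "positive")
  # untransformed objective retains the negative point
  fit <- fit_fr(dat, theta = 1, correction = "controls")
  expect_equal(fit$n, 10)
})

test_that("model ranking labels support and refuses incomparable fits", {
  truth <- fr_params(a = 667 / 2e4^3, h = 1 / 667, theta = 3)
  set.seed(51)
  dat <- make_fr_data(truth, cv = 0.2, n = 20)
  f1 <- fit_fr(dat, theta = 1, correction = "none")
  f3 <- fit_fr(dat, theta = 3, correction = "none")
  rk <- rank_models(list(f1, f3))
  expect_equal(rk$delta_aicc[1], 0)
  expect_equal(rk$support[1], "substantial")
  expect_true(all(diff(rk$aicc) >= 0))
  # invariant to input order
  rk_rev <- rank_models(list(f3, f1))
  expect_equal(rk, rk_rev)
  # single fit: trivial ranking
  rk1 <- rank_models(list(f3))
  expect_equal(rk1$delta_aicc, 0)
  # different transforms are incomparable
  dat_pos <- dat
  dat_pos$i_cells <- abs(dat_pos$i_cells) + 1
  f_log <- fit_fr(dat_pos, theta = 1, transform = "log", correction = "none")
  expect_error(rank_models(list(f1, f_log)), "not comparable")
})

test_that("proportion-ingested quadratic discriminates clearance shapes", {
  # clean type II (monotone decreasing proportion)
  set.seed(61)
  d2 <- make_proportion_data(fr_params(3e-4, 1 / 800, 1), noise_frac = 0.05)
  v2 <- discriminate_fr_type(d2)
  expect_equal(v2$verdict, "typeII")
  # clean type III (unimodal proportion)
  d3 <- make_proportion_data(fr_params(667 / 2e4^3, 1 / 667, 3),
                             noise_frac = 0.05)
  v3 <- discriminate_fr_type(d3)
  expect_equal(v3$verdict, "typeIII")
  # near-constant proportion (type I regime): inconclusive
  dI <- tibble::tibble(density = density_grid(12),
                       proportion_ingested = 0.003 * (1 + rnorm(12, 0, 1e-4)))
  expect_equal(discriminate_fr_type(dI)$verdict, "inconclusive")
  # preconditions
  expect_error(discriminate_fr_type(d2[1:5, ]), "at least 8")
  narrow <- tibble::tibble(density = seq(1000, 2000, length.out = 10),
                           proportion_ingested = runif(10))
  expect_error(discriminate_fr_type(narrow), "order of magnitude")
})

test_that("covariate screens recover known slopes and respect the null", {
  set.seed(71)
  wells <- make_tiny_wells()
  # build a larger synthetic wells table with a known FLW effect on prey
  n <- 10
  flw <- seq(0.45, 0.9, length.out = n)
  mu_true <- 0.1 - 0.8 * flw
  p0 <- rep(10000, n)
  pt <- p0 * exp(mu_true + rnorm(n, 0, 0.02))
  wells10 <- tibble::tibble(
    well_id = sprintf("E%02d", 1:n), role = "experimental",
    target_prey = p0, P0 = p0, Pt = pt,
    R0 = 25, Rt = 25 * exp(rnorm(n, 0, 0.05)),
    counted_prey_0 = round(p0), counted_prey_t = round(pt),
    counted_pred_0 = 75L, counted_pred_t = 75L,
    subsample_mL = 1, t_days = 1, flw_fraction = flw
  )
  rates <- well_rates(wells10, mu_strategy = "uncorrected")
  eff <- suppressMessages(covariate_effects(wells10, rates))
  mu_row <- eff[eff$screen == "mu_experimental~flw" & eff$term == "flw", ]
  expect_lt(mu_row$estimate, 0)
  expect_lt(mu_row$p.value, 0.05)
  expect_equal(unname(mu_row$estimate), -0.8, tolerance = 0.15)
  # interference: I scaled by (rm/25)^-0.5 yields a negative rm coefficient
  # (FLW refreshed at random so the two covariates are not collinear)
  wells_int <- wells10
  wells_int$flw_fraction <- runif(n, 0.45, 0.9)
  wells_int$R0 <- seq(15, 60, length.out = n)
  g_base <- 0.2
  i_true <- 10000 * g_base / wells_int$R0 * (wells_int$R0 / 25)^-0.5
  # encode interference through final prey counts
  wells_int$Pt <- wells_int$P0 *
    exp(-(i_true * wells_int$R0 / wells_int$P0))
  wells_int$Rt <- wells_int$R0
  rates_int <- well_rates(wells_int, mu_strategy = "uncorrected")
  eff_int <- suppressMessages(covariate_effects(wells_int, rates_int))
  rm_row <- eff_int[eff_int$screen == "ingestion~flw+rm" & eff_int$term == "rm", ]
  expect_lt(rm_row$estimate, 0)
  # constant covariate: screen skipped with a message, NA row reported
  wells_const <- wells10
  wells_const$flw_fraction <- 0.5
  expect_message(
    eff_c <- covariate_effects(wells_const,
                               well_rates(wells_const,
                                          mu_strategy = "uncorrected")),
    "skipped"
  )
  expect_true(any(is.na(eff_c$estimate)))
})

test_that("tidy and glance expose parameters and provenance", {
  dat <- make_fr_data(fr_params(3e-4, 1 / 800), cv = 0, n = 10)
  fit <- fit_fr(dat, theta = 1, correction = "none", density_axis = "initial")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_true("imax" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$model_id, "FR2")
  expect_equal(gl$correction, "none")
  expect_equal(gl$density_axis, "initial")
  expect_equal(gl$n, 10)
})
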