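# Shared fixtures, all generated in code.

# Carbon models used throughout the worked examples.
prey_cm <- carbon_model(0.261, 0.860, "prey")
pred_cm <- carbon_model(0.216, 0.939, "predator")

# A geometric density grid spanning the usual experimental range.
density_grid <- function(n = 20, from = 500, to = 70000) {
  exp(seq(log(from), log(to), length.out = n))
}

# Ingestion data from a known FR truth with multiplicative log-normal noise
# (cv = 0 gives noiseless data).
make_fr_data <- function(params, cv = 0, n = 20, from = 500, to = 70000) {
  d <- density_grid(n, from, to)
  i <- fr_predict(d, params)
  if (cv > 0) {
    s2 <- log(1 + cv^2)
    i <- i * stats::rlnorm(n, -s2 / 2, sqrt(s2))
  }
  tibble::tibble(density = d, i_cells = i)
}

# Growth-rate data from a known NR truth with additive Gaussian noise.
make_nr_data <- function(params, sd = 0, n = 20, from = 500, to = 70000) {
  d <- density_grid(n, from, to)
  tibble::tibble(density = d,
                 r = nr_predict(d, params) + stats::rnorm(n, 0, sd))
}

# Proportion-ingested (clearance) data from a known FR truth with additive
# noise scaled to a fraction of the signal's spread.
make_proportion_data <- function(params, noise_frac = 0, n = 20,
                                 from = 500, to = 70000) {
  d <- density_grid(n, from, to)
  cl <- clearance_curve(d, params)
  if (noise_frac > 0) {
    cl <- cl + stats::rnorm(n, 0, noise_frac * stats::sd(cl))
  }
  tibble::tibble(density = d, proportion_ingested = cl)
}

# A minimal valid wells table built by hand (2 controls + 3 experimental).
make_tiny_wells <- function() {
  tibble::tibble(
    well_id = c("C1", "C2", "E1", "E2", "E3"),
    role = c("control", "control", rep("experimental", 3)),
    target_prey = c(1000, 10000, 1000, 5000, 20000),
    P0 = c(900, 9500, 950, 4800, 19000),
    Pt = c(850, 9000, 700, 4000, 16000),
    R0 = c(NA, NA, 25, 27, 24),
    Rt = c(NA, NA, 26, 28, 26),
    counted_prey_0 = c(900, 9500, 950, 4800, 19000),
    counted_prey_t = c(850, 9000, 700, 4000, 16000),
    counted_pred_0 = c(NA, NA, 75, 81, 72),
    counted_pred_t = c(NA, NA, 78, 84, 78),
    subsample_mL = 1,
    t_days = 1,
    flw_fraction = c(0.9, 0.8, 0.5, 0.6, 0.7)
  )
}
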