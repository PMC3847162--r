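# numerical-integration oracle for the exponentially tilted Gaussian
tilt_quadrature <- function(mu0, sigma0, t) {
  norm <- stats::integrate(function(r) exp(r * t) * dnorm(r, mu0, sigma0),
                           mu0 - 12 * sigma0, mu0 + 12 * sigma0,
                           rel.tol = 1e-10)$value
  m <- stats::integrate(function(r) r * exp(r * t) * dnorm(r, mu0, sigma0),
                        mu0 - 12 * sigma0, mu0 + 12 * sigma0,
                        rel.tol = 1e-10)$value / norm
  m2 <- stats::integrate(function(r) r^2 * exp(r * t) * dnorm(r, mu0, sigma0),
                         mu0 - 12 * sigma0, mu0 + 12 * sigma0,
                         rel.tol = 1e-10)$value / norm
  c(mean = m, sd = sqrt(m2 - m^2))
}

test_that("Gaussian tilt closed form matches the quadrature oracle", {
  for (p in list(c(1, 0.3, 2), c(0.5, 0.1, 4), c(1, 0.3, 0))) {
    q <- tilt_quadrature(p[1], p[2], p[3])
    cf <- gaussian_tilt_moments(p[1], p[2], p[3])
    expect_equal(cf$mean, q[["mean"]], tolerance = 1e-8)
    expect_equal(cf$sd, q[["sd"]], tolerance = 1e-8)
  }
  # frozen example: mu0 = 1, sigma0 = 0.3, t = 2 -> mean 1.18, sd 0.3
  cf <- gaussian_tilt_moments(1, 0.3, 2)
  expect_equal(cf$mean, 1.18, tolerance = 1e-12)
  expect_equal(cf$sd, 0.3, tolerance = 1e-12)
  # degenerate cases
  expect_equal(gaussian_tilt_moments(1, 0, 100)$mean, 1)
  expect_equal(gaussian_tilt_moments(1, 0.3, 0)$mean, 1)
})

test_that("finite-lineage tilt moments approach the Gaussian closed form", {
  with_seed_local <- function(s, e) withr::with_seed(s, e)
  r <- with_seed_local(1, rnorm(2e5, 1, 0.3))
  lt <- lineage_tilt_moments(r, 2)
  expect_lt(abs(lt$mean - 1.18), 0.01)
  expect_lt(abs(lt$sd - 0.3), 0.01)
})

test_that("zero founder variance keeps the population mean rate constant", {
  traj <- simulate_population(sim_config(n_founders = 100, founder_cv = 0,
                                         horizon_generations = 4, seed = 1))
  expect_true(all(traj$mean_rate == traj$mean_rate[1]))
  expect_true(all(traj$sd_rate == 0))
})

test_that("stable-mode simulator matches the closed-form oracle", {
  # mean trajectories over 20 seeds, 3 CV values, 5 checkpoints
  t_checks <- c(0.4, 0.8, 1.2, 1.6, 2.0)
  for (cv in c(0.1, 0.2, 0.3)) {
    per_seed <- sapply(1:20, function(s) {
      traj <- simulate_population(sim_config(
        n_founders = 1000, founder_mean_rate = 1, founder_cv = cv,
        horizon_time = 2, checkpoint_interval = 0.4, seed = s))
      vapply(t_checks, function(tc) {
        traj$mean_rate[which.min(abs(traj$time - tc))]
      }, numeric(1))
    })
    m <- rowMeans(per_seed)
    se <- apply(per_seed, 1, sd) / sqrt(20)
    oracle <- gaussian_tilt_moments(1, cv, t_checks)$mean
    expect_true(all(abs(m - oracle) < 3 * se + 1e-9),
                info = sprintf("cv = %g", cv))
  }
})

test_that("Fisher's theorem holds along deterministic trajectories", {
  traj <- simulate_population(sim_config(
    n_founders = 3000, founder_cv = 0.3, horizon_time = 2,
    checkpoint_interval = 0.02, stochastic = FALSE, seed = 2))
  m <- traj$mean_rate
  v <- traj$sd_rate^2
  dt <- diff(traj$time)[1]
  dmdt <- (m[-(1:2)] - m[seq_len(length(m) - 2)]) / (2 * dt)
  expect_equal(dmdt, v[2:(length(v) - 1)], tolerance = 1e-3)
})

test_that("stable-mode mean rate is monotone; switching mode can relax", {
  det <- simulate_population(sim_config(
    n_founders = 500, founder_cv = 0.3, horizon_time = 3,
    stochastic = FALSE, seed = 3))
  expect_true(all(diff(det$mean_rate) >= -1e-12))

  # strong switching erodes the selection gain: the trajectory must be able
  # to plateau or decrease after the initial rise
  sw <- simulate_population(sim_config(
    n_founders = 500, founder_cv = 0.3, inheritance = "switching",
    switch_rate = 2, horizon_time = 6, seed = 3))
  expect_true(any(diff(sw$mean_rate) < 0))
  expect_lt(max(sw$mean_rate), max(det$mean_rate) + 0.2)
})

test_that("generation counter equals log2 cumulative growth", {
  traj <- simulate_population(sim_config(
    n_founders = 200, founder_cv = 0.2, horizon_time = 3,
    stochastic = FALSE, seed = 4))
  expect_equal(traj$generations, log2(traj$size / traj$size[1]),
               tolerance = 1e-9)
  expect_true(all(diff(traj$generations) >= 0))
})

test_that("dilution keeps expected lineage frequencies and guards transfers", {
  # single lineage: exact survivor count
  expect_equal(apply_dilution(1e6, 10, seed = 1), 1e5)

  # two 60/40 lineages: binomial sampling around the frequencies
  reps <- vapply(1:400, function(s) {
    out <- apply_dilution(c(6e3, 4e3), 10, seed = s)
    out[1] / sum(out)
  }, numeric(1))
  se_binom <- sqrt(0.6 * 0.4 / 1e3)
  expect_lt(abs(mean(reps) - 0.6), 3 * se_binom / sqrt(400))

  # guards
  expect_error(apply_dilution(c(50, 50), 200),
               class = "growthdyn_protocol_violation")
  expect_error(apply_dilution(c(1e6), 5, min_transfer = 1e6),
               class = "growthdyn_protocol_violation")
  expect_error(apply_dilution(c(10, 10), 0.5),
               class = "growthdyn_config_error")
})

test_that("serial-dilution protocol violation truncates with explicit status", {
  traj <- simulate_population(sim_config(
    n_founders = 100, founder_mean_rate = 0.05, founder_cv = 0.1,
    protocol = "serial_dilution", dilution_interval = 1,
    dilution_range = c(10, 10), min_transfer = 50, horizon_time = 10,
    checkpoint_interval = 0.5, seed = 5))
  expect_equal(attr(traj, "status"), "protocol_violation")
  expect_lt(max(traj$time), 10)
})

test_that("takeover time matches two-exponential crossing algebra", {
  # lineages at r = 1.2 (40 cells) vs 1.0 (60 cells): the fast lineage
  # reaches 50% at t = ln(1.5)/0.2
  traj <- simulate_population(sim_config(
    n_founders = 2, founder_rates = c(1.2, 1.0), founder_sizes = c(40, 60),
    founder_cv = 0, horizon_time = 3, checkpoint_interval = 0.01,
    stochastic = FALSE, seed = 1))
  tk <- takeover_time(traj, top_fraction = 0.5)
  expect_true(tk$reached)
  expect_equal(tk$time, log(1.5) / 0.2, tolerance = 1e-3)

  # no rate variation -> no selection differential -> never reached
  flat <- simulate_population(sim_config(
    n_founders = 100, founder_cv = 0, horizon_generations = 5, seed = 1))
  expect_false(takeover_time(flat, top_fraction = 0.1)$reached)
})

test_that("takeover of the top decile is faster for broader distributions", {
  g_at <- vapply(c(0.2, 0.4), function(cv) {
    traj <- simulate_population(sim_config(
      n_founders = 500, founder_cv = cv, horizon_time = 25,
      checkpoint_interval = 0.25, stochastic = FALSE, seed = 6))
    takeover_time(traj, top_fraction = 0.1)$generations
  }, numeric(1))
  expect_true(all(is.finite(g_at)))
  expect_lt(g_at[2], g_at[1])
})

test_that("agent and lineage engines agree at 10^4 founders", {
  runs <- function(engine) {
    vapply(1:5, function(s) {
      glance(simulate_population(sim_config(
        n_founders = 1e4, founder_cv = 0.3, horizon_generations = 3,
        checkpoint_interval = 0.2, engine = engine,
        seed = s)))$final_mean_rate
    }, numeric(1))
  }
  a <- runs("agent")
  l <- runs("lineage")
  se <- sqrt(var(a) / 5 + var(l) / 5)
  expect_lt(abs(mean(a) - mean(l)), 3 * se + 0.01)
})
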