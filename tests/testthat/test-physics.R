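# Treatment physics: closed forms, quadrature, coil field, power budget.

test_that("field_at matches the closed form and its bounds", {
  cfg <- field_config(B0_mT = 2.5, f_Hz = 50)
  expect_equal(field_at(cfg, r = 0.3, t = 0), 2.5e-3)
  cfg_phase <- field_config(2.5, 50, phi = pi / 2)
  expect_equal(field_at(cfg_phase, r = 0, t = 0), 0, tolerance = 1e-15)
  cfg_att <- field_config(2.5, 50, alpha = 100)
  expect_equal(field_at(cfg_att, r = 0.01, t = 0), 2.5e-3 * exp(-1))

  # |B(r,t)| <= B0 exp(-alpha r) over random inputs
  set.seed(1)
  for (i in 1:50) {
    cfg_i <- field_config(runif(1, 0, 5), runif(1, 0, 1000),
                          runif(1, -pi, pi), runif(1, 0, 50))
    r <- runif(20, 0, 0.2); t <- runif(20, 0, 10)
    expect_true(all(abs(field_at(cfg_i, r, t)) <=
                      cfg_i$B0 * exp(-cfg_i$alpha * r) + 1e-15))
  }
  expect_error(field_at(cfg, r = -1, t = 0), "distance")
  expect_error(field_at(cfg, r = 0, t = NaN), "finite")
})

test_that("unit conversion round-trips mT -> T -> mT exactly", {
  for (b in c(0.5, 1.7, 3.14159, 5)) {
    expect_identical(field_config(b, 50)$B0 * 1e3, b)
  }
})

test_that("vibration_amplitude limits and resonance peak", {
  mech <- seed_mechanics(f_n = 300, zeta = 0.1)
  scale <- (2e-3)^2 * mech$V_seed / (2 * vibroseed:::MU0 * mech$rho_seed)
  expect_equal(vibration_amplitude(2e-3, 300, mech),
               scale / (2 * 0.1 * 300^2))
  expect_equal(vibration_amplitude(2e-3, 0, mech), scale / 300^2)
  # argmax over a dense grid within one cell of f_n sqrt(1 - 2 zeta^2)
  for (zeta in c(0.05, 0.2, 0.5)) {
    m <- seed_mechanics(f_n = 300, zeta = zeta)
    f_grid <- seq(1, 1000, by = 0.25)
    a <- vibration_amplitude(1e-3, f_grid, m)
    f_peak_theory <- 300 * sqrt(1 - 2 * zeta^2)
    expect_lt(abs(f_grid[which.max(a)] - f_peak_theory), 0.5)
  }
  expect_error(seed_mechanics(f_n = 0), "f_n")
})

test_that("total_energy reproduces analytic cases and converges", {
  mech <- seed_mechanics()
  # constant field (f = 0), eta = 1, 100% duty -> B^2 V T / (2 mu0)
  p <- treatment_protocol(2, 0, 60, duty_cycle_pct = 100, check = FALSE)
  expect_equal(total_energy(p, mech),
               (2e-3)^2 * mech$V_seed * 60 / (2 * vibroseed:::MU0),
               tolerance = 1e-12)
  # eta = 0 -> 0
  mech0 <- seed_mechanics(eta = 0)
  expect_equal(total_energy(p, mech0), 0)
  # oscillating field over whole cycles -> half the constant-field energy
  p2 <- treatment_protocol(2, 50, 60, duty_cycle_pct = 100, check = FALSE)
  expect_equal(total_energy(p2, mech, n_steps = 100001),
               (2e-3)^2 * mech$V_seed * 60 / (4 * vibroseed:::MU0),
               tolerance = 1e-8)
  # Simpson convergence for smooth eta
  mech_s <- seed_mechanics(eta = eta_saturating(30))
  e1 <- total_energy(p2, mech_s, n_steps = 20001)
  e2 <- total_energy(p2, mech_s, n_steps = 40001)
  expect_lt(abs(e1 - e2) / e2, 1e-6)
  # duty gating scales linearly
  p3 <- mid_protocol(duty_cycle_pct = 45)
  p4 <- mid_protocol(duty_cycle_pct = 90)
  expect_equal(total_energy(p4, mech) / total_energy(p3, mech), 2)
})

test_that("helmholtz_center_field matches the printed convention", {
  coil <- coil_spec(n_turns = 500, radius_m = 0.1, separation_m = 0.1)
  expect_equal(helmholtz_center_field(coil, 0), 0)
  b1 <- helmholtz_center_field(coil, 1)
  expect_equal(helmholtz_center_field(coil, 2), 2 * b1)
  # z = R substitution, evaluated independently
  expect_equal(b1, 2 * vibroseed:::MU0 * 500 * 1 / (0.1 * (5 / 4)^1.5))
  # textbook mode restores the conventional (4/5)^(3/2) mu0 N I / R
  expect_equal(helmholtz_center_field(coil, 1, textbook_mode = TRUE),
               (4 / 5)^1.5 * vibroseed:::MU0 * 500 / 0.1)
  expect_error(coil_spec(radius_m = 0), "radius")
})

test_that("electrical_power arithmetic and monotonicity", {
  coil <- coil_spec(coil_resistance_ohm = 3)
  losses0 <- power_model(0, 0)
  expect_equal(electrical_power(0, coil, losses0), 0)
  losses <- power_model(1, 0.5)
  expect_equal(electrical_power(2, coil, losses), 13.5)
  # P(I2) - P(I1) = (I2^2 - I1^2) R for fixed losses
  I <- seq(0, 5, by = 0.5)
  P <- electrical_power(I, coil, losses)
  expect_equal(diff(P), diff(I^2) * 3)
  expect_true(all(diff(P) >= 0))
})

test_that("protocol_energy_cost scales with duration, voltage and field", {
  coil <- coil_spec(); losses <- power_model()
  p <- mid_protocol()
  p0 <- p; p0$duration_s <- 0
  expect_equal(protocol_energy_cost(p0, coil, losses), 0)
  p2 <- p; p2$duration_s <- 240
  expect_equal(protocol_energy_cost(p2, coil, losses),
               2 * protocol_energy_cost(p, coil, losses))
  # strictly increasing in voltage amplitude and in field strength
  volts <- seq(5, 50, by = 5)
  cost_v <- vapply(volts, function(v)
    protocol_energy_cost(mid_protocol(voltage_amplitude_V = v), coil,
                         losses), 0)
  expect_true(all(diff(cost_v) > 0))
  fields <- seq(0.5, 5, by = 0.5)
  cost_b <- vapply(fields, function(b) {
    protocol_energy_cost(treatment_protocol(b, 300, 120), coil, losses)
  }, 0)
  expect_true(all(diff(cost_b) > 0))
})

test_that("protocol constructors enforce the parameter ranges", {
  expect_error(treatment_protocol(6, 300, 120), "field_strength")
  expect_error(treatment_protocol(2.5, 300, 120, duty_cycle_pct = 95),
               "duty_cycle")
  x <- protocol_to_vector(mid_protocol())
  expect_identical(unname(x[1:3]), c(2.5, 300, 120))
  expect_equal(protocol_to_vector(vector_to_protocol(x)), x)
})
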