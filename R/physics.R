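# Treatment physics: applied field, induced vibration, absorbed energy,
# coil field and electrical power. All operations are pure and work in SI
# internally (tesla, metres, seconds); user-facing protocol values keep the
# bench units of the treatment table (mT, Hz, s, V, ms, %).

#' Permeability of free space (H/m)
#' @keywords internal
MU0 <- 4 * pi * 1e-7

#' Decision-variable bounds for a treatment protocol
#'
#' Closed box bounds for the six treatment decision variables:
#' magnetic field strength 0.5--5 mT, vibration frequency 10--1000 Hz,
#' action time 30--300 s, voltage amplitude 5--50 V, pulse width 0.1--10 ms,
#' duty cycle 10--90 %.
#'
#' @return A named list with `lower` and `upper` numeric vectors (length 6,
#'   names `field_strength_mT`, `frequency_Hz`, `duration_s`,
#'   `voltage_amplitude_V`, `pulse_width_ms`, `duty_cycle_pct`).
#' @export
protocol_bounds <- function() {
  nm <- c("field_strength_mT", "frequency_Hz", "duration_s",
          "voltage_amplitude_V", "pulse_width_ms", "duty_cycle_pct")
  list(
    lower = stats::setNames(c(0.5, 10, 30, 5, 0.1, 10), nm),
    upper = stats::setNames(c(5.0, 1000, 300, 50, 10, 90), nm)
  )
}

#' Field configuration for the treatment chamber
#'
#' @param B0_mT peak magnetic flux density in millitesla (stored internally
#'   in tesla).
#' @param f_Hz vibration frequency (Hz).
#' @param phi phase angle (rad).
#' @param alpha spatial attenuation coefficient (1/m); default 0, i.e.
#'   treatment evaluated at the chamber centre.
#' @return An object of class `field_config`.
#' @export
field_config <- function(B0_mT, f_Hz, phi = 0, alpha = 0) {
  stopifnot(is.finite(B0_mT), is.finite(f_Hz), is.finite(phi), is.finite(alpha))
  if (B0_mT < 0) stop("B0 must be >= 0")
  if (f_Hz < 0) stop("frequency must be >= 0")
  if (alpha < 0) stop("attenuation coefficient must be >= 0")
  structure(list(B0 = B0_mT * 1e-3, f = f_Hz, phi = phi, alpha = alpha),
            class = "field_config")
}

#' Treatment protocol (the six decision variables)
#'
#' @param field_strength_mT peak magnetic field strength (mT).
#' @param frequency_Hz vibration frequency (Hz).
#' @param duration_s action time (s).
#' @param voltage_amplitude_V drive voltage amplitude (V).
#' @param pulse_width_ms pulse width (ms).
#' @param duty_cycle_pct duty cycle (%).
#' @param check validate against [protocol_bounds()] (default `TRUE`).
#' @return An object of class `treatment_protocol`.
#' @export
treatment_protocol <- function(field_strength_mT, frequency_Hz, duration_s,
                               voltage_amplitude_V = 25, pulse_width_ms = 5,
                               duty_cycle_pct = 50, check = TRUE) {
  x <- c(field_strength_mT = field_strength_mT, frequency_Hz = frequency_Hz,
         duration_s = duration_s, voltage_amplitude_V = voltage_amplitude_V,
         pulse_width_ms = pulse_width_ms, duty_cycle_pct = duty_cycle_pct)
  if (any(!is.finite(x))) stop("protocol values must be finite")
  if (check) {
    b <- protocol_bounds()
    bad <- x < b$lower - 1e-9 | x > b$upper + 1e-9
    if (any(bad)) {
      stop("protocol outside bounds: ", paste(names(x)[bad], collapse = ", "))
    }
  }
  structure(as.list(x), class = "treatment_protocol")
}

#' Convert a treatment protocol to / from a bare numeric vector
#'
#' The decision-vector representation used by the optimizer, ordered as in
#' [protocol_bounds()].
#' @param protocol a `treatment_protocol`.
#' @return `protocol_to_vector()`: named numeric of length 6;
#'   `vector_to_protocol()`: a `treatment_protocol`.
#' @export
protocol_to_vector <- function(protocol) {
  stopifnot(inherits(protocol, "treatment_protocol"))
  unlist(protocol)
}

#' @rdname protocol_to_vector
#' @param x named or ordered numeric vector of length 6.
#' @param check validate against bounds.
#' @export
vector_to_protocol <- function(x, check = TRUE) {
  stopifnot(length(x) == 6)
  treatment_protocol(x[[1]], x[[2]], x[[3]], x[[4]], x[[5]], x[[6]],
                     check = check)
}

#' Mechanical constants of a seed
#'
#' @param V_seed seed volume (m^3). Default 2.5e-7 (a ~0.25 cm^3 maize kernel).
#' @param rho_seed seed density (kg/m^3). Default 1250.
#' @param f_n natural frequency of the seed matrix (Hz).
#' @param zeta damping ratio, in (0, 1).
#' @param eta absorption efficiency: either a constant in \[0,1\] or a
#'   function of time returning values in \[0,1\]. Default constant 1.
#' @return An object of class `seed_mechanics`.
#' @export
seed_mechanics <- function(V_seed = 2.5e-7, rho_seed = 1250, f_n = 300,
                           zeta = 0.1, eta = 1) {
  stopifnot(V_seed > 0, rho_seed > 0, f_n > 0, zeta > 0, zeta < 1)
  if (is.numeric(eta)) {
    stopifnot(length(eta) == 1, eta >= 0, eta <= 1)
    eta_val <- eta
    eta <- function(t) rep_len(eta_val, length(t))
  }
  stopifnot(is.function(eta))
  structure(list(V_seed = V_seed, rho_seed = rho_seed, f_n = f_n,
                 zeta = zeta, eta = eta),
            class = "seed_mechanics")
}

#' Exponential-saturation absorption efficiency
#'
#' Convenience constructor for `eta(t) = 1 - exp(-t / tau)`.
#' @param tau saturation time constant (s).
#' @return A function of time.
#' @export
eta_saturating <- function(tau) {
  stopifnot(tau > 0)
  function(t) 1 - exp(-t / tau)
}

#' Helmholtz coil specification
#'
#' @param n_turns turns per coil (default 500).
#' @param wire_diameter_mm copper wire diameter (default 1.2).
#' @param radius_m coil radius R (m).
#' @param separation_m axial separation z between the coils (m); the
#'   Helmholtz condition is z = R.
#' @param coil_resistance_ohm total coil resistance (ohm).
#' @return An object of class `coil_spec`.
#' @export
coil_spec <- function(n_turns = 500, wire_diameter_mm = 1.2, radius_m = 0.1,
                      separation_m = radius_m, coil_resistance_ohm = 3) {
  stopifnot(radius_m > 0, n_turns >= 1, coil_resistance_ohm >= 0)
  structure(list(n_turns = n_turns, wire_diameter_mm = wire_diameter_mm,
                 radius_m = radius_m, separation_m = separation_m,
                 coil_resistance_ohm = coil_resistance_ohm),
            class = "coil_spec")
}

#' Power-electronics loss model
#'
#' @param switching_loss_W switching losses (W).
#' @param control_power_W control-circuit power (W).
#' @return An object of class `power_model`.
#' @export
power_model <- function(switching_loss_W = 1, control_power_W = 0.5) {
  stopifnot(switching_loss_W >= 0, control_power_W >= 0)
  structure(list(switching_loss_W = switching_loss_W,
                 control_power_W = control_power_W),
            class = "power_model")
}

#' Magnetic flux density at distance r and time t
#'
#' `B(r, t) = B0 * cos(2 pi f t + phi) * exp(-alpha r)`.
#'
#' @param cfg a [field_config()].
#' @param r distance from the source (m), vectorised.
#' @param t time (s), vectorised.
#' @return Flux density in tesla.
#' @export
field_at <- function(cfg, r, t) {
  stopifnot(inherits(cfg, "field_config"))
  if (any(!is.finite(r)) || any(!is.finite(t))) stop("inputs must be finite")
  if (any(r < 0)) stop("distance r must be >= 0")
  if (any(t < 0)) stop("time t must be >= 0")
  cfg$B0 * cos(2 * pi * cfg$f * t + cfg$phi) * exp(-cfg$alpha * r)
}

#' Induced vibration amplitude in the seed matrix
#'
#' Resonance response of a damped oscillator driven by the magnetic
#' pressure term:
#' `A = B^2 V_seed / (2 mu0 rho_seed) / sqrt((f_n^2 - f^2)^2 + (2 zeta f_n f)^2)`.
#' For damping ratio `zeta < 1/sqrt(2)` the response is unimodal in `f` with
#' its peak at `f_n * sqrt(1 - 2 zeta^2)`.
#'
#' @param B flux density (tesla), vectorised.
#' @param f driving frequency (Hz), vectorised.
#' @param mech a [seed_mechanics()].
#' @return Amplitude (m).
#' @export
vibration_amplitude <- function(B, f, mech) {
  stopifnot(inherits(mech, "seed_mechanics"))
  if (any(f < 0)) stop("frequency must be >= 0")
  denom <- sqrt((mech$f_n^2 - f^2)^2 + (2 * mech$zeta * mech$f_n * f)^2)
  if (any(denom == 0)) stop("degenerate resonance: f_n = f = 0")
  (B^2 * mech$V_seed) / (2 * MU0 * mech$rho_seed) / denom
}

# On/off pulse gate. Period = pulse_width / duty fraction; the field is on
# for the first pulse_width seconds of every period.
pulse_gate <- function(t, pulse_width_s, duty_frac) {
  if (duty_frac >= 1) return(rep_len(1, length(t)))
  period <- pulse_width_s / duty_frac
  as.numeric((t %% period) < pulse_width_s)
}

#' Total electromagnetic energy absorbed by a seed over a treatment
#'
#' Composite-Simpson quadrature of
#' `B(t)^2 V_seed / (2 mu0) * eta(t)` over the action time, with
#' `B(t)` the chamber-centre field of [field_at()] and the integrand gated
#' on/off by the protocol's pulse width and duty cycle (period =
#' `pulse_width / duty`). At 100% duty the gate is identically 1 and the
#' quadrature converges at the usual Simpson rate for smooth `eta`.
#'
#' @param protocol a [treatment_protocol()].
#' @param mech a [seed_mechanics()].
#' @param n_steps number of quadrature points (odd; default 1001).
#' @param phi field phase angle (rad).
#' @param duty_exact if `TRUE` (default) the pulse gate is applied as the
#'   analytic duty fraction multiplying the quadrature (the pulse period,
#'   0.1--10 ms, is orders of magnitude below the 30--300 s action time, so
#'   the fast on/off gate averages to the duty fraction); if `FALSE` the
#'   gate is sampled pointwise (useful only with very large `n_steps`).
#' @return Absorbed energy (J).
#' @export
total_energy <- function(protocol, mech, n_steps = 1001, phi = 0,
                         duty_exact = TRUE) {
  stopifnot(inherits(protocol, "treatment_protocol"),
            inherits(mech, "seed_mechanics"))
  if (protocol$duration_s <= 0) stop("duration must be > 0")
  if (n_steps < 2) stop("n_steps must be >= 2")
  if (n_steps %% 2 == 0) n_steps <- n_steps + 1  # Simpson needs odd points
  T_ <- protocol$duration_s
  t <- seq(0, T_, length.out = n_steps)
  B0 <- protocol$field_strength_mT * 1e-3
  Bt <- B0 * cos(2 * pi * protocol$frequency_Hz * t + phi)
  integrand <- Bt^2 * mech$V_seed / (2 * MU0) * mech$eta(t)
  duty_frac <- protocol$duty_cycle_pct / 100
  if (duty_exact) {
    gate_scale <- if (duty_frac >= 1) 1 else duty_frac
  } else {
    integrand <- integrand *
      pulse_gate(t, protocol$pulse_width_ms * 1e-3, duty_frac)
    gate_scale <- 1
  }
  h <- T_ / (n_steps - 1)
  w <- rep(c(2, 4), length.out = n_steps)
  w[1] <- 1; w[n_steps] <- 1
  gate_scale * h / 3 * sum(w * integrand)
}

#' Field at the centre of a Helmholtz coil pair
#'
#' `B_center = mu0 N I R^2 / (R^2 + (z/2)^2)^(3/2) * 2`, as used by the
#' treatment-system design. Note this convention counts each coil's full
#' Biot-Savart loop term; `textbook_mode = TRUE` applies the conventional
#' 1/2 per-coil factor instead, giving the standard
#' `(4/5)^(3/2) mu0 N I / R` at the Helmholtz condition z = R.
#'
#' @param coil a [coil_spec()].
#' @param current coil current (A), vectorised.
#' @param textbook_mode use the conventional per-coil 1/2 factor.
#' @return Flux density at the centre (tesla).
#' @export
helmholtz_center_field <- function(coil, current, textbook_mode = FALSE) {
  stopifnot(inherits(coil, "coil_spec"))
  if (any(!is.finite(current))) stop("current must be finite")
  R <- coil$radius_m
  if (R <= 0) stop("coil radius must be > 0")
  z <- coil$separation_m
  base <- MU0 * coil$n_turns * current * R^2 / (R^2 + (z / 2)^2)^(3 / 2)
  if (textbook_mode) base else 2 * base
}

#' Electrical power drawn by the electromagnetic system
#'
#' `P_total = I^2 R_coil + P_switching + P_control`.
#'
#' @param current_rms RMS coil current (A), vectorised.
#' @param coil a [coil_spec()].
#' @param losses a [power_model()].
#' @return Power (W).
#' @export
electrical_power <- function(current_rms, coil, losses) {
  stopifnot(inherits(coil, "coil_spec"), inherits(losses, "power_model"))
  if (any(current_rms < 0)) stop("current must be >= 0")
  current_rms^2 * coil$coil_resistance_ohm +
    losses$switching_loss_W + losses$control_power_W
}

#' Electrical energy cost of running a protocol
#'
#' The energy objective used by the optimizer: total electrical power times
#' action time. The RMS coil current combines two linear maps — the current
#' needed to command the requested field (through the coil's
#' field-per-ampere constant, [helmholtz_center_field()] at 1 A) and the
#' auxiliary drive current `V / Z` with a configured impedance — both
#' scaled by the duty cycle (current only flows while the pulse is on).
#' The cost is therefore strictly increasing in both the field strength
#' and the voltage amplitude.
#'
#' @param protocol a [treatment_protocol()].
#' @param coil a [coil_spec()].
#' @param losses a [power_model()].
#' @param impedance_ohm drive impedance Z of the voltage-to-current map
#'   (default 10).
#' @return Electrical energy (J).
#' @export
protocol_energy_cost <- function(protocol, coil, losses, impedance_ohm = 10) {
  stopifnot(inherits(protocol, "treatment_protocol"))
  if (protocol$duration_s == 0) return(0)
  tesla_per_amp <- helmholtz_center_field(coil, 1)
  I_field <- protocol$field_strength_mT * 1e-3 / tesla_per_amp
  I_drive <- protocol$voltage_amplitude_V / impedance_ohm
  I_rms <- (I_field + I_drive) * sqrt(protocol$duty_cycle_pct / 100)
  electrical_power(I_rms, coil, losses) * protocol$duration_s
}
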