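step_on <- step_input(1e-4, 1e-7, cY = 1e-7)
step_off <- step_input(1e-7, 1e-4, cY = 1e-7)

test_that("simple regulation is a pure exponential between its endpoints", {
  p <- preset("ffl_or")
  sr <- simple_regulation_response(p, step_on)
  # half the gap is closed at t = log(2)
  expect_equal(sr$Z_fun(log(2)), (sr$Z_si + sr$Z_sf) / 2, tolerance = 1e-12)
  expect_equal(sr$Z_fun(1e4), sr$Z_sf, tolerance = 1e-12)
  # a degenerate step keeps the output constant
  s0 <- step_input(1e-6, 1e-6)
  sr0 <- simple_regulation_response(p, s0)
  expect_equal(sr0$Z, rep(sr0$Z_si, length(sr0$t)), tolerance = 1e-12)
  # the ODE route agrees with the closed form
  aY <- p_active(p$tfY, step_on$cY)
  f <- function(t, y) -y + inducible:::ffl_z_production(
    p, p_active(p$tfX, step_on$c_final) * p$Xbar / p$KXZ, aY * 1 / p$KYZ)
  tr <- integrate_circuit(f, sr$Z_si, 15, n_steps = 300)
  expect_equal(tr$y[, 1], sr$Z_fun(tr$t), tolerance = 1e-7)
})

test_that("step direction is keyed to the activity of X, not raw concentration", {
  p <- preset("ffl_or")
  # the effector inactivates X, so a concentration drop is an ON step
  expect_identical(delay_analytics(p, step_on)$direction, "ON")
  expect_identical(delay_analytics(p, step_off)$direction, "OFF")
})

test_that("the Y arm relaxes exponentially and Z reaches the steady state", {
  p <- preset("ffl_or")
  tr <- ffl_step_response(p, step_on)
  q <- inducible:::ffl_quantities(p, step_on)
  Yexp <- q$Y_f - (q$Y_f - q$Y_i) * exp(-tr$t)
  expect_equal(tr$y[, 1], Yexp, tolerance = 1e-7)
  expect_equal(tr$y[nrow(tr$y), 2], q$Z_f, tolerance = 1e-6)
  # pre-step state is the steady state of the initial effector level
  expect_lt(max(abs(ffl_rhs(c(q$Y_i, q$Z_i), p, step_on$c_initial,
                            step_on$cY))), 1e-12)
})

test_that("severing the feed-forward arm collapses onto simple regulation", {
  p <- preset("ffl_or")
  p$r1Y <- 0
  da <- delay_analytics(p, step_on)
  expect_equal(da$DeltaY, 0)
  expect_equal(da$avg_dt, 0)
  expect_equal(da$theta(seq(0, 20, by = 0.5)), rep(0, 41))
})

test_that("closed-form offset matches the ODE and its integral the closed-form delay", {
  for (nm in c("ffl_xor", "ffl_and", "ffl_or", "iffl_pulse")) {
    p <- preset(nm)
    for (s in list(step_on, step_off))
      expect_s3_class(delay_analytics(p, s, check = TRUE), "delay_analytics")
  }
  # seeded random parameter sets, both architectures
  set.seed(808)
  for (rep in 1:15) {
    rates <- 10^runif(5, -1, 1)
    pc <- cffl_params(rates[1] / 10, rates[1], rates[2] / 10, rates[2],
                      rates[3], omega = 10^runif(1, -1, 1.5),
                      KXZ = 10^runif(1, -1.5, 1.5), KYZ = 10^runif(1, -1.5, 1.5),
                      tfX = the_tf)
    expect_s3_class(delay_analytics(pc, step_on, check = TRUE),
                    "delay_analytics")
    pi <- iffl_params(rates[1] / 10, rates[1], rates[4] / 10, rates[4],
                      omega = 10^runif(1, -1, 1), KXZ = 10^runif(1, -1.5, 1.5),
                      KYZ = 10^runif(1, -1.5, 1.5), tfX = the_tf)
    expect_s3_class(delay_analytics(pi, step_off, check = TRUE),
                    "delay_analytics")
  }
})

test_that("theta vanishes at both ends of the response", {
  p <- preset("ffl_and")
  da <- delay_analytics(p, step_on)
  expect_equal(da$theta(0), 0, tolerance = 1e-14)
  expect_lt(abs(da$theta(40)), 1e-12)
})

test_that("coherent loops delay and incoherent loops accelerate", {
  set.seed(809)
  for (rep in 1:20) {
    r1Z <- 10^runif(1, -1, 1)
    pc <- cffl_params(0, 10^runif(1, -0.5, 0.5), 0, r1Z,
                      r1Z * 10^runif(1, 0, 1), omega = 10^runif(1, -1, 1.5),
                      KXZ = 10^runif(1, -1.5, 1.5), KYZ = 10^runif(1, -1.5, 1.5),
                      tfX = the_tf)
    for (s in list(step_on, step_off))
      expect_lte(delay_analytics(pc, s)$avg_dt, 1e-12)
    pi <- iffl_params(0, 10^runif(1, -0.5, 0.5), 10^runif(1, -2, 0), r1Z,
                      omega = 10^runif(1, -1, 1), KXZ = 10^runif(1, -1.5, 1.5),
                      KYZ = 10^runif(1, -1.5, 1.5), tfX = the_tf)
    da <- delay_analytics(pi, step_on)
    expect_lt(da$Phi, 0)
    # acceleration (not delay) whenever the output moves with the step;
    # responses that move against it fall outside the no-pulse delay theory
    if (sign(da$Z_f - da$Z_i) == sign(da$DeltaY))
      expect_gte(da$avg_dt, -1e-12)
  }
})

test_that("incoherent acceleration without a strong pulse never beats an instant jump", {
  p <- preset("iffl_pulse")
  kg <- log_grid(1e-2, 1e2, 12)
  sw <- delay_sweep(p, step_on, kg, kg, pulses = TRUE)
  keep <- !sw$strong_pulse & !is.na(sw$avg_dt)
  expect_gt(sum(keep), 0)
  expect_true(all(sw$avg_dt[keep] >= 0))
  expect_true(all(sw$avg_dt[keep] <= 1))
})

test_that("swapping step endpoints reproduces the reverse-step delay", {
  p <- preset("ffl_and")
  q <- inducible:::ffl_quantities(p, step_on)
  qr <- inducible:::ffl_quantities(p, reverse_step <- step_off)
  # recompute the reverse delay by hand from the forward quantities swapped
  Xcf <- q$Xc_i                       # final X activity after the swap
  A <- p$r0Z + p$r1Z * Xcf
  B <- p$r1Z + p$omega * p$r2Z * Xcf
  C <- 1 + Xcf; D <- 1 + p$omega * Xcf
  S <- C + D * q$Yc_i
  Phi <- B * C - A * D
  dY <- q$Yc_i - q$Yc_f
  manual <- Phi * log((S - D * dY) / S) / ((q$Z_i - q$Z_f) * S * D)
  expect_equal(delay_analytics(p, step_off)$avg_dt, manual, tolerance = 1e-12)
})

test_that("the degenerate step errors out of the delay normalisation", {
  p <- preset("ffl_or")
  expect_error(delay_analytics(p, step_input(1e-6, 1e-6)), "degenerate")
})

test_that("coherent gate responses are monotone while the incoherent loop pulses", {
  for (nm in c("ffl_xor", "ffl_and", "ffl_or")) {
    p <- preset(nm)
    for (k in list(c(1, 1), c(0.1, 5), c(5, 0.1))) {
      p$KXZ <- k[1]; p$KYZ <- k[2]
      cf <- inducible:::ffl_closed_form(p, step_on, seq(0, 30, length.out = 500))
      pm <- pulse_metrics(data.frame(t = cf$t, Z = cf$Z), cf$Z_f, cf$Z_i)
      expect_false(pm$strong)
    }
  }
  p <- preset("iffl_pulse")
  p$KXZ <- 1; p$KYZ <- 0.1
  pm <- pulse_metrics(ffl_step_response(p, step_on))
  expect_true(pm$has_pulse)
  expect_true(pm$strong)
  expect_gt(pm$amplitude, 0)
  p$KYZ <- 2
  pm2 <- pulse_metrics(ffl_step_response(p, step_on))
  expect_false(pm2$strong)
  # and the non-pulsing cell is still accelerated
  expect_gt(delay_analytics(p, step_on)$avg_dt, 0)
})

test_that("gate sweeps show the sign-sensitive delay half-planes", {
  kg <- log_grid(1e-2, 1e2, 12)
  xor <- preset("ffl_xor"); and <- preset("ffl_and")
  sw <- list(
    xor_on = delay_sweep(xor, step_on, kg, kg),
    xor_off = delay_sweep(xor, step_off, kg, kg),
    and_on = delay_sweep(and, step_on, kg, kg),
    and_off = delay_sweep(and, step_off, kg, kg))
  lower <- kg < 1; upper <- kg > 1
  # XOR: strong Y binding (small KYZ) delays the OFF step, barely the ON step
  expect_gt(max(abs(sw$xor_off$avg_dt[, lower])), 1)
  expect_gt(median(abs(sw$xor_off$avg_dt[, lower])),
            10 * median(abs(sw$xor_on$avg_dt[, lower])))
  # AND: weak Y binding (large KYZ) delays the ON step, barely the OFF step
  expect_gt(max(abs(sw$and_on$avg_dt[, upper])), 0.5)
  expect_gt(median(abs(sw$and_on$avg_dt[, upper])),
            10 * median(abs(sw$and_off$avg_dt[, upper])))
  # ON/OFF magnitudes differ: the delay is not conserved under endpoint swap
  expect_gt(abs(sw$xor_off$max_abs - sw$xor_on$max_abs), 0.1)
  # OR gate near matched affinities produces only minimal delays
  or <- preset("ffl_or")
  expect_lt(abs(delay_analytics(or, step_on)$avg_dt), 0.6)
  expect_lt(abs(delay_analytics(or, step_off)$avg_dt), 0.6)
})

test_that("ramp responses interpolate between step-like and quasi-stationary", {
  p <- preset("ffl_xor")
  # near-instantaneous ramp reproduces the step response
  r0 <- ramp_input(1e-4, 1e-7, 0, 1e-4)
  cr0 <- continuous_response(p, r0, n_steps = 800)
  q <- inducible:::ffl_quantities(p, step_on)
  expect_equal(cr0$ffl$y[nrow(cr0$ffl$y), 2], q$Z_f, tolerance = 1e-4)
  da <- delay_analytics(p, step_on)
  i5 <- which.min(abs(cr0$ffl$t - 5))
  zstep <- q$Z_i * exp(-5) + q$Z_f * (1 - exp(-5)) + da$theta(5)
  expect_equal(cr0$ffl$y[i5, 2], zstep, tolerance = 1e-3)
  # input timescales: ramp durations 1 and 22 give fast and slow switching
  expect_equal(continuous_response(p, ramp_input(1e-4, 1e-7, 0, 1))$t_c,
               0.235, tolerance = 0.01)
  expect_equal(continuous_response(p, ramp_input(1e-4, 1e-7, 0, 22))$t_c,
               5.18, tolerance = 0.01)
  # slow ramps track the instantaneous steady state ever more closely
  sup_dist <- vapply(c(2, 8, 32), function(dur) {
    r <- ramp_input(1e-4, 1e-7, 0, dur)
    cr <- continuous_response(p, r, n_steps = 600)
    zss <- vapply(cr$ffl$t, function(t) {
      qq <- inducible:::ffl_quantities(p, step_input(r$cX(t), r$cX(t)))
      qq$Z_f
    }, 0)
    max(abs(cr$ffl$y[, 2] - zss))
  }, 0)
  expect_true(all(diff(sup_dist) < 0))
  # undefined switching timescale warns but still returns the trajectory
  expect_warning(cr <- continuous_response(p, ramp_input(1e-5, 8e-6, 0, 2)),
                 "does not traverse")
  expect_true(is.na(cr$t_c))
  expect_s3_class(cr$ffl, "trajectory")
})
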