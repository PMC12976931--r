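#' Step protocol for the feed-forward-loop input effector
#'
#' At dimensionless time `t_step` the effector concentration controlling the
#' input X jumps from `c_initial` to `c_final`, while the effector of Y is
#' held at `cY`. The step direction (ON if the activity of X increases, OFF
#' if it decreases) is a property of the transcription factor, not of the
#' raw concentrations: for an effector that inactivates X, a concentration
#' decrease is an ON step.
#'
#' @param c_initial,c_final Effector concentrations for X before and after
#'   the step (molar, > 0). Unit-suffixed strings accepted.
#' @param cY Fixed effector concentration for Y (molar, default 1e-7).
#' @param t_step Time of the jump (default 0).
#' @return An object of class `step_input`.
#' @export
step_input <- function(c_initial, c_final, cY = 1e-7, t_step = 0) {
  c_initial <- parse_conc(c_initial); c_final <- parse_conc(c_final)
  cY <- parse_conc(cY)
  if (c_initial <= 0 || c_final <= 0 || cY <= 0)
    stop("step concentrations must be positive")
  structure(list(c_initial = c_initial, c_final = c_final, cY = cY,
                 t_step = t_step),
            class = "step_input")
}

#' @export
print.step_input <- function(x, ...) {
  cat(sprintf("step input: cX %.3g -> %.3g M at t = %g (cY = %.3g M)\n",
              x$c_initial, x$c_final, x$t_step, x$cY))
  invisible(x)
}

step_direction <- function(p, step) {
  if (p_active(p$tfX, step$c_final) > p_active(p$tfX, step$c_initial))
    "ON" else "OFF"
}

reverse_step <- function(step) {
  step_input(step$c_final, step$c_initial, cY = step$cY, t_step = step$t_step)
}

# All the step-response bookkeeping shared by the analytics and the ODE
# routes. The Z production is (A + B*Ycal)/(C + D*Ycal) in the Y activity,
# with B = 0 for the incoherent loop.
ffl_quantities <- function(p, step) {
  aXi <- p_active(p$tfX, step$c_initial)
  aXf <- p_active(p$tfX, step$c_final)
  aY <- p_active(p$tfY, step$cY)
  wi <- aXi * p$Xbar; wf <- aXf * p$Xbar
  Yi <- p$r0Y + p$r1Y * wi / (1 + wi)
  Yf <- p$r0Y + p$r1Y * wf / (1 + wf)
  Xci <- wi / p$KXZ; Xcf <- wf / p$KXZ
  Yci <- aY * Yi / p$KYZ; Ycf <- aY * Yf / p$KYZ
  A <- p$r0Z + p$r1Z * Xcf
  B <- if (inherits(p, "iffl_params")) 0 else p$r1Z + p$omega * p$r2Z * Xcf
  C <- 1 + Xcf
  D <- 1 + p$omega * Xcf
  list(aXf = aXf, aY = aY, wf = wf,
       Y_i = Yi, Y_f = Yf, Xc_i = Xci, Xc_f = Xcf, Yc_i = Yci, Yc_f = Ycf,
       A = A, B = B, C = C, D = D,
       S = C + D * Ycf,
       Phi = B * C - A * D,
       DeltaY = Ycf - Yci,
       Z_i = ffl_z_production(p, Xci, Yci),
       Z_f = ffl_z_production(p, Xcf, Ycf))
}

#' Analytic step-response delay of a feed-forward loop
#'
#' Solves the linear-in-Y / rational-in-Y step-response problem in closed
#' form. The output decomposes as
#' `Z(t) = Z_i e^{-t} + Z_f (1 - e^{-t}) + Theta(t)`: a rescaled
#' simple-regulation exponential plus an offset
#' \deqn{\Theta(t) = -\frac{\Phi \Delta\mathcal{Y}}{S^2} e^{-t}
#'   \log\frac{S e^{t} - \Delta\mathcal{Y}(1+\omega\mathcal{X}_f)}
#'            {S - \Delta\mathcal{Y}(1+\omega\mathcal{X}_f)},}
#' whose time integral gives the average delay
#' `avg_dt = Phi * log((S - D*DeltaY)/S) / ((Z_f - Z_i) * S * D)` with
#' `D = 1 + omega * Xc_f`. Negative `avg_dt` is a delay relative to simple
#' regulation, positive an acceleration; for coherent loops it is always
#' `<= 0`, for incoherent loops `Phi < 0` forces `avg_dt >= 0`.
#'
#' `Phi` encodes the rates and cooperativity
#' (`omega Xc_f^2 (r2Z - r1Z) + omega Xc_f (r2Z - r0Z) + (r1Z - r0Z)` for the
#' coherent loop, `-(r0Z + r1Z Xc_f)(1 + omega Xc_f)` for the incoherent
#' loop), `S` is the partition sum of the Z promoter at the final state and
#' `DeltaY` the change in effective Y activity.
#'
#' @param p [cffl_params()] or [iffl_params()].
#' @param step A [step_input()].
#' @param check If TRUE, validates `Theta` against the ODE-derived offset
#'   (sup-norm 1e-6) and `avg_dt` against adaptive quadrature of the Theta
#'   integral (relative 1e-6), stopping on disagreement.
#' @return An object of class `delay_analytics`: list with `DeltaY`, `Phi`,
#'   `S`, `avg_dt`, `Z_i`, `Z_f`, `Y_i`, `Y_f`, `direction`, and the offset
#'   function `theta(t)`.
#' @export
delay_analytics <- function(p, step, check = FALSE) {
  stopifnot(inherits(p, "ffl_params"), inherits(step, "step_input"))
  q <- ffl_quantities(p, step)
  if (abs(q$Z_f - q$Z_i) < 1e-12)
    stop("degenerate step: Z_f equals Z_i, the normalised delay is undefined")
  Phi <- q$Phi; S <- q$S; D <- q$D; dY <- q$DeltaY
  theta <- function(t) {
    # stable form of log(S e^t - D dY) = t + log(S - D dY e^{-t})
    -(Phi * dY / S^2) * exp(-t) *
      (t + log(S - D * dY * exp(-t)) - log(S - D * dY))
  }
  avg_dt <- Phi * log((S - D * dY) / S) / ((q$Z_f - q$Z_i) * S * D)
  out <- structure(
    list(DeltaY = dY, Phi = Phi, S = S, avg_dt = avg_dt,
         Z_i = q$Z_i, Z_f = q$Z_f, Y_i = q$Y_i, Y_f = q$Y_f,
         direction = step_direction(p, step), theta = theta),
    class = "delay_analytics")
  if (check) {
    tr <- ffl_step_response(p, step, t_max = 30, n_steps = 3000)
    zs <- q$Z_i * exp(-tr$t) + q$Z_f * (1 - exp(-tr$t))
    sup <- max(abs(tr$y[, 2] - zs - theta(tr$t)))
    if (sup > 1e-6)
      stop(sprintf("Theta self-check failed: sup-norm %.3g > 1e-6", sup))
    quad <- stats::integrate(theta, 0, Inf, rel.tol = 1e-10)$value /
      (q$Z_f - q$Z_i)
    if (abs(quad - avg_dt) > 1e-6 * max(1e-12, abs(avg_dt)))
      stop(sprintf("avg_dt self-check failed: closed form %.10g vs quadrature %.10g",
                   avg_dt, quad))
  }
  out
}

#' @export
print.delay_analytics <- function(x, ...) {
  cat(sprintf("%s-step response: Z %.4g -> %.4g, avg_dt = %.4g (%s)\n",
              x$direction, x$Z_i, x$Z_f, x$avg_dt,
              if (x$avg_dt < 0) "delay" else "acceleration"))
  cat(sprintf("  DeltaY = %.4g, Phi = %.4g, S = %.4g\n", x$DeltaY, x$Phi, x$S))
  invisible(x)
}

# closed-form step response on a time grid (Y and Z); valid because the Y
# equation is linear at fixed effector
ffl_closed_form <- function(p, step, t) {
  q <- ffl_quantities(p, step)
  da <- delay_analytics(p, step)
  list(t = t,
       Y = q$Y_f - (q$Y_f - q$Y_i) * exp(-t),
       Z = q$Z_i * exp(-t) + q$Z_f * (1 - exp(-t)) + da$theta(t),
       Z_i = q$Z_i, Z_f = q$Z_f)
}

#' Numeric step response of a feed-forward loop
#'
#' Integrates the (Y, Z) system from its pre-step steady state under the
#' post-step effector concentration.
#'
#' @param p [cffl_params()] or [iffl_params()].
#' @param step A [step_input()]; time is measured from the step.
#' @param t_max Integration horizon (default 30).
#' @param n_steps Output resolution (default 2000).
#' @return A `trajectory` (columns of `y`: Y, Z).
#' @export
ffl_step_response <- function(p, step, t_max = 30, n_steps = 2000) {
  stopifnot(inherits(p, "ffl_params"), inherits(step, "step_input"))
  q <- ffl_quantities(p, step)
  f <- circuit_flow(p, cX = step$c_final, cY = step$cY)
  integrate_circuit(f, c(q$Y_i, q$Z_i), t_max, n_steps = n_steps)
}

#' Matched simple-regulation step response (closed form)
#'
#' The reference circuit in which X does not regulate Y: Y is pinned at
#' `Ybar_fixed`, so after the step the output relaxes as a pure exponential
#' `Z_s(t) = Z_si e^{-t} + Z_sf (1 - e^{-t})` between the steady states of
#' the Z production at the initial and final X activity.
#'
#' @param p [cffl_params()] or [iffl_params()].
#' @param step A [step_input()].
#' @param Ybar_fixed Pinned dimensionless Y concentration (default 1).
#' @param t Evaluation times (default 400 points over 0 to 30).
#' @return List with `t`, `Z`, the endpoints `Z_si`, `Z_sf`, and the
#'   response function `Z_fun(t)`.
#' @export
simple_regulation_response <- function(p, step, Ybar_fixed = 1,
                                       t = seq(0, 30, length.out = 400)) {
  stopifnot(inherits(p, "ffl_params"), inherits(step, "step_input"))
  if (Ybar_fixed <= 0) stop("'Ybar_fixed' must be positive")
  aY <- p_active(p$tfY, step$cY)
  Yc <- aY * Ybar_fixed / p$KYZ
  Xci <- p_active(p$tfX, step$c_initial) * p$Xbar / p$KXZ
  Xcf <- p_active(p$tfX, step$c_final) * p$Xbar / p$KXZ
  Zsi <- ffl_z_production(p, Xci, Yc)
  Zsf <- ffl_z_production(p, Xcf, Yc)
  Z_fun <- function(t) Zsi * exp(-t) + Zsf * (1 - exp(-t))
  list(t = t, Z = Z_fun(t), Z_si = Zsi, Z_sf = Zsf, Z_fun = Z_fun)
}

#' Average-delay sweep over the Z-promoter dissociation constants
#'
#' Evaluates the closed-form average delay [delay_analytics()] on a grid of
#' `(KXZ, KYZ)` pairs, optionally adding pulse metrics from the closed-form
#' trajectory (no per-cell ODE integration). Cells with a degenerate step
#' (`Z_f = Z_i`) are NA.
#'
#' @param p Base [cffl_params()] or [iffl_params()] (its `KXZ`, `KYZ` are
#'   overridden cell by cell).
#' @param step A [step_input()].
#' @param KXZ_grid,KYZ_grid Dissociation-constant grids (default 50
#'   log-spaced points over 1e-2 to 1e2).
#' @param pulses If TRUE, also classify each cell's closed-form trajectory
#'   for pulses (see [pulse_metrics()]).
#' @param strong_threshold Relative overshoot defining a strong pulse
#'   (default 0.05).
#' @return An object of class `delay_sweep`: list with the grids, matrix
#'   `avg_dt` (rows index `KXZ`), `max_abs` and `max_at` (named vector), plus
#'   `has_pulse`/`strong_pulse`/`amplitude` matrices when `pulses = TRUE`.
#' @export
delay_sweep <- function(p, step, KXZ_grid = log_grid(1e-2, 1e2, 50),
                        KYZ_grid = log_grid(1e-2, 1e2, 50),
                        pulses = FALSE, strong_threshold = 0.05) {
  stopifnot(inherits(p, "ffl_params"), inherits(step, "step_input"))
  nx <- length(KXZ_grid); ny <- length(KYZ_grid)
  dt <- matrix(NA_real_, nx, ny)
  if (pulses) {
    hp <- sp <- matrix(FALSE, nx, ny)
    amp <- matrix(0, nx, ny)
    tgrid <- seq(0, 30, length.out = 600)
  }
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    pij <- p
    pij$KXZ <- KXZ_grid[i]; pij$KYZ <- KYZ_grid[j]
    da <- tryCatch(delay_analytics(pij, step), error = function(e) NULL)
    if (is.null(da)) next
    dt[i, j] <- da$avg_dt
    if (pulses) {
      cf <- ffl_closed_form(pij, step, tgrid)
      pm <- pulse_metrics(data.frame(t = cf$t, Z = cf$Z), Z_f = cf$Z_f,
                          Z_i = cf$Z_i, strong_threshold = strong_threshold)
      hp[i, j] <- pm$has_pulse; sp[i, j] <- pm$strong
      amp[i, j] <- pm$amplitude
    }
  }
  idx <- which(abs(dt) == max(abs(dt), na.rm = TRUE), arr.ind = TRUE)[1, ]
  out <- list(KXZ_grid = KXZ_grid, KYZ_grid = KYZ_grid, avg_dt = dt,
              direction = step_direction(p, step),
              max_abs = max(abs(dt), na.rm = TRUE),
              max_at = c(KXZ = KXZ_grid[idx[1]], KYZ = KYZ_grid[idx[2]]))
  if (pulses) {
    out$has_pulse <- hp; out$strong_pulse <- sp; out$amplitude <- amp
  }
  structure(out, class = "delay_sweep")
}

#' @export
print.delay_sweep <- function(x, ...) {
  cat(sprintf("%s-step delay sweep: %d x %d grid, max |avg_dt| = %.4g at KXZ = %.3g, KYZ = %.3g\n",
              x$direction, length(x$KXZ_grid), length(x$KYZ_grid),
              x$max_abs, x$max_at[["KXZ"]], x$max_at[["KYZ"]]))
  if (!is.null(x$strong_pulse))
    cat(sprintf("  strong pulses in %d cells\n", sum(x$strong_pulse)))
  invisible(x)
}

#' Pulse metrics of a step-response trajectory
#'
#' A pulse is a transient excursion of the output beyond its final steady
#' state: `Z(t) > Z_f` somewhere for an increasing response, or `Z(t) < Z_f`
#' for a decreasing one. The amplitude is the maximal deviation beyond
#' `Z_f`; a pulse is strong when the amplitude exceeds `strong_threshold`
#' times the response magnitude `|Z_f - Z_i|`.
#'
#' @param traj A `trajectory` (Z in the last column) or a data frame with
#'   columns `t` and `Z`.
#' @param Z_f,Z_i Final and initial steady states (default: trajectory
#'   endpoints).
#' @param strong_threshold Relative overshoot defining "strong" (default
#'   0.05).
#' @return An object of class `pulse_metrics`: list with `has_pulse`,
#'   `strong`, `amplitude` and `t_peak`.
#' @export
pulse_metrics <- function(traj, Z_f = NULL, Z_i = NULL,
                          strong_threshold = 0.05) {
  if (inherits(traj, "trajectory")) {
    if (!isTRUE(traj$converged) && !is.na(traj$converged))
      stop("pulse metrics require a converged trajectory")
    t <- traj$t; Z <- traj$y[, ncol(traj$y)]
  } else {
    t <- traj$t; Z <- traj$Z
  }
  if (is.null(Z_f)) Z_f <- Z[length(Z)]
  if (is.null(Z_i)) Z_i <- Z[1]
  increasing <- Z_f >= Z_i
  dev <- if (increasing) Z - Z_f else Z_f - Z
  amp <- max(dev)
  # ignore numerically tiny overshoot
  has <- amp > 1e-9 * max(1, abs(Z_f - Z_i))
  amp <- if (has) amp else 0
  structure(list(
    has_pulse = has,
    strong = has && amp / max(abs(Z_f - Z_i), 1e-300) > strong_threshold,
    amplitude = amp,
    t_peak = if (has) t[which.max(dev)] else NA_real_),
    class = "pulse_metrics")
}

#' @export
print.pulse_metrics <- function(x, ...) {
  if (x$has_pulse)
    cat(sprintf("pulse: amplitude %.4g at t = %.3g (%s)\n", x$amplitude,
                x$t_peak, if (x$strong) "strong" else "weak"))
  else cat("no pulse: monotone approach to steady state\n")
  invisible(x)
}

#' Log-linear ramp protocol for the input effector
#'
#' The effector concentration of X moves log-linearly from `c_from` to
#' `c_to` between `t_start` and `t_end` and is constant outside that window.
#'
#' @param c_from,c_to Endpoint concentrations (molar, > 0).
#' @param t_start,t_end Ramp window (dimensionless time).
#' @param cY Fixed effector concentration for Y (default 1e-7 M).
#' @return An object of class `ramp_input` with a `cX(t)` schedule function.
#' @export
ramp_input <- function(c_from, c_to, t_start, t_end, cY = 1e-7) {
  c_from <- parse_conc(c_from); c_to <- parse_conc(c_to); cY <- parse_conc(cY)
  if (c_from <= 0 || c_to <= 0 || cY <= 0) stop("concentrations must be positive")
  if (t_end <= t_start) stop("'t_end' must exceed 't_start'")
  l0 <- log10(c_from); l1 <- log10(c_to)
  cX <- function(t) {
    frac <- pmin(pmax((t - t_start) / (t_end - t_start), 0), 1)
    10^(l0 + frac * (l1 - l0))
  }
  structure(list(c_from = c_from, c_to = c_to, t_start = t_start,
                 t_end = t_end, cY = cY, cX = cX),
            class = "ramp_input")
}

#' Feed-forward-loop response to a continuously tuned effector
#'
#' Integrates the loop and the matched fixed-Y simple-regulation reference
#' under a log-linear effector ramp, and measures the input timescale `t_c`:
#' the time taken for the X activity `p_active(tfX, cX(t))` to traverse from
#' 0.2 to 0.8 (or the reverse).
#'
#' @param p [cffl_params()] or [iffl_params()].
#' @param ramp A [ramp_input()].
#' @param Ybar_fixed Pinned Y concentration of the simple-regulation
#'   reference (default 1).
#' @param t_max Integration horizon (default: ramp end + 15).
#' @param n_steps Output resolution (default 2000).
#' @return List with `ffl` and `simple` trajectories (class `trajectory`),
#'   `t_c` (NA, with a warning, when the activity never traverses
#'   (0.2, 0.8)), and the crossing times `t_cross` of activities 0.2/0.8.
#' @export
continuous_response <- function(p, ramp, Ybar_fixed = 1,
                                t_max = ramp$t_end + 15, n_steps = 2000) {
  stopifnot(inherits(p, "ffl_params"), inherits(ramp, "ramp_input"))
  act <- function(t) p_active(p$tfX, ramp$cX(t))
  # initial steady state at the pre-ramp effector level
  q0 <- ffl_quantities(p, step_input(ramp$c_from, ramp$c_from, cY = ramp$cY))
  f <- circuit_flow(p, cX = ramp$cX, cY = ramp$cY)
  tr <- integrate_circuit(f, c(q0$Y_i, q0$Z_i), t_max, n_steps = n_steps)
  # matched simple regulation: Y pinned, same ramp
  aY <- p_active(p$tfY, ramp$cY)
  Yc <- aY * Ybar_fixed / p$KYZ
  fs <- function(t, y) -y + ffl_z_production(p, act(t) * p$Xbar / p$KXZ, Yc)
  Zs0 <- ffl_z_production(p, act(0) * p$Xbar / p$KXZ, Yc)
  trs <- integrate_circuit(fs, Zs0, t_max, n_steps = n_steps)
  a0 <- act(ramp$t_start); a1 <- act(ramp$t_end)
  lo <- min(a0, a1); hi <- max(a0, a1)
  if (lo > 0.2 || hi < 0.8) {
    warning("t_c undefined: X activity does not traverse [0.2, 0.8]")
    t_c <- NA_real_; tcross <- c(NA_real_, NA_real_)
  } else {
    cross <- function(level) stats::uniroot(function(t) act(t) - level,
                                            c(ramp$t_start, ramp$t_end),
                                            tol = 1e-12)$root
    tcross <- c(cross(0.2), cross(0.8))
    t_c <- abs(diff(tcross))
  }
  list(ffl = tr, simple = trs, t_c = t_c,
       t_cross = c(act_0.2 = tcross[1], act_0.8 = tcross[2]))
}
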