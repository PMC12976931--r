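#' Time-derivative closure for a circuit at fixed effector levels
#'
#' Returns a function `f(t, y)` giving the motif's dimensionless rates, for
#' use with [integrate_circuit()]. Effector concentrations may be constants
#' or functions of (dimensionless) time, enabling step and ramp protocols.
#'
#' @param p A `circuit_params` object.
#' @param ... Effector concentrations for the motif: `c` (auto-activation or
#'   Hill), `c1`, `c2` (mutual repression) or `cX`, `cY` (feed-forward loop).
#'   Each may be a scalar (molar) or a function of time returning molar.
#' @return A function `f(t, y)` returning the state derivative.
#' @export
circuit_flow <- function(p, ...) {
  args <- list(...)
  as_fun <- function(x) if (is.function(x)) x else function(t) x
  if (inherits(p, "auto_params")) {
    cf <- as_fun(args$c)
    function(t, y) auto_rhs(y, p, cf(t))
  } else if (inherits(p, "hill_auto_params")) {
    cf <- as_fun(args$c)
    function(t, y) hill_auto_rhs(y, p, cf(t))
  } else if (inherits(p, "mr_params")) {
    c1f <- as_fun(args$c1); c2f <- as_fun(args$c2)
    function(t, y) mr_rhs(y, p, c1f(t), c2f(t))
  } else if (inherits(p, "ffl_params")) {
    cXf <- as_fun(args$cX); cYf <- as_fun(args$cY)
    function(t, y) ffl_rhs(y, p, cXf(t), cYf(t))
  } else stop("unsupported parameter class: ", class(p)[1])
}

#' Integrate a circuit ODE
#'
#' Adaptive integration (lsoda, via \pkg{deSolve}) of `dy/dt = f(t, y)` with
#' tight default tolerances and optional steady-state detection.
#'
#' @param f Derivative function `f(t, y)` (e.g. from [circuit_flow()]).
#' @param y0 Initial state (non-negative numeric vector).
#' @param t_end Final dimensionless time (> 0).
#' @param n_steps Number of output points (default 1000).
#' @param rtol,atol Relative/absolute tolerances (defaults 1e-8, 1e-12).
#' @param steady_tol If non-NULL, the trajectory is marked converged when the
#'   final-state residual `max |f|` falls below this value (default 1e-9;
#'   set NULL to skip the check).
#' @param times Explicit output times overriding `t_end`/`n_steps`.
#' @return An object of class `trajectory`: list with `t` (times), `y`
#'   (matrix, one column per state variable), `converged` (logical) and
#'   `residual` (max |f| at the final state).
#' @export
integrate_circuit <- function(f, y0, t_end, n_steps = 1000,
                              rtol = 1e-8, atol = 1e-12,
                              steady_tol = 1e-9, times = NULL) {
  check_nonneg(y0, "y0")
  if (is.null(times)) {
    if (t_end <= 0) stop("'t_end' must be positive")
    times <- seq(0, t_end, length.out = n_steps)
  }
  drv <- function(t, y, parms) list(f(t, pmax(y, 0)))
  out <- deSolve::ode(y = y0, times = times, func = drv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (any(!is.finite(out)))
    stop("integration failure: non-finite state encountered")
  y <- unname(as.matrix(out[, -1, drop = FALSE]))
  y[y < 0 & y > -atol * 10] <- 0
  yf <- y[nrow(y), ]
  residual <- max(abs(f(times[length(times)], yf)))
  structure(list(t = unname(out[, 1]), y = y,
                 converged = if (is.null(steady_tol)) NA else residual < steady_tol,
                 residual = residual),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d states over t in [%g, %g] (%d points)\n",
              ncol(x$y), min(x$t), max(x$t), length(x$t)))
  cat(sprintf("  final state: (%s), residual %.3g, converged: %s\n",
              paste(signif(x$y[nrow(x$y), ], 5), collapse = ", "),
              x$residual, x$converged))
  invisible(x)
}

#' Linearised relaxation timescale at a fixed point (auto-activation)
#'
#' Near a fixed point `A*` the dynamics reduce to exponential relaxation
#' with dimensionless timescale `1/|f'(A*)|`, where `f'` is the analytic
#' derivative of the right-hand side.
#'
#' @param p [auto_params()].
#' @param c Effector concentration, molar.
#' @param A_star A fixed point of [auto_rhs()].
#' @return List with `tau = 1/|f'|` and `f_prime` (sign gives stability).
#' @export
linear_timescale <- function(p, c, A_star) {
  stopifnot(inherits(p, "auto_params"))
  a <- p_active(p$tf, c)
  fpr <- -1 + auto_production_prime(A_star, p, a)
  if (abs(fpr) < 1e-12)
    stop("marginal point: |f'| < 1e-12, linear timescale undefined")
  list(tau = 1 / abs(fpr), f_prime = fpr)
}

#' Relaxation time of the auto-activation circuit
#'
#' Integrates the circuit from `A0` and estimates the timescale of the
#' approach to its steady state by one of two estimators:
#' \describe{
#'   \item{`fit_exponential`}{least-squares fit of
#'     `A(t) = A_inf + (A0 - A_inf) exp(-t/tau)` (free asymptote) over the
#'     window in which the deviation from steady state exceeds 1% of its
#'     initial value, i.e. an exponential fit to the trajectory itself.}
#'   \item{`threshold_95`}{first time at which the deviation from steady
#'     state falls to 5% of its initial value, divided by log(20) so that a
#'     pure exponential of rate 1 yields tau = 1.}
#' }
#'
#' @param p [auto_params()].
#' @param c Effector concentration, molar.
#' @param A0 Initial dimensionless activator concentration (>= 0, not a
#'   fixed point).
#' @param method `"fit_exponential"` (default) or `"threshold_95"`.
#' @param t_max Integration horizon (default 100).
#' @return An object of class `relaxation_result`: list with `tau`, `method`,
#'   `target_state` (the attractor reached) and `diagnostics`.
#' @export
relaxation_time_auto <- function(p, c, A0,
                                 method = c("fit_exponential", "threshold_95"),
                                 t_max = 100) {
  stopifnot(inherits(p, "auto_params"))
  method <- match.arg(method)
  f <- circuit_flow(p, c = c)
  tr <- integrate_circuit(f, A0, t_max, n_steps = 8000)
  if (!isTRUE(tr$converged))
    stop("trajectory did not converge: A0 may be at or too near the ",
         "unstable fixed point")
  A <- tr$y[, 1]
  Ass <- A[length(A)]
  dev <- abs(A - Ass)
  d0 <- dev[1]
  if (d0 < 1e-12)
    return(structure(list(tau = 0, method = method, target_state = Ass,
                          diagnostics = list(note = "started at steady state")),
                     class = "relaxation_result"))
  if (method == "threshold_95") {
    idx <- which(dev <= 0.05 * d0)[1]
    tau <- tr$t[idx] / log(20)
    diag <- list(crossing_time = tr$t[idx])
  } else {
    w <- which(dev > 0.01 * d0)
    tt <- tr$t[w]; AA <- A[w]
    # trajectories far from exponential (near the unstable point) make the
    # fit ill-conditioned; keep the best parameters found
    fit <- suppressWarnings(
      stats::nls(AA ~ Ainf + (A0 - Ainf) * exp(-tt / tau),
                 start = list(Ainf = Ass, tau = 1),
                 control = stats::nls.control(maxiter = 500, warnOnly = TRUE)))
    tau <- coef(fit)[["tau"]]
    diag <- list(fit_asymptote = coef(fit)[["Ainf"]],
                 fit_converged = fit$convInfo$isConv,
                 rms_residual = sqrt(mean(stats::resid(fit)^2)))
  }
  structure(list(tau = tau, method = method, target_state = Ass,
                 diagnostics = diag),
            class = "relaxation_result")
}

#' @export
print.relaxation_result <- function(x, ...) {
  cat(sprintf("relaxation time: tau = %.4g (%s), attractor at %s\n",
              x$tau, x$method,
              paste(signif(x$target_state, 5), collapse = ", ")))
  invisible(x)
}

#' Relaxation time of the toggle switch
#'
#' Integrates the mutual-repression system from `R0` and reports
#' `tau = max(tau1, tau2)`, where `tau_i` is the last time component `i`
#' lies outside 5% of its steady-state value (the 95% convergence time).
#'
#' @param p [mr_params()].
#' @param c1,c2 Inducer concentrations, molar.
#' @param R0 Initial state `c(R1, R2)`.
#' @param t_max Integration horizon (default 200).
#' @return A `relaxation_result`; if the trajectory has not converged by
#'   `t_max` (an initial condition on the separatrix), `tau` is NA and the
#'   diagnostics carry an `on_separatrix` flag instead of an error.
#' @export
relaxation_time_mr <- function(p, c1, c2, R0, t_max = 200) {
  stopifnot(inherits(p, "mr_params"))
  f <- circuit_flow(p, c1 = c1, c2 = c2)
  tr <- integrate_circuit(f, R0, t_max, n_steps = 4000)
  Rss <- tr$y[nrow(tr$y), ]
  if (!isTRUE(tr$converged))
    return(structure(list(tau = NA_real_, method = "threshold_95",
                          target_state = Rss,
                          diagnostics = list(on_separatrix = TRUE,
                                             residual = tr$residual)),
                     class = "relaxation_result"))
  taus <- vapply(1:2, function(i) {
    tol <- 0.05 * abs(Rss[i])
    outside <- abs(tr$y[, i] - Rss[i]) > tol
    if (!any(outside)) 0 else tr$t[max(which(outside))]
  }, 0)
  structure(list(tau = max(taus), method = "threshold_95",
                 target_state = Rss,
                 diagnostics = list(tau1 = taus[1], tau2 = taus[2])),
            class = "relaxation_result")
}

#' Separatrix of a bistable toggle switch
#'
#' Constructs the boundary between the two basins of attraction as the
#' stable manifold of the saddle point: the time-reversed flow is integrated
#' from small displacements along the saddle's stable eigenvector, in both
#' directions, and the two branches are joined into an ordered polyline.
#'
#' @param p [mr_params()].
#' @param c1,c2 Inducer concentrations (molar) at which the system is
#'   bistable.
#' @param t_back Backward-integration horizon (default 12).
#' @param delta Initial displacement along the eigenvector (default 1e-6).
#' @return Data frame (`R1`, `R2`) tracing the separatrix, ordered along the
#'   curve with the saddle in the middle.
#' @export
mr_separatrix <- function(p, c1, c2, t_back = 12, delta = 1e-6) {
  stopifnot(inherits(p, "mr_params"))
  fps <- mr_fixed_points(p, c1, c2)
  sad <- fps[fps$stability == "saddle", , drop = FALSE]
  if (sum(fps$stability == "stable") < 2L || nrow(sad) == 0L)
    stop("no separatrix: the system is not bistable at (c1, c2)")
  sad <- unlist(sad[1, c("R1", "R2")])
  a1 <- p_active(p$tf1, c1); a2 <- p_active(p$tf2, c2)
  J <- mr_jacobian(sad, p, a1, a2)
  eg <- eigen(J)
  stable_dir <- Re(eg$vectors[, which.min(Re(eg$values))])
  stable_dir <- stable_dir / sqrt(sum(stable_dir^2))
  frev <- function(t, y) -mr_rhs(pmax(y, 0), p, c1, c2)
  branch <- function(sgn) {
    y0 <- pmax(sad + sgn * delta * stable_dir, 0)
    tr <- integrate_circuit(frev, y0, t_back, n_steps = 600,
                            steady_tol = NULL, atol = 1e-12)
    tr$y
  }
  up <- branch(+1)
  dn <- branch(-1)
  # keep the physically relevant window (production caps the attractors at
  # rbar; the reversed flow diverges beyond it)
  lim <- 3 * p$rbar
  clip <- function(m) m[m[, 1] <= lim & m[, 2] <= lim, , drop = FALSE]
  up <- clip(up); dn <- clip(dn)
  out <- rbind(dn[rev(seq_len(nrow(dn))), , drop = FALSE], matrix(sad, 1), up)
  data.frame(R1 = out[, 1], R2 = out[, 2])
}

#' Basins of attraction of a bistable toggle switch
#'
#' Integrates the system from every initial condition on a grid and labels
#' each by the stable fixed point it converges to.
#'
#' @param p [mr_params()].
#' @param c1,c2 Inducer concentrations, molar (bistable regime).
#' @param R1_grid,R2_grid Initial-condition grids (dimensionless).
#' @param t_max Integration horizon (default 200).
#' @return List with `R1_grid`, `R2_grid`, `label` (integer matrix, rows
#'   index `R1_grid`; index into `attractors`, NA when unresolved), `tau`
#'   (matrix of 95% relaxation times) and `attractors` (data frame).
#' @export
mr_basins <- function(p, c1, c2, R1_grid, R2_grid, t_max = 200) {
  stopifnot(inherits(p, "mr_params"))
  fps <- mr_fixed_points(p, c1, c2)
  att <- fps[fps$stability == "stable", c("R1", "R2")]
  if (nrow(att) < 2L) stop("system is not bistable at (c1, c2)")
  lab <- matrix(NA_integer_, length(R1_grid), length(R2_grid))
  tau <- matrix(NA_real_, length(R1_grid), length(R2_grid))
  for (i in seq_along(R1_grid)) for (j in seq_along(R2_grid)) {
    res <- relaxation_time_mr(p, c1, c2, c(R1_grid[i], R2_grid[j]),
                              t_max = t_max)
    if (!is.na(res$tau)) {
      d <- (att$R1 - res$target_state[1])^2 + (att$R2 - res$target_state[2])^2
      lab[i, j] <- which.min(d)
      tau[i, j] <- res$tau
    }
  }
  list(R1_grid = R1_grid, R2_grid = R2_grid, label = lab, tau = tau,
       attractors = att)
}
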