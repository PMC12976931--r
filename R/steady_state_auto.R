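#' Fixed points of the auto-activation circuit
#'
#' Clearing denominators in `auto_rhs(A) = 0` gives a cubic in `A`; all real
#' non-negative roots are recovered (via the companion matrix underlying
#' [polyroot()]), polished by Newton iteration on the rational right-hand
#' side, deduplicated at relative tolerance 1e-6 and classified by the sign
#' of the analytic derivative `f'(A)`: stable (`f' < 0`), unstable
#' (`f' > 0`), or marginal (`|f'| < 1e-8`, a saddle-node point).
#'
#' @param p [auto_params()].
#' @param c Effector concentration, molar.
#' @return A data frame with columns `A` (the fixed point), `f_prime` (the
#'   linearisation) and `stability` (`"stable"`, `"unstable"` or
#'   `"marginal"`), ordered by `A`. Every row satisfies
#'   `|auto_rhs(A, p, c)| < 1e-9`.
#' @export
auto_fixed_points <- function(p, c) {
  stopifnot(inherits(p, "auto_params"))
  a <- p_active(p$tf, c)
  # -omega a^2 A^3 + (r2 omega a^2 - 2a) A^2 + (2 r1 a - 1) A + r0 = 0
  coefs <- c(p$r0, 2 * p$r1 * a - 1, p$r2 * p$omega * a^2 - 2 * a,
             -p$omega * a^2)
  while (length(coefs) > 1L && coefs[length(coefs)] == 0)
    coefs <- coefs[-length(coefs)]
  if (length(coefs) <= 1L) return(classify_auto_roots(numeric(0), p, a))
  z <- polyroot(coefs)
  roots <- Re(z[abs(Im(z)) <= 1e-8 * pmax(1, abs(z))])
  roots <- roots[roots > -1e-10]
  roots[roots < 0] <- 0
  # polish on f itself
  f <- function(A) -A + auto_production(A, p, a)
  fp <- function(A) -1 + auto_production_prime(A, p, a)
  roots <- vapply(roots, function(A) {
    for (i in 1:60) {
      step <- f(A) / fp(A)
      A2 <- A - step
      if (A2 < 0) A2 <- A / 2
      A <- A2
      if (abs(step) < 1e-14 * max(1, abs(A))) break
    }
    A
  }, 0)
  roots <- sort(roots)
  if (length(roots) > 1L) {
    keep <- c(TRUE, diff(roots) > 1e-6 * pmax(1, roots[-1]))
    roots <- roots[keep]
  }
  roots <- roots[abs(f(roots)) < 1e-9]
  classify_auto_roots(roots, p, a)
}

classify_auto_roots <- function(roots, p, a) {
  fpr <- if (length(roots)) -1 + auto_production_prime(roots, p, a) else numeric(0)
  stability <- ifelse(abs(fpr) < 1e-8, "marginal",
                      ifelse(fpr < 0, "stable", "unstable"))
  data.frame(A = roots, f_prime = fpr, stability = stability,
             stringsAsFactors = FALSE)
}

n_stable_auto <- function(p, c) {
  sum(auto_fixed_points(p, c)$stability == "stable")
}

#' Bifurcation diagram of the auto-activation circuit over effector
#'
#' Sweeps the effector concentration, collecting all fixed points and their
#' stability at each grid point, and extracts the interval(s) of
#' bistability (>= 2 stable fixed points). Interval endpoints are refined by
#' bisection in log-concentration to a relative precision of 1e-4.
#'
#' @param p [auto_params()].
#' @param c_grid Effector concentrations (molar, positive, sorted). Default:
#'   200 log-spaced points spanning 1e-9 to 1e-2 M.
#' @return An object of class `bifurcation_diagram`: a list with `points`
#'   (data frame `c`, `A`, `f_prime`, `stability`), `c_grid`, and
#'   `bistable` (data frame of refined interval endpoints `c_lo`, `c_hi`;
#'   zero rows if the circuit is monostable at every grid point).
#' @export
auto_bifurcation <- function(p, c_grid = log_grid(1e-9, 1e-2, 200)) {
  stopifnot(inherits(p, "auto_params"))
  if (length(c_grid) == 0) stop("'c_grid' is empty")
  if (any(c_grid <= 0) || is.unsorted(c_grid))
    stop("'c_grid' must be positive and sorted increasing")
  pts <- lapply(c_grid, function(c) {
    fp <- auto_fixed_points(p, c)
    if (nrow(fp)) cbind(c = c, fp) else NULL
  })
  pts <- do.call(rbind, pts)
  nst <- vapply(c_grid, function(c) n_stable_auto(p, c), 0L)
  bist <- refine_intervals(c_grid, nst >= 2L,
                           function(c) n_stable_auto(p, c) >= 2L)
  structure(list(points = pts, c_grid = c_grid, n_stable = nst,
                 bistable = bist),
            class = "bifurcation_diagram")
}

# refine TRUE/FALSE transitions of flag over grid by log-bisection
refine_intervals <- function(grid, flag, predicate, rel_tol = 1e-4) {
  runs <- rle(flag)
  if (!any(flag))
    return(data.frame(c_lo = numeric(0), c_hi = numeric(0)))
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- NULL
  bisect <- function(c_out, c_in) {
    # c_out fails predicate, c_in satisfies it; returns boundary
    for (i in 1:200) {
      if (abs(log10(c_out) - log10(c_in)) < rel_tol / log(10)) break
      mid <- sqrt(c_out * c_in)
      if (predicate(mid)) c_in <- mid else c_out <- mid
    }
    sqrt(c_out * c_in)
  }
  for (k in which(runs$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    lo <- if (i0 == 1L) grid[1] else bisect(grid[i0 - 1L], grid[i0])
    hi <- if (i1 == length(grid)) grid[length(grid)]
          else bisect(grid[i1 + 1L], grid[i1])
    out <- rbind(out, data.frame(c_lo = lo, c_hi = hi))
  }
  out
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat("bifurcation diagram:", length(x$c_grid), "effector concentrations in [",
      format(min(x$c_grid), digits = 3), ",",
      format(max(x$c_grid), digits = 3), "] M\n")
  if (nrow(x$bistable)) {
    for (i in seq_len(nrow(x$bistable)))
      cat(sprintf("  bistable for c in [%.4g, %.4g] M\n",
                  x$bistable$c_lo[i], x$bistable$c_hi[i]))
  } else cat("  monostable at every grid point\n")
  invisible(x)
}

#' Necessary conditions for auto-activation bistability
#'
#' Evaluates the three analytic inequalities that must all hold for the
#' circuit to be bistable at any effector concentration. They follow from
#' Descartes' rule of signs applied to the steady-state cubic: three
#' positive roots require the coefficient pattern (-, +, -, +), which is
#' achievable for some effector concentration only if
#' \enumerate{
#'   \item `omega * r2 / 2 > 1 + exp(-eps)` (the quadratic coefficient can
#'     turn positive at full activity),
#'   \item `2 * r1 < 1 + exp(-eps) * (K_A/K_I)^2` (the linear coefficient can
#'     turn negative at the leakiness floor),
#'   \item `omega * r2 > 4 * r1` (both can hold at the same concentration).
#' }
#' The combination `omega_eff = omega * r2 / 2`, an effective cooperativity,
#' must exceed 1 whenever condition 1 holds.
#'
#' @param p [auto_params()].
#' @return A list with logical elements `cond1`, `cond2`, `cond3`, their
#'   conjunction `all`, and the numeric `omega_eff`.
#' @export
necessary_conditions_auto <- function(p) {
  stopifnot(inherits(p, "auto_params"))
  e <- exp(-p$tf$eps)
  Kc <- p$tf$K_A / p$tf$K_I
  cond1 <- p$omega * p$r2 / 2 > 1 + e
  cond2 <- 2 * p$r1 < 1 + e * Kc^2
  cond3 <- p$omega * p$r2 > 4 * p$r1
  list(cond1 = cond1, cond2 = cond2, cond3 = cond3,
       all = cond1 && cond2 && cond3,
       omega_eff = p$omega * p$r2 / 2)
}

#' Hysteresis protocol for the auto-activation circuit
#'
#' Follows the occupied stable branch along a monotone effector-concentration
#' path: at each concentration the state relaxes to the stable fixed point
#' continuous with the current one, and jumps to the remaining branch when
#' the occupied branch terminates at a saddle-node. Sweeping up and down
#' yields different switching thresholds, equal to the upper and lower
#' endpoints of the bistable interval.
#'
#' @param p [auto_params()].
#' @param c_path Monotone sequence of effector concentrations (molar).
#' @param A_init Initial activator concentration (>= 0); the trace starts on
#'   the stable branch nearest to it.
#' @return An object of class `hysteresis_trace`: data frame (`c`, `A`) plus
#'   attribute `switches` (data frame `c`, `from`, `to`) marking branch jumps.
#' @export
hysteresis <- function(p, c_path, A_init) {
  stopifnot(inherits(p, "auto_params"))
  check_nonneg(A_init, "A_init")
  dc <- diff(c_path)
  if (length(c_path) < 2L || !(all(dc > 0) || all(dc < 0)))
    stop("'c_path' must be strictly monotone")
  A_cur <- A_init
  out <- numeric(length(c_path))
  switches <- NULL
  for (i in seq_along(c_path)) {
    fp <- auto_fixed_points(p, c_path[i])
    st <- fp[fp$stability == "stable", , drop = FALSE]
    if (!nrow(st)) stop("no stable fixed point at c = ", c_path[i])
    # the branch the state relaxes to: nearest stable point not separated
    # from A_cur by an unstable point
    un <- fp$A[fp$stability == "unstable"]
    reachable <- vapply(st$A, function(A) {
      !any(un > min(A, A_cur) & un < max(A, A_cur))
    }, TRUE)
    cand <- if (any(reachable)) st$A[reachable] else st$A
    A_new <- cand[which.min(abs(cand - A_cur))]
    if (i > 1L && abs(A_new - A_cur) > 0.5 * max(1, A_cur))
      switches <- rbind(switches,
                        data.frame(c = c_path[i], from = A_cur, to = A_new))
    A_cur <- A_new
    out[i] <- A_cur
  }
  structure(data.frame(c = c_path, A = out),
            switches = switches, class = c("hysteresis_trace", "data.frame"))
}

#' Effective Hill coefficient of the open-loop production function
#'
#' Maximum logarithmic sensitivity of the (basal-subtracted) production term
#' with respect to activator concentration at fixed effector:
#' `max_A d log(production(A) - r0) / d log A`, computed by central
#' differences on a log-spaced grid. For a two-site promoter the value lies
#' in (0, 2]; bistability requires it to exceed 1.
#'
#' @param p [auto_params()].
#' @param c Effector concentration, molar.
#' @param A_range Range of dimensionless activator concentrations scanned
#'   (default `c(1e-6, 1e4)`), with `n` grid points.
#' @param n Grid resolution (default 400).
#' @return The maximum log-log slope (dimensionless).
#' @export
effective_hill_coefficient <- function(p, c, A_range = c(1e-6, 1e4), n = 400) {
  stopifnot(inherits(p, "auto_params"))
  a <- p_active(p$tf, c)
  lA <- seq(log(A_range[1]), log(A_range[2]), length.out = n)
  g <- log(pmax(auto_production(exp(lA), p, a) - p$r0, .Machine$double.xmin))
  slope <- diff(g) / diff(lA)
  max(slope)
}

#' Hill-model fixed points (dimensional)
#'
#' @param p [hill_auto_params()].
#' @param c Effector concentration, molar.
#' @return Data frame as in [auto_fixed_points()] with column `A` in molar.
#' @export
hill_fixed_points <- function(p, c) {
  stopifnot(inherits(p, "hill_auto_params"))
  a <- p_active(p$tf, c)
  if (p$n != round(p$n))
    stop("polynomial fixed-point solver requires an integer Hill coefficient")
  n <- as.integer(p$n)
  q <- (a / p$Kd_eff)^n
  # -gamma A (1 + q A^n) + r0 (1 + q A^n) + r2 q A^n = 0
  coefs <- numeric(n + 2L)
  coefs[1] <- p$r0                        # A^0
  coefs[2] <- -p$gamma                    # A^1
  coefs[n + 1L] <- coefs[n + 1L] + (p$r0 + p$r2) * q   # A^n
  coefs[n + 2L] <- coefs[n + 2L] - p$gamma * q         # A^(n+1)
  z <- polyroot(coefs)
  roots <- Re(z[abs(Im(z)) <= 1e-8 * pmax(1, abs(z))])
  roots <- sort(unique(roots[roots > -1e-12]))
  roots[roots < 0] <- 0
  f <- function(A) hill_auto_rhs(A, p, c)
  h <- pmax(1e-8, 1e-7 * roots)
  fpr <- (vapply(roots + h, f, 0) - vapply(pmax(roots - h, 0), f, 0)) / (2 * h)
  keep <- abs(vapply(roots, f, 0)) < 1e-9 * max(1, p$gamma)
  roots <- roots[keep]; fpr <- fpr[keep]
  if (length(roots) > 1L) {
    dedup <- c(TRUE, diff(roots) > 1e-6 * pmax(1e-300, roots[-1]))
    roots <- roots[dedup]; fpr <- fpr[dedup]
  }
  data.frame(A = roots, f_prime = fpr,
             stability = ifelse(abs(fpr) < 1e-8 * p$gamma, "marginal",
                                ifelse(fpr < 0, "stable", "unstable")),
             stringsAsFactors = FALSE)
}

#' Compare Hill and thermodynamic bistability predictions
#'
#' Builds bifurcation verdicts for the dimensional thermodynamic model and
#' its Hill-function counterpart on a shared effector grid and reports where
#' the two disagree about bistability. The matched Hill model uses
#' `Kd_eff = Kd / sqrt(omega)`, the choice forced by the large-cooperativity
#' limit in which the singly-bound promoter state becomes negligible and
#' `(p_act A / Kd_eff)^2` must reproduce `omega (p_act A / Kd)^2`.
#'
#' @param r0,r1,r2 Dimensional production rates (concentration per time);
#'   `r1` is used by the thermodynamic model only.
#' @param gamma Degradation rate (per time).
#' @param Kd DNA dissociation constant (molar).
#' @param omega Cooperativity of the thermodynamic model.
#' @param tf [allosteric_tf()] shared by both models.
#' @param n Hill coefficient (default 2).
#' @param Kd_eff Effective dissociation constant of the Hill model
#'   (default `Kd / sqrt(omega)`).
#' @param c_grid Effector concentrations (molar; default 120 log-spaced
#'   points over 1e-9 to 1e-2 M).
#' @return Data frame with columns `c`, `thermo_bistable`, `hill_bistable`,
#'   `agree`; attribute `disagreement` holds the concentrations where the
#'   verdicts differ.
#' @export
compare_hill_thermo <- function(r0, r1, r2, gamma, Kd, omega, tf, n = 2,
                                Kd_eff = Kd / sqrt(omega),
                                c_grid = log_grid(1e-9, 1e-2, 120)) {
  Kd <- parse_conc(Kd)
  # dimensionless thermodynamic parameters: rates in units of gamma*Kd
  pt <- auto_params(r0 / (gamma * Kd), r1 / (gamma * Kd), r2 / (gamma * Kd),
                    omega, tf)
  ph <- hill_auto_params(n, r0, r2, Kd_eff, gamma, tf)
  tb <- vapply(c_grid, function(c) n_stable_auto(pt, c) >= 2L, TRUE)
  hb <- vapply(c_grid, function(c)
    sum(hill_fixed_points(ph, c)$stability == "stable") >= 2L, TRUE)
  out <- data.frame(c = c_grid, thermo_bistable = tb, hill_bistable = hb,
                    agree = tb == hb)
  attr(out, "disagreement") <- c_grid[tb != hb]
  out
}
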