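#' Fixed points of the mutual-repression toggle switch
#'
#' At steady state each repressor is an explicit function of the other (its
#' nullcline). Substituting the R1 nullcline into the R2 nullcline reduces
#' the problem to one dimension, which is solved by sign-change bracketing
#' on a dense grid over (0, rbar] followed by bisection; every root is
#' back-substituted, verified against the full right-hand side (residual
#' below 1e-9) and classified by the eigenvalues of the 2x2 Jacobian
#' (stable: both negative; saddle: opposite signs).
#'
#' @param p [mr_params()].
#' @param c1,c2 Inducer concentrations, molar.
#' @param n_grid Bracketing grid resolution (default 300).
#' @return Data frame with columns `R1`, `R2`, `eig1`, `eig2` (Jacobian
#'   eigenvalues, `eig1 <= eig2`) and `stability` (`"stable"`, `"saddle"`,
#'   `"unstable"` or `"marginal"`).
#' @export
mr_fixed_points <- function(p, c1, c2, n_grid = 300) {
  stopifnot(inherits(p, "mr_params"))
  a1 <- p_active(p$tf1, c1)
  a2 <- p_active(p$tf2, c2)
  g1 <- function(R2) mr_production(R2, p$rbar, p$omega2, a2)        # R1 = g1(R2)
  g2 <- function(R1) mr_production(R1, p$rbar, p$omega1, a1, p$Kratio)
  h <- function(R2) R2 - g2(g1(R2))
  grid <- c(0, log_grid(1e-8 * p$rbar, p$rbar * 1.0001, n_grid))
  hv <- vapply(grid, h, 0)
  roots2 <- numeric(0)
  for (i in seq_len(length(grid) - 1L)) {
    if (hv[i] == 0) roots2 <- c(roots2, grid[i])
    else if (sign(hv[i]) != sign(hv[i + 1L]))
      roots2 <- c(roots2, stats::uniroot(h, grid[i + 0:1], tol = 1e-14)$root)
  }
  roots2 <- sort(unique(roots2))
  if (length(roots2) > 1L)
    roots2 <- roots2[c(TRUE, diff(roots2) > 1e-9 * pmax(1, roots2[-1]))]
  if (!length(roots2))
    return(data.frame(R1 = numeric(0), R2 = numeric(0), eig1 = numeric(0),
                      eig2 = numeric(0), stability = character(0)))
  out <- lapply(roots2, function(R2) {
    R1 <- g1(R2)
    st <- c(R1, R2)
    # Newton polish on the full 2-D system
    for (k in 1:40) {
      r <- mr_rhs(st, p, c1, c2)
      J <- mr_jacobian(st, p, a1, a2)
      step <- tryCatch(solve(J, r), error = function(e) NULL)
      if (is.null(step)) break
      st <- pmax(st - step, 0)
      if (max(abs(step)) < 1e-14 * max(1, max(abs(st)))) break
    }
    res <- mr_rhs(st, p, c1, c2)
    if (max(abs(res)) > 1e-9) return(NULL)
    ev <- sort(Re(eigen(mr_jacobian(st, p, a1, a2), only.values = TRUE)$values))
    stability <-
      if (any(abs(ev) < 1e-8)) "marginal"
      else if (all(ev < 0)) "stable"
      else if (ev[1] < 0 && ev[2] > 0) "saddle"
      else "unstable"
    data.frame(R1 = st[1], R2 = st[2], eig1 = ev[1], eig2 = ev[2],
               stability = stability, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(R1 = numeric(0), R2 = numeric(0), eig1 = numeric(0),
                      eig2 = numeric(0), stability = character(0)))
  # dedup after polishing
  if (nrow(out) > 1L) {
    ord <- order(out$R2)
    out <- out[ord, ]
    d <- sqrt(diff(out$R1)^2 + diff(out$R2)^2)
    out <- out[c(TRUE, d > 1e-6 * max(1, p$rbar)), ]
  }
  rownames(out) <- NULL
  out
}

mr_jacobian <- function(state, p, a1, a2) {
  d1 <- mr_production_prime(state[2], p$rbar, p$omega2, a2)
  d2 <- mr_production_prime(state[1], p$rbar, p$omega1, a1, p$Kratio)
  matrix(c(-1, d2, d1, -1), 2, 2)  # [dR1'/dR1, dR1'/dR2; dR2'/dR1, dR2'/dR2]
}

mr_production_prime <- function(R_other, rbar, omega, a, K = 1) {
  x <- a * R_other / K
  -rbar * (2 + 2 * omega * x) * (a / K) / (1 + 2 * x + omega * x^2)^2
}

n_stable_mr <- function(p, c1, c2, n_grid = 250) {
  sum(mr_fixed_points(p, c1, c2, n_grid)$stability == "stable")
}

#' Two-dimensional bistability map of the toggle switch
#'
#' Counts stable fixed points on a grid of the two inducer concentrations
#' and flags the bistable region (>= 2 stable states).
#'
#' @param p [mr_params()].
#' @param c1_grid,c2_grid Inducer concentrations, molar (default: 40
#'   log-spaced points over 1e-7 to 1e-4 M each).
#' @return An object of class `bistability_map`: list with `c1_grid`,
#'   `c2_grid` and the logical matrix `bistable` (rows index `c1`, columns
#'   `c2`).
#' @export
mr_bistability_map <- function(p, c1_grid = log_grid(1e-7, 1e-4, 40),
                               c2_grid = log_grid(1e-7, 1e-4, 40)) {
  stopifnot(inherits(p, "mr_params"))
  if (any(c1_grid <= 0) || any(c2_grid <= 0)) stop("grids must be positive")
  m <- matrix(FALSE, length(c1_grid), length(c2_grid))
  for (i in seq_along(c1_grid))
    for (j in seq_along(c2_grid))
      m[i, j] <- n_stable_mr(p, c1_grid[i], c2_grid[j]) >= 2L
  structure(list(c1_grid = c1_grid, c2_grid = c2_grid, bistable = m),
            class = "bistability_map")
}

#' @export
print.bistability_map <- function(x, ...) {
  cat(sprintf("bistability map: %d x %d grid, %d bistable cells (%.1f%%)\n",
              length(x$c1_grid), length(x$c2_grid), sum(x$bistable),
              100 * mean(x$bistable)))
  cat("  geometry:", mr_geometry_class(x), "\n")
  invisible(x)
}

#' Classify the geometry of a 2-D bistable region
#'
#' Distinguishes the three bistable-region geometries seen in the toggle
#' switch's inducer plane, over the scanned concentration window:
#' `"BOTH_SMALL"` (bistability extends to the low-concentration corner, with
#' only upper bounds on both inducers), `"C1_WINDOW"` (at permissively small
#' `c2`, bistability requires `c1` inside a finite window detached from the
#' grid minimum), `"C2_WINDOW"` (the mirrored case) and `"NONE"`.
#'
#' @param map A [mr_bistability_map()] result.
#' @return One of `"C1_WINDOW"`, `"C2_WINDOW"`, `"BOTH_SMALL"`, `"NONE"`.
#' @export
mr_geometry_class <- function(map) {
  stopifnot(inherits(map, "bistability_map"))
  m <- map$bistable
  if (!any(m)) return("NONE")
  if (m[1, 1]) return("BOTH_SMALL")
  # smallest c2 with any bistability: is the smallest c1 excluded there?
  j <- min(which(apply(m, 2, any)))
  if (!m[1, j]) return("C1_WINDOW")
  "C2_WINDOW"
}

#' Necessary condition for toggle-switch bistability
#'
#' Lower bound on the shared production rate below which the symmetric
#' (`Kratio = 1`) toggle cannot be bistable at any inducer pair:
#' `rbar > 1 / ((pact_max - pact_min) + min(omega1, omega2) * pact_max / 2)`.
#'
#' @param p [mr_params()].
#' @return Logical: does `p` satisfy the bound?
#' @export
mr_necessary_condition <- function(p) {
  stopifnot(inherits(p, "mr_params"))
  lim1 <- activity_limits(p$tf1)
  dp <- lim1[["pact_max"]] - lim1[["pact_min"]]
  p$rbar > 1 / (dp + min(p$omega1, p$omega2) * lim1[["pact_max"]] / 2)
}

#' Bistability feasibility over the cooperativity plane
#'
#' For each pair `(omega1, omega2)` (at `Kratio = 1`), scans the inducer
#' plane for any bistable point and records feasibility. The returned
#' boundary is, per `omega1` row, the smallest feasible `omega2`.
#'
#' @param rbar Shared production rate.
#' @param omega1_grid,omega2_grid Cooperativity grids.
#' @param tf [allosteric_tf()] shared by both repressors.
#' @param c_grid Inducer scan grid (molar, both axes; default 12 log-spaced
#'   points over 1e-7 to 1e-4 M).
#' @return List with `omega1_grid`, `omega2_grid`, logical `feasible`
#'   matrix (rows index `omega1`) and `boundary` (data frame `omega1`,
#'   `omega2_min`, NA when no `omega2` in the grid is feasible).
#' @export
mr_feasibility_boundary <- function(rbar, omega1_grid, omega2_grid, tf,
                                    c_grid = log_grid(1e-7, 1e-4, 12)) {
  feas <- matrix(FALSE, length(omega1_grid), length(omega2_grid))
  for (i in seq_along(omega1_grid)) for (j in seq_along(omega2_grid)) {
    p <- mr_params(rbar, omega1_grid[i], omega2_grid[j], 1, tf)
    found <- FALSE
    for (c1 in c_grid) {
      for (c2 in c_grid)
        if (n_stable_mr(p, c1, c2, n_grid = 200) >= 2L) { found <- TRUE; break }
      if (found) break
    }
    feas[i, j] <- found
  }
  boundary <- data.frame(
    omega1 = omega1_grid,
    omega2_min = apply(feas, 1, function(r)
      if (any(r)) omega2_grid[min(which(r))] else NA_real_))
  list(omega1_grid = omega1_grid, omega2_grid = omega2_grid,
       feasible = feas, boundary = boundary)
}

#' Bistable-to-monostable transition along the inducer diagonal
#'
#' Sweeps `c1 = c2 = c` and refines, by bisection in log-concentration, the
#' largest concentration at which the toggle is still bistable (for a
#' symmetric toggle this is the pitchfork bifurcation point where the two
#' asymmetric stable states merge).
#'
#' @param p [mr_params()].
#' @param c_lo,c_hi Search window, molar (default 1e-7 to 1e-4).
#' @param n Coarse-scan resolution (default 30).
#' @param rel_tol Relative precision of the refined endpoint (default 1e-4).
#' @return The transition concentration in molar (NA if no bistable point is
#'   found in the window).
#' @export
mr_diagonal_transition <- function(p, c_lo = 1e-7, c_hi = 1e-4, n = 30,
                                   rel_tol = 1e-4) {
  stopifnot(inherits(p, "mr_params"))
  cg <- log_grid(c_lo, c_hi, n)
  bi <- vapply(cg, function(c) n_stable_mr(p, c, c) >= 2L, TRUE)
  if (!any(bi)) return(NA_real_)
  i1 <- max(which(bi))
  if (i1 == length(cg)) return(cg[i1])
  lo <- cg[i1]; hi <- cg[i1 + 1L]
  while (abs(log10(hi) - log10(lo)) > rel_tol / log(10)) {
    mid <- sqrt(lo * hi)
    if (n_stable_mr(p, mid, mid) >= 2L) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}
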