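#' Auto-activation circuit parameters
#'
#' Dimensionless parameters for the inducible auto-activation motif. Time is
#' measured in units of the protein lifetime 1/gamma and concentration in
#' units of the DNA dissociation constant Kd, so the rates `r0 <= r1 <= r2`
#' are in units of gamma*Kd. The promoter carries two activator sites;
#' `omega` is the Boltzmann weight of the interaction between two bound
#' activators.
#'
#' The ordering `r0 <= r1 <= r2` makes the production term non-decreasing in
#' activator concentration (a genuine activator); it is enforced unless
#' `enforce_monotone = FALSE`.
#'
#' @param r0,r1,r2 Production rates with 0, 1, 2 activators bound
#'   (dimensionless, >= 0).
#' @param omega Cooperativity weight between two bound activators (>= 0).
#' @param tf The activator's [allosteric_tf()].
#' @param enforce_monotone Reject rate orderings that violate
#'   `r0 <= r1 <= r2` (default TRUE).
#' @return An object of class `c("auto_params", "circuit_params")`.
#' @export
auto_params <- function(r0, r1, r2, omega, tf, enforce_monotone = TRUE) {
  stopifnot(is_allosteric_tf(tf))
  check_nonneg(c(r0, r1, r2, omega), "rates and omega")
  if (enforce_monotone && !(r0 <= r1 && r1 <= r2))
    stop("auto-activation requires r0 <= r1 <= r2 ",
         "(set enforce_monotone = FALSE to override)")
  structure(list(r0 = r0, r1 = r1, r2 = r2, omega = omega, tf = tf),
            class = c("auto_params", "circuit_params"))
}

#' Hill-function auto-activation parameters (dimensional)
#'
#' The phenomenological alternative to the thermodynamic production term:
#' `dA/dt = -gamma*A + r0 + r2 * u^n / (1 + u^n)` with
#' `u = p_active(tf, c) * A / Kd_eff`. Kept dimensional (molar, per-minute)
#' so that it can be compared with the thermodynamic model on a common axis.
#'
#' @param n Hill coefficient (>= 1).
#' @param r0,r2 Basal and saturating production rates (molar per unit time).
#' @param Kd_eff Effective dissociation constant (molar).
#' @param gamma Degradation rate (per unit time).
#' @param tf The activator's [allosteric_tf()].
#' @return An object of class `c("hill_auto_params", "circuit_params")`.
#' @export
hill_auto_params <- function(n, r0, r2, Kd_eff, gamma, tf) {
  stopifnot(is_allosteric_tf(tf))
  Kd_eff <- parse_conc(Kd_eff)
  check_nonneg(c(r0, r2), "rates")
  if (n < 1) stop("Hill coefficient 'n' must be >= 1")
  if (Kd_eff <= 0 || gamma <= 0) stop("'Kd_eff' and 'gamma' must be positive")
  structure(list(n = n, r0 = r0, r2 = r2, Kd_eff = Kd_eff, gamma = gamma,
                 tf = tf),
            class = c("hill_auto_params", "circuit_params"))
}

#' Mutual repression (toggle switch) parameters
#'
#' Dimensionless parameters for two genes repressing each other, each
#' repressor inactivated by its own inducer. Concentrations are in units of
#' K2 (the dissociation constant of repressor 2 for promoter 1), time in
#' units of 1/gamma, and `rbar` is the shared unrepressed production rate in
#' units of gamma*K2. `Kratio = K1/K2` sets the relative DNA-binding
#' affinity of the two repressors; `omega1`, `omega2` are the pairwise
#' binding cooperativities of repressor 1 and repressor 2.
#'
#' @param rbar Unrepressed production rate (dimensionless, > 0).
#' @param omega1,omega2 Cooperativity weights (>= 0).
#' @param Kratio Dissociation-constant ratio K1/K2 (> 0), default 1.
#' @param tf1,tf2 [allosteric_tf()] objects for the inducers of repressor 1
#'   and 2; `tf2` defaults to `tf1`.
#' @return An object of class `c("mr_params", "circuit_params")`.
#' @export
mr_params <- function(rbar, omega1, omega2, Kratio = 1, tf1, tf2 = tf1) {
  stopifnot(is_allosteric_tf(tf1), is_allosteric_tf(tf2))
  check_nonneg(c(omega1, omega2), "omega")
  if (rbar <= 0) stop("'rbar' must be positive")
  if (Kratio <= 0) stop("'Kratio' must be positive")
  structure(list(rbar = rbar, omega1 = omega1, omega2 = omega2,
                 Kratio = Kratio, tf1 = tf1, tf2 = tf2),
            class = c("mr_params", "circuit_params"))
}

#' Feed-forward loop parameters
#'
#' Dimensionless parameters for the three-gene feed-forward loop: input X
#' (held at fixed concentration `Xbar`, in units of K_XY) regulates Y and,
#' together with Y, the output Z. Dissociation constants `KXZ = K_XZ/K_XY`
#' and `KYZ = K_YZ/K_XY` set the affinities at the Z promoter; `omega` is
#' the X-Y binding cooperativity there. In the coherent (type-I) loop both
#' arms activate Z; in the incoherent loop Y represses Z (no doubly-bound
#' production, so there is no `r2Z`).
#'
#' @param Xbar Fixed dimensionless input concentration (> 0), default 1.
#' @param r0Y,r1Y Production rates of Y with 0 or 1 X bound (>= 0).
#' @param r0Z,r1Z,r2Z Production rates of Z with 0, 1 or 2 regulators bound
#'   (>= 0); `r2Z` only for the coherent loop.
#' @param omega X-Y cooperativity on the Z promoter (>= 0).
#' @param KXZ,KYZ Dimensionless dissociation constants (> 0).
#' @param tfX,tfY [allosteric_tf()] objects for the effectors of X and Y;
#'   `tfY` defaults to `tfX`.
#' @return An object of class `c("cffl_params", "ffl_params",
#'   "circuit_params")` or `c("iffl_params", "ffl_params", "circuit_params")`.
#' @export
cffl_params <- function(r0Y, r1Y, r0Z, r1Z, r2Z, omega, KXZ = 1, KYZ = 1,
                        Xbar = 1, tfX, tfY = tfX) {
  stopifnot(is_allosteric_tf(tfX), is_allosteric_tf(tfY))
  check_nonneg(c(r0Y, r1Y, r0Z, r1Z, r2Z, omega), "rates and omega")
  if (KXZ <= 0 || KYZ <= 0 || Xbar <= 0)
    stop("'KXZ', 'KYZ' and 'Xbar' must be positive")
  structure(list(r0Y = r0Y, r1Y = r1Y, r0Z = r0Z, r1Z = r1Z, r2Z = r2Z,
                 omega = omega, KXZ = KXZ, KYZ = KYZ, Xbar = Xbar,
                 tfX = tfX, tfY = tfY),
            class = c("cffl_params", "ffl_params", "circuit_params"))
}

#' @rdname cffl_params
#' @export
iffl_params <- function(r0Y, r1Y, r0Z, r1Z, omega, KXZ = 1, KYZ = 1,
                        Xbar = 1, tfX, tfY = tfX) {
  stopifnot(is_allosteric_tf(tfX), is_allosteric_tf(tfY))
  check_nonneg(c(r0Y, r1Y, r0Z, r1Z, omega), "rates and omega")
  if (KXZ <= 0 || KYZ <= 0 || Xbar <= 0)
    stop("'KXZ', 'KYZ' and 'Xbar' must be positive")
  structure(list(r0Y = r0Y, r1Y = r1Y, r0Z = r0Z, r1Z = r1Z,
                 omega = omega, KXZ = KXZ, KYZ = KYZ, Xbar = Xbar,
                 tfX = tfX, tfY = tfY),
            class = c("iffl_params", "ffl_params", "circuit_params"))
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(class(x)[1], "\n")
  flds <- x[!vapply(x, is_allosteric_tf, TRUE)]
  cat(" ", paste(names(flds), unlist(flds), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

## ---- production terms (states-and-weights ratios) -------------------------

# auto-activation production at active fraction a
auto_production <- function(A, p, a) {
  x <- a * A
  (p$r0 + 2 * p$r1 * x + p$r2 * p$omega * x^2) /
    (1 + 2 * x + p$omega * x^2)
}

# d(production)/dA, analytic
auto_production_prime <- function(A, p, a) {
  x <- a * A
  N <- p$r0 + 2 * p$r1 * x + p$r2 * p$omega * x^2
  D <- 1 + 2 * x + p$omega * x^2
  Np <- a * (2 * p$r1 + 2 * p$r2 * p$omega * x)
  Dp <- a * (2 + 2 * p$omega * x)
  (Np * D - N * Dp) / D^2
}

mr_production <- function(R_other, rbar, omega, a, K = 1) {
  x <- a * R_other / K
  rbar / (1 + 2 * x + omega * x^2)
}

# Z-promoter production. Xc, Yc are the effective regulatory activities
# (pact-weighted concentrations over their dissociation constants).
ffl_z_production <- function(p, Xc, Yc) {
  if (inherits(p, "iffl_params"))
    (p$r0Z + p$r1Z * Xc) / (1 + Xc + Yc + p$omega * Xc * Yc)
  else
    (p$r0Z + p$r1Z * (Xc + Yc) + p$omega * p$r2Z * Xc * Yc) /
      (1 + Xc + Yc + p$omega * Xc * Yc)
}

## ---- right-hand sides -----------------------------------------------------

#' Auto-activation right-hand side
#'
#' Dimensionless rate of change of activator concentration,
#' `dA/dt = -A + production(A)`, with the thermodynamic production term
#' weighted by the active fraction `p_active(tf, c)`.
#'
#' @param A Dimensionless activator concentration(s), >= 0.
#' @param p [auto_params()].
#' @param c Effector concentration, molar.
#' @return `dA/dt` (dimensionless rate).
#' @export
auto_rhs <- function(A, p, c) {
  stopifnot(inherits(p, "auto_params"))
  check_nonneg(A, "A")
  -A + auto_production(A, p, p_active(p$tf, c))
}

#' Hill-model auto-activation right-hand side (dimensional)
#'
#' @param A Activator concentration (molar), >= 0.
#' @param p [hill_auto_params()].
#' @param c Effector concentration, molar.
#' @return `dA/dt` in molar per unit time.
#' @export
hill_auto_rhs <- function(A, p, c) {
  stopifnot(inherits(p, "hill_auto_params"))
  check_nonneg(A, "A")
  u <- p_active(p$tf, c) * A / p$Kd_eff
  -p$gamma * A + p$r0 + p$r2 * u^p$n / (1 + u^p$n)
}

#' Mutual-repression right-hand side
#'
#' Dimensionless rates of change of the two repressors. Each production term
#' is the unrepressed rate `rbar` divided by the partition sum over the
#' opposing repressor's binding states, with activities scaled by the
#' respective inducer through `p_active`.
#'
#' @param state Numeric vector `c(R1, R2)`, >= 0.
#' @param p [mr_params()].
#' @param c1,c2 Inducer concentrations for repressor 1 and 2, molar.
#' @return Numeric vector `c(dR1/dt, dR2/dt)`.
#' @export
mr_rhs <- function(state, p, c1, c2) {
  stopifnot(inherits(p, "mr_params"))
  check_nonneg(state, "state")
  a1 <- p_active(p$tf1, c1)
  a2 <- p_active(p$tf2, c2)
  c(-state[1] + mr_production(state[2], p$rbar, p$omega2, a2),
    -state[2] + mr_production(state[1], p$rbar, p$omega1, a1, p$Kratio))
}

#' Feed-forward loop right-hand side
#'
#' Dimensionless rates of change of `(Y, Z)` for the coherent or incoherent
#' feed-forward loop at fixed input concentration `Xbar`. The Y equation is
#' linear in Y at fixed effector; the Z production is the thermodynamic
#' ratio over the four X/Y binding states (for the incoherent loop bound Y
#' contributes to the partition sum only, i.e. represses).
#'
#' @param state Numeric vector `c(Y, Z)`, >= 0.
#' @param p [cffl_params()] or [iffl_params()].
#' @param cX,cY Effector concentrations for X and Y, molar.
#' @return Numeric vector `c(dY/dt, dZ/dt)`.
#' @export
ffl_rhs <- function(state, p, cX, cY) {
  stopifnot(inherits(p, "ffl_params"))
  check_nonneg(state, "state")
  aX <- p_active(p$tfX, cX)
  w <- aX * p$Xbar
  Xc <- w / p$KXZ
  Yc <- p_active(p$tfY, cY) * state[1] / p$KYZ
  c(-state[1] + p$r0Y + p$r1Y * w / (1 + w),
    -state[2] + ffl_z_production(p, Xc, Yc))
}

#' @rdname ffl_rhs
#' @export
cffl_rhs <- function(state, p, cX, cY) {
  stopifnot(inherits(p, "cffl_params"))
  ffl_rhs(state, p, cX, cY)
}

#' @rdname ffl_rhs
#' @export
iffl_rhs <- function(state, p, cX, cY) {
  stopifnot(inherits(p, "iffl_params"))
  ffl_rhs(state, p, cX, cY)
}

#' Logic-gate parameter presets for the coherent feed-forward loop
#'
#' Canonical parameter regimes restricting which occupancy states of the Z
#' promoter enhance expression. In the AND gate only the doubly-bound state
#' activates (`omega > 0`, `r2Z > r1Z = r0Z`); in the XOR gate X and Y cannot
#' bind simultaneously (`omega = 0`) and single-bound states activate; in the
#' OR gate any bound state activates (`r2Z >= r1Z > r0Z`).
#'
#' @param gate One of `"XOR"`, `"AND"`, `"OR"` (case-insensitive).
#' @param tfX,tfY Allosteric transcription factors for the two regulators
#'   (default: the [preset()] MWC transcription factor).
#' @param KXZ,KYZ,Xbar Passed to [cffl_params()].
#' @return A [cffl_params()] object.
#' @export
gate_preset <- function(gate, tfX = preset("mwc_tf"), tfY = tfX,
                        KXZ = 1, KYZ = 1, Xbar = 1) {
  gate <- toupper(gate)
  p <- switch(gate,
    XOR = cffl_params(r0Y = 0, r1Y = 2, r0Z = 0, r1Z = 2, r2Z = 0, omega = 0,
                      KXZ = KXZ, KYZ = KYZ, Xbar = Xbar, tfX = tfX, tfY = tfY),
    AND = cffl_params(r0Y = 0, r1Y = 2, r0Z = 0, r1Z = 0, r2Z = 2, omega = 10,
                      KXZ = KXZ, KYZ = KYZ, Xbar = Xbar, tfX = tfX, tfY = tfY),
    OR  = cffl_params(r0Y = 0, r1Y = 2, r0Z = 0, r1Z = 2, r2Z = 10, omega = 1,
                      KXZ = KXZ, KYZ = KYZ, Xbar = Xbar, tfX = tfX, tfY = tfY),
    stop(sprintf("unknown gate '%s' (expected XOR, AND or OR)", gate)))
  ok <- switch(gate,
    XOR = p$omega == 0 && p$r1Z > p$r0Z,
    AND = p$omega > 0 && p$r2Z > p$r1Z && p$r1Z == p$r0Z,
    OR  = p$r2Z >= p$r1Z && p$r1Z > p$r0Z)
  stopifnot(ok)
  p$gate <- gate
  p
}
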