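#' Allosteric transcription factor (MWC model)
#'
#' Constructs a two-state Monod-Wyman-Changeux description of a transcription
#' factor whose activity is set by a small-molecule effector. The protein
#' fluctuates between an active and an inactive conformation separated by a
#' free-energy difference `eps` (in units of kT; beta is fixed to 1), and the
#' effector binds each conformation at `n_sites` identical sites with
#' dissociation constants `K_A` (active) and `K_I` (inactive).
#'
#' When `K_I < K_A` the effector stabilises the inactive conformation and the
#' active fraction decreases with effector concentration (the LacI/IPTG
#' situation); when `K_I > K_A` it increases; when `K_I == K_A` the effector
#' has no net effect.
#'
#' @param K_A Dissociation constant of the effector for the active
#'   conformation, in molar. Accepts a unit-suffixed string such as
#'   `"140uM"` (see [parse_conc()]).
#' @param K_I Dissociation constant for the inactive conformation, in molar.
#' @param eps Conformational free-energy difference (inactive minus active),
#'   in units of kT.
#' @param n_sites Number of effector binding sites (positive integer,
#'   default 2).
#'
#' @return An object of class `allosteric_tf`.
#' @seealso [p_active()], [activity_limits()], [ec50()], [effective_kd()]
#' @examples
#' tf <- allosteric_tf(K_A = 140e-6, K_I = 530e-9, eps = 4.5)
#' p_active(tf, c(0, 1e-6, 1e-3))
#' @export
allosteric_tf <- function(K_A, K_I, eps, n_sites = 2L) {
  K_A <- parse_conc(K_A)
  K_I <- parse_conc(K_I)
  stopifnot(is.numeric(eps), length(eps) == 1L, is.finite(eps))
  if (!is.numeric(K_A) || length(K_A) != 1L || !is.finite(K_A) || K_A <= 0)
    stop("'K_A' must be a single positive concentration (molar)")
  if (!is.numeric(K_I) || length(K_I) != 1L || !is.finite(K_I) || K_I <= 0)
    stop("'K_I' must be a single positive concentration (molar)")
  n_sites <- as.integer(n_sites)
  if (length(n_sites) != 1L || is.na(n_sites) || n_sites < 1L)
    stop("'n_sites' must be a positive integer")
  structure(list(K_A = K_A, K_I = K_I, eps = eps, n_sites = n_sites),
            class = "allosteric_tf")
}

#' @export
print.allosteric_tf <- function(x, ...) {
  lim <- activity_limits(x)
  cat("MWC allosteric transcription factor\n")
  cat(sprintf("  K_A = %.4g M, K_I = %.4g M, eps = %.3g kT, %d binding site(s)\n",
              x$K_A, x$K_I, x$eps, x$n_sites))
  cat(sprintf("  activity range: [%.4g, %.4g] (%s in effector)\n",
              lim[["pact_min"]], lim[["pact_max"]],
              if (x$K_I < x$K_A) "decreasing"
              else if (x$K_I > x$K_A) "increasing" else "constant"))
  invisible(x)
}

is_allosteric_tf <- function(x) inherits(x, "allosteric_tf")

#' Active fraction of an allosteric transcription factor
#'
#' Probability that the transcription factor is in its active conformation at
#' effector concentration `c`, from the MWC states and weights:
#' \deqn{p_{act}(c) = \frac{(1+c/K_A)^n}{(1+c/K_A)^n +
#'   e^{-\varepsilon} (1+c/K_I)^n}.}
#'
#' @param tf An [allosteric_tf()] object.
#' @param c Effector concentration(s), molar, finite and non-negative.
#' @return Numeric vector of active-state probabilities in (0, 1).
#' @export
p_active <- function(tf, c) {
  stopifnot(is_allosteric_tf(tf))
  if (!is.numeric(c) || any(!is.finite(c)) || any(c < 0))
    stop("effector concentration 'c' must be finite and >= 0 (molar)")
  n <- tf$n_sites
  act <- (1 + c / tf$K_A)^n
  inact <- exp(-tf$eps) * (1 + c / tf$K_I)^n
  act / (act + inact)
}

#' Saturation and leakiness of the activity curve
#'
#' Limits of [p_active()] at zero and saturating effector:
#' `pact_max = 1/(1+e^{-eps})` (the `c -> 0` limit) and
#' `pact_min = 1/(1+e^{-eps} (K_A/K_I)^n)` (the `c -> Inf` limit).
#' For an effector that stabilises the inactive state (`K_I < K_A`) these are
#' the saturation and leakiness of the response; when `K_I > K_A` the two
#' limits swap roles (the curve is increasing).
#'
#' @inheritParams p_active
#' @return Named numeric vector with elements `pact_min` and `pact_max`.
#' @export
activity_limits <- function(tf) {
  stopifnot(is_allosteric_tf(tf))
  Kc <- tf$K_A / tf$K_I
  c(pact_min = 1 / (1 + exp(-tf$eps) * Kc^tf$n_sites),
    pact_max = 1 / (1 + exp(-tf$eps)))
}

#' Effective DNA dissociation constant under induction
#'
#' The effector rescales the apparent affinity of the transcription factor
#' for DNA: `Kd_eff(c) = Kd / p_active(tf, c)`. Over all effector
#' concentrations `Kd_eff` is confined to `[Kd/pact_max, Kd/pact_min]`.
#'
#' @param Kd Bare (physical) dissociation constant, molar, positive.
#' @inheritParams p_active
#' @return Effective dissociation constant(s), molar.
#' @export
effective_kd <- function(Kd, tf, c) {
  Kd <- parse_conc(Kd)
  if (!is.numeric(Kd) || length(Kd) != 1L || !is.finite(Kd) || Kd <= 0)
    stop("'Kd' must be a single positive concentration (molar)")
  Kd / p_active(tf, c)
}

#' Half-maximal effector concentration (EC50)
#'
#' Effector concentration `c*` at which the activity falls midway between its
#' two limits, `p_active(tf, c*) = (pact_max + pact_min) / 2`. Found by
#' bisection on log10(c); the residual at the returned root is below 1e-10.
#'
#' @inheritParams p_active
#' @param bracket Search interval in molar (log-scale bisection), default
#'   `c(1e-15, 10)`.
#' @return The EC50 in molar.
#' @export
ec50 <- function(tf, bracket = c(1e-15, 10)) {
  stopifnot(is_allosteric_tf(tf))
  if (tf$K_A == tf$K_I)
    stop("ec50 is undefined when K_A == K_I: the activity curve is constant")
  lim <- activity_limits(tf)
  mid <- (lim[["pact_min"]] + lim[["pact_max"]]) / 2
  g <- function(lc) p_active(tf, 10^lc) - mid
  lo <- log10(bracket[1]); hi <- log10(bracket[2])
  if (g(lo) * g(hi) > 0)
    stop("ec50 bracket does not contain the midpoint crossing")
  root <- stats::uniroot(g, c(lo, hi), tol = 1e-14)$root
  cstar <- 10^root
  # polish on the linear scale
  if (abs(p_active(tf, cstar) - mid) > 1e-10) {
    cstar <- stats::uniroot(function(c) p_active(tf, c) - mid,
                            cstar * c(0.5, 2), tol = .Machine$double.eps)$root
  }
  cstar
}
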