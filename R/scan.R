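#' Random circuit parameter sets for property scans
#'
#' Draws parameter sets for randomized soundness scans (e.g. verifying that
#' the analytic necessary conditions are never violated by a bistable
#' circuit). Rates are log-uniform and sorted to respect the activator
#' ordering `r0 <= r1 <= r2`; cooperativities are log-uniform. Uses the
#' current RNG state: call `set.seed()` for reproducibility.
#'
#' @param n Number of parameter sets.
#' @param tf [allosteric_tf()] (default `preset("mwc_tf")`).
#' @param rate_range,omega_range Log-uniform sampling ranges (defaults
#'   `c(1e-3, 1e3)`).
#' @return A list of [auto_params()] objects.
#' @export
sample_auto_params <- function(n, tf = preset("mwc_tf"),
                               rate_range = c(1e-3, 1e3),
                               omega_range = c(1e-3, 1e3)) {
  lapply(seq_len(n), function(i) {
    r <- sort(10^stats::runif(3, log10(rate_range[1]), log10(rate_range[2])))
    om <- 10^stats::runif(1, log10(omega_range[1]), log10(omega_range[2]))
    auto_params(r[1], r[2], r[3], omega = om, tf = tf)
  })
}

#' @rdname sample_auto_params
#' @param rbar_range Log-uniform range for the toggle production rate
#'   (default `c(0.1, 20)`).
#' @return For `sample_mr_params`, a list of [mr_params()] objects
#'   (`Kratio = 1`).
#' @export
sample_mr_params <- function(n, tf = preset("mwc_tf"),
                             rbar_range = c(0.1, 20),
                             omega_range = c(0.1, 100)) {
  lapply(seq_len(n), function(i) {
    mr_params(10^stats::runif(1, log10(rbar_range[1]), log10(rbar_range[2])),
              10^stats::runif(1, log10(omega_range[1]), log10(omega_range[2])),
              10^stats::runif(1, log10(omega_range[1]), log10(omega_range[2])),
              Kratio = 1, tf1 = tf)
  })
}

#' Exhaustive bistability scans over effector concentration
#'
#' `any_bistable_auto` scans a log-spaced effector grid and reports whether
#' the auto-activation circuit has two stable fixed points anywhere;
#' `any_bistable_mr` does the same for the toggle switch over an inducer
#' plane.
#'
#' @param p [auto_params()] or [mr_params()].
#' @param c_grid Effector grid, molar (defaults: 80 points over 1e-9 to
#'   1e-2 M for auto-activation; 10 points per axis over 1e-7 to 1e-4 M for
#'   the toggle).
#' @return Logical.
#' @export
any_bistable_auto <- function(p, c_grid = log_grid(1e-9, 1e-2, 80)) {
  stopifnot(inherits(p, "auto_params"))
  for (c in c_grid) if (n_stable_auto(p, c) >= 2L) return(TRUE)
  FALSE
}

#' @rdname any_bistable_auto
#' @export
any_bistable_mr <- function(p, c_grid = log_grid(1e-7, 1e-4, 10)) {
  stopifnot(inherits(p, "mr_params"))
  for (c1 in c_grid) for (c2 in c_grid)
    if (n_stable_mr(p, c1, c2, n_grid = 200) >= 2L) return(TRUE)
  FALSE
}
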