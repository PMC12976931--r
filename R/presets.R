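#' Named parameter presets
#'
#' A registry of ready-made parameter sets used across the package's
#' examples, tests and analyses:
#' \describe{
#'   \item{`mwc_tf`}{the workhorse allosteric transcription factor
#'     (`K_A = 140uM`, `K_I = 530nM`, `eps = 4.5` kT, 2 sites); its effector
#'     inactivates, so activity decreases with concentration.}
#'   \item{`auto_switch`}{bistable auto-activation circuit
#'     (`r0 = 0.1`, `r1 = 1`, `r2 = 20`, `omega = 10`).}
#'   \item{`auto_relax`}{auto-activation set used for relaxation-time
#'     studies (`omega = 7.5`, same rates), typically at `c = 2e-5` M.}
#'   \item{`hill_compare`}{dimensional scales shared by the Hill/thermodynamic
#'     comparison (`r0 = 1e-7`, `r1 = 1e-6`, `r2 = 2e-6` M/min,
#'     `gamma = 1`/min, `Kd = 1e-6` M), as a list.}
#'   \item{`toggle_symmetric`}{symmetric toggle switch (`rbar = 2`,
#'     `omega1 = omega2 = 7.5`, `Kratio = 1`).}
#'   \item{`toggle_asymmetric`}{asymmetric toggle (`omega1 = 50`,
#'     `omega2 = 7.5`), typically at `c1 = 5e-6`, `c2 = 1e-6` M.}
#'   \item{`ffl_xor`, `ffl_and`, `ffl_or`}{coherent feed-forward loop logic
#'     gates (see [gate_preset()]).}
#'   \item{`iffl_pulse`}{incoherent loop used for pulse studies
#'     (`r0Y = r0Z = 0`, `r1Y = r1Z = 2`, `omega = 0`).}
#'   \item{`step_default`}{the default step protocol: `cX` from `1e-4` to
#'     `1e-7` M (an ON step for `mwc_tf`), `cY = 1e-7` M.}
#' }
#'
#' @param name Preset name (see above).
#' @return The corresponding parameter object.
#' @export
preset <- function(name) {
  tf <- allosteric_tf(K_A = 140e-6, K_I = 530e-9, eps = 4.5, n_sites = 2L)
  switch(name,
    mwc_tf = tf,
    auto_switch = auto_params(0.1, 1, 20, omega = 10, tf = tf),
    auto_relax = auto_params(0.1, 1, 20, omega = 7.5, tf = tf),
    hill_compare = list(r0 = 1e-7, r1 = 1e-6, r2 = 2e-6, gamma = 1,
                        Kd = 1e-6),
    toggle_symmetric = mr_params(2, 7.5, 7.5, Kratio = 1, tf1 = tf),
    toggle_asymmetric = mr_params(2, 50, 7.5, Kratio = 1, tf1 = tf),
    ffl_xor = gate_preset("XOR", tfX = tf),
    ffl_and = gate_preset("AND", tfX = tf),
    ffl_or = gate_preset("OR", tfX = tf),
    iffl_pulse = iffl_params(r0Y = 0, r1Y = 2, r0Z = 0, r1Z = 2, omega = 0,
                             tfX = tf),
    step_default = step_input(1e-4, 1e-7, cY = 1e-7),
    stop(sprintf("unknown preset '%s'; see preset_names()", name)))
}

#' @rdname preset
#' @export
preset_names <- function() {
  c("mwc_tf", "auto_switch", "auto_relax", "hill_compare",
    "toggle_symmetric", "toggle_asymmetric",
    "ffl_xor", "ffl_and", "ffl_or", "iffl_pulse", "step_default")
}
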