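test_that("equal rates give the single linear fixed point", {
  p <- auto_params(2.5, 2.5, 2.5, omega = 3, tf = the_tf)
  fp <- auto_fixed_points(p, 1e-6)
  expect_equal(nrow(fp), 1L)
  expect_equal(fp$A, 2.5, tolerance = 1e-12)
  expect_identical(fp$stability, "stable")
})

test_that("the bistable switch preset has two stable and one unstable point", {
  p <- preset("auto_switch")
  fp <- auto_fixed_points(p, 25e-6)
  expect_equal(nrow(fp), 3L)
  expect_identical(fp$stability, c("stable", "unstable", "stable"))
  expect_true(all(abs(auto_rhs(fp$A, p, 25e-6)) < 1e-9))
  # stability labels agree with the sign of the linearisation
  expect_true(all(sign(fp$f_prime) == c(-1, 1, -1)))
})

test_that("cubic roots agree with a dense sign-change scan of the RHS", {
  set.seed(404)
  for (rep in 1:15) {
    r <- sort(10^runif(3, -2, 2))
    p <- auto_params(r[1], r[2], r[3], omega = 10^runif(1, -2, 2.5),
                     tf = the_tf)
    c <- 10^runif(1, -8, -3)
    fp <- auto_fixed_points(p, c)
    scan <- grid_roots(function(A) auto_rhs(A, p, c),
                       seq(0, 2 * r[3], length.out = 4000))
    expect_equal(nrow(fp), length(scan))
    if (length(scan)) expect_equal(fp$A, sort(scan), tolerance = 1e-6)
  }
})

test_that("the bifurcation diagram runs monostable-high, bistable, monostable-low", {
  p <- preset("auto_switch")
  bd <- auto_bifurcation(p, 10^seq(-9, -2, length.out = 100))
  expect_equal(nrow(bd$bistable), 1L)
  expect_true(all(bd$n_stable >= 1L))
  lowc <- bd$points[bd$points$c < bd$bistable$c_lo / 2 &
                      bd$points$stability == "stable", ]
  highc <- bd$points[bd$points$c > bd$bistable$c_hi * 2 &
                       bd$points$stability == "stable", ]
  expect_true(all(lowc$A > 10))      # high branch, magnitude set by r2
  expect_true(all(highc$A < 0.5))    # low branch, magnitude set by r0
  # in the bistable window: exactly 2 stable + 1 unstable
  mid <- sqrt(bd$bistable$c_lo * bd$bistable$c_hi)
  fp <- auto_fixed_points(p, mid)
  expect_identical(sum(fp$stability == "stable"), 2L)
  expect_identical(sum(fp$stability == "unstable"), 1L)
})

test_that("parameter sets violating the necessary conditions never bifurcate", {
  # omega = 0: no doubly-bound state, conditions fail
  p0 <- auto_params(0.1, 1, 20, omega = 0, tf = the_tf)
  expect_false(necessary_conditions_auto(p0)$all)
  expect_false(any_bistable_auto(p0))
  # omega_eff below one
  p1 <- auto_params(0.1, 0.3, 0.9, omega = 2, tf = the_tf)
  expect_lt(necessary_conditions_auto(p1)$omega_eff, 1)
  expect_false(any_bistable_auto(p1))
})

test_that("bistable parameter sets always satisfy the analytic conditions", {
  set.seed(505)
  pars <- sample_auto_params(120)
  cg <- log_grid_test <- 10^seq(-9, -2, length.out = 50)
  for (p in pars) {
    if (any_bistable_auto(p, cg)) {
      nc <- necessary_conditions_auto(p)
      expect_true(nc$all)
      expect_gt(nc$omega_eff, 1)
    }
  }
})

test_that("with full activity the diagram matches the non-inducible system", {
  tf1 <- allosteric_tf(1e-6, 1e-9, eps = 700)
  p <- auto_params(0.1, 1, 20, omega = 10, tf = tf1)
  fp <- auto_fixed_points(p, 0)
  # non-inducible cubic: -om A^3 + (r2 om - 2) A^2 + (2 r1 - 1) A + r0
  z <- polyroot(c(0.1, 2 * 1 - 1, 20 * 10 - 2, -10))
  ref <- sort(Re(z[abs(Im(z)) < 1e-8]))
  expect_equal(fp$A, ref, tolerance = 1e-9)
})

test_that("hysteresis thresholds bracket the bistable interval, up above down", {
  p <- preset("auto_switch")
  cg <- 10^seq(-9, -2, length.out = 250)
  up <- hysteresis(p, cg, A_init = 20)
  dn <- hysteresis(p, rev(cg), A_init = 0)
  su <- attr(up, "switches"); sd <- attr(dn, "switches")
  expect_equal(nrow(su), 1L)
  expect_equal(nrow(sd), 1L)
  expect_gt(su$c, sd$c)
  bd <- auto_bifurcation(p, 10^seq(-9, -2, length.out = 80))
  # jumps occur at the first grid point beyond each saddle-node
  spacing <- cg[2] / cg[1]
  expect_lt(su$c / bd$bistable$c_hi, spacing * 1.01)
  expect_gt(su$c / bd$bistable$c_hi, 1)
  expect_gt(bd$bistable$c_lo / sd$c, 1 / (spacing * 1.01))
  expect_lt(bd$bistable$c_lo / sd$c, spacing * 1.01)
  # a monostable circuit retraces the same branch in both directions
  pm <- auto_params(0.1, 0.2, 0.5, omega = 1, tf = the_tf)
  u2 <- hysteresis(pm, cg, A_init = 5)
  d2 <- hysteresis(pm, rev(cg), A_init = 0)
  expect_equal(u2$A, rev(d2$A), tolerance = 1e-9)
  expect_null(attr(u2, "switches"))
})

test_that("Hill and thermodynamic models disagree at low cooperativity only", {
  sc <- preset("hill_compare")
  cg <- 10^seq(-9, -2, length.out = 120)
  low <- compare_hill_thermo(sc$r0, sc$r1, sc$r2, sc$gamma, sc$Kd, 1, the_tf,
                             c_grid = cg)
  d1 <- attr(low, "disagreement")
  expect_gt(length(d1), 10)
  expect_true(all(d1 < 1e-5))
  # at low effector the Hill model is bistable where the thermodynamic is not
  lowc <- low[low$c < 1e-6, ]
  expect_true(any(lowc$hill_bistable))
  expect_false(any(lowc$thermo_bistable))
  mid <- compare_hill_thermo(sc$r0, sc$r1, sc$r2, sc$gamma, sc$Kd, 7.5, the_tf,
                             c_grid = cg)
  d2 <- attr(mid, "disagreement")
  expect_gt(length(d2), 0)
  expect_true(all(d2 >= 1e-6 & d2 <= 1e-5))
  hi <- compare_hill_thermo(sc$r0, sc$r1, sc$r2, sc$gamma, sc$Kd, 100, the_tf,
                            c_grid = cg)
  # verdicts essentially identical: at most interval-edge cells differ
  expect_gt(mean(hi$agree), 0.98)
  matched <- compare_hill_thermo(sc$r0, sc$r1, sc$r2, sc$gamma, sc$Kd, 1e4,
                                 the_tf, c_grid = cg)
  expect_length(attr(matched, "disagreement"), 0)
})

test_that("effective Hill coefficient is capped at two and exceeds one when bistable", {
  set.seed(606)
  for (rep in 1:8) {
    r <- sort(10^runif(3, -2, 2))
    p <- auto_params(r[1], r[2], r[3], omega = 10^runif(1, -2, 2), tf = the_tf)
    h <- effective_hill_coefficient(p, 10^runif(1, -8, -3))
    expect_lte(h, 2 + 1e-6)
    expect_gte(h, 0)
  }
  # strongly cooperative: slope approaches two
  pbig <- auto_params(0.1, 1, 20, omega = 1e6, tf = the_tf)
  expect_gt(effective_hill_coefficient(pbig, 1e-4), 1.95)
  # every bistable set in a small scan exceeds one
  set.seed(607)
  pars <- sample_auto_params(40)
  for (p in pars) {
    bd <- auto_bifurcation(p, 10^seq(-9, -2, length.out = 40))
    if (nrow(bd$bistable)) {
      cmid <- sqrt(bd$bistable$c_lo[1] * bd$bistable$c_hi[1])
      expect_gt(effective_hill_coefficient(p, cmid), 1)
    }
  }
})
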