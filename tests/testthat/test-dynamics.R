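test_that("the integrator reproduces closed-form linear kinetics", {
  # pure decay
  tr <- integrate_circuit(function(t, y) -y, 1, 5, n_steps = 200)
  expect_equal(tr$y[, 1], exp(-tr$t), tolerance = 1e-7)
  # constant production from zero: r (1 - e^-t)
  r <- 3.7
  tr2 <- integrate_circuit(function(t, y) -y + r, 0, 8, n_steps = 200)
  expect_equal(tr2$y[, 1], r * (1 - exp(-tr2$t)), tolerance = 1e-7)
  expect_true(integrate_circuit(function(t, y) -y + r, 0, 40)$converged)
  # and with an offset start: r(1-e^-t) + y0 e^-t
  tr3 <- integrate_circuit(function(t, y) -y + r, 10, 8, n_steps = 200)
  expect_equal(tr3$y[, 1], r * (1 - exp(-tr3$t)) + 10 * exp(-tr3$t),
               tolerance = 1e-7)
})

test_that("a trajectory started on a stable fixed point stays there", {
  p <- preset("auto_switch")
  fp <- auto_fixed_points(p, 25e-6)
  Ahigh <- max(fp$A[fp$stability == "stable"])
  tr <- integrate_circuit(circuit_flow(p, c = 25e-6), Ahigh, 20)
  expect_lt(max(abs(tr$y[, 1] - Ahigh)), 1e-6)
})

test_that("states remain non-negative along trajectories", {
  p <- preset("toggle_symmetric")
  tr <- integrate_circuit(circuit_flow(p, c1 = 1e-6, c2 = 1e-6), c(0, 0), 30)
  expect_true(all(tr$y >= 0))
  tr2 <- integrate_circuit(circuit_flow(preset("auto_switch"), c = 1e-3), 40, 30)
  expect_true(all(tr2$y >= 0))
})

test_that("linearised timescale matches finite differences and trivial cases", {
  pr <- auto_params(2, 2, 2, omega = 4, tf = the_tf)
  lt <- linear_timescale(pr, 1e-6, 2)
  expect_equal(lt$tau, 1, tolerance = 1e-12)
  expect_equal(lt$f_prime, -1, tolerance = 1e-12)
  p <- preset("auto_relax")
  fp <- auto_fixed_points(p, 2e-5)
  for (A in fp$A) {
    lt <- linear_timescale(p, 2e-5, A)
    h <- 1e-6 * max(1, A)
    fd <- (auto_rhs(A + h, p, 2e-5) - auto_rhs(A - h, p, 2e-5)) / (2 * h)
    expect_equal(lt$f_prime, fd, tolerance = 1e-6)
  }
  # stability cross-check: signs are (-, +, -) for low/unstable/high
  fps <- vapply(fp$A, function(A) linear_timescale(p, 2e-5, A)$f_prime, 0)
  expect_identical(sign(fps), c(-1, 1, -1))
})

test_that("relaxation time near stable fixed points follows the linear theory", {
  p <- preset("auto_relax")
  fp <- auto_fixed_points(p, 2e-5)
  st <- fp$A[fp$stability == "stable"]
  for (A in st) {
    tau_lin <- linear_timescale(p, 2e-5, A)$tau
    r <- relaxation_time_auto(p, 2e-5, A * 1.02, method = "fit_exponential")
    expect_equal(r$tau, tau_lin, tolerance = 0.05)
  }
})

test_that("relaxation slows toward the unstable point and quickens far above", {
  p <- preset("auto_relax")
  fp <- auto_fixed_points(p, 2e-5)
  Aun <- fp$A[fp$stability == "unstable"]
  # approaching the unstable point from above: tau increases monotonically
  A0s <- Aun + c(2, 1, 0.5, 0.2)
  taus <- vapply(A0s, function(A0)
    relaxation_time_auto(p, 2e-5, A0)$tau, 0)
  expect_true(all(diff(taus) > 0))
  # far above the high state the timescale decreases toward the decay limit
  t30 <- relaxation_time_auto(p, 2e-5, 30)$tau
  t40 <- relaxation_time_auto(p, 2e-5, 40)$tau
  expect_lt(t40, t30)
  expect_gt(t30, 1)
  # both estimators are reported
  r95 <- relaxation_time_auto(p, 2e-5, 30, method = "threshold_95")
  expect_gt(r95$tau, 0)
})

test_that("toggle relaxation is symmetric for mirrored starts", {
  p <- preset("toggle_symmetric")
  r1 <- relaxation_time_mr(p, 1e-6, 1e-6, c(1.8, 0.3))
  r2 <- relaxation_time_mr(p, 1e-6, 1e-6, c(0.3, 1.8))
  expect_equal(r1$tau, r2$tau, tolerance = 1e-4)
  expect_equal(r1$target_state, rev(r2$target_state), tolerance = 1e-6)
  # a start at a stable fixed point crosses its band immediately
  fp <- mr_fixed_points(p, 1e-6, 1e-6)
  st <- fp[fp$stability == "stable", ][1, ]
  r0 <- relaxation_time_mr(p, 1e-6, 1e-6, c(st$R1, st$R2))
  expect_lt(r0$tau, 1e-3)
  # starts near the separatrix relax far more slowly than distant ones
  rnear <- relaxation_time_mr(p, 1e-6, 1e-6, c(1.001, 1.0))
  expect_gt(rnear$tau, 3 * r1$tau)
})

test_that("the symmetric separatrix is the diagonal and splits the basins", {
  p <- preset("toggle_symmetric")
  sep <- mr_separatrix(p, 1e-6, 1e-6)
  expect_lt(max(abs(sep$R1 - sep$R2)), 1e-6)
  # side test: points displaced off the separatrix converge to opposite states
  idx <- which(sep$R1 > 0.2 & sep$R1 < 1.5)[c(5, 25)]
  for (i in idx) {
    a <- relaxation_time_mr(p, 1e-6, 1e-6,
                            c(sep$R1[i] + 1e-3, sep$R2[i] - 1e-3))
    b <- relaxation_time_mr(p, 1e-6, 1e-6,
                            c(sep$R1[i] - 1e-3, sep$R2[i] + 1e-3))
    expect_gt(a$target_state[1], a$target_state[2])
    expect_lt(b$target_state[1], b$target_state[2])
  }
  expect_error(mr_separatrix(p, 1e-4, 1e-7), "not bistable")
})

test_that("the asymmetric separatrix deforms away from the diagonal", {
  p <- preset("toggle_asymmetric")
  sep <- mr_separatrix(p, 5e-6, 1e-6)
  inner <- sep[sep$R1 < 2 & sep$R2 < 2, ]
  expect_gt(max(abs(inner$R1 - inner$R2)), 0.05)
})

test_that("basin labels partition the plane consistently with the separatrix", {
  p <- preset("toggle_symmetric")
  g <- seq(0.05, 2, length.out = 9)
  b <- mr_basins(p, 1e-6, 1e-6, g, g)
  expect_true(all(!is.na(b$label)))
  expect_equal(nrow(b$attractors), 2L)
  # mirror symmetry: transposing the grid swaps the two labels (the diagonal
  # sits exactly on the separatrix, where the label is not defined)
  off <- row(b$label) != col(b$label)
  expect_identical(b$label[off], (3L - t(b$label))[off])
  # labels flip exactly across the diagonal separatrix
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (g[i] > g[j]) expect_identical(b$label[i, j], b$label[length(g), 1])
    if (g[i] < g[j]) expect_identical(b$label[i, j], b$label[1, length(g)])
  }
  # asymmetric case: basin areas become unequal
  pa <- preset("toggle_asymmetric")
  ba <- mr_basins(pa, 5e-6, 1e-6, g, g)
  tab <- table(ba$label)
  expect_gt(max(tab) / min(tab), 1.2)
})
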