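# Input-function model, quadrature and the two-tissue kinetic simulator.

test_that("frame schedules validate and expose mids/durations", {
  s <- frame_schedule(c(0, 5), c(5, 10))
  expect_equal(frame_mids(s), c(2.5, 7.5))
  expect_equal(frame_durations(s), c(5, 5))
  expect_error(frame_schedule(c(0, 4), c(5, 10)), "overlap")
  expect_error(frame_schedule(5, 5), "later than its start")
  expect_error(frame_schedule(c(5, 0), c(6, 1)), "increasing")
})

test_that("the 1-h protocol has 29 frames with the stated durations", {
  s <- default_schedule_1h()
  expect_length(s, 29L)
  expect_equal(s$starts[1L], 0)
  expect_equal(s$ends[29L], 60)
  expect_equal(s$starts[29L], 55)
  expect_equal(sum(frame_durations(s)) * 60, 3600)
  expect_equal(frame_durations(s)[1:6], rep(10 / 60, 6))
})

test_that("late schedules are contiguous blocks of equal frames", {
  s <- late_schedule(40, 4, 5)
  expect_equal(s$starts, c(40, 45, 50, 55))
  expect_equal(s$ends, c(45, 50, 55, 60))
  expect_equal(late_schedule(60, 4, 5)$ends[4L], 80)
  expect_length(late_schedule(0, 1, 60), 1L)
})

test_that("Feng input evaluates its closed form and vanishes at t = 0", {
  f <- feng_input()
  expect_equal(eval_input(f, 0), 0)
  # frozen values from an independent high-precision evaluation of the
  # closed-form sum of exponentials
  expect_rel_equal(eval_input(f, c(0.5, 1, 40, 60)),
                   c(89.832197253244496, 53.077363211313159,
                     14.594032895538917, 11.718553071094719), 1e-12)
  zero <- feng_input(A1 = 0, A2 = 0, A3 = 0)
  expect_equal(eval_input(zero, c(0, 10, 60)), c(0, 0, 0))
  expect_error(eval_input(f, -1), "t >= 0")
})

test_that("sampled inputs interpolate, extrapolate and stay non-negative", {
  f <- sampled_input(c(10, 20, 30), c(1, 1, 1))
  expect_equal(eval_input(f, 15), 1)
  expect_equal(eval_input(f, 5), 0.5)  # linear from the implicit origin
  # terminal mono-exponential continuation
  g <- sampled_input(1:6, 10 * exp(-0.2 * (1:6)))
  expect_rel_equal(eval_input(g, 10), 10 * exp(-2), 1e-6)
  expect_error(sampled_input(c(1, 1), c(1, 2)), "increasing")
  expect_error(sampled_input(c(1, 2), c(-1, 2)), "non-negative")
})

test_that("input integration matches closed forms and is additive", {
  f <- sampled_input(c(0, 100), c(2, 2))           # constant Cp = 2
  expect_rel_equal(integrate_input(f, 0, 10), 20, 1e-6)
  expect_equal(integrate_input(f, 7, 7), 0)
  expect_error(integrate_input(f, 5, 3), "t0 <= t1")
  # mono-exponential against its antiderivative
  A <- 8; l <- 0.1
  g <- feng_input(A1 = 0, A2 = A, A3 = 0, l2 = -l)
  expect_rel_equal(integrate_input(g, 3, 47),
                   (A / l) * (exp(-l * 3) - exp(-l * 47)), 1e-6)
  # exact additivity over abutting intervals (shared lattice nodes)
  f2 <- feng_input()
  whole <- integrate_input(f2, 0, 60)
  parts <- integrate_input(f2, 0, 17.23) + integrate_input(f2, 17.23, 60)
  expect_rel_equal(parts, whole, 1e-9)
})

test_that("kinetic parameters validate and derive the net influx rate", {
  p <- kinetic_params(0.1, 0.13, 0.06, vb = 0.05)
  expect_equal(ki_true(p), 0.1 * 0.06 / 0.19)
  expect_equal(ki_true(kinetic_params(0.5, 1, 0)), 0)
  expect_error(kinetic_params(-1, 1, 0), "K1")
  expect_error(kinetic_params(1, 0, 0), "k2")
  expect_error(kinetic_params(1, 1, 1, vb = 1), "vb")
})

test_that("tissue curves reduce to their closed-form limits", {
  f <- feng_input()
  sched <- default_schedule_1h()
  # K1 = 0: pure blood signal
  p0 <- kinetic_params(0, 1, 0, vb = 0.3)
  tc <- tissue_curve(f, p0, sched)
  grid <- seq(0, 60, by = 0.01)
  cp_avg <- relpatlak:::.frame_average(grid, eval_input(f, grid), sched)
  # the brief 10-s frames ride the steep bolus, where the solver's 0.05-min
  # averaging grid is only ~1% accurate; from 2 min on the curves are smooth
  late <- which(sched$starts >= 2)
  expect_rel_equal(tc$values[late], (0.3 * cp_avg)[late], 1e-3)
  # k3 = 0, constant input: one-tissue equilibrium K1 c / k2
  const <- sampled_input(c(0.001, 1000), c(5, 5))
  p1 <- kinetic_params(0.2, 0.5, 0)
  eq <- tissue_curve(const, p1, late_schedule(100, 2, 10))
  expect_rel_equal(eq$values, rep(0.2 * 5 / 0.5, 2), 1e-3)
})

test_that("the convolution solver matches a stiff ODE oracle", {
  skip_if_not_installed("deSolve")
  f <- feng_input()
  sched <- default_schedule_1h()
  sweep <- list(
    kinetic_params(0.85, 0.98, 0.010, 0.10),  # liver
    kinetic_params(0.02, 0.25, 0.012, 0.14),  # lung
    kinetic_params(1.00, 1.30, 0.005, 0.20),  # spleen
    kinetic_params(0.03, 0.25, 0.020, 0.02),  # muscle
    kinetic_params(0.10, 0.13, 0.060, 0.05),  # gray matter
    kinetic_params(0.09, 0.30, 0.030, 0.04),  # marrow
    kinetic_params(0.60, 1.20, 0.100, 0.25),  # myocardium
    kinetic_params(0.35, 0.60, 0.180, 0.05),  # lesion
    kinetic_params(0.50, 2.00, 0.300, 0.00),  # fast kinetics
    kinetic_params(0.01, 0.05, 0.001, 0.00))  # slow kinetics
  mids <- frame_mids(sched)
  for (p in sweep) {
    ode <- deSolve::ode(
      y = c(c1 = 0, c2 = 0), times = c(0, mids),
      parms = p, method = "lsoda", rtol = 1e-9, atol = 1e-10,
      func = function(t, y, parms) {
        cp <- eval_input(f, t)
        list(c(parms$K1 * cp - (parms$k2 + parms$k3) * y[1L],
               parms$k3 * y[1L]))
      })
    ct_mid <- (1 - p$vb) * (ode[-1L, "c1"] + ode[-1L, "c2"]) +
      p$vb * eval_input(f, mids)
    tc <- tissue_curve(f, p, sched)
    # compare at late frames where frame-average vs mid-point sampling
    # differences are negligible
    late <- which(sched$starts >= 10)
    expect_rel_equal(tc$values[late], ct_mid[late], 5e-3)
  }
})

test_that("frame averages converge to instantaneous values as frames shrink", {
  f <- feng_input()
  p <- kinetic_params(0.3, 0.6, 0.1, 0.05)
  tiny <- frame_schedule(c(20, 30) - 1 / 120, c(20, 30) + 1 / 120)
  wide <- frame_schedule(c(17.5, 27.5), c(22.5, 32.5))
  tc_tiny <- tissue_curve(f, p, tiny)
  # 1-s frames sit within 0.05% of the continuous curve; 5-min frames do not
  fine <- tissue_curve(f, p, frame_schedule(c(20, 30) - 1e-4,
                                            c(20, 30) + 1e-4))
  expect_rel_equal(tc_tiny$values, fine$values, 5e-4)
})

test_that("Patlak linearity emerges at late times for irreversible kinetics", {
  f <- feng_input()
  sched <- default_schedule_1h()
  for (p in list(kinetic_params(0.1, 0.13, 0.06),
                 kinetic_params(0.35, 0.60, 0.18),
                 kinetic_params(0.03, 0.25, 0.02))) {
    tc <- tissue_curve(f, p, sched)
    fit <- patlak(tc, f, t_star = 40, method = "standard")
    expect_rel_equal(coef(fit)[["slope"]], ki_true(p), 0.02)
    expect_gt(fit$r2, 0.999)
  }
})
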