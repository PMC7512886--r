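test_that("unforced runs from the origin stay at the origin", {
  traj <- integrate_love(love_params(), forcing_spec(A = 0, B = 0),
                         fast_settings(transient_periods = 0L,
                                       record_periods = 4L,
                                       initial_state = c(0, 0)))
  expect_true(all(traj$R == 0))
  expect_true(all(traj$J == 0))
})

test_that("a stable focus decays to the origin", {
  # det > 0, trace < 0: the origin is asymptotically stable, and 200
  # time units is ~ 50 e-folding times of the slow mode (Re lambda =
  # -0.25). The basin is small — non-normal transient growth ejects
  # initial states of norm ~ 0.1 onto a coexisting limit cycle — so a
  # genuinely small initial state is used.
  traj <- integrate_love(love_params(a = -1.5), forcing_spec(A = 0, B = 0),
                         run_settings(transient_periods = 0L,
                                      record_periods = 100L,
                                      initial_state = c(0.01, 0.01)))
  n <- length(traj$R)
  expect_lt(abs(traj$R[n]), 1e-6)
  expect_lt(abs(traj$J[n]), 1e-6)
})

test_that("trajectories have uniform spacing, equal lengths and are bit-reproducible", {
  p <- love_params(a = -5.41)
  f <- scenario("P_eq_N")
  s <- fast_settings(transient_periods = 50L, record_periods = 8L)
  t1 <- integrate_love(p, f, s)
  t2 <- integrate_love(p, f, s)
  expect_identical(t1$R, t2$R)
  expect_identical(t1$J, t2$J)
  expect_length(t1$times, length(t1$R))
  expect_length(t1$J, length(t1$R))
  expect_equal(diff(t1$times), rep(s$dt, length(t1$times) - 1L),
               tolerance = 1e-9)
  expect_true(all(is.finite(t1$R)) && all(is.finite(t1$J)))
})

test_that("exceeding the overflow guard raises an error naming the failing step", {
  # the forced orbit at a = -5.41 reaches |J| ~ 3.8, so a guard of 2
  # must trip during the transient
  expect_error(
    integrate_love(love_params(a = -5.41), scenario("P_eq_N"),
                   fast_settings(transient_periods = 50L,
                                 record_periods = 8L,
                                 overflow_guard = 2)),
    "diverged at step")
})

test_that("the step must divide the forcing period exactly", {
  expect_error(
    integrate_love(love_params(), scenario("P_eq_N"),
                   run_settings(dt = 0.0003, transient_periods = 0L,
                                record_periods = 1L)),
    "integer multiple")
})

test_that("step halving shows 4th-order convergence on a smooth window", {
  # unforced, initial state away from the |R| = 0, |J| = 0 kinks; the
  # state at t = 0.2 stays in one smooth piece of the vector field
  p <- love_params(a = -1.5)
  f <- forcing_spec(A = 0, B = 0)
  final_at <- function(dt) {
    s <- run_settings(dt = dt, transient_periods = 0L, record_periods = 1L,
                      initial_state = c(0.5, 0.5))
    traj <- integrate_love(p, f, s)
    i <- which.min(abs(traj$times - 0.2))
    # confirm smoothness: no sign change up to the probe time
    expect_true(all(traj$R[1:i] > 0) && all(traj$J[1:i] > 0))
    c(traj$R[i], traj$J[i])
  }
  x1 <- final_at(0.01); x2 <- final_at(0.005); x3 <- final_at(0.0025)
  e12 <- sqrt(sum((x1 - x2)^2)); e23 <- sqrt(sum((x2 - x3)^2))
  order <- log2(e12 / e23)
  expect_gte(order, 3.5)
})

test_that("trajectories obey the odd symmetry of balanced advice", {
  # with B = 0 the field satisfies F(t + 1, -x) = -F(t, x) (half the
  # forcing period), and RK4 commutes with the flip: a run started one
  # time unit later from the negated initial state traces the negated
  # path, sample by sample
  p <- love_params(a = -5.41)
  f <- scenario("P_eq_N")
  s1 <- run_settings(transient_periods = 0L, record_periods = 5L,
                     initial_state = c(0.2, -0.3), t0 = 0)
  s2 <- run_settings(transient_periods = 0L, record_periods = 5L,
                     initial_state = c(-0.2, 0.3), t0 = 1)
  tr1 <- integrate_love(p, f, s1)
  tr2 <- integrate_love(p, f, s2)
  expect_equal(tr2$R, -tr1$R, tolerance = 1e-9)
  expect_equal(tr2$J, -tr1$J, tolerance = 1e-9)
  # broken for B != 0
  fb <- scenario("P_gt_N")
  tb1 <- integrate_love(p, fb, s1)
  tb2 <- integrate_love(p, fb, s2)
  expect_gt(max(abs(tb2$R + tb1$R)), 1e-3)
})

test_that("strobing returns one aligned sample per forcing period", {
  p <- love_params(a = -5.41)
  f <- scenario("P_eq_N")
  s <- fast_settings(transient_periods = 200L, record_periods = 40L)
  traj <- integrate_love(p, f, s)
  sec <- strobe(traj)
  expect_length(sec$R, s$record_periods)
  expect_equal(diff(sec$t), rep(forcing_period(f), s$record_periods - 1L),
               tolerance = 1e-9)
  # period-1 orbit: all strobe points coincide
  expect_lt(max(dist(cbind(sec$R, sec$J))), 1e-6)
  # constant trajectory strobes to identical points
  tr0 <- integrate_love(love_params(), forcing_spec(A = 0, B = 0),
                        fast_settings(transient_periods = 0L,
                                      record_periods = 40L,
                                      initial_state = c(0, 0)))
  s0 <- strobe(tr0)
  expect_true(all(s0$R == 0) && all(s0$J == 0))
  # phase validation
  expect_error(strobe(traj, phase = 2), "\\[0, period\\)")
  expect_error(strobe(traj, phase = 0.0005), "integer multiple")
})

test_that("trajectory and section CSVs round-trip at full precision", {
  traj <- integrate_love(love_params(a = -2.561), scenario("P_eq_N"),
                         fast_settings(transient_periods = 20L,
                                       record_periods = 4L))
  path <- tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_identical(back$R, traj$R)
  expect_identical(back$J, traj$J)
  expect_identical(back$t, traj$times)
  sec <- strobe(traj)
  path2 <- tempfile(fileext = ".csv")
  write_section(sec, path2)
  back2 <- utils::read.csv(path2)
  expect_identical(back2$R, sec$R)
  expect_identical(back2$k, sec$k)
})
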