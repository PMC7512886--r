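test_that("forcing evaluates A sin(omega pi t) + B and exposes advice magnitudes", {
  expect_equal(forcing_value(0, forcing_spec(A = 6, B = 1)), 1.0)
  expect_equal(forcing_value(0.5, forcing_spec(A = 5, B = 0)), 5.0)
  # at t = 1.5 (omega = 1) the sine sits at -1: the negative magnitude
  f <- forcing_spec(A = 6, B = -1)
  expect_equal(forcing_value(1.5, f), -7.0)
  expect_equal(forcing_value(1.5, f), negative_magnitude(f))
  expect_equal(positive_magnitude(f), 5)
  expect_error(forcing_value(NaN, f), "finite")
})

test_that("forcing is periodic with period 2/omega at grid points", {
  for (omega in c(1, 0.5, 2.5)) {
    f <- forcing_spec(A = 3.7, B = 0.4, omega = omega)
    t <- seq(0, 10, by = 0.01)
    expect_equal(forcing_value(t + forcing_period(f), f), forcing_value(t, f),
                 tolerance = 1e-12)
  }
})

test_that("vector field matches the model equations", {
  p <- love_params(a = -5.41, b = -2, c = 1, d = 1)
  f <- forcing_spec(A = 5, B = 0)
  # origin at t = 0: every term vanishes
  expect_equal(vector_field(0, c(0, 0), p, f), c(dR = 0, dJ = 0))
  # only the forcing survives at the origin at peak phase
  expect_equal(vector_field(0.5, c(0, 0), p, f), c(dR = 5, dJ = 0))
  # hand substitution at R = J = 1: nonlinear terms vanish
  expect_equal(vector_field(0, c(1, 1), p, f), c(dR = -5.41, dJ = 1))
  # forcing routed to Juliet or both
  fj <- forcing_spec(A = 5, B = 0, target = "juliet")
  fb <- forcing_spec(A = 5, B = 0, target = "both")
  expect_equal(vector_field(0.5, c(0, 0), p, fj), c(dR = 0, dJ = 5))
  expect_equal(vector_field(0.5, c(0, 0), p, fb), c(dR = 5, dJ = 5))
})

test_that("analytic Jacobian agrees with the linearization and finite differences", {
  p <- love_params(a = -5.41, b = -2, c = 1, d = 1)
  # at the origin the Jacobian is exactly the linear-model matrix
  expect_identical(love_jacobian(c(0, 0), p),
                   matrix(c(p$a, p$c, p$b, p$d), 2, 2))
  # 1 - 2|x| vanishes at |x| = 1/2: off-diagonal terms are zero
  expect_equal(love_jacobian(c(0.5, 0.5), p),
               matrix(c(p$a, 0, 0, p$d), 2, 2))
  # interior points: central differences of the vector field
  f <- forcing_spec(A = 5, B = 0)
  set.seed(7)
  for (i in 1:20) {
    st <- runif(2, -2, 2)
    st[abs(st) < 0.05] <- 0.3  # keep away from the |x| = 0 kink
    expect_equal(love_jacobian(st, p), fd_jacobian(0.3, st, p, f),
                 tolerance = 1e-6)
  }
})

test_that("fixed-point classification reports the saddle dichotomy and spectral class", {
  # reference configuration: ad = -5.41 < bc = -2
  rep1 <- classify_fixed_point(love_params(a = -5.41))
  expect_identical(rep1$paper_label, "saddle")
  expect_identical(rep1$spectral_label, "saddle")
  expect_equal(rep1$determinant, -3.41)
  # boundary of the saddle region: determinant exactly zero
  rep2 <- classify_fixed_point(love_params(a = -2))
  expect_identical(rep2$determinant, 0)
  expect_identical(rep2$spectral_label, "degenerate")
  expect_identical(rep2$paper_label, "non_saddle")
  # det > 0, trace < 0, negative discriminant: stable spiral
  rep3 <- classify_fixed_point(love_params(a = -1.5))
  expect_equal(rep3$determinant, 0.5)
  expect_equal(rep3$trace, -0.5)
  expect_identical(rep3$spectral_label, "stable_spiral")
})

test_that("eigenvalues solve the characteristic polynomial and saddle means split real parts", {
  set.seed(11)
  for (i in 1:50) {
    p <- do.call(love_params, as.list(setNames(runif(4, -3, 3),
                                               c("a", "b", "c", "d"))))
    rep <- classify_fixed_point(p)
    for (ev in rep$eigenvalues)
      expect_equal(Mod(ev^2 - rep$trace * ev + rep$determinant), 0,
                   tolerance = 1e-10)
    saddle <- rep$paper_label == "saddle"
    expect_identical(saddle, p$a * p$d < p$b * p$c)
    if (saddle) {
      expect_true(Re(rep$eigenvalues[1]) > 0 && Re(rep$eigenvalues[2]) < 0)
    }
  }
})

test_that("scenario presets encode the three advice balances", {
  f1 <- scenario("P_eq_N")
  expect_equal(c(f1$A, f1$B, f1$omega), c(5, 0, 1))
  f2 <- scenario("P_gt_N")
  expect_equal(c(f2$A, f2$B, f2$omega), c(6, 1, 1))
  f3 <- scenario("P_lt_N")
  expect_equal(c(f3$A, f3$B, f3$omega), c(6, -1, 1))
  expect_true(all(vapply(scenario_names(),
                         function(n) scenario(n)$target, "") == "romeo"))
  expect_error(scenario("P_weird"))
})

test_that("constructors validate their inputs", {
  expect_error(love_params(a = Inf), "finite")
  expect_error(forcing_spec(A = -1), ">= 0")
  expect_error(forcing_spec(omega = 0), "> 0")
  expect_error(run_settings(dt = 0), "> 0")
  expect_error(run_settings(record_periods = 0), ">= 1")
  expect_error(run_settings(initial_state = c(1, NA)), "finite")
})
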