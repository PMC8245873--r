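test_that("build_system constructs minimal and tabular systems and rejects bad input", {
  sys1 <- build_system(list(L_0_1 = 0.1), topology = list(dosing = 1))
  expect_s3_class(sys1, "compartmental_system")
  expect_equal(sys1$n, 1L)

  expect_error(build_system(list(L_2_1 = -0.3, L_0_2 = 0.1),
                            topology = list(dosing = 1)),
               "negative coefficient")
  expect_error(build_system(list(L_2_1 = NA_real_, L_0_2 = 0.1),
                            topology = list(dosing = 1)),
               "missing")
  # closed system: no path to loss
  expect_error(build_system(list(L_2_1 = 0.5, L_1_2 = 0.5),
                            topology = list(dosing = 1)),
               "unreachable loss")
  expect_error(compartmental_system(matrix(0, 3, 3), loss = c(1, 1, 1),
                                    plasma = 1, storage = c(1, 2)),
               "storage")
  expect_error(compartmental_system(matrix(0, 3, 3), loss = c(1, 1, 1),
                                    storage = c(2, 2, 3)),
               "exactly 2")
})

test_that("generated subject systems are open (all eigenvalues in the left half-plane)", {
  co <- generate_cohort(cohort_design(n_subjects = 4, seed = 10))
  for (s in co) {
    ev <- eigen(state_matrix(s$system), only.values = TRUE)$values
    expect_lt(max(Re(ev)), 0)
  }
})

test_that("tracer solution matches closed forms for one- and two-compartment systems", {
  tc <- solve_tracer(one_comp(0.1), times = c(0, 10))
  expect_equal(unname(tc$q[2, 1]), exp(-1), tolerance = 1e-12)

  k12 <- 0.5; k02 <- 0.25
  tt <- c(0, 1, 2.5, 7, 20)
  tc2 <- solve_tracer(two_comp_chain(k12, k02), times = tt)
  expect_equal(unname(tc2$q[, 1]), exp(-k12 * tt), tolerance = 1e-10)
  q2 <- k12 / (k02 - k12) * (exp(-k12 * tt) - exp(-k02 * tt))
  expect_equal(unname(tc2$q[, 2]), q2, tolerance = 1e-10)
})

test_that("initial condition places the dose correctly, with absorption split to loss", {
  sub <- fixed_subject(absorption = 0.7)
  tc <- solve_tracer(sub$system, times = 0:3)
  expect_equal(unname(tc$q[1, sub$system$dosing]), 0.7, tolerance = 1e-12)
  expect_equal(sum(tc$q[1, -sub$system$dosing]), 0, tolerance = 1e-12)
  expect_equal(tc$cumulative_loss[1], 0.3, tolerance = 1e-12)

  plain <- random_open_system(3)
  tcp <- solve_tracer(plain, times = 0:2)
  expect_equal(tcp$q[1, ], c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(tcp$cumulative_loss[1], 0)
})

test_that("solver agrees with matrix-exponential and stiff-integrator oracles", {
  set.seed(404)
  times <- seq(0, 30, length.out = 50)
  for (i in 1:20) {
    sys <- random_open_system(4)
    tc <- solve_tracer(sys, times = times)
    A <- ridsim:::augmented_matrix(sys)$A
    q0 <- c(1, rep(0, nrow(A) - 1))
    oracle <- t(vapply(times, function(tt) {
      as.numeric(Matrix::expm(A * tt) %*% q0)
    }, numeric(nrow(A))))
    expect_lt(max(abs(cbind(tc$q, tc$cumulative_loss) - oracle)), 1e-8)
  }

  # independent integration route (different algorithm family)
  sys <- random_open_system(5)
  tc <- solve_tracer(sys, times = 0:30)
  A <- state_matrix(sys)
  ode <- deSolve::lsoda(
    y = c(1, rep(0, 4)), times = 0:30,
    func = function(t, y, p) list(A %*% y),
    rtol = 1e-11, atol = 1e-12)
  expect_lt(max(abs(tc$q - ode[, -1])), 1e-7)
})

test_that("solver validates the time grid", {
  sys <- one_comp()
  expect_error(solve_tracer(sys, times = c(1, 2)), "start at 0")
  expect_error(solve_tracer(sys, times = c(0, 2, 1)), "increasing")
})

test_that("steady state solves hand-checkable balances and anchors exactly", {
  st <- steady_state_masses(one_comp(0.5), intake = 1)
  expect_equal(unname(st$masses), 2)

  # chain: m1 = U/k12, m2 = U/k02
  st2 <- steady_state_masses(two_comp_chain(0.5, 0.25), intake = 2)
  expect_equal(unname(st2$masses), c(4, 8), tolerance = 1e-12)

  sub <- fixed_subject()
  st3 <- steady_state_masses(sub$system, M5 = 2)
  expect_identical(unname(st3$masses[5]), 2)

  # per-compartment balance residual: influx equals efflux
  A <- state_matrix(sub$system)
  u <- numeric(8); u[1] <- sub$system$absorption_fraction * st3$intake
  resid <- A %*% st3$masses + u
  expect_lt(max(abs(resid)) / max(st3$masses), 1e-9)
})

test_that("steady-state masses scale linearly with intake", {
  sys <- fixed_subject()$system
  a <- steady_state_masses(sys, intake = 1)
  b <- steady_state_masses(sys, intake = 2)
  expect_equal(b$masses, 2 * a$masses, tolerance = 1e-12)
})

test_that("assigned TBS sums the two storage compartments", {
  sub <- fixed_subject()
  st <- steady_state_masses(sub$system, M5 = sub$M5)
  expect_equal(assigned_tbs(st, sub$system),
               sum(st$masses[c(6, 7)]))

  # storage that receives nothing ends with zero mass and zero TBS
  tr <- matrix(0, 3, 3)
  sys0 <- compartmental_system(tr, loss = c(0.2, 0.1, 0.1),
                               dosing = 1, storage = c(2, 3))
  st0 <- steady_state_masses(sys0, intake = 1)
  expect_equal(assigned_tbs(st0, sys0), 0)
})

test_that("mass balance holds and the delay chain conserves and lags the dose", {
  sub <- fixed_subject()
  tc <- solve_tracer(sub$system, times = 0:30)
  expect_lt(mass_balance(tc), 1e-6)

  nodelay <- fixed_subject(delay = FALSE)
  early <- c(0, 0.05, 0.1)
  tcd <- solve_tracer(sub$system, times = early)
  tc0 <- solve_tracer(nodelay$system, times = early)
  # the absorptive lag holds tracer back from plasma at early times
  expect_lt(tcd$q[2, 5], tc0$q[2, 5])
  expect_lt(mass_balance(tcd), 1e-6)
  expect_lt(mass_balance(tc0), 1e-6)
})

test_that("tracer washes out completely in the long run", {
  set.seed(77)
  for (i in 1:5) {
    sys <- random_open_system(4)
    tc <- solve_tracer(sys, times = c(0, 1000))
    expect_lt(max(abs(tc$q[2, ])), 1e-4)
    expect_equal(tc$cumulative_loss[2], 1, tolerance = 1e-4)
  }
})

test_that("tidy export reshapes the time course", {
  tc <- solve_tracer(two_comp_chain(), times = 0:3)
  td <- as_tidy_timecourse(tc, subject_id = "s1")
  expect_equal(nrow(td), 8L)
  expect_named(td, c("subject_id", "day", "compartment", "fraction_of_dose"))
  expect_equal(td$fraction_of_dose[td$day == 0 & td$compartment == 1], 1)
})
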