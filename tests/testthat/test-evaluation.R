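test_that("the wrapped angular error handles wrap-around and extremes", {
  expect_equal(angular_error(123, 123), 0)
  expect_equal(angular_error(10, 350), 20)
  expect_equal(angular_error(0, 180), 180)
  expect_equal(angular_error(-10, 10), 20)
  expect_true(all(angular_error(runif(50, 0, 720), runif(50, -360, 360)) <=
                    180))
})

test_that("the default protocol enumerates 17 tilt poses", {
  pr <- eval_protocol()
  expect_equal(nrow(pr$tilts), 17)
  expect_equal(sum(pr$tilts$delta == 0), 1)
  expect_equal(sum(pr$tilts$delta == 30), 8)
  expect_equal(sum(pr$tilts$delta == 60), 8)
  expect_equal(nrow(pr$tilts) * pr$n_sun, 8500)
})

test_that("the objective run is reproducible and reports correct errors", {
  arr <- build_dra()
  cmp <- build_compass()
  pr <- eval_protocol(n_sun = 30, seed = 9)
  r1 <- run_objective(cmp, arr, pr)
  r2 <- run_objective(cmp, arr, pr)
  expect_identical(r1$records, r2$records)
  expect_equal(r1$n, 17 * 30)
  expect_equal(r1$J, mean(r1$records$error))
  expect_equal(r1$se, sd(r1$records$error) / sqrt(nrow(r1$records)))
  expect_true(all(r1$by_delta$n == c(30, 240, 240)))
  # a different seed gives different sun ensembles
  r3 <- run_objective(cmp, arr, eval_protocol(n_sun = 30, seed = 10))
  expect_false(isTRUE(all.equal(r1$J, r3$J)))
})

test_that("gating reduces the tilted error at every tilt level", {
  arr <- build_dra()
  pr <- eval_protocol(n_sun = 60, seed = 4)
  rg <- run_objective(build_compass(gating = TRUE), arr, pr,
                      keep_records = FALSE)
  rn <- run_objective(build_compass(gating = FALSE), arr, pr,
                      keep_records = FALSE)
  for (d in c(0, 30, 60)) {
    expect_lt(rg$by_delta$J[rg$by_delta$delta == d],
              rn$by_delta$J[rn$by_delta$delta == d])
  }
})

test_that("the disturbance curve is monotone in error and confidence", {
  arr <- build_dra()
  cmp <- build_compass()
  dc <- disturbance_curve(cmp, arr, etas = c(0, 0.5, 0.97), n_sun = 60,
                          n_seeds = 5, seed = 2)
  expect_equal(nrow(dc), 3)
  expect_true(all(diff(dc$J) > 0))
  expect_true(all(diff(dc$tau_mean) < 0))
  expect_true(all(diff(dc$sigma_median) > 0))
  # the clean entry agrees with the untilted objective scale
  expect_lt(dc$J[1], 1)
})

test_that("a single-cell gating grid is its own argmin", {
  arr <- build_dra()
  sw <- sweep_gating(arr, theta_g_grid = 40, sigma_g_grid = 13,
                     protocol = eval_protocol(n_sun = 20, seed = 3))
  expect_equal(nrow(sw$grid), 1)
  expect_equal(sw$argmin$theta_g, 40)
  expect_equal(sw$argmin$sigma_g, 13)
  expect_true(sw$argmin$J >= 0)
})

test_that("the layout sweep evaluates each cell with its own sensor", {
  sw <- sweep_layout(n_grid = c(12, 60), omega_grid = 56,
                     protocol = eval_protocol(n_sun = 25, seed = 6))
  expect_equal(nrow(sw), 2)
  expect_true(all(sw$J >= 0))
  # few units decode markedly worse than the reference design
  expect_gt(sw$J[sw$n == 12], sw$J[sw$n == 60])
})

test_that("the decoded error is invariant to the population sizes", {
  # each solar-layer neuron carries a pure first harmonic, so any
  # population of >= 3 neurons transmits the full fundamental: the decoded
  # angle (and hence J) is exactly independent of n_SOL and n_TCL
  sw <- sweep_populations(nsol_grid = c(4, 8, 16), ntcl_grid = 8,
                          protocol = eval_protocol(n_sun = 40, seed = 5))
  expect_equal(sw$J[sw$n_sol == 4], sw$J[sw$n_sol == 8], tolerance = 1e-9)
  expect_equal(sw$J[sw$n_sol == 16], sw$J[sw$n_sol == 8], tolerance = 1e-9)
  swt <- sweep_populations(nsol_grid = 8, ntcl_grid = c(4, 8, 16),
                           protocol = eval_protocol(n_sun = 40, seed = 5))
  expect_equal(max(swt$J) - min(swt$J), 0, tolerance = 1e-9)
})
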