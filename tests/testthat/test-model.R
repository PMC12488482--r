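params <- kinetic_parameters()

test_that("default constructors return the published constants and state", {
  expect_equal(unclass(params)[c("k1", "n1", "tau_mtor", "k4", "n4",
                                 "k6", "n6", "tau_geminin")],
               list(k1 = 0.2, n1 = 1, tau_mtor = 0.5, k4 = 0.2, n4 = 2,
                    k6 = 0.4, n6 = 3, tau_geminin = 0.3))
  expect_equal(unname(unclass(initial_state())), c(0, 0, 0, 1, 0))
  expect_error(kinetic_parameters(tau_apc = -1), "tau_apc")
  expect_error(iffl_state(apc = 1.5), "\\[0, 1\\]")
})

test_that("rates at the quiescent state match direct substitution", {
  d0 <- iffl_derivatives(initial_state(), 0, params, stimulus_protocol())
  expect_equal(unname(d0),
               c((3 / 3.2) / 0.5, 0, 0, 0, (0.064 / 1.064) / 0.3))
  # no mitogens: everything upstream is at its fixed point
  dq <- iffl_derivatives(initial_state(), 0, params,
                         stimulus_protocol(mitogen_level = 0))
  expect_equal(unname(dq[1:4]), rep(0, 4))
  expect_equal(unname(dq[5]), (0.064 / 1.064) / 0.3)
  expect_error(iffl_derivatives(initial_state(), -1, params,
                                stimulus_protocol()), "non-negative")
})

test_that("analytic fixed points agree with substitution and long runs", {
  # forward-substitution values, frozen from hand computation
  ss0 <- iffl_steady_state(params, S = 0, pp_active = FALSE)
  expect_equal(unname(unclass(ss0)), c(0, 0, 0, 1, 0.064 / 1.064))
  ss3f <- iffl_steady_state(params, S = 3, pp_active = FALSE)
  expect_equal(ss3f[["pcdh1"]], 0.9375 / 1.2375)
  expect_equal(ss3f[["apc"]], 0.8 / (0.8 + 0.9375 / 1.2375))
  expect_equal(ss3f[["geminin"]], 0.3208, tolerance = 1e-4)
  ss3t <- iffl_steady_state(params, S = 3, pp_active = TRUE)
  expect_equal(ss3t[["pcdh1"]], 0.0330, tolerance = 1e-2)
  expect_equal(ss3t[["apc"]], 0.9604, tolerance = 1e-4)
  expect_equal(ss3t[["geminin"]], 0.0674, tolerance = 1e-3)

  # derivatives vanish at every fixed point
  for (S in c(0, 0.5, 3)) {
    for (pp in c(TRUE, FALSE)) {
      ss <- iffl_steady_state(params, S = S, pp_active = pp)
      pro <- stimulus_protocol(
        mitogen_level = S, pp_onset_time = 0,
        phosphatase_inhibitor_time = if (pp) NULL else 0)
      expect_lt(max(abs(iffl_derivatives(ss, 1, params, pro))), 1e-12)
    }
  }
})

test_that("a simulation started at a steady state stays there", {
  ss <- iffl_steady_state(params, S = 3, pp_active = TRUE)
  pro <- stimulus_protocol(pp_onset_time = 0)
  traj <- iffl_simulate(params, pro, initial = ss, t_end = 12)
  dev <- max(abs(as.matrix(traj$state) -
                   matrix(unclass(ss), nrow = length(traj$times),
                          ncol = 5, byrow = TRUE)))
  expect_lt(dev, 1e-6)
})

test_that("without mitogens the substrate follows its closed form", {
  pro <- stimulus_protocol(mitogen_level = 0)
  traj <- iffl_simulate(params, pro, t_end = 12, output_dt = 0.1)
  expect_equal(max(abs(traj$state$mtor)), 0)
  expect_equal(max(abs(traj$state$pp)), 0)
  expect_equal(max(abs(traj$state$pcdh1)), 0)
  expect_equal(traj$state$apc, rep(1, length(traj$times)))
  closed <- (0.064 / 1.064) * (1 - exp(-traj$times / 0.3))
  expect_equal(traj$state$geminin, closed, tolerance = 1e-7)
})

test_that("adaptive solver agrees with the fixed-step reference (control)", {
  traj <- iffl_simulate(params, stimulus_protocol(), t_end = 12,
                        output_dt = 0.05)
  ref <- ref_simulate(t_end = 12, dt = 1e-3)
  expect_lt(max(abs(as.matrix(traj$state) - ref)), 1e-6)
})

test_that("state stays in the unit hypercube for all scenarios", {
  for (pro in scenario_matrix()) {
    traj <- iffl_simulate(params, pro, t_end = 12, output_dt = 0.1)
    m <- as.matrix(traj$state)
    expect_true(all(m >= -1e-7 & m <= 1 + 1e-7))
  }
})

test_that("the loop produces an APC/C dip and a substrate pulse", {
  traj <- iffl_simulate(params, stimulus_protocol(), t_end = 12,
                        output_dt = 0.05)
  dip <- pulse_metrics(traj, "apc", "minimum")
  expect_true(dip$has_interior_extremum)
  expect_gt(dip$extremum_time, 0)
  expect_lt(dip$extremum_time, 8)
  expect_lte(dip$extremum_value, dip$baseline)
  expect_lte(dip$extremum_value, dip$recovery_value)
  pulse <- pulse_metrics(traj, "geminin", "maximum")
  expect_true(pulse$has_interior_extremum)
  expect_gt(pulse$extremum_time, 4)
  expect_lt(pulse$extremum_time, 6)
})

test_that("pulse metrics handle monotone and triangular series", {
  mono <- structure(list(times = 0:5, state = data.frame(apc = 0:5 / 5)),
                    class = "iffl_trajectory")
  expect_false(pulse_metrics(mono, "apc", "maximum")$has_interior_extremum)
  tri <- structure(list(times = 0:2, state = data.frame(apc = c(0, 1, 0))),
                   class = "iffl_trajectory")
  pm <- pulse_metrics(tri, "apc", "maximum")
  expect_equal(pm$extremum_value, 1)
  expect_equal(pm$extremum_time, 1)
  expect_error(pulse_metrics(tri, "nope"), "unknown")
})

test_that("control and phosphatase-inhibitor runs coincide before PP onset", {
  ctrl <- iffl_simulate(params, stimulus_protocol(), t_end = 12,
                        output_dt = 0.05)
  ppi <- iffl_simulate(params,
                       stimulus_protocol(phosphatase_inhibitor_time = 0),
                       t_end = 12, output_dt = 0.05)
  pre <- ctrl$times <= 4
  expect_lt(max(abs(as.matrix(ctrl$state)[pre, ] -
                      as.matrix(ppi$state)[pre, ])), 1e-7)
})

test_that("rapamycin timing shapes the dip as in the addition-time series", {
  depth <- function(rt) {
    pro <- if (is.finite(rt)) stimulus_protocol(rapamycin_time = rt) else
      stimulus_protocol()
    1 - min(iffl_simulate(params, pro, t_end = 12,
                          output_dt = 0.05)$state$apc)
  }
  depths <- vapply(c(0, 0.5, 1, 2, 4), depth, numeric(1))
  expect_true(all(diff(depths) >= 0))
  expect_lt(depths[1], 1e-6)  # rapamycin at stimulation: APC/C never dips
  d_ctrl <- depth(Inf)
  expect_gte(depths[4], 0.9 * d_ctrl)
  expect_gte(depths[5], 0.9 * d_ctrl)
})

test_that("tidy trajectory export is long-format and faithful", {
  traj <- iffl_simulate(params, stimulus_protocol(), t_end = 2,
                        output_dt = 0.5)
  td <- as.data.frame(traj)
  expect_equal(names(td), c("time_h", "variable", "value"))
  expect_equal(nrow(td), 5 * length(traj$times))
  expect_equal(td$value[td$variable == "apc"], traj$state$apc)
})
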