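test_that("reporter mechanics reproduce linear-ODE closed forms", {
  tt <- seq(0, 10, by = 0.2)
  # no degradation: pure synthesis
  g <- reporter_from_apc(tt, rep(0, length(tt)),
                         reporter_parameters(initial_level = 0))
  expect_equal(g, tt)
  # full APC/C activity: saturating exponential
  g <- reporter_from_apc(tt, rep(1, length(tt)),
                         reporter_parameters(initial_level = 0))
  expect_equal(g, 1 - exp(-tt), tolerance = 1e-12)
  # quasi-steady start stays put
  g <- reporter_from_apc(tt, rep(1, length(tt)), reporter_parameters())
  expect_equal(g, rep(1, length(tt)))
})

test_that("after MG132 the reporter accumulates at the synthesis rate", {
  tt <- seq(0, 12, by = 0.2)
  traj <- iffl_simulate(t_end = 12, output_dt = 0.2)
  rp <- reporter_parameters(synthesis_rate = 1.7, mg132_time = 5)
  g <- reporter_from_apc(tt, traj$state$apc, rp)
  post <- tt >= 5
  slopes <- diff(g[post]) / diff(tt[post])
  expect_equal(slopes, rep(1.7, sum(post) - 1L))
  # MG132 inside a grid interval is split exactly
  rp_mid <- reporter_parameters(synthesis_rate = 1.7, mg132_time = 5.1)
  g_mid <- reporter_from_apc(tt, traj$state$apc, rp_mid)
  after <- tt >= 5.2
  expect_equal(diff(g_mid[after]) / diff(tt[after]),
               rep(1.7, sum(after) - 1L))
})

test_that("degenerate randomness gives identical cells equal to the model", {
  cfg <- population_config(n_cells = 3, parameter_cv = 0, noise_sd = 0,
                           duration = 12, seed = 1)
  tab <- generate_population(cfg = cfg)
  traj <- iffl_simulate(t_end = 12, output_dt = 0.2)
  expect_equal(nrow(tab), 3 * length(traj$times))
  for (id in unique(tab$cell_id)) {
    expect_equal(tab$value[tab$cell_id == id], traj$state$geminin)
  }
  # pointwise low-median of identical traces is the deterministic trace
  med <- median_trace(tab)
  expect_equal(med$value, traj$state$geminin)
})

test_that("grid arithmetic: n_cells x samples records", {
  cfg <- population_config(n_cells = 3, duration = 24,
                           sampling_interval = 0.2, seed = 2)
  tab <- generate_population(cfg = cfg)
  expect_equal(nrow(tab), 3 * 121)
  expect_equal(sort(unique(tab$time_h)), seq(0, 24, by = 0.2))
})

test_that("per-cell lognormal scalings have unit mean at the configured CV", {
  cfg <- population_config(n_cells = 1000, parameter_cv = 0.2, noise_sd = 0,
                           duration = 2, sampling_interval = 0.5, seed = 3,
                           generator_mode = "reporter_mechanics")
  tab <- generate_population(cfg = cfg)
  sc <- cell_info(tab)$synthesis_scale
  se <- 0.2 / sqrt(1000)
  expect_lt(abs(mean(sc) - 1), 3 * se)
  expect_lt(abs(sd(sc) / mean(sc) - 0.2), 0.03)
})

test_that("equal (config, seed) reproduces the table; prefixes are stable", {
  cfg <- population_config(n_cells = 10, seed = 99, duration = 6)
  a <- generate_population(cfg = cfg)
  b <- generate_population(cfg = cfg)
  expect_identical(a, b)
  # growing the population does not reshuffle earlier cells
  cfg_big <- population_config(n_cells = 20, seed = 99, duration = 6)
  big <- generate_population(cfg = cfg_big)
  expect_equal(big$value[big$cell_id %in% unique(a$cell_id)], a$value)
})

test_that("MG132 is rejected in model_direct mode", {
  cfg <- population_config(n_cells = 2, duration = 6)
  expect_error(generate_population(rp = reporter_parameters(mg132_time = 5),
                                   cfg = cfg),
               "reporter_mechanics")
})

test_that("post-MG132 slope recovers each cell's synthesis rate", {
  cfg <- population_config(n_cells = 30, parameter_cv = 0.15, noise_sd = 0,
                           duration = 12, seed = 4,
                           generator_mode = "reporter_mechanics")
  tab <- generate_population(rp = reporter_parameters(mg132_time = 5),
                             cfg = cfg)
  info <- cell_info(tab)
  for (i in seq_len(nrow(info))) {
    cell <- tab[tab$cell_id == info$cell_id[i], ]
    fit <- fit_slope(cell$time_h, cell$value, c(5.5, 7.5))
    expect_equal(fit$slope, info$synthesis_scale[i], tolerance = 0.01)
  }
})

test_that("multiplicative noise is seeded, unbiased and truncated", {
  v <- rep(1, 1e5)
  expect_identical(add_noise(v, 0), v)
  n1 <- add_noise(v, 0.05, seed = 5)
  n2 <- add_noise(v, 0.05, seed = 5)
  expect_identical(n1, n2)
  expect_lt(abs(mean(n1) - 1), 3 * 0.05 / sqrt(1e5))
  expect_true(all(add_noise(rep(0.01, 1000), 5, seed = 6) >= 0))
})

test_that("CDK2 generator honours truth labels and ramp shape", {
  cfg <- population_config(n_cells = 20, noise_sd = 0, duration = 24, seed = 7)
  quiet <- generate_cdk2_population(
    cdk2_parameters(fraction_cycling_true = 0), cfg)
  expect_true(all(quiet$value == 0.5))
  expect_true(all(cell_info(quiet)$true_class == "quiescent"))
  cyc <- generate_cdk2_population(
    cdk2_parameters(fraction_cycling_true = 1), cfg)
  finals <- tapply(cyc$value, cyc$cell_id, function(v) v[length(v)])
  expect_true(all(finals >= 0.99 * 1.5))
  expect_true(all(cell_info(cyc)$true_class == "cycling"))
})

test_that("cycling label counts follow the configured mixture", {
  cfg <- population_config(n_cells = 500, duration = 2,
                           sampling_interval = 0.5, seed = 8)
  tab <- generate_cdk2_population(
    cdk2_parameters(fraction_cycling_true = 0.7), cfg)
  n_cyc <- sum(cell_info(tab)$true_class == "cycling")
  expect_lt(abs(n_cyc - 350), 3 * sqrt(500 * 0.7 * 0.3))
})
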