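test_that("generation is bit-reproducible and validates its configuration", {
  cfg <- simulation_config(seed = 5)
  a <- simulate_instrument_set(cfg)
  b <- simulate_instrument_set(cfg)
  expect_identical(a$instruments, b$instruments)
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  expect_false(identical(
    simulate_instrument_set(simulation_config(seed = 6))$instruments,
    a$instruments))
  expect_error(simulation_config(n_instruments = 1), "at least 2")
  expect_error(simulation_config(se_y = -1), "scales")
  expect_error(simulation_config(n_outliers = 20, n_instruments = 5),
               "n_outliers")
  expect_error(simulation_config(beta_x_range = c(0.2, 0.1)), "beta_x_range")
})

test_that("the noise-free limit returns every Wald ratio at the true effect", {
  cfg <- simulation_config(n_instruments = 8, true_theta = 0.4,
                           se_x = 1e-12, se_y = 1e-12, seed = 2)
  s <- simulate_instrument_set(cfg)
  expect_equal(wald_ratio(s)$estimate, rep(0.4, 8), tolerance = 1e-6)
})

test_that("simulated F statistics span the strength range of real instrument sets", {
  f <- vapply(1:20, function(seed) {
    range(simulate_instrument_set(simulation_config(seed = seed))$instruments$f_statistic)
  }, numeric(2))
  expect_lt(min(f), 60)     # weak end comparable to the fixture's ~32
  expect_gt(max(f), 250)    # strong end comparable to the fixture's ~511
})

test_that("balanced pleiotropy leaves the IVW estimate unbiased at theta = 0", {
  reps <- 500
  ests <- vapply(seq_len(reps), function(r) {
    cfg <- simulation_config(n_instruments = 14, true_theta = 0,
                             pleiotropy_mode = "balanced",
                             pleiotropy_scale = 0.02, seed = 5000 + r)
    mr_ivw(simulate_instrument_set(cfg), model = "fixed")$estimate
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(reps)
  expect_lt(abs(mean(ests)), 3.5 * mc_se + 1e-12)
})

test_that("directional pleiotropy surfaces as the Egger intercept", {
  reps <- 300
  target <- 0.03
  intercepts <- vapply(seq_len(reps), function(r) {
    cfg <- simulation_config(n_instruments = 14, true_theta = 0.2,
                             pleiotropy_mode = "directional",
                             directional_mean = target,
                             pleiotropy_scale = 0.01, seed = 9000 + r)
    mr_egger(simulate_instrument_set(cfg))$intercept$estimate
  }, numeric(1))
  mc_se <- sd(intercepts) / sqrt(reps)
  expect_lt(abs(mean(intercepts) - target), 3.5 * mc_se)
})

test_that("the weighted median resists minority directional pleiotropy better than IVW", {
  reps <- 60
  bias <- vapply(seq_len(reps), function(r) {
    s <- random_set(J = 50, theta = 0.2, seed = 40000 + r)
    d <- s$instruments
    invalid <- seq_len(20)  # 40% of instruments gain a positive direct effect
    d$beta_outcome[invalid] <- d$beta_outcome[invalid] + 0.03
    c(ivw = mr_ivw(d, model = "fixed")$estimate - 0.2,
      wm = mr_weighted_median(d, n_boot = 1)$estimate - 0.2)
  }, numeric(2))
  expect_lt(abs(mean(bias["wm", ])), abs(mean(bias["ivw", ])))
})

test_that("study trios share one exposure draw and honour availability masks", {
  cfg <- simulation_config(n_instruments = 14, true_theta = 0.1, seed = 77)
  trio <- replicate_study_trio(cfg, studies = list(
    a = list(), b = list(se_y = 0.02),
    c = list(drop = c("sim001", "sim002", "sim003"))))
  expect_named(trio, c("a", "b", "c"))
  expect_equal(length(trio$c), 11)
  expect_identical(trio$a$instruments$beta_exposure,
                   trio$b$instruments$beta_exposure)
  expect_false(identical(trio$a$instruments$beta_outcome[4:14],
                         trio$c$instruments$beta_outcome[1:11]))
  expect_identical(attr(trio$a, "truth"), attr(trio$c, "truth"))
  # all-true masks give three sets with identical variant ids
  full <- replicate_study_trio(cfg, studies = list(a = list(), b = list(),
                                                   c = list()))
  expect_identical(full$a$instruments$variant_id,
                   full$c$instruments$variant_id)
  expect_error(replicate_study_trio(cfg, studies = list(a = list(drop = 99))),
               "invalid availability mask")
})

test_that("a null trio pooled by fixed-effect meta rejects at the nominal rate", {
  reps <- 200
  rejections <- 0
  for (r in seq_len(reps)) {
    cfg <- simulation_config(n_instruments = 12, true_theta = 0,
                             seed = 60000 + r)
    trio <- replicate_study_trio(cfg, studies = list(
      a = list(), b = list(se_y = 0.05), c = list(drop = 1:3)))
    ests <- lapply(trio, mr_ivw)
    rejections <- rejections + (meta_fixed(ests)$p_value < 0.05)
  }
  bounds <- binom_bounds(0.05, reps)
  expect_gte(rejections / reps, bounds[1])
  expect_lte(rejections / reps, bounds[2])
})

test_that("simulated sets round-trip through the delimited format", {
  s <- simulate_instrument_set(simulation_config(seed = 123))
  ex_path <- tempfile(fileext = ".tsv")
  ou_path <- tempfile(fileext = ".tsv")
  write_summary_stats(s, ex_path, ou_path)
  cmap <- c(variant_id = "variant_id", effect_allele = "effect_allele",
            beta = "beta", se = "se", p_value = "p_value")
  back <- harmonize(read_summary_stats(ex_path, cmap),
                    read_summary_stats(ou_path, cmap))
  expect_equal(back$instruments$beta_exposure, s$instruments$beta_exposure,
               tolerance = 1e-12)
  expect_equal(back$instruments$beta_outcome, s$instruments$beta_outcome,
               tolerance = 1e-12)
})

test_that("IVW coverage of the true effect is nominal without pleiotropy", {
  reps <- 500
  covered <- 0
  for (r in seq_len(reps)) {
    cfg <- simulation_config(n_instruments = 14, true_theta = 0.25,
                             seed = 70000 + r)
    est <- mr_ivw(simulate_instrument_set(cfg))
    covered <- covered + (est$ci_low <= 0.25 && 0.25 <= est$ci_high)
  }
  bounds <- binom_bounds(0.95, reps)
  expect_gte(covered / reps, bounds[1])
  expect_lte(covered / reps, bounds[2])
})
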