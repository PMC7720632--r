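test_that("clone allocation is feasible, bounded 1..9 and reproducible", {
  cc <- allocate_clones(158, 371, rng_seed = 4)
  expect_length(cc, 158)
  expect_equal(sum(cc), 371)
  expect_true(all(cc >= 1 & cc <= 9))
  expect_identical(cc, allocate_clones(158, 371, rng_seed = 4))
  expect_error(allocate_clones(10, 5), "infeasible")
  expect_error(allocate_clones(10, 91), "infeasible")
})

test_that("default cohort has the study's shape: 371 analytes x 3 replicates, n patients", {
  coh <- generate_cohort(simulation_config(n_patients = 10, rng_seed = 2))
  expect_equal(length(unique(coh$spots$analyte_id)), 371)
  expect_equal(nrow(coh$spots), 10 * 371 * 3)
  expect_equal(nrow(coh$clinical), 10)
  expect_equal(length(unique(coh$annotation$protein_id)), 158)
  expect_equal(sort(unique(coh$spots$replicate)), 1:3)
  expect_length(coh$truth$signature_protein_ids, 11)
  # batch layout needs enough slides (7 patients each) for 3 scan days
  coh21 <- generate_cohort(simulation_config(n_patients = 21, rng_seed = 2))
  expect_equal(length(unique(coh21$spots$scan_batch)), 3)
  expect_equal(length(unique(coh21$spots$slide_batch)), 2)
  # pfs never exceeds os
  expect_true(all(coh$clinical$pfs_months <= coh$clinical$os_months + 1e-9))
})

test_that("generation is deterministic given the seed", {
  cfg <- small_sim(77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$spots, b$spots)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(small_sim(78))
  expect_false(identical(a$spots$fg, c$spots$fg))
})

test_that("null configuration plants nothing and the screen stays at its nominal level", {
  cfg <- simulation_config(n_patients = 100, signature_log_hr_per_sd = 0,
                           rng_seed = 5)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$truth$true_log_hr == 0))
  prep <- preprocess_cohort(coh$spots)
  sv <- surv_data(coh$clinical$os_months, coh$clinical$os_event)
  scr <- suppressWarnings(cox_screen(prep$x, sv))
  # one seed: pass count within a generous binomial band around 371 * 0.05
  expect_lt(sum(scr$pass), 40)
})

test_that("exponential generator has the right mean and degenerate horizon", {
  cfg <- simulation_config(n_patients = 10, baseline_hazard = 0.2,
                           censoring_rate = 0, follow_up_months = 1e6,
                           rng_seed = 1)
  res <- withr::with_seed(8, simulate_survival(rep(0, 20000), cfg))
  expect_true(all(res$event == 1))
  expect_equal(mean(res$time), 5, tolerance = 0.1)
  cfg0 <- simulation_config(n_patients = 10, follow_up_months = 0, rng_seed = 1)
  res0 <- withr::with_seed(8, simulate_survival(rep(0, 10), cfg0))
  expect_true(all(res0$event == 0))
  expect_true(all(res0$time == 0))
})

test_that("a planted log(2) group effect is recovered by Cox at large n", {
  cfg <- simulation_config(n_patients = 10, baseline_hazard = 0.05,
                           censoring_rate = 0.2, follow_up_months = 120,
                           rng_seed = 1)
  res <- withr::with_seed(31, {
    lp <- rep(c(0, log(2)), each = 2500)
    simulate_survival(lp, cfg)
  })
  fit <- survival::coxph(survival::Surv(res$time, res$event) ~
                           rep(c(0, 1), each = 2500))
  expect_equal(exp(unname(fit$coefficients)), 2, tolerance = 0.1)
})

test_that("single planted effect is recovered from the noiseless latent level", {
  cfg <- simulation_config(n_patients = 1000, n_signature_proteins = 1,
                           signature_log_hr_per_sd = -1, mipi_effect = 0,
                           ki67_effect = 0, censoring_rate = 0.2,
                           rng_seed = 19)
  coh <- generate_cohort(cfg)
  z <- coh$truth$latent_z[, coh$truth$signature_protein_ids]
  fit <- survival::coxph(survival::Surv(coh$clinical$os_months,
                                        coh$clinical$os_event) ~ z)
  expect_equal(unname(fit$coefficients), -1, tolerance = 0.1)
  # oracle cross-check: independent Newton partial-likelihood fit
  # (Breslow ties on both sides; clinical months are rounded to 3 dp)
  fitb <- survival::coxph(survival::Surv(coh$clinical$os_months,
                                         coh$clinical$os_event) ~ z,
                          ties = "breslow")
  expect_equal(cox_newton_oracle(z, coh$clinical$os_months,
                                 coh$clinical$os_event),
               unname(fitb$coefficients), tolerance = 1e-6)
})

test_that("realized censoring tracks the requested rate", {
  # calibration of the censoring mechanism itself: homogeneous hazards so
  # the administrative floor does not bind at low targets
  for (target in c(0.2, 0.4, 0.6)) {
    cfg <- simulation_config(n_patients = 1000, censoring_rate = target,
                             signature_log_hr_per_sd = 0, mipi_effect = 0,
                             ki67_effect = 0, rng_seed = 3)
    coh <- generate_cohort(cfg)
    expect_lt(abs((1 - mean(coh$clinical$os_event)) - target), 0.05)
  }
  # heterogeneous default cohort still lands near its default target
  coh_d <- generate_cohort(simulation_config(n_patients = 1000, rng_seed = 4))
  expect_lt(abs((1 - mean(coh_d$clinical$os_event)) - 0.4), 0.07)
})

test_that("replicate emission hits the target CV and supports degenerate settings", {
  cfg0 <- simulation_config(n_patients = 4, replicate_cv = 0,
                            outlier_spot_rate = 0, rng_seed = 1)
  reps <- withr::with_seed(1, emit_spot_replicates(c(100, 500), cfg0))
  expect_equal(reps[, 1], reps[, 2])
  expect_equal(reps[, 2], reps[, 3])

  cfg <- simulation_config(n_patients = 4, replicate_cv = 0.05,
                           outlier_spot_rate = 0, rng_seed = 1)
  reps <- withr::with_seed(2, emit_spot_replicates(rep(1000, 1e4), cfg))
  cvs <- apply(reps, 1, sd) / rowMeans(reps)
  expect_equal(mean(cvs), 0.05, tolerance = 0.005)

  cfg1 <- simulation_config(n_patients = 4, replicate_cv = 0.05,
                            outlier_spot_rate = 1, rng_seed = 1)
  reps1 <- withr::with_seed(3, emit_spot_replicates(rep(1000, 500), cfg1))
  cv1 <- apply(reps1, 1, sd) / rowMeans(reps1)
  expect_true(all(cv1 > 0.15)) # every triplet trips the elimination rule
})

test_that("infeasible or invalid configurations are rejected", {
  expect_error(simulation_config(n_clones = 2000), "infeasible")
  expect_error(simulation_config(signature_log_hr_per_sd = 0.5), "protective")
  expect_error(simulation_config(censoring_rate = 1.2))
  expect_error(simulation_config(baseline_hazard = 0), "positive")
})
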