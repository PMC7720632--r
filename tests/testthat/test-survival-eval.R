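test_that("KM estimate handles degenerate and simple cases", {
  all_cens <- surv_data(c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_equal(nrow(km_estimate(all_cens)[km_estimate(all_cens)$n_event > 0, ]), 0)
  one_death <- surv_data(c(2, 3, 4, 5), c(1, 0, 0, 0))
  km <- km_estimate(one_death)
  expect_equal(km$surv[km$time == 2], 0.75)
})

test_that("KM curve matches step-by-step risk-set recomputation to 1e-12", {
  for (seed in 1:5) {
    sv <- exp_surv(30, seed)
    km <- km_estimate(sv)
    orc <- km_oracle(sv$time, sv$event)
    got <- km$surv[km$n_event > 0]
    expect_equal(got, orc$surv, tolerance = 1e-12)
    # closed form at the last event time
    expect_equal(got[length(got)],
                 prod(1 - orc$time |> sapply(function(t)
                   sum(sv$time == t & sv$event == 1) / sum(sv$time >= t))),
                 tolerance = 1e-12)
    # probabilities non-increasing from 1
    expect_true(all(diff(c(1, km$surv)) <= 1e-15))
  }
})

test_that("log-rank agrees with survdiff and is invariant to relabeling and monotone time transforms", {
  for (seed in 1:10) {
    sv <- exp_surv(60, seed)
    g <- withr::with_seed(seed + 100, sample(1:3, 60, replace = TRUE))
    lt <- logrank_test(g, sv)
    sd_ <- survival::survdiff(survival::Surv(sv$time, sv$event) ~ g)
    expect_equal(lt$chi2, sd_$chisq, tolerance = 1e-8)
    expect_equal(lt$df, 2L)
    # relabel groups
    relab <- c(2L, 3L, 1L)[g]
    expect_equal(logrank_test(relab, sv)$chi2, lt$chi2, tolerance = 1e-12)
    # common monotone time transform
    sv2 <- surv_data(log1p(sv$time), sv$event)
    expect_equal(logrank_test(g, sv2)$chi2, lt$chi2, tolerance = 1e-12)
  }
})

test_that("log-rank is exactly balanced on duplicated groups", {
  sv0 <- exp_surv(40, 3)
  sv3 <- surv_data(rep(sv0$time, 3), rep(sv0$event, 3))
  g <- rep(1:3, each = 40)
  expect_lt(logrank_test(g, sv3)$chi2, 1e-10)
})

test_that("log-rank type-I error is calibrated at the 5% level", {
  n_sim <- 1000
  rej <- withr::with_seed(42, {
    mean(replicate(n_sim, {
      tt <- rexp(100, 0.1)
      cc <- rexp(100, 0.04)
      sv <- surv_data(pmin(tt, cc), as.integer(tt <= cc))
      logrank_test(rep(1:2, each = 50), sv)$p < 0.05
    }))
  })
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("log-rank has power against a 3-fold hazard ratio", {
  hits <- withr::with_seed(7, {
    mean(replicate(200, {
      t1 <- rexp(100, 0.05)
      t2 <- rexp(100, 0.15)
      sv <- surv_data(c(t1, t2), rep(1L, 200))
      logrank_test(rep(1:2, each = 100), sv)$p < 0.001
    }))
  })
  expect_gte(hits, 0.95)
})

test_that("Harrell's C: closed-form cases and sign symmetry", {
  t <- c(5, 3, 8, 1, 9, 2)
  sv <- surv_data(t, rep(1L, 6))
  expect_equal(harrell_c(-t, sv)$c, 1.0)
  expect_equal(harrell_c(rep(1, 6), sv)$c, 0.5)
  sc <- c(0.3, 2, -1, 0.5, 4, -2)
  expect_equal(harrell_c(sc, sv)$c, 1 - harrell_c(-sc, sv)$c)
})

test_that("Harrell's C equals brute-force pair enumeration exactly", {
  for (seed in 1:20) {
    n <- withr::with_seed(seed, sample(20:60, 1))
    sv <- exp_surv(n, seed + 300)
    sc <- withr::with_seed(seed + 600, round(rnorm(n), 1)) # induce ties
    got <- harrell_c(sc, sv)
    orc <- harrell_oracle(sc, sv$time, sv$event)
    expect_identical(got$n_concordant, orc$n_concordant)
    expect_identical(got$n_tied, orc$n_tied)
    expect_equal(got$c, orc$c)
  }
})

test_that("Harrell's C agrees with survival::concordance on tie-free data", {
  for (seed in 1:5) {
    sv <- exp_surv(50, seed)
    sc <- withr::with_seed(seed, rnorm(50))
    ref <- survival::concordance(survival::Surv(sv$time, sv$event) ~ sc,
                                 reverse = TRUE)
    expect_equal(harrell_c(sc, sv)$c, unname(ref$concordance),
                 tolerance = 1e-12)
  }
})

test_that("optimal cutpoints equal an independent brute-force double loop", {
  for (seed in 1:6) {
    sv <- exp_surv(60, seed + 40)
    sc <- withr::with_seed(seed, rnorm(60))
    got <- optimal_cutpoints(sc, sv)
    orc <- cutpoint_oracle(sc, sv$time, sv$event)
    expect_equal(got$cutpoints, c(orc$c1, orc$c2), tolerance = 1e-12)
    expect_equal(got$chi2, orc$chi2, tolerance = 1e-8)
  }
})

test_that("cutpoint stratification is invariant under monotone score transforms", {
  sv <- exp_surv(80, 9)
  sc <- withr::with_seed(9, rnorm(80))
  a <- optimal_cutpoints(sc, sv)
  b <- optimal_cutpoints(sc^3, sv)
  expect_identical(a$groups, b$groups)
  expect_equal(a$chi2, b$chi2, tolerance = 1e-10)
})

test_that("cutpoint search separates hazard clusters at least as well as the true boundaries", {
  ok_chi <- 0
  ok_ord <- 0
  for (seed in 1:10) {
    res <- withr::with_seed(seed, {
      n <- 120
      sc <- c(rnorm(40, -4, 0.3), rnorm(40, 0, 0.3), rnorm(40, 4, 0.3))
      rate <- rep(c(0.01, 0.08, 0.64), each = 40)
      sv <- surv_data(rexp(n, rate), rep(1L, n))
      got <- optimal_cutpoints(sc, sv)
      truth_chi <- logrank_test(rep(0:2, each = 40), sv)$chi2
      med <- tapply(sv$time, got$groups, median)
      list(got = got, truth_chi = truth_chi, med = med)
    })
    # the exhaustive maximizer can never do worse than the true boundaries
    if (res$got$chi2 >= res$truth_chi - 1e-9) ok_chi <- ok_chi + 1
    # and the chosen strata are risk-ordered
    if (all(diff(res$med) < 0)) ok_ord <- ok_ord + 1
  }
  expect_equal(ok_chi, 10)
  expect_gte(ok_ord, 9)
})

test_that("compare_indices ranks a clean score above its noisy copy", {
  wins <- 0
  for (seed in 1:10) {
    res <- withr::with_seed(seed, {
      n <- 120
      lp <- rnorm(n)
      sv <- surv_data(rexp(n, 0.05 * exp(lp)), rep(1L, n))
      noisy <- lp + rnorm(n, 0, 2)
      compare_indices(list(clean = lp, noisy = noisy), sv)
    })
    if (res$harrell_c[res$index == "clean"] >=
        res$harrell_c[res$index == "noisy"]) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("compare_indices is deterministic and honours fixed cutpoints", {
  sv <- exp_surv(60, 5)
  sc <- withr::with_seed(5, rnorm(60))
  res <- compare_indices(list(a = sc, b = sc), sv)
  expect_equal(res$chi2_os[1], res$chi2_os[2])
  expect_equal(res$harrell_c[1], res$harrell_c[2])
  fixed <- compare_indices(list(a = sc), sv, cutpoints = list(a = c(-0.5, 0.5)))
  expect_equal(fixed$cut1, -0.5)
  expect_equal(fixed$cut2, 0.5)
})
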