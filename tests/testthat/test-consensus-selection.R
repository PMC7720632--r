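test_that("Cox screen recovers a strongly planted analyte and matches the oracle fit", {
  for (seed in 1:5) {
    res <- withr::with_seed(seed, {
      n <- 500
      z <- rnorm(n)
      x <- cbind(planted = z, noise = rnorm(n))
      tt <- rexp(n, 0.05 * exp(-z))
      cc <- rexp(n, 0.02)
      sv <- surv_data(pmin(tt, cc), as.integer(tt <= cc))
      list(scr = cox_screen(x, sv), x = x, sv = sv)
    })
    planted <- res$scr[res$scr$analyte_id == "planted", ]
    expect_lt(planted$p, 0.05)
    expect_gt(planted$beta, -1.2)
    expect_lt(planted$beta, -0.8)
    # oracle equivalence: independent Newton partial-likelihood fit
    z <- scale(res$x[, 1])[, 1]
    expect_equal(planted$beta,
                 cox_newton_oracle(z, res$sv$time, res$sv$event),
                 tolerance = 1e-6)
    expect_equal(planted$hr, exp(planted$beta), tolerance = 1e-12)
  }
})

test_that("screen p-values are invariant to positive rescaling of an analyte", {
  sv <- exp_surv(80, 2)
  x <- withr::with_seed(2, matrix(rnorm(160), 80, 2,
                                  dimnames = list(NULL, c("a", "b"))))
  s1 <- cox_screen(x, sv)
  x2 <- x
  x2[, "a"] <- x2[, "a"] * 1000
  s2 <- cox_screen(x2, sv)
  expect_equal(s1$p, s2$p, tolerance = 1e-10)
  expect_equal(s1$beta, s2$beta, tolerance = 1e-10)
})

test_that("screen type-I rate is near the nominal 5%", {
  pass <- withr::with_seed(99, {
    n <- 200
    sv <- exp_surv(n, 1, rate = 0.08)
    x <- matrix(rnorm(n * 800), n)
    colnames(x) <- sprintf("N%03d", seq_len(800))
    scr <- cox_screen(x, sv)
    mean(scr$pass)
  })
  expect_gt(pass, 0.03)
  expect_lt(pass, 0.07)
})

test_that("screen skips constant analytes and requires events", {
  sv <- exp_surv(40, 3)
  x <- cbind(const = rep(1, 40),
             ok = withr::with_seed(3, rnorm(40)))
  expect_warning(scr <- cox_screen(x, sv), "skipped")
  expect_false("const" %in% scr$analyte_id)
  none <- surv_data(1:10, rep(0L, 10))
  expect_error(cox_screen(matrix(rnorm(10), 10, 1), none), "events")
})

test_that("outcome dichotomization uses events (with a median alternative)", {
  sv <- surv_data(c(1, 2, 3, 4, 5, 6), c(1, 1, 0, 0, 1, 0))
  expect_equal(sum(dichotomize_outcome(sv)), 3)
  med <- dichotomize_outcome(sv, "median")
  expect_equal(sum(med), 3) # balanced within one
  all_cens <- surv_data(1:5, rep(0L, 5))
  expect_error(dichotomize_outcome(all_cens), "single class")
})

test_that("LOOCV AUC: separable, constant and null feature sets", {
  x <- matrix(c(seq(-2, -0.1, length.out = 10),
                seq(0.1, 2, length.out = 10)), ncol = 1)
  labels <- rep(c(0, 1), each = 10)
  expect_equal(loocv_auc(x, labels), 1.0)
  xc <- matrix(1, 20, 3)
  expect_equal(loocv_auc(xc, labels), 0.5)
  aucs <- sapply(1:100, function(s) withr::with_seed(s, {
    loocv_auc(matrix(rnorm(100 * 5), 100), rbinom(100, 1, 0.5))
  }))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("LOOCV AUC tracks a reference SVM implementation", {
  skip_if_not_installed("e1071")
  for (seed in 1:3) {
    dat <- withr::with_seed(seed, {
      n <- 40
      x <- matrix(rnorm(n * 4), n)
      list(x = x, y = as.integer(x[, 1] + rnorm(n, 0, 0.7) > 0))
    })
    ref_dec <- sapply(seq_len(nrow(dat$x)), function(i) {
      tr <- setdiff(seq_len(nrow(dat$x)), i)
      mu <- colMeans(dat$x[tr, ])
      sdv <- apply(dat$x[tr, ], 2, sd)
      m <- e1071::svm(scale(dat$x[tr, ], mu, sdv),
                      factor(dat$y[tr], levels = 0:1),
                      kernel = "linear", cost = 1, scale = FALSE)
      d <- attr(predict(m, matrix((dat$x[i, ] - mu) / sdv, 1),
                        decision.values = TRUE), "decision.values")
      if (colnames(d) == "0/1") -d[1] else d[1]
    })
    ref_auc <- auc_midrank(ref_dec, dat$y)
    expect_equal(loocv_auc(dat$x, dat$y), ref_auc, tolerance = 0.06)
  }
})

test_that("AUC helper equals brute-force pair counting", {
  for (seed in 1:5) {
    d <- withr::with_seed(seed, {
      list(s = round(rnorm(40), 1), l = rbinom(40, 1, 0.5))
    })
    if (length(unique(d$l)) < 2) next
    expect_equal(auc_midrank(d$s, d$l), auc_oracle(d$s, d$l))
  }
})

test_that("backward elimination keeps an informative candidate and degrades gracefully", {
  hits <- 0
  for (seed in 1:10) {
    be <- withr::with_seed(seed, {
      n <- 100
      z <- rnorm(n)
      x <- cbind(info = z, matrix(rnorm(n * 9), n))
      colnames(x) <- c("info", sprintf("n%02d", 1:9))
      tt <- rexp(n, 0.05 * exp(-1.5 * z))
      cc <- rexp(n, 0.03)
      sv <- surv_data(pmin(tt, cc), as.integer(tt <= cc))
      suppressWarnings(
        backward_eliminate(x, sv, colnames(x),
                           be_config(n_runs = 12, rng_seed = seed)))
    })
    if ("info" %in% be$consensus) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("backward elimination on pure noise returns a tiny consensus", {
  small <- 0
  for (seed in 1:10) {
    be <- withr::with_seed(seed + 50, {
      n <- 100
      x <- matrix(rnorm(n * 10), n)
      colnames(x) <- sprintf("n%02d", 1:10)
      sv <- exp_surv(n, seed, rate = 0.07)
      suppressWarnings(
        backward_eliminate(x, sv, colnames(x),
                           be_config(n_runs = 12, rng_seed = seed)))
    })
    if (length(be$consensus) <= 1) small <- small + 1
  }
  expect_gte(small, 8)
})

test_that("single full-sample run equals its own consensus; empty candidates warn", {
  n <- 60
  x <- withr::with_seed(1, matrix(rnorm(n * 5), n,
                                  dimnames = list(NULL, sprintf("f%d", 1:5))))
  sv <- exp_surv(n, 7, rate = 0.08)
  be <- suppressWarnings(
    backward_eliminate(x, sv, colnames(x),
                       be_config(n_runs = 1, subsample_fraction = 1,
                                 rng_seed = 3)))
  expect_identical(be$consensus, be$selected[[1]])
  expect_warning(be0 <- backward_eliminate(x, sv, character(),
                                           be_config(rng_seed = 1)),
                 "empty")
  expect_length(be0$consensus, 0)
})

test_that("consensus never grows with more runs", {
  n <- 80
  x <- withr::with_seed(4, matrix(rnorm(n * 6), n,
                                  dimnames = list(NULL, sprintf("f%d", 1:6))))
  sv <- exp_surv(n, 11, rate = 0.08)
  sizes <- sapply(c(2, 6, 12), function(k) {
    be <- suppressWarnings(
      backward_eliminate(x, sv, colnames(x),
                         be_config(n_runs = k, rng_seed = 5)))
    length(be$consensus)
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("clone dedupe keeps the smallest-p clone per protein", {
  screen <- data.frame(analyte_id = c("c1", "c2", "c3"),
                       beta = c(-1, -0.8, -0.5), p = c(0.01, 0.03, 0.2))
  ann <- data.frame(analyte_id = c("c1", "c2", "c3"),
                    protein_id = c("P1", "P1", "P2"))
  dd <- dedupe_clones(c("c1", "c2", "c3"), screen, ann)
  expect_equal(nrow(dd), 2)
  expect_equal(dd$analyte_id[dd$protein_id == "P1"], "c1")
  # 23 selected analytes with one duplicated protein collapse to 22
  scr23 <- data.frame(analyte_id = sprintf("a%02d", 1:23),
                      beta = -1, p = seq(0.001, 0.045, length.out = 23))
  ann23 <- data.frame(analyte_id = sprintf("a%02d", 1:23),
                      protein_id = c(sprintf("Q%02d", 1:22), "Q01"))
  expect_equal(nrow(dedupe_clones(scr23$analyte_id, scr23, ann23)), 22)
  # no duplicates: identity
  dd2 <- dedupe_clones(c("c1", "c3"), screen, ann)
  expect_equal(nrow(dd2), 2)
  expect_error(dedupe_clones("zz", screen, ann), "unannotated")
})

test_that("elastic net recovers planted proteins and flags pure ridge", {
  hits <- 0
  for (seed in 1:6) {
    got <- withr::with_seed(seed, {
      n <- 150
      p <- 100
      x <- matrix(rnorm(n * p), n)
      colnames(x) <- sprintf("a%03d", 1:p)
      f <- rnorm(n)
      x[, 1:11] <- sqrt(0.5) * f + sqrt(0.5) * x[, 1:11]
      lp <- -rowSums(x[, 1:11]) / sqrt(11)
      tt <- rexp(n, 0.05 * exp(1.5 * lp))
      sv <- surv_data(pmin(tt, 60), as.integer(tt <= 60))
      enr <- suppressWarnings(
        enr_select(x, sv, enr_config(rng_seed = seed)))
      sum(sprintf("a%03d", 1:11) %in% enr$selected_analytes)
    })
    if (got >= 7) hits <- hits + 1
  }
  expect_gte(hits, 5)
})

test_that("elastic net under a permuted response shows no test-set skill", {
  good <- 0
  for (seed in 1:10) {
    r2 <- withr::with_seed(seed + 10, {
      n <- 120
      x <- matrix(rnorm(n * 60), n)
      colnames(x) <- sprintf("a%02d", 1:60)
      sv <- surv_data(sample(rexp(n, 0.05)), rep(1L, n))
      suppressWarnings(enr_select(x, sv, enr_config(rng_seed = seed)))$r2
    })
    if (r2 <= 0.1) good <- good + 1
  }
  expect_gte(good, 9)
})

test_that("elastic net errors on a too-small test split", {
  x <- matrix(rnorm(20 * 5), 20)
  colnames(x) <- sprintf("a%d", 1:5)
  sv <- exp_surv(20, 1)
  expect_error(enr_select(x, sv, enr_config(train_fraction = 0.9)),
               "test split")
})

test_that("panel intersection follows set semantics with Cox-weighted output", {
  screen <- data.frame(analyte_id = sprintf("c%d", 1:4),
                       beta = c(-1, -0.7, -0.6, -0.9),
                       p = c(0.01, 0.02, 0.03, 0.005))
  ann <- data.frame(analyte_id = sprintf("c%d", 1:4),
                    protein_id = c("A", "B", "C", "D"))
  pan <- intersect_panels(c("A", "B", "C"), c("B", "C", "D"), screen, ann)
  expect_setequal(pan$protein_id, c("B", "C"))
  expect_equal(pan$beta[pan$protein_id == "B"], -0.7)
  expect_warning(empty <- intersect_panels("A", "D", screen, ann),
                 "overlap")
  expect_equal(nrow(empty), 0)
})

test_that("signature-length comparison ranks the clean panel first", {
  wins <- 0
  for (seed in 1:10) {
    rk <- withr::with_seed(seed, {
      n <- 120
      p <- 20
      x <- matrix(rnorm(n * p), n)
      colnames(x) <- sprintf("a%02d", 1:p)
      lp <- -rowSums(x[, 1:5]) / sqrt(5)
      sv <- surv_data(rexp(n, 0.05 * exp(1.2 * lp)), rep(1L, n))
      clean <- data.frame(protein_id = sprintf("P%d", 1:5),
                          analyte_id = sprintf("a%02d", 1:5), beta = rep(-1, 5))
      padded <- rbind(clean,
                      data.frame(protein_id = sprintf("P%d", 6:10),
                                 analyte_id = sprintf("a%02d", 6:10),
                                 beta = rep(-1, 5)))
      compare_signature_lengths(list(clean = clean, padded = padded), x, sv)
    })
    if (rk$panel[1] == "clean") wins <- wins + 1
  }
  expect_gte(wins, 8)
})
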