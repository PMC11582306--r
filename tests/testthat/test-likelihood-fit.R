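test_that("log-likelihood kernel: plug-in, uniform and block-additive cases", {
  n <- c(10, 20, 30, 40); N <- sum(n)
  expect_equal(rr_loglik(n / N, n), sum(n * log(n / N)))
  expect_equal(rr_loglik(rep(.25, 4), n), N * log(1 / 4))
  ## product multinomial: block logliks add
  d <- rr_design(rr_question(0.8), subsamples = TRUE)
  ps <- rr_forward(d, c(n = .7, y = .2, c = .1), bias = "cdm")
  cts <- c(70, 30, 40, 60)
  expect_equal(rr_loglik(ps, cts),
               rr_loglik(ps[1:2], cts[1:2]) + rr_loglik(ps[3:4], cts[3:4]))
  ll0 <- rr_loglik(c(0, .5, .25, .25), c(1, 1, 1, 1))
  expect_identical(as.numeric(ll0), -Inf)
  expect_true(!is.null(attr(ll0, "zero_probability_profiles")))
})

test_that("ML fit recovers known parameters from exact expected counts", {
  d <- rr_design(rr_ely_pair(5/6), rr_question(5/6))
  pi <- c(.55, .1, .12, .08, .1, .05)
  names(pi) <- d$categories
  cases <- list(
    list(model = "null", theta = 0, tyy = 0),
    list(model = "sp_no", theta = .08, tyy = 0),
    list(model = "sp_last_year", theta = .08, tyy = .15))
  for (cs in cases) {
    bias <- if (cs$model == "null") "none" else cs$model
    ps <- rr_forward(d, pi, bias = bias, theta = cs$theta,
                     theta_yy_yn = cs$tyy)
    fit <- rr_fit(d, 1e4 * as.numeric(ps), model = cs$model, n_starts = 8,
                  se = FALSE)
    expect_lt(max(abs(unname(fit$probs) - unname(pi))), 1e-6)
    if (cs$model != "null") expect_lt(abs(fit$theta - cs$theta), 1e-6)
    if (cs$model == "sp_last_year")
      expect_lt(abs(fit$theta_yy_yn - cs$tyy), 1e-6)
    expect_equal(fit$g2, 0, tolerance = 1e-7)
  }
  ## CDM on the sub-samples design
  ds <- rr_design(rr_question(0.8), subsamples = TRUE)
  tau <- c(n = .7, y = .2, c = .1)
  ps <- rr_forward(ds, tau, bias = "cdm")
  fit <- rr_fit(ds, 1e4 * as.numeric(ps), model = "cdm", n_starts = 8, se = FALSE)
  expect_equal(unname(fit$probs), unname(tau), tolerance = 1e-6)
})

test_that("optimizer matches the dense grid-search oracle", {
  s <- rr_study_fixture("study1_anabolics_collapsed")
  Tmat <- unclass(rr_design_matrix(s$design))
  ## 3-category null model, simplex step 1e-3
  oracle <- grid_search_simplex(Tmat, s$counts, by = 1e-3)
  fit <- rr_fit(s$design, s$counts, se = FALSE)
  expect_gte(fit$loglik, oracle$ll - 1e-9)
  expect_lt(max(abs(unname(fit$probs) - oracle$pi)), 2 * oracle$step)
  ## 4-category CDM (3 free parameters), coarser grid
  Tc <- unclass(rr_design_matrix(s$design, bias = "cdm"))
  oracle4 <- grid_search_simplex(Tc, s$counts, by = 5e-3)
  fit4 <- rr_fit(s$design, s$counts, model = "cdm", se = FALSE)
  expect_gte(fit4$loglik, oracle4$ll - 1e-9)
  expect_lt(max(abs(unname(fit4$probs) - oracle4$pi)), 2 * oracle4$step)
})

test_that("quasi-Newton fit agrees with an independent EM on the mixture models", {
  s2 <- rr_study_fixture("study2")
  Tc <- unclass(rr_design_matrix(s2$design, bias = "cdm"))
  em <- em_mixture(Tc, s2$counts, starts = 10)
  fit <- rr_fit(s2$design, s2$counts, model = "cdm", se = FALSE)
  expect_equal(fit$loglik, em$ll, tolerance = 1e-7)
})

test_that("SP-no and CDM are likelihood-equivalent and related by the correspondence", {
  for (nm in c("study1_anabolics_collapsed", "study1", "study2")) {
    s <- rr_study_fixture(nm)
    f_sp <- rr_fit(s$design, s$counts, model = "sp_no", se = FALSE)
    f_cd <- rr_fit(s$design, s$counts, model = "cdm", se = FALSE)
    expect_equal(f_sp$loglik, f_cd$loglik, tolerance = 1e-6)
    expect_equal(f_sp$g2, f_cd$g2, tolerance = 1e-5)
    ## theta = tau_c and pi = tau / (1 - tau_c)
    K <- length(s$design$categories)
    expect_equal(f_sp$theta, unname(f_cd$probs[["c"]]), tolerance = 1e-4)
    expect_equal(unname(f_sp$probs),
                 unname(f_cd$probs[1:K] / (1 - f_cd$probs[["c"]])),
                 tolerance = 1e-4)
  }
})

test_that("deviance conventions: zero counts, perfect fit, df = 0", {
  expect_equal(rr_g2(c(10, 20), c(10, 20), 1)$g2, 0)
  g <- rr_g2(c(10, 0, 20), c(8, 2, 20), 1)  # 0 * log(0/x) contributes 0
  expect_equal(g$g2, 2 * (10 * log(10 / 8)))
  expect_true(is.na(rr_g2(c(5, 5), c(5, 5), 0)$p_value))
  expect_error(rr_g2(c(5, 5), c(0, 10), 1), "fitted frequency 0")
})

test_that("AIC differences obey 2*dk - dG2 and rank the doping models correctly", {
  s1 <- rr_study_fixture("study1")
  f0 <- rr_fit(s1$design, s1$counts, se = FALSE)
  f1 <- rr_fit(s1$design, s1$counts, model = "sp_no", se = FALSE)
  expect_equal(f1$aic - f0$aic, 2 * (f1$k - f0$k) - (f0$g2 - f1$g2),
               tolerance = 1e-8)
  ## the SP-no/CDM correction is preferred on the three-question data
  f2 <- rr_fit(s1$design, s1$counts, model = "cdm", se = FALSE)
  expect_lt(f1$aic, f0$aic)
  expect_lt(f2$aic, f0$aic)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-5)
  ## stats::AIC through the logLik method matches the stored value
  expect_equal(AIC(f1), f1$aic)
})

test_that("fitted frequencies reproduce the observed block totals exactly", {
  s <- rr_study_fixture("study2")
  fit <- rr_fit(s$design, s$counts, model = "sp_no", se = FALSE)
  expect_equal(sum(fit$fitted), sum(s$counts))
  ds <- rr_design(rr_question(0.8), subsamples = TRUE)
  cts <- c(140, 60, 90, 110)
  for (m in c("null", "cdm", "sp_no")) {
    f <- rr_fit(ds, cts, model = m, se = FALSE)
    expect_equal(as.numeric(tapply(f$fitted, f$block, sum)), c(200, 200))
  }
})

test_that("delta-method standard errors scale with 1/sqrt(n) and are positive", {
  d <- rr_design(rr_ely_pair(5/6))
  pi <- c(nn = .8, yn = .1, yy = .1)
  ps <- rr_forward(d, pi, bias = "sp_no", theta = .1)
  f1 <- rr_fit(d, 2000 * as.numeric(ps), model = "sp_no")
  f4 <- rr_fit(d, 8000 * as.numeric(ps), model = "sp_no")
  expect_true(f1$se_available && f4$se_available)
  expect_true(all(f1$std_errors > 0))
  expect_equal(unname(f1$std_errors / f4$std_errors), rep(2, 4),
               tolerance = 0.15)
})

test_that("likelihood-ratio test: identity with the deviance and degenerate cases", {
  s <- rr_study_fixture("study1_anabolics_collapsed")
  f0 <- rr_fit(s$design, s$counts, se = FALSE)
  f1 <- rr_fit(s$design, s$counts, model = "sp_no", se = FALSE)
  lr <- rr_lr_test(f0, f1)
  ## SP-no is saturated here, so the LR statistic equals the null deviance
  expect_equal(lr$statistic, f0$g2, tolerance = 1e-6)
  expect_equal(lr$df, 1L)
  expect_gte(lr$statistic, 0)
  expect_equal(lr$statistic, f0$g2 - f1$g2, tolerance = 1e-6)
  expect_error(rr_lr_test(f1, f0), "not nested")
  ## data exactly from the null: the free theta gains nothing
  d <- rr_design(rr_ely_pair(5/6))
  ps <- rr_forward(d, c(nn = .8, yn = .1, yy = .1))
  g0 <- rr_fit(d, 1e4 * as.numeric(ps), se = FALSE)
  g1 <- rr_fit(d, 1e4 * as.numeric(ps), model = "sp_no", se = FALSE)
  lr0 <- rr_lr_test(g0, g1)
  expect_equal(lr0$statistic, 0, tolerance = 1e-6)
  expect_equal(lr0$p_value, 1, tolerance = 1e-3)
})

test_that("over-parameterized models are rejected and labels validated", {
  d <- rr_design(rr_ely_pair(5/6))
  expect_error(rr_fit(d, c(nn = 5, ny = 1, yn = 2, yy = 1),
                      model = "sp_last_year"),
               "not identified")
  expect_error(rr_fit(d, c(1, 2, 3)), "expected 4")
  expect_error(rr_fit(d, c(aa = 1, ny = 2, yn = 3, yy = 4)), "do not match")
  expect_error(rr_fit(d, c(nn = -1, ny = 2, yn = 3, yy = 4)), "non-negative")
})

test_that("parameter recovery from large simulated samples", {
  set.seed(202)
  d <- rr_design(rr_ely_pair(5/6), rr_question(5/6))
  pi <- c(.6, .1, .1, .05, .1, .05)
  names(pi) <- d$categories
  cts <- rr_simulate(d, pi, theta = .1, n = 1e5, seed = 77)
  fit <- rr_fit(d, cts, model = "sp_no", n_starts = 8)
  z <- (fit$estimates - c(pi, theta = .1)) / fit$std_errors
  expect_true(all(abs(z) < 3))
})
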