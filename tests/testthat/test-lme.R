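test_that("degenerate limits: OLS is recovered when variance structure is absent", {
  set.seed(10)
  d <- sim_lme_data(8, seq(0, 1, length.out = 6), 5, 1.7,
                    tau = 0, sigma = 0.3, delta = 0)
  ols <- unname(coef(lm(pool ~ time_d, d)))

  # no random intercept, no variance function: exact OLS
  f0 <- lme_varexp(pool ~ time_d, d, random_intercept = FALSE, method = "ML")
  expect_equal(unname(coef(f0)), ols, tolerance = 1e-10)
  expect_equal(f0$loglik,
               as.numeric(logLik(lm(pool ~ time_d, d))), tolerance = 1e-8)

  # variance parameters pinned at the boundary: OLS again
  f1 <- lme_varexp(pool ~ time_d, d, var_time = "time_d",
                   fix = list(ratio = 1e-8, delta = 0), method = "ML")
  expect_equal(unname(coef(f1)), ols, tolerance = 1e-6)

  # freely estimated model can only improve the ML likelihood
  f2 <- lme_varexp(pool ~ time_d, d, var_time = "time_d", method = "ML")
  expect_gte(f2$loglik, f0$loglik - 1e-6)
})

test_that("with variance parameters fixed the fixed effects equal closed-form GLS", {
  set.seed(11)
  d <- sim_lme_data(6, seq(0, 1, length.out = 5), 2, -1.2,
                    tau = 0.5, sigma = 0.2, delta = 0.6)
  ratio <- 0.5 / 0.2
  f <- lme_varexp(pool ~ time_d, d, var_time = "time_d",
                  fix = list(ratio = ratio, delta = 0.6), method = "ML")
  X <- model.matrix(~time_d, d)
  w <- exp(2 * 0.6 * d$time_d)
  beta <- gls_oracle(X, d$pool, d$core_id, w, tau2 = ratio^2)
  expect_equal(unname(coef(f)), unname(beta), tolerance = 1e-9)
})

test_that("ML and REML agree on the fixed effect for a balanced intercept-only design", {
  set.seed(12)
  d <- sim_lme_data(6, seq(0, 1, length.out = 5), 4, 0,
                    tau = 0.4, sigma = 0.3, delta = 0)
  fml <- lme_varexp(pool ~ 1, d, method = "ML")
  frl <- lme_varexp(pool ~ 1, d, method = "REML")
  expect_equal(coef(fml), coef(frl), tolerance = 1e-8)
  expect_equal(unname(coef(fml)), mean(d$pool), tolerance = 1e-8)
})

test_that("lr_test computes chi-squared and boundary-mixture p-values", {
  mk <- function(ll, npar) {
    structure(list(loglik = ll, n_params = npar, n = 84, p = 2,
                   method = "ML"), class = "lme_varexp")
  }
  t1 <- lr_test(mk(-100, 5), mk(-102.5, 4))
  expect_equal(t1$L_ratio, 5)
  expect_equal(t1$p_value, pchisq(5, 1, lower.tail = FALSE))
  expect_equal(t1$p_value, 0.0253, tolerance = 1e-2)

  # identical fits
  t0 <- lr_test(mk(-100, 5), mk(-100, 4))
  expect_equal(t0$L_ratio, 0)
  expect_equal(t0$p_value, 1)

  # boundary-corrected variance-component test
  tb <- lr_test(mk(-100, 5), mk(-100 - 5.390 / 2, 4), boundary = TRUE)
  expect_true(tb$corrected)
  expect_equal(tb$p_value, 0.5 * pchisq(5.390, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_error(lr_test(mk(-100, 4), mk(-99, 5)), "nested")
})

test_that("likelihood never decreases when a parameter is added (ML)", {
  for (s in 1:5) {
    set.seed(100 + s)
    d <- sim_lme_data(8, seq(0, 1, length.out = 6), 3, 1,
                      tau = 0.3, sigma = 0.2, delta = 0.5)
    d$fake <- rep(rep(c("a", "b"), each = 3), 8)[seq_len(nrow(d))]
    base <- lme_varexp(pool ~ time_d, d, method = "ML")
    wider <- list(
      lme_varexp(pool ~ time_d + fake, d, method = "ML"),
      lme_varexp(pool ~ time_d, d, var_time = "time_d", method = "ML")
    )
    for (w in wider) expect_gte(w$loglik, base$loglik - 1e-6)
  }
})

test_that("intraclass correlation follows tau^2 / (tau^2 + sigma^2 exp(2 delta t))", {
  f <- structure(list(tau = 1, sigma = 1, delta = c(all = 0)),
                 class = "lme_varexp")
  expect_equal(icc(f, at_time = 0), 0.5)
  expect_equal(icc(f, at_time = 7), 0.5)
  f$delta <- c(all = 0.5)
  expect_equal(icc(f, at_time = 1), 1 / (1 + exp(1)), tolerance = 1e-9)
  f$tau <- 0
  expect_equal(icc(f, at_time = 1), 0)
  f2 <- structure(list(tau = 1, sigma = 1, delta = c(low = 0, high = 1)),
                  class = "lme_varexp")
  expect_error(icc(f2, 1), "stratum")
  expect_equal(icc(f2, 0, "low"), 0.5)
})

test_that("diagnostics: residual identity, ordering, and calibrated standardized spread", {
  set.seed(13)
  d <- sim_lme_data(12, seq(0, 1, length.out = 7), 5, 1.7,
                    tau = 0.35, sigma = 0.12, delta = 0.8)
  f <- lme_varexp(pool ~ time_d, d, var_time = "time_d")
  dg <- lme_diagnostics(f)
  expect_equal(nrow(dg), nrow(d))
  expect_equal(dg$observed, dg$fitted + dg$residual, tolerance = 1e-12)
  expect_false(is.unsorted(dg$std_residual))
  expect_false(is.unsorted(dg$theoretical_quantile))
  expect_gt(sd(dg$std_residual), 0.8)
  expect_lt(sd(dg$std_residual), 1.2)
})

test_that("predict and simulate are consistent with the fitted structure", {
  set.seed(14)
  d <- sim_lme_data(6, seq(0, 1, length.out = 5), 2, 1,
                    tau = 0.5, sigma = 0.2, delta = 0)
  f <- lme_varexp(pool ~ time_d, d)
  expect_equal(predict(f), fitted(f))
  expect_equal(predict(f, level = 0), fitted(f, level = 0))
  nd <- data.frame(time_d = c(0, 1), core_id = c("C01", "ZZZ"))
  pr0 <- predict(f, nd, level = 0)
  pr1 <- predict(f, nd, level = 1)
  expect_equal(unname(pr1[1] - pr0[1]), unname(ranef(f)["C01"]))
  expect_equal(unname(pr1[2]), unname(pr0[2]))  # unknown core falls back to marginal

  s1 <- simulate(f, nsim = 2, seed = 7)
  s2 <- simulate(f, nsim = 2, seed = 7)
  expect_equal(s1, s2)
  expect_equal(dim(s1), c(nrow(d), 2L))
})

test_that("backward selection drops and keeps terms by the LR criterion, deterministically", {
  ex <- generate_experiment(generator_config(seed = 21))
  d <- solute_model_frame(ex$water, "NH4")
  b1 <- backward_select(pool ~ time_d * treatment, d, var_time = "time_d")
  b2 <- backward_select(pool ~ time_d * treatment, d, var_time = "time_d")
  expect_identical(b1$trail, b2$trail)
  expect_identical(deparse(b1$formula), deparse(b2$formula))
  # no treatment effect was generated: time survives, treatment terms go
  expect_true("time_d" %in% attr(terms(b1$formula), "term.labels"))
  expect_false("time_d:treatment" %in% attr(terms(b1$formula), "term.labels"))
  expect_equal(b1$fit$method, "REML")
  # the trail records at least the interaction test
  expect_true("time_d:treatment" %in% b1$trail$term)
})
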