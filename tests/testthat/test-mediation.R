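# Stacking, the stacked 1-1-1 fit with random a/b paths, the Monte-Carlo
# indirect-effect interval and co-moderation.

test_that("stacking doubles rows with exclusive selectors and round-trips", {
  ms <- make_stacked(n_persons = 10L, seed = 50)
  st <- ms$st
  expect_equal(nrow(st), 2 * nrow(ms$an))
  expect_true(all(st$s_m + st$s_y == 1))
  expect_equal(st$z[st$side == "m"], st$M[st$side == "m"])
  expect_equal(st$z[st$side == "y"], st$Y[st$side == "y"])
  # selector-specific predictors vanish on the other side
  expect_true(all(st$sm_D_w_lag[st$side == "y"] == 0))
  expect_true(all(st$sy_M[st$side == "m"] == 0))
  back <- unstack_mediation(st)
  an <- ms$an[, names(back)]
  rownames(an) <- NULL
  expect_equal(back, an)
  expect_error(stack_for_mediation(ms$an, "nope", "Y", "D_w_lag", "M"),
               "lacks columns")
})

test_that("paths and their covariance are recovered from known truth", {
  tr <- synthetic_truth(a = -0.3, b = 0.4, cprime = 0.1, rho_ab = 0)
  ms <- make_stacked(tr, n_persons = 150L, seed = 51)
  mf <- fit_mediation(ms$st, engine = "lme4", dataset_term = "none")
  expect_lt(abs(mf$a + 0.3), 0.04)
  expect_lt(abs(mf$b - 0.4), 0.04)
  expect_lt(abs(mf$cprime - 0.1), 0.04)
  expect_lt(abs(mf$sigma_ab), 0.008)            # truth: rho_ab = 0
  # the indirect estimate is exactly a*b + sigma_ab
  expect_equal(mf$indirect, mf$a * mf$b + mf$sigma_ab)
})

test_that("a path covariance engineered to offset a*b yields a null indirect effect", {
  # cov(a_i, b_i) = -a*b: the offsetting mechanism
  a <- -0.3; b <- 0.4
  sd_a <- sd_b <- sqrt(abs(a * b))               # |rho| = 1 gives |cov| = |a*b|
  tr2 <- synthetic_truth(a = a, b = b, sd_a = sd_a, sd_b = sd_b, rho_ab = 1)
  expect_equal(tr2$indirect, 0)                  # a*b + (-a*b) exactly
  ms <- make_stacked(tr2, n_persons = 200L, seed = 52)
  mf <- fit_mediation(ms$st, engine = "lme4", dataset_term = "none")
  # 3 sampling SEs (SD ~ 0.015 at N = 200 under this truth); |a*b| itself is 0.12
  expect_lt(abs(mf$indirect), 0.045)
})

test_that("b = 0 leaves the direct path intact and the indirect near zero", {
  tr <- synthetic_truth(a = -0.3, b = 0, cprime = 0.2, sd_a = 0.05,
                        sd_b = 0.05, rho_ab = 0)
  ms <- make_stacked(tr, n_persons = 150L, seed = 53)
  mf <- fit_mediation(ms$st, engine = "lme4", dataset_term = "none")
  expect_lt(abs(mf$cprime - 0.2), 0.04)
  expect_lt(abs(mf$indirect), 0.02)
})

test_that("the nlme engine with heteroscedastic residuals agrees with lme4", {
  tr <- synthetic_truth(a = -0.3, b = 0.4, sigma_m = 1, sigma_y = 1.5)
  ms <- make_stacked(tr, n_persons = 60L, seed = 54)
  m4 <- fit_mediation(ms$st, engine = "lme4", dataset_term = "none")
  mn <- fit_mediation(ms$st, engine = "nlme", het_residuals = TRUE,
                      dataset_term = "none")
  expect_lt(abs(m4$a - mn$a), 0.01)
  expect_lt(abs(m4$b - mn$b), 0.02)
  # heteroscedastic nlme captures the residual-SD ratio
  expect_true(is.finite(mn$sigma_ab_se))
})

test_that("the stacked a-path matches the plain cross-lag a-path", {
  ms <- make_stacked(n_persons = 80L, seed = 55)
  mf <- fit_mediation(ms$st, engine = "lme4", dataset_term = "none")
  sp <- model_spec("M", within = "D_w_lag", ar1 = FALSE,
                   dataset_term = "none", engine = "lme4")
  f <- fit_crosslag(ms$an, sp)
  expect_lt(abs(mf$a - coef_row(f, "D_w_lag")$estimate), 0.01)
})

test_that("Monte-Carlo interval behaves in the degenerate and analytic cases", {
  degenerate <- list(a = 0, b = 0, vcov_ab = matrix(0, 2, 2), sigma_ab = 0,
                     sigma_ab_se = 0, path_vcov = matrix(0, 2, 2))
  mc <- monte_carlo_indirect(degenerate, n_draws = 2000, seed = 1)
  expect_equal(mc$ci, c(0, 0))
  exact <- list(a = 0.5, b = 0.5, vcov_ab = matrix(0, 2, 2), sigma_ab = -0.25,
                sigma_ab_se = 0, path_vcov = matrix(c(1, -0.25, -0.25, 1), 2))
  mc2 <- monte_carlo_indirect(exact, n_draws = 2000, seed = 1)
  expect_equal(mc2$indirect, 0)
  expect_equal(mc2$ci, c(0, 0))
  # seeded determinism
  some <- list(a = 0.3, b = 0.2, vcov_ab = diag(c(0.01, 0.01)), sigma_ab = 0.01,
               sigma_ab_se = 0.005, path_vcov = diag(c(0.02, 0.02)))
  expect_identical(monte_carlo_indirect(some, 5000, seed = 3)$ci,
                   monte_carlo_indirect(some, 5000, seed = 3)$ci)
  expect_error(monte_carlo_indirect(some, 100), "seed")
  bad <- some; bad$vcov_ab <- matrix(c(1, 2, 2, 1), 2)
  expect_error(monte_carlo_indirect(bad, 100, seed = 1), "positive semidefinite")
  # draws violating |rho| <= 1 are clipped and counted
  tight <- list(a = 0.3, b = 0.2, vcov_ab = diag(c(1e-6, 1e-6)), sigma_ab = 0,
                sigma_ab_se = 0.05, path_vcov = diag(c(1e-4, 1e-4)))
  mc3 <- monte_carlo_indirect(tight, 2000, seed = 4)
  expect_gt(mc3$n_clipped, 0)
  expect_true(all(abs(mc3$draws - mc3$indirect) <= 0.3 * 0.2 + 1e-4 + 0.3))
})

test_that("co-moderation recovers a person covariate acting on the a-path", {
  tr <- synthetic_truth(a = -0.3, b = 0.4, sd_a = 0.05, sd_b = 0.05,
                        gamma_a = 0.15)
  ms <- make_stacked(tr, n_persons = 150L, seed = 56)
  cm <- co_moderation(ms$st, "w", engine = "lme4", dataset_term = "none")
  ia <- cm$interactions[cm$interactions$path == "a", ]
  expect_lt(abs(ia$estimate - 0.15), 0.05)
  expect_gt(ia$estimate, 0)
  # null co-moderation: both interactions near zero, CIs cover 0
  tr0 <- synthetic_truth(a = -0.3, b = 0.4, sd_a = 0.05, sd_b = 0.05)
  ms0 <- make_stacked(tr0, n_persons = 100L, seed = 57)
  cm0 <- co_moderation(ms0$st, "w", engine = "lme4", dataset_term = "none")
  expect_true(all(cm0$interactions$ci95_lo < 0 & cm0$interactions$ci95_hi > 0))
  # moderated paths stay close to the unmoderated fit under the null
  mf0 <- fit_mediation(ms0$st, engine = "lme4", dataset_term = "none")
  expect_lt(abs(cm0$fit$a - mf0$a), 0.02)
  expect_lt(abs(cm0$fit$b - mf0$b), 0.02)
})

test_that("the Monte-Carlo interval narrows roughly as 1/sqrt(n_persons)", {
  widths <- vapply(c(50L, 200L), function(n) {
    ms <- make_stacked(n_persons = n, seed = 58)
    mf <- fit_mediation(ms$st, engine = "lme4", dataset_term = "none",
                        random_intercepts = FALSE)
    mc <- monte_carlo_indirect(mf, n_draws = 4000, seed = 58)
    diff(mc$ci)
  }, numeric(1))
  # quadrupling persons should halve the width, within Monte-Carlo slack
  expect_gt(widths[1] / widths[2], 1.4)
  expect_lt(widths[1] / widths[2], 2.9)
})
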