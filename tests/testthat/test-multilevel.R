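# Cross-lag model fitting, TOST equivalence, moderators and between-person
# effects, validated on index-level synthetic data with known truth.

test_that("known within-person slope is recovered with both engines", {
  tr <- synthetic_truth(a = -0.3, b = 0.4)
  ma <- make_analysis(tr, n_persons = 120L, seed = 40)
  sp4 <- model_spec("M", within = "D_w_lag", ar1 = FALSE,
                    dataset_term = "none", engine = "lme4")
  f4 <- fit_crosslag(ma$an, sp4)
  expect_true(f4$converged)
  expect_lt(abs(coef_row(f4, "D_w_lag")$estimate + 0.3), 0.04)
  spn <- model_spec("M", within = "D_w_lag", ar1 = TRUE, dataset_term = "none")
  fn <- fit_crosslag(ma$an, spn)
  expect_true(fn$converged)
  expect_lt(abs(coef_row(fn, "D_w_lag")$estimate + 0.3), 0.04)
  # residuals are white by construction: AR(1) rho near zero
  expect_lt(abs(fn$ar1_rho), 0.1)
  # the two engines agree on the slope
  expect_lt(abs(coef_row(fn, "D_w_lag")$estimate -
                  coef_row(f4, "D_w_lag")$estimate), 0.005)
  # random-slope SD close to sd_a = 0.1
  expect_lt(abs(sqrt(f4$ranef_vcov["D_w_lag", "D_w_lag"]) - 0.1), 0.05)
})

test_that("estimates are invariant to relabeling and row order", {
  ma <- make_analysis(n_persons = 40L, seed = 41)
  sp <- model_spec("M", within = "D_w_lag", ar1 = FALSE,
                   dataset_term = "none", engine = "lme4")
  f0 <- fit_crosslag(ma$an, sp)
  shuf <- ma$an[sample(nrow(ma$an)), ]
  shuf$person_id <- paste0("relabeled_", shuf$person_id)
  f1 <- fit_crosslag(shuf, sp)
  expect_equal(f1$coef$estimate, f0$coef$estimate, tolerance = 1e-6)
  expect_equal(f1$coef$se, f0$coef$se, tolerance = 1e-6)
})

test_that("a single dataset with the dataset term disabled equals a two-level fit", {
  ma <- make_analysis(n_persons = 30L, seed = 42)
  sp_none <- model_spec("M", within = "D_w_lag", ar1 = FALSE,
                        dataset_term = "none", engine = "lme4")
  sp_rand <- model_spec("M", within = "D_w_lag", ar1 = FALSE,
                        dataset_term = "random", engine = "lme4")
  f_none <- fit_crosslag(ma$an, sp_none)
  f_rand <- fit_crosslag(ma$an, sp_rand)   # 1 dataset: term dropped internally
  expect_equal(f_rand$dataset_term, "none")
  expect_equal(f_rand$coef, f_none$coef)
})

test_that("rank-deficient designs raise an error naming the collinear column", {
  ma <- make_analysis(n_persons = 20L, seed = 43)
  ma$an$D_copy <- ma$an$D_w_lag
  sp <- model_spec("M", within = c("D_w_lag", "D_copy"), ar1 = FALSE,
                   dataset_term = "none", engine = "lme4")
  expect_error(fit_crosslag(ma$an, sp), "D_copy")
})

test_that("TOST equivalence follows the 90% CI against fixed bounds", {
  t1 <- tost_equivalence(0, se = 0.05)
  expect_equal(t1$ci90, c(-0.08224268, 0.08224268), tolerance = 1e-6)
  expect_true(t1$concluded)
  t2 <- tost_equivalence(0.15, se = 0.05)
  expect_equal(t2$ci90[2], 0.15 + stats::qnorm(0.95) * 0.05)
  expect_false(t2$concluded)                  # upper limit 0.232 > 0.187
  # widening the SE can only flip concluded -> not concluded
  ses <- seq(0.01, 0.3, by = 0.01)
  conc <- vapply(ses, function(s) tost_equivalence(0.1, se = s)$concluded,
                 logical(1))
  expect_true(all(diff(as.integer(conc)) <= 0))
  # fit interface matches the numeric interface
  ma <- make_analysis(n_persons = 30L, seed = 44)
  sp <- model_spec("M", within = "D_w_lag", ar1 = FALSE,
                   dataset_term = "none", engine = "lme4")
  f <- fit_crosslag(ma$an, sp)
  r <- coef_row(f, "D_w_lag")
  tf <- tost_equivalence(f, "D_w_lag")
  expect_equal(tf$ci90, c(r$ci90_lo, r$ci90_hi))
})

test_that("a constant-zero moderator reduces to the unmoderated model", {
  ma <- make_analysis(n_persons = 40L, seed = 45)
  sp <- model_spec("M", within = "D_w_lag", ar1 = FALSE,
                   dataset_term = "none", engine = "lme4")
  f0 <- fit_crosslag(ma$an, sp)
  spm <- add_moderators(sp, "mod")
  ma$an$mod <- 0                          # constant moderator: no information
  fm <- fit_crosslag(ma$an, spm)
  expect_true(any(grepl("dropped constant", fm$notes)))
  expect_equal(coef_row(fm, "D_w_lag")$estimate,
               coef_row(f0, "D_w_lag")$estimate)
  # moderator with variance but zero true effect: focal estimate barely moves
  set.seed(45)
  ma$an$mod <- stats::ave(stats::rnorm(nrow(ma$an)), ma$an$person_id,
                          FUN = function(z) z[1])
  fm2 <- fit_crosslag(ma$an, add_moderators(sp, "mod"))
  expect_lt(abs(coef_row(fm2, "D_w_lag")$estimate -
                  coef_row(f0, "D_w_lag")$estimate), 0.02)
})

test_that("a synthetic cross-level interaction is recovered", {
  # person slopes depend on the person covariate w: a_i = a + gamma_a * w_i
  tr <- synthetic_truth(a = -0.3, b = 0, cprime = 0, sd_a = 0.05,
                        gamma_a = 0.2)
  ma <- make_analysis(tr, n_persons = 150L, seed = 46)
  sp <- add_moderators(
    model_spec("M", within = "D_w_lag", ar1 = FALSE,
               dataset_term = "none", engine = "lme4"), "w")
  f <- fit_crosslag(ma$an, sp)
  ia <- coef_row(f, grep(":", f$coef$term, value = TRUE)[1])
  expect_lt(abs(ia$estimate - 0.2), 0.05)
})

test_that("zero-intensity indicator flags exact zeros only", {
  expect_equal(zero_intensity_indicator(c(0, 0.2, 0, NA)), c(1L, 0L, 1L, NA))
})

test_that("between-person effects recover a known person-level slope", {
  # build person means directly: x_b predicts person mean of y
  set.seed(47)
  n <- 120
  xb <- stats::rnorm(n)
  yb <- 0.5 * xb + stats::rnorm(n, sd = 0.2)
  d <- data.frame(person_id = rep(sprintf("p%03d", 1:n), each = 15),
                  obs_index = rep(1:15, n),
                  x_b = rep(xb, each = 15))
  d$y <- rep(yb, each = 15) + stats::rnorm(nrow(d))
  d$x_w <- stats::rnorm(nrow(d))
  sp <- model_spec("y", within = "x_w", between = "x_b", ar1 = FALSE,
                   dataset_term = "none", engine = "lme4")
  f <- fit_crosslag(d, sp)
  bp <- between_person_effects(f)
  expect_equal(bp$term, "x_b")
  expect_lt(abs(bp$estimate - 0.5), 0.08)
  # too few persons errors
  expect_error(fit_crosslag(d[d$person_id %in% c("p001", "p002"), ], sp),
               "3 persons")
})
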