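# Rescaling, exclusions, compliance, centering algebra, time centering,
# lag alignment and the multicollinearity screen.

test_that("rescaling maps instrument bounds onto 0-10 and validates input", {
  d <- data.frame(x = c(1, 4, 7), y = c(0, 50, 100), z = c(0, 5, 10))
  out <- rescale_items(d, list(x = c(1, 7), y = c(0, 100), z = c(0, 10)))
  expect_equal(out$x, c(0, 5, 10))
  expect_equal(out$y, c(0, 5, 10))
  expect_equal(out$z, c(0, 5, 10))          # already 0-10: identity
  d$x[2] <- NA
  expect_equal(rescale_items(d, list(x = c(1, 7)))$x[2], NA_real_)
  d$x[3] <- 8
  expect_error(rescale_items(d, list(x = c(1, 7))), "outside declared bounds")
  expect_error(rescale_items(d, list(x = c(7, 1))), "min < max")
})

test_that("zero-variance and fast-RT persons are excluded with per-rule counts", {
  # 10 persons: p3 rates every NA item 0 always, p7 answers in 450 ms
  set.seed(30)
  mk <- function(id, na1, na2, rt) data.frame(
    dataset_id = "d1", person_id = id, obs_index = 1:5,
    rt_ms = rt, na_1 = na1, na_2 = na2,
    er_1 = stats::runif(5, 1, 5), er_2 = stats::runif(5, 1, 5))
  tabs <- lapply(1:10, function(i) {
    if (i == 3) mk("p03", rep(0, 5), rep(0, 5), 1200)
    else if (i == 7) mk("p07", stats::runif(5, 1, 5), stats::runif(5, 1, 5), 450)
    else mk(sprintf("p%02d", i), stats::runif(5, 1, 5), stats::runif(5, 1, 5), 1200)
  })
  d <- do.call(rbind, tabs)
  res <- apply_exclusions(d, items = list(na_ = c("na_1", "na_2"),
                                          er = c("er_1", "er_2")))
  expect_equal(res$report$n_persons_before, 10)
  expect_equal(res$report$n_persons_after, 8)
  expect_false(any(res$data$person_id %in% c("p03", "p07")))
  counts <- res$report$by_dataset$d1
  expect_equal(unname(counts["zero_variance_na"]), 1)
  expect_equal(unname(counts["fast_rt"]), 1)
  # idempotent: re-applying removes nobody
  res2 <- apply_exclusions(res$data, items = list(na_ = c("na_1", "na_2"),
                                                  er = c("er_1", "er_2")))
  expect_equal(res2$report$n_excluded, 0)
  expect_equal(res2$data, res$data)
})

test_that("the reaction-time boundary is strict: 499 out, 500 in", {
  mk <- function(id, rt) data.frame(dataset_id = "d", person_id = id,
                                    obs_index = 1:3, rt_ms = rt,
                                    na_1 = c(1, 2, 3))
  d <- rbind(mk("fast", 499), mk("edge", 500))
  res <- apply_exclusions(d, items = list(na_ = "na_1"))
  expect_equal(unique(res$data$person_id), "edge")
})

test_that("compliance is observed over scheduled", {
  d <- data.frame(dataset_id = "d", person_id = rep(c("a", "b"), c(70, 35)),
                  obs_index = c(1:70, 1:35))
  cs <- compliance_summary(d, n_possible = 70)
  expect_equal(sort(cs$per_person$compliance), c(0.5, 1.0))
  expect_equal(cs$mean, 0.75)
})

test_that("person centering satisfies the decomposition identity", {
  d <- data.frame(person_id = rep(c("a", "b"), each = 3),
                  x = c(2, 4, 6, 1, 1, 1))
  out <- person_center(d, "x")
  expect_equal(out$x_w[1:3], c(-2, 0, 2))
  expect_equal(out$x_w[4:6], c(0, 0, 0))         # constant person
  g <- attr(out, "grand_means")[["x"]]
  expect_equal(g + out$x_b + out$x_w, d$x)        # raw = grand + between + within
  # within sums to zero per person
  expect_equal(as.vector(tapply(out$x_w, d$person_id, sum)), c(0, 0))
  # random table: identity holds with missing values present
  set.seed(31)
  r <- data.frame(person_id = sample(letters[1:6], 100, TRUE),
                  y = stats::rnorm(100))
  r$y[sample(100, 10)] <- NA
  ro <- person_center(r, "y")
  ok <- !is.na(r$y)
  expect_equal(attr(ro, "grand_means")[["y"]] + ro$y_b[ok] + ro$y_w[ok], r$y[ok])
  # centering then aggregating recovers person means
  pm <- tapply(r$y, r$person_id, mean, na.rm = TRUE)
  expect_equal(unname(tapply(ro$y_b, r$person_id, `[`, 1)) +
                 attr(ro, "grand_means")[["y"]], unname(pm))
})

test_that("time is centered at the 35.5th observation", {
  expect_equal(center_time(c(1, 36, 70)), c(-34.5, 0.5, 34.5))
})

test_that("lag alignment stays within persons and flags complete rows", {
  d <- data.frame(dataset_id = "d", person_id = rep(c("a", "b", "c"), c(3, 1, 3)),
                  obs_index = c(1:3, 1, 1:3), x = 1:7)
  out <- align_lags(d, "x")
  a_rows <- out[out$person_id == "a", ]
  expect_equal(a_rows$x_lag, c(NA, 1, 2))
  expect_equal(sum(a_rows$complete), 2)           # obs 1..3 -> 2 complete rows
  expect_equal(sum(out$complete[out$person_id == "b"]), 0)  # single obs, no error
  expect_true(is.na(out$x_lag[out$person_id == "c"][1]))    # never crosses persons
  dup <- d; dup$obs_index[2] <- 1
  expect_error(align_lags(dup, "x"), "duplicated obs_index")
})

test_that("lag alignment is invariant to row shuffling and respects day breaks", {
  set.seed(32)
  d <- data.frame(dataset_id = rep(c("d1", "d2"), each = 20),
                  person_id = rep(c("a", "b", "a", "b"), each = 10),
                  day = rep(rep(1:2, each = 5), 4),
                  obs_index = rep(1:10, 4))
  d$x <- stats::rnorm(40)
  ref <- align_lags(d, "x")
  sh <- align_lags(d[sample(nrow(d)), ], "x")
  expect_equal(sh, ref)
  # person key includes the dataset: same person label, different datasets
  key <- paste(ref$dataset_id, ref$person_id)
  firsts <- !duplicated(key)
  expect_true(all(is.na(ref$x_lag[firsts])))
  wb <- align_lags(d, "x", break_at_day = TRUE)
  crossings <- wb$obs_index == 6       # first beep of day 2
  expect_true(all(is.na(wb$x_lag[crossings])))
})

test_that("multicollinearity screen flags duplicate items and skips constants", {
  set.seed(33)
  d <- data.frame(person_id = rep(1:8, each = 20))
  d$i1 <- stats::rnorm(160)
  d$i2 <- d$i1                                 # duplicate -> r = 1
  d$i3 <- stats::rnorm(160)                    # independent
  d$i4 <- 5                                    # constant within everyone
  res <- multicollinearity_screen(d, list(er = c("i1", "i2", "i3", "i4")))
  r12 <- res[res$item_1 == "i1" & res$item_2 == "i2", ]
  expect_equal(r12$r, 1, tolerance = 1e-12)
  expect_true(r12$flagged)
  r13 <- res[res$item_1 == "i1" & res$item_2 == "i3", ]
  expect_lt(abs(r13$r), 0.3)
  expect_false(r13$flagged)
  expect_true(all(is.na(res$r[res$item_1 == "i4" | res$item_2 == "i4"])))
})
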