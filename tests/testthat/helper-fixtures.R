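# Small builders shared across test files.

# one-dataset design for index-level simulations
one_design <- function(n_persons = 50L, beeps = 10L, days = 7L, missing = 0) {
  data.frame(dataset_id = "d1", n_persons = as.integer(n_persons),
             beeps_per_day = as.integer(beeps), n_days = as.integer(days),
             item_scale_min = 0, item_scale_max = 10, missing_rate = missing)
}

# index-level data taken through centering and lag alignment
make_analysis <- function(truth = synthetic_truth(), n_persons = 50L,
                          seed = 1L, missing = 0) {
  sim <- sim_index_data(one_design(n_persons, missing = missing),
                        truth = truth, seed = seed)
  d <- person_center(sim$data, "D")
  an <- align_lags(d, "D_w")
  list(an = an[an$complete, ], sim = sim)
}

# stacked table for mediation tests
make_stacked <- function(truth = synthetic_truth(), n_persons = 50L, seed = 1L) {
  ma <- make_analysis(truth, n_persons, seed)
  st <- stack_for_mediation(ma$an, mediator = "M", outcome = "Y",
                            m_predictors = "D_w_lag",
                            y_predictors = c("M", "D_w_lag"))
  list(st = st, sim = ma$sim, an = ma$an)
}

# tiny hand-checkable long table: 2 persons x few beeps, 2 NA items
toy_table <- function() {
  data.frame(
    dataset_id = "t", person_id = rep(c("p1", "p2"), each = 4),
    obs_index = rep(1:4, 2), rt_ms = 1000, age = 15, female = c(1, 0)[rep(1:2, each = 4)],
    na_1 = c(2, 4, 6, 8, 1, 1, 3, 3),
    na_2 = c(3, 5, 5, 7, 2, 2, 2, 2))
}
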