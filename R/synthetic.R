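#' Synthetic experience-sampling data with known ground truth
#'
#' Two generators at different fidelity levels: [sim_index_data()] simulates
#' index-level multilevel series with known cross-lag and mediation
#' parameters, the primary surface for estimator-recovery tests;
#' [sim_esm_items()] simulates item-level raw ESM data for the five-dataset
#' pooled design, for end-to-end pipeline tests. Both are synthetic
#' stand-ins: no generative model for the original studies' data is
#' published, so the latent mechanisms here are the package's own choices,
#' documented in the methods vignette.
#'
#' @name synthetic
NULL

#' Study designs of the five pooled ESM datasets
#'
#' One row per dataset: sample size, sampling scheme (10 beeps x 7 days or
#' 5 beeps x 14 days, both 70 scheduled assessments), item counts per scale,
#' missingness rate (1 - compliance), and demographic parameters.
#'
#' @param missing_rate probability an assessment is unanswered (default 0.26,
#'   matching the pooled 74% compliance).
#' @return data.frame of study designs.
#' @export
default_designs <- function(missing_rate = 0.26) {
  data.frame(
    dataset_id = paste0("ds", 1:5),
    n_persons = c(83L, 97L, 202L, 178L, 218L),
    beeps_per_day = c(10L, 10L, 10L, 5L, 5L),
    n_days = c(7L, 7L, 7L, 14L, 14L),
    n_pa_items = c(4L, 2L, 3L, 7L, 3L),
    n_na_items = c(5L, 4L, 6L, 6L, 6L),
    n_er_items = c(5L, 6L, 6L, 7L, 8L),
    item_scale_min = 0,
    item_scale_max = 10,
    missing_rate = missing_rate,
    age_mean = c(16.4, 19.1, 18.3, 20.9, 13.5),
    age_sd = c(0.7, 1.3, 1.0, 1.7, 0.6),
    prop_female = c(0.57, 0.63, 0.55, 0.78, 0.48),
    stringsAsFactors = FALSE
  )
}

validate_designs <- function(designs) {
  stopifnot(is.data.frame(designs), nrow(designs) >= 1L)
  need <- c("dataset_id", "n_persons", "beeps_per_day", "n_days",
            "item_scale_min", "item_scale_max", "missing_rate")
  miss <- setdiff(need, names(designs))
  if (length(miss)) stop("designs lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(designs$n_persons <= 0)) stop("invalid design: non-positive n_persons", call. = FALSE)
  if (any(designs$beeps_per_day * designs$n_days < 3))
    stop("invalid design: series length < 3", call. = FALSE)
  if (any(designs$item_scale_min >= designs$item_scale_max))
    stop("invalid design: item scale min >= max", call. = FALSE)
  if (any(designs$missing_rate < 0 | designs$missing_rate >= 1))
    stop("invalid design: missing_rate outside [0, 1)", call. = FALSE)
  invisible(designs)
}

#' Ground-truth parameters for the index-level generator
#'
#' Person `i` has paths `a_i = a + da_i`, `b_i = b + db_i` with
#' `(da_i, db_i)` bivariate normal (SDs `sd_a`, `sd_b`, correlation
#' `rho_ab`). The true within-person indirect effect is
#' `a * b + rho_ab * sd_a * sd_b`.
#'
#' @param a,b,cprime fixed a-, b- and c'-paths.
#' @param sd_a,sd_b SDs of the person-level path deviations.
#' @param rho_ab correlation of the path deviations, in `[-1, 1]`.
#' @param phi AR(1) coefficient of the exogenous differentiation series,
#'   in `(-1, 1)`.
#' @param sigma_m,sigma_y residual SDs of mediator and outcome.
#' @param gamma_a,gamma_b co-moderation: linear effect of a standardized
#'   person covariate `w_i` on `a_i` / `b_i` (0 = homogeneous slopes).
#' @return a `synthetic_truth` list with `indirect` precomputed.
#' @export
synthetic_truth <- function(a = -0.3, b = 0.4, cprime = 0.1,
                            sd_a = 0.1, sd_b = 0.1, rho_ab = 0,
                            phi = 0.3, sigma_m = 1, sigma_y = 1,
                            gamma_a = 0, gamma_b = 0) {
  stopifnot(abs(rho_ab) <= 1, abs(phi) < 1, sigma_m > 0, sigma_y > 0,
            sd_a >= 0, sd_b >= 0)
  structure(list(a = a, b = b, cprime = cprime, sd_a = sd_a, sd_b = sd_b,
                 rho_ab = rho_ab, phi = phi, sigma_m = sigma_m,
                 sigma_y = sigma_y, gamma_a = gamma_a, gamma_b = gamma_b,
                 indirect = a * b + rho_ab * sd_a * sd_b),
            class = "synthetic_truth")
}

# Per-person substream: one global seed expands to person seeds by a counter,
# seed_i = (seed * 69069 + counter) mod 2^31 - 1, so adding persons or
# datasets never reshuffles earlier persons' draws.
person_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 69069 + counter) %% 2147483647)
}

#' Simulate index-level multilevel series with known cross-lag truth
#'
#' For each person: draw `(a_i, b_i)` around the fixed paths; simulate an
#' exogenous stationary AR(1) differentiation series `D_t` (marginal SD 1);
#' then `M_t = a_i * D_{t-1} + e_M` (regulation-variability stand-in) and
#' `Y_t = b_i * M_t + cprime * D_{t-1} + e_Y` (emotion-intensity stand-in).
#' Assessments are flagged missing completely at random at each design's
#' `missing_rate`. When `gamma_a`/`gamma_b` are nonzero the person paths also
#' depend linearly on a standard-normal person covariate `w` (a baseline-
#' differentiation stand-in), giving a co-moderation structure.
#'
#' @param designs data.frame of study designs ([default_designs()]); only
#'   `dataset_id`, `n_persons`, `beeps_per_day`, `n_days`, `missing_rate`
#'   are used.
#' @param truth a [synthetic_truth()] object.
#' @param seed integer seed; same seed, same table.
#' @return list: `data` (long table with `dataset_id`, `person_id`,
#'   `obs_index`, `D`, `M`, `Y`, `w`, `missing`), `truth`, and `persons`
#'   (realized `a_i`, `b_i`, `w_i`).
#' @export
sim_index_data <- function(designs, truth = synthetic_truth(), seed = 1L) {
  validate_designs(designs)
  stopifnot(inherits(truth, "synthetic_truth"))
  n_rows_total <- sum(designs$n_persons * designs$beeps_per_day * designs$n_days)
  n_pers_total <- sum(designs$n_persons)
  col <- function(mode) vector(mode, n_rows_total)
  out <- list(dataset_id = col("character"), person_id = col("character"),
              obs_index = col("integer"), D = col("numeric"),
              M = col("numeric"), Y = col("numeric"), w = col("numeric"),
              missing = col("logical"))
  pers <- list(dataset_id = character(n_pers_total),
               person_id = character(n_pers_total),
               a_i = numeric(n_pers_total), b_i = numeric(n_pers_total),
               w = numeric(n_pers_total))
  counter <- 0L
  at <- 0L
  # Cholesky of the path-deviation covariance
  L11 <- truth$sd_a
  L21 <- truth$rho_ab * truth$sd_b
  L22 <- truth$sd_b * sqrt(max(0, 1 - truth$rho_ab^2))
  rnorm <- stats::rnorm
  for (d in seq_len(nrow(designs))) {
    Tn <- designs$beeps_per_day[d] * designs$n_days[d]
    ids <- sprintf("%s_p%03d", designs$dataset_id[d],
                   seq_len(designs$n_persons[d]))
    for (p in seq_len(designs$n_persons[d])) {
      counter <- counter + 1L
      set.seed(person_seed(seed, counter))
      z <- rnorm(2)
      w <- rnorm(1)
      a_i <- truth$a + L11 * z[1] + truth$gamma_a * w
      b_i <- truth$b + L21 * z[1] + L22 * z[2] + truth$gamma_b * w
      innov <- rnorm(Tn + 1, sd = sqrt(1 - truth$phi^2))
      innov[1] <- rnorm(1)                         # stationary start, marginal SD 1
      D <- as.numeric(stats::filter(innov[-1], truth$phi,
                                    method = "recursive", init = innov[1]))
      Dlag <- c(innov[1], D[-Tn])
      M <- a_i * Dlag + rnorm(Tn, sd = truth$sigma_m)
      Y <- b_i * M + truth$cprime * Dlag + rnorm(Tn, sd = truth$sigma_y)
      miss <- stats::runif(Tn) < designs$missing_rate[d]
      rows <- at + seq_len(Tn)
      at <- at + Tn
      out$dataset_id[rows] <- designs$dataset_id[d]
      out$person_id[rows] <- ids[p]
      out$obs_index[rows] <- seq_len(Tn)
      out$D[rows] <- ifelse(miss, NA_real_, D)
      out$M[rows] <- ifelse(miss, NA_real_, M)
      out$Y[rows] <- ifelse(miss, NA_real_, Y)
      out$w[rows] <- w
      out$missing[rows] <- miss
      pers$dataset_id[counter] <- designs$dataset_id[d]
      pers$person_id[counter] <- ids[p]
      pers$a_i[counter] <- a_i; pers$b_i[counter] <- b_i; pers$w[counter] <- w
    }
  }
  data <- as.data.frame(out, stringsAsFactors = FALSE)
  list(data = data, truth = truth,
       persons = as.data.frame(pers, stringsAsFactors = FALSE))
}

#' Simulate item-level raw ESM data for the pooled five-dataset design
#'
#' Per person, a latent affect factor per valence follows a stationary AR(1);
#' each same-valence item loads on its factor with a loading that itself
#' varies over moments (loading heterogeneity), so the momentary
#' differentiation index fluctuates: at `het = 0` items move in lockstep and
#' differentiation sits near its attainable minimum. Emotion-regulation items
#' follow a compositional process — a Markov chain over strategy-emphasis
#' regimes (strategy switching) plus a person-level endorsement-intensity
#' random walk (endorsement change) — so both Bray-Curtis subcomponents
#' fluctuate. Ratings are clipped to the item scale; assessments are dropped
#' completely at random at the design's `missing_rate`; reaction times, ages
#' and genders are drawn per design.
#'
#' @param designs data.frame of study designs ([default_designs()]).
#' @param latent list of generator parameters; see Details. Defaults are
#'   calibrated so per-item intraclass correlations fall in the 0.19-0.64
#'   band.
#' @param seed integer seed.
#' @return long data.frame, one row per answered assessment: `dataset_id`,
#'   `person_id`, `day`, `beep`, `obs_index`, `rt_ms`, `age`, `female`, and
#'   item columns `pa_1..`, `na_1..`, `er_1..`.
#' @details `latent` elements (all numeric scalars): `phi` AR(1) of the
#'   affect factors; `het` SD of the moment-varying loading perturbations;
#'   `item_noise` SD of item-specific noise; `person_sd` SD of person item
#'   means; `switch_prob` per-beep probability of changing strategy regime;
#'   `emph` rating bonus of emphasized strategies; `endorse_sd` innovation SD
#'   of the endorsement random walk; `rt_meanlog`, `rt_sdlog` log-normal
#'   reaction-time parameters; `compliance_sd` between-person SD of the
#'   answering probability (a Beta draw per person with mean
#'   `1 - missing_rate`, matching the pooled studies' 74% mean / 23% SD
#'   compliance; 0 gives a constant rate).
#' @export
sim_esm_items <- function(designs = default_designs(), latent = list(), seed = 1L) {
  validate_designs(designs)
  lp <- utils::modifyList(list(
    phi = 0.4, het = 0.6, item_noise = 1.0, person_sd = 1.1,
    switch_prob = 0.25, emph = 2.2, endorse_sd = 0.35,
    rt_meanlog = log(2000), rt_sdlog = 0.35, compliance_sd = 0.23), latent)
  chunks <- vector("list", sum(designs$n_persons))
  counter <- 0L
  for (d in seq_len(nrow(designs))) {
    Tn <- designs$beeps_per_day[d] * designs$n_days[d]
    lo <- designs$item_scale_min[d]; hi <- designs$item_scale_max[d]
    mid <- lo + (hi - lo) * c(pa = 0.55, na = 0.2, er = 0.25)
    k_pa <- designs$n_pa_items[d]; k_na <- designs$n_na_items[d]; k_er <- designs$n_er_items[d]
    for (p in seq_len(designs$n_persons[d])) {
      counter <- counter + 1L
      set.seed(person_seed(seed, 1000000L + counter))

      sim_valence <- function(k, center) {
        f <- as.numeric(stats::filter(stats::rnorm(Tn, sd = sqrt(1 - lp$phi^2)),
                                      lp$phi, method = "recursive",
                                      init = stats::rnorm(1)))
        mu <- center + stats::rnorm(k, sd = lp$person_sd)      # person item means
        lam <- 0.8 + stats::runif(k, -0.15, 0.15)              # base loadings
        # moment-varying loading perturbation -> fluctuating differentiation
        pert <- matrix(stats::rnorm(Tn * k, sd = lp$het), Tn, k)
        x <- matrix(mu, Tn, k, byrow = TRUE) +
          (matrix(lam, Tn, k, byrow = TRUE) + pert) * f +
          matrix(stats::rnorm(Tn * k, sd = lp$item_noise), Tn, k)
        pmin(pmax(x, lo), hi)
      }
      pa <- sim_valence(k_pa, mid["pa"])
      na_ <- sim_valence(k_na, mid["na"])

      # ER: regime switching + endorsement random walk
      switches <- stats::runif(Tn) < lp$switch_prob
      cand <- sample.int(k_er, Tn, replace = TRUE)
      regime <- integer(Tn)
      regime[1] <- cand[1]
      for (t in 2:Tn) regime[t] <- if (switches[t]) cand[t] else regime[t - 1]
      endorse <- cumsum(stats::rnorm(Tn, sd = lp$endorse_sd))
      er_mu <- mid["er"] + stats::rnorm(k_er, sd = lp$person_sd * 0.7)
      er <- matrix(er_mu, Tn, k_er, byrow = TRUE) + endorse
      er[cbind(seq_len(Tn), regime)] <- er[cbind(seq_len(Tn), regime)] + lp$emph
      er <- er + matrix(stats::rnorm(Tn * k_er, sd = lp$item_noise * 0.8), Tn, k_er)
      er <- pmin(pmax(er, lo), hi)

      # person-specific compliance: Beta with mean 1 - missing_rate and SD
      # compliance_sd (the pooled studies: 74% mean, 23% SD), floored at 5%
      p_answer <- 1 - designs$missing_rate[d]
      if (designs$missing_rate[d] > 0 && lp$compliance_sd > 0) {
        v <- min(lp$compliance_sd^2, 0.9 * p_answer * (1 - p_answer))
        ab <- p_answer * (1 - p_answer) / v - 1
        p_answer <- max(0.05, stats::rbeta(1, p_answer * ab, (1 - p_answer) * ab))
      }
      keep <- stats::runif(Tn) < p_answer
      if (!any(keep)) keep[sample.int(Tn, 1)] <- TRUE  # never a fully empty person
      df <- data.frame(
        dataset_id = designs$dataset_id[d],
        person_id = sprintf("%s_p%03d", designs$dataset_id[d], p),
        day = rep(seq_len(designs$n_days[d]), each = designs$beeps_per_day[d]),
        beep = rep(seq_len(designs$beeps_per_day[d]), times = designs$n_days[d]),
        obs_index = seq_len(Tn),
        rt_ms = stats::rlnorm(Tn, lp$rt_meanlog, lp$rt_sdlog),
        age = round(stats::rnorm(1, designs$age_mean[d], designs$age_sd[d]), 1),
        female = as.integer(stats::runif(1) < designs$prop_female[d]),
        stringsAsFactors = FALSE)
      for (j in seq_len(k_pa)) df[[paste0("pa_", j)]] <- pa[, j]
      for (j in seq_len(k_na)) df[[paste0("na_", j)]] <- na_[, j]
      for (j in seq_len(k_er)) df[[paste0("er_", j)]] <- er[, j]
      chunks[[counter]] <- df[keep, , drop = FALSE]
    }
  }
  out <- rbind_fill(chunks)   # item counts differ across datasets
  rownames(out) <- NULL
  out
}

# row-bind data.frames whose columns differ, filling absent columns with NA
rbind_fill <- function(chunks) {
  cols <- unique(unlist(lapply(chunks, names)))
  do.call(rbind, lapply(chunks, function(df) {
    for (v in setdiff(cols, names(df))) df[[v]] <- NA_real_
    df[, cols, drop = FALSE]
  }))
}

#' Per-item intraclass correlations of a long ESM table
#'
#' One-way between-person ICC per item: variance of person means over total
#' variance, the usual check that items retain within-person variance. Used
#' to calibrate the item-level generator; items in the pooled studies ranged
#' from 0.19 to 0.64.
#'
#' @param data long data.frame with `person_id` and item columns.
#' @param items character vector of item columns.
#' @param warn_outside optional length-2 band; warn when any ICC leaves it.
#' @return named numeric vector of ICCs.
#' @export
item_iccs <- function(data, items, warn_outside = NULL) {
  key <- interaction(if (!is.null(data$dataset_id)) data$dataset_id else "",
                     data$person_id, drop = TRUE)
  iccs <- vapply(items, function(v) {
    x <- data[[v]]
    ok <- !is.na(x)
    grp <- droplevels(key[ok])
    fit <- stats::anova(stats::aov(x[ok] ~ grp))
    msb <- fit$`Mean Sq`[1]; msw <- fit$`Mean Sq`[2]
    n0 <- mean(table(grp))
    vb <- max(0, (msb - msw) / n0)
    vb / (vb + msw)
  }, numeric(1))
  if (!is.null(warn_outside) &&
      any(iccs < warn_outside[1] | iccs > warn_outside[2], na.rm = TRUE))
    warning("item ICCs outside [", warn_outside[1], ", ", warn_outside[2], "]: ",
            paste(names(iccs)[iccs < warn_outside[1] | iccs > warn_outside[2]],
                  collapse = ", "))
  iccs
}
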