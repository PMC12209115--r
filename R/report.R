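#' Descriptives, results assembly and the end-to-end pipeline
#'
#' @name report
NULL

#' Descriptive statistics of the momentary indices
#'
#' One row per index: theoretical range, pooled mean, between-person SD (SD
#' of person means), within-person SD (SD of the pooled person-centered
#' values; set `within_sd = "mean_person"` for the mean of per-person SDs),
#' and the within-person minimum/maximum, taken as the mean over persons of
#' each person's own minimum/maximum.
#'
#' @param data index table with `person_id` (and optionally `dataset_id`).
#' @param indices named list: index column -> `c(min, max)` theoretical
#'   range (use `-Inf` for the unbounded differentiation index).
#' @param within_sd `"pooled"` or `"mean_person"`.
#' @return data.frame, one row per index.
#' @export
descriptives <- function(data, indices = default_index_ranges(),
                         within_sd = c("pooled", "mean_person")) {
  within_sd <- match.arg(within_sd)
  key <- interaction(if (!is.null(data$dataset_id)) data$dataset_id else "",
                     data$person_id, drop = TRUE)
  rows <- lapply(names(indices), function(v) {
    x <- data[[v]]
    ok <- !is.na(x)
    pm <- tapply(x[ok], droplevels(key[ok]), mean)
    pc <- x[ok] - pm[as.character(droplevels(key[ok]))]
    wsd <- if (within_sd == "pooled") stats::sd(pc)
    else mean(tapply(x[ok], droplevels(key[ok]), stats::sd), na.rm = TRUE)
    data.frame(
      index = v,
      min_possible = indices[[v]][1], max_possible = indices[[v]][2],
      mean = mean(x, na.rm = TRUE),
      between_sd = stats::sd(pm),
      within_sd = wsd,
      within_min = mean(tapply(x[ok], droplevels(key[ok]), min)),
      within_max = mean(tapply(x[ok], droplevels(key[ok]), max)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

default_index_ranges <- function() {
  list(pa_int = c(0, 10), pa_ed = c(-Inf, 0),
       na_int = c(0, 10), na_ed = c(-Inf, 0),
       er_int = c(0, 10), erv_full = c(0, 10),
       erv_endorse = c(0, 10), erv_switch = c(0, 10))
}

#' Assemble a results table from fits and mediation output
#'
#' Rows keyed by hypothesis, arrow notation for temporal precedence
#' (`"X -> Y"`) and `<->` for between-person associations; every number is
#' taken from the supplied fit objects, nothing is recomputed. A row is
#' flagged significant when its 95% CI excludes zero; the H2 row carries the
#' TOST equivalence conclusion.
#'
#' @param fits named list of `emovar_fit` objects (names `"1A"`, `"1B"`,
#'   `"1C"`, `"2A"`, `"2B"`; any subset).
#' @param mediation optional list with elements `fit` (a `mediation_fit`)
#'   and `mc` (from [monte_carlo_indirect()]).
#' @param valence `"neg"` or `"pos"` (selects index column names).
#' @param tost_bound equivalence bound for the H2 row.
#' @return data.frame: hypothesis, label, model, estimate, CI, significance
#'   flag, TOST conclusion where applicable.
#' @export
results_table <- function(fits, mediation = NULL, valence = "neg",
                          tost_bound = 0.187) {
  v <- if (valence == "neg") "na" else "pa"
  rows <- list()
  add <- function(hyp, label, model, est, lo, hi, tost = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      hypothesis = hyp, label = label, model = model,
      estimate = est, ci95_lo = lo, ci95_hi = hi,
      significant = (lo > 0) | (hi < 0),
      tost_equivalent = tost, stringsAsFactors = FALSE)
  }
  h1_terms <- c("1A" = "erv_full", "1B" = "erv_switch", "1C" = "erv_endorse")
  h1_labels <- c("1A" = "ED -> ERV", "1B" = "ED -> switching",
                 "1C" = "ED -> endorsement")
  for (m in intersect(names(h1_terms), names(fits))) {
    r <- coef_row(fits[[m]], paste0(v, "_ed_w_lag"))
    add("H1", h1_labels[[m]], m, r$estimate, r$ci95_lo, r$ci95_hi)
  }
  if ("2A" %in% names(fits)) {
    r <- coef_row(fits[["2A"]], "erv_full_w")
    ts <- tost_equivalence(fits[["2A"]], "erv_full_w", bound = tost_bound)
    add("H2", "ERV -> ED", "2A", r$estimate, r$ci95_lo, r$ci95_hi,
        tost = ts$concluded)
    rb <- coef_row(fits[["2A"]], "erv_full_b")
    add("H3", "ED <-> ERV", "2A", rb$estimate, rb$ci95_lo, rb$ci95_hi)
  }
  if ("2B" %in% names(fits)) {
    for (tm in c("erv_switch_w", "erv_endorse_w")) {
      r <- coef_row(fits[["2B"]], tm)
      lbl <- if (tm == "erv_switch_w") "switching -> ED" else "endorsement -> ED"
      ts <- tost_equivalence(fits[["2B"]], tm, bound = tost_bound)
      add("H2", lbl, "2B", r$estimate, r$ci95_lo, r$ci95_hi, tost = ts$concluded)
    }
  }
  if (!is.null(mediation)) {
    f <- mediation$fit
    add("RQ", "a-path: ED -> ERV", "1M", f$a,
        f$a - 1.959964 * f$se_a, f$a + 1.959964 * f$se_a)
    add("RQ", "b-path: ERV -> intensity", "1M", f$b,
        f$b - 1.959964 * f$se_b, f$b + 1.959964 * f$se_b)
    cp <- f$coef[grepl("^sy_.*_ed_w_lag$|^sy_.*D_lag$", f$coef$term), , drop = FALSE]
    if (nrow(cp) == 1)
      add("RQ", "c'-path: ED -> intensity", "1M", cp$estimate, cp$ci95_lo, cp$ci95_hi)
    add("RQ", "Mediation (a*b + cov)", "1M", mediation$mc$indirect,
        mediation$mc$ci[1], mediation$mc$ci[2])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline on synthetic or supplied ESM data
#'
#' Generate (or take) an item-level ESM table, then: rescale, apply
#' exclusions, compute compliance, compute the momentary indices, decompose
#' them into within-/between-person components, center time, align lags,
#' fit the requested cross-lag models, run the mediation, and assemble
#' descriptive and results tables. Deterministic given the same config.
#'
#' @param config list, or path to a YAML/JSON file holding one, with
#'   elements (all optional): `designs` (default
#'   [default_designs()]), `data` (skip generation), `seed` (default 1),
#'   `valence` (`"neg"`), `erv_mode`, `models` (default `c("1A", "2A")`),
#'   `ar1` (default `FALSE`; nlme AR(1) fits are the slow path), `engine`,
#'   `mediation` (logical, default `TRUE`), `mc_draws` (default 20000),
#'   `latent` (generator parameters), `output_dir` (write CSV/JSON
#'   artifacts when given).
#' @return list: `data` (analysis table), `exclusions`, `compliance`,
#'   `descriptives`, `fits`, `mediation`, `results`, `config` (with defaults
#'   filled in), `meta`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs needs the 'yaml' package", call. = FALSE)
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.null(config$designs))
      config$designs <- as.data.frame(config$designs, stringsAsFactors = FALSE)
  }
  # designs/data are kept out of modifyList: it would merge data.frames
  # column-wise with the defaults
  cfg <- utils::modifyList(list(
    seed = 1L, valence = "neg",
    erv_mode = "all_moments", models = c("1A", "2A"), ar1 = FALSE,
    engine = "auto", mediation = TRUE, mc_draws = 20000,
    latent = list(), output_dir = NULL),
    config[setdiff(names(config), c("designs", "data"))])
  cfg$designs <- if (is.null(config$designs)) default_designs() else config$designs
  cfg$data <- config$data
  known <- c("1A", "1B", "1C", "2A", "2B")
  if (!all(cfg$models %in% known))
    stop("unknown model id: ", paste(setdiff(cfg$models, known), collapse = ", "),
         call. = FALSE)
  v <- if (cfg$valence == "neg") "na" else "pa"

  raw <- if (is.null(cfg$data))
    sim_esm_items(cfg$designs, latent = cfg$latent, seed = cfg$seed)
  else cfg$data
  item_cols <- function(prefix) grep(paste0("^", prefix, "_\\d+$"),
                                     names(raw), value = TRUE)
  items <- list(pa = item_cols("pa"), na_ = item_cols("na"), er = item_cols("er"))

  excl <- apply_exclusions(raw, items)
  comp <- compliance_summary(excl$data,
                             n_possible = cfg$designs$beeps_per_day[1] *
                               cfg$designs$n_days[1])
  idx <- compute_indices(excl$data, items, erv_mode = cfg$erv_mode)
  desc <- descriptives(idx)

  index_cols <- c("pa_int", "na_int", "er_int", "pa_ed", "na_ed",
                  "erv_full", "erv_switch", "erv_endorse")
  idx <- person_center(idx, index_cols)
  idx$t_c <- center_time(idx$obs_index)
  idx$age_c <- idx$age - mean(tapply(idx$age, idx$person_id, `[`, 1), na.rm = TRUE)
  lag_vars <- c(paste0(v, "_ed_w"), paste0(v, "_int_w"))
  an <- align_lags(idx, lag_vars)

  fits <- list()
  for (m in cfg$models) {
    sp <- canned_spec(m, valence = cfg$valence, ar1 = cfg$ar1,
                      engine = cfg$engine)
    fits[[m]] <- fit_crosslag(an, sp)
  }

  med <- NULL
  if (isTRUE(cfg$mediation)) {
    st <- stack_for_mediation(
      an, mediator = "erv_full", outcome = paste0(v, "_int"),
      m_predictors = c(paste0(v, "_ed_w_lag")),
      y_predictors = c("erv_full_w", paste0(v, "_ed_w_lag")))
    mf <- fit_mediation(st,
                        covariates = c(paste0(v, "_int_w_lag"), "er_int_w",
                                       "t_c", "age_c", "female"),
                        engine = if (cfg$ar1) "nlme" else "lme4",
                        het_residuals = cfg$ar1)
    mc <- monte_carlo_indirect(mf, n_draws = cfg$mc_draws, seed = cfg$seed)
    med <- list(fit = mf, mc = mc)
  }

  res <- results_table(Filter(function(f) isTRUE(f$converged), fits),
                       mediation = med, valence = cfg$valence)
  meta <- list(seed = cfg$seed, valence = cfg$valence, erv_mode = cfg$erv_mode,
               erv_shift = 0.001, erv_scale = 10,
               ar1 = cfg$ar1, models = cfg$models,
               n_persons_before = excl$report$n_persons_before,
               n_persons_after = excl$report$n_persons_after,
               compliance_mean = comp$mean, compliance_sd = comp$sd)
  out <- list(data = an, exclusions = excl$report, compliance = comp,
              descriptives = desc, fits = fits, mediation = med,
              results = res, config = cfg, meta = meta)
  if (!is.null(cfg$output_dir)) write_pipeline_outputs(out, cfg$output_dir)
  out
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index_cols <- c("dataset_id", "person_id", "day", "beep", "obs_index",
                  "pa_int", "na_int", "er_int", "pa_ed", "na_ed",
                  "erv_full", "erv_switch", "erv_endorse")
  utils::write.csv(out$data[, intersect(index_cols, names(out$data))],
                   file.path(dir, "indices.csv"), row.names = FALSE)
  utils::write.csv(out$descriptives, file.path(dir, "descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(out$results, file.path(dir, "results_table.csv"),
                   row.names = FALSE)
  fits_json <- lapply(out$fits, function(f) list(
    converged = f$converged, engine = f$engine, coef = f$coef,
    ar1_rho = f$ar1_rho, n_obs = f$n_obs, n_persons = f$n_persons))
  med_json <- if (!is.null(out$mediation)) list(
    a = out$mediation$fit$a, b = out$mediation$fit$b,
    cprime = out$mediation$fit$cprime,
    sigma_ab = out$mediation$fit$sigma_ab,
    indirect = out$mediation$fit$indirect,
    mc_ci = out$mediation$mc$ci, n_draws = out$mediation$mc$n_draws)
  jsonlite::write_json(list(meta = out$meta, exclusions = out$exclusions,
                            fits = fits_json, mediation = med_json),
                       file.path(dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
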