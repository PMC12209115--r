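#' Multilevel cross-lag models for pooled ESM data
#'
#' Builders and fitters for the within-person cross-lag models: outcome at
#' assessment `t` regressed on person-centered (within) predictors — entered
#' as fixed and random effects — plus between-person components, centered
#' time, age and gender, with persons nested in datasets and optional AR(1)
#' residuals. Estimation uses nlme (AR(1) residuals) or lme4 (fast path when
#' `ar1 = FALSE`).
#'
#' @name multilevel
NULL

#' Specify a cross-lag model
#'
#' @param outcome outcome column.
#' @param within person-centered time-varying predictor columns; entered as
#'   fixed effects and, for those in `random_within`, person-level random
#'   slopes.
#' @param between between-person component columns (fixed only).
#' @param covariates further fixed-effect columns (e.g. `t_c`, `age_c`,
#'   `female`); may include interaction terms like `"x:m"`.
#' @param random_within subset of `within` given random slopes (default all).
#' @param ar1 add a first-order autocorrelation structure on the residuals
#'   (equal intervals, ordered by `obs_index`)?
#' @param dataset_term `"random"` (random intercept per dataset), `"fixed"`
#'   (dataset indicator columns) or `"none"`.
#' @param re_structure `"full"` (random intercept + slopes freely covarying)
#'   or `"diagonal"`.
#' @param engine `"auto"` (nlme when `ar1`, else lme4), `"nlme"` or `"lme4"`.
#' @return a `crosslag_spec` list.
#' @export
model_spec <- function(outcome, within = character(), between = character(),
                       covariates = character(), random_within = within,
                       ar1 = TRUE, dataset_term = c("random", "fixed", "none"),
                       re_structure = c("full", "diagonal"),
                       engine = c("auto", "nlme", "lme4")) {
  structure(list(outcome = outcome, within = within, between = between,
                 covariates = covariates, random_within = random_within,
                 ar1 = ar1, dataset_term = match.arg(dataset_term),
                 re_structure = match.arg(re_structure),
                 engine = match.arg(engine)),
            class = "crosslag_spec")
}

#' Canned specifications of the five cross-lag models
#'
#' Builds the model specifications used in the pooled analysis, for either
#' valence. Variable naming convention: indices from [compute_indices()],
#' within/between components suffixed `_w` / `_b` by [person_center()], lags
#' suffixed `_lag` by [align_lags()].
#'
#' * `1A`: regulation variability (full) on lagged within differentiation,
#'   plus lagged within emotion intensity and concurrent within ER intensity.
#' * `1B` / `1C`: one variability subcomponent as outcome with the other as
#'   an extra covariate.
#' * `2A`: differentiation at `t` on concurrent regulation variability (the
#'   frame of reference makes variability precede differentiation within the
#'   same assessment).
#' * `2B`: as `2A` with both subcomponents as simultaneous predictors.
#'
#' @param model one of `"1A"`, `"1B"`, `"1C"`, `"2A"`, `"2B"`.
#' @param valence `"neg"` or `"pos"`; selects `na_*` or `pa_*` indices.
#' @param ar1,dataset_term,engine passed to [model_spec()].
#' @return a `crosslag_spec`.
#' @export
canned_spec <- function(model = c("1A", "1B", "1C", "2A", "2B"),
                        valence = c("neg", "pos"), ar1 = TRUE,
                        dataset_term = "random", engine = "auto") {
  model <- match.arg(model)
  valence <- match.arg(valence)
  v <- if (valence == "neg") "na" else "pa"
  ed_w_lag <- paste0(v, "_ed_w_lag")
  int_w_lag <- paste0(v, "_int_w_lag")
  base_cov <- c("t_c", "age_c", "female")
  ed_b <- paste0(v, "_ed_b"); int_b <- paste0(v, "_int_b")
  sp <- switch(model,
    "1A" = model_spec("erv_full",
                      within = c(ed_w_lag, int_w_lag, "er_int_w"),
                      between = c(ed_b, int_b, "er_int_b"),
                      covariates = base_cov),
    "1B" = model_spec("erv_switch",
                      within = c(ed_w_lag, int_w_lag, "er_int_w", "erv_endorse_w"),
                      between = c(ed_b, int_b, "er_int_b"),
                      covariates = base_cov),
    "1C" = model_spec("erv_endorse",
                      within = c(ed_w_lag, int_w_lag, "er_int_w", "erv_switch_w"),
                      between = c(ed_b, int_b, "er_int_b"),
                      covariates = base_cov),
    "2A" = model_spec(paste0(v, "_ed"),
                      within = c("erv_full_w", paste0(v, "_int_w"), "er_int_w"),
                      between = c("erv_full_b", int_b, "er_int_b"),
                      covariates = base_cov),
    "2B" = model_spec(paste0(v, "_ed"),
                      within = c("erv_switch_w", "erv_endorse_w",
                                 paste0(v, "_int_w"), "er_int_w"),
                      between = c("erv_switch_b", "erv_endorse_b", int_b, "er_int_b"),
                      covariates = base_cov))
  sp$ar1 <- ar1
  sp$dataset_term <- dataset_term
  sp$engine <- engine
  sp
}

spec_columns <- function(spec) {
  iv <- unique(unlist(strsplit(c(spec$within, spec$between, spec$covariates), ":",
                               fixed = TRUE)))
  c(spec$outcome, iv)
}

fixed_formula <- function(spec, extra = character()) {
  rhs <- c(spec$within, spec$between, spec$covariates, extra)
  if (!length(rhs)) rhs <- "1"
  stats::as.formula(paste(spec$outcome, "~", paste(rhs, collapse = " + ")))
}

#' Fit a cross-lag multilevel model
#'
#' Fits the model described by a `crosslag_spec` on the lag-aligned analysis
#' table, using complete rows on all model columns. Non-convergence triggers
#' staged simplification (drop random-effect covariances, then random
#' slopes), each step recorded in `notes`; a fit that still fails is returned
#' with `converged = FALSE`, never silently.
#'
#' @param data analysis table (see [align_lags()]); needs `person_id`,
#'   `obs_index`, and `dataset_id` unless `dataset_term = "none"`.
#' @param spec a `crosslag_spec` from [model_spec()] or [canned_spec()].
#' @param keep_model keep the underlying nlme/lme4 fit in the result?
#' @return an `emovar_fit`: coefficient table with 95% and 90% Wald CIs,
#'   fixed-effect covariance, person-level random-effect covariance, AR(1)
#'   rho, residual SD, sample sizes, convergence flag and notes.
#' @export
fit_crosslag <- function(data, spec, keep_model = FALSE) {
  stopifnot(inherits(spec, "crosslag_spec"))
  cols <- spec_columns(spec)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("data lacks model columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  need <- unique(c(cols, "person_id",
                   if (spec$dataset_term != "none") "dataset_id",
                   if (spec$ar1) "obs_index"))
  d <- data[stats::complete.cases(data[, intersect(need, names(data)), drop = FALSE]),
            , drop = FALSE]
  d$person_id <- factor(if (!is.null(d$dataset_id))
    paste(d$dataset_id, d$person_id, sep = "/") else as.character(d$person_id))
  if (!is.null(d$dataset_id)) d$dataset_id <- factor(d$dataset_id)
  n_persons <- nlevels(d$person_id)
  n_datasets <- if (!is.null(d$dataset_id)) nlevels(d$dataset_id) else 1L
  if (n_persons < 3L) stop("need at least 3 persons", call. = FALSE)
  dataset_term <- spec$dataset_term
  if (dataset_term != "none" && n_datasets < 2L) dataset_term <- "none"

  # constant columns carry no information: drop the terms with a note
  notes <- character()
  X <- stats::model.matrix(fixed_formula(spec), d)
  const <- colnames(X)[apply(X, 2, function(z) all(z == z[1]))]
  const <- setdiff(const, "(Intercept)")
  if (length(const)) {
    for (fld in c("within", "between", "covariates", "random_within"))
      spec[[fld]] <- setdiff(spec[[fld]], const)
    notes <- c(notes, paste("dropped constant terms:", paste(const, collapse = ", ")))
    X <- stats::model.matrix(fixed_formula(spec), d)
  }
  # rank check with named offenders
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect design; collinear columns: ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }

  extra <- if (dataset_term == "fixed") "dataset_id" else character()
  ffix <- fixed_formula(spec, extra)
  engine <- spec$engine
  if (engine == "auto") engine <- if (spec$ar1) "nlme" else "lme4"
  if (spec$ar1 && engine == "lme4")
    stop("AR(1) residuals require engine = 'nlme'", call. = FALSE)

  res <- NULL
  for (re in unique(c(spec$re_structure, "diagonal", "intercept"))) {
    res <- tryCatch(
      if (engine == "nlme")
        fit_nlme(d, spec, ffix, re, dataset_term)
      else
        fit_lme4(d, spec, ffix, re, dataset_term),
      error = function(e) e, warning = function(w) w)
    if (!inherits(res, "condition")) break
    notes <- c(notes, paste0("re=", re, " failed: ", conditionMessage(res)))
    res <- NULL
  }
  if (is.null(res)) {
    return(structure(list(coef = NULL, converged = FALSE, notes = notes,
                          spec = spec, engine = engine,
                          n_obs = nrow(d), n_persons = n_persons,
                          n_datasets = n_datasets),
                     class = "emovar_fit"))
  }

  est <- res$fixef; se <- res$se
  coef_tab <- data.frame(
    term = names(est), estimate = unname(est), se = unname(se),
    ci95_lo = unname(est - stats::qnorm(0.975) * se),
    ci95_hi = unname(est + stats::qnorm(0.975) * se),
    ci90_lo = unname(est - stats::qnorm(0.95) * se),
    ci90_hi = unname(est + stats::qnorm(0.95) * se),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coef = coef_tab, vcov_fixed = res$vcov,
                 ranef_vcov = res$ranef_vcov, dataset_var = res$dataset_var,
                 ar1_rho = res$ar1_rho, sigma = res$sigma,
                 n_obs = nrow(d), n_persons = n_persons,
                 n_datasets = n_datasets, converged = TRUE,
                 re_structure = res$re_structure, dataset_term = dataset_term,
                 engine = engine, spec = spec, notes = notes,
                 model = if (keep_model) res$model),
            class = "emovar_fit")
}

fit_nlme <- function(d, spec, ffix, re, dataset_term) {
  rw <- spec$random_within
  rform <- if (re == "intercept" || !length(rw)) ~1 else
    stats::as.formula(paste("~ 1 +", paste(rw, collapse = " + ")))
  pd <- if (re == "diagonal" && length(rw)) nlme::pdDiag(rform) else rform
  random <- if (dataset_term == "random")
    stats::setNames(list(~1, pd), c("dataset_id", "person_id"))
  else stats::setNames(list(pd), "person_id")
  corr <- if (spec$ar1) {
    grp <- if (dataset_term == "random") ~ obs_index | dataset_id / person_id
      else ~ obs_index | person_id
    nlme::corAR1(form = grp)
  } else NULL
  fit <- nlme::lme(ffix, data = d, random = random, correlation = corr,
                   method = "REML", na.action = stats::na.fail,
                   control = nlme::lmeControl(opt = "optim", maxIter = 100,
                                              msMaxIter = 100, returnObject = FALSE))
  rho <- if (spec$ar1) unname(stats::coef(fit$modelStruct$corStruct,
                                          unconstrained = FALSE)) else NA_real_
  re_struct <- fit$modelStruct$reStruct
  ds_var <- if (dataset_term == "random")
    as.numeric(as.matrix(re_struct[["dataset_id"]])[1, 1] * fit$sigma^2)
  else NA_real_
  person_vc <- as.matrix(re_struct[["person_id"]]) * fit$sigma^2
  list(fixef = nlme::fixef(fit), se = sqrt(diag(stats::vcov(fit))),
       vcov = as.matrix(stats::vcov(fit)), ranef_vcov = person_vc,
       dataset_var = ds_var, ar1_rho = rho, sigma = fit$sigma,
       re_structure = re, model = fit)
}

fit_lme4 <- function(d, spec, ffix, re, dataset_term) {
  rw <- spec$random_within
  bar <- if (re == "intercept" || !length(rw)) "(1 | person_id)"
  else if (re == "diagonal")
    paste0("(1 + ", paste(rw, collapse = " + "), " || person_id)")
  else paste0("(1 + ", paste(rw, collapse = " + "), " | person_id)")
  if (dataset_term == "random") bar <- paste(bar, "+ (1 | dataset_id)")
  f <- stats::as.formula(paste(deparse(ffix[[2]]), "~",
                               paste(deparse(ffix[[3]], width.cutoff = 500), collapse = ""),
                               "+", bar))
  fit <- lme4::lmer(f, data = d, REML = TRUE, na.action = stats::na.fail,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  vc <- lme4::VarCorr(fit)
  person_vc <- as.matrix(Reduce(`+`, lapply(
    vc[grep("^person_id", names(vc))], function(m) {
      M <- matrix(0, 1 + length(rw), 1 + length(rw),
                  dimnames = list(c("(Intercept)", rw), c("(Intercept)", rw)))
      idx <- match(rownames(m), rownames(M))
      M[idx, idx] <- as.matrix(m)[, , drop = TRUE]
      M
    })))
  ds_var <- if (dataset_term == "random")
    as.numeric(vc$dataset_id[1, 1]) else NA_real_
  list(fixef = lme4::fixef(fit), se = sqrt(diag(as.matrix(stats::vcov(fit)))),
       vcov = as.matrix(stats::vcov(fit)), ranef_vcov = person_vc,
       dataset_var = ds_var, ar1_rho = NA_real_, sigma = stats::sigma(fit),
       re_structure = re, model = fit)
}

#' @export
print.emovar_fit <- function(x, ...) {
  cat("Cross-lag multilevel fit (", x$engine, ")\n", sep = "")
  cat("  obs:", x$n_obs, " persons:", x$n_persons, " datasets:", x$n_datasets, "\n")
  if (!x$converged) {
    cat("  DID NOT CONVERGE\n")
    if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
    return(invisible(x))
  }
  if (!is.na(x$ar1_rho)) cat("  AR(1) rho:", round(x$ar1_rho, 3), "\n")
  print(cbind(x$coef[, "term", drop = FALSE],
              round(x$coef[, c("estimate", "se", "ci95_lo", "ci95_hi")], 4)),
        row.names = FALSE)
  invisible(x)
}

#' Extract one coefficient row from a fit
#'
#' @param fit an `emovar_fit`.
#' @param term coefficient name.
#' @return one-row data.frame (estimate, SE, CIs).
#' @export
coef_row <- function(fit, term) {
  stopifnot(inherits(fit, "emovar_fit"), fit$converged)
  row <- fit$coef[fit$coef$term == term, , drop = FALSE]
  if (!nrow(row)) stop("no coefficient named '", term, "'", call. = FALSE)
  row
}

#' Two one-sided tests (TOST) equivalence for a fixed effect
#'
#' Equivalence is concluded when the 90% Wald confidence interval of the
#' effect lies strictly inside `(-bound, bound)`; the default bound 0.187 is
#' the reference slope of the pooled design's power analysis.
#'
#' @param fit an `emovar_fit`, or a numeric estimate (then give `se`).
#' @param term coefficient name (when `fit` is a model fit).
#' @param bound positive equivalence bound.
#' @param se standard error (numeric-input form).
#' @return list: `estimate`, `se`, `ci90` (length 2), `bounds`, `concluded`.
#' @examples
#' tost_equivalence(0, se = 0.05)$concluded   # TRUE
#' tost_equivalence(0.15, se = 0.05)$concluded # FALSE: upper limit 0.232
#' @export
tost_equivalence <- function(fit, term = NULL, bound = 0.187, se = NULL) {
  if (inherits(fit, "emovar_fit")) {
    row <- coef_row(fit, term)
    est <- row$estimate; se <- row$se
  } else {
    est <- fit
    if (is.null(se)) stop("numeric input needs 'se'", call. = FALSE)
  }
  z <- stats::qnorm(0.95)
  ci90 <- c(est - z * se, est + z * se)
  list(estimate = est, se = se, ci90 = ci90, bounds = c(-bound, bound),
       concluded = ci90[1] > -bound && ci90[2] < bound)
}

#' Add a within-person moderator to a model specification
#'
#' Augments the fixed part with the moderator's main effect and its
#' interaction with the focal within-person predictor (sensitivity analyses:
#' dataset-centered age, or a zero-intensity indicator). The focal
#' predictor's main effect remains in the model and is reported alongside.
#'
#' @param spec a `crosslag_spec`.
#' @param moderator moderator column name.
#' @param focal focal within predictor; default the first in `spec$within`.
#' @return modified `crosslag_spec`.
#' @export
add_moderators <- function(spec, moderator, focal = spec$within[1]) {
  stopifnot(inherits(spec, "crosslag_spec"))
  spec$covariates <- unique(c(spec$covariates, moderator,
                              paste(focal, moderator, sep = ":")))
  spec
}

#' Indicator of zero raw intensity
#'
#' Sensitivity-analysis moderator: 1 when the raw (uncentered) intensity is
#' exactly 0 at that assessment.
#'
#' @param x numeric vector of raw intensities.
#' @return integer 0/1 vector (NA preserved).
#' @export
zero_intensity_indicator <- function(x) as.integer(x == 0)

#' Between-person fixed effects of a fit
#'
#' @param fit an `emovar_fit`.
#' @return coefficient rows of the model specification's between-person components.
#' @export
between_person_effects <- function(fit) {
  stopifnot(inherits(fit, "emovar_fit"), fit$converged)
  fit$coef[fit$coef$term %in% fit$spec$between, , drop = FALSE]
}
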