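#' Preprocessing for pooled experience-sampling data
#'
#' Rescaling to the common 0-10 scale, pre-registered person-level
#' exclusions, compliance, within-/between-person decomposition, time
#' centering, lag alignment and a multicollinearity screen.
#'
#' @name preprocess
NULL

#' Rescale item columns to the common 0-10 scale
#'
#' Linear map `x' = (x - min) / (max - min) * 10` per item; missing values
#' stay missing. Ratings outside the declared instrument bounds raise an
#' error naming the offending rows.
#'
#' @param data long-format data.frame.
#' @param scale_map named list: for each item column, `c(min, max)` on the
#'   instrument scale. Items already on 0-10 may be omitted.
#' @return `data` with mapped item columns.
#' @examples
#' d <- data.frame(x = c(1, 4, 7))
#' rescale_items(d, list(x = c(1, 7)))$x # 0 5 10
#' @export
rescale_items <- function(data, scale_map) {
  for (item in names(scale_map)) {
    b <- scale_map[[item]]
    if (length(b) != 2L || !(b[1] < b[2]))
      stop("scale_map entry for '", item, "' must be c(min, max) with min < max", call. = FALSE)
    x <- data[[item]]
    bad <- which(!is.na(x) & (x < b[1] | x > b[2]))
    if (length(bad))
      stop("item '", item, "' outside declared bounds [", b[1], ", ", b[2],
           "] at rows: ", paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    data[[item]] <- (x - b[1]) / (b[2] - b[1]) * 10
  }
  data
}

#' Apply the pre-registered person-level exclusions
#'
#' Drops (1) persons with zero variance in the positive-emotion, the
#' negative-emotion, or the emotion-regulation item set — variance computed
#' jointly over all items of the set, stacked across the person's
#' observations — and (2) persons whose mean reaction time is strictly below
#' `rt_min_ms` (careless responding). Both rules are idempotent.
#'
#' @param data long-format data.frame with `dataset_id`, `person_id`,
#'   `rt_ms` (may be absent; the RT rule is then skipped) and item columns.
#' @param items named list of item column vectors `pa`, `na_`, `er`.
#' @param rt_min_ms exclusion threshold for the person-mean reaction time.
#' @return list with `data` (filtered), and `report`: per dataset and rule,
#'   counts of excluded persons, plus `n_before` / `n_after`.
#' @export
apply_exclusions <- function(data, items, rt_min_ms = 500) {
  stopifnot(all(c("dataset_id", "person_id") %in% names(data)))
  key <- interaction(data$dataset_id, data$person_id, drop = TRUE)
  persons <- split(seq_len(nrow(data)), key)

  zero_var <- function(rows, cols) {
    if (is.null(cols) || !length(cols)) return(FALSE)
    v <- unlist(data[rows, cols], use.names = FALSE)
    v <- v[!is.na(v)]
    length(v) == 0L || stats::var(v) == 0 || length(v) == 1L
  }
  excl <- lapply(persons, function(rows) {
    reasons <- character()
    if (zero_var(rows, items$pa)) reasons <- c(reasons, "zero_variance_pa")
    if (zero_var(rows, items$na_)) reasons <- c(reasons, "zero_variance_na")
    if (zero_var(rows, items$er)) reasons <- c(reasons, "zero_variance_er")
    if (!is.null(data$rt_ms)) {
      mrt <- mean(data$rt_ms[rows], na.rm = TRUE)
      if (is.finite(mrt) && mrt < rt_min_ms) reasons <- c(reasons, "fast_rt")
    }
    reasons
  })
  drop_person <- vapply(excl, function(r) length(r) > 0L, logical(1))
  keep_rows <- unlist(persons[!drop_person], use.names = FALSE)
  out <- data[sort(keep_rows), , drop = FALSE]
  rownames(out) <- NULL

  ds_of <- vapply(persons, function(rows) as.character(data$dataset_id[rows[1]]), character(1))
  rules <- c("zero_variance_pa", "zero_variance_na", "zero_variance_er", "fast_rt")
  per_ds <- lapply(split(excl, ds_of), function(e) {
    counts <- vapply(rules, function(r) sum(vapply(e, function(x) r %in% x, logical(1))), integer(1))
    c(counts, excluded = sum(vapply(e, length, integer(1)) > 0L), n = length(e))
  })
  report <- list(
    n_persons_before = length(persons),
    n_persons_after = sum(!drop_person),
    n_excluded = sum(drop_person),
    by_dataset = per_ds,
    empty_output = nrow(out) == 0L
  )
  list(data = out, report = report)
}

#' Per-person compliance and its pooled summary
#'
#' @param data long-format data.frame with `dataset_id`, `person_id`.
#' @param n_possible scheduled number of assessments per person (70 for the
#'   default designs).
#' @return list: `per_person` (data.frame with `compliance` = observed /
#'   `n_possible`) and pooled `mean` and `sd`.
#' @export
compliance_summary <- function(data, n_possible = 70) {
  key <- interaction(data$dataset_id, data$person_id, drop = TRUE)
  n_obs <- as.integer(table(key))
  per_person <- data.frame(
    dataset_id = vapply(split(as.character(data$dataset_id), key), `[`, character(1), 1),
    person_id = vapply(split(as.character(data$person_id), key), `[`, character(1), 1),
    n_obs = n_obs,
    compliance = n_obs / n_possible
  )
  list(per_person = per_person,
       mean = mean(per_person$compliance),
       sd = stats::sd(per_person$compliance))
}

#' Decompose variables into within- and between-person components
#'
#' For each variable `v` in `vars`, adds `v_w` (raw minus person mean: the
#' time-varying within-person component) and `v_b` (person mean minus the
#' grand mean over the pooled sample: the trait-like between-person
#' component), so `raw = grand_mean + v_b + v_w`. The within component is
#' missing where the raw value is; person means use all available
#' observations.
#'
#' @param data long-format data.frame with `person_id`.
#' @param vars character vector of column names to decompose.
#' @return `data` with `*_w` and `*_b` columns appended; grand means are
#'   attached as attribute `"grand_means"`.
#' @export
person_center <- function(data, vars) {
  stopifnot("person_id" %in% names(data))
  key <- interaction(if (!is.null(data$dataset_id)) data$dataset_id else "",
                     data$person_id, drop = TRUE)
  gm <- numeric(0)
  for (v in vars) {
    x <- data[[v]]
    pm <- stats::ave(x, key, FUN = function(z) mean(z, na.rm = TRUE))
    pm[is.nan(pm)] <- NA_real_
    g <- mean(x, na.rm = TRUE)
    data[[paste0(v, "_w")]] <- x - pm
    data[[paste0(v, "_b")]] <- pm - g
    gm[v] <- g
  }
  attr(data, "grand_means") <- gm
  data
}

#' Center assessment time at the design midpoint
#'
#' `t_c = obs_index - 35.5`, zero at the midpoint of the 70 scheduled
#' assessments.
#'
#' @param obs_index integer vector of assessment positions (1..70).
#' @param midpoint center, default 35.5.
#' @return numeric vector of centered times.
#' @export
center_time <- function(obs_index, midpoint = 35.5) {
  obs_index - midpoint
}

#' Build the lag-aligned analysis table
#'
#' Orders rows by `obs_index` within person, shifts the named columns by one
#' assessment (so `x` at `t - 1` is paired with the outcome row at `t`), and
#' flags rows that are complete on all columns in `required`. The first
#' assessment of each person has missing lags; lags never cross persons or
#' datasets. Lags cross day boundaries by default (`break_at_day = TRUE`
#' drops pairs spanning two days).
#'
#' @param data data.frame with `person_id`, `obs_index` (and optionally
#'   `dataset_id`, `day`).
#' @param lag_vars columns to lag; each gains a `*_lag` companion.
#' @param required columns (after lagging) that must be non-missing for the
#'   row to count as complete; default: all lagged columns.
#' @param break_at_day if `TRUE`, lagged values spanning a day boundary are
#'   set missing.
#' @return `data` ordered within person, with `*_lag` columns and a logical
#'   `complete` flag.
#' @export
align_lags <- function(data, lag_vars, required = NULL, break_at_day = FALSE) {
  stopifnot(all(c("person_id", "obs_index") %in% names(data)))
  key <- interaction(if (!is.null(data$dataset_id)) data$dataset_id else "",
                     data$person_id, drop = TRUE)
  data <- data[order(key, data$obs_index), , drop = FALSE]
  rownames(data) <- NULL
  key <- interaction(if (!is.null(data$dataset_id)) data$dataset_id else "",
                     data$person_id, drop = TRUE)

  dup <- stats::ave(data$obs_index, key, FUN = function(z) anyDuplicated(z) > 0)
  if (any(dup == 1))
    stop("duplicated obs_index within person", call. = FALSE)

  first_of_person <- !duplicated(key)
  for (v in lag_vars) {
    lagged <- c(NA, data[[v]][-nrow(data)])
    lagged[first_of_person] <- NA
    data[[paste0(v, "_lag")]] <- lagged
  }
  if (break_at_day && !is.null(data$day)) {
    day_lag <- c(NA, data$day[-nrow(data)])
    day_lag[first_of_person] <- NA
    crossed <- !is.na(day_lag) & data$day != day_lag
    for (v in lag_vars) data[[paste0(v, "_lag")]][crossed] <- NA
  }
  if (is.null(required)) required <- paste0(lag_vars, "_lag")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("required columns not present: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  data$complete <- stats::complete.cases(data[, required, drop = FALSE])
  data
}

#' Within-person multicollinearity screen for same-scale items
#'
#' Person-centers each item and computes pooled within-person Pearson
#' correlations for every item pair of each scale; pairs at or above the
#' flag threshold indicate near-duplicate items. Persons with zero within-
#' person variance on an item contribute nothing to that item's pairs.
#'
#' @param data long-format data.frame with `person_id` and item columns.
#' @param scales named list of item-column vectors (e.g. `pa`, `na_`, `er`).
#' @param flag_at threshold for flagging, default 0.80.
#' @return data.frame: scale, item pair, within-person r, `flagged`.
#' @export
multicollinearity_screen <- function(data, scales, flag_at = 0.80) {
  key <- interaction(if (!is.null(data$dataset_id)) data$dataset_id else "",
                     data$person_id, drop = TRUE)
  res <- list()
  for (sc in names(scales)) {
    cols <- scales[[sc]]
    if (length(cols) < 2L) next
    cw <- sapply(cols, function(v) {
      x <- data[[v]]
      x - stats::ave(x, key, FUN = function(z) mean(z, na.rm = TRUE))
    })
    for (i in seq_len(length(cols) - 1L)) for (j in seq((i + 1L), length(cols))) {
      xi <- cw[, i]; xj <- cw[, j]
      ok <- !is.na(xi) & !is.na(xj)
      r <- if (sum(ok) > 2 && stats::sd(xi[ok]) > 0 && stats::sd(xj[ok]) > 0)
        stats::cor(xi[ok], xj[ok]) else NA_real_
      res[[length(res) + 1L]] <- data.frame(
        scale = sc, item_1 = cols[i], item_2 = cols[j], r = r,
        flagged = !is.na(r) && abs(r) >= flag_at)
    }
  }
  do.call(rbind, res)
}
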