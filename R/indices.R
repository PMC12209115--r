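#' Momentary indices for experience-sampling emotion data
#'
#' Functions to compute, per person, the momentary emotion differentiation
#' index (an assessment-level decomposition of the average-measures
#' consistency intraclass correlation), momentary intensities, and momentary
#' emotion regulation variability as Bray-Curtis dissimilarity together with
#' its additive partition into balanced-variation ("strategy switching") and
#' abundance-gradient ("endorsement change") subcomponents.
#'
#' @name indices
NULL

#' Mean intensity of one scale at one or more moments
#'
#' Arithmetic mean over the available items of a scale; a row with no
#' non-missing item yields `NA`.
#'
#' @param x numeric matrix (moments x items) or vector (one moment).
#' @return numeric vector of per-moment means.
#' @examples
#' intensity_mean(c(2, 4, 6)) # 4
#' @export
intensity_mean <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  out <- rowMeans(x, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Momentary emotion differentiation index
#'
#' Per-assessment decomposition of the average-measures consistency ICC over a
#' person's moments x items rating matrix. Ratings are item-centered
#' (`d_jt = x_jt - mean_t(x_jt)`); the index at moment `t` is
#' `ED_t = -k * rbar_t^2 / MS_E`, where `rbar_t` is the mean item deviation at
#' moment `t`, `k` the number of items, and `MS_E` the person-level residual
#' (moment x item interaction) mean square of the two-way layout,
#' `sum(e_jt^2) / ((T - 1)(k - 1))` with `e_jt = d_jt - rbar_t`.
#'
#' The index has an upper bound of 0 and no lower bound: values near 0 mean
#' the same-valence emotions deviated from their person means in different
#' directions (differentiated), strongly negative values mean they moved in
#' lockstep (undifferentiated). The numerator varies by moment; the
#' denominator is a person-level constant, so the person mean of `ED_t` is a
#' decreasing function of the consistency ICC.
#'
#' Moments with any missing item are excluded from the decomposition and get
#' `NA`. At least 3 usable moments and 2 items are required. If `MS_E = 0`
#' (perfectly parallel items) the index is undefined: all moments get `NA`
#' with a warning.
#'
#' @param m numeric matrix, moments (rows) x items (columns) of one person,
#'   same-valence emotion ratings on a common scale.
#' @return numeric vector, one value per row of `m` (`NA` where unusable).
#' @seealso [icc_consistency()] for the between-person summary the index
#'   decomposes.
#' @examples
#' set.seed(1)
#' m <- matrix(runif(70 * 4, 0, 10), 70, 4)
#' ed <- momentary_ed(m)
#' all(ed <= 0) # TRUE: upper bound of 0
#' @export
momentary_ed <- function(m) {
  m <- as.matrix(m)
  k <- ncol(m)
  if (k < 2L) stop("momentary_ed() needs at least 2 items", call. = FALSE)
  out <- rep(NA_real_, nrow(m))
  usable <- stats::complete.cases(m)
  Tn <- sum(usable)
  if (Tn < 3L) return(out)
  x <- m[usable, , drop = FALSE]
  d <- sweep(x, 2L, colMeans(x))      # item-centered deviations d_jt
  rbar <- rowMeans(d)                 # moment effect
  e <- d - rbar                       # interaction residuals
  ms_e <- sum(e^2) / ((Tn - 1) * (k - 1))
  if (ms_e <= .Machine$double.eps * max(1, sum(d^2))) {
    warning("MS_E is zero (perfectly parallel items); momentary differentiation undefined")
    return(out)
  }
  out[usable] <- -k * rbar^2 / ms_e
  out
}

#' Average-measures consistency ICC of a person's item matrix
#'
#' Two-way (moments x items) consistency ICC for average measures,
#' `ICC = (MS_R - MS_E) / MS_R`, where `MS_R` is the between-moment mean
#' square of the item-centered ratings and `MS_E` the residual mean square.
#' High values mean the items move together over time (undifferentiated
#' emotions); the statistic has no lower bound and an upper bound of 1.
#'
#' @inheritParams momentary_ed
#' @return a single ICC value (`NA` when fewer than 3 usable moments).
#' @export
icc_consistency <- function(m) {
  m <- as.matrix(m)
  k <- ncol(m)
  if (k < 2L) stop("icc_consistency() needs at least 2 items", call. = FALSE)
  x <- m[stats::complete.cases(m), , drop = FALSE]
  Tn <- nrow(x)
  if (Tn < 3L) return(NA_real_)
  d <- sweep(x, 2L, colMeans(x))
  rbar <- rowMeans(d)
  e <- d - rbar
  ms_r <- k * sum(rbar^2) / (Tn - 1)
  ms_e <- sum(e^2) / ((Tn - 1) * (k - 1))
  if (ms_r == 0) return(if (ms_e > 0) -Inf else NA_real_)
  (ms_r - ms_e) / ms_r
}

#' Bray-Curtis dissimilarity of a pair of moments, with Baselga's partition
#'
#' For nonnegative abundance vectors `u`, `v` with components
#' `A = sum(pmin(u, v))`, `B = sum(pmax(u - v, 0))`, `C = sum(pmax(v - u, 0))`:
#' the full index is `(B + C) / (2A + B + C)`, the balanced-variation part
#' (quantity substituted between strategies, "strategy switching") is
#' `min(B, C) / (A + min(B, C))`, and the abundance-gradient part (overall
#' quantity change, "endorsement change") is their difference. The three
#' values lie in `[0, 1]` and satisfy `full = bal + gra` exactly.
#'
#' @param u,v nonnegative numeric vectors of equal length (strategy-use
#'   profiles at two moments). Must not both be all-zero.
#' @return named numeric vector `c(full, bal, gra)`.
#' @references Baselga's additive partition of Bray-Curtis dissimilarity into
#'   balanced variation in abundances and abundance gradients.
#' @examples
#' bray_curtis_pair(c(2, 0, 0), c(0, 2, 0)) # pure switch: 1, 1, 0
#' bray_curtis_pair(c(2, 2), c(1, 1))       # pure endorsement change: 1/3, 0, 1/3
#' @export
bray_curtis_pair <- function(u, v) {
  if (length(u) != length(v)) stop("u and v must have equal length", call. = FALSE)
  if (anyNA(u) || anyNA(v)) return(c(full = NA_real_, bal = NA_real_, gra = NA_real_))
  if (any(u < 0) || any(v < 0)) stop("bray_curtis_pair() requires nonnegative entries", call. = FALSE)
  A <- sum(pmin(u, v))
  B <- sum(pmax(u - v, 0))
  C <- sum(pmax(v - u, 0))
  if (A + B + C == 0) stop("both vectors are all-zero; dissimilarity undefined", call. = FALSE)
  full <- (B + C) / (2 * A + B + C)
  m <- min(B, C)
  bal <- if (A + m == 0) 0 else m / (A + m)
  bal <- min(bal, full)           # guard floating error: bal <= full
  c(full = full, bal = bal, gra = full - bal)
}

# Pairwise Bray-Curtis matrices for one person's moments-x-items matrix.
# Uses the identities A = (s_t + s_s - L1)/2, B + C = L1, min(B, C) =
# (L1 - |s_t - s_s|)/2 with s_t = rowSums and L1 the Manhattan distance,
# so the T x T computation stays in compiled code.
bray_curtis_matrix <- function(x) {
  s <- rowSums(x)
  L1 <- as.matrix(stats::dist(x, method = "manhattan"))
  S <- outer(s, s, "+")
  A <- pmax((S - L1) / 2, 0)
  full <- L1 / S                  # 2A + B + C = s_t + s_s
  mBC <- pmax((L1 - abs(outer(s, s, "-"))) / 2, 0)
  bal <- mBC / (A + mBC)
  bal[mBC == 0] <- 0              # covers A + min(B,C) = 0 too
  bal <- pmin(bal, full)          # guard floating error: bal <= full
  diag(full) <- 0
  diag(bal) <- 0
  list(full = full, bal = bal, gra = full - bal)
}

#' Momentary emotion regulation variability (Bray-Curtis)
#'
#' Computes, for each assessment of one person, the Bray-Curtis dissimilarity
#' between that moment's emotion regulation strategy profile and the person's
#' other moments, separately for the full index and its balanced-variation
#' (strategy switching) and abundance-gradient (endorsement change)
#' subcomponents. A small constant (`shift`, default 0.001) is added to every
#' rating first so two all-zero moments remain comparable, and the result is
#' multiplied by `scale` (default 10) so the index ranges from 0 (no
#' deviation from the person's typical regulation) to 10 (maximal).
#'
#' With `mode = "all_moments"` (the default) the index at `t` is the mean of
#' the pairwise dissimilarities between `t` and every other usable moment;
#' with `mode = "successive"` it is the single pairwise dissimilarity between
#' `t` and `t - 1` (missing at the first usable moment). Averaging full, bal
#' and gra separately preserves the additivity `full = bal + gra` at every
#' moment. Moments with a missing item are skipped and get `NA`.
#'
#' @param m numeric matrix, moments x ER strategy items, nonnegative ratings.
#' @param mode `"all_moments"` or `"successive"`.
#' @param shift small positive constant added to every rating.
#' @param scale multiplier applied to the unit-interval index.
#' @return data.frame with columns `erv_full`, `erv_switch`, `erv_endorse`,
#'   one row per row of `m`.
#' @export
momentary_erv <- function(m, mode = c("all_moments", "successive"),
                          shift = 0.001, scale = 10) {
  mode <- match.arg(mode)
  m <- as.matrix(m)
  if (any(m < 0, na.rm = TRUE)) stop("ER ratings must be nonnegative", call. = FALSE)
  n <- nrow(m)
  out <- data.frame(erv_full = rep(NA_real_, n),
                    erv_switch = rep(NA_real_, n),
                    erv_endorse = rep(NA_real_, n))
  usable <- stats::complete.cases(m)
  if (sum(usable) < 2L) return(out)
  x <- m[usable, , drop = FALSE] + shift
  if (mode == "all_moments") {
    bc <- bray_curtis_matrix(x)
    Tn <- nrow(x)
    out$erv_full[usable] <- scale * rowSums(bc$full) / (Tn - 1)
    out$erv_switch[usable] <- scale * rowSums(bc$bal) / (Tn - 1)
    out$erv_endorse[usable] <- scale * rowSums(bc$gra) / (Tn - 1)
  } else {
    idx <- which(usable)
    for (i in seq_along(idx)[-1]) {
      p <- bray_curtis_pair(x[i - 1L, ], x[i, ])
      out$erv_full[idx[i]] <- scale * p[["full"]]
      out$erv_switch[idx[i]] <- scale * p[["bal"]]
      out$erv_endorse[idx[i]] <- scale * p[["gra"]]
    }
  }
  out
}

#' Compute all momentary indices for a long-format ESM table
#'
#' Adds, per person and assessment: mean intensities (`pa_int`, `na_int`,
#' `er_int`), momentary emotion differentiation (`pa_ed`, `na_ed`), and
#' momentary emotion regulation variability (`erv_full`, `erv_switch`,
#' `erv_endorse`).
#'
#' @param data long-format data.frame with `person_id`, `obs_index` and the
#'   item columns named in `items`; ratings on the common 0-10 scale.
#' @param items named list with character vectors `pa`, `na_`, `er` giving
#'   the item column names (any element may be `NULL` to skip that scale).
#' @param erv_mode,erv_shift,erv_scale passed to [momentary_erv()].
#' @return `data` with index columns appended, ordered by person and
#'   `obs_index`.
#' @export
compute_indices <- function(data, items,
                            erv_mode = c("all_moments", "successive"),
                            erv_shift = 0.001, erv_scale = 10) {
  erv_mode <- match.arg(erv_mode)
  stopifnot(is.data.frame(data), all(c("person_id", "obs_index") %in% names(data)))
  pkey <- interaction(if (!is.null(data$dataset_id)) data$dataset_id else "",
                      data$person_id, drop = TRUE)
  data <- data[order(pkey, data$obs_index), , drop = FALSE]
  rownames(data) <- NULL
  pkey <- interaction(if (!is.null(data$dataset_id)) data$dataset_id else "",
                      data$person_id, drop = TRUE)
  n <- nrow(data)
  for (col in c("pa_int", "na_int", "er_int", "pa_ed", "na_ed",
                "erv_full", "erv_switch", "erv_endorse"))
    data[[col]] <- rep(NA_real_, n)

  # a person's scale is the subset of item columns they answered at all
  # (datasets differ in item counts; unused columns are all-NA per person)
  person_items <- function(rows, cols) {
    m <- as.matrix(data[rows, cols, drop = FALSE])
    m[, colSums(!is.na(m)) > 0L, drop = FALSE]
  }
  idx_by_person <- split(seq_len(n), pkey)
  for (rows in idx_by_person) {
    if (length(items$pa)) {
      mp <- person_items(rows, items$pa)
      if (ncol(mp)) data$pa_int[rows] <- intensity_mean(mp)
      if (ncol(mp) >= 2) data$pa_ed[rows] <- momentary_ed(mp)
    }
    if (length(items$na_)) {
      mn <- person_items(rows, items$na_)
      if (ncol(mn)) data$na_int[rows] <- intensity_mean(mn)
      if (ncol(mn) >= 2) data$na_ed[rows] <- momentary_ed(mn)
    }
    if (length(items$er)) {
      me <- person_items(rows, items$er)
      if (ncol(me)) data$er_int[rows] <- intensity_mean(me)
      if (ncol(me) >= 2) {
        erv <- momentary_erv(me, mode = erv_mode, shift = erv_shift, scale = erv_scale)
        data$erv_full[rows] <- erv$erv_full
        data$erv_switch[rows] <- erv$erv_switch
        data$erv_endorse[rows] <- erv$erv_endorse
      }
    }
  }
  data
}
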