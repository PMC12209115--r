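#' Stacked 1-1-1 within-person mediation
#'
#' The mediation model (an extension of the cross-lag model 1A) estimates,
#' simultaneously, the a-path (lagged within-person differentiation to
#' regulation variability), the b-path (regulation variability to emotion
#' intensity) and the c'-path (lagged differentiation to intensity), with
#' person-specific random a and b paths whose covariance enters the indirect
#' effect: `indirect = a*b + sigma_ab`. Because the model is inherently
#' multivariate, each analysis row is split into two stacked rows — one
#' carrying the mediator as outcome, one the outcome proper — with selector
#' indicators switching the predictors on and off per row.
#'
#' @name mediation
NULL

#' Stack an analysis table for the mediation model
#'
#' Each complete row becomes two rows: a mediator row (`s_m = 1`) with
#' `z = <mediator>` and an outcome row (`s_y = 1`) with `z = <outcome>`.
#' Selector-specific predictors are built by multiplying each predictor with
#' the matching selector; columns are named `sm_<col>` / `sy_<col>`.
#'
#' @param data analysis table of complete rows.
#' @param mediator,outcome column names (e.g. `"erv_full"` and `"na_int"`).
#' @param m_predictors columns switched on for mediator rows (the a-path
#'   predictor first).
#' @param y_predictors columns switched on for outcome rows (b-path predictor
#'   first, then c'-path predictor).
#' @return `stacked_table`: the stacked data.frame with `z`, `s_m`, `s_y`,
#'   `side`, a row id `.src`, and the selector-specific predictor columns.
#' @export
stack_for_mediation <- function(data, mediator, outcome,
                                m_predictors, y_predictors) {
  need <- unique(c(mediator, outcome, m_predictors, y_predictors))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  cc <- stats::complete.cases(data[, need, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  d$.src <- seq_len(nrow(d))
  dm <- d; dm$z <- dm[[mediator]]; dm$s_m <- 1; dm$s_y <- 0; dm$side <- "m"
  dy <- d; dy$z <- dy[[outcome]]; dy$s_m <- 0; dy$s_y <- 1; dy$side <- "y"
  st <- rbind(dm, dy)
  for (v in unique(m_predictors)) st[[paste0("sm_", v)]] <- st$s_m * st[[v]]
  for (v in unique(y_predictors)) st[[paste0("sy_", v)]] <- st$s_y * st[[v]]
  st <- st[order(st$.src, st$side), , drop = FALSE]
  rownames(st) <- NULL
  attr(st, "mediation") <- list(mediator = mediator, outcome = outcome,
                                m_predictors = m_predictors,
                                y_predictors = y_predictors)
  class(st) <- c("stacked_table", "data.frame")
  st
}

#' Recover the unstacked analysis rows from a stacked table
#'
#' @param st a `stacked_table`.
#' @return the original complete-row analysis table (one row per `.src`).
#' @export
unstack_mediation <- function(st) {
  d <- as.data.frame(st)[st$side == "m", , drop = FALSE]
  drop <- c("z", "s_m", "s_y", "side", ".src",
            grep("^(sm|sy)_", names(d), value = TRUE))
  d <- d[, setdiff(names(d), drop), drop = FALSE]
  rownames(d) <- NULL
  attr(d, "mediation") <- NULL
  d
}

#' Fit the stacked within-person mediation model
#'
#' One mixed model on the stacked rows: selector-specific intercepts, the
#' a-path on the mediator side, the b- and c'-paths on the outcome side, any
#' covariates entered on both sides, person-level random a and b slopes with
#' estimated covariance `sigma_ab` (plus random selector intercepts), and —
#' with the nlme engine — selector-specific residual variances. The
#' asymptotic SE of `sigma_ab`, needed for the Monte-Carlo interval, comes
#' from the fit's variance-parameter asymptotic covariance by the delta
#' method (nlme: `apVar`; lme4: numeric Hessian of the ML deviance).
#'
#' @param st a `stacked_table` from [stack_for_mediation()]. The a-path is
#'   the first `m_predictors` column; b- and c'-paths the first and second
#'   `y_predictors` columns.
#' @param covariates columns entered (selector-specific) on both sides.
#' @param engine `"nlme"` (heteroscedastic residuals by side) or `"lme4"`
#'   (homoscedastic, fast; used in replicated simulations).
#' @param random_intercepts include random selector intercepts per person?
#' @param het_residuals selector-specific residual variances (nlme only).
#' @param se_sigma_ab compute the asymptotic SE of `sigma_ab`? (Skipping it
#'   saves the numeric Hessian in replicated simulations that only need the
#'   fixed paths.)
#' @param dataset_term `"fixed"`, `"random"` or `"none"` dataset adjustment.
#' @param keep_model keep the underlying model object?
#' @return a `mediation_fit`: paths `a`, `b`, `cprime` with SEs, 2x2
#'   asymptotic covariance of `(a, b)`, `sigma_ab` with its asymptotic SE,
#'   person-level path covariance matrix, `indirect = a*b + sigma_ab`,
#'   sample sizes, coefficient table and notes.
#' @export
fit_mediation <- function(st, covariates = character(),
                          engine = c("nlme", "lme4"),
                          random_intercepts = TRUE, het_residuals = TRUE,
                          se_sigma_ab = TRUE,
                          dataset_term = c("fixed", "random", "none"),
                          keep_model = FALSE) {
  engine <- match.arg(engine)
  dataset_term <- match.arg(dataset_term)
  info <- attr(st, "mediation")
  if (is.null(info)) stop("st must come from stack_for_mediation()", call. = FALSE)
  a_col <- paste0("sm_", info$m_predictors[1])
  b_col <- paste0("sy_", info$y_predictors[1])
  c_col <- if (length(info$y_predictors) >= 2)
    paste0("sy_", info$y_predictors[2]) else NULL

  d <- as.data.frame(st)
  d$person_id <- factor(if (!is.null(d$dataset_id))
    paste(d$dataset_id, d$person_id, sep = "/") else as.character(d$person_id))
  if (!is.null(d$dataset_id)) d$dataset_id <- factor(d$dataset_id)
  n_persons <- nlevels(d$person_id)
  if (n_persons < 3L) stop("need at least 3 persons", call. = FALSE)
  if (dataset_term != "none" &&
      (is.null(d$dataset_id) || nlevels(d$dataset_id) < 2L)) dataset_term <- "none"

  sel_cov <- character()
  for (v in covariates) {
    d[[paste0("sm_", v)]] <- d$s_m * d[[v]]
    d[[paste0("sy_", v)]] <- d$s_y * d[[v]]
    sel_cov <- c(sel_cov, paste0("sm_", v), paste0("sy_", v))
  }
  extra_m <- setdiff(paste0("sm_", info$m_predictors), a_col)
  extra_y <- setdiff(paste0("sy_", info$y_predictors), c(b_col, c_col))
  # fixed dataset adjustment: selector-by-dataset intercepts replace the
  # plain selector intercepts (keeps the no-intercept design full rank)
  sel <- if (dataset_term == "fixed") c("s_m:dataset_id", "s_y:dataset_id")
  else c("s_m", "s_y")
  rhs <- c("0", sel, a_col, b_col, c_col, extra_m, extra_y, sel_cov)
  f <- stats::as.formula(paste("z ~", paste(rhs, collapse = " + ")))

  notes <- character()
  if (engine == "nlme") {
    res <- fit_mediation_nlme(d, f, a_col, b_col, random_intercepts,
                              het_residuals, dataset_term, se_sigma_ab)
  } else {
    res <- fit_mediation_lme4(d, f, a_col, b_col, random_intercepts,
                              dataset_term, se_sigma_ab)
  }
  est <- res$fixef
  se <- sqrt(diag(res$vcov))
  a_i <- match(a_col, names(est)); b_i <- match(b_col, names(est))
  coef_tab <- data.frame(term = names(est), estimate = unname(est),
                         se = unname(se),
                         ci95_lo = unname(est - 1.959964 * se),
                         ci95_hi = unname(est + 1.959964 * se),
                         stringsAsFactors = FALSE)
  if (se_sigma_ab && is.na(res$sigma_ab_se)) {
    notes <- c(notes, "asymptotic SE of sigma_ab unavailable; Monte-Carlo draws hold sigma_ab fixed")
    warning("sigma_ab uncertainty could not be estimated; indirect-effect CI ",
            "ignores it", call. = FALSE)
  }
  structure(list(
    a = unname(est[a_i]), b = unname(est[b_i]),
    cprime = if (!is.null(c_col)) unname(est[match(c_col, names(est))]) else NA_real_,
    se_a = unname(se[a_i]), se_b = unname(se[b_i]),
    vcov_ab = res$vcov[c(a_i, b_i), c(a_i, b_i)],
    sigma_ab = res$sigma_ab, sigma_ab_se = res$sigma_ab_se,
    path_vcov = res$path_vcov,
    indirect = unname(est[a_i] * est[b_i]) + res$sigma_ab,
    coef = coef_tab, vcov_fixed = res$vcov,
    n_obs = nrow(d), n_rows = nrow(d) / 2, n_persons = n_persons,
    engine = engine, converged = TRUE, notes = c(notes, res$notes),
    a_col = a_col, b_col = b_col,
    model = if (keep_model) res$model),
    class = "mediation_fit")
}

fit_mediation_nlme <- function(d, f, a_col, b_col, random_intercepts,
                               het_residuals, dataset_term, se_sigma_ab = TRUE) {
  slope_form <- stats::as.formula(paste("~ 0 +", a_col, "+", b_col))
  pd <- if (random_intercepts)
    nlme::pdBlocked(list(nlme::pdDiag(~ 0 + s_m + s_y), nlme::pdSymm(slope_form)))
  else nlme::pdSymm(slope_form)
  random <- if (dataset_term == "random")
    stats::setNames(list(nlme::pdDiag(~ 0 + s_m + s_y), pd),
                    c("dataset_id", "person_id"))
  else stats::setNames(list(pd), "person_id")
  wts <- if (het_residuals) nlme::varIdent(form = ~ 1 | side) else NULL
  fit <- nlme::lme(f, data = d, random = random, weights = wts,
                   method = "ML", na.action = stats::na.fail,
                   control = nlme::lmeControl(opt = "optim", maxIter = 150,
                                              msMaxIter = 150))
  person_pd <- fit$modelStruct$reStruct[["person_id"]]
  G <- as.matrix(person_pd) * fit$sigma^2
  ab <- match(c(a_col, b_col), colnames(G))
  sigma_ab <- G[ab[1], ab[2]]

  # Delta-method SE of sigma_ab through apVar's natural parametrisation:
  # the slope block contributes (log sd_a, log sd_b, 2*atanh(rho)) as the
  # last three person-level parameters, and sigma enters as lSigma, so
  # sigma_ab = exp(2*lSigma + la + lb) * tanh(x/2).
  sigma_ab_se <- NA_real_
  apv <- if (se_sigma_ab) fit$apVar else NULL
  if (is.matrix(apv) && isTRUE(attr(apv, "natural"))) {
    pars <- attr(apv, "Pars")
    re_idx <- grep("^reStruct\\.person_id", names(pars))
    lsig_idx <- match("lSigma", names(pars))
    if (length(re_idx) >= 3 && !is.na(lsig_idx)) {
      idx <- c(utils::tail(re_idx, 3), lsig_idx)
      la <- pars[idx[1]]; lb <- pars[idx[2]]; x <- pars[idx[3]]
      lsig <- pars[idx[4]]
      s_ab <- exp(2 * lsig + la + lb) * tanh(x / 2)
      grad <- c(s_ab, s_ab,
                exp(2 * lsig + la + lb) * (1 - tanh(x / 2)^2) / 2,
                2 * s_ab)
      V <- apv[idx, idx, drop = FALSE]
      sigma_ab_se <- sqrt(max(0, drop(t(grad) %*% V %*% grad)))
    }
  }
  list(fixef = nlme::fixef(fit), vcov = as.matrix(stats::vcov(fit)),
       sigma_ab = sigma_ab, sigma_ab_se = sigma_ab_se,
       path_vcov = G[ab, ab], notes = character(), model = fit)
}

fit_mediation_lme4 <- function(d, f, a_col, b_col, random_intercepts,
                               dataset_term, se_sigma_ab = TRUE) {
  bars <- paste0("(0 + ", a_col, " + ", b_col, " | person_id)")
  if (random_intercepts) bars <- paste0("(0 + s_m + s_y || person_id) + ", bars)
  if (dataset_term == "random") bars <- paste0(bars, " + (0 + s_m + s_y || dataset_id)")
  ff <- stats::as.formula(paste(
    "z ~", paste(deparse(f[[3]], width.cutoff = 500), collapse = ""), "+", bars))
  fit <- lme4::lmer(ff, data = d, REML = FALSE, na.action = stats::na.fail,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  vc <- lme4::VarCorr(fit)
  slope_block <- NULL
  for (m in vc[grep("^person_id", names(vc))]) {
    if (all(c(a_col, b_col) %in% rownames(m))) slope_block <- as.matrix(m)[, , drop = TRUE]
  }
  G <- slope_block[c(a_col, b_col), c(a_col, b_col)]
  sigma_ab <- G[1, 2]

  # asymptotic covariance of the variance parameters: numeric Hessian of the
  # ML deviance in (theta, log sigma); sigma_ab = sigma^2 * (L L')_{ab}
  sigma_ab_se <- if (!se_sigma_ab) NA_real_ else tryCatch({
    devf <- lme4::lFormula(ff, data = d, REML = FALSE,
                           control = lme4::lmerControl(calc.derivs = FALSE,
                                                       check.conv.singular = "ignore"))
    devfun <- do.call(lme4::mkLmerDevfun, devf)
    th_hat <- lme4::getME(fit, "theta")
    lsig_hat <- log(stats::sigma(fit))
    # profile deviance is in theta only; reparametrize to include sigma
    dev2 <- function(p) {
      th <- p[-length(p)]; lsig <- p[length(p)]
      n <- nrow(d)
      dvp <- devfun(th)  # profiled deviance
      # recover full -2 loglik at (theta, sigma): d(th, sig) =
      #   dvp + n*(sig2hat/sig2 - 1 - log(sig2hat/sig2)) with sig2hat profiled
      pwrss <- environment(devfun)$pp$sqrL(1) + environment(devfun)$resp$wrss()
      sig2hat <- pwrss / n
      sig2 <- exp(2 * lsig)
      dvp + n * (sig2hat / sig2 - 1 + log(sig2 / sig2hat))
    }
    p_hat <- c(th_hat, lsig_hat)
    H <- num_hessian(dev2, p_hat)
    Vp <- solve(H / 2)             # asymptotic covariance of (theta, log sigma)
    ths <- find_slope_theta(fit, a_col, b_col)
    gfun <- function(p) {
      th <- p[-length(p)]; sig2 <- exp(2 * p[length(p)])
      L <- matrix(c(th[ths[1]], th[ths[2]], 0, th[ths[3]]), 2, 2)
      (L %*% t(L))[1, 2] * sig2
    }
    grad <- num_grad(gfun, p_hat)
    sqrt(max(0, drop(t(grad) %*% Vp %*% grad)))
  }, error = function(e) NA_real_)
  list(fixef = lme4::fixef(fit), vcov = as.matrix(stats::vcov(fit)),
       sigma_ab = sigma_ab, sigma_ab_se = sigma_ab_se,
       path_vcov = G, notes = character(), model = fit)
}

# positions, within getME(fit, "theta"), of the L[1,1], L[2,1], L[2,2]
# entries of the a/b slope block; lme4 names them "<grp>.<a>", "<grp>.<b>.<a>"
# and "<grp>.<b>"
find_slope_theta <- function(fit, a_col, b_col) {
  nm <- names(lme4::getME(fit, "theta"))
  i1 <- which(endsWith(nm, paste0(".", a_col)) & !grepl(b_col, nm, fixed = TRUE))
  i2 <- which(endsWith(nm, paste0(".", b_col, ".", a_col)))
  i3 <- which(endsWith(nm, paste0(".", b_col)) & !grepl(a_col, nm, fixed = TRUE))
  if (length(i1) != 1 || length(i2) != 1 || length(i3) != 1)
    stop("could not locate slope block in theta")
  c(i1, i2, i3)
}

num_grad <- function(fn, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, numeric(1))
}

num_hessian <- function(fn, x, eps = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  h <- eps * pmax(1, abs(x))
  f0 <- fn(x)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <-
          (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  (H + t(H)) / 2
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("Stacked 1-1-1 mediation fit (", x$engine, ")\n", sep = "")
  cat(sprintf("  a = %.4f (SE %.4f)  b = %.4f (SE %.4f)  c' = %.4f\n",
              x$a, x$se_a, x$b, x$se_b, x$cprime))
  cat(sprintf("  sigma_ab = %.5f (SE %s)\n", x$sigma_ab,
              if (is.na(x$sigma_ab_se)) "NA" else sprintf("%.5f", x$sigma_ab_se)))
  cat(sprintf("  indirect = a*b + sigma_ab = %.5f\n", x$indirect))
  invisible(x)
}

#' Monte-Carlo confidence interval for the indirect effect
#'
#' Draws `(a*, b*)` from the bivariate normal implied by the fixed-effect
#' estimates and their asymptotic covariance, and `sigma_ab*` from a normal
#' with the estimated asymptotic SE; each draw's indirect effect is
#' `a* b* + sigma_ab*`. Draws whose `sigma_ab*` would imply `|rho| > 1`
#' given the estimated path SDs are clipped to the boundary and counted.
#' The interval is the 2.5/97.5 percentile range.
#'
#' @param fit a `mediation_fit`, or a list with elements `a`, `b`,
#'   `vcov_ab`, `sigma_ab`, `sigma_ab_se` (and optionally `path_vcov`).
#' @param n_draws number of Monte-Carlo draws.
#' @param seed integer seed (mandatory for reproducibility).
#' @param level confidence level.
#' @return list: `indirect` (point estimate), `ci`, `n_draws`, `seed`,
#'   `n_clipped`, and the draw vector (`draws`).
#' @export
monte_carlo_indirect <- function(fit, n_draws = 20000, seed, level = 0.95) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  mu <- c(fit$a, fit$b)
  V <- fit$vcov_ab
  if (any(!is.finite(V))) stop("non-finite covariance of (a, b)", call. = FALSE)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10 * max(abs(ev), 1)))
    stop("covariance of (a, b) is not positive semidefinite", call. = FALSE)
  set.seed(seed)
  Z <- matrix(stats::rnorm(2L * n_draws), n_draws, 2L)
  R <- chol_psd(V)
  ab <- sweep(Z %*% R, 2L, mu, "+")
  s_se <- fit$sigma_ab_se
  s <- if (is.na(s_se) || s_se == 0) rep(fit$sigma_ab, n_draws)
  else stats::rnorm(n_draws, fit$sigma_ab, s_se)
  n_clipped <- 0L
  if (!is.null(fit$path_vcov) && all(is.finite(fit$path_vcov))) {
    lim <- sqrt(fit$path_vcov[1, 1] * fit$path_vcov[2, 2])
    bad <- abs(s) > lim
    n_clipped <- sum(bad)
    s[bad] <- sign(s[bad]) * lim
  }
  draws <- ab[, 1] * ab[, 2] + s
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(draws, c(alpha, 1 - alpha)))
  list(indirect = unname(mu[1] * mu[2] + fit$sigma_ab), ci = ci,
       n_draws = n_draws, seed = seed, n_clipped = n_clipped, draws = draws)
}

# upper-triangular factor tolerant of a PSD (rank-deficient) matrix
chol_psd <- function(V) {
  out <- tryCatch(chol(V), error = function(e) NULL)
  if (!is.null(out)) return(out)
  e <- eigen(V, symmetric = TRUE)
  t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(V)) %*% t(e$vectors))
}

#' Co-moderation of the a- and b-paths by a person-level covariate
#'
#' Refits the stacked mediation model with cross-level interactions
#' `moderator x a-path predictor` (mediator side) and
#' `moderator x b-path predictor` (outcome side); the two interaction
#' coefficients say whether persons high on the moderator (e.g. baseline
#' emotion differentiation) have systematically stronger or weaker temporal
#' paths.
#'
#' @param st a `stacked_table`.
#' @param moderator person-level column name in `st`.
#' @param ... passed to [fit_mediation()].
#' @return list: the refitted `mediation_fit` (`fit`) and `interactions`,
#'   the two moderated-path coefficient rows.
#' @export
co_moderation <- function(st, moderator, ...) {
  info <- attr(st, "mediation")
  a_pred <- info$m_predictors[1]
  b_pred <- info$y_predictors[1]
  st2 <- st
  st2[[paste0(a_pred, "_x_mod")]] <- st2[[a_pred]] * st2[[moderator]]
  st2[[paste0(b_pred, "_x_mod")]] <- st2[[b_pred]] * st2[[moderator]]
  info$m_predictors <- c(info$m_predictors, paste0(a_pred, "_x_mod"), moderator)
  info$y_predictors <- c(info$y_predictors, paste0(b_pred, "_x_mod"), moderator)
  for (v in c(paste0(a_pred, "_x_mod"), moderator))
    st2[[paste0("sm_", v)]] <- st2$s_m * st2[[v]]
  for (v in c(paste0(b_pred, "_x_mod"), moderator))
    st2[[paste0("sy_", v)]] <- st2$s_y * st2[[v]]
  attr(st2, "mediation") <- info
  class(st2) <- class(st)
  fit <- fit_mediation(st2, ...)
  ia <- fit$coef[fit$coef$term %in% c(paste0("sm_", a_pred, "_x_mod"),
                                      paste0("sy_", b_pred, "_x_mod")), ,
                 drop = FALSE]
  ia$path <- ifelse(grepl("^sm_", ia$term), "a", "b")
  list(fit = fit, interactions = ia)
}
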