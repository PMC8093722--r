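#' Prepare the analysis table of outcomes and covariates
#'
#' Adds the transformed outcomes used in the regressions (square-root core
#' home range, log extended home range), dichotomizes age into <1 yr versus
#' >=1 yr, sets the referent levels (intact male; <1 yr; <2 h outside), and
#' screens the four outcomes for collinearity: any pairwise Pearson |r| at
#' or above `r_cut` is flagged, otherwise all four are retained as separate
#' outcomes.
#'
#' @param table data.frame with one row per dog carrying
#'   `daily_distance_km`, `core_hr_ha`, `extended_hr_ha`,
#'   `pct_time_household` and the covariates (`age_class`, `sex_status`,
#'   `reported_time_outside`, `fixes_per_hour`, `recording_hours`, `site`).
#' @param r_cut collinearity threshold on |Pearson r| (default 0.7).
#' @return the table with columns `sqrt_core_hr`, `log_extended_hr`,
#'   `age_dichot` added; attributes `outcome_cor` (correlation matrix) and
#'   `collinear_pairs` (data.frame of flagged pairs, zero rows when all
#'   outcomes are retained).
#' @export
prepare_outcomes <- function(table, r_cut = 0.7) {
  outs <- c("daily_distance_km", "core_hr_ha", "extended_hr_ha",
            "pct_time_household")
  miss <- setdiff(outs, names(table))
  if (length(miss)) stop("missing outcome column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(table[outs])) stop("missing outcome values are not allowed")
  if (any(table$extended_hr_ha <= 0)) {
    stop("non-positive extended_hr_ha cannot be log-transformed")
  }
  if (any(table$core_hr_ha < 0)) stop("negative core_hr_ha")
  table$sqrt_core_hr <- sqrt(table$core_hr_ha)
  table$log_extended_hr <- log(table$extended_hr_ha)
  if ("age_class" %in% names(table)) {
    table$age_dichot <- factor(
      ifelse(as.character(table$age_class) == "<1 yr", "<1 yr", ">=1 yr"),
      levels = c("<1 yr", ">=1 yr"))
  }
  if ("sex_status" %in% names(table)) {
    table$sex_status <- stats::relevel(factor(table$sex_status),
                                       ref = "intact male")
  }
  cm <- stats::cor(table[outs])
  pairs <- which(abs(cm) >= r_cut & upper.tri(cm), arr.ind = TRUE)
  flagged <- data.frame(var1 = rownames(cm)[pairs[, 1]],
                        var2 = colnames(cm)[pairs[, 2]],
                        r = cm[pairs])
  attr(table, "outcome_cor") <- cm
  attr(table, "collinear_pairs") <- flagged
  table
}

#' Fit a random-intercept mixed model for one movement outcome
#'
#' REML fit of `outcome ~ fixed_terms + (1 | site)`. Coefficients are
#' reported against the referent levels with Wald standard errors, z-based
#' p-values (the large-sample convention of the study's software), and a
#' joint Wald chi-square test per categorical term. A boundary fit with
#' zero between-site variance is reported as such, not an error; a table
#' with a single site falls back to ordinary least squares with a warning.
#' Significance is declared at p <= `alpha` (0.1 by default, guarding
#' against type II error at this sample size).
#'
#' @param table a prepared analysis table (see [prepare_outcomes()]).
#' @param outcome name of the response column.
#' @param fixed_terms character vector of fixed-effect column names.
#' @param alpha significance threshold on p.
#' @return a `mixed_fit`: `coefficients` (data.frame term/estimate/se/z/p/
#'   significant), `term_tests` (joint Wald per model term), `var_between`,
#'   `var_within`, `icc`, `n`, `n_sites`, `singular`, and the underlying
#'   `fit` object.
#' @export
fit_mixed_model <- function(table, outcome, fixed_terms, alpha = 0.1) {
  stopifnot(outcome %in% names(table), all(fixed_terms %in% names(table)),
            "site" %in% names(table))
  table$site <- factor(table$site)
  n_sites <- nlevels(droplevels(table$site))
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ")
         else "1"
  if (n_sites < 2) {
    warning("only one site present; fitting ordinary least squares")
    fit <- stats::lm(stats::reformulate(rhs, outcome), data = table)
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    vb <- 0
    vw <- summary(fit)$sigma^2
    singular <- TRUE
  } else {
    form <- stats::as.formula(paste(outcome, "~", rhs, "+ (1 | site)"))
    fit <- lme4::lmer(form, data = table, REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    vb <- vc$vcov[vc$grp == "site"]
    vw <- vc$vcov[vc$grp == "Residual"]
    singular <- lme4::isSingular(fit)
  }
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), z = unname(z), p = unname(p),
                      significant = unname(p) <= alpha,
                      row.names = NULL)
  # joint Wald chi-square per model term (needed for factors with >2 levels)
  assign_idx <- attr(stats::model.matrix(
    stats::reformulate(rhs), data = table), "assign")
  V <- as.matrix(stats::vcov(fit))
  term_labels <- attr(stats::terms(stats::reformulate(rhs)), "term.labels")
  term_tests <- do.call(rbind, lapply(seq_along(term_labels), function(k) {
    idx <- which(assign_idx == k)
    b <- beta[idx]
    W <- drop(t(b) %*% solve(V[idx, idx, drop = FALSE]) %*% b)
    data.frame(term = term_labels[k], df = length(idx), chisq = W,
               p = stats::pchisq(W, length(idx), lower.tail = FALSE))
  }))
  if (!is.null(term_tests)) {
    term_tests$significant <- term_tests$p <= alpha
  }
  structure(list(outcome = outcome, coefficients = coefs,
                 term_tests = term_tests,
                 var_between = vb, var_within = vw,
                 icc = if (vb + vw > 0) vb / (vb + vw) else NA_real_,
                 n = nrow(table), n_sites = n_sites,
                 singular = singular, alpha = alpha, fit = fit),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<mixed_fit> %s: n = %d over %d sites, ICC = %s%s\n",
              x$outcome, x$n, x$n_sites,
              format(x$icc, digits = digits),
              if (x$singular) " (boundary: between-site variance 0)" else ""))
  print(x$coefficients, digits = digits)
  invisible(x)
}

#' Intracluster correlation coefficient of a mixed fit
#'
#' Proportion of total outcome variance attributable to between-site
#' variation: `var_between / (var_between + var_within)`.
#'
#' @param fit a `mixed_fit`.
#' @return proportion in `[0, 1]`; `NA` with a warning when both variance
#'   components are zero.
#' @export
compute_icc <- function(fit) {
  vb <- fit$var_between
  vw <- fit$var_within
  if (vb + vw <= 0) {
    warning("both variance components are zero; ICC undefined")
    return(NA_real_)
  }
  vb / (vb + vw)
}

#' Unconditional (single-covariate) associations
#'
#' For every explanatory variable, fits a single-covariate random-intercept
#' model per outcome and reports the covariate's p-value (joint Wald for
#' categorical variables, coefficient z-test for continuous ones), plus the
#' descriptive statistics: per-category mean (SD) and median of each
#' outcome for categorical covariates, median and range for continuous
#' ones. Covariates without variation are excluded with a warning, as are
#' empty categories.
#'
#' @param table prepared analysis table.
#' @param covariates character vector of explanatory columns.
#' @param outcomes named character vector of outcome columns (names used
#'   for reporting).
#' @param alpha significance threshold.
#' @return list with `p_values` (covariate x outcome data.frame),
#'   `descriptives` (long-format data.frame), `excluded` (character).
#' @export
unconditional_tests <- function(table,
                                covariates = c("age_class", "sex_status",
                                               "reported_time_outside",
                                               "fixes_per_hour",
                                               "recording_hours"),
                                outcomes = c(daily_distance = "daily_distance_km",
                                             core_hr = "sqrt_core_hr",
                                             extended_hr = "log_extended_hr",
                                             pct_household = "pct_time_household"),
                                alpha = 0.1) {
  excluded <- character(0)
  keep <- character(0)
  for (cv in covariates) {
    v <- table[[cv]]
    if (is.factor(v) || is.character(v)) {
      v <- droplevels(factor(v))
      if (nlevels(v) < 2) {
        warning("covariate ", cv, " excluded due to lack of variation")
        excluded <- c(excluded, cv)
        next
      }
      table[[cv]] <- v
    } else if (stats::var(v) == 0) {
      warning("covariate ", cv, " excluded due to lack of variation")
      excluded <- c(excluded, cv)
      next
    }
    keep <- c(keep, cv)
  }
  pv <- expand.grid(covariate = keep, outcome = names(outcomes),
                    stringsAsFactors = FALSE)
  pv$p <- NA_real_
  for (r in seq_len(nrow(pv))) {
    fit <- fit_mixed_model(table, outcomes[[pv$outcome[r]]],
                           pv$covariate[r], alpha = alpha)
    pv$p[r] <- if (is.factor(table[[pv$covariate[r]]])) {
      fit$term_tests$p[1]
    } else {
      fit$coefficients$p[2]
    }
  }
  pv$significant <- pv$p <= alpha

  desc <- list()
  for (cv in keep) {
    v <- table[[cv]]
    if (is.factor(v)) {
      for (lev in levels(v)) {
        rows <- v == lev
        for (on in names(outcomes)) {
          # descriptives on the untransformed scale where available
          raw <- switch(on, core_hr = "core_hr_ha",
                        extended_hr = "extended_hr_ha", outcomes[[on]])
          y <- table[[raw]][rows]
          desc[[length(desc) + 1L]] <- data.frame(
            covariate = cv, level = lev, n = sum(rows), outcome = on,
            mean = mean(y), sd = stats::sd(y), median = stats::median(y))
        }
      }
    } else {
      desc[[length(desc) + 1L]] <- data.frame(
        covariate = cv, level = "(continuous)", n = length(v),
        outcome = "covariate", mean = mean(v), sd = stats::sd(v),
        median = stats::median(v))
    }
  }
  list(p_values = pv, descriptives = do.call(rbind, desc),
       excluded = excluded)
}

#' Leave-one-site-out influence assessment
#'
#' Refits a model dropping each site in turn and records the fixed-effect
#' estimates, flagging terms whose coefficient changes sign; additionally
#' flags observations with standardized residuals beyond `z_cut`.
#'
#' @param table prepared analysis table.
#' @param outcome,fixed_terms as in [fit_mixed_model()].
#' @param z_cut standardized-residual flag threshold.
#' @return list with `site_refits` (data.frame site x term estimates),
#'   `sign_stable` (named logical per term), `outlier_rows` (indices).
#' @export
site_influence <- function(table, outcome, fixed_terms, z_cut = 3) {
  full <- fit_mixed_model(table, outcome, fixed_terms)
  sites <- unique(as.character(table$site))
  refits <- do.call(rbind, lapply(sites, function(s) {
    f <- fit_mixed_model(table[table$site != s, , drop = FALSE],
                         outcome, fixed_terms)
    data.frame(site_dropped = s, term = f$coefficients$term,
               estimate = f$coefficients$estimate)
  }))
  base <- stats::setNames(full$coefficients$estimate,
                          full$coefficients$term)
  sign_stable <- vapply(names(base), function(tm) {
    est <- refits$estimate[refits$term == tm]
    all(sign(est) == sign(base[tm]) | est == 0)
  }, TRUE)
  res <- stats::residuals(full$fit)
  z <- res / stats::sd(res)
  list(site_refits = refits, sign_stable = sign_stable,
       outlier_rows = which(abs(z) > z_cut))
}

#' Simulate an analysis table with known effects
#'
#' Parametric generator for calibration studies of the mixed-model stage:
#' `y = intercept + beta * x + site effect + residual`, with a standard
#' normal continuous covariate `x`, site effects N(0, `sigma_site^2`) and
#' residuals N(0, `sigma_resid^2`). The default variance split gives an
#' intracluster correlation of `sigma_site^2 / (sigma_site^2 +
#' sigma_resid^2)`.
#'
#' @param n dogs; the study analysed 73.
#' @param n_sites sites; the study had 8.
#' @param beta true covariate effect.
#' @param sigma_site,sigma_resid standard deviations of the site effect and
#'   residual.
#' @param seed integer seed.
#' @return data.frame with `y`, `x`, `site`.
#' @export
simulate_analysis_table <- function(n = 73, n_sites = 8, beta = 0,
                                    sigma_site = 1, sigma_resid = 2,
                                    seed = 1L) {
  with_seed(seed, {
    site <- factor(rep_len(seq_len(n_sites), n))
    u <- stats::rnorm(n_sites, 0, sigma_site)
    x <- stats::rnorm(n)
    data.frame(
      y = 10 + beta * x + u[as.integer(site)] +
        stats::rnorm(n, 0, sigma_resid),
      x = x, site = paste0("site", site))
  })
}
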