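#' Model specification for the correlate analyses
#'
#' Fixed effects are education (ref: none), abdominal obesity (ref: normal
#' waist), high cholesterol (ref: normal), marital status (ref: never
#' married), work status (ref: unemployed), smoking (ref: non-smoker) and
#' diabetes (ref: none); diabetes is omitted from the lipid-lowering
#' eligibility model because age-40-plus diabetes is part of that outcome's
#' definition. Random intercepts: country nested within world region. The
#' eligibility outcomes are modelled among records with excess heart age
#' only. Survey weights are never used in these models.
#'
#' @param outcome One of `"excess_pha"`, `"elig_aht"`, `"elig_llt"`.
#' @return List with `outcome`, `fixed` (character vector of terms), and
#'   `subset_excess` (logical).
#' @export
model_spec <- function(outcome = c("excess_pha", "elig_aht", "elig_llt")) {
  outcome <- match.arg(outcome)
  fixed <- c("education4", "abdominal_obesity", "high_cholesterol",
             "marital3", "work5", "smoker", "diabetes")
  if (outcome == "elig_llt") fixed <- setdiff(fixed, "diabetes")
  list(outcome = outcome, fixed = fixed,
       subset_excess = outcome %in% c("elig_aht", "elig_llt"))
}

#' Mixed-effects logistic model for excess heart age or treatment eligibility
#'
#' Fits a logistic GLMM with random intercepts for region and for country
#' within region (`lme4::glmer`), reporting exponentiated fixed effects as
#' odds ratios with Wald 95% CIs and z-test p values, plus the two
#' random-intercept variances. Random terms whose grouping factor has fewer
#' than two observed levels are dropped (variance reported as 0); with no
#' random terms left the model collapses to ordinary logistic regression —
#' the single-country limit of the nested design. The fit either converges or
#' carries an explicit non-convergence status; there is no silent fallback.
#'
#' @param data Cleaned, scored data with the outcome and covariate columns.
#' @param outcome See [model_spec()].
#' @param nAGQ Integrand approximation passed to `lme4::glmer`: 1 (Laplace,
#'   default) or 0 (faster penalized-least-squares step for the random
#'   effects, used for large replicate studies).
#' @return Object of class `pha_glmm`: list with `table` (term, estimate, se,
#'   or, ci_lo, ci_hi, p, separation flag), `varcomp`, `converged`, `status`,
#'   `n`, `outcome`, and the underlying `fit`.
#' @export
fit_glmm <- function(data, outcome = c("excess_pha", "elig_aht", "elig_llt"),
                     nAGQ = 1) {
  spec <- model_spec(outcome)
  if (spec$subset_excess) {
    if (!"excess" %in% names(data)) stop("data lacks the 'excess' flag")
    data <- data[data$excess, , drop = FALSE]
  }
  outcome_col <- if (spec$outcome == "excess_pha") "excess" else spec$outcome
  y <- data[[outcome_col]]
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("degenerate outcome: both levels must be present")
  }
  model_vars <- c(outcome_col, spec$fixed)
  cc <- stats::complete.cases(data[model_vars])
  data <- data[cc, , drop = FALSE]
  data <- droplevels(data)

  re_terms <- c()
  if ("region" %in% names(data) && length(unique(data$region)) >= 2) {
    re_terms <- c(re_terms, "(1 | region)")
  }
  if (all(c("region", "country") %in% names(data)) &&
      length(unique(data$country)) >= 2) {
    re_terms <- c(re_terms, "(1 | region:country)")
  }
  rhs <- paste(c(spec$fixed, re_terms), collapse = " + ")
  form <- stats::as.formula(paste(outcome_col, "~", rhs))

  if (length(re_terms) > 0) {
    fit <- lme4::glmer(form, data = data, family = stats::binomial(),
                       nAGQ = nAGQ)
    msgs <- fit@optinfo$conv$lme4$messages
    converged <- is.null(msgs)
    status <- if (converged) "converged" else paste(msgs, collapse = "; ")
    co <- summary(fit)$coefficients
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_country <- vc$vcov[vc$grp == "region:country"]
    var_region <- vc$vcov[vc$grp == "region"]
  } else {
    fit <- stats::glm(form, data = data, family = stats::binomial())
    converged <- fit$converged
    status <- if (converged) "converged" else "glm did not converge"
    co <- summary(fit)$coefficients
    var_country <- numeric(0)
    var_region <- numeric(0)
  }
  est <- co[, 1]
  se <- co[, 2]
  zcrit <- stats::qnorm(0.975)
  table <- tibble::tibble(
    term = rownames(co),
    estimate = unname(est),
    se = unname(se),
    or = exp(unname(est)),
    ci_lo = exp(unname(est) - zcrit * unname(se)),
    ci_hi = exp(unname(est) + zcrit * unname(se)),
    p = 2 * stats::pnorm(-abs(unname(est) / unname(se))),
    ## complete or quasi-complete separation shows as runaway estimates
    ## with enormous standard errors
    separation = abs(unname(est)) > 15 | unname(se) > 100
  )
  varcomp <- tibble::tibble(
    group = c("region", "country_in_region"),
    variance = c(if (length(var_region)) var_region else 0,
                 if (length(var_country)) var_country else 0)
  )
  structure(
    list(table = table, varcomp = varcomp, converged = converged,
         status = status, n = nrow(data), outcome = spec$outcome, fit = fit),
    class = "pha_glmm"
  )
}

#' @export
print.pha_glmm <- function(x, ...) {
  cat("Mixed-effects logistic model for", x$outcome,
      "(n =", x$n, ",", x$status, ")\n")
  print(x$table, ...)
  cat("Random-intercept variances:\n")
  print(x$varcomp, ...)
  invisible(x)
}

#' Odds-ratio table in reporting layout
#'
#' @param x A `pha_glmm` fit.
#' @return Tibble with term, OR, CI bounds and p value, followed by the
#'   variance-component rows.
#' @export
or_table <- function(x) {
  stopifnot(inherits(x, "pha_glmm"))
  main <- x$table |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::transmute(.data$term, or = .data$or, ci_lo = .data$ci_lo,
                     ci_hi = .data$ci_hi, p = .data$p)
  vc <- tibble::tibble(
    term = paste0("var_", x$varcomp$group),
    or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_
  )
  vc$or <- NA_real_
  vc_val <- tibble::tibble(term = vc$term, value = x$varcomp$variance)
  dplyr::bind_rows(main, dplyr::left_join(vc, vc_val, by = "term"))
}
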