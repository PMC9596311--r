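#' Design-aware weighted prevalence
#'
#' Point estimate is the weighted proportion `sum(w*y)/sum(w)`. The standard
#' error uses stratified between-PSU Taylor linearization of the ratio
#' estimator: with linearized scores `z_i = w_i (y_i - p) / W` accumulated to
#' PSU totals `z_hc`, the variance is
#' `sum_h n_h/(n_h - 1) sum_c (z_hc - mean_h)^2` over strata `h` with `n_h`
#' PSUs. Strata with a single PSU contribute `(z_hc - grand mean)^2`
#' (grand-mean centering). The 95% CI is normal-approximation on the
#' proportion scale, truncated to \[0,1\].
#'
#' @param y Numeric or logical indicator (0/1).
#' @param w Positive sampling weights.
#' @param psu,stratum Cluster and stratum identifiers; `NULL` treats each
#'   record as its own PSU in a single stratum (simple random sampling).
#' @return One-row tibble: `proportion`, `se`, `ci_lo`, `ci_hi`, `n`.
#' @examples
#' weighted_prevalence(c(1, 0, 1, 0), w = c(2, 1, 1, 4))  # 3/8
#' @export
weighted_prevalence <- function(y, w, psu = NULL, stratum = NULL) {
  y <- as.numeric(y)
  keep <- !is.na(y)
  y <- y[keep]
  if (length(y) == 0) stop("weighted_prevalence: empty domain")
  w <- w[keep]
  if (all(w == 0)) stop("weighted_prevalence: all weights are zero")
  stopifnot(all(w > 0))
  psu <- if (is.null(psu)) seq_along(y) else psu[keep]
  stratum <- if (is.null(stratum)) rep(1L, length(y)) else stratum[keep]
  W <- sum(w)
  p <- sum(w * y) / W
  z <- w * (y - p) / W
  psu_tot <- tapply(z, list(stratum = stratum, psu = psu), sum)
  v <- 0
  all_tot <- unlist(lapply(rownames(psu_tot), function(h) {
    tt <- psu_tot[h, ]
    tt[!is.na(tt)]
  }))
  grand_mean <- mean(all_tot)
  for (h in rownames(psu_tot)) {
    tt <- psu_tot[h, ]
    tt <- tt[!is.na(tt)]
    n_h <- length(tt)
    if (n_h >= 2) {
      v <- v + n_h / (n_h - 1) * sum((tt - mean(tt))^2)
    } else {
      v <- v + sum((tt - grand_mean)^2)
    }
  }
  se <- sqrt(v)
  zcrit <- stats::qnorm(0.975)
  tibble::tibble(
    proportion = p, se = se,
    ci_lo = max(0, p - zcrit * se), ci_hi = min(1, p + zcrit * se),
    n = length(y)
  )
}

.svy_by <- function(data, indicator_col) {
  data |>
    dplyr::group_by(.data$country, .data$sex) |>
    dplyr::group_modify(function(d, key) {
      weighted_prevalence(d[[indicator_col]], d$sample_weight,
                          d$psu, d$stratum)
    }) |>
    dplyr::ungroup()
}

#' Prevalence of heart-age gap categories by country and sex
#'
#' Weighted proportions of the four gap classes (low / equal / high /
#' very_high) per country-sex domain, with linearized standard errors. The
#' four proportions sum to one within numerical tolerance because the classes
#' partition every domain.
#'
#' @param scored Data frame with `country`, `sex`, `gap_class`,
#'   `sample_weight`, `psu`, `stratum`.
#' @return Tidy tibble keyed by country, sex, category.
#' @export
category_prevalence_table <- function(scored) {
  out <- lapply(levels(scored$gap_class), function(cat) {
    d <- scored
    d$ind <- d$gap_class == cat
    res <- .svy_by(d, "ind")
    res$category <- cat
    res
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(category = factor(.data$category,
                                    levels = levels(scored$gap_class))) |>
    dplyr::arrange(.data$country, .data$sex, .data$category)
}

#' Treatment eligibility among people with excess heart age
#'
#' For each country-sex domain and excess threshold (gap of at least 1, 5, 10
#' or 20 years, sentinel-aware via the gap lower bound), the weighted
#' proportion eligible for each therapy with excess as the denominator. Empty
#' denominator domains are flagged, not dropped.
#'
#' @param scored Scored data with eligibility columns ([add_eligibility()]).
#' @param thresholds Integer gap thresholds in years.
#' @return Tibble keyed by country, sex, threshold, therapy.
#' @export
eligibility_among_excess <- function(scored, thresholds = c(1, 5, 10, 20)) {
  gap_lb <- pha_gap_lower_bound(scored$age, scored$pha_coded)
  rows <- list()
  for (t in thresholds) {
    denom <- scored[gap_lb >= t, , drop = FALSE]
    for (therapy in c("elig_aht", "elig_llt")) {
      doms <- scored |> dplyr::distinct(.data$country, .data$sex)
      res <- lapply(seq_len(nrow(doms)), function(i) {
        d <- denom[denom$country == doms$country[i] &
                     denom$sex == doms$sex[i], , drop = FALSE]
        if (nrow(d) == 0) {
          return(tibble::tibble(country = doms$country[i], sex = doms$sex[i],
                                proportion = NA_real_, se = NA_real_,
                                ci_lo = NA_real_, ci_hi = NA_real_,
                                n = 0L, empty_domain = TRUE))
        }
        pr <- weighted_prevalence(d[[therapy]], d$sample_weight,
                                  d$psu, d$stratum)
        dplyr::bind_cols(tibble::tibble(country = doms$country[i],
                                        sex = doms$sex[i]),
                         pr, tibble::tibble(empty_domain = FALSE))
      })
      res <- dplyr::bind_rows(res)
      res$threshold <- t
      res$therapy <- therapy
      rows[[length(rows) + 1]] <- res
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::relocate(dplyr::all_of(c("country", "sex", "threshold", "therapy")))
}

#' Weighted quantiles (type 1: left-continuous inverse CDF)
#'
#' Returns the smallest data value whose cumulative weight share reaches each
#' probability.
#'
#' @param x Numeric values.
#' @param w Positive weights.
#' @param probs Probabilities in (0,1).
#' @return Numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Heart-age category prevalence within risk quintiles
#'
#' Per country, quintile cut points of the weighted 10-year-risk distribution
#' are computed and each record assigned Q1--Q5; ties at a boundary fall to
#' the lower quintile (so fully tied risks all land in Q1). Weighted gap-class
#' prevalences are then reported per quintile.
#'
#' @param scored Scored data with `risk_10y`, `gap_class`, design columns.
#' @return Tibble keyed by country, quintile, category.
#' @export
risk_quintile_strata <- function(scored) {
  scored |>
    dplyr::group_by(.data$country) |>
    dplyr::group_modify(function(d, key) {
      q <- weighted_quantile(d$risk_10y, d$sample_weight,
                             c(0.2, 0.4, 0.6, 0.8))
      d$quintile <- 1L + rowSums(outer(d$risk_10y, q, `>`))
      out <- lapply(levels(d$gap_class), function(cat) {
        d |>
          dplyr::group_by(.data$quintile) |>
          dplyr::group_modify(function(dd, k) {
            pr <- weighted_prevalence(dd$gap_class == cat, dd$sample_weight,
                                      dd$psu, dd$stratum)
            pr$category <- cat
            pr
          }) |>
          dplyr::ungroup()
      })
      dplyr::bind_rows(out)
    }) |>
    dplyr::ungroup()
}

#' One-way ANOVA of country-level prevalences across groups
#'
#' Classic one-way ANOVA on country-level prevalence values grouped by region
#' or income band. Groups with fewer than two countries are excluded with a
#' warning (no within-group variance contribution possible).
#'
#' @param prevalence Numeric country-level prevalences.
#' @param group Grouping labels (region or income), same length.
#' @return List: `F`, `df_between`, `df_within`, `p`, `excluded_groups`.
#' @export
group_anova <- function(prevalence, group) {
  group <- as.character(group)
  sizes <- table(group)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("group_anova: excluding groups with <2 countries: ",
            paste(small, collapse = ", "))
    keep <- !(group %in% small)
    prevalence <- prevalence[keep]
    group <- group[keep]
  }
  if (length(unique(group)) < 2) stop("group_anova: need >=2 usable groups")
  fit <- stats::lm(prevalence ~ factor(group))
  an <- stats::anova(fit)
  list(F = an[1, "F value"], df_between = an[1, "Df"],
       df_within = an[2, "Df"], p = an[1, "Pr(>F)"],
       excluded_groups = small)
}

#' Plot-ready flow table of chronological vs predicted heart-age bands
#'
#' Unweighted counts of chronological 5-year band by PHA band by sex (the
#' divergence description deliberately ignores the survey design).
#'
#' @param scored Scored data with `age`, `pha_coded`, `sex`.
#' @return Tibble of counts keyed by sex, age band, PHA band.
#' @export
sankey_flow_table <- function(scored) {
  tb <- tibble::tibble(
    sex = scored$sex,
    age_band = pha_age_group(scored$age),
    pha_band = pha_age_group(scored$pha_coded)
  ) |>
    dplyr::count(.data$sex, .data$age_band, .data$pha_band, name = "count")
  tb
}
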