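#' Fit a cross-sectional age-trend model with parsimonious selection
#'
#' Fits nested linear models of a z-scored outcome on z-scored age, its
#' square, sex and sex-by-age interactions, and selects the smallest model
#' that fits the data best. With the default F-test criterion the selection
#' is forward: a term block enters only when its addition is jointly
#' significant at `alpha` (nested F-test); candidate blocks are tested in
#' the order age, age^2 (only with age present), sex main effect, and
#' sex-specific age slopes (only with both age and sex present). With
#' `criterion = "aic"` the best-AIC candidate wins, with fewest parameters
#' breaking ties. Coefficients are reported on the standardized scale, so a
#' `beta_age` of 0.5 means half a within-cohort SD of the outcome per SD of
#' age.
#'
#' @param cohort A data.frame with `age_years`, `sex` (`"F"`/`"M"` or 0/1)
#'   and the outcome column; typically a [simulate_cohort()] table.
#' @param outcome Name of the outcome column.
#' @param alpha Significance level for nested F-tests.
#' @param criterion `"ftest"` (default) or `"aic"`.
#' @return Object of class `trend_model`: `outcome`, `terms` (character),
#'   `coefficients` (data.frame with standardized estimate, SE, p),
#'   `model_p` (overall F-test vs intercept), `n`, `sex_slopes` (per-sex
#'   standardized age slopes when an interaction is selected), `trace`
#'   (the selection path) and the fitted `lm` object.
#' @examples
#' co <- simulate_cohort(default_cohort_design("mouse"), seed = 1)
#' fit_trend(co, "qrs_ms")
#' @export
fit_trend <- function(cohort, outcome, alpha = 0.05,
                      criterion = c("ftest", "aic")) {
  criterion <- match.arg(criterion)
  if (!outcome %in% names(cohort)) stop("unknown outcome: ", outcome)
  d <- cohort[, c("age_years", "sex", outcome)]
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 10) {
    stop(sprintf("need >= 10 complete rows, got %d", nrow(d)))
  }
  y <- d[[outcome]]
  if (stats::sd(y) < .Machine$double.eps^0.5) stop("constant outcome rejected")
  dz <- data.frame(
    y = as.numeric(scale(y)),
    age = as.numeric(scale(d$age_years)),
    sex = if (is.numeric(d$sex)) d$sex else as.integer(d$sex == "M")
  )
  dz$age2 <- dz$age^2

  if (criterion == "ftest") {
    sel <- select_forward_f(dz, alpha)
  } else {
    sel <- select_by_aic(dz)
  }
  fit <- sel$fit
  sm <- summary(fit)
  cf <- stats::coef(sm)
  coefs <- data.frame(
    term = rownames(cf),
    beta = cf[, "Estimate"],
    se = cf[, "Std. Error"],
    p = cf[, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  fstat <- sm$fstatistic
  model_p <- if (is.null(fstat)) NA_real_ else {
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  }

  sex_slopes <- NULL
  if ("age:sex" %in% sel$terms) {
    b <- stats::coef(fit)
    sex_slopes <- c(female = unname(b["age"]),
                    male = unname(b["age"] + b["age:sex"]))
  }

  structure(
    list(outcome = outcome, terms = sel$terms, coefficients = coefs,
         model_p = model_p, n = nrow(dz), sex_slopes = sex_slopes,
         trace = sel$trace, criterion = criterion, fit = fit),
    class = "trend_model"
  )
}

# Forward nested-F selection over the candidate family.
select_forward_f <- function(dz, alpha) {
  trace <- data.frame(step = character(0), p = numeric(0),
                      added = logical(0), stringsAsFactors = FALSE)
  note <- function(step, p, added) {
    rbind(trace, data.frame(step = step, p = p, added = added,
                            stringsAsFactors = FALSE))
  }
  terms <- character(0)
  fit <- stats::lm(y ~ 1, data = dz)

  try_add <- function(fit, terms, add, label) {
    f2 <- stats::update(fit, stats::as.formula(
      paste("~ . +", paste(add, collapse = " + "))))
    p <- stats::anova(fit, f2)[2, "Pr(>F)"]
    trace <<- note(label, p, !is.na(p) && p < alpha)
    if (!is.na(p) && p < alpha) list(fit = f2, terms = c(terms, add))
    else list(fit = fit, terms = terms)
  }

  r <- try_add(fit, terms, "age", "add age")
  fit <- r$fit; terms <- r$terms
  if ("age" %in% terms) {
    r <- try_add(fit, terms, "age2", "add age^2")
    fit <- r$fit; terms <- r$terms
  }
  r <- try_add(fit, terms, "sex", "add sex")
  fit <- r$fit; terms <- r$terms
  if (all(c("age", "sex") %in% terms)) {
    inter <- c("age:sex", if ("age2" %in% terms) "age2:sex")
    r <- try_add(fit, terms, inter, "add sex-specific age terms")
    fit <- r$fit; terms <- r$terms
  }
  list(fit = fit, terms = terms, trace = trace)
}

# AIC over the full candidate family; fewest parameters breaks ties.
select_by_aic <- function(dz) {
  base <- list(character(0), "age", c("age", "age2"))
  cands <- list()
  for (b in base) {
    cands <- c(cands, list(b, c(b, "sex")))
    if (length(b) > 0) {
      inter <- c("age:sex", if ("age2" %in% b) "age2:sex")
      cands <- c(cands, list(c(b, "sex", inter)))
    }
  }
  fits <- lapply(cands, function(tm) {
    f <- if (length(tm) == 0) y ~ 1 else {
      stats::as.formula(paste("y ~", paste(tm, collapse = " + ")))
    }
    stats::lm(f, data = dz)
  })
  aic <- vapply(fits, stats::AIC, numeric(1))
  npar <- vapply(cands, length, integer(1))
  best <- order(aic, npar)[1]
  trace <- data.frame(
    step = vapply(cands, function(tm) {
      if (length(tm) == 0) "(intercept)" else paste(tm, collapse = "+")
    }, character(1)),
    p = aic, added = seq_along(cands) == best, stringsAsFactors = FALSE)
  names(trace)[2] <- "aic"
  list(fit = fits[[best]], terms = cands[[best]], trace = trace)
}

#' @export
print.trend_model <- function(x, ...) {
  form <- if (length(x$terms) == 0) "(intercept only)" else {
    paste(x$terms, collapse = " + ")
  }
  cat(sprintf("<trend_model: %s ~ %s (n = %d, %s)>\n",
              x$outcome, form, x$n, x$criterion))
  cf <- x$coefficients
  for (i in seq_len(nrow(cf))) {
    if (cf$term[i] == "(Intercept)") next
    cat(sprintf("  %-10s beta = %+6.3f (SE %.3f), p = %.3g\n",
                cf$term[i], cf$beta[i], cf$se[i], cf$p[i]))
  }
  if (!is.null(x$sex_slopes)) {
    cat(sprintf("  age slope: female %+0.3f, male %+0.3f\n",
                x$sex_slopes[["female"]], x$sex_slopes[["male"]]))
  }
  if (!is.na(x$model_p)) cat(sprintf("  overall model p = %.3g\n", x$model_p))
  invisible(x)
}

#' Wilcoxon rank-sum test between two cohorts
#'
#' Two-sided rank-sum test: the p-value is exact (full enumeration of the
#' rank-sum null distribution) when the smaller sample has at most 10
#' observations and there are no ties, and otherwise uses the normal
#' approximation with tie and continuity corrections.
#'
#' @param a,b Numeric samples (non-empty).
#' @return List with `statistic` (Mann-Whitney U for sample `a`), `p_value`
#'   (two-sided) and `exact` (logical).
#' @examples
#' wilcoxon_test(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.10
#' @export
wilcoxon_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("samples must be non-empty")
  ties <- any(duplicated(c(a, b)))
  exact <- min(length(a), length(b)) <= 10 && !ties
  if (length(unique(c(a, b))) == 1) {
    # every observation tied: the rank-sum carries no evidence
    return(list(statistic = length(a) * length(b) / 2, p_value = 1,
                exact = FALSE))
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, exact = exact)
}

#' Arrhythmia prevalence by age bin
#'
#' Percentage of animals with at least one event of each premature-beat
#' class, per age bin.
#'
#' @param events A data.frame with one row per animal and count columns
#'   (default `apb_count`, `vpb_count`, `jpb_count`; a [simulate_cohort()]
#'   table works directly).
#' @param ages Ages in years, aligned with `events` rows (taken from an
#'   `age_years` column when present).
#' @param bins Numeric vector of bin edges covering all ages.
#' @param classes Named character vector mapping class labels to count
#'   columns.
#' @return A data.frame of class `prevalence_table`: one row per bin with
#'   `age_lo`, `age_hi`, `n`, and `<class>_pct` columns.
#' @export
arrhythmia_prevalence <- function(events, ages = events$age_years, bins,
                                  classes = c(APB = "apb_count",
                                              VPB = "vpb_count",
                                              JPB = "jpb_count")) {
  if (is.null(ages)) stop("ages must be supplied")
  if (length(ages) != nrow(events)) stop("ages must align with events rows")
  bin <- cut(ages, bins, include.lowest = TRUE, right = FALSE)
  # the top edge is closed so the oldest animal is binned
  bin[ages == bins[length(bins)]] <- levels(bin)[length(levels(bin))]
  if (anyNA(bin)) stop("animal age outside all bins")
  out <- data.frame(
    age_lo = bins[-length(bins)],
    age_hi = bins[-1],
    n = as.integer(table(bin))
  )
  for (cl in names(classes)) {
    cnt <- events[[classes[[cl]]]]
    if (is.null(cnt)) stop("missing count column: ", classes[[cl]])
    pos <- tapply(cnt >= 1, bin, function(z) 100 * mean(z))
    pos[is.na(pos)] <- 0
    out[[paste0(tolower(cl), "_pct")]] <- as.numeric(pos)
  }
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' Minimal detectable relative change for a two-group comparison
#'
#' Normal-approximation minimal detectable relative difference given a
#' measurement coefficient of variation:
#' `(z_{1-alpha/2} + z_power) * cv * sqrt(2 / n)`. This quantifies how the
#' assay CV and group size jointly bound the smallest age-associated change
#' a cross-sectional two-point comparison can resolve.
#'
#' @param cv Coefficient of variation in percent (>= 0).
#' @param n_per_group Animals per group (>= 2).
#' @param alpha Two-sided type-I level.
#' @param power Target power.
#' @return Minimal detectable relative change, in percent.
#' @examples
#' detectable_change(cv = 2.9, n_per_group = 23)  # ~2.4%
#' @export
detectable_change <- function(cv, n_per_group, alpha = 0.05, power = 0.80) {
  if (any(cv < 0)) stop("cv must be >= 0")
  if (any(n_per_group < 2)) stop("need n >= 2 per group")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) * cv *
    sqrt(2 / n_per_group)
}
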