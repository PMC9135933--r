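#' Cross-sectional cohort design for a synthetic aging study
#'
#' Describes one species' cohort: sample sizes by sex, the age range, and a
#' generative model per outcome. Outcomes are generated on a z-scored scale
#' as `y_z = beta_age * age_z + beta_age2 * age_z^2 + beta_sex * sex + e`,
#' with `e ~ N(0, sigma)`, then mapped to physical units via the configured
#' mean and SD. Sex is coded female = 0, male = 1. When `sigma` is `NULL`
#' it defaults to `sqrt(max(0.04, 1 - beta_age^2 - beta_age2^2 -
#' beta_sex^2))` so the marginal outcome variance is near the configured
#' physical variance.
#'
#' Arrhythmia counts follow a Poisson model `log(lambda) = log(lambda0) +
#' b_age * age_z + b_sex * sex`, split across the three premature-beat
#' classes by `class_mix`; a `lambda0` of zero fixes the rate at zero (the
#' naked mole-rat default, in which no arrhythmias are observed).
#'
#' @param species `"mouse"` or `"nmr"`.
#' @param n_female,n_male Animals per sex (>= 1).
#' @param age_range Age range in years.
#' @param outcomes Named list; each element a list with `mean`, `sd` (> 0)
#'   and optional `beta_age`, `beta_age2`, `beta_sex`, `sigma`.
#' @param arrhythmia List with `lambda0` (expected events per recording at
#'   mean age, female), `b_age`, `b_sex`, `class_mix` (APB/VPB/JPB shares).
#' @return Object of class `cohort_design`.
#' @examples
#' d <- cohort_design("mouse", n_female = 10, n_male = 10,
#'                    outcomes = list(qrs_ms = list(mean = 9.5, sd = 1.2,
#'                                                  beta_age = 0.48)))
#' @export
cohort_design <- function(species = c("mouse", "nmr"),
                          n_female, n_male,
                          age_range = NULL,
                          outcomes,
                          arrhythmia = NULL) {
  species <- match.arg(species)
  if (is.null(age_range)) {
    age_range <- if (species == "mouse") c(0.25, 2.5) else c(2, 34)
  }
  if (n_female < 1 || n_male < 1) stop("need at least 1 animal per group")
  stopifnot(is.list(outcomes), length(outcomes) > 0, !is.null(names(outcomes)))
  for (nm in names(outcomes)) {
    o <- outcomes[[nm]]
    if (is.null(o$mean) || is.null(o$sd)) {
      stop(sprintf("outcome '%s' needs mean and sd", nm))
    }
    if (o$sd <= 0) stop(sprintf("outcome '%s': zero-variance scale rejected", nm))
    for (b in c("beta_age", "beta_age2", "beta_sex")) {
      if (is.null(o[[b]])) outcomes[[nm]][[b]] <- 0
    }
    if (is.null(o$sigma)) {
      o <- outcomes[[nm]]
      outcomes[[nm]]$sigma <- sqrt(max(
        0.04, 1 - o$beta_age^2 - o$beta_age2^2 - o$beta_sex^2))
    }
    if (outcomes[[nm]]$sigma <= 0) stop("residual sigma must be positive")
  }
  if (is.null(arrhythmia)) {
    arrhythmia <- if (species == "mouse") {
      list(lambda0 = 0.4, b_age = 0.5, b_sex = 0.15,
           class_mix = c(APB = 0.6, VPB = 0.25, JPB = 0.15))
    } else {
      list(lambda0 = 0, b_age = 0, b_sex = 0,
           class_mix = c(APB = 1, VPB = 0, JPB = 0))
    }
  }
  structure(
    list(species = species, n_female = n_female, n_male = n_male,
         age_range = age_range, outcomes = outcomes, arrhythmia = arrhythmia),
    class = "cohort_design"
  )
}

#' Default cohort designs mirroring a cross-sectional NMR/mouse study
#'
#' Packaged designs with the study sample sizes (mouse 62 females + 70
#' males over 0.25-2.5 years; NMR 48 females + 72 males over 2-34 years)
#' and standardized generating effect sizes for the core outcomes (body
#' weight, heart rate, conduction intervals, ventricular volumes, E/A
#' ratio), e.g. a linear standardized age effect of 0.48 on mouse QRS
#' duration and essentially flat NMR conduction intervals with quadratic
#' heart-rate and body-weight trends.
#'
#' @param species `"mouse"` or `"nmr"`.
#' @param n_female,n_male Optional overrides of the group sizes.
#' @return A `cohort_design`.
#' @export
default_cohort_design <- function(species = c("mouse", "nmr"),
                                  n_female = NULL, n_male = NULL) {
  species <- match.arg(species)
  if (species == "mouse") {
    if (is.null(n_female)) n_female <- 62
    if (is.null(n_male)) n_male <- 70
    cohort_design(
      "mouse", n_female, n_male,
      outcomes = list(
        bw_g    = list(mean = 34, sd = 2, beta_age = 2.8, beta_age2 = -2.2,
                       beta_sex = 0.8, sigma = 0.6),
        hr_bpm  = list(mean = 550, sd = 40, beta_age = 0.46),
        qrs_ms  = list(mean = 9.5, sd = 1.2, beta_age = 0.48),
        pr_ms   = list(mean = 38, sd = 4, beta_age = 0.56),
        pq_ms   = list(mean = 34, sd = 4, beta_age = 0.50),
        edv_ul  = list(mean = 55, sd = 9, beta_age = 0.57),
        esv_ul  = list(mean = 25, sd = 7, beta_age = 0.53),
        ea_ratio = list(mean = 1.8, sd = 0.4, beta_age = -0.64),
        e_vel_mm_s = list(mean = 750, sd = 120, beta_age = -0.45)
      )
    )
  } else {
    if (is.null(n_female)) n_female <- 48
    if (is.null(n_male)) n_male <- 72
    cohort_design(
      "nmr", n_female, n_male,
      outcomes = list(
        bw_g    = list(mean = 46, sd = 9, beta_age = 0.87, beta_age2 = -0.85,
                       sigma = 0.9),
        hr_bpm  = list(mean = 240, sd = 20, beta_age = -1.16,
                       beta_age2 = 1.02, sigma = 0.9),
        qrs_ms  = list(mean = 12.5, sd = 1.5, beta_age = 0.08),
        pr_ms   = list(mean = 55, sd = 6, beta_age = 0.89, beta_age2 = -0.71,
                       sigma = 0.9),
        pq_ms   = list(mean = 50, sd = 6, beta_age = 0.93, beta_age2 = -0.76,
                       sigma = 0.9),
        edv_ul  = list(mean = 90, sd = 15, beta_age = 0),
        esv_ul  = list(mean = 40, sd = 10, beta_age = 0),
        ea_ratio = list(mean = 1.6, sd = 0.35, beta_age = 0),
        e_vel_mm_s = list(mean = 600, sd = 100, beta_age = 0.05)
      )
    )
  }
}

#' Simulate a cross-sectional cohort table
#'
#' Draws ages uniformly over the design range per sex, generates every
#' outcome from its standardized linear/quadratic age-sex model plus
#' Gaussian noise, maps back to physical units, and draws per-animal
#' arrhythmia counts from the design's Poisson model. The generating
#' parameters are attached as the `"truth"` attribute.
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed (required).
#' @return A data.frame of class `cohort_table`: `animal_id`, `species`,
#'   `sex` (`"F"`/`"M"`), `age_years`, one column per outcome, and
#'   `apb_count`, `vpb_count`, `jpb_count`.
#' @export
simulate_cohort <- function(design, seed) {
  stopifnot(inherits(design, "cohort_design"))
  if (missing(seed)) stop("seed must be supplied")
  set.seed(as.integer(seed))
  n <- design$n_female + design$n_male
  sex <- c(rep(0L, design$n_female), rep(1L, design$n_male))
  age <- stats::runif(n, design$age_range[1], design$age_range[2])
  age_z <- as.numeric(scale(age))

  out <- data.frame(
    animal_id = sprintf("%s%04d", toupper(substr(design$species, 1, 1)),
                        seq_len(n)),
    species = design$species,
    sex = ifelse(sex == 1, "M", "F"),
    age_years = age,
    stringsAsFactors = FALSE
  )
  truth <- list()
  # quadratic age effects use the orthogonalized basis (z^2 - 1)/sqrt(2),
  # zero-mean and near-unit-variance, so large published-style quadratic
  # coefficients do not blow up the outcome range at the age extremes
  age_q <- (age_z^2 - 1) / sqrt(2)
  for (nm in names(design$outcomes)) {
    o <- design$outcomes[[nm]]
    y_z <- o$beta_age * age_z + o$beta_age2 * age_q + o$beta_sex * sex +
      stats::rnorm(n, 0, o$sigma)
    out[[nm]] <- o$mean + o$sd * y_z
    truth[[nm]] <- o
  }
  arr <- design$arrhythmia
  lam <- if (arr$lambda0 <= 0) rep(0, n) else {
    exp(log(arr$lambda0) + arr$b_age * age_z + arr$b_sex * sex)
  }
  total <- stats::rpois(n, lam)
  mix <- arr$class_mix / sum(arr$class_mix)
  counts <- t(vapply(total, function(k) {
    if (k == 0) c(0L, 0L, 0L) else as.integer(stats::rmultinom(1, k, mix))
  }, integer(3)))
  out$apb_count <- counts[, 1]
  out$vpb_count <- counts[, 2]
  out$jpb_count <- counts[, 3]

  class(out) <- c("cohort_table", "data.frame")
  attr(out, "truth") <- truth
  attr(out, "design") <- design
  attr(out, "seed") <- seed
  out
}
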