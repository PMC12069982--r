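#' Nutritional status categories
#'
#' The six categories used throughout the package, ordered by clinical
#' priority (most severe first).  The five malnutrition categories follow
#' WHO child-growth z-score conventions; `adequate` covers children whose
#' three z-scores fall in the normal range, so that the label set is
#' exhaustive.
#'
#' @return Character vector of category names, priority order.
#' @export
#' @examples
#' nutrition_labels()
nutrition_labels <- function() {
  c("severe_wasting", "wasting", "underweight", "stunting", "overweight",
    "adequate")
}

#' Assign a nutritional-status label from z-scores
#'
#' Deterministic labelling from the three WHO anthropometric z-scores:
#' weight-for-height (`z_wfh`), height-for-age (`z_hfa`) and weight-for-age
#' (`z_wfa`).  Thresholds are the WHO cut-offs: severe wasting `z_wfh < -3`,
#' wasting `z_wfh < -2`, underweight `z_wfa < -2`, stunting `z_hfa < -2`,
#' overweight `z_wfh > +2`.  A child may satisfy several conditions; the
#' label is the first match in the fixed priority order
#' `severe_wasting > wasting > underweight > stunting > overweight`,
#' and `adequate` otherwise.
#'
#' @param z_wfh,z_hfa,z_wfa Numeric vectors of z-scores (recycled to a
#'   common length).  Must be finite.
#' @return Factor with levels [nutrition_labels()].
#' @export
#' @examples
#' assign_nutrition_label(-3.5, 0, 0)   # severe_wasting
#' assign_nutrition_label(0, 0, 0)      # adequate
#' assign_nutrition_label(-2.5, -2.5, -2.5) # wasting (priority order)
assign_nutrition_label <- function(z_wfh, z_hfa, z_wfa) {
  n <- max(length(z_wfh), length(z_hfa), length(z_wfa))
  z_wfh <- rep_len(z_wfh, n); z_hfa <- rep_len(z_hfa, n); z_wfa <- rep_len(z_wfa, n)
  assert_finite(z_wfh, "z_wfh"); assert_finite(z_hfa, "z_hfa"); assert_finite(z_wfa, "z_wfa")
  lab <- rep("adequate", n)
  lab[z_wfh > 2]  <- "overweight"
  lab[z_hfa < -2] <- "stunting"
  lab[z_wfa < -2] <- "underweight"
  lab[z_wfh < -2] <- "wasting"
  lab[z_wfh < -3] <- "severe_wasting"
  factor(lab, levels = nutrition_labels())
}

#' Specification of a synthetic child cohort
#'
#' @param n_records Number of children to generate.
#' @param class_mixture Named or unnamed probability vector over
#'   [nutrition_labels()] (length 6, sums to 1).  Default: uniform over the
#'   six categories, giving a balanced, separable cohort.
#' @param noise_sd Standard deviation of the class-conditional z-score
#'   distributions before truncation, in z-score units.  Default 0.5.
#' @param seed Integer seed; generation is reproducible per seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_records = 2000,
                        class_mixture = rep(1 / 6, 6),
                        noise_sd = 0.5,
                        seed = 1L) {
  if (!is.numeric(n_records) || n_records <= 0) {
    abort("n_records must be a positive integer", class = "nutriclass_invalid_input")
  }
  labs <- nutrition_labels()
  if (is.null(names(class_mixture))) names(class_mixture) <- labs
  class_mixture <- class_mixture[labs]
  if (anyNA(class_mixture) || any(class_mixture < 0) ||
      abs(sum(class_mixture) - 1) > 1e-12) {
    abort("class_mixture must be a probability vector over the six labels",
          class = "nutriclass_invalid_input")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    abort("noise_sd must be positive", class = "nutriclass_invalid_input")
  }
  structure(list(n_records = as.integer(n_records),
                 class_mixture = class_mixture,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Truncated-normal draws by inverse-CDF; bounds may be +-Inf.
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- pnorm(lower, mean, sd); pu <- pnorm(upper, mean, sd)
  qnorm(runif(n, pl, pu), mean, sd)
}

#' Internal anthropometric reference table
#'
#' Median and SD of height (cm) and weight (kg) by age in months and sex,
#' used to back-compute anthropometrics from z-scores.  The medians follow
#' a smooth growth curve monotone in age; the table is a fixed synthetic
#' reference, not the WHO standard.
#'
#' @param age_months Integer vector in `[0, 59]`.
#' @param sex Character vector, `"male"` or `"female"`.
#' @return Tibble with columns `height_median`, `height_sd`,
#'   `weight_median`, `weight_sd`.
#' @export
anthro_reference <- function(age_months, sex) {
  stopifnot(all(age_months >= 0 & age_months <= 59))
  s <- ifelse(sex == "male", 1, 0)
  a <- age_months
  tibble(
    height_median = 49.5 + 1.5 * s + 22 * log1p(a / 5),
    height_sd     = 1.9 + 0.035 * a,
    weight_median = 3.3 + 0.25 * s + 5.2 * log1p(a / 5),
    weight_sd     = 0.45 + 0.022 * a
  )
}

# Class-conditional sampling bands: each label's z-scores are drawn from
# truncated Gaussians whose supports guarantee that the priority rule maps
# the triple back to the intended label.
cohort_z_sampler <- function(label, n, sd) {
  eps <- 1e-6
  z <- switch(label,
    severe_wasting = list(
      wfh = rtnorm(n, -3.6, sd, upper = -3 - eps),
      hfa = rnorm(n, -1, sd), wfa = rnorm(n, -1.5, sd)),
    wasting = list(
      wfh = rtnorm(n, -2.5, sd, lower = -3 + eps, upper = -2 - eps),
      hfa = rnorm(n, -0.8, sd), wfa = rnorm(n, -1.2, sd)),
    underweight = list(
      wfh = rtnorm(n, -1, sd, lower = -2 + eps, upper = 2 - eps),
      hfa = rnorm(n, -0.8, sd),
      wfa = rtnorm(n, -2.5, sd, upper = -2 - eps)),
    stunting = list(
      wfh = rtnorm(n, -0.5, sd, lower = -2 + eps, upper = 2 - eps),
      hfa = rtnorm(n, -2.6, sd, upper = -2 - eps),
      wfa = rtnorm(n, -1, sd, lower = -2 + eps)),
    overweight = list(
      wfh = rtnorm(n, 2.6, sd, lower = 2 + eps),
      hfa = rtnorm(n, 0.5, sd, lower = -2 + eps),
      wfa = rtnorm(n, 1, sd, lower = -2 + eps)),
    adequate = list(
      wfh = rtnorm(n, 0, sd, lower = -2 + eps, upper = 2 - eps),
      hfa = rtnorm(n, 0, sd, lower = -2 + eps),
      wfa = rtnorm(n, 0, sd, lower = -2 + eps))
  )
  tibble(z_wfh = z$wfh, z_hfa = z$hfa, z_wfa = z$wfa)
}

#' Generate a synthetic child-level cohort
#'
#' Emulates a UNICEF-style child anthropometry survey: each record carries
#' age, sex, height, weight, MUAC, residence, an income index, the three
#' WHO z-scores and the nutritional-status label.  Labels are drawn from
#' `spec$class_mixture`; z-scores are sampled from class-conditional
#' truncated Gaussians whose supports respect the label thresholds, so the
#' stored label always equals [assign_nutrition_label()] applied to the
#' z-scores.  Height and weight are back-computed from the z-scores against
#' the internal reference table of [anthro_reference()].
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with one row per child, label column last.
#' @export
#' @examples
#' cohort <- generate_child_cohort(cohort_spec(n_records = 100, seed = 42))
#' dplyr::count(cohort, label)
generate_child_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  n <- spec$n_records
  withr::with_seed(spec$seed, {
    label <- sample(nutrition_labels(), n, replace = TRUE,
                    prob = spec$class_mixture)
    age_months <- sample(0:59, n, replace = TRUE)
    sex <- sample(c("male", "female"), n, replace = TRUE)
    residence <- sample(c("rural", "urban"), n, replace = TRUE, prob = c(0.6, 0.4))
    income_index <- runif(n)
    zs <- vector("list", n)
    ord <- order(label)  # sample per class in one block, then restore order
    z <- tibble(z_wfh = numeric(n), z_hfa = numeric(n), z_wfa = numeric(n))
    for (lab in nutrition_labels()) {
      idx <- which(label == lab)
      if (length(idx)) z[idx, ] <- cohort_z_sampler(lab, length(idx), spec$noise_sd)
    }
    ref <- anthro_reference(age_months, sex)
    height_cm <- pmax(40, ref$height_median + z$z_hfa * ref$height_sd)
    weight_kg <- pmax(1.5, ref$weight_median + z$z_wfa * ref$weight_sd)
    muac_cm <- pmax(6, 13.5 + 1.1 * z$z_wfh + 0.02 * age_months +
                      rnorm(n, 0, 0.15))
    out <- tibble(
      age_months = age_months, sex = sex,
      height_cm = height_cm, weight_kg = weight_kg, muac_cm = muac_cm,
      residence = residence, income_index = income_index,
      z_wfh = z$z_wfh, z_hfa = z$z_hfa, z_wfa = z$z_wfa,
      label = factor(label, levels = nutrition_labels())
    )
  })
  stopifnot(identical(as.character(out$label),
                      as.character(assign_nutrition_label(out$z_wfh, out$z_hfa,
                                                          out$z_wfa))))
  out
}

#' Generate a synthetic country-level prevalence table
#'
#' Emulates a cross-country malnutrition prevalence table (one row per
#' country: income index plus wasting, severe wasting, overweight,
#' stunting and underweight percentages) with planted cluster structure.
#' Rows are drawn from `n_clusters` Gaussian blobs whose centres are at
#' least `separation` within-blob standard deviations apart (in the
#' per-indicator standardized metric), then mapped onto natural scales.
#' The planted cluster id is kept in `.true_cluster` for recovery tests;
#' drop it before clustering.
#'
#' @param n_countries Number of rows.
#' @param n_clusters Number of planted blobs (>= 1).
#' @param separation Centre separation in units of the within-blob SD
#'   (must be positive).
#' @param seed Integer seed.
#' @return Tibble with columns `country_id`, `income_index`,
#'   `wasting_pct`, `severe_wasting_pct`, `overweight_pct`,
#'   `stunting_pct`, `underweight_pct`, `.true_cluster`.
#' @export
#' @examples
#' prev <- generate_prevalence_table(152, 4, separation = 8, seed = 1)
#' dplyr::count(prev, .true_cluster)
generate_prevalence_table <- function(n_countries, n_clusters = 4,
                                      separation = 8, seed = 1L) {
  if (!is.numeric(separation) || separation <= 0) {
    abort("separation must be positive", class = "nutriclass_invalid_input")
  }
  if (n_clusters < 1 || n_countries < n_clusters) {
    abort("need n_countries >= n_clusters >= 1", class = "nutriclass_invalid_input")
  }
  d <- 6L
  withr::with_seed(as.integer(seed), {
    # standardized blob centres with min pairwise distance >= separation
    box <- max(4, separation * 1.6) * sqrt(max(1, n_clusters - 1))
    centers <- matrix(runif(d, 0, box), nrow = 1)
    tries <- 0
    while (nrow(centers) < n_clusters) {
      cand <- runif(d, 0, box)
      dmin <- min(sqrt(colSums((t(centers) - cand)^2)))
      tries <- tries + 1
      if (dmin >= separation) centers <- rbind(centers, cand)
      if (tries > 5000) { box <- box * 1.5; tries <- 0 }
    }
    cl <- sort(rep_len(seq_len(n_clusters), n_countries))
    z <- centers[cl, , drop = FALSE] + matrix(rnorm(n_countries * d),
                                              n_countries, d)
    # map standardized coordinates onto natural indicator scales
    z01 <- (z - min(z)) / max(max(z) - min(z), 1e-12)
    income    <- 0.03 + 0.94 * z01[, 1]
    wasting   <- 2 + 40 * z01[, 2]
    sev_ratio <- 0.15 + 0.55 * z01[, 3]
    over      <- 1 + 25 * z01[, 4]
    stunt     <- 3 + 55 * z01[, 5]
    under     <- 3 + 50 * z01[, 6]
    tibble(
      country_id = sprintf("C%03d", seq_len(n_countries)),
      income_index = pmin(1, pmax(0, income)),
      wasting_pct = pmin(100, pmax(0, wasting)),
      severe_wasting_pct = pmin(100, pmax(0, sev_ratio * wasting)),
      overweight_pct = pmin(100, pmax(0, over)),
      stunting_pct = pmin(100, pmax(0, stunt)),
      underweight_pct = pmin(100, pmax(0, under)),
      .true_cluster = cl
    )
  })
}
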