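#' Configuration for the synthetic trial-cohort generator
#'
#' Bundles every parameter the generator needs: arm/site sample sizes,
#' per-site biomarker distributions, missingness and diagnosis rates, the
#' biopsy-referral and histology model, per-category resource-use rates, the
#' rater model for liver-relatedness, and the random seed. Defaults are the
#' conditions of the multi-national trial the package models: 403 imaging /
#' 399 standard-of-care patients over four regions, a 5.2% missing-cT1 rate,
#' diagnosis rates of 57% vs 48%, and annual event rates equal to the
#' published per-arm utilisation counts divided by arm size.
#'
#' @param n_per_arm_per_site data.frame with columns `site`, `imaging`,
#'   `soc`: number of patients per site and arm.
#' @param biomarker_params data.frame with columns `site`, `marker`, `mean`,
#'   `sd`; markers are `age` (years), `bmi` (kg/m2), `alt`, `ast` (IU/L),
#'   `ct1` (ms) and `pdff` (%). cT1 and PDFF are mpMRI readings and are only
#'   realised for imaging-arm patients.
#' @param missing_ct1_rate fraction of imaging-arm patients with missing cT1
#'   (imaging artefacts or fat outside the quantifiable range).
#' @param missing_mechanism `"independent"` (default) imposes missingness
#'   independently of the biomarker values; `"fat_dependent"` makes the
#'   missingness probability proportional to PDFF (same expected rate).
#' @param dx_rate_by_arm named fractions: probability of a final diagnosis by
#'   end of follow-up, per arm.
#' @param biopsy_referral_rate named fractions: probability of biopsy
#'   referral, per arm.
#' @param histology_model list with `imaging_joint`, the joint probabilities
#'   of (MASH-with-fibrosis no/yes) x (cT1 at or below / above 875 ms) among
#'   biopsied imaging-arm patients (names `no_fibrosis_below`,
#'   `no_fibrosis_above`, `fibrosis_below`, `fibrosis_above`, summing to 1),
#'   and `soc_p_no_fibrosis`, the marginal probability that a biopsied
#'   standard-of-care patient does not have MASH with fibrosis.
#' @param hcru_rates data.frame with columns `category`, `imaging`, `soc`:
#'   mean annual event count per patient, per category and arm. The biopsy
#'   row is retained for completeness but biopsy events follow the
#'   `biopsy_referral_rate` flag, not a Poisson rate.
#' @param p_male probability a patient is male.
#' @param p_liver_related named fractions per category: probability an event
#'   of that category is truly liver-related (drives the simulated ratings).
#' @param rater_accuracy probability each blinded rater places an event on
#'   the correct side of the liver-related / not-liver-related divide.
#' @param seed integer seed; fully determines the generated cohort and
#'   events.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [generate_hcru_events()]
#' @export
cohort_config <- function(n_per_arm_per_site = default_arm_site_counts(),
                          biomarker_params = default_biomarker_params(),
                          missing_ct1_rate = 21 / 403,
                          missing_mechanism = c("independent", "fat_dependent"),
                          dx_rate_by_arm = c(imaging = 0.57, soc = 0.48),
                          biopsy_referral_rate = c(imaging = 21 / 403,
                                                   soc = 23 / 399),
                          histology_model = default_histology_model(),
                          hcru_rates = default_hcru_rates(),
                          p_male = 0.56,
                          p_liver_related = default_p_liver_related(),
                          rater_accuracy = 0.9,
                          seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  config <- structure(
    list(
      n_per_arm_per_site = n_per_arm_per_site,
      biomarker_params = biomarker_params,
      missing_ct1_rate = missing_ct1_rate,
      missing_mechanism = missing_mechanism,
      dx_rate_by_arm = dx_rate_by_arm,
      biopsy_referral_rate = biopsy_referral_rate,
      histology_model = histology_model,
      hcru_rates = hcru_rates,
      p_male = p_male,
      p_liver_related = p_liver_related,
      rater_accuracy = rater_accuracy,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(config)
  config
}

#' @rdname cohort_config
#' @export
default_arm_site_counts <- function() {
  data.frame(
    site = trial_sites,
    imaging = c(107L, 89L, 79L, 128L),
    soc = c(109L, 88L, 75L, 127L)
  )
}

#' @rdname cohort_config
#' @export
default_biomarker_params <- function() {
  markers <- c("age", "bmi", "alt", "ast", "ct1", "pdff")
  means <- rbind(
    Ulm     = c(49.6, 29.8, 58.4, 37.8, 805, 13.3),
    Leiden  = c(50.8, 30.8, 56.7, 37.1, 845, 10.9),
    Coimbra = c(61.2, 30.9, 34.9, 26.4, 803, 10.5),
    UK      = c(52.9, 32.5, 57.4, 39.5, 848, 13.5)
  )
  sds <- rbind(
    Ulm     = c(13.5, 5.2, 36.7, 19.4, 112, 9.3),
    Leiden  = c(13.6, 5.4, 31.1, 18.0,  98, 8.4),
    Coimbra = c( 9.2, 5.0, 21.7, 12.9, 104, 8.1),
    UK      = c(13.0, 5.8, 43.6, 21.5, 104, 8.6)
  )
  data.frame(
    site = rep(rownames(means), each = length(markers)),
    marker = rep(markers, times = nrow(means)),
    mean = as.vector(t(means)),
    sd = as.vector(t(sds))
  )
}

#' @rdname cohort_config
#' @export
default_histology_model <- function() {
  list(
    imaging_joint = c(no_fibrosis_below = 9 / 18, no_fibrosis_above = 1 / 18,
                      fibrosis_below = 3 / 18, fibrosis_above = 5 / 18),
    soc_p_no_fibrosis = 11 / 23
  )
}

#' @rdname cohort_config
#' @export
default_hcru_rates <- function() {
  data.frame(
    category = hcru_categories,
    imaging = c(711, 231, 857, 559, 892, 208, 21, 268, 336) / 403,
    soc     = c(768, 248, 769, 864, 873, 294, 23,   0,   0) / 399
  )
}

#' @rdname cohort_config
#' @export
default_p_liver_related <- function() {
  c(gp = 0.4, specialist_outside = 0.5, specialist_hospital = 0.7,
    therapist = 0.3, blood = 0.7, ultrasound = 0.8, biopsy = 0.98,
    mri = 0.8, mpmri = 1.0)
}

# physiologic truncation bounds for the biomarker marginals
biomarker_bounds <- function() {
  rbind(
    age  = c(18, 75),
    bmi  = c(16, 60),
    alt  = c(5, 400),
    ast  = c(5, 400),
    ct1  = c(600, 1250),
    pdff = c(0.5, 45)
  )
}

validate_cohort_config <- function(config) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid cohort_config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  n <- config$n_per_arm_per_site
  if (!is.data.frame(n) ||
      !all(c("site", "imaging", "soc") %in% names(n))) {
    stop_field("n_per_arm_per_site",
               "must be a data.frame with columns site, imaging, soc")
  }
  if (any(n$imaging < 0) || any(n$soc < 0)) {
    stop_field("n_per_arm_per_site", "counts must be non-negative")
  }
  bp <- config$biomarker_params
  if (!is.data.frame(bp) ||
      !all(c("site", "marker", "mean", "sd") %in% names(bp))) {
    stop_field("biomarker_params",
               "must be a data.frame with columns site, marker, mean, sd")
  }
  if (any(bp$sd < 0)) stop_field("biomarker_params", "has negative sd")
  need <- expand.grid(site = n$site,
                      marker = rownames(biomarker_bounds()),
                      stringsAsFactors = FALSE)
  have <- paste(bp$site, bp$marker)
  if (!all(paste(need$site, need$marker) %in% have)) {
    stop_field("biomarker_params", "is missing a site x marker combination")
  }
  check_rate <- function(x, field) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop_field(field, "must lie in [0, 1]")
    }
  }
  check_rate(config$missing_ct1_rate, "missing_ct1_rate")
  check_rate(config$dx_rate_by_arm, "dx_rate_by_arm")
  if (!all(trial_arms %in% names(config$dx_rate_by_arm))) {
    stop_field("dx_rate_by_arm", "must be named for both arms")
  }
  check_rate(config$biopsy_referral_rate, "biopsy_referral_rate")
  if (!all(trial_arms %in% names(config$biopsy_referral_rate))) {
    stop_field("biopsy_referral_rate", "must be named for both arms")
  }
  hj <- config$histology_model$imaging_joint
  if (length(hj) != 4L || abs(sum(hj) - 1) > 1e-8 || any(hj < 0)) {
    stop_field("histology_model",
               "imaging_joint must be 4 non-negative probabilities summing to 1")
  }
  check_rate(config$histology_model$soc_p_no_fibrosis, "histology_model")
  hr <- config$hcru_rates
  if (!is.data.frame(hr) ||
      !all(c("category", "imaging", "soc") %in% names(hr))) {
    stop_field("hcru_rates",
               "must be a data.frame with columns category, imaging, soc")
  }
  if (!all(hr$category %in% hcru_categories)) {
    bad <- setdiff(hr$category, hcru_categories)
    stop_field("hcru_rates",
               sprintf("contains unknown category '%s'", bad[1]))
  }
  if (any(hr$imaging < 0) || any(hr$soc < 0)) {
    stop_field("hcru_rates", "rates must be non-negative")
  }
  check_rate(config$p_male, "p_male")
  check_rate(config$p_liver_related, "p_liver_related")
  check_rate(config$rater_accuracy, "rater_accuracy")
  if (length(config$seed) != 1L || is.na(config$seed)) {
    stop_field("seed", "must be a single integer")
  }
  invisible(config)
}

#' @export
print.cohort_config <- function(x, ...) {
  n <- x$n_per_arm_per_site
  cat("<cohort_config>\n")
  cat(sprintf("  patients: %d imaging / %d soc over %d sites\n",
              sum(n$imaging), sum(n$soc), nrow(n)))
  cat(sprintf("  dx rates: imaging %.2f, soc %.2f; missing cT1 %.3f (%s)\n",
              x$dx_rate_by_arm[["imaging"]], x$dx_rate_by_arm[["soc"]],
              x$missing_ct1_rate, x$missing_mechanism))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
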