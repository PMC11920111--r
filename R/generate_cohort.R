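#' Generate a synthetic trial cohort
#'
#' Draws one patient record per configured slot: exact arm/site counts,
#' biomarkers from per-site truncated-normal marginals, cT1/PDFF realised
#' only in the imaging arm (mpMRI is not performed under standard of care),
#' cT1 missingness at the configured rate, and diagnosis / biopsy-referral /
#' histology outcomes from the configured rates. Output is fully determined
#' by `config$seed`.
#'
#' Histology is generated only for biopsied patients. For biopsied
#' imaging-arm patients the probability of MASH with fibrosis (MAS >= 4 and
#' fibrosis stage >= 2) is conditioned on which side of 875 ms the patient's
#' cT1 falls, so that the configured joint distribution of (histology x cT1
#' side) is recovered; for standard-of-care patients (no cT1) the marginal
#' probability is used.
#'
#' @param config a [cohort_config()] object.
#' @return data.frame with one row per patient: `patient_id`, `arm`, `site`,
#'   `age`, `sex`, `bmi`, `alt`, `ast`, `ct1`, `pdff`, `has_final_dx`,
#'   `biopsied`, `mas`, `fibrosis`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' table(cohort$arm)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)

  bounds <- biomarker_bounds()
  params <- config$biomarker_params
  counts <- config$n_per_arm_per_site

  blocks <- list()
  for (i in seq_len(nrow(counts))) {
    site <- counts$site[i]
    for (arm in trial_arms) {
      n <- counts[[arm]][i]
      if (n == 0L) next
      draw <- function(marker) {
        row <- params[params$site == site & params$marker == marker, ]
        rnorm_trunc(n, row$mean[1], row$sd[1],
                    bounds[marker, 1], bounds[marker, 2])
      }
      block <- data.frame(
        patient_id = sprintf("%s-%s-%04d", toupper(substr(site, 1, 3)),
                             ifelse(arm == "imaging", "IA", "SOC"),
                             seq_len(n)),
        arm = arm,
        site = site,
        age = round(draw("age"), 1),
        sex = ifelse(stats::runif(n) < config$p_male, "M", "F"),
        bmi = round(draw("bmi"), 1),
        alt = round(draw("alt"), 1),
        ast = round(draw("ast"), 1),
        ct1 = NA_real_,
        pdff = NA_real_,
        stringsAsFactors = FALSE
      )
      if (arm == "imaging") {
        block$ct1 <- round(draw("ct1"))
        block$pdff <- round(draw("pdff"), 1)
        block$ct1 <- impose_ct1_missingness(block$ct1, block$pdff, config)
      }
      block$has_final_dx <-
        stats::runif(n) < config$dx_rate_by_arm[[arm]]
      block$biopsied <-
        stats::runif(n) < config$biopsy_referral_rate[[arm]]
      blocks[[length(blocks) + 1L]] <- block
    }
  }
  cohort <- do.call(rbind, blocks)
  rownames(cohort) <- NULL
  cohort <- add_histology(cohort, config)
  cohort
}

# inverse-CDF truncated normal: deterministic given the RNG stream
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(p_lo + stats::runif(n) * (p_hi - p_lo), mean, sd)
}

impose_ct1_missingness <- function(ct1, pdff, config) {
  n <- length(ct1)
  rate <- config$missing_ct1_rate
  if (rate <= 0) return(ct1)
  if (config$missing_mechanism == "independent") {
    miss <- stats::runif(n) < rate
  } else {
    # fat-dependent: probability proportional to PDFF, same expected rate
    p <- rate * pdff / mean(pdff)
    miss <- stats::runif(n) < pmin(p, 1)
  }
  ct1[miss] <- NA_real_
  ct1
}

add_histology <- function(cohort, config) {
  cohort$mas <- NA_integer_
  cohort$fibrosis <- NA_integer_
  hm <- config$histology_model
  joint <- hm$imaging_joint
  # P(MASH with fibrosis | cT1 side of 875)
  p_fib_below <- joint[["fibrosis_below"]] /
    (joint[["fibrosis_below"]] + joint[["no_fibrosis_below"]])
  p_fib_above <- joint[["fibrosis_above"]] /
    (joint[["fibrosis_above"]] + joint[["no_fibrosis_above"]])
  p_fib_marginal_img <- joint[["fibrosis_below"]] + joint[["fibrosis_above"]]

  idx <- which(cohort$biopsied)
  for (i in idx) {
    if (cohort$arm[i] == "imaging" && !is.na(cohort$ct1[i])) {
      p_fib <- if (cohort$ct1[i] <= 875) p_fib_below else p_fib_above
    } else if (cohort$arm[i] == "imaging") {
      p_fib <- p_fib_marginal_img
    } else {
      p_fib <- 1 - hm$soc_p_no_fibrosis
    }
    if (stats::runif(1) < p_fib) {
      cohort$mas[i] <- sample(4:8, 1)
      cohort$fibrosis[i] <- sample(2:4, 1)
    } else {
      # outside the MAS >= 4 & fibrosis >= 2 region
      mas <- sample(0:6, 1)
      fib <- if (mas >= 4) sample(0:1, 1) else sample(0:4, 1)
      cohort$mas[i] <- mas
      cohort$fibrosis[i] <- fib
    }
  }
  cohort
}
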