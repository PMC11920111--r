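#' Generate a synthetic resource-use event table for a cohort
#'
#' Event counts are Poisson per patient and category, except biopsies, which
#' are tied to the cohort's `biopsied` flag (one procedure per referred
#' patient, in a window drawn in proportion to window length). The
#' configured rate is the mean annual count; it is split over the three
#' non-overlapping questionnaire windows (months 0-2, 2-6, 6-12) in
#' proportion to their lengths, so window counts are independent Poissons
#' that sum to the annual rate. Each row carries three simulated
#' blinded-clinician ratings on the five-level scale, driven by a latent
#' per-category probability that the care is truly liver-related and a rater
#' accuracy parameter.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param config the same [cohort_config()] used for the cohort; the event
#'   stream is seeded from `config$seed` (offset so cohort and events use
#'   distinct streams) and is reproducible on its own.
#' @return data.frame with columns `patient_id`, `window` (2, 6 or 12),
#'   `category`, `count`, `rating1`, `rating2`, `rating3`. Rows with a zero
#'   count are not emitted.
#' @examples
#' cfg <- cohort_config(seed = 7)
#' events <- generate_hcru_events(generate_cohort(cfg), cfg)
#' head(events)
#' @export
generate_hcru_events <- function(cohort, config) {
  validate_cohort_config(config)
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop("cohort must be a nonempty data.frame", call. = FALSE)
  }
  set.seed(config$seed + 1000L)

  rates <- config$hcru_rates
  window_frac <- c(`2` = 2, `6` = 4, `12` = 6) / 12

  grid <- expand.grid(
    patient_idx = seq_len(nrow(cohort)),
    category = rates$category,
    window = hcru_windows,
    stringsAsFactors = FALSE
  )
  # deterministic order: patient, category, window
  grid <- grid[order(grid$patient_idx,
                     match(grid$category, hcru_categories),
                     grid$window), ]
  arm <- cohort$arm[grid$patient_idx]
  lambda_annual <- ifelse(
    arm == "imaging",
    rates$imaging[match(grid$category, rates$category)],
    rates$soc[match(grid$category, rates$category)]
  )
  lambda <- lambda_annual * window_frac[as.character(grid$window)]
  lambda[grid$category == "biopsy"] <- 0   # biopsies follow the referral flag
  grid$count <- stats::rpois(nrow(grid), lambda)
  grid <- grid[grid$category == "biopsy" | grid$count > 0L, ]
  is_biopsy <- grid$category == "biopsy"
  referred <- cohort$biopsied[grid$patient_idx]
  window_pick <- hcru_windows[
    findInterval(stats::runif(nrow(cohort)), cumsum(window_frac)) + 1L
  ]
  grid$count[is_biopsy] <- as.integer(
    referred[is_biopsy] &
      grid$window[is_biopsy] == window_pick[grid$patient_idx[is_biopsy]]
  )
  grid <- grid[grid$count > 0L, ]

  events <- data.frame(
    patient_id = cohort$patient_id[grid$patient_idx],
    window = grid$window,
    category = grid$category,
    count = grid$count,
    stringsAsFactors = FALSE
  )
  if (nrow(events) == 0L) {
    events$rating1 <- character(0)
    events$rating2 <- character(0)
    events$rating3 <- character(0)
    rownames(events) <- NULL
    return(events)
  }

  liver <- stats::runif(nrow(events)) <
    config$p_liver_related[events$category]
  for (r in 1:3) {
    correct <- stats::runif(nrow(events)) < config$rater_accuracy
    on_liver_side <- ifelse(correct, liver, !liver)
    rating <- character(nrow(events))
    n_a <- sum(on_liver_side)
    rating[on_liver_side] <- sample(rating_levels[1:3], n_a, replace = TRUE)
    rating[!on_liver_side] <- sample(rating_levels[4:5],
                                     nrow(events) - n_a, replace = TRUE)
    events[[paste0("rating", r)]] <- rating
  }
  rownames(events) <- NULL
  events
}
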