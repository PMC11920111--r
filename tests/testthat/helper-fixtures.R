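# small configurations and hand-built tables shared across tests

tiny_config <- function(n = 5L, seed = 1L, ...) {
  cohort_config(
    n_per_arm_per_site = data.frame(
      site = trial_sites,
      imaging = rep(n, 4L),
      soc = rep(n, 4L)
    ),
    seed = seed,
    ...
  )
}

one_site_config <- function(n_imaging, n_soc, seed = 1L, ...) {
  counts <- default_arm_site_counts()
  counts$imaging <- c(n_imaging, 0L, 0L, 0L)
  counts$soc <- c(n_soc, 0L, 0L, 0L)
  cohort_config(n_per_arm_per_site = counts, seed = seed, ...)
}

# identity-adjustment single-region price table for arithmetic tests
flat_cost_table <- function(unit = 1, currency = "EUR", fx = 1,
                            country = "Ulm") {
  costs <- as.list(stats::setNames(rep(unit, length(hcru_categories)),
                                   hcru_categories))
  structure(
    list(
      fx_gbp_to_eur = fx,
      countries = stats::setNames(
        list(list(currency = currency,
                  cpi = list(price_year = 100, target_year = 100),
                  costs = costs)),
        country
      )
    ),
    class = "unit_cost_table"
  )
}

simple_events <- function(patient_id, category, count, window = 6L) {
  data.frame(patient_id = patient_id,
             window = rep_len(window, length(patient_id)),
             category = category, count = count,
             stringsAsFactors = FALSE)
}

# all permutations of a short vector
combinat_perms <- function(x) {
  n <- length(x)
  if (n <= 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in combinat_perms(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

simple_cohort <- function(patient_id, site = "Ulm", arm = "imaging") {
  data.frame(patient_id = patient_id, site = site, arm = arm,
             stringsAsFactors = FALSE)
}
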