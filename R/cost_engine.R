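#' Unit-cost tables, inflation and currency conversion
#'
#' A `unit_cost_table` holds, per recruiting region, the nominal unit cost of
#' each resource-use category in local currency, the health consumer-price
#' indices used to inflate nominal values to the analysis year (ONS health
#' index for the UK, OECD health CPI elsewhere), and a single GBP-to-EUR
#' exchange rate. All downstream costing is in real (inflation-adjusted)
#' euros: a nominal value is inflated in local currency first and converted
#' to euros second (the order is immaterial for constant rates; it is fixed
#' for reproducibility).
#'
#' @param path path to a YAML file with top-level keys `fx_gbp_to_eur` and
#'   `countries`, the latter keyed region -> `{currency, cpi: {price_year,
#'   target_year}, costs: {category: nominal}}`.
#' @return An object of class `unit_cost_table`.
#' @seealso [default_unit_costs()], [cost_events()]
#' @export
read_unit_costs <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$fx_gbp_to_eur) || raw$fx_gbp_to_eur <= 0) {
    stop("unit-cost file must define a positive fx_gbp_to_eur", call. = FALSE)
  }
  for (country in names(raw$countries)) {
    entry <- raw$countries[[country]]
    if (!entry$currency %in% c("EUR", "GBP")) {
      stop(sprintf("country '%s': currency must be EUR or GBP", country),
           call. = FALSE)
    }
    if (entry$cpi$price_year <= 0 || entry$cpi$target_year <= 0) {
      stop(sprintf("country '%s': CPI indices must be positive", country),
           call. = FALSE)
    }
    if (any(unlist(entry$costs) < 0)) {
      stop(sprintf("country '%s': unit costs must be non-negative", country),
           call. = FALSE)
    }
  }
  structure(
    list(fx_gbp_to_eur = raw$fx_gbp_to_eur, countries = raw$countries),
    class = "unit_cost_table"
  )
}

#' Packaged multi-country unit-cost table
#'
#' Loads the unit-cost table shipped with the package: 2017-2020 national
#' tariffs for Ulm (Germany), Coimbra (Portugal) and the UK, local hospital
#' prices for Leiden (Netherlands), identity CPI indices (the published
#' analysis's country-specific health indices are not public; supply your
#' own file to inflate), and the GBP-to-EUR rate 1.167 implied to five
#' significant figures by the published aggregate expenditure table. A
#' category without a tariff in a region raises an error when a matching
#' event is priced (on demand), not at load time.
#'
#' @return A `unit_cost_table`.
#' @export
default_unit_costs <- function() {
  read_unit_costs(system.file("extdata", "unit_costs.yaml",
                              package = "masldcea", mustWork = TRUE))
}

#' @export
print.unit_cost_table <- function(x, ...) {
  cat("<unit_cost_table>\n")
  cat(sprintf("  regions: %s\n", paste(names(x$countries), collapse = ", ")))
  cat(sprintf("  fx_gbp_to_eur: %.4f\n", x$fx_gbp_to_eur))
  invisible(x)
}

#' Inflate a nominal amount between index years
#'
#' @param value nominal amount (any currency).
#' @param idx_from price index at the pricing year.
#' @param idx_to price index at the target year.
#' @return `value * idx_to / idx_from`.
#' @examples
#' inflate_nominal(100, 100, 110)  # 110
#' inflate_nominal(50, 125, 100)   # 40
#' @export
inflate_nominal <- function(value, idx_from, idx_to) {
  if (any(idx_from <= 0) || any(idx_to <= 0)) {
    stop("price indices must be positive", call. = FALSE)
  }
  value * idx_to / idx_from
}

#' Convert an amount to euros
#'
#' GBP amounts are multiplied by the configured rate; EUR amounts pass
#' through unchanged.
#'
#' @param value amount in `currency`.
#' @param currency `"EUR"` or `"GBP"` (vectorised).
#' @param fx_gbp_to_eur euros per pound; required when any value is GBP.
#' @return amount in EUR.
#' @export
convert_currency <- function(value, currency = "GBP", fx_gbp_to_eur = NULL) {
  stopifnot(all(currency %in% c("EUR", "GBP")))
  if (any(currency == "GBP")) {
    if (is.null(fx_gbp_to_eur) || !is.finite(fx_gbp_to_eur) ||
        fx_gbp_to_eur <= 0) {
      stop("a positive GBP->EUR rate is required for GBP amounts",
           call. = FALSE)
    }
  }
  ifelse(currency == "GBP", value * fx_gbp_to_eur, value)
}

#' Real (inflated, euro) unit cost for a region and category
#'
#' @param table a `unit_cost_table`.
#' @param country region name (one of the table's regions).
#' @param category resource-use category from [hcru_categories] (or
#'   `"elastography"`, priced but outside the event taxonomy).
#' @return unit cost in real EUR.
#' @export
real_unit_cost <- function(table, country, category) {
  entry <- table$countries[[country]]
  if (is.null(entry)) {
    stop(sprintf("no unit costs for country '%s'", country), call. = FALSE)
  }
  nominal <- entry$costs[[category]]
  if (is.null(nominal)) {
    stop(sprintf("no unit cost for country '%s', category '%s'",
                 country, category), call. = FALSE)
  }
  inflated <- inflate_nominal(nominal, entry$cpi$price_year,
                              entry$cpi$target_year)
  convert_currency(inflated, entry$currency, table$fx_gbp_to_eur)
}

#' Cost a resource-use event table
#'
#' Multiplies each patient's event frequency by the real euro unit cost of
#' the category in the patient's region. Costs and consequences are not
#' discounted (short follow-up). One line is produced per observed
#' (patient, category) combination - and per liver-relatedness flag when the
#' events carry one - with full-precision totals.
#'
#' @param events event table (see [generate_hcru_events()]), optionally
#'   flagged by [flag_events()].
#' @param cohort cohort table supplying each patient's `site`.
#' @param table a `unit_cost_table`.
#' @return data.frame of cost lines: `patient_id`, `site`, `category`,
#'   (`liver_related`,) `events`, `unit_cost_real_eur`, `total`.
#' @export
cost_events <- function(events, cohort, table) {
  stopifnot(is.data.frame(events), is.data.frame(cohort))
  if (nrow(events) == 0L) {
    return(data.frame(patient_id = character(0), site = character(0),
                      category = character(0), events = integer(0),
                      unit_cost_real_eur = numeric(0), total = numeric(0)))
  }
  site <- cohort$site[match(events$patient_id, cohort$patient_id)]
  if (anyNA(site)) {
    bad <- events$patient_id[is.na(site)][1]
    stop(sprintf("event references unknown patient '%s'", bad),
         call. = FALSE)
  }
  keys <- list(patient_id = events$patient_id, site = site,
               category = events$category)
  if ("liver_related" %in% names(events)) {
    keys$liver_related <- events$liver_related
  }
  lines <- stats::aggregate(list(events = events$count), keys, sum)
  lines <- lines[order(lines$patient_id, lines$category), ]
  lines$unit_cost_real_eur <- mapply(
    function(ctry, cat) real_unit_cost(table, ctry, cat),
    lines$site, lines$category
  )
  lines$total <- lines$events * lines$unit_cost_real_eur
  rownames(lines) <- NULL
  lines
}

#' Summarise cost lines into Table-2-style group totals
#'
#' Aggregates cost lines into the four reporting groups (practitioner
#' visits, patient assessments, MRI, mpMRI), a grand total, and a
#' per-patient mean whose denominator is ALL patients in the group (every
#' randomised patient, not only resource users). When the lines carry a
#' `liver_related` flag, a liver-related subtotal (flag A only) is reported
#' alongside the all-cause total; indeterminate events count toward the
#' all-cause total but not the liver-related subtotal.
#'
#' @param lines cost lines from [cost_events()].
#' @param cohort cohort table; must contain every grouping column other than
#'   `"arm"`/`"site"` (e.g. a `risk_class` column for risk-stratified
#'   summaries).
#' @param group_by character vector of cohort columns to group by
#'   (default `"arm"`).
#' @return data.frame with one row per group: grouping columns, the four
#'   group totals, `grand_total`, `total_liver_related` (if flagged),
#'   `n_patients`, `per_patient_mean` and `mean_defined`.
#' @export
summarize_costs <- function(lines, cohort, group_by = "arm") {
  stopifnot(all(group_by %in% names(cohort)))
  groups <- unique(cohort[, group_by, drop = FALSE])
  groups <- groups[do.call(order, groups), , drop = FALSE]
  rownames(groups) <- NULL

  line_groups <- cohort[match(lines$patient_id, cohort$patient_id),
                        group_by, drop = FALSE]
  grp_names <- unique(unname(category_groups))
  out <- groups
  for (g in grp_names) out[[g]] <- 0
  out$grand_total <- 0
  has_flag <- "liver_related" %in% names(lines)
  if (has_flag) out$total_liver_related <- 0
  out$n_patients <- 0L
  out$per_patient_mean <- NA_real_
  out$mean_defined <- FALSE

  group_key <- function(df) do.call(paste, c(df, sep = "\r"))
  out_key <- group_key(groups)
  line_key <- if (nrow(lines)) group_key(line_groups) else character(0)
  cohort_key <- group_key(cohort[, group_by, drop = FALSE])

  for (i in seq_len(nrow(out))) {
    sel <- which(line_key == out_key[i])
    n_pat <- sum(cohort_key == out_key[i])
    out$n_patients[i] <- n_pat
    if (length(sel)) {
      lg <- lines[sel, ]
      grp <- category_groups[lg$category]
      for (g in grp_names) out[[g]][i] <- sum(lg$total[grp == g])
      out$grand_total[i] <- sum(lg$total)
      if (has_flag) {
        out$total_liver_related[i] <- sum(lg$total[lg$liver_related == "A"])
      }
    }
    if (n_pat > 0L) {
      out$per_patient_mean[i] <- out$grand_total[i] / n_pat
      out$mean_defined[i] <- TRUE
    }
  }
  out
}
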