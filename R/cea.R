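#' QALY model for the diagnosis-driven cost-effectiveness analysis
#'
#' QALYs are gained through additional diagnoses: each missed diagnosis
#' carries a quality-adjusted life-year loss (0.03 QALY per patient per
#' missed diagnosis by default), so the QALY gain is the diagnosis-count
#' difference times that loss. Willingness-to-pay thresholds default to the
#' euro equivalents of the conventional GBP 10,000 (conservative, ~EUR
#' 11,200) and GBP 20,000 (~EUR 22,400) per QALY gained.
#'
#' Overrides exist because published summary figures are sometimes not
#' derivable from published counts: supplying `incremental_dx_override`
#' and/or `qalys_gained_override` makes downstream functions use those
#' values verbatim, and every result carries a provenance note saying so.
#'
#' @param qaly_loss_per_missed_dx QALY loss per missed diagnosis (> 0).
#' @param wtp_per_qaly named positive vector of WTP thresholds, EUR/QALY.
#' @param incremental_dx_override,qalys_gained_override optional fixed
#'   values replacing the first-principles diagnosis difference / QALY gain.
#' @return list of class `qaly_model`.
#' @export
qaly_model <- function(qaly_loss_per_missed_dx = 0.03,
                       wtp_per_qaly = c(conservative = 11200,
                                        standard = 22400),
                       incremental_dx_override = NULL,
                       qalys_gained_override = NULL) {
  if (qaly_loss_per_missed_dx <= 0) {
    stop("qaly_loss_per_missed_dx must be positive", call. = FALSE)
  }
  if (any(wtp_per_qaly <= 0)) {
    stop("willingness-to-pay thresholds must be positive", call. = FALSE)
  }
  structure(
    list(qaly_loss_per_missed_dx = qaly_loss_per_missed_dx,
         wtp_per_qaly = wtp_per_qaly,
         incremental_dx_override = incremental_dx_override,
         qalys_gained_override = qalys_gained_override),
    class = "qaly_model"
  )
}

#' Incremental cost between arms
#'
#' @param total_ia total cost of the imaging arm (EUR, >= 0).
#' @param total_soc total cost of the standard-of-care arm (EUR, >= 0).
#' @return `total_ia - total_soc`; negative values indicate the dominant
#'   quadrant (imaging cheaper).
#' @export
incremental_cost <- function(total_ia, total_soc) {
  stopifnot(total_ia >= 0, total_soc >= 0)
  total_ia - total_soc
}

#' QALYs gained from the diagnosis-rate difference
#'
#' @param dx_ia,dx_soc diagnosis counts per arm (>= 0).
#' @param model a [qaly_model()]; if it carries `qalys_gained_override` that
#'   value is returned with attribute `override = TRUE` (logged provenance).
#' @return QALYs gained; attribute `flagged_negative` marks a negative
#'   first-principles result (flagged, not an error).
#' @export
qalys_gained <- function(dx_ia, dx_soc, model = qaly_model()) {
  stopifnot(dx_ia >= 0, dx_soc >= 0)
  if (!is.null(model$qalys_gained_override)) {
    q <- model$qalys_gained_override
    attr(q, "override") <- TRUE
    message(sprintf("qalys_gained: using documented override %.4g", q))
    return(q)
  }
  q <- (dx_ia - dx_soc) * model$qaly_loss_per_missed_dx
  if (q < 0) attr(q, "flagged_negative") <- TRUE
  q
}

#' Incremental cost-effectiveness ratios
#'
#' Computes the ICER per additional diagnosis (`delta_cost / delta_dx`) and
#' per QALY gained. Two per-QALY conventions are reported: `icer_per_qaly`
#' is the standard `delta_cost / qalys` (EUR per QALY), while
#' `icer_per_qaly_reported` divides the per-diagnosis ICER by the QALY gain
#' - the convention under which some published trial summaries quote their
#' headline figure. Cost-effectiveness verdicts are evaluated against each
#' configured willingness-to-pay threshold under both conventions.
#'
#' Dominance quadrants are labelled rather than producing misleading
#' ratios: `"dominant"` (cheaper, more effective), `"dominated"` (costlier,
#' no QALY gain - per-QALY ratio undefined), `"tradeoff"` otherwise.
#'
#' @param delta_cost incremental cost, EUR.
#' @param qalys QALYs gained (from [qalys_gained()]).
#' @param delta_dx incremental diagnosis count.
#' @param model a [qaly_model()] supplying WTP thresholds; its
#'   `incremental_dx_override` replaces `delta_dx` when set (logged).
#' @return object of class `icer_result`.
#' @examples
#' icer(192575.13, qalys = 1.11, delta_dx = 37)
#' @export
icer <- function(delta_cost, qalys, delta_dx, model = qaly_model()) {
  overrides <- character(0)
  if (!is.null(model$incremental_dx_override)) {
    delta_dx <- model$incremental_dx_override
    overrides <- c(overrides,
                   sprintf("incremental_dx_override = %g", delta_dx))
  }
  if (isTRUE(attr(qalys, "override"))) {
    overrides <- c(overrides,
                   sprintf("qalys_gained_override = %g", as.numeric(qalys)))
  }
  qalys <- as.numeric(qalys)
  per_dx <- if (delta_dx != 0) delta_cost / delta_dx else NA_real_
  per_qaly <- if (qalys != 0) delta_cost / qalys else NA_real_
  per_qaly_reported <- if (!is.na(per_dx) && qalys != 0) per_dx / qalys
                       else NA_real_
  quadrant <- if (delta_cost < 0 && qalys > 0) "dominant"
              else if (delta_cost > 0 && qalys <= 0) "dominated"
              else "tradeoff"
  structure(
    list(delta_cost = delta_cost, delta_dx = delta_dx,
         qalys_gained = qalys,
         icer_per_dx = per_dx,
         icer_per_qaly = per_qaly,
         icer_per_qaly_reported = per_qaly_reported,
         quadrant = quadrant,
         cost_effective =
           if (quadrant == "dominant") {
             stats::setNames(rep(TRUE, length(model$wtp_per_qaly)),
                             names(model$wtp_per_qaly))
           } else if (is.na(per_qaly)) {
             stats::setNames(rep(FALSE, length(model$wtp_per_qaly)),
                             names(model$wtp_per_qaly))
           } else per_qaly <= model$wtp_per_qaly,
         cost_effective_reported =
           if (is.na(per_qaly_reported)) {
             stats::setNames(rep(NA, length(model$wtp_per_qaly)),
                             names(model$wtp_per_qaly))
           } else per_qaly_reported <= model$wtp_per_qaly,
         wtp_per_qaly = model$wtp_per_qaly,
         overrides = overrides),
    class = "icer_result"
  )
}

#' @export
print.icer_result <- function(x, ...) {
  cat("<icer_result>\n")
  cat(sprintf("  delta cost: %.2f EUR; delta dx: %g; QALYs gained: %.4g\n",
              x$delta_cost, x$delta_dx, x$qalys_gained))
  cat(sprintf("  ICER per diagnosis: %.2f EUR\n", x$icer_per_dx))
  cat(sprintf("  ICER per QALY: %.2f EUR (reported convention: %.2f)\n",
              x$icer_per_qaly, x$icer_per_qaly_reported))
  cat(sprintf("  quadrant: %s\n", x$quadrant))
  if (length(x$overrides)) {
    cat("  overrides:", paste(x$overrides, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Invert a willingness-to-pay threshold into a maximum mpMRI price
#'
#' Treats the mpMRI unit price as the free variable: with `n_ia` scans
#' purchased, `ICER(price) = (delta_cost_at_current + n_ia * (price -
#' current_price)) / qalys`. Solving `ICER(price) = wtp` gives the maximum
#' admissible price; the inversion identity `ICER(bound) == wtp` holds to
#' numerical tolerance. If even a free scan (price 0) exceeds the
#' threshold, the result is flagged infeasible.
#'
#' @param delta_cost incremental cost at the current price, EUR.
#' @param n_ia number of mpMRI scans purchased in the imaging arm.
#' @param current_price current mpMRI unit price, EUR.
#' @param qalys QALYs gained (> 0).
#' @param wtp willingness-to-pay threshold, EUR/QALY.
#' @return list of class `price_bound`: `max_price`, `feasible`, `wtp`,
#'   `icer_at_bound`.
#' @export
price_threshold_inversion <- function(delta_cost, n_ia, current_price,
                                      qalys, wtp) {
  if (qalys <= 0) stop("qalys must be positive for price inversion",
                       call. = FALSE)
  stopifnot(n_ia > 0, wtp > 0)
  max_price <- current_price + (wtp * qalys - delta_cost) / n_ia
  icer_at <- function(p) {
    (delta_cost + n_ia * (p - current_price)) / qalys
  }
  structure(
    list(max_price = max_price,
         feasible = max_price >= 0,
         wtp = wtp,
         icer_at_bound = icer_at(max_price)),
    class = "price_bound"
  )
}

#' @export
print.price_bound <- function(x, ...) {
  cat(sprintf("<price_bound> WTP %.0f EUR/QALY -> max mpMRI price %.2f EUR%s\n",
              x$wtp, x$max_price,
              if (x$feasible) "" else " (INFEASIBLE: exceeds WTP even free)"))
  invisible(x)
}
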