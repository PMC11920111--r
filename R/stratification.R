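#' Threshold set for mpMRI risk stratification and biopsy avoidance
#'
#' @param pdff_high PDFF threshold (%) for high MASH risk; default 10.
#' @param ct1_high cT1 threshold (ms) for high MASH risk; default 800.
#' @param ct1_avoid cT1 threshold (ms) for the biopsy-avoidance rule;
#'   default 875.
#' @param mas_min,fibrosis_min histological criteria for MASH with fibrosis
#'   (MAS >= 4 and fibrosis stage >= 2 by default).
#' @return list of class `risk_thresholds`.
#' @export
risk_thresholds <- function(pdff_high = 10, ct1_high = 800, ct1_avoid = 875,
                            mas_min = 4L, fibrosis_min = 2L) {
  th <- list(pdff_high = pdff_high, ct1_high = ct1_high,
             ct1_avoid = ct1_avoid, mas_min = mas_min,
             fibrosis_min = fibrosis_min)
  if (any(unlist(th) <= 0)) stop("all thresholds must be positive",
                                 call. = FALSE)
  structure(th, class = "risk_thresholds")
}

#' Classify MASH risk from cT1 and PDFF
#'
#' High risk if either PDFF >= `pdff_high` or cT1 >= `ct1_high` on a present
#' value; low risk only if both values are present and both below; otherwise
#' unclassified. A missing cT1 with PDFF below threshold is unclassified
#' (the decisive value is unavailable), while a missing cT1 with PDFF at or
#' above threshold is still high risk.
#'
#' @param ct1 cT1 in ms (NA for missing); vectorised.
#' @param pdff PDFF in percent (NA for missing); vectorised.
#' @param thresholds a [risk_thresholds()] object.
#' @return character vector in {"high", "low", "unclassified"}.
#' @examples
#' classify_risk(795, 5.2)      # "low"
#' classify_risk(800, 0)        # "high" (thresholds are inclusive)
#' classify_risk(NA, 9.9)       # "unclassified"
#' @export
classify_risk <- function(ct1, pdff, thresholds = risk_thresholds()) {
  high <- (!is.na(ct1) & ct1 >= thresholds$ct1_high) |
    (!is.na(pdff) & pdff >= thresholds$pdff_high)
  low <- !is.na(ct1) & !is.na(pdff) &
    ct1 < thresholds$ct1_high & pdff < thresholds$pdff_high
  ifelse(high, "high", ifelse(low, "low", "unclassified"))
}

#' Histological MASH with fibrosis
#'
#' @param mas MASLD activity score (0-8); vectorised.
#' @param fibrosis fibrosis stage (0-4); vectorised.
#' @param thresholds a [risk_thresholds()] object.
#' @return logical: MAS >= `mas_min` and fibrosis >= `fibrosis_min`.
#' @export
mash_with_fibrosis <- function(mas, fibrosis,
                               thresholds = risk_thresholds()) {
  if (anyNA(mas) || anyNA(fibrosis)) {
    stop("mas and fibrosis must be present (histology missing)",
         call. = FALSE)
  }
  mas >= thresholds$mas_min & fibrosis >= thresholds$fibrosis_min
}

#' Avoidable-biopsy rule
#'
#' A biopsy is avoidable when histology shows no MASH with fibrosis AND the
#' patient's cT1 falls below the avoidance threshold. The comparison is
#' inclusive (cT1 <= 875 ms) by default, matching the published subgroup
#' arithmetic (9/10 spared); set `strict = TRUE` for a strict `<`.
#'
#' @param mas,fibrosis histology scores (must be present).
#' @param ct1 cT1 in ms (must be present; records with missing cT1 are
#'   excluded upstream).
#' @param thresholds a [risk_thresholds()] object.
#' @param strict use strict inequality at the threshold.
#' @return logical vector.
#' @export
avoidable_biopsy <- function(mas, fibrosis, ct1,
                             thresholds = risk_thresholds(),
                             strict = FALSE) {
  if (anyNA(ct1)) {
    stop("ct1 must be present for the avoidance rule", call. = FALSE)
  }
  below <- if (strict) ct1 < thresholds$ct1_avoid else
    ct1 <= thresholds$ct1_avoid
  !mash_with_fibrosis(mas, fibrosis, thresholds) & below
}

#' 2x2 contingency table of a binary flag against a binary condition
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return object of class `contingency_table`.
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("contingency counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(counts), n = sum(counts), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("flag+", "flag-"),
                              c("condition+", "condition-")))
  cat("<contingency_table> n =", attr(x, "n"), "\n")
  print(m)
  invisible(x)
}

#' Build a 2x2 table from records and two rules
#'
#' @param records data.frame of patient records.
#' @param flag_rule function(records) -> logical (the test / flag).
#' @param condition_rule function(records) -> logical (the condition;
#'   condition polarity is up to the caller - the biopsy-avoidance analysis
#'   uses *absence* of MASH with fibrosis as the condition-positive state).
#' @return a [contingency_table()].
#' @export
build_contingency <- function(records, flag_rule, condition_rule) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a nonempty data.frame", call. = FALSE)
  }
  flag <- flag_rule(records)
  cond <- condition_rule(records)
  if (anyNA(flag) || anyNA(cond)) {
    stop("every record must be evaluable by both rules", call. = FALSE)
  }
  contingency_table(
    tp = sum(flag & cond), fp = sum(flag & !cond),
    fn = sum(!flag & cond), tn = sum(!flag & !cond)
  )
}

#' Diagnostic operating characteristics of a 2x2 table
#'
#' @param t a [contingency_table()].
#' @return list with `sensitivity` (tp/(tp+fn)), `specificity` (tn/(tn+fp)),
#'   `ppv` (tp/(tp+fp)) and `npv` (tn/(tn+fn)); a metric with a zero
#'   denominator is `NA` (undefined), not an error.
#' @examples
#' diagnostic_metrics(contingency_table(tp = 9, fp = 3, fn = 1, tn = 5))
#' @export
diagnostic_metrics <- function(t) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  list(
    sensitivity = ratio(t$tp, t$tp + t$fn),
    specificity = ratio(t$tn, t$tn + t$fp),
    ppv = ratio(t$tp, t$tp + t$fp),
    npv = ratio(t$tn, t$tn + t$fn)
  )
}
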