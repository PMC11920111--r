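#' Deterministic biopsy-subgroup fixture
#'
#' Returns the 21 biopsied imaging-arm patient records implied by the
#' published subgroup counts: 18 analyzable records plus 2 excluded for
#' missing data and 1 excluded for comorbid autoimmune hepatitis (an
#' exclusion criterion for a MASLD/MASH diagnosis).
#'
#' Among the 18 analyzable records, 10 do not meet the histological criteria
#' for MASH with fibrosis (MAS >= 4 and fibrosis stage >= 2); of these, 9
#' have cT1 at or below 875 ms (one of them is the published low-risk case:
#' MAS 2, fibrosis 0, cT1 795 ms, PDFF 5.2%) and 1 is above. The 8 records
#' with MASH with fibrosis split 3 at-or-below / 5 above 875 ms: this is the
#' unique split of 8 for which the 2x2 table of (cT1 <= 875) against
#' (absence of MASH with fibrosis) reproduces, under half-up rounding, all
#' four published operating characteristics (sensitivity 0.9, specificity
#' 0.63, PPV 0.75, NPV 0.83), as verified by enumerating all nine splits.
#' The resulting table is tp = 9, fp = 3, fn = 1, tn = 5.
#'
#' Two denominators circulate for this subgroup: percentages are
#' conventionally quoted against 20 (analyzable plus the two missing-data
#' exclusions), while the 2x2 uses the 18 fully-evaluable records; use the
#' `excluded` flag to switch between them.
#'
#' @return data.frame with columns `patient_id`, `arm`, `site`, `ct1`,
#'   `pdff`, `biopsied`, `mas`, `fibrosis`, `excluded`, `excluded_reason`.
#' @examples
#' fx <- make_biopsy_fixture()
#' sum(!fx$excluded)  # 18 analyzable
#' @export
make_biopsy_fixture <- function() {
  rec <- function(id, ct1, pdff, mas, fibrosis,
                  excluded = FALSE, reason = NA_character_) {
    data.frame(
      patient_id = sprintf("BX-%02d", id), arm = "imaging", site = "UK",
      ct1 = ct1, pdff = pdff, biopsied = TRUE,
      mas = mas, fibrosis = fibrosis,
      excluded = excluded, excluded_reason = reason,
      stringsAsFactors = FALSE
    )
  }
  fixture <- rbind(
    # --- no MASH with fibrosis, cT1 <= 875 ms (9; first is the published
    #     low-risk case, the rest are high risk via cT1 >= 800 or PDFF >= 10)
    rec(1, 795, 5.2, 2L, 0L),
    rec(2, 805, 12.1, 3L, 1L),
    rec(3, 820, 14.8, 2L, 1L),
    rec(4, 832, 11.3, 3L, 0L),
    rec(5, 845, 16.0, 1L, 1L),
    rec(6, 851, 10.4, 3L, 3L),   # fibrosis high but MAS < 4
    rec(7, 860, 13.7, 5L, 1L),   # MAS high but fibrosis < 2
    rec(8, 868, 18.2, 2L, 0L),
    rec(9, 874, 12.9, 3L, 1L),
    # --- no MASH with fibrosis, cT1 > 875 ms (1)
    rec(10, 902, 15.5, 3L, 1L),
    # --- MASH with fibrosis, cT1 <= 875 ms (3)
    rec(11, 810, 13.2, 4L, 2L),
    rec(12, 840, 17.6, 5L, 2L),
    rec(13, 866, 19.9, 6L, 3L),
    # --- MASH with fibrosis, cT1 > 875 ms (5)
    rec(14, 880, 14.4, 4L, 2L),
    rec(15, 895, 21.0, 5L, 3L),
    rec(16, 910, 16.8, 6L, 2L),
    rec(17, 950, 22.5, 7L, 3L),
    rec(18, 1010, 18.1, 8L, 4L),
    # --- exclusions
    rec(19, NA_real_, 11.0, NA_integer_, NA_integer_,
        excluded = TRUE, reason = "missing data"),
    rec(20, 842, 12.0, NA_integer_, NA_integer_,
        excluded = TRUE, reason = "missing data"),
    rec(21, 905, 13.0, 5L, 2L,
        excluded = TRUE, reason = "autoimmune hepatitis")
  )
  rownames(fixture) <- NULL
  fixture
}
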