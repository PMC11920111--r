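#' Resource-use taxonomy, rating scale, sites and arms
#'
#' Fixed vocabularies used throughout the pipeline. Every healthcare
#' resource-use (HCRU) event belongs to one of nine categories; each event may
#' carry up to three clinician ratings of liver-relatedness on a five-level
#' scale; patients belong to one of four recruiting regions and one of two
#' randomisation arms (standard of care, or imaging = SoC + mpMRI).
#'
#' @format Character vectors of allowed values.
#' @name taxonomy
NULL

#' @rdname taxonomy
#' @export
hcru_categories <- c(
  "gp", "specialist_outside", "specialist_hospital", "therapist",
  "blood", "ultrasound", "biopsy", "mri", "mpmri"
)

#' @rdname taxonomy
#' @export
rating_levels <- c(
  "definitely_liver", "probably_liver", "possibly_liver",
  "probably_not", "definitely_not"
)

#' @rdname taxonomy
#' @export
trial_sites <- c("Ulm", "Leiden", "Coimbra", "UK")

#' @rdname taxonomy
#' @export
trial_arms <- c("imaging", "soc")

#' @rdname taxonomy
#' @export
hcru_windows <- c(2L, 6L, 12L)

# reporting groups used in cost summaries (Table-2-style layout)
category_groups <- c(
  gp                  = "practitioner_visits",
  specialist_outside  = "practitioner_visits",
  specialist_hospital = "practitioner_visits",
  therapist           = "practitioner_visits",
  blood               = "patient_assessments",
  ultrasound          = "patient_assessments",
  biopsy              = "patient_assessments",
  mri                 = "mri",
  mpmri               = "mpmri"
)
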