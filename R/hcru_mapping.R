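#' Map a five-level liver-relatedness rating to the binary classification
#'
#' The inclusive mapping collapses the five-level clinician categorisation to
#' liver-related (A) or not liver-related (B): definitely, probably and
#' possibly liver-related all map to A; probably-not and definitely-not map
#' to B.
#'
#' @param rating character vector of levels from [rating_levels].
#' @return character vector of "A" / "B", same length; `NA` in, `NA` out.
#' @examples
#' map_rating_to_binary("possibly_liver")   # "A"
#' map_rating_to_binary("definitely_not")   # "B"
#' @export
map_rating_to_binary <- function(rating) {
  out <- rep(NA_character_, length(rating))
  known <- is.na(rating) | rating %in% rating_levels
  if (!all(known)) {
    stop(sprintf("unknown rating level '%s'", rating[!known][1]),
         call. = FALSE)
  }
  out[rating %in% rating_levels[1:3]] <- "A"
  out[rating %in% rating_levels[4:5]] <- "B"
  out
}

#' Adjudicate multiple raters' liver-relatedness ratings
#'
#' Combines 1-3 ratings by majority vote over their binary mapping. With a
#' single rating the verdict is that rating's mapping; with two ratings that
#' disagree the verdict is `"indeterminate"`; with three the majority wins
#' (no tie is possible). The verdict is invariant to rater order.
#'
#' @param ratings character vector of 1-3 five-level ratings (or already
#'   binary "A"/"B" values).
#' @return one of `"A"`, `"B"`, `"indeterminate"`.
#' @examples
#' adjudicate_ratings(c("definitely_liver", "possibly_liver", "probably_not"))
#' @export
adjudicate_ratings <- function(ratings) {
  ratings <- ratings[!is.na(ratings)]
  if (length(ratings) == 0L) {
    stop("at least one rating is required", call. = FALSE)
  }
  if (length(ratings) > 3L) {
    stop("at most three raters are supported", call. = FALSE)
  }
  bin <- ifelse(ratings %in% c("A", "B"), ratings,
                map_rating_to_binary(ratings))
  n_a <- sum(bin == "A")
  n_b <- sum(bin == "B")
  if (n_a > n_b) "A" else if (n_b > n_a) "B" else "indeterminate"
}

#' Flag a resource-use event table with liver-relatedness
#'
#' Applies [adjudicate_ratings()] row-wise to the `rating1..rating3` columns
#' and appends a `liver_related` column in {A, B, indeterminate}. Input row
#' order is preserved. Events with no ratings at all receive
#' `unrated_default` (the inclusive mapping treats unrated care as
#' liver-related by default).
#'
#' @param events data.frame with optional columns `rating1`, `rating2`,
#'   `rating3` (missing ratings as `NA`).
#' @param unrated_default verdict for events without any rating: `"A"`
#'   (default), `"B"` or `"indeterminate"`.
#' @return `events` with a `liver_related` column appended.
#' @export
flag_events <- function(events,
                        unrated_default = c("A", "B", "indeterminate")) {
  unrated_default <- match.arg(unrated_default)
  stopifnot(is.data.frame(events))
  rating_cols <- intersect(paste0("rating", 1:3), names(events))
  if (nrow(events) == 0L) {
    events$liver_related <- character(0)
    return(events)
  }
  flags <- vapply(seq_len(nrow(events)), function(i) {
    r <- unlist(events[i, rating_cols], use.names = FALSE)
    r <- r[!is.na(r)]
    if (length(r) == 0L) unrated_default else adjudicate_ratings(r)
  }, character(1))
  events$liver_related <- flags
  events
}
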