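# Five-question publication appraisal rubric, scored independently by three
# raters; the publication's final score is the rounded mean of the three
# per-rater totals. Point maps:
#   q1 source of organism reported        yes 1 / no 0
#   q2 method details reproducible        yes 1 / incompletely 0 / no -1
#   q3 growth medium described            yes 1 / referenced 0 / no -1
#   q4 axenicity verified after treatment multiple 1 / one 0 / none -1
#   q5 contaminants identified            yes 1 / no 0
# Per-rater totals therefore lie in [-3, 5].

rubric_points <- function() {
  list(q1 = c(yes = 1, no = 0),
       q2 = c(yes = 1, incompletely = 0, no = -1),
       q3 = c(yes = 1, referenced = 0, no = -1),
       q4 = c(multiple = 1, one = 0, none = -1),
       q5 = c(yes = 1, no = 0))
}

#' Score one rater's rubric response
#'
#' @param response Either a named character vector/list with elements
#'   `q1`..`q5`, or a single `"|"`-joined string of the five answers in
#'   question order (the master-table serialisation).
#' @return Integer total in `[-3, 5]`.
#' @export
#' @examples
#' score_response(c(q1 = "yes", q2 = "yes", q3 = "yes",
#'                  q4 = "multiple", q5 = "yes"))  # 5
#' score_response("no|no|no|none|no")              # -3
score_response <- function(response) {
  if (is.character(response) && length(response) == 1 &&
      grepl("|", response, fixed = TRUE)) {
    response <- parse_rubric_string(response)
  }
  response <- unlist(response)
  if (!all(paste0("q", 1:5) %in% names(response))) {
    abort("rubric response must provide answers q1..q5",
          class = "axenet_validation_error")
  }
  pts <- rubric_points()
  total <- 0L
  for (k in paste0("q", 1:5)) {
    val <- pts[[k]][[response[[k]]]]
    if (is.null(val)) {
      abort(paste0("invalid answer '", response[[k]], "' for ", k),
            class = "axenet_validation_error")
    }
    total <- total + val
  }
  as.integer(total)
}

#' Aggregate three rater totals into the final publication score
#'
#' The final score is the mean of the three per-rater totals rounded half
#' away from zero (so a mean of 0.5 becomes 1 and -0.5 becomes -1); the
#' rounding rule is explicit because the below-zero quality classification
#' depends on it.
#'
#' @param totals Numeric vector of exactly three per-rater totals, each in
#'   `[-3, 5]`.
#' @return Integer final score in `[-3, 5]`.
#' @export
#' @examples
#' aggregate_raters(c(3, 4, 4))    # mean 3.67 -> 4
#' aggregate_raters(c(-1, -2, -2)) # mean -1.67 -> -2
aggregate_raters <- function(totals) {
  if (length(totals) != 3) {
    abort("exactly three rater totals are required",
          class = "axenet_validation_error")
  }
  if (any(totals < -3 | totals > 5)) {
    abort("rater totals must lie in [-3, 5]",
          class = "axenet_validation_error")
  }
  as.integer(round_half_away(mean(totals)))
}

#' Final quality score for each record of a master table
#'
#' @param table A `master_table`.
#' @return Integer vector of final scores, one per record (records of the
#'   same publication share the publication's score).
#' @export
record_quality_scores <- function(table) {
  stopifnot(inherits(table, "master_table"))
  vapply(seq_len(nrow(table)), function(i) {
    aggregate_raters(c(score_response(table$rater1[i]),
                       score_response(table$rater2[i]),
                       score_response(table$rater3[i])))
  }, integer(1))
}

#' Publication-level quality score summary
#'
#' Aggregates rubric responses to one final score per publication and tallies
#' them, overall and by publication period (decade), together with the count
#' of publications scoring below zero.
#'
#' @param table A `master_table`.
#' @param period_width Width in years of the period bins (default 10).
#' @return A list with `scores` (tibble: `publication_id`, `year`,
#'   `final_score`), `histogram` (tibble: `score`, `n_publications`),
#'   `by_period` (tibble: `period`, `score`, `n_publications`) and
#'   `n_below_zero`.
#' @export
summarize_scores <- function(table, period_width = 10) {
  stopifnot(inherits(table, "master_table"))
  if (nrow(table) == 0) {
    return(list(scores = tibble(publication_id = character(0),
                                year = integer(0), final_score = integer(0)),
                histogram = tibble(score = integer(0),
                                   n_publications = integer(0)),
                by_period = tibble(period = character(0), score = integer(0),
                                   n_publications = integer(0)),
                n_below_zero = 0L))
  }
  per_rec <- tibble(publication_id = table$publication_id,
                    year = table$year,
                    final_score = record_quality_scores(table))
  # rows of one publication replicate its rubric; one score per publication
  scores <- per_rec %>%
    group_by(.data$publication_id) %>%
    summarise(year = first(.data$year),
              final_score = first(.data$final_score), .groups = "drop") %>%
    arrange(.data$publication_id)
  inconsistent <- per_rec %>%
    group_by(.data$publication_id) %>%
    summarise(k = n_distinct(.data$final_score), .groups = "drop") %>%
    filter(.data$k > 1)
  if (nrow(inconsistent) > 0) {
    abort(paste0("publications with inconsistent rubric responses across ",
                 "species rows: ",
                 paste(inconsistent$publication_id, collapse = ", ")),
          class = "axenet_validation_error")
  }
  histogram <- scores %>%
    count(score = .data$final_score, name = "n_publications") %>%
    arrange(.data$score)
  by_period <- scores %>%
    mutate(period = paste0(floor(.data$year / period_width) * period_width,
                           "s")) %>%
    count(.data$period, score = .data$final_score,
          name = "n_publications") %>%
    arrange(.data$period, .data$score)
  list(scores = scores, histogram = histogram, by_period = by_period,
       n_below_zero = sum(scores$final_score < 0))
}
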