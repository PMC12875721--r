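# Per-method success rates with the minimum-representation filter: a rate
# is only reported for methods used in more than `filter_limit` (default 6)
# species-level records within the division; below that the entry is
# flagged BFL (below filter limit). A method counts once per record no
# matter how often it recurs in the workflow; a record's methods count as
# successes only when the record's outcome is success (partial outcomes
# contribute uses but no successes — conservative attribution).

#' Per-method success rates for a division
#'
#' @param table A `master_table`.
#' @param division Division label, or `NULL` for all records.
#' @param filter_limit Representation filter: rates are defined only for
#'   `n_uses > filter_limit` (default 6).
#' @return Tibble: `division`, `method`, `n_uses`, `n_success`, `rate`
#'   (NA when below the filter limit), `bfl` (logical).
#' @export
method_success_rates <- function(table, division = NULL, filter_limit = 6) {
  stopifnot(inherits(table, "master_table"))
  if (!is.null(division)) table <- filter_division(table, division)
  if (nrow(table) == 0) {
    abort("no records to compute success rates from",
          class = "axenet_validation_error")
  }
  uses <- purrr::map_dfr(seq_len(nrow(table)), function(i) {
    tibble(method = unique(table$methods[[i]]),
           success = table$outcome[i] == "success")
  })
  uses %>%
    group_by(.data$method) %>%
    summarise(n_uses = n(), n_success = sum(.data$success),
              .groups = "drop") %>%
    mutate(division = division %||% "all",
           bfl = .data$n_uses <= filter_limit,
           rate = ifelse(.data$bfl, NA_real_,
                         .data$n_success / .data$n_uses)) %>%
    select("division", "method", "n_uses", "n_success", "rate", "bfl") %>%
    arrange(.data$method)
}

# Publication-level outcome within a division: success across all its
# species rows -> "Yes", failure across all -> "No", anything mixed or
# partial -> "Multi/Part". Publications spanning divisions are tallied in
# each, so per-division tallies sum to that division's publication count.
publication_outcomes <- function(table) {
  as_tibble(table) %>%
    group_by(.data$publication_id, .data$division) %>%
    summarise(
      outcome = {
        o <- unique(.data$outcome)
        if (identical(o, "success")) "Yes"
        else if (identical(o, "failure")) "No"
        else "Multi/Part"
      },
      .groups = "drop")
}

#' Publication-level summary per division
#'
#' Major data points per division at publication resolution: publication
#' and species counts, counts of distinct methods used by category, genus,
#' media and country diversity, and the outcome tally (Yes / No /
#' Multi-Part).
#'
#' @param table A `master_table`.
#' @return Tibble with one row per division present in the table.
#' @export
division_summary <- function(table) {
  stopifnot(inherits(table, "master_table"))
  if (nrow(table) == 0) {
    return(tibble(division = character(0), n_publications = integer(0),
                  n_species = integer(0), methods_biological = integer(0),
                  methods_chemical = integer(0), methods_physical = integer(0),
                  n_genera = integer(0), n_media = integer(0),
                  n_countries = integer(0), outcome_yes = integer(0),
                  outcome_no = integer(0), outcome_multi_part = integer(0)))
  }
  vocab <- method_vocabulary()
  pub_out <- publication_outcomes(table)
  purrr::map_dfr(sort(unique(table$division)), function(dv) {
    dsub <- filter_division(table, dv)
    meths <- unique(unlist(dsub$methods))
    cats <- vocab$category[match(meths, vocab$code)]
    po <- pub_out$outcome[pub_out$division == dv]
    tibble(division = dv,
           n_publications = n_distinct(dsub$publication_id),
           n_species = n_distinct(dsub$species),
           methods_biological = sum(cats == "Biological"),
           methods_chemical = sum(cats == "Chemical"),
           methods_physical = sum(cats == "Physical"),
           n_genera = n_distinct(sub("^(\\S+).*$", "\\1", dsub$species)),
           n_media = n_distinct(dsub$media),
           n_countries = n_distinct(unlist(dsub$countries)),
           outcome_yes = sum(po == "Yes"),
           outcome_no = sum(po == "No"),
           outcome_multi_part = sum(po == "Multi/Part"))
  })
}
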