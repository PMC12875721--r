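# Antibiotic use summaries: class-level concentration tables (median with
# min-max range, mg/L), compound frequencies, and cocktail co-occurrence
# counts, all at publication resolution. A publication reporting the same
# compound at several concentrations is reduced to one value (its median)
# before cross-publication statistics.

#' Tidy antibiotic uses from a master table
#'
#' Unnests the per-record antibiotic cocktails into one row per
#' (publication, division, compound) with the publication-level
#' concentration (median when a publication reports several values for the
#' same compound in one division).
#'
#' @param table A `master_table`.
#' @return Tibble: `publication_id`, `division`, `class`, `compound`,
#'   `concentration` (mg/L).
#' @export
antibiotic_uses <- function(table) {
  stopifnot(inherits(table, "master_table"))
  raw <- purrr::map_dfr(seq_len(nrow(table)), function(i) {
    ab <- table$antibiotics[[i]]
    if (is.null(ab) || nrow(ab) == 0) return(NULL)
    mutate(ab, publication_id = table$publication_id[i],
           division = table$division[i])
  })
  if (nrow(raw) > 0) {
    # blank classes resolve through the packaged lookup; unmapped -> Others
    lookup <- antibiotic_class_lookup()
    need <- is.na(raw$class) | !nzchar(raw$class)
    raw$class[need] <- lookup$class[match(raw$compound[need],
                                          lookup$compound)]
    raw$class[is.na(raw$class)] <- "Others"
  }
  if (nrow(raw) == 0) {
    return(tibble(publication_id = character(0), division = character(0),
                  class = character(0), compound = character(0),
                  concentration = numeric(0)))
  }
  raw %>%
    group_by(.data$publication_id, .data$division, .data$class,
             .data$compound) %>%
    summarise(concentration = median(.data$concentration),
              .groups = "drop") %>%
    arrange(.data$publication_id, .data$compound)
}

#' Concentration summary per antibiotic class and division
#'
#' @param uses Tibble from [antibiotic_uses()].
#' @return Tibble: `class`, `division`, `n_publications`, `median`, `min`,
#'   `max` (mg/L), plus a formatted `summary` string
#'   `"median (min-max)"`. Classes without uses in a division are absent.
#' @export
class_concentration_summary <- function(uses) {
  if (nrow(uses) == 0) {
    return(tibble(class = character(0), division = character(0),
                  n_publications = integer(0), median = numeric(0),
                  min = numeric(0), max = numeric(0), summary = character(0)))
  }
  uses %>%
    group_by(.data$class, .data$division) %>%
    summarise(n_publications = n_distinct(.data$publication_id),
              median = median(.data$concentration),
              min = min(.data$concentration),
              max = max(.data$concentration), .groups = "drop") %>%
    mutate(summary = paste0(format(.data$median, trim = TRUE), " (",
                            format(.data$min, trim = TRUE), "-",
                            format(.data$max, trim = TRUE), ")")) %>%
    arrange(.data$class, .data$division)
}

#' Compound usage frequency and median concentration
#'
#' @param uses Tibble from [antibiotic_uses()].
#' @return Tibble: `compound`, `class`, `n_publications`,
#'   `median_concentration` (mg/L, over publication-level values).
#' @export
compound_frequency <- function(uses) {
  if (nrow(uses) == 0) {
    return(tibble(compound = character(0), class = character(0),
                  n_publications = integer(0),
                  median_concentration = numeric(0)))
  }
  uses %>%
    group_by(.data$publication_id, .data$compound, .data$class) %>%
    summarise(concentration = median(.data$concentration),
              .groups = "drop") %>%
    group_by(.data$compound, .data$class) %>%
    summarise(n_publications = n_distinct(.data$publication_id),
              median_concentration = median(.data$concentration),
              .groups = "drop") %>%
    arrange(dplyr::desc(.data$n_publications), .data$compound)
}

#' Cocktail pair combinations
#'
#' Counts, per unordered pair, the number of publications whose cocktail
#' contains both members; reported for compounds and for classes. A
#' publication with a single compound contributes no pairs; one with k
#' distinct compounds contributes choose(k, 2) compound pairs.
#'
#' @param uses Tibble from [antibiotic_uses()].
#' @return List of two tibbles, `compound_pairs` and `class_pairs`, each
#'   with `a`, `b`, `n_publications`.
#' @export
cocktail_combinations <- function(uses) {
  pair_counts <- function(items_by_pub) {
    pairs <- purrr::map_dfr(items_by_pub, function(it) {
      it <- sort(unique(it))
      if (length(it) < 2) return(NULL)
      cb <- combn(it, 2)
      tibble(a = cb[1, ], b = cb[2, ])
    })
    if (nrow(pairs) == 0) {
      return(tibble(a = character(0), b = character(0),
                    n_publications = integer(0)))
    }
    pairs %>% count(.data$a, .data$b, name = "n_publications") %>%
      arrange(dplyr::desc(.data$n_publications), .data$a, .data$b)
  }
  by_pub <- split(uses, uses$publication_id)
  list(compound_pairs = pair_counts(lapply(by_pub, `[[`, "compound")),
       class_pairs = pair_counts(lapply(by_pub, `[[`, "class")))
}
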