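# Master table: the canonical record of publication x species axenisation
# attempts. One row per (publication, species); ordered method lists, outcome,
# verification methods, antibiotic cocktail and the three-rater rubric
# responses travel with each row. List fields are serialised with ";" in the
# CSV form; the order of `methods` is the order of application.

master_table_columns <- function() {
  c("publication_id", "year", "countries", "division", "species", "habitat",
    "media", "methods", "outcome", "verification", "antibiotics",
    "rater1", "rater2", "rater3")
}

rubric_levels <- function() {
  list(q1 = c("yes", "no"),
       q2 = c("yes", "incompletely", "no"),
       q3 = c("yes", "referenced", "no"),
       q4 = c("multiple", "one", "none"),
       q5 = c("yes", "no"))
}

#' Construct a master table from a tidy tibble
#'
#' Validates a tibble of workflow records and stamps it as a `master_table`.
#' Expected columns: `publication_id`, `year`, `countries` (list of character),
#' `division`, `species`, `habitat`, `media`, `methods` (list of character,
#' ordered as applied), `outcome`, `verification` (list of character),
#' `antibiotics` (list of tibbles with `class`, `compound`, `concentration`
#' in mg/L), and `rater1`/`rater2`/`rater3` (each a `"|"`-joined string of the
#' five rubric answers).
#'
#' @param records A tibble with the columns above.
#' @param vocabulary Method vocabulary tibble (default the packaged one).
#' @return A validated `master_table`.
#' @export
as_master_table <- function(records, vocabulary = method_vocabulary()) {
  records <- as_tibble(records)
  validate_master_table(records, vocabulary)
  class(records) <- c("master_table", class(tibble()))
  records
}

#' @export
print.master_table <- function(x, ...) {
  cat("<master_table> ", nrow(x), " species-level records, ",
      n_distinct(x$publication_id), " publications\n", sep = "")
  NextMethod()
}

validate_master_table <- function(records, vocabulary = method_vocabulary()) {
  missing_cols <- setdiff(master_table_columns(), names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("master table schema error: missing column(s) ",
                 paste(missing_cols, collapse = ", ")),
          class = "axenet_schema_error")
  }
  if (nrow(records) == 0) return(invisible(records))

  key <- paste(records$publication_id, records$species, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), c("publication_id", "species")]
    abort(paste0("duplicate (publication_id, species) pair(s): ",
                 paste(paste(dup$publication_id, dup$species, sep = " / "),
                       collapse = "; ")),
          class = "axenet_validation_error")
  }

  bad_div <- which(!records$division %in% divisions_known())
  if (length(bad_div) > 0) {
    abort(paste0("row ", bad_div[1], ": unknown division '",
                 records$division[bad_div[1]], "'"),
          class = "axenet_validation_error")
  }
  bad_out <- which(!records$outcome %in% outcomes_known())
  if (length(bad_out) > 0) {
    abort(paste0("row ", bad_out[1], ": unknown outcome '",
                 records$outcome[bad_out[1]], "'"),
          class = "axenet_validation_error")
  }
  bad_hab <- which(!records$habitat %in% habitats_known())
  if (length(bad_hab) > 0) {
    abort(paste0("row ", bad_hab[1], ": unknown habitat '",
                 records$habitat[bad_hab[1]], "'"),
          class = "axenet_validation_error")
  }

  for (i in seq_len(nrow(records))) {
    meths <- records$methods[[i]]
    if (length(meths) < 1) {
      abort(paste0("row ", i, ": workflow has no methods"),
            class = "axenet_validation_error")
    }
    unknown <- setdiff(meths, vocabulary$code)
    if (length(unknown) > 0) {
      abort(paste0("row ", i, ": unknown method code(s) ",
                   paste(unknown, collapse = ", ")),
            class = "axenet_validation_error")
    }
    ab <- records$antibiotics[[i]]
    if (!is.null(ab) && nrow(ab) > 0) {
      if (any(!is.finite(ab$concentration)) || any(ab$concentration <= 0)) {
        abort(paste0("row ", i, ": malformed antibiotic concentration ",
                     "(must be a positive number of mg/L)"),
              class = "axenet_validation_error")
      }
    }
    for (rt in c("rater1", "rater2", "rater3")) {
      parse_rubric_string(records[[rt]][i], where = paste0("row ", i, " ", rt))
    }
  }
  invisible(records)
}

# "yes|yes|referenced|one|no" -> named character vector q1..q5, validated.
parse_rubric_string <- function(x, where = "rubric") {
  ans <- split_field(x, sep = "|")
  if (length(ans) != 5) {
    abort(paste0(where, ": expected 5 '|'-separated rubric answers, got ",
                 length(ans)),
          class = "axenet_validation_error")
  }
  lv <- rubric_levels()
  for (k in 1:5) {
    if (!ans[k] %in% lv[[k]]) {
      abort(paste0(where, ": answer '", ans[k], "' not allowed for q", k,
                   " (one of ", paste(lv[[k]], collapse = "/"), ")"),
            class = "axenet_validation_error")
    }
  }
  setNames(ans, paste0("q", 1:5))
}

serialise_antibiotics <- function(ab) {
  if (is.null(ab) || nrow(ab) == 0) return("")
  paste(paste(ab$class, ab$compound, format(ab$concentration, trim = TRUE,
                                            scientific = FALSE),
              sep = ":"), collapse = ";")
}

parse_antibiotics <- function(x, row_ix, lookup = antibiotic_class_lookup()) {
  parts <- split_field(x)
  if (length(parts) == 0) {
    return(tibble(class = character(0), compound = character(0),
                  concentration = numeric(0)))
  }
  fields <- strsplit(parts, ":", fixed = TRUE)
  bad <- which(lengths(fields) != 3)
  if (length(bad) > 0) {
    abort(paste0("row ", row_ix, ": malformed antibiotic entry '",
                 parts[bad[1]], "' (expected class:compound:concentration)"),
          class = "axenet_validation_error")
  }
  cls <- vapply(fields, `[`, "", 1)
  cmp <- vapply(fields, `[`, "", 2)
  conc <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  if (any(is.na(conc)) || any(conc <= 0)) {
    abort(paste0("row ", row_ix, ": malformed antibiotic concentration in '",
                 x, "'"),
          class = "axenet_validation_error")
  }
  # blank class -> lookup by compound, unmapped compounds fall into Others
  need <- !nzchar(cls)
  if (any(need)) {
    cls[need] <- lookup$class[match(cmp[need], lookup$compound)]
    cls[is.na(cls)] <- "Others"
  }
  tibble(class = cls, compound = cmp, concentration = conc)
}

#' Read a workflow master table from CSV
#'
#' Reads and validates the canonical CSV serialisation of the master table.
#' Each row is one publication x species axenisation attempt; `methods`,
#' `countries` and `verification` are `";"`-delimited in the file (method
#' order is order of application), `antibiotics` entries are
#' `class:compound:concentration` triples joined with `";"` (class may be
#' left blank to be filled from the packaged lookup), and each `rater*`
#' column holds the five rubric answers joined with `"|"`.
#'
#' @param path Path to the CSV file.
#' @param vocabulary Method vocabulary tibble.
#' @param alias Optional tibble (`raw_label`, `code`) mapping free-text method
#'   labels onto vocabulary codes before validation.
#' @return A validated `master_table`.
#' @export
read_master_table <- function(path, vocabulary = method_vocabulary(),
                              alias = NULL) {
  if (!file.exists(path)) {
    abort(paste0("master table file not found: ", path),
          class = "axenet_schema_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(master_table_columns(), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("master table schema error: missing column(s) ",
                 paste(missing_cols, collapse = ", ")),
          class = "axenet_schema_error")
  }
  lookup <- antibiotic_class_lookup()
  methods <- lapply(raw$methods, split_field)
  if (!is.null(alias)) {
    stopifnot(all(c("raw_label", "code") %in% names(alias)))
    methods <- lapply(methods, function(m) {
      hit <- match(m, alias$raw_label)
      m[!is.na(hit)] <- alias$code[hit[!is.na(hit)]]
      m
    })
  }
  records <- tibble(
    publication_id = raw$publication_id,
    year = as.integer(raw$year),
    countries = lapply(raw$countries, split_field),
    division = raw$division,
    species = raw$species,
    habitat = raw$habitat,
    media = raw$media,
    methods = methods,
    outcome = raw$outcome,
    verification = lapply(raw$verification, split_field),
    antibiotics = lapply(seq_len(nrow(raw)), function(i)
      parse_antibiotics(raw$antibiotics[i], i, lookup)),
    rater1 = raw$rater1, rater2 = raw$rater2, rater3 = raw$rater3
  )
  out <- as_master_table(records, vocabulary)
  attr(out, "provenance") <- list(
    source = normalizePath(path),
    sha_like = unname(sum(utf8ToInt(paste(raw$publication_id, collapse = "")))))
  out
}

#' Write a master table to CSV
#'
#' Serialises a master table into the canonical CSV form after canonical
#' ordering by (`publication_id`, `species`); reading the file back yields an
#' equal table, and writing it again yields a byte-identical file.
#'
#' @param table A `master_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_master_table <- function(table, path) {
  stopifnot(inherits(table, "master_table"))
  tb <- arrange(as_tibble(table), .data$publication_id, .data$species)
  flat <- tibble(
    publication_id = tb$publication_id,
    year = tb$year,
    countries = vapply(tb$countries, join_field, ""),
    division = tb$division,
    species = tb$species,
    habitat = tb$habitat,
    media = tb$media,
    methods = vapply(tb$methods, join_field, ""),
    outcome = tb$outcome,
    verification = vapply(tb$verification, join_field, ""),
    antibiotics = vapply(tb$antibiotics, serialise_antibiotics, ""),
    rater1 = tb$rater1, rater2 = tb$rater2, rater3 = tb$rater3
  )
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' Restrict a master table to one microalgal division
#'
#' @param table A `master_table`.
#' @param division One of `"diatoms"`, `"dinoflagellates"`, `"green_algae"`,
#'   `"other"`.
#' @return A `master_table` containing only that division's records (possibly
#'   zero rows).
#' @export
filter_division <- function(table, division) {
  stopifnot(inherits(table, "master_table"))
  if (!division %in% divisions_known()) {
    abort(paste0("unknown division '", division, "' (known: ",
                 paste(divisions_known(), collapse = ", "), ")"),
          class = "axenet_validation_error")
  }
  out <- table[table$division == division, , drop = FALSE]
  class(out) <- class(table)
  out
}
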