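# Packaged vocabularies: axenisation methods, verification methods,
# antibiotic compound -> class lookup.

#' Axenisation method vocabulary
#'
#' The closed vocabulary of 24 purification methods reported for microalgal
#' axenisation, each with a four-character code and a mode-of-action category
#' (Biological, Chemical or Physical). Workflows in a master table may only
#' use codes from this vocabulary (or codes mapped onto it via an alias
#' table).
#'
#' @return A tibble with columns `code`, `name`, `category`.
#' @export
#' @examples
#' method_vocabulary()
method_vocabulary <- function() {
  path <- system.file("extdata", "method_vocabulary.csv", package = "axenet",
                      mustWork = TRUE)
  vocab <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  stopifnot(nrow(vocab) == 24L, !anyDuplicated(vocab$code))
  vocab
}

#' Verification (axenicity screening) method vocabulary
#'
#' The 13 distinct methods used in the literature to verify axenicity of the
#' final culture, grouped into microscopy, counting, sequencing and
#' physiology-based approaches.
#'
#' @return A tibble with columns `code`, `name`, `group`.
#' @export
verification_vocabulary <- function() {
  path <- system.file("extdata", "verification_vocabulary.csv",
                      package = "axenet", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}

#' Antibiotic compound to class lookup
#'
#' Maps antibiotic compounds reported in axenisation cocktails onto the 12
#' antibiotic classes used in the summaries (Aminoglycosides ... Others).
#' Compounds absent from the lookup fall into `"Others"`.
#'
#' @return A tibble with columns `compound`, `class`.
#' @export
antibiotic_class_lookup <- function() {
  path <- system.file("extdata", "antibiotic_classes.csv", package = "axenet",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}

#' Antibiotic classes
#' @return Character vector of the 12 recognised antibiotic classes.
#' @export
antibiotic_classes <- function() {
  c("Aminoglycosides", "Carbapenems", "Fluoroquinolones", "Penicillins",
    "Tetracyclines", "Cephalosporins", "Macrolides", "Polypeptides",
    "Rifamycins", "Nitrofurans", "Antifungal Agents", "Others")
}

#' Code of the incubation sink node
#'
#' Every workflow ends in incubation of the putatively axenic culture; the
#' incubation step is represented as a dedicated sink node appended to each
#' workflow when networks are built. It is not part of the method vocabulary.
#'
#' @return The string `"INCB"`.
#' @export
incubation_code <- function() "INCB"

divisions_known <- function() {
  c("diatoms", "dinoflagellates", "green_algae", "other")
}

habitats_known <- function() c("freshwater", "marine", "brackish", "unknown")

outcomes_known <- function() c("success", "failure", "partial")
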