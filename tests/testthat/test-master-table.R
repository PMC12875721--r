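test_that("vocabulary has 24 methods split 3 biological / 8 chemical / 13 physical", {
  vocab <- method_vocabulary()
  expect_equal(nrow(vocab), 24)
  expect_equal(anyDuplicated(vocab$code), 0)
  counts <- table(vocab$category)
  expect_equal(unname(counts[["Biological"]]), 3)
  expect_equal(unname(counts[["Chemical"]]), 8)
  expect_equal(unname(counts[["Physical"]]), 13)
})

test_that("rows parse into ordered workflows and round-trip byte-identically", {
  tab <- make_table(
    make_record("P1", "Navicula sp.", c("Fltr", "Wash", "Mkpk"),
                verification = c("Plate", "Seq16"),
                antibiotics = tibble::tibble(class = "Aminoglycosides",
                                             compound = "streptomycin",
                                             concentration = 100)),
    make_record("P1", "Amphora sp.", c("AntB"), outcome = "failure"),
    make_record("P2", "Chlorella sp.", c("StPl"), division = "green_algae"))
  expect_identical(tab$methods[[1]], c("Fltr", "Wash", "Mkpk"))

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_master_table(tab, f1)
  back <- read_master_table(f1)
  # files are written in canonical (publication, species) order
  canon <- dplyr::arrange(tibble::as_tibble(tab), publication_id, species)
  expect_identical(as.list(back$methods), as.list(canon$methods))
  nav <- which(back$species == "Navicula sp.")
  expect_equal(back$antibiotics[[nav]]$concentration, 100)
  expect_equal(back$antibiotics[[nav]]$class, "Aminoglycosides")
  write_master_table(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  # read -> write -> read is a fixed point (provenance tracks the file read)
  again <- read_master_table(f2)
  expect_equal(tibble::as_tibble(again), tibble::as_tibble(back),
               ignore_attr = TRUE)
})

test_that("validation rejects unknown codes, bad schema and bad values", {
  expect_error(make_table(make_record("P1", "s", c("XXXX"))),
               "row 1.*XXXX", class = "axenet_validation_error")
  expect_error(make_table(make_record("P1", "s", character(0))),
               "no methods", class = "axenet_validation_error")
  expect_error(
    make_table(make_record("P1", "s", "Fltr", division = "seaweed")),
    "unknown division", class = "axenet_validation_error")
  expect_error(
    make_table(make_record("P1", "s", "Fltr",
                           antibiotics = tibble::tibble(
                             class = "Others", compound = "x",
                             concentration = -5))),
    "concentration", class = "axenet_validation_error")
  expect_error(
    make_table(make_record("P1", "s", "Fltr", rater1 = "yes|maybe|no|one|no")),
    "not allowed", class = "axenet_validation_error")
  expect_error(make_table(make_record("P1", "s", "Fltr"),
                          make_record("P1", "s", "Wash")),
               "duplicate", class = "axenet_validation_error")

  bad_csv <- withr::local_tempfile(fileext = ".csv")
  writeLines("publication_id,year\nP1,2020", bad_csv)
  expect_error(read_master_table(bad_csv), "missing column",
               class = "axenet_schema_error")
})

test_that("alias table maps raw labels onto vocabulary codes", {
  tab <- make_table(make_record("P1", "s", c("Fltr", "Wash")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_master_table(tab, f)
  raw <- readLines(f)
  raw[2] <- sub("Fltr;Wash", "filtration (0.2um);Wash", raw[2])
  writeLines(raw, f)
  expect_error(read_master_table(f), class = "axenet_validation_error")
  alias <- tibble::tibble(raw_label = "filtration (0.2um)", code = "Fltr")
  fixed <- read_master_table(f, alias = alias)
  expect_identical(fixed$methods[[1]], c("Fltr", "Wash"))
})

test_that("division filter partitions the table exhaustively and disjointly", {
  tab <- generate_master_table(synthetic_config(seed = 11))$table
  parts <- lapply(divisions <- sort(unique(tab$division)),
                  function(d) filter_division(tab, d))
  expect_equal(sum(vapply(parts, nrow, 0L)), nrow(tab))
  keys <- unlist(lapply(parts, function(p)
    paste(p$publication_id, p$species)))
  expect_equal(anyDuplicated(keys), 0)
  expect_true(all(filter_division(tab, "diatoms")$division == "diatoms"))
  expect_error(filter_division(tab, "kelp"), "unknown division")
  empty <- filter_division(tab[0, ], "diatoms")
  expect_equal(nrow(empty), 0)
})
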