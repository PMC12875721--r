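test_that("generation is deterministic given the seed and validates cleanly", {
  cfg <- synthetic_config(seed = 123)
  a <- generate_master_table(cfg)
  b <- generate_master_table(cfg)
  expect_identical(tibble::as_tibble(a$table), tibble::as_tibble(b$table))
  expect_identical(a$ledger$record_success_prob, b$ledger$record_success_prob)
  # different seed, different table
  c <- generate_master_table(synthetic_config(seed = 124))
  expect_false(identical(tibble::as_tibble(a$table),
                         tibble::as_tibble(c$table)))
  # generated tables survive the CSV round trip through the validator
  f <- withr::local_tempfile(fileext = ".csv")
  write_master_table(a$table, f)
  expect_silent(back <- read_master_table(f))
  expect_equal(nrow(back), nrow(a$table))
})

test_that("invalid configurations fail before any generation", {
  expect_error(synthetic_config(seed = 1, p_in = 0.3, p_out = 0.5),
               "p_out", class = "axenet_config_error")
  expect_error(synthetic_config(seed = 1, workflow_length = c(0, 3)),
               class = "axenet_config_error")
  expect_error(synthetic_config(seed = 1, n_publications = 0),
               class = "axenet_config_error")
  expect_error(
    synthetic_config(seed = 1,
                     planted_partition = c(BADC = 1, Fltr = 1)),
    class = "axenet_config_error")
  expect_error(
    synthetic_config(seed = 1,
                     success_prob = c(Fltr = 1.5)),
    class = "axenet_config_error")
})

test_that("p_in = p_out would remove structure; transition rows are as configured", {
  # transition_probs is uniform when p_in == p_out (checked directly since
  # the config validator requires p_out < p_in for planted tables)
  clusters <- setNames(rep(1:2, each = 3), letters[1:6])
  p_flat <- axenet:::transition_probs("a", letters[1:6], clusters, 0.4, 0.4)
  expect_true(all(abs(p_flat - 1 / 6) < 1e-12))
  p_str <- axenet:::transition_probs("a", letters[1:6], clusters, 0.8, 0.05)
  expect_equal(sum(p_str), 1)
  expect_gt(p_str[["b"]], p_str[["d"]])
})

test_that("empirical transition frequencies match the planted matrix", {
  # big table, few methods -> chi-square goodness of fit per source method
  planted <- setNames(rep(1:2, each = 3),
                      c("Fltr", "Wash", "Mkpk", "Ctfg", "UltS", "DenG"))
  cfg <- synthetic_config(seed = 77, n_publications = 400,
                          species_per_publication = c(1L, 2L),
                          planted_partition = planted,
                          workflow_length = c(3L, 5L))
  tab <- generate_master_table(cfg)$table
  trans <- do.call(rbind, lapply(tab$methods, function(m) {
    if (length(m) < 2) return(NULL)
    cbind(m[-length(m)], m[-1])
  }))
  methods <- names(planted)
  for (src in c("Fltr", "Ctfg")) {
    obs <- table(factor(trans[trans[, 1] == src, 2], levels = methods))
    expected_p <- axenet:::transition_probs(src, methods, planted,
                                            cfg$p_in, cfg$p_out)
    chi <- suppressWarnings(stats::chisq.test(obs, p = expected_p))
    expect_gt(chi$p.value, 0.01)
  }
})

test_that("empirical method success rates sit within 3 binomial SE of truth", {
  # all other methods at probability 1 so workflows containing Mkpk succeed
  # with probability exactly 0.9
  probs <- setNames(rep(1, 24), method_vocabulary()$code)
  probs["Mkpk"] <- 0.9
  cfg <- synthetic_config(seed = 2024, n_publications = 200,
                          success_prob = probs)
  out <- generate_master_table(cfg)
  rates <- method_success_rates(out$table)
  mk <- rates[rates$method == "Mkpk", ]
  expect_false(mk$bfl)
  se <- sqrt(0.9 * 0.1 / mk$n_uses)
  expect_lt(abs(mk$rate - 0.9), 3 * se)
})

test_that("recovery report flags a mismatched ledger and returns sane fields", {
  out <- generate_master_table(synthetic_config(seed = 8, n_publications = 30))
  rr <- recovery_report(out$table, out$ledger)
  expect_true(rr$ari >= -1 && rr$ari <= 1)
  expect_true(all(rr$rates$abs_error[!rr$rates$bfl] >= 0, na.rm = TRUE))
  bad_ledger <- out$ledger
  bad_ledger$record_key <- rev(bad_ledger$record_key)
  expect_error(recovery_report(out$table, bad_ledger), "ledger",
               class = "axenet_validation_error")
})

test_that("large samples drive filtered rate errors toward zero", {
  probs <- setNames(rep(1, 24), method_vocabulary()$code)
  probs[c("Mkpk", "AntB", "Fltr")] <- c(0.9, 0.7, 0.8)
  cfg <- synthetic_config(seed = 31, n_publications = 1500,
                          species_per_publication = c(1L, 3L),
                          success_prob = probs)
  out <- generate_master_table(cfg)
  rr <- recovery_report(out$table, out$ledger)
  expect_lt(rr$max_rate_error, 0.05)
})
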