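# Seeded synthetic master tables with known ground truth. The generator
# emulates the structure of the curated corpus: ~60 publications, one to six
# species each across four divisions, workflows of one to five methods drawn
# as a random walk whose transition matrix carries planted method clusters
# (within-cluster probability mass p_in, between-cluster p_out), Bernoulli
# success outcomes with per-method probabilities, antibiotic cocktails for
# workflows that use AntB, and rubric responses drawn per question. Every
# planted quantity is returned in a ledger so downstream estimates can be
# checked against truth.

default_planted_partition <- function() {
  codes <- method_vocabulary()$code
  setNames(rep(1:4, each = 6), codes)
}

default_success_prob <- function() {
  vocab <- method_vocabulary()
  p <- c(Biological = 0.70, Chemical = 0.75, Physical = 0.85)
  setNames(p[vocab$category], vocab$code)
}

default_rubric_distribution <- function() {
  list(q1 = c(yes = 0.70, no = 0.30),
       q2 = c(yes = 0.50, incompletely = 0.30, no = 0.20),
       q3 = c(yes = 0.60, referenced = 0.25, no = 0.15),
       q4 = c(multiple = 0.35, one = 0.40, none = 0.25),
       q5 = c(yes = 0.30, no = 0.70))
}

#' Configuration for the synthetic master-table generator
#'
#' Defaults mirror the curated corpus: 63 publications weighted across the
#' four divisions as in the literature (11 diatom, 15 dinoflagellate, 33
#' green-algae, 22 other publication equivalents), about half the
#' publications reporting a single species and the rest two to six,
#' workflows of 1-5 methods over the 24-method vocabulary with four planted
#' clusters of six methods (p_in = 0.8, p_out = 0.05), and per-method
#' success probabilities by category (Physical 0.85, Chemical 0.75,
#' Biological 0.70).
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_publications Number of publications.
#' @param species_per_publication Length-2 integer range.
#' @param single_species_prob Probability a publication reports one species.
#' @param division_weights Named sampling weights over divisions.
#' @param planted_partition Named integer vector: method code -> cluster id.
#'   Methods absent from it never appear in workflows.
#' @param p_in,p_out Within/between-cluster transition probability mass
#'   (`0 <= p_out < p_in <= 1`).
#' @param workflow_length Length-2 integer range (>= 1).
#' @param success_prob Named per-method success probabilities; a workflow
#'   succeeds with probability equal to the product over its distinct
#'   methods.
#' @param rubric_distribution List of per-question named answer
#'   probabilities.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed,
                             n_publications = 63,
                             species_per_publication = c(1L, 6L),
                             single_species_prob = 0.54,
                             division_weights = c(diatoms = 11,
                                                  dinoflagellates = 15,
                                                  green_algae = 33,
                                                  other = 22),
                             planted_partition = default_planted_partition(),
                             p_in = 0.8, p_out = 0.05,
                             workflow_length = c(1L, 5L),
                             success_prob = default_success_prob(),
                             rubric_distribution =
                               default_rubric_distribution()) {
  cfg <- list(seed = as.integer(seed), n_publications = n_publications,
              species_per_publication = as.integer(species_per_publication),
              single_species_prob = single_species_prob,
              division_weights = division_weights,
              planted_partition = planted_partition,
              p_in = p_in, p_out = p_out,
              workflow_length = as.integer(workflow_length),
              success_prob = success_prob,
              rubric_distribution = rubric_distribution)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  fail <- function(msg) abort(paste0("invalid synthetic config: ", msg),
                              class = "axenet_config_error")
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) fail("seed must be an integer")
  if (cfg$n_publications < 1) fail("n_publications must be >= 1")
  if (length(cfg$workflow_length) != 2 || cfg$workflow_length[1] < 1 ||
      diff(cfg$workflow_length) < 0) {
    fail("workflow_length must be an increasing range with minimum >= 1")
  }
  if (length(cfg$species_per_publication) != 2 ||
      cfg$species_per_publication[1] < 1 ||
      diff(cfg$species_per_publication) < 0) {
    fail("species_per_publication must be an increasing range >= 1")
  }
  if (!(cfg$p_out >= 0 && cfg$p_out < cfg$p_in && cfg$p_in <= 1)) {
    fail("need 0 <= p_out < p_in <= 1")
  }
  vocab_codes <- method_vocabulary()$code
  if (is.null(names(cfg$planted_partition)) ||
      !all(names(cfg$planted_partition) %in% vocab_codes)) {
    fail("planted_partition must be named by vocabulary method codes")
  }
  if (any(!names(cfg$planted_partition) %in% names(cfg$success_prob))) {
    fail("success_prob must cover every planted method")
  }
  if (any(cfg$success_prob < 0 | cfg$success_prob > 1)) {
    fail("success probabilities must lie in [0, 1]")
  }
  if (!all(names(cfg$division_weights) %in% divisions_known()) ||
      any(cfg$division_weights < 0) || sum(cfg$division_weights) <= 0) {
    fail("division_weights must be non-negative over known divisions")
  }
  lv <- rubric_levels()
  for (k in paste0("q", 1:5)) {
    d <- cfg$rubric_distribution[[k]]
    if (is.null(d) || !setequal(names(d), lv[[k]]) || any(d < 0)) {
      fail(paste0("rubric_distribution$", k, " must weight answers ",
                  paste(lv[[k]], collapse = "/")))
    }
  }
  invisible(cfg)
}

# Planted transition probabilities out of method `cur`: mass p_in spread
# over same-cluster methods (incl. cur itself -> self-loops), p_out over the
# rest, normalised.
transition_probs <- function(cur, methods, clusters, p_in, p_out) {
  w <- ifelse(clusters == clusters[[cur]], p_in, p_out)
  w / sum(w)
}

genus_pool <- function(division) {
  switch(division,
    diatoms = c("Navicula", "Nitzschia", "Chaetoceros", "Skeletonema",
                "Thalassiosira", "Amphora"),
    dinoflagellates = c("Alexandrium", "Karenia", "Symbiodinium",
                        "Prorocentrum", "Heterocapsa"),
    green_algae = c("Chlorella", "Chlamydomonas", "Scenedesmus", "Dunaliella",
                    "Haematococcus", "Tetraselmis"),
    other = c("Euglena", "Isochrysis", "Nannochloropsis", "Rhodomonas",
              "Porphyridium"))
}

media_pool <- function() {
  c("f/2", "f/2 + Si", "BG11", "BBM", "L1 medium", "K medium", "TAP medium",
    "Cramer-Myers medium", "artificial seawater", "not mentioned")
}

country_pool <- function() {
  c("China", "USA", "Japan", "Germany", "South Korea", "France", "Ireland",
    "Australia", "Canada", "India", "Mexico", "Russia")
}

#' Generate a synthetic master table with ground truth
#'
#' Reproducible given the seed: each publication derives its own sub-seed
#' deterministically, so tables are identical across runs and platforms.
#'
#' @param config A `synthetic_config`.
#' @return List with `table` (a validated `master_table`) and `ledger`
#'   (planted partition, per-method success probabilities, per-record true
#'   workflow success probability, per-publication final rubric scores, and
#'   the config).
#' @export
#' @examples
#' out <- generate_master_table(synthetic_config(seed = 42))
#' out$table
generate_master_table <- function(config) {
  validate_synthetic_config(config)
  methods_avail <- names(config$planted_partition)
  clusters <- config$planted_partition
  sp_range <- config$species_per_publication
  len_range <- config$workflow_length
  ver_codes <- verification_vocabulary()$code
  ab_lookup <- antibiotic_class_lookup()
  rows <- vector("list", config$n_publications)
  pub_scores <- integer(config$n_publications)
  for (i in seq_len(config$n_publications)) {
    set.seed((config$seed * 1000003 + i) %% (2^31 - 1))
    pub_id <- sprintf("PUB%03d", i)
    year <- sample(1960:2025, 1)
    division <- sample(names(config$division_weights), 1,
                       prob = config$division_weights)
    countries <- sample(country_pool(), sample(1:2, 1))
    media <- sample(media_pool(), 1)
    habitat <- sample(habitats_known(), 1, prob = c(0.3, 0.5, 0.1, 0.1))
    raters <- vapply(1:3, function(r) {
      ans <- vapply(paste0("q", 1:5), function(k) {
        d <- config$rubric_distribution[[k]]
        sample(names(d), 1, prob = d)
      }, "")
      paste(ans, collapse = "|")
    }, "")
    pub_scores[i] <- aggregate_raters(vapply(raters, score_response,
                                             integer(1)))
    n_ver <- sample(0:4, 1, prob = c(0.1, 0.35, 0.2, 0.2, 0.15))
    verification <- if (n_ver == 0) character(0) else
      sort(sample(ver_codes, n_ver,
                  prob = ifelse(ver_codes %in% c("Plate", "Epifl", "Seq16",
                                                 "Light"), 3, 1)))
    n_sp <- if (runif(1) < config$single_species_prob ||
                sp_range[2] == 1) sp_range[1] else
      sample(seq(max(2L, sp_range[1]), sp_range[2]), 1)
    genera <- genus_pool(division)
    sp_rows <- vector("list", n_sp)
    for (j in seq_len(n_sp)) {
      len <- if (len_range[1] == len_range[2]) len_range[1] else
        sample(seq(len_range[1], len_range[2]), 1)
      wf <- character(len)
      wf[1] <- sample(methods_avail, 1)
      if (len > 1) {
        for (s in 2:len) {
          p <- transition_probs(wf[s - 1], methods_avail, clusters,
                                config$p_in, config$p_out)
          wf[s] <- sample(methods_avail, 1, prob = p)
        }
      }
      p_succ <- prod(config$success_prob[unique(wf)])
      outcome <- if (runif(1) < p_succ) "success" else "failure"
      antibiotics <- if ("AntB" %in% wf) {
        k <- sample(1:3, 1)
        cmp <- sample(ab_lookup$compound, k)
        tibble(class = ab_lookup$class[match(cmp, ab_lookup$compound)],
               compound = cmp,
               concentration = round(10^runif(k, 0.7, 3), 1))
      } else {
        tibble(class = character(0), compound = character(0),
               concentration = numeric(0))
      }
      sp_rows[[j]] <- tibble(
        publication_id = pub_id, year = year, countries = list(countries),
        division = division,
        species = paste0(sample(genera, 1), " sp. ", j),
        habitat = habitat, media = media, methods = list(wf),
        outcome = outcome, verification = list(verification),
        antibiotics = list(antibiotics),
        rater1 = raters[1], rater2 = raters[2], rater3 = raters[3],
        true_p_success = p_succ)
    }
    rows[[i]] <- bind_rows(sp_rows)
  }
  all_rows <- bind_rows(rows)
  true_p <- all_rows$true_p_success
  all_rows$true_p_success <- NULL
  table <- as_master_table(all_rows)
  ledger <- list(
    planted_partition = config$planted_partition,
    success_prob = config$success_prob,
    record_success_prob = true_p,
    record_key = paste(table$publication_id, table$species, sep = "/"),
    publication_scores = setNames(pub_scores,
                                  sprintf("PUB%03d",
                                          seq_len(config$n_publications))),
    config = config)
  list(table = table, ledger = ledger)
}

#' Parameter-recovery report for a synthetic table
#'
#' Rebuilds the full pipeline on a generated table and compares what it
#' recovers against the generator's ledger: adjusted Rand index between the
#' modularity partition of the method network (all divisions pooled) and
#' the planted clusters, and the largest absolute error between estimated
#' success rates (methods above the representation filter) and the true
#' expected success rate of workflows containing each method.
#'
#' @param table Master table from [generate_master_table()].
#' @param ledger Matching ledger.
#' @param max_exact_n Passed to [optimal_partition()].
#' @param filter_limit Passed to [method_success_rates()].
#' @return List with `ari`, `n_nodes`, `partition`, `rates` (tibble with
#'   `truth` and `abs_error` columns) and `max_rate_error`.
#' @export
recovery_report <- function(table, ledger, max_exact_n = 20,
                            filter_limit = 6) {
  stopifnot(inherits(table, "master_table"))
  key <- paste(table$publication_id, table$species, sep = "/")
  if (!identical(key, ledger$record_key)) {
    abort("ledger does not match table (record keys differ)",
          class = "axenet_validation_error")
  }
  net <- build_axenisation_network(table)
  und <- to_undirected(net)
  part <- optimal_partition(und, max_exact_n = max_exact_n)
  planted <- ledger$planted_partition[method_nodes(net)]
  ari <- compare_partitions(part$assignment, planted)
  rates <- method_success_rates(table, filter_limit = filter_limit)
  truth <- vapply(rates$method, function(m) {
    hit <- vapply(table$methods, function(wf) m %in% wf, TRUE)
    mean(ledger$record_success_prob[hit])
  }, 0)
  rates$truth <- truth
  rates$abs_error <- abs(rates$rate - truth)
  defined <- !rates$bfl
  list(ari = ari, n_nodes = length(method_nodes(net)), partition = part,
       rates = rates,
       max_rate_error = if (any(defined)) max(rates$abs_error[defined])
                        else NA_real_)
}
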