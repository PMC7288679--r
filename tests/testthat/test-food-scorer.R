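# Mid-sized planted-signal fixture shared by the scorer tests; generated
# once per session.
local_scorer_fixture <- local({
  cache <- NULL
  function(env = parent.frame()) {
    if (!is.null(cache)) return(cache)
    dir <- file.path(tempdir(), "phytoscreen-scorer-fixture")
    spec <- fixture_spec(seed = 19, n_positives = 24, n_decoys = 250,
                         n_food_compounds = 30, n_food_actives = 5)
    fx <- quiet(generate_fixture(spec, dir))
    cache <<- list(dir = dir, fx = fx,
                   bio = quiet(open_bioactivity_store(fx$bioactivity_store)),
                   food = quiet(open_food_store(fx$food_store)))
    cache
  }
})

test_that("food scoring ranks planted motif carriers above decoys", {
  h <- local_scorer_fixture()
  pos <- add_fingerprints(quiet(fetch_positives(h$bio, "NR9X1", "agonist")))
  neg <- quiet(sample_negatives(h$bio, pos, seed = 1))
  final <- retrain_full(build_dataset(pos, neg), n_trees = 100L, seed = 2)
  scored <- quiet(score_food_library(final, h$food))

  expect_equal(nrow(scored), 30L)
  expect_true(all(diff(scored$score) <= 0))
  actives <- h$fx$ground_truth$food_actives
  active_scores <- scored$score[scored$compound_id %in% actives]
  decoy_scores <- scored$score[!scored$compound_id %in% actives]
  # carriers clear the decision threshold, decoys never do, and the two
  # groups are cleanly separated with the carriers on top
  expect_true(all(active_scores > 0.5))
  expect_true(all(decoy_scores < 0.5))
  expect_gt(min(active_scores), max(decoy_scores))
  expect_setequal(scored$compound_id[seq_along(actives)], actives)

  empty_dir <- withr::local_tempdir()
  write_food_store(empty_dir,
                   food_compounds = tibble::tibble(
                     compound_id = character(0), smiles = character(0),
                     name = character(0), cas_id = character(0)),
                   food_contents = tibble::tibble(
                     compound_id = character(0), food_name = character(0),
                     amount_min = numeric(0), amount_max = numeric(0)))
  expect_error(score_food_library(final, quiet(open_food_store(empty_dir))),
               "empty")
})

test_that("equal scores fall back to id order (stable tie-break)", {
  records <- tibble::tibble(
    compound_id = c("F9", "F1", "F5"),
    name = c("c", "a", "b"), cas_id = NA_character_,
    smiles = c("CCO", "CCN", "CCS"), score = c(0.8, 0.9, 0.8)
  )
  bio <- quiet(open_bioactivity_store(write_bio_store(withr::local_tempdir())))
  food <- quiet(open_food_store(write_food_store(withr::local_tempdir())))
  out <- filter_and_annotate(records, bio, food, "GENE1",
                             score_threshold = 0.5)
  expect_equal(out$compound_id, c("F1", "F5", "F9"))
})

test_that("output filtering is strict and novelty tracks store evidence", {
  bio <- quiet(open_bioactivity_store(write_bio_store(withr::local_tempdir())))
  food <- quiet(open_food_store(write_food_store(withr::local_tempdir())))
  records <- tibble::tibble(
    compound_id = c("F1", "F2", "F3"),
    name = c("one", "two", "three"), cas_id = NA_character_,
    smiles = c("CCO", "c1ccccc1O", "CC(C)O"), # F1 matches known ligand CCO
    score = c(0.92, 0.50, 0.61)
  )
  out <- filter_and_annotate(records, bio, food, "GENE1",
                             score_threshold = 0.5)
  # score 0.50 exactly is excluded (strict >)
  expect_setequal(out$compound_id, c("F1", "F3"))
  expect_false(out$novel[out$compound_id == "F1"])
  expect_true(out$novel[out$compound_id == "F3"])
  # foods come from the content table; F3 has none recorded
  expect_equal(nrow(out$foods[[which(out$compound_id == "F1")]]), 2L)
  expect_equal(nrow(out$foods[[which(out$compound_id == "F3")]]), 0L)

  # table mode: require at least one associated food
  tab <- filter_and_annotate(records, bio, food, "GENE1",
                             score_threshold = 0.5, require_foods = TRUE)
  expect_equal(tab$compound_id, "F1")

  # raising the threshold never adds records
  for (thr in c(0.3, 0.5, 0.6, 0.9)) {
    lo <- filter_and_annotate(records, bio, food, "GENE1",
                              score_threshold = thr)
    hi <- filter_and_annotate(records, bio, food, "GENE1",
                              score_threshold = min(thr + 0.2, 1))
    expect_length(setdiff(hi$compound_id, lo$compound_id), 0L)
  }
})

test_that("prediction TSV renders scores, novelty and amount ranges", {
  bio <- quiet(open_bioactivity_store(write_bio_store(withr::local_tempdir())))
  food <- quiet(open_food_store(write_food_store(withr::local_tempdir())))
  records <- tibble::tibble(
    compound_id = c("F1", "F2"),
    name = c("one", "two"), cas_id = c("50-00-0", NA),
    smiles = c("CCO", "c1ccccc1O"), score = c(0.925, 0.675)
  )
  out <- filter_and_annotate(records, bio, food, "GENE1", 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(out, path)
  lines <- readLines(path)
  expect_equal(lines[1],
               "compound_id\tname\tcas_id\tscore\tnovel\tfoods")
  expect_match(lines[2], "^F1\tone\t50-00-0\t0\\.9250\tfalse\t")
  # F1 in oat has both bounds (1.5-3.5), in rye only a max
  expect_match(lines[2], "oat 1\\.5-3\\.5 mg/100g; rye 7\\.2 mg/100g")
  expect_match(lines[3], "^F2\ttwo\t\t0\\.6750\ttrue\tkale 10 mg/100g$")
})

test_that("the pipeline is deterministic and its manifest counts add up", {
  h <- local_scorer_fixture()
  out1 <- file.path(withr::local_tempdir(), "runA")
  out2 <- file.path(withr::local_tempdir(), "runB")
  cfg1 <- pipeline_config("NR9X1", "agonist", h$fx$bioactivity_store,
                          h$fx$food_store, seed = 5, out_dir = out1)
  cfg2 <- pipeline_config("NR9X1", "agonist", h$fx$bioactivity_store,
                          h$fx$food_store, seed = 5, out_dir = out2)
  r1 <- quiet(run_pipeline(cfg1))
  r2 <- quiet(run_pipeline(cfg2))

  expect_identical(readLines(file.path(out1, "predictions.tsv")),
                   readLines(file.path(out2, "predictions.tsv")))
  expect_identical(tibble::as_tibble(r1$metrics),
                   tibble::as_tibble(r2$metrics))

  cnt <- r1$manifest$counts
  expect_equal(cnt$n_negatives_requested, 10L * cnt$n_positive)
  expect_lte(cnt$n_negative, cnt$n_negatives_requested)
  expect_equal(cnt$n_train + cnt$n_test, cnt$n_positive + cnt$n_negative)
  expect_equal(cnt$n_positive,
               length(h$fx$ground_truth$positives_pass_filter))

  # every reported food pair exists in the food store's content table
  contents <- h$food$contents
  for (k in seq_len(nrow(r1$predictions))) {
    fds <- r1$predictions$foods[[k]]
    if (nrow(fds) == 0L) next
    for (f in fds$food_name) {
      expect_true(any(contents$compound_id == r1$predictions$compound_id[k] &
                        contents$food_name == f))
    }
  }

  # a gene with no ligands aborts with the gene named
  bad <- pipeline_config("NOSUCH", "agonist", h$fx$bioactivity_store,
                         h$fx$food_store, seed = 5)
  expect_error(quiet(run_pipeline(bad)), "NOSUCH")
})

test_that("glance on a run summarises counts and held-out metrics", {
  h <- local_scorer_fixture()
  cfg <- pipeline_config("NR9X1", "agonist", h$fx$bioactivity_store,
                         h$fx$food_store, seed = 5)
  run <- quiet(run_pipeline(cfg))
  gl <- generics::glance(run)
  expect_equal(gl$n_food_scored, 30L)
  expect_equal(gl$n_train + gl$n_test, gl$n_positive + gl$n_negative)
  expect_true(gl$f1 >= 0 && gl$f1 <= 1)
  rep <- run$predictions
  expect_s3_class(autoplot(run), "ggplot")
  if (nrow(rep) > 0) expect_s3_class(autoplot(rep), "ggplot")
})
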