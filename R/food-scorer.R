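#' Score every food compound with the final model
#'
#' Fingerprints each food compound and scores it with the full-data model.
#' Compounds whose SMILES fail to parse are skipped (a note reports how
#' many). Records are sorted by descending score, ties broken by
#' `compound_id`, so output order is fully deterministic.
#'
#' @param model The final (full-data) `bioactivity_model`.
#' @param food_store A `food_store`.
#' @return Tibble with columns `compound_id`, `name`, `cas_id`, `smiles`,
#'   `score`.
#' @export
score_food_library <- function(model, food_store) {
  stopifnot(inherits(food_store, "food_store"))
  foods <- fetch_food_compounds(food_store)
  if (nrow(foods) == 0L) {
    stop("food store is empty", call. = FALSE)
  }
  foods <- add_fingerprints(foods)
  if (nrow(foods) == 0L) {
    stop("no food compound has a parseable SMILES", call. = FALSE)
  }
  foods$score <- predict_proba(model, foods$fp)
  foods |>
    dplyr::arrange(dplyr::desc(.data$score), .data$compound_id) |>
    dplyr::select("compound_id", "name", "cas_id", "smiles", "score")
}

#' Filter scored food compounds and annotate novelty and source foods
#'
#' Keeps records scoring strictly above `score_threshold`, flags each as
#' novel when the bioactivity store holds no activity evidence for the
#' target under the same (whitespace-normalized) SMILES, and attaches the
#' compound's source foods with amount ranges. Two reporting conventions are
#' supported: the default (threshold 0.5, foods optional) and a table mode
#' (`score_threshold = 0.6, require_foods = TRUE`) restricted to compounds
#' with at least one associated food.
#'
#' @param records Scored records from [score_food_library()].
#' @param bioactivity_store A `bioactivity_store` (novelty lookup).
#' @param food_store A `food_store` (source foods and amounts).
#' @param gene HGNC gene symbol of the target.
#' @param score_threshold Keep records with `score > score_threshold`
#'   (default 0.5; strictly greater).
#' @param require_foods Keep only compounds with at least one recorded
#'   source food (default FALSE).
#' @return A `prediction_report`: tibble with columns `compound_id`,
#'   `name`, `cas_id`, `score`, `novel`, and a `foods` list-column of
#'   content tibbles (`food_name`, `amount_min`, `amount_max`).
#' @export
filter_and_annotate <- function(records, bioactivity_store, food_store,
                                gene, score_threshold = 0.5,
                                require_foods = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("compound_id", "smiles", "score") %in% names(records)),
            inherits(bioactivity_store, "bioactivity_store"),
            inherits(food_store, "food_store"),
            score_threshold >= 0, score_threshold <= 1)
  kept <- dplyr::filter(records, .data$score > score_threshold)
  kept$novel <- !has_target_evidence(bioactivity_store, kept$smiles, gene)
  kept$foods <- lapply(kept$compound_id, function(id) {
    fetch_contents(food_store, id)[c("food_name", "amount_min", "amount_max")]
  })
  if (require_foods) {
    kept <- kept[vapply(kept$foods, nrow, integer(1)) > 0L, , drop = FALSE]
  }
  out <- kept |>
    dplyr::arrange(dplyr::desc(.data$score), .data$compound_id) |>
    dplyr::select("compound_id", "name", "cas_id", "score", "novel", "foods")
  class(out) <- c("prediction_report", class(out))
  out
}

# "food[ 1.2-3.4 mg/100g]" entries joined by "; "
format_foods <- function(foods) {
  vapply(foods, function(tab) {
    if (nrow(tab) == 0L) return("")
    entry <- vapply(seq_len(nrow(tab)), function(i) {
      lo <- tab$amount_min[i]
      hi <- tab$amount_max[i]
      amount <- if (!is.na(lo) && !is.na(hi)) {
        if (lo == hi) format_amount(lo) else
          paste0(format_amount(lo), "-", format_amount(hi))
      } else if (!is.na(lo)) format_amount(lo)
      else if (!is.na(hi)) format_amount(hi)
      else NA_character_
      if (is.na(amount)) tab$food_name[i]
      else paste0(tab$food_name[i], " ", amount, " mg/100g")
    }, character(1))
    paste(entry, collapse = "; ")
  }, character(1))
}

format_amount <- function(x) {
  sub("\\.?0+$", "", sprintf("%.1f", x))
}

#' Write a prediction report as a TSV file
#'
#' Columns: `compound_id`, `name`, `cas_id`, `score` (4 decimals), `novel`
#' (`true`/`false`), `foods` (semicolon-joined
#' `"food_name amount_min-amount_max mg/100g"`, amounts when available).
#' Output is byte-deterministic for a fixed pipeline seed.
#'
#' @param report A `prediction_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(report, path) {
  flat <- tibble::tibble(
    compound_id = report$compound_id,
    name = report$name,
    cas_id = ifelse(is.na(report$cas_id), "", report$cas_id),
    score = sprintf("%.4f", report$score),
    novel = ifelse(report$novel, "true", "false"),
    foods = format_foods(report$foods)
  )
  readr::write_tsv(flat, path, quote = "none", escape = "none",
                   progress = FALSE)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' Collects and validates every tunable of the screening pipeline. Defaults
#' follow the method's standard settings: potency cutoff 20000 nM, 10
#' negatives per positive, Tanimoto similarity cutoff 0.6 for negative
#' filtering, 30% held-out test split, 100 trees, output score threshold
#' 0.5.
#'
#' @param gene HGNC gene symbol of the protein target.
#' @param effect `"agonist"` or `"antagonist"`.
#' @param bioactivity_store,food_store Store paths (or already-open
#'   handles).
#' @param threshold_nm Potency cutoff in nM (strict `<`).
#' @param neg_ratio Negatives per positive.
#' @param tanimoto_cutoff Similarity cutoff for negative exclusion.
#' @param test_fraction Held-out fraction for evaluation.
#' @param n_trees Ensemble size.
#' @param score_threshold Output score cutoff (strict `>`).
#' @param require_foods Restrict output to compounds with recorded foods.
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param out_dir Optional directory for the predictions TSV and run
#'   manifest JSON.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(gene, effect = c("agonist", "antagonist"),
                            bioactivity_store, food_store,
                            threshold_nm = 20000, neg_ratio = 10L,
                            tanimoto_cutoff = 0.6, test_fraction = 0.3,
                            n_trees = 100L, score_threshold = 0.5,
                            require_foods = FALSE, seed = 1L,
                            out_dir = NULL) {
  effect <- match.arg(effect)
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene),
            threshold_nm > 0, neg_ratio >= 1L,
            tanimoto_cutoff >= 0, tanimoto_cutoff <= 1,
            test_fraction >= 0, test_fraction < 1,
            n_trees >= 1L, score_threshold >= 0, score_threshold <= 1)
  structure(
    list(gene = gene, effect = effect,
         bioactivity_store = bioactivity_store, food_store = food_store,
         threshold_nm = threshold_nm, neg_ratio = as.integer(neg_ratio),
         tanimoto_cutoff = tanimoto_cutoff, test_fraction = test_fraction,
         n_trees = as.integer(n_trees), score_threshold = score_threshold,
         require_foods = require_foods, seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full target-to-food-compound screening pipeline
#'
#' Executes, in order: positive retrieval (potency-filtered by assay type),
#' Tanimoto-filtered negative sampling, fingerprinting, a 30% held-out
#' split, random-forest training, held-out evaluation, a full-data refit,
#' food-library scoring, and output filtering/annotation. Fully
#' deterministic for a fixed seed: stage seeds are derived from the master
#' seed so sampling, splitting and training randomness are independent.
#'
#' When `config$out_dir` is set, writes `predictions.tsv`
#' (see [write_predictions()]) and `manifest.json` (configuration echo,
#' per-stage counts, held-out metrics, elapsed time).
#'
#' @param config A [pipeline_config()].
#' @return A `screen_run` list: `metrics` (held-out `model_metrics`),
#'   `predictions` (filtered `prediction_report`), `scores` (all scored
#'   food compounds), `model` (the final full-data model), and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  bio <- if (inherits(config$bioactivity_store, "bioactivity_store")) {
    config$bioactivity_store
  } else open_bioactivity_store(config$bioactivity_store)
  food <- if (inherits(config$food_store, "food_store")) {
    config$food_store
  } else open_food_store(config$food_store)

  positives <- fetch_positives(bio, config$gene, config$effect,
                               config$threshold_nm) |>
    suppressWarnings()
  if (nrow(positives) == 0L) {
    stop("pipeline error at stage fetch_positives: no qualifying compounds ",
         "for gene '", config$gene, "'", call. = FALSE)
  }
  positives <- add_fingerprints(positives)
  if (nrow(positives) == 0L) {
    stop("pipeline error at stage fingerprint: no positive SMILES parsed",
         call. = FALSE)
  }

  negatives <- sample_negatives(bio, positives, ratio = config$neg_ratio,
                                tanimoto_cutoff = config$tanimoto_cutoff,
                                seed = config$seed)
  data <- build_dataset(positives, negatives)
  split <- split_dataset(data, test_fraction = config$test_fraction,
                         seed = config$seed + 1L)
  model <- train_forest(split$train, n_trees = config$n_trees,
                        seed = config$seed + 2L)
  metrics <- evaluate_model(model, split$test)
  final <- retrain_full(data, n_trees = config$n_trees,
                        seed = config$seed + 3L)
  scores <- score_food_library(final, food)
  report <- filter_and_annotate(scores, bio, food, config$gene,
                                score_threshold = config$score_threshold,
                                require_foods = config$require_foods)

  manifest <- list(
    tool = "phytoscreen",
    version = as.character(utils::packageVersion("phytoscreen")),
    config = config[c("gene", "effect", "threshold_nm", "neg_ratio",
                      "tanimoto_cutoff", "test_fraction", "n_trees",
                      "score_threshold", "require_foods", "seed")],
    counts = list(
      n_positive = nrow(positives),
      n_negatives_requested = config$neg_ratio * nrow(positives),
      n_negative = nrow(negatives),
      n_train = nrow(split$train),
      n_test = nrow(split$test),
      n_food_scored = nrow(scores),
      n_reported = nrow(report)
    ),
    metrics = as.list(tibble::as_tibble(metrics)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_predictions(report, file.path(config$out_dir, "predictions.tsv"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(
    list(metrics = metrics, predictions = report, scores = scores,
         model = final, manifest = manifest),
    class = "screen_run"
  )
}

#' @export
print.screen_run <- function(x, ...) {
  m <- x$metrics
  cat("<screen_run> target ", x$manifest$config$gene, " (",
      x$manifest$config$effect, ")\n", sep = "")
  cat(sprintf("  training: %d positives, %d negatives; held-out F1 = %.3f (precision %.3f, recall %.3f)\n",
              x$manifest$counts$n_positive, x$manifest$counts$n_negative,
              m$f1, m$precision, m$recall))
  cat(sprintf("  food compounds scored: %d; reported above %.2f: %d\n",
              x$manifest$counts$n_food_scored,
              x$manifest$config$score_threshold,
              x$manifest$counts$n_reported))
  invisible(x)
}
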