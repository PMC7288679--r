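#' Specification for a synthetic screening fixture
#'
#' Describes a pair of synthetic stores (drug bioactivity + food
#' composition) with a planted structure-activity signal: active compounds
#' are built from a small library of "active" scaffold motifs plus random
#' decorations, decoys come from unrelated scaffold families, and potencies
#' are drawn log-uniformly over a range that deliberately straddles the
#' 20000 nM cutoff so the potency filter is exercised with known ground
#' truth. Generated this way, activity is perfectly separable from
#' structure, so end-to-end recovery failures implicate the pipeline, not
#' the data.
#'
#' @param seed Integer seed; the whole fixture is a pure function of the
#'   spec and this seed.
#' @param n_positive_scaffolds Number of active motifs used (max 3).
#' @param n_positives Active compounds in the bioactivity store (default
#'   60).
#' @param n_decoys Inactive compounds in the bioactivity store (default
#'   2000).
#' @param n_food_compounds Food-store compounds (default 300).
#' @param n_food_actives Motif-carrying food compounds, the planted ground
#'   truth (default 10).
#' @param motif_library SMILES of the active scaffolds.
#' @param activity_range_nm Log-uniform sampling range for active-compound
#'   EC50/IC50 values; must straddle 20000 nM.
#' @param target_gene Synthetic HGNC-style symbol for the planted target.
#' @param effect Planted effect type (`"agonist"` uses EC50 records).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_positive_scaffolds = 3L,
                         n_positives = 60L, n_decoys = 2000L,
                         n_food_compounds = 300L, n_food_actives = 10L,
                         motif_library = active_motifs(),
                         activity_range_nm = c(100, 1e6),
                         target_gene = "NR9X1",
                         effect = c("agonist", "antagonist")) {
  effect <- match.arg(effect)
  stopifnot(n_positive_scaffolds >= 1L,
            n_positive_scaffolds <= length(motif_library),
            n_positives >= n_positive_scaffolds,
            n_decoys >= 1L,
            n_food_actives <= n_food_compounds,
            length(activity_range_nm) == 2L)
  if (!(activity_range_nm[1] < 20000 && 20000 < activity_range_nm[2])) {
    stop("activity_range_nm must straddle the 20000 nM potency cutoff",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed),
         n_positive_scaffolds = as.integer(n_positive_scaffolds),
         n_positives = as.integer(n_positives),
         n_decoys = as.integer(n_decoys),
         n_food_compounds = as.integer(n_food_compounds),
         n_food_actives = as.integer(n_food_actives),
         motif_library = motif_library,
         activity_range_nm = activity_range_nm,
         target_gene = target_gene, effect = effect),
    class = "fixture_spec"
  )
}

#' Built-in scaffold grammars of the fixture generator
#'
#' `active_motifs()` returns the "active" scaffolds planted into positive
#' compounds; `decoy_scaffolds()` the unrelated families used for decoys;
#' `decoration_units()` the small substituents appended to either. All are
#' syntactically append-safe SMILES fragments, so concatenation always
#' yields a parseable string.
#'
#' @return Character vector of SMILES fragments.
#' @export
active_motifs <- function() {
  c("c1cc(O)ccc1C(=O)NCCSC",
    "C1=CC(=O)OC2=CC(O)=CC=C12",
    "CC(C)Cc1ccc(cc1)C(C)C(=O)O")
}

#' @rdname active_motifs
#' @export
decoy_scaffolds <- function() {
  c("OCC(O)C(O)C(O)C(O)CO",
    "CCCCCCCCC(=O)O",
    "C1CCNCC1CCCl",
    "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",
    "C1CC1CSSCC2CC2",
    "NC(CCSC)C(=O)NC(CO)C(=O)O")
}

#' @rdname active_motifs
#' @export
decoration_units <- function() {
  c("C", "CC", "CO", "CN", "CCl", "CBr", "C(C)C", "OC", "N", "CF")
}

decorate <- function(scaffold, n_units) {
  if (n_units == 0L) return(scaffold)
  paste0(scaffold,
         paste(sample(decoration_units(), n_units, replace = TRUE),
               collapse = ""))
}

#' Generate a synthetic bioactivity + food fixture
#'
#' Writes a bioactivity store (`bioactivity/`), a food store (`food/`) and
#' a ground-truth manifest (`ground_truth.json`) under `out_dir`. See
#' [fixture_spec()] for what is planted. Structural invariants are enforced
#' during generation: every motif carrier has Tanimoto similarity > 0.6 to
#' at least one other carrier, and every decoy is resampled until its
#' similarity to all carriers is at most 0.6. Two of the planted food
#' actives share an exact SMILES with a bioactivity-store active, so the
#' novelty flag is exercised in both directions.
#'
#' Determinism: the same spec and seed yield byte-identical store files.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @param format `"tsv"` (directory stores) or `"sqlite"`.
#' @return Invisibly, a list with the two store paths and the ground-truth
#'   manifest.
#' @export
generate_fixture <- function(spec, out_dir, format = c("tsv", "sqlite")) {
  stopifnot(inherits(spec, "fixture_spec"))
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  built <- withr::with_seed(spec$seed, build_fixture_tables(spec))

  if (format == "tsv") {
    bio_path <- file.path(out_dir, "bioactivity")
    food_path <- file.path(out_dir, "food")
    dir.create(bio_path, showWarnings = FALSE)
    dir.create(food_path, showWarnings = FALSE)
    write_fixture_tsv(built$compounds, file.path(bio_path, "compounds.tsv"))
    write_fixture_tsv(built$activities, file.path(bio_path, "activities.tsv"))
    write_fixture_tsv(built$food_compounds,
                      file.path(food_path, "food_compounds.tsv"))
    write_fixture_tsv(built$food_contents,
                      file.path(food_path, "food_contents.tsv"))
  } else {
    if (!requireNamespace("DBI", quietly = TRUE) ||
        !requireNamespace("RSQLite", quietly = TRUE)) {
      stop("sqlite fixtures require the DBI and RSQLite packages",
           call. = FALSE)
    }
    bio_path <- file.path(out_dir, "bioactivity.sqlite")
    food_path <- file.path(out_dir, "food.sqlite")
    for (p in c(bio_path, food_path)) if (file.exists(p)) unlink(p)
    con <- DBI::dbConnect(RSQLite::SQLite(), bio_path)
    DBI::dbWriteTable(con, "compounds", flatten_synonyms(built$compounds))
    DBI::dbWriteTable(con, "activities", built$activities)
    DBI::dbDisconnect(con)
    con <- DBI::dbConnect(RSQLite::SQLite(), food_path)
    DBI::dbWriteTable(con, "food_compounds", built$food_compounds)
    DBI::dbWriteTable(con, "food_contents", built$food_contents)
    DBI::dbDisconnect(con)
  }

  manifest <- built$ground_truth
  manifest$format <- format
  jsonlite::write_json(manifest, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(bioactivity_store = bio_path, food_store = food_path,
                 ground_truth = manifest))
}

write_fixture_tsv <- function(tab, path) {
  readr::write_tsv(tab, path, na = "", quote = "none", escape = "none",
                   progress = FALSE)
}

flatten_synonyms <- function(compounds) {
  compounds
}

build_fixture_tables <- function(spec) {
  motifs <- spec$motif_library[seq_len(spec$n_positive_scaffolds)]
  other_genes <- c("ABCA1", "BRCA2", "EGFR", "INSR", "TP53")

  # --- bioactivity actives: motif + light decoration ------------------
  carrier_motif <- rep_len(seq_along(motifs), spec$n_positives)
  carriers <- vapply(carrier_motif, function(m) {
    decorate(motifs[m], sample(0:2, 1, prob = c(0.3, 0.4, 0.3)))
  }, character(1))

  # every carrier must have a close (> 0.6) neighbour among the carriers;
  # resample decorations for isolated ones
  for (round in 1:25) {
    sim <- tanimoto_matrix(fp_matrix(fingerprint_smiles(carriers)),
                           fp_matrix(fingerprint_smiles(carriers)))
    diag(sim) <- 0
    lonely <- which(apply(sim, 1, max) <= 0.6)
    if (length(lonely) == 0L) break
    for (i in lonely) {
      carriers[i] <- decorate(motifs[carrier_motif[i]], sample(0:1, 1))
    }
  }
  if (length(lonely) > 0L) {
    stop("fixture generation failed: isolated motif carriers remain",
         call. = FALSE)
  }
  carrier_fp_mat <- fp_matrix(fingerprint_smiles(carriers))

  # --- decoys: unrelated scaffold families, Tanimoto <= 0.6 to carriers
  sample_decoy <- function(n) {
    vapply(seq_len(n), function(i) {
      decorate(sample(decoy_scaffolds(), 1), sample(0:2, 1))
    }, character(1))
  }
  decoys <- sample_decoy(spec$n_decoys)
  for (round in 1:25) {
    dmax <- max_carrier_similarity(decoys, carrier_fp_mat)
    bad <- which(dmax > 0.6)
    if (length(bad) == 0L) break
    decoys[bad] <- sample_decoy(length(bad))
  }
  if (length(bad) > 0L) {
    stop("fixture generation failed: decoys too similar to carriers remain",
         call. = FALSE)
  }

  n_bio <- spec$n_positives + spec$n_decoys
  bio_ids <- sprintf("CPD%06d", seq_len(n_bio))
  active_ids <- bio_ids[seq_len(spec$n_positives)]
  decoy_ids <- bio_ids[spec$n_positives + seq_len(spec$n_decoys)]
  synonyms <- vapply(bio_ids, function(id) {
    k <- sample(0:2, 1)
    if (k == 0L) "" else paste(paste0("syn-", id, "-", seq_len(k)),
                               collapse = "|")
  }, character(1), USE.NAMES = FALSE)
  compounds <- tibble::tibble(
    compound_id = bio_ids,
    smiles = c(carriers, decoys),
    name = paste0("compound-", tolower(bio_ids)),
    synonyms = synonyms
  )

  assay <- if (spec$effect == "agonist") "EC50" else "IC50"
  lo <- log(spec$activity_range_nm[1]); hi <- log(spec$activity_range_nm[2])
  active_vals <- round(exp(stats::runif(spec$n_positives, lo, hi)), 2)
  decoy_vals <- round(exp(stats::runif(spec$n_decoys, log(10), log(1e6))), 2)
  activities <- tibble::tibble(
    compound_id = c(active_ids, decoy_ids),
    gene_symbol = c(rep(spec$target_gene, spec$n_positives),
                    sample(other_genes, spec$n_decoys, replace = TRUE)),
    assay_type = c(rep(assay, spec$n_positives),
                   sample(c("IC50", "EC50"), spec$n_decoys, replace = TRUE)),
    value_nm = c(active_vals, decoy_vals)
  )
  pass_filter <- active_ids[active_vals < 20000]

  # --- food store -----------------------------------------------------
  n_known <- min(2L, spec$n_food_actives)
  food_active_smiles <- c(
    carriers[seq_len(n_known)], # exact overlap with known ligands
    vapply(seq_len(spec$n_food_actives - n_known), function(i) {
      decorate(motifs[(i - 1L) %% length(motifs) + 1L], sample(0:2, 1))
    }, character(1))
  )
  n_food_decoys <- spec$n_food_compounds - spec$n_food_actives
  food_decoys <- sample_decoy(n_food_decoys)
  for (round in 1:25) {
    dmax <- max_carrier_similarity(food_decoys, carrier_fp_mat)
    bad <- which(dmax > 0.6)
    if (length(bad) == 0L) break
    food_decoys[bad] <- sample_decoy(length(bad))
  }

  food_ids <- sprintf("FDB%06d", seq_len(spec$n_food_compounds))
  food_active_ids <- food_ids[seq_len(spec$n_food_actives)]
  cas <- vapply(food_ids, function(id) {
    if (stats::runif(1) < 0.7) {
      sprintf("%05d-%02d-%d", sample(1e5, 1) - 1L, sample(99, 1),
              sample(9, 1))
    } else ""
  }, character(1), USE.NAMES = FALSE)
  food_compounds <- tibble::tibble(
    compound_id = food_ids,
    smiles = c(food_active_smiles, food_decoys),
    name = paste0("phytochemical-", tolower(food_ids)),
    cas_id = cas
  )

  foods <- c("barley", "black bean", "chickpea", "fenugreek", "flaxseed",
             "kale", "leek", "lentil", "lima bean", "millet", "oat",
             "parsnip", "pea", "quinoa", "rye", "sesame", "sorghum",
             "spinach", "turnip", "walnut", "wheat")
  food_contents <- dplyr::bind_rows(lapply(food_ids, function(id) {
    k <- sample(1:3, 1)
    chosen <- sample(foods, k)
    amt <- lapply(seq_len(k), function(j) {
      u <- stats::runif(1)
      mn <- round(stats::runif(1, 0.5, 400), 1)
      mx <- round(mn * stats::runif(1, 1, 4), 1)
      if (u < 0.7) c(mn, mx)
      else if (u < 0.8) c(mn, NA)
      else if (u < 0.9) c(NA, mx)
      else c(NA, NA)
    })
    tibble::tibble(
      compound_id = id,
      food_name = chosen,
      amount_min = vapply(amt, `[`, numeric(1), 1),
      amount_max = vapply(amt, `[`, numeric(1), 2)
    )
  }))

  ground_truth <- list(
    seed = spec$seed,
    target_gene = spec$target_gene,
    effect = spec$effect,
    motif_library = motifs,
    bioactivity_actives = active_ids,
    positives_pass_filter = pass_filter,
    food_actives = food_active_ids,
    food_actives_with_known_evidence =
      food_active_ids[food_active_smiles %in% carriers],
    n_decoys = spec$n_decoys,
    n_food_compounds = spec$n_food_compounds
  )

  list(compounds = compounds, activities = activities,
       food_compounds = food_compounds, food_contents = food_contents,
       ground_truth = ground_truth)
}

max_carrier_similarity <- function(smiles, carrier_fp_mat) {
  uniq <- unique(smiles)
  sim <- tanimoto_matrix(fp_matrix(fingerprint_smiles(uniq)), carrier_fp_mat)
  mx <- apply(sim, 1, max)
  names(mx) <- uniq
  unname(mx[smiles])
}

#' Check pipeline recovery of the planted fixture signal
#'
#' Compares a pipeline run against the fixture's ground-truth manifest:
#' held-out F1, the fraction of planted food actives scored above the
#' threshold, and the count of false-positive food compounds above it.
#'
#' @param out_dir Directory written by [generate_fixture()].
#' @param run A `screen_run` from [run_pipeline()] on that fixture.
#' @param score_threshold Recovery score cutoff (default 0.5, strict `>`).
#' @return One-row tibble: `f1`, `precision`, `recall`,
#'   `n_food_actives`, `n_recovered`, `recovered_fraction`,
#'   `n_false_positive_foods`.
#' @export
validate_recovery <- function(out_dir, run, score_threshold = 0.5) {
  manifest_path <- file.path(out_dir, "ground_truth.json")
  if (!file.exists(manifest_path)) {
    stop("missing ground-truth manifest: ", manifest_path, call. = FALSE)
  }
  truth <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  stopifnot(inherits(run, "screen_run"))
  scores <- run$scores
  above <- scores$compound_id[scores$score > score_threshold]
  actives <- truth$food_actives
  n_rec <- sum(actives %in% above)
  tibble::tibble(
    f1 = run$metrics$f1,
    precision = run$metrics$precision,
    recall = run$metrics$recall,
    n_food_actives = length(actives),
    n_recovered = n_rec,
    recovered_fraction = n_rec / length(actives),
    n_false_positive_foods = sum(!above %in% actives)
  )
}

#' Random small molecules from the fixture grammar
#'
#' Generates random parseable SMILES of at most `max_atoms` heavy atoms —
#' chains, branches, small rings, aromatic rings, occasional charged
#' bracket atoms — with the true heavy-atom count attached. Used for
#' property testing of the parser and fragment enumerator against
#' brute-force oracles.
#'
#' @param n Number of molecules.
#' @param max_atoms Maximum heavy atoms per molecule (default 8).
#' @param seed Integer seed.
#' @return Tibble with columns `smiles` and `n_atoms`.
#' @export
random_small_smiles <- function(n, max_atoms = 8L, seed = 1L) {
  stopifnot(n >= 1L, max_atoms >= 1L)
  withr::with_seed(seed, {
    out <- lapply(seq_len(n), function(i) {
      k <- sample(seq_len(max_atoms), 1)
      one_random_smiles(k)
    })
  })
  tibble::tibble(
    smiles = vapply(out, `[[`, character(1), "smiles"),
    n_atoms = vapply(out, `[[`, integer(1), "n_atoms")
  )
}

one_random_smiles <- function(k) {
  atoms <- c("C", "N", "O", "S", "P")
  bonds <- c("", "", "", "-", "=", "#")
  bracket <- c("[N+]", "[O-]", "[NH2+]")

  pick_atom <- function() {
    if (stats::runif(1) < 0.08) sample(bracket, 1) else sample(atoms, 1)
  }

  if (k >= 6L && stats::runif(1) < 0.25) {
    # aromatic benzene core plus an aliphatic tail
    tail_n <- k - 6L
    tail <- if (tail_n > 0L) {
      paste(vapply(seq_len(tail_n), function(i) pick_atom(), character(1)),
            collapse = "")
    } else ""
    return(list(smiles = paste0("c1ccccc1", tail), n_atoms = k))
  }

  if (k >= 3L && stats::runif(1) < 0.3) {
    # aliphatic ring of size r, remaining atoms appended as a chain
    rmax <- min(6L, k)
    r <- if (rmax == 3L) 3L else sample(3:rmax, 1)
    ring_mid <- if (r > 2L) {
      paste(vapply(seq_len(r - 2L), function(i) sample(atoms, 1),
                   character(1)), collapse = "")
    } else ""
    ring <- paste0("C1", ring_mid, "C1")
    tail_n <- k - r
    tail <- if (tail_n > 0L) {
      paste(vapply(seq_len(tail_n), function(i) {
        paste0(sample(bonds, 1), pick_atom())
      }, character(1)), collapse = "")
    } else ""
    return(list(smiles = paste0(ring, tail), n_atoms = k))
  }

  # chain with optional single branch
  toks <- pick_atom()
  remaining <- k - 1L
  branch_at <- if (k >= 4L && stats::runif(1) < 0.3) sample(remaining - 1L, 1)
               else -1L
  for (i in seq_len(remaining)) {
    unit <- paste0(sample(bonds, 1), pick_atom())
    toks <- if (i == branch_at) paste0(toks, "(", unit, ")")
            else paste0(toks, unit)
  }
  list(smiles = toks, n_atoms = k)
}
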