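#' Open a local drug-bioactivity store
#'
#' A bioactivity store holds drug-like compounds (with SMILES) and their
#' activity records against protein targets (HGNC gene symbol, assay type
#' IC50/EC50, potency in nM). Two equivalent on-disk layouts are supported:
#'
#' * a directory containing `compounds.tsv` and `activities.tsv` (UTF-8,
#'   tab-separated, mandatory header, no quoting, empty cell = absent;
#'   `synonyms` is a `|`-joined list), or
#' * a SQLite file with tables `compounds(compound_id, smiles, name,
#'   synonyms)` and `activities(compound_id, gene_symbol, assay_type,
#'   value_nm)`.
#'
#' Both layouts are loaded into memory and validated: missing tables or
#' columns raise a schema error naming them; duplicated `compound_id`s,
#' non-positive potencies, or assay types outside \{IC50, EC50\} raise a load
#' error.
#'
#' @param path Directory of TSVs or SQLite file.
#' @return A `bioactivity_store` handle.
#' @export
open_bioactivity_store <- function(path) {
  tabs <- read_store_tables(
    path,
    list(
      compounds = c("compound_id", "smiles", "name", "synonyms"),
      activities = c("compound_id", "gene_symbol", "assay_type", "value_nm")
    )
  )
  compounds <- dplyr::mutate(
    tabs$compounds,
    synonyms = split_synonyms(.data$synonyms),
    smiles = gsub("[[:space:]]+", "", .data$smiles)
  )
  activities <- dplyr::mutate(tabs$activities,
                              value_nm = as.numeric(.data$value_nm))
  check_unique_ids(compounds$compound_id, path)
  if (any(!nzchar(compounds$smiles))) {
    stop("load error in '", path, "': empty smiles", call. = FALSE)
  }
  bad_assay <- setdiff(unique(activities$assay_type), c("IC50", "EC50"))
  if (length(bad_assay) > 0L) {
    stop("load error in '", path, "': assay_type must be IC50 or EC50, got ",
         paste(bad_assay, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(activities$value_nm) | activities$value_nm <= 0)) {
    stop("load error in '", path, "': value_nm must be positive",
         call. = FALSE)
  }
  rlang::inform(sprintf("bioactivity store '%s': %d compounds, %d activity records",
                        path, nrow(compounds), nrow(activities)))
  structure(list(compounds = compounds, activities = activities,
                 path = path),
            class = "bioactivity_store")
}

#' Open a local food-composition store
#'
#' A food store holds food compounds (with SMILES, names, optional CAS
#' registry numbers) and food-content records (food name, amount range in
#' mg per 100 g; either bound may be absent). Layouts mirror
#' [open_bioactivity_store()]: a directory with `food_compounds.tsv` and
#' `food_contents.tsv`, or a SQLite file with tables `food_compounds` and
#' `food_contents` of the same columns.
#'
#' @param path Directory of TSVs or SQLite file.
#' @return A `food_store` handle.
#' @export
open_food_store <- function(path) {
  tabs <- read_store_tables(
    path,
    list(
      food_compounds = c("compound_id", "smiles", "name", "cas_id"),
      food_contents = c("compound_id", "food_name", "amount_min", "amount_max")
    )
  )
  compounds <- dplyr::mutate(
    tabs$food_compounds,
    smiles = gsub("[[:space:]]+", "", .data$smiles),
    cas_id = dplyr::na_if(.data$cas_id, "")
  )
  contents <- dplyr::mutate(tabs$food_contents,
                            amount_min = as.numeric(.data$amount_min),
                            amount_max = as.numeric(.data$amount_max))
  check_unique_ids(compounds$compound_id, path)
  if (any(!nzchar(compounds$smiles))) {
    stop("load error in '", path, "': empty smiles", call. = FALSE)
  }
  both <- !is.na(contents$amount_min) & !is.na(contents$amount_max)
  if (any(contents$amount_min[both] > contents$amount_max[both])) {
    stop("load error in '", path, "': amount_min > amount_max", call. = FALSE)
  }
  rlang::inform(sprintf("food store '%s': %d compounds, %d content records",
                        path, nrow(compounds), nrow(contents)))
  structure(list(compounds = compounds, contents = contents, path = path),
            class = "food_store")
}

read_store_tables <- function(path, schema) {
  if (!file.exists(path)) {
    stop("store path '", path, "' does not exist", call. = FALSE)
  }
  if (dir.exists(path)) {
    tabs <- lapply(names(schema), function(tab) {
      f <- file.path(path, paste0(tab, ".tsv"))
      if (!file.exists(f)) {
        stop("schema error: missing table '", tab, "' (no file ", f, ")",
             call. = FALSE)
      }
      d <- readr::read_tsv(f, col_types = readr::cols(.default = "c"),
                           quote = "", na = character(),
                           progress = FALSE)
      d[d == ""] <- NA
      d
    })
  } else {
    if (!requireNamespace("DBI", quietly = TRUE) ||
        !requireNamespace("RSQLite", quietly = TRUE)) {
      stop("reading SQLite stores requires the DBI and RSQLite packages",
           call. = FALSE)
    }
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con), add = TRUE)
    present <- DBI::dbListTables(con)
    tabs <- lapply(names(schema), function(tab) {
      if (!tab %in% present) {
        stop("schema error: missing table '", tab, "' in ", path,
             call. = FALSE)
      }
      d <- tibble::as_tibble(DBI::dbReadTable(con, tab))
      d[] <- lapply(d, function(col) {
        col <- as.character(col)
        col[!is.na(col) & col == ""] <- NA
        col
      })
      d
    })
  }
  names(tabs) <- names(schema)
  for (tab in names(schema)) {
    missing <- setdiff(schema[[tab]], names(tabs[[tab]]))
    if (length(missing) > 0L) {
      stop("schema error: table '", tab, "' is missing column(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    tabs[[tab]] <- tabs[[tab]][schema[[tab]]]
  }
  tabs
}

split_synonyms <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else strsplit(s, "|", fixed = TRUE)[[1]]
  })
}

check_unique_ids <- function(ids, path) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("load error in '", path, "': duplicate compound_id ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
}

#' @export
print.bioactivity_store <- function(x, ...) {
  cat("<bioactivity_store> ", nrow(x$compounds), " compounds, ",
      nrow(x$activities), " activity records (", x$path, ")\n", sep = "")
  invisible(x)
}

#' @export
print.food_store <- function(x, ...) {
  cat("<food_store> ", nrow(x$compounds), " compounds, ",
      nrow(x$contents), " content records (", x$path, ")\n", sep = "")
  invisible(x)
}

#' Retrieve the positive training compounds for a target
#'
#' Selects distinct compounds with at least one sufficiently potent activity
#' record for the target gene. Potency is read from the assay type matched to
#' the requested effect — IC50 for antagonists, EC50 for agonists (drug
#' databases rarely annotate effect type explicitly, so assay type serves as
#' the heuristic) — and must be strictly below `threshold_nm`.
#'
#' @param store A `bioactivity_store`.
#' @param gene HGNC gene symbol of the protein target.
#' @param effect `"agonist"` or `"antagonist"`.
#' @param threshold_nm Potency cutoff in nanomolar; records with
#'   `value_nm < threshold_nm` qualify (default 20000).
#' @return Tibble of compound records (`compound_id`, `smiles`, `name`,
#'   `synonyms`), ordered by `compound_id`. Zero qualifying compounds yields
#'   an empty tibble with a warning.
#' @export
fetch_positives <- function(store, gene, effect = c("agonist", "antagonist"),
                            threshold_nm = 20000) {
  stopifnot(inherits(store, "bioactivity_store"), threshold_nm > 0)
  effect <- match.arg(effect)
  assay <- if (effect == "agonist") "EC50" else "IC50"
  hits <- store$activities |>
    dplyr::filter(.data$gene_symbol == gene,
                  .data$assay_type == assay,
                  .data$value_nm < threshold_nm) |>
    dplyr::distinct(.data$compound_id)
  out <- store$compounds |>
    dplyr::semi_join(hits, by = "compound_id") |>
    dplyr::arrange(.data$compound_id)
  if (nrow(out) == 0L) {
    warning("no compounds qualify for gene '", gene, "' (effect = ", effect,
            ", assay = ", assay, ", < ", threshold_nm, " nM)", call. = FALSE)
  }
  out
}

#' All compounds in a bioactivity store, minus an exclusion set
#'
#' @param store A `bioactivity_store`.
#' @param exclude Character vector of compound ids to omit.
#' @return Tibble of compound records ordered by `compound_id`.
#' @export
fetch_all_compounds <- function(store, exclude = character(0)) {
  stopifnot(inherits(store, "bioactivity_store"))
  store$compounds |>
    dplyr::filter(!.data$compound_id %in% exclude) |>
    dplyr::arrange(.data$compound_id)
}

#' Food compounds and their food contents
#'
#' `fetch_food_compounds()` returns the compound table of a food store;
#' `fetch_contents()` returns the content records (foods and amount ranges)
#' for one compound, empty when none are recorded.
#'
#' @param store A `food_store`.
#' @return A tibble.
#' @export
fetch_food_compounds <- function(store) {
  stopifnot(inherits(store, "food_store"))
  dplyr::arrange(store$compounds, .data$compound_id)
}

#' @rdname fetch_food_compounds
#' @param compound_id A single food-compound id.
#' @export
fetch_contents <- function(store, compound_id) {
  stopifnot(inherits(store, "food_store"), length(compound_id) == 1L)
  store$contents |>
    dplyr::filter(.data$compound_id == !!compound_id) |>
    dplyr::arrange(.data$food_name)
}

#' Does a structure have recorded activity evidence for a target?
#'
#' Exact whitespace-normalized SMILES string matching against bioactivity
#' store compounds that have any activity record for the gene. This is a
#' string-level check: the same molecule written with a different atom
#' ordering will not match (structure canonicalization is out of scope).
#' The novelty flag reported for scored food compounds is the negation of
#' this value.
#'
#' @param store A `bioactivity_store`.
#' @param smiles Character vector of SMILES strings.
#' @param gene HGNC gene symbol.
#' @return Logical vector, one element per input SMILES.
#' @export
has_target_evidence <- function(store, smiles, gene) {
  stopifnot(inherits(store, "bioactivity_store"))
  ids <- unique(store$activities$compound_id[
    store$activities$gene_symbol == gene])
  known <- store$compounds$smiles[store$compounds$compound_id %in% ids]
  gsub("[[:space:]]+", "", smiles) %in% known
}
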