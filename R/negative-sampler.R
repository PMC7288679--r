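#' Sample a Tanimoto-filtered negative training set
#'
#' Draws random non-target compounds to serve as negative examples, aiming
#' for `ratio` times the positive count (10x by default), while excluding
#' anything structurally similar to the positive set: a candidate is rejected
#' when its Tanimoto similarity to any positive fingerprint exceeds
#' `tanimoto_cutoff` (a candidate at exactly the cutoff is kept).
#'
#' Candidates are drawn without replacement in seeded random order and
#' fingerprinted lazily (rejection sampling), so the similarity constraint
#' and the count target are both honoured without fingerprinting the whole
#' store. Candidates whose SMILES fail to parse are skipped and counted.
#' When the eligible pool is exhausted before the quota, all eligible
#' compounds are returned with a prominent warning.
#'
#' The sampler uses its own seeded random stream, independent of model
#' training, so sampling and training randomness are separately
#' reproducible.
#'
#' @param store A `bioactivity_store`.
#' @param positives Tibble of positive compounds carrying a fingerprint
#'   list-column `fp` (e.g. from [fetch_positives()] +
#'   [add_fingerprints()]).
#' @param ratio Negatives per positive (default 10).
#' @param tanimoto_cutoff Maximum allowed similarity to any positive
#'   (default 0.6).
#' @param seed Integer seed for the candidate draw order.
#' @return Tibble of negative compound records with an `fp` list-column,
#'   in the sampled order.
#' @export
sample_negatives <- function(store, positives, ratio = 10L,
                             tanimoto_cutoff = 0.6, seed = 1L) {
  stopifnot(inherits(store, "bioactivity_store"),
            ratio >= 1L, tanimoto_cutoff >= 0, tanimoto_cutoff <= 1)
  if (!is.data.frame(positives) || nrow(positives) == 0L) {
    stop("`positives` must be a non-empty data frame", call. = FALSE)
  }
  if (!"fp" %in% names(positives)) {
    stop("`positives` must carry an `fp` fingerprint list-column; ",
         "see add_fingerprints()", call. = FALSE)
  }
  candidates <- fetch_all_compounds(store, exclude = positives$compound_id)
  if (nrow(candidates) == 0L) {
    stop("bioactivity store has no candidate compounds outside the positive set",
         call. = FALSE)
  }

  pos_mat <- fp_matrix(positives$fp)
  pos_sz <- rowSums(pos_mat)
  target <- as.integer(ratio) * nrow(positives)

  ord <- withr::with_seed(seed, sample.int(nrow(candidates)))
  keep <- integer(0)
  fps <- vector("list", 0)
  n_unparseable <- 0L
  for (i in ord) {
    if (length(keep) >= target) break
    fp <- fingerprint_smiles(candidates$smiles[i])[[1]]
    if (is.null(fp)) {
      n_unparseable <- n_unparseable + 1L
      next
    }
    v <- as.numeric(fp)
    inter <- drop(pos_mat %*% v)
    union <- pos_sz + sum(v) - inter
    sims <- ifelse(union == 0, 0, inter / union)
    if (max(sims) <= tanimoto_cutoff) {
      keep <- c(keep, i)
      fps[[length(fps) + 1L]] <- fp
    }
  }
  if (n_unparseable > 0L) {
    rlang::inform(sprintf("negative sampling: skipped %d candidate(s) with unparseable SMILES",
                          n_unparseable))
  }
  if (length(keep) < target) {
    warning("negative pool exhausted: requested ", target,
            " negatives but only ", length(keep),
            " eligible compounds (Tanimoto <= ", tanimoto_cutoff,
            " to all positives)", call. = FALSE)
  }
  out <- candidates[keep, , drop = FALSE]
  out$fp <- fps
  out
}

#' Attach fingerprints to a compound table
#'
#' Parses each row's SMILES and adds a `chem_fp` list-column `fp`.
#' Unparseable SMILES yield `NULL` fingerprints; set `drop_unparseable`
#' to remove those rows (a note reports how many were dropped).
#'
#' @param compounds Data frame with a `smiles` column.
#' @param drop_unparseable Drop rows whose SMILES fail to parse
#'   (default TRUE).
#' @inheritParams compute_fingerprint
#' @return The input tibble with an added `fp` list-column.
#' @export
add_fingerprints <- function(compounds, drop_unparseable = TRUE,
                             n_bits = 1024L, max_atoms = 7L) {
  stopifnot(is.data.frame(compounds), "smiles" %in% names(compounds))
  out <- tibble::as_tibble(compounds)
  out$fp <- fingerprint_smiles(out$smiles, n_bits = n_bits,
                               max_atoms = max_atoms)
  if (drop_unparseable) {
    bad <- vapply(out$fp, is.null, logical(1))
    if (any(bad)) {
      rlang::inform(sprintf("dropped %d compound(s) with unparseable SMILES",
                            sum(bad)))
      out <- out[!bad, , drop = FALSE]
    }
  }
  out
}
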