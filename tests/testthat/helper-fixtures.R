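# Shared test helpers: independent oracles and tiny in-code store fixtures.

# Brute-force simple-path enumerator, independent of the package's DFS.
# Works directly off the atoms/bonds tables of a parsed graph: builds its
# own adjacency, enumerates every simple path of 1..max_atoms atoms by
# naive recursion, encodes forward and reverse with the documented code
# scheme, and canonicalizes via a radix sort. Returns the sorted unique
# fragment set (and, via attribute, the pre-dedup path count).
oracle_fragments <- function(graph, max_atoms = 7L,
                             exclude_single_cno = TRUE) {
  atoms <- graph$atoms
  bonds <- graph$bonds
  n <- nrow(atoms)
  if (n == 0L) return(character(0))
  acode <- ifelse(atoms$aromatic, tolower(atoms$element), atoms$element)
  ch <- atoms$charge
  acode <- ifelse(ch == 0L, acode,
                  paste0(acode, ifelse(ch > 0L, "+", "-"), abs(ch)))
  bmap <- c(single = "1", double = "2", triple = "3", aromatic = "a")

  adj <- lapply(seq_len(n), function(i) list(to = integer(0), bc = character(0)))
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k] + 1L; b <- bonds$b[k] + 1L
    bc <- bmap[[bonds$order[k]]]
    adj[[a]]$to <- c(adj[[a]]$to, b); adj[[a]]$bc <- c(adj[[a]]$bc, bc)
    adj[[b]]$to <- c(adj[[b]]$to, a); adj[[b]]$bc <- c(adj[[b]]$bc, bc)
  }

  paths <- list()
  extend <- function(path, toks) {
    paths[[length(paths) + 1L]] <<- toks
    if (length(path) == max_atoms) return(invisible())
    u <- path[length(path)]
    for (k in seq_along(adj[[u]]$to)) {
      w <- adj[[u]]$to[k]
      if (!w %in% path) {
        extend(c(path, w), c(toks, adj[[u]]$bc[k], acode[w]))
      }
    }
  }
  excluded_single <- exclude_single_cno & atoms$element %in% c("C", "N", "O") &
    !atoms$aromatic & atoms$charge == 0L
  for (s in seq_len(n)) extend(s, acode[s])

  fwd <- vapply(paths, paste, character(1), collapse = "~")
  rev_ <- vapply(paths, function(t) paste(rev(t), collapse = "~"),
                 character(1))
  both <- rbind(fwd, rev_)
  canon <- apply(both, 2, function(p) sort(p, method = "radix")[1])
  if (any(excluded_single)) {
    canon <- canon[!canon %in% acode[excluded_single]]
  }
  out <- sort(unique(canon), method = "radix")
  attr(out, "n_paths") <- length(paths)
  out
}

# Write a tiny bioactivity store as TSVs; rows given as plain vectors.
write_bio_store <- function(dir,
                            compounds = NULL,
                            activities = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(compounds)) {
    compounds <- tibble::tibble(
      compound_id = c("C1", "C2", "C3"),
      smiles = c("CCO", "CCN", "CCS"),
      name = c("alpha", "beta", "gamma"),
      synonyms = c("a1|a2", "", "g1")
    )
  }
  if (is.null(activities)) {
    activities <- tibble::tibble(
      compound_id = c("C1", "C2", "C3"),
      gene_symbol = c("GENE1", "GENE1", "OTHER"),
      assay_type = c("EC50", "IC50", "EC50"),
      value_nm = c(100, 50, 10)
    )
  }
  readr::write_tsv(compounds, file.path(dir, "compounds.tsv"), na = "",
                   quote = "none", escape = "none", progress = FALSE)
  readr::write_tsv(activities, file.path(dir, "activities.tsv"), na = "",
                   quote = "none", escape = "none", progress = FALSE)
  dir
}

write_food_store <- function(dir,
                             food_compounds = NULL,
                             food_contents = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(food_compounds)) {
    food_compounds <- tibble::tibble(
      compound_id = c("F1", "F2", "F3"),
      smiles = c("CCO", "c1ccccc1O", "CC(C)O"),
      name = c("fc-one", "fc-two", "fc-three"),
      cas_id = c("50-00-0", "", "64-17-5")
    )
  }
  if (is.null(food_contents)) {
    food_contents <- tibble::tibble(
      compound_id = c("F1", "F1", "F2"),
      food_name = c("oat", "rye", "kale"),
      amount_min = c(1.5, NA, 10),
      amount_max = c(3.5, 7.2, NA)
    )
  }
  readr::write_tsv(food_compounds, file.path(dir, "food_compounds.tsv"),
                   na = "", quote = "none", escape = "none",
                   progress = FALSE)
  readr::write_tsv(food_contents, file.path(dir, "food_contents.tsv"),
                   na = "", quote = "none", escape = "none",
                   progress = FALSE)
  dir
}

# Linearly separable labeled dataset: positives all carry a marker
# substructure (an aromatic thiophene amide, spanning many fragment bits
# so ensemble votes concentrate on it), negatives never do. Built from
# real fingerprints so bit-level separability holds by construction.
separable_dataset <- function(n_pos = 12L, n_neg = 24L) {
  pos_smiles <- paste0("c1ccsc1C(=O)NCC",
                       c("C", "CC", "CO", "CN", "CCl", "CCC",
                         "COC", "CCO", "CCN", "C(C)C", "CS",
                         "CCS"))[seq_len(n_pos)]
  neg_base <- c("CCCCCC", "CCOCC", "CCNCC", "CCCCO", "CCCCN", "CC(C)CC",
                "CCCC(C)C", "OCCCCO", "NCCCCN", "CCOC(C)C", "CCCCCN",
                "CCCCCO", "CC(C)OC", "CCNC(C)C", "OCCOCC", "NCCOCC",
                "CCCNCC", "CCCOCC", "CC(C)NC", "CCCCCS?", "CCCCCC(C)C",
                "CCOCCO", "CCNCCN", "CCOCCC")
  neg_base[20] <- "CCCCCCC"
  neg_smiles <- neg_base[seq_len(n_neg)]
  pos <- tibble::tibble(compound_id = sprintf("P%03d", seq_len(n_pos)),
                        smiles = pos_smiles)
  neg <- tibble::tibble(compound_id = sprintf("N%03d", seq_len(n_neg)),
                        smiles = neg_smiles)
  build_dataset(add_fingerprints(pos), add_fingerprints(neg))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
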