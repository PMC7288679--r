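#' Enumerate canonical linear fragments of a molecular graph
#'
#' Enumerates every simple path (no repeated atom) of 1 to `max_atoms` atoms
#' in the graph, encodes each as an alternating atom/bond code string, and
#' canonicalizes by taking the byte-wise lexicographic minimum of the forward
#' and reversed encodings, so that a path read from either end yields the same
#' fragment. The deduplicated fragment set is what the binary fingerprint
#' indexes.
#'
#' Atom codes carry element (lower-case when aromatic) and formal charge;
#' bond codes are `1`, `2`, `3`, `a` for single/double/triple/aromatic.
#' Single-atom fragments of uncharged non-aromatic C, N or O are excluded by
#' default, mirroring the documented behaviour of path-based (FP2-style)
#' fingerprints; set `exclude_single_cno = FALSE` to keep them.
#'
#' @param graph A `mol_graph` from [parse_smiles()].
#' @param max_atoms Maximum path length in atoms (default 7).
#' @param exclude_single_cno Drop single-atom C/N/O fragments (default TRUE).
#' @return Character vector of unique canonical fragment codes, sorted.
#' @examples
#' enumerate_linear_fragments(parse_smiles("CCO"))
#' @export
enumerate_linear_fragments <- function(graph, max_atoms = 7L,
                                       exclude_single_cno = TRUE) {
  stopifnot(inherits(graph, "mol_graph"), max_atoms >= 1L)
  n <- nrow(graph$atoms)
  if (n == 0L) return(character(0))

  acode <- atom_codes(graph)
  bcode <- c("1", "2", "3", "a")
  nbr <- graph$adj$nbr
  code <- graph$adj$code

  # collected path encodings, forward and reverse, grown geometrically
  cap <- 256L
  fwd <- character(cap)
  rev_ <- character(cap)
  cnt <- 0L
  push <- function(f, r) {
    cnt <<- cnt + 1L
    if (cnt > cap) {
      cap <<- cap * 2L
      length(fwd) <<- cap
      length(rev_) <<- cap
    }
    fwd[cnt] <<- f
    rev_[cnt] <<- r
  }

  visited <- logical(n)
  dfs <- function(u, f, r, depth) {
    push(f, r)
    if (depth == max_atoms) return(invisible())
    visited[u] <<- TRUE
    nb <- nbr[[u]]
    cd <- code[[u]]
    for (k in seq_along(nb)) {
      w <- nb[k]
      if (!visited[w]) {
        bc <- bcode[cd[k]]
        dfs(w,
            paste0(f, "~", bc, "~", acode[w]),
            paste0(acode[w], "~", bc, "~", r),
            depth + 1L)
      }
    }
    visited[u] <<- FALSE
    invisible()
  }

  singles_excluded <- exclude_single_cno &
    graph$atoms$element %in% c("C", "N", "O") &
    !graph$atoms$aromatic & graph$atoms$charge == 0L

  for (start in seq_len(n)) {
    if (singles_excluded[start] && length(nbr[[start]]) == 0L) next
    dfs(start, acode[start], acode[start], 1L)
  }

  fwd <- fwd[seq_len(cnt)]
  rev_ <- rev_[seq_len(cnt)]
  canon <- canonical_min(fwd, rev_)
  if (any(singles_excluded)) {
    canon <- canon[!canon %in% acode[singles_excluded]]
  }
  sort(unique(canon), method = "radix")
}

# element code: lower-case when aromatic, charge appended as +k/-k
atom_codes <- function(graph) {
  code <- ifelse(graph$atoms$aromatic,
                 tolower(graph$atoms$element),
                 graph$atoms$element)
  ch <- graph$atoms$charge
  ifelse(ch == 0L, code,
         paste0(code, ifelse(ch > 0L, "+", "-"), abs(ch)))
}

# byte-wise (C-locale) element-wise minimum of two string vectors
canonical_min <- function(f, r) {
  n <- length(f)
  if (n == 0L) return(character(0))
  comb <- c(f, r)
  o <- order(comb, method = "radix")
  rk <- integer(2L * n)
  rk[o] <- seq_along(o)
  ifelse(rk[seq_len(n)] <= rk[n + seq_len(n)], f, r)
}

#' Hash a fragment code to a fingerprint bit index
#'
#' Deterministic 32-bit FNV-1a hash of the canonical fragment code, reduced
#' modulo the fingerprint width. Identical codes always map to the same
#' index, on every platform and run.
#'
#' @param fragment Character vector of canonical fragment codes.
#' @param n_bits Fingerprint width (default 1024).
#' @return Integer vector of 0-based bit indices in `[0, n_bits)`.
#' @examples
#' hash_fragment("C~1~C")
#' @export
hash_fragment <- function(fragment, n_bits = 1024L) {
  stopifnot(is.character(fragment), n_bits >= 1L)
  as.integer(vapply(fragment, fnv1a32, numeric(1), USE.NAMES = FALSE) %% n_bits)
}

# FNV-1a 32-bit, in double arithmetic kept exact below 2^53
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Compute a binary path fingerprint for a molecule
#'
#' Sets one bit for each canonical linear fragment of up to `max_atoms` atoms
#' (see [enumerate_linear_fragments()]), hashed into a fixed-width binary
#' vector. Deterministic: the same graph always yields the same fingerprint.
#'
#' @inheritParams enumerate_linear_fragments
#' @param n_bits Fingerprint width (default 1024).
#' @return A `chem_fp`: logical vector of length `n_bits`.
#' @examples
#' fp <- compute_fingerprint(parse_smiles("c1ccccc1O"))
#' sum(fp)
#' @export
compute_fingerprint <- function(graph, n_bits = 1024L, max_atoms = 7L,
                                exclude_single_cno = TRUE) {
  frags <- enumerate_linear_fragments(graph, max_atoms = max_atoms,
                                      exclude_single_cno = exclude_single_cno)
  bits <- logical(n_bits)
  if (length(frags) > 0L) {
    bits[hash_fragment(frags, n_bits) + 1L] <- TRUE
  }
  structure(bits, class = "chem_fp")
}

#' @export
print.chem_fp <- function(x, ...) {
  cat("<chem_fp> ", length(x), " bits, ", sum(x), " set\n", sep = "")
  invisible(x)
}

#' Tanimoto similarity between two binary fingerprints
#'
#' The Tanimoto (Jaccard) coefficient of the two bit sets,
#' \eqn{|A \cap B| / |A \cup B|}, the standard chemical-similarity measure
#' for binary fingerprints. Two all-zero fingerprints have similarity 0 by
#' convention.
#'
#' @param a,b Equal-length logical fingerprint vectors.
#' @return Similarity in `[0, 1]`.
#' @examples
#' fa <- compute_fingerprint(parse_smiles("CCO"))
#' tanimoto(fa, fa)
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprints have different lengths (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  }
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

#' Pairwise Tanimoto similarity between two fingerprint sets
#'
#' @param a,b Logical matrices, one fingerprint per row, equal column count.
#' @return Numeric matrix of similarities, `nrow(a)` by `nrow(b)`.
#' @export
tanimoto_matrix <- function(a, b) {
  a <- fp_matrix(a)
  b <- fp_matrix(b)
  if (ncol(a) != ncol(b)) {
    stop("fingerprints have different lengths (", ncol(a), " vs ",
         ncol(b), ")", call. = FALSE)
  }
  inter <- tcrossprod(a, b)
  union <- outer(rowSums(a), rowSums(b), "+") - inter
  out <- ifelse(union == 0, 0, inter / union)
  dimnames(out) <- list(rownames(a), rownames(b))
  out
}

#' Stack fingerprints into a 0/1 feature matrix
#'
#' @param fps A list of `chem_fp` vectors, or a matrix already in row form.
#' @return Numeric 0/1 matrix, one fingerprint per row.
#' @export
fp_matrix <- function(fps) {
  if (is.matrix(fps)) return(fps * 1)
  if (inherits(fps, "chem_fp")) fps <- list(fps)
  stopifnot(is.list(fps))
  if (length(fps) == 0L) return(matrix(numeric(0), nrow = 0, ncol = 1024L))
  lens <- lengths(fps)
  if (length(unique(lens)) != 1L) {
    stop("fingerprints have different lengths", call. = FALSE)
  }
  m <- matrix(as.numeric(unlist(fps, use.names = FALSE)),
              nrow = length(fps), byrow = TRUE)
  rownames(m) <- names(fps)
  m
}

#' Fingerprint a vector of SMILES strings
#'
#' Parses and fingerprints each SMILES, memoizing on the (whitespace
#' normalized) string so duplicated structures are computed once. Strings
#' that fail to parse yield `NULL` entries.
#'
#' @param smiles Character vector.
#' @inheritParams compute_fingerprint
#' @return List of `chem_fp` (or `NULL` for unparseable entries), same
#'   length and order as `smiles`.
#' @export
fingerprint_smiles <- function(smiles, n_bits = 1024L, max_atoms = 7L,
                               exclude_single_cno = TRUE) {
  norm <- gsub("[[:space:]]+", "", smiles)
  uniq <- unique(norm)
  memo <- lapply(uniq, function(s) {
    g <- tryCatch(parse_smiles(s), error = function(e) NULL)
    if (is.null(g)) NULL
    else compute_fingerprint(g, n_bits = n_bits, max_atoms = max_atoms,
                             exclude_single_cno = exclude_single_cno)
  })
  names(memo) <- uniq
  out <- memo[norm]
  names(out) <- NULL
  out
}

#' Serialize a fingerprint to a hex string
#'
#' Packs the bit vector into hexadecimal, 4 bits per character, most
#' significant bit first within each nibble; a 1024-bit fingerprint becomes
#' 256 characters. [fp_from_hex()] inverts it.
#'
#' @param fp A `chem_fp` (logical vector, length a multiple of 4).
#' @return A single hex string.
#' @export
fp_to_hex <- function(fp) {
  stopifnot(length(fp) %% 4L == 0L)
  nib <- matrix(as.integer(fp), nrow = 4L)
  vals <- 8L * nib[1, ] + 4L * nib[2, ] + 2L * nib[3, ] + nib[4, ]
  paste(c("0123456789abcdef" |> strsplit("") |> unlist())[vals + 1L],
        collapse = "")
}

#' @rdname fp_to_hex
#' @param hex A hex string produced by [fp_to_hex()].
#' @export
fp_from_hex <- function(hex) {
  vals <- strtoi(strsplit(hex, "")[[1]], base = 16L)
  if (anyNA(vals)) stop("invalid hex string", call. = FALSE)
  bits <- as.logical(rbind(vals %/% 8L %% 2L, vals %/% 4L %% 2L,
                           vals %/% 2L %% 2L, vals %% 2L))
  structure(as.vector(bits), class = "chem_fp")
}
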