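#' Parse a SMILES string into a molecular graph
#'
#' Converts a SMILES (simplified molecular-input line-entry system) string
#' into an explicit heavy-atom graph: a table of atoms, a table of bonds, and
#' an adjacency index. This graph is the substrate for linear-fragment
#' fingerprinting ([compute_fingerprint()]); only the features that matter for
#' path-based fragments are retained.
#'
#' The supported subset covers: organic-subset atoms (`B C N O P S F Cl Br I`),
#' aromatic lowercase atoms (`b c n o p s`), bracket atoms with optional
#' isotope, stereo marks, attached-H count and formal charge (isotope and
#' stereo are accepted and ignored; the H count is recorded but implicit
#' hydrogens are never instantiated as graph atoms), explicit bonds
#' `- = # :`, directional bonds `/ \\` (accepted, treated as unspecified),
#' branches, ring closures (`1`-`9` and two-digit `%nn`), and the `.`
#' disconnection separator (components share one graph). An unspecified bond
#' between two aromatic atoms is aromatic, otherwise single. Aromaticity is
#' taken syntactically from lowercase notation; no perception or kekulization
#' is performed, and no valence checking is done.
#'
#' All whitespace is stripped before parsing, so strings copied from typeset
#' sources (which may contain spaces around `=`) parse as written.
#'
#' @param smiles A single SMILES string. Must be non-empty after removing
#'   whitespace.
#' @return A `mol_graph` object: a list with
#'   \describe{
#'     \item{atoms}{tibble with columns `index` (0-based), `element`,
#'       `aromatic`, `charge`, `hcount` (`NA` unless bracket-specified).}
#'     \item{bonds}{tibble with columns `a`, `b` (0-based atom indices,
#'       `a < b`) and `order` (one of `"single"`, `"double"`, `"triple"`,
#'       `"aromatic"`).}
#'     \item{adj}{adjacency: for each atom, integer vectors of neighbour
#'       atom indices (1-based into `atoms`) and parallel bond-order codes.}
#'   }
#' @examples
#' g <- parse_smiles("C1CC1O")
#' g$atoms
#' g$bonds
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    stop("`smiles` must be a single string", call. = FALSE)
  }
  s <- gsub("[[:space:]]+", "", smiles)
  if (!nzchar(s)) {
    stop("SMILES parse error: empty string", call. = FALSE)
  }

  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)

  elem <- character(0)
  arom <- logical(0)
  chrg <- integer(0)
  hcnt <- integer(0)

  bond_a <- integer(0)
  bond_b <- integer(0)
  bond_o <- integer(0) # 1 single, 2 double, 3 triple, 4 aromatic

  prev <- NA_integer_        # current attachment atom (1-based)
  pending <- NA_integer_     # explicit bond code awaiting the next atom
  stack <- integer(0)        # branch stack of attachment atoms
  rings <- list()            # open ring closures: label -> c(atom, code)

  add_bond <- function(a, b, code) {
    if (a == b) stop("SMILES parse error: ring closure bonds an atom to itself",
                     call. = FALSE)
    lo <- min(a, b); hi <- max(a, b)
    if (any(bond_a == lo & bond_b == hi)) {
      stop("SMILES parse error: duplicate bond between atoms ",
           lo - 1L, " and ", hi - 1L, call. = FALSE)
    }
    bond_a[length(bond_a) + 1L] <<- lo
    bond_b[length(bond_b) + 1L] <<- hi
    bond_o[length(bond_o) + 1L] <<- code
  }

  default_code <- function(a, b) {
    if (arom[a] && arom[b]) 4L else 1L
  }

  new_atom <- function(element, aromatic, charge = 0L, hcount = NA_integer_) {
    if (aromatic && !element %in% c("B", "C", "N", "O", "P", "S")) {
      stop("SMILES parse error: aromatic form not supported for element '",
           element, "'", call. = FALSE)
    }
    elem[length(elem) + 1L] <<- element
    arom[length(arom) + 1L] <<- aromatic
    chrg[length(chrg) + 1L] <<- charge
    hcnt[length(hcnt) + 1L] <<- hcount
    idx <- length(elem)
    if (!is.na(prev)) {
      code <- if (is.na(pending)) default_code(prev, idx) else pending
      add_bond(prev, idx, code)
    }
    pending <<- NA_integer_
    prev <<- idx
    invisible(idx)
  }

  close_or_open_ring <- function(label) {
    if (is.na(prev)) {
      stop("SMILES parse error: ring closure digit ", label,
           " before any atom", call. = FALSE)
    }
    key <- as.character(label)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- c(prev, if (is.na(pending)) NA_integer_ else pending)
    } else {
      open <- rings[[key]]
      code <- if (!is.na(pending)) pending
              else if (!is.na(open[2])) open[2]
              else default_code(open[1], prev)
      add_bond(open[1], prev, code)
      rings[[key]] <<- NULL
    }
    pending <<- NA_integer_
  }

  organic_two <- c(Cl = "Cl", Br = "Br")
  organic_one <- c("B", "C", "N", "O", "P", "S", "F", "I")
  aromatic_one <- c("b", "c", "n", "o", "p", "s")

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""

    if (two %in% organic_two) {
      new_atom(two, FALSE)
      i <- i + 2L
    } else if (ch %in% organic_one) {
      new_atom(ch, FALSE)
      i <- i + 1L
    } else if (ch %in% aromatic_one) {
      new_atom(toupper(ch), TRUE)
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("SMILES parse error: unterminated bracket atom",
                      call. = FALSE)
      body <- substr(s, i + 1L, j - 1L)
      at <- parse_bracket_atom(body)
      new_atom(at$element, at$aromatic, at$charge, at$hcount)
      i <- j + 1L
    } else if (ch == "-") {
      pending <- 1L; i <- i + 1L
    } else if (ch == "=") {
      pending <- 2L; i <- i + 1L
    } else if (ch == "#") {
      pending <- 3L; i <- i + 1L
    } else if (ch == ":") {
      pending <- 4L; i <- i + 1L
    } else if (ch == "/" || ch == "\\") {
      # stereo direction markers: bond order left unspecified
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("SMILES parse error: branch opened before any atom",
                            call. = FALSE)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) {
        stop("SMILES parse error: unbalanced parentheses", call. = FALSE)
      }
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_or_open_ring(as.integer(ch))
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9][0-9]$", substr(s, i + 1L, i + 2L))) {
        stop("SMILES parse error: '%' must be followed by two digits",
             call. = FALSE)
      }
      close_or_open_ring(as.integer(substr(s, i + 1L, i + 2L)))
      i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending <- NA_integer_
      i <- i + 1L
    } else {
      stop("SMILES parse error: unknown element or symbol '", ch, "'",
           call. = FALSE)
    }
  }

  if (length(stack) > 0L) {
    stop("SMILES parse error: unbalanced parentheses", call. = FALSE)
  }
  if (length(rings) > 0L) {
    stop("SMILES parse error: unmatched ring closure digit ",
         paste(names(rings), collapse = ", "), call. = FALSE)
  }

  new_mol_graph(elem, arom, chrg, hcnt, bond_a, bond_b, bond_o)
}

# bracket body grammar: [isotope] symbol [@|@@] [H[count]] [charge] [:class]
parse_bracket_atom <- function(body) {
  m <- regmatches(
    body,
    regexec(
      "^([0-9]+)?([A-Z][a-z]?|[bcnops])(@{1,2})?(H[0-9]*)?((?:\\+[0-9]*)|(?:-[0-9]*)|\\++|-+)?(:[0-9]+)?$",
      body
    )
  )[[1]]
  if (length(m) == 0L) {
    stop("SMILES parse error: cannot parse bracket atom '[", body, "]'",
         call. = FALSE)
  }
  sym <- m[3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
  element <- if (aromatic) toupper(sym) else sym
  hfield <- m[5]
  hcount <- if (!nzchar(hfield)) NA_integer_
            else if (hfield == "H") 1L
            else as.integer(substr(hfield, 2L, nchar(hfield)))
  cfield <- m[6]
  charge <- if (!nzchar(cfield)) 0L
            else if (grepl("^\\++$", cfield)) nchar(cfield)
            else if (grepl("^-+$", cfield)) -nchar(cfield)
            else if (grepl("^\\+[0-9]+$", cfield)) as.integer(substr(cfield, 2L, nchar(cfield)))
            else if (cfield == "+") 1L
            else if (cfield == "-") -1L
            else -as.integer(substr(cfield, 2L, nchar(cfield)))
  list(element = element, aromatic = aromatic, charge = charge,
       hcount = hcount)
}

new_mol_graph <- function(elem, arom, chrg, hcnt, bond_a, bond_b, bond_o) {
  n <- length(elem)
  order_names <- c("single", "double", "triple", "aromatic")
  nbr <- vector("list", n)
  nbr_code <- vector("list", n)
  for (k in seq_along(nbr)) {
    nbr[[k]] <- integer(0)
    nbr_code[[k]] <- integer(0)
  }
  for (k in seq_along(bond_a)) {
    a <- bond_a[k]; b <- bond_b[k]
    nbr[[a]] <- c(nbr[[a]], b)
    nbr_code[[a]] <- c(nbr_code[[a]], bond_o[k])
    nbr[[b]] <- c(nbr[[b]], a)
    nbr_code[[b]] <- c(nbr_code[[b]], bond_o[k])
  }
  structure(
    list(
      atoms = tibble::tibble(
        index = seq_len(n) - 1L,
        element = elem,
        aromatic = arom,
        charge = chrg,
        hcount = hcnt
      ),
      bonds = tibble::tibble(
        a = bond_a - 1L,
        b = bond_b - 1L,
        order = order_names[bond_o]
      ),
      adj = list(nbr = nbr, code = nbr_code)
    ),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  comp <- graph_components(x)
  cat("<mol_graph> ", nrow(x$atoms), " heavy atoms, ", nrow(x$bonds),
      " bonds, ", max(comp, 0L), " component(s)\n", sep = "")
  counts <- sort(table(x$atoms$element), decreasing = TRUE)
  cat("  formula (heavy atoms): ",
      paste0(names(counts), counts, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Number of heavy atoms in a molecular graph
#' @param graph A `mol_graph`.
#' @return Integer atom count.
#' @export
n_atoms <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  nrow(graph$atoms)
}

#' Connected-component labels of a molecular graph
#'
#' Breadth-first labelling; used for disconnected (salt-form) inputs and for
#' cycle-count bookkeeping (bonds = atoms - components + rings).
#'
#' @param graph A `mol_graph`.
#' @return Integer vector of component labels (1-based), one per atom;
#'   `integer(0)` for an empty graph.
#' @export
graph_components <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  n <- nrow(graph$atoms)
  if (n == 0L) return(integer(0))
  lab <- integer(n)
  comp <- 0L
  for (start in seq_len(n)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue) > 0L) {
      u <- queue[1]
      queue <- queue[-1]
      for (w in graph$adj$nbr[[u]]) {
        if (lab[w] == 0L) {
          lab[w] <- comp
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}
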