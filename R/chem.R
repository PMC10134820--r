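#' Parse a SMILES string into a molecular graph
#'
#' A small SMILES reader covering the subset needed for drug-like reference
#' compounds: the organic subset (B, C, N, O, P, S, F, Cl, Br, I) and their
#' aromatic forms, bracket atoms with charge and explicit hydrogen counts,
#' single/double/triple/aromatic bonds, branches, ring closures (including
#' `%nn`), and dot-separated fragments. Stereo markers (`@`, `/`, `\`),
#' isotopes and atom maps are accepted and ignored. Implicit hydrogens are
#' filled from standard valences (aromatic bonds counted as 1.5, summed
#' bond order rounded up), with the formal charge added to the valence.
#'
#' @param smiles a single SMILES string.
#' @return a `molecule`: list with `atoms` (data frame `element`, `atomic_num`,
#'   `aromatic`, `charge`, `hcount`, `degree`, `in_ring`) and `bonds`
#'   (data frame `a1`, `a2`, `order`; aromatic order is 1.5).
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("`smiles` must be a single non-empty string", call. = FALSE)
  }
  fail <- function(msg, pos = NA) {
    stop(sprintf("SMILES parse error in '%s'%s: %s", smiles,
                 if (is.na(pos)) "" else sprintf(" at position %d", pos),
                 msg), call. = FALSE)
  }
  atomic_nums <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11,
                   Mg = 12, Si = 14, P = 15, S = 16, Cl = 17, K = 19,
                   Ca = 20, Fe = 26, Zn = 30, Se = 34, Br = 35, I = 53)
  valences <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2, F = 1, Cl = 1,
                Br = 1, I = 1, H = 1)

  elem <- character(); arom <- logical(); charge <- numeric()
  hexp <- numeric()  # NA = implicit
  b1 <- integer(); b2 <- integer(); bord <- numeric()

  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  prev <- NA_integer_
  stack <- integer()
  pending <- NA_real_
  rings <- list()  # ring number -> list(atom, order)

  add_bond <- function(a, b, order) {
    if (is.na(order)) {
      order <- if (arom[a] && arom[b]) 1.5 else 1
    }
    b1 <<- c(b1, a); b2 <<- c(b2, b); bord <<- c(bord, order)
  }
  add_atom <- function(el, aromatic, chg = 0, h = NA_real_) {
    elem <<- c(elem, el); arom <<- c(arom, aromatic)
    charge <<- c(charge, chg); hexp <<- c(hexp, h)
    id <- length(elem)
    if (!is.na(prev)) add_bond(prev, id, pending)
    pending <<- NA_real_
    prev <<- id
    id
  }
  ring_bond <- function(num) {
    key <- as.character(num)
    if (is.na(prev)) fail("ring closure before any atom", i)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, order = pending)
    } else {
      open <- rings[[key]]
      order <- if (!is.na(pending)) pending else open$order
      add_bond(open$atom, prev, order)
      rings[[key]] <<- NULL
    }
    pending <<- NA_real_
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) fail("unclosed bracket atom", i)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regexec(
        "^(\\d+)?([A-Za-z][a-z]?)(@{1,2})?(H(\\d+)?)?(([+-])(\\d+)?([+-]*))?(:\\d+)?$",
        body)[[1]]
      g <- regmatches(body, list(m))[[1]]
      if (length(g) == 0L) fail(sprintf("cannot parse bracket atom [%s]",
                                        body), i)
      sym <- g[3]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se")
      el <- if (aromatic) {
        paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      } else sym
      if (!el %in% names(atomic_nums)) fail(sprintf("unsupported element '%s'",
                                                    el), i)
      h <- if (nzchar(g[5])) if (nzchar(g[6])) as.numeric(g[6]) else 1 else 0
      chg <- 0
      if (nzchar(g[7])) {
        sgn <- if (g[8] == "+") 1 else -1
        mag <- if (nzchar(g[9])) as.numeric(g[9]) else 1 + nchar(g[10])
        chg <- sgn * mag
      }
      add_atom(el, aromatic, chg, h)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, chars[i + 1L]), FALSE)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, FALSE)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE)
      i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending <- 1; i <- i + 1L
    } else if (ch == "=") {
      pending <- 2; i <- i + 1L
    } else if (ch == "#") {
      pending <- 3; i <- i + 1L
    } else if (ch == ":") {
      pending <- 1.5; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) fail("branch before any atom", i)
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) fail("unbalanced ')'", i)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      ring_bond(as.integer(ch)); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) fail("truncated %nn ring closure", i)
      ring_bond(as.integer(paste(chars[(i + 1L):(i + 2L)], collapse = "")))
      i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NA_real_; i <- i + 1L
    } else if (ch == "@") {
      i <- i + 1L  # stereo, ignored outside brackets too
    } else {
      fail(sprintf("unexpected character '%s'", ch), i)
    }
  }
  if (length(stack)) fail("unbalanced '('")
  if (length(rings)) fail(sprintf("unclosed ring bond(s): %s",
                                  paste(names(rings), collapse = ", ")))
  if (length(elem) == 0L) fail("no atoms")

  natoms <- length(elem)
  degree <- tabulate(c(b1, b2), nbins = natoms)
  bondsum <- rep(0, natoms)
  for (e in seq_along(b1)) {
    bondsum[b1[e]] <- bondsum[b1[e]] + bord[e]
    bondsum[b2[e]] <- bondsum[b2[e]] + bord[e]
  }
  hcount <- hexp
  implicit <- is.na(hcount)
  val <- unname(valences[elem]) + charge
  hcount[implicit] <- pmax(0, val[implicit] - ceiling(bondsum[implicit]))
  hcount[is.na(hcount)] <- 0  # elements with no standard valence

  in_ring <- rep(FALSE, natoms)
  if (length(b1)) {
    g <- igraph::graph_from_edgelist(cbind(b1, b2), directed = FALSE)
    if (igraph::vcount(g) < natoms) {
      g <- igraph::add_vertices(g, natoms - igraph::vcount(g))
    }
    cyc_edges <- setdiff(seq_along(b1), igraph::bridges(g))
    in_ring[unique(c(b1[cyc_edges], b2[cyc_edges]))] <- TRUE
  }

  list(atoms = data.frame(element = elem,
                          atomic_num = unname(atomic_nums[elem]),
                          aromatic = arom, charge = charge, hcount = hcount,
                          degree = degree, in_ring = in_ring,
                          stringsAsFactors = FALSE),
       bonds = data.frame(a1 = b1, a2 = b2, order = bord))
}

#' Morgan-style circular fingerprint
#'
#' Hashed circular-substructure fingerprint of a molecule: every atom's
#' environment up to `radius` bonds is encoded by iterated neighbourhood
#' hashing (ECFP-style). Round 0 hashes the atom invariants (atomic number,
#' heavy-atom degree, attached hydrogens, formal charge, aromaticity, ring
#' membership); each subsequent round re-hashes an atom with its sorted
#' (bond order, neighbour identifier) list. All identifiers from all rounds
#' are folded modulo `n_bits` into a bit set. The encoding is deterministic
#' and depends only on the molecular graph, so SMILES rewritings of the
#' same molecule (e.g. "CCO" vs "OCC") give identical fingerprints. Bit
#' values are not interchangeable with any external toolkit's fingerprints;
#' all comparisons in this package are internal.
#'
#' @param smiles SMILES string (see [parse_smiles()] for the dialect).
#' @param radius neighbourhood radius in bonds, default 2 (ECFP4-like).
#' @param n_bits fingerprint width, default 2048.
#' @return a `morgan_fp`: list with sorted integer `bits` (0-based indices),
#'   `n_bits`, `radius`.
#' @examples
#' fp <- morgan_fingerprint("CC(=O)Oc1ccccc1C(=O)O")
#' length(fp$bits)
#' @export
morgan_fingerprint <- function(smiles, radius = 2L, n_bits = 2048L) {
  stopifnot(radius >= 0, n_bits >= 2)
  mol <- parse_smiles(smiles)
  a <- mol$atoms
  natoms <- nrow(a)
  nbrs <- vector("list", natoms)
  if (nrow(mol$bonds)) {
    for (e in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[e]; j <- mol$bonds$a2[e]
      o <- round(mol$bonds$order[e] * 10)
      nbrs[[i]] <- rbind(nbrs[[i]], c(o, j))
      nbrs[[j]] <- rbind(nbrs[[j]], c(o, i))
    }
  }
  inv <- vapply(seq_len(natoms), function(i) {
    cpp_hash_numvec(c(a$atomic_num[i], a$degree[i], a$hcount[i],
                      a$charge[i], as.numeric(a$aromatic[i]),
                      as.numeric(a$in_ring[i])), seed = 1)
  }, numeric(1))
  ids <- inv
  if (radius > 0) {
    for (r in seq_len(radius)) {
      inv <- vapply(seq_len(natoms), function(i) {
        env <- c(r, inv[i])
        if (!is.null(nbrs[[i]])) {
          pairs <- cbind(nbrs[[i]][, 1], inv[nbrs[[i]][, 2]])
          pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
          env <- c(env, as.vector(t(pairs)))
        }
        cpp_hash_numvec(env, seed = 2)
      }, numeric(1))
      ids <- c(ids, inv)
    }
  }
  structure(list(bits = sort(unique(as.integer(ids %% n_bits))),
                 n_bits = as.integer(n_bits), radius = as.integer(radius)),
            class = "morgan_fp")
}

#' Tanimoto similarity between fingerprints
#'
#' `|A intersect B| / |A union B|` over set bits; 0 when both fingerprints
#' are empty.
#'
#' @param a,b `morgan_fp` objects of equal width.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "morgan_fp"), inherits(b, "morgan_fp"))
  if (a$n_bits != b$n_bits) {
    stop("fingerprints must have the same width", call. = FALSE)
  }
  u <- length(union(a$bits, b$bits))
  if (u == 0L) return(0)
  length(intersect(a$bits, b$bits)) / u
}
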