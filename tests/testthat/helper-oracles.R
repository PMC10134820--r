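# Independent oracles used by property tests. These deliberately avoid the
# package's own code paths: k-mers are enumerated as strings and canonicalized
# with Biostrings, and graph components are computed with a plain union-find.

# set of canonical k-mers (lexicographic min of k-mer and reverse complement)
oracle_canonical_kmers <- function(seqs, k) {
  out <- character()
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    kms <- substring(s, 1:(n - k + 1), k:n)
    kms <- kms[!grepl("N", kms, fixed = TRUE)]
    if (!length(kms)) next
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(kms)))
    out <- c(out, pmin(kms, rc))
  }
  unique(out)
}

oracle_kmer_jaccard <- function(seqs_a, seqs_b, k) {
  a <- oracle_canonical_kmers(seqs_a, k)
  b <- oracle_canonical_kmers(seqs_b, k)
  length(intersect(a, b)) / length(union(a, b))
}

# connected components by union-find over vertices 1..n
oracle_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small fixed region used across similarity tests
make_region <- function(region_id = "R1", n_genes = 4L, products = "NRPS",
                        on_edge = FALSE, contig_length = 50000) {
  genes <- data.frame(
    locus_tag = sprintf("%s_g%d", region_id, seq_len(n_genes)),
    start = (seq_len(n_genes) - 1L) * 1000,
    end = seq_len(n_genes) * 1000 - 100,
    strand = 1L, role_label = "biosynthetic", stringsAsFactors = FALSE)
  bgc_region(region_id, "G1", "c1", 0, n_genes * 1000, products,
             on_edge, genes, contig_length)
}

make_ref <- function(accession, n_genes = 4L, compounds = character()) {
  genes <- data.frame(
    locus_tag = sprintf("%s_g%d", accession, seq_len(n_genes)),
    start = (seq_len(n_genes) - 1L) * 1000,
    end = seq_len(n_genes) * 1000 - 100,
    strand = 1L, role_label = "biosynthetic", stringsAsFactors = FALSE)
  reference_bgc(accession, genes, compounds)
}

# hits covering the first `n_hit` genes of a region against a reference
make_hits <- function(region, accession, n_hit,
                      ref_genes = sprintf("%s_g%d", accession,
                                          seq_len(max(n_hit, 1L)))) {
  if (n_hit == 0L) return(hit_table())
  hit_table(region$region_id, region$genes$locus_tag[seq_len(n_hit)],
            accession, rep(ref_genes, length.out = n_hit), 100)
}

# Hill-order molecular formula from the package's own SMILES parser
formula_from_parser <- function(smiles) {
  mol <- parse_smiles(smiles)
  counts <- tapply(rep(1L, nrow(mol$atoms)), mol$atoms$element, sum)
  h <- sum(mol$atoms$hcount)
  parts <- character()
  for (e in c("C", sort(setdiff(names(counts), "C")))) {
    if (is.na(counts[e])) next
    parts <- c(parts, paste0(e, ifelse(counts[[e]] > 1, counts[[e]], "")))
    if (e == "C" && h > 0) parts <- c(parts, paste0("H", ifelse(h > 1, h, "")))
  }
  paste(parts, collapse = "")
}
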