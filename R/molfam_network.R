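#' Reference BGC records with linked compounds
#'
#' A `reference_bgc` mirrors one MIBiG-like entry: accession, gene table and
#' the SMILES strings of its characterized compounds. References whose
#' compounds cannot all be parsed keep the parsable ones; an entry with no
#' parsable compound forms no chemical edges.
#'
#' @param accession unique MIBiG-like accession (e.g. "BGC0000001").
#' @param genes gene data frame (`locus_tag`, `start`, `end`, `strand`,
#'   `role_label`).
#' @param compounds character vector of SMILES strings (possibly empty).
#' @param taxon_label producing-taxon label (input field, not looked up).
#' @return a `reference_bgc`.
#' @export
reference_bgc <- function(accession, genes = empty_gene_table(),
                          compounds = character(),
                          taxon_label = NA_character_) {
  stopifnot(is.character(accession), length(accession) == 1L)
  structure(list(accession = accession, genes = genes,
                 compounds = as.character(compounds),
                 taxon_label = taxon_label),
            class = "reference_bgc")
}

#' Read and write reference libraries as JSON
#'
#' The library format is a flat JSON array of records with `accession`,
#' `taxon_label`, `compounds` (SMILES list) and `genes`. `read_mibig_entry()`
#' converts one genuine MIBiG 2.0 JSON entry (fields
#' `cluster$mibig_accession` and `cluster$compounds[[i]]$chem_struct`).
#'
#' @param refs list of `reference_bgc`.
#' @param path file path.
#' @export
write_reference_library <- function(refs, path) {
  recs <- lapply(refs, function(r) {
    g <- r$genes
    list(accession = r$accession, taxon_label = r$taxon_label,
         compounds = as.list(r$compounds),
         genes = lapply(seq_len(nrow(g)), function(i) {
           list(locus_tag = g$locus_tag[i], start = g$start[i],
                end = g$end[i], strand = g$strand[i],
                role_label = g$role_label[i])
         }))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_reference_library
#' @export
read_reference_library <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    genes <- if (length(r$genes)) {
      do.call(rbind, lapply(r$genes, function(g) {
        data.frame(locus_tag = g$locus_tag, start = as.numeric(g$start),
                   end = as.numeric(g$end), strand = as.integer(g$strand),
                   role_label = g$role_label, stringsAsFactors = FALSE)
      }))
    } else empty_gene_table()
    reference_bgc(r$accession, genes, unlist(r$compounds),
                  r$taxon_label %||% NA_character_)
  })
}

#' @rdname write_reference_library
#' @export
read_mibig_entry <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  cl <- doc$cluster %||% doc
  smiles <- unlist(lapply(cl$compounds, function(cp) cp$chem_struct))
  reference_bgc(cl$mibig_accession %||% basename(path),
                compounds = smiles[!is.na(smiles) & nzchar(smiles)],
                taxon_label = cl$organism_name %||% NA_character_)
}

#' Chemical edges between reference BGCs
#'
#' Fingerprints every parsable compound of every reference and places an
#' undirected edge between two references when the MAXIMUM Tanimoto
#' similarity over their compound pairs reaches `threshold` (inclusive).
#' Unparsable SMILES are skipped with a warning; self-edges are never
#' produced.
#'
#' @param refs list of `reference_bgc`.
#' @param threshold inclusive Tanimoto threshold, default 0.5.
#' @param radius,n_bits fingerprint parameters (see
#'   [morgan_fingerprint()]).
#' @return data frame with columns `accession_a`, `accession_b`, `weight`
#'   (the maximal Tanimoto).
#' @export
compound_edges <- function(refs, threshold = 0.5, radius = 2L,
                           n_bits = 2048L) {
  assert_fraction(threshold, "threshold")
  fps <- lapply(refs, function(r) {
    out <- list()
    for (smi in r$compounds) {
      fp <- tryCatch(morgan_fingerprint(smi, radius, n_bits),
                     error = function(e) {
                       warning(sprintf("skipping compound of %s: %s",
                                       r$accession, conditionMessage(e)),
                               call. = FALSE)
                       NULL
                     })
      if (!is.null(fp)) out[[length(out) + 1L]] <- fp
    }
    out
  })
  accs <- vapply(refs, function(r) r$accession, character(1))
  rows <- list()
  n <- length(refs)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (length(fps[[i]]) == 0L || length(fps[[j]]) == 0L) next
        best <- max(vapply(fps[[i]], function(fa) {
          max(vapply(fps[[j]], function(fb) tanimoto(fa, fb), numeric(1)))
        }, numeric(1)))
        if (best >= threshold) {
          rows[[length(rows) + 1L]] <- data.frame(
            accession_a = accs[i], accession_b = accs[j], weight = best,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(accession_a = character(), accession_b = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  }
  out
}

#' Build the molecular-family network
#'
#' Union graph over query BGC nodes and reference BGC nodes with two edge
#' types: genomic edges (query region to its linked reference, weight = the
#' similarity score, from [link_table()]) and chemical edges (reference to
#' reference, weight = Tanimoto, from [compound_edges()]). Query BGCs with
#' no link can be included as isolated nodes via `all_query_ids`.
#'
#' @param links data frame from [link_table()].
#' @param chem_edges data frame from [compound_edges()].
#' @param all_query_ids,all_reference_ids optional full node inventories;
#'   ids not present in any edge become isolated nodes.
#' @return an `mf_network`: list with `graph` (igraph, vertex attribute
#'   `node_type` in query_bgc/reference_bgc, edge attributes `edge_type`
#'   and `weight`), `nodes` data frame and `membership` (component id per
#'   node).
#' @export
build_network <- function(links, chem_edges,
                          all_query_ids = NULL, all_reference_ids = NULL) {
  q_ids <- unique(c(as.character(links$region_id), all_query_ids))
  r_ids <- unique(c(as.character(links$reference_accession),
                    as.character(chem_edges$accession_a),
                    as.character(chem_edges$accession_b),
                    all_reference_ids))
  overlap <- intersect(q_ids, r_ids)
  if (length(overlap)) {
    stop(sprintf("ids used both as query and reference: %s",
                 paste(head(overlap, 5), collapse = ", ")), call. = FALSE)
  }
  nodes <- data.frame(
    name = c(q_ids, r_ids),
    node_type = rep(c("query_bgc", "reference_bgc"),
                    c(length(q_ids), length(r_ids))),
    stringsAsFactors = FALSE)
  edges <- rbind(
    if (nrow(links)) data.frame(from = links$region_id,
                                to = links$reference_accession,
                                weight = links$score,
                                edge_type = "genomic",
                                stringsAsFactors = FALSE),
    if (nrow(chem_edges)) data.frame(from = chem_edges$accession_a,
                                     to = chem_edges$accession_b,
                                     weight = chem_edges$weight,
                                     edge_type = "chemical",
                                     stringsAsFactors = FALSE))
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), edge_type = character(),
                        stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  membership <- igraph::components(g)$membership
  structure(list(graph = g, nodes = nodes,
                 membership = setNames(as.integer(membership), nodes$name)),
            class = "mf_network")
}

#' Molecular families of a network
#'
#' A molecular family (MF) is a connected component of the network that
#' contains at least one query BGC AND at least one reference BGC — a
#' family needs a chemistry anchor. Components made only of query nodes
#' (unlinked regions) or only of reference nodes are reported separately.
#' `min_size` filters the REPORTED family list by total node count only
#' (default 1 = no filtering; 6 reproduces the published display filter);
#' the headline counts are given both before and after filtering.
#'
#' @param net an `mf_network`.
#' @param min_size minimum node count for a family to be listed.
#' @return an `mf_report`: list with `n_mfs` (all), `n_mfs_reported`
#'   (after `min_size`), `n_query_in_mfs`, `n_reference_in_mfs`,
#'   `families` (data frame `mf_id`, `n_nodes`, `n_query`, `n_reference`
#'   with list-columns `query_ids`, `reference_ids`), `min_size`, and
#'   `n_isolated_query` (query nodes in no MF).
#' @export
molecular_families <- function(net, min_size = 1L) {
  stopifnot(inherits(net, "mf_network"), min_size >= 1L)
  type <- setNames(net$nodes$node_type, net$nodes$name)
  comp <- split(names(net$membership), net$membership)
  is_mf <- vapply(comp, function(members) {
    any(type[members] == "query_bgc") && any(type[members] == "reference_bgc")
  }, logical(1))
  mfs <- comp[is_mf]
  fam <- data.frame(
    mf_id = sprintf("MF%04d", seq_along(mfs)),
    n_nodes = vapply(mfs, length, numeric(1)),
    n_query = vapply(mfs, function(m) sum(type[m] == "query_bgc"),
                     numeric(1)),
    n_reference = vapply(mfs, function(m) sum(type[m] == "reference_bgc"),
                         numeric(1)),
    stringsAsFactors = FALSE)
  fam$query_ids <- lapply(mfs, function(m) sort(m[type[m] == "query_bgc"]))
  fam$reference_ids <- lapply(mfs, function(m) {
    sort(m[type[m] == "reference_bgc"])
  })
  fam <- fam[order(-fam$n_nodes, fam$mf_id), , drop = FALSE]
  rownames(fam) <- NULL
  reported <- fam[fam$n_nodes >= min_size, , drop = FALSE]
  structure(list(
    n_mfs = nrow(fam), n_mfs_reported = nrow(reported),
    n_query_in_mfs = as.integer(sum(fam$n_query)),
    n_reference_in_mfs = as.integer(sum(fam$n_reference)),
    families = reported, all_families = fam, min_size = as.integer(min_size),
    n_isolated_query = as.integer(sum(type == "query_bgc") -
                                    sum(fam$n_query))),
    class = "mf_report")
}

#' Compare molecular-family and GCF groupings
#'
#' Quantifies how the chemical-space grouping (MFs) and the BiG-SLiCE GCF
#' partition agree on which query BGCs and reference BGCs get grouped with
#' the other node type. A query BGC is "grouped" under MF when it belongs
#' to an MF; under GCF when it shares a `gcf_id` with at least one
#' reference BGC (and vice versa for references).
#'
#' @param mf_report an `mf_report`.
#' @param gcf_assignments `gcf_assignment` rows for the query BGCs.
#' @param reference_gcf_assignments `gcf_assignment` rows for the reference
#'   BGCs.
#' @return list of counts (`n_query_mf`, `n_query_gcf`, `n_query_both`,
#'   same for references, `n_shared_gcfs`) and the underlying id sets.
#' @export
compare_grouping <- function(mf_report, gcf_assignments,
                             reference_gcf_assignments) {
  stopifnot(inherits(mf_report, "mf_report"))
  qa <- as.data.frame(gcf_assignments)
  ra <- as.data.frame(reference_gcf_assignments)
  mf_query <- unique(unlist(mf_report$all_families$query_ids))
  mf_ref <- unique(unlist(mf_report$all_families$reference_ids))
  shared_gcfs <- intersect(unique(qa$gcf_id), unique(ra$gcf_id))
  gcf_query <- unique(qa$bgc_id[qa$gcf_id %in% shared_gcfs])
  gcf_ref <- unique(ra$bgc_id[ra$gcf_id %in% shared_gcfs])
  list(n_query_mf = length(mf_query), n_query_gcf = length(gcf_query),
       n_query_both = length(intersect(mf_query, gcf_query)),
       n_reference_mf = length(mf_ref), n_reference_gcf = length(gcf_ref),
       n_reference_both = length(intersect(mf_ref, gcf_ref)),
       n_shared_gcfs = length(shared_gcfs),
       query_mf = sort(mf_query), query_gcf = sort(gcf_query),
       reference_mf = sort(mf_ref), reference_gcf = sort(gcf_ref))
}

#' Network and MF-report serialization
#'
#' The network is written as an edge-list TSV (`from`, `to`, `from_type`,
#' `to_type`, `edge_type`, `weight`) plus isolated nodes with empty edge
#' fields, and optionally as GraphML via [igraph::write_graph()]. The MF
#' report is written as JSON.
#'
#' @param net an `mf_network`.
#' @param path output path.
#' @export
write_network_tsv <- function(net, path) {
  stopifnot(inherits(net, "mf_network"))
  g <- net$graph
  type <- setNames(net$nodes$node_type, net$nodes$name)
  el <- igraph::as_data_frame(g, what = "edges")
  df <- data.frame(from = el$from, to = el$to,
                   from_type = unname(type[el$from]),
                   to_type = unname(type[el$to]),
                   edge_type = el$edge_type, weight = el$weight,
                   stringsAsFactors = FALSE)
  iso <- setdiff(net$nodes$name, unique(c(el$from, el$to)))
  if (length(iso)) {
    df <- rbind(df, data.frame(from = iso, to = "", from_type = type[iso],
                               to_type = "", edge_type = "isolated",
                               weight = NA_real_, stringsAsFactors = FALSE))
  }
  write_tsv(df, path)
}

#' @rdname write_network_tsv
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "mf_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_tsv
#' @param report an `mf_report`.
#' @export
write_mf_report <- function(report, path) {
  stopifnot(inherits(report, "mf_report"))
  fam <- report$families
  jsonlite::write_json(list(
    n_mfs = report$n_mfs, n_mfs_reported = report$n_mfs_reported,
    n_query_in_mfs = report$n_query_in_mfs,
    n_reference_in_mfs = report$n_reference_in_mfs,
    min_size = report$min_size,
    n_isolated_query = report$n_isolated_query,
    families = lapply(seq_len(nrow(fam)), function(i) {
      list(mf_id = fam$mf_id[i], n_nodes = fam$n_nodes[i],
           n_query = fam$n_query[i], n_reference = fam$n_reference[i],
           query_ids = fam$query_ids[[i]],
           reference_ids = fam$reference_ids[[i]])
    })), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
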