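#' Hit tables linking query genes to reference genes
#'
#' A hit table holds KnownClusterBlast/cblaster-style homology hits: one row
#' per (region, query gene, reference cluster, reference gene) combination,
#' with the bitscore carried for provenance only. Duplicate rows are
#' dropped, which makes all downstream scores invariant to duplicated hits
#' and row order.
#'
#' @param region_id,query_locus_tag,reference_accession,reference_gene_id
#'   character vectors (recycled to a common length).
#' @param bitscore numeric vector of alignment scores (provenance only).
#' @return a `hit_table` data frame.
#' @export
hit_table <- function(region_id = character(), query_locus_tag = character(),
                      reference_accession = character(),
                      reference_gene_id = character(), bitscore = numeric()) {
  df <- data.frame(region_id = as.character(region_id),
                   query_locus_tag = as.character(query_locus_tag),
                   reference_accession = as.character(reference_accession),
                   reference_gene_id = as.character(reference_gene_id),
                   bitscore = as.numeric(bitscore),
                   stringsAsFactors = FALSE)
  key <- df[, c("region_id", "query_locus_tag", "reference_accession",
                "reference_gene_id")]
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hit_table", "data.frame")
  df
}

as_hit_table <- function(df) {
  stopifnot(is.data.frame(df))
  hit_table(df$region_id, df$query_locus_tag, df$reference_accession,
            df$reference_gene_id, df$bitscore %||% rep(0, nrow(df)))
}

#' @rdname hit_table
#' @param path TSV file with the five hit-table columns.
#' @export
read_hit_table <- function(path) {
  as_hit_table(read_tsv(path))
}

#' @rdname hit_table
#' @param hits a `hit_table`.
#' @export
write_hit_table <- function(hits, path) {
  write_tsv(as.data.frame(hits), path)
}

#' Region-to-reference similarity score
#'
#' The survey's similarity statistic for one query region against one
#' reference cluster. The numerator counts DISTINCT query genes of the
#' region with at least one hit to the reference (multiple HSPs to the same
#' gene count once). The denominator is the region's gene count
#' (`mode = "query-genes"`, the Methods equation) or the count of distinct
#' reference genes receiving hits (`mode = "reference-genes"`, the variant
#' of the worked 4/4 example). Scores are capped at 1.
#'
#' @param hits a `hit_table`.
#' @param region a `bgc_region` with at least one gene.
#' @param reference_accession reference cluster accession.
#' @param mode `"query-genes"` (default) or `"reference-genes"`.
#' @return a `similarity_score`: list with `region_id`,
#'   `reference_accession`, `score`, `numerator`, `denominator`, `mode`.
#' @export
knowncluster_similarity <- function(hits, region, reference_accession,
                                    mode = c("query-genes",
                                             "reference-genes")) {
  mode <- match.arg(mode)
  stopifnot(inherits(region, "bgc_region"))
  if (nrow(region$genes) == 0L) {
    stop(sprintf("region '%s' has no genes", region$region_id), call. = FALSE)
  }
  hits <- as_hit_table(hits)
  rel <- hits[hits$region_id == region$region_id &
                hits$reference_accession == reference_accession &
                hits$query_locus_tag %in% region$genes$locus_tag, ,
              drop = FALSE]
  num <- length(unique(rel$query_locus_tag))
  den <- switch(mode,
                "query-genes" = nrow(region$genes),
                "reference-genes" = length(unique(rel$reference_gene_id)))
  score <- if (den == 0L) 0 else min(1, num / den)
  structure(list(region_id = region$region_id,
                 reference_accession = reference_accession,
                 score = score, numerator = num, denominator = den,
                 mode = mode),
            class = "similarity_score")
}

#' Highest-scoring reference for a region
#'
#' Maximizes [knowncluster_similarity()] over all reference accessions
#' present in the hit table for the region; ties go to the
#' lexicographically smallest accession. A region with no hits gets score 0
#' and an empty accession.
#'
#' @inheritParams knowncluster_similarity
#' @return list with `reference_accession` and `score`.
#' @export
best_reference <- function(hits, region, mode = "query-genes") {
  hits <- as_hit_table(hits)
  accs <- sort(unique(hits$reference_accession[
    hits$region_id == region$region_id]))
  if (length(accs) == 0L) {
    return(list(reference_accession = "", score = 0))
  }
  scores <- vapply(accs, function(a) {
    knowncluster_similarity(hits, region, a, mode)$score
  }, numeric(1))
  best <- which.max(scores)  # first max = lexicographically smallest (sorted)
  list(reference_accession = accs[best], score = unname(scores[best]))
}

#' Thresholded genomic link table
#'
#' One row per region whose best reference scores at least `cutoff`
#' (inclusive; the survey links at 0.2); regions below the cutoff are
#' omitted. These links are the genomic edges of the molecular-family
#' network.
#'
#' @inheritParams knowncluster_similarity
#' @param regions list of `bgc_region`.
#' @param cutoff inclusive score cutoff, default 0.2.
#' @return data frame with columns `region_id`, `reference_accession`,
#'   `score`.
#' @export
link_table <- function(hits, regions, cutoff = 0.2, mode = "query-genes") {
  assert_fraction(cutoff, "cutoff")
  rows <- lapply(regions, function(r) {
    if (nrow(r$genes) == 0L) return(NULL)
    b <- best_reference(hits, r, mode)
    if (b$score >= cutoff && nzchar(b$reference_accession)) {
      data.frame(region_id = r$region_id,
                 reference_accession = b$reference_accession,
                 score = b$score, stringsAsFactors = FALSE)
    } else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(region_id = character(),
                      reference_accession = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
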