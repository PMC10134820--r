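#' MinHash genome sketch
#'
#' Builds a bottom-`s` MinHash sketch of a genome's canonical k-mers, the
#' Mash representation underlying genome-wide ANI estimation. Each k-mer is
#' replaced by the lexicographically smaller of itself and its reverse
#' complement, hashed with a fixed platform-stable 64-bit mixer (seed 42,
#' truncated to 53 bits so hashes are exact doubles), and the `s` smallest
#' distinct hash values are retained. k-mers containing `N` are skipped.
#'
#' @param genome a `genome_record` (see [generate_genome()]).
#' @param k k-mer length, between 11 and 31. Default 21, the Mash default.
#' @param s sketch size. Default 1000, the Mash default.
#' @return a `kmer_sketch`: list with `genome_id`, `k`, `s` and `hashes`
#'   (strictly increasing numeric vector, length <= `s`).
#' @examples
#' g <- generate_genome(5000, seed = 1)
#' sk <- sketch(g, k = 21, s = 500)
#' length(sk$hashes)
#' @export
sketch <- function(genome, k = 21L, s = 1000L) {
  stopifnot(inherits(genome, "genome_record"))
  k <- as.integer(k); s <- as.integer(s)
  if (is.na(k) || k < 11L || k > 31L) {
    stop("`k` must be an integer in [11, 31]", call. = FALSE)
  }
  if (is.na(s) || s < 1L) stop("`s` must be a positive integer", call. = FALSE)
  if (!any(nchar(genome$contigs$sequence) >= k)) {
    stop(sprintf("empty sketch: no contig of genome '%s' reaches length k=%d",
                 genome$genome_id, k), call. = FALSE)
  }
  hashes <- cpp_sketch_hashes(genome$contigs$sequence, k, s)
  if (length(hashes) == 0L) {
    stop(sprintf("empty sketch: genome '%s' has no valid k-mer window",
                 genome$genome_id), call. = FALSE)
  }
  structure(list(genome_id = genome$genome_id, k = k, s = s, hashes = hashes),
            class = "kmer_sketch")
}

#' Mash-style Jaccard estimate between two sketches
#'
#' Among the `s` smallest hashes of the union of the two bottom-`s` sketches,
#' the fraction present in both; an unbiased MinHash estimate of the Jaccard
#' index of the two canonical k-mer sets. When the union holds fewer than
#' `s` distinct hashes (small genomes) the estimate is exact.
#'
#' @param a,b `kmer_sketch` objects with matching `k` and `s`.
#' @return estimated Jaccard index in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  stopifnot(inherits(a, "kmer_sketch"), inherits(b, "kmer_sketch"))
  if (a$k != b$k || a$s != b$s) {
    stop("sketches must share k and s to be comparable", call. = FALSE)
  }
  u <- sort(unique(c(a$hashes, b$hashes)))
  u <- u[seq_len(min(a$s, length(u)))]
  sum(u %in% a$hashes & u %in% b$hashes) / length(u)
}

#' Mash distance from a Jaccard estimate
#'
#' `d = -(1/k) * log(2j / (1 + j))`, the Mash point estimate of per-base
#' divergence (so `1 - d` approximates ANI). Distances are capped at 1;
#' `j = 0` maps to the cap.
#'
#' @param j Jaccard estimate in \[0, 1\].
#' @param k k-mer length used for the sketches.
#' @return distance in \[0, 1\].
#' @examples
#' mash_distance(0.5, 21)  # ~0.019308
#' @export
mash_distance <- function(j, k = 21L) {
  if (!is.numeric(j) || any(is.na(j)) || any(j < 0) || any(j > 1)) {
    stop("`j` must lie in [0, 1]", call. = FALSE)
  }
  d <- ifelse(j == 0, 1, -(1 / k) * log(2 * j / (1 + j)))
  pmin(d, 1)
}

#' All-pairs Mash distance matrix
#'
#' @param sketches list of `kmer_sketch` objects with consistent `k`/`s` and
#'   unique genome ids; at least two.
#' @return a `distance_matrix`: list with `ids` and symmetric zero-diagonal
#'   matrix `D`.
#' @export
distance_matrix <- function(sketches) {
  stopifnot(is.list(sketches))
  if (length(sketches) < 2L) stop("need at least two sketches", call. = FALSE)
  ks <- vapply(sketches, function(x) x$k, numeric(1))
  ss <- vapply(sketches, function(x) x$s, numeric(1))
  if (length(unique(ks)) != 1L || length(unique(ss)) != 1L) {
    stop("all sketches must share k and s", call. = FALSE)
  }
  ids <- vapply(sketches, function(x) x$genome_id, character(1))
  if (anyDuplicated(ids)) stop("genome ids must be unique", call. = FALSE)
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (jj in (i + 1L):n) {
      d <- mash_distance(jaccard(sketches[[i]], sketches[[jj]]), ks[1])
      D[i, jj] <- d
      D[jj, i] <- d
    }
  }
  structure(list(ids = ids, D = D), class = "distance_matrix")
}

as_distance_matrix <- function(D) {
  if (inherits(D, "distance_matrix")) return(D)
  if (is.matrix(D) && !is.null(rownames(D))) {
    return(structure(list(ids = rownames(D), D = D), class = "distance_matrix"))
  }
  stop("expected a distance_matrix", call. = FALSE)
}

#' Average-linkage clustering at a distance cutoff
#'
#' Agglomerative hierarchical clustering (average linkage / UPGMA) of the
#' distance matrix, keeping every merge whose linkage distance is at most
#' `cutoff` (ties in agglomeration are resolved by [stats::hclust()]'s
#' deterministic smallest-index rule). Cluster ids are contiguous integers
#' from 0, numbered by first appearance in the input id order.
#'
#' @param D a `distance_matrix`.
#' @param cutoff non-negative linkage-distance cutoff.
#' @return a `cluster_assignment`: list with named integer vector
#'   `assignment` (genome id -> cluster id), `linkage = "average"`, `cutoff`.
#' @export
average_linkage_clusters <- function(D, cutoff) {
  D <- as_distance_matrix(D)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0) {
    stop("`cutoff` must be a non-negative number", call. = FALSE)
  }
  tree <- hclust(as.dist(D$D), method = "average")
  raw <- cutree(tree, h = cutoff)
  cl <- as.integer(match(raw, unique(raw[D$ids])) - 1L)
  structure(list(assignment = setNames(cl, D$ids), linkage = "average",
                 cutoff = cutoff),
            class = "cluster_assignment")
}

#' Dereplicate genomes at a strain-level distance cutoff
#'
#' Clusters at `cutoff` (default 0.005, i.e. >= 99.5% ANI between members of
#' a cluster) and keeps one representative per cluster: the
#' lexicographically smallest genome id.
#'
#' @inheritParams average_linkage_clusters
#' @return character vector of representative genome ids, one per cluster.
#' @export
dereplicate <- function(D, cutoff = 0.005) {
  cl <- average_linkage_clusters(D, cutoff)
  reps <- vapply(split(names(cl$assignment), cl$assignment),
                 function(ids) sort(ids)[1L], character(1))
  unname(reps)
}

#' Delineate putative species at the 96% ANI cutoff
#'
#' [average_linkage_clusters()] at a species-level cutoff, default 0.04
#' (Mash distance 4%, i.e. 96% ANI).
#'
#' @inheritParams average_linkage_clusters
#' @export
delineate_species <- function(D, cutoff = 0.04) {
  average_linkage_clusters(D, cutoff)
}

#' Sketch serialization
#'
#' Sketches are written as JSON (`genome_id`, `k`, `s`, `hashes`), distance
#' matrices as PHYLIP-like square TSV, cluster assignments as two-column TSV.
#'
#' @param x object to write.
#' @param path file path.
#' @return `path` (writers, invisibly) or the reconstructed object (readers).
#' @export
write_sketch <- function(x, path) {
  stopifnot(inherits(x, "kmer_sketch"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sketch
#' @export
read_sketch <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(genome_id = x$genome_id, k = as.integer(x$k),
                 s = as.integer(x$s), hashes = as.numeric(x$hashes)),
            class = "kmer_sketch")
}

#' @rdname write_sketch
#' @export
write_distance_matrix <- function(x, path) {
  x <- as_distance_matrix(x)
  df <- data.frame(id = x$ids, x$D, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_sketch
#' @export
read_distance_matrix <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$id
  storage.mode(m) <- "double"
  structure(list(ids = df$id, D = m), class = "distance_matrix")
}

#' @rdname write_sketch
#' @export
write_clusters <- function(x, path) {
  stopifnot(inherits(x, "cluster_assignment"))
  write_tsv(data.frame(genome_id = names(x$assignment),
                       cluster_id = unname(x$assignment)), path)
}
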