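#' GCF assignment tables
#'
#' A GCF assignment records, for one BGC, the gene cluster family it was
#' mapped to and the BiG-SLiCE-style distance `d` between the BGC and the
#' GCF centroid model. `d` is consumed, never computed, by this package.
#'
#' @param bgc_id,gcf_id,chem_class,genome_id,dataset_label character
#'   vectors (recycled).
#' @param d non-negative numeric distances.
#' @return a `gcf_assignment` data frame.
#' @export
gcf_assignment <- function(bgc_id, gcf_id, d, chem_class = NA_character_,
                           genome_id = NA_character_,
                           dataset_label = "dataset") {
  if (any(d < 0, na.rm = TRUE)) stop("`d` must be >= 0", call. = FALSE)
  df <- data.frame(bgc_id = as.character(bgc_id),
                   gcf_id = as.character(gcf_id), d = as.numeric(d),
                   chem_class = as.character(chem_class),
                   genome_id = as.character(genome_id),
                   dataset_label = as.character(dataset_label),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("bgc_id", "dataset_label")])) {
    stop("one row per bgc_id per dataset", call. = FALSE)
  }
  class(df) <- c("gcf_assignment", "data.frame")
  df
}

as_gcf_assignment <- function(df) {
  stopifnot(is.data.frame(df))
  gcf_assignment(df$bgc_id, df$gcf_id, df$d,
                 df$chem_class %||% NA_character_,
                 df$genome_id %||% NA_character_,
                 df$dataset_label %||% "dataset")
}

#' @rdname gcf_assignment
#' @param path TSV file with the `gcf_assignment` columns.
#' @export
read_gcf_table <- function(path) {
  as_gcf_assignment(read_tsv(path))
}

#' @rdname gcf_assignment
#' @param assignments a `gcf_assignment`.
#' @export
write_gcf_table <- function(assignments, path) {
  write_tsv(as.data.frame(assignments), path)
}

#' Convert a BiG-SLiCE query export to a GCF assignment table
#'
#' Ingests the tabular layout exported from a BiG-SLiCE query run (one row
#' per BGC with its assigned GCF, membership distance and chemical class;
#' the layout of the survey's supplementary spreadsheet saved as TSV).
#' Column names are matched case-insensitively against common aliases.
#'
#' @param path TSV export.
#' @param dataset_label label stamped on the resulting rows.
#' @return a `gcf_assignment`.
#' @export
read_bigslice_export <- function(path, dataset_label = "dataset") {
  df <- read_tsv(path)
  nm <- tolower(names(df))
  pick <- function(aliases, required = TRUE) {
    i <- which(nm %in% aliases)[1]
    if (is.na(i)) {
      if (required) stop(sprintf("no column matching %s in %s",
                                 paste(aliases, collapse = "/"), path),
                         call. = FALSE)
      return(NULL)
    }
    df[[i]]
  }
  gcf_assignment(
    bgc_id = pick(c("bgc_id", "bgc", "bgc_name", "region_id")),
    gcf_id = pick(c("gcf_id", "gcf", "gcf_membership")),
    d = as.numeric(pick(c("d", "dist", "distance", "membership_value",
                          "gcf_value"))),
    chem_class = pick(c("chem_class", "class", "chemclass"),
                      required = FALSE) %||% NA_character_,
    genome_id = pick(c("genome_id", "genome", "isolate"),
                     required = FALSE) %||% NA_character_,
    dataset_label = dataset_label)
}

#' Membership class from a BiG-SLiCE distance
#'
#' Strata of BGC-to-GCF distance: "core" (`d <= t_core`), "putative"
#' (`t_core < d <= t_putative`) and "orphan" (`d > t_putative`); defaults
#' 900 and 1,800, under which orphans mark the most novel BGCs.
#'
#' @param d non-negative distance(s).
#' @param t_core,t_putative stratum boundaries (inclusive on the left
#'   stratum, per the printed inequalities).
#' @return factor with ordered levels core < putative < orphan.
#' @examples
#' classify_membership(c(549, 2051))  # core, orphan
#' @export
classify_membership <- function(d, t_core = 900, t_putative = 1800) {
  if (!is.numeric(d) || any(is.na(d)) || any(d < 0)) {
    stop("`d` must be non-negative", call. = FALSE)
  }
  stopifnot(t_core < t_putative)
  cls <- ifelse(d <= t_core, "core",
                ifelse(d <= t_putative, "putative", "orphan"))
  factor(cls, levels = c("core", "putative", "orphan"), ordered = TRUE)
}

#' Membership breakdown, optionally grouped
#'
#' Counts and percentages of core/putative/orphan memberships, overall or
#' grouped by chemical class, genome taxon or source label. Percentages are
#' rounded half-up to two decimals, matching the survey's printed style
#' (e.g. 26.83%).
#'
#' @param assignments a `gcf_assignment`.
#' @param group_by one of "none", "chem_class", "genome_taxon",
#'   "source_label".
#' @param metadata for the taxon/source groupings: data frame mapping
#'   `genome_id` to `genome_taxon` / `source_label`; every genome in
#'   `assignments` must be present.
#' @param t_core,t_putative stratum boundaries (see
#'   [classify_membership()]).
#' @return data frame with columns `group`, `n`, `core`, `putative`,
#'   `orphan`, `pct_core`, `pct_putative`, `pct_orphan`.
#' @export
membership_summary <- function(assignments,
                               group_by = c("none", "chem_class",
                                            "genome_taxon", "source_label"),
                               metadata = NULL, t_core = 900,
                               t_putative = 1800) {
  group_by <- match.arg(group_by)
  a <- as.data.frame(assignments)
  key <- switch(group_by,
    none = rep("all", nrow(a)),
    chem_class = a$chem_class,
    {
      if (is.null(metadata) || !all(c("genome_id", group_by) %in%
                                      names(metadata))) {
        stop(sprintf("`metadata` with columns genome_id and %s required",
                     group_by), call. = FALSE)
      }
      i <- match(a$genome_id, metadata$genome_id)
      if (anyNA(i)) {
        stop(sprintf("no metadata for bgc(s): %s",
                     paste(head(a$bgc_id[is.na(i)], 10), collapse = ", ")),
             call. = FALSE)
      }
      metadata[[group_by]][i]
    })
  if (anyNA(key)) {
    stop(sprintf("missing grouping key for bgc(s): %s",
                 paste(head(a$bgc_id[is.na(key)], 10), collapse = ", ")),
         call. = FALSE)
  }
  cls <- classify_membership(a$d, t_core, t_putative)
  groups <- sort(unique(key))
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- cls[key == g]
    n <- length(sub)
    counts <- table(sub)
    data.frame(group = g, n = n,
               core = as.integer(counts[["core"]]),
               putative = as.integer(counts[["putative"]]),
               orphan = as.integer(counts[["orphan"]]),
               pct_core = round_half_up(100 * counts[["core"]] / n),
               pct_putative = round_half_up(100 * counts[["putative"]] / n),
               pct_orphan = round_half_up(100 * counts[["orphan"]] / n),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare GCF content across datasets
#'
#' For two or more labelled assignment tables, computes the GCF id set of
#' each dataset, the intersection size of every non-empty subset of
#' datasets (so a three-dataset comparison yields the Venn counts), the
#' fraction of each dataset's GCFs found in no other dataset, and each
#' dataset's membership distribution.
#'
#' @param assignment_sets named list of `gcf_assignment` tables (names are
#'   the dataset labels) or list of `list(label =, assignments =)` pairs.
#' @param t_core,t_putative stratum boundaries.
#' @return a `dataset_comparison`: list with `labels`, `gcf_sets`, `sizes`,
#'   `intersections` (named by "A&B" style keys), `unique_gcfs`,
#'   `unique_fraction`, `membership` (per-dataset summary rows).
#' @export
dataset_comparison <- function(assignment_sets, t_core = 900,
                               t_putative = 1800) {
  if (!is.null(names(assignment_sets)) &&
      all(nzchar(names(assignment_sets)))) {
    labels <- names(assignment_sets)
    tables <- assignment_sets
  } else {
    labels <- vapply(assignment_sets, function(x) x$label, character(1))
    tables <- lapply(assignment_sets, function(x) x$assignments)
  }
  if (length(labels) < 2L) stop("need at least two datasets", call. = FALSE)
  if (anyDuplicated(labels)) stop("duplicate dataset labels", call. = FALSE)
  sets <- lapply(tables, function(t) unique(as.data.frame(t)$gcf_id))
  names(sets) <- labels
  n <- length(labels)
  subsets <- unlist(lapply(seq_len(n), function(k) {
    combn(labels, k, simplify = FALSE)
  }), recursive = FALSE)
  intersections <- vapply(subsets, function(sub) {
    length(Reduce(intersect, sets[sub]))
  }, numeric(1))
  names(intersections) <- vapply(subsets, paste, character(1), collapse = "&")
  unique_gcfs <- lapply(labels, function(l) {
    setdiff(sets[[l]], unlist(sets[setdiff(labels, l)]))
  })
  names(unique_gcfs) <- labels
  unique_fraction <- vapply(labels, function(l) {
    if (length(sets[[l]]) == 0L) return(NA_real_)
    length(unique_gcfs[[l]]) / length(sets[[l]])
  }, numeric(1))
  membership <- do.call(rbind, lapply(labels, function(l) {
    s <- membership_summary(tables[[l]], "none", t_core = t_core,
                            t_putative = t_putative)
    s$group <- l
    s
  }))
  structure(list(labels = labels, gcf_sets = sets,
                 sizes = vapply(sets, length, numeric(1)),
                 intersections = intersections, unique_gcfs = unique_gcfs,
                 unique_fraction = unique_fraction, membership = membership),
            class = "dataset_comparison")
}

#' @rdname dataset_comparison
#' @param x a `dataset_comparison`.
#' @param path output JSON path for the Venn counts.
#' @export
write_venn_json <- function(x, path) {
  stopifnot(inherits(x, "dataset_comparison"))
  jsonlite::write_json(list(sizes = as.list(x$sizes),
                            intersections = as.list(x$intersections),
                            unique_fraction = as.list(x$unique_fraction)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Most prevalent GCFs
#'
#' Ranks GCFs by the number of distinct genomes contributing at least one
#' member BGC (ties broken lexicographically by GCF id) and returns the top
#' `top_n` with their member distance values.
#'
#' @param assignments a `gcf_assignment` with `genome_id` populated.
#' @param top_n number of GCFs to return (default 5); if larger than the
#'   number of GCFs, the full ranking is returned.
#' @return data frame with columns `gcf_id`, `n_genomes`, `n_bgcs` and a
#'   list-column `d_values`.
#' @export
prevalent_gcfs <- function(assignments, top_n = 5L) {
  if (!is.numeric(top_n) || top_n < 1L) {
    stop("`top_n` must be a positive integer", call. = FALSE)
  }
  a <- as.data.frame(assignments)
  if (all(is.na(a$genome_id))) stop("`genome_id` must be populated",
                                    call. = FALSE)
  by_gcf <- split(a, a$gcf_id)
  out <- data.frame(
    gcf_id = names(by_gcf),
    n_genomes = vapply(by_gcf, function(s) length(unique(s$genome_id)),
                       numeric(1)),
    n_bgcs = vapply(by_gcf, nrow, numeric(1)),
    stringsAsFactors = FALSE)
  out$d_values <- lapply(by_gcf, function(s) sort(s$d))
  out <- out[order(-out$n_genomes, out$gcf_id), , drop = FALSE]
  rownames(out) <- NULL
  head(out, n = min(nrow(out), as.integer(top_n)))
}
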