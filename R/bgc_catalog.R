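#' BGC region records
#'
#' A `bgc_region` mirrors one antiSMASH-style region: genomic coordinates
#' (0-based, half-open throughout the package), one or more product types
#' from the antiSMASH vocabulary, the contig-edge flag marking potentially
#' truncated clusters, and a gene table. `contig_length` is carried so the
#' catalogue can enforce the rule that only contigs longer than 5,000 bp
#' were processed.
#'
#' @param region_id,genome_id,contig_id identifiers.
#' @param start,end region coordinates, 0-based half-open, `end > start`.
#' @param products non-empty character vector of product types
#'   (e.g. "NRPS", "T1PKS", "lanthipeptide").
#' @param on_contig_edge logical; `TRUE` marks a region truncated by an
#'   assembly break (incomplete).
#' @param genes data frame with columns `locus_tag`, `start`, `end`,
#'   `strand` (+1/-1), `role_label`; coordinates within `[start, end)`.
#' @param contig_length length of the host contig in bp (`NA` if unknown).
#' @return a `bgc_region` object.
#' @export
bgc_region <- function(region_id, genome_id, contig_id, start, end,
                       products, on_contig_edge = FALSE,
                       genes = empty_gene_table(), contig_length = NA_real_) {
  if (!is.numeric(start) || !is.numeric(end) || end <= start || start < 0) {
    stop("need 0 <= start < end", call. = FALSE)
  }
  products <- as.character(products)
  if (length(products) == 0L) stop("`products` must be non-empty", call. = FALSE)
  stopifnot(is.data.frame(genes),
            all(c("locus_tag", "start", "end", "strand", "role_label")
                %in% names(genes)))
  if (anyDuplicated(genes$locus_tag)) {
    stop("locus tags must be unique within a region", call. = FALSE)
  }
  if (nrow(genes) &&
      (any(genes$start < start) || any(genes$end > end) ||
       any(genes$end <= genes$start))) {
    stop("genes must lie within [start, end) with end > start", call. = FALSE)
  }
  structure(list(region_id = region_id, genome_id = genome_id,
                 contig_id = contig_id, start = as.numeric(start),
                 end = as.numeric(end), products = products,
                 on_contig_edge = isTRUE(on_contig_edge), genes = genes,
                 contig_length = as.numeric(contig_length)),
            class = "bgc_region")
}

empty_gene_table <- function() {
  data.frame(locus_tag = character(), start = numeric(), end = numeric(),
             strand = integer(), role_label = character(),
             stringsAsFactors = FALSE)
}

#' antiSMASH product-type to chemical-class table
#'
#' The packaged mapping of antiSMASH product types (subclasses) to the seven
#' reporting classes (NRP, Polyketide, RiPP, Terpene, Saccharide, Other,
#' plus "hybrid" for multi-class regions), together with the survey counts
#' used as default sampling weights by [generate_bgc_collection()].
#'
#' @return data frame with columns `product`, `class`, `weight`.
#' @export
product_class_table <- function() {
  tab <- list(
    NRP        = c(CDPS = 14, NRPS = 1305, "NRPS-like" = 295),
    Polyketide = c("PKS-like" = 36, T1PKS = 852, T2PKS = 158, T3PKS = 351,
                   "hglE-KS" = 24, "transAT-PKS" = 5, "transAT-PKS-like" = 4),
    RiPP       = c(LAP = 37, "TfuA-related" = 14, bacteriocin = 481,
                   lanthipeptide = 355, lassopeptide = 151, linaridin = 62,
                   thiopeptide = 8),
    Saccharide = c(amglyccycl = 2, oligosaccharide = 6),
    Terpene    = c(terpene = 1129),
    Other      = c(NAGGN = 1, arylpolyene = 12, betalactone = 85,
                   blactam = 18, butyrolactone = 273, ectoine = 290,
                   furan = 5, fused = 4, hserlactone = 1, indole = 21,
                   ladderane = 8, melanin = 220, nucleoside = 16, other = 69,
                   phenazine = 12, phosphonate = 5, siderophore = 481))
  do.call(rbind, lapply(names(tab), function(cl) {
    data.frame(product = names(tab[[cl]]), class = cl,
               weight = unname(tab[[cl]]), stringsAsFactors = FALSE)
  }))
}

#' Chemical class of a region from its product types
#'
#' Single product types map through [product_class_table()]; a region
#' carrying two or more product types from different classes is "hybrid",
#' while multiple types within one class keep that class. Unknown product
#' types are classed "Other" with a warning. Matching is case-insensitive
#' and order-invariant.
#'
#' @param products character vector of product types (non-empty).
#' @return single class string.
#' @examples
#' classify_region("NRPS")              # "NRP"
#' classify_region(c("T1PKS", "NRPS"))  # "hybrid"
#' @export
classify_region <- function(products) {
  if (inherits(products, "bgc_region")) products <- products$products
  products <- unique(as.character(products))
  if (length(products) == 0L) stop("`products` must be non-empty", call. = FALSE)
  map <- product_class_table()
  idx <- match(tolower(products), tolower(map$product))
  if (anyNA(idx)) {
    warning(sprintf("unknown product type(s) %s classified as Other",
                    paste(sQuote(products[is.na(idx)]), collapse = ", ")),
            call. = FALSE)
  }
  classes <- unique(ifelse(is.na(idx), "Other", map$class[idx]))
  if (length(classes) > 1L) "hybrid" else classes
}

bgc_classes <- function() {
  c("NRP", "Polyketide", "RiPP", "Terpene", "Saccharide", "Other", "hybrid")
}

#' Read and write region records (region-JSON dialect)
#'
#' The dialect is a flat JSON array of records with the `bgc_region` fields
#' (`region_id`, `genome_id`, `contig_id`, `start`, `end`, `products`,
#' `on_contig_edge`, `contig_length`, `genes`). On load, regions sitting on
#' contigs of 5,000 bp or shorter are dropped — mirroring that the upstream
#' annotation only processed sequences larger than 5,000 bp — and the number
#' of exclusions is reported via `message()`.
#'
#' @param path JSON file in the dialect above.
#' @param contig_min_bp minimum contig length (exclusive) for a region to be
#'   retained; default 5000. Regions with unknown contig length are kept.
#' @return `load_regions()`: list of `bgc_region`; `write_regions()`: `path`.
#' @export
load_regions <- function(path, contig_min_bp = 5000) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  regions <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    ok <- tryCatch({
      genes <- if (length(r$genes)) {
        do.call(rbind, lapply(r$genes, function(g) {
          data.frame(locus_tag = g$locus_tag, start = as.numeric(g$start),
                     end = as.numeric(g$end), strand = as.integer(g$strand),
                     role_label = g$role_label, stringsAsFactors = FALSE)
        }))
      } else empty_gene_table()
      bgc_region(r$region_id, r$genome_id, r$contig_id, r$start, r$end,
                 unlist(r$products), isTRUE(r$on_contig_edge), genes,
                 if (is.null(r$contig_length)) NA_real_ else r$contig_length)
    }, error = function(e) e)
    if (inherits(ok, "error")) {
      stop(sprintf("malformed region record %d (%s): %s", i,
                   if (is.null(recs[[i]]$region_id)) "<no id>"
                   else recs[[i]]$region_id,
                   conditionMessage(ok)), call. = FALSE)
    }
    ok
  })
  keep <- vapply(regions, function(r) {
    is.na(r$contig_length) || r$contig_length > contig_min_bp
  }, logical(1))
  if (any(!keep)) {
    message(sprintf("excluded %d region(s) on contigs <= %d bp",
                    sum(!keep), contig_min_bp))
  }
  regions[keep]
}

#' @rdname load_regions
#' @param regions list of `bgc_region`.
#' @export
write_regions <- function(regions, path) {
  recs <- lapply(regions, function(r) {
    g <- r$genes
    list(region_id = r$region_id, genome_id = r$genome_id,
         contig_id = r$contig_id, start = r$start, end = r$end,
         products = as.list(r$products), on_contig_edge = r$on_contig_edge,
         contig_length = r$contig_length,
         genes = lapply(seq_len(nrow(g)), function(i) {
           list(locus_tag = g$locus_tag[i], start = g$start[i],
                end = g$end[i], strand = g$strand[i],
                role_label = g$role_label[i])
         }))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Reader for genuine antiSMASH 5 region JSON
#'
#' Best-effort extraction from an antiSMASH 5 result file: for each record
#' (contig), every `region` feature yields a `bgc_region` with its
#' `contig_edge` and `product` qualifiers, and the CDS features inside the
#' region become gene stubs. antiSMASH locations (`[start:end]`, 0-based
#' half-open) are kept as-is.
#'
#' @param path antiSMASH 5 JSON result file.
#' @param genome_id genome identifier to stamp on the regions (default: the
#'   file's `input_file` field, else the file name).
#' @return list of `bgc_region`.
#' @export
read_antismash_regions <- function(path, genome_id = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(genome_id)) {
    genome_id <- if (!is.null(doc$input_file)) doc$input_file
                 else basename(path)
  }
  parse_loc <- function(loc) {
    m <- regmatches(loc, regexec("\\[(\\d+):(\\d+)\\](\\(([+-])\\))?", loc))[[1]]
    if (length(m) < 3L) stop(sprintf("cannot parse location '%s'", loc),
                             call. = FALSE)
    list(start = as.numeric(m[2]), end = as.numeric(m[3]),
         strand = if (identical(m[5], "-")) -1L else 1L)
  }
  out <- list()
  for (rec in doc$records) {
    contig_id <- rec$id
    contig_len <- nchar(rec$seq$data %||% "")
    feats <- rec$features
    is_type <- function(t) vapply(feats, function(f) identical(f$type, t),
                                  logical(1))
    for (f in feats[is_type("region")]) {
      loc <- parse_loc(f$location)
      q <- f$qualifiers
      number <- if (!is.null(q$region_number)) unlist(q$region_number)[1] else
        length(out) + 1L
      genes <- list()
      for (cds in feats[is_type("CDS")]) {
        gl <- parse_loc(cds$location)
        if (gl$start >= loc$start && gl$end <= loc$end) {
          tag <- unlist(cds$qualifiers$locus_tag %||%
                          cds$qualifiers$gene %||% "cds")[1]
          genes[[length(genes) + 1L]] <- data.frame(
            locus_tag = tag, start = gl$start, end = gl$end,
            strand = gl$strand, role_label = "CDS", stringsAsFactors = FALSE)
        }
      }
      genes <- if (length(genes)) do.call(rbind, genes) else empty_gene_table()
      genes$locus_tag <- make.unique(genes$locus_tag)
      out[[length(out) + 1L]] <- bgc_region(
        region_id = sprintf("%s_r%s", contig_id, number),
        genome_id = genome_id, contig_id = contig_id,
        start = loc$start, end = loc$end,
        products = unlist(q$product),
        on_contig_edge = identical(tolower(unlist(q$contig_edge)[1]), "true"),
        genes = genes,
        contig_length = if (contig_len > 0) contig_len else NA_real_)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Completeness summary by chemical class
#'
#' Counts regions per chemical class, split into complete
#' (`on_contig_edge = FALSE`) and incomplete (`TRUE`).
#'
#' @param regions list of `bgc_region`.
#' @return a `class_summary`: list with `by_class` (data frame `class`,
#'   `total`, `complete`, `incomplete`) and `overall` (totals plus
#'   `incomplete_fraction`).
#' @export
completeness_summary <- function(regions) {
  cls <- vapply(regions, function(r) classify_region(r$products), character(1))
  edge <- vapply(regions, function(r) r$on_contig_edge, logical(1))
  lev <- bgc_classes()
  by_class <- data.frame(
    class = lev,
    total = as.integer(table(factor(cls, lev))),
    complete = as.integer(table(factor(cls[!edge], lev))),
    stringsAsFactors = FALSE)
  by_class$incomplete <- by_class$total - by_class$complete
  structure(list(
    by_class = by_class,
    overall = list(total = length(regions), complete = sum(!edge),
                   incomplete = sum(edge),
                   incomplete_fraction = if (length(regions))
                     sum(edge) / length(regions) else NA_real_)),
    class = "class_summary")
}

#' Region length statistics
#'
#' Mean and maximum region length in kb (rounded to one decimal, the
#' reporting convention of the survey) plus the id of the longest region.
#'
#' @param regions non-empty list of `bgc_region`.
#' @return list with `mean_kb`, `max_kb`, `argmax_region_id`.
#' @export
length_stats <- function(regions) {
  if (length(regions) == 0L) stop("`regions` must be non-empty", call. = FALSE)
  len <- vapply(regions, function(r) r$end - r$start, numeric(1))
  ids <- vapply(regions, function(r) r$region_id, character(1))
  list(mean_kb = round_half_up(mean(len) / 1000, 1L),
       max_kb = round_half_up(max(len) / 1000, 1L),
       argmax_region_id = ids[which.max(len)])
}

#' @rdname completeness_summary
#' @param x a `class_summary`.
#' @param path output TSV path.
#' @export
write_class_summary <- function(x, path) {
  stopifnot(inherits(x, "class_summary"))
  write_tsv(x$by_class, path)
}
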