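#' Packaged scaffold SMILES templates
#'
#' Twenty-four small drug-like molecules (written without stereo markers)
#' used as molecular-family scaffolds by [generate_reference_library()].
#' Each template's first atom can accept one extra substituent bond, so
#' family members can be derived by prefixing a short alkyl/heteroalkyl
#' decoration.
#'
#' @return named character vector of SMILES strings.
#' @export
scaffold_smiles <- function() {
  c(acetylsalicylic_acid = "CC(=O)Oc1ccccc1C(=O)O",
    caffeine             = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    acetaminophen        = "CC(=O)Nc1ccc(O)cc1",
    ibuprofen            = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    naproxen             = "COc1ccc2cc(ccc2c1)C(C)C(=O)O",
    salbutamol           = "CC(C)(C)NCC(O)c1ccc(O)c(CO)c1",
    nicotine             = "CN1CCCC1c1cccnc1",
    benzocaine           = "CCOC(=O)c1ccc(N)cc1",
    procaine             = "CCN(CC)CCOC(=O)c1ccc(N)cc1",
    lidocaine            = "CCN(CC)CC(=O)Nc1c(C)cccc1C",
    sulfanilamide        = "Nc1ccc(cc1)S(=O)(=O)N",
    isoniazid            = "NNC(=O)c1ccncc1",
    coumarin             = "c1ccc2c(c1)C=CC(=O)O2",
    phenobarbital        = "CCC1(c2ccccc2)C(=O)NC(=O)NC1=O",
    theobromine          = "Cn1cnc2c1c(=O)[nH]c(=O)n2C",
    vanillin             = "COc1cc(C=O)ccc1O",
    cinnamic_acid        = "OC(=O)C=Cc1ccccc1",
    serotonin            = "NCCc1c[nH]c2ccccc12",
    dopamine             = "NCCc1ccc(O)c(O)c1",
    tryptophan           = "NC(Cc1c[nH]c2ccccc12)C(=O)O",
    menthol              = "CC(C)C1CCC(C)CC1O",
    camphor              = "CC1(C)C2CCC1(C)C(=O)C2",
    nicotinamide         = "NC(=O)c1ccncc1",
    eugenol              = "C(C=C)c1ccc(O)c(OC)c1")
}

# substituents prefixed to a scaffold to derive within-family congeners;
# the last chain atom of the prefix bonds the scaffold's first atom
decoration_prefixes <- function() {
  c("", "C", "CC", "CCC", "OC", "NC", "OCC", "CCCC", "NCC", "OCCC",
    "CCCCC", "NCCC")
}

#' Simulated antiSMASH-style BGC collection
#'
#' Draws `n_regions` BGC regions spread over synthetic genomes: product
#' types sampled from `class_weights`, hybrid regions (two distinct product
#' types) emitted with probability `hybrid_prob`, contig-edge flags set
#' with probability `edge_fraction`, region lengths uniform on
#' `length_range` (default 5-60 kb, bracketing the survey's 31.9 kb mean)
#' and gene stubs tiled every ~1.5 kb.
#'
#' @param n_regions number of regions.
#' @param class_weights named numeric vector of sampling weights over
#'   product types, summing to 1 (within 1e-9). Default: the packaged
#'   survey distribution of non-hybrid product types
#'   ([product_class_table()]).
#' @param edge_fraction expected fraction of regions flagged on a contig
#'   edge; default 0.372, the survey's observed rate.
#' @param seed integer seed.
#' @param hybrid_prob probability that a region carries two sampled product
#'   types; default 0.2 (the survey: 1,731 of 8,541 multi-type regions).
#' @param regions_per_genome mean regions per synthetic genome (default 26,
#'   survey-like).
#' @param length_range region length range in bp.
#' @return list of `bgc_region`.
#' @export
generate_bgc_collection <- function(n_regions, class_weights = NULL,
                                    edge_fraction = 0.372, seed = 1L,
                                    hybrid_prob = 0.2,
                                    regions_per_genome = 26,
                                    length_range = c(5000, 60000)) {
  stopifnot(n_regions >= 1)
  assert_fraction(edge_fraction, "edge_fraction")
  assert_fraction(hybrid_prob, "hybrid_prob")
  if (is.null(class_weights)) {
    tab <- product_class_table()
    class_weights <- setNames(tab$weight / sum(tab$weight), tab$product)
  }
  if (any(class_weights < 0)) {
    stop("`class_weights` must be non-negative", call. = FALSE)
  }
  if (abs(sum(class_weights) - 1) > 1e-9) {
    stop("`class_weights` must sum to 1 (within 1e-9)", call. = FALSE)
  }
  types <- names(class_weights)
  if (is.null(types)) stop("`class_weights` must be named by product type",
                           call. = FALSE)
  with_seed(seed, {
    n_genomes <- max(1L, round(n_regions / regions_per_genome))
    genome_of <- sort(sample.int(n_genomes, n_regions, replace = TRUE))
    counter <- integer(n_genomes)
    lapply(seq_len(n_regions), function(i) {
      gi <- genome_of[i]
      counter[gi] <<- counter[gi] + 1L
      genome_id <- sprintf("G%03d", gi)
      len <- round(runif(1, length_range[1], length_range[2]))
      start <- round(runif(1, 0, 5000))
      contig_length <- start + len + round(runif(1, 1000, 40000))
      hybrid <- runif(1) < hybrid_prob && length(types) > 1L
      prods <- unique(sample(types, if (hybrid) 2L else 1L,
                             replace = FALSE, prob = class_weights))
      n_genes <- max(3L, round(len / 1500))
      bounds <- round(seq(start, start + len, length.out = n_genes + 1L))
      genes <- data.frame(
        locus_tag = sprintf("%s_r%dc1_g%02d", genome_id, counter[gi],
                            seq_len(n_genes)),
        start = bounds[-length(bounds)],
        end = pmax(bounds[-1L] - 50, bounds[-length(bounds)] + 1),
        strand = sample(c(1L, -1L), n_genes, replace = TRUE),
        role_label = sample(c("biosynthetic", "transport", "regulatory",
                              "tailoring", "other"), n_genes, replace = TRUE),
        stringsAsFactors = FALSE)
      bgc_region(region_id = sprintf("%s_r%dc1", genome_id, counter[gi]),
                 genome_id = genome_id,
                 contig_id = sprintf("%s_c%d", genome_id, counter[gi]),
                 start = start, end = start + len, products = prods,
                 on_contig_edge = runif(1) < edge_fraction,
                 genes = genes, contig_length = contig_length)
    })
  })
}

#' Simulated reference BGC library with planted compound families
#'
#' Builds `n_families` molecular families, each around one scaffold from
#' the packaged template list ([scaffold_smiles()]); within-family members
#' are small decorations of the scaffold. The planted chemistry is verified
#' at generation time with the package's own fingerprints: every
#' within-family compound pair must reach Tanimoto `threshold` and every
#' between-family pair must stay below it; scaffolds violating this against
#' already-accepted families are discarded and the next template is tried.
#' Exhausting the template list is an error.
#'
#' @param n_families,refs_per_family library dimensions (positive;
#'   `refs_per_family` at most 12, the number of packaged decorations).
#' @param seed integer seed (gene stubs and taxon labels only; chemistry is
#'   deterministic given the template list).
#' @param threshold the Tanimoto threshold the planted structure is
#'   verified against (default 0.5).
#' @return list of `reference_bgc` with attribute `family_truth`: data
#'   frame `accession`, `family_id`, `scaffold`, `compound`.
#' @export
generate_reference_library <- function(n_families, refs_per_family,
                                       seed = 1L, threshold = 0.5) {
  if (n_families < 1 || refs_per_family < 1) {
    stop("`n_families` and `refs_per_family` must be positive", call. = FALSE)
  }
  prefixes <- decoration_prefixes()
  if (refs_per_family > length(prefixes)) {
    stop(sprintf("at most %d references per family are supported",
                 length(prefixes)), call. = FALSE)
  }
  templates <- scaffold_smiles()
  accepted <- list()  # per family: list(name, compounds, fps)
  t_idx <- 0L
  while (length(accepted) < n_families) {
    t_idx <- t_idx + 1L
    if (t_idx > length(templates)) {
      stop("scaffold template list exhausted before planting all families",
           call. = FALSE)
    }
    scaffold <- templates[[t_idx]]
    compounds <- paste0(prefixes[seq_len(refs_per_family)], scaffold)
    fps <- lapply(compounds, function(s) {
      tryCatch(morgan_fingerprint(s), error = function(e) NULL)
    })
    if (any(vapply(fps, is.null, logical(1)))) next
    within_ok <- TRUE
    if (refs_per_family > 1L) {
      for (i in seq_len(refs_per_family - 1L)) {
        for (j in (i + 1L):refs_per_family) {
          if (tanimoto(fps[[i]], fps[[j]]) < threshold) within_ok <- FALSE
        }
      }
    }
    if (!within_ok) next
    between_ok <- all(vapply(accepted, function(fam) {
      all(vapply(fps, function(fa) {
        all(vapply(fam$fps, function(fb) tanimoto(fa, fb) < threshold,
                   logical(1)))
      }, logical(1)))
    }, logical(1)))
    if (!between_ok) next
    accepted[[length(accepted) + 1L]] <- list(
      name = names(templates)[t_idx], compounds = compounds, fps = fps)
  }
  with_seed(seed, {
    refs <- list()
    truth <- list()
    acc_i <- 0L
    for (f in seq_along(accepted)) {
      fam <- accepted[[f]]
      for (m in seq_len(refs_per_family)) {
        acc_i <- acc_i + 1L
        accession <- sprintf("BGC%07d", acc_i)
        n_genes <- sample(4:10, 1L)
        bounds <- round(seq(0, n_genes * 1500, length.out = n_genes + 1L))
        genes <- data.frame(
          locus_tag = sprintf("%s_g%02d", accession, seq_len(n_genes)),
          start = bounds[-length(bounds)], end = bounds[-1L] - 50,
          strand = sample(c(1L, -1L), n_genes, replace = TRUE),
          role_label = "biosynthetic", stringsAsFactors = FALSE)
        refs[[accession]] <- reference_bgc(
          accession, genes, fam$compounds[m],
          taxon_label = sample(c("Streptomyces", "Amycolatopsis",
                                 "Nocardia", "Micromonospora"), 1L))
        truth[[accession]] <- data.frame(
          accession = accession, family_id = sprintf("FAM%02d", f),
          scaffold = fam$name, compound = fam$compounds[m],
          stringsAsFactors = FALSE)
      }
    }
    structure(unname(refs), family_truth = do.call(rbind, unname(truth)))
  })
}

#' Simulated KnownClusterBlast-style hit table
#'
#' For every planted link `region_id -> (accession, score)`, exactly
#' `score * n_genes` distinct query genes (the score must be realizable,
#' i.e. `score * n_genes` integral) receive hits to genes of the named
#' reference, so [knowncluster_similarity()] in query-genes mode recovers
#' the planted score exactly. `noise_links` additional random region-
#' reference pairs receive hits covering strictly less than 20% of the
#' region's genes, so they never survive the 0.2 link cutoff.
#'
#' @param regions list of `bgc_region`.
#' @param refs list of `reference_bgc`.
#' @param planted_links named list: `region_id = list(accession =, score =)`.
#' @param noise_links number of sub-threshold noise links to add.
#' @param seed integer seed.
#' @return a `hit_table`.
#' @export
generate_hit_table <- function(regions, refs, planted_links = list(),
                               noise_links = 0L, seed = 1L) {
  region_by_id <- setNames(regions,
                           vapply(regions, function(r) r$region_id,
                                  character(1)))
  ref_by_acc <- setNames(refs,
                         vapply(refs, function(r) r$accession, character(1)))
  rows <- list()
  add_hits <- function(region, ref, n_query_genes) {
    if (n_query_genes == 0L) return()
    q <- region$genes$locus_tag[seq_len(n_query_genes)]
    rg <- ref$genes$locus_tag
    if (length(rg) == 0L) rg <- paste0(ref$accession, "_g01")
    rows[[length(rows) + 1L]] <<- data.frame(
      region_id = region$region_id, query_locus_tag = q,
      reference_accession = ref$accession,
      reference_gene_id = rep(rg, length.out = n_query_genes),
      bitscore = round(runif(n_query_genes, 50, 500), 1),
      stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    for (rid in names(planted_links)) {
      link <- planted_links[[rid]]
      region <- region_by_id[[rid]]
      if (is.null(region)) stop(sprintf("unknown region '%s'", rid),
                                call. = FALSE)
      ref <- ref_by_acc[[link$accession]]
      if (is.null(ref)) stop(sprintf("unknown reference '%s'",
                                     link$accession), call. = FALSE)
      score <- link$score
      assert_fraction(score, "score")
      n <- nrow(region$genes)
      k <- score * n
      if (abs(k - round(k)) > 1e-9) {
        stop(sprintf(
          "score %.4f is not realizable on the %d genes of region '%s'",
          score, n, rid), call. = FALSE)
      }
      add_hits(region, ref, as.integer(round(k)))
    }
    if (noise_links > 0L && length(regions) && length(refs)) {
      for (i in seq_len(noise_links)) {
        region <- region_by_id[[sample(names(region_by_id), 1L)]]
        planted_acc <- planted_links[[region$region_id]]$accession
        free <- setdiff(names(ref_by_acc), planted_acc)
        if (length(free) == 0L) next
        ref <- ref_by_acc[[sample(free, 1L)]]
        n <- nrow(region$genes)
        max_hits <- max(0L, as.integer(ceiling(0.2 * n) - 1L))
        add_hits(region, ref, sample(0:max_hits, 1L))
      }
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(out)) return(hit_table())
  as_hit_table(out)
}

#' Simulated BiG-SLiCE-style GCF assignment table
#'
#' Each BGC id is assigned a membership stratum by a multinomial draw over
#' `fractions` and a distance `d` uniform on the stratum's range
#' (`[0, t_core]`, `(t_core, t_putative]`, `(t_putative, d_max]`), a GCF id
#' from a pool, and a chemical class drawn from the survey's class
#' proportions.
#'
#' @param region_ids character vector of BGC ids.
#' @param fractions numeric length-3 vector `(core, putative, orphan)`
#'   summing to 1 within 1e-9; default the survey's observed fractions
#'   (5,146 / 3,073 / 322 of 8,541).
#' @param seed integer seed.
#' @param n_gcfs size of the GCF id pool (default `ceiling(n / 8)`,
#'   survey-like).
#' @param t_core,t_putative,d_max stratum boundaries.
#' @param genome_ids genome id per BGC; default: everything before the
#'   final `_r` of the BGC id.
#' @param dataset_label dataset label stamped on the rows.
#' @return a `gcf_assignment` with attribute `membership_truth` (the drawn
#'   stratum per BGC).
#' @export
generate_gcf_table <- function(region_ids,
                               fractions = c(core = 5146, putative = 3073,
                                             orphan = 322) / 8541,
                               seed = 1L, n_gcfs = NULL,
                               t_core = 900, t_putative = 1800, d_max = 3000,
                               genome_ids = NULL,
                               dataset_label = "dataset") {
  n <- length(region_ids)
  stopifnot(n >= 1)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must be three non-negative values summing to 1",
         call. = FALSE)
  }
  if (is.null(genome_ids)) genome_ids <- sub("_r[0-9]+.*$", "", region_ids)
  if (is.null(n_gcfs)) n_gcfs <- max(1L, ceiling(n / 8))
  class_weights <- c(Polyketide = 2193, Other = 1807, NRP = 1621,
                     RiPP = 1539, Terpene = 1340, Saccharide = 41)
  with_seed(seed, {
    stratum <- sample(c("core", "putative", "orphan"), n, replace = TRUE,
                      prob = fractions)
    d <- numeric(n)
    d[stratum == "core"] <- runif(sum(stratum == "core"), 0, t_core)
    d[stratum == "putative"] <- runif(sum(stratum == "putative"),
                                      t_core + 1e-6, t_putative)
    d[stratum == "orphan"] <- runif(sum(stratum == "orphan"),
                                    t_putative + 1e-6, d_max)
    out <- gcf_assignment(
      bgc_id = region_ids,
      gcf_id = sprintf("GCF_%06d", sample.int(n_gcfs, n, replace = TRUE)),
      d = d,
      chem_class = sample(names(class_weights), n, replace = TRUE,
                          prob = class_weights),
      genome_id = genome_ids, dataset_label = dataset_label)
    structure(out, membership_truth = setNames(stratum, region_ids))
  })
}
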