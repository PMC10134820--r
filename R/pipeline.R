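#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one validated
#' object. Defaults are the survey's stated parameters: sketching k = 21 /
#' s = 1000 (Mash defaults), dereplication at Mash distance 0.005 (99.5%
#' ANI), species delineation at 0.04 (96% ANI), the 5,000 bp contig rule,
#' genomic links at similarity 0.2, chemical edges at Tanimoto 0.5 with
#' radius-2 2048-bit fingerprints, membership strata at d = 900 / 1,800,
#' and the size-6 molecular-family display filter.
#'
#' @param k,s sketch parameters.
#' @param derep_cutoff,species_cutoff clustering cutoffs (Mash distance).
#' @param contig_min_bp minimum contig length (exclusive).
#' @param link_cutoff similarity cutoff for genomic links.
#' @param tanimoto_threshold chemical edge threshold.
#' @param fp_radius,fp_bits fingerprint parameters.
#' @param t_core,t_putative membership boundaries.
#' @param mf_min_size display filter for reported molecular families.
#' @param seed master seed; all stage randomness derives from it.
#' @param sim simulation-scale parameters for the `simulate` stage: a list
#'   with `n_species`, `strains_per_species`, `genome_length`,
#'   `within_rate`, `between_rate`, `n_regions`, `n_families`,
#'   `refs_per_family`, `n_planted_links`, `noise_links`.
#' @return a validated `pipeline_config` (list).
#' @export
pipeline_config <- function(k = 21L, s = 1000L, derep_cutoff = 0.005,
                            species_cutoff = 0.04, contig_min_bp = 5000,
                            link_cutoff = 0.2, tanimoto_threshold = 0.5,
                            fp_radius = 2L, fp_bits = 2048L, t_core = 900,
                            t_putative = 1800, mf_min_size = 6L, seed = 1L,
                            sim = list()) {
  sim_defaults <- list(n_species = 3L, strains_per_species = 3L,
                       genome_length = 60000L, within_rate = 0.005,
                       between_rate = 0.08, n_regions = 120L,
                       n_families = 4L, refs_per_family = 3L,
                       n_planted_links = 30L, noise_links = 40L)
  sim <- utils::modifyList(sim_defaults, sim)
  cfg <- list(k = as.integer(k), s = as.integer(s),
              derep_cutoff = derep_cutoff, species_cutoff = species_cutoff,
              contig_min_bp = contig_min_bp, link_cutoff = link_cutoff,
              tanimoto_threshold = tanimoto_threshold,
              fp_radius = as.integer(fp_radius),
              fp_bits = as.integer(fp_bits), t_core = t_core,
              t_putative = t_putative, mf_min_size = as.integer(mf_min_size),
              seed = as.integer(seed), sim = sim)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  check <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid config field `%s`: %s", field, msg),
                  call. = FALSE)
  }
  check(cfg$k >= 11 && cfg$k <= 31, "k", "must be in [11, 31]")
  check(cfg$s >= 1, "s", "must be positive")
  check(cfg$derep_cutoff >= 0 && cfg$derep_cutoff <= 1, "derep_cutoff",
        "must be in [0, 1]")
  check(cfg$species_cutoff >= 0 && cfg$species_cutoff <= 1, "species_cutoff",
        "must be in [0, 1]")
  check(cfg$contig_min_bp >= 0, "contig_min_bp", "must be non-negative")
  check(cfg$link_cutoff >= 0 && cfg$link_cutoff <= 1, "link_cutoff",
        "must be in [0, 1]")
  check(cfg$tanimoto_threshold >= 0 && cfg$tanimoto_threshold <= 1,
        "tanimoto_threshold", "must be in [0, 1]")
  check(cfg$fp_radius >= 0, "fp_radius", "must be non-negative")
  check(cfg$fp_bits >= 2, "fp_bits", "must be at least 2")
  check(cfg$t_core >= 0 && cfg$t_core < cfg$t_putative, "t_core",
        "need 0 <= t_core < t_putative")
  check(cfg$mf_min_size >= 1, "mf_min_size", "must be at least 1")
  check(is.integer(cfg$seed) && !is.na(cfg$seed), "seed",
        "must be an integer")
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @return `config_hash()`: stable hash string of the configuration.
#' @export
config_hash <- function(cfg) {
  ser <- paste(deparse(unclass(cfg), control = "all"), collapse = "")
  sprintf("%013.0f", cpp_hash_string(ser))
}

stage_names <- function() {
  c("simulate", "sketch", "derep", "species", "catalog", "link",
    "membership", "compare-datasets", "molfam", "compare-grouping", "all")
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

write_manifest <- function(stage, cfg, out_dir, outputs, elapsed) {
  jsonlite::write_json(
    list(stage = stage, config = unclass(cfg), config_hash = config_hash(cfg),
         seed = cfg$seed, outputs = outputs,
         elapsed_s = round(elapsed, 3)),
    file.path(out_dir, sprintf("manifest_%s.json", stage)),
    auto_unbox = TRUE, digits = NA)
}

#' Run one pipeline stage (or all of them)
#'
#' File-based orchestration of the analysis over a working directory:
#' `simulate` writes every synthetic input (FASTA genomes, region JSON,
#' reference-library JSON, hit/GCF TSVs with planted truth),
#' `sketch`/`derep`/`species` run the MinHash stage, `catalog` the region
#' catalogue, `link` the similarity links, `membership` and
#' `compare-datasets` the GCF analytics, `molfam` and `compare-grouping`
#' the molecular-family network. `all` chains every stage on the synthetic
#' inputs. Each stage logs to stderr, writes its outputs as TSV/JSON under
#' `out_dir` and drops a JSON run manifest embedding the config and its
#' hash; identical configs reproduce byte-identical outputs.
#'
#' @param name stage name, one of
#'   `simulate, sketch, derep, species, catalog, link, membership,
#'   compare-datasets, molfam, compare-grouping, all`.
#' @param config a `pipeline_config`.
#' @param out_dir working directory holding stage inputs/outputs.
#' @return invisibly, the character vector of files written by the stage.
#' @export
run_stage <- function(name = stage_names(), config = pipeline_config(),
                      out_dir = ".") {
  name <- match.arg(name)
  validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  need <- function(...) {
    paths <- file.path(out_dir, c(...))
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop(sprintf("stage '%s' missing input file(s): %s", name,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    paths
  }
  outputs <- switch(
    name,
    "simulate" = stage_simulate(config, out_dir),
    "sketch" = {
      need("genomes.fasta")
      genomes <- read_genomes_fasta(file.path(out_dir, "genomes.fasta"))
      sketches <- lapply(genomes, sketch, k = config$k, s = config$s)
      D <- distance_matrix(sketches)
      write_distance_matrix(D, file.path(out_dir, "mash_distances.tsv"))
      "mash_distances.tsv"
    },
    "derep" = {
      need("mash_distances.tsv")
      D <- read_distance_matrix(file.path(out_dir, "mash_distances.tsv"))
      reps <- dereplicate(D, config$derep_cutoff)
      write_tsv(data.frame(representative = reps),
                file.path(out_dir, "representatives.tsv"))
      "representatives.tsv"
    },
    "species" = {
      need("mash_distances.tsv")
      D <- read_distance_matrix(file.path(out_dir, "mash_distances.tsv"))
      cl <- delineate_species(D, config$species_cutoff)
      write_clusters(cl, file.path(out_dir, "species_clusters.tsv"))
      "species_clusters.tsv"
    },
    "catalog" = {
      need("regions.json")
      regions <- load_regions(file.path(out_dir, "regions.json"),
                              config$contig_min_bp)
      cs <- completeness_summary(regions)
      write_class_summary(cs, file.path(out_dir, "class_summary.tsv"))
      ls <- length_stats(regions)
      jsonlite::write_json(c(ls, list(incomplete_fraction =
                                        cs$overall$incomplete_fraction)),
                           file.path(out_dir, "catalog_stats.json"),
                           auto_unbox = TRUE, digits = NA)
      c("class_summary.tsv", "catalog_stats.json")
    },
    "link" = {
      need("regions.json", "hits.tsv")
      regions <- load_regions(file.path(out_dir, "regions.json"),
                              config$contig_min_bp)
      hits <- read_hit_table(file.path(out_dir, "hits.tsv"))
      links <- link_table(hits, regions, config$link_cutoff)
      write_tsv(links, file.path(out_dir, "links.tsv"))
      "links.tsv"
    },
    "membership" = {
      need("gcf_assignments.tsv")
      a <- read_gcf_table(file.path(out_dir, "gcf_assignments.tsv"))
      overall <- membership_summary(a, "none", t_core = config$t_core,
                                    t_putative = config$t_putative)
      by_class <- membership_summary(a, "chem_class",
                                     t_core = config$t_core,
                                     t_putative = config$t_putative)
      write_tsv(rbind(overall, by_class),
                file.path(out_dir, "membership_summary.tsv"))
      write_tsv(prevalent_gcfs(a, 5L)[, c("gcf_id", "n_genomes", "n_bgcs")],
                file.path(out_dir, "prevalent_gcfs.tsv"))
      c("membership_summary.tsv", "prevalent_gcfs.tsv")
    },
    "compare-datasets" = {
      paths <- Sys.glob(file.path(out_dir, "gcf_assignments*.tsv"))
      if (length(paths) < 2L) {
        stop(sprintf(
          "stage 'compare-datasets' needs >= 2 files gcf_assignments*.tsv under %s",
          out_dir), call. = FALSE)
      }
      tables <- lapply(paths, read_gcf_table)
      names(tables) <- vapply(tables, function(t) t$dataset_label[1],
                              character(1))
      cmp <- dataset_comparison(tables, config$t_core, config$t_putative)
      write_venn_json(cmp, file.path(out_dir, "gcf_venn.json"))
      "gcf_venn.json"
    },
    "molfam" = {
      need("links.tsv", "reference_library.json", "regions.json")
      links <- read_tsv(file.path(out_dir, "links.tsv"))
      refs <- read_reference_library(file.path(out_dir,
                                               "reference_library.json"))
      regions <- load_regions(file.path(out_dir, "regions.json"),
                              config$contig_min_bp)
      chem <- compound_edges(refs, config$tanimoto_threshold,
                             config$fp_radius, config$fp_bits)
      net <- build_network(
        links, chem,
        all_query_ids = vapply(regions, function(r) r$region_id,
                               character(1)),
        all_reference_ids = vapply(refs, function(r) r$accession,
                                   character(1)))
      write_network_tsv(net, file.path(out_dir, "mf_network.tsv"))
      report <- molecular_families(net, config$mf_min_size)
      write_mf_report(report, file.path(out_dir, "mf_report.json"))
      c("mf_network.tsv", "mf_report.json")
    },
    "compare-grouping" = {
      need("mf_network.tsv", "gcf_assignments.tsv",
           "reference_gcf_assignments.tsv")
      el <- read_tsv(file.path(out_dir, "mf_network.tsv"))
      edges <- el[el$edge_type != "isolated", , drop = FALSE]
      iso <- el[el$edge_type == "isolated", , drop = FALSE]
      links <- edges[edges$edge_type == "genomic",
                     c("from", "to", "weight")]
      names(links) <- c("region_id", "reference_accession", "score")
      chem <- edges[edges$edge_type == "chemical",
                    c("from", "to", "weight")]
      names(chem) <- c("accession_a", "accession_b", "weight")
      net <- build_network(
        links, chem,
        all_query_ids = iso$from[iso$from_type == "query_bgc"],
        all_reference_ids = iso$from[iso$from_type == "reference_bgc"])
      report <- molecular_families(net, config$mf_min_size)
      cmp <- compare_grouping(
        report,
        read_gcf_table(file.path(out_dir, "gcf_assignments.tsv")),
        read_gcf_table(file.path(out_dir, "reference_gcf_assignments.tsv")))
      jsonlite::write_json(
        cmp[c("n_query_mf", "n_query_gcf", "n_query_both", "n_reference_mf",
              "n_reference_gcf", "n_reference_both", "n_shared_gcfs")],
        file.path(out_dir, "grouping_comparison.json"),
        auto_unbox = TRUE, digits = NA)
      "grouping_comparison.json"
    },
    "all" = {
      stages <- setdiff(stage_names(), "all")
      unlist(lapply(stages, function(st) run_stage(st, config, out_dir)))
    })
  elapsed <- proc.time()[["elapsed"]] - t0
  log_stage(name, sprintf("done in %.2fs (%s)", elapsed,
                          paste(outputs, collapse = ", ")))
  if (name != "all") write_manifest(name, config, out_dir, outputs, elapsed)
  invisible(outputs)
}

# The `simulate` stage: every synthetic input, with planted truth tables.
stage_simulate <- function(config, out_dir) {
  sim <- config$sim
  seeds <- derive_seeds(config$seed, 5L)
  panel <- generate_strain_panel(sim$n_species, sim$strains_per_species,
                                 sim$within_rate, sim$between_rate,
                                 sim$genome_length, seed = seeds[1])
  write_genomes_fasta(panel$genomes, file.path(out_dir, "genomes.fasta"))
  write_tsv(panel$truth, file.path(out_dir, "truth_species.tsv"))

  regions <- generate_bgc_collection(sim$n_regions, seed = seeds[2])
  write_regions(regions, file.path(out_dir, "regions.json"))

  refs <- generate_reference_library(sim$n_families, sim$refs_per_family,
                                     seed = seeds[3],
                                     threshold = config$tanimoto_threshold)
  write_reference_library(refs, file.path(out_dir, "reference_library.json"))
  write_tsv(attr(refs, "family_truth"),
            file.path(out_dir, "truth_families.tsv"))

  # plant links: one reference per linked region, realizable scores >= 0.5
  n_link <- min(sim$n_planted_links, length(regions))
  accs <- vapply(refs, function(r) r$accession, character(1))
  planted <- with_seed(seeds[4], {
    chosen <- sample(seq_along(regions), n_link)
    links <- lapply(chosen, function(i) {
      n <- nrow(regions[[i]]$genes)
      k <- sample(seq(ceiling(n / 2), n), 1L)
      list(accession = sample(accs, 1L), score = k / n)
    })
    names(links) <- vapply(regions[chosen], function(r) r$region_id,
                           character(1))
    links
  })
  hits <- generate_hit_table(regions, refs, planted, sim$noise_links,
                             seed = seeds[4])
  write_hit_table(hits, file.path(out_dir, "hits.tsv"))
  write_tsv(data.frame(
    region_id = names(planted),
    accession = vapply(planted, function(l) l$accession, character(1)),
    score = vapply(planted, function(l) l$score, numeric(1))),
    file.path(out_dir, "truth_links.tsv"))

  region_ids <- vapply(regions, function(r) r$region_id, character(1))
  gcf <- generate_gcf_table(region_ids, seed = seeds[5],
                            t_core = config$t_core,
                            t_putative = config$t_putative,
                            dataset_label = "lichen")
  write_gcf_table(gcf, file.path(out_dir, "gcf_assignments.tsv"))
  ref_gcf <- generate_gcf_table(accs, seed = seeds[5] %% 100000L + 7L,
                                n_gcfs = max(1L, ceiling(length(region_ids) / 8)),
                                t_core = config$t_core,
                                t_putative = config$t_putative,
                                genome_ids = accs,
                                dataset_label = "mibig")
  write_gcf_table(ref_gcf, file.path(out_dir,
                                     "reference_gcf_assignments.tsv"))

  # two further environmental datasets drawing GCFs from the same pool,
  # so the compare-datasets stage has a non-trivial Venn structure
  for (ds in c("insect", "marine")) {
    ids <- sprintf("%s_r%dc1", toupper(substr(ds, 1, 1)),
                   seq_len(max(10L, sim$n_regions %/% 3L)))
    extra <- generate_gcf_table(
      ids, fractions = c(0.7, 0.28, 0.02),
      seed = seeds[5] %% 100000L + if (ds == "insect") 11L else 13L,
      n_gcfs = max(1L, ceiling(length(region_ids) / 8)),
      t_core = config$t_core, t_putative = config$t_putative,
      dataset_label = ds)
    write_gcf_table(extra,
                    file.path(out_dir, sprintf("gcf_assignments_%s.tsv", ds)))
  }
  c("genomes.fasta", "truth_species.tsv", "regions.json",
    "reference_library.json", "truth_families.tsv", "hits.tsv",
    "truth_links.tsv", "gcf_assignments.tsv",
    "reference_gcf_assignments.tsv", "gcf_assignments_insect.tsv",
    "gcf_assignments_marine.tsv")
}

#' @rdname run_stage
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = ".") {
  run_stage("all", config, out_dir)
}
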