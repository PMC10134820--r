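#' Simulated genome assemblies with planted divergence
#'
#' `generate_genome()` draws an i.i.d. nucleotide sequence with a target GC
#' content; `mutate_genome()` applies independent per-site substitutions so
#' that pairs of genomes with a known divergence can be planted;
#' `generate_strain_panel()` builds a panel of species (one ancestor each,
#' derived from a common root) and strains (derived from their species
#' ancestor) with the planted species labels recorded. These are the inputs
#' to the sketching/dereplication stage; no attempt is made to simulate
#' reads, repeats or realistic gene content.
#'
#' @param length sequence length in bp (single contig).
#' @param gc target GC fraction, strictly between 0 and 1.
#' @param seed integer seed; generation is deterministic given all arguments.
#' @param genome_id,taxon_label identifiers carried on the record.
#' @return a `genome_record`: list with `genome_id`, `taxon_label` and
#'   `contigs` (data frame of `contig_id`, `sequence`).
#' @examples
#' g <- generate_genome(5000, gc = 0.6, seed = 1)
#' nchar(g$contigs$sequence)
#' @export
generate_genome <- function(length, gc = 0.5, seed = 1L,
                            genome_id = "g1", taxon_label = "Synthetica") {
  if (!is.numeric(length) || length(length) != 1L || length < 1) {
    stop("`length` must be a positive number of base pairs", call. = FALSE)
  }
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) {
    stop("`gc` must be strictly between 0 and 1", call. = FALSE)
  }
  seq <- with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), size = as.integer(length),
                    replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    paste(bases, collapse = "")
  })
  genome_record(genome_id, contigs = data.frame(
    contig_id = paste0(genome_id, "_c1"), sequence = seq,
    stringsAsFactors = FALSE), taxon_label = taxon_label)
}

#' @rdname generate_genome
#' @param contigs data frame with columns `contig_id`, `sequence`.
#' @export
genome_record <- function(genome_id, contigs, taxon_label = "Synthetica") {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  if (!is.data.frame(contigs) ||
      !all(c("contig_id", "sequence") %in% names(contigs))) {
    stop("`contigs` must have columns contig_id and sequence", call. = FALSE)
  }
  if (anyDuplicated(contigs$contig_id)) {
    stop("contig ids must be unique within a genome", call. = FALSE)
  }
  if (any(nchar(contigs$sequence) == 0)) {
    stop("contig sequences must be non-empty", call. = FALSE)
  }
  if (any(grepl("[^ACGTN]", contigs$sequence))) {
    stop("contig sequences restricted to alphabet A,C,G,T,N", call. = FALSE)
  }
  structure(list(genome_id = genome_id, contigs = contigs,
                 taxon_label = taxon_label),
            class = "genome_record")
}

#' @rdname generate_genome
#' @param genome a `genome_record`.
#' @param rate per-site substitution probability, in \[0, 0.3\]. Each
#'   substituted site receives a base drawn uniformly from the three
#'   alternatives; contig structure is preserved.
#' @export
mutate_genome <- function(genome, rate, seed = 1L) {
  stopifnot(inherits(genome, "genome_record"))
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate > 0.3) {
    stop("`rate` must be in [0, 0.3]", call. = FALSE)
  }
  if (rate == 0) return(genome)
  bases <- c("A", "C", "G", "T")
  contigs <- genome$contigs
  contigs$sequence <- with_seed(seed, vapply(contigs$sequence, function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(v)) < rate & v != "N")
    if (length(hit)) {
      # uniform over the three non-identical bases
      cur <- match(v[hit], bases)
      off <- sample.int(3L, length(hit), replace = TRUE)
      v[hit] <- bases[((cur - 1L + off) %% 4L) + 1L]
    }
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE))
  genome_record(genome$genome_id, contigs, genome$taxon_label)
}

#' Panel of species and strains with recorded truth
#'
#' One root genome is drawn; each species ancestor diverges from the root at
#' `between_rate`; each strain diverges from its species ancestor at
#' `within_rate`. The expected pairwise divergence is therefore about
#' `2 * within_rate` within species and about `2 * between_rate` between
#' species, so a delineation cutoff sitting between those two scales
#' recovers the planted species exactly.
#'
#' @param n_species,strains_per_species panel dimensions.
#' @param within_rate,between_rate per-site substitution rates; the panel is
#'   only meaningful (and only accepted) when `between_rate > within_rate`.
#' @param genome_length bp per genome (single contig).
#' @param gc GC fraction of the root genome.
#' @param seed integer seed.
#' @return list with `genomes` (list of `genome_record`) and `truth`
#'   (data frame `genome_id`, `species_id`).
#' @export
generate_strain_panel <- function(n_species, strains_per_species,
                                  within_rate = 0.005, between_rate = 0.08,
                                  genome_length = 100000L, gc = 0.6,
                                  seed = 1L) {
  stopifnot(n_species >= 1, strains_per_species >= 1)
  if (!(between_rate > within_rate)) {
    stop("`between_rate` must exceed `within_rate`", call. = FALSE)
  }
  seeds <- derive_seeds(seed, 1L + n_species * (1L + strains_per_species))
  root <- generate_genome(genome_length, gc, seeds[1], genome_id = "root")
  idx <- 2L
  genomes <- list()
  truth <- list()
  for (sp in seq_len(n_species)) {
    sp_id <- sprintf("sp%02d", sp)
    ancestor <- mutate_genome(root, between_rate, seeds[idx]); idx <- idx + 1L
    for (st in seq_len(strains_per_species)) {
      gid <- sprintf("%s_strain%02d", sp_id, st)
      g <- mutate_genome(ancestor, within_rate, seeds[idx]); idx <- idx + 1L
      g$genome_id <- gid
      g$contigs$contig_id <- paste0(gid, "_c1")
      genomes[[gid]] <- g
      truth[[gid]] <- data.frame(genome_id = gid, species_id = sp_id,
                                 stringsAsFactors = FALSE)
    }
  }
  list(genomes = genomes, truth = do.call(rbind, unname(truth)))
}

#' Write genome records as FASTA
#'
#' @param genomes list of `genome_record`.
#' @param path output FASTA file; headers are `<genome_id>|<contig_id>`.
#' @return `path`, invisibly.
#' @export
write_genomes_fasta <- function(genomes, path) {
  seqs <- unlist(unname(lapply(genomes, function(g) {
    setNames(g$contigs$sequence,
             paste(g$genome_id, g$contigs$contig_id, sep = "|"))
  })))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read genome records from FASTA written by [write_genomes_fasta()]
#'
#' @param path FASTA file with `<genome_id>|<contig_id>` headers.
#' @return list of `genome_record`.
#' @export
read_genomes_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(set), "|", fixed = TRUE)
  gid <- vapply(parts, `[`, character(1), 1L)
  cid <- vapply(parts, function(p) paste(p[-1L], collapse = "|"), character(1))
  lapply(split(seq_along(set), gid)[unique(gid)], function(i) {
    genome_record(gid[i][1L], data.frame(
      contig_id = cid[i], sequence = as.character(set[i]),
      stringsAsFactors = FALSE))
  })
}
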