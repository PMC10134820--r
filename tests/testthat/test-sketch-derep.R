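test_that("sketching is deterministic and strand-canonical", {
  g <- genome_record("g1", data.frame(
    contig_id = "c1", sequence = strrep("ACGTTGCAAGCTTGCATGCCT", 40),
    stringsAsFactors = FALSE))
  s1 <- sketch(g, k = 21, s = 1000)
  s2 <- sketch(g, k = 21, s = 1000)
  expect_identical(s1$hashes, s2$hashes)
  expect_true(all(diff(s1$hashes) > 0))
  expect_lte(length(s1$hashes), 1000L)

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g$contigs$sequence)))
  g_rc <- genome_record("g1rc", data.frame(contig_id = "c1", sequence = rc,
                                           stringsAsFactors = FALSE))
  expect_identical(sketch(g_rc, k = 21, s = 1000)$hashes, s1$hashes)

  short <- genome_record("tiny", data.frame(contig_id = "c1",
                                            sequence = "ACGTACGTAC",
                                            stringsAsFactors = FALSE))
  expect_error(sketch(short, k = 21), "empty sketch")
})

test_that("a sketch wider than the genome holds every distinct canonical k-mer", {
  set.seed(11)
  for (i in 1:5) {
    seqs <- replicate(2, random_dna(sample(500:2000, 1)))
    g <- genome_record("g", data.frame(contig_id = c("c1", "c2"),
                                       sequence = seqs,
                                       stringsAsFactors = FALSE))
    sk <- sketch(g, k = 15, s = 10000)
    expect_identical(length(sk$hashes),
                     length(oracle_canonical_kmers(seqs, 15)))
  }
})

test_that("N-containing k-mers are skipped, not substituted", {
  plain <- genome_record("a", data.frame(contig_id = "c1",
                                         sequence = random_dna(300),
                                         stringsAsFactors = FALSE))
  seq_n <- paste0(substr(plain$contigs$sequence, 1, 150), "N",
                  substr(plain$contigs$sequence, 151, 300))
  with_n <- genome_record("b", data.frame(contig_id = "c1", sequence = seq_n,
                                          stringsAsFactors = FALSE))
  expect_identical(length(sketch(with_n, 15, 10000)$hashes),
                   length(oracle_canonical_kmers(
                     c(substr(seq_n, 1, 150), substr(seq_n, 152, 301)), 15)))
  expect_true(all(sketch(with_n, 15, 10000)$hashes %in%
                    sketch(plain, 15, 10000)$hashes))
})

test_that("sketch Jaccard equals the exact k-mer-set Jaccard when s covers the union", {
  set.seed(21)
  for (i in 1:6) {
    a_seq <- random_dna(sample(2000:10000, 1))
    # overlap: b shares a chunk of a plus new sequence
    b_seq <- paste0(substr(a_seq, 1, nchar(a_seq) %/% 2),
                    random_dna(sample(1000:5000, 1)))
    a <- sketch(genome_record("a", data.frame(contig_id = "c", sequence = a_seq,
                                              stringsAsFactors = FALSE)),
                k = 21, s = 50000)
    b <- sketch(genome_record("b", data.frame(contig_id = "c", sequence = b_seq,
                                              stringsAsFactors = FALSE)),
                k = 21, s = 50000)
    expect_equal(jaccard(a, b), oracle_kmer_jaccard(a_seq, b_seq, 21),
                 tolerance = 1e-12)
  }
})

test_that("jaccard handles identity, disjointness and parameter mismatch", {
  g1 <- generate_genome(3000, seed = 1)
  g2 <- generate_genome(3000, seed = 2)
  s1 <- sketch(g1, 21, 1000); s2 <- sketch(g2, 21, 1000)
  expect_equal(jaccard(s1, s1), 1.0)
  expect_equal(jaccard(s1, s2), 0.0)  # 3 kb random sequences share no 21-mers
  expect_error(jaccard(s1, sketch(g2, 17, 1000)), "share k and s")
  expect_error(jaccard(s1, sketch(g2, 21, 500)), "share k and s")
})

test_that("mash_distance matches the closed form and is monotone", {
  expect_equal(mash_distance(1, 21), 0)
  expect_equal(mash_distance(0, 21), 1)
  expect_equal(mash_distance(0.5, 21), -(1 / 21) * log(2 * 0.5 / 1.5),
               tolerance = 1e-9)
  expect_lt(abs(mash_distance(0.5, 21) - 0.019308), 1e-6)
  expect_error(mash_distance(1.2, 21), "\\[0, 1\\]")

  j <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(mash_distance(j, 21)) < 0))
})

test_that("mash distance recovers planted substitution rates within 30%", {
  rates <- rep(c(0.01, 0.02, 0.035, 0.05), 5)  # 20 seeded replicates
  est <- vapply(seq_along(rates), function(i) {
    g <- generate_genome(200000, seed = 100 + i)
    m <- mutate_genome(g, rates[i], seed = 200 + i)
    m$genome_id <- "mut"
    mash_distance(jaccard(sketch(g, 21, 1000), sketch(m, 21, 1000)), 21)
  }, numeric(1))
  expect_true(all(abs(est - rates) / rates < 0.30))
  # the specific derived example: rate 0.02 lands in [0.012, 0.028]
  r02 <- est[rates == 0.02]
  expect_true(all(r02 >= 0.012 & r02 <= 0.028))
})

test_that("distance matrices are symmetric compositions of pairwise distances", {
  gs <- lapply(1:3, function(i) generate_genome(20000, seed = i,
                                                genome_id = paste0("g", i)))
  sks <- lapply(gs, sketch, k = 21, s = 1000)
  D <- distance_matrix(sks)
  expect_identical(D$D, t(D$D))
  expect_true(all(diag(D$D) == 0))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(D$D[i, j],
                 mash_distance(jaccard(sks[[i]], sks[[j]]), 21))
  }
  # duplicated genome: off-diagonal zero
  dup <- sks; dup[[4]] <- sks[[1]]; dup[[4]]$genome_id <- "g1dup"
  expect_equal(distance_matrix(dup)$D["g1", "g1dup"], 0)
  expect_error(distance_matrix(sks[1]), "at least two")
})

test_that("average-linkage cutoffs behave at the extremes", {
  gs <- lapply(1:4, function(i) generate_genome(20000, seed = 10 + i,
                                                genome_id = paste0("g", i)))
  D <- distance_matrix(lapply(gs, sketch))
  tiny <- average_linkage_clusters(D, min(D$D[upper.tri(D$D)]) / 2)
  expect_identical(length(unique(tiny$assignment)), 4L)
  one <- average_linkage_clusters(D, max(D$D))
  expect_identical(length(unique(one$assignment)), 1L)
  expect_identical(sort(unique(one$assignment)), 0L)
  expect_error(average_linkage_clusters(D, -0.1), "non-negative")
})

test_that("cluster count is non-increasing in the cutoff", {
  panel <- generate_strain_panel(3, 2, 0.01, 0.1, genome_length = 30000,
                                 seed = 5)
  D <- distance_matrix(lapply(panel$genomes, sketch))
  counts <- vapply(c(0, 0.005, 0.02, 0.05, 0.1, 0.3, 1),
                   function(h) {
                     length(unique(average_linkage_clusters(D, h)$assignment))
                   }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("species delineation at 0.04 recovers planted panels (10 seeds)", {
  for (sd in 1:10) {
    panel <- generate_strain_panel(3, 3, within_rate = 0.005,
                                   between_rate = 0.08,
                                   genome_length = 50000, seed = sd)
    D <- distance_matrix(lapply(panel$genomes, sketch, k = 21, s = 1000))
    # within-species distances all below between-species distances
    same <- outer(panel$truth$species_id, panel$truth$species_id, "==")
    expect_lt(max(D$D[same & upper.tri(same)]),
              min(D$D[!same & upper.tri(same)]))
    cl <- delineate_species(D, 0.04)
    expect_identical(length(unique(cl$assignment)), 3L)
    # clusters coincide with the planted species partition
    tab <- table(cl$assignment[panel$truth$genome_id],
                 panel$truth$species_id)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("dereplication collapses planted duplicates to representatives", {
  base <- lapply(1:3, function(i) generate_genome(40000, seed = 30 + i,
                                                  genome_id = sprintf("s%d", i)))
  dups <- lapply(1:3, function(i) {
    m <- mutate_genome(base[[i]], 0.001, seed = 40 + i)
    m$genome_id <- sprintf("s%d_dup", i)
    m
  })
  D <- distance_matrix(lapply(c(base, dups), sketch))
  reps <- dereplicate(D, 0.005)
  expect_identical(sort(reps), c("s1", "s2", "s3"))
  # all distances above the cutoff: everything is its own representative
  Dfar <- distance_matrix(lapply(base, sketch))
  expect_identical(sort(dereplicate(Dfar, 0.005)), c("s1", "s2", "s3"))
})

test_that("sketch and distance-matrix files round-trip", {
  g <- generate_genome(5000, seed = 2)
  sk <- sketch(g)
  p <- withr::local_tempfile(fileext = ".json")
  write_sketch(sk, p)
  expect_equal(read_sketch(p), sk)

  gs <- lapply(1:3, function(i) generate_genome(10000, seed = i,
                                                genome_id = paste0("g", i)))
  D <- distance_matrix(lapply(gs, sketch))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(D, p2)
  expect_equal(read_distance_matrix(p2)$D, D$D, tolerance = 1e-12)
})
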