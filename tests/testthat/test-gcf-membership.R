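test_that("membership classification matches the printed strata", {
  # printed (d, class) pairs from the survey's worked examples
  expect_identical(as.character(classify_membership(c(549, 324, 1938, 2051))),
                   c("core", "core", "orphan", "orphan"))
  # boundary semantics of the printed inequalities
  expect_identical(as.character(classify_membership(900)), "core")
  expect_identical(as.character(classify_membership(900 + 1e-9)), "putative")
  expect_identical(as.character(classify_membership(1800)), "putative")
  expect_identical(as.character(classify_membership(1800 + 1e-9)), "orphan")
  expect_error(classify_membership(-1), "non-negative")
  # exactly one class per d: the strata partition [0, inf)
  d <- seq(0, 3000, by = 7.5)
  expect_false(anyNA(classify_membership(d)))
})

test_that("membership summaries count, percentage and round as printed", {
  # 41 BGCs of which 11 orphan: the survey prints 26.83%
  a <- gcf_assignment(sprintf("b%02d", 1:41), "GCF_1",
                      d = c(rep(100, 25), rep(1000, 5), rep(2500, 11)),
                      chem_class = "Saccharide")
  s <- membership_summary(a, "chem_class")
  expect_identical(s$orphan, 11L)
  expect_equal(s$pct_orphan, 26.83)
  expect_equal(s$pct_core + s$pct_putative + s$pct_orphan, 100,
               tolerance = 0.02)

  all_core <- gcf_assignment(letters[1:5], "GCF_1", d = rep(10, 5))
  expect_equal(membership_summary(all_core)$pct_core, 100)

  # grouped by taxon via metadata; missing key is an error naming the bgc
  meta <- data.frame(genome_id = c("g1", "g2"),
                     genome_taxon = c("Streptomyces", "Nocardia"))
  b <- gcf_assignment(c("x1", "x2"), "GCF_1", c(100, 2000),
                      genome_id = c("g1", "g3"))
  expect_error(membership_summary(b, "genome_taxon", meta), "x2")
  b_ok <- gcf_assignment(c("x1", "x2"), "GCF_1", c(100, 2000),
                         genome_id = c("g1", "g2"))
  s2 <- membership_summary(b_ok, "genome_taxon", meta)
  expect_identical(s2$group, c("Nocardia", "Streptomyces"))
  expect_identical(s2$orphan, c(1L, 0L))
})

test_that("planted multinomial fractions are recovered within 2% at n = 5000", {
  ids <- sprintf("G%03d_r%dc1", rep(1:250, each = 20), 1:20)
  tab <- generate_gcf_table(ids, fractions = c(0.6, 0.3, 0.1), seed = 42)
  s <- membership_summary(tab)
  expect_identical(s$n, 5000L)
  expect_lt(abs(s$pct_core / 100 - 0.6), 0.02)
  expect_lt(abs(s$pct_putative / 100 - 0.3), 0.02)
  expect_lt(abs(s$pct_orphan / 100 - 0.1), 0.02)
})

test_that("dataset comparison reports Venn structure and unique fractions", {
  mk <- function(ids, gcfs, label) {
    gcf_assignment(ids, gcfs, d = rep(100, length(ids)),
                   dataset_label = label)
  }
  # identical sets: full overlap, zero unique
  same <- lapply(c("a", "b", "c"), function(l) {
    mk(paste0(l, 1:4), paste0("GCF_", 1:4), l)
  })
  names(same) <- c("a", "b", "c")
  cmp <- dataset_comparison(same)
  expect_equal(unname(cmp$intersections[["a&b&c"]]), 4)
  expect_equal(unname(cmp$unique_fraction), rep(0, 3))

  # pairwise disjoint: unique fractions 1
  disj <- list(a = mk("x1", "GCF_1", "a"), b = mk("x2", "GCF_2", "b"))
  expect_equal(unname(dataset_comparison(disj)$unique_fraction), c(1, 1))

  expect_error(dataset_comparison(disj["a"]), "at least two")
  expect_error(dataset_comparison(setNames(disj, c("a", "a"))), "duplicate")
})

test_that("a planted three-way overlap of 42 GCFs is reported exactly", {
  shared <- sprintf("GCF_S%03d", 1:42)
  mk <- function(label, extra) {
    gcfs <- c(shared, sprintf("GCF_%s%03d", label, seq_len(extra)))
    gcf_assignment(paste0(label, seq_along(gcfs)), gcfs,
                   d = rep(100, length(gcfs)), dataset_label = label)
  }
  cmp <- dataset_comparison(list(lichen = mk("L", 58), insect = mk("I", 20),
                                 marine = mk("M", 5)))
  expect_equal(unname(cmp$intersections[["lichen&insect&marine"]]), 42)
  expect_equal(unname(cmp$intersections[["lichen&insect"]]), 42)
  expect_equal(unname(cmp$sizes), c(100, 62, 47))
  expect_equal(unname(cmp$unique_fraction["lichen"]), 58 / 100)
  # inclusion-exclusion identity: unique + shared partitions each set
  for (l in cmp$labels) {
    others <- setdiff(cmp$labels, l)
    in_any_other <- length(intersect(cmp$gcf_sets[[l]],
                                     unique(unlist(cmp$gcf_sets[others]))))
    expect_equal(length(cmp$unique_gcfs[[l]]) + in_any_other,
                 unname(cmp$sizes[l]))
  }
})

test_that("prevalent GCFs rank by genome prevalence with lexicographic ties", {
  a <- gcf_assignment(
    bgc_id = sprintf("b%02d", 1:15),
    gcf_id = c(rep("GCF_9", 9), rep("GCF_2", 3), rep("GCF_1", 3)),
    d = rep(100, 15),
    genome_id = c(paste0("g", 1:9), "g1", "g2", "g3", "g1", "g2", "g3"))
  top <- prevalent_gcfs(a, 2)
  expect_identical(top$gcf_id, c("GCF_9", "GCF_1"))  # tie at 3 -> GCF_1 first
  expect_equal(top$n_genomes, c(9, 3))
  expect_identical(sort(top$d_values[[1]]), rep(100, 9))

  one_each <- gcf_assignment(c("b1", "b2", "b3"),
                             c("GCF_c", "GCF_a", "GCF_b"),
                             d = c(1, 2, 3), genome_id = "g1")
  expect_identical(prevalent_gcfs(one_each, 10)$gcf_id,
                   c("GCF_a", "GCF_b", "GCF_c"))
  expect_error(prevalent_gcfs(a, 0), "positive")
})

test_that("GCF tables and BiG-SLiCE-style exports read back consistently", {
  ids <- sprintf("G%03d_r%dc1", rep(1:4, each = 3), 1:3)
  tab <- generate_gcf_table(ids, seed = 3)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_gcf_table(tab, p)
  expect_equal(as.data.frame(read_gcf_table(p)), as.data.frame(tab),
               tolerance = 1e-9, ignore_attr = TRUE)

  # spreadsheet-style aliases: bgc / gcf_membership / membership_value
  p2 <- withr::local_tempfile(fileext = ".tsv")
  alias <- data.frame(bgc = c("r1", "r2"), gcf_membership = c("G1", "G2"),
                      membership_value = c(549, 2051),
                      class = c("NRP", "Polyketide"))
  write.table(alias, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  imp <- read_bigslice_export(p2, "lichen")
  expect_identical(imp$bgc_id, c("r1", "r2"))
  expect_identical(as.character(classify_membership(imp$d)),
                   c("core", "orphan"))
})
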