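test_that("fingerprints are deterministic and depend only on the graph", {
  f1 <- morgan_fingerprint("CCO")
  f2 <- morgan_fingerprint("CCO")
  expect_identical(f1$bits, f2$bits)
  # SMILES rewriting of the same molecule
  expect_identical(morgan_fingerprint("OCC")$bits, f1$bits)
  expect_identical(morgan_fingerprint("C(O)C")$bits, f1$bits)
  # aromatic ring written from different start atoms
  expect_identical(morgan_fingerprint("c1ccccc1O")$bits,
                   morgan_fingerprint("Oc1ccccc1")$bits)
  # different molecules differ
  expect_false(identical(morgan_fingerprint("CCO")$bits,
                         morgan_fingerprint("CCN")$bits))
  expect_error(morgan_fingerprint("not_a_smiles"), "parse error")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("C(C"), "unbalanced")
})

test_that("the SMILES subset parser fills valences and perceives rings", {
  mol <- parse_smiles("CC(=O)Oc1ccccc1C(=O)O")  # aspirin
  expect_identical(nrow(mol$atoms), 13L)
  expect_identical(sum(mol$atoms$aromatic), 6L)
  expect_identical(sum(mol$atoms$in_ring), 6L)
  # methyl has 3 H, carbonyl O none, acid O one
  expect_identical(mol$atoms$hcount[1], 3)
  ooh <- which(mol$atoms$element == "O" & mol$atoms$hcount == 1)
  expect_length(ooh, 1L)
  # charge handling: quaternary ammonium has no implicit H
  quat <- parse_smiles("C[N+](C)(C)C")
  expect_identical(quat$atoms$hcount[quat$atoms$element == "N"], 0)
  expect_identical(quat$atoms$charge[quat$atoms$element == "N"], 1)
  # explicit bracket H: pyrrole nitrogen
  pyr <- parse_smiles("c1cc[nH]c1")
  expect_identical(pyr$atoms$hcount[pyr$atoms$element == "N"], 1)
})

test_that("tanimoto is symmetric, bounded, and exact on known overlaps", {
  fp <- function(bits) structure(list(bits = bits, n_bits = 64L,
                                      radius = 2L), class = "morgan_fp")
  a <- fp(c(1L, 2L, 3L)); b <- fp(c(2L, 3L, 4L))
  expect_equal(tanimoto(a, b), 2 / 4)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(fp(integer()), fp(integer())), 0)
  expect_equal(tanimoto(a, fp(c(10L, 11L))), 0)
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  expect_error(tanimoto(a, morgan_fingerprint("CCO")), "width")

  set.seed(5)
  for (i in 1:20) {
    x <- morgan_fingerprint(sample(scaffold_smiles(), 1))
    y <- morgan_fingerprint(sample(scaffold_smiles(), 1))
    t <- tanimoto(x, y)
    expect_gte(t, 0); expect_lte(t, 1)
  }
})

test_that("compound edges use the max over compound pairs, inclusively", {
  shared <- "CC(=O)Oc1ccccc1C(=O)O"
  r1 <- make_ref("BGC0000001", compounds = c("CCO", shared))
  r2 <- make_ref("BGC0000002", compounds = shared)
  r3 <- make_ref("BGC0000003", compounds = "CCCCCCCC")
  edges <- compound_edges(list(r1, r2, r3), 0.5)
  expect_identical(nrow(edges), 1L)
  expect_identical(edges$accession_a, "BGC0000001")
  expect_identical(edges$accession_b, "BGC0000002")
  expect_equal(edges$weight, 1.0)

  # no parsable compound: no edges, with a warning
  r_bad <- make_ref("BGC0000004", compounds = "!!")
  expect_warning(e2 <- compound_edges(list(r_bad, r2), 0.5), "skipping")
  expect_identical(nrow(e2), 0L)
  # all pairwise below threshold: no edges
  expect_identical(nrow(compound_edges(list(r1, r3), 0.5)), 0L)
})

test_that("network construction joins genomic and chemical edges", {
  links <- data.frame(region_id = c("A", "B"),
                      reference_accession = c("R1", "R2"),
                      score = c(0.8, 0.5))
  chem <- data.frame(accession_a = "R1", accession_b = "R2", weight = 0.7)
  net <- build_network(links, chem)
  expect_identical(length(unique(net$membership)), 1L)
  expect_identical(sort(names(net$membership)), c("A", "B", "R1", "R2"))

  # no edges at all: every node isolated
  empty <- build_network(links[0, ], chem[0, ],
                         all_query_ids = c("A", "B"),
                         all_reference_ids = "R1")
  expect_identical(length(unique(empty$membership)), 3L)

  expect_error(build_network(
    data.frame(region_id = "X", reference_accession = "X", score = 1),
    chem[0, ]), "both as query and reference")
})

test_that("components agree with a union-find oracle on random graphs", {
  set.seed(17)
  for (rep in 1:8) {
    nq <- sample(20:100, 1); nr <- sample(20:100, 1)
    q_ids <- sprintf("q%03d", seq_len(nq))
    r_ids <- sprintf("r%03d", seq_len(nr))
    links <- data.frame(
      region_id = sample(q_ids, 80, replace = TRUE),
      reference_accession = sample(r_ids, 80, replace = TRUE),
      score = 1)
    links <- links[!duplicated(links[, 1:2]), ]
    chem <- data.frame(accession_a = sample(r_ids, 40, replace = TRUE),
                       accession_b = sample(r_ids, 40, replace = TRUE),
                       weight = 1)
    chem <- chem[chem$accession_a != chem$accession_b, ]
    net <- build_network(links, chem, all_query_ids = q_ids,
                         all_reference_ids = r_ids)
    all_ids <- names(net$membership)
    oracle <- oracle_components(
      length(all_ids),
      rbind(cbind(match(links$region_id, all_ids),
                  match(links$reference_accession, all_ids)),
            cbind(match(chem$accession_a, all_ids),
                  match(chem$accession_b, all_ids))))
    # identical partitions: same co-membership relation
    expect_identical(length(unique(net$membership)),
                     length(unique(oracle)))
    expect_true(all(tapply(oracle, net$membership,
                           function(x) length(unique(x))) == 1L))
  }
})

test_that("molecular families require both node types and honour min_size", {
  links <- data.frame(region_id = c("A", "B"),
                      reference_accession = c("R1", "R2"), score = 0.5)
  chem <- data.frame(accession_a = "R1", accession_b = "R2", weight = 0.7)
  net <- build_network(links, chem, all_query_ids = c("A", "B", "C"),
                       all_reference_ids = c("R1", "R2", "R3"))
  rep1 <- molecular_families(net)
  expect_identical(rep1$n_mfs, 1L)            # A-R1-R2-B
  expect_identical(rep1$n_query_in_mfs, 2L)
  expect_identical(rep1$n_reference_in_mfs, 2L)
  expect_identical(rep1$n_isolated_query, 1L)  # C
  expect_identical(rep1$families$n_nodes, 4)

  # isolated query nodes only: no MFs
  none <- molecular_families(build_network(links[0, ], chem[0, ],
                                           all_query_ids = c("A", "B")))
  expect_identical(none$n_mfs, 0L)

  # min_size filters the reported list, not the headline component count
  big <- molecular_families(net, min_size = 5)
  expect_identical(big$n_mfs, 1L)
  expect_identical(big$n_mfs_reported, 0L)
})

test_that("a planted family structure yields exactly the planted MF count", {
  refs <- generate_reference_library(3, 3, seed = 11)
  accs <- vapply(refs, function(r) r$accession, character(1))
  truth <- attr(refs, "family_truth")
  # two query BGCs linked into each planted family via its first member
  first <- truth$accession[!duplicated(truth$family_id)]
  links <- data.frame(
    region_id = sprintf("Q%02d", seq_len(2 * length(first))),
    reference_accession = rep(first, each = 2), score = 0.6)
  net <- build_network(links, compound_edges(refs, 0.5),
                       all_reference_ids = accs)
  rep <- molecular_families(net)
  expect_identical(rep$n_mfs, 3L)
  expect_identical(rep$n_query_in_mfs, 6L)
  expect_identical(rep$n_reference_in_mfs, 9L)

  # filtering at min_size 6 keeps only families with >= 6 nodes (here: 2+3)
  expect_identical(molecular_families(net, 6)$n_mfs_reported, 0L)
  expect_identical(molecular_families(net, 5)$n_mfs_reported, 3L)
})

test_that("compare_grouping intersects MF and GCF co-assignment sets", {
  links <- data.frame(region_id = c("A", "B"),
                      reference_accession = c("R1", "R2"), score = 0.5)
  net <- build_network(links, data.frame(accession_a = character(),
                                         accession_b = character(),
                                         weight = numeric()))
  mf <- molecular_families(net)
  # GCF partition groups A with R1 (same gcf) but B's gcf has no reference
  qa <- gcf_assignment(c("A", "B"), c("GCF_1", "GCF_2"), c(100, 100))
  ra <- gcf_assignment(c("R1", "R2"), c("GCF_1", "GCF_3"), c(100, 100),
                       dataset_label = "mibig")
  cmp <- compare_grouping(mf, qa, ra)
  expect_identical(cmp$n_query_mf, 2L)
  expect_identical(cmp$n_query_gcf, 1L)
  expect_identical(cmp$n_query_both, 1L)
  expect_identical(intersect(cmp$query_mf, cmp$query_gcf), "A")
  expect_identical(cmp$n_reference_both, 1L)

  # identical singleton groupings: intersection is the full set
  qa2 <- gcf_assignment(c("A", "B"), c("GCF_1", "GCF_2"), c(1, 1))
  ra2 <- gcf_assignment(c("R1", "R2"), c("GCF_1", "GCF_2"), c(1, 1),
                        dataset_label = "mibig")
  cmp2 <- compare_grouping(mf, qa2, ra2)
  expect_identical(cmp2$n_query_both, 2L)
  # MF groups nothing: intersection 0
  mf0 <- molecular_families(build_network(links[0, ],
                                          data.frame(accession_a = character(),
                                                     accession_b = character(),
                                                     weight = numeric()),
                                          all_query_ids = c("A", "B")))
  expect_identical(compare_grouping(mf0, qa2, ra2)$n_query_both, 0L)
})

test_that("network and MF-report files are written consistently", {
  links <- data.frame(region_id = "A", reference_accession = "R1",
                      score = 0.75)
  chem <- data.frame(accession_a = "R1", accession_b = "R2", weight = 0.6)
  net <- build_network(links, chem, all_query_ids = c("A", "Z"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(net, p)
  el <- read.delim(p)
  expect_identical(nrow(el), 3L)  # 2 edges + 1 isolated node
  expect_setequal(el$edge_type, c("genomic", "chemical", "isolated"))

  pg <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, pg)
  expect_true(file.size(pg) > 0)

  pj <- withr::local_tempfile(fileext = ".json")
  write_mf_report(molecular_families(net), pj)
  rep <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_identical(rep$n_mfs, 1L)
  expect_identical(rep$families$n_query, 1L)
})

test_that("parser hydrogen filling agrees with an external cheminformatics oracle", {
  # RDKit (via the system python) as an independent oracle for molecular
  # formulas, exercising valence/aromatic-H perception on every scaffold
  smis <- unname(scaffold_smiles())
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem.rdMolDescriptors import CalcMolFormula",
    "for s in sys.stdin.read().split():",
    "    print(CalcMolFormula(Chem.MolFromSmiles(s)))",
    sep = "\n")
  oracle <- system2("python", c("-c", shQuote(script)),
                    input = paste(smis, collapse = "\n"), stdout = TRUE)
  expect_length(oracle, length(smis))
  expect_identical(vapply(smis, formula_from_parser, character(1),
                          USE.NAMES = FALSE), oracle)
})
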