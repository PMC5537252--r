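test_that("sequence window encoding is one-hot with the stated dimension", {
  v <- encode_sequence_window("MKTAYIAKQ")
  expect_length(v, 180)
  expect_equal(sum(v), 9)

  v1 <- encode_sequence_window("XXXXSXXXX")
  expect_equal(sum(v1), 1)
  # position-5 block, serine column (S is 16th of ACDEFGHIKLMNPQRSTVWY)
  expect_equal(which(v1 == 1), (5 - 1) * 20 + 16)

  # single-position substitution flips exactly two coordinates
  a <- encode_sequence_window("MKTAYIAKQ")
  b <- encode_sequence_window("MKTAYPAKQ")
  expect_equal(sum(a != b), 2)

  expect_error(encode_sequence_window("MKTAY"), "length 9")
  expect_error(encode_sequence_window("MKTAbIAKQ"), "Invalid track symbol")
})

test_that("structure-track encoders have dimensions 27, 63 and 18", {
  ss <- encode_secondary_structure("CCCCCCCCC")
  expect_length(ss, 27)
  expect_equal(sum(ss), 9)
  expect_equal(which(ss == 1), seq(3, 27, by = 3))  # C is third of (H, E, C)
  expect_equal(sum(encode_secondary_structure("CCCCXCCCC")), 8)

  sa <- encode_solvent_accessibility("000000000")
  expect_length(sa, 63)
  expect_equal(which(sa == 1), seq(1, 63, by = 7))
  expect_equal(sum(encode_solvent_accessibility(strrep("X", 9))), 0)

  di <- encode_disorder("DDDDDDDDD")
  expect_length(di, 18)
  expect_equal(which(di == 1), seq(2, 18, by = 2))
  alt <- encode_disorder("ODODODODO")
  expect_equal(sum(alt), 9)
  expect_equal(which(alt == 1), c(1, 4, 5, 8, 9, 12, 13, 16, 17))
})

test_that("layout arithmetic reproduces the published block indexing", {
  seq_only <- make_layout(sequence_block_sizes())
  expect_equal(seq_only$total, 288)

  published <- make_layout(c(
    AAseq = 180, SS = 27, SA = 63, DISO = 18,
    BP = 248, CC = 51, InterPro = 187, pathway = 44,
    MF = 77, domain = 51, PPI = 4752
  ))
  expect_equal(published$total, 5698)
  ppi <- published$blocks[published$blocks$block == "PPI", ]
  expect_equal(ppi$start, 947)
  expect_equal(ppi$end, 5698)
  expect_equal(ppi$size, 4752)
  # spot-check published feature-type labels at their V-indices
  expect_equal(published$features$label[107], "AA6_AAseq")
  expect_equal(published$features$label[192], "AA4_SS")
  expect_equal(published$features$label[272], "AA1_DISO")
  expect_equal(published$features$label[789], "Pro_pathway")

  expect_error(make_layout(c(AAseq = 179)), "inconsistent with window length")
  expect_error(make_layout(c(BP = 3), term_index = list(BP = c("a", "b"))),
               "does not match")
  expect_error(make_layout(c(Foo = 3)), "Unknown feature blocks")
})

test_that("V-index name mapping round-trips over the whole layout", {
  lay <- layout_from_terms(list(BP = c("b1", "b2"), PPI = c("p1")))
  expect_equal(lay$total, 291)
  idx <- seq_len(lay$total)
  expect_equal(vname_index(lay, vindex_name(lay, idx)), idx)
  expect_error(vname_index(lay, "V9999"), "Unknown feature name")
})

test_that("functional encoding is protein-level and zero for unannotated", {
  lay <- layout_from_terms(list(BP = c("bp1", "bp9"), CC = c("cc1"),
                                PPI = c("partner1")))
  cat <- toy_catalog()
  v1 <- encode_functional_blocks("P1", cat, lay)
  expect_equal(v1, c(1L, 0L, 1L, 1L))
  v2 <- encode_functional_blocks("P2", cat, lay)
  expect_equal(v2, c(1L, 0L, 0L, 0L))
  expect_warning(v3 <- encode_functional_blocks("P3", cat, lay),
                 "no annotations")
  expect_equal(sum(v3), 0)
})

test_that("assembled matrices conserve dimensions and row identity", {
  ds <- build_dataset(toy_sites(), toy_proteins(), toy_structures())
  lay <- layout_from_terms(list(BP = c("bp1"), CC = c("cc1"),
                                PPI = c("partner1")))

  fm_aa <- assemble_feature_matrix(ds, lay, blocks = "AAseq")
  expect_equal(dim(fm_aa$x), c(3, 180))

  fm <- assemble_feature_matrix(ds, lay, catalog = toy_catalog())
  expect_equal(ncol(fm$x), 291)
  expect_true(all(fm$x %in% c(0, 1)))
  # pad-free windows carry exactly 9 ones per sequence-derived block
  interior <- which(!grepl("X", ds$peptide, fixed = TRUE))
  for (i in interior) {
    expect_equal(sum(fm$x[i, 1:180]), 9)
    expect_equal(sum(fm$x[i, 181:207]), 9)
    expect_equal(sum(fm$x[i, 208:270]), 9)
    expect_equal(sum(fm$x[i, 271:288]), 9)
  }
  # functional sub-vectors identical for two sites on the same protein
  p1_rows <- which(ds$protein_id == "P1")
  expect_equal(fm$x[p1_rows[1], 289:291], fm$x[p1_rows[2], 289:291])

  # permuting dataset rows permutes matrix rows identically
  perm <- c(3, 1, 2)
  fm_perm <- assemble_feature_matrix(ds[perm, ], lay, catalog = toy_catalog())
  expect_equal(unname(fm_perm$x), unname(fm$x[perm, ]))

  # functional blocks need a catalog
  expect_error(assemble_feature_matrix(ds, lay), "no annotation catalog")
  expect_error(assemble_feature_matrix(ds, lay, blocks = "nope"),
               "not in layout")
})

test_that("a padded serine window on an unannotated protein has one nonzero", {
  prot <- tibble::tibble(protein_id = "LONE", sequence = "SAAAAAAAA")
  tracks <- tibble::tibble(protein_id = "LONE",
                           ss = strrep("C", 9), sa = strrep("0", 9),
                           diso = strrep("O", 9))
  site <- tibble::tibble(protein_id = "LONE", position = 1L, residue = "S",
                         kinase = "CDKs", label = "positive")
  ds <- suppressWarnings(build_dataset(site, prot, tracks))
  lay <- layout_from_terms(list(BP = c("bp1")))
  cat <- annotation_catalog(
    tibble::tibble(protein_id = "OTHER", category = "BP", term = "bp1"),
    background = c("OTHER", "LONE"))
  fm <- suppressWarnings(
    assemble_feature_matrix(ds, lay, catalog = cat, blocks = c("AAseq", "BP")))
  # peptide is XXXXSAAAA: 5 AAseq ones, 0 functional
  expect_equal(sum(fm$x), 5)
})
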