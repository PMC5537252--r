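test_that("protein generation is seeded with near-uniform composition", {
  cfg <- synthetic_config(seed = 1)
  p1 <- generate_proteins(cfg, n = 10, seed = 5)
  expect_equal(nrow(p1), 10)
  expect_identical(p1, generate_proteins(cfg, n = 10, seed = 5))
  expect_true(all(nchar(p1$sequence) >= cfg$protein_length$min))

  big <- generate_proteins(synthetic_config(
    protein_length = list(mean = 1000, min = 900), seed = 1),
    n = 100, seed = 9)
  freq <- table(strsplit(paste(big$sequence, collapse = ""), "")[[1]])
  n_res <- sum(freq)
  # each residue within 3 SD of the uniform 0.05 expectation
  se <- sqrt(0.05 * 0.95 / n_res)
  expect_true(all(abs(freq / n_res - 0.05) < 3 * se + 1e-6))
})

test_that("planted sites carry the proline-directed motif at the set rate", {
  base <- generate_proteins(synthetic_config(seed = 2),
                            n = 200, prefix = "SUB", seed = 2)

  all_p <- plant_sites(base, synthetic_config(p_motif = 1, seed = 2), seed = 3)
  plus1 <- substring(all_p$proteins$sequence[match(all_p$sites$protein_id,
                                                   all_p$proteins$protein_id)],
                     all_p$sites$position + 1, all_p$sites$position + 1)
  expect_true(all(plus1 == "P"))
  centre <- substring(all_p$proteins$sequence[match(all_p$sites$protein_id,
                                                    all_p$proteins$protein_id)],
                      all_p$sites$position, all_p$sites$position)
  expect_true(all(centre %in% c("S", "T")))

  part <- plant_sites(base, synthetic_config(p_motif = 0.8, seed = 2), seed = 4)
  plus1 <- substring(part$proteins$sequence[match(part$sites$protein_id,
                                                  part$proteins$protein_id)],
                     part$sites$position + 1, part$sites$position + 1)
  phat <- mean(plus1 == "P")
  # binomial 99% band around 0.8 over 200 draws (background P adds ~1%)
  expect_gt(phat, 0.8 - 2.58 * sqrt(0.8 * 0.2 / 200) - 0.02)
  expect_lt(phat, 0.8 + 2.58 * sqrt(0.8 * 0.2 / 200) + 0.02)

  none <- plant_sites(base, synthetic_config(p_motif = 0, p_motif_minus1 = 0,
                                             seed = 2), seed = 5)
  plus1 <- substring(none$proteins$sequence[match(none$sites$protein_id,
                                                  none$proteins$protein_id)],
                     none$sites$position + 1, none$sites$position + 1)
  expect_lt(mean(plus1 == "P"), 0.15)  # background rate ~1/20
})

test_that("disorder bias controls positive-site disorder coverage", {
  cfg1 <- synthetic_config(n_substrates = 100, n_background = 50,
                           disorder_bias = 1, seed = 3)
  st1 <- generate_synthetic_study(cfg1)
  d_at <- substring(st1$structures$diso[match(st1$sites$protein_id,
                                              st1$structures$protein_id)],
                    st1$sites$position, st1$sites$position)
  expect_true(all(d_at == "D"))

  cfg <- synthetic_config(n_substrates = 200, n_background = 200,
                          disorder_bias = 0.8, base_disorder = 0.2, seed = 4)
  st <- generate_synthetic_study(cfg)
  d_pos <- substring(st$structures$diso[match(st$sites$protein_id,
                                              st$structures$protein_id)],
                     st$sites$position, st$sites$position) == "D"
  bg_sites <- enumerate_background_sites(
    st$proteins[st$proteins$protein_id %in% st$background_ids, ])
  set.seed(1)
  bg_sites <- bg_sites[sample(nrow(bg_sites), 200), ]
  d_bg <- substring(st$structures$diso[match(bg_sites$protein_id,
                                             st$structures$protein_id)],
                    bg_sites$position, bg_sites$position) == "D"
  test <- prop.test(c(sum(d_pos), c(sum(d_bg))), c(200, 200))
  expect_lt(test$p.value, 0.001)
  expect_gt(mean(d_pos), mean(d_bg))
})

test_that("planted annotation terms are recovered; noise terms are not", {
  cfg <- synthetic_config(
    n_substrates = 50, n_background = 1000,
    planted_terms = tibble::tibble(category = "BP", term = "PLANTED",
                                   freq_substrate = 0.9,
                                   freq_background = 0.05),
    n_noise_terms = 5, seed = 1)
  study <- paste0("S", 1:50)
  bg <- paste0("B", 1:1000)
  hits <- 0; null_sig <- 0; null_total <- 0
  for (s in 1:20) {
    cat <- simulate_annotation_catalog(study, bg, cfg, seed = 100 + s)
    rec <- test_terms(study, cat, "BP")
    hits <- hits + rec$significant[rec$term == "PLANTED"]
    noise <- rec[rec$term != "PLANTED", ]
    null_sig <- null_sig + sum(noise$significant)
    null_total <- null_total + nrow(noise)
  }
  expect_equal(hits, 20)
  expect_lte(null_sig / null_total, 0.01 + 3 * sqrt(0.01 * 0.99 / null_total))

  # empty planted list -> no functional signal to find
  cfg0 <- synthetic_config(planted_terms = default_planted_terms()[0, ],
                           n_noise_terms = 0, seed = 1)
  cat0 <- simulate_annotation_catalog(study, bg, cfg0, seed = 7)
  expect_equal(nrow(cat0$annotations), 0)
})

test_that("full fixtures are byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_substrates = 15, n_background = 30, seed = 6)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- generate_full_fixture(cfg, d1)
  p2 <- generate_full_fixture(cfg, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     info = paste("file:", f))
  }
  # fixture loads end-to-end through the reader layer
  prot <- read_fasta(p1[["fasta"]])
  sites <- read_site_table(p1[["sites"]])
  tracks <- read_structure_table(p1[["structures"]])
  validate_structures(tracks, prot)
  validate_sites(sites, prot)
  expect_equal(sum(sites$label == "positive"), 15)
  expect_equal(sum(sites$label == "negative"), 15)
  ds <- build_dataset(sites, prot, tracks)
  expect_equal(nrow(ds), 30)
})

test_that("null fixtures drive downstream discrimination to chance", {
  cfg <- synthetic_config(
    n_substrates = 40, n_background = 80,
    p_motif = 0, p_motif_minus1 = 0,
    disorder_bias = 0.2, base_disorder = 0.2,
    planted_terms = default_planted_terms()[0, ],
    seed = 8)
  st <- generate_synthetic_study(cfg)
  ds <- study_dataset(st, seed = 2)
  fm <- assemble_feature_matrix(ds, make_layout(sequence_block_sizes()))
  cv <- cross_validate(fm, folds = 5, repeats = 3, n_trees = 100, seed = 3)
  auc <- cv$summary[cv$summary$metric == "AUC", ]
  expect_lt(abs(auc$mean - 0.5), 3 * max(auc$sd, 0.05))
})
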