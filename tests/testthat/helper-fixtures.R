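# Shared toy fixtures, built in code.

toy_proteins <- function() {
  tibble::tibble(
    protein_id = c("P1", "P2"),
    sequence = c("MKTAYIAKQRQISFVKSHFSRQLEE",  # 25 aa
                 "ASTYAASPTSPA")               # 12 aa
  )
}

toy_structures <- function(proteins = toy_proteins()) {
  tibble::tibble(
    protein_id = proteins$protein_id,
    ss = vapply(nchar(proteins$sequence),
                function(L) paste(rep(c("C", "H", "E"), length.out = L),
                                  collapse = ""), character(1)),
    sa = vapply(nchar(proteins$sequence),
                function(L) paste(rep(as.character(0:6), length.out = L),
                                  collapse = ""), character(1)),
    diso = vapply(nchar(proteins$sequence),
                  function(L) paste(rep(c("O", "D"), length.out = L),
                                    collapse = ""), character(1))
  )
}

toy_sites <- function() {
  tibble::tibble(
    protein_id = c("P1", "P1", "P2"),
    position = c(5L, 17L, 2L),
    residue = c("Y", "S", "S"),
    kinase = "CDKs",
    label = c("positive", "positive", "negative")
  )
}

toy_catalog <- function() {
  annotation_catalog(
    tibble::tibble(
      protein_id = c("P1", "P1", "P1", "P2"),
      category = c("BP", "CC", "PPI", "BP"),
      term = c("bp1", "cc1", "partner1", "bp1")
    ),
    background = c("P1", "P2", "P3", "P4")
  )
}

# Small planted-signal study used by several suites (cheap to build).
small_study <- function(seed = 42, n_sub = 30, n_bg = 60) {
  generate_synthetic_study(synthetic_config(
    n_substrates = n_sub, n_background = n_bg, seed = seed))
}

# Labeled dataset (positives + 1:1 negatives) from a study.
study_dataset <- function(study, seed = 1) {
  bg <- enumerate_background_sites(
    study$proteins[study$proteins$protein_id %in% study$background_ids, ])
  neg <- sample_negatives(bg, study$sites, n = nrow(study$sites), seed = seed)
  build_dataset(dplyr::bind_rows(study$sites, neg),
                study$proteins, study$structures)
}

# Exact hypergeometric tails by combinatorial counting (independent of
# stats::phyper): P[X <= q] = sum_j C(m, j) C(n, k - j) / C(m + n, k).
enum_hyper_tails <- function(q, m, n, k) {
  total <- choose(m + n, k)
  js <- 0:min(m, k)
  mass <- choose(m, js) * choose(n, k - js) / total
  c(lower = sum(mass[js <= q]), upper = sum(mass[js >= q]))
}
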