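# Average amino-acid composition of UniProtKB/Swiss-Prot, used by the
# optional empirical-composition mode of the generator.
EMPIRICAL_AA_FREQ <- c(
  A = 0.0825, C = 0.0138, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0707, H = 0.0227, I = 0.0591, K = 0.0580, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0474, Q = 0.0393, R = 0.0553,
  S = 0.0665, T = 0.0536, V = 0.0686, W = 0.0110, Y = 0.0292
)

#' Configuration for the synthetic planted-motif study generator
#'
#' Defines the statistical structure the prediction method assumes: positive
#' windows carrying a proline-directed motif (P at +1 with probability
#' `p_motif`, and at -1 with a lesser probability), elevated intrinsic
#' disorder at positive sites, and annotation terms enriched among
#' substrates relative to the background proteome.
#'
#' @param kinase Kinase family of the planted signal (default `"MAPKs"`,
#'   the proline-directed case).
#' @param n_substrates Number of substrate proteins (one planted site each).
#' @param n_background Number of background proteins.
#' @param protein_length List with `mean` and `min` residue counts.
#' @param p_motif Probability a positive site has P at +1.
#' @param p_motif_minus1 Probability of P at -1 (the weaker preference).
#' @param disorder_bias Probability a positive site lies in a disordered
#'   run; background sites see `base_disorder`.
#' @param base_disorder Marginal disorder rate of background residues.
#' @param planted_terms Tibble (`category`, `term`, `freq_substrate`,
#'   `freq_background`) of enriched annotation terms.
#' @param n_noise_terms Unenriched terms per category.
#' @param noise_term_freq Carrier frequency of noise terms in both groups.
#' @param composition `"uniform"` residue composition (default; keeps
#'   analytic error bounds exact) or `"empirical"` (database-average).
#' @param seed Integer seed; the whole fixture is reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(kinase = "MAPKs",
                             n_substrates = 200L,
                             n_background = 400L,
                             protein_length = list(mean = 60L, min = 30L),
                             p_motif = 0.8,
                             p_motif_minus1 = 0.6,
                             disorder_bias = 0.6,
                             base_disorder = 0.2,
                             planted_terms = default_planted_terms(),
                             n_noise_terms = 5L,
                             noise_term_freq = 0.1,
                             composition = c("uniform", "empirical"),
                             seed = 1L) {
  composition <- match.arg(composition)
  probs <- c(p_motif, p_motif_minus1, disorder_bias, base_disorder,
             noise_term_freq)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must be in [0, 1]")
  if (n_substrates < 1 || n_background < 1) abort("Counts must be positive")
  if (protein_length$min < 9) abort("Minimum length must cover a 9-mer window")
  if (nrow(planted_terms) > 0) {
    stopifnot(all(c("category", "term", "freq_substrate",
                    "freq_background") %in% names(planted_terms)))
    if (any(planted_terms$freq_substrate < planted_terms$freq_background)) {
      abort("Planted over-represented terms need freq_substrate >= freq_background")
    }
    bad <- setdiff(planted_terms$category, ANNOTATION_CATEGORIES)
    if (length(bad) > 0) {
      abort(paste0("Unknown planted-term categories: ",
                   paste(bad, collapse = ", ")))
    }
  }
  structure(list(kinase = kinase, n_substrates = as.integer(n_substrates),
                 n_background = as.integer(n_background),
                 protein_length = protein_length,
                 p_motif = p_motif, p_motif_minus1 = p_motif_minus1,
                 disorder_bias = disorder_bias,
                 base_disorder = base_disorder,
                 planted_terms = tibble::as_tibble(planted_terms),
                 n_noise_terms = as.integer(n_noise_terms),
                 noise_term_freq = noise_term_freq,
                 composition = composition,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default planted enrichment signal (three terms)
#' @return Tibble of planted terms.
#' @export
default_planted_terms <- function() {
  tibble::tibble(
    category = c("BP", "CC", "PPI"),
    term = c("BP_PLANTED_1", "CC_PLANTED_1", "PARTNER_HUB_1"),
    freq_substrate = c(0.6, 0.5, 0.4),
    freq_background = c(0.1, 0.1, 0.05)
  )
}

#' Generate random protein sequences
#'
#' Residues are i.i.d. from the configured composition; lengths are
#' `min + Poisson(mean - min)`.
#'
#' @param config A `synthetic_config`.
#' @param n Number of proteins (default: substrates + background).
#' @param prefix Identifier prefix.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Protein tibble.
#' @export
generate_proteins <- function(config, n = NULL, prefix = "PROT",
                              seed = NULL) {
  n <- n %||% (config$n_substrates + config$n_background)
  gen <- function() {
    lens <- config$protein_length$min +
      rpois(n, max(0, config$protein_length$mean - config$protein_length$min))
    prob <- if (config$composition == "uniform") NULL else EMPIRICAL_AA_FREQ
    seqs <- vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE, prob = prob), collapse = "")
    }, character(1))
    tibble::tibble(
      protein_id = sprintf("%s_%04d", prefix, seq_len(n)),
      sequence = seqs
    )
  }
  if (is.null(seed)) gen() else with_seed_local(seed, gen())
}

#' Plant kinase-motif phosphosites into substrate proteins
#'
#' For each substrate protein one interior S/T (or Y for tyrosine kinases)
#' site is placed with a full window available; the +1 flank is set to P
#' with probability `p_motif` and the -1 flank with `p_motif_minus1`.
#' Sequences are edited in place, so the returned proteins must be used
#' downstream.
#'
#' @param proteins Substrate protein tibble.
#' @param config A `synthetic_config`.
#' @param seed Optional seed.
#' @return List with `proteins` (edited) and `sites` (positive tibble).
#' @export
plant_sites <- function(proteins, config, seed = NULL) {
  half_width <- 4L
  target <- kinase_target_residues(config$kinase)
  gen <- function() {
    seqs <- proteins$sequence
    rows <- vector("list", nrow(proteins))
    for (i in seq_len(nrow(proteins))) {
      L <- nchar(seqs[i])
      if (L < 2L * half_width + 1L) {
        warn(paste0("Protein ", proteins$protein_id[i],
                    " too short for a window; skipped"))
        next
      }
      pos <- sample((half_width + 1L):(L - half_width), 1)
      res <- sample(target, 1)
      s <- seqs[i]
      substr(s, pos, pos) <- res
      if (runif(1) < config$p_motif) substr(s, pos + 1L, pos + 1L) <- "P"
      if (runif(1) < config$p_motif_minus1) substr(s, pos - 1L, pos - 1L) <- "P"
      seqs[i] <- s
      rows[[i]] <- tibble::tibble(protein_id = proteins$protein_id[i],
                                  position = pos, residue = res,
                                  kinase = config$kinase,
                                  label = "positive")
    }
    list(proteins = tibble::tibble(protein_id = proteins$protein_id,
                                   sequence = seqs),
         sites = dplyr::bind_rows(rows))
  }
  if (is.null(seed)) gen() else with_seed_local(seed, gen())
}

# Two-state run process over `states` with geometric run lengths chosen so
# the stationary fraction of the second state is `rate`.
run_track <- function(L, states, rate, mean_run = 8) {
  if (rate <= 0) return(strrep(states[1], L))
  if (rate >= 1) return(strrep(states[2], L))
  len_on <- mean_run
  len_off <- mean_run * (1 - rate) / rate
  out <- character(0)
  state <- runif(1) < rate
  while (sum(nchar(out)) < L) {
    run <- 1 + rpois(1, (if (state) len_on else len_off) - 1)
    out <- c(out, strrep(states[1 + state], run))
    state <- !state
  }
  substr(paste(out, collapse = ""), 1, L)
}

#' Simulate structural annotation tracks
#'
#' Secondary structure and solvent accessibility are run-length processes
#' (uninformative about the planted sites); disorder covers each positive
#' site's window with probability `disorder_bias` (else the site is forced
#' ordered), while background residues follow the base disorder rate. At
#' `disorder_bias = base_disorder` positive and background sites are
#' indistinguishable in expectation.
#'
#' @param proteins Protein tibble (post [plant_sites()]).
#' @param positives Positive site tibble (may be empty).
#' @param config A `synthetic_config`.
#' @param seed Optional seed.
#' @return Structure tibble (`protein_id`, `ss`, `sa`, `diso`).
#' @export
simulate_structure_tracks <- function(proteins, positives, config,
                                      seed = NULL) {
  half_width <- 4L
  gen <- function() {
    tracks <- purrr::map2_dfr(proteins$protein_id, proteins$sequence,
                              function(id, s) {
      L <- nchar(s)
      ss_runs <- character(0)
      while (sum(nchar(ss_runs)) < L) {
        ss_runs <- c(ss_runs, strrep(sample(SS_LEVELS, 1, prob = c(.35, .2, .45)),
                                     1 + rpois(1, 5)))
      }
      sa_runs <- character(0)
      while (sum(nchar(sa_runs)) < L) {
        sa_runs <- c(sa_runs, strrep(sample(SA_LEVELS, 1), 1 + rpois(1, 3)))
      }
      tibble::tibble(
        protein_id = id,
        ss = substr(paste(ss_runs, collapse = ""), 1, L),
        sa = substr(paste(sa_runs, collapse = ""), 1, L),
        diso = run_track(L, c("O", "D"), config$base_disorder)
      )
    })
    if (!is.null(positives) && nrow(positives) > 0) {
      for (i in seq_len(nrow(positives))) {
        row <- match(positives$protein_id[i], tracks$protein_id)
        L <- nchar(tracks$diso[row])
        pos <- positives$position[i]
        if (runif(1) < config$disorder_bias) {
          lo <- max(1L, pos - half_width)
          hi <- min(L, pos + half_width)
          substr(tracks$diso[row], lo, hi) <- strrep("D", hi - lo + 1L)
        } else {
          substr(tracks$diso[row], pos, pos) <- "O"
        }
      }
    }
    tracks
  }
  if (is.null(seed)) gen() else with_seed_local(seed, gen())
}

#' Simulate a functional annotation catalog with planted enrichment
#'
#' Planted terms are assigned per protein as Bernoulli draws with the two
#' configured carrier frequencies; noise terms use a common frequency in
#' both groups. PPI terms are interaction-partner identifiers, so PPI
#' enrichment means partner over-representation.
#'
#' @param substrate_ids Substrate protein ids.
#' @param background_ids Background protein ids.
#' @param config A `synthetic_config`.
#' @param seed Optional seed.
#' @return An `annotation_catalog` whose background is the union of both
#'   id sets.
#' @export
simulate_annotation_catalog <- function(substrate_ids, background_ids,
                                        config, seed = NULL) {
  gen <- function() {
    all_ids <- c(substrate_ids, background_ids)
    is_sub <- c(rep(TRUE, length(substrate_ids)),
                rep(FALSE, length(background_ids)))
    rows <- list()
    pt <- config$planted_terms
    for (i in seq_len(nrow(pt))) {
      p <- ifelse(is_sub, pt$freq_substrate[i], pt$freq_background[i])
      carrier <- runif(length(all_ids)) < p
      rows[[length(rows) + 1]] <- tibble::tibble(
        protein_id = all_ids[carrier],
        category = pt$category[i], term = pt$term[i])
    }
    if (config$n_noise_terms > 0) {
      for (cat in ANNOTATION_CATEGORIES) {
        for (j in seq_len(config$n_noise_terms)) {
          term <- sprintf("%s_NOISE_%02d", cat, j)
          carrier <- runif(length(all_ids)) < config$noise_term_freq
          rows[[length(rows) + 1]] <- tibble::tibble(
            protein_id = all_ids[carrier], category = cat, term = term)
        }
      }
    }
    annotation_catalog(dplyr::bind_rows(rows), background = all_ids)
  }
  if (is.null(seed)) gen() else with_seed_local(seed, gen())
}

#' Generate a complete in-memory synthetic study
#'
#' Deterministic under `config$seed`: substrate and background proteins,
#' planted positive sites, structural tracks and an annotation catalog, all
#' consistent with each other and loadable by the rest of the pipeline.
#'
#' @param config A `synthetic_config`.
#' @return List with `proteins`, `sites` (positives), `structures`,
#'   `catalog`, `substrate_ids`, `background_ids`, `config`.
#' @export
generate_synthetic_study <- function(config = synthetic_config()) {
  with_seed_local(config$seed, {
    substrates <- generate_proteins(config, n = config$n_substrates,
                                    prefix = "SUB")
    background <- generate_proteins(config, n = config$n_background,
                                    prefix = "BG")
    planted <- plant_sites(substrates, config)
    proteins <- dplyr::bind_rows(planted$proteins, background)
    structures <- simulate_structure_tracks(proteins, planted$sites, config)
    catalog <- simulate_annotation_catalog(planted$proteins$protein_id,
                                           background$protein_id, config)
    list(proteins = proteins, sites = planted$sites,
         structures = structures, catalog = catalog,
         substrate_ids = planted$proteins$protein_id,
         background_ids = background$protein_id,
         config = config)
  })
}

#' Write a full synthetic fixture to disk
#'
#' Emits `proteins.fasta`, `sites.tsv` (planted positives plus 1:1 sampled
#' negatives), `structures.tsv`, `annotations.tsv` and `manifest.yaml`
#' echoing the configuration. Byte-identical under a fixed seed.
#'
#' @param config A `synthetic_config`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly; the study list
#'   is attached as attribute `study`.
#' @export
generate_full_fixture <- function(config = synthetic_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- generate_synthetic_study(config)
  negatives <- with_seed_local(config$seed + 1L, {
    bg_sites <- enumerate_background_sites(
      study$proteins[study$proteins$protein_id %in% study$background_ids, ])
    sample_negatives(bg_sites, study$sites, n = nrow(study$sites))
  })
  sites <- dplyr::bind_rows(study$sites, negatives)
  paths <- c(
    fasta = file.path(out_dir, "proteins.fasta"),
    sites = file.path(out_dir, "sites.tsv"),
    structures = file.path(out_dir, "structures.tsv"),
    annotations = file.path(out_dir, "annotations.tsv"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  write_fasta(study$proteins, paths[["fasta"]])
  write_site_table(sites, paths[["sites"]])
  write_structure_table(study$structures, paths[["structures"]])
  write_annotation_table(study$catalog, paths[["annotations"]])
  manifest <- unclass(config)
  manifest$planted_terms <- as.list(as.data.frame(config$planted_terms))
  yaml::write_yaml(manifest, paths[["manifest"]])
  attr(paths, "study") <- study
  invisible(paths)
}
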