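#' Extract a site-centred window with aligned structural tracks
#'
#' Returns the peptide of `2 * half_width + 1` residues centred on
#' `position`, with the secondary-structure, solvent-accessibility and
#' disorder tracks cut identically. Flanks that fall outside the protein are
#' padded with `X` simultaneously on all four tracks.
#'
#' @param sequence Protein sequence string.
#' @param position 1-based centre position.
#' @param ss,sa,diso Per-residue track strings of the same length as
#'   `sequence`; `NULL` yields all-`X` tracks.
#' @param half_width Number of flanking residues on each side (default 4,
#'   i.e. a 9-mer window).
#' @return A one-row tibble with `peptide`, `ss_track`, `sa_track`,
#'   `diso_track`.
#' @export
#' @examples
#' extract_window("MKTAYIAKQRQISFVKSHFSRQLEE", 10)
extract_window <- function(sequence, position, ss = NULL, sa = NULL,
                           diso = NULL, half_width = 4L) {
  len <- nchar(sequence)
  if (position < 1L || position > len) {
    abort(paste0("Position ", position, " out of range 1..", len))
  }
  cut <- function(track) {
    if (is.null(track)) return(strrep("X", 2L * half_width + 1L))
    offs <- (position - half_width):(position + half_width)
    chars <- ifelse(offs >= 1L & offs <= len,
                    substring(track, offs, offs), "X")
    paste(chars, collapse = "")
  }
  tibble::tibble(
    peptide = cut(sequence),
    ss_track = cut(ss),
    sa_track = cut(sa),
    diso_track = cut(diso)
  )
}

#' Enumerate all candidate sites in a protein set
#'
#' Scans each sequence for the requested residue types (default S/T/Y) and
#' returns one unlabeled site per occurrence, in protein order then position
#' order. This is the background site universe from which negatives are
#' sampled and over which proteome scans run.
#'
#' @param proteins Protein tibble (`protein_id`, `sequence`).
#' @param residues Residue types to collect.
#' @return Tibble with `protein_id`, `position`, `residue`.
#' @export
enumerate_background_sites <- function(proteins, residues = c("S", "T", "Y")) {
  stopifnot(nrow(proteins) > 0)
  purrr::map2_dfr(proteins$protein_id, proteins$sequence, function(id, s) {
    chars <- strsplit(s, "")[[1]]
    hit <- which(chars %in% residues)
    tibble::tibble(protein_id = rep(id, length(hit)),
                   position = hit, residue = chars[hit])
  })
}

#' Sample negative sites from the background universe
#'
#' Draws `n` distinct sites from the background that do not coincide with a
#' known positive (same protein and position). Under the default
#' `match_positive_types` policy, candidate residues are restricted to the
#' residue types observed among the positives, so e.g. negatives for a
#' tyrosine kinase are tyrosines only.
#'
#' @param background Tibble from [enumerate_background_sites()].
#' @param positives Tibble of positive sites (needs `protein_id`, `position`,
#'   `residue`, `kinase`).
#' @param n Number of negatives to draw.
#' @param residue_policy `"match_positive_types"` or `"all_STY"`.
#' @param seed Optional integer seed for reproducible sampling.
#' @return Tibble of sites labeled `negative`, carrying the positives' kinase.
#' @export
sample_negatives <- function(background, positives, n,
                             residue_policy = c("match_positive_types",
                                                "all_STY"),
                             seed = NULL) {
  residue_policy <- match.arg(residue_policy)
  stopifnot(n >= 0)
  kinase <- unique(positives$kinase)
  if (length(kinase) != 1) {
    abort("Positives must belong to a single kinase family")
  }
  pool <- dplyr::anti_join(background, positives,
                           by = c("protein_id", "position"))
  if (residue_policy == "match_positive_types") {
    pool <- dplyr::filter(pool, .data$residue %in% unique(positives$residue))
  }
  if (nrow(pool) < n) {
    abort(paste0("Insufficient negative candidates: need ", n,
                 ", have ", nrow(pool)))
  }
  draw <- function() pool[sample.int(nrow(pool), n), , drop = FALSE]
  picked <- if (is.null(seed)) draw() else with_seed_local(seed, draw())
  dplyr::mutate(picked, kinase = kinase, label = "negative")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Pairwise global sequence identity
#'
#' Needleman-Wunsch global alignment with unit match score, zero mismatch
#' score and a linear gap penalty of -1; identity is the number of exact
#' matches divided by the alignment length (including gap columns).
#'
#' @param a,b Sequence strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
sequence_identity <- function(a, b) {
  letters21 <- c(AA20, "X")
  submat <- matrix(0, 21, 21, dimnames = list(letters21, letters21))
  diag(submat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = submat,
    gapOpening = 0, gapExtension = 1
  )
  aligned_a <- as.character(Biostrings::alignedPattern(aln))
  aligned_b <- as.character(Biostrings::alignedSubject(aln))
  matches <- sum(strsplit(aligned_a, "")[[1]] == strsplit(aligned_b, "")[[1]])
  matches / nchar(aligned_a)
}

#' Remove redundant proteins by greedy identity clustering
#'
#' Greedy longest-first clustering: proteins are visited in decreasing length
#' order (ties by id) and retained unless their global-alignment identity to
#' an already-retained protein reaches the threshold. This enforces the same
#' contract as CD-HIT-style redundancy reduction (no retained pair at or
#' above the identity threshold) without an external binary; it is an
#' approximation, not CD-HIT-equivalent.
#'
#' @param proteins Protein tibble.
#' @param identity_threshold Identity fraction in (0, 1]; default 0.70.
#' @return Character vector of retained protein ids.
#' @export
reduce_redundancy <- function(proteins, identity_threshold = 0.70) {
  stopifnot(nrow(proteins) >= 1)
  if (identity_threshold <= 0 || identity_threshold > 1) {
    abort("identity_threshold must be in (0, 1]")
  }
  ord <- order(-nchar(proteins$sequence), proteins$protein_id)
  retained_id <- character(0)
  retained_seq <- character(0)
  for (i in ord) {
    s <- proteins$sequence[i]
    redundant <- FALSE
    for (r in retained_seq) {
      if (sequence_identity(s, r) >= identity_threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) {
      retained_id <- c(retained_id, proteins$protein_id[i])
      retained_seq <- c(retained_seq, s)
    }
  }
  retained_id
}

#' Build a labeled window dataset for one kinase
#'
#' Validates every site against sequences and structural tracks, extracts the
#' 9-mer window (or `2 * half_width + 1`) around each site, and returns one
#' row per site with the peptide and aligned tracks. A dataset without both
#' labels present is flagged not trainable.
#'
#' @param sites Site tibble with positives and (usually) negatives.
#' @param proteins Protein tibble.
#' @param structures Structure tibble; required for every site's protein.
#' @param kinase Kinase family name; default taken from `sites`.
#' @param half_width Window half-width (default 4).
#' @return A tibble of windows (class `phos_dataset`) with attributes
#'   `kinase` and `trainable`.
#' @export
build_dataset <- function(sites, proteins, structures,
                          kinase = NULL, half_width = 4L) {
  kinase <- kinase %||% unique(sites$kinase)
  if (length(kinase) != 1) abort("Dataset must cover a single kinase family")
  validate_sites(sites, proteins)
  validate_structures(structures, proteins)
  missing_tracks <- setdiff(unique(sites$protein_id), structures$protein_id)
  if (length(missing_tracks) > 0) {
    abort(paste0("No structure track for protein(s): ",
                 paste(missing_tracks, collapse = ", ")))
  }
  joined <- sites |>
    dplyr::left_join(proteins, by = "protein_id") |>
    dplyr::left_join(structures, by = "protein_id")
  windows <- purrr::pmap_dfr(
    list(joined$sequence, joined$position, joined$ss, joined$sa, joined$diso),
    function(seq, pos, ss, sa, diso) {
      extract_window(seq, pos, ss, sa, diso, half_width = half_width)
    }
  )
  out <- dplyr::bind_cols(
    sites[, c("protein_id", "position", "residue", "kinase", "label")],
    windows
  )
  trainable <- all(c("positive", "negative") %in% out$label)
  if (!trainable) {
    warn("Dataset lacks one of the two labels; flagged not trainable")
  }
  structure(out, class = c("phos_dataset", class(out)),
            kinase = kinase, trainable = trainable,
            half_width = as.integer(half_width))
}

#' @export
print.phos_dataset <- function(x, ...) {
  cat("<phos_dataset> kinase:", attr(x, "kinase"),
      " windows:", nrow(x),
      " (", sum(x$label == "positive"), "positive /",
      sum(x$label == "negative"), "negative )\n")
  NextMethod()
}

#' Write a dataset manifest TSV
#'
#' The manifest is the site table plus provenance columns recording how the
#' dataset was assembled.
#'
#' @param dataset A `phos_dataset`.
#' @param path Output path.
#' @param source Provenance label stored per row.
#' @param representatives Optional retained-id vector from
#'   [reduce_redundancy()]; marks each row's cluster representative status.
#' @return `path`, invisibly.
#' @export
write_dataset_manifest <- function(dataset, path, source = "unspecified",
                                   representatives = NULL) {
  manifest <- tibble::as_tibble(dataset)[, c("protein_id", "position",
                                             "residue", "kinase", "label")]
  manifest$source <- source
  manifest$cluster_representative <-
    if (is.null(representatives)) TRUE else manifest$protein_id %in% representatives
  readr::write_tsv(manifest, path)
  invisible(path)
}
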