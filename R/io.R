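#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and any character outside the 20-letter amino-acid
#' alphabet (plus `X`) is replaced by `X` with a warning, so downstream
#' encoders see a closed alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `protein_id` and `sequence`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1", "MKTAYIAKQR"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    abort(paste0("Empty FASTA file: ", path))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    abort(paste0("Malformed FASTA: line ", nonblank[1],
                 " is not a '>' header in ", path))
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) abort(paste0("No sequences in FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(seqs))
  sequence <- toupper(as.character(seqs))
  if (any(!nzchar(sequence))) {
    abort(paste0("Empty sequence for entry: ",
                 paste(ids[!nzchar(sequence)], collapse = ", ")))
  }
  bad <- gsub(paste0("[", paste(AA20, collapse = ""), "X]"), "", sequence)
  if (any(nzchar(bad))) {
    warn(paste0("Non-standard residues mapped to 'X' in: ",
                paste(unique(ids[nzchar(bad)]), collapse = ", ")))
    sequence <- gsub(paste0("[^", paste(AA20, collapse = ""), "X]"), "X",
                     sequence)
  }
  tibble::tibble(protein_id = unname(ids), sequence = unname(sequence))
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Tibble with `protein_id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  chunks <- purrr::map2(proteins$protein_id, proteins$sequence, function(id, s) {
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  })
  writeLines(unlist(chunks), path)
  invisible(path)
}

read_tsv_strict <- function(path, col_types) {
  readr::read_tsv(path, comment = "#", col_types = col_types,
                  progress = FALSE, na = character())
}

#' Read a phosphosite table
#'
#' Expects a TSV with columns `protein_id`, `position` (1-based),
#' `residue` (S/T/Y), `kinase` and `label` (`positive`/`negative`).
#' Duplicate (protein, position, kinase) rows are dropped with a warning.
#' Positions are validated against sequences on join (see
#' [validate_sites()]), not here.
#'
#' @param path Path to a tab-separated site table.
#' @return Tibble of sites.
#' @export
read_site_table <- function(path) {
  sites <- read_tsv_strict(path, readr::cols(
    protein_id = readr::col_character(),
    position = readr::col_integer(),
    residue = readr::col_character(),
    kinase = readr::col_character(),
    label = readr::col_character()
  ))
  missing_cols <- setdiff(c("protein_id", "position", "residue", "kinase", "label"),
                          names(sites))
  if (length(missing_cols) > 0) {
    abort(paste0("Site table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_label <- setdiff(unique(sites$label), c("positive", "negative"))
  if (length(bad_label) > 0) {
    abort(paste0("Unknown site labels (expected positive/negative): ",
                 paste(bad_label, collapse = ", ")))
  }
  bad_res <- setdiff(unique(sites$residue), c("S", "T", "Y"))
  if (length(bad_res) > 0) {
    abort(paste0("Unknown residues (expected S/T/Y): ",
                 paste(bad_res, collapse = ", ")))
  }
  if (any(is.na(sites$position)) || any(sites$position < 1L)) {
    abort("Site positions must be positive 1-based integers")
  }
  n0 <- nrow(sites)
  sites <- dplyr::distinct(sites, .data$protein_id, .data$position,
                           .data$kinase, .keep_all = TRUE)
  if (nrow(sites) < n0) {
    warn(paste0(n0 - nrow(sites),
                " duplicate (protein, position, kinase) rows dropped"))
  }
  sites
}

#' Write a phosphosite table
#' @param sites Tibble of sites.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  readr::write_tsv(sites[, c("protein_id", "position", "residue",
                             "kinase", "label")], path)
  invisible(path)
}

#' Validate site positions against protein sequences
#'
#' Checks every site's protein is present and its `residue` matches the
#' sequence character at `position`.
#'
#' @param sites Site tibble.
#' @param proteins Protein tibble from [read_fasta()].
#' @return `sites`, invisibly, or an error listing offenders.
#' @export
validate_sites <- function(sites, proteins) {
  joined <- dplyr::left_join(sites, proteins, by = "protein_id")
  if (any(is.na(joined$sequence))) {
    abort(paste0("Sites reference unknown proteins: ",
                 paste(unique(joined$protein_id[is.na(joined$sequence)]),
                       collapse = ", ")))
  }
  out_of_range <- joined$position > nchar(joined$sequence)
  if (any(out_of_range)) {
    abort(paste0("Site positions beyond sequence length: ",
                 paste(site_key(joined$protein_id, joined$position,
                                joined$kinase)[out_of_range], collapse = ", ")))
  }
  at <- substring(joined$sequence, joined$position, joined$position)
  mism <- at != joined$residue
  if (any(mism)) {
    abort(paste0("Site residue does not match sequence: ",
                 paste(site_key(joined$protein_id, joined$position,
                                joined$kinase)[mism], collapse = ", ")))
  }
  invisible(sites)
}

#' Read a functional annotation table into a catalog
#'
#' Expects a TSV with columns `protein_id`, `category`, `term`; `category`
#' must be one of BP, CC, MF, InterPro, KEGG, Pfam, PPI. Term membership is
#' set-valued: repeated rows collapse to one.
#'
#' @param path Path to the annotation TSV.
#' @param background Character vector of background protein ids. Defaults to
#'   all protein ids occurring in the table.
#' @return An `annotation_catalog` object.
#' @export
read_annotation_table <- function(path, background = NULL) {
  ann <- read_tsv_strict(path, readr::cols(
    protein_id = readr::col_character(),
    category = readr::col_character(),
    term = readr::col_character()
  ))
  missing_cols <- setdiff(c("protein_id", "category", "term"), names(ann))
  if (length(missing_cols) > 0) {
    abort(paste0("Annotation table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  annotation_catalog(ann, background = background)
}

#' Construct an annotation catalog
#'
#' A catalog is the protein-to-term map over the seven functional categories
#' plus the background protein universe against which enrichment is tested.
#'
#' @param annotations Tibble with `protein_id`, `category`, `term`.
#' @param background Background protein ids (default: ids in `annotations`).
#' @return An `annotation_catalog`.
#' @export
annotation_catalog <- function(annotations, background = NULL) {
  annotations <- tibble::as_tibble(annotations)
  if (nrow(annotations) == 0) {
    annotations <- tibble::tibble(protein_id = character(),
                                  category = character(),
                                  term = character())
  }
  bad <- setdiff(unique(annotations$category), ANNOTATION_CATEGORIES)
  if (length(bad) > 0) {
    abort(paste0("Unknown annotation categories: ",
                 paste(bad, collapse = ", "),
                 " (expected ", paste(ANNOTATION_CATEGORIES, collapse = "/"), ")"))
  }
  annotations <- dplyr::distinct(tibble::as_tibble(annotations),
                                 .data$protein_id, .data$category, .data$term)
  background <- background %||% unique(annotations$protein_id)
  orphan <- setdiff(unique(annotations$protein_id), background)
  if (length(orphan) > 0) {
    abort(paste0("Annotated proteins missing from background: ",
                 paste(head(orphan, 5), collapse = ", ")))
  }
  structure(list(annotations = annotations,
                 background = unique(background)),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("<annotation_catalog>\n")
  cat("  background proteins:", length(x$background), "\n")
  counts <- dplyr::count(x$annotations, .data$category)
  for (i in seq_len(nrow(counts))) {
    cat("  ", counts$category[i], ": ", counts$n[i], " annotations\n", sep = "")
  }
  invisible(x)
}

#' Write an annotation catalog to TSV
#' @param catalog An `annotation_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(catalog, path) {
  readr::write_tsv(catalog$annotations, path)
  invisible(path)
}

#' Read per-protein structural annotation tracks
#'
#' Expects a TSV with columns `protein_id`, `ss` (per-residue string over
#' H/E/C), `sa` (levels 0–6, buried to exposed) and `diso` (O/D). The three
#' tracks of a protein must have equal length; length against the FASTA is
#' checked in [validate_structures()].
#'
#' @param path Path to the structure TSV.
#' @return Tibble with columns `protein_id`, `ss`, `sa`, `diso`.
#' @export
read_structure_table <- function(path) {
  tracks <- read_tsv_strict(path, readr::cols(
    protein_id = readr::col_character(),
    ss = readr::col_character(),
    sa = readr::col_character(),
    diso = readr::col_character()
  ))
  missing_cols <- setdiff(c("protein_id", "ss", "sa", "diso"), names(tracks))
  if (length(missing_cols) > 0) {
    abort(paste0("Structure table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  check_charset <- function(x, allowed, what) {
    bad <- nzchar(gsub(paste0("[", paste(allowed, collapse = ""), "]"), "", x))
    if (any(bad)) {
      abort(paste0("Invalid ", what, " characters for protein(s): ",
                   paste(tracks$protein_id[bad], collapse = ", ")))
    }
  }
  check_charset(tracks$ss, SS_LEVELS, "secondary-structure")
  check_charset(tracks$sa, SA_LEVELS, "solvent-accessibility")
  check_charset(tracks$diso, DISO_LEVELS, "disorder")
  uneven <- nchar(tracks$ss) != nchar(tracks$sa) |
    nchar(tracks$ss) != nchar(tracks$diso)
  if (any(uneven)) {
    abort(paste0("Track length mismatch within protein(s): ",
                 paste(tracks$protein_id[uneven], collapse = ", ")))
  }
  tracks
}

#' Validate structural tracks against protein sequences
#' @param structures Structure tibble.
#' @param proteins Protein tibble.
#' @return `structures`, invisibly.
#' @export
validate_structures <- function(structures, proteins) {
  joined <- dplyr::left_join(structures, proteins, by = "protein_id")
  if (any(is.na(joined$sequence))) {
    abort(paste0("Structure tracks for unknown proteins: ",
                 paste(joined$protein_id[is.na(joined$sequence)], collapse = ", ")))
  }
  bad <- nchar(joined$ss) != nchar(joined$sequence)
  if (any(bad)) {
    abort(paste0("Structure track length differs from sequence length for: ",
                 paste(joined$protein_id[bad], collapse = ", ")))
  }
  invisible(structures)
}

#' Write a structure table
#' @param structures Structure tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_table <- function(structures, path) {
  readr::write_tsv(structures[, c("protein_id", "ss", "sa", "diso")], path)
  invisible(path)
}

#' Write site predictions to TSV
#'
#' Rows are sorted by score descending, ties broken by (protein_id, position)
#' ascending; scores are printed with four decimals.
#'
#' @param predictions Tibble with `protein_id`, `position`, `residue`,
#'   `kinase`, `peptide`, `score`, `call`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  cols <- c("protein_id", "position", "residue", "kinase",
            "peptide", "score", "call")
  missing_cols <- setdiff(cols, names(predictions))
  if (length(missing_cols) > 0) {
    abort(paste0("Prediction table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  stopifnot(all(predictions$score >= 0 & predictions$score <= 1))
  out <- dplyr::arrange(predictions[, cols], dplyr::desc(.data$score),
                        .data$protein_id, .data$position)
  out$score <- sprintf("%.4f", out$score)
  out$call <- ifelse(out$call, "TRUE", "FALSE")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a prediction table written by [write_predictions()]
#' @param path Path to the TSV.
#' @return Tibble of predictions.
#' @export
read_predictions <- function(path) {
  preds <- read_tsv_strict(path, readr::cols(
    protein_id = readr::col_character(),
    position = readr::col_integer(),
    residue = readr::col_character(),
    kinase = readr::col_character(),
    peptide = readr::col_character(),
    score = readr::col_double(),
    call = readr::col_logical()
  ))
  stopifnot(all(preds$score >= 0 & preds$score <= 1))
  preds
}
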