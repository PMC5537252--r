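#' Sequence-derived block sizes for a given window
#'
#' The four per-residue blocks are one-hot over 20 residues, 3 secondary
#' structure states (H/E/C), 7 solvent-accessibility levels (0-6) and 2
#' disorder states (O/D); at the default 9-mer window this gives
#' 180 + 27 + 63 + 18 columns.
#'
#' @param half_width Window half-width (default 4).
#' @return Named integer vector of block sizes.
#' @export
sequence_block_sizes <- function(half_width = 4L) {
  w <- 2L * half_width + 1L
  c(AAseq = 20L * w, SS = 3L * w, SA = 7L * w, DISO = 2L * w)
}

#' Build a feature layout
#'
#' A layout fixes the ordered feature blocks of the design matrix and the
#' global 1-based "V" index of every column (the first column of the first
#' block is V1). Functional blocks additionally carry an ordered term list
#' defining what each indicator column means.
#'
#' @param block_sizes Named vector of block sizes; names must be drawn from
#'   the canonical order `AAseq, SS, SA, DISO, BP, CC, InterPro, pathway,
#'   MF, domain, PPI` (any subset, order is imposed canonically).
#' @param term_index Named list of ordered term vectors for functional
#'   blocks; when given for a block, its length must equal the block size.
#' @param half_width Window half-width used for per-position labels.
#' @return A `feature_layout` object with `$blocks`, `$features`, `$total`.
#' @export
#' @examples
#' make_layout(sequence_block_sizes())$total  # 288
make_layout <- function(block_sizes, term_index = list(), half_width = 4L) {
  bad <- setdiff(names(block_sizes), BLOCK_ORDER)
  if (length(bad) > 0) {
    abort(paste0("Unknown feature blocks: ", paste(bad, collapse = ", ")))
  }
  if (any(block_sizes <= 0)) abort("Block sizes must be positive")
  blocks <- intersect(BLOCK_ORDER, names(block_sizes))
  sizes <- as.integer(block_sizes[blocks])
  for (b in intersect(blocks, names(term_index))) {
    if (length(term_index[[b]]) != block_sizes[[b]]) {
      abort(paste0("Block ", b, " size ", block_sizes[[b]],
                   " does not match its term list length ",
                   length(term_index[[b]])))
    }
  }
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  block_tbl <- tibble::tibble(block = blocks, size = sizes,
                              start = starts, end = ends)
  w <- 2L * half_width + 1L
  per_pos <- c(AAseq = 20L, SS = 3L, SA = 7L, DISO = 2L)
  symbols <- list(AAseq = AA20, SS = SS_LEVELS, SA = SA_LEVELS,
                  DISO = DISO_LEVELS)
  features <- purrr::pmap_dfr(block_tbl, function(block, size, start, end) {
    b <- block
    if (b %in% SEQUENCE_BLOCKS) {
      if (size != per_pos[[b]] * w) {
        abort(paste0("Block ", b, " size ", size,
                     " inconsistent with window length ", w))
      }
      pos <- rep(seq_len(w), each = per_pos[[b]])
      tibble::tibble(
        index = start:end,
        block = rep(b, size),
        label = paste0("AA", pos, "_", b),
        term = rep(symbols[[b]], times = w)
      )
    } else {
      terms <- term_index[[b]] %||% rep(NA_character_, size)
      tibble::tibble(
        index = start:end,
        block = rep(b, size),
        label = rep(paste0("Pro_", b), size),
        term = terms
      )
    }
  })
  features$vname <- paste0("V", features$index)
  structure(list(blocks = block_tbl,
                 features = features[, c("index", "vname", "block",
                                         "label", "term")],
                 total = sum(sizes),
                 half_width = as.integer(half_width)),
            class = "feature_layout")
}

#' @export
print.feature_layout <- function(x, ...) {
  cat("<feature_layout> total:", x$total, "columns\n")
  for (i in seq_len(nrow(x$blocks))) {
    cat(sprintf("  %-9s V%d-V%d (%d)\n", x$blocks$block[i],
                x$blocks$start[i], x$blocks$end[i], x$blocks$size[i]))
  }
  invisible(x)
}

#' Build a layout from enrichment-derived term indices
#'
#' Convenience wrapper: sequence blocks sized from the window, functional
#' blocks sized by their significant-term lists (empty lists drop the block).
#'
#' @param term_index Named list (names among BP, CC, InterPro, pathway, MF,
#'   domain, PPI) of ordered significant terms, e.g. from
#'   [build_significant_term_index()].
#' @param half_width Window half-width.
#' @return A `feature_layout`.
#' @export
layout_from_terms <- function(term_index = list(), half_width = 4L) {
  term_index <- term_index[lengths(term_index) > 0]
  sizes <- c(sequence_block_sizes(half_width), lengths(term_index))
  make_layout(sizes, term_index = term_index, half_width = half_width)
}

#' Map a global V-index to its feature name and back
#'
#' @param layout A `feature_layout`.
#' @param index Integer V-index (for `vindex_name`).
#' @param vname Character V-name such as `"V107"` (for `vname_index`).
#' @return The V-name, or the integer index.
#' @export
vindex_name <- function(layout, index) {
  stopifnot(all(index >= 1), all(index <= layout$total))
  layout$features$vname[index]
}

#' @rdname vindex_name
#' @export
vname_index <- function(layout, vname) {
  idx <- match(vname, layout$features$vname)
  if (anyNA(idx)) {
    abort(paste0("Unknown feature name(s): ",
                 paste(vname[is.na(idx)], collapse = ", ")))
  }
  layout$features$index[idx]
}

# One-hot encode a vector of equal-length track strings over `levels`.
# Unknown level 'X' (padding) maps to an all-zero column group.
one_hot_track <- function(strings, levels, width) {
  n <- length(strings)
  if (any(nchar(strings) != width)) {
    abort(paste0("Track must have length ", width))
  }
  chars <- matrix(unlist(strsplit(strings, "")), nrow = n, byrow = TRUE)
  bad <- !(chars %in% c(levels, "X"))
  if (any(bad)) {
    abort(paste0("Invalid track symbol(s): ",
                 paste(unique(chars[bad]), collapse = ", ")))
  }
  k <- length(levels)
  out <- matrix(0L, nrow = n, ncol = k * width)
  lev <- match(chars, levels)          # NA for pad 'X'
  hit <- which(!is.na(lev))
  rows <- ((hit - 1L) %% n) + 1L
  cols <- ((hit - 1L) %/% n)           # 0-based position in window
  out[cbind(rows, cols * k + lev[hit])] <- 1L
  out
}

#' One-hot encode a peptide window
#'
#' Each position becomes a 20-column indicator group in fixed alphabetical
#' residue order (ACDEFGHIKLMNPQRSTVWY); the pad character `X` contributes
#' all zeros. A 9-mer yields a 180-dimensional vector.
#'
#' @param peptide Window string (length `2 * half_width + 1`).
#' @param half_width Window half-width.
#' @return Integer 0/1 vector.
#' @export
#' @examples
#' sum(encode_sequence_window("XXXXSXXXX"))  # 1
encode_sequence_window <- function(peptide, half_width = 4L) {
  drop(one_hot_track(peptide, AA20, 2L * half_width + 1L))
}

#' One-hot encode a secondary-structure track (H/E/C)
#' @inheritParams encode_sequence_window
#' @param ss_track Track string over H/E/C (and pad `X`).
#' @return Integer 0/1 vector (27 columns for a 9-mer).
#' @export
encode_secondary_structure <- function(ss_track, half_width = 4L) {
  drop(one_hot_track(ss_track, SS_LEVELS, 2L * half_width + 1L))
}

#' One-hot encode a solvent-accessibility track (levels 0-6)
#' @inheritParams encode_sequence_window
#' @param sa_track Track string over 0-6 (and pad `X`).
#' @return Integer 0/1 vector (63 columns for a 9-mer).
#' @export
encode_solvent_accessibility <- function(sa_track, half_width = 4L) {
  drop(one_hot_track(sa_track, SA_LEVELS, 2L * half_width + 1L))
}

#' One-hot encode a disorder track (O/D)
#' @inheritParams encode_sequence_window
#' @param diso_track Track string over O/D (and pad `X`).
#' @return Integer 0/1 vector (18 columns for a 9-mer).
#' @export
encode_disorder <- function(diso_track, half_width = 4L) {
  drop(one_hot_track(diso_track, DISO_LEVELS, 2L * half_width + 1L))
}

#' Encode the functional indicator blocks for one protein
#'
#' Functional features are protein-level: a column is 1 iff the protein
#' carries that term in the block's annotation category, so all sites of a
#' protein share the same functional sub-vector. Proteins absent from the
#' catalog encode as all zeros with a warning.
#'
#' @param protein_id Protein identifier.
#' @param catalog An `annotation_catalog`.
#' @param layout A `feature_layout` whose functional blocks carry term lists.
#' @return Integer 0/1 vector over the layout's functional blocks.
#' @export
encode_functional_blocks <- function(protein_id, catalog, layout) {
  func_blocks <- setdiff(layout$blocks$block, SEQUENCE_BLOCKS)
  if (length(func_blocks) == 0) return(integer(0))
  if (!protein_id %in% unique(catalog$annotations$protein_id)) {
    warn(paste0("Protein ", protein_id,
                " has no annotations; functional features all zero"))
  }
  unlist(lapply(func_blocks, function(b) {
    terms <- layout$features$term[layout$features$block == b]
    if (anyNA(terms)) {
      abort(paste0("Layout block ", b, " has no term index; ",
                   "build the layout from enrichment output"))
    }
    has <- catalog$annotations$term[
      catalog$annotations$protein_id == protein_id &
        catalog$annotations$category == BLOCK_CATEGORY[[b]]]
    as.integer(terms %in% has)
  }), use.names = FALSE)
}

#' Assemble the design matrix for a dataset
#'
#' Encodes every window of a `phos_dataset` into the requested feature
#' blocks, concatenated in canonical order, with columns named by their
#' global V-indices.
#'
#' @param dataset A `phos_dataset` from [build_dataset()].
#' @param layout A `feature_layout`.
#' @param catalog An `annotation_catalog`; required when functional blocks
#'   are requested.
#' @param blocks Subset of layout blocks to encode (default: all).
#' @return A `feature_matrix`: list with `$x` (0/1 matrix, V-named columns),
#'   `$sites` (site tibble), `$labels`, `$features` (column metadata),
#'   `$layout`.
#' @export
assemble_feature_matrix <- function(dataset, layout, catalog = NULL,
                                    blocks = NULL) {
  blocks <- blocks %||% layout$blocks$block
  bad <- setdiff(blocks, layout$blocks$block)
  if (length(bad) > 0) {
    abort(paste0("Blocks not in layout: ", paste(bad, collapse = ", ")))
  }
  blocks <- intersect(layout$blocks$block, blocks)  # canonical order
  func_blocks <- setdiff(blocks, SEQUENCE_BLOCKS)
  if (length(func_blocks) > 0 && is.null(catalog)) {
    abort("Functional blocks requested but no annotation catalog given")
  }
  w <- 2L * layout$half_width + 1L
  parts <- list()
  if ("AAseq" %in% blocks) parts$AAseq <- one_hot_track(dataset$peptide, AA20, w)
  if ("SS" %in% blocks) parts$SS <- one_hot_track(dataset$ss_track, SS_LEVELS, w)
  if ("SA" %in% blocks) parts$SA <- one_hot_track(dataset$sa_track, SA_LEVELS, w)
  if ("DISO" %in% blocks) {
    parts$DISO <- one_hot_track(dataset$diso_track, DISO_LEVELS, w)
  }
  if (length(func_blocks) > 0) {
    func_layout <- layout
    prot <- unique(dataset$protein_id)
    enc <- t(vapply(prot, function(p) {
      as.numeric(encode_functional_blocks(p, catalog, func_layout))
    }, numeric(sum(layout$blocks$size[layout$blocks$block %in%
                                        setdiff(layout$blocks$block,
                                                SEQUENCE_BLOCKS)]))))
    # columns of enc follow the layout's functional blocks in order
    func_all <- setdiff(layout$blocks$block, SEQUENCE_BLOCKS)
    offsets <- c(0L, cumsum(layout$blocks$size[match(func_all,
                                                     layout$blocks$block)]))
    for (bi in seq_along(func_all)) {
      b <- func_all[bi]
      if (b %in% func_blocks) {
        cols <- (offsets[bi] + 1L):offsets[bi + 1L]
        parts[[b]] <- enc[match(dataset$protein_id, prot), cols, drop = FALSE]
      }
    }
  }
  x <- do.call(cbind, parts[blocks])
  features <- layout$features[layout$features$block %in% blocks, ]
  colnames(x) <- features$vname
  rownames(x) <- site_key(dataset$protein_id, dataset$position,
                          dataset$kinase)
  structure(list(x = x,
                 sites = tibble::as_tibble(dataset),
                 labels = dataset$label,
                 features = features,
                 layout = layout),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x$x), "windows x", ncol(x$x), "features (",
      paste(unique(x$features$block), collapse = "+"), ")\n")
  invisible(x)
}

#' @export
tidy.feature_matrix <- function(x, ...) {
  dplyr::bind_cols(
    x$sites[, c("protein_id", "position", "residue", "kinase", "label")],
    tibble::as_tibble(x$x)
  )
}

#' Write a feature matrix and its layout sidecar
#'
#' The matrix goes to `path` as TSV (site key column plus V-named columns);
#' the sidecar `paste0(path, ".layout")` records block name, size and term
#' list per column so the matrix can be re-read unambiguously.
#'
#' @param fm A `feature_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  out <- dplyr::bind_cols(tibble::tibble(site = rownames(fm$x)),
                          tibble::as_tibble(fm$x))
  readr::write_tsv(out, path)
  readr::write_tsv(fm$features, paste0(path, ".layout"))
  invisible(path)
}
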