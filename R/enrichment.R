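#' Two-sided hypergeometric p-value for a term count
#'
#' Tests whether `q` of `k` study-set proteins carrying a term is surprising
#' given that `m` of the `m + n` background proteins carry it. Both tails of
#' Hypergeometric(m + n, m, k) are computed; the two-sided p-value doubles
#' the smaller tail, capped at 1. Direction is `over` when `q` is at or
#' above the expected count `k * m / (m + n)`, else `under`.
#'
#' @param q Study-set proteins with the term.
#' @param m Background proteins with the term.
#' @param n Background proteins without the term.
#' @param k Study-set size.
#' @return One-row tibble with `p`, `lower`, `upper`, `direction`.
#' @export
#' @examples
#' hypergeometric_pvalue(q = 2, m = 2, n = 3, k = 2)  # p = 0.2
hypergeometric_pvalue <- function(q, m, n, k) {
  if (any(c(q, m, n, k) < 0) || q > m || q > k || k > m + n) {
    abort("Impossible hypergeometric counts: need 0 <= q <= min(m, k), k <= m + n")
  }
  lower <- phyper(q, m, n, k)
  upper <- phyper(q - 1, m, n, k, lower.tail = FALSE)
  expected <- k * m / (m + n)
  tibble::tibble(
    p = min(1, 2 * min(lower, upper)),
    lower = lower,
    upper = upper,
    direction = if (q >= expected) "over" else "under"
  )
}

#' Test all terms of a category for over/under-representation
#'
#' One hypergeometric test per term occurring in the background for the
#' category, Bonferroni-corrected by the number of terms tested within that
#' category (set `global_correction` to correct across all categories
#' jointly). Terms with corrected p below `alpha` are flagged significant.
#'
#' @param study_ids Study-set protein ids (must be in the catalog
#'   background).
#' @param catalog An `annotation_catalog`.
#' @param category One of BP, CC, MF, InterPro, KEGG, Pfam, PPI.
#' @param alpha Corrected-p significance threshold (default 0.01).
#' @param bonferroni_factor Override for the correction factor (used by the
#'   global-correction wrapper); default = number of terms in the category.
#' @return Tibble of enrichment records (term, category, q, m, n, k, p_raw,
#'   p_corrected, direction, significant).
#' @export
test_terms <- function(study_ids, catalog, category, alpha = 0.01,
                       bonferroni_factor = NULL) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  if (length(study_ids) == 0) abort("Empty study set")
  if (!category %in% ANNOTATION_CATEGORIES) {
    abort(paste0("Unknown category: ", category))
  }
  outside <- setdiff(study_ids, catalog$background)
  if (length(outside) > 0) {
    abort(paste0("Study proteins outside the background: ",
                 paste(head(outside, 5), collapse = ", ")))
  }
  bg_size <- length(catalog$background)
  k <- length(unique(study_ids))
  ann <- dplyr::filter(catalog$annotations, .data$category == !!category)
  if (nrow(ann) == 0) {
    return(tibble::tibble(term = character(), category = character(),
                          q = integer(), m = integer(), n = integer(),
                          k = integer(), p_raw = double(),
                          p_corrected = double(), direction = character(),
                          significant = logical()))
  }
  counts <- ann |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(m = dplyr::n_distinct(.data$protein_id),
                     q = dplyr::n_distinct(
                       .data$protein_id[.data$protein_id %in% study_ids]),
                     .groups = "drop")
  n_tests <- bonferroni_factor %||% nrow(counts)
  res <- purrr::pmap_dfr(counts, function(term, m, q) {
    hp <- hypergeometric_pvalue(q, m, bg_size - m, k)
    tibble::tibble(term = term, category = category,
                   q = q, m = m, n = bg_size - m, k = k,
                   p_raw = hp$p, direction = hp$direction)
  })
  res$p_corrected <- pmin(1, res$p_raw * n_tests)
  res$significant <- res$p_corrected < alpha
  dplyr::arrange(res, .data$p_corrected, .data$term)
}

#' Test every annotation category at once
#'
#' @inheritParams test_terms
#' @param global_correction If `TRUE`, Bonferroni-correct by the total term
#'   count across all categories instead of within each category.
#' @return Row-bound enrichment records across categories.
#' @export
test_all_categories <- function(study_ids, catalog, alpha = 0.01,
                                global_correction = FALSE) {
  present <- intersect(ANNOTATION_CATEGORIES,
                       unique(catalog$annotations$category))
  factor_all <- if (global_correction) {
    nrow(dplyr::distinct(catalog$annotations, .data$category, .data$term))
  } else NULL
  purrr::map_dfr(present, function(cat) {
    test_terms(study_ids, catalog, cat, alpha = alpha,
               bonferroni_factor = factor_all)
  })
}

#' Build the significant-term index that defines functional feature columns
#'
#' Keeps significant terms only (both directions by default), ordered within
#' each category by corrected p ascending then term name; the resulting
#' per-block ordered term lists feed [layout_from_terms()].
#'
#' @param records Enrichment records from [test_terms()] /
#'   [test_all_categories()].
#' @param directions Which directions to retain (default both).
#' @return Named list of ordered term vectors keyed by feature block
#'   (`BP`, `CC`, `InterPro`, `pathway`, `MF`, `domain`, `PPI`).
#' @export
build_significant_term_index <- function(records,
                                         directions = c("over", "under")) {
  sig <- records |>
    dplyr::filter(.data$significant, .data$direction %in% directions) |>
    dplyr::arrange(.data$p_corrected, .data$term)
  cat_to_block <- stats::setNames(names(BLOCK_CATEGORY), BLOCK_CATEGORY)
  out <- split(sig$term, cat_to_block[sig$category])
  out[lengths(out) > 0]
}

#' Estimate smoothed term frequencies in substrates and background
#'
#' Frequencies with additive smoothing:
#' `f = (count_pos + pseudocount) / (n_pos + 2 * pseudocount)` and the same
#' for `g` over the background, so log-odds ratios are always finite.
#'
#' @param positive_ids Substrate protein ids.
#' @param background_ids Background protein ids.
#' @param catalog An `annotation_catalog`.
#' @param terms Tibble with `category` and `term` (e.g. significant
#'   records), or a named list as from [build_significant_term_index()].
#' @param pseudocount Smoothing constant (> 0 required whenever any count
#'   can be zero; default 1).
#' @return Tibble with `category`, `term`, `f`, `g`, `log2_ratio`.
#' @export
estimate_term_frequencies <- function(positive_ids, background_ids, catalog,
                                      terms, pseudocount = 1) {
  if (length(positive_ids) == 0) abort("Empty positive set")
  if (is.list(terms) && !is.data.frame(terms)) {
    block_to_cat <- BLOCK_CATEGORY
    terms <- purrr::imap_dfr(terms, function(tt, b) {
      tibble::tibble(category = block_to_cat[[b]], term = tt)
    })
  }
  if (nrow(terms) == 0) abort("Term list is empty")
  n_pos <- length(unique(positive_ids))
  n_bg <- length(unique(background_ids))
  count_in <- function(ids) {
    # per-term distinct protein counts restricted to `ids`
    sub <- dplyr::filter(catalog$annotations, .data$protein_id %in% ids)
    cnt <- dplyr::count(dplyr::distinct(sub, .data$protein_id,
                                        .data$category, .data$term),
                        .data$category, .data$term, name = "n_with")
    dplyr::left_join(terms, cnt, by = c("category", "term")) |>
      dplyr::mutate(n_with = dplyr::coalesce(.data$n_with, 0L)) |>
      dplyr::pull(.data$n_with)
  }
  cp <- count_in(positive_ids)
  cb <- count_in(background_ids)
  if (pseudocount <= 0 && (any(cp == 0) || any(cb == 0))) {
    abort("pseudocount must be positive when any term count is zero")
  }
  f <- (cp + pseudocount) / (n_pos + 2 * pseudocount)
  g <- (cb + pseudocount) / (n_bg + 2 * pseudocount)
  tibble::tibble(category = terms$category, term = terms$term,
                 f = f, g = g, log2_ratio = log2(f / g))
}

#' Log-odds functional score of proteins
#'
#' A protein's score is the sum over the significant terms it carries of
#' `log2(f / g)`, where `f` and `g` are the term's smoothed frequencies in
#' substrates and background. Terms the protein lacks contribute zero;
#' under-represented terms contribute negatively.
#'
#' @param protein_ids Protein ids to score.
#' @param catalog An `annotation_catalog`.
#' @param freqs Frequency tibble from [estimate_term_frequencies()].
#' @return Tibble with `protein_id` and `score` (bits).
#' @export
log_odds_score <- function(protein_ids, catalog, freqs) {
  ann <- dplyr::filter(catalog$annotations,
                       .data$protein_id %in% protein_ids)
  contrib <- dplyr::inner_join(ann, freqs, by = c("category", "term")) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(score = sum(.data$log2_ratio), .groups = "drop")
  tibble::tibble(protein_id = protein_ids) |>
    dplyr::left_join(contrib, by = "protein_id") |>
    dplyr::mutate(score = dplyr::coalesce(.data$score, 0))
}

#' Compare functional score distributions of substrates vs background
#'
#' Welch two-sample t-test of the two score vectors. Degenerate identical
#' zero-variance samples return p = 1 by convention (no difference).
#'
#' @param pos_scores Scores of substrate proteins.
#' @param background_scores Scores of background proteins.
#' @return A `score_comparison`: list with `statistic`, `p_value`, `data`
#'   (long tibble of scores for plotting).
#' @export
compare_score_distributions <- function(pos_scores, background_scores) {
  stopifnot(length(pos_scores) >= 2, length(background_scores) >= 2)
  data <- dplyr::bind_rows(
    tibble::tibble(set = "substrate", score = pos_scores),
    tibble::tibble(set = "background", score = background_scores)
  )
  degenerate <- sd(pos_scores) == 0 && sd(background_scores) == 0
  if (degenerate) {
    if (pos_scores[1] != background_scores[1]) {
      abort("Zero-variance samples with different means: t undefined")
    }
    inform("Identical zero-variance samples; p set to 1")
    res <- list(statistic = 0, p_value = 1)
  } else {
    tt <- t.test(pos_scores, background_scores)
    res <- list(statistic = unname(tt$statistic), p_value = tt$p.value)
  }
  structure(c(res, list(data = data)), class = "score_comparison")
}

#' @export
print.score_comparison <- function(x, ...) {
  cat("<score_comparison> Welch t =", format(x$statistic, digits = 4),
      ", p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' @export
glance.score_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_substrate = sum(x$data$set == "substrate"),
                 n_background = sum(x$data$set == "background"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot substrate vs background functional-score distributions
#' @param object A `score_comparison`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.score_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$score, fill = .data$set)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 30) +
    ggplot2::labs(x = "log-odds functional score (bits)", y = "proteins",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Write enrichment records to TSV
#' @param records Enrichment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}
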