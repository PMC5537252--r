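#' Mutual information between two discrete vectors
#'
#' Plug-in estimate in bits: `sum p(a,b) log2(p(a,b) / (p(a) p(b)))` over
#' observed cells; empty cells contribute zero.
#'
#' @param x,y Equal-length discrete vectors.
#' @return Mutual information in bits.
#' @export
#' @examples
#' mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1))  # 1 bit
mutual_information <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) == 0) abort("Empty vectors")
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  terms <- p * log2(p / outer(px, py))
  sum(terms[p > 0])
}

# Vectorized MI (bits) between each 0/1 column of X and 0/1 vector v.
mi_binary_columns <- function(X, v) {
  n <- length(v)
  n11 <- as.numeric(crossprod(X, v))
  n1_ <- as.numeric(colSums(X))
  n_1 <- sum(v)
  n10 <- n1_ - n11
  n01 <- n_1 - n11
  n00 <- n - n1_ - n01
  cell <- function(nab, na, nb) {
    out <- numeric(length(nab))
    pos <- nab > 0
    out[pos] <- (nab[pos] / n) * log2((nab[pos] * n) / (na[pos] * nb))
    out
  }
  cell(n11, n1_, n_1) + cell(n10, n1_, n - n_1) +
    cell(n01, n - n1_, n_1) + cell(n00, n - n1_, n - n_1)
}

is_binary_matrix <- function(X) {
  all(X == 0 | X == 1)
}

#' Rank features by minimum-redundancy maximum-relevance (mRMR)
#'
#' Greedy ranking: the first feature maximizes relevance `I(x_j; y)`; each
#' subsequent feature maximizes, over unselected `j`, the MID criterion
#' `I(x_j; y) - mean_{i in S} I(x_j; x_i)` (or the MIQ quotient variant),
#' with ties broken by the smaller column index. All mutual information is
#' in bits.
#'
#' @param x A `feature_matrix` or a discrete matrix (columns = features).
#' @param labels Class labels (vector or factor); defaults to the
#'   `feature_matrix` labels.
#' @param k Number of features to rank (default 50); capped at the column
#'   count.
#' @param variant `"MID"` (difference, default) or `"MIQ"` (quotient with an
#'   epsilon guard against zero redundancy).
#' @param epsilon Denominator guard for MIQ.
#' @return A `ranked_features` tibble with `rank`, `index`, `vname`,
#'   `label`, `score` (criterion value at selection time; rank 1's score is
#'   its relevance).
#' @export
mrmr_rank <- function(x, labels = NULL, k = 50L,
                      variant = c("MID", "MIQ"), epsilon = 1e-12) {
  variant <- match.arg(variant)
  if (k < 1) abort("k must be >= 1")
  if (inherits(x, "feature_matrix")) {
    labels <- labels %||% x$labels
    features <- x$features
    X <- x$x
  } else {
    X <- as.matrix(x)
    features <- tibble::tibble(
      index = seq_len(ncol(X)),
      vname = colnames(X) %||% paste0("V", seq_len(ncol(X))),
      label = NA_character_
    )
    if (is.null(colnames(X))) colnames(X) <- features$vname
  }
  if (length(labels) != nrow(X)) abort("labels length must match row count")
  if (length(unique(labels)) < 2) abort("Both classes must be present")
  y <- as.integer(as.factor(labels)) - 1L
  p <- ncol(X)
  k <- min(as.integer(k), p)
  binary <- is_binary_matrix(X) && all(y %in% c(0L, 1L))
  relevance <- if (binary) {
    mi_binary_columns(X, y)
  } else {
    vapply(seq_len(p), function(j) mutual_information(X[, j], y), numeric(1))
  }
  selected <- integer(0)
  scores <- numeric(0)
  redundancy_sum <- numeric(p)
  remaining <- rep(TRUE, p)
  for (step in seq_len(k)) {
    crit <- if (step == 1) {
      relevance
    } else if (variant == "MID") {
      relevance - redundancy_sum / length(selected)
    } else {
      relevance / pmax(redundancy_sum / length(selected), epsilon)
    }
    crit[!remaining] <- -Inf
    best <- which(crit == max(crit[remaining]) & remaining)[1]  # smallest index wins ties
    selected <- c(selected, best)
    scores <- c(scores, crit[best])
    remaining[best] <- FALSE
    if (step < k) {
      new_mi <- if (binary) {
        mi_binary_columns(X, X[, best])
      } else {
        vapply(seq_len(p), function(j) {
          if (remaining[j]) mutual_information(X[, j], X[, best]) else 0
        }, numeric(1))
      }
      redundancy_sum <- redundancy_sum + new_mi
    }
  }
  out <- tibble::tibble(
    rank = seq_along(selected),
    index = features$index[selected],
    vname = features$vname[selected],
    label = features$label[selected],
    score = scores
  )
  structure(out, class = c("ranked_features", class(out)),
            k = k, variant = variant,
            relevance = relevance[selected])
}

#' Reduce a feature matrix to the ranked features
#'
#' Columns are reordered by rank; V-names and column metadata are preserved
#' so reduced matrices remain portable across models.
#'
#' @param fm A `feature_matrix`.
#' @param ranked A `ranked_features` from [mrmr_rank()].
#' @return A reduced `feature_matrix`.
#' @export
apply_selection <- function(fm, ranked) {
  stopifnot(inherits(fm, "feature_matrix"))
  idx <- match(ranked$vname, colnames(fm$x))
  if (anyNA(idx)) {
    abort(paste0("Ranked features absent from matrix: ",
                 paste(ranked$vname[is.na(idx)], collapse = ", ")))
  }
  out <- fm
  out$x <- fm$x[, idx, drop = FALSE]
  out$features <- fm$features[match(ranked$vname, fm$features$vname), ]
  out$selected <- ranked
  out
}

#' Write an mRMR ranking table
#'
#' Columns mirror a published top-k feature table: rank, V-index, feature
#' type label, criterion score.
#'
#' @param ranked A `ranked_features`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking_table <- function(ranked, path) {
  readr::write_tsv(tibble::as_tibble(ranked), path)
  invisible(path)
}
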