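#' Train a random-forest kinase model
#'
#' Fits a random forest on a binary 0/1 design matrix; the prediction score
#' of a window is the fraction of trees voting for the positive class.
#' Defaults follow the classical implementation: 500 trees,
#' `mtry = floor(sqrt(p))`, unlimited depth.
#'
#' @param x A `feature_matrix` or numeric matrix (rows = windows).
#' @param labels `positive` / `negative` labels; defaults to the
#'   `feature_matrix` labels.
#' @param n_trees Number of trees (default 500).
#' @param mtry Variables tried per split; default `floor(sqrt(ncol))`.
#' @param seed Optional integer seed (training is stochastic).
#' @param kinase Kinase family name stored with the model.
#' @param threshold Initial score threshold for calls (default 0.5; see
#'   [calibrate_threshold()]).
#' @return A `kinase_model`: fitted ensemble plus feature names, layout,
#'   selection, threshold and a training manifest.
#' @export
train_random_forest <- function(x, labels = NULL, n_trees = 500L,
                                mtry = NULL, seed = NULL, kinase = NULL,
                                threshold = 0.5) {
  if (inherits(x, "feature_matrix")) {
    labels <- labels %||% x$labels
    kinase <- kinase %||% unique(x$sites$kinase)
    X <- x$x
    layout <- x$layout
    features <- x$features
    selected <- x$selected
  } else {
    X <- as.matrix(x)
    if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
    layout <- NULL
    features <- NULL
    selected <- NULL
  }
  if (is.null(labels)) abort("labels are required")
  if (length(unique(labels)) < 2) abort("Both classes must be present")
  if (!all(is.finite(X))) abort("Design matrix must be finite")
  y <- factor(labels, levels = c("negative", "positive"))
  if (anyNA(y)) abort("Labels must be 'positive' or 'negative'")
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(X))))
  fit <- function() {
    randomForest::randomForest(x = X, y = y, ntree = n_trees, mtry = mtry)
  }
  forest <- if (is.null(seed)) fit() else with_seed_local(seed, fit())
  structure(list(
    forest = forest,
    vnames = colnames(X),
    kinase = kinase %||% "unspecified",
    layout = layout,
    features = features,
    selected = selected,
    threshold = threshold,
    manifest = list(
      n_trees = n_trees, mtry = mtry, seed = seed,
      n_samples = nrow(X), n_features = ncol(X),
      class_counts = as.list(table(y)),
      data_fingerprint = sum(X) + nrow(X) * 1e-3
    )
  ), class = "kinase_model")
}

#' @export
print.kinase_model <- function(x, ...) {
  cat("<kinase_model>", x$kinase, "-", x$manifest$n_trees, "trees,",
      x$manifest$n_features, "features, threshold",
      format(x$threshold, digits = 3), "\n")
  invisible(x)
}

#' @export
glance.kinase_model <- function(x, ...) {
  tibble::tibble(kinase = x$kinase, n_trees = x$manifest$n_trees,
                 mtry = x$manifest$mtry,
                 n_features = x$manifest$n_features,
                 n_samples = x$manifest$n_samples,
                 threshold = x$threshold)
}

#' Score windows with a trained model
#'
#' Columns of `newdata` are aligned to the model's feature space by name,
#' so column order does not matter; missing features are an error.
#'
#' @param model A `kinase_model`.
#' @param newdata A `feature_matrix` or matrix with the model's columns.
#' @return Numeric score vector in `[0, 1]`.
#' @export
predict_scores <- function(model, newdata) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$x else as.matrix(newdata)
  missing_cols <- setdiff(model$vnames, colnames(X))
  if (length(missing_cols) > 0) {
    abort(paste0("Input lacks model features: ",
                 paste(head(missing_cols, 5), collapse = ", "),
                 " (expected ", length(model$vnames), " columns)"))
  }
  X <- X[, model$vnames, drop = FALSE]
  unname(predict(model$forest, X, type = "prob")[, "positive"])
}

#' Tally a confusion table at a score threshold
#'
#' The call rule is `score >= threshold` (ties at the cutoff are called
#' positive).
#'
#' @param scores Numeric scores.
#' @param labels True `positive` / `negative` labels.
#' @param threshold Score cutoff.
#' @return One-row tibble with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  call <- scores >= threshold
  truth <- labels == "positive"
  tibble::tibble(
    TP = sum(call & truth),
    TN = sum(!call & !truth),
    FP = sum(call & !truth),
    FN = sum(!call & truth)
  )
}

#' Performance measures from a confusion table
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, accuracy, F-score `2TP/(2TP+FP+FN)` and the Matthews
#' correlation coefficient. A 0/0 ratio is reported as `NA` (undefined);
#' MCC is 0 when its denominator vanishes.
#'
#' @param counts One-row tibble (or list) with `TP`, `TN`, `FP`, `FN`.
#' @return One-row tibble with `SEN`, `SPE`, `PRE`, `ACC`, `F_score`, `MCC`.
#' @export
compute_metrics <- function(counts) {
  TP <- as.numeric(counts$TP); TN <- as.numeric(counts$TN)
  FP <- as.numeric(counts$FP); FN <- as.numeric(counts$FN)
  total <- TP + TN + FP + FN
  if (total == 0) abort("Empty confusion table")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt((TP + FN) * (TP + FP) * (TN + FN) * (TN + FP))
  tibble::tibble(
    SEN = ratio(TP, TP + FN),
    SPE = ratio(TN, TN + FP),
    PRE = ratio(TP, TP + FP),
    ACC = (TP + TN) / total,
    F_score = ratio(2 * TP, 2 * TP + FP + FN),
    MCC = if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den
  )
}

#' ROC curve and AUC from scores
#'
#' Sweeps all distinct score thresholds; AUC is the trapezoidal area, which
#' equals the Mann-Whitney probability that a random positive outscores a
#' random negative (ties counted 1/2).
#'
#' @param scores Numeric scores.
#' @param labels True `positive` / `negative` labels.
#' @return A `roc_curve`: list with `points` tibble (`threshold`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  truth <- labels == "positive"
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present")
  tab <- tibble::tibble(score = scores, truth = truth) |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise(tp = sum(.data$truth), fp = sum(!.data$truth),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score))
  points <- tibble::tibble(
    threshold = c(Inf, tab$score),
    tpr = c(0, cumsum(tab$tp) / n1),
    fpr = c(0, cumsum(tab$fp) / n0)
  )
  auc <- sum(diff(points$fpr) *
               (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> AUC =", format(x$auc, digits = 4), "(",
      nrow(x$points) - 1, "thresholds )\n")
  invisible(x)
}

#' @export
tidy.roc_curve <- function(x, ...) x$points

#' @export
glance.roc_curve <- function(x, ...) tibble::tibble(auc = x$auc)

#' Plot a ROC curve
#' @param object A `roc_curve`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = paste0("AUC = ", format(object$auc, digits = 3))) +
    ggplot2::theme_minimal()
}

#' Repeated stratified k-fold cross-validation
#'
#' Each repeat draws a fresh stratified random partition (class proportions
#' preserved per fold), trains on k-1 folds and evaluates the held-out
#' fold at threshold 0.5 plus AUC. With `selection_mode = "strict"`, mRMR
#' runs inside each training fold (no leakage); `"paper"` ranks once on the
#' full matrix before CV; `"none"` skips selection.
#'
#' @param x A `feature_matrix` or 0/1 matrix.
#' @param labels Class labels; default from the `feature_matrix`.
#' @param folds Number of folds (default 5).
#' @param repeats Number of randomized repeats (default 100).
#' @param selection_mode `"none"`, `"strict"` or `"paper"`.
#' @param k Features kept when selection is active (default 50).
#' @param n_trees,mtry Forest parameters (see [train_random_forest()]).
#' @param seed Integer seed; fold assignments and training derive from it.
#' @param pooled If `TRUE`, pool held-out predictions within a repeat before
#'   computing metrics instead of averaging per-fold metrics.
#' @return A `cv_result`: `$summary` (metric, mean, sd across repeats),
#'   `$per_repeat`, `$per_fold`, `$folds` (n x repeats assignment matrix),
#'   `$params`.
#' @export
cross_validate <- function(x, labels = NULL, folds = 5L, repeats = 100L,
                           selection_mode = c("none", "strict", "paper"),
                           k = 50L, n_trees = 500L, mtry = NULL,
                           seed = NULL, pooled = FALSE) {
  selection_mode <- match.arg(selection_mode)
  if (inherits(x, "feature_matrix")) {
    labels <- labels %||% x$labels
    X <- x$x
  } else {
    X <- as.matrix(x)
    if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  }
  n <- nrow(X)
  if (length(labels) != n) abort("labels length must match row count")
  y <- factor(labels, levels = c("negative", "positive"))
  if (any(table(y) < folds)) {
    abort("Each class needs at least `folds` samples for stratification")
  }
  if (selection_mode == "paper") {
    ranked <- mrmr_rank(X, labels = labels, k = k)
    X <- X[, ranked$vname, drop = FALSE]
    selection_mode <- "none"
  }
  seed <- seed %||% sample.int(.Machine$integer.max, 1)
  metric_names <- c("SEN", "SPE", "PRE", "ACC", "F_score", "MCC", "AUC")
  fold_matrix <- matrix(NA_integer_, nrow = n, ncol = repeats)
  per_fold <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    repeat_seed <- (seed + r * 1000003) %% 2147483647L
    res_r <- with_seed_local(repeat_seed, {
      assignment <- integer(n)
      for (cl in levels(y)) {
        idx <- which(y == cl)
        assignment[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      fold_rows <- vector("list", folds)
      for (f in seq_len(folds)) {
        train <- assignment != f
        Xtr <- X[train, , drop = FALSE]
        Xte <- X[!train, , drop = FALSE]
        if (selection_mode == "strict") {
          ranked <- mrmr_rank(Xtr, labels = labels[train], k = k)
          Xtr <- Xtr[, ranked$vname, drop = FALSE]
          Xte <- Xte[, ranked$vname, drop = FALSE]
        }
        model <- train_random_forest(Xtr, labels = labels[train],
                                     n_trees = n_trees, mtry = mtry)
        sc <- predict_scores(model, Xte)
        fold_rows[[f]] <- list(scores = sc, truth = labels[!train], fold = f)
      }
      list(assignment = assignment, fold_rows = fold_rows)
    })
    fold_matrix[, r] <- res_r$assignment
    per_fold[[r]] <- purrr::map_dfr(res_r$fold_rows, function(fr) {
      m <- compute_metrics(confusion_counts(fr$scores, fr$truth, 0.5))
      m$AUC <- roc_auc(fr$scores, fr$truth)$auc
      dplyr::bind_cols(tibble::tibble(repeat_id = r, fold = fr$fold), m)
    })
    if (pooled) {
      sc <- unlist(purrr::map(res_r$fold_rows, "scores"))
      tr <- unlist(purrr::map(res_r$fold_rows, "truth"))
      m <- compute_metrics(confusion_counts(sc, tr, 0.5))
      m$AUC <- roc_auc(sc, tr)$auc
      per_fold[[r]] <- dplyr::bind_cols(
        tibble::tibble(repeat_id = r, fold = NA_integer_), m)
    }
  }
  per_fold <- dplyr::bind_rows(per_fold)
  per_repeat <- per_fold |>
    dplyr::group_by(.data$repeat_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_names),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  summary <- per_repeat |>
    tidyr::pivot_longer(dplyr::all_of(metric_names), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$metric, metric_names))
  structure(list(summary = summary, per_repeat = per_repeat,
                 per_fold = per_fold, folds = fold_matrix,
                 params = list(folds = folds, repeats = repeats,
                               selection_mode = selection_mode, k = k,
                               n_trees = n_trees, seed = seed,
                               pooled = pooled)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", x$params$folds, "folds x", x$params$repeats,
      "repeats (selection:", x$params$selection_mode, ")\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$per_fold

#' @export
glance.cv_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::bind_cols(wide, tibble::as_tibble(x$params[c("folds", "repeats",
                                                      "selection_mode")]))
}

#' Plot cross-validation metric distributions
#' @param object A `cv_result`.
#' @param ... Ignored.
#' @return A ggplot of per-repeat metric values.
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_repeat, -"repeat_id",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "per-repeat mean") +
    ggplot2::theme_minimal()
}

#' Calibrate the call threshold to a target specificity
#'
#' Returns the smallest threshold `t` such that the fraction of negative
#' calibration scores strictly below `t` reaches the target, so calling
#' `score >= t` attains at least the requested specificity on those
#' negatives by construction.
#'
#' @param negative_scores Scores of known-negative sites.
#' @param target_specificity Target in (0, 1); default 0.99.
#' @return Numeric threshold.
#' @export
calibrate_threshold <- function(negative_scores, target_specificity = 0.99) {
  if (target_specificity <= 0 || target_specificity >= 1) {
    abort("target_specificity must be in (0, 1)")
  }
  n <- length(negative_scores)
  if (n < 1 / (1 - target_specificity)) {
    warn(paste0("Only ", n, " negative scores; specificity ",
                target_specificity, " is coarsely resolved"))
  }
  s <- sort(negative_scores)
  step <- max(.Machine$double.eps,
              abs(s[n]) * .Machine$double.eps * 4)
  candidates <- c(unique(s), s[n] + step)
  for (t in candidates) {
    if (mean(negative_scores < t) >= target_specificity) return(t)
  }
  s[n] + step
}

#' Scan a proteome for kinase-specific phosphosites
#'
#' Enumerates every candidate residue (the model kinase's target types),
#' encodes windows with the model's layout and selected features, scores
#' them, and calls sites at the threshold. The summary counts predicted
#' substrates (proteins with at least one call) and called sites.
#'
#' @param model A `kinase_model` trained on a `feature_matrix` (so it
#'   carries its layout).
#' @param proteins Protein tibble.
#' @param structures Structure tibble covering the proteins.
#' @param catalog An `annotation_catalog` when the model uses functional
#'   blocks.
#' @param threshold Score cutoff (default: the model's threshold).
#' @param residues Candidate residue types; default from the model kinase.
#' @return A `proteome_scan`: list with `$predictions` tibble and
#'   `$summary` (`n_substrates`, `n_sites`, threshold).
#' @export
proteome_scan <- function(model, proteins, structures, catalog = NULL,
                          threshold = NULL,
                          residues = NULL) {
  if (is.null(model$layout)) {
    abort("Model carries no feature layout; train it on a feature_matrix")
  }
  threshold <- threshold %||% model$threshold
  residues <- residues %||% kinase_target_residues(model$kinase)
  sites <- enumerate_background_sites(proteins, residues = residues)
  if (nrow(sites) == 0) {
    empty <- tibble::tibble(protein_id = character(), position = integer(),
                            residue = character(), kinase = character(),
                            peptide = character(), score = double(),
                            call = logical())
    return(structure(list(predictions = empty,
                          summary = tibble::tibble(n_substrates = 0L,
                                                   n_sites = 0L,
                                                   threshold = threshold)),
                     class = "proteome_scan"))
  }
  sites$kinase <- model$kinase
  sites$label <- "negative"  # placeholder; labels unused for scanning
  ds <- suppressWarnings(
    build_dataset(sites, proteins, structures, kinase = model$kinase,
                  half_width = model$layout$half_width)
  )
  blocks <- unique(model$features$block)
  fm <- assemble_feature_matrix(ds, model$layout, catalog = catalog,
                                blocks = blocks)
  scores <- predict_scores(model, fm)
  predictions <- tibble::tibble(
    protein_id = ds$protein_id, position = ds$position,
    residue = ds$residue, kinase = model$kinase,
    peptide = ds$peptide, score = scores,
    call = scores >= threshold
  )
  summary <- tibble::tibble(
    n_substrates = dplyr::n_distinct(predictions$protein_id[predictions$call]),
    n_sites = sum(predictions$call),
    threshold = threshold
  )
  structure(list(predictions = predictions, summary = summary),
            class = "proteome_scan")
}

#' @export
print.proteome_scan <- function(x, ...) {
  cat("<proteome_scan>", x$summary$n_substrates, "predicted substrates,",
      x$summary$n_sites, "sites at threshold",
      format(x$summary$threshold, digits = 3), "\n")
  invisible(x)
}

#' @export
tidy.proteome_scan <- function(x, ...) x$predictions

#' @export
glance.proteome_scan <- function(x, ...) x$summary

#' Write an evaluation report TSV (one row per metric, mean and SD)
#' @param cv A `cv_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(cv, path) {
  readr::write_tsv(cv$summary, path)
  invisible(path)
}
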