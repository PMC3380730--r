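#' Residue-level classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall), specificity, precision, Matthews
#' correlation coefficient and F1 from the 2x2 confusion table. MCC uses the
#' standard form with the square root over the four-factor product in the
#' denominator, so it stays within \[-1, 1\]. Any metric whose denominator is
#' zero is reported as `NA` (undefined), never coerced to 0.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return One-row tibble: `TP`, `FP`, `TN`, `FN`, `ACC`, `SN`, `SP`, `PR`,
#'   `MCC`, `F1`.
#' @export
#' @examples
#' metrics_from_counts(71, 289, 711, 29)
metrics_from_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be non-negative integers.")
  }
  # doubles: integer counts overflow in the tp*tn / fp*fn products
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  n <- tp + fp + tn + fn
  acc <- safe_div(tp + tn, n)
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  pr <- safe_div(tp, tp + fp)
  mcc_den <- sqrt((tp + fn) * (tp + fp) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  f1 <- if (is.na(sn) || is.na(pr) || (sn + pr) == 0) NA_real_ else
    2 * sn * pr / (sn + pr)
  tibble::tibble(TP = as.integer(tp), FP = as.integer(fp),
                 TN = as.integer(tn), FN = as.integer(fn),
                 ACC = acc, SN = sn, SP = sp, PR = pr, MCC = mcc, F1 = f1)
}

#' ROC curve and AUC from continuous scores
#'
#' Sweeps every distinct score as a threshold, plotting sensitivity against
#' 1 - specificity, and integrates by the trapezoid rule; with midrank tie
#' handling this equals the Mann-Whitney statistic. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores Numeric decision values, higher = more binding-like.
#' @param labels Binary labels (1 = binding).
#' @return List with `auc` and `points`, a tibble of (`threshold`, `fpr`,
#'   `tpr`) from (1,1) down to (0,0).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("ROC undefined: both classes must be present.")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tps <- cumsum(y == 1L)
  fps <- cumsum(y == 0L)
  last <- c(diff(s) != 0, TRUE) # last index of each distinct score
  pts <- tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fps[last] / n0),
    tpr = c(0, tps[last] / n1)
  )
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(auc = auc, points = pts)
}

#' Build a balanced-sampling cross-validation plan
#'
#' Partitions residue samples into `folds` folds — by chain (default; keeps
#' all residues of a chain together, so overlapping windows never straddle a
#' train/test split) or by residue. For each fold the training set is the
#' complement, reduced to all of its positive samples plus an equal number of
#' negatives drawn uniformly without replacement; evaluation uses the whole
#' held-out fold at its natural class imbalance.
#'
#' @param samples Tibble with `chain_id`, `position`, `label`.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed making the plan (and the negative draws)
#'   reproducible.
#' @param grouping `"chain"` or `"residue"`.
#' @return A `ppr_cv_plan`: list with `assignment` (samples plus `sample_id`
#'   and `fold`), `negative_draw` (per-fold training-negative ids), `folds`,
#'   `seed`, `grouping`.
#' @export
build_cv_plan <- function(samples, folds = 5, seed = 1,
                          grouping = c("chain", "residue")) {
  grouping <- match.arg(grouping)
  check_samples(samples)
  folds <- as.integer(folds)
  samples <- tibble::as_tibble(samples)
  samples$sample_id <- seq_len(nrow(samples))

  assignment <- with_seed(seed, {
    if (grouping == "chain") {
      chains <- unique(samples$chain_id)
      if (length(chains) < folds) {
        abort(sprintf("Chain-grouped CV needs at least %d chains (have %d); use fewer folds or grouping = 'residue'.",
                      folds, length(chains)))
      }
      ord <- sample(chains)
      fold_of <- setNames(rep_len(seq_len(folds), length(ord)), ord)
      dplyr::mutate(samples, fold = unname(fold_of[.data$chain_id]))
    } else {
      if (nrow(samples) < folds) abort("Fewer samples than folds.")
      dplyr::mutate(samples, fold = sample(rep_len(seq_len(folds), nrow(samples))))
    }
  })

  pos_per_fold <- dplyr::count(dplyr::filter(assignment, .data$label == 1L), .data$fold)
  if (nrow(pos_per_fold) < folds || any(pos_per_fold$n == 0)) {
    abort("Some fold contains no positive sample; use fewer folds.")
  }

  negative_draw <- with_seed(seed + 1L, {
    purrr::map_dfr(seq_len(folds), function(f) {
      train <- dplyr::filter(assignment, .data$fold != f)
      n_pos <- sum(train$label == 1L)
      negs <- train$sample_id[train$label == 0L]
      if (n_pos == 0L) abort(sprintf("Training set of fold %d has no positives; use fewer folds.", f))
      if (length(negs) < n_pos) {
        abort(sprintf("Training set of fold %d has too few negatives (%d) to balance %d positives.",
                      f, length(negs), n_pos))
      }
      tibble::tibble(fold = f, sample_id = sort(sample(negs, n_pos)))
    })
  })

  structure(
    list(assignment = assignment, negative_draw = negative_draw,
         folds = folds, seed = seed, grouping = grouping),
    class = "ppr_cv_plan"
  )
}

#' @export
print.ppr_cv_plan <- function(x, ...) {
  cat(sprintf("<ppr_cv_plan> %d folds, %s-grouped, seed %d, %d samples\n",
              x$folds, x$grouping, x$seed, nrow(x$assignment)))
  invisible(x)
}

#' Train the residue classifier
#'
#' Fits a support vector machine with a radial basis function kernel at the
#' library's default hyperparameters (e1071/LibSVM), exposing a real-valued
#' decision score per sample oriented so that larger means more
#' binding-like. Features are passed unscaled: every encoder already emits
#' bounded, comparable channels (scaled PSSM in (0,1), zero-mean unit-sd
#' property values, 0/1 bits).
#'
#' @param x Numeric feature matrix (or `ppr_features` tibble).
#' @param labels Binary labels, one per row.
#' @return A `ppr_svm` model object.
#' @export
train_classifier <- function(x, labels) {
  if (inherits(x, "ppr_features")) x <- feature_matrix(x)
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    abort("Training set must contain both classes.")
  }
  y <- factor(labels, levels = c(0L, 1L))
  fit <- e1071::svm(x, y, kernel = "radial", scale = FALSE)
  structure(list(model = fit, n_features = ncol(x),
                 feature_names = colnames(x)),
            class = "ppr_svm")
}

#' Decision scores for new samples
#'
#' @param object A `ppr_svm` from [train_classifier()].
#' @param newdata Feature matrix or `ppr_features` tibble.
#' @param ... Unused.
#' @return Numeric decision values; positive favors the binding class.
#' @export
predict.ppr_svm <- function(object, newdata, ...) {
  if (inherits(newdata, "ppr_features")) newdata <- feature_matrix(newdata)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    abort(sprintf("Feature mismatch: model expects %d columns, got %d.",
                  object$n_features, ncol(newdata)))
  }
  p <- stats::predict(object$model, newdata, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  score <- as.numeric(dv[, 1])
  # LibSVM orients the decision value toward the first training label level;
  # flip if that level is the negative class.
  lab <- colnames(dv)[1]
  if (!is.null(lab) && grepl("^0/", lab)) score <- -score
  score
}

#' Balanced-sampling cross-validation of a residue classifier
#'
#' For every fold of `plan`: encode the training complement, keep all its
#' positives plus the plan's pre-drawn equal number of negatives, fit the
#' RBF SVM, and score every held-out sample (the full, naturally imbalanced
#' fold). Metrics are pooled over the concatenated held-out scores at the
#' decision threshold (default 0, the SVM decision boundary), and the pooled
#' ROC/AUC is computed from the same scores.
#'
#' @param samples Tibble with `chain_id`, `position`, `label`.
#' @param profiles Named list of [pssm_profile()] objects (or sequences for
#'   the sequence-only encoders).
#' @param scales Normalized selected scales (where the encoder needs them).
#' @param encoder,window Passed to [encode_residues()].
#' @param plan A [build_cv_plan()] result; built from `folds`, `seed`,
#'   `grouping` when `NULL`.
#' @param folds,seed,grouping Used only when `plan` is `NULL`.
#' @param threshold Decision-score cutoff for the confusion counts.
#' @return A `ppr_cv` object: `predictions` (per-sample tibble with fold,
#'   score, predicted and true label), `fold_metrics`, pooled `metrics`,
#'   `auc`, `roc` points, the `plan` and the encoder settings. See
#'   [tidy.ppr_cv()], [glance.ppr_cv()], [autoplot.ppr_cv()].
#' @export
cross_validate <- function(samples, profiles, scales = NULL,
                           encoder = "pssmpp", window = 17, plan = NULL,
                           folds = 5, seed = 1,
                           grouping = c("chain", "residue"), threshold = 0) {
  check_samples(samples)
  if (is.null(plan)) {
    plan <- build_cv_plan(samples, folds = folds, seed = seed,
                          grouping = match.arg(grouping))
  }
  if (nrow(plan$assignment) != nrow(samples)) {
    abort("Plan was built for a different sample table.")
  }
  features <- encode_residues(samples, profiles, scales = scales,
                              encoder = encoder, window = window)
  X <- feature_matrix(features)
  assignment <- plan$assignment

  preds <- purrr::map_dfr(seq_len(plan$folds), function(f) {
    train_pos <- assignment$sample_id[assignment$fold != f & assignment$label == 1L]
    train_neg <- plan$negative_draw$sample_id[plan$negative_draw$fold == f]
    tr <- c(train_pos, train_neg)
    te <- assignment$sample_id[assignment$fold == f]
    fit <- tryCatch(
      train_classifier(X[tr, , drop = FALSE], assignment$label[tr]),
      error = function(e) abort(sprintf("Fold %d training failed: %s", f,
                                        conditionMessage(e)))
    )
    tibble::tibble(
      chain_id = assignment$chain_id[te],
      position = assignment$position[te],
      label = assignment$label[te],
      fold = f,
      score = predict(fit, X[te, , drop = FALSE])
    )
  })
  preds$pred <- as.integer(preds$score > threshold)

  fold_metrics <- preds |>
    dplyr::group_by(.data$fold) |>
    dplyr::group_modify(~ {
      m <- metrics_from_counts(
        tp = sum(.x$pred == 1L & .x$label == 1L),
        fp = sum(.x$pred == 1L & .x$label == 0L),
        tn = sum(.x$pred == 0L & .x$label == 0L),
        fn = sum(.x$pred == 0L & .x$label == 1L)
      )
      m$AUC <- if (length(unique(.x$label)) == 2L) roc_auc(.x$score, .x$label)$auc else NA_real_
      m
    }) |>
    dplyr::ungroup()

  pooled <- metrics_from_counts(
    tp = sum(preds$pred == 1L & preds$label == 1L),
    fp = sum(preds$pred == 1L & preds$label == 0L),
    tn = sum(preds$pred == 0L & preds$label == 0L),
    fn = sum(preds$pred == 0L & preds$label == 1L)
  )
  roc <- roc_auc(preds$score, preds$label)
  pooled$AUC <- roc$auc

  structure(
    list(predictions = preds, fold_metrics = fold_metrics, metrics = pooled,
         auc = roc$auc, roc = roc$points, plan = plan, encoder = encoder,
         window = window, threshold = threshold,
         accessions = attr(features, "accessions")),
    class = "ppr_cv"
  )
}

#' @export
print.ppr_cv <- function(x, ...) {
  cat(sprintf("<ppr_cv> %s encoder, w = %d, %d-fold %s-grouped CV, %d residues\n",
              x$encoder, x$window, x$plan$folds, x$plan$grouping,
              nrow(x$predictions)))
  print(glance(x))
  invisible(x)
}

#' Tidy per-fold cross-validation metrics
#'
#' @param x A `ppr_cv`.
#' @param ... Unused.
#' @return Tibble with one row per fold (counts, ACC..F1, AUC).
#' @method tidy ppr_cv
#' @export
tidy.ppr_cv <- function(x, ...) x$fold_metrics

#' One-row pooled cross-validation summary
#'
#' @param x A `ppr_cv`.
#' @param ... Unused.
#' @return One-row tibble: encoder, window, pooled metrics and AUC.
#' @method glance ppr_cv
#' @export
glance.ppr_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(encoder = x$encoder, window = x$window,
                   folds = x$plan$folds, threshold = x$threshold),
    x$metrics
  )
}

#' ROC curve of a cross-validation run
#'
#' @param object A `ppr_cv`.
#' @param ... Unused.
#' @return A ggplot of pooled sensitivity vs 1 - specificity.
#' @method autoplot ppr_cv
#' @export
autoplot.ppr_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("Pooled ROC, %s (w = %d), AUC = %.3f",
                      object$encoder, object$window, object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Write cross-validation artifacts
#'
#' `write_predictions()` writes the per-residue score table;
#' `write_metrics()` the fold and pooled metric rows; `write_roc()` the ROC
#' points as CSV.
#'
#' @param cv A `ppr_cv`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(cv, path) {
  readr::write_tsv(cv$predictions, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
write_metrics <- function(cv, path) {
  out <- dplyr::bind_rows(
    dplyr::mutate(cv$fold_metrics, fold = as.character(.data$fold)),
    dplyr::mutate(dplyr::bind_cols(tibble::tibble(fold = "pooled"), cv$metrics))
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
write_roc <- function(cv, path) {
  readr::write_csv(cv$roc, path)
  invisible(path)
}
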