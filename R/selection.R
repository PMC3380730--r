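#' Pearson correlation between two per-sample value vectors
#'
#' Standard product-moment correlation, used to measure redundancy between
#' two property scales over the per-residue values they assign to a dataset
#' (equivalent to the composition-weighted correlation of the two 20-value
#' scales).
#'
#' @param x,y Numeric vectors of equal length (>= 2), non-constant.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    abort("Need two equal-length vectors with at least 2 samples.")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Correlation undefined for a constant input.")
  }
  stats::cor(x, y)
}

#' Configuration of the greedy property-selection loop
#'
#' @param preselect_k Number of top-AUC candidates forming the initial
#'   candidate set C (default 20).
#' @param corr_threshold Absolute Pearson bound rho: after a candidate is
#'   accepted, every remaining candidate correlated with it at |r| >= rho is
#'   pruned (default 0.8 — high enough to keep moderately related scales,
#'   low enough to drop near-duplicates).
#' @param improvement_epsilon Minimum cross-validated AUC gain required to
#'   accept a candidate (default 0.002, the order of the CV-AUC estimation
#'   noise; a zero margin accepts almost any candidate because pooled CV AUC
#'   fluctuates upward as easily as downward, and yields needlessly large
#'   subsets).
#' @param cv_folds,grouping,seed Cross-validation settings used to assess
#'   each candidate set (see [build_cv_plan()]).
#' @param encoder Encoder used for the assessment: `pssmpp` (default) or
#'   `pp`.
#' @param window Window size for the assessment encoder.
#' @return A `ppr_selection_config` list.
#' @export
selection_config <- function(preselect_k = 20, corr_threshold = 0.8,
                             improvement_epsilon = 0.002, cv_folds = 5,
                             grouping = "chain", seed = 1,
                             encoder = c("pssmpp", "pp"), window = 17) {
  encoder <- match.arg(encoder)
  if (corr_threshold <= 0 || corr_threshold > 1) {
    abort("corr_threshold must be in (0, 1].")
  }
  if (preselect_k < 1) abort("preselect_k must be >= 1.")
  structure(
    list(preselect_k = as.integer(preselect_k),
         corr_threshold = corr_threshold,
         improvement_epsilon = improvement_epsilon,
         cv_folds = as.integer(cv_folds), grouping = grouping,
         seed = as.integer(seed), encoder = encoder,
         window = as.integer(window)),
    class = "ppr_selection_config"
  )
}

#' Greedy forward selection of property scales with correlation pruning
#'
#' Implements the iterative selection workflow: the candidate set C starts
#' as the `preselect_k` top-ranked scales by discrimination AUC; the loop
#' pops the highest-AUC candidate f, assesses the current selection S with
#' and without f by balanced cross-validation of the chosen encoder
#' (baseline AUC for an empty S is 0.5), accepts f when the pooled CV AUC
#' improves by more than `improvement_epsilon`, and on acceptance prunes
#' from C every candidate whose per-residue values correlate with f at
#' |r| >= `corr_threshold`; rejected candidates are simply discarded. The
#' loop ends when C is empty. The same CV plan (folds and negative draws)
#' is used for every assessment so candidate sets are compared on identical
#' splits.
#'
#' @param samples Tibble with `chain_id`, `position`, `label`.
#' @param scales Normalized scale table ([normalize_scales()]).
#' @param profiles Named list of [pssm_profile()] objects.
#' @param ranking Optional precomputed [rank_scales()] result; computed from
#'   the inputs when `NULL`.
#' @param config A [selection_config()].
#' @return A `ppr_selection`: `selected` (accessions in acceptance order),
#'   `auc` (final CV AUC of S), `trace` (per-iteration tibble: candidate,
#'   its scale AUC, CV AUC with the candidate, best AUC before, accepted
#'   flag, accessions pruned), `ranking`, `config`, `plan`.
#' @export
greedy_select <- function(samples, scales, profiles, ranking = NULL,
                          config = selection_config()) {
  check_samples(samples)
  if (!"normalized" %in% names(scales)) {
    abort("Scales must be normalized first; see normalize_scales().")
  }
  if (is.null(ranking)) {
    ranking <- rank_scales(samples, scales, profiles)
  }
  if (nrow(ranking) == 0) {
    return(structure(
      list(selected = character(0), auc = 0.5,
           trace = tibble::tibble(), ranking = ranking, config = config,
           plan = NULL),
      class = "ppr_selection"
    ))
  }

  plan <- build_cv_plan(samples, folds = config$cv_folds, seed = config$seed,
                        grouping = config$grouping)
  aa <- sample_residues(samples, profiles)
  value_of <- function(acc) {
    lookup_aa_values(scales$normalized[[match(acc, scales$accession)]], aa)
  }
  assess <- function(accs) {
    cv <- cross_validate(
      samples, profiles,
      scales = scales[match(accs, scales$accession), , drop = FALSE],
      encoder = config$encoder, window = config$window, plan = plan
    )
    cv$auc
  }

  C <- utils::head(ranking$accession, config$preselect_k)
  S <- character(0)
  best_auc <- 0.5
  trace <- list()
  it <- 0L
  while (length(C) > 0) {
    it <- it + 1L
    f <- C[1]
    C <- C[-1]
    cand_auc <- tryCatch(assess(c(S, f)), error = function(e) {
      abort(sprintf("CV assessment of candidate %s failed: %s", f,
                    conditionMessage(e)))
    })
    accepted <- cand_auc > best_auc + config$improvement_epsilon
    best_auc_prev <- best_auc
    pruned <- character(0)
    if (accepted) {
      S <- c(S, f)
      fv <- value_of(f)
      keep <- vapply(C, function(g) {
        abs(pearson_correlation(value_of(g), fv)) < config$corr_threshold
      }, logical(1))
      pruned <- C[!keep]
      C <- C[keep]
      best_auc <- cand_auc
    }
    trace[[it]] <- tibble::tibble(
      iteration = it, accession = f,
      scale_auc = ranking$auc[match(f, ranking$accession)],
      cv_auc = cand_auc,
      best_auc_before = if (accepted) best_auc_prev else best_auc,
      accepted = accepted, pruned = list(pruned)
    )
  }
  trace <- dplyr::bind_rows(trace)

  structure(
    list(selected = S, auc = best_auc, trace = trace, ranking = ranking,
         config = config, plan = plan),
    class = "ppr_selection"
  )
}

#' @export
print.ppr_selection <- function(x, ...) {
  cat(sprintf("<ppr_selection> %d scale(s) selected, CV AUC %.3f\n",
              length(x$selected), x$auc))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the greedy-selection audit trail
#'
#' @param x A `ppr_selection`.
#' @param ... Unused.
#' @return Per-iteration tibble; the `pruned` list column is flattened to a
#'   comma-separated string.
#' @method tidy ppr_selection
#' @export
tidy.ppr_selection <- function(x, ...) {
  if (nrow(x$trace) == 0) return(x$trace)
  dplyr::mutate(x$trace,
                pruned = vapply(.data$pruned, paste, character(1), collapse = ","))
}

#' @method glance ppr_selection
#' @export
glance.ppr_selection <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    cv_auc = x$auc,
    n_candidates = min(nrow(x$ranking), x$config$preselect_k),
    encoder = x$config$encoder,
    corr_threshold = x$config$corr_threshold
  )
}

#' Selection trajectory plot
#'
#' CV AUC of each tried candidate over the greedy iterations, accepted
#' candidates highlighted.
#'
#' @param object A `ppr_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ppr_selection
#' @export
autoplot.ppr_selection <- function(object, ...) {
  tr <- tidy(object)
  if (nrow(tr) == 0) abort("Empty selection trace.")
  ggplot2::ggplot(tr, ggplot2::aes(.data$iteration, .data$cv_auc)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_auc_before),
                       colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$accepted), size = 2) +
    ggplot2::geom_text(data = tr[tr$accepted, ],
                       ggplot2::aes(label = .data$accession),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Iteration", y = "Pooled CV AUC",
                  colour = "Accepted",
                  title = "Greedy property selection") +
    ggplot2::theme_minimal()
}

#' Write the selection report
#'
#' TSV trace plus a plain-text list of the selected accessions.
#'
#' @param selection A `ppr_selection`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_selection <- function(selection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tidy(selection), file.path(dir, "selection_trace.tsv"))
  writeLines(selection$selected, file.path(dir, "selected_scales.txt"))
  invisible(dir)
}

#' Read / write a selection configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [selection_config()].
#' @return A `ppr_selection_config` (reader); `path` invisibly (writer).
#' @export
read_selection_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(selection_config, vals)
}

#' @rdname read_selection_config
#' @export
write_selection_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
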