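#' Read AAindex1 physicochemical scales
#'
#' Parses the AAindex1 flat-file format: records delimited by `//`, with an
#' `H` line (accession), `D` line (description) and an `I` line whose header
#' names amino-acid pairs (`A/L R/K ...`) followed by two rows of ten values
#' (row one = first letter of each pair, row two = second). Values are
#' remapped to the canonical order [aa_order()]; `NA` marks a missing value.
#'
#' Entries with any missing value are kept but flagged `complete = FALSE`;
#' downstream ranking and encoding only use complete entries (incomplete
#' scales cannot be normalized over all 20 amino acids).
#'
#' @param file Path to an AAindex1 file, or a character vector of lines.
#' @return A tibble with one row per record: `accession`, `description`,
#'   `complete`, and `raw` (list column of named 20-vectors in canonical
#'   amino-acid order).
#' @seealso [normalize_scales()], [rank_scales()]
#' @export
read_aaindex <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else if (length(file) > 1L) {
    file # already split into lines
  } else {
    strsplit(file, "\n", fixed = TRUE)[[1]]
  }
  records <- list()
  acc <- NULL
  desc <- character(0)
  header <- NULL
  values <- list()
  in_desc <- FALSE

  flush_record <- function(line_no) {
    if (is.null(acc)) {
      abort(sprintf("AAindex1 record ending at line %d has no H (accession) line.", line_no))
    }
    if (is.null(header) || length(values) != 2L) {
      abort(sprintf("AAindex1 record '%s' (line %d): expected an I line followed by two value rows.",
                    acc, line_no))
    }
    row1 <- values[[1]]
    row2 <- values[[2]]
    if (length(row1) != 10L || length(row2) != 10L) {
      abort(sprintf("AAindex1 record '%s' (line %d): value rows must hold 10 entries each (got %d and %d).",
                    acc, line_no, length(row1), length(row2)))
    }
    pairs <- strsplit(header, "/", fixed = TRUE)
    if (length(pairs) != 10L || any(lengths(pairs) != 2L)) {
      abort(sprintf("AAindex1 record '%s': malformed I header.", acc))
    }
    aa1 <- vapply(pairs, `[`, character(1), 1L)
    aa2 <- vapply(pairs, `[`, character(1), 2L)
    v <- setNames(c(row1, row2), c(aa1, aa2))
    if (!setequal(names(v), AA_ORDER)) {
      abort(sprintf("AAindex1 record '%s': I header does not cover the 20 standard amino acids.", acc))
    }
    v <- v[AA_ORDER]
    records[[length(records) + 1L]] <<- list(
      accession = acc,
      description = paste(desc, collapse = " "),
      raw = v,
      complete = !anyNA(v)
    )
    acc <<- NULL; desc <<- character(0); header <<- NULL; values <<- list()
    in_desc <<- FALSE
  }

  parse_values <- function(line, line_no) {
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    out <- suppressWarnings(as.numeric(ifelse(toks == "NA", NA, toks)))
    if (any(is.na(out) & toks != "NA")) {
      abort(sprintf("AAindex1 record '%s' (line %d): unparsable value '%s'.",
                    acc %||% "?", line_no, toks[which(is.na(out) & toks != "NA")[1]]))
    }
    out
  }

  expecting_values <- FALSE
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("^//", line)) {
      flush_record(i)
      expecting_values <- FALSE
      next
    }
    tag <- substr(line, 1L, 1L)
    if (expecting_values && (tag == " " || tag == "\t")) {
      values[[length(values) + 1L]] <- parse_values(line, i)
      if (length(values) == 2L) expecting_values <- FALSE
      next
    }
    in_desc <- in_desc && tag == " "
    if (tag == "H") {
      acc <- trimws(substring(line, 2L))
    } else if (tag == "D") {
      desc <- trimws(substring(line, 2L))
      in_desc <- TRUE
    } else if (tag == " " && in_desc) {
      desc <- c(desc, trimws(line))
    } else if (tag == "I") {
      header <- strsplit(trimws(substring(line, 2L)), "\\s+")[[1]]
      expecting_values <- TRUE
      in_desc <- FALSE
    } else {
      in_desc <- FALSE
    }
  }
  if (!is.null(acc)) {
    abort(sprintf("AAindex1 stream ends inside record '%s': missing '//' terminator.", acc))
  }

  tibble::tibble(
    accession = vapply(records, `[[`, character(1), "accession"),
    description = vapply(records, `[[`, character(1), "description"),
    complete = vapply(records, `[[`, logical(1), "complete"),
    raw = lapply(records, `[[`, "raw")
  )
}

#' Normalize a 20-value amino-acid scale
#'
#' Centers and scales the raw values to zero mean and unit *population*
#' standard deviation (denominator 20, not 19): the normalized value for
#' amino acid j is (P_j - mu) / sigma with mu the mean over the 20 values and
#' sigma the square root of the mean squared deviation.
#'
#' @param raw Numeric vector of 20 values (canonical amino-acid order).
#' @return Numeric vector of 20 normalized values, same names as input.
#' @export
#' @examples
#' z <- normalize_scale(1:20)
#' mean(z)                      # 0
#' sqrt(mean((z - mean(z))^2))  # 1
normalize_scale <- function(raw) {
  if (length(raw) != 20L || anyNA(raw)) {
    abort("`raw` must be 20 non-missing numeric values.")
  }
  mu <- mean(raw)
  sigma <- sqrt(mean((raw - mu)^2))
  if (sigma == 0) {
    abort("Degenerate scale: all 20 values identical (sigma = 0).")
  }
  (raw - mu) / sigma
}

#' Normalize every complete scale in a scale table
#'
#' Drops incomplete entries (those with missing values) and adds a
#' `normalized` list column holding the output of [normalize_scale()].
#'
#' @param scales Tibble from [read_aaindex()] (or [simulate_scales()]).
#' @return The filtered tibble with an added `normalized` list column.
#' @export
normalize_scales <- function(scales) {
  dropped <- sum(!scales$complete)
  if (dropped > 0) {
    inform(sprintf("Dropping %d incomplete scale(s) with missing values.", dropped))
  }
  scales <- dplyr::filter(scales, .data$complete)
  if (nrow(scales) == 0) abort("No complete scales to normalize.")
  dplyr::mutate(scales, normalized = purrr::map(.data$raw, normalize_scale))
}

# P x 20 -> 20 x P matrix of normalized values for the given accessions,
# preserving the order of `accessions` (selection order matters downstream).
scale_matrix <- function(scales, accessions = scales$accession) {
  if (!"normalized" %in% names(scales)) {
    abort("Scales must be normalized first; see normalize_scales().")
  }
  idx <- match(accessions, scales$accession)
  if (anyNA(idx)) {
    abort(sprintf("Unknown accession(s): %s",
                  paste(accessions[is.na(idx)], collapse = ", ")))
  }
  W <- do.call(cbind, scales$normalized[idx])
  dimnames(W) <- list(AA_ORDER, accessions)
  for (j in seq_along(accessions)) {
    w <- W[, j]
    if (abs(mean(w)) > 1e-6 || abs(sqrt(mean((w - mean(w))^2)) - 1) > 1e-6) {
      abort(sprintf("Scale %s is not normalized (mean 0 / population sd 1 required).",
                    accessions[j]))
    }
  }
  W
}

#' Discrimination AUC of one scalar feature
#'
#' Area under the ROC curve of a value sequence against binary labels,
#' computed as the Mann-Whitney statistic with midrank tie handling (tied
#' positive/negative pairs contribute 1/2). No classifier is fitted, so no
#' cross-validation is involved; this equals the trapezoidal area under the
#' ROC over all thresholds.
#'
#' @param values Numeric vector, one value per sample.
#' @param labels Binary vector (1 = positive class), same length.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' scale_auc(c(3, 1, 2, 0), c(1, 1, 0, 0)) # 0.75
scale_auc <- function(values, labels) {
  if (length(values) != length(labels)) abort("values and labels differ in length.")
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort("AUC undefined: both classes must be present.")
  }
  r <- rank(values) # midranks for ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rank property scales by classifier-free AUC
#'
#' Assigns each residue sample the normalized scale value of its amino-acid
#' type and scores the scale by [scale_auc()] against the binding labels.
#' With `fold = TRUE` (default) an AUC below 0.5 is reported as 1 - AUC: a
#' scale that separates the classes in either direction is informative, and
#' folding makes the ranking orientation-free.
#'
#' @param samples Tibble with `chain_id`, `position`, `label`.
#' @param scales Normalized scale table ([normalize_scales()]).
#' @param sequences Named character vector of chain sequences, or a list of
#'   [read_pssm()] profiles.
#' @param fold Fold AUC below 0.5 to 1 - AUC before ranking?
#' @param dataset_tag Provenance string stored on the result.
#' @return A tibble (class `ppr_ranking`) with `accession`, `description`,
#'   `auc`, `rank`, sorted by descending AUC (accession breaks ties).
#' @export
rank_scales <- function(samples, scales, sequences, fold = TRUE,
                        dataset_tag = "unnamed") {
  check_samples(samples)
  if (nrow(scales) == 0) abort("Empty scale list.")
  if (!"normalized" %in% names(scales)) {
    abort("Scales must be normalized first; see normalize_scales().")
  }
  if (!any(samples$label == 1L) || !any(samples$label == 0L)) {
    abort("Both binding and non-binding residues are required to rank scales.")
  }
  aa <- sample_residues(samples, sequences)
  aucs <- vapply(scales$normalized, function(w) {
    scale_auc(lookup_aa_values(w, aa), samples$label)
  }, numeric(1))
  if (fold) aucs <- pmax(aucs, 1 - aucs)
  out <- tibble::tibble(
    accession = scales$accession,
    description = scales$description,
    auc = aucs
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$auc), .data$accession)
  out$rank <- seq_len(nrow(out))
  attr(out, "dataset_tag") <- dataset_tag
  attr(out, "folded") <- fold
  class(out) <- c("ppr_ranking", class(out))
  out
}

#' @describeIn rank_scales Bar-chart of per-scale AUC.
#' @param object,x A `ppr_ranking`.
#' @param top_n Show only the first `top_n` scales.
#' @param ... Unused.
#' @method autoplot ppr_ranking
#' @export
autoplot.ppr_ranking <- function(object, top_n = 20, ...) {
  df <- utils::head(as.data.frame(object), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$accession, .data$auc), y = .data$auc
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "AUC (folded)",
                  title = "Per-scale discrimination AUC") +
    ggplot2::theme_minimal()
}

#' Write a scale ranking to TSV
#'
#' @param ranking A `ppr_ranking` from [rank_scales()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  readr::write_tsv(
    dplyr::select(tibble::as_tibble(ranking),
                  "accession", "description", "auc", "rank"),
    path
  )
  invisible(path)
}
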