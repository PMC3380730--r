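#' Sliding-window positions around a residue
#'
#' The w consecutive sequence positions centered on `center`; slots falling
#' outside `[1, L]` (terminal-spanning windows) are returned as `NA`.
#'
#' @param center 1-based residue index.
#' @param w Odd window size.
#' @param L Chain length.
#' @return Integer vector of length `w`, `NA` marking out-of-sequence slots.
#' @export
#' @examples
#' window_positions(1, 5, 100) # NA NA 1 2 3
window_positions <- function(center, w, L) {
  if (w < 1 || w %% 2 == 0) abort("Window size must be an odd positive integer.")
  if (center < 1 || center > L) abort("center must lie in [1, L].")
  p <- center + seq.int(-(w - 1L) / 2L, (w - 1L) / 2L)
  p[p < 1L | p > L] <- NA_integer_
  p
}

encoder_names <- function() c("pssmpp", "pssm", "pp", "pssm_pp_concat", "binary")

# Channel names within one slot, by encoder (terminal bit appended later).
channel_names <- function(encoder, accessions) {
  switch(encoder,
    pssm = paste0("pssm.", AA_ORDER),
    binary = paste0("bin.", AA_ORDER),
    pp = paste0("prop.", accessions),
    pssmpp = paste0("prop.", accessions),
    pssm_pp_concat = c(paste0("pssm.", AA_ORDER), paste0("prop.", accessions)),
    abort(sprintf("Unknown encoder '%s'.", encoder))
  )
}

# Per-position channel matrix (L x k) for one chain.
channel_matrix <- function(encoder, profile, sequence, W) {
  aa <- strsplit(sequence, "")[[1]]
  idx <- match(aa, AA_ORDER)
  onehot <- function() {
    m <- matrix(0, length(aa), 20L, dimnames = list(NULL, AA_ORDER))
    ok <- !is.na(idx)
    if (any(!ok)) {
      inform(sprintf("%d non-standard residue(s) encoded as all-zero.", sum(!ok)))
    }
    m[cbind(which(ok), idx[ok])] <- 1
    m
  }
  ppmat <- function() {
    m <- matrix(0, length(aa), ncol(W), dimnames = list(NULL, colnames(W)))
    ok <- !is.na(idx)
    if (any(!ok)) {
      inform(sprintf("%d non-standard residue(s) mapped to the scale mean.", sum(!ok)))
    }
    m[ok, ] <- W[idx[ok], , drop = FALSE]
    m
  }
  switch(encoder,
    pssm = profile$scaled,
    binary = onehot(),
    pp = ppmat(),
    pssmpp = profile$scaled %*% W,
    pssm_pp_concat = cbind(profile$scaled, ppmat())
  )
}

#' Encode residue samples as sliding-window feature vectors
#'
#' Builds one feature row per sample by stacking, for each of the `w` window
#' slots (N- to C-terminal), the slot's channel values followed by a terminal
#' indicator bit. An in-sequence slot carries its channel values and bit 0;
#' a slot beyond either chain end carries all-zero channels and bit 1 (zero
#' is the mean of a normalized scale, so padding is neutral).
#'
#' Encoders and their per-slot channels:
#' \describe{
#'   \item{`pssm`}{the 20 logistic-scaled PSSM log-odds (21 w columns).}
#'   \item{`binary`}{one-hot amino-acid identity (21 w columns).}
#'   \item{`pp`}{the P normalized property values of the slot's amino acid
#'     ((P+1) w columns).}
#'   \item{`pssm_pp_concat`}{PSSM channels then PP channels, one shared bit
#'     ((20+P+1) w columns).}
#'   \item{`pssmpp`}{the integrative profile: for each selected property p,
#'     F_p = sum over the 20 amino acids j of w_pj * M_ij, the scale's
#'     normalized values dotted with the scaled PSSM row ((P+1) w columns).}
#' }
#' With the default window of 17 and 4 selected scales this yields the
#' contract dimensions 357 (pssm/binary), 85 (pp/pssmpp) and 425 (concat).
#'
#' @param samples Tibble with `chain_id`, `position` (and optionally
#'   `label`, carried through).
#' @param profiles Named list of [pssm_profile()] objects (`binary` and `pp`
#'   only need the sequences; a named character vector is accepted then).
#' @param scales Normalized scale table restricted to the selected
#'   properties, in selection order; required for pp/pssmpp/concat.
#' @param encoder One of `pssmpp`, `pssm`, `pp`, `pssm_pp_concat`, `binary`.
#' @param window Odd window size (default 17).
#' @return A tibble (class `ppr_features`): `chain_id`, `position`, `label`
#'   if supplied, then one column per feature, named
#'   `pos<offset>.<channel>` (e.g. `pos-8.pssm.A`, `pos+0.prop.QIAN880117`,
#'   `pos+3.term`). Attributes `encoder`, `window`, `accessions`,
#'   `feature_cols`.
#' @export
encode_residues <- function(samples, profiles, scales = NULL,
                            encoder = c("pssmpp", "pssm", "pp",
                                        "pssm_pp_concat", "binary"),
                            window = 17) {
  encoder <- match.arg(encoder)
  check_samples(samples, need_label = FALSE)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    abort("Window size must be an odd positive integer.")
  }

  needs_scales <- encoder %in% c("pp", "pssmpp", "pssm_pp_concat")
  W <- NULL
  accessions <- character(0)
  if (needs_scales) {
    if (is.null(scales) || nrow(scales) == 0) {
      abort(sprintf("Encoder '%s' needs at least one selected scale.", encoder))
    }
    W <- scale_matrix(scales) # validates normalization
    accessions <- colnames(W)
  }

  needs_pssm <- encoder %in% c("pssm", "pssmpp", "pssm_pp_concat")
  if (needs_pssm) {
    if (!is.list(profiles) || length(profiles) == 0 ||
        !inherits(profiles[[1]], "pssm_profile")) {
      abort(sprintf("Encoder '%s' needs a list of pssm_profile objects.", encoder))
    }
    sequences <- as_sequences(profiles)
  } else {
    sequences <- as_sequences(profiles)
  }

  chan <- channel_names(encoder, accessions)
  k <- length(chan)
  offsets <- seq.int(-(window - 1L) / 2L, (window - 1L) / 2L)
  slot_lbl <- sprintf("pos%+d", offsets)
  feat_names <- unlist(lapply(slot_lbl, function(l) c(paste0(l, ".", chan),
                                                      paste0(l, ".term"))))
  missing_chain <- setdiff(unique(samples$chain_id), names(sequences))
  if (length(missing_chain) > 0) {
    abort(sprintf("No profile/sequence for chain(s): %s",
                  paste(missing_chain, collapse = ", ")))
  }

  out <- matrix(0, nrow(samples), (k + 1L) * window)
  colnames(out) <- feat_names
  for (cid in unique(samples$chain_id)) {
    rows <- which(samples$chain_id == cid)
    sq <- sequences[[cid]]
    L <- nchar(sq)
    centers <- samples$position[rows]
    if (any(centers < 1L | centers > L)) {
      abort(sprintf("Chain %s: sample position outside [1, %d].", cid, L))
    }
    M <- channel_matrix(encoder, profiles[[cid]], sq, W)
    if (nrow(M) != L) {
      abort(sprintf("Chain %s: profile has %d rows for a %d-residue sequence.",
                    cid, nrow(M), L))
    }
    for (s in seq_len(window)) {
      p <- centers + offsets[s]
      ok <- p >= 1L & p <= L
      block <- matrix(0, length(rows), k)
      if (any(ok)) block[ok, ] <- M[p[ok], , drop = FALSE]
      cols <- (s - 1L) * (k + 1L) + seq_len(k)
      out[rows, cols] <- block
      out[rows, s * (k + 1L)] <- as.numeric(!ok)
    }
  }

  meta <- dplyr::select(tibble::as_tibble(samples),
                        dplyr::any_of(c("chain_id", "position", "label")))
  res <- dplyr::bind_cols(meta, tibble::as_tibble(out))
  attr(res, "encoder") <- encoder
  attr(res, "window") <- window
  attr(res, "accessions") <- accessions
  attr(res, "feature_cols") <- feat_names
  class(res) <- c("ppr_features", class(res))
  res
}

#' Extract the numeric feature matrix from an encoded table
#'
#' @param features A `ppr_features` tibble from [encode_residues()].
#' @return Numeric matrix, rows aligned with the samples.
#' @export
feature_matrix <- function(features) {
  cols <- attr(features, "feature_cols")
  if (is.null(cols)) {
    cols <- setdiff(names(features), c("chain_id", "position", "label"))
  }
  as.matrix(features[, cols, drop = FALSE])
}

#' Write / read encoded features as TSV
#'
#' Dense tab-separated table whose header names every column
#' (`chain_id`, `position`, `label`, then `pos-8.pssm.A`, ...).
#'
#' @param features A `ppr_features` tibble.
#' @param path Output path.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_features <- function(features, path) {
  readr::write_tsv(tibble::as_tibble(features), path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    chain_id = readr::col_character(),
    .default = readr::col_double()
  ))
  if ("position" %in% names(out)) out$position <- as.integer(out$position)
  if ("label" %in% names(out)) out$label <- as.integer(out$label)
  attr(out, "feature_cols") <-
    setdiff(names(out), c("chain_id", "position", "label"))
  out
}
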