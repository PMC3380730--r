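#' Logistic scaling of PSSM log-odds
#'
#' Maps a log-odds score to (0, 1) with the standard logistic function
#' 1 / (1 + exp(-x)); strictly increasing, 0 maps to 0.5.
#'
#' @param x Numeric (finite).
#' @return Values in (0, 1).
#' @export
#' @examples
#' logistic_scale(0)  # 0.5
#' logistic_scale(7)  # ~0.99909
logistic_scale <- function(x) {
  if (any(!is.finite(x))) abort("logistic_scale() requires finite input.")
  1 / (1 + exp(-x))
}

#' Construct a PSSM profile object
#'
#' A chain's sequence together with its L x 20 log-odds matrix (columns in
#' canonical amino-acid order) and the logistic-scaled twin used by the
#' encoders.
#'
#' @param chain_id Chain identifier.
#' @param sequence Amino-acid string of length L.
#' @param log_odds L x 20 numeric matrix, rows = positions 1..L.
#' @return An object of class `pssm_profile`.
#' @export
pssm_profile <- function(chain_id, sequence, log_odds) {
  log_odds <- as.matrix(log_odds)
  storage.mode(log_odds) <- "double"
  L <- nchar(sequence)
  if (nrow(log_odds) != L || ncol(log_odds) != 20L) {
    abort(sprintf("log_odds must be %d x 20 for chain '%s' (got %d x %d).",
                  L, chain_id, nrow(log_odds), ncol(log_odds)))
  }
  colnames(log_odds) <- AA_ORDER
  rownames(log_odds) <- NULL
  structure(
    list(chain_id = as.character(chain_id), sequence = sequence,
         log_odds = log_odds, scaled = logistic_scale(log_odds)),
    class = "pssm_profile"
  )
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> chain %s, %d residues\n", x$chain_id,
              nchar(x$sequence)))
  cat(strtrim(x$sequence, 60),
      if (nchar(x$sequence) > 60) "...\n" else "\n")
  invisible(x)
}

#' @method tidy pssm_profile
#' @export
tidy.pssm_profile <- function(x, ...) {
  L <- nchar(x$sequence)
  tibble::tibble(
    chain_id = x$chain_id,
    position = rep(seq_len(L), each = 20L),
    residue = rep(strsplit(x$sequence, "")[[1]], each = 20L),
    aa = rep(AA_ORDER, L),
    log_odds = as.vector(t(x$log_odds)),
    scaled = as.vector(t(x$scaled))
  )
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the `-out_ascii_pssm` dialect: header lines, a column-header line
#' naming the amino-acid order, then one line per position holding the index,
#' the residue letter, and two 20-column blocks. Only the first block (the
#' log-odds substitution scores) is used; the weighted-percentage block is
#' ignored. Columns are remapped to the canonical order if the file's header
#' differs.
#'
#' @param file Path to the PSSM file, or a character vector of lines.
#' @param chain_id Chain identifier; defaults to the file name without
#'   extension.
#' @return A [pssm_profile()].
#' @export
read_pssm <- function(file, chain_id = NULL) {
  from_file <- length(file) == 1L && !grepl("\n", file) && file.exists(file)
  lines <- if (from_file) readLines(file, warn = FALSE)
    else if (length(file) > 1L) file # already split into lines
    else strsplit(file, "\n", fixed = TRUE)[[1]]
  if (is.null(chain_id)) {
    chain_id <- if (from_file) sub("\\.[^.]*$", "", basename(file)) else "chain"
  }

  col_order <- NULL
  header_line <- NA_integer_
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(toks) %in% c(20L, 40L) && all(toks %in% AA_ORDER)) {
      col_order <- toks[1:20]
      header_line <- i
      break
    }
  }
  if (is.null(col_order)) {
    abort("Not an ASCII PSSM: no amino-acid column header line found.")
  }

  res <- character(0)
  rows <- list()
  expected <- 1L
  for (i in seq.int(header_line + 1L, length(lines))) {
    line <- lines[[i]]
    if (!grepl("^\\s*\\d+\\s+[A-Za-z]", line)) {
      if (length(rows) > 0) break # footer (K, Lambda, ...) ends the table
      next
    }
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    idx <- suppressWarnings(as.integer(toks[1]))
    vals <- suppressWarnings(as.numeric(toks[3:min(22L, length(toks))]))
    if (length(toks) < 22L || anyNA(vals)) {
      abort(sprintf("PSSM parse error at line %d: expected index, residue and 20 log-odds values.", i))
    }
    if (is.na(idx) || idx != expected) {
      abort(sprintf("PSSM parse error at line %d: position index %s, expected %d (indices must be consecutive from 1).",
                    i, toks[1], expected))
    }
    res[expected] <- toupper(toks[2])
    rows[[expected]] <- vals
    expected <- expected + 1L
  }
  if (length(rows) == 0) abort("ASCII PSSM contains no data rows.")
  m <- do.call(rbind, rows)
  colnames(m) <- col_order
  m <- m[, AA_ORDER, drop = FALSE]
  pssm_profile(chain_id, paste(res, collapse = ""), m)
}

#' Read every PSSM in a directory
#'
#' @param dir Directory holding one ASCII PSSM per chain.
#' @param pattern File-name pattern (default `*.pssm`).
#' @return Named list of [pssm_profile()] objects, keyed by chain id.
#' @export
read_pssm_dir <- function(dir, pattern = "\\.pssm$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0) {
    abort(sprintf("No PSSM files matching '%s' under %s", pattern, dir))
  }
  profiles <- lapply(files, read_pssm)
  setNames(profiles, vapply(profiles, function(p) p$chain_id, character(1)))
}

#' Read per-residue binding labels
#'
#' Tab-separated file with columns `chain_id`, `position`, `label`
#' (1 = heme binding). Labels are assigned externally (e.g. from
#' ligand-protein contacts of solved structures); this package consumes them.
#'
#' @param file Path to the TSV.
#' @return Tibble with `chain_id` (chr), `position` (int), `label` (int).
#' @export
read_labels <- function(file) {
  out <- readr::read_tsv(file, col_types = readr::cols(
    chain_id = readr::col_character(),
    position = readr::col_integer(),
    label = readr::col_integer()
  ))
  check_samples(out)
  out
}

#' Cross-check profile sequences against a FASTA file
#'
#' Compares each profile's sequence (reconstructed from the PSSM residue
#' column) with the corresponding FASTA record; mismatching positions raise a
#' warning naming chain and position.
#'
#' @param profiles Named list of [pssm_profile()] objects.
#' @param fasta Path to a FASTA file whose record ids match chain ids.
#' @return Tibble of mismatches (`chain_id`, `position`, `pssm`, `fasta`),
#'   empty when everything agrees.
#' @export
check_sequences <- function(profiles, fasta) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("check_sequences() needs the Biostrings package.")
  }
  seqs <- Biostrings::readAAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  mism <- purrr::map_dfr(profiles, function(p) {
    if (!p$chain_id %in% names(seqs)) {
      warn(sprintf("Chain %s missing from FASTA.", p$chain_id))
      return(NULL)
    }
    fs <- as.character(seqs[[p$chain_id]])
    ps <- p$sequence
    n <- min(nchar(fs), nchar(ps))
    if (nchar(fs) != nchar(ps)) {
      warn(sprintf("Chain %s: FASTA length %d vs PSSM length %d.",
                   p$chain_id, nchar(fs), nchar(ps)))
    }
    a <- strsplit(substr(ps, 1, n), "")[[1]]
    b <- strsplit(substr(fs, 1, n), "")[[1]]
    bad <- which(a != b)
    for (i in bad) {
      warn(sprintf("Chain %s position %d: PSSM '%s' vs FASTA '%s'.",
                   p$chain_id, i, a[i], b[i]))
    }
    if (length(bad) == 0) return(NULL)
    tibble::tibble(chain_id = p$chain_id, position = bad,
                   pssm = a[bad], fasta = b[bad])
  })
  mism
}
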