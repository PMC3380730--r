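# Independent oracles and tiny in-code fixtures shared across tests.

# Exhaustive pairwise AUC: count wins + half-ties over all pos x neg pairs.
brute_force_auc <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# Naive triple-loop integrative-profile encoder for a single window slot:
# for each property p, sum over the 20 amino acids of w_pj * M_ij.
naive_pssmpp_slot <- function(scaled_row, W) {
  P <- ncol(W)
  out <- numeric(P)
  for (p in seq_len(P)) {
    acc <- 0
    for (j in 1:20) acc <- acc + W[j, p] * scaled_row[j]
    out[p] <- acc
  }
  out
}

# Direct formula evaluation of the metric suite for cross-checking.
naive_metrics <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  list(
    ACC = (tp + tn) / (tp + tn + fp + fn),
    SN = tp / (tp + fn),
    SP = tn / (tn + fp),
    PR = tp / (tp + fp),
    MCC = (tp * tn - fp * fn) /
      sqrt((tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)),
    F1 = {
      sn <- tp / (tp + fn); pr <- tp / (tp + fp)
      2 * sn * pr / (sn + pr)
    }
  )
}

# Small deterministic profile: sequence drawn from the canonical alphabet,
# integer log-odds like a real PSSM.
toy_profile <- function(chain_id = "toy", L = 12, seed = 42) {
  pssmpp:::with_seed(seed, {
    seq <- paste(sample(aa_order(), L, replace = TRUE), collapse = "")
    m <- matrix(sample(-8:8, L * 20, replace = TRUE), L, 20)
    pssm_profile(chain_id, seq, m)
  })
}

toy_scales <- function(n = 4, seed = 7) simulate_scales(n, 0, seed = seed)

# Text of a minimal two-record AAindex1 file (second record has a missing
# value), mirroring the database layout.
aaindex_fixture_text <- function() {
  c(
    "H QIAN880117",
    "D Weights for beta-sheet at the window position of -3",
    "R LIT:1A",
    "A Author, A.",
    "T A synthetic stand-in entry used only for parser tests",
    "J Nowhere (0000)",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "    0.10   -0.20    0.30   -0.40    0.50   -0.60    0.70   -0.80    0.90   -1.00",
    "    1.10   -1.20    1.30   -1.40    1.50   -1.60    1.70   -1.80    1.90   -2.00",
    "//",
    "H TEST000002",
    "D Synthetic incomplete scale",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "    0.10    0.20      NA    0.40    0.50    0.60    0.70    0.80    0.90    1.00",
    "    1.10    1.20    1.30    1.40    1.50    1.60    1.70    1.80    1.90    2.00",
    "//"
  )
}

# Text of a 5-row ASCII PSSM in the PSI-BLAST layout.
pssm_fixture_text <- function() {
  aa <- aa_order()
  hdr <- paste0("           ", paste(sprintf("%3s", c(aa, aa)), collapse = ""))
  rows <- vapply(1:5, function(i) {
    lo <- ((seq_len(20) + i) %% 9) - 4
    lo[i] <- 0 # plant a zero so logistic(0) = 0.5 is visible
    paste0(sprintf("%5d %s ", i, c("M", "K", "A", "W", "V")[i]),
           paste(sprintf("%3d", lo), collapse = ""),
           paste(sprintf("%4d", rep(0, 20)), collapse = ""),
           "  0.30      0.09")
  }, character(1))
  c("",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    hdr, rows, "",
    "                      K         Lambda",
    "Standard Ungapped    0.1337     0.3176")
}

small_dataset <- function(seed = 11, n_chains = 12, effect_size = 2,
                          n_scales = 6, n_informative = 2,
                          chain_length = c(25, 40)) {
  simulate_dataset(fixture_config(
    n_chains = n_chains, chain_length = chain_length, n_scales = n_scales,
    n_informative = n_informative, effect_size = effect_size, seed = seed
  ))
}
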