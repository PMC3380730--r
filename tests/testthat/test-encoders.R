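test_that("window_positions marks terminal-spanning slots", {
  expect_equal(sum(is.na(window_positions(1, 17, 100))), 8L)
  expect_equal(window_positions(9, 17, 100), 1:17)
  expect_equal(window_positions(50, 3, 50), c(49L, 50L, NA))
  expect_error(window_positions(5, 4, 100), "odd")
  expect_error(window_positions(0, 3, 100), "\\[1, L\\]")
})

test_that("every encoder satisfies its dimensional contract", {
  ds <- small_dataset()
  sc4 <- ds$scales[1:4, ]
  cases <- list(
    list(encoder = "pssm", scales = NULL, w = 17, dim = 357),
    list(encoder = "binary", scales = NULL, w = 17, dim = 357),
    list(encoder = "pp", scales = sc4, w = 17, dim = 85),
    list(encoder = "pssmpp", scales = sc4, w = 17, dim = 85),
    list(encoder = "pssm_pp_concat", scales = sc4, w = 17, dim = 425),
    list(encoder = "pssmpp", scales = ds$scales[1:2, ], w = 9, dim = 27),
    list(encoder = "pssm", scales = NULL, w = 1, dim = 21)
  )
  samp <- head(ds$samples, 5)
  for (cs in cases) {
    f <- encode_residues(samp, ds$profiles, scales = cs$scales,
                         encoder = cs$encoder, window = cs$w)
    expect_equal(ncol(feature_matrix(f)), cs$dim,
                 info = paste(cs$encoder, cs$w))
    expect_true(all(is.finite(feature_matrix(f))))
  }
})

test_that("terminal padding zero-fills channels and raises the slot bit", {
  ds <- small_dataset()
  cid <- ds$samples$chain_id[1]
  samp <- tibble::tibble(chain_id = cid, position = 1L)
  f <- feature_matrix(encode_residues(samp, ds$profiles, encoder = "pssm",
                                      window = 3))
  # slot at offset -1 lies before the N-terminus: 20 zeros then bit 1
  expect_equal(unname(f[1, 1:20]), rep(0, 20))
  expect_equal(unname(f[1, 21]), 1)
  # center slot is in sequence: bit 0 and scaled values in (0,1)
  expect_equal(unname(f[1, 42]), 0)
  expect_true(all(f[1, 22:41] > 0 & f[1, 22:41] < 1))
})

test_that("binary encoding is one-hot over the canonical alphabet", {
  sq <- c(c1 = "GAG")
  samp <- tibble::tibble(chain_id = "c1", position = 1:3)
  f <- feature_matrix(encode_residues(samp, sq, encoder = "binary", window = 1))
  expect_equal(dim(f), c(3L, 21L))
  expect_equal(unname(rowSums(f[, 1:20])), c(1, 1, 1))
  expect_equal(unname(f[, 21]), c(0, 0, 0))
  expect_equal(colnames(f)[which(f[1, ] == 1)], "pos+0.bin.G")
  expect_equal(colnames(f)[which(f[2, ] == 1)], "pos+0.bin.A")
})

test_that("pp encoding repeats each slot's amino-acid scale values", {
  sc <- toy_scales(3)
  sq <- c(c1 = "GGGGG")
  samp <- tibble::tibble(chain_id = "c1", position = 3L)
  f <- feature_matrix(encode_residues(samp, sq, scales = sc,
                                      encoder = "pp", window = 5))
  g_vals <- vapply(sc$normalized, function(v) v[["G"]], numeric(1))
  # every slot is glycine: the 3 scale values repeat in every slot, bits 0
  expect_equal(unname(f[1, ]), rep(c(g_vals, 0), 5))
})

test_that("integrative profile equals the naive triple-loop oracle", {
  set.seed(123)
  for (rep in 1:100) {
    L <- sample(3:12, 1)
    prof <- toy_profile(L = L, seed = sample.int(1e6, 1))
    P <- sample(1:5, 1)
    sc <- simulate_scales(P, 0, seed = sample.int(1e6, 1))
    W <- do.call(cbind, sc$normalized)
    center <- sample(seq_len(L), 1)
    w <- 1 + 2 * sample(0:3, 1)
    f <- feature_matrix(encode_residues(
      tibble::tibble(chain_id = prof$chain_id, position = center),
      setNames(list(prof), prof$chain_id),
      scales = sc, encoder = "pssmpp", window = w
    ))
    slots <- window_positions(center, w, L)
    expected <- unlist(lapply(slots, function(pos) {
      if (is.na(pos)) c(rep(0, P), 1) else
        c(naive_pssmpp_slot(prof$scaled[pos, ], W), 0)
    }))
    expect_equal(unname(f[1, ]), expected, tolerance = 1e-12)
  }
})

test_that("a uniform scaled row yields exactly zero integrative features", {
  # sum_j w_pj = 0 for a normalized scale, so constant M_ij = c kills F_ip
  sc <- toy_scales(4)
  prof <- pssm_profile("flat", "AAAA", matrix(0, 4, 20)) # scaled row = 0.5
  samp <- tibble::tibble(chain_id = "flat", position = 2L)
  f <- feature_matrix(encode_residues(samp, list(flat = prof), scales = sc,
                                      encoder = "pssmpp", window = 3))
  expect_equal(unname(f[1, ]), c(rep(0, 4), 0, rep(0, 4), 0, rep(0, 4), 0))
})

test_that("concatenated encoder interleaves pssm and pp blocks with one bit", {
  ds <- small_dataset()
  sc <- ds$scales[1:3, ]
  samp <- ds$samples[10:14, c("chain_id", "position")]
  w <- 5
  f_cat <- feature_matrix(encode_residues(samp, ds$profiles, scales = sc,
                                          encoder = "pssm_pp_concat", window = w))
  f_pssm <- feature_matrix(encode_residues(samp, ds$profiles,
                                           encoder = "pssm", window = w))
  f_pp <- feature_matrix(encode_residues(samp, ds$profiles, scales = sc,
                                         encoder = "pp", window = w))
  k <- 20 + 3 + 1
  for (s in seq_len(w)) {
    expect_equal(f_cat[, (s - 1) * k + 1:20], f_pssm[, (s - 1) * 21 + 1:20],
                 ignore_attr = TRUE)
    expect_equal(f_cat[, (s - 1) * k + 21:23], f_pp[, (s - 1) * 4 + 1:3],
                 ignore_attr = TRUE)
    expect_equal(f_cat[, s * k], f_pssm[, s * 21], ignore_attr = TRUE)
  }
})

test_that("shifting the center shifts the slot blocks by one block width", {
  ds <- small_dataset()
  cid <- ds$samples$chain_id[1]
  L <- nchar(ds$sequences[[cid]])
  w <- 7
  samp <- tibble::tibble(chain_id = cid, position = c(10L, 11L))
  f <- feature_matrix(encode_residues(samp, ds$profiles, encoder = "pssm",
                                      window = w))
  # slots 2..w of the center-10 row equal slots 1..w-1 of the center-11 row
  expect_equal(unname(f[1, 22:(21 * w)]), unname(f[2, 1:(21 * (w - 1))]))
})

test_that("unnormalized scales are rejected by the scale contract", {
  ds <- small_dataset()
  sc <- ds$scales[1:2, ]
  sc$normalized[[1]] <- sc$normalized[[1]] + 1 # break zero mean
  expect_error(
    encode_residues(head(ds$samples, 2), ds$profiles, scales = sc,
                    encoder = "pssmpp"),
    "not normalized"
  )
})

test_that("feature tables round-trip through the TSV writer", {
  ds <- small_dataset()
  f <- encode_residues(head(ds$samples, 6), ds$profiles,
                       scales = ds$scales[1:2, ], encoder = "pssmpp",
                       window = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_features(f, path)
  back <- read_features(path)
  expect_equal(names(back), names(f))
  expect_equal(feature_matrix(back), feature_matrix(f), tolerance = 1e-12,
               ignore_attr = TRUE)
})
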