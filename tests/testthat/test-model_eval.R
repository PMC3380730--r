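test_that("metric suite matches direct formula evaluation", {
  m <- metrics_from_counts(71, 289, 711, 29)
  o <- naive_metrics(71, 289, 711, 29)
  for (k in names(o)) expect_equal(m[[k]], o[[k]], tolerance = 1e-12, info = k)

  perfect <- metrics_from_counts(10, 0, 10, 0)
  expect_equal(unlist(perfect[c("ACC", "SN", "SP", "PR", "MCC", "F1")]),
               setNames(rep(1, 6), c("ACC", "SN", "SP", "PR", "MCC", "F1")))

  none <- metrics_from_counts(5, 5, 5, 5)
  expect_equal(none$ACC, 0.5)
  expect_equal(none$MCC, 0)

  # zero denominators are reported as undefined, not zero
  no_pred_pos <- metrics_from_counts(0, 0, 8, 2)
  expect_true(is.na(no_pred_pos$PR))
  expect_true(is.na(no_pred_pos$MCC))
  expect_error(metrics_from_counts(-1, 0, 0, 1), "non-negative")
})

test_that("roc_auc sweeps thresholds and matches the pairwise oracle", {
  perfect <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8), c(1, 1, 0))$auc, 0)
  # curve anchors at (0,0) and (1,1)
  expect_equal(perfect$points$fpr[1], 0)
  expect_equal(tail(perfect$points$tpr, 1), 1)

  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    s <- round(rnorm(n), 1) # ties likely
    l <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(s, l)$auc, brute_force_auc(s, l), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("roc_auc is invariant under strictly monotone score transforms", {
  set.seed(5)
  s <- rnorm(100)
  l <- rbinom(100, 1, 0.3)
  base <- roc_auc(s, l)$auc
  expect_equal(roc_auc(exp(s), l)$auc, base, tolerance = 1e-12)
  expect_equal(roc_auc(2 * s + 7, l)$auc, base, tolerance = 1e-12)
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  s <- rnorm(150)
  l <- rbinom(150, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(roc_auc(s, l)$auc, ref, tolerance = 1e-10)
})

test_that("balanced CV plans draw equal negatives and partition the samples", {
  set.seed(1)
  samples <- tibble::tibble(
    chain_id = rep(sprintf("c%02d", 1:20), each = 50),
    position = rep(1:50, 20),
    label = rbinom(1000, 1, 0.10)
  )
  for (grouping in c("chain", "residue")) {
    plan <- build_cv_plan(samples, folds = 5, seed = 7, grouping = grouping)
    expect_equal(sort(plan$assignment$sample_id), 1:1000)
    expect_equal(nrow(plan$assignment), 1000L)
    for (f in 1:5) {
      train <- plan$assignment[plan$assignment$fold != f, ]
      drawn <- plan$negative_draw$sample_id[plan$negative_draw$fold == f]
      expect_equal(length(drawn), sum(train$label == 1L))
      expect_equal(length(unique(drawn)), length(drawn)) # without replacement
      expect_true(all(plan$assignment$label[drawn] == 0L))
      expect_true(all(plan$assignment$fold[drawn] != f))
    }
    # chains never straddle folds under chain grouping
    if (grouping == "chain") {
      per_chain <- tapply(plan$assignment$fold, plan$assignment$chain_id,
                          function(x) length(unique(x)))
      expect_true(all(per_chain == 1))
    }
  }
})

test_that("CV plans are reproducible under a seed and error sensibly", {
  samples <- tibble::tibble(
    chain_id = rep(sprintf("c%02d", 1:10), each = 30),
    position = rep(1:30, 10),
    label = rep(c(1L, rep(0L, 9)), 30)
  )
  p1 <- build_cv_plan(samples, seed = 42)
  p2 <- build_cv_plan(samples, seed = 42)
  expect_identical(p1$assignment, p2$assignment)
  expect_identical(p1$negative_draw, p2$negative_draw)

  three <- dplyr::filter(samples, chain_id %in% c("c01", "c02", "c03"))
  expect_error(build_cv_plan(three, folds = 5, grouping = "chain"),
               "at least 5 chains")
  onepos <- dplyr::mutate(samples, label = as.integer(position == 1 & chain_id == "c01"))
  expect_error(build_cv_plan(onepos, folds = 5), "no positive")
})

test_that("the RBF SVM separates blobs, is deterministic, and flags one-class input", {
  set.seed(10)
  x <- rbind(matrix(rnorm(200, 0), ncol = 2), matrix(rnorm(200, 4), ncol = 2))
  y <- rep(c(0L, 1L), each = 100)
  fit <- train_classifier(x, y)
  s <- predict(fit, x)
  expect_equal(roc_auc(s, y)$auc, 1)
  # positives must receive the larger decision values (orientation contract)
  expect_gt(mean(s[y == 1]), mean(s[y == 0]))

  fit2 <- train_classifier(x, y)
  expect_identical(predict(fit2, x), s)

  expect_error(train_classifier(x, rep(1L, 200)), "both classes")
  expect_error(predict(fit, x[, 1, drop = FALSE]), "mismatch")
})

test_that("cross-validation evaluates imbalanced held-out folds and pools counts", {
  ds <- small_dataset(seed = 31, n_chains = 15)
  cv <- cross_validate(ds$samples, ds$profiles, scales = ds$scales[1:2, ],
                       encoder = "pssmpp", window = 9, seed = 2)
  # held-out folds partition the data at natural imbalance
  expect_equal(nrow(cv$predictions), nrow(ds$samples))
  expect_equal(sum(cv$predictions$label), sum(ds$samples$label))
  expect_equal(sort(unique(cv$predictions$fold)), 1:5)
  # pooled confusion counts equal the sum over folds
  with(cv$metrics, expect_equal(TP + FP + TN + FN, nrow(ds$samples)))
  expect_equal(sum(cv$fold_metrics$TP), cv$metrics$TP)
  expect_equal(sum(cv$fold_metrics$FN), cv$metrics$FN)

  g <- glance(cv)
  expect_equal(g$encoder, "pssmpp")
  expect_true(g$AUC >= 0 && g$AUC <= 1)
  expect_equal(nrow(tidy(cv)), 5L)
})

test_that("cross-validation is bit-reproducible under a fixed seed", {
  ds <- small_dataset(seed = 17, n_chains = 10, chain_length = c(20, 30))
  cv1 <- cross_validate(ds$samples, ds$profiles, scales = ds$scales[1:2, ],
                        window = 5, seed = 9)
  cv2 <- cross_validate(ds$samples, ds$profiles, scales = ds$scales[1:2, ],
                        window = 5, seed = 9)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(cv1$metrics, cv2$metrics)
})

test_that("strong planted signal yields high pooled AUC; permuted labels do not", {
  ds <- small_dataset(seed = 53, n_chains = 60, effect_size = 4,
                      chain_length = c(30, 60))
  sc <- ds$scales[ds$scales$informative, ]
  cv <- cross_validate(ds$samples, ds$profiles, scales = sc, seed = 3)
  expect_gt(cv$auc, 0.9)

  null <- ds$samples
  null$label <- pssmpp:::with_seed(99, sample(null$label))
  cv0 <- cross_validate(null, ds$profiles, scales = sc, seed = 3)
  expect_gt(cv0$auc, 0.45)
  expect_lt(cv0$auc, 0.55)
})

test_that("cross-validation artifacts write as documented tables", {
  ds <- small_dataset(seed = 6, n_chains = 10, chain_length = c(20, 30))
  cv <- cross_validate(ds$samples, ds$profiles, scales = ds$scales[1:2, ],
                       window = 5)
  dir <- withr::local_tempdir()
  write_metrics(cv, file.path(dir, "m.tsv"))
  write_predictions(cv, file.path(dir, "p.tsv"))
  write_roc(cv, file.path(dir, "r.csv"))
  m <- readr::read_tsv(file.path(dir, "m.tsv"), show_col_types = FALSE)
  expect_equal(nrow(m), 6L) # 5 folds + pooled
  expect_true(all(c("ACC", "SN", "SP", "PR", "MCC", "F1", "AUC") %in% names(m)))
  p <- readr::read_tsv(file.path(dir, "p.tsv"), show_col_types = FALSE)
  expect_equal(names(p), c("chain_id", "position", "label", "fold", "score", "pred"))
})
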