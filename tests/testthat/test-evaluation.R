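test_that("cv plans partition the known associations with balanced folds", {
  set.seed(31)
  A <- matrix(0, 8, 6)
  A[sample(48, 20)] <- 1
  plan <- make_cv_plan(A, folds = 10, repeats = 3, seed = 5)
  for (r in 1:3) {
    a <- plan$assignments[plan$assignments$rep == r, ]
    expect_identical(as.integer(table(a$fold)), rep(2L, 10))  # N=20 -> 2 per fold
    # union of folds = all 1-entries, no duplicates
    keys <- paste(a$disease, a$drug)
    expect_setequal(keys, paste(which(A == 1, arr.ind = TRUE)[, 1],
                                which(A == 1, arr.ind = TRUE)[, 2]))
    expect_identical(anyDuplicated(keys), 0L)
  }
  expect_identical(make_cv_plan(A, 10, 3, seed = 5)$assignments,
                   plan$assignments)
  A2 <- matrix(0, 20, 20); A2[sample(400, 100)] <- 1
  expect_false(identical(make_cv_plan(A2, 10, 1, seed = 1)$assignments$fold,
                         make_cv_plan(A2, 10, 1, seed = 2)$assignments$fold))
  expect_error(make_cv_plan(matrix(c(1, 0, 0, 0), 2), folds = 10), "at least")
})

test_that("roc_auc equals brute-force pair counting, ties at one half", {
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_identical(r$auc, 1)
  expect_identical(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1))$auc, 0)
  set.seed(32)
  for (i in 1:5) {
    scores <- round(runif(200), 2)          # rounding forces ties
    labels <- rbinom(200, 1, 0.3)
    if (!any(labels == 1) || !any(labels == 0)) next
    expect_equal(roc_auc(scores, labels)$auc, pair_count_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("the ROC curve is a step function from (0,0) to (1,1)", {
  set.seed(33)
  scores <- runif(50); labels <- rbinom(50, 1, 0.4)
  roc <- roc_auc(scores, labels)$roc
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
})

test_that("pr_curve matches an all-thresholds sweep oracle", {
  p <- pr_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_identical(p$aupr, 1)
  allpos <- pr_curve(c(0.3, 0.9, 0.5), c(1, 1, 1))
  expect_true(all(allpos$pr$precision == 1))

  set.seed(34)
  scores <- round(runif(60), 1)
  labels <- rbinom(60, 1, 0.3)
  p2 <- pr_curve(scores, labels)
  # oracle: enumerate every distinct threshold, count TP/FP directly
  for (thr in sort(unique(scores), decreasing = TRUE)) {
    called <- scores >= thr
    tp <- sum(called & labels == 1); fp <- sum(called & labels == 0)
    row <- which(abs(p2$pr$recall - tp / sum(labels == 1)) < 1e-12 &
                 abs(p2$pr$precision - tp / (tp + fp)) < 1e-12)
    expect_gte(length(row), 1)
  }
  expect_error(pr_curve(runif(5), rep(0, 5)), "positive")
})

test_that("top-k counts are direct and non-decreasing", {
  expect_identical(unname(topk_counts(c(1, 7, 12), c(1, 5, 10))), c(1, 1, 2))
  expect_identical(unname(topk_counts(rep(1, 4), 1)), 4)
  cnt <- topk_counts(sample(1:100, 40))
  expect_true(all(diff(cnt) >= 0))
})

test_that("run_cv scores perfect and uninformative oracles correctly", {
  g <- small_synth(seed = 10)
  ds <- g$dataset
  truth <- ds$assoc
  plan <- make_cv_plan(ds$assoc, folds = 10, repeats = 1, seed = 3)

  oracle <- function(d, params) {
    structure(list(scores = truth, method = "oracle", params = params,
                   converged = TRUE, fits = list()),
              class = "omc_prediction")
  }
  expect_identical(run_cv(ds, oracle, omc_params(), plan)$auc, 1)

  constant <- function(d, params) {
    structure(list(scores = labeled_matrix(array(0.5, dim(truth)),
                                           rownames(truth), colnames(truth)),
                   method = "const", params = params, converged = TRUE,
                   fits = list()),
              class = "omc_prediction")
  }
  expect_equal(run_cv(ds, constant, omc_params(), plan)$auc, 0.5)
})

test_that("run_cv never leaks held-out entries into training", {
  g <- small_synth(seed = 11)
  ds <- g$dataset
  plan <- make_cv_plan(ds$assoc, folds = 5, repeats = 1, seed = 4)
  seen <- new.env()
  spy <- function(d, params) {
    a <- plan$assignments
    for (f in unique(a$fold)) {
      test <- a[a$fold == f, ]
      if (all(d$assoc[cbind(test$disease, test$drug)] == 0)) {
        assign(paste0("fold", f), TRUE, envir = seen)
      }
    }
    structure(list(scores = labeled_matrix(array(0.5, dim(d$assoc)),
                                           rownames(d$assoc),
                                           colnames(d$assoc)),
                   method = "spy", params = params, converged = TRUE,
                   fits = list()),
              class = "omc_prediction")
  }
  run_cv(ds, spy, omc_params(), plan)
  # every fold's test entries were zero in at least one training matrix
  expect_length(ls(seen), 5)
})

test_that("per-drug candidate sets exclude that drug's training positives", {
  g <- small_synth(seed = 12)
  ds <- g$dataset
  plan <- make_cv_plan(ds$assoc, folds = 5, repeats = 1, seed = 6)
  res <- run_cv(ds, "omc2", omc_params(), plan)
  for (i in seq_len(nrow(res$records))) {
    rec <- res$records[i, ]
    j <- match(rec$drug_id, colnames(ds$assoc))
    fold_mask <- plan$assignments$fold == rec$fold & plan$assignments$drug == j
    n_test_pos <- sum(fold_mask)
    n_train_pos <- sum(ds$assoc[, j]) - n_test_pos
    expect_equal(rec$n_candidates, nrow(ds$assoc) - n_train_pos)
  }
})

test_that("macro-averaged pooling is available and sane", {
  g <- small_synth(seed = 13)
  plan <- make_cv_plan(g$dataset$assoc, folds = 5, repeats = 1, seed = 7)
  res <- run_cv(g$dataset, "omc2", omc_params(), plan,
                pooling = "per_drug_macro")
  expect_true(res$auc > 0.5 && res$auc <= 1)
})

all_double_assoc <- function(ds) {
  ds$assoc[, ] <- 0
  ds$assoc[1, ] <- 1
  ds$assoc[2, ] <- 1
  ds
}

test_that("de novo protocol ranks the removed single association", {
  ds <- toy_bilayer()
  # drugs with exactly one known association are eligible
  expect_identical(colnames(ds$assoc)[colSums(ds$assoc) == 1],
                   c("r1", "r3", "r4"))
  truth <- ds$assoc
  oracle <- function(d, params) {            # top-scores the removed disease
    structure(list(scores = truth, method = "oracle",
                   params = params, converged = TRUE, fits = list()),
              class = "omc_prediction")
  }
  res <- de_novo_test(ds, oracle)
  expect_setequal(res$records$drug_id, c("r1", "r3", "r4"))
  expect_identical(unname(res$topk["top1"]), 3)
  # restriction to a named subset of eligible drugs
  res1 <- de_novo_test(ds, oracle, drugs = "r3")
  expect_identical(res1$records$disease_id, "d2")
  expect_error(de_novo_test(all_double_assoc(ds), "omc2"), "exactly one")
})

test_that("metrics are invariant to the order of test records", {
  set.seed(35)
  scores <- runif(100); labels <- rbinom(100, 1, 0.3)
  labels[1] <- 1; labels[2] <- 0
  perm <- sample(100)
  expect_equal(roc_auc(scores, labels)$auc,
               roc_auc(scores[perm], labels[perm])$auc)
  expect_equal(pr_curve(scores, labels)$aupr,
               pr_curve(scores[perm], labels[perm])$aupr)
})
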