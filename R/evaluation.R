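#' Plan a repeated k-fold cross-validation over known associations
#'
#' Within each repeat the known (value 1) association entries are randomly
#' partitioned into `folds` parts whose sizes differ by at most one.  The
#' plan is fully determined by `seed` and reproducible.
#'
#' @param assoc binary disease x drug association matrix.
#' @param folds number of folds (default 10).
#' @param repeats number of repeats (default 10).
#' @param seed integer RNG seed.
#' @return object of class `cv_plan`: list with `folds`, `repeats`, `seed`
#'   and `assignments`, a data.frame with one row per (repeat, known
#'   association) giving `rep`, `fold`, `disease` and `drug` indices.
#' @export
make_cv_plan <- function(assoc, folds = 10L, repeats = 10L, seed = 1L) {
  known <- which(assoc == 1, arr.ind = TRUE)
  N <- nrow(known)
  if (N < folds) {
    stop("need at least ", folds, " known associations, found ", N)
  }
  set.seed(seed)
  assignments <- do.call(rbind, lapply(seq_len(repeats), function(r) {
    data.frame(rep = r,
               fold = sample(rep(seq_len(folds), length.out = N)),
               disease = known[, 1L], drug = known[, 2L])
  }))
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed), assignments = assignments),
            class = "cv_plan")
}

#' Empirical ROC curve and AUC
#'
#' The AUC equals the Mann-Whitney statistic: the probability that a random
#' positive outscores a random negative, ties counted one half (midranks).
#' ROC points are computed at every distinct score threshold, giving a step
#' function from (0, 0) to (1, 1).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels, both classes present.
#' @return list with `roc` (data.frame `fpr`, `tpr`) and scalar `auc`.
#' @export
roc_auc <- function(scores, labels) {
  check_two_class(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  sw <- threshold_sweep(scores, labels)
  roc <- data.frame(fpr = c(0, sw$fp / n0), tpr = c(0, sw$tp / n1))
  list(roc = roc, auc = auc)
}

#' Precision-recall curve and non-interpolated AUPR
#'
#' Precision and recall at every distinct score threshold, descending; the
#' area is accumulated step-wise (no interpolation):
#' `AUPR = sum_i (R_i - R_{i-1}) P_i`.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels with at least one positive.
#' @return list with `pr` (data.frame `recall`, `precision`) and `aupr`.
#' @export
pr_curve <- function(scores, labels) {
  if (!any(labels == 1)) stop("pr_curve requires at least one positive label")
  n1 <- sum(labels == 1)
  sw <- threshold_sweep(scores, labels)
  recall <- sw$tp / n1
  precision <- sw$tp / (sw$tp + sw$fp)
  aupr <- sum(diff(c(0, recall)) * precision)
  list(pr = data.frame(recall = recall, precision = precision), aupr = aupr)
}

check_two_class <- function(labels) {
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("metric undefined: both classes must be present")
  }
}

# cumulative TP/FP counts at each distinct score threshold, descending
threshold_sweep <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- cumsum(rle(s)$lengths)   # last index of each tied score group
  data.frame(threshold = s[last],
             tp = cumsum(l == 1)[last],
             fp = cumsum(l == 0)[last])
}

#' Top-k retrieval counts
#'
#' For each threshold `k`, the number of held-out true associations whose
#' per-drug rank is within the top `k` candidates.
#'
#' @param ranks numeric ranks of the held-out associations.
#' @param thresholds integer rank cutoffs.
#' @return named integer vector of counts, non-decreasing in `k`.
#' @export
topk_counts <- function(ranks, thresholds = c(1, 5, 10, 30, 50, 100)) {
  stats::setNames(vapply(thresholds, function(k) sum(ranks <= k), numeric(1)),
                  paste0("top", thresholds))
}

resolve_method <- function(method) {
  if (is.function(method)) return(method)
  switch(method,
         omc2 = omc2,
         omc3 = omc3,
         omc_drug = function(ds, params) one_sided(ds, "drug", params),
         omc_disease = function(ds, params) one_sided(ds, "disease", params),
         stop("unknown method: ", method))
}

replace_assoc <- function(ds, assoc) {
  ds$assoc <- assoc
  ds
}

# midrank (average rank under ties) of each element of `take` among `scores`,
# ranking by descending score
descending_midrank <- function(scores, take) {
  r <- rank(-scores)
  r[take]
}

#' Run the repeated cross-validation protocol
#'
#' For each (repeat, fold) the fold's associations are hidden: set to 0 in
#' the training matrix (thereby also leaving the solver's observed set).
#' The predictor is trained on the remainder and, for every test drug, all
#' diseases except that drug's remaining training positives are scored as
#' candidates.  Per test association the midrank among candidates is
#' recorded.  ROC/PR metrics are computed on the pooled candidate scores of
#' each repeat and averaged across repeats; `pooling = "per_drug_macro"`
#' instead macro-averages per-drug AUCs.
#'
#' @param ds a `bilayer_dataset` or `trilayer_dataset`.
#' @param method `"omc2"`, `"omc3"`, `"omc_drug"`, `"omc_disease"`, or a
#'   function `(ds, params) -> omc_prediction`.
#' @param params an [omc_params()].
#' @param plan a [make_cv_plan()] plan for `ds$assoc`.
#' @param pooling `"pooled"` (default) or `"per_drug_macro"`.
#' @return object of class `evaluation_result`: list with per-pair
#'   `records`, `per_repeat` metric table, mean `auc` and `aupr`, pooled
#'   `roc` and `pr` point tables, and mean `topk` counts.
#' @export
run_cv <- function(ds, method = "omc2", params = omc_params(), plan,
                   pooling = c("pooled", "per_drug_macro")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(plan, "cv_plan"))
  predfun <- resolve_method(method)
  records <- list()
  rep_metrics <- list()
  all_scores <- numeric(0)
  all_labels <- integer(0)
  for (r in seq_len(plan$repeats)) {
    rep_assign <- plan$assignments[plan$assignments$rep == r, ]
    rep_scores <- numeric(0)
    rep_labels <- integer(0)
    for (f in seq_len(plan$folds)) {
      test <- rep_assign[rep_assign$fold == f, ]
      train_assoc <- ds$assoc
      train_assoc[cbind(test$disease, test$drug)] <- 0
      pred <- predfun(replace_assoc(ds, train_assoc), params)
      for (j in unique(test$drug)) {
        test_dis <- test$disease[test$drug == j]
        train_pos <- which(train_assoc[, j] == 1)
        cand <- setdiff(seq_len(nrow(ds$assoc)), train_pos)
        sc <- pred$scores[cand, j]
        lab <- as.integer(cand %in% test_dis)
        rk <- descending_midrank(sc, match(test_dis, cand))
        records[[length(records) + 1L]] <- data.frame(
          rep = r, fold = f,
          drug_id = colnames(ds$assoc)[j],
          disease_id = rownames(ds$assoc)[test_dis],
          score = unname(pred$scores[cbind(test_dis, j)]),
          rank = rk, n_candidates = length(cand),
          stringsAsFactors = FALSE)
        rep_scores <- c(rep_scores, sc)
        rep_labels <- c(rep_labels, lab)
      }
    }
    auc_r <- if (pooling == "pooled") {
      roc_auc(rep_scores, rep_labels)$auc
    } else {
      macro_auc(records, r)
    }
    rep_metrics[[r]] <- data.frame(rep = r, auc = auc_r,
                                   aupr = pr_curve(rep_scores, rep_labels)$aupr)
    all_scores <- c(all_scores, rep_scores)
    all_labels <- c(all_labels, rep_labels)
  }
  records <- do.call(rbind, records)
  per_repeat <- do.call(rbind, rep_metrics)
  topk <- Reduce(`+`, lapply(seq_len(plan$repeats), function(r) {
    topk_counts(records$rank[records$rep == r])
  })) / plan$repeats
  structure(list(records = records, per_repeat = per_repeat,
                 auc = mean(per_repeat$auc), aupr = mean(per_repeat$aupr),
                 roc = roc_auc(all_scores, all_labels)$roc,
                 pr = pr_curve(all_scores, all_labels)$pr,
                 topk = topk, pooling = pooling),
            class = "evaluation_result")
}

# macro-average of per-(fold, drug) AUCs within one repeat; each group has
# its own candidate set, so the midrank AUC formula applies per group
macro_auc <- function(records, r) {
  recs <- do.call(rbind, records)
  recs <- recs[recs$rep == r, ]
  groups <- split(recs, paste(recs$fold, recs$drug_id))
  per_group <- vapply(groups, function(d) {
    npos <- nrow(d)
    ncand <- d$n_candidates[1L]
    if (ncand <= npos) return(NA_real_)
    # mean over positives of the fraction of negatives ranked below them,
    # ties counted one half (midranks)
    mean((ncand - d$rank - (npos - 1) / 2) / (ncand - npos))
  }, numeric(1))
  mean(per_group, na.rm = TRUE)
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("evaluation over", nrow(x$per_repeat), "repeat(s),",
      nrow(x$records), "test associations\n")
  cat("  mean AUC: ", format(x$auc, digits = 4),
      "  mean AUPR:", format(x$aupr, digits = 4), "\n")
  cat("  mean top-k counts:",
      paste(names(x$topk), round(x$topk, 1), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' De novo prediction test for new drugs
#'
#' Every drug with exactly one known association is eligible.  In turn, that
#' single association is removed — leaving the drug with an all-zero column,
#' which triggers the KNN cold-start preprocessing inside the predictor —
#' the model is retrained, and the removed disease's rank among all diseases
#' is recorded.  Scores are pooled over eligible drugs for ROC/PR.
#'
#' @param ds a `bilayer_dataset` or `trilayer_dataset`.
#' @param method as in [run_cv()].
#' @param params an [omc_params()].
#' @param drugs optional character vector restricting the eligible drugs.
#' @return an `evaluation_result` (single repeat).
#' @export
de_novo_test <- function(ds, method = "omc2", params = omc_params(),
                         drugs = NULL) {
  predfun <- resolve_method(method)
  eligible <- which(colSums(ds$assoc) == 1)
  if (!is.null(drugs)) {
    eligible <- eligible[colnames(ds$assoc)[eligible] %in% drugs]
  }
  if (!length(eligible)) stop("no drugs with exactly one known association")
  records <- list()
  all_scores <- numeric(0)
  all_labels <- integer(0)
  for (j in eligible) {
    true_dis <- which(ds$assoc[, j] == 1)
    train_assoc <- ds$assoc
    train_assoc[true_dis, j] <- 0
    pred <- predfun(replace_assoc(ds, train_assoc), params)
    sc <- pred$scores[, j]
    rk <- descending_midrank(sc, true_dis)
    records[[length(records) + 1L]] <- data.frame(
      rep = 1L, fold = NA_integer_,
      drug_id = colnames(ds$assoc)[j],
      disease_id = rownames(ds$assoc)[true_dis],
      score = unname(sc[true_dis]), rank = rk,
      n_candidates = nrow(ds$assoc), stringsAsFactors = FALSE)
    all_scores <- c(all_scores, sc)
    all_labels <- c(all_labels, as.integer(seq_len(nrow(ds$assoc)) == true_dis))
  }
  records <- do.call(rbind, records)
  ra <- roc_auc(all_scores, all_labels)
  pc <- pr_curve(all_scores, all_labels)
  structure(list(records = records,
                 per_repeat = data.frame(rep = 1L, auc = ra$auc,
                                         aupr = pc$aupr),
                 auc = ra$auc, aupr = pc$aupr, roc = ra$roc, pr = pc$pr,
                 topk = topk_counts(records$rank), pooling = "pooled"),
            class = "evaluation_result")
}
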