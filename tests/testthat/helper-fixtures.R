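# small hand-built datasets shared across tests

toy_sim <- function(values, ids) {
  labeled_matrix(values, ids, ids)
}

# 4 drugs x 3 diseases; drug r2 and disease d3 are cold (all-zero)
toy_bilayer <- function() {
  drug_ids <- paste0("r", 1:4)
  disease_ids <- paste0("d", 1:3)
  drug_sim <- toy_sim(rbind(c(1.0, 0.2, 0.9, 0.4),
                            c(0.2, 1.0, 0.3, 0.8),
                            c(0.9, 0.3, 1.0, 0.5),
                            c(0.4, 0.8, 0.5, 1.0)), drug_ids)
  disease_sim <- toy_sim(rbind(c(1.0, 0.7, 0.6),
                               c(0.7, 1.0, 0.3),
                               c(0.6, 0.3, 1.0)), disease_ids)
  assoc <- labeled_matrix(rbind(c(1, 0, 0, 1),
                                c(0, 0, 1, 0),
                                c(0, 0, 0, 0)),
                          disease_ids, drug_ids)
  build_bilayer(drug_sim, disease_sim, assoc)
}

random_labeled <- function(nr, nc) {
  labeled_matrix(matrix(runif(nr * nc), nr, nc),
                 paste0("r", seq_len(nr)), paste0("c", seq_len(nc)))
}

small_synth <- function(seed = 1, ...) {
  args <- utils::modifyList(list(m = 40L, n = 30L, n_cold_drugs = 2L,
                                 n_cold_diseases = 2L, seed = seed),
                            list(...))
  generate_dataset(do.call(synth_params, args))
}

bilayer_part <- function(ds) {
  structure(list(drug_sim = ds$drug_sim, disease_sim = ds$disease_sim,
                 assoc = ds$assoc), class = "bilayer_dataset")
}

# planted rank-2 matrix in [0, 1] with a balanced spectrum: the two factor
# pairs load on complementary halves of the rows/columns, so both singular
# values are strong and the recovery target is genuinely two-dimensional
planted_rank2 <- function(nr, nc) {
  mk <- function(n) {
    half <- n %/% 2
    c(runif(half, 0.7, 1), runif(n - half, 0.05, 0.3))
  }
  M <- outer(mk(nr), mk(nc)) + outer(rev(mk(nr)), rev(mk(nc)))
  M / max(M)
}

# brute-force Mann-Whitney AUC: all positive-negative pairs, ties = 1/2
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
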