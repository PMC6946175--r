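#' Parameters of the synthetic network generator
#'
#' The generator plants a low-rank latent structure: nonnegative drug and
#' disease factors whose inner products define a continuous indication
#' propensity.  Associations are the top `density` fraction of propensities;
#' similarities are the cosine similarities of the factors plus bounded
#' symmetric noise.  Designated cold-start nodes have their association
#' row/column zeroed, and optional single-association drugs (for de novo
#' experiments) keep only their strongest indication.
#'
#' @param m,n numbers of drugs and diseases.
#' @param s,t numbers of proteins in the drug-side and disease-side panels
#'   (0 = bilayer).  The two panels receive independent protein identities.
#' @param rank latent rank r of the planted structure.
#' @param density fraction of (disease, drug) pairs that are associations.
#' @param noise standard deviation of the similarity noise, in similarity
#'   units.
#' @param n_cold_drugs,n_cold_diseases numbers of nodes whose associations
#'   are zeroed out (cold start).
#' @param n_single_drugs number of drugs reduced to a single association.
#' @param protein_density association density of the protein panels.
#' @param seed integer RNG seed.
#' @return object of class `synth_params`.
#' @export
synth_params <- function(m = 120L, n = 80L, s = 0L, t = 0L, rank = 5L,
                         density = 0.08, noise = 0.1,
                         n_cold_drugs = 6L, n_cold_diseases = 4L,
                         n_single_drugs = 0L, protein_density = 0.1,
                         seed = 1L) {
  stopifnot(rank <= min(m, n), density > 0, density < 1, noise >= 0,
            n_cold_drugs < m, n_cold_diseases < n,
            n_cold_drugs + n_single_drugs <= m)
  structure(list(m = as.integer(m), n = as.integer(n), s = as.integer(s),
                 t = as.integer(t), rank = as.integer(rank),
                 density = density, noise = noise,
                 n_cold_drugs = as.integer(n_cold_drugs),
                 n_cold_diseases = as.integer(n_cold_diseases),
                 n_single_drugs = as.integer(n_single_drugs),
                 protein_density = protein_density,
                 seed = as.integer(seed)),
            class = "synth_params")
}

pad_ids <- function(prefix, k) sprintf("%s%03d", prefix, seq_len(k))

# cosine similarity of nonnegative factor rows: entries in [0, 1], unit diag
cosine_sim <- function(F) {
  G <- F %*% t(F)
  d <- sqrt(diag(G))
  G / outer(d, d)
}

noisy_sim <- function(S, noise) {
  if (noise > 0) {
    E <- matrix(stats::rnorm(length(S), 0, noise), nrow(S))
    S <- S + (E + t(E)) / 2
  }
  S <- pmin(pmax(S, 0), 1)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

# binary matrix keeping exactly `count` largest entries of `scores`
top_threshold <- function(scores, count) {
  thr <- sort(scores, decreasing = TRUE)[count]
  (scores >= thr) * 1
}

#' Generate a synthetic bilayer or tri-layer dataset with ground truth
#'
#' Fully seeded and reproducible.  Protein panels (when `s`, `t` > 0) are
#' generated from the same latent drug/disease factors, so protein evidence
#' genuinely carries the association signal — in particular for cold-start
#' drugs, whose protein interactions survive the association zeroing.
#'
#' @param params a [synth_params()].
#' @return list with `dataset` (a `bilayer_dataset` or `trilayer_dataset`)
#'   and `truth`: latent factors, the continuous `scores` matrix, the full
#'   pre-zeroing binary association matrix `assoc_full`, and `hidden`, a
#'   data.frame of entries removed by cold-node zeroing or
#'   single-association reduction (`disease_id`, `drug_id`, `reason`).
#' @export
generate_dataset <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  set.seed(p$seed)
  drug_ids <- pad_ids("drug", p$m)
  disease_ids <- pad_ids("disease", p$n)
  Fd <- abs(matrix(stats::rnorm(p$m * p$rank), p$m, p$rank))
  Fs <- abs(matrix(stats::rnorm(p$n * p$rank), p$n, p$rank))
  scores <- Fs %*% t(Fd)                         # n x m propensities
  count <- max(1L, round(p$density * p$n * p$m))
  assoc_full <- top_threshold(scores, count)
  dimnames(assoc_full) <- list(disease_ids, drug_ids)

  drug_sim <- noisy_sim(cosine_sim(Fd), p$noise)
  disease_sim <- noisy_sim(cosine_sim(Fs), p$noise)
  dimnames(drug_sim) <- list(drug_ids, drug_ids)
  dimnames(disease_sim) <- list(disease_ids, disease_ids)

  assoc <- assoc_full
  hidden <- list()
  note_hidden <- function(dis, drug, reason) {
    k <- max(length(dis), length(drug))
    if (k == 0L || length(dis) == 0L || length(drug) == 0L) return(NULL)
    data.frame(disease_id = disease_ids[rep_len(dis, k)],
               drug_id = drug_ids[rep_len(drug, k)],
               reason = reason, stringsAsFactors = FALSE)
  }
  if (p$n_single_drugs > 0L) {
    multi <- which(colSums(assoc) >= 2)
    single <- sample(multi, min(p$n_single_drugs, length(multi)))
    for (j in single) {
      keep <- which.max(scores[, j] * (assoc[, j] == 1))
      dropped <- setdiff(which(assoc[, j] == 1), keep)
      hidden[[length(hidden) + 1L]] <-
        note_hidden(dropped, j, "single_drug_reduction")
      assoc[dropped, j] <- 0
    }
  } else {
    single <- integer(0)
  }
  if (p$n_cold_drugs > 0L) {
    cold_d <- sample(setdiff(seq_len(p$m), single), p$n_cold_drugs)
    for (j in cold_d) {
      ones <- which(assoc[, j] == 1)
      hidden[[length(hidden) + 1L]] <- note_hidden(ones, j, "cold_drug")
      assoc[, j] <- 0
    }
  }
  if (p$n_cold_diseases > 0L) {
    cold_s <- sample(seq_len(p$n), p$n_cold_diseases)
    for (i in cold_s) {
      ones <- which(assoc[i, ] == 1)
      hidden[[length(hidden) + 1L]] <- note_hidden(i, ones, "cold_disease")
      assoc[i, ] <- 0
    }
  }
  hidden <- if (length(hidden)) do.call(rbind, hidden) else
    data.frame(disease_id = character(0), drug_id = character(0),
               reason = character(0), stringsAsFactors = FALSE)

  ds <- build_bilayer(drug_sim, disease_sim, assoc)
  if (p$s > 0L || p$t > 0L) {
    protein_drug <- matrix(0, p$s, p$m,
                           dimnames = list(pad_ids("proteinA", p$s), drug_ids))
    if (p$s > 0L) {
      Fp1 <- abs(matrix(stats::rnorm(p$s * p$rank), p$s, p$rank))
      pr_scores <- Fp1 %*% t(Fd)
      protein_drug[] <- top_threshold(pr_scores,
                                      max(1L, round(p$protein_density * p$s * p$m)))
    }
    disease_protein <- matrix(0, p$n, p$t,
                              dimnames = list(disease_ids,
                                              pad_ids("proteinB", p$t)))
    if (p$t > 0L) {
      Fp2 <- abs(matrix(stats::rnorm(p$t * p$rank), p$t, p$rank))
      dp_scores <- Fs %*% t(Fp2)
      disease_protein[] <- top_threshold(dp_scores,
                                         max(1L, round(p$protein_density * p$n * p$t)))
    }
    ds <- build_trilayer(ds, protein_drug, disease_protein)
  }
  truth <- list(drug_factors = Fd, disease_factors = Fs,
                scores = labeled_matrix(scores, disease_ids, drug_ids),
                assoc_full = labeled_matrix(assoc_full),
                hidden = hidden)
  list(dataset = ds, truth = truth)
}

#' Hide a fraction of known associations for planted-recovery experiments
#'
#' Uniformly samples the requested fraction of 1-entries, zeroes them in a
#' training copy of the dataset, and returns the held-out list.  Hidden and
#' remaining entries partition the original positives.
#'
#' @param ds a `bilayer_dataset` (or `trilayer_dataset`).
#' @param fraction fraction of positives to hide, in (0, 1).
#' @param seed integer RNG seed.
#' @return list with `dataset` (training copy) and `hidden`, a data.frame
#'   with `disease_id`, `drug_id` and the integer indices `disease`, `drug`.
#' @export
hide_entries <- function(ds, fraction, seed = 1L) {
  stopifnot(inherits(ds, "bilayer_dataset"), fraction > 0, fraction < 1)
  ones <- which(ds$assoc == 1, arr.ind = TRUE)
  n_hide <- max(1L, round(fraction * nrow(ones)))
  set.seed(seed)
  pick <- sample(nrow(ones), n_hide)
  hidden <- ones[pick, , drop = FALSE]
  assoc <- ds$assoc
  assoc[hidden] <- 0
  list(dataset = replace_assoc(ds, assoc),
       hidden = data.frame(disease_id = rownames(ds$assoc)[hidden[, 1L]],
                           drug_id = colnames(ds$assoc)[hidden[, 2L]],
                           disease = hidden[, 1L], drug = hidden[, 2L],
                           stringsAsFactors = FALSE))
}
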