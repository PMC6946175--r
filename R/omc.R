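block_layout <- function(blocks) {
  structure(blocks, class = "block_layout")
}

#' Extract a named block from an assembled matrix
#'
#' Slicing is driven by the stored layout, never recomputed from shapes, so
#' block extraction stays correct for tri-layer assemblies with protein
#' panels of any height/width (including zero).
#'
#' @param M assembled (or completed) matrix.
#' @param layout a `block_layout` as returned by [assemble_drugside()].
#' @param name block name (`"drug_sim"`, `"protein"`, `"assoc"`, ...).
#' @return the sub-matrix of `M` occupied by the block.
#' @export
extract_block <- function(M, layout, name) {
  b <- layout[[name]]
  if (is.null(b)) stop("no block named '", name, "' in layout")
  M[b$rows, b$cols, drop = FALSE]
}

block_omega <- function(M, blocks, omega_mode) {
  if (omega_mode == "nonzero") return(M != 0)
  omega <- M != 0
  for (b in blocks) {
    if (b$fully_observed) omega[b$rows, b$cols] <- TRUE
  }
  omega
}

#' Assemble the drug-side block matrix
#'
#' Stacks the drug similarity on top of (optionally) the protein-drug panel
#' and the preprocessed association matrix: `M1 = [A_RR; A_PR; A_DR1]`, of
#' shape (m+n) x m in bilayer mode or (m+s+n) x m in tri-layer mode.  All
#' blocks share the drug axis as columns.
#'
#' The observed-entry set depends on `omega_mode`: under `"blockwise"` the
#' similarity block counts as fully observed (similarities are measured
#' data, zeros included) while association/protein zeros are unobserved
#' candidates; under `"nonzero"` only nonzero entries anywhere are observed.
#'
#' @param drug_sim m x m drug similarity.
#' @param assoc n x m (preprocessed) association matrix.
#' @param protein_drug optional s x m protein-drug panel.
#' @param omega_mode `"blockwise"` or `"nonzero"`.
#' @return list with the assembled matrix `M`, logical mask `omega`, and
#'   `layout` (a `block_layout` naming `drug_sim`, optionally `protein`, and
#'   `assoc`).
#' @export
assemble_drugside <- function(drug_sim, assoc, protein_drug = NULL,
                              omega_mode = c("blockwise", "nonzero")) {
  omega_mode <- match.arg(omega_mode)
  m <- ncol(drug_sim)
  if (!identical(colnames(assoc), colnames(drug_sim))) {
    stop("association drug identifiers do not match the drug similarity")
  }
  parts <- list(drug_sim)
  blocks <- list(drug_sim = list(rows = seq_len(m), cols = seq_len(m),
                                 fully_observed = TRUE))
  offset <- m
  if (!is.null(protein_drug) && nrow(protein_drug) > 0L) {
    if (!identical(colnames(protein_drug), colnames(drug_sim))) {
      stop("protein-drug drug identifiers do not match the drug similarity")
    }
    s <- nrow(protein_drug)
    parts <- c(parts, list(protein_drug))
    blocks$protein <- list(rows = offset + seq_len(s), cols = seq_len(m),
                           fully_observed = FALSE)
    offset <- offset + s
  }
  n <- nrow(assoc)
  parts <- c(parts, list(assoc))
  blocks$assoc <- list(rows = offset + seq_len(n), cols = seq_len(m),
                       fully_observed = FALSE)
  M <- do.call(rbind, lapply(parts, unname))
  list(M = M, omega = block_omega(M, blocks, omega_mode),
       layout = block_layout(blocks))
}

#' Assemble the disease-side block matrix
#'
#' Concatenates the preprocessed association matrix, (optionally) the
#' disease-protein panel, and the disease similarity:
#' `M2 = [A_DR2, A_DP, A_DD]`, of shape n x (m+n) or n x (m+t+n).  All
#' blocks share the disease axis as rows.
#'
#' @param assoc n x m (preprocessed) association matrix.
#' @param disease_sim n x n disease similarity.
#' @param disease_protein optional n x t disease-protein panel.
#' @inheritParams assemble_drugside
#' @return as [assemble_drugside()], with blocks `assoc`, optionally
#'   `protein`, and `disease_sim`.
#' @export
assemble_diseaseside <- function(assoc, disease_sim, disease_protein = NULL,
                                 omega_mode = c("blockwise", "nonzero")) {
  omega_mode <- match.arg(omega_mode)
  n <- nrow(disease_sim)
  if (!identical(rownames(assoc), rownames(disease_sim))) {
    stop("association disease identifiers do not match the disease similarity")
  }
  m <- ncol(assoc)
  parts <- list(assoc)
  blocks <- list(assoc = list(rows = seq_len(n), cols = seq_len(m),
                              fully_observed = FALSE))
  offset <- m
  if (!is.null(disease_protein) && ncol(disease_protein) > 0L) {
    if (!identical(rownames(disease_protein), rownames(disease_sim))) {
      stop("disease-protein disease identifiers do not match the disease similarity")
    }
    t_ <- ncol(disease_protein)
    parts <- c(parts, list(disease_protein))
    blocks$protein <- list(rows = seq_len(n), cols = offset + seq_len(t_),
                           fully_observed = FALSE)
    offset <- offset + t_
  }
  parts <- c(parts, list(disease_sim))
  blocks$disease_sim <- list(rows = seq_len(n), cols = offset + seq_len(n),
                             fully_observed = TRUE)
  M <- do.call(cbind, lapply(parts, unname))
  list(M = M, omega = block_omega(M, blocks, omega_mode),
       layout = block_layout(blocks))
}

complete_side <- function(side, ds, pp, params) {
  tri <- inherits(ds, "trilayer_dataset")
  asm <- if (side == "drug") {
    assemble_drugside(ds$drug_sim, pp$A_DR1,
                      if (tri) ds$protein_drug, params$omega_mode)
  } else {
    assemble_diseaseside(pp$A_DR2, ds$disease_sim,
                         if (tri) ds$disease_protein, params$omega_mode)
  }
  fit <- bnnr(masked_matrix(asm$M, asm$omega), params)
  list(block = extract_block(fit$M_star, asm$layout, "assoc"), fit = fit)
}

new_prediction <- function(scores, ds, method, params, fits) {
  structure(list(scores = labeled_matrix(scores,
                                         rownames(ds$assoc),
                                         colnames(ds$assoc)),
                 method = method, params = params,
                 converged = all(vapply(fits, function(f) f$converged,
                                        logical(1))),
                 fits = fits),
            class = "omc_prediction")
}

#' @export
print.omc_prediction <- function(x, ...) {
  cat(x$method, "prediction:", nrow(x$scores), "diseases x",
      ncol(x$scores), "drugs",
      if (x$converged) "(solver converged)" else "(solver NOT converged)", "\n")
  invisible(x)
}

#' Bilayer overlap matrix completion (OMC2)
#'
#' The full bilayer pipeline: KNN-preprocess the association matrix for
#' cold-start diseases and drugs, assemble the drug-side block matrix
#' `[A_RR; A_DR1]` and the disease-side block matrix `[A_DR2, A_DD]`,
#' complete each with the bounded nuclear-norm solver, extract the two
#' predicted association blocks, and return their entrywise mean.
#'
#' @param ds a `bilayer_dataset` (the protein panels of a tri-layer dataset
#'   are ignored here; see [omc3()]).
#' @param params an [omc_params()].
#' @return an `omc_prediction`: disease x drug score matrix in \[0, 1\] plus
#'   provenance (method, parameters, solver convergence, per-side fits).
#' @export
omc2 <- function(ds, params = omc_params()) {
  stopifnot(inherits(ds, "bilayer_dataset"))
  ds <- as_bilayer(ds)
  pp <- knn_preprocess(ds, params$k)
  d <- complete_side("drug", ds, pp, params)
  s <- complete_side("disease", ds, pp, params)
  new_prediction((d$block + s$block) / 2, ds, "OMC2", params,
                 list(drug_side = d$fit, disease_side = s$fit))
}

as_bilayer <- function(ds) {
  structure(list(drug_sim = ds$drug_sim, disease_sim = ds$disease_sim,
                 assoc = ds$assoc),
            class = "bilayer_dataset")
}

#' Tri-layer overlap matrix completion (OMC3)
#'
#' As [omc2()], with the protein panels inserted between the similarity and
#' association blocks: `M1 = [A_RR; A_PR; A_DR1]` and
#' `M2 = [A_DR2, A_DP, A_DD]`.  With empty protein panels the assembled
#' matrices are identical to the bilayer ones, so the output equals
#' [omc2()] exactly.
#'
#' @param ds a `trilayer_dataset`.
#' @inheritParams omc2
#' @return an `omc_prediction`.
#' @export
omc3 <- function(ds, params = omc_params()) {
  stopifnot(inherits(ds, "trilayer_dataset"))
  pp <- knn_preprocess(ds, params$k)
  d <- complete_side("drug", ds, pp, params)
  s <- complete_side("disease", ds, pp, params)
  new_prediction((d$block + s$block) / 2, ds, "OMC3", params,
                 list(drug_side = d$fit, disease_side = s$fit))
}

#' Single-side ablations (OMC-drug / OMC-disease)
#'
#' Returns the predicted association block of only one side, without
#' averaging: `side = "drug"` completes the drug-side network
#' `[A_RR; A_DR1]`, `side = "disease"` completes `[A_DR2, A_DD]`.  The mean
#' of the two ablations equals the [omc2()] output entrywise.
#'
#' @param ds a `bilayer_dataset`.
#' @param side `"drug"` or `"disease"`.
#' @inheritParams omc2
#' @return an `omc_prediction`.
#' @export
one_sided <- function(ds, side = c("drug", "disease"),
                      params = omc_params()) {
  side <- match.arg(side)
  stopifnot(inherits(ds, "bilayer_dataset"))
  ds <- as_bilayer(ds)
  pp <- knn_preprocess(ds, params$k)
  r <- complete_side(side, ds, pp, params)
  new_prediction(r$block, ds, paste0("OMC-", side), params,
                 stats::setNames(list(r$fit), paste0(side, "_side")))
}

#' Rank candidate diseases for a drug
#'
#' Candidates are sorted by descending predicted score; diseases named in
#' `exclude_known` (typically the drug's already-known indications) are
#' dropped first.  Ties are broken lexicographically by disease identifier.
#'
#' @param pred an `omc_prediction`.
#' @param drug_id drug identifier (must be a column of the score matrix).
#' @param exclude_known character vector of disease identifiers to exclude.
#' @return data.frame with columns `rank`, `disease_id`, `score`.
#' @export
rank_candidates <- function(pred, drug_id, exclude_known = character()) {
  stopifnot(inherits(pred, "omc_prediction"))
  if (!drug_id %in% colnames(pred$scores)) {
    stop("unknown drug identifier: ", drug_id)
  }
  sc <- pred$scores[, drug_id]
  sc <- sc[!names(sc) %in% exclude_known]
  ord <- order(-sc, names(sc))
  data.frame(rank = seq_along(ord),
             disease_id = names(sc)[ord],
             score = unname(sc[ord]),
             stringsAsFactors = FALSE)
}
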