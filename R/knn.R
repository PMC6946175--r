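#' Indices of all-zero rows or columns
#'
#' Zero rows of the disease-drug association matrix are novel (cold-start)
#' diseases; zero columns are novel drugs.
#'
#' @param A numeric matrix.
#' @return ascending integer indices.
#' @export
find_zero_rows <- function(A) which(rowSums(A != 0) == 0L)

#' @rdname find_zero_rows
#' @export
find_zero_cols <- function(A) which(colSums(A != 0) == 0L)

#' K nearest neighbours of a node under a similarity matrix
#'
#' Returns the `k` indices with the largest similarity to `node`, in
#' descending similarity order.  The node itself is never its own neighbour:
#' the unit self-similarity would otherwise add a zero association profile to
#' the weighted sum while inflating the normalizer.  Ties are broken by
#' ascending index for determinism.
#'
#' @param S square similarity matrix.
#' @param k neighbourhood size, between 1 and `nrow(S) - 1`.
#' @param node index of the query node.
#' @return integer vector of length `k`.
#' @export
knn_neighbors <- function(S, k, node) {
  n <- nrow(S)
  if (k < 1L || k > n - 1L) {
    stop("k must be between 1 and ", n - 1L, " (got ", k, ")")
  }
  sims <- S[node, ]
  sims[node] <- -Inf
  order(sims, decreasing = TRUE)[seq_len(k)]
}

#' Fill zero rows or columns by similarity-weighted neighbour profiles
#'
#' Each all-zero row `p` (novel disease) is replaced by the normalized
#' similarity-weighted mean of its K nearest neighbours' association rows:
#' `sum_u S[p,u] * A[u, ] / sum_u S[p,u]`.  Columns (novel drugs) are filled
#' analogously with weights from the drug similarity.  Weights always come
#' from the original association matrix, so neighbours that are themselves
#' cold contribute zero profiles.  Filled values are convex combinations of
#' neighbour entries and therefore stay in \[0, 1\].
#'
#' If all K neighbour similarities are exactly zero there is no information
#' to impute from; the row/column is left at zero with a warning.
#'
#' @param A association matrix (diseases x drugs).
#' @param S similarity matrix on the filled axis (disease similarity for
#'   `axis = "rows"`, drug similarity for `axis = "columns"`).
#' @param k neighbourhood size.
#' @param axis `"rows"` or `"columns"`.
#' @return a copy of `A` with cold rows/columns filled; known entries are
#'   never overwritten.
#' @export
knn_fill <- function(A, S, k, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  if (axis == "columns") {
    return(t(knn_fill(t(A), S, k, "rows")))
  }
  if (nrow(S) != nrow(A)) {
    stop("similarity size (", nrow(S), ") does not match filled axis length (",
         nrow(A), ")")
  }
  out <- A
  for (p in find_zero_rows(A)) {
    nb <- knn_neighbors(S, k, p)
    w <- S[p, nb]
    sw <- sum(w)
    if (sw > 0) {
      out[p, ] <- as.numeric(w %*% A[nb, , drop = FALSE]) / sw
    } else {
      warning("all neighbour similarities are zero for index ", p,
              "; leaving it unfilled")
    }
  }
  out
}

#' Cold-start KNN preprocessing of the association matrix
#'
#' Produces the two preprocessed association matrices consumed by the
#' drug-side and disease-side block completions: `A_DR1` fills zero rows
#' (novel diseases) using disease similarity; `A_DR2` independently fills
#' zero columns (novel drugs) using drug similarity.  Both start from the
#' original association matrix.  With no cold nodes both outputs equal the
#' input.
#'
#' @param ds a `bilayer_dataset`.
#' @param k neighbourhood size (default 10).
#' @return list with elements `A_DR1` and `A_DR2`.
#' @export
knn_preprocess <- function(ds, k = 10L) {
  stopifnot(inherits(ds, "bilayer_dataset"))
  list(A_DR1 = knn_fill(ds$assoc, ds$disease_sim, k, "rows"),
       A_DR2 = knn_fill(ds$assoc, ds$drug_sim, k, "columns"))
}
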