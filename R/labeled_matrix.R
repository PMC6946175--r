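#' Construct a labeled matrix
#'
#' A labeled matrix is the universal carrier for similarity, association and
#' block matrices in this package: a dense numeric matrix whose rows and
#' columns carry unique string identifiers (drug, disease or protein names).
#' It is represented as a base matrix with `dimnames`; this constructor
#' validates the invariants that every downstream function relies on.
#'
#' @param values numeric matrix (or something coercible to one).
#' @param row_ids character vector of unique row identifiers; defaults to
#'   `rownames(values)`.
#' @param col_ids character vector of unique column identifiers; defaults to
#'   `colnames(values)`.
#' @return a numeric matrix with validated dimnames.
#' @details Missing entries are not representable: absence of an association
#'   is encoded by the value 0, matching the convention of binary
#'   drug-disease association matrices.  `NA`/`NaN` values are rejected.
#' @export
labeled_matrix <- function(values, row_ids = rownames(values),
                           col_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  # R drops zero-length dimnames to NULL, so empty axes need no identifiers
  if (is.null(row_ids) && nrow(values) == 0L) row_ids <- character(0)
  if (is.null(col_ids) && ncol(values) == 0L) col_ids <- character(0)
  if (is.null(row_ids) || is.null(col_ids)) {
    stop("labeled_matrix requires row and column identifiers")
  }
  row_ids <- as.character(row_ids)
  col_ids <- as.character(col_ids)
  if (length(row_ids) != nrow(values)) {
    stop("length of row_ids (", length(row_ids), ") does not match nrow (",
         nrow(values), ")")
  }
  if (length(col_ids) != ncol(values)) {
    stop("length of col_ids (", length(col_ids), ") does not match ncol (",
         ncol(values), ")")
  }
  dup_r <- row_ids[duplicated(row_ids)]
  if (length(dup_r)) stop("duplicate row identifier(s): ",
                          paste(unique(dup_r), collapse = ", "))
  dup_c <- col_ids[duplicated(col_ids)]
  if (length(dup_c)) stop("duplicate column identifier(s): ",
                          paste(unique(dup_c), collapse = ", "))
  if (length(values) && any(!is.finite(values))) {
    stop("matrix contains missing or non-finite entries")
  }
  dimnames(values) <- list(row_ids, col_ids)
  values
}

#' Read a labeled matrix from delimited text
#'
#' The expected layout is a header row of column identifiers followed by one
#' row per entity, whose first field is the row identifier.  Tab and comma
#' delimiters are auto-detected from the header when `delimiter = NULL`.
#'
#' @param path path to the file.
#' @param delimiter field separator; `NULL` (default) auto-detects tab or
#'   comma.
#' @return a labeled matrix (see [labeled_matrix()]).
#' @export
read_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty matrix file: ", path)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "", fill = FALSE,
                          row.names = NULL, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed header in ", path,
                          ": expected row-id column plus data columns")
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  body <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(vals) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric cell at row '", row_ids[bad[1L, 1L]], "', column '",
         col_ids[bad[1L, 2L]], "' in ", path)
  }
  labeled_matrix(vals, row_ids, col_ids)
}

#' Write a labeled matrix as delimited text
#'
#' Values are written with 17 significant digits so that
#' `read_matrix(write_matrix(m))` round-trips doubles exactly.
#'
#' @param m labeled matrix.
#' @param path output path.
#' @param delimiter field separator (default tab).
#' @export
write_matrix <- function(m, path, delimiter = "\t") {
  m <- labeled_matrix(m)
  header <- paste(c("id", colnames(m)), collapse = delimiter)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = delimiter)
  }, character(1))
  con <- suppressWarnings(try(file(path, "w"), silent = TRUE))
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(NULL)
}

#' Read a sparse binary matrix in MatrixMarket coordinate format
#'
#' Companion identifier files hold one row (column) identifier per line, in
#' matrix order.
#'
#' @param mtx_path path to the MatrixMarket file.
#' @param row_ids_path,col_ids_path paths to plain-text id files.
#' @return a dense labeled matrix.
#' @export
read_matrix_mm <- function(mtx_path, row_ids_path, col_ids_path) {
  sp <- Matrix::readMM(mtx_path)
  labeled_matrix(as.matrix(sp),
                 readLines(row_ids_path),
                 readLines(col_ids_path))
}

#' Write a matrix in MatrixMarket coordinate format with id sidecars
#'
#' @param m labeled matrix (typically sparse binary associations).
#' @param mtx_path,row_ids_path,col_ids_path output paths.
#' @export
write_matrix_mm <- function(m, mtx_path, row_ids_path, col_ids_path) {
  m <- labeled_matrix(m)
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), mtx_path)
  writeLines(rownames(m), row_ids_path)
  writeLines(colnames(m), col_ids_path)
  invisible(NULL)
}

check_similarity <- function(S, what, tol = 1e-8) {
  S <- labeled_matrix(S)
  if (nrow(S) != ncol(S)) stop(what, " similarity must be square")
  if (!identical(rownames(S), colnames(S))) {
    stop(what, " similarity row and column identifiers differ")
  }
  if (nrow(S) && (min(S) < 0 || max(S) > 1)) {
    stop(what, " similarity has entries outside [0, 1]")
  }
  asym <- max(abs(S - t(S)), 0)
  if (asym > tol) {
    stop(what, " similarity is asymmetric beyond tolerance (max |S - t(S)| = ",
         format(asym), ")")
  }
  # near-symmetry is silently repaired; true asymmetry was rejected above
  S <- (S + t(S)) / 2
  if (nrow(S) && max(abs(diag(S) - 1)) > tol) {
    stop(what, " similarity diagonal must be 1 (self-similarity)")
  }
  diag(S) <- 1
  S
}

check_binary <- function(A, what) {
  A <- labeled_matrix(A)
  if (length(A) && !all(A == 0 | A == 1)) {
    stop(what, " matrix must be binary (0/1); found value ",
         format(A[which(A != 0 & A != 1)[1L]]))
  }
  A
}

align_ids <- function(have, want, what) {
  extra <- setdiff(have, want)
  if (length(extra)) {
    stop("identifier(s) in ", what, " absent from the similarity matrix: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  missing <- setdiff(want, have)
  if (length(missing)) {
    stop("identifier(s) missing from ", what, ": ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  match(want, have)
}

#' Assemble and validate a bilayer drug-disease dataset
#'
#' Reconciles identifier order (the association matrix is permuted to the
#' similarity matrices' orders), averages near-symmetric similarities, and
#' enforces all dataset invariants: similarities square, symmetric, in
#' \[0, 1\] with unit diagonal; associations binary with diseases in rows and
#' drugs in columns.
#'
#' @param drug_sim m x m drug-drug similarity.
#' @param disease_sim n x n disease-disease similarity.
#' @param assoc n x m binary disease-drug association matrix (disease rows,
#'   drug columns).
#' @return an object of class `bilayer_dataset`: a list with elements
#'   `drug_sim`, `disease_sim`, `assoc`.
#' @export
build_bilayer <- function(drug_sim, disease_sim, assoc) {
  drug_sim <- check_similarity(drug_sim, "drug")
  disease_sim <- check_similarity(disease_sim, "disease")
  assoc <- check_binary(assoc, "association")
  ri <- align_ids(rownames(assoc), rownames(disease_sim), "association rows")
  ci <- align_ids(colnames(assoc), rownames(drug_sim), "association columns")
  assoc <- assoc[ri, ci, drop = FALSE]
  structure(list(drug_sim = drug_sim, disease_sim = disease_sim,
                 assoc = assoc),
            class = "bilayer_dataset")
}

#' Extend a bilayer dataset with protein association panels
#'
#' The two protein panels need not share protein identifiers: the drug-side
#' and disease-side block matrices are completed independently, so each panel
#' only has to align with the drug (respectively disease) axis.  Panels of
#' zero height/width are valid and make OMC3 degenerate to OMC2.
#'
#' @param bilayer a `bilayer_dataset`.
#' @param protein_drug s x m binary protein-drug interaction matrix (protein
#'   rows, drug columns).
#' @param disease_protein n x t binary disease-protein association matrix
#'   (disease rows, protein columns).
#' @return an object of class `trilayer_dataset` (also a `bilayer_dataset`).
#' @export
build_trilayer <- function(bilayer, protein_drug, disease_protein) {
  stopifnot(inherits(bilayer, "bilayer_dataset"))
  protein_drug <- check_binary(protein_drug, "protein-drug")
  disease_protein <- check_binary(disease_protein, "disease-protein")
  ci <- align_ids(colnames(protein_drug), rownames(bilayer$drug_sim),
                  "protein-drug columns")
  protein_drug <- protein_drug[, ci, drop = FALSE]
  ri <- align_ids(rownames(disease_protein), rownames(bilayer$disease_sim),
                  "disease-protein rows")
  disease_protein <- disease_protein[ri, , drop = FALSE]
  structure(c(unclass(bilayer),
              list(protein_drug = protein_drug,
                   disease_protein = disease_protein)),
            class = c("trilayer_dataset", "bilayer_dataset"))
}

#' @export
print.bilayer_dataset <- function(x, ...) {
  cat(if (inherits(x, "trilayer_dataset")) "tri-layer" else "bilayer",
      "drug-disease dataset:\n")
  cat("  drugs:    ", ncol(x$assoc), "\n")
  cat("  diseases: ", nrow(x$assoc), "\n")
  cat("  known associations: ", sum(x$assoc), "\n")
  if (inherits(x, "trilayer_dataset")) {
    cat("  proteins (drug side): ", nrow(x$protein_drug), "\n")
    cat("  proteins (disease side): ", ncol(x$disease_protein), "\n")
  }
  invisible(x)
}

#' Read a dataset described by a manifest file
#'
#' The manifest is a YAML key-value file naming the matrix files.  Required
#' keys: `drug_sim`, `disease_sim`, `assoc`; optional: `protein_drug`,
#' `disease_protein` (both or neither), and `assoc_orientation`
#' (`"disease_rows"`, the default, or `"drug_rows"` for files stored
#' transposed).  Relative paths are resolved against the manifest location.
#'
#' @param manifest_path path to the manifest.
#' @return a `bilayer_dataset` or `trilayer_dataset`.
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  cfg <- yaml::read_yaml(manifest_path)
  base <- dirname(normalizePath(manifest_path))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  need <- c("drug_sim", "disease_sim", "assoc")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("manifest missing key(s): ", paste(miss, collapse = ", "))
  assoc <- read_matrix(resolve(cfg$assoc))
  orient <- cfg$assoc_orientation %||% "disease_rows"
  if (identical(orient, "drug_rows")) {
    assoc <- labeled_matrix(t(assoc))
  } else if (!identical(orient, "disease_rows")) {
    stop("assoc_orientation must be 'disease_rows' or 'drug_rows'")
  }
  ds <- build_bilayer(read_matrix(resolve(cfg$drug_sim)),
                      read_matrix(resolve(cfg$disease_sim)),
                      assoc)
  has_pr <- !is.null(cfg$protein_drug)
  has_dp <- !is.null(cfg$disease_protein)
  if (xor(has_pr, has_dp)) {
    stop("manifest must name both protein panels or neither")
  }
  if (has_pr) {
    ds <- build_trilayer(ds,
                         read_matrix(resolve(cfg$protein_drug)),
                         read_matrix(resolve(cfg$disease_protein)))
  }
  ds
}

#' Write a dataset and its manifest to a directory
#'
#' @param ds a `bilayer_dataset` or `trilayer_dataset`.
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "bilayer_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(drug_sim = "drug_sim.tsv", disease_sim = "disease_sim.tsv",
                assoc = "assoc.tsv")
  if (inherits(ds, "trilayer_dataset")) {
    files$protein_drug <- "protein_drug.tsv"
    files$disease_protein <- "disease_protein.tsv"
  }
  for (k in names(files)) write_matrix(ds[[k]], file.path(dir, files[[k]]))
  cfg <- c(files, list(assoc_orientation = "disease_rows"))
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(cfg, manifest)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
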