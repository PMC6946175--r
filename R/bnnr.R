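#' Bundle a matrix with its observed-entry set
#'
#' The solver's input contract: the to-be-completed matrix together with the
#' set Omega of entries regarded as observed.  Unobserved entries of `M` are
#' ignored by the data-fit term (the initialization projects them to zero).
#'
#' @param M numeric matrix.
#' @param omega either a logical matrix of `dim(M)` or a two-column integer
#'   matrix of (row, col) index pairs.
#' @return object of class `masked_matrix`: list with `M` and logical `omega`.
#' @export
masked_matrix <- function(M, omega) {
  M <- as.matrix(M)
  if (is.logical(omega) && is.matrix(omega)) {
    if (!identical(dim(omega), dim(M))) stop("omega mask dimensions differ from M")
    mask <- omega
  } else {
    omega <- as.matrix(omega)
    if (ncol(omega) != 2L) stop("omega must be a logical mask or a 2-column index matrix")
    if (nrow(omega) &&
        (min(omega) < 1L || max(omega[, 1L]) > nrow(M) || max(omega[, 2L]) > ncol(M))) {
      stop("omega index out of bounds")
    }
    mask <- matrix(FALSE, nrow(M), ncol(M))
    mask[omega] <- TRUE
  }
  obs <- M[mask]
  if (length(obs) && (min(obs) < 0 || max(obs) > 1)) {
    stop("observed entries must lie in [0, 1]")
  }
  structure(list(M = M, omega = mask), class = "masked_matrix")
}

#' Solver and pipeline parameters
#'
#' `alpha` weighs the data-fit term against the nuclear norm, `beta` is the
#' ADMM penalty, `k` the KNN neighbourhood size, and `omega_mode` selects the
#' observed-entry convention for assembled block matrices (see
#' [assemble_drugside()]).  Defaults `alpha = 1`, `beta = 10`, `k = 10` are
#' the grid-search optima reported for the gold-standard benchmark.
#'
#' @param alpha positive data-fit weight.
#' @param beta positive ADMM penalty parameter.
#' @param k positive integer KNN neighbourhood size.
#' @param tol positive convergence tolerance on the relative primal residual.
#' @param max_iter maximum ADMM iterations.
#' @param omega_mode `"blockwise"` (similarity blocks fully observed,
#'   association zeros unobserved) or `"nonzero"` (only nonzero entries of
#'   the assembled matrix observed).
#' @return object of class `omc_params`.
#' @export
omc_params <- function(alpha = 1, beta = 10, k = 10L, tol = 1e-4,
                       max_iter = 300L,
                       omega_mode = c("blockwise", "nonzero")) {
  omega_mode <- match.arg(omega_mode)
  stopifnot(alpha > 0, beta > 0, tol > 0, max_iter >= 1L, k >= 1L)
  structure(list(alpha = alpha, beta = beta, k = as.integer(k), tol = tol,
                 max_iter = as.integer(max_iter), omega_mode = omega_mode),
            class = "omc_params")
}

#' Project a matrix onto the observed-entry set
#'
#' Entries in Omega are kept; all others are set to zero.
#'
#' @param X numeric matrix.
#' @param omega logical mask or two-column index matrix (see
#'   [masked_matrix()]).
#' @return matrix of `dim(X)`.
#' @export
project_omega <- function(X, omega) {
  if (!(is.logical(omega) && is.matrix(omega))) {
    omega <- masked_matrix(array(0, dim(X)), omega)$omega
  }
  X * omega
}

#' Clamp matrix entries to the unit interval
#'
#' The box projection Q_\[0,1\]: values above 1 become 1, below 0 become 0.
#'
#' @param W numeric matrix.
#' @return clamped matrix.
#' @export
box_project <- function(W) pmin(pmax(W, 0), 1)

#' Singular value thresholding
#'
#' The proximal operator of the nuclear norm: every singular value is shrunk
#' by `tau` and those at or below `tau` are dropped, i.e.
#' `D_tau(X) = sum_{sigma_i >= tau} (sigma_i - tau) u_i v_i'`.
#'
#' @param X numeric matrix with finite entries.
#' @param tau nonnegative shrinkage threshold.
#' @return matrix of `dim(X)`.
#' @export
svt <- function(X, tau) {
  stopifnot(tau >= 0)
  if (any(!is.finite(X))) stop("svt requires finite input")
  s <- svd(X)
  d <- pmax(s$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(array(0, dim(X)))
  s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
}

#' Closed-form W-update of the ADMM scheme
#'
#' Minimizes the augmented Lagrangian over the box-constrained splitting
#' variable.  With `Z = Y/beta + (alpha/beta) P_Omega(M) + X`, the
#' unconstrained minimizer is `W* = (I - alpha/(alpha+beta) P_Omega)(Z)` —
#' entries on Omega are scaled by `beta/(alpha+beta)` — and the constrained
#' solution is its box projection.
#'
#' @param X,Y current primal and multiplier matrices.
#' @param data a `masked_matrix`.
#' @param alpha,beta positive solver parameters.
#' @return the clamped update `W_{k+1}`, all entries in \[0, 1\].
#' @export
w_update <- function(X, Y, data, alpha, beta) {
  stopifnot(inherits(data, "masked_matrix"),
            identical(dim(X), dim(data$M)), identical(dim(Y), dim(data$M)))
  Z <- Y / beta + (alpha / beta) * (data$M * data$omega) + X
  Z[data$omega] <- Z[data$omega] * (beta / (alpha + beta))
  box_project(Z)
}

#' SVT-based X-update of the ADMM scheme
#'
#' Solves `argmin_X ||X||_* + (beta/2) ||X - (W - Y/beta)||_F^2`, whose
#' closed form is singular value thresholding at `1/beta`.
#'
#' @param W,Y current splitting and multiplier matrices.
#' @param beta positive penalty parameter.
#' @return the update `X_{k+1}`.
#' @export
x_update <- function(W, Y, beta) svt(W - Y / beta, 1 / beta)

#' Bounded nuclear-norm-regularized matrix completion
#'
#' Completes a partially observed matrix under a \[0, 1\] box constraint by
#' minimizing `||X||_* + (alpha/2) ||P_Omega(X) - P_Omega(M)||_F^2` subject
#' to `0 <= X <= 1`, via ADMM with a splitting variable W: iterate the
#' closed-form box-projected W-update, the SVT X-update, and the dual ascent
#' `Y <- Y + beta (X - W)`, starting from `X = W = Y = P_Omega(M)`.
#' Iteration stops when the relative primal residual
#' `||X - W||_F / max(1, ||X||_F)` drops below `tol` *and* the relative
#' change between successive primal iterates drops below `10 * tol`: the
#' primal residual alone can dip below tolerance transiently in early
#' iterations (X tracks W closely long before either has converged), so the
#' dual-residual analogue guards against premature termination without
#' demanding the much slower late-stage drift to fall all the way to `tol`.
#'
#' @param data a `masked_matrix`.
#' @param params an `omc_params` (only `alpha`, `beta`, `tol`, `max_iter`
#'   are used).
#' @return object of class `bnnr_fit`: list with the completed matrix
#'   `M_star` (equal to the final W, entries exactly in \[0, 1\]),
#'   `iterations`, final relative residual `residual`, `converged` flag, and
#'   the per-iteration `residual_trace`.
#' @export
bnnr <- function(data, params = omc_params()) {
  stopifnot(inherits(data, "masked_matrix"))
  alpha <- params$alpha; beta <- params$beta
  X <- data$M * data$omega
  W <- X
  Y <- X
  res <- Inf
  trace <- numeric(0)
  it <- 0L
  converged <- FALSE
  for (k in seq_len(params$max_iter)) {
    X_prev <- X
    W <- w_update(X, Y, data, alpha, beta)
    X <- x_update(W, Y, beta)
    Y <- Y + beta * (X - W)
    res <- norm(X - W, "F") / max(1, norm(X, "F"))
    change <- norm(X - X_prev, "F") / max(1, norm(X_prev, "F"))
    trace <- c(trace, res)
    it <- k
    if (res < params$tol && change < 10 * params$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("BNNR did not converge in ", params$max_iter,
            " iterations (residual ", format(res), ")")
  }
  structure(list(M_star = W, iterations = it, residual = res,
                 converged = converged, residual_trace = trace),
            class = "bnnr_fit")
}

#' @export
print.bnnr_fit <- function(x, ...) {
  cat("BNNR completion:", nrow(x$M_star), "x", ncol(x$M_star),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  iterations:", x$iterations, " residual:", format(x$residual), "\n")
  invisible(x)
}

#' Objective value of the bounded completion model
#'
#' `||X||_* + (alpha/2) ||P_Omega(X) - P_Omega(M)||_F^2`; used by tests and
#' diagnostics to compare candidate completions.
#'
#' @param X candidate matrix.
#' @param data a `masked_matrix`.
#' @param alpha data-fit weight.
#' @return scalar objective value.
#' @export
bnnr_objective <- function(X, data, alpha) {
  sum(svd(X, nu = 0, nv = 0)$d) +
    (alpha / 2) * sum(((X - data$M)[data$omega])^2)
}
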