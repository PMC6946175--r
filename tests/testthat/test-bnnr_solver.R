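# objective of the W-subproblem (augmented Lagrangian terms involving W)
w_subproblem_objective <- function(W, X, Y, data, alpha, beta) {
  (alpha / 2) * sum(((W - data$M)[data$omega])^2) +
    sum(Y * (X - W)) + (beta / 2) * sum((X - W)^2)
}

# prox objective solved by the X-update
x_subproblem_objective <- function(X, A, beta) {
  sum(svd(X, nu = 0, nv = 0)$d) + (beta / 2) * sum((X - A)^2)
}

test_that("project_omega keeps observed entries and zeroes the rest", {
  X <- rbind(c(0.5, 0.2), c(0.3, 0.9))
  idx <- rbind(c(1L, 1L), c(2L, 2L))
  expect_equal(project_omega(X, idx), rbind(c(0.5, 0), c(0, 0.9)))
  expect_equal(project_omega(X, matrix(TRUE, 2, 2)), X)
  expect_equal(project_omega(X, matrix(FALSE, 2, 2)), matrix(0, 2, 2))
  expect_error(masked_matrix(X, rbind(c(3L, 1L))), "out of bounds")
})

test_that("box_project clamps to the unit interval and is idempotent", {
  W <- rbind(c(1.3, -0.2), c(0.5, 1.0))
  expect_equal(box_project(W), rbind(c(1, 0), c(0.5, 1)))
  inside <- matrix(runif(9), 3)
  expect_equal(box_project(inside), inside)
  expect_equal(box_project(box_project(W)), box_project(W))
})

test_that("svt shrinks singular values exactly as the definition states", {
  expect_equal(svt(diag(c(3, 1)), 2), diag(c(1, 0)))
  set.seed(11)
  X <- matrix(rnorm(15), 5, 3)
  expect_lt(norm(svt(X, 0) - X, "F"), 1e-10)
  # brute-force oracle: full SVD, shrink, reassemble with all triples
  s <- svd(X)
  oracle <- s$u %*% diag(pmax(s$d - 0.5, 0)) %*% t(s$v)
  expect_lt(norm(svt(X, 0.5) - oracle, "F"), 1e-10)
  expect_equal(svt(X, max(s$d) + 1), matrix(0, 5, 3))
})

test_that("svt is non-expansive and reduces nuclear norm and rank", {
  set.seed(12)
  nuc <- function(M) sum(svd(M, nu = 0, nv = 0)$d)
  for (i in 1:10) {
    A <- matrix(rnorm(24), 6, 4)
    B <- matrix(rnorm(24), 6, 4)
    tau <- runif(1, 0, 2)
    expect_lte(norm(svt(A, tau) - svt(B, tau), "F"), norm(A - B, "F") + 1e-12)
    expect_lte(nuc(svt(A, tau)), nuc(A) + 1e-12)
    expect_lte(qr(svt(A, tau))$rank, qr(A)$rank)
  }
})

test_that("w_update matches its algebraic special cases", {
  set.seed(13)
  X <- matrix(rnorm(12, 0.5, 0.3), 4, 3)
  Y <- matrix(rnorm(12, 0, 0.2), 4, 3)
  M <- matrix(runif(12), 4, 3)
  alpha <- 1; beta <- 10
  # empty omega: W* = Y/beta + X, clamped
  d0 <- masked_matrix(M, matrix(FALSE, 4, 3))
  expect_equal(w_update(X, Y, d0, alpha, beta), box_project(Y / beta + X))
  # full omega: W* = (Y + alpha M + beta X) / (alpha + beta), clamped
  d1 <- masked_matrix(M, matrix(TRUE, 4, 3))
  expect_equal(w_update(X, Y, d1, alpha, beta),
               box_project((Y + alpha * M + beta * X) / (alpha + beta)))
  expect_true(all(w_update(X, Y, d1, alpha, beta) >= 0 &
                  w_update(X, Y, d1, alpha, beta) <= 1))
})

test_that("the closed-form W-update minimizes its subproblem over the box", {
  set.seed(14)
  for (i in 1:5) {
    M <- matrix(runif(20), 5, 4)
    omega <- matrix(runif(20) < 0.6, 5, 4)
    data <- masked_matrix(M, omega)
    X <- matrix(rnorm(20, 0.5, 0.4), 5, 4)
    Y <- matrix(rnorm(20, 0, 0.5), 5, 4)
    alpha <- runif(1, 0.5, 5); beta <- runif(1, 1, 20)
    W <- w_update(X, Y, data, alpha, beta)
    f0 <- w_subproblem_objective(W, X, Y, data, alpha, beta)
    for (j in 1:50) {
      P <- box_project(W + matrix(rnorm(20, 0, 0.1), 5, 4))
      expect_gte(w_subproblem_objective(P, X, Y, data, alpha, beta),
                 f0 - 1e-10)
    }
  }
})

test_that("the X-update solves the nuclear-norm proximal problem", {
  set.seed(15)
  beta <- 10
  W <- matrix(runif(16), 4, 4)
  Y <- matrix(rnorm(16, 0, 0.3), 4, 4)
  expect_equal(x_update(Y / beta, Y, beta), matrix(0, 4, 4))
  A <- W - Y / beta
  X <- x_update(W, Y, beta)
  f0 <- x_subproblem_objective(X, A, beta)
  for (j in 1:100) {
    P <- X + matrix(rnorm(16, 0, 0.05), 4, 4)
    expect_gte(x_subproblem_objective(P, A, beta), f0 - 1e-10)
  }
})

test_that("bnnr fixed points and bound constraints hold", {
  z <- masked_matrix(matrix(0, 4, 4), matrix(TRUE, 4, 4))
  fit <- bnnr(z)
  expect_equal(fit$M_star, matrix(0, 4, 4))
  expect_true(fit$converged)

  set.seed(16)
  M <- matrix(runif(30), 6, 5)
  fit2 <- bnnr(masked_matrix(M, matrix(runif(30) < 0.5, 6, 5)))
  expect_true(all(fit2$M_star >= 0 & fit2$M_star <= 1))
  expect_true(fit2$converged && fit2$residual < 1e-4)
})

test_that("bnnr recovers a fully observed rank-1 matrix under strong data fit", {
  set.seed(17)
  u <- runif(8, 0.35, 0.95); v <- runif(6, 0.35, 0.95)
  M <- outer(u, v); M <- 0.1 + 0.8 * (M - min(M)) / (max(M) - min(M))
  fit <- bnnr(masked_matrix(M, matrix(TRUE, 8, 6)),
              omc_params(alpha = 100, beta = 10))
  expect_lt(norm(fit$M_star - M, "F") / norm(M, "F"), 1e-2)
})

test_that("bnnr recovers unobserved entries of a planted rank-2 matrix", {
  set.seed(18)
  M <- planted_rank2(150, 100)
  omega <- matrix(runif(length(M)) < 0.5, nrow(M), ncol(M))
  fit <- bnnr(masked_matrix(M, omega), omc_params(alpha = 1, beta = 10))
  rel <- norm((fit$M_star - M) * !omega, "F") / norm(M * !omega, "F")
  expect_lt(rel, 0.1)
})

test_that("bnnr never does worse than the trivial feasible completion", {
  set.seed(19)
  for (i in 1:3) {
    M <- matrix(runif(35), 7, 5)
    omega <- matrix(runif(35) < 0.6, 7, 5)
    data <- masked_matrix(M, omega)
    fit <- bnnr(data)
    base <- box_project(M * omega)
    expect_lte(bnnr_objective(fit$M_star, data, 1),
               bnnr_objective(base, data, 1) + 1e-8)
  }
})

test_that("larger alpha drives the observed entries toward the data", {
  set.seed(20)
  M <- matrix(runif(40), 8, 5)
  omega <- matrix(runif(40) < 0.7, 8, 5)
  data <- masked_matrix(M, omega)
  errs <- vapply(c(1, 10, 100, 1000), function(a) {
    fit <- bnnr(data, omc_params(alpha = a, beta = 10, max_iter = 500))
    norm((fit$M_star - M) * omega, "F")
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-6))
})

test_that("non-convergence is flagged, never silent", {
  set.seed(21)
  M <- matrix(runif(25), 5, 5)
  data <- masked_matrix(M, matrix(runif(25) < 0.5, 5, 5))
  expect_warning(fit <- bnnr(data, omc_params(max_iter = 2)), "not converge")
  expect_false(fit$converged)
  expect_true(all(fit$M_star >= 0 & fit$M_star <= 1))
})
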