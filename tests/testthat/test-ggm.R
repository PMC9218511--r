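test_that("chemical covariance equals the direct summation formula", {
  truth <- sim_truth(n_genes = 25, panel_size = 3, seed = 1)
  lfc <- gen_lfc_panel(truth, seed = 2)
  ch <- truth$labels$chemical[5]
  ci <- chemical_covariance(lfc, ch, truth$panel_genes)
  expect_equal(ci$n_obs, 5)
  m <- as.matrix(lfc[lfc$chemical == ch, truth$panel_genes])
  n <- nrow(m)
  brute <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    brute[a, b] <- sum((m[, a] - mean(m[, a])) * (m[, b] - mean(m[, b]))) /
      (n - 1)
  }
  expect_equal(unname(ci$S), brute, tolerance = 1e-12)
})

test_that("degenerate covariance inputs behave as specified", {
  panel <- tibble::tibble(
    chemical = "c1",
    dose_level = dose_level(c("1/1", "1/2", "1/4", "1/8", "1/16")),
    g1 = c(1, 2, 3, 4, 5), g2 = 2, g3 = rnorm(5))
  ci <- chemical_covariance(panel, "c1", c("g1", "g2", "g3"))
  expect_equal(unname(ci$S[2, ]), rep(0, 3))  # constant gene: zero row
  # n = 2 observations: rank at most 1
  ci2 <- chemical_covariance(panel[1:2, ], "c1", c("g1", "g2", "g3"))
  expect_lte(qr(ci2$S)$rank, 1)
  expect_error(chemical_covariance(panel[1, ], "c1", c("g1", "g2", "g3")),
               ">= 2")
})

test_that("the penalty path spans the empty graph and the MLE limit", {
  set.seed(3)
  A <- matrix(rnorm(36), 6)
  S <- crossprod(A) / 6 + diag(6)
  path <- glasso_path(S, nlambda = 8, lambda_min_ratio = 1e-7,
                      standardize = FALSE, n_obs = 100)
  p1 <- path$theta[, , 1]
  expect_equal(max(abs(p1[upper.tri(p1)])), 0)  # empty at lambda_max
  pn <- path$theta[, , 8]
  expect_lt(max(abs(pn - solve(S))) / max(abs(solve(S))), 1e-4)
})

test_that("chain-graph support is recovered along the path", {
  p <- 8
  theta <- diag(p)
  for (i in 1:(p - 1)) theta[i, i + 1] <- theta[i + 1, i] <- -0.4
  sigma <- solve(theta)
  set.seed(4)
  z <- matrix(rnorm(500 * p), 500, p) %*% chol(sigma)
  S <- cov(z)
  path <- glasso_path(S, nlambda = 60, n_obs = 500)
  truth_support <- abs(theta[upper.tri(theta)]) > 0
  hit <- FALSE
  for (i in seq_along(path$lambda)) {
    if (!path$converged[i]) next
    est <- path$theta[, , i]
    if (identical(unname(est[upper.tri(est)] != 0), truth_support)) {
      hit <- TRUE
      break
    }
  }
  expect_true(hit)
})

test_that("BIC selection matches an exhaustive criterion scan", {
  set.seed(5)
  A <- matrix(rnorm(9), 3)
  S <- cov(matrix(rnorm(60), 20, 3) %*% A)
  n_obs <- 20
  path <- glasso_path(S, nlambda = 40, standardize = FALSE, n_obs = n_obs)
  fit <- select_by_ebic(path)
  # brute-force criterion over the path
  crit <- sapply(seq_along(path$lambda), function(i) {
    th <- path$theta[, , i]
    e <- sum(th[upper.tri(th)] != 0)
    ll <- n_obs / 2 * (determinant(th)$modulus - sum(S * th))
    -2 * as.numeric(ll) + e * log(n_obs)
  })
  expect_equal(fit$ebic[path$converged], crit[path$converged],
               tolerance = 1e-10)
  expect_equal(fit$chosen_index, which.min(crit))
  # gamma = 0 differences equal BIC differences by construction;
  # positive gamma adds 4 * gamma * E * log(p)
  fit2 <- select_by_ebic(path, gamma = 0.5)
  e_vec <- sapply(seq_along(path$lambda), function(i) {
    th <- path$theta[, , i]
    sum(th[upper.tri(th)] != 0)
  })
  expect_equal(fit2$ebic[path$converged],
               crit[path$converged] +
                 4 * 0.5 * e_vec[path$converged] * log(3),
               tolerance = 1e-10)
})

test_that("criterion ties resolve toward the sparser model", {
  # construct a fake path with two equal-criterion points
  p <- 3
  th_dense <- matrix(c(1, -0.2, 0, -0.2, 1, 0, 0, 0, 1), 3)
  path <- list(lambda = c(0.5, 0.4), theta = array(0, c(p, p, 2)),
               converged = c(TRUE, TRUE), S_work = diag(p), n_obs = 10,
               genes = c("a", "b", "c"))
  path$theta[, , 1] <- diag(p)
  path$theta[, , 2] <- diag(p)   # same model twice: tie on criterion
  class(path) <- "ggm_path"
  fit <- select_by_ebic(path)
  expect_equal(fit$chosen_index, 1)
  expect_equal(fit$n_edges, 0)
})

test_that("partial correlations follow the precision-matrix formula", {
  th <- matrix(c(2, -1, -1, 2), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(precision_to_partial(th)), 0.5)

  # regression-residual oracle: partial correlation of a MVN
  p <- 4
  theta <- diag(p)
  theta[1, 2] <- theta[2, 1] <- -0.3
  theta[3, 4] <- theta[4, 3] <- 0.25
  set.seed(8)
  z <- matrix(rnorm(2e5 * p), 2e5, p) %*% chol(solve(theta))
  colnames(z) <- paste0("v", 1:p)
  rho <- precision_to_partial(theta + 0, edge_index(colnames(z)))
  r12 <- cor(resid(lm(z[, 1] ~ z[, 3] + z[, 4])),
             resid(lm(z[, 2] ~ z[, 3] + z[, 4])))
  expect_equal(unname(rho["v1|v2"]), r12, tolerance = 0.02)

  # sign flips against the precision entry; diagonal precision: all zero
  expect_true(all(sign(rho) == -sign(theta[upper.tri(theta)]) |
                    rho == 0))
  expect_equal(max(abs(precision_to_partial(diag(3) * 2,
                                            edge_index(c("x", "y", "z"))))),
               0)
  bad <- diag(c(1, -1))
  dimnames(bad) <- list(c("a", "b"), c("a", "b"))
  expect_error(precision_to_partial(bad), "diagonal")
})

test_that("edge vectors are scale equivariant and canonically ordered", {
  truth <- sim_truth(n_genes = 25, panel_size = 6, seed = 9)
  lfc <- gen_lfc_panel(truth, seed = 10)
  ch <- truth$labels$chemical[2]
  f1 <- fit_ggm(lfc, ch, truth$panel_genes, nlambda = 100)
  expect_equal(length(f1$partial_corr), 15)
  expect_named(f1$partial_corr, f1$index$edge)
  expect_true(all(abs(f1$partial_corr) <= 1 + 1e-8))

  lfc2 <- lfc
  lfc2[truth$panel_genes] <- lfc2[truth$panel_genes] * 3.7
  f2 <- fit_ggm(lfc2, ch, truth$panel_genes, nlambda = 100)
  expect_equal(f2$partial_corr, f1$partial_corr, tolerance = 1e-8)
})

test_that("rank-deficient five-dose covariances still fit", {
  truth <- sim_truth(seed = 30)
  lfc <- gen_lfc_panel(truth, seed = 31)
  fit <- fit_ggm(lfc, truth$labels$chemical[1], truth$panel_genes,
                 nlambda = 200)
  expect_s3_class(fit, "ggm_fit")
  expect_equal(length(fit$partial_corr), 190)
  expect_true(is.finite(fit$ebic[fit$chosen_index]))
})
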