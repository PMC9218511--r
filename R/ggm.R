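# Per-chemical Gaussian graphical models: sample covariance of the dose-
# level LFC vectors, an L1 graphical-lasso penalty path, (E)BIC penalty
# selection, and partial-correlation edge vectors in canonical order.

#' Sample covariance of one chemical's dose-level LFC vectors
#'
#' The n dose-level LFC vectors of a chemical (n = 5 for the full
#' design), restricted to the feature-panel genes, are the observations;
#' `S` is their sample covariance (denominator n - 1).
#'
#' @param panel_lfc LFC panel tibble ([compute_lfc()] / [ddct_lfc()]).
#' @param chemical Chemical name.
#' @param genes Character vector of panel genes (order = panel order), or
#'   a [pca_select_genes()] result.
#' @param timepoint Optional timepoint filter (hours).
#' @return Object of class `cov_input`: list with `S` (p x p), `n_obs`,
#'   `genes`, `standardized = FALSE`.
#' @export
chemical_covariance <- function(panel_lfc, chemical, genes,
                                timepoint = NULL) {
  if (inherits(genes, "feature_panel")) genes <- genes$gene
  rows <- panel_lfc$chemical == chemical
  if (!is.null(timepoint) && "timepoint" %in% names(panel_lfc)) {
    rows <- rows & panel_lfc$timepoint == timepoint
  }
  sub <- panel_lfc[rows, , drop = FALSE]
  if (nrow(sub) < 2) {
    abort(sprintf("Chemical '%s' has %d dose-level LFC vector(s); need >= 2.",
                  chemical, nrow(sub)))
  }
  missing_genes <- setdiff(genes, names(sub))
  if (length(missing_genes) > 0) {
    abort(paste0("Panel gene(s) absent from LFC panel: ",
                 paste(missing_genes, collapse = ", ")))
  }
  m <- as.matrix(sub[, genes, drop = FALSE])
  out <- list(S = cov(m), n_obs = nrow(m), genes = genes,
              standardized = FALSE)
  class(out) <- "cov_input"
  out
}

# covariance -> correlation; zero-variance variables get a zero row/col
# (diag 1) so they simply carry no edges
standardize_cov <- function(S) {
  v <- diag(S)
  s <- sqrt(pmax(v, 0))
  ok <- s > 0
  R <- S
  R[] <- 0
  if (any(ok)) {
    R[ok, ok] <- S[ok, ok, drop = FALSE] / tcrossprod(s[ok])
  }
  diag(R) <- 1
  R
}

#' L1 graphical-lasso penalty path
#'
#' Estimates sparse precision matrices along a log-spaced penalty path of
#' `nlambda` values from `lambda_max` (the largest off-diagonal absolute
#' value of the working matrix, at which the graph is empty) down to
#' `lambda_max * lambda_min_ratio`. By default the covariance is
#' standardised to a correlation matrix first, which stabilises
#' estimation from few observations and makes the result scale
#' equivariant; partial correlations are unaffected by this choice.
#' Non-positive-definite inputs are accepted; a penalty value where the
#' solver stalls is recorded as non-converged and refitted once with
#' `1e-8` diagonal jitter, never aborting the path.
#'
#' @param S A `cov_input` from [chemical_covariance()], or a symmetric
#'   matrix (then give `n_obs`).
#' @param nlambda Number of penalty values (default 1000).
#' @param lambda_min_ratio Smallest penalty as a fraction of
#'   `lambda_max` (default 0.01).
#' @param standardize Work on the correlation matrix (default TRUE).
#' @param n_obs Number of observations (taken from `S` if a
#'   `cov_input`).
#' @param tol,maxit Solver control.
#' @return Object of class `ggm_path`: list with `lambda` (decreasing),
#'   `theta` (p x p x nlambda array), `converged`, `S_work`, `n_obs`,
#'   `genes`.
#' @export
glasso_path <- function(S, nlambda = 1000, lambda_min_ratio = 0.01,
                        standardize = TRUE, n_obs = NULL,
                        tol = 1e-4, maxit = 200) {
  genes <- NULL
  if (inherits(S, "cov_input")) {
    n_obs <- S$n_obs
    genes <- S$genes
    S <- S$S
  }
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (max(abs(S - t(S))) > 1e-8) abort("S must be symmetric.")
  if (is.null(genes)) genes <- rownames(S) %||% paste0("V", seq_len(nrow(S)))
  W <- if (standardize) standardize_cov(S) else S
  off <- abs(W[upper.tri(W)])
  lambda_max <- max(off)
  if (lambda_max == 0) {
    # no marginal association at all: the empty graph at any penalty
    lambda <- 1
    fit <- glasso_path_cpp(W, lambda, tol = tol, maxit = maxit)
  } else {
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
    fit <- glasso_path_cpp(W, lambda, tol = tol, maxit = maxit)
    if (any(!fit$converged)) {
      jit <- W + diag(1e-8, nrow(W))
      refit <- glasso_path_cpp(jit, lambda[!fit$converged],
                               tol = tol, maxit = maxit)
      idx <- which(!fit$converged)
      fit$theta[, , idx] <- refit$theta
      fit$converged[idx] <- refit$converged
      if (any(refit$converged)) {
        inform(sprintf(
          "glasso: %d penalty value(s) needed 1e-8 diagonal jitter.",
          sum(refit$converged)))
      }
    }
  }
  out <- list(lambda = lambda, theta = fit$theta,
              converged = as.logical(fit$converged),
              S_work = W, n_obs = n_obs, genes = genes)
  class(out) <- "ggm_path"
  out
}

# Gaussian log-likelihood of a precision matrix against sample
# covariance S (constants dropped): n/2 (log det Theta - tr(S Theta))
ggm_loglik <- function(theta, S, n_obs) {
  ld <- determinant(theta, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  n_obs / 2 * (as.numeric(ld$modulus) - sum(S * theta))
}

#' Select a penalty by the extended Bayesian information criterion
#'
#' `EBIC = -2 loglik + E log(n) + 4 gamma E log(p)` with `E` the number
#' of nonzero upper-triangle edges; `gamma = 0` (the default) reduces to
#' the ordinary BIC. Ties are broken toward the sparser model.
#'
#' @param path A [glasso_path()] object.
#' @param n_obs Observations behind the covariance (defaults to the
#'   path's).
#' @param gamma EBIC hyperparameter (default 0 = BIC).
#' @return Object of class `ggm_fit`: list with `lambda_path`, `ebic`,
#'   `chosen_lambda`, `chosen_index`, `theta`, `partial_corr` (edge
#'   vector in [edge_index()] order), `index`, `n_edges`, `n_obs`,
#'   `gamma`, `genes`.
#' @export
select_by_ebic <- function(path, n_obs = NULL, gamma = 0) {
  stopifnot(inherits(path, "ggm_path"))
  n_obs <- n_obs %||% path$n_obs
  if (is.null(n_obs)) abort("`n_obs` is required for the likelihood.")
  if (!any(path$converged)) abort("No converged penalty value in the path.")
  nl <- length(path$lambda)
  p <- nrow(path$S_work)
  ebic <- rep(Inf, nl)
  n_edges <- rep(NA_integer_, nl)
  up <- upper.tri(matrix(0, p, p))
  for (i in seq_len(nl)) {
    if (!path$converged[i]) next
    th <- path$theta[, , i]
    e <- sum(th[up] != 0)
    n_edges[i] <- e
    ll <- ggm_loglik(th, path$S_work, n_obs)
    ebic[i] <- -2 * ll + e * log(n_obs) + 4 * gamma * e * log(p)
  }
  best <- which(ebic == min(ebic))
  if (length(best) > 1) best <- best[which.min(n_edges[best])]
  theta <- path$theta[, , best]
  rownames(theta) <- colnames(theta) <- path$genes
  idx <- edge_index(path$genes)
  out <- list(lambda_path = path$lambda, ebic = ebic,
              chosen_lambda = path$lambda[best], chosen_index = best,
              theta = theta,
              partial_corr = precision_to_partial(theta, idx),
              index = idx, n_edges = n_edges[best], n_obs = n_obs,
              gamma = gamma, genes = path$genes)
  class(out) <- "ggm_fit"
  out
}

#' Partial correlations from a precision matrix
#'
#' `rho_ij = -theta_ij / sqrt(theta_ii theta_jj)`, serialised in
#' [edge_index()] order.
#'
#' @param theta Symmetric precision matrix with positive diagonal.
#' @param index An [edge_index()] over the matching panel; defaults to
#'   the row names of `theta`.
#' @return Named numeric vector, one entry per edge.
#' @export
precision_to_partial <- function(theta, index = NULL) {
  stopifnot(is.matrix(theta), nrow(theta) == ncol(theta))
  if (any(diag(theta) <= 0)) {
    abort("Precision matrix has non-positive diagonal entries.")
  }
  if (is.null(index)) index <- edge_index(rownames(theta))
  d <- sqrt(diag(theta))
  rho <- -theta / tcrossprod(d)
  setNames(rho[cbind(index$i, index$j)], index$edge)
}

#' Estimate one chemical's network end to end
#'
#' Covariance of the dose-level LFC vectors, penalty path, BIC selection.
#'
#' @inheritParams chemical_covariance
#' @inheritParams glasso_path
#' @inheritParams select_by_ebic
#' @return A `ggm_fit` (see [select_by_ebic()]).
#' @export
fit_ggm <- function(panel_lfc, chemical, genes, timepoint = NULL,
                    nlambda = 1000, lambda_min_ratio = 0.01,
                    standardize = TRUE, gamma = 0) {
  ci <- chemical_covariance(panel_lfc, chemical, genes, timepoint)
  path <- glasso_path(ci, nlambda = nlambda,
                      lambda_min_ratio = lambda_min_ratio,
                      standardize = standardize)
  select_by_ebic(path, gamma = gamma)
}

#' Edge-feature matrix over all chemicals
#'
#' Fits a network per chemical and stacks the partial-correlation edge
#' vectors into the classifier's feature matrix: one row per chemical,
#' one column per edge (190 for a 20-gene panel).
#'
#' @inheritParams fit_ggm
#' @param chemicals Chemicals to fit (default: all in the panel).
#' @return Tibble: `chemical` plus one numeric column per edge.
#' @export
fit_ggm_all <- function(panel_lfc, genes, timepoint = NULL,
                        chemicals = NULL, nlambda = 1000,
                        lambda_min_ratio = 0.01, standardize = TRUE,
                        gamma = 0) {
  if (inherits(genes, "feature_panel")) genes <- genes$gene
  if (is.null(chemicals)) {
    keep <- if (!is.null(timepoint) && "timepoint" %in% names(panel_lfc)) {
      panel_lfc$timepoint == timepoint
    } else TRUE
    chemicals <- unique(panel_lfc$chemical[keep])
  }
  rows <- lapply(chemicals, function(ch) {
    fit <- fit_ggm(panel_lfc, ch, genes, timepoint, nlambda,
                   lambda_min_ratio, standardize, gamma)
    fit$partial_corr
  })
  bind_cols(tibble(chemical = chemicals),
            as_tibble(do.call(rbind, rows)))
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat(sprintf(
    "Gaussian graphical model: %d genes, %d edges at lambda = %.4g (BIC, gamma = %g)\n",
    length(x$genes), x$n_edges, x$chosen_lambda, x$gamma))
  invisible(x)
}

#' @export
tidy.ggm_fit <- function(x, ...) {
  out <- x$index
  out$partial_correlation <- unname(x$partial_corr)
  out
}

#' @export
glance.ggm_fit <- function(x, ...) {
  tibble(chosen_lambda = x$chosen_lambda, n_edges = x$n_edges,
         n_obs = x$n_obs, gamma = x$gamma,
         ebic = x$ebic[x$chosen_index])
}

#' @export
autoplot.ggm_fit <- function(object, ...) {
  el <- tidy(object)
  el <- dplyr::filter(el, .data$partial_correlation != 0)
  g <- igraph::graph_from_data_frame(
    el[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = object$genes)
  lay <- igraph::layout_in_circle(g)
  nodes <- tibble(gene = object$genes, x = lay[, 1], y = lay[, 2])
  seg <- el %>%
    left_join(rename(nodes, xa = "x", ya = "y"),
              by = c(gene_a = "gene")) %>%
    left_join(rename(nodes, xb = "x", yb = "y"),
              by = c(gene_b = "gene"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb,
                   colour = .data$partial_correlation > 0,
                   linewidth = abs(.data$partial_correlation)),
      show.legend = c(colour = TRUE, linewidth = FALSE)) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "darkgreen", `FALSE` = "firebrick"),
      labels = c(`TRUE` = "positive", `FALSE` = "negative"),
      name = "partial correlation") +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 2) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x * 1.12, .data$y * 1.12,
                                    label = .data$gene), size = 3) +
    ggplot2::theme_void()
}
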