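# Feature-gene selection: PCA of the conditions x genes LFC panel; from
# each of the top PCs take the gene with the largest positive and the
# gene with the largest negative loading.

#' Select feature genes from principal-component loadings
#'
#' PCA (centering only by default) of the LFC panel, conditions as
#' observations and genes as variables. For each of the first `n_pcs`
#' components the `genes_per_sign` genes with the largest positive
#' loadings and the `genes_per_sign` genes with the most negative
#' loadings are taken; with the default five PCs and two genes per sign
#' this yields the 20-gene feature panel. Because
#' an eigenvector's sign is arbitrary, each PC is first oriented so that
#' its largest-magnitude loading is positive, making the selection
#' deterministic. If a gene is extreme on more than one PC the
#' next-ranked gene is taken so the panel keeps its full size.
#'
#' @param panel LFC panel tibble ([compute_lfc()] format) or a numeric
#'   conditions x genes matrix.
#' @param n_pcs Number of leading components (default 5).
#' @param genes_per_sign Genes taken per PC and sign (default 2).
#' @param scale. Scale genes to unit variance before PCA (default FALSE).
#' @return Object of class `feature_panel`: tibble with `gene`, `pc`,
#'   `sign` and `loading`, in selection order; the gene vector is
#'   available via `$gene` and the PCA via attribute `pca`.
#' @export
pca_select_genes <- function(panel, n_pcs = 5, genes_per_sign = 2,
                             scale. = FALSE) {
  m <- if (is.matrix(panel)) panel else lfc_matrix(panel)
  if (nrow(m) < n_pcs || ncol(m) < 2 * n_pcs * genes_per_sign) {
    abort("Panel too small for the requested number of PCs/genes.")
  }
  pca <- prcomp(m, center = TRUE, scale. = scale.)
  rot <- pca$rotation
  n_pcs <- min(n_pcs, ncol(rot))

  picked <- character(0)
  rows <- list()
  for (pc in seq_len(n_pcs)) {
    load <- rot[, pc]
    # orient: largest-|loading| entry positive
    if (load[which.max(abs(load))] < 0) load <- -load
    for (sgn in c("+", "-")) {
      ord <- if (sgn == "+") order(load, decreasing = TRUE) else order(load)
      cand <- setdiff(colnames(m)[ord], picked)
      take <- head(cand, genes_per_sign)
      if (length(take) < genes_per_sign) {
        abort("Fewer distinct genes available than requested.")
      }
      picked <- c(picked, take)
      rows[[length(rows) + 1]] <- tibble(
        gene = take, pc = pc, sign = sgn,
        loading = unname(load[take]))
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("feature_panel", class(out))
  attr(out, "pca") <- pca
  out
}

#' @export
print.feature_panel <- function(x, ...) {
  cat(sprintf("Feature panel: %d genes from %d PCs\n",
              nrow(x), max(x$pc)))
  NextMethod()
}
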