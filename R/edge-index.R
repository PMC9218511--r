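#' Canonical edge index over a gene panel
#'
#' Enumerates every unordered gene pair of a panel in a fixed, reproducible
#' order: lexicographic by panel position with `i < j`. All edge-feature
#' vectors in the package (partial correlations, classifier features, file
#' exports) follow this order, so edge columns are comparable across
#' chemicals, timepoints and cell lines. A 20-gene panel yields
#' `20 * 19 / 2 = 190` edges.
#'
#' @param gene_panel Character vector of distinct gene identifiers, in panel
#'   order. Identifiers are treated as opaque strings.
#'
#' @return A tibble with one row per unordered pair: `i`, `j` (panel
#'   positions, `i < j`), `gene_a`, `gene_b` (the corresponding identifiers)
#'   and `edge` (`"gene_a|gene_b"`), carrying the panel as attribute
#'   `gene_panel`.
#'
#' @examples
#' edge_index(c("NANOG", "POU5F1", "SOX2"))
#' @export
edge_index <- function(gene_panel) {
  gene_panel <- as.character(gene_panel)
  if (length(gene_panel) < 2) {
    abort("`gene_panel` needs at least 2 identifiers.")
  }
  dup <- unique(gene_panel[duplicated(gene_panel)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate gene identifier(s) in panel: ",
                 paste(dup, collapse = ", ")))
  }
  p <- length(gene_panel)
  i <- rep(seq_len(p - 1L), times = (p - 1L):1L)
  j <- unlist(lapply(seq_len(p - 1L), function(k) (k + 1L):p), use.names = FALSE)
  out <- tibble(
    i = i, j = j,
    gene_a = gene_panel[i],
    gene_b = gene_panel[j],
    edge = paste(gene_panel[i], gene_panel[j], sep = "|")
  )
  attr(out, "gene_panel") <- gene_panel
  out
}

#' Look up edge positions for gene pairs
#'
#' Unordered lookup: `(b, a)` maps to the same edge row as `(a, b)`.
#'
#' @param index An [edge_index()] tibble.
#' @param gene_a,gene_b Character vectors of gene identifiers (recycled).
#'
#' @return Integer vector of row positions in `index` (NA when a pair is
#'   absent from the panel).
#' @export
edge_position <- function(index, gene_a, gene_b) {
  panel <- attr(index, "gene_panel")
  pos_a <- match(gene_a, panel)
  pos_b <- match(gene_b, panel)
  lo <- pmin(pos_a, pos_b)
  hi <- pmax(pos_a, pos_b)
  match(paste(lo, hi), paste(index$i, index$j))
}
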