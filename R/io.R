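# File I/O for every tabular format the pipeline touches. Counts travel as
# genes x samples TSV; everything else is CSV/TSV with a header row.

dose_level_values <- function() c("vehicle", "1/16", "1/8", "1/4", "1/2", "1/1")

#' Dose-level factor in increasing-dose order
#'
#' Dose levels are the fraction strings of the two-fold dilution series,
#' ordered `vehicle < 1/16 < 1/8 < 1/4 < 1/2 < 1/1`.
#'
#' @param x Character vector of dose-level strings.
#' @return Ordered factor.
#' @export
dose_level <- function(x) {
  bad <- setdiff(unique(as.character(x)), dose_level_values())
  if (length(bad) > 0) {
    abort(paste0("Unknown dose level(s): ", paste(bad, collapse = ", ")))
  }
  factor(as.character(x), levels = dose_level_values(), ordered = TRUE)
}

#' Validate a sample sheet
#'
#' A sample sheet has one row per RNA-seq sample with columns `sample_id`,
#' `chemical`, `dose_level` (`vehicle`, `1/16` ... `1/1`), `timepoint`
#' (hours, 24 or 48), `replicate`, `batch` and `solvent` (`DMSO` or
#' `water`). Vehicle rows carry the solvent name as `chemical`. Every
#' exposed condition must have a same-solvent, same-timepoint vehicle row
#' to normalise against.
#'
#' @param sheet A data frame.
#' @return The sheet as a tibble with `dose_level` as an ordered factor.
#' @export
validate_sample_sheet <- function(sheet) {
  needed <- c("sample_id", "chemical", "dose_level", "timepoint",
              "replicate", "batch", "solvent")
  missing_cols <- setdiff(needed, names(sheet))
  if (length(missing_cols) > 0) {
    abort(paste0("Sample sheet is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  sheet <- as_tibble(sheet)
  if (anyDuplicated(sheet$sample_id)) {
    abort(paste0("Duplicate sample_id(s): ",
                 paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
                       collapse = ", ")))
  }
  sheet$dose_level <- dose_level(sheet$dose_level)
  bad_solvent <- setdiff(unique(sheet$solvent), c("DMSO", "water"))
  if (length(bad_solvent) > 0) {
    abort(paste0("Unknown solvent(s): ", paste(bad_solvent, collapse = ", ")))
  }
  exposed <- dplyr::filter(sheet, .data$dose_level != "vehicle")
  veh <- dplyr::filter(sheet, .data$dose_level == "vehicle")
  orphan <- anti_join(distinct(exposed, .data$solvent, .data$timepoint),
                      distinct(veh, .data$solvent, .data$timepoint),
                      by = c("solvent", "timepoint"))
  if (nrow(orphan) > 0) {
    abort(paste0("Exposed condition(s) without a matched vehicle: ",
                 paste(paste(orphan$solvent, orphan$timepoint, sep = "/"),
                       collapse = ", ")))
  }
  sheet
}

#' Read / write a sample sheet CSV
#'
#' @param path File path.
#' @return `read_sample_sheet()` returns a validated tibble.
#' @seealso [validate_sample_sheet()]
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(readr::read_csv(path, show_col_types = FALSE,
                                        progress = FALSE))
}

#' @param sheet A sample sheet tibble.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_csv(validate_sample_sheet(sheet), path)
  invisible(path)
}

#' Read a gene count matrix TSV
#'
#' The file has gene identifiers in the first column and one column of
#' non-negative integer counts per sample. Columns are re-ordered to match
#' the sample sheet; a mismatch between file samples and sheet samples is
#' an error.
#'
#' @param path TSV file, genes x samples.
#' @param sheet A validated sample sheet.
#' @return An integer matrix (genes x samples) with dimnames, columns in
#'   sheet order.
#' @export
read_count_matrix <- function(path, sheet) {
  sheet <- validate_sample_sheet(sheet)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) {
    abort(paste0("Duplicate gene identifier(s) in count file: ",
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  file_samples <- names(tab)[-1]
  extra <- setdiff(file_samples, sheet$sample_id)
  absent <- setdiff(sheet$sample_id, file_samples)
  if (length(extra) > 0 || length(absent) > 0) {
    abort(paste0(
      "Count file / sample sheet mismatch.",
      if (length(extra) > 0)
        paste0(" In file but not sheet: ", paste(extra, collapse = ", "), "."),
      if (length(absent) > 0)
        paste0(" In sheet but not file: ", paste(absent, collapse = ", "), ".")
    ))
  }
  m <- as.matrix(tab[, sheet$sample_id, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Invalid count at gene '%s', sample '%s': %s",
      genes[bad[1, 1]], sheet$sample_id[bad[1, 2]], m[bad[1, , drop = FALSE]]))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' @param counts Integer matrix, genes x samples, with dimnames.
#' @rdname read_count_matrix
#' @export
write_count_matrix <- function(counts, path) {
  tab <- bind_cols(tibble(gene = rownames(counts)),
                   as_tibble(as.data.frame(counts)))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Toxicity-category label table
#'
#' `tox_labels()` returns the packaged reference table for the 24 study
#' chemicals: one row per chemical and one `P`/`N` column per category
#' (NT, HT, CT, GT, TT, NGC). Positive counts are 13, 15, 13, 6, 7 and 9.
#' `read_label_table()` reads the same format from a CSV.
#'
#' @return A tibble, one row per chemical.
#' @examples
#' colSums(tox_labels()[tox_categories()] == "P")
#' @export
tox_labels <- function() {
  read_label_table(system.file("extdata", "toxicity_labels.csv",
                               package = "ggmtox", mustWork = TRUE))
}

#' @param path CSV file with a `chemical` column and one P/N column per
#'   category.
#' @rdname tox_labels
#' @export
read_label_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0) abort("Label table is empty.")
  if (!"chemical" %in% names(tab)) abort("Label table needs a 'chemical' column.")
  if (anyDuplicated(tab$chemical)) {
    abort(paste0("Duplicate chemical(s) in label table: ",
                 paste(unique(tab$chemical[duplicated(tab$chemical)]),
                       collapse = ", ")))
  }
  cats <- setdiff(names(tab), "chemical")
  vals <- unlist(tab[cats], use.names = FALSE)
  bad <- setdiff(unique(vals), c("P", "N"))
  if (length(bad) > 0) {
    abort(paste0("Label values must be P or N; found: ",
                 paste(bad, collapse = ", ")))
  }
  tab
}

#' Read a gene panel file
#'
#' Plain text, one gene identifier per line; blank lines and `#` comments
#' are ignored.
#'
#' @param path File path.
#' @return Character vector of identifiers.
#' @export
read_gene_panel <- function(path) {
  x <- trimws(readr::read_lines(path, progress = FALSE))
  x <- x[x != "" & !startsWith(x, "#")]
  if (anyDuplicated(x)) {
    abort(paste0("Duplicate gene identifier(s) in panel file: ",
                 paste(unique(x[duplicated(x)]), collapse = ", ")))
  }
  x
}

#' Read an ATP-assay luminescence table CSV
#'
#' Long format with columns `chemical`, `concentration`, `replicate`,
#' `luminescence`; optional blank wells are rows with concentration 0 or
#' `NA` and are kept (the fitter subtracts their mean).
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_atp_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("chemical", "concentration", "replicate", "luminescence")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("ATP table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tab
}

#' Read a qPCR CT table CSV
#'
#' Long format with columns `chemical`, `dose_level`, `timepoint`,
#' `replicate`, `gene`, `ct`. Vehicle rows carry the solvent name
#' (`DMSO`/`water`) as `chemical` and `vehicle` as `dose_level`.
#'
#' @param path File path.
#' @return Tibble with `dose_level` as ordered factor.
#' @export
read_ct_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("chemical", "dose_level", "timepoint", "replicate", "gene", "ct")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("CT table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tab$dose_level <- dose_level(tab$dose_level)
  if (any(!is.finite(tab$ct))) abort("Non-finite CT value(s) in table.")
  tab
}

#' Read / write an edge-feature matrix TSV
#'
#' One row per chemical, one column per edge named `"geneA|geneB"` in
#' [edge_index()] order; first column `chemical`.
#'
#' @param path File path.
#' @return `read_edge_matrix()` returns a tibble.
#' @export
read_edge_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @param edges Tibble with `chemical` plus edge columns.
#' @rdname read_edge_matrix
#' @export
write_edge_matrix <- function(edges, path) {
  readr::write_tsv(edges, path)
  invisible(path)
}

#' Export one chemical's network as an edge list
#'
#' Writes `gene_a`, `gene_b`, `partial_correlation` TSV, optionally also
#' GraphML (via igraph) with the partial correlation as edge weight and
#' its sign as edge attribute, mirroring the convention of drawing
#' positive edges and negative edges in different colours.
#'
#' @param fit A [fit_ggm()] object.
#' @param path Output TSV path.
#' @param graphml Optional GraphML output path.
#' @param drop_zero Drop zero-weight edges (default TRUE).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(fit, path, graphml = NULL, drop_zero = TRUE) {
  stopifnot(inherits(fit, "ggm_fit"))
  el <- fit$index
  el$partial_correlation <- fit$partial_corr
  if (drop_zero) el <- dplyr::filter(el, .data$partial_correlation != 0)
  readr::write_tsv(select(el, "gene_a", "gene_b", "partial_correlation"), path)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      select(el, "gene_a", "gene_b"),
      directed = FALSE,
      vertices = attr(fit$index, "gene_panel"))
    igraph::E(g)$weight <- el$partial_correlation
    igraph::E(g)$sign <- ifelse(el$partial_correlation >= 0,
                                "positive", "negative")
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}
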