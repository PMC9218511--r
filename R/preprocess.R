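# Counts -> filtered, normalised, batch-corrected log2 expression ->
# per-condition log fold changes vs the matched vehicle -> moderated-t
# differential expression. The LFC panel (conditions x genes) is the
# substrate for feature-gene selection and network estimation.

#' Low-count gene filter
#'
#' Keeps genes whose counts-per-million exceed the cutoff implied by
#' `min_count` at the median library size in at least `k` samples, where
#' `k` is the smallest condition-group size, and whose total count is at
#' least `min_total`. With the full exposure design the groups are the
#' 122 conditions (120 chemical x dose combinations plus the two solvent
#' vehicles) per timepoint, so `k = 2` replicates.
#'
#' @param counts Integer matrix, genes x samples.
#' @param groups Factor/character of condition assignment per sample.
#' @param min_count Minimum count at the median library size (default 30).
#' @param min_total Minimum total count across samples (default 0).
#' @return The filtered count matrix (possibly 0 rows, with a warning).
#' @export
filter_low_counts <- function(counts, groups, min_count = 30, min_total = 0) {
  stopifnot(is.matrix(counts), length(groups) == ncol(counts))
  lib <- colSums(counts)
  if (all(lib == 0)) {
    warn("Low-count filter removed every gene.")
    return(counts[integer(0), , drop = FALSE])
  }
  cpm_cutoff <- min_count / median(lib) * 1e6
  cpm <- t(t(counts) / pmax(lib, 1) * 1e6)
  k <- min(table(groups))
  keep <- rowSums(cpm >= cpm_cutoff) >= (k - 1e-14) &
    rowSums(counts) >= min_total
  if (!any(keep)) warn("Low-count filter removed every gene.")
  counts[keep, , drop = FALSE]
}

#' log2 counts per million
#'
#' `log2((count + 0.5) / (library_size + 1) * 1e6)`, the standard
#' pseudo-counted logCPM transform.
#'
#' @param counts Matrix, genes x samples; library sizes are column sums.
#' @return Real matrix of the same shape.
#' @export
logcpm <- function(counts) {
  lib <- colSums(counts)
  if (any(lib == 0)) {
    abort(paste0("Zero library size for sample(s): ",
                 paste(colnames(counts)[lib == 0], collapse = ", ")))
  }
  log2(t((t(counts) + 0.5) / (lib + 1)) * 1e6)
}

#' Remove batch effects from log-expression
#'
#' Fits, per gene, a linear model with condition (design) and batch
#' indicator columns and subtracts the fitted batch contribution
#' (reference-batch coding: the first batch is the untouched baseline),
#' preserving the design effects. A single batch is an identity
#' transform. Any per-gene constant convention cancels downstream when
#' log fold changes are taken against the matched vehicle.
#'
#' @param x Log-expression matrix, genes x samples.
#' @param batch Factor/character of batch per sample.
#' @param design Factor/character of condition per sample.
#' @return Corrected matrix, same shape and order.
#' @export
remove_batch_effect <- function(x, batch, design) {
  stopifnot(length(batch) == ncol(x), length(design) == ncol(x))
  batch <- factor(batch)
  if (nlevels(batch) < 2) return(x)
  design <- factor(design)
  D <- model.matrix(~design)
  B <- model.matrix(~batch)[, -1, drop = FALSE]
  M <- cbind(D, B)
  fit <- lm.fit(M, t(x))
  beta <- fit$coefficients
  bat_rows <- (ncol(D) + 1):ncol(M)
  if (anyNA(beta[bat_rows, ])) {
    warn("Batch is confounded with the design; unidentifiable batch terms left in place.")
    beta[is.na(beta)] <- 0
  }
  x - t(B %*% beta[bat_rows, , drop = FALSE])
}

#' Per-condition log fold changes vs matched vehicle
#'
#' For every exposed (chemical, dose level, timepoint) condition, the LFC
#' of each gene is the mean log-expression over the condition's replicates
#' minus the mean over the matched vehicle replicates (same solvent, same
#' timepoint). Replicates are averaged here, after batch removal. The full
#' 24-chemical x 5-dose design yields 120 condition rows per timepoint.
#'
#' @param x Log-expression matrix, genes x samples (post batch removal).
#' @param sheet Sample sheet matching the columns of `x`.
#' @return An LFC panel: a tibble with `chemical`, `dose_level`,
#'   `timepoint` and one numeric column per gene.
#' @export
compute_lfc <- function(x, sheet) {
  sheet <- validate_sample_sheet(sheet)
  stopifnot(ncol(x) == nrow(sheet))
  if (!is.null(colnames(x)) &&
      !identical(colnames(x), as.character(sheet$sample_id))) {
    x <- x[, match(sheet$sample_id, colnames(x)), drop = FALSE]
  }
  veh <- sheet$dose_level == "vehicle"
  veh_key <- paste(sheet$solvent, sheet$timepoint)
  veh_means <- lapply(split(which(veh), veh_key[veh]), function(idx) {
    rowMeans(x[, idx, drop = FALSE])
  })
  conds <- distinct(dplyr::filter(sheet, !veh),
                    .data$chemical, .data$dose_level, .data$timepoint,
                    .data$solvent)
  rows <- purrr::pmap(conds, function(chemical, dose_level, timepoint,
                                      solvent) {
    idx <- which(sheet$chemical == chemical &
                   sheet$dose_level == dose_level &
                   sheet$timepoint == timepoint)
    vm <- veh_means[[paste(solvent, timepoint)]]
    if (is.null(vm)) {
      abort(sprintf("No matched vehicle for %s / %s / %s h.",
                    chemical, as.character(dose_level), timepoint))
    }
    rowMeans(x[, idx, drop = FALSE]) - vm
  })
  lfc <- do.call(rbind, rows)
  out <- bind_cols(select(conds, -"solvent"),
                   as_tibble(as.data.frame(lfc)))
  attr(out, "genes") <- rownames(x)
  out
}

#' Extract the gene-value matrix of an LFC panel
#'
#' @param panel An LFC panel tibble from [compute_lfc()] or [ddct_lfc()].
#' @return Numeric matrix, conditions x genes.
#' @export
lfc_matrix <- function(panel) {
  meta <- intersect(c("chemical", "dose_level", "timepoint"), names(panel))
  m <- as.matrix(panel[, setdiff(names(panel), meta), drop = FALSE])
  rownames(m) <- do.call(paste, c(panel[meta], sep = "_"))
  m
}

# moments estimator for the scaled-inverse-chi-square variance prior:
# match mean and variance of log sample variances; see moderated_t_deg.
estimate_variance_prior <- function(s2, df) {
  s2 <- s2[s2 > 0 & is.finite(s2)]
  if (length(s2) < 2) return(list(d0 = 0, s02 = median(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- var(z) - trigamma(df / 2)
  if (!is.finite(ev) || ev <= 0) {
    # no excess dispersion beyond chi-square sampling: infinite shrinkage
    return(list(d0 = Inf, s02 = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(ev)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton solve of trigamma(y) = x for y > 0
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Moderated-t differential expression vs matched vehicle
#'
#' Per-gene group-means linear model over the condition groups, with
#' gene-wise residual variances shrunk toward an empirical-Bayes prior:
#' `s2_tilde = (d0 s0^2 + d s^2) / (d0 + d)`, where `(d0, s0^2)` are
#' estimated by a method-of-moments fit on the log sample variances
#' (overridable). Each exposed condition is contrasted against its
#' matched vehicle; the moderated t has `d0 + d` degrees of freedom and
#' p-values are Benjamini-Hochberg adjusted across all genes and
#' contrasts. DEGs satisfy `fdr < fdr_cut` and `|lfc| > lfc_cut`.
#'
#' @param x Log-expression matrix, genes x samples.
#' @param sheet Matching sample sheet.
#' @param fdr_cut FDR threshold (default 0.01).
#' @param lfc_cut Absolute log2-fold-change threshold (default 1).
#' @param d0,s02 Optional prior df and prior variance overriding the
#'   moments estimate (`d0 = 0` gives the ordinary t; `d0 = Inf` full
#'   shrinkage to `s02`).
#' @return Tibble with one row per (gene, condition): `lfc`,
#'   `moderated_t`, `p_value`, `fdr`, `deg`, plus attributes `d0`, `s02`,
#'   `residual_df`.
#' @export
moderated_t_deg <- function(x, sheet, fdr_cut = 0.01, lfc_cut = 1,
                            d0 = NULL, s02 = NULL) {
  sheet <- validate_sample_sheet(sheet)
  stopifnot(ncol(x) == nrow(sheet))
  group <- paste(sheet$chemical, sheet$dose_level, sheet$timepoint, sep = "|")
  glev <- unique(group)
  gidx <- split(seq_along(group), factor(group, levels = glev))
  n_g <- lengths(gidx)
  d <- ncol(x) - length(glev)
  if (d < 1) abort("Zero residual degrees of freedom: cannot moderate.")

  means <- sapply(gidx, function(idx) rowMeans(x[, idx, drop = FALSE]))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(rownames(x), glev))
  rss <- rowSums(x^2) - colSums(t(means^2) * n_g)
  s2 <- pmax(rss, 0) / d

  if (is.null(d0) || is.null(s02)) {
    prior <- estimate_variance_prior(s2, d)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s02)) s02 <- prior$s02
  }
  s2_tilde <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  df_total <- d0 + d

  veh <- sheet$dose_level == "vehicle"
  veh_key <- paste(sheet$solvent, sheet$timepoint)
  conds <- distinct(dplyr::filter(sheet, !veh),
                    .data$chemical, .data$dose_level, .data$timepoint,
                    .data$solvent)
  res <- purrr::pmap(conds, function(chemical, dose_level, timepoint,
                                     solvent) {
    g1 <- paste(chemical, dose_level, timepoint, sep = "|")
    vidx <- which(veh & veh_key == paste(solvent, timepoint))
    n1 <- n_g[[g1]]
    n0 <- length(vidx)
    lfc <- means[, g1] - rowMeans(x[, vidx, drop = FALSE])
    se <- sqrt(s2_tilde * (1 / n1 + 1 / n0))
    tstat <- lfc / se
    p <- 2 * pt(-abs(tstat), df = df_total)
    tibble(gene = rownames(x), chemical = chemical,
           dose_level = as.character(dose_level), timepoint = timepoint,
           lfc = unname(lfc), moderated_t = unname(tstat),
           p_value = unname(p))
  })
  out <- bind_rows(res)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out$deg <- out$fdr < fdr_cut & abs(out$lfc) > lfc_cut
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "residual_df") <- d
  out
}

#' One-call preprocessing: counts to LFC panel
#'
#' Restriction to a gene panel (if given), low-count filtering, logCPM,
#' batch removal and per-condition LFC against the matched vehicle,
#' applied per timepoint jointly.
#'
#' @param counts Integer matrix, genes x samples.
#' @param sheet Matching sample sheet.
#' @param gene_panel Optional character vector restricting the genes
#'   before filtering (e.g. a transcription-factor panel).
#' @param min_count,min_total Passed to [filter_low_counts()].
#' @return LFC panel tibble (see [compute_lfc()]).
#' @export
preprocess_counts <- function(counts, sheet, gene_panel = NULL,
                              min_count = 30, min_total = 0) {
  sheet <- validate_sample_sheet(sheet)
  if (!is.null(gene_panel)) {
    counts <- counts[intersect(rownames(counts), gene_panel), , drop = FALSE]
  }
  group <- paste(sheet$chemical, sheet$dose_level, sheet$timepoint, sep = "|")
  counts <- filter_low_counts(counts, group, min_count, min_total)
  x <- logcpm(counts)
  x <- remove_batch_effect(x, sheet$batch, group)
  compute_lfc(x, sheet)
}
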