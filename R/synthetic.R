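# Synthetic-data generator: every input the pipeline consumes, with known
# ground truth. It emulates the study design -- 24 chemicals x 6 doses
# (incl. vehicle) x 2 replicates x 2 timepoints = 576 RNA-seq samples --
# with a category-structured covariance signal planted on a 20-gene
# feature panel: each toxicity category owns a clique of panel genes
# whose precision-matrix block induces partial correlations of a chosen
# strength, plus a category-specific dose-dependent mean shift that
# follows a sigmoidal dose profile (mechanisms switch on at different
# dose thresholds, so the mean responses of different categories are not
# collinear across the five dose ranks). A chemical's dose-level LFC
# vectors are sums of independent draws from the multivariate normals of
# its positive categories (log-scale additivity for multi-label
# chemicals) plus isotropic noise.

#' Ground truth for the synthetic study
#'
#' Fixes everything the generators need: gene identifiers, the 20-gene
#' panel, per-category precision matrices (3-gene cliques with partial
#' correlation `rho`, scaled by `theta_scale`), per-category dose-effect
#' vectors of size `mu` with sigmoidal dose profiles, per-chemical DEG
#' gene sets with planted log fold change `deg_lfc`, lognormal baseline
#' expression, batch shifts, negative-binomial dispersion, and
#' per-chemical dose-response parameters.
#'
#' @param n_genes Number of synthetic genes (default 500).
#' @param labels Label table; its chemicals and P/N structure drive the
#'   planted signal (default [tox_labels()]).
#' @param mu Dose-effect size on a category's own genes, log2 units
#'   (default 5).
#' @param rho Planted partial correlation within a category clique
#'   (default 0.45; must stay below 0.5 for positive definiteness).
#' @param theta_scale Overall precision magnitude (default 36): larger
#'   values shrink the covariance draws relative to the dose-trend
#'   signal without changing the planted partial correlations.
#' @param profile_steepness Slope of the sigmoidal per-category dose
#'   profiles (default 4); category thresholds are spread evenly over
#'   the five dose ranks and each profile is scaled to the dose-rank
#'   variance of a linear ramp so `mu` keeps a comparable meaning
#'   across categories.
#' @param sigma0 Isotropic LFC noise SD (default 0.1).
#' @param deg_lfc Planted DEG log fold change at the top dose (default 3).
#' @param n_deg DEG genes per chemical (default 5).
#' @param batch_sd SD of the per-gene additive batch-2 shift (default 0.3).
#' @param dispersion Negative-binomial dispersion (default 0.05).
#' @param panel_size Feature-panel size (default 20).
#' @param seed Seed fixing the randomly drawn truth components.
#' @return Object of class `sim_truth`.
#' @export
sim_truth <- function(n_genes = 500, labels = tox_labels(), mu = 5,
                      rho = 0.45, theta_scale = 36, profile_steepness = 4,
                      sigma0 = 0.1, deg_lfc = 3, n_deg = 5,
                      batch_sd = 0.3, dispersion = 0.05, panel_size = 20,
                      seed = 0) {
  stopifnot(rho > 0, rho < 0.5, n_genes >= panel_size + 1)
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  panel <- genes[seq_len(panel_size)]
  cats <- setdiff(names(labels), "chemical")

  # each category owns a 3-gene clique on the panel
  theta <- list()
  mu_vec <- list()
  for (ci in seq_along(cats)) {
    own <- ((ci - 1) * 3 + 1):((ci - 1) * 3 + 3)
    own <- ((own - 1) %% panel_size) + 1
    th <- diag(panel_size)
    th[own, own] <- -rho
    diag(th) <- 1
    ev <- min(eigen(th, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) abort("Category precision matrix is not positive definite.")
    theta[[cats[ci]]] <- th * theta_scale
    m <- rep(0, panel_size)
    m[own] <- mu * c(1, -1, 1)[seq_along(own)]
    mu_vec[[cats[ci]]] <- m
  }
  sigma_chol <- lapply(theta, function(th) chol(solve(th)))

  # sigmoidal per-category dose profiles over the 5 dose ranks, scaled
  # to the variance of the linear ramp r/5 so effect sizes compare
  thresholds <- seq(1, 5, length.out = length(cats))
  ranks <- 1:5
  dose_profiles <- sapply(thresholds, function(t0) {
    pr <- stats::plogis(profile_steepness * (ranks - t0))
    pr / sd(pr) * sqrt(0.1)
  })
  colnames(dose_profiles) <- cats

  chem <- labels$chemical
  deg_pool <- genes[(panel_size + 1):min(panel_size + 100, n_genes)]
  deg_genes <- lapply(seq_along(chem), function(i) {
    sample(deg_pool, n_deg)
  })
  names(deg_genes) <- chem
  deg_sign <- lapply(deg_genes, function(g) {
    setNames(sample(c(-1, 1), length(g), replace = TRUE), g)
  })

  out <- list(
    genes = genes, panel_genes = panel, categories = cats,
    labels = labels, theta = theta, sigma_chol = sigma_chol,
    mu_vec = mu_vec, mu = mu, rho = rho, theta_scale = theta_scale,
    dose_profiles = dose_profiles, sigma0 = sigma0,
    deg_lfc = deg_lfc, deg_genes = deg_genes, deg_sign = deg_sign,
    batch_shift = setNames(rnorm(n_genes, 0, batch_sd), genes),
    log2_baseline = setNames(
      pmax(rnorm(n_genes, 9, 1.5), 5), genes),
    dispersion = dispersion,
    dose_response = tibble(
      chemical = chem,
      b = runif(length(chem), 1, 3),
      d = 5e4,
      e = rlnorm(length(chem), log(10), 1)),
    seed = seed)
  # panel genes get high baselines so the low-count filter keeps them
  out$log2_baseline[panel] <- pmax(out$log2_baseline[panel], 9)
  class(out) <- "sim_truth"
  out
}

#' Full-factorial sample sheet for the synthetic design
#'
#' Defaults reproduce the study design: 24 chemicals x 6 doses (five
#' dilutions plus vehicle) x 2 replicates x 2 timepoints = 576 samples.
#' Vehicle samples carry the solvent name as `chemical`, so the
#' condition groups are the chemical-dose combinations plus one vehicle
#' group per solvent (122 groups for the full design per timepoint).
#' Batch is the replicate run; solvent alternates deterministically over
#' chemicals.
#'
#' @param chemicals Chemical names or a count (default: the 24 packaged
#'   chemicals).
#' @param doses Number of dose levels including vehicle (default 6).
#' @param reps Replicates (default 2).
#' @param timepoints Timepoints in hours (default `c(24, 48)`).
#' @return A validated sample sheet tibble.
#' @export
gen_design <- function(chemicals = tox_labels()$chemical, doses = 6,
                       reps = 2, timepoints = c(24, 48)) {
  if (is.numeric(chemicals) && length(chemicals) == 1) {
    chemicals <- sprintf("chem%02d", seq_len(chemicals))
  }
  stopifnot(doses >= 2, doses <= 6, reps >= 1, length(timepoints) >= 1)
  solvent <- ifelse(seq_along(chemicals) %% 2 == 1, "DMSO", "water")
  levels_used <- rev(dose_level_values())[seq_len(doses - 1)]
  rows <- tidyr::expand_grid(
    chem_i = seq_along(chemicals),
    dose_level = c(levels_used, "vehicle"),
    timepoint = timepoints,
    replicate = seq_len(reps))
  rows$solvent <- solvent[rows$chem_i]
  rows$chemical <- ifelse(rows$dose_level == "vehicle",
                          rows$solvent, chemicals[rows$chem_i])
  rows$batch <- paste0("run", rows$replicate)
  rows$sample_id <- sprintf("s%04d", seq_len(nrow(rows)))
  validate_sample_sheet(
    select(rows, "sample_id", "chemical", "dose_level", "timepoint",
           "replicate", "batch", "solvent"))
}

derive_seed <- function(seed, timepoint) {
  (abs(seed) * 97L + as.integer(timepoint)) %% .Machine$integer.max
}

# draw the true dose-level LFC vectors of every chemical on the panel
# genes: sum over the chemical's positive categories of
# N(mu_c * rank/5, Sigma_c) draws, plus N(0, sigma0^2 I)
draw_panel_lfc <- function(truth, timepoint, seed, n_dose = 5) {
  set.seed(derive_seed(seed, timepoint))
  p <- length(truth$panel_genes)
  lev <- rev(dose_level_values())[seq_len(n_dose)]  # 1/1 first
  out <- list()
  for (ch in truth$labels$chemical) {
    pos <- truth$categories[
      unlist(truth$labels[truth$labels$chemical == ch,
                          truth$categories]) == "P"]
    lfc <- matrix(rnorm(n_dose * p, 0, truth$sigma0), n_dose, p)
    for (cat in pos) {
      z <- matrix(rnorm(n_dose * p), n_dose, p) %*% truth$sigma_chol[[cat]]
      # profile is indexed by dose rank (5 = top); rows here run 1/1 down
      prof <- truth$dose_profiles[seq(5, 6 - n_dose), cat]
      lfc <- lfc + z + outer(prof, truth$mu_vec[[cat]])
    }
    colnames(lfc) <- truth$panel_genes
    out[[ch]] <- tibble(chemical = ch, dose_level = lev,
                        timepoint = timepoint) %>%
      bind_cols(as_tibble(as.data.frame(lfc)))
  }
  res <- bind_rows(out)
  res$dose_level <- dose_level(res$dose_level)
  res
}

#' True panel LFC vectors for one timepoint
#'
#' The ground-truth dose-level LFC panel over the 20 feature genes, in
#' the same schema as [compute_lfc()] output: what the RNA-seq stages
#' would recover with no measurement noise.
#'
#' @param truth A [sim_truth()].
#' @param timepoint Timepoint (hours; default 24).
#' @param seed Seed.
#' @return LFC panel tibble (chemicals x 5 doses rows, panel genes).
#' @export
gen_lfc_panel <- function(truth, timepoint = 24, seed = 0) {
  draw_panel_lfc(truth, timepoint, seed)
}

#' Synthetic RNA-seq counts for a sample sheet
#'
#' Negative-binomial counts with lognormal baselines. Exposed samples of
#' the panel genes receive the ground-truth dose-level LFC shifts of
#' [gen_lfc_panel()] (identical draws for the same `(truth, seed,
#' timepoint)`); each chemical's DEG genes receive the planted
#' dose-ranked shift; batch 2 samples get the additive per-gene batch
#' shift on the log scale.
#'
#' @param sheet Sample sheet ([gen_design()]).
#' @param truth A [sim_truth()].
#' @param seed Seed.
#' @return Integer count matrix genes x samples, with the true panel
#'   LFC tibble in attribute `true_panel_lfc`.
#' @export
gen_counts <- function(sheet, truth, seed = 0) {
  sheet <- validate_sample_sheet(sheet)
  genes <- truth$genes
  n_dose_levels <- dose_level_values()
  tps <- sort(unique(sheet$timepoint))
  panel_lfc <- bind_rows(lapply(tps, function(tp) {
    draw_panel_lfc(truth, tp, seed)
  }))

  lfc_of <- function(chemical, dose, tp) {
    # full-length log2 shift vector for one condition
    shift <- setNames(rep(0, length(genes)), genes)
    if (dose == "vehicle") return(shift)
    row <- which(panel_lfc$chemical == chemical &
                   panel_lfc$dose_level == dose &
                   panel_lfc$timepoint == tp)
    if (length(row) > 0) {
      shift[truth$panel_genes] <-
        unlist(panel_lfc[row[1], truth$panel_genes], use.names = FALSE)
    }
    rank_frac <- (match(dose, n_dose_levels) - 1) / 5
    dg <- truth$deg_genes[[chemical]]
    if (!is.null(dg)) {
      shift[dg] <- shift[dg] + truth$deg_sign[[chemical]] *
        truth$deg_lfc * rank_frac
    }
    shift
  }

  set.seed(derive_seed(seed, 9999L))
  counts <- matrix(0L, length(genes), nrow(sheet),
                   dimnames = list(genes, sheet$sample_id))
  size <- 1 / truth$dispersion
  for (s in seq_len(nrow(sheet))) {
    shift <- lfc_of(sheet$chemical[s], as.character(sheet$dose_level[s]),
                    sheet$timepoint[s])
    log2mu <- truth$log2_baseline + shift +
      if (sheet$batch[s] != "run1") truth$batch_shift else 0
    counts[, s] <- rnbinom(length(genes), size = size, mu = 2^log2mu)
  }
  attr(counts, "true_panel_lfc") <- panel_lfc
  counts
}

#' Synthetic qPCR CT table from a known LFC panel
#'
#' `CT = baseline_gene + reference_ct - sign_convention * lfc + noise`,
#' two replicates per concentration, plus reference-gene rows (GAPDH at
#' `reference_ct`) and vehicle rows per solvent. With `noise_sd = 0` and
#' the default sign convention, [delta_ct()] + [ddct_lfc()] (with its
#' default `lfc_sign = 1`) recover the input panel exactly.
#'
#' @param lfc_truth LFC panel tibble (conditions x genes).
#' @param sheet Sample sheet mapping chemicals to solvents.
#' @param noise_sd Gaussian CT noise SD on gene wells (default 0).
#' @param sign_convention -1 (default; makes the ddCT value equal the
#'   input LFC) or +1 (biological orientation: more transcript, lower
#'   CT).
#' @param reference_ct Reference-gene CT (default 20).
#' @param n_rep Replicates per concentration (default 2).
#' @param seed Seed.
#' @return Long CT tibble ([read_ct_table()] format).
#' @export
gen_ct_table <- function(lfc_truth, sheet, noise_sd = 0,
                         sign_convention = -1, reference_ct = 20,
                         n_rep = 2, seed = 0) {
  stopifnot(sign_convention %in% c(-1, 1))
  sheet <- validate_sample_sheet(sheet)
  set.seed(derive_seed(seed, 777L))
  meta <- intersect(c("chemical", "dose_level", "timepoint"),
                    names(lfc_truth))
  genes <- setdiff(names(lfc_truth), meta)
  baseline <- setNames(5 + 0.2 * seq_along(genes), genes)
  solvent_of <- distinct(
    dplyr::filter(sheet, .data$dose_level != "vehicle"),
    .data$chemical, .data$solvent)
  tps <- unique(lfc_truth$timepoint %||% 24)

  long <- tidyr::pivot_longer(lfc_truth, all_of(genes),
                              names_to = "gene", values_to = "lfc")
  rows <- tidyr::expand_grid(long, replicate = seq_len(n_rep))
  rows$ct <- baseline[rows$gene] + reference_ct -
    sign_convention * rows$lfc +
    rnorm(nrow(rows), 0, noise_sd)

  veh <- tidyr::expand_grid(
    chemical = unique(solvent_of$solvent),
    dose_level = "vehicle",
    timepoint = tps,
    replicate = seq_len(n_rep),
    gene = genes)
  veh$ct <- baseline[veh$gene] + reference_ct

  ref <- bind_rows(
    distinct(rows, .data$chemical, .data$dose_level, .data$timepoint,
             .data$replicate),
    distinct(veh, .data$chemical, .data$dose_level, .data$timepoint,
             .data$replicate))
  ref$gene <- "GAPDH"
  ref$ct <- reference_ct

  out <- bind_rows(
    select(rows, "chemical", "dose_level", "timepoint", "replicate",
           "gene", "ct"),
    select(veh, "chemical", "dose_level", "timepoint", "replicate",
           "gene", "ct"),
    ref)
  out$dose_level <- dose_level(as.character(out$dose_level))
  out
}

#' Synthetic ATP-assay luminescence for one chemical
#'
#' Responses follow the three-parameter log-logistic curve with
#' multiplicative lognormal noise of coefficient of variation `cv`,
#' measured over 10 serial three-fold dilutions of a stock (default
#' stock `81 * e`, placing the inflection inside the range) with 4
#' replicates, plus blank wells.
#'
#' @param b,d,e Curve parameters (slope, upper asymptote, inflection).
#' @param concentrations Optional explicit concentrations.
#' @param cv Coefficient of variation of the noise (default 0).
#' @param n_rep Replicates per concentration (default 4).
#' @param blank Blank luminescence level (default 0 = no blank offset).
#' @param chemical Chemical name for the output table.
#' @param seed Seed.
#' @return ATP table tibble ([read_atp_table()] format), including blank
#'   rows with concentration 0.
#' @export
gen_atp <- function(b, d, e, concentrations = NULL, cv = 0, n_rep = 4,
                    blank = 0, chemical = "chem", seed = 0) {
  if (is.null(concentrations)) concentrations <- 81 * e / 3^(0:9)
  set.seed(derive_seed(seed, 555L))
  grid <- tidyr::expand_grid(concentration = concentrations,
                             replicate = seq_len(n_rep))
  sdlog <- sqrt(log(1 + cv^2))
  noise <- if (cv > 0) rlnorm(nrow(grid), -sdlog^2 / 2, sdlog) else 1
  grid$luminescence <- blank + ll3(grid$concentration, b, d, e) * noise
  blanks <- tibble(concentration = 0, replicate = seq_len(n_rep),
                   luminescence = blank)
  out <- bind_rows(grid, blanks)
  out$chemical <- chemical
  select(out, "chemical", "concentration", "replicate", "luminescence")
}

#' Write a complete synthetic fixture directory
#'
#' Emits counts TSV, sample sheet CSV, label CSV, gene panel TXT, CT
#' CSV, ATP CSV and a truth summary JSON into `dir`.
#'
#' @param dir Output directory (created if needed).
#' @param truth A [sim_truth()] (default: `sim_truth()`).
#' @param seed Seed.
#' @return `dir`, invisibly.
#' @export
write_sim_fixtures <- function(dir, truth = sim_truth(), seed = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- gen_design(truth$labels$chemical)
  counts <- gen_counts(sheet, truth, seed)
  write_sample_sheet(sheet, file.path(dir, "sample_sheet.csv"))
  write_count_matrix(counts, file.path(dir, "counts.tsv"))
  readr::write_csv(truth$labels, file.path(dir, "labels.csv"))
  writeLines(truth$panel_genes, file.path(dir, "gene_panel.txt"))
  lfc24 <- gen_lfc_panel(truth, 24, seed)
  ct <- gen_ct_table(lfc24, sheet, seed = seed)
  readr::write_csv(ct, file.path(dir, "ct_table.csv"))
  atp <- bind_rows(lapply(seq_len(nrow(truth$dose_response)), function(i) {
    dr <- truth$dose_response[i, ]
    gen_atp(dr$b, dr$d, dr$e, cv = 0.05, chemical = dr$chemical,
            seed = seed + i)
  }))
  readr::write_csv(atp, file.path(dir, "atp_table.csv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(seed = seed, panel_genes = truth$panel_genes,
           categories = truth$categories, mu = truth$mu, rho = truth$rho,
           sigma0 = truth$sigma0),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
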