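# Small in-code fixtures shared across test files.

tiny_sheet <- function(n_chem = 2, doses = 3, reps = 2, timepoints = 24) {
  gen_design(sprintf("chem%02d", seq_len(n_chem)), doses = doses,
             reps = reps, timepoints = timepoints)
}

# counts with deterministic values, genes x samples
tiny_counts <- function(sheet, n_genes = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * nrow(sheet), mu = 200, size = 20),
              n_genes, nrow(sheet),
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sheet$sample_id))
  storage.mode(m) <- "integer"
  m
}

# session-cached expensive objects (computed once per test run)
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# the study-scale synthetic run shared by several acceptance checks
e2e_pipeline <- function(seed = 1) {
  cached(paste0("e2e_", seed), {
    truth <- sim_truth(seed = 42)
    sheet <- gen_design()
    counts <- gen_counts(sheet, truth, seed = seed)
    s24 <- sheet[sheet$timepoint == 24, ]
    lfc <- preprocess_counts(counts[, s24$sample_id], s24)
    panel <- pca_select_genes(lfc)
    edges <- fit_ggm_all(lfc, panel, timepoint = 24)
    list(truth = truth, sheet = sheet, counts = counts, lfc = lfc,
         panel = panel, edges = edges)
  })
}
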