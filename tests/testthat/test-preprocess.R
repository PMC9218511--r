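test_that("low-count filter reproduces the stated rule", {
  sheet <- tiny_sheet(n_chem = 2, doses = 3, reps = 2)
  groups <- paste(sheet$chemical, sheet$dose_level)
  set.seed(7)
  counts <- tiny_counts(sheet, n_genes = 6, seed = 7)
  counts[1, ] <- 0L                      # all-zero: must go
  counts[2, ] <- 3000L                   # far above cutoff: must stay
  kept <- filter_low_counts(counts, groups, min_count = 30)
  expect_false("g01" %in% rownames(kept))
  expect_true("g02" %in% rownames(kept))

  # brute-force application of the rule
  lib <- colSums(counts)
  cutoff <- 30 / median(lib) * 1e6
  cpm <- t(t(counts) / lib * 1e6)
  k <- min(table(groups))
  keep <- unname(rowSums(cpm >= cutoff) >= k)
  expect_identical(rownames(kept), rownames(counts)[keep])

  # independent implementation agrees on a random fixture
  expect_identical(
    keep,
    unname(edgeR::filterByExpr(counts, group = groups, min.count = 30,
                               min.total.count = 0)))
})

test_that("filter is a no-op when everything is expressed", {
  sheet <- tiny_sheet(n_chem = 1, doses = 3)
  counts <- tiny_counts(sheet, n_genes = 4) + 10000L
  kept <- filter_low_counts(counts, seq_len(ncol(counts)) %% 2)
  expect_identical(kept, counts)
  expect_warning(filter_low_counts(counts * 0L, rep(1, ncol(counts))),
                 "every gene")
})

test_that("logCPM matches its closed form", {
  counts <- matrix(c(0L, 999999L), 2, 1,
                   dimnames = list(c("a", "b"), "s1"))
  x <- logcpm(counts)
  expect_equal(x["a", 1], -1)  # log2(0.5 / 1e6 * 1e6)
  expect_equal(x["b", 1], log2((999999 + 0.5) / 1e6 * 1e6))

  # scale near-invariance up to the pseudo-count
  sheet <- tiny_sheet()
  c1 <- tiny_counts(sheet, n_genes = 5) + 10000L
  expect_lt(max(abs(logcpm(c1 * 2L) - logcpm(c1))), 1e-3)

  c0 <- c1
  c0[, 2] <- 0L
  expect_error(logcpm(c0), colnames(c1)[2])
})

test_that("batch removal is exact for additive shifts and matches the
           normal-equations oracle", {
  sheet <- tiny_sheet(n_chem = 2, doses = 3, reps = 2)
  design <- paste(sheet$chemical, sheet$dose_level)
  batch <- sheet$batch
  set.seed(21)
  x <- matrix(rnorm(8 * nrow(sheet)), 8, nrow(sheet),
              dimnames = list(paste0("g", 1:8), sheet$sample_id))

  # single batch: identity
  expect_identical(remove_batch_effect(x, rep("b1", ncol(x)), design), x)

  # constant shift on batch 2 is removed exactly
  shifted <- x
  shifted[3, batch == "run2"] <- shifted[3, batch == "run2"] + 5
  cleaned <- remove_batch_effect(shifted, batch, design)
  expect_equal(cleaned[3, ], remove_batch_effect(x, batch, design)[3, ],
               tolerance = 1e-10)

  # explicit least-squares residualisation oracle
  cleaned2 <- remove_batch_effect(x, batch, design)
  D <- model.matrix(~factor(design))
  B <- model.matrix(~factor(batch))[, -1, drop = FALSE]
  M <- cbind(D, B)
  for (g in 1:3) {
    beta <- solve(crossprod(M), crossprod(M, x[g, ]))
    expect_equal(unname(cleaned2[g, ]),
                 unname(x[g, ] - drop(B %*% beta[(ncol(D) + 1):ncol(M)])),
                 tolerance = 1e-10)
  }

  # idempotent
  expect_equal(remove_batch_effect(cleaned2, batch, design), cleaned2,
               tolerance = 1e-10)
})

test_that("LFC is the exposed mean minus the matched vehicle mean", {
  sheet <- tiny_sheet(n_chem = 2, doses = 3, reps = 2)
  x <- matrix(0, 2, nrow(sheet),
              dimnames = list(c("g1", "g2"), sheet$sample_id))
  is_chem1 <- sheet$chemical == "chem01" & sheet$dose_level == "1/1"
  x[1, is_chem1] <- 1
  panel <- compute_lfc(x, sheet)
  row <- panel[panel$chemical == "chem01" & panel$dose_level == "1/1", ]
  expect_equal(row$g1, 1)
  expect_equal(row$g2, 0)

  # full-design condition count: 24 chemicals x 5 doses
  full <- gen_design()
  full24 <- full[full$timepoint == 24, ]
  xf <- matrix(rnorm(3 * nrow(full24)), 3, nrow(full24),
               dimnames = list(paste0("g", 1:3), full24$sample_id))
  expect_equal(nrow(compute_lfc(xf, full24)), 120)
})

test_that("moderated t has the ordinary-t and full-shrinkage limits", {
  sheet <- tiny_sheet(n_chem = 2, doses = 3, reps = 3)
  set.seed(5)
  x <- matrix(rnorm(20 * nrow(sheet)), 20, nrow(sheet),
              dimnames = list(paste0("g", 1:20), sheet$sample_id))
  group <- paste(sheet$chemical, sheet$dose_level, sheet$timepoint)

  res0 <- moderated_t_deg(x, sheet, d0 = 0, s02 = 1)
  # ordinary t oracle for one condition, per gene
  cond <- res0[res0$chemical == "chem01" & res0$dose_level == "1/1", ]
  idx1 <- which(sheet$chemical == "chem01" & sheet$dose_level == "1/1")
  idxv <- which(sheet$dose_level == "vehicle" & sheet$solvent == "DMSO")
  d <- ncol(x) - length(unique(group))
  for (g in c(1, 7, 20)) {
    gm <- vapply(split(seq_len(ncol(x)), group),
                 function(ii) mean(x[g, ii]), 0)
    s2 <- sum((x[g, ] - gm[group])^2) / d
    tt <- (mean(x[g, idx1]) - mean(x[g, idxv])) /
      sqrt(s2 * (1 / length(idx1) + 1 / length(idxv)))
    expect_equal(cond$moderated_t[cond$gene == paste0("g", g)], tt,
                 tolerance = 1e-10)
  }

  resInf <- moderated_t_deg(x, sheet, d0 = Inf, s02 = 0.5)
  condI <- resInf[resInf$chemical == "chem01" & resInf$dose_level == "1/1", ]
  # statistic is lfc divided by a constant: equal-lfc genes tie
  expect_equal(condI$moderated_t,
               condI$lfc / sqrt(0.5 * (1 / length(idx1) + 1 / length(idxv))),
               tolerance = 1e-12)
})

test_that("moderated t agrees with the established empirical-Bayes fit", {
  sheet <- tiny_sheet(n_chem = 3, doses = 3, reps = 2)
  set.seed(6)
  x <- matrix(rnorm(50 * nrow(sheet), sd = rep(c(0.5, 1, 2), length.out = 50)),
              50, nrow(sheet),
              dimnames = list(paste0("g", 1:50), sheet$sample_id))
  group <- factor(paste(sheet$chemical, sheet$dose_level, sep = "."))
  group <- stats::relevel(group, ref = "DMSO.vehicle")
  design <- model.matrix(~group)
  eb <- limma::eBayes(limma::lmFit(x, design))
  res <- moderated_t_deg(x, sheet, d0 = eb$df.prior, s02 = eb$s2.prior)
  # the chem01 1/1 coefficient is the difference vs the DMSO vehicle
  mine <- res[res$chemical == "chem01" & res$dose_level == "1/1", ]
  expect_equal(mine$moderated_t, unname(eb$t[, "groupchem01.1/1"]),
               tolerance = 1e-8)
  expect_equal(mine$p_value, unname(eb$p.value[, "groupchem01.1/1"]),
               tolerance = 1e-8)
})

test_that("BH adjustment matches the brute-force definition", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(9)
  for (i in 1:5) {
    p <- runif(50)
    expect_equal(p.adjust(p, "BH"), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("moderated test keeps its size under the null", {
  sheet <- tiny_sheet(n_chem = 1, doses = 2, reps = 4)
  set.seed(31)
  x <- matrix(rnorm(2000 * nrow(sheet), sd = rlnorm(2000, 0, 0.5)),
              2000, nrow(sheet),
              dimnames = list(paste0("g", 1:2000), sheet$sample_id))
  res <- moderated_t_deg(x, sheet)
  alpha <- mean(res$p_value < 0.05)
  expect_lt(abs(alpha - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(res)) + 0.01)
  expect_true(all(res$fdr >= res$p_value - 1e-12))
})

test_that("planted DEGs are recovered from synthetic counts", {
  truth <- sim_truth(n_genes = 120, seed = 2)
  sheet <- gen_design(truth$labels$chemical, timepoints = 24)
  counts <- gen_counts(sheet, truth, seed = 3)
  keep <- filter_low_counts(
    counts, paste(sheet$chemical, sheet$dose_level))
  x <- remove_batch_effect(logcpm(keep), sheet$batch,
                           paste(sheet$chemical, sheet$dose_level))
  res <- moderated_t_deg(x, sheet)
  ch <- truth$labels$chemical[1]
  top <- res[res$chemical == ch & res$dose_level == "1/1", ]
  planted <- intersect(truth$deg_genes[[ch]], top$gene)
  expect_gt(length(planted), 0)
  expect_true(mean(top$deg[match(planted, top$gene)]) >= 0.8)
})
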