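# Six binary toxicity-category tasks over edge features: leave-one-out
# SVM with per-fold two-sample t-test feature ranking and a sweep over
# kernels and top-k feature counts; a transductive transfer mode that
# predicts unlabeled second-cell-line instances; uniform-random baselines
# and a one-sample t-test on the observed maximum accuracy.

#' SVM kernel/hyperparameter grid
#'
#' The default grid: linear (cost 0.01-100), polynomial (degree 2-3,
#' inhomogeneous, same costs) and RBF (gamma = scale / k with scale 0.1,
#' 1, 10). A sigmoid kernel can be enabled as a fourth kernel family.
#'
#' @param kernels Kernel families to include.
#' @param cost Cost values.
#' @param degree Polynomial degrees.
#' @param gamma_scale RBF gamma multipliers of the 1/k default.
#' @return Tibble with one row per configuration: `kernel`, `cost`,
#'   `degree`, `gamma_scale`, `coef0`, `config`.
#' @export
svm_grid <- function(kernels = c("linear", "polynomial", "radial"),
                     cost = c(0.01, 0.1, 1, 10, 100),
                     degree = 2:3, gamma_scale = c(0.1, 1, 10)) {
  rows <- list()
  for (kern in kernels) {
    rows[[kern]] <- switch(
      kern,
      linear = tidyr::expand_grid(kernel = "linear", cost = cost,
                                  degree = 3, gamma_scale = 1, coef0 = 0),
      polynomial = tidyr::expand_grid(kernel = "polynomial", cost = cost,
                                      degree = degree, gamma_scale = 1,
                                      coef0 = 1),
      radial = tidyr::expand_grid(kernel = "radial", cost = cost,
                                  degree = 3, gamma_scale = gamma_scale,
                                  coef0 = 0),
      sigmoid = tidyr::expand_grid(kernel = "sigmoid", cost = cost,
                                   degree = 3, gamma_scale = gamma_scale,
                                   coef0 = 0),
      abort(paste0("Unknown kernel family: ", kern)))
  }
  out <- bind_rows(rows)
  out$config <- sprintf("%s_c%g_d%d_g%g", out$kernel, out$cost, out$degree,
                        out$gamma_scale)
  out
}

#' Reduced sweep protocol for baseline simulations
#'
#' A smaller kernel grid (linear and RBF, cost 1 and 10) and a coarse
#' top-k grid, used for the uniform-random baseline replicates so ten
#' full leave-one-out sweeps stay desk-scale. Reports produced with this
#' protocol carry it in their `protocol` field.
#'
#' @return `reduced_svm_grid()`: a [svm_grid()] tibble with 4
#'   configurations.
#' @export
reduced_svm_grid <- function() {
  svm_grid(kernels = c("linear", "radial"), cost = c(1, 10),
           gamma_scale = 1)
}

#' @param n_features Total number of features.
#' @rdname reduced_svm_grid
#' @return `reduced_k_grid()`: an increasing integer vector of top-k
#'   values, dense for small k and coarse above.
#' @export
reduced_k_grid <- function(n_features) {
  k <- c(1:15, seq(20, 60, by = 5), seq(70, 190, by = 10))
  k <- k[k <= n_features]
  if (length(k) == 0) k <- seq_len(n_features)
  k
}

#' The documented baseline-simulation protocol
#'
#' The exact sweep used for the ten-replicate uniform-random baselines:
#' linear (cost 1, 10) and RBF (gamma scale 0.1, 1, 10; cost 1, 10)
#' kernels, and a top-k grid dense for k <= 30 and progressively
#' coarser up to 190, where neighbouring k values are nearly redundant.
#' Reports produced with it carry its name in their `protocol` field,
#' and baseline levels are only comparable between runs of the same
#' protocol.
#'
#' @param n_features Number of edge features (default 190).
#' @return List with `grid` (a [svm_grid()] tibble) and `k_range`.
#' @export
baseline_protocol <- function(n_features = 190) {
  k <- c(1:30, seq(32, 60, by = 2), seq(65, 190, by = 5))
  k <- k[k <= n_features]
  if (length(k) == 0) k <- seq_len(n_features)
  list(grid = svm_grid(kernels = c("linear", "radial"), cost = c(1, 10),
                       gamma_scale = c(0.1, 1, 10)),
       k_range = k)
}

#' Welch two-sample t feature ranking
#'
#' Features are ranked by descending absolute Welch t statistic between
#' the two classes; ties break by feature index. A feature identical
#' across classes gets t = 0 and ranks last; a feature with zero
#' within-class variance but different class means dominates.
#'
#' @param train Numeric matrix (instances x features) or tibble with a
#'   `chemical` column plus features.
#' @param labels Binary labels (`P`/`N` character/factor or logical)
#'   aligned with the rows.
#' @return Tibble `feature`, `t_stat`, `rank`, ordered by rank.
#' @export
rank_features_ttest <- function(train, labels) {
  m <- feature_values(train)
  y <- as_pn(labels)
  if (length(unique(y)) < 2) {
    abort("Both classes must be present in the training fold.")
  }
  o <- welch_order(m, y == "P")
  tibble(feature = colnames(m)[o$order],
         t_stat = unname(o$t[o$order]),
         rank = seq_along(o$order))
}

# vectorised Welch t over columns; returns list(t, order)
welch_order <- function(m, pos) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  m1 <- colMeans(m[pos, , drop = FALSE])
  m0 <- colMeans(m[!pos, , drop = FALSE])
  v1 <- if (n1 > 1) matrixStats_colVars(m[pos, , drop = FALSE], m1) else
    rep(0, ncol(m))
  v0 <- if (n0 > 1) matrixStats_colVars(m[!pos, , drop = FALSE], m0) else
    rep(0, ncol(m))
  se <- sqrt(v1 / n1 + v0 / n0)
  d <- m1 - m0
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  list(t = t, order = order(-abs(t), seq_along(t)))
}

matrixStats_colVars <- function(m, mu) {
  colSums((t(t(m) - mu))^2) / (nrow(m) - 1)
}

#' Classification accuracy from a confusion matrix
#'
#' `100 * (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return Percent accuracy.
#' @export
accuracy <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) abort("Counts must be non-negative.")
  total <- tp + tn + fp + fn
  if (any(total == 0)) abort("Total count is zero.")
  100 * (tp + tn) / total
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of decision values against binary
#' labels; tied decision values receive half credit.
#'
#' @param decisions Numeric decision values (larger = more positive).
#' @param labels Binary labels (`P`/`N`, factor or logical).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(decisions, labels) {
  y <- as_pn(labels) == "P"
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present.")
  r <- rank(decisions)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_pn <- function(labels) {
  if (is.logical(labels)) return(ifelse(labels, "P", "N"))
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("P", "N"))
  if (length(bad) > 0) {
    abort(paste0("Labels must be P/N (or logical); found: ",
                 paste(bad, collapse = ", ")))
  }
  labels
}

feature_values <- function(x) {
  if (is.matrix(x)) return(x)
  x <- as_tibble(x)
  meta <- intersect(c("chemical", "domain"), names(x))
  m <- as.matrix(x[, setdiff(names(x), meta), drop = FALSE])
  if ("chemical" %in% meta) rownames(m) <- x$chemical
  m
}

# decision value of a fitted binary e1071::svm for one unscaled test
# vector, oriented so positive means class "P"; equivalent to
# predict(fit, decision.values = TRUE) but without the dispatch overhead
# of scoring one point hundreds of thousands of times in a sweep
svm_decision_p <- function(fit, xt, kernel, gamma, coef0, degree) {
  sv <- fit$SV
  kv <- switch(kernel,
    linear = drop(sv %*% xt),
    radial = exp(-gamma * rowSums(sweep(sv, 2, xt)^2)),
    polynomial = (gamma * drop(sv %*% xt) + coef0)^degree,
    sigmoid = tanh(gamma * drop(sv %*% xt) + coef0))
  d <- sum(fit$coefs * kv) - fit$rho
  # libsvm orients the decision value toward the class of the first
  # training example; fit$labels records that order
  if (fit$levels[fit$labels[1]] == "P") d else -d
}

# Evaluate one leave-one-out fold: rank and standardise on the training
# instances only, then score the held-out vector for every grid
# configuration and top-k count. Returns oriented decision values
# (positive = class P), one row per configuration, one column per k.
# `scale_stats` optionally supplies transductive standardisation moments.
svm_fold_eval <- function(x_train, y_train, x_test, grid, k_range,
                          scale_stats = NULL) {
  y <- factor(as_pn(y_train), levels = c("N", "P"))
  o <- welch_order(x_train, y == "P")$order
  if (is.null(scale_stats)) {
    mu <- colMeans(x_train)
    sdv <- sqrt(matrixStats_colVars(x_train, mu))
  } else {
    mu <- scale_stats$mu
    sdv <- scale_stats$sd
  }
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  xs <- t((t(x_train) - mu) / sdv)
  xt <- (x_test - mu) / sdv
  dv <- matrix(NA_real_, nrow(grid), length(k_range))
  for (ci in seq_len(nrow(grid))) {
    g <- grid[ci, ]
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      sel <- o[seq_len(k)]
      fit <- e1071::svm(xs[, sel, drop = FALSE], y, scale = FALSE,
                        kernel = g$kernel, cost = g$cost,
                        degree = g$degree, gamma = g$gamma_scale / k,
                        coef0 = g$coef0)
      dv[ci, ki] <- svm_decision_p(fit, xt[sel], g$kernel,
                                   g$gamma_scale / k, g$coef0, g$degree)
    }
  }
  list(dv = dv, order = o)
}

new_prediction_run <- function(category, chemicals, truth, dv_array, grid,
                               k_range, fold_rankings, protocol) {
  ncfg <- dim(dv_array)[1]
  nk <- dim(dv_array)[2]
  acc <- matrix(NA_real_, ncfg, nk)
  aucs <- matrix(NA_real_, ncfg, nk)
  pos <- truth == "P"
  for (ci in seq_len(ncfg)) {
    for (ki in seq_len(nk)) {
      d <- dv_array[ci, ki, ]
      pred <- ifelse(d > 0, "P", "N")
      acc[ci, ki] <- 100 * mean(pred == truth)
      aucs[ci, ki] <- auc(d, truth)
    }
  }
  # max accuracy; ties -> higher AUC, then smaller k, then grid order
  ord <- order(-acc, -aucs, rep(k_range, each = ncfg),
               rep(seq_len(ncfg), nk))
  best <- ord[1]
  ci <- (best - 1) %% ncfg + 1
  ki <- (best - 1) %/% ncfg + 1
  d <- dv_array[ci, ki, ]
  out <- list(
    category = category,
    chemicals = chemicals,
    truth = truth,
    decision_values = setNames(d, chemicals),
    predicted = setNames(ifelse(d > 0, "P", "N"), chemicals),
    best_kernel = grid$config[ci],
    best_config = grid[ci, ],
    best_k = k_range[ki],
    max_accuracy = acc[ci, ki],
    auc_at_max = aucs[ci, ki],
    accuracy_grid = acc,
    auc_grid = aucs,
    k_range = k_range,
    grid = grid,
    fold_rankings = fold_rankings,
    protocol = protocol)
  class(out) <- "prediction_run"
  out
}

#' Leave-one-out SVM sweep over kernels and top-k features
#'
#' For every left-out instance, features are ranked by the two-sided
#' two-sample t-test and standardised using the training instances only;
#' an SVM is fitted for every kernel configuration and every top-k count
#' and the held-out instance is scored. The reported result is the
#' maximum accuracy over the whole grid, with the AUC of the
#' accuracy-maximising configuration (ties resolved toward higher AUC,
#' then smaller k, then grid order).
#'
#' @param x Feature matrix: tibble with `chemical` plus one column per
#'   edge feature, or a numeric matrix.
#' @param labels Binary labels: a `P`/`N` vector aligned with rows, or a
#'   label table ([tox_labels()] format) combined with `category`.
#' @param category Category column to use when `labels` is a table.
#' @param grid Kernel grid ([svm_grid()]; default full grid).
#' @param k_range Top-k values to sweep (default `1:n_features`).
#' @return Object of class `prediction_run`; see [tidy.prediction_run()].
#' @export
loocv_sweep <- function(x, labels, category = NULL, grid = svm_grid(),
                        k_range = NULL) {
  m <- feature_values(x)
  if (any(!is.finite(m))) abort("Feature values must be finite.")
  chem <- rownames(m) %||% as.character(seq_len(nrow(m)))
  truth <- resolve_labels(labels, category, chem)
  if (sum(truth == "P") < 2 || sum(truth == "N") < 2) {
    abort("Need at least 2 instances in each class for LOOCV.")
  }
  if (is.null(k_range)) k_range <- seq_len(ncol(m))
  k_range <- k_range[k_range >= 1 & k_range <= ncol(m)]
  if (length(k_range) == 0) abort("`k_range` is empty after clamping.")
  n <- nrow(m)
  dv <- array(NA_real_, c(nrow(grid), length(k_range), n))
  rankings <- vector("list", n)
  for (i in seq_len(n)) {
    fe <- svm_fold_eval(m[-i, , drop = FALSE], truth[-i], m[i, ],
                        grid, k_range)
    dv[, , i] <- fe$dv
    rankings[[i]] <- colnames(m)[fe$order]
  }
  new_prediction_run(category %||% "task", chem, truth, dv, grid, k_range,
                     rankings, protocol = "loocv")
}

resolve_labels <- function(labels, category, chemicals) {
  if (is.data.frame(labels)) {
    if (is.null(category)) {
      abort("Give `category` when `labels` is a label table.")
    }
    if (!category %in% names(labels)) {
      abort(paste0("Category '", category, "' not in label table."))
    }
    missing_chem <- setdiff(chemicals, labels$chemical)
    if (length(missing_chem) > 0) {
      abort(paste0("Chemical(s) absent from label table: ",
                   paste(missing_chem, collapse = ", ")))
    }
    as_pn(labels[[category]][match(chemicals, labels$chemical)])
  } else {
    if (length(labels) != length(chemicals)) {
      abort("`labels` length must match the number of instances.")
    }
    as_pn(labels)
  }
}

#' Transductive transfer prediction of unlabeled second-domain data
#'
#' Source-domain (ES) edge features carry the category labels; the
#' target-domain (iPS) features of the same chemicals are unlabeled.
#' In `stacked` mode (default) both domains share the 190-edge feature
#' space: for each chemical, the SVM is trained on the labeled ES
#' instances excluding that chemical, with standardisation moments
#' computed transductively over all retained instances of both domains,
#' and the chemical's iPS instance is scored. In `concat` mode the two
#' domains are concatenated into 380 features per chemical and evaluated
#' by plain LOOCV. Either way the sweep over kernels and top-k is as in
#' [loocv_sweep()] and accuracy is measured against the true labels of
#' the 24 chemicals.
#'
#' @param es Labeled source-domain feature tibble (`chemical` + edges).
#' @param ips Unlabeled target-domain feature tibble; same chemicals and
#'   the same edge columns as `es`.
#' @param labels Label table ([tox_labels()] format).
#' @param categories Categories to run (default all in `labels`).
#' @param mode `"stacked"` or `"concat"`.
#' @param grid,k_range Sweep controls; `k_range` defaults to the full
#'   1..190 (stacked) or 1..380 (concat) range.
#' @return Named list of `prediction_run`, one per category.
#' @export
transfer_predict <- function(es, ips, labels, categories = NULL,
                             mode = c("stacked", "concat"),
                             grid = svm_grid(), k_range = NULL) {
  mode <- match.arg(mode)
  me <- feature_values(es)
  mi <- feature_values(ips)
  if (!identical(colnames(me), colnames(mi))) {
    abort("ES and iPS feature matrices must share an identical edge index.")
  }
  if (!setequal(rownames(me), rownames(mi))) {
    abort("ES and iPS must cover the same chemical set.")
  }
  mi <- mi[rownames(me), , drop = FALSE]
  chem <- rownames(me)
  if (is.null(categories)) {
    categories <- intersect(tox_categories(), names(labels))
    if (length(categories) == 0) categories <- setdiff(names(labels),
                                                       "chemical")
  }

  if (mode == "concat") {
    mc <- cbind(me, mi)
    colnames(mc) <- c(paste0("ES:", colnames(me)),
                      paste0("iPS:", colnames(mi)))
    runs <- lapply(categories, function(cat) {
      r <- loocv_sweep(mc, labels, cat, grid = grid, k_range = k_range)
      r$protocol <- "transfer_concat"
      r
    })
    return(setNames(runs, categories))
  }

  if (is.null(k_range)) k_range <- seq_len(ncol(me))
  k_range <- k_range[k_range >= 1 & k_range <= ncol(me)]
  if (length(k_range) == 0) abort("`k_range` is empty after clamping.")
  runs <- lapply(categories, function(cat) {
    truth <- resolve_labels(labels, cat, chem)
    n <- length(chem)
    dv <- array(NA_real_, c(nrow(grid), length(k_range), n))
    rankings <- vector("list", n)
    for (i in seq_len(n)) {
      x_train <- me[-i, , drop = FALSE]
      pool <- rbind(x_train, mi)  # labeled source + unlabeled target
      mu <- colMeans(pool)
      sdv <- sqrt(matrixStats_colVars(pool, mu))
      fe <- svm_fold_eval(x_train, truth[-i], mi[i, ], grid, k_range,
                          scale_stats = list(mu = mu, sd = sdv))
      dv[, , i] <- fe$dv
      rankings[[i]] <- colnames(me)[fe$order]
    }
    new_prediction_run(cat, chem, truth, dv, grid, k_range, rankings,
                       protocol = "transfer_stacked")
  })
  setNames(runs, categories)
}

#' Uniform-random feature baselines
#'
#' Repeats the identical sweep with features replaced by uniform random
#' numbers on (-1, 1): the whole instance-by-feature matrix for the
#' single-domain task, or only the target-domain (iPS) block for the
#' transfer task. Because features are standardised per training fold
#' the results are invariant to the affine range of the uniform draw.
#'
#' @param labels Label table or label vector (see [loocv_sweep()]).
#' @param category Category column when `labels` is a table.
#' @param n_chem Number of instances (default 24).
#' @param n_features Number of edge features (default 190).
#' @param grid,k_range Sweep controls (defaults: [reduced_svm_grid()] and
#'   [reduced_k_grid()]).
#' @param n_rep Number of random replicates (default 10).
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @param es_features When given, run the transfer task instead: these
#'   real source-domain features are kept and only the iPS block is
#'   randomised.
#' @param transfer_mode Transfer mode when `es_features` is given.
#' @return Tibble `replicate`, `max_accuracy`, `auc_at_max`.
#' @export
random_baseline <- function(labels, category = NULL, n_chem = 24,
                            n_features = 190, grid = reduced_svm_grid(),
                            k_range = NULL, n_rep = 10, seed = 0,
                            es_features = NULL,
                            transfer_mode = "stacked") {
  if (n_rep < 2) abort("Need at least 2 random replicates.")
  if (!is.null(es_features)) {
    me <- feature_values(es_features)
    n_chem <- nrow(me)
    n_features <- ncol(me)
  }
  if (is.null(k_range)) k_range <- reduced_k_grid(n_features)
  chem <- if (!is.null(es_features)) rownames(feature_values(es_features))
          else if (is.data.frame(labels)) labels$chemical[seq_len(n_chem)]
          else as.character(seq_len(n_chem))
  res <- purrr::map(seq_len(n_rep), function(r) {
    set.seed(seed + r)
    rnd <- matrix(runif(n_chem * n_features, -1, 1), n_chem, n_features)
    rownames(rnd) <- chem
    if (is.null(es_features)) {
      colnames(rnd) <- paste0("f", seq_len(n_features))
      run <- loocv_sweep(rnd, labels, category, grid = grid,
                         k_range = k_range)
    } else {
      colnames(rnd) <- colnames(me)
      run <- transfer_predict(tibble_features(me), tibble_features(rnd),
                              labels, categories = category,
                              mode = transfer_mode, grid = grid,
                              k_range = k_range)[[1]]
    }
    tibble(replicate = r, max_accuracy = run$max_accuracy,
           auc_at_max = run$auc_at_max)
  })
  bind_rows(res)
}

tibble_features <- function(m) {
  bind_cols(tibble(chemical = rownames(m)), as_tibble(as.data.frame(m)))
}

#' One-sample t-test of an observed result against random baselines
#'
#' `t = (actual - mean(random)) / (sd(random) / sqrt(n))`, one-sided
#' upper-tail p from the t distribution with `n - 1` degrees of freedom
#' (9 for the standard 10 replicates). Flags at p < 0.05 and p < 0.01.
#'
#' @param actual Observed value (accuracy percent or AUC).
#' @param random_values Baseline replicate values (typically 10).
#' @return Object of class `significance_result`.
#' @export
significance_test <- function(actual, random_values) {
  n <- length(random_values)
  if (n < 2) abort("Need at least 2 random values.")
  m <- mean(random_values)
  s <- sd(random_values)
  if (s == 0) {
    warn("Random baseline has zero standard deviation.")
    p <- if (actual > m) 0 else 1
    t_stat <- if (actual > m) Inf else -Inf
  } else {
    t_stat <- (actual - m) / (s / sqrt(n))
    p <- pt(t_stat, df = n - 1, lower.tail = FALSE)
  }
  out <- list(random_values = random_values, random_mean = m,
              random_sd = s, actual = actual, t_stat = t_stat,
              df = n - 1, p_one_sided = p,
              significant_05 = p < 0.05, significant_01 = p < 0.01)
  class(out) <- "significance_result"
  out
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf(
    "One-sample t-test (one-sided, df = %d)\n  actual %.4g vs random %.4g +/- %.4g\n  t = %.3f, p = %.4g%s\n",
    x$df, x$actual, x$random_mean, x$random_sd, x$t_stat, x$p_one_sided,
    if (x$significant_01) " (p < 0.01)"
    else if (x$significant_05) " (p < 0.05)" else ""))
  invisible(x)
}

#' @export
tidy.significance_result <- function(x, ...) {
  tibble(actual = x$actual, random_mean = x$random_mean,
         random_sd = x$random_sd, t_stat = x$t_stat, df = x$df,
         p_one_sided = x$p_one_sided,
         significant_05 = x$significant_05,
         significant_01 = x$significant_01)
}

#' Per-chemical prediction accuracy across the six category tasks
#'
#' For every chemical, the fraction of the six category tasks in which
#' its held-out prediction was correct.
#'
#' @param runs Named list of the six category `prediction_run`s.
#' @return Tibble `chemical`, `n_correct`, `n_tasks`, `accuracy`
#'   (percent).
#' @export
per_chemical_report <- function(runs) {
  missing_cat <- setdiff(tox_categories(), names(runs))
  if (length(missing_cat) > 0) {
    abort(paste0("Missing category run(s): ",
                 paste(missing_cat, collapse = ", ")))
  }
  runs <- runs[tox_categories()]
  chem <- runs[[1]]$chemicals
  correct <- sapply(runs, function(r) {
    r$predicted[chem] == r$truth[match(chem, r$chemicals)]
  })
  tibble(chemical = chem,
         n_correct = unname(rowSums(correct)),
         n_tasks = length(runs),
         accuracy = unname(100 * rowSums(correct) / length(runs)))
}

#' @export
print.prediction_run <- function(x, ...) {
  cat(sprintf(
    "Prediction run [%s, %s]\n  max accuracy %.1f%% (AUC %.3f) at %s, k = %d\n",
    x$category, x$protocol, x$max_accuracy, x$auc_at_max,
    x$best_kernel, x$best_k))
  invisible(x)
}

#' Tidy a prediction run
#'
#' @param x A `prediction_run`.
#' @param ... Unused.
#' @return One row per chemical: decision value, predicted and true
#'   label, correctness.
#' @export
tidy.prediction_run <- function(x, ...) {
  tibble(category = x$category, chemical = x$chemicals,
         decision_value = unname(x$decision_values),
         predicted = unname(x$predicted), truth = x$truth,
         correct = unname(x$predicted) == x$truth)
}

#' @export
glance.prediction_run <- function(x, ...) {
  tibble(category = x$category, protocol = x$protocol,
         max_accuracy = x$max_accuracy, auc_at_max = x$auc_at_max,
         best_kernel = x$best_kernel, best_k = x$best_k,
         n_instances = length(x$chemicals))
}

#' @export
autoplot.prediction_run <- function(object, ...) {
  d <- tidy(object)
  d$chemical <- factor(d$chemical, levels = d$chemical[order(d$decision_value)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$decision_value,
                                  y = .data$chemical,
                                  colour = .data$truth,
                                  shape = .data$correct)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "SVM decision value", y = NULL,
                  title = sprintf("%s: accuracy %.1f%%, AUC %.2f",
                                  object$category, object$max_accuracy,
                                  object$auc_at_max))
}

#' @export
autoplot.significance_result <- function(object, ...) {
  scale <- object$random_sd / sqrt(object$df + 1)
  xs <- seq(object$random_mean - 6 * scale,
            max(object$actual + scale, object$random_mean + 6 * scale),
            length.out = 400)
  dens <- stats::dt((xs - object$random_mean) / scale, df = object$df) / scale
  crit <- object$random_mean + qt(0.95, object$df) * scale
  d <- tibble(x = xs, density = dens)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$density)) +
    ggplot2::geom_area(data = dplyr::filter(d, .data$x >= crit),
                       fill = "grey30") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$actual, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "maximum accuracy under random features",
                  y = "density (t distribution)")
}
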