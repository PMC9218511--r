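# Three-parameter log-logistic viability model:
#   f(x) = d / (1 + exp(b * (log(x) - log(e))))
# with lower asymptote fixed at 0. b > 0 gives a decreasing curve (the
# usual orientation for a cytotoxicity ATP assay), d is the untreated
# luminescence level and e the inflection concentration (= IC50).

ll3 <- function(x, b, d, e) d / (1 + exp(b * (log(x) - log(e))))

#' Fit a three-parameter log-logistic dose-response curve
#'
#' Least-squares fit of `f(x) = d / (1 + exp(b (ln x - ln e)))` to
#' blank-corrected luminescence, in log-concentration space, with
#' multi-start Levenberg-Marquardt (starts: `d` = max response, `e` =
#' concentration nearest half-max, `b` in {0.5, 1, 2, 4} and their
#' negatives). 95% confidence intervals are asymptotic Wald intervals from
#' the estimated covariance. A response with no usable dose effect (e.g.
#' all responses identical) yields `converged = FALSE`; no IC can be read
#' off such a fit.
#'
#' @param assay Data frame with columns `concentration` (strictly positive
#'   except optional blank rows with 0/NA), `luminescence`, and optionally
#'   `replicate` and `chemical` (a single chemical per call). Rows with
#'   concentration 0 or NA are treated as blanks; the mean blank is
#'   subtracted before fitting.
#' @param blank Optional explicit blank value(s) overriding blank rows.
#'
#' @return An object of class `drfit`: a list with `b`, `d`, `e`,
#'   `residual_sse`, `ci95` (tibble), `converged`, `n`, `data`.
#'
#' @examples
#' conc <- 10 * 3^seq(-5, 4)
#' assay <- data.frame(concentration = conc,
#'                     luminescence = 100 / (1 + conc / 10))
#' fit <- fit_log_logistic(assay)
#' c(fit$b, fit$d, fit$e)
#' @export
fit_log_logistic <- function(assay, blank = NULL) {
  assay <- as_tibble(assay)
  stopifnot(all(c("concentration", "luminescence") %in% names(assay)))
  is_blank <- is.na(assay$concentration) | assay$concentration == 0
  if (is.null(blank)) blank <- assay$luminescence[is_blank]
  dat <- assay[!is_blank, , drop = FALSE]
  if (any(dat$concentration <= 0)) {
    abort("Concentrations must be strictly positive (blanks coded 0/NA).")
  }
  if (length(unique(dat$concentration)) < 4) {
    abort("Need at least 4 distinct concentrations to fit.")
  }
  y <- dat$luminescence - if (length(blank) > 0) mean(blank) else 0
  lx <- log(dat$concentration)

  out <- list(b = NA_real_, d = NA_real_, e = NA_real_,
              residual_sse = NA_real_, ci95 = NULL, converged = FALSE,
              n = length(y), data = tibble(log_conc = lx, response = y))
  class(out) <- "drfit"

  if (sd(y) == 0) return(out)

  d0 <- max(y)
  half <- dat$concentration[which.min(abs(y - d0 / 2))]
  best <- NULL
  for (b0 in c(0.5, 1, 2, 4, -0.5, -1, -2, -4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        resp ~ d / (1 + exp(b * (lc - log(e)))),
        data = data.frame(resp = y, lc = lx),
        start = list(b = b0, d = d0, e = half),
        lower = c(-Inf, 1e-12, 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best_sse) {
      best <- fit
      best_sse <- sse
    }
  }
  if (is.null(best)) return(out)

  cf <- coef(best)
  # a fit that explains no variance beyond the mean is not a dose effect
  tss <- sum((y - mean(y))^2)
  if (best_sse >= tss * (1 - 1e-8)) return(out)

  out$b <- unname(cf["b"])
  out$d <- unname(cf["d"])
  out$e <- unname(cf["e"])
  out$residual_sse <- best_sse
  out$converged <- TRUE
  vc <- tryCatch(vcov(best), error = function(e) NULL)
  if (!is.null(vc)) {
    se <- sqrt(pmax(diag(vc), 0))
    z <- qt(0.975, df = max(length(y) - 3, 1))
    out$ci95 <- tibble(
      parameter = names(cf),
      estimate = unname(cf),
      se = unname(se),
      lower = unname(cf - z * se),
      upper = unname(cf + z * se))
  }
  out
}

#' @export
print.drfit <- function(x, ...) {
  cat("Three-parameter log-logistic fit\n")
  if (!x$converged) {
    cat("  not converged (no usable dose effect)\n")
    return(invisible(x))
  }
  cat(sprintf("  b = %.4g, d = %.4g, e (IC50) = %.4g\n", x$b, x$d, x$e))
  cat(sprintf("  residual SSE = %.4g on %d observations\n",
              x$residual_sse, x$n))
  invisible(x)
}

#' @export
tidy.drfit <- function(x, ...) {
  if (!x$converged) {
    return(tibble(parameter = c("b", "d", "e"), estimate = NA_real_,
                  se = NA_real_, lower = NA_real_, upper = NA_real_))
  }
  x$ci95
}

#' @export
glance.drfit <- function(x, ...) {
  tibble(converged = x$converged, residual_sse = x$residual_sse,
         n = x$n, ic50 = if (x$converged) invert_icp(x, 50) else NA_real_)
}

#' Invert a fitted curve to an inhibitory concentration
#'
#' Closed-form ICp: the concentration at which the fitted response drops
#' to `(1 - p/100) * d`, i.e. `x = e * (q / (1 - q))^(1/b)` with
#' `q = p/100`. IC50 equals `e` for any slope.
#'
#' @param fit A converged [fit_log_logistic()] object.
#' @param p Percent inhibition, in (0, 100).
#' @return Concentration (assay units).
#' @export
invert_icp <- function(fit, p) {
  stopifnot(inherits(fit, "drfit"))
  if (!fit$converged) abort("Cannot invert a non-converged fit.")
  if (any(p <= 0 | p >= 100)) abort("`p` must lie strictly in (0, 100).")
  if (fit$b <= 0) {
    abort("Fitted slope b <= 0: response is not decreasing with dose.")
  }
  q <- p / 100
  fit$e * (q / (1 - q))^(1 / fit$b)
}

#' Build the exposure dilution series from a fitted curve
#'
#' The maximum exposure dose is set at ICp (between IC0.1 and IC50,
#' default IC50) and diluted two-fold five times (1/1, 1/2, 1/4, 1/8,
#' 1/16); vehicle (0) completes the six-entry series.
#'
#' @param fit A converged [fit_log_logistic()] object.
#' @param p_max Percent inhibition defining the maximum dose, in
#'   \[0.1, 50\].
#' @return Tibble with `dose_level` (ordered factor) and `concentration`
#'   (0 for vehicle), decreasing dose order.
#' @export
build_exposure_series <- function(fit, p_max = 50) {
  if (p_max < 0.1 || p_max > 50) abort("`p_max` must lie in [0.1, 50].")
  max_dose <- invert_icp(fit, p_max)
  tibble(
    dose_level = dose_level(c("1/1", "1/2", "1/4", "1/8", "1/16", "vehicle")),
    concentration = c(max_dose / c(1, 2, 4, 8, 16), 0))
}

#' Fit curves and tabulate ICs for many chemicals
#'
#' @param atp ATP table ([read_atp_table()] format).
#' @param p_max Percent inhibition defining the maximum exposure dose.
#' @return Tibble with one row per chemical: parameter estimates, CIs,
#'   IC0.1, IC50 and the chosen maximum dose.
#' @export
fit_atp_table <- function(atp, p_max = 50) {
  atp %>%
    group_by(.data$chemical) %>%
    dplyr::group_modify(function(df, key) {
      fit <- fit_log_logistic(df)
      if (!fit$converged) {
        return(tibble(b = NA_real_, d = NA_real_, e = NA_real_,
                      converged = FALSE, ic0.1 = NA_real_, ic50 = NA_real_,
                      max_dose = NA_real_))
      }
      tibble(b = fit$b, d = fit$d, e = fit$e, converged = TRUE,
             ic0.1 = invert_icp(fit, 0.1), ic50 = invert_icp(fit, 50),
             max_dose = invert_icp(fit, p_max))
    }) %>%
    ungroup()
}

#' @export
autoplot.drfit <- function(object, ...) {
  dat <- object$data
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$log_conc,
                                         y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "log concentration", y = "blank-corrected luminescence")
  if (object$converged) {
    grid <- tibble(log_conc = seq(min(dat$log_conc), max(dat$log_conc),
                                  length.out = 200))
    grid$response <- ll3(exp(grid$log_conc), object$b, object$d, object$e)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}
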