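#' Fit two-sample Mendelian randomization estimators
#'
#' The central fitting function: applies the requested causal estimators to a
#' harmonized instrument set and returns a classed model object. The five
#' standard methods are the inverse-variance weighted estimator ([mr_ivw()]),
#' MR-Egger regression ([mr_egger()]), the weighted median
#' ([mr_weighted_median()]) and the simple and weighted mode estimators
#' ([mr_mode()]). Methods whose instrument-count minimum is not met (Egger,
#' median and modes need 3) are skipped with a warning rather than failing the
#' whole fit.
#'
#' @param h a `harmonized_set` (from [harmonize()] or [new_harmonized_set()]).
#' @param methods character vector of estimators to fit.
#' @param ivw_model `"multiplicative_random"` or `"fixed"`, passed to
#'   [mr_ivw()].
#' @param n_boot,seed bootstrap settings for the median and mode estimators.
#' @param phi mode bandwidth multiplier.
#' @return An object of class `mr_fit`: list with `estimates` (one-row-per-
#'   method data.frame), `details` (the underlying `mr_estimate` objects),
#'   `harmonized` (the input set) and `call`. Supports `print`, `summary`,
#'   `coef`, `confint`, `plot` and `residuals`.
#' @examples
#' h <- new_harmonized_set(data.frame(
#'   rsid = paste0("rs", 1:5),
#'   beta_exp = c(0.12, 0.09, 0.15, 0.11, 0.08), se_exp = 0.01,
#'   beta_out = c(0.036, 0.027, 0.045, 0.033, 0.024), se_out = 0.02))
#' fit <- mr_fit(h, n_boot = 100)
#' coef(fit)
#' @export
mr_fit <- function(h,
                   methods = c("ivw", "egger", "weighted_median",
                               "simple_mode", "weighted_mode"),
                   ivw_model = "multiplicative_random",
                   n_boot = 1000, seed = 1, phi = 1.0) {
  stopifnot(inherits(h, "harmonized_set"))
  methods <- match.arg(methods, several.ok = TRUE)
  details <- list()
  for (m in methods) {
    est <- tryCatch(switch(m,
      ivw             = mr_ivw(h, model = ivw_model),
      egger           = mr_egger(h),
      weighted_median = mr_weighted_median(h, n_boot = n_boot, seed = seed),
      simple_mode     = mr_mode(h, weighted = FALSE, phi = phi,
                                n_boot = n_boot, seed = seed),
      weighted_mode   = mr_mode(h, weighted = TRUE, phi = phi,
                                n_boot = n_boot, seed = seed)
    ), error = function(e) {
      warning("method '", m, "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(est)) details[[m]] <- est
  }
  if (!length(details)) stop("no estimator could be fitted")
  estimates <- do.call(rbind, lapply(details, function(e) {
    data.frame(method = e$method, n_snp = e$n_snp, beta = e$beta, se = e$se,
               pval = e$pval, or = e$or, ci_low = e$ci_low,
               ci_high = e$ci_high, stringsAsFactors = FALSE)
  }))
  rownames(estimates) <- NULL
  structure(list(estimates = estimates, details = details, harmonized = h,
                 call = match.call()),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR fit: %s -> %s (%d instruments)\n",
              x$harmonized$exposure_id, x$harmonized$outcome_id,
              nrow(x$harmonized$rows)))
  tab <- x$estimates
  tab$`OR(95%CI)` <- fmt_or_ci(tab$or, tab$ci_low, tab$ci_high)
  tab$pval <- signif(tab$pval, 3)
  print(data.frame(method = tab$method, n_snp = tab$n_snp,
                   beta = round(tab$beta, digits), se = round(tab$se, digits),
                   pval = tab$pval, `OR(95%CI)` = tab$`OR(95%CI)`,
                   check.names = FALSE), row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  out <- list(fit = object,
              strength = instrument_strength(object$harmonized),
              q = if (nrow(object$harmonized$rows) >= 2)
                cochran_q(object$harmonized) else NULL)
  class(out) <- "summary.mr_fit"
  out
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nMean instrument F-statistic: %.1f\n", x$strength$mean_f))
  if (!is.null(x$q))
    cat(sprintf("Cochran Q = %.2f on %d df, p = %.3g\n",
                x$q$q_stat, x$q$df, x$q$q_pval))
  eg <- x$fit$details$egger
  if (!is.null(eg))
    cat(sprintf("Egger intercept = %.4f (se %.4f), p = %.3g\n",
                eg$egger_intercept, eg$egger_intercept_se,
                eg$egger_intercept_pval))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$estimates
  out <- cbind(est$beta - z * est$se, est$beta + z * est$se)
  dimnames(out) <- list(est$method,
                        sprintf("%.1f %%", c((1 - level) / 2,
                                             1 - (1 - level) / 2) * 100))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
residuals.mr_fit <- function(object, method = "ivw", ...) {
  est <- object$details[[method]]
  if (is.null(est)) stop("method '", method, "' was not fitted")
  r <- object$harmonized$rows
  intercept <- if (!is.na(est$egger_intercept)) est$egger_intercept else 0
  stats::setNames(r$beta_out - intercept - est$beta * r$beta_exp, r$rsid)
}

#' @export
plot.mr_fit <- function(x, ...) {
  r <- x$harmonized$rows
  graphics::plot(r$beta_exp, r$beta_out,
                 xlab = sprintf("SNP effect on %s", x$harmonized$exposure_id),
                 ylab = sprintf("SNP effect on %s", x$harmonized$outcome_id),
                 pch = 19, ...)
  graphics::segments(r$beta_exp, r$beta_out - CI_Z * r$se_out,
                     r$beta_exp, r$beta_out + CI_Z * r$se_out,
                     col = "grey60")
  cols <- stats::setNames(seq_len(nrow(x$estimates)) + 1, x$estimates$method)
  for (m in x$estimates$method) {
    e <- x$details[[m]]
    a <- if (!is.na(e$egger_intercept)) e$egger_intercept else 0
    graphics::abline(a = a, b = e$beta, col = cols[[m]], lty = 2)
  }
  graphics::legend("topleft", legend = names(cols), col = cols, lty = 2,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Estimates table in the conventional reporting format
#'
#' Flattens one or more fits into a table mirroring the usual publication
#' layout: exposure, outcome, method, number of instruments, p-value and
#' `OR(95%CI)` formatted as `"x.xxx(a.aaa-b.bbb)"`.
#'
#' @param ... `mr_fit` objects (or a single list of them).
#' @return A data.frame, one row per (fit, method).
#' @export
mr_table <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "mr_fit")) fits <- fits[[1]]
  do.call(rbind, lapply(fits, function(f) {
    stopifnot(inherits(f, "mr_fit"))
    est <- f$estimates
    data.frame(exposure = f$harmonized$exposure_id,
               outcome = f$harmonized$outcome_id,
               method = est$method, n_snp = est$n_snp,
               pval = est$pval,
               `OR(95%CI)` = fmt_or_ci(est$or, est$ci_low, est$ci_high),
               beta = est$beta, se = est$se,
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
}
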