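# Two-step MR mediation: total, step-wise, mediated and direct effects and
# the mediated proportion.

#' Two-step MR mediation decomposition
#'
#' Combines three IVW estimates — the total effect of the exposure on the
#' outcome (`alpha_total`), the exposure's effect on the mediator (`alpha_1`)
#' and the mediator's effect on the outcome (`alpha_2`) — by the
#' product-of-coefficients method:
#' `alpha_mediated = alpha_1 * alpha_2`,
#' `alpha_direct = alpha_total - alpha_mediated`, and the mediated proportion
#' `alpha_mediated / alpha_total * 100` (percent). The mediated effect's
#' standard error is the first-order delta method,
#' `sqrt(alpha_1^2 se_2^2 + alpha_2^2 se_1^2)`; set `second_order = TRUE` to
#' add the `se_1^2 se_2^2` term. Its 95% interval is
#' `alpha_mediated -/+ 1.96 se`. No interval is propagated onto the
#' proportion (ratio intervals are unstable when the total effect is small).
#' When `alpha_total` is zero the proportion is undefined and reported `NA`;
#' all other fields are still returned.
#'
#' @param total,step1,step2 `mr_estimate` objects (or lists with finite
#'   `beta` and `se`) for the exposure->outcome, exposure->mediator and
#'   mediator->outcome effects.
#' @param second_order include the second-order delta-method term?
#' @return An object of class `mr_mediation` with fields `alpha_total`,
#'   `alpha_1`, `alpha_2`, `alpha_mediated`, `se_mediated`, `ci_mediated`,
#'   `alpha_direct`, `proportion_mediated` (percent, `NA` when undefined).
#' @export
two_step_mediation <- function(total, step1, step2, second_order = FALSE) {
  grab <- function(e) {
    stopifnot(is.list(e), is_scalar_number(e$beta), is_scalar_number(e$se))
    c(e$beta, e$se)
  }
  tt <- grab(total); s1 <- grab(step1); s2 <- grab(step2)
  a_total <- tt[1]; a1 <- s1[1]; a2 <- s2[1]
  a_med <- a1 * a2
  se_med <- sqrt(a1^2 * s2[2]^2 + a2^2 * s1[2]^2 +
                   if (second_order) s1[2]^2 * s2[2]^2 else 0)
  structure(list(
    alpha_total = a_total, se_total = tt[2],
    alpha_1 = a1, se_1 = s1[2],
    alpha_2 = a2, se_2 = s2[2],
    alpha_mediated = a_med, se_mediated = se_med,
    ci_mediated = c(a_med - CI_Z * se_med, a_med + CI_Z * se_med),
    alpha_direct = a_total - a_med,
    proportion_mediated = if (a_total == 0) NA_real_ else 100 * a_med / a_total
  ), class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat("Two-step MR mediation\n")
  cat(sprintf("  total effect      alpha_total    = %8.4f (se %.4f)\n",
              x$alpha_total, x$se_total))
  cat(sprintf("  exposure->mediator alpha_1       = %8.4f (se %.4f)\n",
              x$alpha_1, x$se_1))
  cat(sprintf("  mediator->outcome  alpha_2       = %8.4f (se %.4f)\n",
              x$alpha_2, x$se_2))
  cat(sprintf("  mediated effect   alpha_mediated = %8.4f (95%% CI %.4f to %.4f)\n",
              x$alpha_mediated, x$ci_mediated[1], x$ci_mediated[2]))
  cat(sprintf("  direct effect     alpha_direct   = %8.4f\n", x$alpha_direct))
  if (is.na(x$proportion_mediated)) {
    cat("  proportion mediated: undefined (alpha_total = 0)\n")
  } else {
    cat(sprintf("  proportion mediated: %.2f%% of the total effect\n",
                x$proportion_mediated))
  }
  if (!is.null(x$legs)) {
    cat("  instruments per leg:",
        paste(sprintf("%s=%d", names(x$legs), unlist(x$legs)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Full mediation pipeline from summary statistics
#'
#' Runs select -> clump -> harmonize -> IVW for each of the three legs
#' (instruments re-selected for whichever trait plays the exposure role):
#' exposure->outcome (total), exposure->mediator (step 1) and
#' mediator->outcome (step 2), then combines them with
#' [two_step_mediation()]. The returned object carries a provenance report of
#' instrument counts per leg.
#'
#' @param exposure,mediator,outcome [summary_stats] objects.
#' @param p_threshold instrument-selection threshold.
#' @param r2_threshold,window_kb,ld clumping settings ([clump()]).
#' @param palindrome_eaf_window see [harmonize()].
#' @param second_order see [two_step_mediation()].
#' @return An `mr_mediation` with elements `legs` (instrument counts) and
#'   `fits` (the three IVW `mr_estimate`s).
#' @export
mediation_pipeline <- function(exposure, mediator, outcome,
                               p_threshold = 1e-5, r2_threshold = 0.001,
                               window_kb = 10000, ld = NULL,
                               palindrome_eaf_window = c(0.40, 0.60),
                               second_order = FALSE) {
  leg <- function(exp_stats, out_stats, name) {
    iv <- select_instruments(exp_stats, p_threshold)
    if (!length(iv))
      stop("no instruments at p < ", p_threshold, " for leg ", name)
    iv <- clump(exp_stats, iv, r2_threshold, window_kb, ld)
    h <- tryCatch(harmonize(exp_stats, out_stats, iv, palindrome_eaf_window),
                  error = function(e)
                    stop("harmonization failed for leg ", name, ": ",
                         conditionMessage(e), call. = FALSE))
    if (nrow(h$rows) == 0L)
      stop("no instruments survived harmonization for leg ", name)
    mr_ivw(h)
  }
  total <- leg(exposure, outcome, "exposure->outcome")
  step1 <- leg(exposure, mediator, "exposure->mediator")
  step2 <- leg(mediator, outcome, "mediator->outcome")
  out <- two_step_mediation(total, step1, step2, second_order = second_order)
  out$legs <- list("exposure->outcome" = total$n_snp,
                   "exposure->mediator" = step1$n_snp,
                   "mediator->outcome" = step2$n_snp)
  out$fits <- list(total = total, step1 = step1, step2 = step2)
  out
}

#' Serialize a mediation result to a one-row TSV
#'
#' @param x an `mr_mediation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mediation <- function(x, path) {
  stopifnot(inherits(x, "mr_mediation"))
  df <- data.frame(alpha_total = x$alpha_total, alpha_1 = x$alpha_1,
                   alpha_2 = x$alpha_2, alpha_mediated = x$alpha_mediated,
                   se_mediated = x$se_mediated,
                   ci_low = x$ci_mediated[1], ci_high = x$ci_mediated[2],
                   alpha_direct = x$alpha_direct,
                   proportion_pct = x$proportion_mediated)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
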