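# Orchestration of the end-to-end screen: forward MR over many exposures,
# reverse-MR filter, mediator screen, mediation; plus the H-score utility.

#' Forward + reverse MR screen over many exposures
#'
#' For every exposure: select and clump instruments, harmonize against the
#' outcome, and fit the forward IVW estimate. Exposures passing the forward
#' threshold (`p < p_forward`, strict) additionally get a reverse-MR fit with
#' the outcome as instrument source; they pass the reverse filter when the
#' reverse p-value exceeds `reverse_alpha` (no evidence of reverse causality).
#' Exposures whose reverse analysis is untestable (no outcome instruments)
#' are excluded, not passed. Exposures with no usable instruments are
#' reported as untestable rather than dropped silently, so every input
#' appears in the output exactly once. No multiple-testing correction is
#' applied (the screen operates on raw p-values; set `fdr = TRUE` to append
#' Benjamini-Hochberg adjusted forward p-values as an extra column).
#'
#' @param exposures named list of [summary_stats] objects.
#' @param outcome a [summary_stats].
#' @param p_forward forward screening threshold (strict inequality).
#' @param p_instrument instrument-selection threshold for both directions.
#' @param reverse_alpha reverse-causality retention level.
#' @param r2_threshold,window_kb,ld clumping settings.
#' @param palindrome_eaf_window see [harmonize()].
#' @param fdr append BH-adjusted forward p-values?
#' @return A data.frame of class `mr_screen`, one row per exposure, sorted by
#'   forward p ascending (untestable rows last): `exposure_id, status, n_snp,
#'   beta, se, pval, or, ci_low, ci_high, classification, reverse_pval,
#'   passes_forward, passes_reverse`. Thresholds are attached as attributes.
#' @export
screen_exposures <- function(exposures, outcome, p_forward = 0.01,
                             p_instrument = 1e-5, reverse_alpha = 0.05,
                             r2_threshold = 0.001, window_kb = 10000,
                             ld = NULL,
                             palindrome_eaf_window = c(0.40, 0.60),
                             fdr = FALSE) {
  stopifnot(is.list(exposures), length(exposures) >= 1)
  ids <- names(exposures) %||% vapply(exposures, trait_id, character(1))
  if (is.null(names(exposures))) names(exposures) <- ids

  rows <- lapply(ids, function(id) {
    ex <- exposures[[id]]
    fit <- tryCatch({
      iv <- select_instruments(ex, p_instrument)
      if (!length(iv)) stop("no instruments")
      iv <- clump(ex, iv, r2_threshold, window_kb, ld)
      h <- harmonize(ex, outcome, iv, palindrome_eaf_window)
      if (nrow(h$rows) == 0L) stop("no instruments survived harmonization")
      mr_ivw(h)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(exposure_id = id, status = "untestable",
                        n_snp = 0L, beta = NA_real_, se = NA_real_,
                        pval = NA_real_, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, classification = NA_character_,
                        reverse_pval = NA_real_, passes_forward = NA,
                        passes_reverse = NA, stringsAsFactors = FALSE))
    }
    passes_forward <- fit$pval < p_forward
    reverse_pval <- NA_real_
    passes_reverse <- NA
    if (passes_forward) {
      rev <- reverse_mr(outcome, ex, p_instrument, r2_threshold, window_kb,
                        ld, palindrome_eaf_window)
      if (inherits(rev, "mr_untestable")) {
        passes_reverse <- FALSE    # conservative: untestable is excluded
      } else {
        reverse_pval <- rev$pval
        passes_reverse <- rev$pval > reverse_alpha
      }
    }
    data.frame(exposure_id = id, status = "ok", n_snp = fit$n_snp,
               beta = fit$beta, se = fit$se, pval = fit$pval, or = fit$or,
               ci_low = fit$ci_low, ci_high = fit$ci_high,
               classification = if (fit$or > 1) "risk" else "protective",
               reverse_pval = reverse_pval,
               passes_forward = passes_forward,
               passes_reverse = passes_reverse,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(is.na(out$pval), out$pval, out$exposure_id), , drop = FALSE]
  rownames(out) <- NULL
  if (fdr) out$pval_fdr <- stats::p.adjust(out$pval, method = "BH")
  structure(out,
            class = c("mr_screen", "data.frame"),
            thresholds = list(p_forward = p_forward,
                              p_instrument = p_instrument,
                              reverse_alpha = reverse_alpha))
}

#' @export
print.mr_screen <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf("Exposure screen: %d exposures (forward p < %g, instruments p < %g, reverse retention p > %g)\n",
              nrow(x), th$p_forward, th$p_instrument, th$reverse_alpha))
  cat(sprintf("  forward passes: %d | forward+reverse passes: %d | untestable: %d\n",
              sum(x$passes_forward, na.rm = TRUE),
              sum(x$passes_forward & x$passes_reverse, na.rm = TRUE),
              sum(x$status == "untestable")))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE,
                   digits = 3)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Mediator screen
#'
#' For each candidate mediator, fits the mediator->outcome IVW estimate;
#' survivors (`p < p_mediator`, strict) get the exposure->mediator leg with
#' all five estimators. A candidate passes when that leg's IVW p-value is
#' below 0.05 **and** all five estimates agree in direction
#' ([direction_consistency()]). Candidates are ranked by the
#' mediator->outcome p-value.
#'
#' @param mediators named list of [summary_stats].
#' @param exposure,outcome [summary_stats] objects.
#' @param p_mediator mediator->outcome screening threshold.
#' @param p_instrument,r2_threshold,window_kb,ld,palindrome_eaf_window as in
#'   [screen_exposures()].
#' @param n_boot,seed bootstrap settings for the five-method leg.
#' @return A data.frame of class `mr_mediator_screen`, one row per mediator,
#'   candidates first (ranked by `step2_pval`): `mediator_id, status,
#'   step2_n_snp, step2_beta, step2_pval, step2_or, step1_ivw_pval,
#'   direction_consistent, candidate`.
#' @export
screen_mediators <- function(mediators, exposure, outcome, p_mediator = 0.05,
                             p_instrument = 1e-5, r2_threshold = 0.001,
                             window_kb = 10000, ld = NULL,
                             palindrome_eaf_window = c(0.40, 0.60),
                             n_boot = 500, seed = 1) {
  stopifnot(is.list(mediators), length(mediators) >= 1)
  ids <- names(mediators) %||% vapply(mediators, trait_id, character(1))
  if (is.null(names(mediators))) names(mediators) <- ids

  fit_leg <- function(exp_stats, out_stats) {
    iv <- select_instruments(exp_stats, p_instrument)
    if (!length(iv)) stop("no instruments")
    iv <- clump(exp_stats, iv, r2_threshold, window_kb, ld)
    h <- harmonize(exp_stats, out_stats, iv, palindrome_eaf_window)
    if (nrow(h$rows) == 0L) stop("no instruments survived harmonization")
    h
  }

  rows <- lapply(ids, function(id) {
    md <- mediators[[id]]
    base <- data.frame(mediator_id = id, status = "ok", step2_n_snp = NA_integer_,
                       step2_beta = NA_real_, step2_pval = NA_real_,
                       step2_or = NA_real_, step1_ivw_pval = NA_real_,
                       direction_consistent = NA, candidate = FALSE,
                       stringsAsFactors = FALSE)
    step2 <- tryCatch(mr_ivw(fit_leg(md, outcome)), error = function(e) NULL)
    if (is.null(step2)) { base$status <- "untestable"; return(base) }
    base$step2_n_snp <- step2$n_snp
    base$step2_beta <- step2$beta
    base$step2_pval <- step2$pval
    base$step2_or <- step2$or
    if (step2$pval >= p_mediator) return(base)
    step1 <- tryCatch({
      h1 <- fit_leg(exposure, md)
      mr_fit(h1, n_boot = n_boot, seed = seed)
    }, error = function(e) NULL)
    if (is.null(step1) || nrow(step1$estimates) < 5) {
      base$status <- "step1_untestable"
      return(base)
    }
    base$step1_ivw_pval <- step1$details$ivw$pval
    base$direction_consistent <- direction_consistency(step1)
    base$candidate <- base$direction_consistent && base$step1_ivw_pval < 0.05
    base
  })
  out <- do.call(rbind, rows)
  out <- out[order(!out$candidate, out$step2_pval, out$mediator_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("mr_mediator_screen", "data.frame"),
            thresholds = list(p_mediator = p_mediator,
                              p_instrument = p_instrument))
}

#' @export
print.mr_mediator_screen <- function(x, ...) {
  n_cand <- sum(x$candidate, na.rm = TRUE)
  cat(sprintf("Mediator screen: %d candidates evaluated\n", nrow(x)))
  if (n_cand == 0) {
    cat("  no mediator passed both filters\n")
  } else {
    cat(sprintf("  %d candidate mediator(s); top: %s (step2 p = %.3g)\n",
                n_cand, x$mediator_id[1], x$step2_pval[1]))
  }
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE,
                   digits = 3)
  invisible(x)
}

#' End-to-end screening pipeline
#'
#' Runs the full chain: forward MR over all exposures with the reverse-MR
#' filter ([screen_exposures()]); for the top-ranked passing exposure, the
#' mediator screen ([screen_mediators()]); and for the top (exposure,
#' mediator) pair, the two-step mediation decomposition
#' ([mediation_pipeline()]).
#'
#' @param exposures,mediators named lists of [summary_stats].
#' @param outcome a [summary_stats].
#' @param p_forward,p_mediator stage thresholds.
#' @param p_instrument instrument-selection threshold.
#' @param reverse_alpha reverse-causality retention level.
#' @param r2_threshold,window_kb,ld,palindrome_eaf_window clumping and
#'   harmonization settings.
#' @param n_boot,seed bootstrap settings for the five-method mediator leg.
#' @return List of class `mr_screen_result`: `exposures` (screen table),
#'   `mediators` (mediator table or NULL), `top` (list with `exposure` and
#'   `mediator` ids, NULL when nothing passed) and `mediation`
#'   (an `mr_mediation` or NULL).
#' @export
screen_pipeline <- function(exposures, mediators, outcome, p_forward = 0.01,
                            p_mediator = 0.05, p_instrument = 1e-5,
                            reverse_alpha = 0.05, r2_threshold = 0.001,
                            window_kb = 10000, ld = NULL,
                            palindrome_eaf_window = c(0.40, 0.60),
                            n_boot = 500, seed = 1) {
  ex <- screen_exposures(exposures, outcome, p_forward = p_forward,
                         p_instrument = p_instrument,
                         reverse_alpha = reverse_alpha,
                         r2_threshold = r2_threshold, window_kb = window_kb,
                         ld = ld,
                         palindrome_eaf_window = palindrome_eaf_window)
  hits <- ex[!is.na(ex$passes_forward) & ex$passes_forward &
               !is.na(ex$passes_reverse) & ex$passes_reverse, , drop = FALSE]
  out <- list(exposures = ex, mediators = NULL, top = NULL, mediation = NULL)
  class(out) <- "mr_screen_result"
  if (!nrow(hits)) return(out)
  top_exp <- hits$exposure_id[1]
  md <- screen_mediators(mediators, exposures[[top_exp]], outcome,
                         p_mediator = p_mediator,
                         p_instrument = p_instrument,
                         r2_threshold = r2_threshold, window_kb = window_kb,
                         ld = ld,
                         palindrome_eaf_window = palindrome_eaf_window,
                         n_boot = n_boot, seed = seed)
  out$mediators <- md
  cand <- md[md$candidate, , drop = FALSE]
  if (!nrow(cand)) { out$top <- list(exposure = top_exp, mediator = NULL); return(out) }
  top_med <- cand$mediator_id[1]
  out$top <- list(exposure = top_exp, mediator = top_med)
  out$mediation <- tryCatch(
    mediation_pipeline(exposures[[top_exp]], mediators[[top_med]], outcome,
                       p_threshold = p_instrument,
                       r2_threshold = r2_threshold, window_kb = window_kb,
                       ld = ld,
                       palindrome_eaf_window = palindrome_eaf_window),
    error = function(e) NULL)
  out
}

#' @export
print.mr_screen_result <- function(x, ...) {
  print(x$exposures)
  if (is.null(x$top)) {
    cat("\nNo exposure passed the forward and reverse filters.\n")
    return(invisible(x))
  }
  cat("\nTop exposure:", x$top$exposure, "\n")
  if (!is.null(x$mediators)) print(x$mediators)
  if (is.null(x$top$mediator)) {
    cat("\nNo mediator passed both filters.\n")
  } else {
    cat("\nTop pair:", x$top$exposure, "->", x$top$mediator, "\n")
    if (!is.null(x$mediation)) print(x$mediation)
  }
  invisible(x)
}

#' Immunostaining H-score
#'
#' The semi-quantitative histochemistry score
#' `H = 1 x %weak + 2 x %moderate + 3 x %strong`, ranging 0 (all cells
#' unstained) to 300 (all cells strongly stained). The three percentages must
#' each lie in \[0, 100\] and sum to at most 100 (the remainder is unstained).
#'
#' @param pct_weak,pct_moderate,pct_strong percentages of weakly, moderately
#'   and strongly stained cells.
#' @return An object of class `h_score` with fields `pct_weak`,
#'   `pct_moderate`, `pct_strong` and `score`.
#' @export
h_score <- function(pct_weak, pct_moderate, pct_strong) {
  for (p in list(pct_weak, pct_moderate, pct_strong)) {
    if (!is_scalar_number(p) || p < 0 || p > 100)
      stop("each staining percentage must be a number in [0, 100]")
  }
  if (pct_weak + pct_moderate + pct_strong > 100 + 1e-9)
    stop("staining percentages sum to more than 100")
  structure(list(pct_weak = pct_weak, pct_moderate = pct_moderate,
                 pct_strong = pct_strong,
                 score = pct_weak + 2 * pct_moderate + 3 * pct_strong),
            class = "h_score")
}

#' @export
print.h_score <- function(x, ...) {
  cat(sprintf("H-score = %.1f (weak %.0f%%, moderate %.0f%%, strong %.0f%%)\n",
              x$score, x$pct_weak, x$pct_moderate, x$pct_strong))
  invisible(x)
}
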