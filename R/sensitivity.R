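# Leave-one-out analysis, reverse-MR screening, and the five-method
# direction-consistency filter.

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW causal effect after removing each instrument in turn.
#' An instrument is flagged influential when its removal changes the sign of
#' the estimate or moves it outside the 95% confidence interval of the
#' full-set estimate (the reproducible operationalization of "no single SNP
#' had a substantial influence").
#'
#' @param h a `harmonized_set` with at least 2 instruments.
#' @param model IVW variant, passed to [mr_ivw()].
#' @return An object of class `mr_loo`: list with `results` (data.frame
#'   `dropped_rsid, n_snp, beta, se, ci_low, ci_high, flag_influential`, CI on
#'   the log scale), `full` (the all-instrument `mr_estimate`) and
#'   `influential` (flagged rsids).
#' @export
leave_one_out <- function(h, model = "multiplicative_random") {
  stopifnot(inherits(h, "harmonized_set"))
  n <- nrow(h$rows)
  if (n < 2) stop("leave-one-out requires at least 2 instruments (got ", n, ")")
  full <- mr_ivw(h, model = model)
  lo <- full$beta - CI_Z * full$se
  hi <- full$beta + CI_Z * full$se
  res <- lapply(seq_len(n), function(i) {
    sub <- new_harmonized_set(h$rows[-i, , drop = FALSE],
                              h$exposure_id, h$outcome_id)
    est <- mr_ivw(sub, model = model)
    data.frame(dropped_rsid = h$rows$rsid[i], n_snp = est$n_snp,
               beta = est$beta, se = est$se,
               ci_low = est$beta - CI_Z * est$se,
               ci_high = est$beta + CI_Z * est$se,
               flag_influential =
                 sign(est$beta) != sign(full$beta) ||
                 est$beta < lo || est$beta > hi,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  structure(list(results = res, full = full,
                 influential = res$dropped_rsid[res$flag_influential]),
            class = "mr_loo")
}

#' @export
print.mr_loo <- function(x, ...) {
  cat(sprintf("Leave-one-out IVW analysis over %d instruments\n",
              nrow(x$results)))
  cat(sprintf("  full estimate: beta = %.4f (se %.4f)\n",
              x$full$beta, x$full$se))
  if (length(x$influential)) {
    cat("  influential instruments:",
        paste(x$influential, collapse = ", "), "\n")
  } else {
    cat("  no single instrument is influential\n")
  }
  invisible(x)
}

#' Export a leave-one-out analysis as forest-plot-ready TSV
#'
#' @param loo an `mr_loo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loo <- function(loo, path) {
  stopifnot(inherits(loo, "mr_loo"))
  utils::write.table(loo$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Reverse Mendelian randomization
#'
#' Tests the reverse causal direction by swapping the roles: instruments are
#' selected from the disease (outcome) GWAS at `p_threshold`, harmonized
#' against the exposure GWAS, and the IVW estimate of disease -> exposure is
#' returned. In a screen, exposures whose reverse p-value exceeds 0.05 are
#' retained (no evidence of reverse causality). When no variant in the
#' disease GWAS reaches the instrument threshold — common for rare outcomes —
#' the result is an explicit `mr_untestable` object, not an estimate.
#'
#' @param outcome_stats the disease GWAS (instrument source).
#' @param exposure_stats the trait GWAS the reverse effect is estimated on.
#' @param p_threshold instrument-selection threshold.
#' @param r2_threshold,window_kb,ld clumping settings, see [clump()].
#' @param palindrome_eaf_window see [harmonize()].
#' @return An `mr_estimate` (IVW, disease as exposure) or an `mr_untestable`
#'   object with a `reason` field.
#' @export
reverse_mr <- function(outcome_stats, exposure_stats, p_threshold = 1e-5,
                       r2_threshold = 0.001, window_kb = 10000, ld = NULL,
                       palindrome_eaf_window = c(0.40, 0.60)) {
  iv <- select_instruments(outcome_stats, p_threshold)
  untestable <- function(reason) {
    structure(list(exposure_id = trait_id(outcome_stats),
                   outcome_id = trait_id(exposure_stats),
                   reason = reason),
              class = "mr_untestable")
  }
  if (!length(iv)) return(untestable("no_instruments"))
  iv <- clump(outcome_stats, iv, r2_threshold, window_kb, ld)
  h <- tryCatch(harmonize(outcome_stats, exposure_stats, iv,
                          palindrome_eaf_window),
                error = function(e) NULL)
  if (is.null(h) || nrow(h$rows) == 0L)
    return(untestable("no_shared_instruments"))
  mr_ivw(h)
}

#' @export
print.mr_untestable <- function(x, ...) {
  cat(sprintf("MR untestable (%s -> %s): %s\n",
              x$exposure_id, x$outcome_id, x$reason))
  invisible(x)
}

#' Direction consistency across the five estimators
#'
#' TRUE iff all five methods (ivw, egger, weighted_median, simple_mode,
#' weighted_mode) agree on the sign of the causal estimate — equivalently,
#' all odds ratios fall on the same side of 1. A zero estimate counts as
#' inconsistent. The result does not depend on the order of the estimates.
#'
#' @param x an [mr_fit()] containing all five methods, or a list of five
#'   `mr_estimate` objects.
#' @return Logical flag.
#' @export
direction_consistency <- function(x) {
  ests <- if (inherits(x, "mr_fit")) x$details else x
  stopifnot(is.list(ests))
  required <- c("ivw", "egger", "weighted_median", "simple_mode",
                "weighted_mode")
  methods <- vapply(ests, function(e) e$method, character(1))
  missing <- setdiff(required, methods)
  if (length(missing))
    stop("missing method(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(methods, required)
  if (length(extra))
    stop("unexpected method(s): ", paste(extra, collapse = ", "))
  betas <- vapply(ests, function(e) e$beta, numeric(1))
  all(betas > 0) || all(betas < 0)
}
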