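#' Select genetic instruments by p-value threshold
#'
#' Returns the identifiers of all variants associated with the trait below the
#' significance threshold, sorted by p-value ascending (ties broken by rsid).
#' The conventional threshold for these screens is `p < 1e-5`.
#'
#' @param stats a [summary_stats] object.
#' @param p_threshold strict upper bound on the association p-value.
#' @return Character vector of rsids; may be empty.
#' @export
select_instruments <- function(stats, p_threshold = 1e-5) {
  stopifnot(inherits(stats, "summary_stats"), nrow(stats) > 0,
            is_scalar_number(p_threshold))
  hit <- stats$pval < p_threshold
  df <- stats[hit, c("rsid", "pval")]
  df <- df[order(df$pval, df$rsid), , drop = FALSE]
  df$rsid
}

#' Greedy LD clumping
#'
#' Iterates the selected variants in p-ascending order (ties broken by rsid)
#' and retains a variant unless it lies within `window_kb` of an already
#' retained variant on the same chromosome with squared correlation at or
#' above `r2_threshold`. With no LD provider, clumping is distance-only: any
#' same-chromosome variant within the window is removed. Defaults mirror the
#' de facto standard for two-sample MR (r2 = 0.001, 10,000 kb window).
#'
#' @param stats the [summary_stats] the candidates were selected from
#'   (provides chromosome, position and p-value).
#' @param selected character vector of candidate rsids, all present in `stats`.
#' @param r2_threshold squared-correlation threshold.
#' @param window_kb clumping window in kilobases.
#' @param ld optional pairwise-correlation provider: a function
#'   `(rsid_a, rsid_b) -> r^2`.
#' @return Character vector of retained rsids in p-ascending order.
#' @export
clump <- function(stats, selected, r2_threshold = 0.001, window_kb = 10000,
                  ld = NULL) {
  stopifnot(inherits(stats, "summary_stats"))
  if (!length(selected)) return(character(0))
  unknown <- setdiff(selected, stats$rsid)
  if (length(unknown))
    stop("unknown rsid(s): ", paste(unknown, collapse = ", "))
  df <- as.data.frame(stats)[match(selected, stats$rsid),
                             c("rsid", "chrom", "pos", "pval")]
  df <- df[order(df$pval, df$rsid), , drop = FALSE]
  window_bp <- window_kb * 1000
  kept <- integer(0)
  for (i in seq_len(nrow(df))) {
    conflict <- FALSE
    for (k in kept) {
      if (df$chrom[i] == df$chrom[k] &&
          abs(df$pos[i] - df$pos[k]) <= window_bp) {
        r2 <- if (is.null(ld)) 1 else ld(df$rsid[i], df$rsid[k])
        if (r2 >= r2_threshold) { conflict <- TRUE; break }
      }
    }
    if (!conflict) kept <- c(kept, i)
  }
  df$rsid[kept]
}

# Strand-ambiguous single-base pair?
.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome effect alleles
#'
#' Aligns the outcome association of every instrument to the exposure's
#' effect allele. For each instrument present in both sets: if the alleles
#' match directly the row is kept as is; if they match after swapping effect
#' and other allele, the outcome beta is negated (and its allele frequency
#' reflected) and the row flagged `flipped`; strand-ambiguous (A/T or C/G)
#' variants are aligned by allele frequency when both frequencies are
#' informative, and dropped as `palindromic_ambiguous` when either frequency
#' is missing or falls inside `palindrome_eaf_window`; irreconcilable alleles
#' are dropped as `allele_mismatch`. Instruments absent from the outcome are
#' dropped as `missing_in_outcome`.
#'
#' @param exposure,outcome [summary_stats] objects.
#' @param instruments character vector of instrument rsids, all present in
#'   `exposure` (typically from [select_instruments()] + [clump()]).
#' @param palindrome_eaf_window frequency interval inside which a palindromic
#'   variant's strand cannot be resolved.
#' @return A `harmonized_set`: list with `exposure_id`, `outcome_id`, `rows`
#'   (data.frame `rsid, beta_exp, se_exp, beta_out, se_out, eaf, flipped`,
#'   sorted by rsid) and `dropped` (data.frame `rsid, reason`).
#' @export
harmonize <- function(exposure, outcome, instruments,
                      palindrome_eaf_window = c(0.40, 0.60)) {
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"),
            is.character(instruments))
  missing_in_exp <- setdiff(instruments, exposure$rsid)
  if (length(missing_in_exp))
    stop("instrument(s) not present in exposure: ",
         paste(missing_in_exp, collapse = ", "))
  if (!length(intersect(instruments, outcome$rsid)) &&
      length(instruments) > 0)
    stop("no shared instruments between exposure and outcome")
  if (!length(instruments)) stop("no instruments supplied")

  lo <- palindrome_eaf_window[1]; hi <- palindrome_eaf_window[2]
  rows <- list(); dropped <- list()
  for (rs in sort(instruments)) {
    e <- exposure[exposure$rsid == rs, ]
    if (!rs %in% outcome$rsid) {
      dropped[[rs]] <- "missing_in_outcome"; next
    }
    o <- outcome[outcome$rsid == rs, ]
    pal <- .is_palindromic(e$effect_allele, e$other_allele)
    same_pair_any_order <-
      (o$effect_allele == e$effect_allele && o$other_allele == e$other_allele) ||
      (o$effect_allele == e$other_allele && o$other_allele == e$effect_allele)

    if (pal) {
      if (!same_pair_any_order) { dropped[[rs]] <- "allele_mismatch"; next }
      amb <- function(f) is.na(f) || (f > lo && f < hi)
      if (amb(e$eaf) || amb(o$eaf)) {
        dropped[[rs]] <- "palindromic_ambiguous"; next
      }
      # Strand resolved by frequency: same side of 0.5 means aligned.
      aligned <- sign(e$eaf - 0.5) == sign(o$eaf - 0.5)
      rows[[rs]] <- data.frame(
        rsid = rs, beta_exp = e$beta, se_exp = e$se,
        beta_out = if (aligned) o$beta else -o$beta, se_out = o$se,
        eaf = e$eaf, flipped = !aligned, stringsAsFactors = FALSE)
    } else if (o$effect_allele == e$effect_allele &&
               o$other_allele == e$other_allele) {
      rows[[rs]] <- data.frame(
        rsid = rs, beta_exp = e$beta, se_exp = e$se,
        beta_out = o$beta, se_out = o$se,
        eaf = e$eaf, flipped = FALSE, stringsAsFactors = FALSE)
    } else if (o$effect_allele == e$other_allele &&
               o$other_allele == e$effect_allele) {
      rows[[rs]] <- data.frame(
        rsid = rs, beta_exp = e$beta, se_exp = e$se,
        beta_out = -o$beta, se_out = o$se,
        eaf = e$eaf, flipped = TRUE, stringsAsFactors = FALSE)
    } else {
      dropped[[rs]] <- "allele_mismatch"
    }
  }
  rows_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rsid = character(0), beta_exp = numeric(0), se_exp = numeric(0),
               beta_out = numeric(0), se_out = numeric(0), eaf = numeric(0),
               flipped = logical(0))
  rownames(rows_df) <- NULL
  dropped_df <- data.frame(rsid = names(dropped),
                           reason = unlist(dropped, use.names = FALSE),
                           stringsAsFactors = FALSE)
  new_harmonized_set(rows_df, trait_id(exposure), trait_id(outcome),
                     dropped = dropped_df)
}

#' Construct a harmonized instrument set directly
#'
#' Builds the per-instrument table the estimators consume, for data already
#' aligned to a common effect allele (e.g. hand fixtures or externally
#' harmonized exports).
#'
#' @param rows data.frame with columns `rsid`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`; optional `eaf` and `flipped`.
#' @param exposure_id,outcome_id trait labels.
#' @param dropped optional data.frame `rsid, reason` of excluded variants.
#' @return A `harmonized_set` object.
#' @export
new_harmonized_set <- function(rows, exposure_id = "exposure",
                               outcome_id = "outcome",
                               dropped = data.frame(rsid = character(0),
                                                    reason = character(0))) {
  stopifnot(is.data.frame(rows),
            all(c("rsid", "beta_exp", "se_exp", "beta_out", "se_out") %in%
                  names(rows)))
  if (!"eaf" %in% names(rows)) rows$eaf <- NA_real_
  if (!"flipped" %in% names(rows)) rows$flipped <- FALSE
  if (nrow(rows)) {
    if (any(rows$se_exp <= 0) || any(rows$se_out <= 0))
      stop("all standard errors must be positive")
    rows <- rows[order(rows$rsid), , drop = FALSE]
    rownames(rows) <- NULL
  }
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 rows = rows, dropped = dropped),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized instrument set: %s -> %s\n",
              x$exposure_id, x$outcome_id))
  cat(sprintf("  %d instruments (%d flipped), %d dropped\n",
              nrow(x$rows), sum(x$rows$flipped), nrow(x$dropped)))
  if (nrow(x$dropped)) {
    tab <- table(x$dropped$reason)
    cat("  drop reasons:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of retained instruments in a harmonized set
#'
#' @param h a `harmonized_set`.
#' @return Integer count of harmonized instrument rows.
#' @export
n_instruments <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  nrow(h$rows)
}

#' Per-instrument F-statistics
#'
#' The conventional instrument-strength diagnostic
#' `F_j = (beta_exp_j / se_exp_j)^2`, with its mean across instruments. For a
#' trait with `m` instruments explaining `h2` of the variance in a GWAS of
#' size `n`, the expected mean F is approximately `1 + n * h2 / m`.
#'
#' @param h a `harmonized_set`.
#' @return List with `f` (data.frame `rsid, f_stat`) and `mean_f`.
#' @export
instrument_strength <- function(h) {
  stopifnot(inherits(h, "harmonized_set"), nrow(h$rows) > 0)
  f <- (h$rows$beta_exp / h$rows$se_exp)^2
  list(f = data.frame(rsid = h$rows$rsid, f_stat = f,
                      stringsAsFactors = FALSE),
       mean_f = mean(f))
}

#' Serialize a harmonized set to TSV
#'
#' Writes the instrument table (columns `rsid, beta_exp, se_exp, beta_out,
#' se_out, eaf, flipped`) and, when any variant was excluded, a sidecar
#' `<path>.dropped.tsv` with the drop log.
#'
#' @param h a `harmonized_set`.
#' @param path output path for the instrument table.
#' @return `path`, invisibly.
#' @export
write_harmonized_set <- function(h, path) {
  stopifnot(inherits(h, "harmonized_set"))
  utils::write.table(h$rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(h$dropped))
    utils::write.table(h$dropped, paste0(path, ".dropped.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
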