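#' GWAS summary statistics container
#'
#' Construct a validated set of per-variant association estimates for one
#' trait. Each row is one variant: identifier, chromosome, position, effect
#' and other allele, effect-allele frequency, effect size (`beta`, log-odds
#' for binary traits, trait units for continuous traits), standard error,
#' two-sided p-value and sample sizes. Rows violating the invariants (se > 0,
#' 0 < p <= 1, eaf in \[0,1\] or missing, distinct non-empty alleles, non-empty
#' rsid) are dropped and counted in the attached load report; duplicate rsids
#' are resolved by keeping the record with the smallest p-value.
#'
#' @param data data.frame with columns `rsid`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`; optional `eaf`, `n`, `n_cases`,
#'   `n_controls`. Alleles are uppercased; multi-base (indel-style) alleles are
#'   accepted and are non-palindromic by construction. Positions are 1-based.
#' @param trait_id character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"`. If `NULL`, inferred: binary
#'   iff case/control counts are present.
#' @param provenance free-text source tag.
#' @return An object of class `summary_stats`: the validated data.frame with
#'   attributes `trait_id`, `trait_type`, `provenance` and `load_report`
#'   (counts of rows dropped per reason and duplicate collisions).
#' @export
summary_stats <- function(data, trait_id, trait_type = NULL, provenance = "") {
  stopifnot(is.data.frame(data), is.character(trait_id), length(trait_id) == 1L)
  required <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "pval")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  optional <- c("eaf", "n", "n_cases", "n_controls")
  for (col in optional) if (!col %in% names(data)) data[[col]] <- NA_real_

  df <- data.frame(
    rsid          = as.character(data$rsid),
    chrom         = as.character(data$chrom),
    pos           = as.numeric(data$pos),
    effect_allele = toupper(as.character(data$effect_allele)),
    other_allele  = toupper(as.character(data$other_allele)),
    eaf           = as.numeric(data$eaf),
    beta          = as.numeric(data$beta),
    se            = as.numeric(data$se),
    pval          = as.numeric(data$pval),
    n             = as.numeric(data$n),
    n_cases       = as.numeric(data$n_cases),
    n_controls    = as.numeric(data$n_controls),
    stringsAsFactors = FALSE
  )

  # Binary traits: fill n from the case/control split, flag contradictions.
  have_cc <- !is.na(df$n_cases) & !is.na(df$n_controls)
  fill_n <- have_cc & is.na(df$n)
  df$n[fill_n] <- df$n_cases[fill_n] + df$n_controls[fill_n]
  cc_conflict <- have_cc & !is.na(df$n) &
    abs(df$n_cases + df$n_controls - df$n) > 1e-8

  drop_reasons <- list(
    missing_rsid   = is.na(df$rsid) | df$rsid == "",
    bad_alleles    = is.na(df$effect_allele) | is.na(df$other_allele) |
      df$effect_allele == "" | df$other_allele == "" |
      df$effect_allele == df$other_allele,
    nonpositive_se = is.na(df$se) | df$se <= 0,
    bad_pval       = is.na(df$pval) | df$pval <= 0 | df$pval > 1,
    missing_beta   = is.na(df$beta),
    bad_eaf        = !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1),
    case_control_mismatch = cc_conflict
  )
  bad <- Reduce(`|`, drop_reasons)
  report <- list(
    n_input   = nrow(df),
    n_dropped = sum(bad),
    dropped_by_reason = vapply(drop_reasons, sum, integer(1)),
    n_duplicates = 0L
  )
  df <- df[!bad, , drop = FALSE]

  # Duplicate rsid policy: keep the smallest p-value (ties: smallest se, then
  # first occurrence); log the number of collisions.
  if (anyDuplicated(df$rsid)) {
    ord <- order(df$rsid, df$pval, df$se)
    df <- df[ord, , drop = FALSE]
    dup <- duplicated(df$rsid)
    report$n_duplicates <- sum(dup)
    df <- df[!dup, , drop = FALSE]
  }
  df <- df[order(df$rsid), , drop = FALSE]
  rownames(df) <- NULL
  report$n_kept <- nrow(df)

  if (is.null(trait_type)) {
    trait_type <- if (nrow(df) && any(!is.na(df$n_cases))) "binary" else "continuous"
  }
  trait_type <- match.arg(trait_type, c("continuous", "binary"))
  if (trait_type == "continuous") {
    df$n_cases <- rep(NA_real_, nrow(df))
    df$n_controls <- rep(NA_real_, nrow(df))
  }

  structure(df,
            class = c("summary_stats", "data.frame"),
            trait_id = trait_id,
            trait_type = trait_type,
            provenance = provenance,
            load_report = report)
}

#' @export
print.summary_stats <- function(x, ...) {
  rep <- attr(x, "load_report")
  cat(sprintf("GWAS summary statistics: %s (%s)\n",
              attr(x, "trait_id"), attr(x, "trait_type")))
  cat(sprintf("  %d variants", nrow(x)))
  if (!is.null(rep) && rep$n_dropped > 0)
    cat(sprintf(" (%d rows dropped at load)", rep$n_dropped))
  if (!is.null(rep) && rep$n_duplicates > 0)
    cat(sprintf(" (%d duplicate rsids collapsed)", rep$n_duplicates))
  cat("\n")
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat("  source:", prov, "\n")
  invisible(x)
}

#' Trait accessors
#'
#' @param x a [summary_stats] object.
#' @return The trait identifier / trait type stored on the object.
#' @export
trait_id <- function(x) attr(x, "trait_id")

#' @rdname trait_id
#' @export
trait_type <- function(x) attr(x, "trait_type")

# Column dialects ------------------------------------------------------------

# Canonical -> file column name maps. `alt` is the effect allele in the
# FinnGen export convention.
.dialects <- list(
  generic = c(rsid = "rsid", chrom = "chrom", pos = "pos",
              effect_allele = "effect_allele", other_allele = "other_allele",
              eaf = "eaf", beta = "beta", se = "se", pval = "pval",
              n = "n", n_cases = "n_cases", n_controls = "n_controls"),
  finngen = c(rsid = "rsids", chrom = "#chrom", pos = "pos",
              effect_allele = "alt", other_allele = "ref",
              eaf = "af_alt", beta = "beta", se = "sebeta", pval = "pval")
)

#' Read GWAS summary statistics from delimited text
#'
#' Loads a tab-delimited summary-statistics file (plain or gzip-compressed)
#' under a named column dialect, validates every row, and returns a
#' [summary_stats] object. Rows failing an invariant are dropped and counted
#' in the load report.
#'
#' @param path file path; `.gz` files are decompressed transparently.
#' @param dialect `"generic"`, `"finngen"`, or a named character vector mapping
#'   canonical column names (`rsid`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, optionally `n`, `n_cases`,
#'   `n_controls`) to the file's column names. The FinnGen dialect maps
#'   `#chrom, pos, ref, alt, rsids, af_alt, beta, sebeta, pval` with `alt` as
#'   the effect allele.
#' @param trait_id trait name; defaults to the file name without extension.
#' @param trait_type,provenance passed to [summary_stats].
#' @return A [summary_stats] object.
#' @export
read_summary_stats <- function(path, dialect = "generic", trait_id = NULL,
                               trait_type = NULL, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path)
  map <- if (is.character(dialect) && length(dialect) == 1L) {
    if (!dialect %in% names(.dialects))
      stop("unknown dialect: ", dialect)
    .dialects[[dialect]]
  } else {
    stopifnot(is.character(dialect), !is.null(names(dialect)))
    dialect
  }
  required <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "pval")
  if (!all(required %in% names(map)))
    stop("dialect must map column(s): ",
         paste(setdiff(required, names(map)), collapse = ", "))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  raw <- utils::read.delim(con, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  missing_cols <- setdiff(unname(map[required]), names(raw))
  if (length(missing_cols))
    stop("missing required column(s) in file: ",
         paste(missing_cols, collapse = ", "))

  present <- map[map %in% names(raw)]
  df <- stats::setNames(raw[unname(present)], names(present))
  if (is.null(trait_id)) trait_id <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  out <- summary_stats(df, trait_id = trait_id, trait_type = trait_type,
                       provenance = provenance)
  if (nrow(out) == 0L) stop("no valid rows in ", path)
  out
}

#' Write GWAS summary statistics as tab-delimited text
#'
#' Writes the generic dialect. Floating-point fields are printed with 17
#' significant digits so that a read/write round trip reproduces every value
#' exactly. Case/control columns are emitted for binary traits only. Paths
#' ending in `.gz` are gzip-compressed.
#'
#' @param stats a [summary_stats] object with at least one record.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  if (nrow(stats) == 0L) stop("refusing to write an empty summary-statistics set")
  cols <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval", "n")
  if (attr(stats, "trait_type") == "binary")
    cols <- c(cols, "n_cases", "n_controls")
  df <- as.data.frame(stats)[cols]
  for (col in c("pos", "eaf", "beta", "se", "pval", "n", "n_cases",
                "n_controls")) {
    if (col %in% names(df)) df[[col]] <- fmt_num(df[[col]])
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
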