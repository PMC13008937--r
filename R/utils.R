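# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state on
# exit so seeded estimators never perturb a user's random stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Normal-theory 95% interval multiplier. The literal 1.96 (not qnorm(0.975)) is
# used throughout so that exp(beta -/+ 1.96*se) reproduces the conventional
# "OR (lower-upper)" table structure exactly.
CI_Z <- 1.96

# Two-sided p-value from a z statistic.
z_pval <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

# Format doubles so that read-back with as.numeric() is bit-exact.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

fmt_or_ci <- function(or, lo, hi) sprintf("%.3f(%.3f-%.3f)", or, lo, hi)
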