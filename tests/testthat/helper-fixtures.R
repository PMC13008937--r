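# Shared fixture builders. Everything is generated in code at test time.

# Quick summary_stats from parallel vectors, with sensible defaults.
make_stats <- function(rsid, beta, se, pval = NULL,
                       chrom = "1", pos = NULL,
                       effect_allele = "A", other_allele = "G",
                       eaf = 0.3, n = 10000,
                       n_cases = NA_real_, n_controls = NA_real_,
                       trait_id = "trait", trait_type = NULL) {
  m <- length(rsid)
  if (is.null(pos)) pos <- seq_len(m) * 25000L
  if (is.null(pval)) pval <- pmin(1, 2 * pnorm(-abs(beta / se)))
  summary_stats(data.frame(
    rsid = rsid, chrom = rep_len(chrom, m), pos = pos,
    effect_allele = rep_len(effect_allele, m),
    other_allele = rep_len(other_allele, m),
    eaf = rep_len(eaf, m), beta = beta, se = rep_len(se, m), pval = pval,
    n = rep_len(n, m), n_cases = rep_len(n_cases, m),
    n_controls = rep_len(n_controls, m)
  ), trait_id = trait_id, trait_type = trait_type)
}

# A harmonized set straight from exposure/outcome effect vectors.
make_h <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.02,
                   rsid = sprintf("rs%03d", seq_along(beta_exp))) {
  new_harmonized_set(data.frame(
    rsid = rsid, beta_exp = beta_exp,
    se_exp = rep_len(se_exp, length(beta_exp)),
    beta_out = beta_out, se_out = rep_len(se_out, length(beta_exp))
  ))
}

# Flip the allele representation of chosen rows of a summary_stats object:
# swap alleles, negate beta, reflect eaf. Statistically a no-op.
flip_representation <- function(stats, rows) {
  df <- as.data.frame(stats)
  ea <- df$effect_allele[rows]
  df$effect_allele[rows] <- df$other_allele[rows]
  df$other_allele[rows] <- ea
  df$beta[rows] <- -df$beta[rows]
  df$eaf[rows] <- 1 - df$eaf[rows]
  summary_stats(df, trait_id = attr(stats, "trait_id"),
                trait_type = attr(stats, "trait_type"))
}
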