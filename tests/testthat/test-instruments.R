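# Instrument selection, clumping, harmonization and strength diagnostics.

test_that("instrument selection applies a strict p threshold, sorted by p", {
  st <- make_stats(c("rsA", "rsB", "rsC"), beta = c(1, 1, 1), se = 1,
                   pval = c(2e-5, 1e-6, 1e-4))
  expect_equal(select_instruments(st, 1e-5), "rsB")
  expect_equal(select_instruments(st, 1.0), c("rsB", "rsA", "rsC"))
  expect_equal(select_instruments(st, 1e-8), character(0))
})

test_that("selection count under the null matches the binomial expectation", {
  # 1,000 null variants at 1e-5, 100 seeded draws: mean count 0.01.
  counts <- vapply(1:100, function(s) {
    set.seed(s)
    p <- runif(1000)
    st <- make_stats(sprintf("rs%04d", 1:1000), beta = rnorm(1000), se = 1,
                     pval = p)
    length(select_instruments(st, 1e-5))
  }, numeric(1))
  lambda <- 100 * 1000 * 1e-5   # expected total selections
  expect_lt(abs(sum(counts) - lambda), 3 * sqrt(lambda) + 1)
})

test_that("greedy clumping keeps the smaller-p variant of a correlated nearby pair", {
  st <- make_stats(c("rs1", "rs2"), beta = c(1, 1), se = 1,
                   pval = c(1e-8, 1e-6), chrom = "5", pos = c(100000L, 101000L))
  ld <- function(a, b) 0.9
  expect_equal(clump(st, c("rs1", "rs2"), r2_threshold = 0.001,
                     window_kb = 10000, ld = ld), "rs1")
  # below the r2 threshold both survive
  expect_equal(sort(clump(st, c("rs1", "rs2"), r2_threshold = 0.95,
                          window_kb = 10000, ld = ld)), c("rs1", "rs2"))
})

test_that("variants on distinct chromosomes are never clumped", {
  st <- make_stats(sprintf("rs%d", 1:5), beta = rep(1, 5), se = 1,
                   pval = c(0.1, 0.2, 0.3, 0.4, 0.5),
                   chrom = as.character(1:5), pos = rep(1000L, 5))
  expect_setequal(clump(st, st$rsid), st$rsid)
})

test_that("clumping matches an independently coded greedy oracle on a 10-SNP instance", {
  set.seed(11)
  m <- 10
  pos <- sort(sample.int(5e7, m))
  st <- make_stats(sprintf("rs%02d", 1:m), beta = rnorm(m), se = 1,
                   pval = runif(m), chrom = "2", pos = pos)
  r2 <- matrix(runif(m * m), m, m); r2 <- (r2 + t(r2)) / 2; diag(r2) <- 1
  dimnames(r2) <- list(st$rsid, st$rsid)
  ld <- function(a, b) r2[a, b]

  # independent oracle: straight transcription of the greedy rule
  oracle <- local({
    df <- as.data.frame(st)[order(st$pval, st$rsid), ]
    kept <- character(0)
    for (i in seq_len(nrow(df))) {
      ok <- TRUE
      for (k in kept) {
        same_chrom <- df$chrom[i] == df$chrom[df$rsid == k]
        close <- abs(df$pos[i] - df$pos[df$rsid == k]) <= 10000 * 1000
        if (same_chrom && close && r2[df$rsid[i], k] >= 0.3) ok <- FALSE
      }
      if (ok) kept <- c(kept, df$rsid[i])
    }
    kept
  })
  expect_equal(clump(st, st$rsid, r2_threshold = 0.3, window_kb = 10000,
                     ld = ld), oracle)
})

test_that("clumping an unknown rsid raises a lookup error", {
  st <- make_stats("rs1", beta = 1, se = 1, pval = 0.5)
  expect_error(clump(st, c("rs1", "rs99")), "rs99")
})

test_that("harmonization flips swapped alleles, negating the outcome beta", {
  ex <- make_stats("rs1", beta = 0.2, se = 0.05, pval = 1e-8,
                   effect_allele = "A", other_allele = "G", eaf = 0.2)
  out <- make_stats("rs1", beta = -0.1, se = 0.02, pval = 0.01,
                    effect_allele = "G", other_allele = "A", eaf = 0.8)
  h <- harmonize(ex, out, "rs1")
  expect_equal(h$rows$beta_out, 0.1)
  expect_true(h$rows$flipped)
  expect_equal(nrow(h$dropped), 0L)
})

test_that("palindromic variants with ambiguous frequency are dropped", {
  ex <- make_stats("rs1", beta = 0.2, se = 0.05, pval = 1e-8,
                   effect_allele = "A", other_allele = "T", eaf = 0.5)
  out <- make_stats("rs1", beta = 0.1, se = 0.02, pval = 0.01,
                    effect_allele = "A", other_allele = "T", eaf = 0.5)
  h <- harmonize(ex, out, "rs1")
  expect_equal(nrow(h$rows), 0L)
  expect_equal(h$dropped$reason, "palindromic_ambiguous")

  # informative frequencies on opposite sides of 0.5: strand flip inferred
  ex2 <- make_stats("rs1", beta = 0.2, se = 0.05, pval = 1e-8,
                    effect_allele = "A", other_allele = "T", eaf = 0.2)
  out2 <- make_stats("rs1", beta = 0.1, se = 0.02, pval = 0.01,
                     effect_allele = "A", other_allele = "T", eaf = 0.8)
  h2 <- harmonize(ex2, out2, "rs1")
  expect_equal(h2$rows$beta_out, -0.1)
  expect_true(h2$rows$flipped)
})

test_that("irreconcilable alleles and missing outcome variants are logged", {
  ex <- make_stats(c("rs1", "rs2"), beta = c(0.2, 0.3), se = 0.05,
                   pval = 1e-8, effect_allele = "A", other_allele = "G")
  out <- make_stats("rs1", beta = 0.1, se = 0.02, pval = 0.01,
                    effect_allele = "C", other_allele = "T")
  h <- harmonize(ex, out, c("rs1", "rs2"))
  expect_equal(nrow(h$rows), 0L)
  expect_setequal(h$dropped$reason, c("allele_mismatch", "missing_in_outcome"))
})

test_that("harmonization is invariant to the allele representation of the outcome", {
  cfg <- sim_config(m_snps = 50, h2_x = 0.1, seed = 99)
  tri <- simulate_triple(cfg)
  iv <- select_instruments(tri$exposure, 1e-5)
  h1 <- harmonize(tri$exposure, tri$outcome, iv)
  set.seed(31)
  rows <- sample(nrow(tri$outcome), 25)
  out_flipped <- flip_representation(tri$outcome, rows)
  h2 <- harmonize(tri$exposure, out_flipped, iv)
  stat_cols <- c("rsid", "beta_exp", "se_exp", "beta_out", "se_out", "eaf")
  expect_equal(h1$rows[stat_cols], h2$rows[stat_cols])
  expect_equal(h1$dropped, h2$dropped)
})

test_that("harmonizing an already-aligned pair is the identity (no flips)", {
  ex <- make_stats(c("rs1", "rs2"), beta = c(0.2, -0.3), se = 0.05,
                   pval = 1e-8, effect_allele = "A", other_allele = "G")
  out <- make_stats(c("rs1", "rs2"), beta = c(0.1, 0.05), se = 0.02,
                    pval = 0.01, effect_allele = "A", other_allele = "G")
  h1 <- harmonize(ex, out, c("rs1", "rs2"))
  expect_false(any(h1$rows$flipped))
  # write the harmonized outcome back as stats and harmonize again
  out2 <- make_stats(h1$rows$rsid, beta = h1$rows$beta_out,
                     se = h1$rows$se_out, pval = 0.01,
                     effect_allele = "A", other_allele = "G")
  h2 <- harmonize(ex, out2, c("rs1", "rs2"))
  expect_equal(h1$rows, h2$rows)
})

test_that("select + clump is stable under permutation of input record order", {
  cfg <- sim_config(m_snps = 30, h2_x = 0.15, seed = 5)
  tri <- simulate_triple(cfg)
  st <- tri$exposure
  set.seed(8)
  perm <- summary_stats(as.data.frame(st)[sample(nrow(st)), ],
                        trait_id = trait_id(st))
  a <- clump(st, select_instruments(st))
  b <- clump(perm, select_instruments(perm))
  expect_equal(a, b)
})

test_that("per-instrument F-statistics follow the (beta/se)^2 rule", {
  h <- make_h(beta_exp = c(0.1, 0), beta_out = c(0.01, 0.01),
              se_exp = 0.02, se_out = 0.02)
  fs <- instrument_strength(h)
  expect_equal(sort(fs$f$f_stat), c(0, 25))
  expect_equal(fs$mean_f, 12.5)
})

test_that("block-correlated duplicates are removed by LD-aware clumping", {
  cfg <- sim_config(m_snps = 10, h2_x = 0.2, block_copies = 3, seed = 17)
  tri <- simulate_triple(cfg)
  iv <- select_instruments(tri$exposure, 1e-5)
  expect_gt(length(iv), 10)   # copies get selected too
  ld <- block_ld_provider(tri$exposure)
  kept <- clump(tri$exposure, iv, r2_threshold = 0.001, window_kb = 10000,
                ld = ld)
  blocks <- attr(tri$exposure, "block_map")[kept]
  expect_false(any(duplicated(blocks)))   # one representative per block
})
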