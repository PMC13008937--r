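#' Configuration for the synthetic GWAS generator
#'
#' Defines the causal diagram and sampling layout for
#' [simulate_triple()] and friends: `m_snps` independent instruments explain a
#' fraction `h2_x` of the variance of a standardized quantitative exposure X;
#' X affects a standardized quantitative mediator M with effect `theta_xm`;
#' M and X affect a binary outcome D on the log-odds scale with effects
#' `theta_md` and `theta_xd`. The mediator additionally carries `m_snps_m`
#' instruments of its own explaining `h2_m` of its variance (without them a
#' mediator GWAS at a few thousand samples could never yield instruments).
#' The implied true total effect of X on D is
#' `theta_xd + theta_xm * theta_md`.
#'
#' Default sample sizes anchor the three layers to the study conditions this
#' generator emulates: a large plasma-proteomics exposure GWAS (n = 35,559),
#' a small immune-phenotype mediator GWAS (n = 3,757), and a rare binary
#' outcome with extreme case/control imbalance (126 cases, 412,055 controls).
#'
#' @param m_snps number of exposure instruments.
#' @param maf_range interval within (0, 0.5] for minor-allele frequencies.
#' @param h2_x variance of X explained by its instruments, in \[0, 1).
#' @param theta_xm,theta_md,theta_xd causal effects X->M (trait units), M->D
#'   and X->D (log-odds per unit).
#' @param n_x,n_m GWAS sample sizes for X and M.
#' @param n_cases,n_controls outcome GWAS composition.
#' @param m_snps_m,h2_m the mediator's own instrument count and explained
#'   variance; `theta_xm^2 + h2_m` must stay below 1 (unit-variance budget).
#' @param pleiotropy_mode `"none"`, `"balanced"` (direct SNP->D effects drawn
#'   from a zero-mean normal) or `"directional"` (mean shifted to
#'   `pleiotropy_mean`). Pleiotropy applies to the exposure instruments.
#' @param pleiotropy_sd,pleiotropy_mean scale and (directional) mean of the
#'   direct SNP->D effects, log-odds units.
#' @param block_copies if > 1, every exposure instrument is emitted
#'   `block_copies` times at nearby positions, tagged as an LD block, so the
#'   clumping stage can be exercised without a reference panel (see
#'   [block_ld_provider()]).
#' @param seed integer random seed; the same config yields identical output.
#' @return A list of class `sim_config` with an `alpha_total_true` element.
#' @export
sim_config <- function(m_snps = 20, maf_range = c(0.05, 0.5), h2_x = 0.1,
                       theta_xm = 0, theta_md = 0, theta_xd = 0,
                       n_x = 35559, n_m = 3757,
                       n_cases = 126, n_controls = 412055,
                       m_snps_m = 15, h2_m = 0.25,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0, pleiotropy_mean = 0.05,
                       block_copies = 1, seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  cfg <- list(m_snps = as.integer(m_snps), maf_range = as.numeric(maf_range),
              h2_x = h2_x, theta_xm = theta_xm, theta_md = theta_md,
              theta_xd = theta_xd, n_x = n_x, n_m = n_m,
              n_cases = n_cases, n_controls = n_controls,
              m_snps_m = as.integer(m_snps_m), h2_m = h2_m,
              pleiotropy_mode = pleiotropy_mode,
              pleiotropy_sd = pleiotropy_sd,
              pleiotropy_mean = pleiotropy_mean,
              block_copies = as.integer(block_copies),
              seed = as.integer(seed))
  if (cfg$m_snps < 1L || cfg$m_snps_m < 1L)
    stop("configuration error: m_snps and m_snps_m must be >= 1")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("configuration error: maf_range must lie within (0, 0.5]")
  if (cfg$h2_x < 0 || cfg$h2_x >= 1)
    stop("configuration error: h2_x must be in [0, 1)")
  if (cfg$h2_m < 0 || cfg$h2_m >= 1)
    stop("configuration error: h2_m must be in [0, 1)")
  if (cfg$theta_xm^2 + cfg$h2_m >= 1)
    stop("configuration error: theta_xm^2 + h2_m must be < 1 ",
         "(the mediator is standardized to unit variance)")
  if (any(c(cfg$n_x, cfg$n_m, cfg$n_cases, cfg$n_controls) < 1))
    stop("configuration error: sample sizes must be >= 1")
  if (cfg$block_copies < 1L) stop("configuration error: block_copies must be >= 1")
  cfg$alpha_total_true <- cfg$theta_xd + cfg$theta_xm * cfg$theta_md
  class(cfg) <- "sim_config"
  cfg
}

# Allele pairs excluding the strand-ambiguous (palindromic) A/T and C/G pairs,
# so that simulated instruments survive harmonization by construction.
.allele_pairs <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G")
)

# Draw a variant table: rsid, chrom, pos, alleles, eaf. `offset` keeps rsids
# and positions globally unique across the components of a registry. Variants
# are spaced 25 Mb apart within a chromosome so that the default distance-only
# clumping window (10,000 kb) never links independent instruments.
.draw_variants <- function(m, maf_range, offset = 0L) {
  idx <- offset + seq_len(m)
  f <- stats::runif(m, maf_range[1], maf_range[2])
  pair <- .allele_pairs[sample.int(nrow(.allele_pairs), m, replace = TRUE), ,
                        drop = FALSE]
  chrom <- as.character((idx - 1L) %% 22L + 1L)
  pos <- 1e6 + ((idx - 1L) %/% 22L) * 25e6
  data.frame(rsid = sprintf("rs%07d", idx), chrom = chrom, pos = pos,
             effect_allele = pair[, 1], other_allele = pair[, 2],
             eaf = f, block = idx, stringsAsFactors = FALSE)
}

# Per-allele effects scaled so the instruments explain exactly h2 of a
# unit-variance trait: sum(2 f (1-f) b^2) == h2.
.scale_effects <- function(f, h2) {
  m <- length(f)
  if (h2 == 0) return(numeric(m))
  u <- stats::rnorm(m)
  u * sqrt(h2 / sum(2 * f * (1 - f) * u^2))
}

.se_cont <- function(f, n) 1 / sqrt(2 * f * (1 - f) * n)
.se_bin <- function(f, n_cases, n_controls) {
  1 / sqrt(2 * f * (1 - f) * n_cases * n_controls / (n_cases + n_controls))
}

# Sample a summary_stats object around true per-allele effects.
.sample_stats <- function(variants, beta_true, se, trait_id, trait_type,
                          n, n_cases = NA_real_, n_controls = NA_real_) {
  beta_hat <- stats::rnorm(nrow(variants), beta_true, se)
  df <- data.frame(
    rsid = variants$rsid, chrom = variants$chrom, pos = variants$pos,
    effect_allele = variants$effect_allele, other_allele = variants$other_allele,
    eaf = variants$eaf, beta = beta_hat, se = se,
    # clamp: astronomically significant draws must stay in (0, 1]
    pval = pmax(pmin(1, 2 * stats::pnorm(-abs(beta_hat / se))),
                .Machine$double.xmin),
    n = n, n_cases = n_cases, n_controls = n_controls,
    stringsAsFactors = FALSE
  )
  out <- summary_stats(df, trait_id = trait_id, trait_type = trait_type,
                       provenance = "synthetic")
  attr(out, "block_map") <- stats::setNames(variants$block, variants$rsid)
  out
}

# Draw the causal diagram (variants and true effects) for one triple. Called
# inside a seeded block; simulate_triple and simulate_individual_oracle consume
# the RNG in the same order here, so both see identical ground truth.
.draw_dag <- function(config, offset = 0L) {
  vx <- .draw_variants(config$m_snps, config$maf_range, offset)
  vm <- .draw_variants(config$m_snps_m, config$maf_range,
                       offset + config$m_snps)
  b <- .scale_effects(vx$eaf, config$h2_x)
  cc <- .scale_effects(vm$eaf, config$h2_m)
  pleio <- switch(config$pleiotropy_mode,
    none        = numeric(config$m_snps),
    balanced    = stats::rnorm(config$m_snps, 0, config$pleiotropy_sd),
    directional = stats::rnorm(config$m_snps, config$pleiotropy_mean,
                               config$pleiotropy_sd))
  # Direct SNP->D effects are defined per exposure-increasing allele, the
  # orientation MR-Egger regresses in; otherwise a directional mean would
  # cancel across sign-symmetric exposure effects.
  pleio <- pleio * ifelse(b >= 0, 1, -1)
  if (config$block_copies > 1L) {
    k <- config$block_copies
    rep_idx <- rep(seq_len(nrow(vx)), each = k)
    vx <- vx[rep_idx, , drop = FALSE]
    copy <- rep(seq_len(k) - 1L, config$m_snps)
    vx$pos <- vx$pos + copy * 100L
    vx$rsid <- ifelse(copy == 0L, vx$rsid, paste0(vx$rsid, "_", copy))
    b <- b[rep_idx]
    pleio <- pleio[rep_idx]
    rownames(vx) <- NULL
  }
  list(vx = vx, vm = vm, b = b, cc = cc, pleio = pleio)
}

#' Simulate an exposure/mediator/outcome GWAS triple
#'
#' Draws three summary-statistics sets over a shared variant panel under the
#' causal diagram in `config`. Per-variant estimates are sampled directly from
#' their asymptotic distributions: `beta_hat ~ Normal(beta_true, se^2)` with
#' `se = 1/sqrt(2 n f (1-f))` for standardized continuous traits and
#' `se = 1/sqrt(2 f (1-f) n_cases n_controls / n)` for the binary outcome.
#' True marginal effects follow the diagram: an exposure instrument with
#' per-allele effect `b` has effect `theta_xm * b` on the mediator and
#' `b * (theta_xd + theta_xm * theta_md) + pleiotropy` on the outcome
#' log-odds; a mediator instrument with effect `c` has effect `c * theta_md`
#' on the outcome. The same seed yields byte-identical output;
#' [simulate_individual_oracle()] is the individual-level cross-check.
#'
#' @param config a [sim_config()].
#' @return A list with elements `exposure`, `mediator`, `outcome` (each a
#'   [summary_stats]) and `truth` (the drawn per-variant effects and the
#'   implied `alpha_total_true`).
#' @export
simulate_triple <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    dag <- .draw_dag(config)
    variants <- rbind(dag$vx, dag$vm)
    beta_x <- c(dag$b, numeric(config$m_snps_m))
    beta_m <- c(config$theta_xm * dag$b, dag$cc)
    beta_d <- c(dag$b * (config$theta_xd + config$theta_xm * config$theta_md) +
                  dag$pleio,
                dag$cc * config$theta_md)
    se_x <- .se_cont(variants$eaf, config$n_x)
    se_m <- .se_cont(variants$eaf, config$n_m)
    se_d <- .se_bin(variants$eaf, config$n_cases, config$n_controls)
    x <- .sample_stats(variants, beta_x, se_x, "X", "continuous", config$n_x)
    m <- .sample_stats(variants, beta_m, se_m, "M", "continuous", config$n_m)
    d <- .sample_stats(variants, beta_d, se_d, "D", "binary",
                       config$n_cases + config$n_controls,
                       config$n_cases, config$n_controls)
    list(exposure = x, mediator = m, outcome = d,
         truth = list(b = dag$b, c = dag$cc, pleio = dag$pleio,
                      variants = variants,
                      beta_x = beta_x, beta_m = beta_m, beta_d = beta_d,
                      alpha_total_true = config$alpha_total_true))
  })
}

#' Individual-level simulation oracle
#'
#' Generates genotypes (binomial with the drawn allele frequencies), builds X
#' and M as linear traits and D through a logistic model with the configured
#' effects, then computes per-variant regression summary statistics directly.
#' Under the same `config` seed it reproduces the exact ground-truth effects
#' used by [simulate_triple()], so the two generators can be compared
#' distributionally; this is the independent oracle for the summary-level
#' sampler. The logistic intercept is set so the expected case fraction
#' matches `n_cases / (n_cases + n_controls)`.
#'
#' @param config a [sim_config()] with `block_copies = 1`.
#' @param n_subsample number of individuals to simulate (all three traits are
#'   measured on independent samples of this size).
#' @return As [simulate_triple()].
#' @export
simulate_individual_oracle <- function(config, n_subsample) {
  stopifnot(inherits(config, "sim_config"), is_scalar_number(n_subsample),
            n_subsample >= 10)
  if (config$block_copies > 1L)
    stop("the individual-level oracle does not support LD block copies")
  n <- as.integer(n_subsample)
  with_seed(config$seed, {
    dag <- .draw_dag(config)
    variants <- rbind(dag$vx, dag$vm)
    m_all <- nrow(variants)
    f <- variants$eaf

    draw_geno <- function() {
      g <- matrix(stats::rbinom(n * m_all, 2L, rep(f, each = n)), nrow = n)
      g
    }
    lin_trait <- function(g, eff, resid_var) {
      drop(g %*% eff) + stats::rnorm(n, 0, sqrt(resid_var))
    }
    # Centered per-variant simple regression: slope and classical SE.
    reg_cont <- function(g, y) {
      out <- vapply(seq_len(ncol(g)), function(j) {
        gj <- g[, j] - mean(g[, j])
        sxx <- sum(gj^2)
        bj <- sum(gj * (y - mean(y))) / sxx
        res <- (y - mean(y)) - bj * gj
        sej <- sqrt(sum(res^2) / (n - 2) / sxx)
        c(bj, sej)
      }, numeric(2))
      list(beta = out[1, ], se = out[2, ])
    }
    reg_bin <- function(g, d) {
      out <- vapply(seq_len(ncol(g)), function(j) {
        fit <- stats::glm(d ~ g[, j], family = stats::binomial())
        s <- summary(fit)$coefficients
        c(s[2, 1], s[2, 2])
      }, numeric(2))
      list(beta = out[1, ], se = out[2, ])
    }

    eff_x <- c(dag$b, numeric(config$m_snps_m))
    eff_m_direct <- c(numeric(config$m_snps), dag$cc)
    pleio_all <- c(dag$pleio, numeric(config$m_snps_m))

    gx <- draw_geno()
    # The genetic part of X is built on centered genotypes so var(X) = 1.
    gx_c <- sweep(gx, 2, 2 * f)
    x <- drop(gx_c %*% eff_x) + stats::rnorm(n, 0, sqrt(1 - config$h2_x))
    rx <- reg_cont(gx, x)

    gm <- draw_geno()
    gm_c <- sweep(gm, 2, 2 * f)
    xm <- drop(gm_c %*% eff_x) + stats::rnorm(n, 0, sqrt(1 - config$h2_x))
    mm <- config$theta_xm * xm + drop(gm_c %*% eff_m_direct) +
      stats::rnorm(n, 0, sqrt(1 - config$theta_xm^2 - config$h2_m))
    rm_ <- reg_cont(gm, mm)

    gd <- draw_geno()
    gd_c <- sweep(gd, 2, 2 * f)
    xd <- drop(gd_c %*% eff_x) + stats::rnorm(n, 0, sqrt(1 - config$h2_x))
    md <- config$theta_xm * xd + drop(gd_c %*% eff_m_direct) +
      stats::rnorm(n, 0, sqrt(1 - config$theta_xm^2 - config$h2_m))
    b0 <- stats::qlogis(config$n_cases / (config$n_cases + config$n_controls))
    eta <- b0 + config$theta_xd * xd + config$theta_md * md +
      drop(gd_c %*% pleio_all)
    d <- stats::rbinom(n, 1L, stats::plogis(eta))
    if (sum(d) < 2 || sum(d) > n - 2)
      stop("configuration error: outcome prevalence too extreme for an ",
           "individual-level simulation of this size")
    rd <- reg_bin(gd, d)

    mk <- function(r, id, type, ntot, ncase = NA_real_, nctrl = NA_real_) {
      .sample_stats_from(variants, r$beta, r$se, id, type, ntot, ncase, nctrl)
    }
    list(exposure = mk(rx, "X", "continuous", n),
         mediator = mk(rm_, "M", "continuous", n),
         outcome = mk(rd, "D", "binary", n, sum(d), n - sum(d)),
         truth = list(b = dag$b, c = dag$cc, pleio = dag$pleio,
                      variants = variants,
                      alpha_total_true = config$alpha_total_true))
  })
}

# Build a summary_stats from already-computed estimates (no extra sampling).
.sample_stats_from <- function(variants, beta, se, trait_id, trait_type,
                               n, n_cases = NA_real_, n_controls = NA_real_) {
  df <- data.frame(
    rsid = variants$rsid, chrom = variants$chrom, pos = variants$pos,
    effect_allele = variants$effect_allele, other_allele = variants$other_allele,
    eaf = variants$eaf, beta = beta, se = se,
    pval = pmax(pmin(1, 2 * stats::pnorm(-abs(beta / se))),
                .Machine$double.xmin),
    n = n, n_cases = n_cases, n_controls = n_controls,
    stringsAsFactors = FALSE
  )
  summary_stats(df, trait_id = trait_id, trait_type = trait_type,
                provenance = "synthetic-individual-level")
}

#' Null exposure registry
#'
#' Generates `k_exposures` independent exposure GWAS, each with its own
#' instruments, none of which has any effect on a shared outcome GWAS. Used to
#' measure the false-positive behaviour of the screening pipeline.
#'
#' @param config a [sim_config()]; its causal effects are ignored (forced to
#'   zero), its sample sizes and instrument layout are used.
#' @param k_exposures number of null exposures, >= 1.
#' @return A list with `exposures` (named list of [summary_stats]) and
#'   `outcome` (one [summary_stats] covering every exposure's variants).
#' @export
null_registry <- function(config, k_exposures) {
  stopifnot(inherits(config, "sim_config"), is_scalar_number(k_exposures),
            k_exposures >= 1)
  k <- as.integer(k_exposures)
  with_seed(config$seed, {
    exposures <- vector("list", k)
    all_variants <- vector("list", k)
    offset <- 0L
    for (i in seq_len(k)) {
      v <- .draw_variants(config$m_snps, config$maf_range, offset)
      offset <- offset + config$m_snps
      b <- .scale_effects(v$eaf, config$h2_x)
      exposures[[i]] <- .sample_stats(v, b, .se_cont(v$eaf, config$n_x),
                                      sprintf("EXP%03d", i), "continuous",
                                      config$n_x)
      all_variants[[i]] <- v
    }
    names(exposures) <- sprintf("EXP%03d", seq_len(k))
    v_all <- do.call(rbind, all_variants)
    outcome <- .sample_stats(v_all, numeric(nrow(v_all)),
                             .se_bin(v_all$eaf, config$n_cases, config$n_controls),
                             "D", "binary",
                             config$n_cases + config$n_controls,
                             config$n_cases, config$n_controls)
    list(exposures = exposures, outcome = outcome)
  })
}

#' Synthetic registry for the end-to-end screen
#'
#' Builds the study-shaped screening scenario: one true
#' exposure -> mediator -> outcome path (with the effects in `config`) hidden
#' among null exposures and null mediators, plus a handful of large-effect
#' disease-susceptibility variants in the outcome GWAS so that reverse MR is
#' testable (their minor-allele frequencies are drawn from (0.2, 0.5) and they
#' carry `disease_beta` log-odds per allele). Every exposure set contains its
#' own instruments plus the disease variants; every mediator set additionally
#' contains the true exposure's instruments; the outcome covers all variants.
#'
#' @param config a [sim_config()] giving the true-path effects and layer sizes.
#' @param k_null_exposures,k_null_mediators numbers of null traits.
#' @param n_disease_snps,disease_beta count and per-allele log-odds of the
#'   outcome-specific susceptibility variants.
#' @return A list with `exposures`, `mediators` (named lists of
#'   [summary_stats]), `outcome`, and `truth` (names of the true exposure and
#'   mediator plus the implied total effect and mediated proportion).
#' @export
simulate_screen_registry <- function(config, k_null_exposures = 50,
                                     k_null_mediators = 10,
                                     n_disease_snps = 5, disease_beta = 1.5) {
  stopifnot(inherits(config, "sim_config"))
  kx <- as.integer(k_null_exposures)
  km <- as.integer(k_null_mediators)
  with_seed(config$seed, {
    offset <- 0L
    nxt <- function(m, maf = config$maf_range) {
      v <- .draw_variants(m, maf, offset)
      offset <<- offset + m
      v
    }
    v_true_x <- nxt(config$m_snps)
    v_true_m <- nxt(config$m_snps_m)
    b <- .scale_effects(v_true_x$eaf, config$h2_x)
    cc <- .scale_effects(v_true_m$eaf, config$h2_m)

    v_null_x <- lapply(seq_len(kx), function(i) nxt(config$m_snps))
    b_null <- lapply(v_null_x, function(v) .scale_effects(v$eaf, config$h2_x))
    v_null_m <- lapply(seq_len(km), function(i) nxt(config$m_snps_m))
    c_null <- lapply(v_null_m, function(v) .scale_effects(v$eaf, config$h2_m))
    v_dis <- nxt(n_disease_snps, maf = c(0.2, 0.5))
    gamma <- rep(disease_beta, n_disease_snps)

    n_exp <- kx + 1L
    n_med <- km + 1L
    true_x_at <- sample.int(n_exp, 1L)
    true_m_at <- sample.int(n_med, 1L)
    exp_names <- sprintf("EXP%03d", seq_len(n_exp))
    med_names <- sprintf("MED%03d", seq_len(n_med))

    exp_stats <- function(v_own, b_own, id) {
      v <- rbind(v_own, v_dis)
      beta <- c(b_own, numeric(n_disease_snps))
      .sample_stats(v, beta, .se_cont(v$eaf, config$n_x), id, "continuous",
                    config$n_x)
    }
    med_stats <- function(v_own, c_own, on_true_x, id) {
      v <- rbind(v_own, v_true_x, v_dis)
      beta <- c(c_own,
                if (on_true_x) config$theta_xm * b else numeric(config$m_snps),
                numeric(n_disease_snps))
      .sample_stats(v, beta, .se_cont(v$eaf, config$n_m), id, "continuous",
                    config$n_m)
    }

    exposures <- vector("list", n_exp)
    j <- 0L
    for (i in seq_len(n_exp)) {
      if (i == true_x_at) {
        exposures[[i]] <- exp_stats(v_true_x, b, exp_names[i])
      } else {
        j <- j + 1L
        exposures[[i]] <- exp_stats(v_null_x[[j]], b_null[[j]], exp_names[i])
      }
    }
    names(exposures) <- exp_names

    mediators <- vector("list", n_med)
    j <- 0L
    for (i in seq_len(n_med)) {
      if (i == true_m_at) {
        mediators[[i]] <- med_stats(v_true_m, cc, TRUE, med_names[i])
      } else {
        j <- j + 1L
        mediators[[i]] <- med_stats(v_null_m[[j]], c_null[[j]], FALSE,
                                    med_names[i])
      }
    }
    names(mediators) <- med_names

    v_all <- do.call(rbind, c(list(v_true_x, v_true_m),
                              v_null_x, v_null_m, list(v_dis)))
    beta_d <- c(b * config$alpha_total_true,
                cc * config$theta_md,
                numeric(sum(vapply(v_null_x, nrow, integer(1)))),
                numeric(sum(vapply(v_null_m, nrow, integer(1)))),
                gamma)
    outcome <- .sample_stats(v_all, beta_d,
                             .se_bin(v_all$eaf, config$n_cases, config$n_controls),
                             "D", "binary",
                             config$n_cases + config$n_controls,
                             config$n_cases, config$n_controls)
    prop_true <- if (config$alpha_total_true == 0) NA_real_ else
      100 * config$theta_xm * config$theta_md / config$alpha_total_true
    list(exposures = exposures, mediators = mediators, outcome = outcome,
         truth = list(exposure = exp_names[true_x_at],
                      mediator = med_names[true_m_at],
                      alpha_total = config$alpha_total_true,
                      proportion_mediated = prop_true))
  })
}

#' Pairwise LD provider for simulated block copies
#'
#' Returns a function `(rsid_a, rsid_b) -> r^2` that reports 0.99 for two
#' variants emitted as copies of the same simulated LD block and 0 otherwise,
#' suitable as the `ld` argument of [clump()].
#'
#' @param stats a [summary_stats] produced by [simulate_triple()] with
#'   `block_copies > 1`.
#' @return A function of two rsids returning a squared correlation.
#' @export
block_ld_provider <- function(stats) {
  map <- attr(stats, "block_map")
  if (is.null(map)) stop("no block map attached to these summary statistics")
  blk <- map
  function(a, b) {
    if (!a %in% names(blk) || !b %in% names(blk)) return(0)
    if (blk[[a]] == blk[[b]]) 0.99 else 0
  }
}
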