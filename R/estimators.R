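# The five causal-effect estimators plus heterogeneity and OR reporting.
# All estimators consume a harmonized_set and return an `mr_estimate`.

new_mr_estimate <- function(method, beta, se, n_snp,
                            q_stat = NA_real_, q_df = NA_real_,
                            q_pval = NA_real_,
                            egger_intercept = NA_real_,
                            egger_intercept_se = NA_real_,
                            egger_intercept_pval = NA_real_,
                            seed = NA_integer_) {
  orci <- to_or(beta, se)
  structure(list(method = method, beta = beta, se = se,
                 pval = z_pval(beta, se),
                 or = orci$or, ci_low = orci$ci_low, ci_high = orci$ci_high,
                 n_snp = n_snp,
                 q_stat = q_stat, q_df = q_df, q_pval = q_pval,
                 egger_intercept = egger_intercept,
                 egger_intercept_se = egger_intercept_se,
                 egger_intercept_pval = egger_intercept_pval,
                 seed = seed),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (se %.4f), p = %.3g, OR %s [%d SNPs]\n",
              x$method, x$beta, x$se, x$pval,
              fmt_or_ci(x$or, x$ci_low, x$ci_high), x$n_snp))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  pleiotropy intercept = %.4f (se %.4f), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se,
                x$egger_intercept_pval))
  invisible(x)
}

#' Odds ratio with 95% confidence bounds
#'
#' Exponentiates a log-odds estimate: `or = exp(beta)`,
#' `ci = exp(beta -/+ 1.96 se)`. By construction the geometric mean of the
#' bounds equals the point estimate, `sqrt(ci_low * ci_high) == or`, which is
#' exactly the structure of the conventional "OR(lower-upper)" table format.
#'
#' @param beta log-odds (or log-ratio) estimate.
#' @param se standard error, > 0.
#' @return List with `or`, `ci_low`, `ci_high`.
#' @export
to_or <- function(beta, se) {
  stopifnot(is_scalar_number(beta), is_scalar_number(se), se > 0)
  list(or = exp(beta), ci_low = exp(beta - CI_Z * se),
       ci_high = exp(beta + CI_Z * se))
}

#' Per-instrument Wald ratios
#'
#' The shared primitive of all five estimators: `ratio_j = beta_out_j /
#' beta_exp_j` with first-order (delta) standard error
#' `se_j = se_out_j / |beta_exp_j|`. Instruments with a zero exposure effect
#' are excluded with a warning.
#'
#' @param h a `harmonized_set`.
#' @return data.frame `rsid, ratio, se, w` (`w = 1/se^2`), sorted by rsid.
#' @export
wald_ratios <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  r <- h$rows
  zero <- r$beta_exp == 0
  if (any(zero)) {
    warning(sum(zero), " instrument(s) with zero exposure effect excluded")
    r <- r[!zero, , drop = FALSE]
  }
  if (!nrow(r)) stop("no usable instruments (all exposure effects are zero)")
  ratio <- r$beta_out / r$beta_exp
  se <- r$se_out / abs(r$beta_exp)
  data.frame(rsid = r$rsid, ratio = ratio, se = se, w = 1 / se^2,
             stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimator
#'
#' The primary estimator: the inverse-variance weighted average of the
#' per-instrument Wald ratios, `beta = sum(w_j ratio_j) / sum(w_j)` with
#' `w_j = se_j^-2` (algebraically identical to a weighted regression of
#' outcome on exposure effects through the origin with weights `se_out^-2`).
#' Under the fixed-effect model `se = 1/sqrt(sum(w_j))`; the default
#' multiplicative random-effects model inflates the standard error by
#' `max(1, sqrt(Q / (n - 1)))`, where Q is Cochran's heterogeneity statistic.
#' P-values are two-sided normal. With a single instrument the estimate and
#' its standard error collapse to the Wald ratio exactly.
#'
#' @param h a `harmonized_set` with at least one usable instrument.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` (method `"ivw"`) carrying `q_stat`, `q_df`,
#'   `q_pval` when two or more instruments are available.
#' @export
mr_ivw <- function(h, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  wr <- wald_ratios(h)
  n <- nrow(wr)
  beta <- sum(wr$w * wr$ratio) / sum(wr$w)
  se <- sqrt(1 / sum(wr$w))
  q <- df <- qp <- NA_real_
  if (n >= 2) {
    q <- sum(wr$w * (wr$ratio - beta)^2)
    df <- n - 1
    qp <- stats::pchisq(q, df, lower.tail = FALSE)
    if (model == "multiplicative_random") se <- se * max(1, sqrt(q / df))
  }
  new_mr_estimate("ivw", beta, se, n, q_stat = q, q_df = df, q_pval = qp)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with an
#' intercept (weights `se_out^-2`), after orienting every instrument so its
#' exposure effect is non-negative (the intercept is orientation-dependent;
#' this is the conventional choice). The slope is the causal estimate; the
#' intercept, with its standard error and p-value, is the directional
#' horizontal-pleiotropy diagnostic. Standard errors use the multiplicative
#' random-effects convention: the classical weighted-least-squares errors
#' inflated by `max(1, sigma)` where `sigma^2` is the weighted residual mean
#' square on `n - 2` degrees of freedom.
#'
#' @param h a `harmonized_set` with at least 3 instruments.
#' @return An `mr_estimate` (method `"egger"`) with `egger_intercept*` fields
#'   and residual heterogeneity `q_stat` on `n - 2` degrees of freedom.
#' @export
mr_egger <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  r <- h$rows
  n <- nrow(r)
  if (n < 3) stop("MR-Egger requires at least 3 instruments (got ", n, ")")
  flip <- sign(r$beta_exp)
  flip[flip == 0] <- 1
  bx <- r$beta_exp * flip
  by <- r$beta_out * flip
  w <- 1 / r$se_out^2
  X <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(X, w * X)
  coefs <- solve(xtwx, crossprod(X, w * by))
  fitted <- drop(X %*% coefs)
  rss_w <- sum(w * (by - fitted)^2)
  sigma <- sqrt(rss_w / (n - 2))
  se_cl <- sqrt(diag(solve(xtwx)))
  se <- se_cl * max(1, sigma)
  slope <- unname(coefs["slope", 1]); icpt <- unname(coefs["intercept", 1])
  new_mr_estimate("egger", beta = slope, se = unname(se["slope"]),
                  n_snp = n,
                  q_stat = rss_w, q_df = n - 2,
                  q_pval = stats::pchisq(rss_w, n - 2, lower.tail = FALSE),
                  egger_intercept = icpt,
                  egger_intercept_se = unname(se["intercept"]),
                  egger_intercept_pval = z_pval(icpt, unname(se["intercept"])))
}

# Weighted median of ratios: the value where the cumulative normalized weights
# cross 0.5, linearly interpolated between bracketing ratios.
.weighted_median <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]; ww <- w[ord]
  p <- (cumsum(ww) - ww / 2) / sum(ww)
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap SE shared by the median and mode estimators: each
# ratio is resampled from Normal(ratio_j, se_j) with the weights held fixed;
# rows are sorted by rsid beforehand so the draw is order-invariant.
.boot_se <- function(wr, stat_fn, n_boot, seed) {
  n <- nrow(wr)
  with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(i) {
      stat_fn(stats::rnorm(n, wr$ratio, wr$se))
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted median estimator
#'
#' Orders the Wald ratios and takes the value at which the cumulative
#' normalized inverse-variance weights cross one half, with linear
#' interpolation between the bracketing ratios. Consistent when instruments
#' carrying at least half the weight are valid. The standard error comes from
#' a seeded parametric bootstrap (each ratio resampled from its sampling
#' distribution).
#'
#' @param h a `harmonized_set` with at least 3 instruments.
#' @param n_boot bootstrap draws for the standard error.
#' @param seed bootstrap seed (logged in the result).
#' @return An `mr_estimate` (method `"weighted_median"`).
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1) {
  wr <- wald_ratios(h)
  n <- nrow(wr)
  if (n < 3) stop("weighted median requires at least 3 instruments (got ", n, ")")
  beta <- .weighted_median(wr$ratio, wr$w)
  se <- .boot_se(wr, function(r) .weighted_median(r, wr$w), n_boot, seed)
  new_mr_estimate("weighted_median", beta, se, n, seed = as.integer(seed))
}

# Kernel-density mode of the ratios on a fixed 512-point grid spanning the
# ratio range padded by 3 bandwidths. Bandwidth: phi x modified Silverman rule
# 0.9 min(sd, mad) n^(-1/5); falls back to the sd when the mad degenerates.
.kde_mode <- function(ratio, w, phi) {
  if (diff(range(ratio)) < .Machine$double.eps^0.5) return(ratio[1])
  s <- min(stats::sd(ratio), stats::mad(ratio))
  if (s <= 0) s <- stats::sd(ratio)
  bw <- phi * 0.9 * s * length(ratio)^(-1 / 5)
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = 512)
  dens <- colSums(w / sum(w) * outer(ratio, grid,
                                     function(r, g) stats::dnorm(g, r, bw)))
  grid[which.max(dens)]
}

#' Mode-based estimators (simple and weighted)
#'
#' The causal estimate is the argmax of a normal-kernel smoothed density of
#' the Wald ratios, evaluated on a fixed 512-point grid spanning the ratio
#' range padded by three bandwidths; the bandwidth is `phi` times the modified
#' Silverman rule `0.9 min(sd, mad) n^(-1/5)`. The weighted variant weights
#' each ratio by its inverse variance in the density; the simple variant uses
#' equal weights. Standard errors are by seeded parametric bootstrap, as for
#' the weighted median. Consistent when the largest group of instruments
#' sharing the same ratio is valid (zero modal pleiotropy).
#'
#' @param h a `harmonized_set` with at least 3 instruments.
#' @param weighted use inverse-variance weights in the density?
#' @param phi bandwidth multiplier.
#' @param n_boot,seed bootstrap settings.
#' @return An `mr_estimate` (method `"weighted_mode"` or `"simple_mode"`).
#' @export
mr_mode <- function(h, weighted = FALSE, phi = 1.0, n_boot = 1000, seed = 1) {
  wr <- wald_ratios(h)
  n <- nrow(wr)
  if (n < 3) stop("mode estimators require at least 3 instruments (got ", n, ")")
  w <- if (weighted) wr$w else rep(1, n)
  beta <- .kde_mode(wr$ratio, w, phi)
  se <- .boot_se(wr, function(r) .kde_mode(r, w, phi), n_boot, seed)
  new_mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
                  beta, se, n, seed = as.integer(seed))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (ratio_j - beta_ivw_fixed)^2` across the per-instrument
#' Wald ratios, on `n - 1` degrees of freedom, with an upper-tail chi-square
#' p-value. Q = 0 (p = 1) when all ratios agree.
#'
#' @param h a `harmonized_set` with at least 2 instruments.
#' @return List with `q_stat`, `df`, `q_pval`.
#' @export
cochran_q <- function(h) {
  wr <- wald_ratios(h)
  n <- nrow(wr)
  if (n < 2) stop("Cochran's Q requires at least 2 instruments (got ", n, ")")
  beta <- sum(wr$w * wr$ratio) / sum(wr$w)
  q <- sum(wr$w * (wr$ratio - beta)^2)
  list(q_stat = q, df = n - 1,
       q_pval = stats::pchisq(q, n - 1, lower.tail = FALSE))
}
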