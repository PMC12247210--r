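#' Construct an MR estimate
#'
#' Container for one method's causal estimate. Confidence bounds use the
#' normal 1.96 multiplier except MR-Egger, which supplies t-quantile
#' bounds; the odds-ratio scale is the exponentiated log-odds scale.
#'
#' @param method Estimator label.
#' @param beta,se Causal effect (log-odds for binary outcomes) and its se.
#' @param n_snps Number of instruments used.
#' @param pvalue P-value; computed from the normal approximation when NULL.
#' @param ci_mult CI multiplier (1.96 default; Egger passes a t quantile).
#' @param extras Named list of method-specific quantities.
#' @return An object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, n_snps, pvalue = NULL,
                        ci_mult = 1.96, extras = list()) {
  stopifnot(is.numeric(beta), length(beta) == 1L)
  if (is.null(pvalue)) pvalue <- 2 * stats::pnorm(-abs(beta / se))
  ci_low <- beta - ci_mult * se
  ci_high <- beta + ci_mult * se
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = ci_low, ci_high = ci_high, pvalue = pvalue,
    or_ = exp(beta), or_low = exp(ci_low), or_high = exp(ci_high),
    n_snps = n_snps, extras = extras
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNPs): beta %.4f (se %.4f), 95%% CI [%.4f, %.4f], p %.3g\n",
              x$method, x$n_snps, x$beta, x$se, x$ci_low, x$ci_high, x$pvalue))
  cat(sprintf("  OR %.3f [%.3f, %.3f]\n", x$or_, x$or_low, x$or_high))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$n_snps, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, p = x$pvalue,
             or = x$or_, or_low = x$or_low, or_high = x$or_high,
             stringsAsFactors = FALSE)
}

#' Per-SNP Wald ratio
#'
#' The building block of all estimators: the outcome effect divided by
#' the exposure effect, with the first-order standard error
#' `|se_out / beta_exp|` that ignores exposure-side sampling error
#' (the no-measurement-error approximation, justified upstream by the
#' F > 10 instrument filter).
#'
#' @param beta_exp,se_exp Exposure effect and se.
#' @param beta_out,se_out Outcome effect and se.
#' @return An `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (any(beta_exp == 0)) stop("Wald ratio undefined for beta_exp = 0")
  mr_estimate("wald", beta_out / beta_exp, abs(se_out / beta_exp), n_snps = 1L)
}

# per-SNP ratios and their first-order variances/weights
.ratios <- function(hs) {
  p <- hs$pairs
  if (any(p$beta_exposure == 0)) stop("Wald ratio undefined for beta_exposure = 0")
  r <- p$beta_outcome / p$beta_exposure
  se <- abs(p$se_outcome / p$beta_exposure)
  list(r = r, se = se, w = 1 / se^2)
}

#' Inverse-variance weighted estimator
#'
#' Precision-weighted combination of per-SNP Wald ratios; equivalently the
#' weighted least-squares regression of outcome on exposure effects
#' through the origin with weights `1/se_outcome^2`. The
#' `multiplicative_random` flavour (default) inflates the fixed-effect
#' standard error by `max(1, sqrt(Q/(k-1)))` to absorb balanced
#' heterogeneity; `fixed` uses the model-based standard error.
#'
#' @param hs A `harmonized_set`.
#' @param mode `"multiplicative_random"` or `"fixed"`.
#' @return An `mr_estimate`; `extras` holds `q_stat`, `q_df`, `q_pvalue`.
#' @export
mr_ivw <- function(hs, mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  rt <- .ratios(hs)
  k <- length(rt$r)
  if (k < 1L) stop("IVW requires at least one SNP")
  beta <- sum(rt$w * rt$r) / sum(rt$w)
  se_fixed <- sqrt(1 / sum(rt$w))
  q <- sum(rt$w * (rt$r - beta)^2)
  scale <- if (mode == "multiplicative_random" && k >= 2L)
    max(1, sqrt(q / (k - 1))) else 1
  se <- se_fixed * scale
  mr_estimate(if (mode == "fixed") "ivw_fixed" else "ivw_mre",
              beta, se, n_snps = k,
              extras = list(q_stat = q, q_df = k - 1L,
                            q_pvalue = if (k >= 2L)
                              stats::pchisq(q, k - 1L, lower.tail = FALSE)
                            else NA_real_))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with an
#' unconstrained intercept (weights `1/se_outcome^2`), after orienting
#' every pair so the exposure effect is positive. The slope is the causal
#' estimate; the intercept is the average directional-pleiotropy effect
#' and its test is reported in `extras`. Inference uses the t distribution
#' with k - 2 degrees of freedom and a multiplicative residual scale
#' bounded below by 1.
#'
#' @param hs A `harmonized_set` with at least 3 SNPs.
#' @return An `mr_estimate`; `extras` holds `intercept`, `intercept_se`,
#'   `intercept_p`, `residual_scale`.
#' @export
mr_egger <- function(hs) {
  p <- hs$pairs
  k <- nrow(p)
  if (k < 3L) stop("insufficient SNPs for Egger regression (need >= 3)")
  flip <- sign(p$beta_exposure)
  bx <- abs(p$beta_exposure)
  by <- p$beta_outcome * flip
  w <- 1 / p$se_outcome^2

  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  denom <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / denom
  icpt <- (swy - slope * swx) / sw

  resid <- by - icpt - slope * bx
  scale <- max(1, sqrt(sum(w * resid^2) / (k - 2)))
  se_slope <- scale * sqrt(sw / denom)
  se_icpt <- scale * sqrt(swxx / denom)

  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = k - 2)
  p_icpt <- 2 * stats::pt(-abs(icpt / se_icpt), df = k - 2)
  mr_estimate("egger", slope, se_slope, n_snps = k, pvalue = p_slope,
              ci_mult = stats::qt(0.975, df = k - 2),
              extras = list(intercept = icpt, intercept_se = se_icpt,
                            intercept_p = p_icpt, residual_scale = scale))
}

# point estimate of the weighted median of Wald ratios (cumulative-weight
# interpolation at 0.5)
.weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(r[1])
  if (cum[length(cum)] <= 0.5) return(r[length(r)])
  below <- max(which(cum < 0.5))
  r[below] + (r[below + 1] - r[below]) *
    (0.5 - cum[below]) / (cum[below + 1] - cum[below])
}

# canonical pair order (by snp_id), so bootstrap draws do not depend on
# the input row order
.canonical <- function(hs) {
  hs$pairs <- hs$pairs[order(hs$pairs$snp_id), , drop = FALSE]
  hs
}

# parametric bootstrap over per-SNP effect estimates; returns sd of the
# statistic computed by `fn(bx, by)` over n_boot seeded draws
.bootstrap_se <- function(hs, fn, n_boot, seed) {
  p <- hs$pairs
  k <- nrow(p)
  with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(k, p$beta_exposure, p$se_exposure)
      by <- stats::rnorm(k, p$beta_outcome, p$se_outcome)
      fn(bx, by)
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted median estimator
#'
#' Orders the per-SNP Wald ratios and returns the value at which the
#' cumulative inverse-variance weight crosses one half (with linear
#' interpolation); consistent when at least half of the total instrument
#' weight comes from valid instruments. The standard error is a seeded
#' parametric bootstrap over the per-SNP effect estimates.
#'
#' @param hs A `harmonized_set` with at least 3 SNPs.
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed RNG seed for the bootstrap (default 1).
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(hs, n_boot = 1000, seed = 1L) {
  hs <- .canonical(hs)
  rt <- .ratios(hs)
  if (length(rt$r) < 3L) stop("weighted median requires at least 3 SNPs")
  beta <- .weighted_median_point(rt$r, rt$w)
  p <- hs$pairs
  se <- .bootstrap_se(hs, function(bx, by) {
    .weighted_median_point(by / bx, bx^2 / p$se_outcome^2)
  }, n_boot, seed)
  mr_estimate("weighted_median", beta, se, n_snps = length(rt$r))
}

# kernel-density mode of ratios r with weights w and bandwidth h:
# coarse grid over [min(r), max(r)] refined by local optimization
.kde_mode <- function(r, w, h) {
  w <- w / sum(w)
  f <- function(x) vapply(x, function(xi) sum(w * stats::dnorm(xi, r, h)),
                          numeric(1))
  lo <- min(r); hi <- max(r)
  if (lo == hi) return(lo)
  grid <- seq(lo, hi, length.out = 512L)
  fx <- f(grid)
  i <- which.max(fx)
  step <- grid[2] - grid[1]
  stats::optimize(f, lower = max(lo, grid[i] - step),
                  upper = min(hi, grid[i] + step), maximum = TRUE,
                  tol = 1e-8)$maximum
}

# modified Silverman bandwidth on the ratios
.mode_bandwidth <- function(r, phi) {
  s <- 0.9 * min(stats::sd(r), stats::mad(r)) * length(r)^(-1 / 5)
  phi * s
}

#' Mode-based estimators (simple and weighted mode)
#'
#' The causal estimate is the mode of the normal-kernel density of the
#' per-SNP Wald ratios, with bandwidth `phi` times the modified Silverman
#' rule `0.9 min(sd, mad) k^(-1/5)`; consistent when the largest
#' homogeneous cluster of instruments is valid (the plurality-validity
#' assumption). The weighted variant weights each kernel by the ratio's
#' inverse variance. When all ratios coincide (zero bandwidth) that common
#' ratio is returned. Standard error by seeded parametric bootstrap.
#'
#' @param hs A `harmonized_set` with at least 3 SNPs.
#' @param weighted Use inverse-variance kernel weights (default FALSE).
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed RNG seed (default 1).
#' @return An `mr_estimate` with method `"simple_mode"` or
#'   `"weighted_mode"`.
#' @export
mr_mode <- function(hs, weighted = FALSE, phi = 1, n_boot = 1000, seed = 1L) {
  hs <- .canonical(hs)
  rt <- .ratios(hs)
  k <- length(rt$r)
  if (k < 3L) stop("mode estimator requires at least 3 SNPs")
  point <- function(r, w) {
    h <- .mode_bandwidth(r, phi)
    if (!is.finite(h) || h <= 0) return(r[1])
    .kde_mode(r, w, h)
  }
  wts <- if (weighted) rt$w else rep(1, k)
  beta <- point(rt$r, wts)
  p <- hs$pairs
  se <- .bootstrap_se(hs, function(bx, by) {
    r <- by / bx
    point(r, if (weighted) bx^2 / p$se_outcome^2 else rep(1, k))
  }, n_boot, seed)
  mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
              beta, se, n_snps = k)
}

#' Convert a log-odds effect to the odds-ratio scale
#'
#' @param beta Log-odds effect.
#' @param se Its standard error (> 0).
#' @return Named numeric vector `or_`, `or_low`, `or_high` (95% bounds,
#'   normal approximation).
#' @export
beta_to_or <- function(beta, se) {
  if (any(se <= 0)) stop("se must be positive")
  z <- 1.96
  c(or_ = exp(beta), or_low = exp(beta - z * se), or_high = exp(beta + z * se))
}

#' Run the full estimator battery
#'
#' Applies IVW (both flavours), MR-Egger, weighted median, simple mode and
#' weighted mode to one harmonized exposure-outcome set.
#'
#' @param hs A `harmonized_set`.
#' @param n_boot,seed Bootstrap settings for median/mode estimators.
#' @param phi Mode bandwidth multiplier.
#' @return Data frame with one row per method (columns `exposure`,
#'   `outcome`, `method`, `nsnp`, `beta`, `se`, `ci_low`, `ci_high`, `p`,
#'   `or`, `or_low`, `or_high`).
#' @export
mr_all <- function(hs, n_boot = 1000, seed = 1L, phi = 1) {
  k <- nrow(hs$pairs)
  ests <- list(mr_ivw(hs), mr_ivw(hs, "fixed"))
  if (k >= 3L) {
    ests <- c(ests, list(
      mr_egger(hs),
      mr_weighted_median(hs, n_boot = n_boot, seed = seed),
      mr_mode(hs, weighted = FALSE, phi = phi, n_boot = n_boot, seed = seed + 1L),
      mr_mode(hs, weighted = TRUE, phi = phi, n_boot = n_boot, seed = seed + 2L)
    ))
  }
  out <- do.call(rbind, lapply(ests, as.data.frame))
  cbind(data.frame(exposure = hs$exposure_name, outcome = hs$outcome_name,
                   stringsAsFactors = FALSE), out)
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state.
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
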