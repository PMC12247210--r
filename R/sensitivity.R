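#' Cochran's Q heterogeneity test
#'
#' Q = sum of w_i (ratio_i - pooled)^2 over per-SNP Wald ratios with
#' inverse-variance weights; p-value from the chi-square distribution with
#' k - 1 degrees of freedom. By convention the pooled estimate is the
#' fixed-effect IVW estimate unless supplied.
#'
#' @param hs A `harmonized_set` with at least 2 SNPs.
#' @param pooled_beta Pooled causal estimate; fixed-effect IVW when NULL.
#' @return List with `q_stat`, `q_df`, `q_pvalue`.
#' @export
cochran_q <- function(hs, pooled_beta = NULL) {
  rt <- .ratios(hs)
  k <- length(rt$r)
  if (k < 2L) stop("Cochran's Q requires at least 2 SNPs")
  if (is.null(pooled_beta)) pooled_beta <- sum(rt$w * rt$r) / sum(rt$w)
  q <- sum(rt$w * (rt$r - pooled_beta)^2)
  list(q_stat = q, q_df = k - 1L,
       q_pvalue = stats::pchisq(q, k - 1L, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Re-runs the IVW estimator excluding each SNP in turn, to expose
#' estimates driven by a single influential variant. An exclusion is
#' flagged when it changes the sign of the estimate or moves its p-value
#' across 0.05 relative to the full-set fit.
#'
#' @param hs A `harmonized_set` with at least 3 SNPs.
#' @param mode IVW flavour passed to [mr_ivw()].
#' @return Data frame with one row per excluded SNP: `snp_id_excluded`,
#'   `ivw_beta`, `ivw_se`, `ivw_p`, `flag`; attribute `full` holds the
#'   full-set estimate.
#' @export
leave_one_out <- function(hs, mode = "multiplicative_random") {
  k <- nrow(hs$pairs)
  if (k < 3L) stop("leave-one-out requires at least 3 SNPs")
  full <- mr_ivw(hs, mode)
  rows <- lapply(seq_len(k), function(i) {
    sub <- hs
    sub$pairs <- hs$pairs[-i, , drop = FALSE]
    est <- mr_ivw(sub, mode)
    data.frame(snp_id_excluded = hs$pairs$snp_id[i],
               ivw_beta = est$beta, ivw_se = est$se, ivw_p = est$pvalue,
               flag = sign(est$beta) != sign(full$beta) ||
                 (est$pvalue < 0.05) != (full$pvalue < 0.05),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values (via [stats::p.adjust()]), monotone in rank,
#' capped at 1, order-preserving.
#'
#' @param pvalues Numeric vector in (0, 1].
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Assemble the full sensitivity report for one exposure-outcome pair
#'
#' Runs Cochran's Q, MR-Egger intercept test, MR-PRESSO and leave-one-out,
#' and applies [robustness_verdict()].
#'
#' @param hs A `harmonized_set` (>= 4 SNPs for the PRESSO component).
#' @param n_sim PRESSO simulation draws.
#' @param seed PRESSO seed.
#' @param alpha_outlier PRESSO outlier level.
#' @return List of class `sensitivity_report` with fields `q_stat`, `q_df`,
#'   `q_pvalue`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_p`, `presso_global_p`, `presso_outliers`,
#'   `presso_distortion_p`, `loo`, `verdict`.
#' @export
sensitivity_report <- function(hs, n_sim = 1000, seed = 1L,
                               alpha_outlier = 0.05) {
  q <- cochran_q(hs)
  eg <- mr_egger(hs)
  pr <- mr_presso(hs, n_sim = n_sim, seed = seed,
                  alpha_outlier = alpha_outlier)
  rep <- structure(list(
    q_stat = q$q_stat, q_df = q$q_df, q_pvalue = q$q_pvalue,
    egger_intercept = eg$extras$intercept,
    egger_intercept_se = eg$extras$intercept_se,
    egger_intercept_p = eg$extras$intercept_p,
    presso_global_p = pr$presso_global_p,
    presso_global_p_corrected = pr$presso_global_p_corrected,
    presso_outliers = pr$presso_outliers,
    presso_distortion_p = pr$presso_distortion_p,
    presso_corrected = pr$corrected_estimate,
    loo = leave_one_out(hs),
    verdict = NA
  ), class = "sensitivity_report")
  rep$verdict <- robustness_verdict(rep)
  rep
}

#' Robustness verdict over the sensitivity battery
#'
#' TRUE iff none of the three named sensitivity tests rejects at 0.05:
#' Cochran's Q p >= 0.05, Egger intercept p >= 0.05 and the MR-PRESSO
#' global p >= 0.05 (the post-outlier-removal global p when outliers were
#' removed). The comparison is inclusive at 0.05. Leave-one-out flags are
#' advisory and do not enter the verdict; nor does the PRESSO distortion
#' test.
#'
#' @param report A `sensitivity_report` (or list with the needed fields).
#' @return Logical.
#' @export
robustness_verdict <- function(report) {
  need <- c("q_pvalue", "egger_intercept_p", "presso_global_p")
  miss <- vapply(need, function(f) is.null(report[[f]]) ||
                   is.na(report[[f]]), logical(1))
  if (any(miss))
    stop("incomplete sensitivity report: missing ",
         paste(need[miss], collapse = ", "))
  g <- report$presso_global_p
  gc <- report$presso_global_p_corrected
  if (length(report$presso_outliers) > 0 && !is.null(gc) && !is.na(gc))
    g <- gc
  report$q_pvalue >= 0.05 && report$egger_intercept_p >= 0.05 && g >= 0.05
}

#' Write a sensitivity report as JSON
#' @param report A `sensitivity_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_report <- function(report, path) {
  out <- unclass(report)
  out$presso_corrected <- if (!is.null(out$presso_corrected))
    as.data.frame(out$presso_corrected) else NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
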