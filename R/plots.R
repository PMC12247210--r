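#' Forest plot of MR estimates
#'
#' One row per method (or per exposure-outcome pair), point estimate with
#' 95% CI on the odds-ratio scale.
#'
#' @param estimates Data frame from [mr_all()] (rows from several runs
#'   can be concatenated).
#' @param log_scale Plot on the log (beta) scale instead of OR
#'   (default FALSE).
#' @return A ggplot object.
#' @export
plot_forest <- function(estimates, log_scale = FALSE) {
  d <- estimates
  d$label <- paste(d$exposure, "→", d$outcome, "|", d$method)
  if (log_scale) {
    d$x <- d$beta; d$xlo <- d$ci_low; d$xhi <- d$ci_high
    ref <- 0; xlab <- "causal effect (log odds)"
  } else {
    d$x <- d$or; d$xlo <- d$or_low; d$xhi <- d$or_high
    ref <- 1; xlab <- "odds ratio (95% CI)"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$label)) +
    ggplot2::geom_vline(xintercept = ref, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$xlo, xmax = .data$xhi),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = xlab, y = NULL) +
    ggplot2::theme_bw()
}

#' Scatter plot of per-SNP effects with fitted estimator lines
#'
#' Outcome effect against exposure effect, one point per instrument with
#' error bars, overlaid with the IVW (through-origin) and MR-Egger
#' (free-intercept) fits.
#'
#' @param hs A `harmonized_set`.
#' @return A ggplot object.
#' @export
plot_scatter <- function(hs) {
  p <- hs$pairs
  ivw <- mr_ivw(hs)
  lines <- data.frame(method = "IVW", intercept = 0, slope = ivw$beta,
                      stringsAsFactors = FALSE)
  if (nrow(p) >= 3L) {
    eg <- mr_egger(hs)
    lines <- rbind(lines, data.frame(method = "MR-Egger",
                                     intercept = eg$extras$intercept,
                                     slope = eg$beta))
  }
  ggplot2::ggplot(p, ggplot2::aes(x = .data$beta_exposure,
                                  y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$beta_outcome - 1.96 * .data$se_outcome,
      ymax = .data$beta_outcome + 1.96 * .data$se_outcome),
      width = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$beta_exposure - 1.96 * .data$se_exposure,
      xmax = .data$beta_exposure + 1.96 * .data$se_exposure),
      height = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(intercept = .data$intercept,
                                      slope = .data$slope,
                                      colour = .data$method)) +
    ggplot2::labs(x = paste("SNP effect on", hs$exposure_name),
                  y = paste("SNP effect on", hs$outcome_name),
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' Leave-one-out plot
#'
#' IVW estimate (with 95% CI) after excluding each SNP in turn, with the
#' full-set estimate as reference line.
#'
#' @param loo Result of [leave_one_out()].
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo) {
  full <- attr(loo, "full")
  d <- loo
  d$lo <- d$ivw_beta - 1.96 * d$ivw_se
  d$hi <- d$ivw_beta + 1.96 * d$ivw_se
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ivw_beta,
                                  y = .data$snp_id_excluded)) +
    ggplot2::geom_vline(xintercept = full$beta, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "IVW estimate excluding this SNP", y = NULL) +
    ggplot2::theme_bw()
}
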