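#' Mediated (indirect) effect of an exposure through one mediator
#'
#' Two-step product-of-coefficients mediation: the mediated effect is
#' `beta1 * beta2`, the product of the exposure-to-mediator effect and
#' the mediator-to-outcome effect. Two variance pairings for the 95% CI
#' are available:
#' \describe{
#'   \item{`"delta"`}{(default) the standard first-order delta-method
#'     variance of a product, `beta2^2 se1^2 + beta1^2 se2^2`;}
#'   \item{`"paper_compat"`}{the pairing `beta1^2 se1^2 + beta2^2 se2^2`,
#'     which pairs each coefficient with its own standard error. The two
#'     coincide when `|beta1| = |beta2|`. This variant exists to replay
#'     published mediation tables computed with this pairing.}
#' }
#'
#' @param beta1,se1 Exposure-to-mediator effect and its se (> 0).
#' @param beta2,se2 Mediator-to-outcome effect and its se (> 0).
#' @param pairing `"delta"` or `"paper_compat"`.
#' @return List with `effect`, `se`, `ci_low`, `ci_high`, `pairing`.
#' @export
mediated_effect <- function(beta1, se1, beta2, se2,
                            pairing = c("delta", "paper_compat")) {
  pairing <- match.arg(pairing)
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive")
  effect <- beta1 * beta2
  se <- if (pairing == "delta")
    sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)
  else
    sqrt(beta1^2 * se1^2 + beta2^2 * se2^2)
  z <- 1.96
  list(effect = effect, se = se,
       ci_low = effect - z * se, ci_high = effect + z * se,
       pairing = pairing)
}

#' Mediated proportion
#'
#' The fraction of the total effect transmitted through the mediator:
#' `mediated effect / beta_all`. Its confidence bounds divide the
#' mediated-effect bounds by `beta_all`, treating the total effect as
#' fixed (its uncertainty is not propagated). When `beta_all < 0` this
#' transformation reverses the bound order; the raw (unordered)
#' orientation is reported as `mp_ci_low`/`mp_ci_high` alongside an
#' ordered form. Proportions outside [0, 1] are flagged as suppression /
#' inconsistent mediation (the mediated path opposes the total effect).
#'
#' @param effect Mediated effect (`beta1 * beta2`).
#' @param me_ci_low,me_ci_high 95% bounds of the mediated effect.
#' @param beta_all Total exposure-to-outcome effect (non-zero).
#' @return List with `proportion`, `mp_ci_low`, `mp_ci_high` (raw
#'   orientation: the images of the mediated-effect bounds in order),
#'   `mp_ci_ordered` (sorted), `suppression` flag. All proportions are
#'   fractions (multiply by 100 for percent).
#' @export
mediated_proportion <- function(effect, me_ci_low, me_ci_high, beta_all) {
  if (beta_all == 0) stop("beta_all must be non-zero")
  prop <- effect / beta_all
  lo <- me_ci_low / beta_all
  hi <- me_ci_high / beta_all
  list(proportion = prop, mp_ci_low = lo, mp_ci_high = hi,
       mp_ci_ordered = sort(c(lo, hi)),
       suppression = prop < 0 || prop > 1)
}

#' Attach study labels to an MR estimate
#'
#' @param est An `mr_estimate`.
#' @param exposure,outcome Study labels.
#' @return The estimate with `exposure` and `outcome` fields set.
#' @export
mr_label <- function(est, exposure, outcome) {
  est$exposure <- exposure
  est$outcome <- outcome
  est
}

#' Two-step MR mediation for one pathway
#'
#' Assembles exposure -> mediator (`step1`, beta1), mediator -> outcome
#' (`step2`, beta2) and exposure -> outcome (`total`, beta_all) estimates
#' (IVW by convention) into a mediation result with mediated effect, CI,
#' and mediated proportion. Pathway consistency is checked from the
#' labels attached with [mr_label()]: step1's outcome must equal step2's
#' exposure, step1's exposure must equal total's exposure, and step2's
#' outcome must equal total's outcome.
#'
#' @param step1,step2,total `mr_estimate` objects carrying labels.
#' @param pairing CI variance pairing, see [mediated_effect()].
#' @return An object of class `mediation_result`.
#' @export
two_step_mediation <- function(step1, step2, total,
                               pairing = c("delta", "paper_compat")) {
  pairing <- match.arg(pairing)
  labs <- function(e) c(e$exposure %||% NA_character_, e$outcome %||% NA_character_)
  l1 <- labs(step1); l2 <- labs(step2); lt <- labs(total)
  if (anyNA(c(l1, l2, lt)))
    stop("estimates must carry exposure/outcome labels; see mr_label()")
  if (l1[2] != l2[1] || l1[1] != lt[1] || l2[2] != lt[2])
    stop("pathway mismatch: step1 ", l1[1], "->", l1[2],
         ", step2 ", l2[1], "->", l2[2], ", total ", lt[1], "->", lt[2])

  me <- mediated_effect(step1$beta, step1$se, step2$beta, step2$se, pairing)
  mp <- mediated_proportion(me$effect, me$ci_low, me$ci_high, total$beta)
  structure(list(
    pathway = c(exposure = l1[1], mediator = l1[2], outcome = l2[2]),
    beta1 = step1$beta, se1 = step1$se,
    beta2 = step2$beta, se2 = step2$se,
    beta_all = total$beta, se_all = total$se,
    mediated_effect = me$effect, me_se = me$se,
    me_ci_low = me$ci_low, me_ci_high = me$ci_high,
    mediated_proportion = mp$proportion,
    mp_ci_low = mp$mp_ci_low, mp_ci_high = mp$mp_ci_high,
    suppression = mp$suppression,
    ci_pairing = pairing
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("%s -> %s -> %s\n", x$pathway[1], x$pathway[2], x$pathway[3]))
  cat(sprintf("  beta1 %.4f, beta2 %.4f, beta_all %.4f\n",
              x$beta1, x$beta2, x$beta_all))
  cat(sprintf("  mediated effect %.4f [%.3f, %.3f] (%s pairing)\n",
              x$mediated_effect, x$me_ci_low, x$me_ci_high, x$ci_pairing))
  cat(sprintf("  mediated proportion %.1f%% [%.1f%%, %.1f%%]%s\n",
              100 * x$mediated_proportion, 100 * x$mp_ci_low,
              100 * x$mp_ci_high,
              if (x$suppression) "  [suppression/inconsistent mediation]" else ""))
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(exposure = x$pathway[1], mediator = x$pathway[2],
             outcome = x$pathway[3],
             beta1 = x$beta1, se1 = x$se1, beta2 = x$beta2, se2 = x$se2,
             beta_all = x$beta_all, se_all = x$se_all,
             mediated_effect = x$mediated_effect,
             me_ci_low = x$me_ci_low, me_ci_high = x$me_ci_high,
             mediated_proportion = x$mediated_proportion,
             mp_ci_low = x$mp_ci_low, mp_ci_high = x$mp_ci_high,
             suppression = x$suppression, ci_pairing = x$ci_pairing,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Replay a table of published pathway estimates through the mediation
#' module
#'
#' Accepts a table of per-pathway IVW effects with printed 95% CIs
#' (columns: `exposure`, `mediator`, `outcome`, `beta1`, `b1_lo`, `b1_hi`,
#' `beta2`, `b2_lo`, `b2_hi`, `beta_all`, `ball_lo`, `ball_hi`),
#' back-derives each standard error as CI width / 3.92, and runs
#' [two_step_mediation()] on every row. This is how a published mediation
#' table is reproduced when only point estimates and CIs are available.
#'
#' @param tab Data frame (or TSV path) in the format above.
#' @param pairing CI variance pairing; `"paper_compat"` reproduces tables
#'   computed with the own-se pairing.
#' @return List of `mediation_result`, one per row.
#' @export
replay_mediation_table <- function(tab, pairing = "paper_compat") {
  if (is.character(tab))
    tab <- utils::read.table(tab, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  se_from_ci <- function(lo, hi) (hi - lo) / 3.92
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    s1 <- mr_label(mr_estimate("ivw_mre", r$beta1, se_from_ci(r$b1_lo, r$b1_hi),
                               n_snps = NA_integer_), r$exposure, r$mediator)
    s2 <- mr_label(mr_estimate("ivw_mre", r$beta2, se_from_ci(r$b2_lo, r$b2_hi),
                               n_snps = NA_integer_), r$mediator, r$outcome)
    tot <- mr_label(mr_estimate("ivw_mre", r$beta_all,
                                se_from_ci(r$ball_lo, r$ball_hi),
                                n_snps = NA_integer_), r$exposure, r$outcome)
    two_step_mediation(s1, s2, tot, pairing = pairing)
  })
}

#' Write mediation results as a TSV table
#'
#' @param results List of `mediation_result` (or a single one).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mediation_table <- function(results, path) {
  if (inherits(results, "mediation_result")) results <- list(results)
  tab <- do.call(rbind, lapply(results, as.data.frame))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled example pathway table
#'
#' Path to the packaged six-pathway example of beverage -> serum
#' metabolite -> chronic-renal-failure IVW estimates (log-odds effects
#' with 95% CIs), for use with [replay_mediation_table()].
#'
#' @return File path.
#' @export
example_pathway_table <- function() {
  system.file("extdata", "beverage_crf_pathways.tsv", package = "mrmediate",
              mustWork = TRUE)
}
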