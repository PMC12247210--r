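#' Harmonize exposure and outcome summary statistics to a common effect allele
#'
#' Intersects two studies by SNP identifier and aligns the outcome effects
#' to the exposure study's effect allele. When the outcome study reports
#' the same pair of alleles with effect/other swapped, its beta is negated
#' and its effect-allele frequency replaced by 1 - eaf. When the outcome
#' alleles match only after complementing (a strand flip between studies),
#' they are complemented before matching. Palindromic SNPs (A/T, C/G) are
#' handled by `palindrome_policy`:
#' \describe{
#'   \item{`"remove"`}{(default) drop every palindromic SNP;}
#'   \item{`"infer_by_eaf"`}{keep a palindromic SNP when both studies'
#'     allele frequencies fall on the same side of 0.5 and are at least
#'     `eaf_margin` away from it (frequencies on opposite sides imply the
#'     outcome study reports the other allele, so beta is negated);
#'     ambiguous frequencies are dropped.}
#' }
#' SNPs whose allele pairs cannot be reconciled by swap or strand flip are
#' dropped with reason `"allele_mismatch"`. Every SNP present in both
#' inputs is accounted for either in `pairs` or in `dropped`.
#'
#' @param exposure,outcome `sumstats` data frames (see [read_sumstats()]);
#'   SNP ids must be unique within each.
#' @param palindrome_policy `"remove"` or `"infer_by_eaf"`.
#' @param eaf_margin Minimum |eaf - 0.5| for `"infer_by_eaf"`.
#' @return An object of class `harmonized_set`: a list with
#'   \item{pairs}{data frame with `snp_id`, `beta_exposure`, `se_exposure`,
#'     `pvalue_exposure`, `beta_outcome`, `se_outcome`, `pvalue_outcome`,
#'     `eaf_exposure`, `eaf_outcome`, `effect_allele`, `other_allele`,
#'     `chrom`, `pos`, `n_exposure`, `n_outcome`}
#'   \item{dropped}{data frame with `snp_id`, `reason`}
#'   \item{exposure_name, outcome_name}{study labels}
#' @export
harmonize <- function(exposure, outcome, palindrome_policy = c("remove", "infer_by_eaf"),
                      eaf_margin = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (nrow(exposure) == 0L || nrow(outcome) == 0L)
    stop("both exposure and outcome sumstats must be non-empty")
  if (anyDuplicated(exposure$snp_id) || anyDuplicated(outcome$snp_id))
    stop("SNP ids must be unique within each study")

  common <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(common) == 0L)
    stop("no SNPs shared between exposure and outcome studies")
  ex <- exposure[match(common, exposure$snp_id), ]
  ou <- outcome[match(common, outcome$snp_id), ]

  k <- length(common)
  action <- rep(NA_character_, k)  # keep | flip | drop:<reason>
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)

  same <- ou$effect_allele == ex$effect_allele & ou$other_allele == ex$other_allele
  swap <- ou$effect_allele == ex$other_allele & ou$other_allele == ex$effect_allele
  # strand flip: complement the outcome alleles, then re-test (no-op for
  # palindromic SNPs, which complement onto themselves)
  fea <- flip_allele(ou$effect_allele); foa <- flip_allele(ou$other_allele)
  same_f <- !pal & fea == ex$effect_allele & foa == ex$other_allele
  same_any <- same | same_f
  swap_any <- swap | (!pal & fea == ex$other_allele & foa == ex$effect_allele)

  action[same_any] <- "keep"
  action[!same_any & swap_any] <- "flip"
  action[is.na(action)] <- "drop:allele_mismatch"

  if (any(pal)) {
    if (palindrome_policy == "remove") {
      action[pal] <- "drop:palindromic"
    } else {
      ef <- ex$eaf; of <- ou$eaf
      usable <- pal & !is.na(ef) & !is.na(of) &
        abs(ef - 0.5) > eaf_margin & abs(of - 0.5) > eaf_margin
      same_side <- (ef - 0.5) * (of - 0.5) > 0
      action[usable & same_side] <- "keep"
      action[usable & !same_side] <- "flip"
      action[pal & !usable] <- "drop:palindromic_ambiguous_eaf"
    }
  }

  keep <- action %in% c("keep", "flip")
  flip <- action == "flip"
  beta_out <- ifelse(flip, -ou$beta, ou$beta)
  eaf_out <- ifelse(flip, 1 - ou$eaf, ou$eaf)

  pairs <- data.frame(
    snp_id = common[keep],
    beta_exposure = ex$beta[keep], se_exposure = ex$se[keep],
    pvalue_exposure = ex$pvalue[keep],
    beta_outcome = beta_out[keep], se_outcome = ou$se[keep],
    pvalue_outcome = ou$pvalue[keep],
    eaf_exposure = ex$eaf[keep], eaf_outcome = eaf_out[keep],
    effect_allele = ex$effect_allele[keep], other_allele = ex$other_allele[keep],
    chrom = ex$chrom[keep], pos = ex$pos[keep],
    n_exposure = ex$n[keep], n_outcome = ou$n[keep],
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL
  dropped <- data.frame(
    snp_id = common[!keep],
    reason = sub("^drop:", "", action[!keep]),
    stringsAsFactors = FALSE
  )
  new_harmonized_set(pairs, dropped,
                     exposure_name = attr(exposure, "study_name") %||% "exposure",
                     outcome_name = attr(outcome, "study_name") %||% "outcome")
}

#' Construct a harmonized set directly
#'
#' Low-level constructor used by [harmonize()] and by the simulator/tests
#' to build already-aligned exposure/outcome effect pairs.
#'
#' @param pairs Data frame with at least `snp_id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`.
#' @param dropped Data frame with `snp_id`, `reason`.
#' @param exposure_name,outcome_name Study labels.
#' @return A `harmonized_set`.
#' @export
new_harmonized_set <- function(pairs, dropped = data.frame(snp_id = character(),
                                                           reason = character()),
                               exposure_name = "exposure",
                               outcome_name = "outcome") {
  stopifnot(all(c("snp_id", "beta_exposure", "se_exposure",
                  "beta_outcome", "se_outcome") %in% names(pairs)))
  structure(list(pairs = pairs, dropped = dropped,
                 exposure_name = exposure_name, outcome_name = outcome_name),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized set:", x$exposure_name, "->", x$outcome_name, "\n")
  cat("  ", nrow(x$pairs), "aligned SNPs,", nrow(x$dropped), "dropped\n")
  if (nrow(x$dropped))
    print(table(x$dropped$reason))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
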