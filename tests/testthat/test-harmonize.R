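exposure3 <- function() {
  make_ss(c("rs1", "rs2", "rs3"), beta = c(0.10, -0.05, 0.20),
          se = c(0.01, 0.01, 0.02),
          ea = c("A", "C", "G"), oa = c("G", "T", "C"), eaf = c(0.3, 0.4, 0.25))
}

test_that("aligned studies pass through unchanged; swapped alleles flip beta and eaf", {
  ex <- exposure3()
  ou <- make_ss(c("rs1", "rs2"), beta = c(0.05, 0.20), se = c(0.02, 0.02),
                ea = c("A", "T"), oa = c("G", "C"), eaf = c(0.31, 0.62))
  # rs1 aligned; rs2 alleles swapped relative to exposure (C/T vs T/C)
  hs <- harmonize(ex[1:2, ], ou)
  expect_equal(hs$pairs$beta_outcome[hs$pairs$snp_id == "rs1"], 0.05)
  expect_equal(hs$pairs$eaf_outcome[hs$pairs$snp_id == "rs1"], 0.31)
  expect_equal(hs$pairs$beta_outcome[hs$pairs$snp_id == "rs2"], -0.20)
  expect_equal(hs$pairs$eaf_outcome[hs$pairs$snp_id == "rs2"], 1 - 0.62)
  expect_equal(nrow(hs$dropped), 0L)
})

test_that("strand-flipped outcome alleles are complemented before matching", {
  ex <- make_ss("rs1", beta = 0.1, se = 0.01, ea = "A", oa = "G")
  # same SNP reported on the other strand: T/C complements to A/G
  ou_same <- make_ss("rs1", beta = 0.07, se = 0.02, ea = "T", oa = "C")
  hs <- harmonize(ex, ou_same)
  expect_equal(hs$pairs$beta_outcome, 0.07)
  # other strand AND swapped: C/T complements to G/A -> flip
  ou_swap <- make_ss("rs1", beta = 0.07, se = 0.02, ea = "C", oa = "T")
  hs2 <- harmonize(ex, ou_swap)
  expect_equal(hs2$pairs$beta_outcome, -0.07)
  # irreconcilable alleles are dropped with a reason
  ou_bad <- make_ss("rs1", beta = 0.07, se = 0.02, ea = "A", oa = "C")
  hs3 <- harmonize(ex, ou_bad)
  expect_equal(nrow(hs3$pairs), 0L)
  expect_equal(hs3$dropped$reason, "allele_mismatch")
})

test_that("palindromic SNPs are removed by default and resolved by eaf on request", {
  ex <- make_ss(c("rs1", "rs2"), beta = c(0.1, 0.1), se = 0.01,
                ea = c("A", "A"), oa = c("T", "G"), eaf = c(0.2, 0.3))
  ou <- make_ss(c("rs1", "rs2"), beta = c(0.05, 0.05), se = 0.02,
                ea = c("A", "A"), oa = c("T", "G"), eaf = c(0.21, 0.3))
  hs <- harmonize(ex, ou)
  expect_equal(hs$dropped$snp_id, "rs1")
  expect_equal(hs$dropped$reason, "palindromic")
  expect_equal(hs$pairs$snp_id, "rs2")

  # infer_by_eaf: frequencies on the same side of 0.5 keep the alignment
  hs2 <- harmonize(ex, ou, palindrome_policy = "infer_by_eaf")
  expect_true("rs1" %in% hs2$pairs$snp_id)
  expect_equal(hs2$pairs$beta_outcome[hs2$pairs$snp_id == "rs1"], 0.05)

  # opposite sides imply the other allele: beta negated, eaf reflected
  ou_flip <- ou
  ou_flip$eaf[1] <- 0.79
  hs3 <- harmonize(ex, ou_flip, palindrome_policy = "infer_by_eaf")
  expect_equal(hs3$pairs$beta_outcome[hs3$pairs$snp_id == "rs1"], -0.05)
  expect_equal(hs3$pairs$eaf_outcome[hs3$pairs$snp_id == "rs1"], 1 - 0.79)

  # frequencies too close to 0.5 stay ambiguous
  ou_amb <- ou
  ou_amb$eaf[1] <- 0.52
  hs4 <- harmonize(ex, ou_amb, palindrome_policy = "infer_by_eaf")
  expect_equal(hs4$dropped$reason, "palindromic_ambiguous_eaf")
})

test_that("every shared SNP lands in pairs or dropped, and harmonization is idempotent", {
  ex <- exposure3()
  ou <- make_ss(c("rs1", "rs2", "rs3", "rs9"), beta = c(0.05, 0.1, 0.2, 1),
                se = 0.02, ea = c("A", "C", "C", "A"),
                oa = c("G", "T", "A", "G"), eaf = c(0.3, 0.4, 0.2, 0.5))
  hs <- harmonize(ex, ou)
  shared <- intersect(ex$snp_id, ou$snp_id)
  expect_setequal(c(hs$pairs$snp_id, hs$dropped$snp_id), shared)

  # feed the harmonized outcome back in: nothing changes
  ou2 <- make_ss(hs$pairs$snp_id, beta = hs$pairs$beta_outcome,
                 se = hs$pairs$se_outcome, ea = hs$pairs$effect_allele,
                 oa = hs$pairs$other_allele, eaf = hs$pairs$eaf_outcome)
  hs2 <- harmonize(ex[ex$snp_id %in% ou2$snp_id, ], ou2)
  expect_equal(hs2$pairs$beta_outcome, hs$pairs$beta_outcome)
  expect_equal(hs2$pairs$eaf_outcome, hs$pairs$eaf_outcome)
  expect_equal(nrow(hs2$dropped), 0L)
})

test_that("allele bookkeeping leaves Wald ratios invariant", {
  ex <- exposure3()
  ou <- make_ss(c("rs1", "rs2", "rs3"), beta = c(0.05, 0.08, -0.1), se = 0.02,
                ea = c("A", "C", "G"), oa = c("G", "T", "C"),
                eaf = c(0.3, 0.4, 0.25))
  # same data with every outcome record reported for the other allele
  ou_flipped <- ou
  ou_flipped$effect_allele <- ou$other_allele
  ou_flipped$other_allele <- ou$effect_allele
  ou_flipped$beta <- -ou$beta
  ou_flipped$eaf <- 1 - ou$eaf

  r1 <- with(harmonize(ex, ou)$pairs, beta_outcome / beta_exposure)
  r2 <- with(harmonize(ex, ou_flipped)$pairs, beta_outcome / beta_exposure)
  expect_equal(r1, r2)
})

test_that("degenerate harmonization inputs raise errors", {
  ex <- exposure3()
  expect_error(harmonize(ex, make_ss("rsX", 0.1, 0.01)), "no SNPs shared")
  dup <- rbind(ex, ex[1, ])
  expect_error(harmonize(dup, ex), "unique")
  expect_error(harmonize(ex[0, ], ex), "non-empty")
})
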