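test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_snps = 0), "n_snps")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(n_exposure = 2), "n_exposure")
  expect_error(sim_config(pleiotropy_frac = 1), "pleiotropy_frac")
  expect_error(sim_config(outcome_prevalence = 0), "outcome_prevalence")
  expect_error(sim_config(ld_blocks = list(size = 0, r2 = 0.5)), "ld_blocks")
  expect_warning(sim_config(pleiotropy_frac = 0.6), "majority-validity")
})

test_that("ground-truth algebraic identities hold exactly", {
  sim <- simulate_study(sim_config(alpha = 0.5, gamma = 0.4, theta = 0.1,
                                   seed = 9L))
  expect_equal(sim$truth$total_effect, 0.30)
  expect_equal(sim$truth$mediated_proportion_true, 2 / 3)
  ps <- sim$truth$per_snp
  e <- ps$role == "exposure_iv"
  expect_equal(ps$beta_mediator[e], 0.5 * ps$beta_exposure[e])
  expect_equal(ps$beta_outcome[e], 0.30 * ps$beta_exposure[e])
  expect_equal(ps$beta_exposure[!e], rep(0, sum(!e)))
  expect_equal(ps$beta_outcome[!e], 0.4 * ps$beta_mediator[!e])
})

test_that("the same seed regenerates byte-identical studies and fixture files", {
  a <- simulate_study(sim_config(seed = 77L))
  b <- simulate_study(sim_config(seed = 77L))
  expect_identical(a$exposure, b$exposure)
  expect_identical(a$outcome, b$outcome)
  expect_identical(a$truth, b$truth)

  d1 <- file.path(withr::local_tempdir(), "s1")
  d2 <- file.path(withr::local_tempdir(), "s2")
  write_study(a, d1)
  write_study(b, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("a fully null design produces uniform outcome p-values", {
  sim <- simulate_study(sim_config(n_snps = 1000L, n_snps_mediator = 0L,
                                   theta = 0, alpha = 0, gamma = 0,
                                   seed = 55L))
  frac <- mean(sim$outcome$pvalue < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("simulated standard errors scale as one over the square root of n", {
  s1 <- simulate_study(sim_config(n_exposure = 5e4, seed = 12L))
  s2 <- simulate_study(sim_config(n_exposure = 2e5, seed = 12L))
  ratio <- mean(s1$exposure$se) / mean(s2$exposure$se)
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("LD blocks are emitted in the matrix and collapse to index SNPs under clumping", {
  sim <- simulate_study(sim_config(n_snps = 12L, n_snps_mediator = 0L,
                                   ld_blocks = list(size = 3, r2 = 0.9),
                                   seed = 31L))
  m <- sim$ld$r2
  expect_equal(m[1, 2], 0.9)
  expect_equal(m[1, 4], 0)
  expect_true(isSymmetric(m))

  sig <- sim$exposure[sim$exposure$pvalue < 5e-8, , drop = FALSE]
  kept <- clump(sig, sim$ld)
  # one representative per 3-SNP block among the significant SNPs
  blocks_hit <- unique((match(sig$snp_id, sim$exposure$snp_id) - 1) %/% 3)
  expect_equal(nrow(kept), length(blocks_hit))
})

test_that("the analytic generator's moments match an individual-level simulation", {
  cfg <- sim_config(n_snps = 12L, n_snps_mediator = 0L,
                    n_exposure = 2e4, n_mediator = 2e4, n_outcome = 2e4,
                    outcome_prevalence = 0.2, instrument_r2 = 0.04,
                    seed = 61L)
  ind <- simulate_study_individual(cfg)
  # analytic standard errors for the same design
  se_exp_analytic <- 1 / sqrt(2 * ind$maf * (1 - ind$maf) * 2e4)
  expect_equal(mean(ind$exposure$se), mean(se_exp_analytic), tolerance = 0.05)
  se_out_analytic <- 1 / sqrt(2 * ind$maf * (1 - ind$maf) * 2e4 * 0.2 * 0.8)
  expect_equal(mean(ind$outcome$se), mean(se_out_analytic), tolerance = 0.1)
  # estimated exposure effects track the true per-SNP effects
  expect_gt(cor(ind$exposure$beta, ind$b_exp), 0.95)
})

test_that("the fixture suite is complete, pinned, and regenerable bit-for-bit", {
  out1 <- file.path(withr::local_tempdir(), "fx1")
  dirs <- suppressWarnings(make_fixture_suite(out1))
  expect_length(dirs, 5L)
  expect_setequal(names(dirs), c("clean-mediation", "directional-pleiotropy",
                                 "planted-outlier", "null", "pathway-replay"))
  for (d in dirs[names(dirs) != "pathway-replay"])
    expect_setequal(list.files(d), c("exposure.tsv", "mediator.tsv",
                                     "outcome.tsv", "ld.tsv", "truth.json"))
  replay <- utils::read.table(file.path(dirs[["pathway-replay"]],
                                        "pathways.tsv"),
                              header = TRUE, sep = "\t")
  expect_equal(nrow(replay), 6L)

  out2 <- file.path(withr::local_tempdir(), "fx2")
  dirs2 <- suppressWarnings(make_fixture_suite(out2))
  for (nm in names(dirs)) {
    for (f in list.files(dirs[[nm]]))
      expect_identical(unname(tools::md5sum(file.path(dirs[[nm]], f))),
                       unname(tools::md5sum(file.path(dirs2[[nm]], f))))
  }
})
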