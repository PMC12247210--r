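test_that("Cochran's Q is zero for homogeneous ratios and matches the hand-computed sum", {
  bx <- c(0.1, 0.2, 0.3)
  hs <- make_hs(bx, 0.01, 0.4 * bx, 0.02)
  q <- cochran_q(hs)
  expect_equal(q$q_stat, 0)
  expect_equal(q$q_df, 2L)
  expect_equal(q$q_pvalue, 1)

  # two ratios 0 and 1 with unit ratio-weights, pooled 0.5: Q = 0.5
  hs2 <- make_hs(c(1, 1), 0.01, c(0, 1), 1)
  q2 <- cochran_q(hs2, pooled_beta = 0.5)
  expect_equal(q2$q_stat, 0.5)

  expect_error(cochran_q(make_hs(1, 0.01, 0.5, 0.02)), "at least 2")
})

test_that("Q p-value agrees with the closed-form chi-square survival function", {
  # k = 5 SNPs: df = 4, an even df with exact survival
  # S(q) = exp(-q/2) * (1 + q/2)
  set.seed(3)
  bx <- runif(5, 0.05, 0.2)
  hs <- make_hs(bx, 0.01, 0.4 * bx + rnorm(5, 0, 0.03), 0.03)
  q <- cochran_q(hs)
  expect_equal(q$q_pvalue, exp(-q$q_stat / 2) * (1 + q$q_stat / 2),
               tolerance = 1e-12)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")

  brute_bh <- function(p) {
    m <- length(p)
    ord <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      j <- seq(i, m)
      q[ord[i]] <- min(1, min(m * p[ord[j]] / j))
    }
    q
  }
  set.seed(8)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }

  # permutation invariance with index bookkeeping
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("leave-one-out recomputes IVW per exclusion and ranks influence correctly", {
  bx <- c(0.1, 0.2, 0.15, 0.12, 0.18)
  hs <- make_hs(bx, 0.01, 0.4 * bx, 0.02)
  loo <- leave_one_out(hs)
  expect_equal(nrow(loo), 5L)
  expect_true(all(abs(loo$ivw_beta - 0.4) < 1e-12))
  expect_false(any(loo$flag))

  # plant one high-weight outlier: its exclusion moves the estimate most
  by <- 0.4 * bx
  by[3] <- by[3] + 0.3
  seby <- c(0.05, 0.05, 0.005, 0.05, 0.05)
  hs2 <- make_hs(bx, 0.01, by, seby)
  loo2 <- leave_one_out(hs2)
  full <- mr_ivw(hs2)$beta
  # direct recomputation oracle
  deltas <- vapply(1:5, function(i) {
    sub <- make_hs(bx[-i], 0.01, by[-i], seby[-i])
    abs(mr_ivw(sub)$beta - full)
  }, numeric(1))
  expect_equal(abs(loo2$ivw_beta - full), deltas)
  expect_equal(which.max(deltas), 3L)
  expect_error(leave_one_out(make_hs(c(1, 2), 0.01, c(1, 2), 0.02)),
               "at least 3")
})

test_that("the robustness verdict requires all three sensitivity tests to pass at 0.05", {
  base <- list(q_pvalue = 0.5, egger_intercept_p = 0.5,
               presso_global_p = 0.5, presso_outliers = character(0),
               presso_global_p_corrected = NA_real_)
  expect_true(robustness_verdict(base))

  fail_egger <- base; fail_egger$egger_intercept_p <- 0.01
  expect_false(robustness_verdict(fail_egger))

  boundary <- base; boundary$q_pvalue <- 0.05  # inclusive threshold
  expect_true(robustness_verdict(boundary))

  # after outlier removal the corrected global p governs
  corrected <- base
  corrected$presso_global_p <- 0.01
  corrected$presso_outliers <- "rs1"
  corrected$presso_global_p_corrected <- 0.6
  expect_true(robustness_verdict(corrected))

  incomplete <- base; incomplete$q_pvalue <- NA_real_
  expect_error(robustness_verdict(incomplete), "incomplete")
})

test_that("MR-PRESSO leaves clean data alone, flags a planted outlier, and is seed-reproducible", {
  sim <- simulate_study(sim_config(seed = 301L))
  hs <- sim_hs(sim)
  clean <- mr_presso(hs, n_sim = 400, seed = 4L)
  expect_length(clean$presso_outliers, 0)
  expect_gt(clean$presso_global_p, 0.05)
  expect_true(is.na(clean$presso_distortion_p))

  # with k instruments the Bonferroni outlier-p floor is k/(n_sim + 1),
  # so detecting any outlier at 0.05 needs n_sim well above k/0.05
  planted <- plant_outlier(simulate_study(sim_config(seed = 302L)),
                           snp = 5L, displacement = 10)
  hs2 <- sim_hs(planted)
  res <- mr_presso(hs2, n_sim = 2000, seed = 4L)
  expect_true(planted$truth$planted_outlier %in% res$presso_outliers)
  expect_false(is.null(res$corrected_estimate))
  expect_false(is.na(res$presso_distortion_p))

  # bit-reproducible under a fixed seed
  res2 <- mr_presso(hs2, n_sim = 2000, seed = 4L)
  expect_identical(res, res2)

  expect_error(mr_presso(hs, n_sim = 50, seed = 1L), "at least 100")
  expect_error(mr_presso(make_hs(1:3 / 10, 0.01, 1:3 / 20, 0.02),
                         n_sim = 100, seed = 1L), "at least 4")
})

test_that("the assembled sensitivity report carries every component and a verdict", {
  sim <- simulate_study(sim_config(seed = 303L))
  hs <- sim_hs(sim)
  rep <- sensitivity_report(hs, n_sim = 300, seed = 2L)
  expect_equal(rep$q_df, nrow(hs$pairs) - 1L)
  expect_equal(nrow(rep$loo), nrow(hs$pairs))
  expect_true(is.logical(rep$verdict))
  # clean simulated data should pass the battery
  expect_true(rep$verdict)

  path <- withr::local_tempfile(fileext = ".json")
  write_sensitivity_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$q_df, rep$q_df)
  expect_equal(length(parsed$loo), nrow(rep$loo))
})
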