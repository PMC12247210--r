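random_hs <- function(k, seed, slope = 0.4, icpt = 0, noise = 1) {
  set.seed(seed)
  bx <- runif(k, 0.03, 0.2)
  seby <- runif(k, 0.02, 0.08)
  by <- icpt + slope * bx + noise * rnorm(k, 0, seby)
  make_hs(bx, runif(k, 0.005, 0.02), by, seby)
}

test_that("Wald ratio divides outcome by exposure effect with first-order se", {
  w <- wald_ratio(0.1, 0.01, 0.05, 0.02)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.2)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.02)$beta, 0)
  # ratio invariance under joint sign flip
  expect_equal(wald_ratio(-0.1, 0.01, -0.05, 0.02)$beta, 0.5)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.02), "beta_exp")
})

test_that("IVW reduces to the Wald ratio at k = 1 and is exact on homogeneous ratios", {
  hs1 <- make_hs(0.1, 0.01, 0.05, 0.02)
  expect_equal(mr_ivw(hs1)$beta, wald_ratio(0.1, 0.01, 0.05, 0.02)$beta)
  expect_equal(mr_ivw(hs1)$se, wald_ratio(0.1, 0.01, 0.05, 0.02)$se)

  # three SNPs, all Wald ratios exactly 0.3
  bx <- c(0.1, 0.2, 0.05)
  hs <- make_hs(bx, 0.01, 0.3 * bx, c(0.02, 0.03, 0.04))
  fixed <- mr_ivw(hs, "fixed")
  mre <- mr_ivw(hs)
  expect_equal(fixed$beta, 0.3)
  expect_equal(fixed$extras$q_stat, 0)
  expect_equal(fixed$se, mre$se)  # Q = 0: no inflation
})

test_that("IVW matches a weighted-least-squares-through-origin oracle to 1e-10", {
  hs <- random_hs(10, seed = 21)
  p <- hs$pairs
  fit <- lm(beta_outcome ~ 0 + beta_exposure, data = p,
            weights = 1 / p$se_outcome^2)
  s <- summary(fit)
  expect_equal(mr_ivw(hs, "fixed")$beta, unname(coef(fit)), tolerance = 1e-10)
  expect_equal(mr_ivw(hs, "fixed")$se,
               unname(s$coefficients[1, 2] / s$sigma), tolerance = 1e-10)
  q <- sum(residuals(fit)^2 / p$se_outcome^2)
  expect_equal(mr_ivw(hs)$se,
               unname(s$coefficients[1, 2] / s$sigma) *
                 max(1, sqrt(q / (nrow(p) - 1))), tolerance = 1e-10)
})

test_that("Egger recovers an exact linear law and matches a weighted regression oracle", {
  bx <- seq(0.05, 0.2, length.out = 6)
  hs <- make_hs(bx, 0.01, 0.02 + 0.4 * bx, 0.03)
  eg <- mr_egger(hs)
  expect_equal(eg$beta, 0.4)
  expect_equal(eg$extras$intercept, 0.02)
  expect_equal(eg$extras$residual_scale, 1)  # exact fit: scale at the lower bound

  expect_error(mr_egger(make_hs(c(0.1, 0.2), 0.01, c(0.05, 0.1), 0.02)),
               "insufficient SNPs")

  hs20 <- random_hs(20, seed = 22, icpt = 0.03)
  p <- hs20$pairs
  fit <- lm(beta_outcome ~ beta_exposure, data = p,
            weights = 1 / p$se_outcome^2)
  s <- summary(fit)
  eg20 <- mr_egger(hs20)
  expect_equal(eg20$beta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(eg20$extras$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  expect_equal(eg20$se,
               unname(s$coefficients[2, 2] / s$sigma) * max(1, s$sigma),
               tolerance = 1e-10)
  expect_equal(eg20$extras$intercept_se,
               unname(s$coefficients[1, 2] / s$sigma) * max(1, s$sigma),
               tolerance = 1e-10)
})

test_that("weighted median interpolates the half-weight crossing", {
  # equal weights reduce to the plain median
  bx <- rep(0.1, 5)
  hs <- make_hs(bx, 0.01, 0.1 * seq(0.1, 0.5, 0.1), 0.02)
  wm <- mr_weighted_median(hs, n_boot = 200, seed = 5)
  expect_equal(wm$beta, 0.3)

  # permutation invariance, including the bootstrap se at a fixed seed
  perm <- hs
  perm$pairs <- hs$pairs[c(4, 1, 5, 3, 2), ]
  wm2 <- mr_weighted_median(perm, n_boot = 200, seed = 5)
  expect_equal(wm2$beta, wm$beta)
  expect_equal(wm2$se, wm$se)

  # dominant-weight case against the cumulative-weight definition
  r <- c(0.1, 0.25, 0.6)
  se_r <- sqrt(1 / c(0.98, 0.01, 0.01))
  hs3 <- make_hs(rep(1, 3), 0.01, r, se_r)
  wm3 <- mr_weighted_median(hs3, n_boot = 100, seed = 1)
  oracle <- local({
    w <- (1 / se_r^2)[order(r)] / sum(1 / se_r^2)
    rs <- sort(r)
    cum <- cumsum(w) - w / 2
    if (cum[1] >= 0.5) rs[1]
    else {
      i <- max(which(cum < 0.5))
      rs[i] + (rs[i + 1] - rs[i]) * (0.5 - cum[i]) / (cum[i + 1] - cum[i])
    }
  })
  expect_equal(wm3$beta, oracle)
  expect_lt(abs(wm3$beta - 0.1), 0.16)  # pinned to the dominant SNP's neighborhood
})

test_that("mode estimators find the kernel-density mode, robust to a minority cluster", {
  bx <- rep(0.1, 4)
  hs_eq <- make_hs(bx, 0.01, 0.25 * bx, 0.02)
  expect_equal(mr_mode(hs_eq, n_boot = 50, seed = 2)$beta, 0.25)

  hs <- make_hs(bx, 0.01, c(0.03, 0.03, 0.03, 0.15), 0.02)
  sm <- mr_mode(hs, weighted = FALSE, n_boot = 50, seed = 2)
  expect_lt(abs(sm$beta - 0.3), 0.1)       # near the majority cluster
  expect_gt(abs(sm$beta - mean(c(0.3, 0.3, 0.3, 1.5))), 0.2)

  # grid-search oracle over [min, max] at step 1e-4
  hs2 <- random_hs(15, seed = 31)
  got <- mr_mode(hs2, weighted = TRUE, n_boot = 50, seed = 3)$beta
  p <- hs2$pairs
  r <- p$beta_outcome / p$beta_exposure
  w <- (p$beta_exposure / p$se_outcome)^2
  w <- w / sum(w)
  h <- 1 * 0.9 * min(sd(r), mad(r)) * length(r)^(-1 / 5)
  grid <- seq(min(r), max(r), by = 1e-4)
  dens <- vapply(grid, function(x) sum(w * dnorm(x, r, h)), numeric(1))
  expect_equal(got, grid[which.max(dens)], tolerance = 1e-3)
})

test_that("log-odds effects convert to odds ratios with 95% bounds", {
  expect_equal(unname(beta_to_or(0, 0.1)["or_"]), 1.0)
  expect_equal(unname(round(beta_to_or(-0.7951, 0.1)["or_"], 3)), 0.452)
  expect_equal(unname(round(beta_to_or(-0.1215, 0.1)["or_"], 3)), 0.886)
  b <- beta_to_or(0.2, 0.05)
  expect_equal(unname(b["or_low"]), exp(0.2 - 1.96 * 0.05))
  expect_error(beta_to_or(0.1, 0), "positive")
})

test_that("all estimators are equivariant under outcome negation and exact on homogeneous ratios", {
  for (seed in c(101, 202)) {
    hs <- random_hs(12, seed = seed)
    neg <- hs
    neg$pairs$beta_outcome <- -hs$pairs$beta_outcome
    expect_equal(mr_ivw(neg)$beta, -mr_ivw(hs)$beta)
    expect_equal(mr_egger(neg)$beta, -mr_egger(hs)$beta)
    expect_equal(mr_weighted_median(neg, n_boot = 50, seed = 1)$beta,
                 -mr_weighted_median(hs, n_boot = 50, seed = 1)$beta)
    expect_equal(mr_mode(neg, n_boot = 20, seed = 1)$beta,
                 -mr_mode(hs, n_boot = 20, seed = 1)$beta, tolerance = 1e-6)
  }

  # identical ratios: every estimator returns the common ratio
  bx <- c(0.05, 0.1, 0.15, 0.2)
  hs <- make_hs(bx, 0.01, -0.25 * bx, c(0.02, 0.03, 0.02, 0.05))
  expect_equal(mr_ivw(hs)$beta, -0.25)
  eg <- mr_egger(hs)
  expect_equal(eg$beta, -0.25)
  expect_equal(eg$extras$intercept, 0, tolerance = 1e-12)
  expect_equal(mr_weighted_median(hs, n_boot = 20, seed = 1)$beta, -0.25)
  expect_equal(mr_mode(hs, n_boot = 20, seed = 1)$beta, -0.25)
  expect_equal(mr_mode(hs, weighted = TRUE, n_boot = 20, seed = 1)$beta, -0.25)
  expect_equal(cochran_q(hs)$q_stat, 0)
})

test_that("weighted median resists large directional pleiotropy far better than IVW", {
  R <- 500
  ivw_b <- wm_b <- numeric(R)
  for (r in seq_len(R)) {
    sim <- simulate_study(sim_config(pleiotropy_frac = 0.3,
                                     pleiotropy_mean = 0.3,
                                     pleiotropy_sd = 0.05,
                                     seed = 40000L + r))
    hs <- sim_hs(sim)
    p <- hs$pairs
    ivw_b[r] <- mr_ivw(hs)$beta
    wm_b[r] <- mrmediate:::.weighted_median_point(
      p$beta_outcome / p$beta_exposure,
      (p$beta_exposure / p$se_outcome)^2)
  }
  truth <- 0.3
  expect_lt(abs(mean(wm_b) - truth), abs(mean(ivw_b) - truth) / 2)
})

test_that("the estimator battery returns one labelled row per method", {
  hs <- random_hs(8, seed = 77)
  tab <- mr_all(hs, n_boot = 50, seed = 9)
  expect_setequal(tab$method, c("ivw_mre", "ivw_fixed", "egger",
                                "weighted_median", "simple_mode",
                                "weighted_mode"))
  expect_true(all(tab$ci_low <= tab$beta & tab$beta <= tab$ci_high))
  expect_equal(tab$or, exp(tab$beta))
})
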