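#' Simulation configuration for a two-sample MR mediation study
#'
#' Defines a three-study design — exposure GWAS, mediator GWAS and a
#' binary-outcome (case/control, log-odds scale) GWAS drawn from three
#' mutually independent samples — with known causal structure:
#' exposure -> outcome direct effect `theta`, exposure -> mediator effect
#' `alpha`, and mediator -> outcome effect `gamma`, so the total effect is
#' `theta + alpha * gamma` and the true mediated proportion is
#' `alpha * gamma / (theta + alpha * gamma)`. A fraction of instruments
#' can be made invalid by giving them direct SNP-to-outcome (pleiotropic)
#' effects drawn from N(`pleiotropy_mean`, `pleiotropy_sd`).
#'
#' Defaults describe a well-powered modern design: 50 independent
#' instruments jointly explaining ~5% of exposure variance, 100,000
#' participants per study, and a low-prevalence binary outcome
#' (prevalence 0.017, the case fraction of a typical end-stage
#' renal-failure GWAS).
#'
#' @param n_snps Number of exposure instruments (default 50).
#' @param n_snps_mediator Number of mediator-specific instruments —
#'   variants acting on the mediator directly, not through the exposure,
#'   as real metabolite GWAS loci do (default: same as `n_snps`; may be
#'   0). These carry the mediator -> outcome signal `gamma` and are what
#'   the second mediation step instruments.
#' @param maf_range Minor-allele-frequency range, within (0, 0.5]
#'   (default c(0.05, 0.5)).
#' @param n_exposure,n_mediator,n_outcome Per-study sample sizes
#'   (default 1e5 each).
#' @param theta Direct exposure -> outcome effect, log-odds (default 0.1).
#' @param alpha Exposure -> mediator effect (default 0.5).
#' @param gamma Mediator -> outcome effect, log-odds (default 0.4).
#' @param pleiotropy_frac Fraction of invalid instruments in [0, 1)
#'   (default 0; a warning is issued at 0.5 or above, where
#'   median-validity no longer holds).
#' @param pleiotropy_mean,pleiotropy_sd Distribution of the direct
#'   SNP-to-outcome effects of invalid instruments (defaults 0, 0.02).
#' @param outcome_prevalence Case fraction of the outcome study in (0, 1)
#'   (default 0.017).
#' @param instrument_r2 Total trait variance explained by each trait's
#'   own instruments (default 0.05); per-SNP shares vary uniformly
#'   within +/-50% of the mean.
#' @param ld_blocks Optional list(size =, r2 =): arrange SNPs in LD blocks
#'   of `size` with within-block squared correlation `r2`; block members
#'   tag the index SNP's signal. NULL (default) = independent SNPs.
#' @param seed Integer seed; every draw is derived from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 50L, n_snps_mediator = n_snps,
                       maf_range = c(0.05, 0.5),
                       n_exposure = 1e5, n_mediator = 1e5, n_outcome = 1e5,
                       theta = 0.1, alpha = 0.5, gamma = 0.4,
                       pleiotropy_frac = 0, pleiotropy_mean = 0,
                       pleiotropy_sd = 0.02, outcome_prevalence = 0.017,
                       instrument_r2 = 0.05, ld_blocks = NULL, seed = 1L) {
  cfg <- list(n_snps = as.integer(n_snps),
              n_snps_mediator = as.integer(n_snps_mediator),
              maf_range = maf_range,
              n_exposure = n_exposure, n_mediator = n_mediator,
              n_outcome = n_outcome, theta = theta, alpha = alpha,
              gamma = gamma, pleiotropy_frac = pleiotropy_frac,
              pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
              outcome_prevalence = outcome_prevalence,
              instrument_r2 = instrument_r2, ld_blocks = ld_blocks,
              seed = as.integer(seed))
  if (cfg$n_snps < 1L) stop("invalid config field: n_snps")
  if (cfg$n_snps_mediator < 0L) stop("invalid config field: n_snps_mediator")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) stop("invalid config field: maf_range")
  for (f in c("n_exposure", "n_mediator", "n_outcome"))
    if (cfg[[f]] <= 2) stop("invalid config field: ", f)
  if (pleiotropy_frac < 0 || pleiotropy_frac >= 1)
    stop("invalid config field: pleiotropy_frac")
  if (pleiotropy_frac >= 0.5)
    warning("pleiotropy_frac >= 0.5: majority-validity assumptions ",
            "of median/mode estimators will not hold")
  if (outcome_prevalence <= 0 || outcome_prevalence >= 1)
    stop("invalid config field: outcome_prevalence")
  if (instrument_r2 <= 0 || instrument_r2 >= 1)
    stop("invalid config field: instrument_r2")
  if (!is.null(ld_blocks) &&
      (is.null(ld_blocks$size) || is.null(ld_blocks$r2) ||
       ld_blocks$size < 1 || ld_blocks$r2 < 0 || ld_blocks$r2 > 1))
    stop("invalid config field: ld_blocks")
  structure(cfg, class = "sim_config")
}

#' Simulate a two-sample GWAS summary-statistics study
#'
#' Draws per-SNP minor-allele frequencies and true exposure effects, then
#' generates the three studies' summary statistics analytically: each
#' observed effect is the true marginal effect plus normal noise at the
#' single-SNP regression standard error for that study's sample size and
#' allele frequency — `se = 1/sqrt(2 f (1-f) n)` for the quantitative
#' exposure and mediator (unit trait variance), scaled by
#' `1/sqrt(prev (1-prev))` for the binary outcome's log-odds effects.
#' No individual-level genotypes are simulated (see
#' [simulate_study_individual()] for the slow validation path). SNPs are
#' placed 1 Mb apart (200 per chromosome from chr1) so window-based
#' clumping is exercised; alleles are drawn from non-complementary pairs
#' so no instrument is lost to palindrome removal unless planted.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_study`:
#'   \item{exposure, mediator, outcome}{`sumstats` data frames}
#'   \item{ld}{an `ld_matrix` (identity unless `ld_blocks` given)}
#'   \item{truth}{per-SNP true effects plus `total_effect`
#'     (= theta + alpha gamma) and `mediated_proportion_true`
#'     (= alpha gamma / total); the config is echoed}
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_study_impl(config))
}

.simulate_study_impl <- function(cfg) {
  ke <- cfg$n_snps
  km <- cfg$n_snps_mediator
  k <- ke + km
  maf <- stats::runif(k, cfg$maf_range[1], cfg$maf_range[2])

  # per-SNP effects on each instrument's own trait: explained-variance
  # shares uniform within +/-50% of instrument_r2/count, random sign
  own_effect <- function(idx, count) {
    r2_j <- (cfg$instrument_r2 / count) * stats::runif(count, 0.5, 1.5)
    sample(c(-1, 1), count, replace = TRUE) *
      sqrt(r2_j / (2 * maf[idx] * (1 - maf[idx])))
  }
  b_exp <- own_effect(seq_len(ke), ke)
  c_med <- if (km > 0) own_effect(ke + seq_len(km), km) else numeric(0)

  # LD: block-diagonal r2 over the exposure instruments; block members
  # tag the index SNP's signal. Mediator instruments stay independent.
  ldm <- diag(k)
  if (!is.null(cfg$ld_blocks)) {
    size <- cfg$ld_blocks$size; r2b <- cfg$ld_blocks$r2
    block <- rep(seq_len(ceiling(ke / size)), each = size)[seq_len(ke)]
    for (b in unique(block)) {
      idx <- which(block == b)
      ldm[idx, idx] <- r2b
      tag <- setdiff(idx, idx[1])
      b_exp[tag] <- sqrt(r2b) * b_exp[idx[1]]
    }
    diag(ldm) <- 1
  }

  # Direct (pleiotropic) SNP-to-outcome effects are planted in the
  # oriented frame — relative to the direction in which the SNP raises
  # the exposure — so a nonzero pleiotropy_mean is directional in the
  # sense the Egger intercept measures (a constant offset in raw
  # outcome-effect space would cancel across randomly signed exposure
  # effects and act as balanced pleiotropy instead).
  n_invalid <- floor(cfg$pleiotropy_frac * ke)
  pleio <- numeric(k)
  if (n_invalid > 0) {
    idx <- sample.int(ke, n_invalid)
    pleio[idx] <- sign(b_exp[idx]) *
      stats::rnorm(n_invalid, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
  }

  total <- cfg$theta + cfg$alpha * cfg$gamma
  true_exp <- c(b_exp, numeric(km))
  true_med <- c(cfg$alpha * b_exp, c_med)
  true_out <- c(total * b_exp, cfg$gamma * c_med) + pleio

  var_g <- 2 * maf * (1 - maf)
  se_exp <- 1 / sqrt(var_g * cfg$n_exposure)
  se_med <- 1 / sqrt(var_g * cfg$n_mediator)
  prev <- cfg$outcome_prevalence
  se_out <- 1 / sqrt(var_g * cfg$n_outcome * prev * (1 - prev))

  snp_id <- sprintf("rs%07d", seq_len(k))
  chrom <- as.character(1L + (seq_len(k) - 1L) %/% 200L)
  pos <- as.integer((((seq_len(k) - 1L) %% 200L) + 1L) * 1e6)
  allele_pairs <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                           "G", "A", "G", "T", "T", "C", "T", "G"),
                         ncol = 2, byrow = TRUE)
  pick <- sample.int(nrow(allele_pairs), k, replace = TRUE)

  make_study <- function(true_beta, se, n) {
    beta <- stats::rnorm(k, true_beta, se)
    df <- data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = allele_pairs[pick, 1],
      other_allele = allele_pairs[pick, 2],
      beta = beta, se = se,
      pvalue = 2 * stats::pnorm(-abs(beta / se)),
      eaf = maf, n = n, stringsAsFactors = FALSE
    )
    attr(df, "rejects") <- data.frame(row = integer(), snp_id = character(),
                                      reason = character())
    class(df) <- c("sumstats", "data.frame")
    df
  }

  truth <- list(
    per_snp = data.frame(snp_id = snp_id, maf = maf,
                         role = rep(c("exposure_iv", "mediator_iv"),
                                    c(ke, km)),
                         beta_exposure = true_exp, beta_mediator = true_med,
                         beta_outcome = true_out, pleiotropy = pleio,
                         stringsAsFactors = FALSE),
    theta = cfg$theta, alpha = cfg$alpha, gamma = cfg$gamma,
    total_effect = total,
    mediated_proportion_true = if (total != 0) cfg$alpha * cfg$gamma / total
    else NA_real_,
    config = unclass(cfg)
  )

  structure(list(
    exposure = make_study(true_exp, se_exp, cfg$n_exposure),
    mediator = make_study(true_med, se_med, cfg$n_mediator),
    outcome = make_study(true_out, se_out, cfg$n_outcome),
    ld = ld_matrix(snp_id, ldm),
    truth = truth
  ), class = "sim_study")
}

#' Individual-level validation simulator
#'
#' Slow companion to [simulate_study()]: draws Hardy-Weinberg genotypes
#' for three independent samples, builds a quantitative exposure and
#' mediator and a binary outcome (logistic model with intercept set to
#' the target prevalence), and estimates each study's summary statistics
#' by per-SNP regression (closed-form OLS for the quantitative traits,
#' single-SNP logistic fits for the outcome). Used to validate the
#' analytic generator's moments; sample sizes beyond ~5e4 are slow.
#'
#' @param config A [sim_config()] (no LD support on this path).
#' @return List with `exposure`, `mediator`, `outcome` `sumstats`.
#' @export
simulate_study_individual <- function(config) {
  stopifnot(inherits(config, "sim_config"), is.null(config$ld_blocks))
  cfg <- config
  with_seed(cfg$seed + 1L, {
    k <- cfg$n_snps
    maf <- stats::runif(k, cfg$maf_range[1], cfg$maf_range[2])
    r2_j <- (cfg$instrument_r2 / k) * stats::runif(k, 0.5, 1.5)
    b_exp <- sample(c(-1, 1), k, replace = TRUE) *
      sqrt(r2_j / (2 * maf * (1 - maf)))

    genotypes <- function(n) {
      g <- vapply(maf, function(f) stats::rbinom(n, 2L, f), numeric(nrow <- n))
      g
    }
    ols_scan <- function(g, y) {
      # per-SNP simple regression, closed form
      gm <- colMeans(g); ym <- mean(y)
      sxx <- colSums(sweep(g, 2, gm)^2)
      sxy <- as.numeric(crossprod(sweep(g, 2, gm), y - ym))
      beta <- sxy / sxx
      n <- length(y)
      resid_var <- vapply(seq_along(beta), function(j)
        sum((y - ym - beta[j] * (g[, j] - gm[j]))^2) / (n - 2), numeric(1))
      se <- sqrt(resid_var / sxx)
      list(beta = beta, se = se)
    }

    # exposure sample
    g1 <- genotypes(cfg$n_exposure)
    x1 <- as.numeric(g1 %*% b_exp) +
      stats::rnorm(cfg$n_exposure, 0, sqrt(max(1e-8, 1 - cfg$instrument_r2)))
    sc_exp <- ols_scan(g1, x1)

    # mediator sample
    g2 <- genotypes(cfg$n_mediator)
    x2 <- as.numeric(g2 %*% b_exp) +
      stats::rnorm(cfg$n_mediator, 0, sqrt(max(1e-8, 1 - cfg$instrument_r2)))
    m2 <- cfg$alpha * x2 +
      stats::rnorm(cfg$n_mediator, 0, sqrt(max(1e-8, 1 - cfg$alpha^2 *
                                                 stats::var(x2))))
    sc_med <- ols_scan(g2, m2)

    # outcome sample: logistic liability on exposure + mediator
    g3 <- genotypes(cfg$n_outcome)
    x3 <- as.numeric(g3 %*% b_exp) + stats::rnorm(cfg$n_outcome)
    m3 <- cfg$alpha * x3 + stats::rnorm(cfg$n_outcome)
    eta <- stats::qlogis(cfg$outcome_prevalence) +
      cfg$theta * scale(x3)[, 1] + cfg$gamma * scale(m3)[, 1]
    y <- stats::rbinom(cfg$n_outcome, 1L, stats::plogis(eta))
    sc_out <- list(beta = numeric(k), se = numeric(k))
    for (j in seq_len(k)) {
      fit <- stats::glm(y ~ g3[, j], family = stats::binomial())
      sc_out$beta[j] <- stats::coef(fit)[2]
      sc_out$se[j] <- sqrt(stats::vcov(fit)[2, 2])
    }

    snp_id <- sprintf("rs%07d", seq_len(k))
    pack <- function(sc, n) {
      df <- data.frame(snp_id = snp_id, chrom = "1",
                       pos = as.integer(seq_len(k) * 1e6),
                       effect_allele = "A", other_allele = "G",
                       beta = sc$beta, se = sc$se,
                       pvalue = 2 * stats::pnorm(-abs(sc$beta / sc$se)),
                       eaf = maf, n = n, stringsAsFactors = FALSE)
      class(df) <- c("sumstats", "data.frame")
      df
    }
    list(exposure = pack(sc_exp, cfg$n_exposure),
         mediator = pack(sc_med, cfg$n_mediator),
         outcome = pack(sc_out, cfg$n_outcome),
         maf = maf, b_exp = b_exp)
  })
}

#' Write a simulated study to a directory
#'
#' Emits `exposure.tsv`, `mediator.tsv`, `outcome.tsv` (standard sumstats
#' dialect), `ld.tsv` and `truth.json`.
#'
#' @param sim A `sim_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  write_sumstats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(sim$mediator, file.path(dir, "mediator.tsv"))
  write_sumstats(sim$outcome, file.path(dir, "outcome.tsv"))
  write_ld_matrix(sim$ld, file.path(dir, "ld.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Generate the canonical fixture suite
#'
#' Writes the five named fixtures used throughout the test suite, each
#' with pinned seeds:
#' \describe{
#'   \item{clean-mediation}{50 valid instruments, alpha 0.5, gamma 0.4,
#'     theta 0.1, 100,000 per study;}
#'   \item{directional-pleiotropy}{pervasive directional pleiotropy —
#'     98% of instruments carry oriented direct outcome effects
#'     (mean 0.08, sd 0.01), the positive-control scenario for the
#'     Egger intercept test;}
#'   \item{planted-outlier}{clean design with one SNP's outcome effect
#'     displaced by 10 standard errors;}
#'   \item{null}{theta = alpha = gamma = 0;}
#'   \item{pathway-replay}{the bundled six-pathway beverage-metabolite
#'     example table (copied for replay through the mediation module).}
#' }
#'
#' @param out_dir Writable output directory.
#' @return Named character vector of fixture directories, invisibly.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop("output directory not writable: ", out_dir)

  dirs <- c(
    `clean-mediation` = file.path(out_dir, "clean-mediation"),
    `directional-pleiotropy` = file.path(out_dir, "directional-pleiotropy"),
    `planted-outlier` = file.path(out_dir, "planted-outlier"),
    null = file.path(out_dir, "null"),
    `pathway-replay` = file.path(out_dir, "pathway-replay")
  )
  write_study(simulate_study(sim_config(seed = 101L)), dirs[["clean-mediation"]])
  write_study(suppressWarnings(
    simulate_study(sim_config(pleiotropy_frac = 0.98,
                              pleiotropy_mean = 0.08,
                              pleiotropy_sd = 0.01, seed = 102L))),
    dirs[["directional-pleiotropy"]])
  write_study(plant_outlier(simulate_study(sim_config(seed = 103L)),
                            displacement = 10),
              dirs[["planted-outlier"]])
  write_study(simulate_study(sim_config(theta = 0, alpha = 0, gamma = 0,
                                        seed = 104L)), dirs[["null"]])
  dir.create(dirs[["pathway-replay"]], showWarnings = FALSE)
  file.copy(example_pathway_table(),
            file.path(dirs[["pathway-replay"]], "pathways.tsv"),
            overwrite = TRUE)
  invisible(dirs)
}

#' Displace one SNP's outcome effect (planted outlier)
#'
#' @param sim A `sim_study`.
#' @param snp Index of the SNP to displace (default 1).
#' @param displacement Displacement in units of that SNP's outcome se
#'   (default 10).
#' @return The modified `sim_study`; the planted SNP id is recorded in
#'   `truth$planted_outlier`.
#' @export
plant_outlier <- function(sim, snp = 1L, displacement = 10) {
  se <- sim$outcome$se[snp]
  sim$outcome$beta[snp] <- sim$outcome$beta[snp] + displacement * se
  sim$outcome$pvalue[snp] <-
    2 * stats::pnorm(-abs(sim$outcome$beta[snp] / se))
  sim$truth$planted_outlier <- sim$outcome$snp_id[snp]
  sim
}
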