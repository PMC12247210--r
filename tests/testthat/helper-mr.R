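# shared builders for small in-code fixtures

make_hs <- function(bx, sebx, by, seby,
                    ids = sprintf("rs%03d", seq_along(bx)),
                    exposure = "exposure", outcome = "outcome") {
  new_harmonized_set(
    data.frame(snp_id = ids, beta_exposure = bx, se_exposure = sebx,
               beta_outcome = by, se_outcome = seby,
               stringsAsFactors = FALSE),
    exposure_name = exposure, outcome_name = outcome
  )
}

make_ss <- function(snp_id, beta, se, pvalue = NULL,
                    chrom = "1", pos = seq_along(snp_id) * 1e6L,
                    ea = "A", oa = "G", eaf = 0.3, n = 1e5) {
  if (is.null(pvalue)) pvalue <- 2 * stats::pnorm(-abs(beta / se))
  df <- data.frame(snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
                   effect_allele = ea, other_allele = oa, beta = beta,
                   se = se, pvalue = pvalue, eaf = eaf, n = n,
                   stringsAsFactors = FALSE)
  class(df) <- c("sumstats", "data.frame")
  df
}

# a harmonized set from a simulated study, instruments selected from the
# exposure side (the standard route through the package)
sim_hs <- function(sim) {
  iv <- suppressWarnings(select_instruments(sim$exposure))
  harmonize(iv, sim$outcome[sim$outcome$snp_id %in% iv$snp_id, , drop = FALSE])
}

# printed six-pathway example values (betas, CIs, effects, proportions as
# published), used by the mediation and acceptance tests
printed_pathways <- function() {
  data.frame(
    mediator = c("op_ratio", "x23655", "mcs", "glutarate", "salicylate",
                 "x23655"),
    exposure = c("alcohol", "alcohol", "tea", "tea", "tea", "tea"),
    effect = c(0.0332, -0.0218, 0.205, 0.116, -0.0995, 0.149),
    effect_dp = c(4, 4, 3, 3, 4, 3),
    prop_pct = c(13.7, -8.97, -25.70, -14.60, 12.5, -18.7),
    me_lo = c(-0.001, -0.058, -1.64, -0.701, -0.693, -1.55),
    me_hi = c(0.068, 0.015, 2.05, 0.933, 0.494, 1.85),
    stringsAsFactors = FALSE
  )
}

# a panel of candidate mediator studies sharing one outcome study:
# each candidate is an independent simulated trait (its own SNP panel,
# ids prefixed) whose outcome effects are null or carry `effect`
make_screen_panel <- function(n_null, planted_effect = NULL, seed0 = 6000L) {
  cands <- list(); outs <- list()
  n_tot <- n_null + as.integer(!is.null(planted_effect))
  for (i in seq_len(n_tot)) {
    planted <- !is.null(planted_effect) && i == n_tot
    # the planted trait is a strong, well-instrumented signal (design
    # z about 6 at the outcome), so its recovery tests the cascade, not
    # the luck of one draw
    cfg <- sim_config(n_snps = if (planted) 30L else 20L,
                      n_snps_mediator = 0L,
                      instrument_r2 = if (planted) 0.1 else 0.05,
                      theta = if (planted) planted_effect else 0,
                      alpha = 0, gamma = 0, seed = seed0 + i)
    sim <- simulate_study(cfg)
    pre <- function(df) { df$snp_id <- paste0("c", i, "_", df$snp_id); df }
    nm <- if (planted) "planted" else sprintf("null%02d", i)
    cands[[nm]] <- pre(sim$exposure)
    outs[[i]] <- pre(sim$outcome)
  }
  outcome <- do.call(rbind, outs)
  class(outcome) <- c("sumstats", "data.frame")
  list(candidates = cands, outcome = outcome)
}
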