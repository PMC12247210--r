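#' Screening configuration for the mediator cascade
#'
#' @param p_screen_1 First-pass IVW p threshold (default 0.05).
#' @param p_screen_2 Second-pass threshold (default 0.01); must not
#'   exceed `p_screen_1`.
#' @param require_sensitivity_pass Keep only mediators whose sensitivity
#'   battery passes [robustness_verdict()] (default TRUE).
#' @param fdr_level Level at which BH q-values are reported (default
#'   0.05; q-values are reported alongside, they do not gate the cascade).
#' @return List of class `screen_config`.
#' @export
screen_config <- function(p_screen_1 = 0.05, p_screen_2 = 0.01,
                          require_sensitivity_pass = TRUE,
                          fdr_level = 0.05) {
  if (!(p_screen_2 > 0 && p_screen_2 <= p_screen_1 && p_screen_1 < 1))
    stop("invalid screening thresholds: need 0 < p_screen_2 <= p_screen_1 < 1")
  structure(list(p_screen_1 = p_screen_1, p_screen_2 = p_screen_2,
                 require_sensitivity_pass = require_sensitivity_pass,
                 fdr_level = fdr_level), class = "screen_config")
}

# Select instruments from `exposure`, harmonize onto `outcome`, return a
# harmonized_set (or the condition, for "not estimable" handling).
.instrumented_set <- function(exposure, outcome, ld = NULL,
                              p_threshold = 5e-8, r2_max = 0.001,
                              window_kb = 10000, f_min = 10,
                              exposure_name = "exposure",
                              outcome_name = "outcome") {
  iv <- select_instruments(exposure, ld = ld, p_threshold = p_threshold,
                           r2_max = r2_max, window_kb = window_kb,
                           f_min = f_min)
  hs <- harmonize(iv, outcome[outcome$snp_id %in% iv$snp_id, , drop = FALSE])
  hs$exposure_name <- exposure_name
  hs$outcome_name <- outcome_name
  attr(hs, "attrition") <- attr(iv, "attrition")
  attr(hs, "mean_f") <- attr(iv, "mean_f")
  hs
}

#' One-direction MR analysis with full estimator battery and sensitivity
#'
#' Selects instruments from the exposure study, harmonizes them onto the
#' outcome study, runs all five estimators and the sensitivity battery.
#'
#' @param exposure,outcome `sumstats` data frames.
#' @param exposure_name,outcome_name Labels carried into results.
#' @param ld Optional `ld_matrix` for clumping.
#' @param p_threshold,r2_max,window_kb,f_min Instrument-selection
#'   parameters (defaults 5e-8, 0.001, 10000 kb, 10).
#' @param n_boot,seed Bootstrap/simulation settings.
#' @return List with `estimates` (data frame from [mr_all()]),
#'   `sensitivity` (a `sensitivity_report`), `set` (the
#'   `harmonized_set`), `ivw` (the IVW `mr_estimate`, labelled).
#' @export
run_mr <- function(exposure, outcome, exposure_name = "exposure",
                   outcome_name = "outcome", ld = NULL,
                   p_threshold = 5e-8, r2_max = 0.001, window_kb = 10000,
                   f_min = 10, n_boot = 1000, seed = 1L) {
  hs <- .instrumented_set(exposure, outcome, ld = ld,
                          p_threshold = p_threshold, r2_max = r2_max,
                          window_kb = window_kb, f_min = f_min,
                          exposure_name = exposure_name,
                          outcome_name = outcome_name)
  est <- mr_all(hs, n_boot = n_boot, seed = seed)
  sens <- if (nrow(hs$pairs) >= 4L)
    sensitivity_report(hs, n_sim = max(100L, n_boot), seed = seed)
  else NULL
  list(estimates = est, sensitivity = sens, set = hs,
       ivw = mr_label(mr_ivw(hs), exposure_name, outcome_name))
}

#' Bidirectional MR between an exposure and an outcome
#'
#' Runs the forward (exposure -> outcome) and reverse (outcome ->
#' exposure) analyses, re-selecting instruments from the outcome study
#' for the reverse direction. A direction in which no instrument survives
#' selection is reported as not estimable rather than failing the run.
#'
#' @inheritParams run_mr
#' @param exposure,outcome Distinct `sumstats` data frames.
#' @return List with `forward` and `reverse`, each either a [run_mr()]
#'   result or the string `"not estimable"`.
#' @export
run_bidirectional_mr <- function(exposure, outcome,
                                 exposure_name = "exposure",
                                 outcome_name = "outcome", ld = NULL,
                                 p_threshold = 5e-8, r2_max = 0.001,
                                 window_kb = 10000, f_min = 10,
                                 n_boot = 1000, seed = 1L) {
  if (identical(exposure[names(exposure) != "n"], outcome[names(outcome) != "n"]))
    stop("exposure and outcome studies are identical; self-MR is not meaningful")
  one_way <- function(ex, ou, en, on, sd) {
    tryCatch(run_mr(ex, ou, en, on, ld = ld, p_threshold = p_threshold,
                    r2_max = r2_max, window_kb = window_kb, f_min = f_min,
                    n_boot = n_boot, seed = sd),
             error = function(e) {
               message("direction ", en, " -> ", on, " not estimable: ",
                       conditionMessage(e))
               "not estimable"
             })
  }
  list(forward = one_way(exposure, outcome, exposure_name, outcome_name, seed),
       reverse = one_way(outcome, exposure, outcome_name, exposure_name,
                         seed + 1L))
}

#' Screen candidate mediators against the outcome
#'
#' The three-stage cascade used to narrow a metabolite panel: stage 1
#' keeps candidates whose IVW p-value against the outcome is below
#' `p_screen_1`; stage 2 tightens to `p_screen_2`; stage 3 keeps those
#' whose sensitivity battery passes [robustness_verdict()]. BH-FDR
#' q-values across all stage-1 survivors are reported alongside (they do
#' not gate the cascade unless you filter on them yourself).
#'
#' @param candidates Named list of mediator `sumstats`.
#' @param outcome Outcome `sumstats`.
#' @param config A [screen_config()].
#' @param ld Optional `ld_matrix`.
#' @param p_threshold,r2_max,window_kb,f_min Instrument selection, as in
#'   [run_mr()].
#' @param n_sim,seed PRESSO settings for stage 3.
#' @return List with `qualified` (names surviving all stages), `results`
#'   (per-candidate data frame: `mediator`, `nsnp`, `ivw_beta`, `ivw_se`,
#'   `ivw_p`, `stage1`, `stage2`, `qvalue`, `sensitivity_pass`, `final`),
#'   and `cascade` (data frame of per-stage counts).
#' @export
screen_mediators <- function(candidates, outcome, config = screen_config(),
                             ld = NULL, p_threshold = 5e-8, r2_max = 0.001,
                             window_kb = 10000, f_min = 10,
                             n_sim = 1000, seed = 1L) {
  stopifnot(inherits(config, "screen_config"), length(candidates) >= 1L,
            !is.null(names(candidates)))
  rows <- lapply(names(candidates), function(nm) {
    est <- tryCatch({
      hs <- .instrumented_set(candidates[[nm]], outcome, ld = ld,
                              p_threshold = p_threshold, r2_max = r2_max,
                              window_kb = window_kb, f_min = f_min,
                              exposure_name = nm)
      list(hs = hs, ivw = mr_ivw(hs))
    }, error = function(e) NULL)
    if (is.null(est))
      return(data.frame(mediator = nm, nsnp = 0L, ivw_beta = NA_real_,
                        ivw_se = NA_real_, ivw_p = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(mediator = nm, nsnp = est$ivw$n_snps, ivw_beta = est$ivw$beta,
               ivw_se = est$ivw$se, ivw_p = est$ivw$pvalue,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$stage1 <- !is.na(res$ivw_p) & res$ivw_p < config$p_screen_1
  res$stage2 <- res$stage1 & res$ivw_p < config$p_screen_2
  res$qvalue <- NA_real_
  if (any(res$stage1))
    res$qvalue[res$stage1] <- bh_fdr(res$ivw_p[res$stage1])

  res$sensitivity_pass <- NA
  if (config$require_sensitivity_pass) {
    for (i in which(res$stage2)) {
      nm <- res$mediator[i]
      res$sensitivity_pass[i] <- tryCatch({
        hs <- .instrumented_set(candidates[[nm]], outcome, ld = ld,
                                p_threshold = p_threshold, r2_max = r2_max,
                                window_kb = window_kb, f_min = f_min,
                                exposure_name = nm)
        if (nrow(hs$pairs) < 4L) TRUE
        else sensitivity_report(hs, n_sim = n_sim, seed = seed)$verdict
      }, error = function(e) FALSE)
    }
    res$final <- res$stage2 & res$sensitivity_pass %in% TRUE
  } else {
    res$final <- res$stage2
  }

  cascade <- data.frame(
    stage = c("candidates", "p_screen_1", "p_screen_2", "sensitivity"),
    n = c(nrow(res), sum(res$stage1), sum(res$stage2), sum(res$final))
  )
  list(qualified = res$mediator[res$final], results = res, cascade = cascade)
}

#' Assemble two-step mediation results for qualified mediators
#'
#' For each qualified mediator, estimates the exposure -> mediator effect
#' (beta1), the mediator -> outcome effect (beta2) and the total exposure
#' -> outcome effect (beta_all), all by IVW, and composes them with
#' [two_step_mediation()]. A mediator only enters when the exposure ->
#' mediator IVW itself is significant (p < `p_gate`); excluded mediators
#' are listed in the `excluded` element with their gate p-values.
#'
#' @param exposure Exposure `sumstats`.
#' @param mediators Named list of mediator `sumstats`.
#' @param outcome Outcome `sumstats`.
#' @param exposure_name,outcome_name Labels.
#' @param pairing CI pairing for [mediated_effect()].
#' @param p_gate Significance gate on the exposure -> mediator IVW
#'   (default 0.05).
#' @param ld,p_threshold,r2_max,window_kb,f_min Instrument selection.
#' @return List with `results` (list of `mediation_result`), `table`
#'   (their data-frame form, zero rows when nothing qualifies) and
#'   `excluded` (data frame `mediator`, `reason`).
#' @export
assemble_mediation <- function(exposure, mediators, outcome,
                               exposure_name = "exposure",
                               outcome_name = "outcome",
                               pairing = "delta", p_gate = 0.05, ld = NULL,
                               p_threshold = 5e-8, r2_max = 0.001,
                               window_kb = 10000, f_min = 10) {
  total_hs <- .instrumented_set(exposure, outcome, ld = ld,
                                p_threshold = p_threshold, r2_max = r2_max,
                                window_kb = window_kb, f_min = f_min,
                                exposure_name = exposure_name,
                                outcome_name = outcome_name)
  total <- mr_label(mr_ivw(total_hs), exposure_name, outcome_name)

  results <- list(); excluded <- list()
  for (nm in names(mediators)) {
    step1 <- tryCatch({
      hs1 <- .instrumented_set(exposure, mediators[[nm]], ld = ld,
                               p_threshold = p_threshold, r2_max = r2_max,
                               window_kb = window_kb, f_min = f_min,
                               exposure_name = exposure_name,
                               outcome_name = nm)
      mr_label(mr_ivw(hs1), exposure_name, nm)
    }, error = function(e) NULL)
    if (is.null(step1)) {
      excluded[[nm]] <- "exposure->mediator not estimable"
      next
    }
    if (step1$pvalue >= p_gate) {
      excluded[[nm]] <- sprintf("exposure->mediator IVW p = %.3g >= %.2g",
                                step1$pvalue, p_gate)
      next
    }
    step2 <- tryCatch({
      hs2 <- .instrumented_set(mediators[[nm]], outcome, ld = ld,
                               p_threshold = p_threshold, r2_max = r2_max,
                               window_kb = window_kb, f_min = f_min,
                               exposure_name = nm, outcome_name = outcome_name)
      mr_label(mr_ivw(hs2), nm, outcome_name)
    }, error = function(e) NULL)
    if (is.null(step2)) {
      excluded[[nm]] <- "mediator->outcome not estimable"
      next
    }
    results[[nm]] <- two_step_mediation(step1, step2, total, pairing = pairing)
  }
  tab <- if (length(results))
    do.call(rbind, lapply(results, as.data.frame))
  else {
    message("no qualifying mediators; mediation table is empty")
    as.data.frame(two_step_mediation(
      mr_label(mr_estimate("ivw_mre", 0, 1, 0L), "x", "m"),
      mr_label(mr_estimate("ivw_mre", 0, 1, 0L), "m", "y"),
      mr_label(mr_estimate("ivw_mre", 1, 1, 0L), "x", "y")))[0, ]
  }
  rownames(tab) <- NULL
  list(results = results, table = tab,
       excluded = data.frame(mediator = names(excluded),
                             reason = unlist(excluded, use.names = FALSE),
                             stringsAsFactors = FALSE))
}

#' Run a full study from a YAML manifest
#'
#' The manifest names the sumstats files and parameters:
#' \preformatted{
#' exposures: {tea: path/to/tea.tsv, ...}
#' mediators: {salicylate: path/to/salicylate.tsv, ...}
#' outcome: path/to/crf.tsv
#' ld: path/to/ld.tsv            # optional
#' iv_params: {p_threshold: 5e-8, r2_max: 0.001, window_kb: 10000, f_min: 10}
#' screen: {p_screen_1: 0.05, p_screen_2: 0.01}
#' pairing: delta
#' seed: 1
#' }
#' For every exposure it runs the bidirectional MR against the outcome,
#' screens the mediators, assembles mediation results, and writes results
#' TSVs, sensitivity JSONs and a provenance JSON (manifest, seeds,
#' config hash, attrition) under `out_dir`.
#'
#' @param manifest Path to a YAML manifest, or an equivalent list.
#' @param out_dir Output directory.
#' @return Invisibly, a list with all in-memory results.
#' @export
run_study <- function(manifest, out_dir) {
  if (is.character(manifest)) manifest <- yaml::read_yaml(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(manifest$seed %||% 1L)
  ivp <- manifest$iv_params %||% list()
  iv <- list(p_threshold = ivp$p_threshold %||% 5e-8,
             r2_max = ivp$r2_max %||% 0.001,
             window_kb = ivp$window_kb %||% 10000,
             f_min = ivp$f_min %||% 10)
  scr <- manifest$screen %||% list()
  cfg <- screen_config(p_screen_1 = scr$p_screen_1 %||% 0.05,
                       p_screen_2 = scr$p_screen_2 %||% 0.01)
  pairing <- manifest$pairing %||% "delta"
  ld <- if (!is.null(manifest$ld)) read_ld_matrix(manifest$ld) else NULL

  for (p in c(unlist(manifest$exposures), unlist(manifest$mediators),
              manifest$outcome))
    if (!file.exists(p)) stop("manifest references missing file: ", p)

  outcome <- read_sumstats(manifest$outcome)
  mediators <- lapply(manifest$mediators, read_sumstats)

  screen <- screen_mediators(mediators, outcome, config = cfg, ld = ld,
                             p_threshold = iv$p_threshold, r2_max = iv$r2_max,
                             window_kb = iv$window_kb, f_min = iv$f_min,
                             seed = seed)
  utils::write.table(screen$results, file.path(out_dir, "screen_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(screen$cascade, file.path(out_dir, "screen_cascade.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  bidir <- list(); mediation <- list()
  for (en in names(manifest$exposures)) {
    exposure <- read_sumstats(manifest$exposures[[en]])
    bd <- run_bidirectional_mr(exposure, outcome, exposure_name = en,
                               outcome_name = "outcome", ld = ld,
                               p_threshold = iv$p_threshold,
                               r2_max = iv$r2_max, window_kb = iv$window_kb,
                               f_min = iv$f_min, seed = seed)
    bidir[[en]] <- bd
    if (is.list(bd$forward)) {
      utils::write.table(bd$forward$estimates,
                         file.path(out_dir, paste0("mr_", en, "_forward.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(bd$forward$sensitivity))
        write_sensitivity_report(bd$forward$sensitivity,
                                 file.path(out_dir,
                                           paste0("sensitivity_", en, ".json")))
    }
    med <- assemble_mediation(exposure, mediators[screen$qualified], outcome,
                              exposure_name = en, outcome_name = "outcome",
                              pairing = pairing, ld = ld,
                              p_threshold = iv$p_threshold,
                              r2_max = iv$r2_max, window_kb = iv$window_kb,
                              f_min = iv$f_min)
    mediation[[en]] <- med
    utils::write.table(med$table,
                       file.path(out_dir, paste0("mediation_", en, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  provenance <- list(
    manifest = manifest,
    config_hash = config_hash(manifest),
    seed = seed,
    screen_cascade = screen$cascade,
    timestamp_free = TRUE  # outputs carry no wall-clock state, so re-runs are identical
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(screen = screen, bidirectional = bidir,
                 mediation = mediation, provenance = provenance))
}

#' Stable polynomial hash of a configuration object
#'
#' Hashes the canonical JSON serialization; used to stamp outputs so a
#' re-run under the same manifest is recognizably identical.
#'
#' @param x Any jsonlite-serializable object.
#' @return 8-hex-digit hash string.
#' @export
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  # base-31 polynomial rolling hash, kept exactly representable in doubles
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
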