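#' Variance in the exposure explained by a single SNP
#'
#' Under Hardy-Weinberg equilibrium and a standardized trait, a variant
#' with minor-allele frequency MAF and per-allele effect beta explains
#' R^2 = 2 (1 - MAF) MAF beta^2 of the trait variance.
#'
#' @param maf Minor-allele frequency in [0, 0.5] (fold `eaf > 0.5` to
#'   `1 - eaf` first, or use [fold_maf()]).
#' @param beta Per-allele effect size.
#' @return Explained-variance proportion, vectorized.
#' @export
compute_r2 <- function(maf, beta) {
  if (any(is.na(maf)) || any(maf < 0 | maf > 0.5))
    stop("maf must lie in [0, 0.5]; fold eaf > 0.5 to 1 - eaf")
  2 * (1 - maf) * maf * beta^2
}

#' Single-instrument F-statistic
#'
#' Strength of a single instrument from its explained variance and the
#' exposure-study sample size: F = R^2 (N - 2) / (1 - R^2). F > 10 is the
#' conventional weak-instrument cutoff.
#'
#' @param r2 Explained-variance proportion in [0, 1).
#' @param n Exposure sample size (> 2).
#' @return F statistic, vectorized.
#' @export
compute_f <- function(r2, n) {
  if (any(is.na(r2)) || any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0, 1)")
  if (any(is.na(n)) || any(n <= 2)) stop("sample size must exceed 2")
  r2 * (n - 2) / (1 - r2)
}

#' Fold an effect-allele frequency to a minor-allele frequency
#' @param eaf Effect-allele frequency in [0, 1].
#' @return `pmin(eaf, 1 - eaf)`.
#' @export
fold_maf <- function(eaf) pmin(eaf, 1 - eaf)

#' Construct a linkage-disequilibrium matrix
#'
#' @param snp_ids Character vector of SNP identifiers.
#' @param r2 Square symmetric matrix of squared allelic correlations with
#'   unit diagonal, in SNP order; defaults to the identity (no LD).
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(snp_ids, r2 = diag(length(snp_ids))) {
  r2 <- as.matrix(r2)
  k <- length(snp_ids)
  if (!all(dim(r2) == c(k, k))) stop("r2 must be ", k, " x ", k)
  if (any(abs(r2 - t(r2)) > 1e-12)) stop("r2 must be symmetric")
  if (any(abs(diag(r2) - 1) > 1e-12)) stop("r2 must have unit diagonal")
  if (any(r2 < 0 | r2 > 1 + 1e-12)) stop("r2 entries must lie in [0, 1]")
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, r2 = r2), class = "ld_matrix")
}

#' Read an LD matrix from TSV
#'
#' Accepts either a square matrix with SNP ids as header row and first
#' column, or a long table with columns `snp_a`, `snp_b`, `r2` (missing
#' pairs taken as 0).
#'
#' @param path TSV path.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  if (identical(sort(header), sort(c("snp_a", "snp_b", "r2")))) {
    long <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    ids <- sort(unique(c(long$snp_a, long$snp_b)))
    m <- diag(length(ids)); dimnames(m) <- list(ids, ids)
    m[cbind(long$snp_a, long$snp_b)] <- long$r2
    m[cbind(long$snp_b, long$snp_a)] <- long$r2
    diag(m) <- 1
    return(ld_matrix(ids, m))
  }
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  ld_matrix(rownames(m), m)
}

#' Write an LD matrix as a square TSV
#' @param ld An `ld_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  utils::write.table(data.frame(snp = ld$snp_ids, ld$r2, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Greedy LD clumping
#'
#' Reduces a set of SNPs to independent index variants: SNPs are ranked by
#' ascending p-value (ties broken on SNP id) and accepted greedily; a
#' candidate is rejected iff it has r^2 >= `r2_max` with an
#' already-accepted SNP on the same chromosome within `window_kb`
#' kilobases. Both the correlation and the distance condition must hold
#' for exclusion, so SNPs on different chromosomes never exclude one
#' another. Output preserves acceptance (p-value) order; the result is
#' independent of the input row order.
#'
#' @param records A `sumstats` data frame (needs `chrom`, `pos`, `pvalue`).
#' @param ld An `ld_matrix` covering all records.
#' @param r2_max Squared-correlation exclusion threshold (default 0.001).
#' @param window_kb Exclusion window in kb around each index SNP
#'   (default 10000).
#' @return The retained rows of `records`, in acceptance order.
#' @export
clump <- function(records, ld, r2_max = 0.001, window_kb = 10000) {
  missing_ld <- setdiff(records$snp_id, ld$snp_ids)
  if (length(missing_ld))
    stop("SNP(s) absent from LD matrix: ", paste(missing_ld, collapse = ", "))
  ord <- order(records$pvalue, records$snp_id)
  rec <- records[ord, , drop = FALSE]
  accepted <- integer(0)
  for (i in seq_len(nrow(rec))) {
    if (length(accepted)) {
      same_chr <- rec$chrom[accepted] == rec$chrom[i]
      in_window <- abs(rec$pos[accepted] - rec$pos[i]) <= window_kb * 1000
      r2 <- ld$r2[rec$snp_id[accepted], rec$snp_id[i]]
      if (any(same_chr & in_window & r2 >= r2_max)) next
    }
    accepted <- c(accepted, i)
  }
  out <- rec[accepted, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select genetic instruments from exposure summary statistics
#'
#' Applies, in order: the genome-wide significance filter
#' (`pvalue < p_threshold`), palindromic-SNP removal, greedy LD clumping
#' ([clump()]), explained-variance and F-statistic computation
#' ([compute_r2()], [compute_f()]), and the weak-instrument filter
#' (`f_stat > f_min`). Per-stage attrition counts are attached as the
#' `"attrition"` attribute and also reported in the error message when no
#' instrument survives.
#'
#' F-statistics require an allele frequency and sample size; SNPs missing
#' either are dropped at the F stage with a warning.
#'
#' @param records Exposure `sumstats`.
#' @param ld An `ld_matrix`; defaults to no LD between the significant SNPs.
#' @param p_threshold Significance threshold (default 5e-8).
#' @param r2_max,window_kb Clumping parameters (defaults 0.001, 10000 kb).
#' @param f_min Weak-instrument threshold (default 10).
#' @param remove_palindromic Drop A/T and C/G SNPs (default TRUE).
#' @return Data frame of instruments: the input columns plus `maf`,
#'   `r2_explained`, `f_stat`; attributes `attrition` (data frame
#'   `stage`, `n_in`, `n_out`) and `mean_f`.
#' @export
select_instruments <- function(records, ld = NULL, p_threshold = 5e-8,
                               r2_max = 0.001, window_kb = 10000,
                               f_min = 10, remove_palindromic = TRUE) {
  stages <- character(0); n_in <- integer(0); n_out <- integer(0)
  note <- function(stage, before, after) {
    stages <<- c(stages, stage); n_in <<- c(n_in, before); n_out <<- c(n_out, after)
  }

  sig <- records[records$pvalue < p_threshold, , drop = FALSE]
  note("significance", nrow(records), nrow(sig))

  if (remove_palindromic && nrow(sig)) {
    pal <- is_palindromic(sig$effect_allele, sig$other_allele)
    nonpal <- sig[!pal, , drop = FALSE]
  } else nonpal <- sig
  note("palindrome", nrow(sig), nrow(nonpal))

  if (nrow(nonpal)) {
    if (is.null(ld)) ld <- ld_matrix(nonpal$snp_id)
    clumped <- clump(nonpal, ld, r2_max = r2_max, window_kb = window_kb)
  } else clumped <- nonpal
  note("clumping", nrow(nonpal), nrow(clumped))

  if (nrow(clumped)) {
    usable <- !is.na(clumped$eaf) & !is.na(clumped$n)
    if (any(!usable))
      warning(sum(!usable), " SNP(s) missing eaf or n; ",
              "F-statistic cannot be computed, dropped at F stage")
    inst <- clumped[usable, , drop = FALSE]
    inst$maf <- fold_maf(inst$eaf)
    inst$r2_explained <- compute_r2(inst$maf, inst$beta)
    inst$f_stat <- compute_f(inst$r2_explained, inst$n)
    inst <- inst[inst$f_stat > f_min, , drop = FALSE]
  } else {
    inst <- clumped
    inst$maf <- inst$r2_explained <- inst$f_stat <- numeric(0)
  }
  note("f_filter", nrow(clumped), nrow(inst))

  attrition <- data.frame(stage = stages, n_in = n_in, n_out = n_out)
  if (nrow(inst) == 0L)
    stop("0 instruments survive selection; attrition: ",
         paste(sprintf("%s %d->%d", stages, n_in, n_out), collapse = "; "))
  rownames(inst) <- NULL
  attr(inst, "attrition") <- attrition
  attr(inst, "mean_f") <- mean(inst$f_stat)
  inst
}

#' Write a stage-attrition report
#' @param instruments Result of [select_instruments()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_attrition <- function(instruments, path) {
  utils::write.table(attr(instruments, "attrition"), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
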