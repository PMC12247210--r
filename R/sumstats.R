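#' Default column mapping for GWAS summary-statistics files
#'
#' Maps the canonical field names used throughout the package to the column
#' names expected in an input file. Override any entry to accommodate the
#' dialect of a particular study.
#'
#' @return Named character vector: canonical field -> file column name.
#' @export
default_column_map <- function() {
  c(
    snp_id = "snp", chrom = "chr", pos = "pos",
    effect_allele = "ea", other_allele = "oa",
    beta = "beta", se = "se", pvalue = "p",
    eaf = "eaf", n = "n"
  )
}

.mandatory_fields <- c(
  "snp_id", "chrom", "pos", "effect_allele", "other_allele",
  "beta", "se", "pvalue"
)

.valid_alleles <- c("A", "C", "G", "T")

#' Read GWAS summary statistics from delimited text
#'
#' Reads a header-bearing delimited file of per-SNP association summaries
#' into a validated `sumstats` data frame. Rows violating the per-record
#' invariants (non-ACGT or identical alleles, non-positive standard error,
#' p-value outside (0, 1], allele frequency outside [0, 1], unparseable
#' numerics) are not silently dropped: they are collected into a rejects
#' table attached as the `"rejects"` attribute, with one reason per row.
#' Rows whose p-value disagrees with the two-sided normal test implied by
#' beta/se by more than a factor of 2 are kept with a warning.
#'
#' Gzip-compressed files are read transparently.
#'
#' @param path Path to the file.
#' @param column_map Named vector mapping canonical fields to file columns;
#'   see [default_column_map()]. `eaf` and `n` are optional.
#' @param delimiter Field delimiter, `"\t"` or `","`.
#' @return A data frame of class `sumstats` with columns `snp_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, `eaf`,
#'   `n`, and attribute `rejects` (data frame with `row`, `snp_id`, `reason`).
#' @export
read_sumstats <- function(path, column_map = default_column_map(),
                          delimiter = "\t") {
  if (!file.exists(path)) stop("sumstats file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", quote = "",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty sumstats file: ", path)
  missing_cols <- setdiff(unname(column_map[.mandatory_fields]), names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))

  get_col <- function(field) {
    col <- column_map[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  df <- data.frame(
    snp_id = get_col("snp_id"),
    chrom = get_col("chrom"),
    pos = suppressWarnings(as.integer(get_col("pos"))),
    effect_allele = toupper(get_col("effect_allele")),
    other_allele = toupper(get_col("other_allele")),
    beta = suppressWarnings(as.numeric(get_col("beta"))),
    se = suppressWarnings(as.numeric(get_col("se"))),
    pvalue = suppressWarnings(as.numeric(get_col("pvalue"))),
    eaf = suppressWarnings(as.numeric(get_col("eaf"))),
    n = suppressWarnings(as.numeric(get_col("n"))),
    stringsAsFactors = FALSE
  )

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) ifelse(bad & is.na(reason), why, reason)
  num_bad <- is.na(df$beta) | is.na(df$se) | is.na(df$pvalue) | is.na(df$pos)
  reason <- flag(num_bad, "unparseable numeric")
  reason <- flag(!(df$effect_allele %in% .valid_alleles) |
                   !(df$other_allele %in% .valid_alleles), "invalid allele")
  reason <- flag(df$effect_allele == df$other_allele, "identical alleles")
  reason <- flag(!is.na(df$se) & df$se <= 0, "nonpositive se")
  reason <- flag(!is.na(df$pvalue) & (df$pvalue <= 0 | df$pvalue > 1),
                 "pvalue outside (0,1]")
  reason <- flag(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1),
                 "eaf outside [0,1]")

  keep <- is.na(reason)
  rejects <- data.frame(row = which(!keep), snp_id = df$snp_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL

  # p/z consistency: warn (don't reject) when off by more than a factor of 2
  if (nrow(out)) {
    p_imp <- 2 * stats::pnorm(-abs(out$beta / out$se))
    off <- p_imp > 0 & (out$pvalue / p_imp > 2 | p_imp / out$pvalue > 2)
    if (any(off))
      warning(sum(off), " row(s) have p-values inconsistent with beta/se ",
              "beyond a factor of 2 (kept)")
  }
  attr(out, "rejects") <- rejects
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Write GWAS summary statistics to delimited text
#'
#' Inverse of [read_sumstats()]: writes the canonical columns under the
#' names given by `column_map`. Numeric fields are written at full
#' precision so that a read/write round trip is exact.
#'
#' @inheritParams read_sumstats
#' @param x A `sumstats` data frame.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path, column_map = default_column_map(),
                           delimiter = "\t") {
  fields <- intersect(names(default_column_map()), names(x))
  out <- x[, fields, drop = FALSE]
  names(out) <- unname(column_map[fields])
  for (col in names(out))
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a rejects report
#'
#' @param x A `sumstats` object from [read_sumstats()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rejects <- function(x, path) {
  rej <- attr(x, "rejects")
  if (is.null(rej)) rej <- data.frame(row = integer(), snp_id = character(),
                                      reason = character())
  utils::write.table(rej, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Is an allele pair palindromic?
#'
#' A palindromic (ambiguous-strand) SNP carries complementary alleles
#' (A/T or C/G), so the strand of a reporting study cannot be resolved
#' from the alleles alone.
#'
#' @param effect_allele,other_allele Single nucleotides (A/C/G/T),
#'   vectorized.
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  effect_allele <- toupper(effect_allele)
  other_allele <- toupper(other_allele)
  if (!all(effect_allele %in% .valid_alleles) ||
      !all(other_allele %in% .valid_alleles))
    stop("alleles must be single nucleotides A/C/G/T")
  flip_allele(effect_allele) == other_allele
}

#' Complement alleles (strand flip)
#' @param a Character vector of A/C/G/T alleles.
#' @return The complementary alleles.
#' @keywords internal
flip_allele <- function(a) {
  unname(c(A = "T", T = "A", C = "G", G = "C")[a])
}
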