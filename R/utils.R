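#' @importFrom stats sd rgamma rlnorm rnorm runif wilcox.test
#' @importFrom utils read.delim write.table
#' @import data.table
NULL

# Condition subclass so the CLI can distinguish bad inputs (exit 1) from
# runtime failures (exit 2).
stop_validation <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c("txrank_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Strip Ensembl-style version suffixes from accessions
#'
#' Removes a trailing \code{.N} version from IDs such as
#' \code{ENST00000367439.5}.  Idempotent: stripping twice equals stripping
#' once.  Annotation releases, expression matrices and MANE summaries carry
#' different versions of the same accession, so every join in the package is
#' performed on version-stripped IDs.
#'
#' @param x character vector of accessions.
#' @return character vector without version suffixes.
#' @export
#' @examples
#' strip_version(c("ENSG00000000001.5", "ENST00000367439.3", "ENST00000367440"))
strip_version <- function(x) {
  sub("\\.[0-9]+$", "", as.character(x))
}

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; reported ratios and percentage
#' shares use conventional half-up rounding to match printed-table precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.  Used
#' to score the cross-tissue variability of a transcript's TPM or rank
#' profile.  Undefined (returns \code{NA}) for vectors of length < 2 or with
#' non-positive mean; an all-zero profile therefore yields \code{NA}, never 0.
#'
#' @param values numeric vector.
#' @return a single non-negative number, or \code{NA_real_} when undefined.
#' @export
#' @examples
#' cv(c(5, 5, 5, 5))  # 0
#' cv(c(2, 4))        # sqrt(2) / 3
cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  sd(values) / m
}

# Row-wise CV over a matrix, vectorised (avoids an apply() per transcript).
row_cv <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  s2 <- rowSums((m - mu)^2) / (n - 1L)
  out <- sqrt(s2) / mu
  out[!is.finite(mu) | mu <= 0] <- NA_real_
  out
}

#' Average number of transcripts per gene
#'
#' Reporting ratio rounded half-up to two decimals, the precision used in
#' published expression-catalogue summary tables.
#'
#' @param transcript_count total number of transcripts.
#' @param gene_count total number of genes; must be > 0.
#' @return the ratio rounded to 2 decimals.
#' @export
#' @examples
#' transcripts_per_gene(199324, 58219)  # 3.42
transcripts_per_gene <- function(transcript_count, gene_count) {
  if (any(gene_count <= 0)) stop_validation("gene_count must be positive")
  round_half_up(transcript_count / gene_count, 2)
}

#' Percentage share of a subset
#'
#' \code{100 * part / whole}, rounded half-up to one decimal — the precision
#' at which coding/noncoding shares are conventionally reported.
#'
#' @param part,whole numeric; \code{whole} must be > 0.
#' @param digits decimals to keep (default 1).
#' @return percentage on the 0-100 scale.
#' @export
percent_share <- function(part, whole, digits = 1) {
  if (any(whole <= 0)) stop_validation("whole must be positive")
  round_half_up(100 * part / whole, digits)
}

# TSV writers/readers used throughout: plain tab-separated, no quoting,
# NA written as "NA".
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = "NA", data.table = FALSE, ...))
}
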