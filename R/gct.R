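# GCT 1.2 expression matrices and tissue collapsing.
#
# Matrices are plain numeric matrices: rows = version-stripped transcript
# IDs (rownames), columns = sample IDs or tissue labels (colnames).  An
# optional "description" attribute carries the GCT Description column
# (GTEx stores the gene ID there).

validate_tpm_matrix <- function(m, what = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop_validation("%s must be a numeric matrix", what)
  if (is.null(rownames(m)) && nrow(m) > 0)
    stop_validation("%s must have transcript IDs as rownames", what)
  if (anyDuplicated(rownames(m)))
    stop_validation("duplicate transcript IDs in %s", what)
  if (anyDuplicated(colnames(m)))
    stop_validation("duplicate column labels in %s", what)
  if (anyNA(m) || (length(m) && min(m) < 0))
    stop_validation("%s contains negative or missing TPM values", what)
  invisible(m)
}

#' Read a GCT 1.2 expression matrix
#'
#' Parses the GTEx dialect: a \code{#1.2} version line, a
#' \code{<rows>\\t<columns>} dimensions line, then a header row starting
#' with \code{Name} and \code{Description}.  The Name column becomes the
#' (version-stripped) rownames; the Description column is kept as the
#' \code{"description"} attribute.  Gzip input is handled transparently.
#' The declared dimensions are checked against the observed ones and
#' negative values are rejected.
#'
#' @param path GCT file (\code{.gct} or \code{.gct.gz}).
#' @return numeric matrix, transcripts x samples.
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  version <- readLines(con, n = 1L)
  if (!length(version) || !startsWith(version, "#1.2"))
    stop_validation("not a GCT 1.2 file (first line %s)",
                    if (length(version)) sQuote(version) else "missing")
  dims <- strsplit(readLines(con, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(dims) < 2L)
    stop_validation("malformed GCT dimensions line")
  nr <- as.integer(dims[1L]); nc <- as.integer(dims[2L])
  if (is.na(nr) || is.na(nc) || nr < 0 || nc < 0)
    stop_validation("malformed GCT dimensions line")
  body <- readLines(con)
  if (!length(body)) stop_validation("GCT file has no header row")
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[1L] != "Name" || header[2L] != "Description")
    stop_validation("GCT header must start with Name\tDescription columns")
  samples <- header[-(1:2)]
  if (length(samples) != nc)
    stop_validation("GCT dimension mismatch: declared %d columns, observed %d",
                    nc, length(samples))
  rows <- body[-1L][nzchar(body[-1L])]
  if (length(rows) != nr)
    stop_validation("GCT dimension mismatch: declared %d rows, observed %d",
                    nr, length(rows))
  if (nr == 0L) {
    m <- matrix(numeric(), nrow = 0L, ncol = nc,
                dimnames = list(NULL, samples))
    attr(m, "description") <- character()
    return(m)
  }
  parts <- strsplit(rows, "\t", fixed = TRUE)
  if (any(lengths(parts) != nc + 2L))
    stop_validation("GCT row %d has %d fields, expected %d",
                    which(lengths(parts) != nc + 2L)[1L],
                    lengths(parts)[lengths(parts) != nc + 2L][1L], nc + 2L)
  ids <- strip_version(vapply(parts, `[[`, character(1), 1L))
  desc <- vapply(parts, `[[`, character(1), 2L)
  vals <- suppressWarnings(
    as.numeric(unlist(lapply(parts, `[`, -(1:2)), use.names = FALSE)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE,
              dimnames = list(ids, samples))
  validate_tpm_matrix(m, sprintf("GCT file %s", path))
  attr(m, "description") <- desc
  m
}

#' Write a matrix as GCT 1.2
#'
#' Inverse of \code{\link{read_gct}}; works for sample-level and
#' tissue-level matrices alike.  Values are serialised at full double
#' precision (\code{\%.17g}) so that a write/read round trip is numerically
#' exact.  A path ending in \code{.gz} is gzip-compressed.
#'
#' @param m numeric matrix with transcript rownames.
#' @param path output path.
#' @param description optional Description column; defaults to the matrix's
#'   \code{"description"} attribute or the rownames.
#' @return the path, invisibly.
#' @export
write_gct <- function(m, path, description = NULL) {
  validate_tpm_matrix(m)
  if (is.null(description)) description <- attr(m, "description")
  if (is.null(description)) description <- rownames(m)
  if (nrow(m) && length(description) != nrow(m))
    stop_validation("description length (%d) != number of rows (%d)",
                    length(description), nrow(m))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c("#1.2", sprintf("%d\t%d", nrow(m), ncol(m)),
               paste(c("Name", "Description", colnames(m)), collapse = "\t")),
             con)
  if (nrow(m)) {
    body <- vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], description[i], sprintf("%.17g", m[i, ])),
            collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a sample-to-tissue mapping table
#'
#' Accepts the GTEx sample-attribute dialect (columns \code{SAMPID} and
#' \code{SMTSD}) or any two-column \code{sample}/\code{tissue} TSV.
#'
#' @param path TSV file.
#' @return data.frame with columns \code{sample_id}, \code{tissue}.
#' @export
read_sample_map <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  df <- read_tsv(path)
  if (all(c("SAMPID", "SMTSD") %in% names(df))) {
    out <- data.frame(sample_id = df$SAMPID, tissue = df$SMTSD,
                      stringsAsFactors = FALSE)
  } else if (all(c("sample_id", "tissue") %in% names(df))) {
    out <- df[c("sample_id", "tissue")]
  } else if (ncol(df) >= 2L) {
    out <- data.frame(sample_id = df[[1L]], tissue = df[[2L]],
                      stringsAsFactors = FALSE)
  } else {
    stop_validation("sample map needs SAMPID/SMTSD or sample_id/tissue columns")
  }
  if (anyDuplicated(out$sample_id))
    stop_validation("duplicate sample IDs in sample map")
  out
}

#' Collapse a sample-level matrix to per-tissue means
#'
#' Each tissue column of the result is the equal-weight arithmetic mean of
#' its member samples' TPM, transcript by transcript; tissues are ordered
#' alphabetically.  Samples absent from the map are an error unless
#' \code{drop_unmapped = TRUE}; tissues present in the map but with no
#' samples in the matrix are dropped with a warning.
#'
#' @param m transcripts x samples matrix.
#' @param sample_map data.frame from \code{\link{read_sample_map}}.
#' @param drop_unmapped drop samples missing from the map instead of
#'   erroring.
#' @param stat \code{"mean"} (default) or \code{"median"} per-tissue
#'   summary.
#' @return transcripts x tissues matrix of per-tissue summary TPM.
#' @export
collapse_to_tissues <- function(m, sample_map, drop_unmapped = FALSE,
                                stat = c("mean", "median")) {
  validate_tpm_matrix(m, "sample matrix")
  stat <- match.arg(stat)
  tissue_of <- sample_map$tissue[match(colnames(m), sample_map$sample_id)]
  unmapped <- is.na(tissue_of)
  if (any(unmapped) && !drop_unmapped)
    stop_validation("sample(s) missing from sample map: %s",
                    paste(colnames(m)[unmapped], collapse = ", "))
  if (all(unmapped))
    stop_validation("no sample in the matrix is present in the sample map")
  keep <- !unmapped
  missing_tissues <- setdiff(unique(sample_map$tissue),
                             unique(tissue_of[keep]))
  if (length(missing_tissues))
    warning(sprintf("tissue(s) with no samples in the matrix, excluded: %s",
                    paste(sort(missing_tissues), collapse = ", ")))
  tissues <- sort(unique(tissue_of[keep]))
  fun <- if (stat == "mean") rowMeans else
    function(x) apply(x, 1L, stats::median)
  out <- vapply(tissues, function(tt) {
    cols <- which(keep & tissue_of == tt)
    if (length(cols) == 1L) m[, cols] else fun(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m), ncol = length(tissues),
                dimnames = list(rownames(m), tissues))
  attr(out, "description") <- attr(m, "description")
  out
}

#' Remove transcripts never expressed in any tissue
#'
#' Drops exactly those rows whose TPM is 0 in every column — the strict
#' "no expression values in any tissue" rule, not a small-TPM cutoff — and
#' reports how many were removed.  Idempotent, and the bookkeeping identity
#' \code{nrow(input) - removed = nrow(output)} always holds.
#'
#' @param m transcripts x tissues (or x samples) matrix.
#' @return list with elements \code{matrix} (the retained rows) and
#'   \code{removed} (integer count of all-zero rows dropped).
#' @export
filter_expressed <- function(m) {
  validate_tpm_matrix(m)
  expressed <- rowSums(m > 0) > 0
  out <- m[expressed, , drop = FALSE]
  desc <- attr(m, "description")
  if (!is.null(desc)) attr(out, "description") <- desc[expressed]
  list(matrix = out, removed = sum(!expressed))
}
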