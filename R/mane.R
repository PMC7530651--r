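# Concordance between MANE-select transcripts and the computed rank
# classes: how often the curated representative transcript is also the
# expression-dominant one.

#' Cross-tabulate MANE-select transcripts against overall ranks
#'
#' Joins the MANE table to the rank table on version-stripped
#' (gene_id, transcript_id) pairs and tabulates the overall rank held by
#' each matched MANE-select transcript.  MANE records whose transcript is
#' absent from the expression set (including transcripts removed as
#' never-expressed, and genes outside the matrix) are counted as
#' unmatched rather than given a pseudo-rank, so the per-rank counts form
#' a true rank histogram.  \code{coverage_top5} is the fraction of matched
#' MANE transcripts holding rank 1-5.
#'
#' @param rt a \code{\link{build_rank_table}} result.
#' @param mane data.frame from \code{\link{read_mane_summary}}.
#' @return object of class \code{"mane_concordance"}: list with
#'   \code{matched_genes}, \code{per_rank_counts} (named integer vector),
#'   \code{unmatched_transcripts}, \code{coverage_top5}, and \code{table}
#'   (per-record detail data.frame).
#' @export
compare_mane <- function(rt, mane) {
  need <- c("gene_id", "mane_transcript_id")
  missing <- setdiff(need, names(mane))
  if (length(missing))
    stop_validation("MANE table is missing columns: %s",
                    paste(missing, collapse = ", "))
  mane <- mane
  mane$gene_id <- strip_version(mane$gene_id)
  mane$mane_transcript_id <- strip_version(mane$mane_transcript_id)

  tx <- rt$transcripts
  key <- paste(tx$gene_id, tx$transcript_id)
  i <- match(paste(mane$gene_id, mane$mane_transcript_id), key)
  matched <- !is.na(i)
  detail <- data.frame(
    gene_id = mane$gene_id,
    mane_transcript_id = mane$mane_transcript_id,
    matched = matched,
    overall_rank = ifelse(matched, tx$overall_rank[i], NA_integer_),
    overall_mean_tpm = ifelse(matched, tx$overall_mean_tpm[i], NA_real_),
    stringsAsFactors = FALSE
  )
  ranks <- detail$overall_rank[matched]
  per_rank <- if (length(ranks)) {
    tab <- table(ranks)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(), character())
  }
  structure(list(
    matched_genes = length(unique(detail$gene_id[matched])),
    per_rank_counts = per_rank,
    unmatched_transcripts = sum(!matched),
    coverage_top5 = if (length(ranks)) mean(ranks <= 5L) else NA_real_,
    table = detail
  ), class = "mane_concordance")
}

#' @export
print.mane_concordance <- function(x, ...) {
  cat(mane_summary_line(x), "\n")
  invisible(x)
}

mane_summary_line <- function(x) {
  topn <- function(r) {
    v <- x$per_rank_counts[as.character(r)]
    if (is.na(v)) 0L else v
  }
  sprintf(paste0(
    "MANE-select concordance: %d matched genes; rank1 %d, rank2 %d, ",
    "rank3 %d; top-5 coverage %.1f%%; %d unmatched transcripts"),
    x$matched_genes, topn(1), topn(2), topn(3),
    100 * x$coverage_top5, x$unmatched_transcripts)
}
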