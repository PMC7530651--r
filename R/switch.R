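# Rank1 switch events: genes whose per-tissue dominant isoform differs
# from the overall top-ranked one in some tissues.

#' Number of tissues where a gene's overall rank1 isoform stays dominant
#'
#' Counts the tissues in which the gene's overall rank1 transcript also
#' holds per-tissue rank 1.  With T tissues, a gene with one switching
#' tissue reports T - 1, and the identity
#' \code{rank1_tissue_count + #switch tissues = T} always holds because
#' every tissue assigns a full rank permutation.
#'
#' @param rt a \code{\link{build_rank_table}} result.
#' @param gene_id a single gene ID present in the table.
#' @return integer in [0, T].
#' @export
rank1_tissue_count <- function(rt, gene_id) {
  tx <- rt$transcripts
  rows <- which(tx$gene_id == gene_id)
  if (!length(rows)) stop_validation("unknown gene: %s", gene_id)
  top <- tx$transcript_id[rows][tx$overall_rank[rows] == 1L]
  sum(rt$rank[top, ] == 1L)
}

#' Detect rank1 switch events
#'
#' Scans all genes for tissues where the per-tissue dominant isoform is not
#' the overall rank1 transcript, and reports the genes whose count of
#' still-dominant tissues falls in \code{[min_count, max_count]}.  With T
#' tissues, \code{max_count = T - 1} selects genes with at least one
#' switching tissue; the window \code{[T - 4, T - 1]} mirrors the
#' conventional 1-to-4-switch-tissue interrogation.  Optional filters:
#' \code{cv_cutoff} keeps genes whose rank1 transcript has cross-tissue
#' TPM CV at or above the cutoff (high CV = tissue-modulated), and
#' \code{min_rank1_fraction} requires the rank1 transcript to carry at
#' least that overall expression fraction.
#'
#' @param rt a \code{\link{build_rank_table}} result with >= 2 tissues.
#' @param min_count,max_count inclusive bounds on
#'   \code{rank1_tissue_count}; defaults \code{T - 4} and \code{T - 1}.
#' @param cv_cutoff optional lower bound on the rank1 transcript's
#'   \code{cv_tpm}.
#' @param min_rank1_fraction optional lower bound on the rank1 overall
#'   expression fraction.
#' @return data.frame sorted by gene_id, one row per event: \code{gene_id},
#'   \code{gene_name}, \code{overall_rank1_transcript},
#'   \code{transcript_count}, \code{rank1_tissue_count},
#'   \code{switch_tissues} and \code{switching_transcripts} (comma-joined,
#'   aligned), \code{rank1_mean_tpm}, \code{rank1_fraction},
#'   \code{rank1_cv_tpm}.
#' @export
detect_switch_events <- function(rt, min_count = NULL, max_count = NULL,
                                 cv_cutoff = NULL,
                                 min_rank1_fraction = NULL) {
  tt <- length(rt$tissues)
  if (tt < 2L) stop_validation("switch detection needs >= 2 tissues")
  if (is.null(min_count)) min_count <- max(0L, tt - 4L)
  if (is.null(max_count)) max_count <- tt - 1L
  if (min_count > max_count)
    stop_validation("min_count (%d) > max_count (%d)", min_count, max_count)

  tx <- rt$transcripts
  top <- tx[tx$overall_rank == 1L, ]
  cnt <- top$rank1_tissue_count
  keep <- cnt >= min_count & cnt <= max_count
  if (!is.null(cv_cutoff))
    keep <- keep & !is.na(top$cv_tpm) & top$cv_tpm >= cv_cutoff
  if (!is.null(min_rank1_fraction))
    keep <- keep & !is.na(top$overall_fraction) &
      top$overall_fraction >= min_rank1_fraction
  top <- top[keep, , drop = FALSE]
  if (!nrow(top)) {
    return(data.frame(gene_id = character(), gene_name = character(),
                      overall_rank1_transcript = character(),
                      transcript_count = integer(),
                      rank1_tissue_count = integer(),
                      switch_tissues = character(),
                      switching_transcripts = character(),
                      rank1_mean_tpm = numeric(), rank1_fraction = numeric(),
                      rank1_cv_tpm = numeric(), stringsAsFactors = FALSE))
  }
  top <- top[order(top$gene_id), ]

  # For each event gene, list the tissues where its overall rank1 loses
  # per-tissue rank1 and which isoform wins there.
  sw_tissues <- character(nrow(top))
  sw_tx <- character(nrow(top))
  for (i in seq_len(nrow(top))) {
    g <- top$gene_id[i]
    rows <- which(tx$gene_id == g)
    rank_g <- rt$rank[tx$transcript_id[rows], , drop = FALSE]
    lost <- which(rank_g[match(top$transcript_id[i], rownames(rank_g)), ] != 1L)
    if (length(lost)) {
      winners <- vapply(lost, function(j) rownames(rank_g)[rank_g[, j] == 1L],
                        character(1))
      sw_tissues[i] <- paste(rt$tissues[lost], collapse = ",")
      sw_tx[i] <- paste(winners, collapse = ",")
    }
  }
  data.frame(
    gene_id = top$gene_id,
    gene_name = top$gene_name,
    overall_rank1_transcript = top$transcript_id,
    transcript_count = top$transcript_count,
    rank1_tissue_count = top$rank1_tissue_count,
    switch_tissues = sw_tissues,
    switching_transcripts = sw_tx,
    rank1_mean_tpm = top$overall_mean_tpm,
    rank1_fraction = top$overall_fraction,
    rank1_cv_tpm = top$cv_tpm,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-tissue display table for one gene
#'
#' Long-format table (one row per tissue x isoform) with TPM, per-tissue
#' expression fraction, per-tissue rank and overall rank — enough to plot
#' the classic dominant-isoform-switch panels (fraction and TPM per tissue
#' for the top-ranked isoforms).  Tissues where the gene is entirely
#' unexpressed report NA fractions.
#'
#' @param rt a \code{\link{build_rank_table}} result.
#' @param gene_id a single gene ID.
#' @return data.frame with \code{tissue}, \code{transcript_id},
#'   \code{overall_rank}, \code{tissue_rank}, \code{tpm}, \code{fraction};
#'   \code{T * k} rows for a gene with k isoforms.
#' @export
gene_switch_report <- function(rt, gene_id) {
  tx <- rt$transcripts
  rows <- which(tx$gene_id == gene_id)
  if (!length(rows)) stop_validation("unknown gene: %s", gene_id)
  if (length(rows) == 1L)
    warning(sprintf("gene %s has a single isoform; report is trivial",
                    gene_id))
  ids <- tx$transcript_id[rows]
  out <- expand.grid(transcript_id = ids, tissue = rt$tissues,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$overall_rank <- tx$overall_rank[rows][match(out$transcript_id, ids)]
  idx <- cbind(match(out$transcript_id, rownames(rt$rank)),
               match(out$tissue, colnames(rt$rank)))
  out$tissue_rank <- rt$rank[idx]
  out$tpm <- rt$tpm[idx]
  out$fraction <- rt$fraction[idx]
  out$gene_id <- gene_id
  out[order(out$tissue, out$overall_rank),
      c("gene_id", "tissue", "transcript_id", "overall_rank", "tissue_rank",
        "tpm", "fraction")]
}
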