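# Dataset-level summaries over a rank table: per-rank mean TPM, dominance
# fractions by isoform-count class, per-tissue rank fractions, counting
# tables, and the coding-vs-noncoding expression comparison.

#' Mean expression per overall rank class
#'
#' For ranks 1..\code{max_rank}, the mean overall TPM over all transcripts
#' holding that rank.  Single-transcript genes can be excluded: their lone
#' (necessarily rank1) isoform tends to carry markedly higher expression
#' and inflates the rank1 class mean.  Rank classes with no members are
#' absent from the output rather than reported as 0.
#'
#' @param rt a \code{\link{build_rank_table}} result.
#' @param max_rank deepest rank class to report (default 10).
#' @param exclude_single drop single-transcript genes first.
#' @return data.frame: \code{rank}, \code{mean_tpm}, \code{n}.
#' @export
rank_summary <- function(rt, max_rank = 10L, exclude_single = FALSE) {
  tx <- rt$transcripts
  if (exclude_single) tx <- tx[tx$transcript_count > 1L, ]
  tx <- tx[tx$overall_rank <= max_rank, ]
  if (!nrow(tx))
    return(data.frame(rank = integer(), mean_tpm = numeric(), n = integer()))
  agg <- tapply(tx$overall_mean_tpm, tx$overall_rank, mean)
  data.frame(rank = as.integer(names(agg)),
             mean_tpm = unname(agg),
             n = as.integer(table(tx$overall_rank)[names(agg)]),
             row.names = NULL)
}

#' Mean dominance fraction by isoform-count class and rank
#'
#' Genes are grouped by their number of expressed isoforms (classes
#' 1..\code{max_class}); within each class the mean overall expression
#' fraction of the rank-r transcripts is reported (genes weighted equally),
#' together with the cumulative fraction over ranks 1..r.  Class 1 is
#' forced to fraction 1 and each class's fractions sum to 1, so the
#' cumulative column measures how much of a gene's output its top-ranked
#' isoforms carry.
#'
#' @param rt a \code{\link{build_rank_table}} result.
#' @param max_class largest isoform-count class (default 10).
#' @return data.frame: \code{transcript_count} (class), \code{rank},
#'   \code{mean_fraction}, \code{cum_fraction}, \code{n_genes}.
#' @export
dominance_by_isoform_class <- function(rt, max_class = 10L) {
  tx <- rt$transcripts
  tx <- tx[tx$transcript_count <= max_class & !is.na(tx$overall_fraction), ]
  if (!nrow(tx))
    return(data.frame(transcript_count = integer(), rank = integer(),
                      mean_fraction = numeric(), cum_fraction = numeric(),
                      n_genes = integer()))
  dt <- data.table::as.data.table(tx)
  agg <- dt[, list(mean_fraction = mean(overall_fraction),
                   n_genes = .N),
            by = c("transcript_count", "overall_rank")]
  data.table::setnames(agg, "overall_rank", "rank")
  data.table::setorder(agg, transcript_count, rank)
  agg[, "cum_fraction" := cumsum(mean_fraction), by = "transcript_count"]
  as.data.frame(agg[, c("transcript_count", "rank", "mean_fraction",
                        "cum_fraction", "n_genes"), with = FALSE])
}

#' Per-tissue mean expression fraction by rank label
#'
#' For each tissue, the mean per-tissue expression fraction of transcripts
#' grouped by rank.  By default transcripts are labelled by their overall
#' (cross-tissue average) rank, so a tissue where many genes promote a
#' different isoform shows a depressed rank1 fraction — the display that
#' makes tissue-specific dominance switches visible.  Setting
#' \code{rank_label = "per_tissue"} labels transcripts by their rank within
#' each tissue instead.  Undefined fractions (gene TPM 0 in the tissue) are
#' excluded from the means.
#'
#' @param rt a \code{\link{build_rank_table}} result.
#' @param max_rank deepest rank label to report (default 5).
#' @param rank_label \code{"overall"} or \code{"per_tissue"}.
#' @return data.frame: \code{tissue}, \code{rank}, \code{mean_fraction},
#'   \code{n}.
#' @export
tissue_rank_distribution <- function(rt, max_rank = 5L,
                                     rank_label = c("overall", "per_tissue")) {
  rank_label <- match.arg(rank_label)
  out <- vector("list", length(rt$tissues))
  for (j in seq_along(rt$tissues)) {
    labels <- if (rank_label == "overall") rt$transcripts$overall_rank
              else rt$rank[, j]
    frac <- rt$fraction[, j]
    ok <- !is.na(frac) & labels <= max_rank
    agg <- tapply(frac[ok], labels[ok], mean)
    out[[j]] <- data.frame(tissue = rt$tissues[j],
                           rank = as.integer(names(agg)),
                           mean_fraction = unname(agg),
                           n = as.integer(table(labels[ok])[names(agg)]),
                           row.names = NULL)
  }
  do.call(rbind, out)
}

#' Expressed transcript/gene counting table
#'
#' The bookkeeping that frames the whole analysis: how many transcripts
#' survive the never-expressed filter, how they and their genes partition
#' into protein-coding and noncoding, the transcripts-per-gene ratios
#' (half-up, 2 decimals) and mean TPM per group.  Counting is over the full
#' annotation universe, so a rank table built with \code{coding_only =
#' FALSE} is expected here.
#'
#' @param rt a \code{\link{build_rank_table}} result (ideally
#'   \code{coding_only = FALSE}).
#' @param removed_count number of all-zero transcripts dropped by
#'   \code{\link{filter_expressed}} upstream (NA if unknown).
#' @return data.frame with one row per group (\code{expressed_all},
#'   \code{expressed_coding_genes}, \code{expressed_noncoding_genes}):
#'   transcript and gene counts, transcripts-per-gene, mean transcript and
#'   gene TPM.
#' @export
expression_summary <- function(rt, removed_count = NA_integer_) {
  tx <- rt$transcripts
  genes <- rt$genes
  grp <- function(label, keep_tx, keep_g) {
    n_g <- sum(keep_g)
    data.frame(
      group = label,
      transcript_count = sum(keep_tx),
      gene_count = n_g,
      transcripts_per_gene = if (n_g > 0)
        transcripts_per_gene(sum(keep_tx), n_g) else NA_real_,
      mean_transcript_tpm = if (sum(keep_tx) > 0)
        mean(tx$overall_mean_tpm[keep_tx]) else NA_real_,
      mean_gene_tpm = if (n_g > 0)
        mean(genes$overall_mean_tpm[keep_g]) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    grp("expressed_all", rep(TRUE, nrow(tx)), rep(TRUE, nrow(genes))),
    grp("expressed_coding_genes", tx$gene_coding, genes$coding),
    grp("expressed_noncoding_genes", !tx$gene_coding, !genes$coding)
  )
  attr(out, "removed_count") <- removed_count
  out
}

#' Coding vs noncoding isoform expression comparison
#'
#' Within protein-coding genes, compares the overall mean TPM of
#' protein-coding isoforms against that of noncoding isoforms
#' (retained_intron, processed_transcript, ...) with a one-sided
#' Mann-Whitney U test (coding greater).  Translatable isoforms are
#' expected to dominate; the test quantifies that gap.
#'
#' @param rt a \code{\link{build_rank_table}} result.
#' @param exclude_single drop single-transcript genes (whose lone coding
#'   isoform has elevated expression) before testing.
#' @return list: \code{p_value}, \code{mean_coding}, \code{mean_noncoding},
#'   \code{n_coding}, \code{n_noncoding}, and the underlying \code{htest}.
#' @export
coding_noncoding_test <- function(rt, exclude_single = FALSE) {
  tx <- rt$transcripts[rt$transcripts$gene_coding, ]
  if (exclude_single) tx <- tx[tx$transcript_count > 1L, ]
  is_coding <- tx$biotype == "protein_coding"
  x <- tx$overall_mean_tpm[is_coding]
  y <- tx$overall_mean_tpm[!is_coding]
  if (!length(x) || !length(y))
    stop_validation("need both coding and noncoding isoforms to compare")
  ht <- wilcox.test(x, y, alternative = "greater", exact = FALSE)
  list(p_value = ht$p.value, mean_coding = mean(x), mean_noncoding = mean(y),
       n_coding = length(x), n_noncoding = length(y), htest = ht)
}

# The download-table schema: one row per transcript with the columns
# published for reuse in expression-analysis pipelines.
download_table <- function(rt, max_rank = 10L) {
  tx <- rt$transcripts[rt$transcripts$overall_rank <= max_rank, ]
  o <- order(tx$gene_id, tx$overall_rank)
  tx <- tx[o, ]
  data.frame(
    gene_id = tx$gene_id,
    transcript_id = tx$transcript_id,
    gene_name = tx$gene_name,
    transcript_name = tx$transcript_name,
    transcript_count = tx$transcript_count,
    rank = tx$overall_rank,
    transcript_tpm = tx$overall_mean_tpm,
    gene_tpm = tx$gene_overall_tpm,
    expression_percentage = 100 * tx$overall_fraction,
    biotype = tx$biotype,
    transcript_length = tx$transcript_length,
    cds_length = tx$cds_length,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
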