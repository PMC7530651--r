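# Core computation: within-gene expression ranking of transcript isoforms,
# overall (cross-tissue average) and per tissue, with the deterministic
# tie-break cascade, plus gene-level expression, dominance fractions and
# CV scores.

# Deterministic within-gene ordering: descending scope TPM, then descending
# CDS length, then descending transcript length, then ascending transcript
# ID.  Returns integer ranks 1..k within each gene.
rank_within_genes <- function(gene_id, tpm, cds_length, transcript_length,
                              transcript_id) {
  o <- order(gene_id, -tpm, -cds_length, -transcript_length, transcript_id,
             method = "radix")
  r <- integer(length(o))
  r[o] <- sequence(rle(gene_id[o])$lengths)
  r
}

#' Gene-level expression from isoform TPM
#'
#' Gene TPM is the sum of its member isoforms' TPM, per tissue — the
#' additive relationship that TPM-level isoform quantification guarantees.
#' Only the transcripts present in the matrix (i.e. the expressed set after
#' \code{\link{filter_expressed}}) contribute, and \code{transcript_count}
#' counts those expressed isoforms.
#'
#' @param m transcripts x tissues TPM matrix.
#' @param annotation transcript annotation covering every matrix row.
#' @return list with \code{genes} (data.frame: \code{gene_id},
#'   \code{transcript_count}, \code{overall_mean_tpm}) and \code{tpm}
#'   (genes x tissues matrix).
#' @export
gene_expression <- function(m, annotation) {
  validate_tpm_matrix(m)
  orphans <- setdiff(rownames(m), annotation$transcript_id)
  if (length(orphans))
    stop_validation("transcript(s) missing from annotation: %s",
                    paste(orphans, collapse = ", "))
  gene <- annotation$gene_id[match(rownames(m), annotation$transcript_id)]
  gm <- rowsum(m, group = gene, reorder = TRUE)
  genes <- data.frame(
    gene_id = rownames(gm),
    transcript_count = as.integer(table(gene)[rownames(gm)]),
    overall_mean_tpm = rowMeans(gm),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(genes = genes, tpm = gm)
}

#' Rank isoforms within genes for one scope
#'
#' Sorts each gene's isoforms by expression in the requested scope —
#' \code{"overall"} (the cross-tissue average) or a single tissue label —
#' breaking exact expression ties by larger CDS length, then larger
#' transcript length, then lexicographically smaller transcript ID, and
#' assigns ranks 1..k.  The final ID key makes the ranking fully
#' deterministic.
#'
#' @param m transcripts x tissues TPM matrix (expressed transcripts only).
#' @param annotation transcript annotation covering every matrix row.
#' @param scope \code{"overall"} or one of \code{colnames(m)}.
#' @return data.frame: \code{gene_id}, \code{transcript_id}, \code{tpm}
#'   (scope TPM), \code{rank}.
#' @export
rank_isoforms <- function(m, annotation, scope = "overall") {
  validate_tpm_matrix(m)
  orphans <- setdiff(rownames(m), annotation$transcript_id)
  if (length(orphans))
    stop_validation("transcript(s) missing from annotation: %s",
                    paste(orphans, collapse = ", "))
  i <- match(rownames(m), annotation$transcript_id)
  s <- if (identical(scope, "overall")) {
    rowMeans(m)
  } else {
    if (!scope %in% colnames(m))
      stop_validation("unknown scope %s", sQuote(scope))
    m[, scope]
  }
  data.frame(
    gene_id = annotation$gene_id[i],
    transcript_id = rownames(m),
    tpm = unname(s),
    rank = rank_within_genes(annotation$gene_id[i], s,
                             annotation$cds_length[i],
                             annotation$transcript_length[i],
                             rownames(m)),
    stringsAsFactors = FALSE
  )
}

#' Per-transcript expression fractions
#'
#' Fraction of its gene's expression that each transcript carries in the
#' requested scope: transcript TPM divided by gene TPM.  Where the gene's
#' TPM is 0 in that scope the fraction is undefined and returned as
#' \code{NA} (never imputed as 0); downstream averages exclude these.
#'
#' @param m transcripts x tissues TPM matrix.
#' @param gene_expr result of \code{\link{gene_expression}} on the same
#'   matrix/annotation.
#' @param annotation transcript annotation.
#' @param scope \code{"overall"} or a tissue label.
#' @return numeric vector of fractions in [0, 1] (NA where undefined),
#'   aligned with \code{rownames(m)}.
#' @export
expression_fractions <- function(m, gene_expr, annotation,
                                 scope = "overall") {
  validate_tpm_matrix(m)
  gene <- annotation$gene_id[match(rownames(m), annotation$transcript_id)]
  gi <- match(gene, rownames(gene_expr$tpm))
  if (anyNA(gi))
    stop_validation("gene_expression result does not cover all genes")
  if (identical(scope, "overall")) {
    tx <- rowMeans(m)
    g <- rowMeans(gene_expr$tpm)[gi]
  } else {
    if (!scope %in% colnames(m))
      stop_validation("unknown scope %s", sQuote(scope))
    tx <- m[, scope]
    g <- gene_expr$tpm[gi, scope]
  }
  out <- ifelse(g > 0, tx / g, NA_real_)
  unname(out)
}

#' Build the full rank table
#'
#' One pass over a tissue-level TPM matrix producing everything the
#' downstream summaries, switch detection and MANE comparison need: overall
#' and per-tissue ranks (deterministic tie-break cascade), overall and
#' per-tissue expression fractions (NA where gene TPM is 0), the
#' coefficient of variation of each transcript's per-tissue TPM
#' (\code{cv_tpm}) and of its per-tissue ranks (\code{cv_rank}), and for
#' the overall rank1 transcript of each gene the number of tissues where it
#' also holds per-tissue rank 1 (\code{rank1_tissue_count}).
#'
#' Ranks are computed on the supplied (expressed) transcript set; run
#' \code{\link{filter_expressed}} first.  Tissues where a gene is entirely
#' unexpressed still receive ranks through the tie-break cascade, so
#' per-gene ranks are a permutation of 1..k in every tissue and the
#' identity \code{rank1_tissue_count + #switch tissues = #tissues} is
#' exact.
#'
#' @param m transcripts x tissues TPM matrix (>= 2 tissues for CV scores).
#' @param annotation transcript annotation covering every matrix row.
#' @param coding_only keep only protein-coding genes (the usual analysis
#'   universe); default TRUE.
#' @return object of class \code{"rank_table"}: a list with
#'   \describe{
#'     \item{transcripts}{per-transcript data.frame (annotation columns,
#'       \code{overall_mean_tpm}, \code{overall_rank},
#'       \code{overall_fraction}, \code{cv_tpm}, \code{cv_rank},
#'       \code{rank1_tissue_count}, \code{transcript_count},
#'       \code{gene_overall_tpm})}
#'     \item{genes}{per-gene data.frame from
#'       \code{\link{classify_gene_biotype}} + expression}
#'     \item{tpm, rank, fraction}{transcripts x tissues matrices}
#'     \item{gene_tpm}{genes x tissues matrix}
#'     \item{tissues}{tissue labels}
#'   }
#' @export
build_rank_table <- function(m, annotation, coding_only = TRUE) {
  validate_tpm_matrix(m)
  validate_annotation(annotation)
  orphans <- setdiff(rownames(m), annotation$transcript_id)
  if (length(orphans))
    stop_validation("transcript(s) missing from annotation: %s",
                    paste(orphans, collapse = ", "))
  if (!nrow(m)) stop_validation("empty expression matrix")

  ann <- annotation[match(rownames(m), annotation$transcript_id), ]
  if (coding_only) {
    gene_flags <- classify_gene_biotype(ann)
    coding_genes <- gene_flags$gene_id[gene_flags$coding]
    keep <- ann$gene_id %in% coding_genes
    if (!any(keep))
      stop_validation("no protein-coding genes in the expression matrix")
    m <- m[keep, , drop = FALSE]
    ann <- ann[keep, , drop = FALSE]
  }
  tissues <- colnames(m)

  ge <- gene_expression(m, ann)
  gi <- match(ann$gene_id, rownames(ge$tpm))
  overall_tpm <- rowMeans(m)
  gene_overall <- rowMeans(ge$tpm)

  overall_rank <- rank_within_genes(ann$gene_id, overall_tpm,
                                    ann$cds_length, ann$transcript_length,
                                    ann$transcript_id)
  rank_m <- matrix(NA_integer_, nrow(m), length(tissues),
                   dimnames = list(rownames(m), tissues))
  for (tt in tissues) {
    rank_m[, tt] <- rank_within_genes(ann$gene_id, m[, tt], ann$cds_length,
                                      ann$transcript_length,
                                      ann$transcript_id)
  }
  gene_tpm_rows <- ge$tpm[gi, , drop = FALSE]
  frac_m <- m / gene_tpm_rows
  frac_m[gene_tpm_rows == 0] <- NA_real_
  dimnames(frac_m) <- dimnames(m)

  gene_flags <- classify_gene_biotype(ann)
  genes <- merge(gene_flags, ge$genes, by = "gene_id", sort = TRUE)
  stopifnot(all(genes$n_transcripts == genes$transcript_count))
  genes$n_transcripts <- NULL

  transcripts <- data.frame(
    ann,
    overall_mean_tpm = unname(overall_tpm),
    overall_rank = overall_rank,
    overall_fraction = ifelse(gene_overall[gi] > 0,
                              unname(overall_tpm) / gene_overall[gi],
                              NA_real_),
    cv_tpm = row_cv(m),
    cv_rank = row_cv(rank_m),
    rank1_tissue_count = as.integer(rowSums(rank_m == 1L)),
    transcript_count = genes$transcript_count[match(ann$gene_id,
                                                    genes$gene_id)],
    gene_overall_tpm = unname(gene_overall[gi]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  coding_flag <- genes$coding[match(transcripts$gene_id, genes$gene_id)]
  transcripts$gene_coding <- coding_flag

  structure(list(transcripts = transcripts, genes = genes, tpm = m,
                 rank = rank_m, fraction = frac_m, gene_tpm = ge$tpm,
                 tissues = tissues),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf(
    "rank_table: %d transcripts, %d genes, %d tissues\n",
    nrow(x$transcripts), nrow(x$genes), length(x$tissues)))
  n1 <- sum(x$transcripts$overall_rank == 1L)
  cat(sprintf("  overall rank1 transcripts: %d (mean TPM %.3f)\n", n1,
              mean(x$transcripts$overall_mean_tpm[x$transcripts$overall_rank == 1L])))
  invisible(x)
}

# On-disk cache of a rank table (all TSV) so `switch`/`mane` CLI commands
# can reuse a `rank` run without recomputing.
write_rank_table <- function(rt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(rt$transcripts, file.path(dir, "transcripts.tsv"))
  write_tsv(rt$genes, file.path(dir, "genes.tsv"))
  wide <- function(m) data.frame(transcript_id = rownames(m), m,
                                 check.names = FALSE,
                                 stringsAsFactors = FALSE)
  write_tsv(wide(rt$tpm), file.path(dir, "tpm.tsv"))
  write_tsv(wide(rt$rank), file.path(dir, "rank.tsv"))
  write_tsv(wide(rt$fraction), file.path(dir, "fraction.tsv"))
  gw <- data.frame(gene_id = rownames(rt$gene_tpm), rt$gene_tpm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(gw, file.path(dir, "gene_tpm.tsv"))
  invisible(dir)
}

read_rank_table <- function(dir) {
  need <- c("transcripts.tsv", "genes.tsv", "tpm.tsv", "rank.tsv",
            "fraction.tsv", "gene_tpm.tsv")
  paths <- file.path(dir, need)
  if (!all(file.exists(paths)))
    stop_validation("incomplete rank-table cache in %s", dir)
  unwide <- function(path, idcol) {
    df <- read_tsv(path)
    m <- as.matrix(df[-1L])
    rownames(m) <- df[[idcol]]
    m
  }
  rank_m <- unwide(paths[4L], "transcript_id")
  storage.mode(rank_m) <- "integer"
  structure(list(
    transcripts = read_tsv(paths[1L]),
    genes = read_tsv(paths[2L]),
    tpm = unwide(paths[3L], "transcript_id"),
    rank = rank_m,
    fraction = unwide(paths[5L], "transcript_id"),
    gene_tpm = unwide(paths[6L], "gene_id"),
    tissues = colnames(unwide(paths[3L], "transcript_id"))
  ), class = "rank_table")
}
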