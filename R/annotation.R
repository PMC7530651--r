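# Transcript annotation tables
#
# The pipeline's static metadata: one row per transcript with its gene,
# biotype and the two tie-break lengths.  Columns:
#   transcript_id, gene_id, gene_name, transcript_name, biotype,
#   transcript_length, cds_length
# All IDs are version-stripped.

ANNOTATION_COLS <- c("transcript_id", "gene_id", "gene_name",
                     "transcript_name", "biotype",
                     "transcript_length", "cds_length")

NONCODING_BIOTYPES <- c("processed_transcript", "retained_intron",
                        "nonsense_mediated_decay")

validate_annotation <- function(ann) {
  missing <- setdiff(ANNOTATION_COLS, names(ann))
  if (length(missing))
    stop_validation("annotation is missing columns: %s",
                    paste(missing, collapse = ", "))
  if (anyDuplicated(ann$transcript_id))
    stop_validation("duplicate transcript_id in annotation: %s",
                    paste(unique(ann$transcript_id[duplicated(ann$transcript_id)]),
                          collapse = ", "))
  if (any(is.na(ann$biotype) | !nzchar(ann$biotype)))
    stop_validation("empty biotype for transcripts: %s",
                    paste(ann$transcript_id[is.na(ann$biotype) | !nzchar(ann$biotype)],
                          collapse = ", "))
  if (nrow(ann) && any(ann$transcript_length < 1))
    stop_validation("transcript_length must be >= 1")
  if (nrow(ann) && any(ann$cds_length < 0))
    stop_validation("cds_length must be >= 0")
  bad <- ann$cds_length > ann$transcript_length
  if (any(bad))
    stop_validation("cds_length exceeds transcript_length for: %s",
                    paste(ann$transcript_id[bad], collapse = ", "))
  invisible(ann)
}

# First attribute value among `keys` present in a GTF attribute string, or NA.
# GENCODE dialect: key "value"; pairs separated by "; ".
gtf_attr <- function(attrs, keys) {
  out <- rep(NA_character_, length(attrs))
  for (key in keys) {
    need <- is.na(out)
    if (!any(need)) break
    m <- regmatches(attrs[need],
                    regexec(paste0(key, ' "([^"]*)"'), attrs[need]))
    val <- vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
                  character(1))
    out[need] <- val
  }
  out
}

#' Read transcript annotation from a GENCODE-style GTF
#'
#' Builds the transcript annotation table from \code{transcript},
#' \code{exon} and (optional) \code{CDS} features.  Lengths are computed as
#' \code{end - start + 1} summed over features (GTF coordinates are 1-based
#' inclusive; strand does not affect lengths).  The biotype is taken from
#' the transcript-level \code{transcript_type} (or \code{transcript_biotype})
#' attribute, and all gene/transcript IDs are version-stripped.
#'
#' A transcript annotated as \code{protein_coding} but lacking CDS features
#' keeps \code{cds_length = 0} with a warning: such edge cases exist in real
#' annotation releases and ranking then falls through to the transcript
#' length tie-break.
#'
#' @param path GTF file (plain or gzip).
#' @return data.frame with the annotation columns (see
#'   \code{\link{read_annotation_tsv}}).
#' @export
read_annotation_gtf <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  lines <- readLines(gzfile(path))
  keep <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) {
    ann <- data.frame(transcript_id = character(), gene_id = character(),
                      gene_name = character(), transcript_name = character(),
                      biotype = character(), transcript_length = integer(),
                      cds_length = integer(), stringsAsFactors = FALSE)
    return(validate_annotation(ann))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop_validation("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                    idx[which(nf != 9L)[1L]], nf[nf != 9L][1L])
  feature <- vapply(fields, `[[`, character(1), 3L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 4L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 5L)))
  bad <- which(is.na(start) | is.na(end) | end < start)
  use <- feature %in% c("transcript", "exon", "CDS")
  if (length(intersect(bad, which(use))))
    stop_validation("malformed GTF line %d: invalid coordinates",
                    idx[intersect(bad, which(use))[1L]])
  attrs <- vapply(fields, `[[`, character(1), 9L)

  tx_rows <- which(feature == "transcript")
  if (!length(tx_rows))
    stop_validation("GTF contains no transcript features")
  tid <- strip_version(gtf_attr(attrs[tx_rows], "transcript_id"))
  ann <- data.frame(
    transcript_id = tid,
    gene_id = strip_version(gtf_attr(attrs[tx_rows], "gene_id")),
    gene_name = gtf_attr(attrs[tx_rows], "gene_name"),
    transcript_name = gtf_attr(attrs[tx_rows], "transcript_name"),
    biotype = gtf_attr(attrs[tx_rows], c("transcript_type", "transcript_biotype")),
    stringsAsFactors = FALSE
  )
  if (any(is.na(ann$transcript_id)) || any(is.na(ann$gene_id)))
    stop_validation("transcript feature without gene_id/transcript_id attribute")
  ann$gene_name[is.na(ann$gene_name)] <- ann$gene_id[is.na(ann$gene_name)]
  ann$transcript_name[is.na(ann$transcript_name)] <-
    ann$transcript_id[is.na(ann$transcript_name)]

  span_sum <- function(rows) {
    if (!length(rows)) return(integer())
    id <- strip_version(gtf_attr(attrs[rows], "transcript_id"))
    len <- end[rows] - start[rows] + 1L
    tapply(len, id, sum)
  }
  exon_len <- span_sum(which(feature == "exon"))
  cds_len <- span_sum(which(feature == "CDS"))

  no_exon <- setdiff(ann$transcript_id, names(exon_len))
  if (length(no_exon))
    stop_validation("transcript(s) with no exon features: %s",
                    paste(no_exon, collapse = ", "))
  ann$transcript_length <- as.integer(exon_len[ann$transcript_id])
  ann$cds_length <- as.integer(cds_len[ann$transcript_id])
  ann$cds_length[is.na(ann$cds_length)] <- 0L

  coding_no_cds <- ann$biotype == "protein_coding" & ann$cds_length == 0L
  if (any(coding_no_cds))
    warning(sprintf("protein_coding transcript(s) without CDS features (cds_length set to 0): %s",
                    paste(ann$transcript_id[coding_no_cds], collapse = ", ")))
  validate_annotation(ann[ANNOTATION_COLS])
}

#' Read transcript annotation from a flat TSV
#'
#' Fixture-friendly alternative to \code{\link{read_annotation_gtf}}: a
#' tab-separated file whose header covers the six annotation fields
#' (\code{transcript_id}, \code{gene_id}, \code{gene_name},
#' \code{transcript_name}, \code{biotype}, \code{transcript_length},
#' \code{cds_length}).  IDs are version-stripped and the same invariants are
#' enforced (unique transcripts, \code{cds_length <= transcript_length},
#' nonempty biotype).
#'
#' @param path TSV file.
#' @return annotation data.frame.
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  ann <- read_tsv(path)
  missing <- setdiff(ANNOTATION_COLS, names(ann))
  if (length(missing))
    stop_validation("annotation TSV is missing columns: %s",
                    paste(missing, collapse = ", "))
  ann <- ann[ANNOTATION_COLS]
  if (!nrow(ann)) {
    ann$transcript_length <- integer()
    ann$cds_length <- integer()
    return(validate_annotation(ann))
  }
  ann$transcript_id <- strip_version(ann$transcript_id)
  ann$gene_id <- strip_version(ann$gene_id)
  ann$transcript_length <- as.integer(ann$transcript_length)
  ann$cds_length <- as.integer(ann$cds_length)
  validate_annotation(ann)
}

#' Read a MANE-select summary file
#'
#' Accepts either the NCBI MANE summary header (\code{Ensembl_Gene},
#' \code{Ensembl_nuc}, \code{RefSeq_nuc}, with an optional
#' \code{MANE_status} column from which only MANE Select rows are kept) or a
#' generic header (\code{gene_id}, \code{mane_transcript_id} or
#' \code{transcript_id}, \code{refseq_id}).  Ensembl IDs are
#' version-stripped; exact duplicate records are collapsed, and a gene
#' listed with two different select transcripts is an error, since
#' MANE-select is one transcript per gene by construction.
#'
#' @param path TSV file (plain or gzip).
#' @return data.frame with columns \code{gene_id},
#'   \code{mane_transcript_id}, \code{refseq_id}.
#' @export
read_mane_summary <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  df <- read_tsv(path)
  names(df) <- sub("^#", "", names(df))
  pick <- function(candidates) {
    hit <- intersect(candidates, names(df))
    if (!length(hit))
      stop_validation("MANE summary lacks a column among: %s",
                      paste(candidates, collapse = ", "))
    df[[hit[1L]]]
  }
  if ("MANE_status" %in% names(df))
    df <- df[df$MANE_status == "MANE Select", , drop = FALSE]
  mane <- data.frame(
    gene_id = strip_version(pick(c("Ensembl_Gene", "gene_id"))),
    mane_transcript_id = strip_version(
      pick(c("Ensembl_nuc", "mane_transcript_id", "transcript_id"))),
    refseq_id = as.character(pick(c("RefSeq_nuc", "refseq_id"))),
    stringsAsFactors = FALSE
  )
  mane <- unique(mane[c("gene_id", "mane_transcript_id", "refseq_id")])
  dup <- duplicated(mane$gene_id)
  if (any(dup))
    stop_validation("gene(s) with conflicting MANE-select transcripts: %s",
                    paste(unique(mane$gene_id[dup]), collapse = ", "))
  mane
}

#' Read an NCBI gene2ensembl cross-reference table
#'
#' Minimal support for the RefSeq-query pathway: maps NCBI GeneIDs and
#' RefSeq transcript accessions to Ensembl gene/transcript IDs.  Version
#' suffixes are stripped from all accessions.
#'
#' @param path gene2ensembl-style TSV (plain or gzip).
#' @return data.frame with columns \code{entrez_gene_id}, \code{gene_id},
#'   \code{refseq_id}, \code{transcript_id}.
#' @export
read_gene2ensembl <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  df <- read_tsv(path)
  names(df) <- sub("^#", "", names(df))
  need <- c("GeneID", "Ensembl_gene_identifier",
            "RNA_nucleotide_accession.version", "Ensembl_rna_identifier")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_validation("gene2ensembl file is missing columns: %s",
                    paste(missing, collapse = ", "))
  data.frame(
    entrez_gene_id = df$GeneID,
    gene_id = strip_version(df$Ensembl_gene_identifier),
    refseq_id = strip_version(df$RNA_nucleotide_accession.version),
    transcript_id = strip_version(df$Ensembl_rna_identifier),
    stringsAsFactors = FALSE
  )
}

#' Flag protein-coding genes
#'
#' A gene is protein-coding iff at least one of its transcripts carries the
#' \code{protein_coding} biotype; genes whose isoforms are all noncoding
#' (e.g. a single \code{processed_transcript}) are flagged noncoding.  Note
#' that protein-coding genes routinely carry noncoding isoforms
#' (retained_intron, processed_transcript, nonsense_mediated_decay) — those
#' do not affect the gene-level flag.
#'
#' @param annotation transcript annotation data.frame.
#' @return data.frame with one row per gene: \code{gene_id},
#'   \code{gene_name}, \code{n_transcripts}, \code{coding} (logical).
#' @export
classify_gene_biotype <- function(annotation) {
  validate_annotation(annotation)
  if (!nrow(annotation))
    stop_validation("annotation is empty")
  dt <- data.table::as.data.table(annotation)
  out <- dt[, list(gene_name = gene_name[1L],
                   n_transcripts = .N,
                   coding = any(biotype == "protein_coding")),
            by = "gene_id"]
  data.table::setorder(out, gene_id)
  as.data.frame(out)
}
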