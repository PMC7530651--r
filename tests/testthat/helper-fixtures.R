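# Fixtures built in code: tiny handwritten GTF/GCT text, and a dataset of
# genes with engineered exact expression ties that exercises the whole
# tie-break cascade (TPM tie -> CDS, CDS tie -> transcript length, both
# tied -> transcript ID).

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

toy_gct_lines <- function(m, ids = rownames(m), desc = ids) {
  c("#1.2",
    sprintf("%d\t%d", nrow(m), ncol(m)),
    paste(c("Name", "Description", colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i)
      paste(c(ids[i], desc[i], format(m[i, ], trim = TRUE)), collapse = "\t"),
      character(1)))
}

# n_genes genes x 4 isoforms, all isoforms of a gene share the same TPM in
# every tissue; CDS/length/ID patterns force each stage of the cascade.
make_tie_dataset <- function(n_genes, n_tissues = 4, seed = 99) {
  set.seed(seed)
  ann <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    data.frame(
      transcript_id = sprintf("TIE%05dT%d", g, 1:4),
      gene_id = sprintf("TIEG%05d", g),
      gene_name = sprintf("TIEN%05d", g),
      transcript_name = sprintf("TIEN%05d-%d", g, 1:4),
      biotype = c("protein_coding", "protein_coding", "retained_intron",
                  "retained_intron"),
      # T1 vs T2: equal CDS 300, lengths 900 vs 800 -> length breaks it.
      # T3 vs T4: CDS 0, equal length 700 -> ID breaks it.
      transcript_length = c(900L, 800L, 700L, 700L),
      cds_length = c(300L, 300L, 0L, 0L),
      stringsAsFactors = FALSE)
  }))
  tpm <- matrix(rep(round(runif(n_genes, 1, 50), 3), each = 4),
                nrow = 4 * n_genes, ncol = n_tissues,
                dimnames = list(ann$transcript_id,
                                sprintf("tissue%02d", seq_len(n_tissues))))
  list(tpm = tpm, annotation = ann)
}

# Hand-built two-isoform switch world: every gene dominated by isoform A
# except in `switch_tissue`, where B wins.  Used for the tissue-level
# monotonicity checks without relying on the generator.
make_switch_dataset <- function(n_genes = 5, tissues = sprintf("t%02d", 1:6),
                                switch_tissue = "t03") {
  ann <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    data.frame(
      transcript_id = sprintf("SW%04dT%d", g, 1:2),
      gene_id = sprintf("SWG%04d", g),
      gene_name = sprintf("SWN%04d", g),
      transcript_name = sprintf("SWN%04d-%d", g, 1:2),
      biotype = c("protein_coding", "processed_transcript"),
      transcript_length = c(1000L, 600L),
      cds_length = c(600L, 0L),
      stringsAsFactors = FALSE)
  }))
  tpm <- matrix(0, nrow(ann), length(tissues),
                dimnames = list(ann$transcript_id, tissues))
  for (g in seq_len(n_genes)) {
    a <- 2 * g - 1; b <- 2 * g
    tpm[a, ] <- 9; tpm[b, ] <- 1
    tpm[a, switch_tissue] <- 1; tpm[b, switch_tissue] <- 9
  }
  list(tpm = tpm, annotation = ann)
}

read_tsv_file <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = "NA", data.table = FALSE))
}
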