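test_that("GTF reader sums exon and CDS spans and strips versions", {
  attrs <- paste0('gene_id "ENSG00000000001.5"; transcript_id "ENST00000000001.2"; ',
                  'gene_name "GA"; transcript_name "GA-201"; ',
                  'transcript_type "protein_coding";')
  gtf <- write_lines_tmp(c(
    "##comment",
    sprintf("chr1\tx\ttranscript\t1\t250\t.\t+\t.\t%s", attrs),
    sprintf("chr1\tx\texon\t1\t100\t.\t+\t.\t%s", attrs),
    sprintf("chr1\tx\texon\t201\t250\t.\t+\t.\t%s", attrs),
    sprintf("chr1\tx\tCDS\t11\t100\t.\t+\t.\t%s", attrs)
  ), ".gtf")
  ann <- read_annotation_gtf(gtf)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$transcript_id, "ENST00000000001")
  expect_equal(ann$gene_id, "ENSG00000000001")
  expect_equal(ann$transcript_length, 150L)
  expect_equal(ann$cds_length, 90L)
  expect_equal(ann$biotype, "protein_coding")
})

test_that("GTF reader handles noncoding transcripts and error cases", {
  attrs <- paste0('gene_id "G1"; transcript_id "T1"; gene_name "GA"; ',
                  'transcript_name "GA-202"; transcript_type "retained_intron";')
  gtf <- write_lines_tmp(c(
    sprintf("chr1\tx\ttranscript\t1\t80\t.\t-\t.\t%s", attrs),
    sprintf("chr1\tx\texon\t1\t80\t.\t-\t.\t%s", attrs)
  ), ".gtf")
  expect_equal(read_annotation_gtf(gtf)$cds_length, 0L)

  bad <- write_lines_tmp(c(
    sprintf("chr1\tx\ttranscript\t1\t80\t.\t+\t.\t%s", attrs),
    "chr1\tonly\tthree"
  ), ".gtf")
  expect_error(read_annotation_gtf(bad), "line 2")

  no_exon <- write_lines_tmp(
    sprintf("chr1\tx\ttranscript\t1\t80\t.\t+\t.\t%s", attrs), ".gtf")
  expect_error(read_annotation_gtf(no_exon), "no exon")

  coding_attrs <- sub("retained_intron", "protein_coding", attrs)
  no_cds <- write_lines_tmp(c(
    sprintf("chr1\tx\ttranscript\t1\t80\t.\t+\t.\t%s", coding_attrs),
    sprintf("chr1\tx\texon\t1\t80\t.\t+\t.\t%s", coding_attrs)
  ), ".gtf")
  expect_warning(ann <- read_annotation_gtf(no_cds), "without CDS")
  expect_equal(ann$cds_length, 0L)
})

test_that("simulator GTF round-trips to the truth annotation", {
  sim <- simulate_expression(sim_config(n_genes = 12, seed = 11))
  expect_gte(nrow(sim$annotation), 20L)
  dir <- tempfile(); paths <- write_fixture_bundle(sim, dir)
  got <- read_annotation_gtf(paths[["annotation_gtf"]])
  expect_equal(got, sim$annotation, ignore_attr = TRUE)
  # and the paired TSV reader agrees with the GTF reader
  expect_equal(read_annotation_tsv(paths[["annotation_tsv"]]), got,
               ignore_attr = TRUE)
})

test_that("TSV reader validates and version-strips", {
  df <- data.frame(transcript_id = c("ENST1.3", "ENST2.10", "ENST3"),
                   gene_id = c("ENSG1.2", "ENSG1.2", "ENSG2"),
                   gene_name = "G", transcript_name = c("a", "b", "c"),
                   biotype = "protein_coding",
                   transcript_length = c(100L, 200L, 300L),
                   cds_length = c(90L, 150L, 0L))
  p <- tempfile(fileext = ".tsv")
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- read_annotation_tsv(p)
  expect_equal(ann$transcript_id, c("ENST1", "ENST2", "ENST3"))
  expect_equal(unique(ann$gene_id), c("ENSG1", "ENSG1", "ENSG2")[c(1, 3)])

  bad <- df; bad$cds_length[1] <- 500L
  write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_annotation_tsv(p), "exceeds transcript_length")

  write.table(df[0, ], p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_annotation_tsv(p)), 0L)

  write.table(df[, -5], p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_annotation_tsv(p), "biotype")
})

test_that("version stripping is idempotent", {
  ids <- c("ENSG00000000003.14", "ENST1", "NM_000546.6", "abc.def.2")
  expect_equal(strip_version(strip_version(ids)), strip_version(ids))
})

test_that("MANE summary reader normalizes, deduplicates, rejects conflicts", {
  p <- write_lines_tmp(c(
    "gene_id\tmane_transcript_id\trefseq_id",
    "ENSG1.5\tENST1.3\tNM_1.2",
    "ENSG2\tENST2\tNM_2",
    "ENSG2\tENST2\tNM_2"))
  mane <- read_mane_summary(p)
  expect_equal(nrow(mane), 2L)
  expect_equal(mane$gene_id, c("ENSG1", "ENSG2"))
  expect_equal(mane$mane_transcript_id, c("ENST1", "ENST2"))

  # NCBI header dialect, with a non-select row filtered out
  p2 <- write_lines_tmp(c(
    "#NCBI_GeneID\tEnsembl_Gene\tRefSeq_nuc\tEnsembl_nuc\tMANE_status",
    "1\tENSG1.4\tNM_1.1\tENST1.9\tMANE Select",
    "2\tENSG9.1\tNM_9.1\tENST9.1\tMANE Plus Clinical"))
  mane2 <- read_mane_summary(p2)
  expect_equal(mane2$gene_id, "ENSG1")
  expect_equal(mane2$mane_transcript_id, "ENST1")

  conflict <- write_lines_tmp(c(
    "gene_id\tmane_transcript_id\trefseq_id",
    "ENSG1\tENST1\tNM_1",
    "ENSG1\tENST2\tNM_2"))
  expect_error(read_mane_summary(conflict), "conflicting")
})

test_that("gene2ensembl reader maps RefSeq accessions", {
  p <- write_lines_tmp(c(
    "#tax_id\tGeneID\tEnsembl_gene_identifier\tRNA_nucleotide_accession.version\tEnsembl_rna_identifier",
    "9606\t7157\tENSG00000141510.16\tNM_000546.6\tENST00000269305.9"))
  g2e <- read_gene2ensembl(p)
  expect_equal(g2e$gene_id, "ENSG00000141510")
  expect_equal(g2e$refseq_id, "NM_000546")
  expect_equal(g2e$transcript_id, "ENST00000269305")
})

test_that("gene biotype classification follows the any-coding-isoform rule", {
  ann <- data.frame(
    transcript_id = c("T1", "T2", "T3"),
    gene_id = c("G1", "G1", "G2"),
    gene_name = c("A", "A", "B"), transcript_name = c("a1", "a2", "b1"),
    biotype = c("protein_coding", "retained_intron", "processed_transcript"),
    transcript_length = c(100L, 100L, 100L), cds_length = c(60L, 0L, 0L),
    stringsAsFactors = FALSE)
  cls <- classify_gene_biotype(ann)
  expect_true(cls$coding[cls$gene_id == "G1"])   # coding + retained_intron
  expect_false(cls$coding[cls$gene_id == "G2"])  # lone processed_transcript
  expect_error(classify_gene_biotype(ann[0, ]), "empty")
})

test_that("classification matches a per-gene any() oracle and partitions", {
  sim <- simulate_expression(sim_config(n_genes = 50, seed = 7))
  cls <- classify_gene_biotype(sim$annotation)
  oracle <- vapply(cls$gene_id, function(g)
    any(sim$annotation$biotype[sim$annotation$gene_id == g] ==
          "protein_coding"), logical(1))
  expect_equal(cls$coding, unname(oracle))
  expect_equal(sum(cls$coding) + sum(!cls$coding), nrow(cls))
  expect_equal(nrow(cls), length(unique(sim$annotation$gene_id)))
})
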