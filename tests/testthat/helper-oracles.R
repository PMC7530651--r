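# Independent brute-force oracles.  These deliberately avoid the package's
# radix-order implementation: ranks come from pairwise "beats" counting,
# sums/means from explicit per-group loops.

# Rank of isoform i within its gene = 1 + number of siblings that beat it
# under the cascade (higher TPM, then longer CDS, then longer transcript,
# then lexicographically smaller ID).
oracle_rank_gene <- function(tpm, cds, tlen, tid) {
  k <- length(tpm)
  beats <- outer(tpm, tpm, ">") |
    (outer(tpm, tpm, "==") & outer(cds, cds, ">")) |
    (outer(tpm, tpm, "==") & outer(cds, cds, "==") &
       outer(tlen, tlen, ">")) |
    (outer(tpm, tpm, "==") & outer(cds, cds, "==") &
       outer(tlen, tlen, "==") & outer(tid, tid, "<"))
  1L + colSums(beats)
}

# Full-table oracle for one scope: returns integer ranks aligned with
# rownames(m).
oracle_rank <- function(m, ann, scope = "overall") {
  s <- if (identical(scope, "overall")) rowMeans(m) else m[, scope]
  i <- match(rownames(m), ann$transcript_id)
  out <- integer(nrow(m))
  for (g in unique(ann$gene_id[i])) {
    rows <- which(ann$gene_id[i] == g)
    out[rows] <- oracle_rank_gene(s[rows], ann$cds_length[i][rows],
                                  ann$transcript_length[i][rows],
                                  rownames(m)[rows])
  }
  out
}

# Per-gene per-tissue sum by explicit loop.
oracle_gene_sum <- function(m, ann) {
  gene <- ann$gene_id[match(rownames(m), ann$transcript_id)]
  genes <- sort(unique(gene))
  out <- matrix(0, length(genes), ncol(m),
                dimnames = list(genes, colnames(m)))
  for (g in genes)
    for (j in seq_len(ncol(m)))
      out[g, j] <- sum(m[gene == g, j])
  out
}

# Per-tissue mean over member samples by explicit loop.
oracle_collapse <- function(m, map) {
  tissues <- sort(unique(map$tissue[map$sample_id %in% colnames(m)]))
  out <- matrix(0, nrow(m), length(tissues),
                dimnames = list(rownames(m), tissues))
  for (tt in tissues) {
    ss <- map$sample_id[map$tissue == tt]
    ss <- intersect(ss, colnames(m))
    for (i in seq_len(nrow(m))) out[i, tt] <- mean(m[i, ss])
  }
  out
}
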