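sim_mid <- simulate_expression(sim_config(n_genes = 200, noise_sd = 0.2,
                                          seed = 21))
fe_mid <- filter_expressed(sim_mid$tpm)
rt_mid <- build_rank_table(fe_mid$matrix, sim_mid$annotation,
                           coding_only = FALSE)

test_that("gene expression is the per-tissue isoform sum", {
  ann <- data.frame(transcript_id = c("T1", "T2", "T3"),
                    gene_id = c("G1", "G1", "G2"),
                    gene_name = "g", transcript_name = c("a", "b", "c"),
                    biotype = "protein_coding",
                    transcript_length = 100L, cds_length = 50L,
                    stringsAsFactors = FALSE)
  m <- rbind(T1 = c(1, 2), T2 = c(3, 4), T3 = c(5, 6))
  colnames(m) <- c("x", "y")
  ge <- gene_expression(m, ann)
  expect_equal(unname(ge$tpm["G1", ]), c(4, 6))
  expect_equal(unname(ge$tpm["G2", ]), c(5, 6))  # single isoform: identity
  expect_equal(ge$genes$transcript_count, c(2L, 1L))
  expect_error(gene_expression(rbind(m, ZZ = c(1, 1)), ann), "ZZ")
})

test_that("gene expression matches the groupby-sum oracle", {
  ge <- gene_expression(fe_mid$matrix, sim_mid$annotation)
  expect_equal(ge$tpm[, ], oracle_gene_sum(fe_mid$matrix, sim_mid$annotation))
  # gene vector dominates every member transcript componentwise
  gi <- match(sim_mid$annotation$gene_id[
    match(rownames(fe_mid$matrix), sim_mid$annotation$transcript_id)],
    rownames(ge$tpm))
  expect_true(all(ge$tpm[gi, ] - fe_mid$matrix >= -1e-12))
})

test_that("isoform ranking orders by TPM with the tie-break cascade", {
  ann <- data.frame(
    transcript_id = c("TA", "TB", "TC", "TD", "TE"),
    gene_id = c("G1", "G1", "G1", "G2", "G2"),
    gene_name = "g", transcript_name = letters[1:5],
    biotype = "protein_coding",
    transcript_length = c(500L, 500L, 500L, 500L, 400L),
    cds_length = c(100L, 300L, 150L, 0L, 0L),
    stringsAsFactors = FALSE)
  m <- rbind(TA = c(10, 10), TB = c(2, 2), TC = c(1, 1),
             TD = c(0, 0), TE = c(0, 0))
  colnames(m) <- c("t1", "t2")
  r <- rank_isoforms(m, ann, "overall")
  expect_equal(r$rank[match(c("TA", "TB", "TC"), r$transcript_id)],
               c(1L, 2L, 3L))
  # equal TPM (both zero), equal CDS: transcript length decides
  expect_equal(r$rank[match(c("TD", "TE"), r$transcript_id)], c(1L, 2L))

  tie <- rbind(TA = c(5, 5), TB = c(5, 5), TC = c(1, 1),
               TD = c(0, 0), TE = c(0, 0))
  colnames(tie) <- c("t1", "t2")
  r2 <- rank_isoforms(tie, ann, "overall")
  # equal TPM: larger CDS (TB, 300) beats TA (100)
  expect_equal(r2$rank[match(c("TB", "TA", "TC"), r2$transcript_id)],
               c(1L, 2L, 3L))
  expect_error(rank_isoforms(m, ann, "nope"), "unknown scope")
})

test_that("ranking agrees with the pairwise-beats oracle on random and tied genes", {
  tie <- make_tie_dataset(60)
  r_tie <- rank_isoforms(tie$tpm, tie$annotation, "overall")
  expect_equal(r_tie$rank, oracle_rank(tie$tpm, tie$annotation, "overall"))
  # engineered cascade: equal TPM everywhere, so CDS -> length -> ID
  expect_equal(r_tie$rank, rep(1:4, 60))

  r_sim <- rank_isoforms(fe_mid$matrix, sim_mid$annotation, "overall")
  expect_equal(r_sim$rank, oracle_rank(fe_mid$matrix, sim_mid$annotation,
                                       "overall"))
  for (tt in colnames(fe_mid$matrix)[c(1, 20, 54)]) {
    expect_equal(rank_isoforms(fe_mid$matrix, sim_mid$annotation, tt)$rank,
                 oracle_rank(fe_mid$matrix, sim_mid$annotation, tt))
  }
})

test_that("ranks are a per-gene permutation in every scope", {
  tx <- rt_mid$transcripts
  for (g in unique(tx$gene_id)) {
    k <- sum(tx$gene_id == g)
    expect_equal(sort(tx$overall_rank[tx$gene_id == g]), seq_len(k))
  }
  for (j in seq_along(rt_mid$tissues)) {
    r <- rt_mid$rank[, j]
    bygene <- split(r, tx$gene_id)
    expect_true(all(vapply(bygene, function(x)
      identical(sort(unname(x)), seq_along(x)), logical(1))))
  }
  # overall rank1 has the highest overall TPM in its gene
  top <- tx[tx$overall_rank == 1L, ]
  maxes <- tapply(tx$overall_mean_tpm, tx$gene_id, max)
  expect_equal(top$overall_mean_tpm, as.numeric(maxes[top$gene_id]))
})

test_that("rank tables are deterministic and byte-identical across runs", {
  rt2 <- build_rank_table(fe_mid$matrix, sim_mid$annotation,
                          coding_only = FALSE)
  expect_identical(rt_mid$transcripts, rt2$transcripts)
  d1 <- tempfile(); d2 <- tempfile()
  txrank:::write_rank_table(rt_mid, d1)
  txrank:::write_rank_table(rt2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  back <- txrank:::read_rank_table(d1)
  expect_equal(back$rank, rt_mid$rank)
  expect_equal(back$tpm, rt_mid$tpm, tolerance = 1e-12)
})

test_that("expression fractions divide transcript by gene TPM, NA when gene silent", {
  ann <- data.frame(transcript_id = c("T1", "T2"), gene_id = "G1",
                    gene_name = "g", transcript_name = c("a", "b"),
                    biotype = "protein_coding",
                    transcript_length = c(100L, 90L),
                    cds_length = c(60L, 30L), stringsAsFactors = FALSE)
  m <- rbind(T1 = c(9, 0), T2 = c(3, 0)); colnames(m) <- c("t1", "t2")
  ge <- gene_expression(m, ann)
  f1 <- expression_fractions(m, ge, ann, "t1")
  expect_equal(f1, c(0.75, 0.25))
  f2 <- expression_fractions(m, ge, ann, "t2")
  expect_true(all(is.na(f2)))  # gene TPM 0: undefined, not 0

  single <- m[1, , drop = FALSE]
  ges <- gene_expression(single, ann[1, ])
  expect_equal(expression_fractions(single, ges, ann[1, ], "t1"), 1)
})

test_that("within-gene fractions sum to 1 wherever gene TPM > 0", {
  sim <- simulate_expression(sim_config(n_genes = 500, noise_sd = 0.3,
                                        seed = 33))
  fe <- filter_expressed(sim$tpm)
  rt <- build_rank_table(fe$matrix, sim$annotation, coding_only = FALSE)
  gene <- rt$transcripts$gene_id
  for (j in c(1L, 27L, 54L)) {
    sums <- tapply(rt$fraction[, j], gene, sum)
    gtpm <- rt$gene_tpm[names(sums), j]
    expect_equal(as.numeric(sums[gtpm > 0]),
                 rep(1, sum(gtpm > 0)), tolerance = 1e-9)
    expect_true(all(is.na(sums[gtpm == 0])))
  }
  o <- tapply(rt$transcripts$overall_fraction, gene, sum)
  expect_equal(as.numeric(o), rep(1, length(o)), tolerance = 1e-9)
})

test_that("cv follows the sample-sd-over-mean definition", {
  expect_equal(cv(c(5, 5, 5, 5)), 0)
  expect_equal(cv(c(2, 4)), sqrt(2) / 3)
  expect_true(is.na(cv(c(0, 0, 0))))
  expect_true(is.na(cv(7)))
  v <- c(1.5, 8, 0.25, 4)
  expect_equal(cv(v), sd(v) / mean(v))
  # row_cv used in the rank table agrees with the scalar definition
  expect_equal(rt_mid$transcripts$cv_tpm[1:20],
               unname(apply(rt_mid$tpm[1:20, ], 1, cv)))
  expect_true(all(rt_mid$transcripts$cv_tpm >= 0, na.rm = TRUE))
})

test_that("rank-class mean TPM summary", {
  ann <- data.frame(transcript_id = c("T1", "T2", "T3"),
                    gene_id = c("G1", "G2", "G2"),
                    gene_name = "g", transcript_name = c("a", "b", "c"),
                    biotype = "protein_coding",
                    transcript_length = 100L, cds_length = 50L,
                    stringsAsFactors = FALSE)
  m <- rbind(T1 = c(10, 10), T2 = c(20, 20), T3 = c(2, 2))
  colnames(m) <- c("x", "y")
  rt <- build_rank_table(m, ann)
  rs <- rank_summary(rt, max_rank = 10)
  expect_equal(rs$mean_tpm[rs$rank == 1], 15)  # {10, 20}
  expect_equal(rs$rank, c(1L, 2L))             # no empty rank rows
  rs_ex <- rank_summary(rt, max_rank = 10, exclude_single = TRUE)
  expect_equal(rs_ex$mean_tpm[rs_ex$rank == 1], 20)

  # oracle on simulated data: direct filtered means
  rs_mid <- rank_summary(rt_mid, max_rank = 10)
  tx <- rt_mid$transcripts
  for (r in rs_mid$rank)
    expect_equal(rs_mid$mean_tpm[rs_mid$rank == r],
                 mean(tx$overall_mean_tpm[tx$overall_rank == r]))
})

test_that("dominance by isoform-count class: forced cases and conservation", {
  d <- dominance_by_isoform_class(rt_mid)
  expect_equal(d$mean_fraction[d$transcript_count == 1 & d$rank == 1], 1.0)
  for (k in intersect(2:10, unique(d$transcript_count))) {
    expect_equal(max(d$cum_fraction[d$transcript_count == k]), 1.0,
                 tolerance = 1e-9)
  }
})

test_that("class-3 rank1 dominance recovers the Dirichlet order statistic", {
  cfg <- sim_config(n_genes = 400, max_isoforms = 3,
                    isoform_weights = c(0, 0, 1),
                    dirichlet_alpha = c(8, 1, 1),
                    zero_transcript_fraction = 0, seed = 17)
  sim <- simulate_expression(cfg)
  rt <- build_rank_table(filter_expressed(sim$tpm)$matrix, sim$annotation,
                         coding_only = FALSE)
  d <- dominance_by_isoform_class(rt, max_class = 3)
  got <- d$mean_fraction[d$transcript_count == 3 & d$rank == 1]
  # independent Monte-Carlo oracle for E[max of Dirichlet(8,1,1)]
  set.seed(1234)
  draws <- matrix(rgamma(3 * 20000, c(8, 1, 1)), ncol = 3, byrow = TRUE)
  expected <- mean(apply(draws / rowSums(draws), 1, max))
  expect_equal(got, expected, tolerance = 0.03)
})

test_that("tissue rank distribution flags the switching tissue", {
  sw <- make_switch_dataset(n_genes = 6, switch_tissue = "t03")
  rt <- build_rank_table(sw$tpm, sw$annotation)
  td <- tissue_rank_distribution(rt, max_rank = 2)
  r1 <- td[td$rank == 1, ]
  expect_equal(r1$mean_fraction[r1$tissue != "t03"], rep(0.9, 5))
  expect_equal(r1$mean_fraction[r1$tissue == "t03"], 0.1)
  expect_lt(r1$mean_fraction[r1$tissue == "t03"],
            min(r1$mean_fraction[r1$tissue != "t03"]))
  # per-tissue labelling instead reports the within-tissue dominant share
  td_pt <- tissue_rank_distribution(rt, max_rank = 2,
                                    rank_label = "per_tissue")
  expect_equal(td_pt$mean_fraction[td_pt$rank == 1],
               rep(0.9, length(rt$tissues)))
  # conservation: summing mean fractions over all rank labels gives 1
  sums <- tapply(td$mean_fraction, td$tissue, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
})

test_that("all-dominant datasets report rank1 fraction 1 per tissue", {
  ann <- data.frame(transcript_id = c("T1", "T2"), gene_id = c("G1", "G2"),
                    gene_name = "g", transcript_name = c("a", "b"),
                    biotype = "protein_coding",
                    transcript_length = 100L, cds_length = 60L,
                    stringsAsFactors = FALSE)
  m <- rbind(T1 = c(4, 7), T2 = c(1, 2)); colnames(m) <- c("x", "y")
  rt <- build_rank_table(m, ann)
  td <- tissue_rank_distribution(rt)
  expect_equal(td$mean_fraction, rep(1, nrow(td)))
})

test_that("reporting ratios use half-up rounding at printed precision", {
  expect_equal(transcripts_per_gene(10, 10), 1.00)
  expect_equal(transcripts_per_gene(7, 2), 3.5)
  expect_equal(round_half_up(2.345, 2), 2.35)  # plain round() would give 2.34
  expect_error(transcripts_per_gene(5, 0), "positive")
  expect_equal(percent_share(1, 3), 33.3)
  expect_error(percent_share(1, 0), "positive")
})

test_that("coding isoforms out-express noncoding ones in coding genes", {
  res <- coding_noncoding_test(rt_mid)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$mean_coding, res$mean_noncoding)
  res2 <- coding_noncoding_test(rt_mid, exclude_single = TRUE)
  expect_gt(res2$mean_coding, res2$mean_noncoding)
})
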