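# Synthetic GTEx-like transcript expression with known ground truth.
#
# The generator states a world with the structure the analysis assumes:
# multi-isoform genes with skewed (dominant-isoform) Dirichlet usage,
# a mix of coding and noncoding biotypes inside protein-coding genes,
# single-transcript genes with elevated expression, transcripts that are
# zero everywhere, and injected tissue-specific rank1 switches implemented
# as usage swaps (so recovery is exact at zero noise).

#' Simulation configuration
#'
#' Defaults describe a GTEx-like world: 54 tissues, up to 10 isoforms per
#' gene with a single-transcript-heavy count distribution, lognormal
#' gene-level TPM (meanlog 2.5, sdlog 1.5, i.e. median ~12 TPM), a 3x
#' expression multiplier for single-transcript genes, and isoform usage
#' drawn from a Dirichlet with geometrically decaying concentration
#' \code{dirichlet_base * dirichlet_decay^(r-1)} — calibrated once so the
#' dominant isoform carries > 50\% and the top five isoforms > 95\% of
#' gene expression, the dominance profile seen in real tissue panels.
#' About 2.6\% of transcripts are zeroed in every tissue, matching the
#' never-expressed share of a real transcript catalogue.
#'
#' @param n_genes number of genes.
#' @param n_tissues number of tissues (default 54).
#' @param max_isoforms largest isoform count K (default 10).
#' @param isoform_weights probability weights over 1..K isoforms.
#' @param dirichlet_alpha optional explicit concentration vector of length
#'   \code{max_isoforms}; overrides base/decay.
#' @param dirichlet_base,dirichlet_decay geometric concentration profile.
#' @param gene_log_mean,gene_log_sd lognormal parameters for gene TPM.
#' @param single_transcript_multiplier expression multiplier for
#'   single-isoform genes.
#' @param n_switch_genes genes given injected rank1 switches.
#' @param switch_tissues_per_gene switching tissues per switch gene (1-4).
#' @param noncoding_isoform_fraction probability a non-dominant isoform is
#'   noncoding.
#' @param rank1_coding_prob probability the dominant isoform of a
#'   multi-isoform gene is protein-coding (some dominant isoforms are
#'   noncoding in real data).
#' @param zero_transcript_fraction fraction of transcripts zeroed in all
#'   tissues.
#' @param noise_sd multiplicative lognormal usage noise per tissue (0 =
#'   deterministic usage).
#' @param samples_per_tissue 1 = emit an already-collapsed tissue matrix;
#'   > 1 = emit a sample-level matrix plus sample map.
#' @param sample_noise_sd per-sample multiplicative lognormal noise.
#' @param seed integer RNG seed; the whole simulation is reproducible from
#'   it.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_genes = 500L,
                       n_tissues = 54L,
                       max_isoforms = 10L,
                       isoform_weights = c(0.20, 0.15, 0.12, 0.10, 0.09,
                                           0.08, 0.07, 0.07, 0.06, 0.06),
                       dirichlet_alpha = NULL,
                       dirichlet_base = 8,
                       dirichlet_decay = 0.45,
                       gene_log_mean = 2.5,
                       gene_log_sd = 1.5,
                       single_transcript_multiplier = 3,
                       n_switch_genes = 0L,
                       switch_tissues_per_gene = 1L,
                       noncoding_isoform_fraction = 0.5,
                       rank1_coding_prob = 0.9,
                       zero_transcript_fraction = 0.026,
                       noise_sd = 0,
                       samples_per_tissue = 1L,
                       sample_noise_sd = 0,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_tissues = as.integer(n_tissues),
              max_isoforms = as.integer(max_isoforms),
              isoform_weights = isoform_weights,
              dirichlet_alpha = dirichlet_alpha,
              dirichlet_base = dirichlet_base,
              dirichlet_decay = dirichlet_decay,
              gene_log_mean = gene_log_mean, gene_log_sd = gene_log_sd,
              single_transcript_multiplier = single_transcript_multiplier,
              n_switch_genes = as.integer(n_switch_genes),
              switch_tissues_per_gene = as.integer(switch_tissues_per_gene),
              noncoding_isoform_fraction = noncoding_isoform_fraction,
              rank1_coding_prob = rank1_coding_prob,
              zero_transcript_fraction = zero_transcript_fraction,
              noise_sd = noise_sd,
              samples_per_tissue = as.integer(samples_per_tissue),
              sample_noise_sd = sample_noise_sd,
              seed = as.integer(seed))
  if (cfg$n_genes < 0L) stop_validation("n_genes must be >= 0")
  if (cfg$n_tissues < 1L) stop_validation("n_tissues must be >= 1")
  if (length(cfg$isoform_weights) != cfg$max_isoforms)
    stop_validation("isoform_weights must have length max_isoforms (%d)",
                    cfg$max_isoforms)
  if (any(cfg$isoform_weights < 0) ||
      abs(sum(cfg$isoform_weights) - 1) > 1e-8)
    stop_validation("isoform_weights must be nonnegative and sum to 1")
  probs <- c(cfg$noncoding_isoform_fraction, cfg$rank1_coding_prob,
             cfg$zero_transcript_fraction)
  if (any(probs < 0 | probs > 1))
    stop_validation("probabilities must lie in [0, 1]")
  if (!is.null(cfg$dirichlet_alpha)) {
    if (length(cfg$dirichlet_alpha) != cfg$max_isoforms ||
        any(cfg$dirichlet_alpha <= 0))
      stop_validation("dirichlet_alpha must be %d positive values",
                      cfg$max_isoforms)
  } else if (cfg$dirichlet_base <= 0 || cfg$dirichlet_decay <= 0) {
    stop_validation("dirichlet_base and dirichlet_decay must be positive")
  }
  if (cfg$n_switch_genes > cfg$n_genes)
    stop_validation("n_switch_genes exceeds n_genes")
  if (cfg$switch_tissues_per_gene < 1L ||
      cfg$switch_tissues_per_gene >= cfg$n_tissues)
    if (cfg$n_switch_genes > 0L)
      stop_validation("switch_tissues_per_gene must be in [1, n_tissues - 1]")
  if (cfg$noise_sd < 0 || cfg$sample_noise_sd < 0)
    stop_validation("noise sds must be >= 0")
  if (cfg$samples_per_tissue < 1L)
    stop_validation("samples_per_tissue must be >= 1")
  structure(cfg, class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' Simulate a transcript-by-tissue expression world
#'
#' Per gene: draw the isoform count, isoform lengths and biotypes, a
#' baseline usage vector from the (sorted, so isoform 1 is the intended
#' dominant one) Dirichlet, and a lognormal gene-level TPM.  Per tissue,
#' usage is perturbed by multiplicative lognormal noise and renormalised;
#' in each switch gene's designated tissues the promoted isoform's usage
#' is swapped with the dominant isoform's, which guarantees the promoted
#' isoform wins there at any noise level.  TPM = gene level x usage, with
#' a shared per-(gene, tissue) lognormal factor (same \code{noise_sd})
#' that moves whole-gene expression but not ranks or fractions.  Selected
#' non-dominant, non-promoted transcripts are zeroed in every tissue.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list: \code{tpm} (transcripts x tissues, or x samples when
#'   \code{samples_per_tissue > 1}), \code{sample_map}, \code{annotation},
#'   and \code{truth} (list: \code{usage} baseline per gene,
#'   \code{intended_rank1} named vector, \code{switches} data.frame of
#'   (gene_id, tissue, promoted_transcript), \code{zeroed_transcripts},
#'   \code{tissues}).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$max_isoforms
  alpha_full <- if (!is.null(config$dirichlet_alpha)) config$dirichlet_alpha
                else config$dirichlet_base * config$dirichlet_decay^(0:(K - 1))
  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))

  if (config$n_genes == 0L) {
    ann <- data.frame(transcript_id = character(), gene_id = character(),
                      gene_name = character(), transcript_name = character(),
                      biotype = character(), transcript_length = integer(),
                      cds_length = integer(), stringsAsFactors = FALSE)
    m <- matrix(numeric(), 0L, config$n_tissues,
                dimnames = list(NULL, tissues))
    return(list(tpm = m, sample_map = data.frame(sample_id = tissues,
                                                 tissue = tissues),
                annotation = ann,
                truth = list(usage = list(),
                             intended_rank1 = character(),
                             switches = data.frame(gene_id = character(),
                                                   tissue = character(),
                                                   promoted_transcript = character()),
                             zeroed_transcripts = character(),
                             tissues = tissues),
                config = config))
  }

  k <- sample.int(K, config$n_genes, replace = TRUE,
                  prob = config$isoform_weights)
  if (config$n_switch_genes > 0L) {
    eligible <- which(k >= 2L)
    if (length(eligible) < config$n_switch_genes)
      stop_validation(
        "infeasible config: %d switch genes requested but only %d genes have >= 2 isoforms",
        config$n_switch_genes, length(eligible))
    switch_genes <- sort(sample(eligible, config$n_switch_genes))
  } else switch_genes <- integer()

  gene_ids <- sprintf("ENSG%011d", seq_len(config$n_genes))
  gene_names <- sprintf("GENE%05d", seq_len(config$n_genes))
  n_tx <- sum(k)
  tx_gene <- rep(seq_len(config$n_genes), k)
  iso_idx <- sequence(k)
  tx_ids <- sprintf("ENST%011d", seq_len(n_tx))

  # Lengths: lognormal transcript length; coding isoforms get a CDS of
  # 30-80% of the transcript (multiple-of-3-agnostic; only the length
  # matters for tie-breaking).
  tlen <- pmax(200L, as.integer(round(rlnorm(n_tx, log(1800), 0.35))))
  coding <- logical(n_tx)
  coding[iso_idx == 1L] <- runif(sum(iso_idx == 1L)) < config$rank1_coding_prob
  single_gene_tx <- rep(k == 1L, k)
  coding[iso_idx == 1L & single_gene_tx] <- TRUE  # single-tx genes: coding
  nd <- iso_idx > 1L
  coding[nd] <- runif(sum(nd)) >= config$noncoding_isoform_fraction
  biotype <- ifelse(coding, "protein_coding",
                    sample(NONCODING_BIOTYPES, n_tx, replace = TRUE))
  cds <- integer(n_tx)
  cds[coding] <- pmin(tlen[coding],
                      pmax(90L, as.integer(round(tlen[coding] *
                                                   runif(sum(coding), 0.3, 0.8)))))

  annotation <- data.frame(
    transcript_id = tx_ids,
    gene_id = gene_ids[tx_gene],
    gene_name = gene_names[tx_gene],
    transcript_name = sprintf("%s-%03d", gene_names[tx_gene], 200L + iso_idx),
    biotype = biotype,
    transcript_length = tlen,
    cds_length = cds,
    stringsAsFactors = FALSE
  )

  # Baseline usage, sorted so isoform 1 is the intended dominant one.
  usage <- lapply(seq_len(config$n_genes), function(g) {
    sort(rdirichlet1(alpha_full[seq_len(k[g])]), decreasing = TRUE)
  })
  gene_level <- rlnorm(config$n_genes, config$gene_log_mean,
                       config$gene_log_sd)
  gene_level[k == 1L] <- gene_level[k == 1L] *
    config$single_transcript_multiplier

  switches <- data.frame(gene_id = character(), tissue = character(),
                         promoted_transcript = character(),
                         stringsAsFactors = FALSE)
  switch_tissue_idx <- vector("list", config$n_genes)
  first_tx <- c(0L, cumsum(k))[seq_len(config$n_genes)]  # offset per gene
  for (g in switch_genes) {
    st <- sort(sample.int(config$n_tissues, config$switch_tissues_per_gene))
    switch_tissue_idx[[g]] <- st
    switches <- rbind(switches, data.frame(
      gene_id = gene_ids[g], tissue = tissues[st],
      promoted_transcript = tx_ids[first_tx[g] + 2L],
      stringsAsFactors = FALSE))
  }

  m <- matrix(0, n_tx, config$n_tissues, dimnames = list(tx_ids, tissues))
  for (g in seq_len(config$n_genes)) {
    u0 <- usage[[g]]
    kk <- k[g]
    rows <- first_tx[g] + seq_len(kk)
    ut <- matrix(u0, kk, config$n_tissues)
    if (config$noise_sd > 0) {
      ut <- ut * exp(matrix(rnorm(kk * config$n_tissues, 0, config$noise_sd),
                            kk, config$n_tissues))
      ut <- sweep(ut, 2L, colSums(ut), "/")
    }
    st <- switch_tissue_idx[[g]]
    if (length(st)) {
      # swap so the promoted isoform always receives the larger of the two
      # noisy usage values: its dominance in switch tissues is guaranteed
      # at any noise level, keeping recovery exact at noise 0 and
      # well-powered at small noise
      pair <- ut[c(1L, 2L), st, drop = FALSE]
      ut[1L, st] <- apply(pair, 2L, min)
      ut[2L, st] <- apply(pair, 2L, max)
    }
    gfac <- if (config$noise_sd > 0)
      exp(rnorm(config$n_tissues, 0, config$noise_sd)) else 1
    m[rows, ] <- ut * rep(gene_level[g] * gfac, each = kk)
  }

  # Zero a fraction of transcripts everywhere, never the intended dominant
  # isoform or a promoted switch isoform.
  protected <- first_tx + 1L
  protected <- c(protected, first_tx[switch_genes] + 2L)
  candidates <- setdiff(seq_len(n_tx), protected)
  n_zero <- min(length(candidates),
                floor(config$zero_transcript_fraction * n_tx))
  zeroed <- if (n_zero > 0L) sort(sample(candidates, n_zero)) else integer()
  m[zeroed, ] <- 0

  truth <- list(usage = stats::setNames(usage, gene_ids),
                intended_rank1 = stats::setNames(tx_ids[first_tx + 1L],
                                                 gene_ids),
                switches = switches,
                zeroed_transcripts = tx_ids[zeroed],
                tissues = tissues)

  if (config$samples_per_tissue > 1L) {
    reps <- config$samples_per_tissue
    sample_ids <- as.vector(t(outer(tissues, seq_len(reps),
                                    function(tt, r) sprintf("%s.S%02d", tt, r))))
    sm <- matrix(0, n_tx, length(sample_ids),
                 dimnames = list(tx_ids, sample_ids))
    for (j in seq_along(tissues)) {
      cols <- (j - 1L) * reps + seq_len(reps)
      base <- m[, j]
      for (r in seq_len(reps)) {
        fac <- if (config$sample_noise_sd > 0)
          exp(rnorm(n_tx, 0, config$sample_noise_sd)) else 1
        sm[, cols[r]] <- base * fac
      }
    }
    sample_map <- data.frame(sample_id = sample_ids,
                             tissue = rep(tissues, each = reps),
                             stringsAsFactors = FALSE)
    return(list(tpm = sm, sample_map = sample_map, annotation = annotation,
                truth = truth, config = config))
  }
  list(tpm = m,
       sample_map = data.frame(sample_id = tissues, tissue = tissues,
                               stringsAsFactors = FALSE),
       annotation = annotation, truth = truth, config = config)
}

# Write the simulated annotation as a GENCODE-dialect GTF.  Exon structure
# is invented (two exons once the transcript exceeds 400 nt, else one) so
# the GTF reader's span-summing is genuinely exercised; CDS features are
# laid inside the exons and sum to cds_length.
write_annotation_gtf <- function(annotation, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##format: gtf", con)
  offset <- 0L
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    attrs <- sprintf(
      paste0('gene_id "%s.1"; transcript_id "%s.1"; gene_name "%s"; ',
             'transcript_name "%s"; transcript_type "%s";'),
      a$gene_id, a$transcript_id, a$gene_name, a$transcript_name, a$biotype)
    len <- a$transcript_length
    if (len > 400L) {
      e1 <- len %/% 2L
      exons <- rbind(c(offset + 1L, offset + e1),
                     c(offset + e1 + 1001L, offset + 1000L + len))
    } else {
      exons <- rbind(c(offset + 1L, offset + len))
    }
    feat <- function(type, s, e)
      sprintf("chr1\tsim\t%s\t%d\t%d\t.\t+\t.\t%s", type, s, e, attrs)
    lines <- feat("transcript", exons[1L, 1L], exons[nrow(exons), 2L])
    for (j in seq_len(nrow(exons)))
      lines <- c(lines, feat("exon", exons[j, 1L], exons[j, 2L]))
    cds_left <- a$cds_length
    for (j in seq_len(nrow(exons))) {
      if (cds_left <= 0L) break
      take <- min(cds_left, exons[j, 2L] - exons[j, 1L] + 1L)
      lines <- c(lines, feat("CDS", exons[j, 1L], exons[j, 1L] + take - 1L))
      cds_left <- cds_left - take
    }
    writeLines(lines, con)
    offset <- offset + len + 2000L
  }
  invisible(path)
}

#' Write a simulation as an on-disk fixture bundle
#'
#' Materialises everything the CLI needs to run end-to-end from disk:
#' \code{expression.gct} (sample- or tissue-level), \code{sample_map.tsv},
#' \code{annotation.tsv} and an equivalent \code{annotation.gtf}, a
#' synthetic \code{mane_summary.tsv} (the intended dominant isoform of
#' each coding gene plays the MANE-select role, with invented NM_
#' accessions), and the ground-truth tables
#' (\code{truth_rank1.tsv}, \code{truth_switches.tsv},
#' \code{truth_zeroed.tsv}).
#'
#' @param sim result of \code{\link{simulate_expression}}.
#' @param dir output directory (created if needed).
#' @return named character vector of paths, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  gene_of <- sim$annotation$gene_id[match(rownames(sim$tpm),
                                          sim$annotation$transcript_id)]
  write_gct(sim$tpm, p("expression.gct"),
            description = if (nrow(sim$tpm)) gene_of else character())
  write_tsv(sim$sample_map, p("sample_map.tsv"))
  write_tsv(sim$annotation, p("annotation.tsv"))
  write_annotation_gtf(sim$annotation, p("annotation.gtf"))

  coding_genes <- unique(sim$annotation$gene_id[
    sim$annotation$biotype == "protein_coding"])
  r1 <- sim$truth$intended_rank1
  mane_genes <- intersect(names(r1), coding_genes)
  mane <- data.frame(
    gene_id = mane_genes,
    mane_transcript_id = unname(r1[mane_genes]),
    refseq_id = sprintf("NM_%06d", seq_along(mane_genes)),
    stringsAsFactors = FALSE
  )
  write_tsv(mane, p("mane_summary.tsv"))
  write_tsv(data.frame(gene_id = names(r1), transcript_id = unname(r1),
                       stringsAsFactors = FALSE), p("truth_rank1.tsv"))
  write_tsv(sim$truth$switches, p("truth_switches.tsv"))
  write_tsv(data.frame(transcript_id = sim$truth$zeroed_transcripts,
                       stringsAsFactors = FALSE), p("truth_zeroed.tsv"))
  invisible(c(gct = p("expression.gct"), sample_map = p("sample_map.tsv"),
              annotation_tsv = p("annotation.tsv"),
              annotation_gtf = p("annotation.gtf"),
              mane = p("mane_summary.tsv"),
              truth_rank1 = p("truth_rank1.tsv"),
              truth_switches = p("truth_switches.tsv"),
              truth_zeroed = p("truth_zeroed.tsv")))
}
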