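#' Generate synthetic sequencing data for all assays
#'
#' Draws negative-binomial gene- and isoform-level counts for TRAP-seq and
#' bulk RNA-seq across compartments (cell bodies CB, neuropil NP), genotypes
#' and Cre states, plus the ancillary tables the discovery pipeline consumes:
#' whole-cell and compartment PAPERCLIP polyA-site tag tables (true sites plus
#' low-count noise peaks), splice-junction read tables (true junctions plus
#' noise junctions), per-experiment base coverage, and isoform-resolved
#' junction reads for percent-spliced-in analyses.
#'
#' True dendrite-enriched genes receive `localization_lfc` log2 units of extra
#' expression in Cre-positive neuropil TRAP; "present-only" genes receive it
#' in Cre-positive TRAP of both compartments. Multi-isoform genes split their
#' counts multinomially by the true compartment-specific isoform usage.
#'
#' @param models a `sim_models` object from [gen_gene_models()].
#' @param cfg the [sim_config()] used to build `models` (defaults to the one
#'   stored in `models`).
#' @return a list of class `sim_counts`: `samples`, `counts`, `isoform_counts`,
#'   `tpm`, `lengths`, `polya_wc`, `polya_np`, `junction_reads`,
#'   `junction_iso`, `coverage`.
#' @export
gen_count_data <- function(models, cfg = models$cfg) {
  stopifnot(inherits(models, "sim_models"))
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed + 1000L)

  genes <- models$genes
  iso <- models$isoforms
  truth <- models$truth
  n <- nrow(genes)
  nr <- cfg$n_replicates

  groups <- data.frame(
    assay       = c("TRAP", "TRAP", "RNA", "RNA", "TRAP", "TRAP", "TRAP"),
    compartment = c("CB", "NP", "CB", "NP", "NP", "CB", "NP"),
    genotype    = c("WT", "WT", "WT", "WT", "WT", "KO", "KO"),
    cre         = c("pos", "pos", "pos", "pos", "neg", "pos", "pos"),
    stringsAsFactors = FALSE)
  samples <- groups[rep(seq_len(nrow(groups)), each = nr), ]
  samples$replicate <- rep(seq_len(nr), nrow(groups))
  samples$batch <- ifelse(samples$replicate %% 2L == 1L, "b1", "b2")
  samples$sample_id <- with(samples, sprintf("%s_%s_%s_%s_r%d",
                                             assay, compartment, genotype,
                                             cre, replicate))
  rownames(samples) <- samples$sample_id

  # baseline expression (a gene-model property) and true effects (log2)
  base_l2 <- truth$base_log2
  names(base_l2) <- genes$gene_id
  lfc_present <- ifelse(truth$localization == "present",
                        cfg$localization_lfc, 0)
  lfc_enriched <- ifelse(truth$localization == "enriched",
                         cfg$localization_lfc, 0)
  batch_genes <- runif(n) < 0.3
  batch_lfc <- ifelse(batch_genes, 0.5, 0)

  norm <- cfg$library_size_mean / sum(2^base_l2)
  sf <- exp(rnorm(nrow(samples), 0, cfg$library_size_cv))

  counts <- matrix(0L, n, nrow(samples),
                   dimnames = list(genes$gene_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    s <- samples[j, ]
    trap_pos <- s$assay == "TRAP" && s$cre == "pos"
    eff <- lfc_present * trap_pos +
      lfc_enriched * (trap_pos && s$compartment == "NP") +
      batch_lfc * (s$batch == "b2")
    mu <- norm * sf[j] * 2^(base_l2 + eff)
    counts[, j] <- rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
  }

  # isoform-level counts: multinomial split of gene counts by true usage
  iso_counts <- matrix(0L, nrow(iso), nrow(samples),
                       dimnames = list(iso$isoform_id, samples$sample_id))
  iso_by_gene <- split(seq_len(nrow(iso)), iso$gene_id)
  for (g in names(iso_by_gene)) {
    rows <- iso_by_gene[[g]]
    if (length(rows) == 1L) {
      iso_counts[rows, ] <- counts[g, ]
      next
    }
    for (j in seq_len(nrow(samples))) {
      p <- if (samples$compartment[j] == "NP") iso$usage_np[rows]
           else iso$usage_cb[rows]
      iso_counts[rows, j] <- as.integer(rmultinom(1L, counts[g, j], p))
    }
  }

  # transcript lengths (full-length isoform) and TPM
  exon_len <- tapply(models$exons$end - models$exons$start,
                     models$exons$gene_id, sum)
  lengths <- as.numeric(exon_len[genes$gene_id])
  names(lengths) <- genes$gene_id
  rate <- counts / lengths
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6

  # whole-cell PAPERCLIP tag table: true sites + sub-threshold noise peaks
  usage_wc <- (iso$usage_cb + iso$usage_np) / 2
  tot_tags <- pmax(200, 2^base_l2[iso$gene_id] / 10)
  wc_tags <- rnbinom(nrow(iso), mu = tot_tags * usage_wc,
                     size = 1 / cfg$nb_dispersion)
  polya_wc <- data.frame(
    gene_id = iso$gene_id, chrom = "chrS",
    strand = genes$strand[match(iso$gene_id, genes$gene_id)],
    pos = iso$polya_pos, tags = wc_tags, is_true = TRUE,
    stringsAsFactors = FALSE)
  noise_sel <- runif(n) < 0.4
  if (any(noise_sel)) {
    gsel <- which(noise_sel)
    noise <- data.frame(
      gene_id = genes$gene_id[gsel], chrom = "chrS",
      strand = genes$strand[gsel],
      pos = genes$start[gsel] +
        sample(50:400, length(gsel), replace = TRUE),
      tags = sample(1:8, length(gsel), replace = TRUE), is_true = FALSE,
      stringsAsFactors = FALSE)
    polya_wc <- rbind(polya_wc, noise)
  }
  # compartment PAPERCLIP: same sites with neuropil replicate support
  polya_np <- polya_wc
  polya_np$rep_support <- ifelse(polya_np$is_true, 3L, 1L)

  # splice-junction reads: true junctions clear the filters, noise does not
  jx <- models$junctions
  iso_l <- split(iso, iso$gene_id)
  share <- mapply(function(g, d_pos) {
    it <- iso_l[[g]]
    if (nrow(it) == 1L) return(1)
    # junction is present in isoforms whose polyA lies 3'-ward of its donor
    st <- genes$strand[match(g, genes$gene_id)]
    inc <- if (st == "+") it$polya_pos > d_pos else it$polya_pos < d_pos
    sum((it$usage_cb[inc] + it$usage_np[inc]) / 2)
  }, jx$gene_id, jx$donor)
  mu_j <- pmax(30, 2^base_l2[jx$gene_id] / 20) * share
  jx$reads <- rnbinom(nrow(jx), mu = mu_j, size = 1 / cfg$nb_dispersion)
  noise_j <- jx[runif(nrow(jx)) < 0.2, , drop = FALSE]
  if (nrow(noise_j) > 0L) {
    noise_j$acceptor <- noise_j$acceptor +
      ifelse(noise_j$strand == "+", 37L, -37L)
    noise_j$reads <- sample(1:3, nrow(noise_j), replace = TRUE)
  }
  junction_reads <- rbind(jx, noise_j)

  # isoform-resolved junction reads from a shared upstream exon, per
  # compartment (the percent-spliced-in input)
  multi <- names(iso_by_gene)[vapply(iso_by_gene, length, 1L) > 1L]
  junction_iso <- do.call(rbind, lapply(multi, function(g) {
    rows <- iso_by_gene[[g]]
    do.call(rbind, lapply(c("CB", "NP"), function(cp) {
      tot <- rpois(1L, 30)
      p <- if (cp == "NP") iso$usage_np[rows] else iso$usage_cb[rows]
      r <- as.integer(rmultinom(1L, tot, p))
      data.frame(gene_id = g, isoform_id = iso$isoform_id[rows],
                 compartment = cp, reads = r, stringsAsFactors = FALSE)
    }))
  }))

  # complete per-experiment coverage: every exon and every expressed 3'UTR
  cov_iv <- rbind(
    data.frame(chrom = "chrS", start = models$exons$start,
               end = models$exons$end),
    data.frame(chrom = "chrS",
               start = pmin(iso$utr5_pos, iso$polya_pos),
               end = pmax(iso$utr5_pos, iso$polya_pos)))
  ir <- IRanges::reduce(IRanges::IRanges(cov_iv$start + 1L, cov_iv$end))
  cov_df <- data.frame(chrom = "chrS", start = IRanges::start(ir) - 1L,
                       end = IRanges::end(ir))
  coverage <- list(expt1 = cov_df, expt2 = cov_df)

  structure(list(samples = samples, counts = counts,
                 isoform_counts = iso_counts, tpm = tpm, lengths = lengths,
                 polya_wc = polya_wc, polya_np = polya_np,
                 junction_reads = junction_reads,
                 junction_iso = junction_iso, coverage = coverage,
                 base_log2 = base_l2),
            class = "sim_counts")
}

#' Generate synthetic CLIP replicates
#'
#' Draws per-gene CLIP tag counts for each replicate and compartment. The
#' expected log10 CLIP signal is linear in log10 TRAP TPM with slope 1, plus
#' the configured spiked enrichment for truly FMRP-bound genes and log-normal
#' replicate noise. Neuropil libraries are scaled down by
#' `clip_np_lib_ratio` relative to cell-body libraries, mirroring the ~10x
#' smaller dendritic tag yield of compartment CLIP. Genes with zero TPM in a
#' compartment produce zero tags there.
#'
#' @param models a `sim_models` object.
#' @param tpm gene x sample TPM matrix from [gen_count_data()].
#' @param samples sample sheet matching `tpm` columns.
#' @param cfg the [sim_config()].
#' @return a list of class `sim_clip`: `tags` (long data.frame with gene_id,
#'   compartment, replicate, tags), `tpm_by_compartment`, and `truth`.
#' @export
gen_clip_replicates <- function(models, tpm, samples, cfg = models$cfg) {
  stopifnot(inherits(models, "sim_models"))
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed + 2000L)

  truth <- models$truth
  sel <- function(cp) samples$assay == "TRAP" & samples$cre == "pos" &
    samples$genotype == "WT" & samples$compartment == cp
  tpm_cp <- cbind(CB = rowMeans(tpm[, sel("CB"), drop = FALSE]),
                  NP = rowMeans(tpm[, sel("NP"), drop = FALSE]))

  out <- list()
  for (cp in c("CB", "NP")) {
    lib_scale <- if (cp == "NP") cfg$clip_np_lib_ratio else 1
    t_cp <- tpm_cp[, cp]
    for (r in seq_len(cfg$n_clip_replicates)) {
      log10_mu <- log10(pmax(t_cp, 1e-8)) +
        cfg$clip_enrichment_log10 * truth$fmrp_bound +
        rnorm(length(t_cp), 0, cfg$clip_rep_sd)
      mu <- ifelse(t_cp > 0, 10^log10_mu * lib_scale, 0)
      tags <- rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = truth$gene_id, compartment = cp, replicate = r,
        tags = tags, stringsAsFactors = FALSE)
    }
  }
  structure(list(tags = do.call(rbind, out),
                 tpm_by_compartment = tpm_cp,
                 truth = truth),
            class = "sim_clip")
}
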