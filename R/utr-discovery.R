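#' @importFrom stats setNames
NULL

per_gene_fraction <- function(value, gene) {
  tot <- tapply(value, gene, sum)
  as.numeric(value / pmax(as.numeric(tot[gene]), 1e-300))
}

#' Filter polyA-site peaks
#'
#' Applies the peak-level filters used before 3'UTR assembly. Whole-cell
#' PAPERCLIP peaks are kept if they carry at least `min_tags` tags AND at
#' least `min_frac` of the gene's tags; compartment (microdissected) peaks
#' are kept if they have tag support in more than one neuropil experiment,
#' i.e. `rep_support >= min_rep_support`.
#'
#' @param sites data.frame with columns `gene_id`, `pos`, `tags`, and (for
#'   compartment sources) `rep_support`.
#' @param source `"whole-cell"` or `"compartment"`.
#' @param min_tags,min_frac whole-cell thresholds (defaults 10 tags, 5%).
#' @param min_rep_support compartment replicate-support threshold (default 2).
#' @return the kept rows with a `fraction` column, sorted by gene then
#'   position.
#' @export
filter_polya_sites <- function(sites, source = c("whole-cell", "compartment"),
                               min_tags = 10, min_frac = 0.05,
                               min_rep_support = 2L) {
  source <- match.arg(source)
  stopifnot(is.data.frame(sites),
            all(c("gene_id", "pos", "tags") %in% names(sites)))
  if (any(sites$tags < 0)) stop("negative tag counts", call. = FALSE)
  sites$fraction <- per_gene_fraction(sites$tags, sites$gene_id)
  keep <- if (source == "whole-cell") {
    sites$tags >= min_tags & sites$fraction >= min_frac
  } else {
    if (!"rep_support" %in% names(sites))
      stop("compartment sites need a 'rep_support' column", call. = FALSE)
    sites$rep_support >= min_rep_support
  }
  out <- sites[keep, , drop = FALSE]
  out[order(out$gene_id, out$pos), , drop = FALSE]
}

#' Filter splice junctions
#'
#' Keeps junctions found in at least `min_reads` reads OR representing at
#' least `min_frac` of the gene's junction reads (defaults 10 reads, 10%).
#'
#' @param junctions data.frame with `gene_id`, `donor`, `acceptor`, `reads`.
#' @param min_reads,min_frac thresholds.
#' @return kept rows with a `fraction` column.
#' @export
filter_junctions <- function(junctions, min_reads = 10, min_frac = 0.10) {
  stopifnot(is.data.frame(junctions),
            all(c("gene_id", "donor", "acceptor", "reads") %in%
                  names(junctions)))
  if (any(junctions$reads < 0)) stop("negative read counts", call. = FALSE)
  if (any(junctions$donor == junctions$acceptor))
    stop("junction with donor == acceptor", call. = FALSE)
  junctions$fraction <- per_gene_fraction(junctions$reads, junctions$gene_id)
  keep <- junctions$reads >= min_reads | junctions$fraction >= min_frac
  junctions[keep, , drop = FALSE]
}

#' Pair polyA sites with upstream splice junctions into candidate 3'UTRs
#'
#' For each kept polyA site the nearest upstream kept junction is identified
#' and its acceptor becomes the candidate 5' boundary; symmetrically, each
#' junction is paired with its nearest downstream polyA site. "Upstream" and
#' "downstream" are in the transcription sense (reversed on the minus
#' strand). When no kept junction lies upstream of a polyA site within the
#' gene, the 5' boundary falls back to the annotated start of the
#' stop-codon-containing exon. Equidistant acceptors are resolved in favour
#' of the junction with more reads, then the 5'-most.
#'
#' @param sites filtered polyA sites (`gene_id`, `pos`, ...).
#' @param junctions filtered junctions (`gene_id`, `donor`, `acceptor`,
#'   `reads`).
#' @param models a `sim_models` object or a list with `genes` and `exons`
#'   data.frames (strand, stop codon, exon coordinates).
#' @return data.frame of candidate 3'UTRs: `gene_id`, `chrom`, `strand`,
#'   `utr5` (5' boundary), `polya` (3' boundary), `start`/`end` (genomic,
#'   0-based half-open), `fallback` flag.
#' @export
pair_boundaries <- function(sites, junctions, models) {
  genes <- models$genes
  exons <- models$exons
  out <- list()
  for (g in unique(sites$gene_id)) {
    gi <- genes[genes$gene_id == g, ]
    if (nrow(gi) == 0L) {
      warning("gene model missing for ", g, "; skipped")
      next
    }
    plus <- gi$strand == "+"
    ss <- sites[sites$gene_id == g, ]
    jj <- junctions[junctions$gene_id == g, ]
    ex <- exons[exons$gene_id == g, ]
    # transcription-sense start of the stop-codon-containing exon
    sc <- gi$stop_codon
    sc_exon <- ex[ex$start <= sc & sc < ex$end, ]
    fb <- if (nrow(sc_exon) == 1L) {
      if (plus) sc_exon$start else sc_exon$end
    } else NA_real_

    pair_one <- function(pos) {
      ups <- if (plus) jj$acceptor < pos else jj$acceptor > pos
      if (!any(ups)) return(c(fb, NA, TRUE))
      cand <- jj[ups, , drop = FALSE]
      d <- abs(pos - cand$acceptor)
      cand <- cand[d == min(d), , drop = FALSE]
      if (nrow(cand) > 1L) {
        cand <- cand[cand$reads == max(cand$reads), , drop = FALSE]
        acc5 <- if (plus) min(cand$acceptor) else max(cand$acceptor)
        cand <- cand[cand$acceptor == acc5, , drop = FALSE]
      }
      c(cand$acceptor[1L], cand$reads[1L], FALSE)
    }
    # pass 1: each polyA site -> nearest upstream junction
    p1 <- t(vapply(ss$pos, pair_one, numeric(3)))
    # pass 2: each junction -> nearest downstream polyA
    p2 <- do.call(rbind, lapply(seq_len(nrow(jj)), function(k) {
      dn <- if (plus) ss$pos > jj$acceptor[k] else ss$pos < jj$acceptor[k]
      if (!any(dn)) return(NULL)
      pos <- ss$pos[dn]
      pos <- pos[which.min(abs(pos - jj$acceptor[k]))]
      c(jj$acceptor[k], pos)
    }))
    cand <- rbind(
      data.frame(utr5 = p1[, 1], polya = ss$pos, fallback = p1[, 3] == 1),
      if (!is.null(p2))
        data.frame(utr5 = p2[, 1], polya = p2[, 2], fallback = FALSE))
    cand <- cand[!is.na(cand$utr5), , drop = FALSE]
    ok <- if (plus) cand$utr5 < cand$polya else cand$utr5 > cand$polya
    cand <- unique(cand[ok, , drop = FALSE])
    # a final exon cannot contain a splice acceptor in its interior: drop
    # pairs spanning another kept junction's acceptor
    if (nrow(cand) > 0L && nrow(jj) > 0L) {
      clean <- vapply(seq_len(nrow(cand)), function(i) {
        inside <- if (plus)
          jj$acceptor > cand$utr5[i] & jj$acceptor < cand$polya[i]
        else jj$acceptor < cand$utr5[i] & jj$acceptor > cand$polya[i]
        !any(inside)
      }, logical(1))
      cand <- cand[clean, , drop = FALSE]
    }
    if (nrow(cand) == 0L) next
    out[[g]] <- data.frame(
      gene_id = g, chrom = gi$chrom, strand = gi$strand,
      utr5 = cand$utr5, polya = cand$polya,
      start = pmin(cand$utr5, cand$polya),
      end = pmax(cand$utr5, cand$polya),
      fallback = cand$fallback, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), utr5 = numeric(),
                      polya = numeric(), start = numeric(), end = numeric(),
                      fallback = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

utr_covered_fraction <- function(utrs, cov_df) {
  cov_ir <- IRanges::reduce(IRanges::IRanges(cov_df$start + 1L, cov_df$end))
  utr_ir <- IRanges::IRanges(utrs$start + 1L, utrs$end)
  ov <- IRanges::findOverlaps(utr_ir, cov_ir)
  inter <- IRanges::pintersect(utr_ir[S4Vectors::queryHits(ov)],
                               cov_ir[S4Vectors::subjectHits(ov)])
  covered <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
  frac <- numeric(nrow(utrs))
  frac[as.integer(names(covered))] <- as.numeric(covered)
  frac / IRanges::width(utr_ir)
}

#' Coverage-filter candidate 3'UTRs
#'
#' Keeps candidates whose bases are covered to at least `min_cov` (default
#' 80%, inclusive) in at least one experiment. Coverage is supplied either
#' as a named list of data.frames of covered intervals (`chrom`, `start`,
#' `end`; 0-based half-open), one per experiment, or as a named list (per
#' experiment) of per-base depth vectors named by candidate row.
#'
#' @param utrs candidate table from [pair_boundaries()].
#' @param coverage per-experiment coverage (see Details).
#' @param min_cov minimum covered-base fraction.
#' @return kept candidates with a `max_covered_frac` column.
#' @export
coverage_filter <- function(utrs, coverage, min_cov = 0.80) {
  if (nrow(utrs) == 0L) return(cbind(utrs, max_covered_frac = numeric()))
  frac <- sapply(coverage, function(cov) {
    if (is.data.frame(cov)) return(utr_covered_fraction(utrs, cov))
    # per-base depth vectors keyed by row index
    vapply(seq_len(nrow(utrs)), function(i) {
      v <- cov[[i]]
      w <- utrs$end[i] - utrs$start[i]
      if (is.null(v)) return(0)
      if (length(v) < w)
        stop("coverage array shorter than UTR for row ", i, call. = FALSE)
      mean(v[seq_len(w)] > 0)
    }, numeric(1))
  })
  frac <- matrix(frac, nrow = nrow(utrs))
  utrs$max_covered_frac <- apply(frac, 1, max)
  utrs[utrs$max_covered_frac >= min_cov, , drop = FALSE]
}

#' Remove ambiguous genes and overlapping 3'UTRs
#'
#' Drops candidate 3'UTRs of ambiguous genes (genes whose annotated spans
#' overlap another gene on the same strand) and candidates that overlap
#' another gene's span or another gene's candidate 3'UTR.
#'
#' @param utrs candidate table.
#' @param models gene models (list with a `genes` data.frame).
#' @return the retained candidates.
#' @export
remove_ambiguous <- function(utrs, models) {
  if (nrow(utrs) == 0L) return(utrs)
  genes <- models$genes
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start + 1L,
                                                 genes$end),
                                strand = genes$strand)
  names(ggr) <- genes$gene_id
  # ambiguous genes: same-strand overlap with another gene
  self <- GenomicRanges::findOverlaps(ggr, ggr, ignore.strand = FALSE)
  self <- self[S4Vectors::queryHits(self) != S4Vectors::subjectHits(self)]
  ambiguous <- unique(genes$gene_id[S4Vectors::queryHits(self)])
  keep <- !(utrs$gene_id %in% ambiguous)

  ugr <- GenomicRanges::GRanges(utrs$chrom,
                                IRanges::IRanges(utrs$start + 1L, utrs$end))
  # overlap with another gene's span (any strand)
  ov <- GenomicRanges::findOverlaps(ugr, ggr, ignore.strand = TRUE)
  bad <- genes$gene_id[S4Vectors::subjectHits(ov)] !=
    utrs$gene_id[S4Vectors::queryHits(ov)]
  keep[unique(S4Vectors::queryHits(ov)[bad])] <- FALSE
  # overlap with another gene's UTR
  uu <- GenomicRanges::findOverlaps(ugr, ugr, ignore.strand = TRUE)
  bad2 <- utrs$gene_id[S4Vectors::queryHits(uu)] !=
    utrs$gene_id[S4Vectors::subjectHits(uu)]
  keep[unique(S4Vectors::queryHits(uu)[bad2])] <- FALSE
  utrs[keep, , drop = FALSE]
}

#' Classify alternative-polyadenylation events
#'
#' For genes with two or more retained 3'UTR isoforms, classifies each polyA
#' site relative to the annotated stop codon: sites 3'-ward of the stop codon
#' are tandem 3'UTR sites (3'UTR-APA; no effect on the CDS) and among them
#' the most stop-proximal is `proximal`, the most distal `distal`, the rest
#' `internal`; sites 5'-ward of the stop codon are upstream-region sites
#' (UR-APA) that truncate the CDS. Genes carrying both kinds are typed
#' `both`.
#'
#' @param utrs retained candidate 3'UTRs.
#' @param models gene models with `genes` (stop_codon, strand).
#' @return list with `sites` (per-isoform classes) and `genes` (per-gene APA
#'   type); single-isoform genes yield no events.
#' @export
classify_apa <- function(utrs, models) {
  genes <- models$genes
  tab <- table(utrs$gene_id)
  multi <- names(tab)[tab >= 2L]
  sites <- do.call(rbind, lapply(multi, function(g) {
    gi <- genes[genes$gene_id == g, ]
    uu <- utrs[utrs$gene_id == g, , drop = FALSE]
    plus <- gi$strand == "+"
    downstream <- if (plus) uu$polya > gi$stop_codon
                  else uu$polya < gi$stop_codon
    cls <- rep("upstream", nrow(uu))
    if (any(downstream)) {
      d <- abs(uu$polya - gi$stop_codon)[downstream]
      term_cls <- rep("internal", sum(downstream))
      term_cls[which.min(d)] <- "proximal"
      term_cls[which.max(d)] <- "distal"
      if (sum(downstream) == 1L) term_cls <- "distal"
      cls[downstream] <- term_cls
    }
    data.frame(gene_id = g, utr5 = uu$utr5, polya = uu$polya,
               site_class = cls, cds_altering = !downstream,
               stringsAsFactors = FALSE)
  }))
  if (is.null(sites))
    return(list(sites = data.frame(), genes = data.frame()))
  # event-based typing: >= 2 terminal sites form a 3'UTR-APA event; an
  # upstream site together with a terminal site forms a UR-APA event
  gene_type <- vapply(split(sites$cds_altering, sites$gene_id), function(a) {
    has_tandem <- sum(!a) >= 2L
    has_ur <- any(a)
    if (has_tandem && has_ur) "both"
    else if (has_ur) "UR-APA" else "3UTR-APA"
  }, character(1))
  list(sites = sites,
       genes = data.frame(gene_id = names(gene_type), type = gene_type,
                          row.names = NULL, stringsAsFactors = FALSE))
}

#' Run the full 3'UTR discovery pipeline
#'
#' Filters polyA sites and junctions, pairs boundaries, applies the coverage
#' and ambiguity filters, and classifies APA events.
#'
#' @param polya_sites,junctions,coverage,models inputs as for the stage
#'   functions.
#' @param source polyA-site source passed to [filter_polya_sites()].
#' @inheritParams filter_polya_sites
#' @inheritParams coverage_filter
#' @return list with `utrs` (retained candidates) and `apa` (classification).
#' @export
discover_utrs <- function(polya_sites, junctions, coverage, models,
                          source = "whole-cell", min_cov = 0.80) {
  ps <- filter_polya_sites(polya_sites, source = source)
  jx <- filter_junctions(junctions)
  cand <- pair_boundaries(ps, jx, models)
  cand <- coverage_filter(cand, coverage, min_cov = min_cov)
  cand <- remove_ambiguous(cand, models)
  list(utrs = cand, apa = classify_apa(cand, models))
}
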