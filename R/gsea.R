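#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walk statistic of preranked GSEA with weight exponent 1: genes are sorted
#' by decreasing ranking value; hits advance the running sum in proportion
#' to |value|, misses retreat it by 1/(N - Nh); the ES is the extremum of
#' the running sum.
#'
#' @param ranking named numeric vector (no NA).
#' @param set character vector of gene ids.
#' @return the enrichment score.
#' @export
gsea_es <- function(ranking, set) {
  ord <- order(ranking, decreasing = TRUE)
  r <- ranking[ord]
  hit <- names(r) %in% set
  if (!any(hit) || all(hit)) return(NA_real_)
  w <- abs(r)
  w[hit & w == 0] <- .Machine$double.eps
  p_hit <- ifelse(hit, w, 0)
  p_hit <- p_hit / sum(p_hit)
  p_miss <- ifelse(hit, 0, 1 / sum(!hit))
  walk <- cumsum(p_hit - p_miss)
  walk[which.max(abs(walk))]
}

#' Preranked gene-set enrichment analysis
#'
#' Computes the weighted KS enrichment score for each gene set on a ranked
#' gene list and estimates significance by gene-label permutation: null
#' scores are the ES of `n_permutations` random sets of the same size. The
#' nominal p is the fraction of same-sign null scores at least as extreme;
#' NES is ES divided by the mean absolute null ES of the same sign; FDR is
#' Benjamini-Hochberg across sets. Sets intersecting the universe in fewer
#' than `min_size` genes are skipped.
#'
#' @param ranking named numeric vector, no NA.
#' @param gene_sets named list of character vectors.
#' @param n_permutations number of label permutations.
#' @param seed integer seed for the permutation stream.
#' @param min_size minimum set size after intersection with the universe.
#' @return data.frame `set_id`, `size`, `ES`, `NES`, `p`, `FDR`,
#'   `leading_edge` (comma-separated gene ids).
#' @export
gsea_preranked <- function(ranking, gene_sets, n_permutations = 1000,
                           seed = 1L, min_size = 5L) {
  if (anyNA(ranking)) stop("ranking contains NA", call. = FALSE)
  set.seed(seed)
  universe <- names(ranking)
  rows <- list()
  for (sid in names(gene_sets)) {
    set <- intersect(gene_sets[[sid]], universe)
    if (length(set) < min_size) {
      message("skipping set '", sid, "': fewer than ", min_size,
              " genes in universe")
      next
    }
    es <- gsea_es(ranking, set)
    null_es <- vapply(seq_len(n_permutations), function(i)
      gsea_es(ranking, sample(universe, length(set))), numeric(1))
    same <- null_es[sign(null_es) == sign(es)]
    p <- if (length(same) == 0L) 1 / (n_permutations + 1)
         else (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    nes <- if (length(same) == 0L) NA_real_ else es / mean(abs(same))
    ord <- order(ranking, decreasing = TRUE)
    sorted <- names(ranking)[ord]
    hit <- sorted %in% set
    walk_peak <- which.max(abs(cumsum(
      ifelse(hit, abs(ranking[ord]) / sum(abs(ranking[ord])[hit]), 0) -
        ifelse(hit, 0, 1 / sum(!hit)))))
    le <- if (es >= 0) sorted[seq_len(walk_peak)][hit[seq_len(walk_peak)]]
          else sorted[walk_peak:length(sorted)][hit[walk_peak:length(sorted)]]
    rows[[sid]] <- data.frame(
      set_id = sid, size = length(set), ES = es, NES = nes, p = p,
      leading_edge = paste(le, collapse = ","), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(set_id = character(), size = integer(),
                      ES = numeric(), NES = numeric(), p = numeric(),
                      FDR = numeric(), leading_edge = character()))
  out <- do.call(rbind, rows)
  out$FDR <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[c("set_id", "size", "ES", "NES", "p", "FDR", "leading_edge")]
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one set per line, tab-separated
#'   (name, description, genes...).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  sets
}
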