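# Independent brute-force oracles used across tests. These re-derive each
# result from first principles and must stay independent of the package's
# implementation paths.

# per-row filter of polyA sites, recomputing gene totals with a plain loop
bf_filter_polya <- function(sites, min_tags = 10, min_frac = 0.05) {
  keep <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    tot <- 0
    for (j in seq_len(nrow(sites)))
      if (sites$gene_id[j] == sites$gene_id[i]) tot <- tot + sites$tags[j]
    keep[i] <- sites$tags[i] >= min_tags && sites$tags[i] / tot >= min_frac
  }
  keep
}

bf_filter_junctions <- function(jx, min_reads = 10, min_frac = 0.10) {
  keep <- logical(nrow(jx))
  for (i in seq_len(nrow(jx))) {
    tot <- sum(jx$reads[jx$gene_id == jx$gene_id[i]])
    keep[i] <- jx$reads[i] >= min_reads || jx$reads[i] / tot >= min_frac
  }
  keep
}

# exhaustive nearest-upstream pairing, O(n^2), one gene at a time
bf_pair_upstream <- function(pos, acceptors, reads, plus) {
  best <- NA_real_
  best_d <- Inf
  best_reads <- -Inf
  for (k in seq_along(acceptors)) {
    ups <- if (plus) acceptors[k] < pos else acceptors[k] > pos
    if (!ups) next
    d <- abs(pos - acceptors[k])
    better <- d < best_d ||
      (d == best_d && (reads[k] > best_reads ||
                       (reads[k] == best_reads &&
                        ((plus && acceptors[k] < best) ||
                         (!plus && acceptors[k] > best)))))
    if (better) {
      best <- acceptors[k]; best_d <- d; best_reads <- reads[k]
    }
  }
  best
}

# base-by-base covered fraction of [start, end) given covered intervals
bf_covered_fraction <- function(start, end, cov_df) {
  bases <- seq(start, end - 1L)
  cov <- logical(length(bases))
  for (r in seq_len(nrow(cov_df)))
    cov <- cov | (bases >= cov_df$start[r] & bases < cov_df$end[r])
  mean(cov)
}

# quadratic all-pairs interval overlap (0-based half-open)
bf_overlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

# brute-force GSEA walk statistic
bf_gsea_es <- function(ranking, set) {
  ord <- names(sort(ranking, decreasing = TRUE))
  nh <- sum(ord %in% set)
  nm <- length(ord) - nh
  wsum <- sum(abs(ranking[ord[ord %in% set]]))
  run <- 0; best <- 0
  for (g in ord) {
    run <- if (g %in% set) run + abs(ranking[[g]]) / wsum else run - 1 / nm
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# exhaustive G4 motif presence: try every start position and every gap
# combination of the four [AU]GGA units with gaps of 0..6
bf_has_g4 <- function(s) {
  s <- chartr("T", "U", toupper(s))
  n <- nchar(s)
  unit_at <- function(p) {
    p + 3 <= n &&
      substr(s, p, p) %in% c("A", "U") &&
      substr(s, p + 1, p + 3) == "GGA"
  }
  for (p1 in 1:max(1, n)) {
    if (!unit_at(p1)) next
    for (g1 in 0:6) {
      p2 <- p1 + 4 + g1
      if (p2 + 3 > n || !unit_at(p2)) next
      for (g2 in 0:6) {
        p3 <- p2 + 4 + g2
        if (p3 + 3 > n || !unit_at(p3)) next
        for (g3 in 0:6) {
          p4 <- p3 + 4 + g3
          if (p4 + 3 > n || !unit_at(p4)) next
          return(TRUE)
        }
      }
    }
  }
  FALSE
}

# hypergeometric enumeration of the two-sided Fisher p for a 2x2 table
bf_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random nucleotide sequence
rand_seq <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# nuclei pixel cloud for a flat cell-body band (cb side low unless flipped)
flat_field <- function(c_um, layer = 30, width = 100, n_px = 20000,
                       um_per_px = 0.14, cb_side = "low",
                       shift_slice = NULL, shift_by = 50) {
  x <- runif(n_px, 0, width)
  y <- if (cb_side == "low") c_um - runif(n_px, 0, layer)
       else c_um + runif(n_px, 0, layer)
  if (!is.null(shift_slice)) {
    lo <- (shift_slice - 1) * width / 25
    hi <- shift_slice * width / 25
    sel <- x >= lo & x < hi
    y[sel] <- y[sel] + if (cb_side == "low") -shift_by else shift_by
  }
  list(nuclei_px = data.frame(col = x / um_per_px, row = y / um_per_px),
       um_per_px = um_per_px, cb_side = cb_side)
}
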