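#' Percent spliced in from junction reads
#'
#' Computes PSI from inclusion- and skipping-junction read counts. Skipped
#' exons (SE) and mutually exclusive exons (MXE) are supported by two
#' inclusion junctions versus one skipping junction, so inclusion reads are
#' halved for effective-length correction: PSI = (I/2) / (I/2 + S).
#' Alternative 3'/5' splice sites (A3SS, A5SS) are one-vs-one:
#' PSI = I / (I + S). PSI is NA when I + S = 0.
#'
#' @param inclusion summed inclusion-junction reads (one value per event, or
#'   vector).
#' @param skipping skipping-junction reads.
#' @param type event type, one of `"SE"`, `"MXE"`, `"A3SS"`, `"A5SS"`
#'   (recycled).
#' @return numeric PSI in `[0, 1]` (NA where undefined).
#' @export
compute_psi <- function(inclusion, skipping, type = "SE") {
  stopifnot(all(type %in% c("SE", "MXE", "A3SS", "A5SS")))
  if (any(inclusion < 0) || any(skipping < 0))
    stop("negative junction counts", call. = FALSE)
  i_eff <- ifelse(type %in% c("SE", "MXE"), inclusion / 2, inclusion)
  tot <- i_eff + skipping
  ifelse(tot > 0, i_eff / tot, NA_real_)
}

#' Per-isoform junction-read fractions
#'
#' Fraction of junction reads from a shared exon assigned to each isoform.
#'
#' @param reads named or unnamed numeric vector of per-isoform junction
#'   reads.
#' @return numeric fractions summing to 1 (all NA when total is 0).
#' @export
isoform_junction_fraction <- function(reads) {
  if (any(reads < 0)) stop("negative junction counts", call. = FALSE)
  tot <- sum(reads)
  if (tot == 0) return(rep(NA_real_, length(reads)))
  reads / tot
}

#' Correlate PSI vectors across datasets
#'
#' Pearson product-moment correlation over shared events with defined PSI in
#' both vectors, with the two-sided t-approximation p-value and the fitted
#' line for plotting.
#'
#' @param psi_a,psi_b named numeric PSI vectors.
#' @return list `r`, `p`, `n`, `slope`, `intercept` (NA with a warning if a
#'   vector has zero variance).
#' @export
correlate_psi <- function(psi_a, psi_b) {
  shared <- intersect(names(psi_a), names(psi_b))
  a <- psi_a[shared]; b <- psi_b[shared]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L)
    stop("fewer than 3 shared events with defined PSI", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in a PSI vector; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(a),
                slope = NA_real_, intercept = NA_real_))
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  fit <- stats::lm(b ~ a)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Filter differential-splicing events by significance
#'
#' Keeps events with FDR < `fdr_cutoff` and |dPSI| > `dpsi_cutoff` and
#' labels them by the sign of dPSI (positive: included more in the neuropil;
#' negative: included more in cell bodies). Events missing either field are
#' skipped with a message.
#'
#' @param events data.frame with `event_id`, `type`, `dPSI`, `FDR`.
#' @param fdr_cutoff,dpsi_cutoff thresholds (defaults 0.05 and 0.1).
#' @return kept events with a `direction` column.
#' @export
filter_significant_events <- function(events, fdr_cutoff = 0.05,
                                      dpsi_cutoff = 0.1) {
  stopifnot(all(c("event_id", "dPSI", "FDR") %in% names(events)))
  bad <- is.na(events$dPSI) | is.na(events$FDR)
  if (any(bad)) {
    message("skipping ", sum(bad), " event(s) with missing fields")
    events <- events[!bad, , drop = FALSE]
  }
  keep <- events$FDR < fdr_cutoff & abs(events$dPSI) > dpsi_cutoff
  out <- events[keep, , drop = FALSE]
  out$direction <- ifelse(out$dPSI > 0, "NP-included", "CB-included")
  out
}

#' Splice-event type summary
#'
#' Counts and half-up-rounded percentages of kept events by type.
#'
#' @param types character vector of event types.
#' @return data.frame `type`, `n`, `percent`.
#' @export
event_type_summary <- function(types) {
  tab <- sort(table(types), decreasing = TRUE)
  data.frame(type = names(tab), n = as.integer(tab),
             percent = round_half_up(100 * as.integer(tab) / sum(tab), 1),
             stringsAsFactors = FALSE)
}

#' Two-sample rank test on replicate-level PSI
#'
#' Wilcoxon rank-sum comparison of per-replicate PSI values between two
#' conditions: a simple replicate-level alternative for synthetic workflows,
#' not a reimplementation of junction-count splicing tests.
#'
#' @param psi_a,psi_b per-replicate PSI values in the two conditions.
#' @return list `dPSI` (mean difference b - a), `p`.
#' @export
psi_rank_test <- function(psi_a, psi_b) {
  wt <- suppressWarnings(stats::wilcox.test(psi_b, psi_a, exact = TRUE))
  list(dPSI = mean(psi_b, na.rm = TRUE) - mean(psi_a, na.rm = TRUE),
       p = wt$p.value)
}
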