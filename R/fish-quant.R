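#' Estimate the cell-body-layer boundary from nuclei positions
#'
#' Slices the nuclei scatterplot into `n_slices` vertical slices, locates in
#' each slice the edge of the nuclei density on the neuropil side, and fits
#' a polynomial through the per-slice anchor points in two rounds, removing
#' anchors with absolute round-1 residuals above `outlier_sd` standard
#' deviations in between. The per-slice anchor is the y position where the
#' kernel-smoothed density first falls below `density_frac` of the slice
#' maximum moving from the cell-body side, corrected for the deterministic
#' offset a Gaussian kernel of the given bandwidth imposes on a sharp band
#' edge (`bandwidth * qnorm(1 - density_frac)`), so the anchor estimates the
#' true edge rather than the smoothed tail.
#'
#' @param field a `fish_field` (or any list with `nuclei_px` and
#'   `um_per_px`).
#' @param n_slices number of vertical slices (default 25).
#' @param degree polynomial degree, 1-5 (default 3).
#' @param bandwidth kernel bandwidth in µm (default 5).
#' @param density_frac threshold as a fraction of the slice density maximum.
#' @param outlier_sd residual cutoff (in round-1 residual SDs) for anchor
#'   removal.
#' @param cb_side which side of the boundary holds the cell bodies,
#'   `"low"` or `"high"` y; defaults to the field's own flag.
#' @param min_px minimum nuclei pixels for a slice to contribute an anchor.
#' @return list of class `boundary_curve`: `coeffs` (increasing degree),
#'   `degree`, `anchors` (x, y, kept), `sd_round1`, `sd_round2`,
#'   `n_outliers`, `x_range`, `cb_side`.
#' @export
estimate_boundary <- function(field, n_slices = 25L, degree = 3L,
                              bandwidth = 5, density_frac = 0.1,
                              outlier_sd = 2,
                              cb_side = field$cb_side %||% "low",
                              min_px = 20L) {
  stopifnot(degree >= 1L, degree <= 5L)
  px <- field$um_per_px
  x <- field$nuclei_px$col * px
  y <- field$nuclei_px$row * px
  if (diff(range(x)) < 1e-6) stop("degenerate x-range", call. = FALSE)
  breaks <- seq(min(x), max(x), length.out = n_slices + 1L)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  slice <- cut(x, breaks, include.lowest = TRUE, labels = FALSE)
  offset <- bandwidth * stats::qnorm(1 - density_frac)

  anchors <- vapply(seq_len(n_slices), function(s) {
    ys <- y[slice == s]
    if (length(ys) < min_px) return(NA_real_)
    d <- stats::density(ys, bw = bandwidth)
    peak <- which.max(d$y)
    thr <- density_frac * d$y[peak]
    if (cb_side == "low") {
      beyond <- which(d$y < thr & seq_along(d$y) > peak)
      if (length(beyond) == 0L) return(NA_real_)
      d$x[min(beyond)] - offset
    } else {
      beyond <- which(d$y < thr & seq_along(d$y) < peak)
      if (length(beyond) == 0L) return(NA_real_)
      d$x[max(beyond)] + offset
    }
  }, numeric(1))

  ok <- !is.na(anchors)
  if (sum(ok) < degree + 2L)
    stop("too few valid slices for a degree-", degree, " fit",
         call. = FALSE)
  ax <- mids[ok]; ay <- anchors[ok]
  fit1 <- stats::lm(ay ~ poly(ax, degree, raw = TRUE))
  res1 <- stats::residuals(fit1)
  sd1 <- stats::sd(res1)
  keep <- abs(res1) <= outlier_sd * sd1
  fit2 <- stats::lm(ay[keep] ~ poly(ax[keep], degree, raw = TRUE))
  sd2 <- stats::sd(stats::residuals(fit2))

  structure(list(coeffs = unname(stats::coef(fit2)), degree = degree,
                 anchors = data.frame(x = ax, y = ay, kept = keep),
                 sd_round1 = sd1, sd_round2 = sd2,
                 n_outliers = sum(!keep),
                 x_range = range(ax), cb_side = cb_side),
            class = "boundary_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signed spot-to-boundary distances
#'
#' Minimum Euclidean distance from each spot to the fitted boundary curve,
#' found by dense sampling of the curve at `step` µm in x, signed positive
#' on the neuropil side. Spots outside the curve's x-range take the distance
#' to the nearest curve endpoint and are flagged.
#'
#' @param spots data.frame with `x_um`, `y_um` (and optionally `spot_id`,
#'   `image_id`).
#' @param curve a `boundary_curve` from [estimate_boundary()].
#' @param step curve sampling step in µm (default 0.1).
#' @return data.frame with the spot columns plus `distance` (signed, µm)
#'   and `out_of_range`.
#' @export
spot_distances <- function(spots, curve, step = 0.1) {
  xg <- seq(curve$x_range[1], curve$x_range[2], by = step)
  yg <- poly_eval(curve$coeffs, xg)
  np_sign <- if (curve$cb_side == "low") 1 else -1
  d <- vapply(seq_len(nrow(spots)), function(i) {
    dx <- spots$x_um[i] - xg
    dy <- spots$y_um[i] - yg
    sqrt(min(dx * dx + dy * dy))
  }, numeric(1))
  x_cl <- pmin(pmax(spots$x_um, curve$x_range[1]), curve$x_range[2])
  above <- spots$y_um > poly_eval(curve$coeffs, x_cl)
  out <- spots
  out$distance <- d * ifelse(above, np_sign, -np_sign)
  out$out_of_range <- spots$x_um < curve$x_range[1] |
    spots$x_um > curve$x_range[2]
  out
}

#' Classify spots into compartments
#'
#' A spot is in the neuropil when its signed distance to the cell-body-layer
#' boundary exceeds `cutoff` µm (strictly; default 10 µm); the per-image
#' neuropil fraction is also reported.
#'
#' @param dist_table output of [spot_distances()].
#' @param cutoff distance threshold in µm.
#' @return list with `spots` (adds `compartment`) and `fractions`
#'   (per-image neuropil fraction).
#' @export
classify_spots <- function(dist_table, cutoff = 10) {
  dist_table$compartment <- ifelse(dist_table$distance > cutoff,
                                   "neuropil", "cell-body")
  img <- if ("image_id" %in% names(dist_table)) dist_table$image_id
         else rep("img", nrow(dist_table))
  fr <- tapply(dist_table$compartment == "neuropil", img, mean)
  list(spots = dist_table,
       fractions = data.frame(image_id = names(fr),
                              neuropil_fraction = as.numeric(fr),
                              row.names = NULL, stringsAsFactors = FALSE))
}

#' Compare spot-distance distributions between probes or conditions
#'
#' Two-sample Kolmogorov-Smirnov test on the distance vectors and, when
#' per-image neuropil fractions are supplied, a Wilcoxon rank-sum test on
#' the fractions (exact for small samples without ties, normal
#' approximation with tie correction otherwise).
#'
#' @param distances_a,distances_b distance vectors (µm).
#' @param fractions_a,fractions_b optional per-image neuropil fractions.
#' @return list `ks_D`, `ks_p`, and (when fractions are given)
#'   `wilcox_p`.
#' @export
compare_probe_distributions <- function(distances_a, distances_b,
                                        fractions_a = NULL,
                                        fractions_b = NULL) {
  if (length(distances_a) < 5L || length(distances_b) < 5L)
    stop("need at least 5 observations per group for the KS test",
         call. = FALSE)
  ks <- suppressWarnings(stats::ks.test(distances_a, distances_b))
  out <- list(ks_D = unname(ks$statistic), ks_p = ks$p.value)
  if (!is.null(fractions_a) && !is.null(fractions_b)) {
    if (length(fractions_a) < 3L || length(fractions_b) < 3L)
      stop("need at least 3 images per group for the Wilcoxon test",
           call. = FALSE)
    wt <- suppressWarnings(stats::wilcox.test(fractions_a, fractions_b))
    out$wilcox_p <- wt$p.value
  }
  out
}

#' Binned WT-vs-KO comparison of spot distances
#'
#' From each image, samples `n_sample` spots (seeded; with replacement, with
#' a message, when an image holds fewer), bins their distances into `n_bins`
#' equal-width bins over `range`, converts bin counts to per-image percents,
#' and per bin runs a two-sample t-test of the per-image percents between
#' genotypes, with BH correction across bins.
#'
#' @param dist_table data.frame with `image_id`, `distance`.
#' @param genotypes named vector mapping image_id to `"WT"`/`"KO"`.
#' @param n_sample spots sampled per image (default 1000).
#' @param n_bins number of distance bins (default 15).
#' @param range distance range covered by the bins, µm.
#' @param seed integer seed for the sampling.
#' @return data.frame per bin: `bin`, `lo`, `hi`, `mean_WT`, `mean_KO`,
#'   `t`, `p`, `FDR`.
#' @export
binned_wt_ko_comparison <- function(dist_table, genotypes, n_sample = 1000L,
                                    n_bins = 15L, range = c(0, 150),
                                    seed = 1L) {
  set.seed(seed)
  imgs <- unique(dist_table$image_id)
  gt <- genotypes[imgs]
  if (min(table(gt)) < 2L)
    stop("need at least 2 images per genotype", call. = FALSE)
  breaks <- seq(range[1], range[2], length.out = n_bins + 1L)
  pct <- sapply(imgs, function(im) {
    d <- dist_table$distance[dist_table$image_id == im]
    if (length(d) < n_sample)
      message("image ", im, ": sampling with replacement (",
              length(d), " < ", n_sample, " spots)")
    d <- sample(d, n_sample, replace = length(d) < n_sample)
    b <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
    tabulate(b[!is.na(b)], n_bins) / sum(!is.na(b)) * 100
  })
  rows <- lapply(seq_len(n_bins), function(k) {
    wt_v <- pct[k, gt == "WT"]; ko_v <- pct[k, gt == "KO"]
    tt <- tryCatch(stats::t.test(wt_v, ko_v),
                   error = function(e) list(statistic = NA, p.value = NA))
    data.frame(bin = k, lo = breaks[k], hi = breaks[k + 1L],
               mean_WT = mean(wt_v), mean_KO = mean(ko_v),
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$FDR <- stats::p.adjust(out$p, method = "BH")
  out
}
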