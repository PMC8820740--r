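#' Median-of-ratios size factors
#'
#' Computes per-sample size factors as the median across features of the
#' ratio of each sample's count to the feature's geometric mean, using only
#' features with all-positive counts.
#'
#' @param counts feature x sample count matrix.
#' @return numeric vector of size factors, one per column.
#' @export
estimate_size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no feature with all-positive counts", call. = FALSE)
  logg <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2,
              function(y) exp(stats::median(log(y) - logg)))
  sf / exp(mean(log(sf)))
}

fit_dispersions <- function(counts, design, sf, prior_df = 10) {
  n <- nrow(counts)
  mean_norm <- rowMeans(sweep(counts, 2, sf, "/"))
  alpha_hat <- rep(NA_real_, n)
  off <- log(sf)
  for (i in seq_len(n)) {
    y <- counts[i, ]
    if (all(y == 0)) next
    fit <- suppressWarnings(
      stats::glm.fit(design, y, family = stats::poisson(), offset = off))
    mu <- fit$fitted.values
    # moment estimator with df correction: residuals from a fitted mean
    # underestimate the variance by (n - p)/n
    s2 <- sum((y - mu)^2) / (1 - ncol(design) / length(y))
    alpha_hat[i] <- (s2 - sum(mu)) / sum(mu^2)
  }
  alpha_hat <- pmax(alpha_hat, 1e-8)
  use <- !is.na(alpha_hat) & alpha_hat > 1e-8 & mean_norm > 1
  trend <- if (sum(use) >= 10) {
    tf <- stats::lm(alpha_hat[use] ~ I(1 / mean_norm[use]))
    a0 <- max(stats::coef(tf)[1], 1e-8)
    a1 <- max(stats::coef(tf)[2], 0)
    pmax(a0 + a1 / mean_norm, 1e-8)
  } else rep(stats::median(alpha_hat, na.rm = TRUE), n)
  df_res <- ncol(counts) - ncol(design)
  alpha <- (df_res * alpha_hat + prior_df * trend) / (df_res + prior_df)
  pmax(ifelse(is.na(alpha), trend, alpha), 1e-8)
}

#' Negative-binomial Wald test for differential abundance
#'
#' Per-feature negative-binomial log-linear model with median-of-ratios size
#' factors, method-of-moments dispersion estimates shrunk toward a fitted
#' mean-dispersion trend (weights proportional to residual degrees of
#' freedom against a fixed prior weight), and a Wald test on the condition
#' coefficient. Batch enters as an additive covariate when supplied.
#' Benjamini-Hochberg FDR is computed across features with defined p-values;
#' all-zero features return NA and are excluded from the BH denominator.
#'
#' @param counts feature x sample integer count matrix.
#' @param condition two-level factor (or coercible) of length `ncol(counts)`;
#'   the reported LFC is level 2 over level 1.
#' @param batch optional factor of batch labels for additive adjustment.
#' @param prior_df prior weight of the dispersion trend.
#' @param size_factors optional externally supplied size factors.
#' @return data.frame with `feature_id`, `baseMean`, `LFC` (log2), `SE`,
#'   `stat` (= LFC/SE), `p`, `FDR`.
#' @export
nb_wald_test <- function(counts, condition, batch = NULL, prior_df = 10,
                         size_factors = NULL) {
  counts <- as.matrix(counts)
  condition <- factor(condition)
  stopifnot(length(condition) == ncol(counts), nlevels(condition) == 2L)
  if (min(table(condition)) < 2L)
    stop("need at least 2 replicates per group", call. = FALSE)
  design <- if (is.null(batch)) stats::model.matrix(~condition)
            else stats::model.matrix(~ condition + factor(batch))
  sf <- if (is.null(size_factors)) estimate_size_factors(counts)
        else size_factors
  alpha <- fit_dispersions(counts, design, sf, prior_df)
  off <- log(sf)
  n <- nrow(counts)
  lfc <- se <- p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    y <- counts[i, ]
    if (all(y == 0)) next
    fam <- MASS::negative.binomial(theta = 1 / alpha[i], link = "log")
    fit <- suppressWarnings(
      stats::glm.fit(design, y, family = fam, offset = off))
    cf <- fit$coefficients[2L]
    # expected-information covariance of the coefficients
    w <- fit$weights
    xtx <- crossprod(design * sqrt(w))
    v <- tryCatch(solve(xtx)[2L, 2L], error = function(e) NA_real_)
    if (!is.finite(v) || v <= 0) next
    lfc[i] <- cf / log(2)
    se[i] <- sqrt(v) / log(2)
    p[i] <- 2 * stats::pnorm(-abs(cf / sqrt(v)))
  }
  fdr <- rep(NA_real_, n)
  ok <- !is.na(p)
  fdr[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(feature_id = rownames(counts),
             baseMean = rowMeans(sweep(counts, 2, sf, "/")),
             LFC = lfc, SE = se, stat = lfc / se, p = p, FDR = fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call dendrite-present and dendrite-enriched mRNAs
#'
#' A gene is dendrite-present when neuropil TRAP is significantly enriched
#' over neuropil RNA-seq (FDR < `fdr_cutoff` and LFC > 0) and enriched in
#' Cre-positive over Cre-negative TRAP (LFC > 0); it is dendrite-enriched
#' when, in addition, neuropil TRAP is significantly enriched over cell-body
#' TRAP (FDR < `fdr_cutoff` and LFC > 0). Genes missing from any input table
#' are classed `neither`.
#'
#' @param trap_vs_rna,cre_pos_vs_neg,np_vs_cb [nb_wald_test()] results for
#'   the three contrasts (neuropil TRAP vs neuropil RNA-seq, Cre+ vs Cre-
#'   neuropil TRAP, neuropil vs cell-body TRAP).
#' @param fdr_cutoff FDR threshold (default 0.05).
#' @return data.frame `gene_id`, `class` in
#'   {`dendrite-enriched`, `dendrite-present`, `neither`}.
#' @export
call_localization <- function(trap_vs_rna, cre_pos_vs_neg, np_vs_cb,
                              fdr_cutoff = 0.05) {
  universe <- unique(c(trap_vs_rna$feature_id, cre_pos_vs_neg$feature_id,
                       np_vs_cb$feature_id))
  idx <- function(res) match(universe, res$feature_id)
  a <- trap_vs_rna[idx(trap_vs_rna), ]
  b <- cre_pos_vs_neg[idx(cre_pos_vs_neg), ]
  c_ <- np_vs_cb[idx(np_vs_cb), ]
  present <- !is.na(a$FDR) & a$FDR < fdr_cutoff & a$LFC > 0 &
    !is.na(b$LFC) & b$LFC > 0
  enriched <- present & !is.na(c_$FDR) & c_$FDR < fdr_cutoff & c_$LFC > 0
  present[is.na(present)] <- FALSE
  enriched[is.na(enriched)] <- FALSE
  data.frame(gene_id = universe,
             class = ifelse(enriched, "dendrite-enriched",
                     ifelse(present, "dendrite-present", "neither")),
             stringsAsFactors = FALSE)
}

#' Dendritic localization metric
#'
#' Returns, per gene, the dendritic localization defined as the log2 fold
#' change of neuropil over cell-body TRAP, together with the Wald statistic
#' LFC/SE used for ranking and plotting.
#'
#' @param np_vs_cb an [nb_wald_test()] result for neuropil vs cell-body TRAP.
#' @return data.frame `gene_id`, `LFC`, `stat`.
#' @export
dendritic_localization_metric <- function(np_vs_cb) {
  data.frame(gene_id = np_vs_cb$feature_id, LFC = np_vs_cb$LFC,
             stat = np_vs_cb$stat, stringsAsFactors = FALSE)
}

bb_negloglik <- function(par, X, k, n) {
  beta <- par[-length(par)]
  rho <- stats::plogis(par[length(par)])
  rho <- min(max(rho, 1e-8), 1 - 1e-8)
  p <- stats::plogis(drop(X %*% beta))
  p <- pmin(pmax(p, 1e-8), 1 - 1e-8)
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  -sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

fit_bb <- function(X, k, n) {
  p0 <- min(max(sum(k) / sum(n), 1e-3), 1 - 1e-3)
  init <- c(stats::qlogis(p0), rep(0, ncol(X) - 1L), stats::qlogis(0.01))
  fit <- suppressWarnings(
    stats::optim(init, bb_negloglik, X = X, k = k, n = n,
                 method = "BFGS", control = list(maxit = 200)))
  fit
}

#' Beta-binomial test of differential 3'UTR isoform usage
#'
#' For each isoform of each multi-isoform gene, tests whether the isoform's
#' usage proportion (isoform counts over gene totals) differs between
#' conditions using a beta-binomial likelihood-ratio test with a
#' logit-linear mean model and a shared overdispersion parameter. With a
#' covariate supplied (e.g. genotype alongside region), both models include
#' the additive terms and the test is on the condition x covariate
#' interaction. The reported LFC is the log2 ratio of fitted usage between
#' condition levels; `stat` is the signed root of the LRT statistic so that
#' `stat * SE = LFC`. Samples with zero gene totals are dropped per gene;
#' BH FDR is computed across all tested isoforms.
#'
#' @param iso_counts isoform x sample count matrix.
#' @param gene_ids gene of each isoform row.
#' @param condition two-level factor over samples.
#' @param covariate optional second factor; switches the test to the
#'   interaction term.
#' @return data.frame `feature_id`, `gene_id`, `LFC`, `SE`, `stat`, `p`,
#'   `FDR`.
#' @export
diff_utr_usage <- function(iso_counts, gene_ids, condition,
                           covariate = NULL) {
  iso_counts <- as.matrix(iso_counts)
  condition <- factor(condition)
  stopifnot(length(gene_ids) == nrow(iso_counts),
            length(condition) == ncol(iso_counts),
            nlevels(condition) == 2L)
  rows_by_gene <- split(seq_len(nrow(iso_counts)), gene_ids)
  rows_by_gene <- rows_by_gene[vapply(rows_by_gene, length, 1L) >= 2L]
  res <- list()
  for (g in names(rows_by_gene)) {
    rows <- rows_by_gene[[g]]
    tot <- colSums(iso_counts[rows, , drop = FALSE])
    use <- tot > 0
    if (sum(use) < 4L) next
    cond_u <- droplevels(condition[use])
    if (nlevels(cond_u) < 2L) next
    if (is.null(covariate)) {
      X1 <- stats::model.matrix(~cond_u)
      X0 <- X1[, 1L, drop = FALSE]
    } else {
      cov_u <- droplevels(factor(covariate[use]))
      X1 <- stats::model.matrix(~ cond_u * cov_u)
      X0 <- stats::model.matrix(~ cond_u + cov_u)
    }
    for (r in rows) {
      k <- iso_counts[r, use]
      n <- tot[use]
      f1 <- fit_bb(X1, k, n)
      f0 <- fit_bb(X0, k, n)
      lrt <- max(0, 2 * (f0$value - f1$value))
      df <- ncol(X1) - ncol(X0)
      pval <- stats::pchisq(lrt, df = df, lower.tail = FALSE)
      # fitted usage in the two condition levels (reference covariate level)
      bx <- f1$par[-length(f1$par)]
      x_a <- x_b <- rep(0, ncol(X1)); x_a[1] <- x_b[1] <- 1
      ci <- grep("^cond_u", colnames(X1))[1L]
      x_b[ci] <- 1
      p_a <- stats::plogis(sum(x_a * bx))
      p_b <- stats::plogis(sum(x_b * bx))
      lfc <- log2(p_b / p_a)
      stat <- sign(lfc) * sqrt(lrt)
      res[[length(res) + 1L]] <- data.frame(
        feature_id = rownames(iso_counts)[r], gene_id = g,
        LFC = lfc, SE = if (stat != 0) lfc / stat else NA_real_,
        stat = stat, p = pval, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L)
    return(data.frame(feature_id = character(), gene_id = character(),
                      LFC = numeric(), SE = numeric(), stat = numeric(),
                      p = numeric(), FDR = numeric()))
  out <- do.call(rbind, res)
  out$FDR <- stats::p.adjust(out$p, method = "BH")
  out
}
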