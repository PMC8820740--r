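#' Normalize CLIP tag counts
#'
#' Converts per-replicate CLIP tag counts into (i) CLIP expression values,
#' normalized first for transcript length (kb) and then for sequencing depth
#' scaled to 10,000 tags, and (ii) library-normalized tags-per-10,000 with no
#' length term (the quantity the reproducibility rule uses). Replicates with
#' zero library total are excluded with a message.
#'
#' @param tags long data.frame with `gene_id`, `compartment`, `replicate`,
#'   `tags`.
#' @param lengths named numeric vector of transcript lengths in nt (the
#'   gene's most highly expressed transcript).
#' @return list with `expr` and `tags_per_10k`, each a long data.frame with
#'   `gene_id`, `compartment`, `replicate`, `value`.
#' @export
normalize_clip <- function(tags, lengths) {
  stopifnot(all(c("gene_id", "compartment", "replicate", "tags") %in%
                  names(tags)))
  miss <- setdiff(unique(tags$gene_id), names(lengths))
  if (length(miss) > 0L)
    stop("missing transcript length for ", miss[1L], call. = FALSE)
  key <- interaction(tags$compartment, tags$replicate, drop = TRUE)
  lib <- tapply(tags$tags, key, sum)
  zero <- names(lib)[lib == 0]
  if (length(zero) > 0L) {
    message("excluding zero-total replicate(s): ",
            paste(zero, collapse = ", "))
    tags <- tags[!(key %in% zero), , drop = FALSE]
    key <- droplevels(key[!(key %in% zero)])
  }
  lib_tot <- as.numeric(lib[key])
  len_kb <- as.numeric(lengths[tags$gene_id]) / 1000
  t10k <- tags$tags * 1e4 / lib_tot
  expr <- (tags$tags / len_kb) * (1e4 / lib_tot)
  base <- tags[c("gene_id", "compartment", "replicate")]
  list(expr = cbind(base, value = expr),
       tags_per_10k = cbind(base, value = t10k))
}

#' Flag reproducibly detected genes
#'
#' A gene is reproducibly detected in a compartment when its
#' tags-per-10,000 exceed `threshold` (strictly) in at least `k` of the
#' compartment's replicates (default: > 5 in at least 3 of 5).
#'
#' @param tags_per_10k long table from [normalize_clip()].
#' @param compartment compartment to evaluate.
#' @param threshold tags-per-10,000 cutoff (strict inequality).
#' @param k minimum number of qualifying replicates.
#' @return named logical vector over genes.
#' @export
detect_reproducible <- function(tags_per_10k, compartment = "NP",
                                threshold = 5, k = 3L) {
  t10 <- tags_per_10k[tags_per_10k$compartment == compartment, ]
  n_rep <- length(unique(t10$replicate))
  if (n_rep < k)
    stop("only ", n_rep, " replicates but k = ", k, call. = FALSE)
  hits <- tapply(t10$value > threshold, t10$gene_id, sum)
  out <- as.vector(hits >= k)
  names(out) <- names(hits)
  out
}

#' Fit the CLIP-expression vs TRAP-abundance model and score genes
#'
#' For one replicate of one compartment, fits an ordinary least-squares line
#' of log10 CLIP expression on log10 TRAP TPM over the fit universe (genes
#' with TPM > 1 and CLIP tags in at least `min_rep_detect` replicates of
#' that compartment) and scores every gene with positive CLIP expression as
#' the log10 residual, observed minus fitted.
#'
#' @param expr long CLIP-expression table from [normalize_clip()].
#' @param tpm named numeric vector of TRAP TPM for the compartment.
#' @param compartment,replicate which replicate to fit.
#' @param min_tpm TPM cutoff defining the fit universe.
#' @param min_rep_detect replicate-detection cutoff for the fit universe.
#' @return list with `scores` (named numeric over scoreable genes),
#'   `intercept`, `slope`, `n_fit`.
#' @export
fit_clip_trap_model <- function(expr, tpm, compartment, replicate,
                                min_tpm = 1, min_rep_detect = 3L) {
  ec <- expr[expr$compartment == compartment, ]
  det <- tapply(ec$value > 0, ec$gene_id, sum)
  er <- ec[ec$replicate == replicate, ]
  x <- as.numeric(tpm[er$gene_id])
  universe <- !is.na(x) & x > min_tpm & er$value > 0 &
    as.numeric(det[er$gene_id]) >= min_rep_detect
  if (sum(universe) < 10L)
    stop("fewer than 10 genes in fit universe; fit refused", call. = FALSE)
  fit <- stats::lm(log10(er$value[universe]) ~ log10(x[universe]))
  b <- stats::coef(fit)
  scoreable <- er$value > 0 & !is.na(x) & x > 0
  scores <- log10(er$value[scoreable]) -
    (b[1] + b[2] * log10(x[scoreable]))
  names(scores) <- er$gene_id[scoreable]
  list(scores = scores, intercept = unname(b[1]), slope = unname(b[2]),
       n_fit = sum(universe))
}

#' Mean CLIP score across replicates
#'
#' Arithmetic mean of per-replicate residual CLIP scores over replicates in
#' which the gene was scored (NA scores excluded); genes with no defined
#' score return NA.
#'
#' @param score_list list of named per-replicate score vectors.
#' @return data.frame `gene_id`, `mean_score`, `n_replicates`.
#' @export
mean_clip_score <- function(score_list) {
  all_genes <- unique(unlist(lapply(score_list, names)))
  m <- sapply(score_list, function(s) s[all_genes])
  m <- matrix(m, nrow = length(all_genes))
  data.frame(gene_id = all_genes,
             mean_score = rowMeans(m, na.rm = TRUE),
             n_replicates = rowSums(!is.na(m)),
             stringsAsFactors = FALSE)
}

#' Compute compartment CLIP scores end to end
#'
#' Runs [normalize_clip()], fits the per-replicate CLIP-vs-TRAP models for
#' one compartment, and aggregates mean CLIP scores and reproducibility
#' flags.
#'
#' @param tags long CLIP tag table (`gene_id`, `compartment`, `replicate`,
#'   `tags`).
#' @param tpm named TPM vector for the compartment.
#' @param lengths named transcript lengths (nt).
#' @param compartment compartment to score.
#' @inheritParams fit_clip_trap_model
#' @inheritParams detect_reproducible
#' @return data.frame `gene_id`, `mean_score`, `n_replicates`,
#'   `reproducible`.
#' @export
clip_score_table <- function(tags, tpm, lengths, compartment = "NP",
                             min_tpm = 1, min_rep_detect = 3L,
                             threshold = 5, k = 3L) {
  nrm <- normalize_clip(tags, lengths)
  reps <- sort(unique(tags$replicate[tags$compartment == compartment]))
  scores <- lapply(reps, function(r)
    fit_clip_trap_model(nrm$expr, tpm, compartment, r,
                        min_tpm = min_tpm,
                        min_rep_detect = min_rep_detect)$scores)
  ms <- mean_clip_score(scores)
  rep_flag <- detect_reproducible(nrm$tags_per_10k, compartment,
                                  threshold = threshold, k = k)
  ms$reproducible <- as.logical(rep_flag[ms$gene_id])
  ms$reproducible[is.na(ms$reproducible)] <- FALSE
  # genes flagged reproducible but never scored still belong in the table
  extra <- setdiff(names(rep_flag)[rep_flag], ms$gene_id)
  if (length(extra) > 0L)
    ms <- rbind(ms, data.frame(gene_id = extra, mean_score = NA_real_,
                               n_replicates = 0L, reproducible = TRUE))
  ms
}

#' Call dendritic FMRP targets by the two-rule criterion
#'
#' A gene is a dendritic FMRP target if it is reproducibly detected in the
#' neuropil (rule A) or its mean neuropil CLIP score exceeds 1 (rule B,
#' strict). Per-rule provenance is reported alongside the union.
#'
#' @param score_table output of [clip_score_table()] for the neuropil.
#' @param score_cutoff rule-B threshold on the mean CLIP score.
#' @return data.frame `gene_id`, `rule_a`, `rule_b`, `target`.
#' @export
call_dendritic_targets <- function(score_table, score_cutoff = 1) {
  rule_a <- score_table$reproducible
  rule_b <- !is.na(score_table$mean_score) &
    score_table$mean_score > score_cutoff
  data.frame(gene_id = score_table$gene_id,
             rule_a = rule_a, rule_b = rule_b,
             target = rule_a | rule_b, stringsAsFactors = FALSE)
}

round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summarize overlaps between gene sets
#'
#' Pairwise overlap counts and percentages (|A intersect B| / |A|, rounded
#' half-up to one decimal), with a chi-squared test of whether membership in
#' B among A differs from the universe proportion.
#'
#' @param sets named list of character vectors.
#' @param universe character vector containing every set member.
#' @return data.frame with one row per ordered pair: `set_a`, `set_b`,
#'   `n_a`, `n_overlap`, `percent`, `chisq_p`.
#' @export
set_summary <- function(sets, universe = unique(unlist(sets))) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  combos <- expand.grid(a = names(sets), b = names(sets),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$a != combos$b, ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    A <- sets[[combos$a[i]]]; B <- sets[[combos$b[i]]]
    n_ov <- length(intersect(A, B))
    pct <- if (length(A) == 0L) NA_real_
           else round_half_up(100 * n_ov / length(A), 1)
    p <- NA_real_
    if (length(A) > 0L && length(B) > 0L) {
      in_b_univ <- sum(universe %in% B)
      tab <- rbind(c(n_ov, length(A) - n_ov),
                   c(in_b_univ, length(universe) - in_b_univ))
      p <- tryCatch(
        suppressWarnings(stats::chisq.test(tab)$p.value),
        error = function(e) NA_real_)
    }
    data.frame(set_a = combos$a[i], set_b = combos$b[i],
               n_a = length(A), n_overlap = n_ov, percent = pct,
               chisq_p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Overlap percentage of two counts
#'
#' Convenience: 100 * n_overlap / n_set rounded half-up to one decimal, the
#' form in which set overlaps are reported.
#'
#' @param n_overlap,n_set counts.
#' @return percentage rounded half-up to one decimal.
#' @export
overlap_percent <- function(n_overlap, n_set) {
  if (n_set == 0) return(NA_real_)
  round_half_up(100 * n_overlap / n_set, 1)
}
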