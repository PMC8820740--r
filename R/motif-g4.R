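G4_PATTERN <- "[AU]GGA(.{0,6})[AU]GGA(.{0,6})[AU]GGA(.{0,6})[AU]GGA"

to_rna <- function(sequence, what = "sequence") {
  s <- toupper(sequence)
  s <- chartr("T", "U", s)
  bad <- regexpr("[^ACGU]", s)
  if (bad > 0)
    stop("non-nucleotide character in ", what, " at position ", bad,
         call. = FALSE)
  s
}

#' Scan a 3'UTR sequence for G-quadruplex motifs
#'
#' Searches the G-quadruplex motif pattern
#' `[AU]GGA(.{0,6})[AU]GGA(.{0,6})[AU]GGA(.{0,6})[AU]GGA` (four AGGA/UGGA
#' units separated by gaps of up to six nucleotides) in an RNA sequence.
#' DNA input is mapped T to U first. The default reports leftmost
#' non-overlapping greedy matches; `overlap = TRUE` reports one match per
#' admissible start position.
#'
#' @param sequence a single character string over A/C/G/U (or T).
#' @param overlap report overlapping matches.
#' @return data.frame `start`, `end` (1-based inclusive offsets), `match`;
#'   attribute `has_motif` gives per-sequence presence.
#' @export
find_g4_motifs <- function(sequence, overlap = FALSE) {
  stopifnot(length(sequence) == 1L)
  s <- to_rna(sequence)
  if (!overlap) {
    m <- gregexpr(G4_PATTERN, s)[[1L]]
    if (m[1L] == -1L) {
      out <- data.frame(start = integer(), end = integer(),
                        match = character())
    } else {
      len <- attr(m, "match.length")
      out <- data.frame(start = as.integer(m),
                        end = as.integer(m) + len - 1L,
                        match = substring(s, m, m + len - 1L),
                        stringsAsFactors = FALSE)
    }
  } else {
    starts <- ends <- integer(0)
    for (i in seq_len(nchar(s))) {
      m <- regexpr(G4_PATTERN, substring(s, i))
      if (m == 1L) {
        starts <- c(starts, i)
        ends <- c(ends, i + attr(m, "match.length") - 1L)
      }
    }
    out <- data.frame(start = starts, end = ends,
                      match = substring(s, starts, ends),
                      stringsAsFactors = FALSE)
  }
  attr(out, "has_motif") <- nrow(out) > 0L
  out
}

#' G-quadruplex motif presence across sequences
#'
#' @param sequences named character vector of UTR sequences.
#' @return data.frame `seq_id`, `n_hits`, `has_motif`.
#' @export
scan_g4 <- function(sequences) {
  hits <- vapply(sequences, function(s) nrow(find_g4_motifs(s)), integer(1))
  data.frame(seq_id = names(sequences) %||% as.character(seq_along(hits)),
             n_hits = hits, has_motif = hits > 0L,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Match experimentally defined G-quadruplex sequences
#'
#' Flags each UTR that contains any of the supplied G-quadruplex sequences
#' as an exact substring (both sides mapped T to U).
#'
#' @param utr_sequences named character vector of 3'UTR sequences.
#' @param g4_sequences character vector of experimentally determined G4
#'   sequences.
#' @return named logical vector over UTRs.
#' @export
match_experimental_g4 <- function(utr_sequences, g4_sequences) {
  if (length(g4_sequences) == 0L)
    stop("empty G-quadruplex sequence set", call. = FALSE)
  g4 <- vapply(g4_sequences, to_rna, character(1), what = "G4 sequence")
  vapply(utr_sequences, function(u) {
    if (nchar(u) == 0L) return(FALSE)
    s <- to_rna(u)
    any(vapply(g4, function(q) grepl(q, s, fixed = TRUE), logical(1)))
  }, logical(1))
}

#' Test G-quadruplex enrichment between gene sets
#'
#' Fisher's exact test (two-sided) on the 2x2 table of target/nontarget
#' versus motif presence.
#'
#' @param targets,nontargets disjoint character vectors of gene ids.
#' @param has_motif named logical vector covering both sets.
#' @return list `table`, `odds_ratio`, `p` (NA with a warning on an empty
#'   margin).
#' @export
test_g4_enrichment <- function(targets, nontargets, has_motif) {
  stopifnot(length(intersect(targets, nontargets)) == 0L)
  if (anyNA(has_motif[c(targets, nontargets)]))
    stop("has_motif flags missing for some genes", call. = FALSE)
  tab <- rbind(
    target = c(motif = sum(has_motif[targets]),
               no_motif = sum(!has_motif[targets])),
    nontarget = c(motif = sum(has_motif[nontargets]),
                  no_motif = sum(!has_motif[nontargets])))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    warning("degenerate 2x2 margin; enrichment test undefined")
    return(list(table = tab, odds_ratio = NA_real_, p = NA_real_))
  }
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}
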