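make_models <- function(genes, exons) list(genes = genes, exons = exons)

test_that("polyA-site filter applies the tag-count AND fraction rules", {
  sites <- data.frame(gene_id = c("a", "a", "b", "b"),
                      pos = c(100, 200, 100, 300),
                      tags = c(12, 88, 12, 988))
  kept <- filter_polya_sites(sites, "whole-cell")
  # 12/100 = 12% kept; 12/1000 = 1.2% fails the fraction rule
  expect_true(any(kept$gene_id == "a" & kept$pos == 100))
  expect_false(any(kept$gene_id == "b" & kept$pos == 100))

  comp <- cbind(sites, rep_support = c(1, 2, 3, 1))
  keptc <- filter_polya_sites(comp, "compartment")
  expect_setequal(paste(keptc$gene_id, keptc$pos), c("a 200", "b 100"))
  expect_error(filter_polya_sites(sites, "nope"))
})

test_that("junction filter uses OR semantics of reads and fraction", {
  jx <- data.frame(gene_id = c("a", "a", "b", "b"),
                   donor = c(1, 50, 1, 50), acceptor = c(10, 60, 10, 60),
                   reads = c(10, 990, 1, 7))
  kept <- filter_junctions(jx)
  expect_true(any(kept$gene_id == "a" & kept$reads == 10))   # count rule
  expect_true(any(kept$gene_id == "b" & kept$reads == 1))    # 12.5% rule
  expect_error(filter_junctions(transform(jx, reads = c(-1, 1, 1, 1))),
               "negative")
})

test_that("random filter inputs match the brute-force oracles exactly", {
  set.seed(21)
  sites <- data.frame(
    gene_id = sample(paste0("g", 1:40), 500, replace = TRUE),
    pos = sample.int(1e6, 500),
    tags = rnbinom(500, mu = 30, size = 0.5))
  kept <- filter_polya_sites(sites, "whole-cell")
  oracle <- sites[bf_filter_polya(sites), ]
  expect_setequal(paste(kept$gene_id, kept$pos),
                  paste(oracle$gene_id, oracle$pos))

  jx <- data.frame(
    gene_id = sample(paste0("g", 1:40), 500, replace = TRUE),
    donor = sample.int(1e6, 500), acceptor = sample.int(1e6, 500),
    reads = rnbinom(500, mu = 15, size = 0.5))
  keptj <- filter_junctions(jx)
  oj <- jx[bf_filter_junctions(jx), ]
  expect_setequal(paste(keptj$gene_id, keptj$donor, keptj$acceptor),
                  paste(oj$gene_id, oj$donor, oj$acceptor))
})

test_that("boundary pairing follows the nearest-upstream rule per strand", {
  genes <- data.frame(gene_id = "g", chrom = "c", strand = "+",
                      start = 0, end = 2000, stop_codon = 950)
  exons <- data.frame(gene_id = "g", exon_rank = 1:2,
                      start = c(0, 900), end = c(100, 2000))
  mod <- make_models(genes, exons)
  sites <- data.frame(gene_id = "g", pos = 1500, tags = 50)
  jx <- data.frame(gene_id = "g", donor = 100, acceptor = 1000, reads = 20)
  utr <- pair_boundaries(sites, jx, mod)
  expect_equal(utr$start, 1000)
  expect_equal(utr$end, 1500)

  # two junctions upstream: only the nearest acceptor pairs
  jx2 <- rbind(jx, data.frame(gene_id = "g", donor = 100, acceptor = 1200,
                              reads = 20))
  utr2 <- pair_boundaries(sites, jx2, mod)
  expect_true(all(utr2$utr5[utr2$polya == 1500] == 1200))

  # no junction upstream: fall back to the stop-codon exon start
  utr3 <- pair_boundaries(sites, jx[0, ], mod)
  expect_equal(utr3$utr5, 900)
  expect_true(utr3$fallback)
})

test_that("random pairings equal the exhaustive nearest-neighbour oracle", {
  set.seed(22)
  for (strand in c("+", "-")) {
    plus <- strand == "+"
    genes <- data.frame(gene_id = "g", chrom = "c", strand = strand,
                        start = 0, end = 1e5, stop_codon = 5e4)
    exons <- data.frame(gene_id = "g", exon_rank = 1:2,
                        start = c(0, 45000), end = c(100, 1e5))
    mod <- make_models(genes, exons)
    for (rep in 1:20) {
      sites <- data.frame(gene_id = "g",
                          pos = sample.int(1e5, 8), tags = 50)
      jx <- data.frame(gene_id = "g", donor = sample.int(1e5, 6),
                       acceptor = sample.int(1e5, 6),
                       reads = sample(10:40, 6, replace = TRUE))
      jx <- jx[jx$donor != jx$acceptor, ]
      utr <- pair_boundaries(sites, jx, mod)
      for (p in sites$pos) {
        expected <- bf_pair_upstream(p, jx$acceptor, jx$reads, plus)
        got <- utr$utr5[utr$polya == p & !utr$fallback]
        if (is.na(expected)) {
          expect_length(got, 0)
        } else {
          expect_true(expected %in% got)
        }
      }
    }
  }
})

test_that("coverage filter is inclusive at 80% and matches base counting", {
  utrs <- data.frame(gene_id = "g", chrom = "c", strand = "+",
                     utr5 = 0, polya = 100, start = 0, end = 100,
                     fallback = FALSE)
  cov80 <- list(e1 = data.frame(chrom = "c", start = 0, end = 80))
  expect_equal(nrow(coverage_filter(utrs, cov80)), 1)   # exactly 80% kept
  cov79 <- list(e1 = data.frame(chrom = "c", start = 0, end = 79))
  expect_equal(nrow(coverage_filter(utrs, cov79)), 0)
  covfull <- list(e1 = data.frame(chrom = "c", start = 0, end = 100))
  expect_equal(coverage_filter(utrs, covfull)$max_covered_frac, 1)

  set.seed(23)
  for (rep in 1:10) {
    u <- data.frame(gene_id = "g", chrom = "c", strand = "+",
                    utr5 = 0, polya = 200, start = 0, end = 200,
                    fallback = FALSE)
    iv_start <- sort(sample.int(200, 4)) - 1
    cov <- data.frame(chrom = "c", start = iv_start,
                      end = pmin(iv_start + sample.int(60, 4), 200))
    got <- coverage_filter(u, list(e = cov), min_cov = 0)
    expect_equal(got$max_covered_frac,
                 bf_covered_fraction(0, 200, cov), tolerance = 1e-12)
  }

  # per-base mode rejects short arrays
  expect_error(
    coverage_filter(utrs, list(e1 = list(rep(1, 50)))), "shorter")
})

test_that("ambiguity removal drops overlapping genes and UTRs", {
  genes <- data.frame(gene_id = c("a", "b"), chrom = "c",
                      strand = c("+", "+"), start = c(0, 5000),
                      end = c(2000, 8000), stop_codon = c(500, 5500))
  utrs <- data.frame(gene_id = c("a", "a"), chrom = "c", strand = "+",
                     utr5 = c(600, 600), polya = c(1500, 6000),
                     start = c(600, 600), end = c(1500, 6000),
                     fallback = FALSE)
  kept <- remove_ambiguous(utrs, list(genes = genes))
  expect_equal(nrow(kept), 1)           # the UTR reaching into gene b drops
  expect_equal(kept$end, 1500)

  # overlapping same-strand genes are ambiguous: all their UTRs drop
  genes2 <- transform(genes, start = c(0, 1500))
  expect_equal(nrow(remove_ambiguous(utrs, list(genes = genes2))), 0)

  # quadratic oracle on random intervals
  set.seed(24)
  for (rep in 1:10) {
    g <- data.frame(gene_id = paste0("g", 1:6), chrom = "c",
                    strand = sample(c("+", "-"), 6, replace = TRUE),
                    start = sample.int(1e4, 6))
    g$end <- g$start + sample(500:3000, 6)
    g$stop_codon <- g$start + 100
    u <- data.frame(gene_id = g$gene_id, chrom = "c", strand = g$strand,
                    utr5 = g$start + 200, polya = g$end,
                    start = g$start + 200, end = g$end, fallback = FALSE)
    kept <- remove_ambiguous(u, list(genes = g))
    for (i in seq_len(nrow(u))) {
      amb <- any(vapply(seq_len(nrow(g)), function(j)
        g$gene_id[j] != u$gene_id[i] && g$strand[j] == u$strand[i] &&
          bf_overlaps(g$start[g$gene_id == u$gene_id[i]],
                      g$end[g$gene_id == u$gene_id[i]],
                      g$start[j], g$end[j]), logical(1)))
      hit_gene <- any(vapply(seq_len(nrow(g)), function(j)
        g$gene_id[j] != u$gene_id[i] &&
          bf_overlaps(u$start[i], u$end[i], g$start[j], g$end[j]),
        logical(1)))
      hit_utr <- any(vapply(seq_len(nrow(u)), function(j)
        u$gene_id[j] != u$gene_id[i] &&
          bf_overlaps(u$start[i], u$end[i], u$start[j], u$end[j]),
        logical(1)))
      expect_equal(i %in% which(
        paste(kept$gene_id, kept$start) %in% paste(u$gene_id[i], u$start[i])
      ) || paste(u$gene_id[i], u$start[i]) %in%
        paste(kept$gene_id, kept$start),
        !(amb || hit_gene || hit_utr))
    }
  }
})

test_that("APA classification distinguishes tandem and upstream sites", {
  genes <- data.frame(gene_id = "g", chrom = "c", strand = "+",
                      start = 0, end = 5000, stop_codon = 2000)
  # two sites downstream of the stop codon: proximal and distal
  u2 <- data.frame(gene_id = "g", chrom = "c", strand = "+",
                   utr5 = c(1900, 1900), polya = c(2500, 5000),
                   start = c(1900, 1900), end = c(2500, 5000),
                   fallback = FALSE)
  cl <- classify_apa(u2, list(genes = genes))
  expect_equal(cl$genes$type, "3UTR-APA")
  expect_setequal(cl$sites$site_class, c("proximal", "distal"))
  expect_false(any(cl$sites$cds_altering))

  # intronic site upstream of the stop codon: UR-APA, CDS-altering
  u_ur <- data.frame(gene_id = "g", chrom = "c", strand = "+",
                     utr5 = c(500, 1900), polya = c(1200, 5000),
                     start = c(500, 1900), end = c(1200, 5000),
                     fallback = FALSE)
  cl2 <- classify_apa(u_ur, list(genes = genes))
  expect_equal(cl2$genes$type, "UR-APA")
  expect_true(cl2$sites$cds_altering[cl2$sites$polya == 1200])

  # three tandem sites: the middle one is internal
  u3 <- data.frame(gene_id = "g", chrom = "c", strand = "+",
                   utr5 = 1900, polya = c(2500, 3500, 5000),
                   start = 1900, end = c(2500, 3500, 5000),
                   fallback = FALSE)
  cl3 <- classify_apa(u3, list(genes = genes))
  expect_equal(cl3$sites$site_class[cl3$sites$polya == 3500], "internal")

  # single-isoform gene yields no events
  expect_equal(nrow(classify_apa(u3[1, ], list(genes = genes))$sites), 0)
})

test_that("strand reversal of the whole input mirrors the boundaries", {
  L <- 1e5
  genes <- data.frame(gene_id = "g", chrom = "c", strand = "+",
                      start = 1000, end = 9000, stop_codon = 5000)
  exons <- data.frame(gene_id = "g", exon_rank = 1:2,
                      start = c(1000, 4500), end = c(1500, 9000))
  sites <- data.frame(gene_id = "g", pos = c(7000, 9000), tags = 50)
  jx <- data.frame(gene_id = "g", donor = 1500, acceptor = 4500,
                   reads = 30)
  fwd <- pair_boundaries(sites, jx, make_models(genes, exons))

  mirror <- function(x) L - x
  genes_m <- transform(genes, strand = "-", start = mirror(end),
                       end = mirror(start),
                       stop_codon = mirror(stop_codon) - 3)
  exons_m <- transform(exons, start = mirror(end), end = mirror(start))
  sites_m <- transform(sites, pos = mirror(pos))
  jx_m <- transform(jx, donor = mirror(donor), acceptor = mirror(acceptor))
  rev <- pair_boundaries(sites_m, jx_m, make_models(genes_m, exons_m))
  expect_setequal(paste(mirror(rev$end), mirror(rev$start)),
                  paste(fwd$start, fwd$end))
})

test_that("retained candidates pass every filter when re-checked", {
  cfg <- sim_config(n_genes = 100, seed = 31)
  m <- gen_gene_models(cfg)
  cnt <- gen_count_data(m, cfg)
  disc <- discover_utrs(cnt$polya_wc, cnt$junction_reads, cnt$coverage, m)
  u <- disc$utrs
  # re-apply the coverage and ambiguity filters: nothing further drops
  expect_equal(nrow(coverage_filter(u, cnt$coverage)), nrow(u))
  expect_equal(nrow(remove_ambiguous(u, m)), nrow(u))
  # and the sites feeding each retained candidate passed the site filter
  kept_sites <- filter_polya_sites(cnt$polya_wc, "whole-cell")
  expect_true(all(paste(u$gene_id, u$polya) %in%
                    paste(kept_sites$gene_id, kept_sites$pos)))
})
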