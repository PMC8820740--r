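#' Read and write the pipeline's tabular formats
#'
#' Thin wrappers fixing the dialect used throughout: tab-separated, header,
#' no quoting, no row names.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv_file` returns a data.frame.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_file
#' @export
read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write gene models as GTF
#'
#' Exports the synthetic gene models (gene and exon features) as GTF via
#' rtracklayer.
#'
#' @param models a `sim_models` object.
#' @param path output path.
#' @export
write_gene_models_gtf <- function(models, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to write GTF", call. = FALSE)
  ex <- models$exons
  st <- models$genes$strand[match(ex$gene_id, models$genes$gene_id)]
  gr <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(ex$start + 1L, ex$end), strand = st,
    type = "exon", gene_id = ex$gene_id,
    transcript_id = paste0(ex$gene_id, ".t1"))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write polyA sites or CLIP tags as BED6
#'
#' @param sites data.frame with `chrom`, `pos` (0-based cleavage point),
#'   `gene_id`, `tags`, `strand`.
#' @param path output path.
#' @export
write_polya_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$chrom, start = sites$pos,
                    end = sites$pos + 1L, name = sites$gene_id,
                    score = sites$tags, strand = sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read 3'UTR sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_utr_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @export
write_utr_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(sequences), path)
  invisible(path)
}
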