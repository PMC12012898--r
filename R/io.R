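#' File format readers and writers
#'
#' Thin wrappers around Biostrings and rtracklayer plus small writers for
#' tabular formats. Conventions: FASTA/FASTQ via Biostrings; GFF3 and BED via
#' rtracklayer (GFF3 1-based inclusive on disk, BED 0-based half-open);
#' internal gene/feature coordinates are 0-based half-open throughout the
#' package. TSVs carry a single header row.
#'
#' @param x Named character vector of sequences (names become record ids).
#' @param path File path.
#' @name formats
NULL

#' @rdname formats
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' @rdname formats
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname formats
#' @param quality Constant quality character written for every base.
#' @export
write_fastq <- function(x, path, quality = "I") {
  seqs <- Biostrings::DNAStringSet(x)
  quals <- Biostrings::BStringSet(strrep(quality, nchar(x)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' @rdname formats
#' @export
read_fastq <- function(path) {
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines %% 4L != 0L)
    stop("malformed FASTQ in '", path, "': truncated record at line ",
         (n_lines %/% 4L) * 4L + 1L)
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  list(reads = setNames(as.character(x), sub(" .*", "", names(x))),
       qualities = as.character(Biostrings::quality(x)))
}

#' @rdname formats
#' @param genes Gene-model data.frame with 0-based half-open \code{start},
#'   \code{end} plus \code{gene_id}, \code{seqid}, \code{strand}.
#' @export
write_gff3 <- function(genes, path) {
  if (nrow(genes) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$seqid,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname formats
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    return(data.frame(gene_id = character(), seqid = character(),
                      start = integer(), end = integer(),
                      strand = character(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(gene_id = as.character(S4Vectors::mcols(gr)$ID),
                   seqid = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # to 0-based
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$seqid, df$start), , drop = FALSE]
  df$rank <- stats::ave(seq_len(nrow(df)), df$seqid, FUN = seq_along)
  rownames(df) <- NULL
  df
}

#' @rdname formats
#' @param df Data frame to serialize.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname formats
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname formats
#' @param regions Telomere/feature data.frame with \code{seqid},
#'   0-based half-open \code{start}, \code{end}, \code{name}, \code{score},
#'   \code{strand}.
#' @export
write_bed6 <- function(regions, path) {
  bed <- regions[, c("seqid", "start", "end", "name", "score", "strand")]
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write diagnostic SNPs as a minimal VCF
#'
#' Four mandatory columns plus an INFO tag recording the parental origin of
#' REF/ALT (REF = maternal allele, ALT = paternal allele).
#' @param snps A diagnostic-SNP data.frame from [call_diagnostic_snps()].
#' @param path File path.
#' @export
write_vcf_minimal <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=PO,Number=1,Type=String,Description=\"Parental origin of REF/ALT: maternal/paternal\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snps)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tPO=maternal/paternal",
                       snps$seqid, snps$pos, snps$maternal, snps$paternal),
               con)
  }
  invisible(path)
}

#' Coordinate conversions between external 1-based inclusive and internal
#' 0-based half-open intervals
#'
#' @param start,end Interval bounds in the source convention.
#' @return A list with converted \code{start} and \code{end}.
#' @export
to_internal_coords <- function(start, end) list(start = start - 1L, end = end)

#' @rdname to_internal_coords
#' @export
to_external_coords <- function(start, end) list(start = start + 1L, end = end)
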