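# Plain-text I/O for the pipeline's standard formats: TSV matrices
# (features in rows, header row of sample ids), BED6+seq read sets, GFF3
# miRNA loci, FASTA UTRs, TSV/VCF genotypes.

#' Write a features-x-samples matrix as TSV
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a features-x-samples TSV matrix
#' @param path TSV with a `feature` id column and one column per sample.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write aligned reads as BED6 plus sequence (and sample) columns
#' @param reads read data frame (chrom, start, end, name, score, strand,
#'   seq, sample).
#' @param path output path.
#' @export
write_reads_bed <- function(reads, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand", "seq",
            "sample")
  cols <- intersect(cols, names(reads))
  utils::write.table(reads[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6+seq read set
#' @param path BED-like TSV without header: chrom, start, end, name, score,
#'   strand and optional seq, sample columns.
#' @return read data frame (0-based half-open coordinates).
#' @export
read_reads_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score", "strand",
                 "seq", "sample")[seq_len(ncol(df))]
  df
}

#' Write miRNA loci as GFF3
#'
#' One `miRNA` feature per locus; 0-based half-open input coordinates are
#' converted to GFF3's 1-based closed convention. The mature sequence, when
#' present, is stored in a `sequence` attribute.
#'
#' @param loci locus data frame (name, chrom, start, end, strand,
#'   optional mature_sequence).
#' @param path output path.
#' @export
write_loci_gff3 <- function(loci, path) {
  attr_col <- sprintf("ID=%s%s", loci$name,
                      if (!is.null(loci$mature_sequence))
                        sprintf(";sequence=%s", loci$mature_sequence)
                      else "")
  lines <- sprintf("%s\tmirmednet\tmiRNA\t%d\t%d\t.\t%s\t.\t%s",
                   loci$chrom, loci$start + 1L, loci$end, loci$strand,
                   attr_col)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read miRNA loci from GFF3
#'
#' Imports `miRNA`-type features via rtracklayer and converts to the
#' package's 0-based half-open locus table.
#'
#' @param path GFF3 file.
#' @return locus data frame (name, chrom, start, end, strand,
#'   mature_sequence when annotated).
#' @export
read_loci_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "miRNA"]
  df <- data.frame(
    name = if (!is.null(gr$ID)) gr$ID else as.character(seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  if (!is.null(gr$sequence)) df$mature_sequence <- gr$sequence
  df
}

#' Read a genotype matrix from TSV or VCF
#'
#' TSV: SNPs in rows (id column first), samples in columns, entries 0/1/2
#' (NA allowed). VCF: GT fields are converted to alternate-allele dosages
#' (requires the vcfR package).
#'
#' @param path input file (`.vcf` triggers VCF parsing).
#' @return integer matrix, SNPs x samples.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("VCF input requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v)
    dos <- apply(gt, c(1, 2), function(x) {
      if (is.na(x)) return(NA_integer_)
      sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0)
    })
    storage.mode(dos) <- "integer"
    return(dos)
  }
  m <- read_matrix_tsv(path)
  if (!all(m[!is.na(m)] %in% 0:2))
    stop("genotype entries must be 0, 1, 2 or NA")
  storage.mode(m) <- "integer"
  m
}

#' Read 3'UTR sequences from FASTA
#' @param path FASTA keyed by gene id.
#' @return named character vector of sequences.
#' @export
read_utrs_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a covariate/phenotype table as TSV
#' @param covariates data frame with a `sample` column.
#' @param path output path.
#' @export
write_covariates_tsv <- function(covariates, path) {
  utils::write.table(covariates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a covariate/phenotype table
#' @param path TSV with a `sample` column.
#' @return data frame.
#' @export
read_covariates_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
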