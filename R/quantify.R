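#' Construct a miRNA count matrix object
#'
#' Container for integer miRNA x sample counts together with the per-sample
#' total of locus-aligned reads (the RPM denominator) and a batch/protocol
#' label per sample.
#'
#' @param counts nonnegative integer matrix, miRNAs in rows.
#' @param sample_totals per-sample locus-aligned read totals; defaults to the
#'   column sums.
#' @param batch optional per-sample batch labels.
#' @return list of class `mirna_counts`.
#' @export
mirna_counts <- function(counts, sample_totals = NULL, batch = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(sample_totals)) sample_totals <- colSums(counts)
  if (length(sample_totals) != ncol(counts))
    stop("sample_totals must have one entry per sample")
  # NOTE: column sums may legitimately exceed sample_totals because a read
  # overlapping k loci increments all k while counting once in the total
  if (is.null(names(sample_totals))) names(sample_totals) <- colnames(counts)
  structure(list(counts = counts, sample_totals = sample_totals,
                 batch = batch), class = "mirna_counts")
}

#' @export
print.mirna_counts <- function(x, ...) {
  cat(sprintf("miRNA count matrix: %d miRNAs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("locus-aligned totals: %s .. %s\n",
              format(min(x$sample_totals)), format(max(x$sample_totals))))
  invisible(x)
}

.loci_granges <- function(loci) {
  if (any(loci$end <= loci$start))
    stop("malformed locus interval: end <= start")
  GenomicRanges::GRanges(loci$chrom,
                         IRanges::IRanges(loci$start + 1L, loci$end),
                         strand = loci$strand, name = loci$name)
}

.reads_granges <- function(reads) {
  if (any(reads$end <= reads$start))
    stop("malformed read interval: end <= start")
  GenomicRanges::GRanges(reads$chrom,
                         IRanges::IRanges(reads$start + 1L, reads$end),
                         strand = reads$strand)
}

#' Count reads per mature miRNA locus
#'
#' A read increments a locus when it overlaps it by at least one base on the
#' same strand; a read overlapping k loci increments all k. The per-sample
#' total records the number of reads assigned to at least one locus (the RPM
#' denominator).
#'
#' @param reads data frame of aligned reads (BED-style 0-based half-open:
#'   `chrom`, `start`, `end`, `strand`; optional `sample`).
#' @param loci data frame of mature miRNA loci (`name`, `chrom`, `start`,
#'   `end` 0-based half-open, `strand`).
#' @return a [mirna_counts()] object (loci x samples).
#' @export
count_reads_per_mirna <- function(reads, loci) {
  samples <- if (!is.null(reads$sample)) reads$sample
             else rep("sample_1", nrow(reads))
  sample_levels <- unique(samples)
  gr_loci <- .loci_granges(loci)
  counts <- matrix(0L, nrow(loci), length(sample_levels),
                   dimnames = list(loci$name, sample_levels))
  totals <- stats::setNames(integer(length(sample_levels)), sample_levels)
  if (nrow(reads) > 0) {
    gr_reads <- .reads_granges(reads)
    hits <- GenomicRanges::findOverlaps(gr_reads, gr_loci,
                                        ignore.strand = FALSE)
    if (length(hits) > 0) {
      tab <- table(factor(loci$name[S4Vectors::subjectHits(hits)],
                          levels = loci$name),
                   factor(samples[S4Vectors::queryHits(hits)],
                          levels = sample_levels))
      counts[] <- as.integer(tab)
      assigned <- unique(S4Vectors::queryHits(hits))
      tt <- table(factor(samples[assigned], levels = sample_levels))
      totals[] <- as.integer(tt)
    }
  }
  mirna_counts(counts, sample_totals = totals,
               batch = NULL)
}

#' Read-length quality control
#'
#' Builds each sample's read-length histogram over 15-36 nt bins
#' (proportions), computes the Euclidean distance of each profile from the
#' per-bin median profile, and fails samples whose distance exceeds
#' `outlier_threshold` times the median absolute deviation of the distances.
#' Samples without reads fail automatically.
#'
#' @param read_lengths named list: one integer vector of read lengths per
#'   sample (>= 3 samples).
#' @param outlier_threshold multiplier on the MAD of profile distances.
#' @return data frame with per-sample `distance`, `pass`, `reason`.
#' @export
read_length_qc <- function(read_lengths, outlier_threshold = 5) {
  if (length(read_lengths) < 3)
    stop("need at least 3 samples for a robust median profile")
  bins <- 15:36
  prof <- t(vapply(read_lengths, function(l) {
    l <- l[l >= 15 & l <= 36]
    if (length(l) == 0) return(rep(NA_real_, length(bins)))
    as.numeric(table(factor(l, levels = bins))) / length(l)
  }, numeric(length(bins))))
  empty <- apply(prof, 1, function(r) all(is.na(r)))
  med <- apply(prof[!empty, , drop = FALSE], 2, stats::median)
  dist <- apply(prof, 1, function(r) sqrt(sum((r - med)^2)))
  m <- stats::mad(dist[!empty])
  pass <- !empty & (dist <= outlier_threshold * m | dist == 0)
  data.frame(sample = names(read_lengths),
             distance = dist,
             pass = pass,
             reason = ifelse(empty, "no reads in 15-36 nt range",
                             ifelse(pass, "", "length profile outlier")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' RPM-normalize a count matrix
#'
#' value = log2((count + 1) / total * 1e6) where `total` is the raw
#' (pre-pseudocount) per-sample sum of locus-aligned reads.
#'
#' @param cm a [mirna_counts()] object.
#' @return list of class `mirna_norm` with `values`, `pseudocount`,
#'   `batch_adjusted`, `batch`.
#' @export
rpm_normalize <- function(cm) {
  stopifnot(inherits(cm, "mirna_counts"))
  zero <- cm$sample_totals <= 0
  if (any(zero))
    stop("zero locus-aligned total for sample(s): ",
         paste(names(cm$sample_totals)[zero], collapse = ", "))
  values <- log2(sweep(cm$counts + 1, 2, cm$sample_totals, "/") * 1e6)
  structure(list(values = values, pseudocount = 1,
                 batch_adjusted = FALSE, batch = cm$batch),
            class = "mirna_norm")
}

#' Detection filter
#'
#' Keep a miRNA iff it has at least `min_count` reads in at least
#' `min_fraction` of samples.
#'
#' @param counts integer matrix or [mirna_counts()].
#' @param min_count minimum count per sample (default 2).
#' @param min_fraction minimum fraction of samples (default 0.5).
#' @return character vector of retained miRNA names.
#' @export
detection_filter <- function(counts, min_count = 2, min_fraction = 0.5) {
  if (inherits(counts, "mirna_counts")) counts <- counts$counts
  frac <- rowMeans(counts >= min_count)
  rownames(counts)[frac >= min_fraction]
}

#' Group reads at a locus into 5' isomiRs
#'
#' Reads assigned to a locus are grouped by their distinct 5' start; the
#' offset is computed strand-aware (for a minus-strand locus the 5' end is
#' the interval end, and negative offsets are upstream of the canonical 5'
#' end). Reads on the wrong strand are ignored with a message.
#'
#' @param reads data frame of reads (BED-style; optional `sample`).
#' @param locus one-row data frame or list describing the locus.
#' @param genome optional named chromosome-sequence vector used to derive
#'   each isomiR's shifted seed via [extract_seed()].
#' @return data frame: `locus`, `offset5`, `sample`, `count`, `seed`.
#' @export
group_isomirs <- function(reads, locus, genome = NULL) {
  minus <- identical(as.character(locus$strand), "-")
  same <- reads$chrom == locus$chrom & reads$strand == locus$strand &
    reads$start < locus$end & reads$end > locus$start
  wrong <- reads$chrom == locus$chrom & reads$strand != locus$strand &
    reads$start < locus$end & reads$end > locus$start
  if (any(wrong))
    message(sum(wrong), " read(s) on the opposite strand ignored at ",
            locus$name)
  reads <- reads[same, , drop = FALSE]
  if (nrow(reads) == 0) {
    return(data.frame(locus = character(), offset5 = integer(),
                      sample = character(), count = integer(),
                      seed = character(), stringsAsFactors = FALSE))
  }
  offset5 <- if (minus) locus$end - reads$end else reads$start - locus$start
  samples <- if (!is.null(reads$sample)) reads$sample
             else rep("sample_1", nrow(reads))
  agg <- stats::aggregate(list(count = rep(1L, nrow(reads))),
                          by = list(offset5 = offset5, sample = samples),
                          FUN = sum)
  agg$locus <- locus$name
  agg$seed <- NA_character_
  if (!is.null(genome) && !is.null(genome[[locus$chrom]])) {
    chromseq <- genome[[locus$chrom]]
    mature <- substring(chromseq, locus$start + 1, locus$end)
    up <- substring(chromseq, max(1, locus$start - 9), locus$start)
    down <- substring(chromseq, locus$end + 1,
                      min(nchar(chromseq), locus$end + 10))
    if (minus) {
      tmp <- .revcomp(mature); u2 <- .revcomp(down); d2 <- .revcomp(up)
      mature <- tmp; up <- u2; down <- d2
    }
    agg$seed <- vapply(agg$offset5, function(o)
      tryCatch(extract_seed(mature, o, upstream = up, downstream = down),
               error = function(e) NA_character_), character(1))
  }
  agg[order(agg$sample, agg$offset5),
      c("locus", "offset5", "sample", "count", "seed")]
}

#' Empirical-Bayes batch adjustment (ComBat)
#'
#' Removes batch/protocol location-scale effects from a normalized matrix by
#' parametric empirical-Bayes adjustment, preserving the signal of supplied
#' covariates by including them in the standardization model. With a single
#' batch the data are returned unchanged.
#'
#' @param norm a `mirna_norm` object or plain numeric matrix
#'   (features x samples).
#' @param batch per-sample batch labels (>= 2 samples per batch).
#' @param covariates optional data frame of biological covariates whose
#'   signal must be preserved.
#' @return object of the same shape with `batch_adjusted = TRUE`.
#' @export
batch_adjust <- function(norm, batch = NULL, covariates = NULL) {
  is_obj <- inherits(norm, "mirna_norm")
  values <- if (is_obj) norm$values else as.matrix(norm)
  if (is.null(batch) && is_obj) batch <- norm$batch
  if (is.null(batch)) stop("batch labels are required")
  batch <- as.factor(batch)
  if (length(batch) != ncol(values))
    stop("need one batch label per sample")
  if (nlevels(droplevels(batch)) > 1 && any(table(batch) < 2))
    stop("each batch needs at least 2 samples")
  if (nlevels(droplevels(batch)) == 1) {
    adjusted <- values
  } else {
    mod <- NULL
    if (!is.null(covariates))
      mod <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    adjusted <- suppressMessages(
      sva::ComBat(dat = values, batch = batch, mod = mod))
  }
  if (is_obj) {
    norm$values <- adjusted
    norm$batch_adjusted <- TRUE
    norm
  } else {
    structure(list(values = adjusted, pseudocount = NA,
                   batch_adjusted = TRUE, batch = batch),
              class = "mirna_norm")
  }
}
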