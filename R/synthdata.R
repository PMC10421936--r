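#' Simulation configuration for synthetic cohorts
#'
#' Collects every knob of the synthetic-cohort generator in one validated
#' object. Defaults emulate the statistical structure of a two-protocol
#' lung-tissue small-RNA cohort: negative-binomial counts with batch effects,
#' SNPs in Hardy-Weinberg equilibrium, planted SNP-miRNA-mRNA mediation
#' triplets, and clinical covariates (age, gender, smoking) with disease
#' labels.
#'
#' @param n_subjects number of subjects (columns of every matrix).
#' @param n_snps number of background SNPs beyond the planted triplet SNPs.
#' @param maf_range minor-allele-frequency range, both ends in (0, 0.5].
#' @param n_mirna number of background (non-triplet) miRNAs.
#' @param n_gene number of background (non-triplet) genes.
#' @param triplet_spec data frame with columns `class` (one of `"causal"`,
#'   `"reactive"`, `"independent"`, `"null"`), `effect_snp_mirna` and
#'   `effect_mirna_gene` (standardized slopes). One row per planted triplet.
#' @param nb_dispersion negative-binomial size parameter theta (> 0) used
#'   when counts are generated from expression.
#' @param lib_size_range range of per-sample library sizes (>= 1).
#' @param batch_labels optional per-subject batch/protocol labels; defaults
#'   to two equal batches.
#' @param seed integer seed controlling every random draw.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 200,
                       n_snps = 50,
                       maf_range = c(0.2, 0.5),
                       n_mirna = 50,
                       n_gene = 100,
                       triplet_spec = NULL,
                       nb_dispersion = 2,
                       lib_size_range = c(5e5, 2e6),
                       batch_labels = NULL,
                       seed = 1L) {
  stopifnot(n_subjects >= 2, n_snps >= 0, n_mirna >= 0, n_gene >= 0)
  .check_maf_range(maf_range)
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0)
    stop("nb_dispersion must be > 0")
  if (any(lib_size_range < 1)) stop("library sizes must be >= 1")
  if (is.null(triplet_spec)) {
    triplet_spec <- data.frame(
      class = rep(c("causal", "reactive", "independent", "null"), each = 5),
      effect_snp_mirna = 0.8,
      effect_mirna_gene = 0.8,
      stringsAsFactors = FALSE
    )
  }
  bad <- setdiff(triplet_spec$class,
                 c("causal", "reactive", "independent", "null"))
  if (length(bad)) stop("unknown triplet class: ", paste(bad, collapse = ", "))
  if (!all(is.finite(triplet_spec$effect_snp_mirna)) ||
      !all(is.finite(triplet_spec$effect_mirna_gene)))
    stop("triplet effects must be finite")
  if (is.null(batch_labels)) {
    batch_labels <- rep(c("protocolA", "protocolB"), length.out = n_subjects)
  }
  if (length(batch_labels) != n_subjects)
    stop("batch_labels must have one entry per subject")
  structure(list(n_subjects = n_subjects, n_snps = n_snps,
                 maf_range = maf_range, n_mirna = n_mirna, n_gene = n_gene,
                 triplet_spec = triplet_spec, nb_dispersion = nb_dispersion,
                 lib_size_range = lib_size_range,
                 batch_labels = batch_labels, seed = as.integer(seed)),
            class = "sim_config")
}

.check_maf_range <- function(maf_range) {
  if (length(maf_range) != 2 || any(!is.finite(maf_range)) ||
      any(maf_range <= 0) || any(maf_range > 0.5))
    stop("minor allele frequencies must lie in (0, 0.5]")
  invisible(TRUE)
}

#' Simulate genotypes in Hardy-Weinberg equilibrium
#'
#' Each SNP draws an allele frequency uniformly from `maf_range` and each
#' subject's genotype as Binomial(2, maf), i.e. unlinked SNPs in HWE.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_snps number of SNPs.
#' @param maf_range allele-frequency range, both ends in (0, 0.5].
#' @param seed optional integer seed.
#' @return integer matrix (SNPs x subjects) with entries in 0/1/2; the
#'   per-SNP allele frequencies are attached as attribute `"maf"`.
#' @export
simulate_genotypes <- function(n_subjects, n_snps, maf_range = c(0.1, 0.5),
                               seed = NULL) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  .check_maf_range(maf_range)
  if (!is.null(seed)) set.seed(seed)
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  g <- matrix(stats::rbinom(n_snps * n_subjects, 2L, rep(maf, n_subjects)),
              nrow = n_snps, ncol = n_subjects)
  dimnames(g) <- list(sprintf("snp_%d", seq_len(n_snps)),
                      sprintf("subject_%d", seq_len(n_subjects)))
  attr(g, "maf") <- stats::setNames(maf, rownames(g))
  storage.mode(g) <- "integer"
  g
}

#' Simulate SNP-miRNA-mRNA triplets of known generative class
#'
#' For each row of `config$triplet_spec` one SNP (L), one miRNA (G) and one
#' gene (T) are generated according to the class:
#' \itemize{
#'   \item causal: `G = a*L + e1`, `T = b*G + e2` (miRNA mediates),
#'   \item reactive: `T = a*L + e3`, `G = b*T + e4` (gene drives miRNA),
#'   \item independent: `G = a*L + e1`, `T = b*L + e3` (shared driver,
#'     no G-T path),
#'   \item null: pure noise.
#' }
#' Noise is standard normal; slopes apply to the standardized genotype so
#' effects are standardized slopes. Background SNPs, miRNAs and genes are
#' appended as independent noise features.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (SNPs x subjects), `mirna` and `gene`
#'   expression matrices (features x subjects), `truth` (one row per planted
#'   triplet: class, ids, slopes) and `covariates` (per-sample age, gender,
#'   smoking, batch).
#' @export
simulate_triplets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  spec <- config$triplet_spec
  k <- nrow(spec)

  geno_t <- simulate_genotypes(n, k, config$maf_range)
  rownames(geno_t) <- sprintf("snp_t%d", seq_len(k))
  mirna <- matrix(0, k, n)
  gene <- matrix(0, k, n)
  for (i in seq_len(k)) {
    L <- as.numeric(geno_t[i, ])
    sL <- stats::sd(L)
    Ls <- if (sL > 0) (L - mean(L)) / sL else L * 0
    a <- spec$effect_snp_mirna[i]
    b <- spec$effect_mirna_gene[i]
    cls <- spec$class[i]
    if (cls == "causal") {
      G <- a * Ls + stats::rnorm(n)
      Tv <- b * G + stats::rnorm(n)
    } else if (cls == "reactive") {
      Tv <- a * Ls + stats::rnorm(n)
      G <- b * Tv + stats::rnorm(n)
    } else if (cls == "independent") {
      G <- a * Ls + stats::rnorm(n)
      Tv <- b * Ls + stats::rnorm(n)
    } else if (cls == "null") {
      G <- stats::rnorm(n)
      Tv <- stats::rnorm(n)
    } else stop("unknown triplet class: ", cls)
    mirna[i, ] <- G
    gene[i, ] <- Tv
  }
  rownames(mirna) <- sprintf("mir_t%d", seq_len(k))
  rownames(gene) <- sprintf("gene_t%d", seq_len(k))

  geno_bg <- if (config$n_snps > 0)
    simulate_genotypes(n, config$n_snps, config$maf_range) else NULL
  mirna_bg <- if (config$n_mirna > 0)
    matrix(stats::rnorm(config$n_mirna * n), config$n_mirna, n,
           dimnames = list(sprintf("mir_bg%d", seq_len(config$n_mirna)), NULL))
  else NULL
  gene_bg <- if (config$n_gene > 0)
    matrix(stats::rnorm(config$n_gene * n), config$n_gene, n,
           dimnames = list(sprintf("gene_bg%d", seq_len(config$n_gene)), NULL))
  else NULL

  genotypes <- rbind(geno_t, geno_bg)
  mirna <- rbind(mirna, mirna_bg)
  gene <- rbind(gene, gene_bg)
  subjects <- sprintf("subject_%d", seq_len(n))
  colnames(genotypes) <- colnames(mirna) <- colnames(gene) <- subjects

  covariates <- data.frame(
    sample = subjects,
    age = round(stats::rnorm(n, 63, 10), 1),
    gender = sample(c("male", "female"), n, replace = TRUE),
    smoking = sample(c("never", "former", "current"), n, replace = TRUE,
                     prob = c(0.25, 0.65, 0.10)),
    batch = config$batch_labels,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    triplet = seq_len(k),
    class = spec$class,
    snp_id = sprintf("snp_t%d", seq_len(k)),
    mirna_id = sprintf("mir_t%d", seq_len(k)),
    gene_id = sprintf("gene_t%d", seq_len(k)),
    effect_snp_mirna = spec$effect_snp_mirna,
    effect_mirna_gene = spec$effect_mirna_gene,
    stringsAsFactors = FALSE
  )
  list(genotypes = genotypes, mirna = mirna, gene = gene,
       truth = truth, covariates = covariates)
}

#' Simulate negative-binomial miRNA counts
#'
#' Counts are drawn from a negative binomial with mean
#' `exp(log_mean + log(lib_size / median(lib_size)) + batch_shift)` and size
#' theta. The library-size term enters the log-mean as a predictor-style
#' offset relative to the median depth.
#'
#' @param log_means matrix (features x samples) or vector (recycled across
#'   samples) of natural-log baseline means; must be finite.
#' @param dispersion NB size parameter theta (> 0).
#' @param lib_sizes per-sample library sizes (>= 1).
#' @param batch_shifts optional per-sample additive shift on the log-mean.
#' @param seed optional integer seed.
#' @return integer count matrix (features x samples).
#' @export
simulate_counts <- function(log_means, dispersion, lib_sizes,
                            batch_shifts = NULL, seed = NULL) {
  if (!is.numeric(dispersion) || dispersion <= 0)
    stop("dispersion must be > 0")
  if (any(lib_sizes < 1)) stop("library sizes must be >= 1")
  n <- length(lib_sizes)
  if (is.matrix(log_means)) {
    if (ncol(log_means) != n) stop("log_means columns must match lib_sizes")
    lm_mat <- log_means
  } else {
    lm_mat <- matrix(log_means, length(log_means), n)
    rownames(lm_mat) <- names(log_means)
  }
  if (any(!is.finite(lm_mat)))
    stop("log_means must be finite (a zero mean is outside the NB domain)")
  if (is.null(batch_shifts)) batch_shifts <- rep(0, n)
  if (length(batch_shifts) != n) stop("batch_shifts must match lib_sizes")
  if (!is.null(seed)) set.seed(seed)
  depth <- log(lib_sizes / stats::median(lib_sizes))
  mu <- exp(sweep(lm_mat, 2, depth + batch_shifts, "+"))
  counts <- matrix(stats::rnbinom(length(mu), size = dispersion, mu = mu),
                   nrow = nrow(mu), ncol = ncol(mu), dimnames = dimnames(lm_mat))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("mir_%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample_%d", seq_len(ncol(counts)))
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate aligned small-RNA reads at a miRNA locus
#'
#' Draws `n_reads` reads whose 5' start is shifted from the canonical locus
#' start by a multinomial draw over `offset_distribution` (negative offsets
#' are upstream of the 5' end, strand-aware). Read sequences are taken from
#' the genomic sequence at the shifted window when `genome` is supplied.
#'
#' @param locus one-row data frame or list with `name`, `chrom`, `start`,
#'   `end` (0-based half-open) and `strand`.
#' @param offset_distribution named numeric vector mapping signed integer 5'
#'   offsets to probabilities summing to 1 (within 1e-9).
#' @param n_reads number of reads to draw (0 yields an empty read set).
#' @param seed optional integer seed.
#' @param genome optional named character vector of chromosome sequences
#'   (plain ACGT strings) used to fill the read sequence column.
#' @param sample_id sample label attached to every read.
#' @return data frame in BED6-plus style: chrom, start, end, name, score,
#'   strand, seq, sample.
#' @export
simulate_reads_at_locus <- function(locus, offset_distribution, n_reads,
                                    seed = NULL, genome = NULL,
                                    sample_id = "sample_1") {
  p <- as.numeric(offset_distribution)
  offs <- as.integer(names(offset_distribution))
  if (any(is.na(offs))) stop("offset names must be signed integers")
  if (abs(sum(p) - 1) > 1e-9) stop("offset probabilities must sum to 1")
  if (any(p < 0)) stop("offset probabilities must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  if (n_reads == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = integer(),
                      strand = character(), seq = character(),
                      sample = character(), stringsAsFactors = FALSE))
  }
  draw <- sample(seq_along(offs), n_reads, replace = TRUE, prob = p)
  o <- offs[draw]
  len <- locus$end - locus$start
  if (identical(as.character(locus$strand), "-")) {
    end <- locus$end - o          # 5' end of a minus-strand read is `end`
    start <- end - len
  } else {
    start <- locus$start + o
    end <- start + len
  }
  seqs <- rep(NA_character_, n_reads)
  if (!is.null(genome) && !is.null(genome[[locus$chrom]])) {
    chromseq <- genome[[locus$chrom]]
    seqs <- substring(chromseq, start + 1, end)
    if (identical(as.character(locus$strand), "-"))
      seqs <- .revcomp(seqs)
  }
  data.frame(chrom = locus$chrom, start = as.integer(start),
             end = as.integer(end),
             name = sprintf("read_%d", seq_len(n_reads)),
             score = 0L, strand = as.character(locus$strand), seq = seqs,
             sample = sample_id, stringsAsFactors = FALSE)
}

#' Simulate a full synthetic cohort
#'
#' Bundles the generators into one cohort with ground truth for every
#' downstream stage: HWE genotypes, mediation triplets, NB miRNA counts with
#' batch/protocol and disease effects, and clinical covariates with sample
#' cluster labels.
#'
#' @param config a [sim_config()].
#' @param n_de number of background miRNAs given a disease effect.
#' @param de_lfc natural-log fold change planted on disease-affected miRNAs.
#' @param batch_lfc natural-log shift applied to the second protocol.
#' @return list with `genotypes`, `mirna`, `gene`, `counts`, `covariates`
#'   (including `disease` and `cluster`), and `truth`.
#' @export
simulate_cohort <- function(config, n_de = 10, de_lfc = 0.7,
                            batch_lfc = 0.3) {
  trip <- simulate_triplets(config)
  set.seed(config$seed + 1L)
  n <- config$n_subjects
  covs <- trip$covariates
  covs$disease <- sample(c("control", "COPD", "ILD"), n, replace = TRUE,
                         prob = c(0.2, 0.4, 0.4))
  covs$cluster <- ifelse(covs$disease == "control", "S1",
                         ifelse(covs$disease == "COPD", "S2", "S3"))
  n_feat <- nrow(trip$mirna)
  base <- stats::runif(n_feat, log(20), log(500))
  lm_mat <- matrix(base, n_feat, n)
  de_idx <- integer(0)
  if (n_de > 0) {
    de_idx <- which(startsWith(rownames(trip$mirna), "mir_bg"))[seq_len(n_de)]
    lm_mat[de_idx, covs$disease != "control"] <-
      lm_mat[de_idx, covs$disease != "control"] + de_lfc
  }
  lib <- round(stats::runif(n, config$lib_size_range[1],
                            config$lib_size_range[2]))
  shift <- ifelse(covs$batch == covs$batch[1], 0, batch_lfc)
  counts <- simulate_counts(lm_mat, config$nb_dispersion, lib,
                            batch_shifts = shift)
  rownames(counts) <- rownames(trip$mirna)
  colnames(counts) <- colnames(trip$mirna)
  truth <- trip$truth
  attr(truth, "de_mirnas") <- rownames(trip$mirna)[de_idx]
  list(genotypes = trip$genotypes, mirna = trip$mirna, gene = trip$gene,
       counts = counts, lib_sizes = stats::setNames(lib, colnames(counts)),
       covariates = covs, truth = truth)
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    chartr("ACGTUacgtu", "TGCAAtgcaa",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
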