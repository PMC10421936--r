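#' Extract a (possibly 5'-shifted) miRNA seed
#'
#' Returns the 7-mer at positions 2-8 (1-based) of the mature sequence after
#' shifting its 5' start by `offset5` (negative = upstream). Shifts that
#' reach outside the mature sequence require flanking locus sequence.
#' U and T are interchangeable; output uses the input alphabet.
#'
#' @param mature mature miRNA sequence, 5' to 3'.
#' @param offset5 signed integer 5' shift (0 = canonical).
#' @param upstream,downstream flanking locus sequence 5' and 3' of the
#'   mature sequence (same strand orientation).
#' @return the 7-character seed string.
#' @export
extract_seed <- function(mature, offset5 = 0, upstream = "", downstream = "") {
  mature <- toupper(mature); upstream <- toupper(upstream)
  downstream <- toupper(downstream)
  full <- paste0(upstream, mature, downstream)
  if (grepl("[^ACGTUN]", full)) stop("sequence contains non-nucleotide characters")
  start <- nchar(upstream) + 1 + offset5   # 1-based shifted 5' start
  from <- start + 1                         # seed = positions 2..8
  to <- start + 7
  if (from < 1 || to > nchar(full))
    stop("shifted seed window (positions 2-8) outside the available sequence")
  substr(full, from, to)
}

.revcomp_dna <- function(x) {
  x <- chartr("U", "T", toupper(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Scan a 3'UTR for seed-match target sites
#'
#' Site classes follow the canonical seed-match taxonomy: 7mer-m8 = reverse
#' complement of seed positions 2-8; 7mer-A1 = reverse complement of
#' positions 2-7 followed by A; 8mer = both (reverse complement of 2-8
#' followed by A). All overlapping occurrences are reported; an 8mer
#' suppresses the 7mers it contains at the same position. Ambiguous bases
#' (N) never match.
#'
#' @param seed 7-mer seed (positions 2-8 of the mature miRNA).
#' @param utr 3'UTR sequence (DNA alphabet; U tolerated).
#' @return data frame: `site_type`, `position` (0-based start in the UTR).
#' @export
scan_target_sites <- function(seed, utr) {
  seed <- chartr("U", "T", toupper(seed))
  if (nchar(seed) != 7 || grepl("[^ACGT]", seed))
    stop("seed must be an unambiguous 7-mer")
  utr <- chartr("U", "T", toupper(utr))
  empty <- data.frame(site_type = character(), position = integer(),
                      stringsAsFactors = FALSE)
  if (nchar(utr) == 0) return(empty)
  m8 <- .revcomp_dna(seed)                                  # 7mer-m8 core
  a1 <- paste0(.revcomp_dna(substr(seed, 1, 6)), "A")       # 7mer-A1
  mer8 <- paste0(m8, "A")                                   # 8mer
  find <- function(pat) {
    hits <- Biostrings::matchPattern(pat, Biostrings::DNAString(utr),
                                     fixed = TRUE)
    Biostrings::start(hits) - 1L   # 0-based
  }
  p8 <- find(mer8)
  pm8 <- setdiff(find(m8), p8)        # 7mer-m8 shares the 8mer's start
  pa1 <- setdiff(find(a1), p8 + 1L)   # 7mer-A1 sits one base inside the 8mer
  out <- rbind(
    if (length(p8)) data.frame(site_type = "8mer", position = p8),
    if (length(pm8)) data.frame(site_type = "7mer-m8", position = pm8),
    if (length(pa1)) data.frame(site_type = "7mer-A1", position = pa1))
  if (is.null(out)) return(empty)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predicted target genes of a seed over a UTR set
#'
#' @param seed 7-mer seed.
#' @param utrs named character vector or `Biostrings::DNAStringSet` of
#'   3'UTR sequences keyed by gene id.
#' @return character vector of genes with at least one seed-match site.
#' @export
scan_target_genes <- function(seed, utrs) {
  if (methods::is(utrs, "DNAStringSet")) utrs <- as.character(utrs)
  hit <- vapply(utrs, function(u) nrow(scan_target_sites(seed, u)) > 0,
                logical(1))
  names(utrs)[hit]
}

#' Partition a gene universe by canonical/isomiR target status
#'
#' @param canonical,isomir predicted target gene sets (subsets of universe).
#' @param universe full gene universe.
#' @return list of class `target_groups`: `canonical_only`, `isomir_only`,
#'   `both`, `neither` (pairwise disjoint, union = universe).
#' @export
categorize_genes <- function(canonical, isomir, universe) {
  if (length(setdiff(canonical, universe)) || length(setdiff(isomir, universe)))
    stop("target genes outside the universe")
  both <- intersect(canonical, isomir)
  structure(list(canonical_only = setdiff(canonical, both),
                 isomir_only = setdiff(isomir, both),
                 both = both,
                 neither = setdiff(universe, union(canonical, isomir))),
            class = "target_groups")
}

#' Correlate predicted targets with miRNA expression
#'
#' Spearman correlation of each gene with the miRNA across samples, plus a
#' two-sided Wilcoxon rank-sum test of each target group's correlation
#' coefficients against the "neither" group (predicted targets of a
#' repressive miRNA should shift toward negative correlations). Genes with
#' constant expression are excluded with a message.
#'
#' @param mirna_expr numeric vector of miRNA expression over samples.
#' @param gene_expr numeric matrix, genes x samples.
#' @param groups a `target_groups` partition of the gene rows.
#' @return list: `rho` (named per-gene Spearman coefficients), `tests`
#'   (data frame: group, n, median_rho, p).
#' @export
correlate_targets <- function(mirna_expr, gene_expr, groups) {
  if (length(mirna_expr) < 3) stop("need at least 3 samples")
  sds <- apply(gene_expr, 1, stats::sd)
  if (any(sds == 0)) {
    message("excluding ", sum(sds == 0), " constant gene profile(s)")
    gene_expr <- gene_expr[sds > 0, , drop = FALSE]
  }
  rho <- apply(gene_expr, 1, function(g)
    stats::cor(g, mirna_expr, method = "spearman"))
  neither <- rho[intersect(groups$neither, names(rho))]
  tests <- lapply(c("canonical_only", "isomir_only", "both"), function(gl) {
    v <- rho[intersect(groups[[gl]], names(rho))]
    p <- if (length(v) == 0 || length(neither) == 0) NA_real_
         else suppressWarnings(stats::wilcox.test(v, neither)$p.value)
    data.frame(group = gl, n = length(v),
               median_rho = if (length(v)) stats::median(v) else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  list(rho = rho, tests = do.call(rbind, tests),
       n_neither = length(neither))
}

#' Anticorrelated-target overlap statistics
#'
#' Percent of each set distinct from the other
#' (`|S \ R| / |S| * 100`) and the Jaccard index of the two sets.
#'
#' @param set_a,set_b gene id sets (e.g. anticorrelated predicted targets of
#'   the canonical and isomiR seeds).
#' @return list: `percent_distinct_a`, `percent_distinct_b` (NA for an
#'   empty set), `jaccard`.
#' @export
anticorrelated_overlap <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  un <- union(set_a, set_b)
  jac <- if (length(un) == 0) {
    message("both sets empty; Jaccard defined as 0")
    0
  } else length(intersect(set_a, set_b)) / length(un)
  pd <- function(s, r) if (length(s) == 0) NA_real_
                       else length(setdiff(s, r)) / length(s) * 100
  list(percent_distinct_a = pd(set_a, set_b),
       percent_distinct_b = pd(set_b, set_a),
       jaccard = jac)
}

#' Preranked gene-set enrichment (running-sum ES)
#'
#' Genes are ranked by decreasing score; hits increment the running sum by
#' `|score|^weight` (normalized to 1 over the set), misses decrement by
#' `1/(N - m)`. ES is the maximum-magnitude deviation. Significance comes
#' from a seeded gene-label permutation null; NES divides ES by the mean
#' magnitude of same-sign permuted ES values.
#'
#' @param scores named numeric vector of per-gene ranking scores.
#' @param gene_set character vector, subset of `names(scores)` (and not the
#'   whole universe).
#' @param weight exponent on |score| for hit increments (0 = unweighted).
#' @param n_perm number of gene-label permutations.
#' @param seed integer seed.
#' @return list: `es`, `nes`, `p`, `q`, `leading_edge`.
#' @export
gsea_preranked <- function(scores, gene_set, weight = 1, n_perm = 1000,
                           seed = 1L) {
  if (is.null(names(scores))) stop("scores must be named by gene")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% names(scores)))
    stop("gene_set must be a subset of the ranked universe")
  N <- length(scores)
  m <- length(gene_set)
  if (m < 1) stop("gene_set must contain at least 1 gene")
  if (m >= N) stop("gene_set must be a proper subset of the universe")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  hit <- names(s) %in% gene_set
  es_stat <- function(hit_mask) {
    w <- abs(s)^weight
    wh <- w * hit_mask
    denom <- sum(wh)
    inc <- if (denom > 0) wh / denom else hit_mask / sum(hit_mask)
    dec <- (!hit_mask) / (N - m)
    run <- cumsum(inc - dec)
    unname(run[which.max(abs(run))])
  }
  es <- es_stat(hit)
  if (!is.null(seed)) set.seed(seed)
  es_null <- vapply(seq_len(n_perm), function(i) {
    mask <- logical(N)
    mask[sample.int(N, m)] <- TRUE
    es_stat(mask)
  }, numeric(1))
  same <- es_null[sign(es_null) == sign(es) | es == 0]
  p <- if (length(same) == 0) 1 / (n_perm + 1)
       else (1 + sum(abs(same) >= abs(es))) / (length(same) + 1)
  nes <- if (length(same) && mean(abs(same)) > 0) es / mean(abs(same))
         else NA_real_
  peak <- which.max(abs(cumsum((abs(s)^weight * hit) /
                                 max(sum(abs(s)^weight * hit), .Machine$double.eps)
                               - (!hit) / (N - m))))
  leading <- if (es >= 0) names(s)[seq_len(peak)][hit[seq_len(peak)]]
             else names(s)[peak:N][hit[peak:N]]
  list(es = es, nes = nes, p = p, q = p, leading_edge = leading)
}

#' Jaccard clustering of miRNA target-gene modules
#'
#' Pairwise dissimilarity 1 - Jaccard between per-miRNA gene sets, with an
#' average-linkage hierarchical tree and a deterministic leaf order.
#'
#' @param gene_sets named list (>= 2) of gene id vectors.
#' @return list: `dissimilarity` (matrix), `tree` (`hclust`), `order`
#'   (leaf labels in dendrogram order).
#' @export
jaccard_module_cluster <- function(gene_sets) {
  k <- length(gene_sets)
  if (k < 2) stop("need at least 2 gene sets")
  nm <- names(gene_sets)
  if (is.null(nm)) nm <- sprintf("set_%d", seq_len(k))
  d <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- unique(gene_sets[[i]]); b <- unique(gene_sets[[j]])
    un <- length(union(a, b))
    jac <- if (un == 0) {
      message("two empty sets; Jaccard defined as 0")
      0
    } else length(intersect(a, b)) / un
    d[i, j] <- d[j, i] <- 1 - jac
  }
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  list(dissimilarity = d, tree = tree, order = tree$labels[tree$order])
}
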