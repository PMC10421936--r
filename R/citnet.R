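#' Causality inference test for one SNP-miRNA-mRNA triplet
#'
#' Tests whether the mediator M (miRNA) transmits the effect of the genetic
#' variant L (SNP) to the outcome T (mRNA). For the causal direction
#' L -> M -> T four component tests are combined:
#' \enumerate{
#'   \item T is associated with L,
#'   \item M is associated with L given T,
#'   \item T is associated with M given L,
#'   \item L is independent of T given M (equivalence test): the observed F
#'     statistic for L in `T ~ M + L` is compared against a reference
#'     distribution obtained by permuting the mediator within genotype
#'     strata. The permutation preserves the mediator's genotype association
#'     while breaking its link to the outcome, so the permuted F statistics
#'     represent the no-mediation alternative and
#'     `p4 = (1 + #\{F* <= F_obs\}) / (n_perm + 1)` is small exactly when
#'     conditioning on the true mediator absorbs the L-T association.
#' }
#' The omnibus p-value is the maximum of the four component p-values; the
#' reactive direction swaps the roles of M and T (identical permutation
#' indices, so the directional p-values are exactly symmetric under
#' argument swap). Covariates are residualized out of M and T beforehand;
#' the genotype is left raw and enters additively by default.
#'
#' @param L genotype vector (0/1/2; must be polymorphic).
#' @param M mediator expression vector (miRNA).
#' @param T_ outcome expression vector (mRNA).
#' @param covariates optional per-sample covariate table.
#' @param n_perm permutations for the equivalence test (default 100; a
#'   warning is issued below 20).
#' @param seed integer seed for the permutation stream.
#' @param alpha significance level used for the classification call.
#' @param coding `"additive"` (allele dosage) or `"factor"` (genotype as a
#'   3-level factor) inside the component regressions.
#' @return list of class `cit_result`: `p_causal`, `p_reactive`, component
#'   p-values `p1..p4` (causal direction) and `r1..r4` (reactive), `call`,
#'   `alpha`.
#' @export
cit_test <- function(L, M, T_, covariates = NULL, n_perm = 100, seed = NULL,
                     alpha = 0.05, coding = c("additive", "factor")) {
  coding <- match.arg(coding)
  n <- length(L)
  if (n < 30) stop("CIT requires at least 30 samples")
  if (length(unique(L)) < 2) stop("genotype must be polymorphic")
  if (stats::sd(M) == 0 || stats::sd(T_) == 0)
    stop("constant mediator or outcome")
  if (n_perm < 20) warning("n_perm < 20 gives a coarse equivalence p-value")
  if (!is.null(covariates)) {
    rr <- residualize(rbind(M, T_), covariates)
    M <- rr[1, ]; T_ <- rr[2, ]
  }
  if (!is.null(seed)) set.seed(seed)
  # one permutation index matrix, shared by both directions: strata depend
  # only on the genotype
  strata <- split(seq_len(n), L)
  perm_idx <- matrix(0L, n, n_perm)
  for (j in seq_len(n_perm)) {
    idx <- integer(n)
    for (s in strata) idx[s] <- if (length(s) > 1) s[sample.int(length(s))] else s
    perm_idx[, j] <- idx
  }
  Lx <- if (coding == "additive") matrix(as.numeric(L), ncol = 1)
        else stats::model.matrix(~ factor(L))[, -1, drop = FALSE]
  fwd <- .cit_direction(Lx, M, T_, perm_idx)
  rev <- .cit_direction(Lx, T_, M, perm_idx)
  p_causal <- max(fwd$p)
  p_reactive <- max(rev$p)
  structure(list(p_causal = p_causal, p_reactive = p_reactive,
                 p1 = fwd$p[1], p2 = fwd$p[2], p3 = fwd$p[3], p4 = fwd$p[4],
                 r1 = rev$p[1], r2 = rev$p[2], r3 = rev$p[3], r4 = rev$p[4],
                 call = classify_triplet(p_causal, p_reactive, alpha),
                 alpha = alpha),
            class = "cit_result")
}

# F test for adding columns `add` to a model already containing `X0`
# (an intercept is always included); returns c(F, p)
.f_added <- function(y, X0, add) {
  X0 <- if (is.null(X0)) matrix(1, length(y), 1) else cbind(1, X0)
  q0 <- qr(X0)
  r0 <- qr.resid(q0, y)
  A <- qr.resid(q0, as.matrix(add))
  qa <- qr(A)
  m <- qa$rank
  rss0 <- sum(r0^2)
  if (m == 0) return(c(0, 1))
  Q <- qr.Q(qa)[, seq_len(m), drop = FALSE]
  proj <- crossprod(Q, r0)
  rss1 <- max(rss0 - sum(proj^2), 0)
  df2 <- length(y) - q0$rank - m
  f <- (rss0 - rss1) / m / (rss1 / df2)
  c(f, stats::pf(f, m, df2, lower.tail = FALSE))
}

# component p-values for one direction L -> med -> out
.cit_direction <- function(Lx, med, out, perm_idx) {
  p1 <- .f_added(out, NULL, Lx)[2]
  p2 <- .f_added(med, out, Lx)[2]
  p3 <- .f_added(out, Lx, med)[2]
  f_obs <- .f_added(out, med, Lx)[1]
  n_perm <- ncol(perm_idx)
  f_star <- vapply(seq_len(n_perm), function(j)
    .f_added(out, med[perm_idx[, j]], Lx)[1], numeric(1))
  p4 <- (1 + sum(f_star <= f_obs)) / (n_perm + 1)
  list(p = c(p1, p2, p3, p4), f_obs = f_obs)
}

#' Classify a triplet from its two directional CIT p-values
#'
#' causal if `p_causal < alpha <= p_reactive`; reactive if
#' `p_reactive < alpha <= p_causal`; independent if both are at least
#' `alpha`; non_inferable if both are below `alpha` (causality cannot be
#' distinguished from a feedback or measurement artifact).
#'
#' @param p_causal,p_reactive omnibus p-values in [0, 1] (vectorized).
#' @param alpha significance level (default 0.05).
#' @return character vector of calls.
#' @export
classify_triplet <- function(p_causal, p_reactive, alpha = 0.05) {
  stopifnot(all(p_causal >= 0 & p_causal <= 1),
            all(p_reactive >= 0 & p_reactive <= 1))
  ifelse(p_causal < alpha & p_reactive >= alpha, "causal",
         ifelse(p_reactive < alpha & p_causal >= alpha, "reactive",
                ifelse(p_causal >= alpha & p_reactive >= alpha,
                       "independent", "non_inferable")))
}

#' Run the CIT over a table of candidate triplets
#'
#' @param triplets data frame with `snp_id`, `mirna_id`, `gene_id`.
#' @param genotypes SNPs x samples matrix.
#' @param mirna,gene expression matrices (features x samples).
#' @param covariates optional covariate table.
#' @param n_perm,alpha,coding passed to [cit_test()].
#' @param seed seed; each triplet uses `seed + row index` so results do not
#'   depend on scan order.
#' @return data frame with ids, directional p-values and calls.
#' @export
cit_scan <- function(triplets, genotypes, mirna, gene, covariates = NULL,
                     n_perm = 100, seed = 1L, alpha = 0.05,
                     coding = "additive") {
  res <- lapply(seq_len(nrow(triplets)), function(i) {
    tr <- triplets[i, ]
    ct <- tryCatch(
      cit_test(genotypes[tr$snp_id, ], mirna[tr$mirna_id, ],
               gene[tr$gene_id, ], covariates = covariates,
               n_perm = n_perm, seed = seed + i, alpha = alpha,
               coding = coding),
      error = function(e) NULL)
    if (is.null(ct))
      return(data.frame(tr, p_causal = NA_real_, p_reactive = NA_real_,
                        call = "non_inferable", stringsAsFactors = FALSE))
    data.frame(tr, p_causal = ct$p_causal, p_reactive = ct$p_reactive,
               call = ct$call, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Candidate triplets from eQTL records
#'
#' Pairs every SNP-miRNA eQTL with every SNP-gene eQTL sharing the SNP:
#' triplets where the SNP is not associated with the miRNA are never
#' examined.
#'
#' @param mirna_eqtl,gene_eqtl eQTL record data frames (`snp`, `feature`).
#' @return data frame: `snp_id`, `mirna_id`, `gene_id`.
#' @export
candidate_triplets <- function(mirna_eqtl, gene_eqtl) {
  m <- unique(mirna_eqtl[, c("snp", "feature")])
  g <- unique(gene_eqtl[, c("snp", "feature")])
  out <- merge(m, g, by = "snp", suffixes = c("_mirna", "_gene"))
  data.frame(snp_id = out$snp, mirna_id = out$feature_mirna,
             gene_id = out$feature_gene, stringsAsFactors = FALSE)
}

#' Build a condition-specific miRNA regulatory network
#'
#' Edge miRNA -> gene iff at least one triplet with that mediator/outcome
#' was called causal and its SNP-miRNA pair is present in the condition's
#' eQTL set. Independent and non-inferable triplets never contribute; no
#' gene -> miRNA edges are ever emitted.
#'
#' @param cit_results data frame from [cit_scan()].
#' @param eqtl_records SNP-miRNA eQTL records for the condition.
#' @param condition condition label (e.g. "COPD", "ILD", "Control").
#' @return list of class `mirna_network`: `condition`, `edges` data frame
#'   (`mirna`, `gene`, `n_triplets`), `triplets` (provenance rows).
#' @export
build_network <- function(cit_results, eqtl_records, condition = "condition") {
  key <- paste(eqtl_records$snp, eqtl_records$feature)
  causal <- cit_results[cit_results$call == "causal" &
                        paste(cit_results$snp_id, cit_results$mirna_id)
                        %in% key, , drop = FALSE]
  if (nrow(causal) == 0) {
    edges <- data.frame(mirna = character(), gene = character(),
                        n_triplets = integer(), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(list(n_triplets = rep(1L, nrow(causal))),
                            by = list(mirna = causal$mirna_id,
                                      gene = causal$gene_id), FUN = sum)
    edges <- agg[order(agg$mirna, agg$gene), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(condition = condition, edges = edges, triplets = causal),
            class = "mirna_network")
}

#' @export
print.mirna_network <- function(x, ...) {
  cat(sprintf("%s network: %d miRNA(s), %d edge(s)\n", x$condition,
              length(unique(x$edges$mirna)), nrow(x$edges)))
  invisible(x)
}

#' Degree vector of a miRNA network
#' @param network a `mirna_network`.
#' @return named integer vector: genes connected per miRNA.
#' @export
network_degrees <- function(network) {
  if (nrow(network$edges) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(network$edges$mirna)
  stats::setNames(as.integer(tab), names(tab))
}

#' Scale-free fit of a degree distribution
#'
#' Least-squares line of log10(frequency of degree d) on log10(d) over the
#' positive node degrees; a strongly negative slope/correlation indicates a
#' power-law (scale-free) degree distribution.
#'
#' @param network a `mirna_network`, or a vector of node degrees.
#' @return list: `slope`, `r` (Pearson correlation), `n_degrees`.
#' @export
scale_free_fit <- function(network) {
  degrees <- if (inherits(network, "mirna_network")) network_degrees(network)
             else as.numeric(network)
  degrees <- degrees[degrees > 0]
  tab <- table(degrees)
  if (length(tab) < 3) stop("need at least 3 distinct positive degrees")
  d <- log10(as.numeric(names(tab)))
  f <- log10(as.numeric(tab))
  fit <- stats::lm(f ~ d)
  list(slope = unname(stats::coef(fit)[2]),
       r = if (stats::sd(f) == 0) 0 else stats::cor(d, f),
       n_degrees = length(tab))
}

#' Two-sided Fisher exact test
#'
#' Sum of hypergeometric probabilities not exceeding that of the observed
#' 2x2 table, with the margins fixed.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("table entries must be nonnegative")
  if (any(tab != floor(tab))) stop("table entries must be integers")
  if (sum(tab) == 0) return(1)
  stats::fisher.test(tab)$p.value
}

#' Differential connectivity between two condition networks
#'
#' Per miRNA, compares the number of connected genes between two networks
#' with a two-sided Fisher exact test on the 2x2 table
#' [connected, not connected] x [condition a, condition b], using the union
#' gene universe of the pair as the denominator; BH adjustment with a
#' q < `fdr` flag. miRNAs absent from one network count with degree 0 there.
#'
#' @param network_a,network_b `mirna_network` objects.
#' @param universe_a,universe_b gene universes tested in each condition
#'   (default: genes appearing in either network).
#' @param fdr flag threshold (default 0.2).
#' @return data frame: `mirna`, `degree_a`, `degree_b`, `p`, `q`,
#'   `differentially_connected`.
#' @export
differential_connectivity <- function(network_a, network_b,
                                      universe_a = NULL, universe_b = NULL,
                                      fdr = 0.2) {
  if (is.null(universe_a))
    universe_a <- union(network_a$edges$gene, network_b$edges$gene)
  if (is.null(universe_b)) universe_b <- universe_a
  U <- length(union(universe_a, universe_b))
  da <- network_degrees(network_a)
  db <- network_degrees(network_b)
  mirnas <- sort(union(names(da), names(db)))
  rows <- lapply(mirnas, function(m) {
    ka <- if (m %in% names(da)) da[[m]] else 0L
    kb <- if (m %in% names(db)) db[[m]] else 0L
    p <- fisher_exact(matrix(c(ka, U - ka, kb, U - kb), 2, byrow = TRUE))
    data.frame(mirna = m, degree_a = ka, degree_b = kb, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(mirna = character(), degree_a = integer(),
                      degree_b = integer(), p = numeric(), q = numeric(),
                      differentially_connected = logical()))
  }
  out$q <- bh_fdr(out$p)
  out$differentially_connected <- out$q < fdr
  out
}
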