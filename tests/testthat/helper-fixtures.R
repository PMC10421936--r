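# Shared fixture builders: everything is generated in code at test time.

# one triplet of (genotype, mediator, outcome) vectors of a known class
make_triplet <- function(class, n = 400, a = 0.8, b = 0.8, maf = 0.3) {
  L <- stats::rbinom(n, 2, maf)
  while (length(unique(L)) < 2) L <- stats::rbinom(n, 2, maf)
  Ls <- as.numeric(scale(L))
  if (class == "causal") {
    G <- a * Ls + stats::rnorm(n); Tv <- b * G + stats::rnorm(n)
  } else if (class == "reactive") {
    Tv <- a * Ls + stats::rnorm(n); G <- b * Tv + stats::rnorm(n)
  } else if (class == "independent") {
    G <- a * Ls + stats::rnorm(n); Tv <- b * Ls + stats::rnorm(n)
  } else {
    G <- stats::rnorm(n); Tv <- stats::rnorm(n)
  }
  list(L = L, G = G, T = Tv)
}

# a small locus table in 0-based half-open coordinates
make_loci <- function() {
  data.frame(
    name = c("mir-a", "mir-b", "mir-c"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(90L, 300L, 100L),
    end = c(130L, 322L, 122L),
    strand = c("+", "+", "-"),
    stringsAsFactors = FALSE)
}

make_read <- function(chrom, start, end, strand, sample = "s1",
                      name = "r", seq = NA_character_) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = name, score = 0L, strand = strand, seq = seq,
             sample = sample, stringsAsFactors = FALSE)
}

# expression matrix with three well-separated planted sample clusters
make_planted_clusters <- function(n_feat = 20, per_cluster = 10,
                                  separation = 10, seed = 42) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(n_feat * 3, sd = separation), n_feat, 3)
  mat <- do.call(cbind, lapply(1:3, function(k)
    centers[, k] + matrix(stats::rnorm(n_feat * per_cluster, sd = 1),
                          n_feat, per_cluster)))
  colnames(mat) <- sprintf("s%d", seq_len(3 * per_cluster))
  rownames(mat) <- sprintf("f%d", seq_len(n_feat))
  list(mat = mat, truth = rep(1:3, each = per_cluster))
}

# brute-force two-sided Fisher exact p by enumerating feasible tables
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  if (n == 0) return(1)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a)
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1)), numeric(1))
  p_obs <- probs[tab[1, 1] - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force BH step-up q-values
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- which(o == i)
    q[i] <- min(1, min(p[o][rank_i:n] * n / (rank_i:n)))
  }
  q
}

# brute-force GSEA running-sum ES
gsea_brute <- function(scores, gene_set, weight = 1) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  hit <- names(s) %in% gene_set
  nh <- sum(abs(s[hit])^weight)
  run <- 0; best <- 0
  for (i in seq_along(s)) {
    run <- run + if (hit[i]) abs(s[[i]])^weight / nh
                 else -1 / (length(s) - sum(hit))
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# naive overlapping substring scan
substr_scan <- function(pat, x) {
  k <- nchar(pat); L <- nchar(x)
  if (L < k) return(integer(0))
  which(vapply(1:(L - k + 1), function(i) substr(x, i, i + k - 1) == pat,
               logical(1))) - 1L
}
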