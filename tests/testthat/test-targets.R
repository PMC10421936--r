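mir34c <- "AGGCAGTGTAGTTAGCTGATTGC"

test_that("seed extraction handles canonical and shifted 5' starts", {
  expect_equal(extract_seed(mir34c, 0), "GGCAGTG")
  expect_equal(extract_seed(mir34c, -1), "AGGCAGT")
  expect_equal(extract_seed(mir34c, 1), "GCAGTGT")
  # a 2-base upstream shift needs flanking locus sequence
  expect_error(extract_seed(mir34c, -2), "outside")
  expect_equal(extract_seed(mir34c, -2, upstream = "CT"), "TAGGCAG")
  expect_error(extract_seed("ACGTAC", 0), "outside")
  expect_error(extract_seed("ACGTXX$AA", 0), "non-nucleotide")
  # U and T are interchangeable on input
  expect_equal(extract_seed(chartr("T", "U", mir34c), 0), "GGCAGUG")
})

test_that("site scanning matches the seed-match taxonomy and a naive oracle", {
  # hand example: revcomp(GGCAGTG) = CACTGCC; with the trailing A -> 8mer
  sites <- scan_target_sites("GGCAGTG", "AAACACTGCCAAA")
  expect_equal(nrow(sites), 1)
  expect_equal(sites$site_type, "8mer")
  expect_equal(sites$position, 3L)

  # 7mer-m8 without the A1 anchor
  s2 <- scan_target_sites("GGCAGTG", "AACACTGCCG")
  expect_equal(s2$site_type, "7mer-m8")
  # 7mer-A1 without the m8 match
  s3 <- scan_target_sites("GGCAGTG", "AAGACTGCCAGG")
  expect_equal(s3$site_type, "7mer-A1")

  expect_equal(nrow(scan_target_sites("GGCAGTG", "")), 0)
  # ambiguous bases never match
  expect_equal(nrow(scan_target_sites("GGCAGTG", "AAACACTGCCNAA")), 1)
  expect_equal(nrow(scan_target_sites("GGCAGTG", "AAACACTGNCAAA")), 0)
  expect_error(scan_target_sites("ACGT", "AAAA"), "7-mer")

  # random UTRs: every reported site equals the naive substring oracle
  set.seed(73)
  seed7 <- "GGCAGTG"
  m8 <- "CACTGCC"; mer8 <- "CACTGCCA"; a1 <- "ACTGCCA"
  for (i in 1:20) {
    utr <- paste(sample(c("A", "C", "G", "T"), 200, TRUE,
                        prob = c(0.35, 0.2, 0.15, 0.3)), collapse = "")
    got <- scan_target_sites(seed7, utr)
    p8 <- substr_scan(mer8, utr)
    pm8 <- setdiff(substr_scan(m8, utr), p8)
    pa1 <- setdiff(substr_scan(a1, utr), p8 + 1L)
    expect_setequal(got$position[got$site_type == "8mer"], p8)
    expect_setequal(got$position[got$site_type == "7mer-m8"], pm8)
    expect_setequal(got$position[got$site_type == "7mer-A1"], pa1)
  }

  # duality: a UTR built around the reverse complement always has a site
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  utr2 <- paste0("AAAA", rc("GGCAGTG"), "AAAA")
  expect_gt(nrow(scan_target_sites("GGCAGTG", utr2)), 0)
})

test_that("gene universes partition exactly by target category", {
  g <- categorize_genes(c("g1", "g2"), c("g2", "g3"),
                        c("g1", "g2", "g3", "g4"))
  expect_equal(g$canonical_only, "g1")
  expect_equal(g$isomir_only, "g3")
  expect_equal(g$both, "g2")
  expect_equal(g$neither, "g4")
  expect_error(categorize_genes("gX", character(0), c("g1")), "universe")

  ident <- categorize_genes(c("g1"), c("g1"), c("g1", "g2"))
  expect_length(ident$canonical_only, 0)
  expect_length(ident$isomir_only, 0)
  disj <- categorize_genes("g1", "g2", c("g1", "g2"))
  expect_length(disj$both, 0)

  # partition property on random universes
  set.seed(79)
  for (i in 1:10) {
    uni <- sprintf("g%d", 1:50)
    can <- sample(uni, 15); iso <- sample(uni, 20)
    gg <- categorize_genes(can, iso, uni)
    parts <- c(gg$canonical_only, gg$isomir_only, gg$both, gg$neither)
    expect_setequal(parts, uni)
    expect_equal(length(parts), length(uni))   # pairwise disjoint
  }
})

test_that("target-group correlation tests detect planted repression", {
  set.seed(83)
  n <- 30
  mir <- rnorm(n)
  gene_expr <- rbind(anti = -mir,
                     flat = rep(1, n),
                     matrix(rnorm(20 * n), 20,
                            dimnames = list(sprintf("g%d", 1:20), NULL)))
  groups <- categorize_genes("anti", character(0),
                             rownames(gene_expr))
  expect_message(res <- correlate_targets(mir, gene_expr, groups),
                 "constant")
  expect_equal(unname(res$rho["anti"]), -1)
  expect_false("flat" %in% names(res$rho))

  # identical value distributions in target and background give p = 1
  t_genes <- matrix(rnorm(3 * n), 3, dimnames = list(c("t1", "t2", "t3"),
                                                     NULL))
  ge2 <- rbind(t_genes, t_genes)
  rownames(ge2)[4:6] <- c("n1", "n2", "n3")
  gr2 <- categorize_genes(c("t1", "t2", "t3"), character(0), rownames(ge2))
  res2 <- correlate_targets(rnorm(n), ge2, gr2)
  expect_equal(res2$tests$p[res2$tests$group == "canonical_only"], 1)

  # planted anticorrelation shift: Wilcoxon detects it
  set.seed(84)
  hits <- vapply(1:10, function(i) {
    ns <- 100
    mirv <- rnorm(ns)
    targets <- t(sapply(1:50, function(j) -0.6 * mirv + rnorm(ns)))
    background <- matrix(rnorm(50 * ns), 50)
    ge <- rbind(targets, background)
    rownames(ge) <- sprintf("g%d", 1:100)
    gr <- categorize_genes(sprintf("g%d", 1:50), character(0), rownames(ge))
    correlate_targets(mirv, ge, gr)$tests$p[1] < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("overlap statistics follow inclusion-exclusion", {
  ov <- anticorrelated_overlap(c("g2", "g3"), c("g1", "g2"))
  expect_equal(ov$percent_distinct_a, 50)
  expect_equal(ov$percent_distinct_b, 50)
  expect_equal(ov$jaccard, 1 / 3)

  same <- anticorrelated_overlap(c("a", "b"), c("a", "b"))
  expect_equal(same$percent_distinct_a, 0)
  expect_equal(same$jaccard, 1)
  disj <- anticorrelated_overlap("a", "b")
  expect_equal(disj$percent_distinct_a, 100)
  expect_equal(disj$jaccard, 0)
  empty <- suppressMessages(anticorrelated_overlap(character(0), character(0)))
  expect_true(is.na(empty$percent_distinct_a))
  expect_equal(empty$jaccard, 0)

  # inclusion-exclusion consistency on random sets
  set.seed(89)
  for (i in 1:10) {
    a <- sample(letters, 10); b <- sample(letters, 12)
    o <- anticorrelated_overlap(a, b)
    n_int <- length(intersect(a, b))
    expect_equal(o$percent_distinct_a, (10 - n_int) / 10 * 100)
    expect_equal(o$percent_distinct_b, (12 - n_int) / 12 * 100)
  }
})

test_that("preranked GSEA matches the brute-force running sum", {
  scores <- c(a = 0.9, b = 0.5, c = -0.4, d = -0.8)
  out <- gsea_preranked(scores, "a", n_perm = 50, seed = 1)
  expect_equal(out$es, 1.0)
  # a set at the exact bottom of the ranking scores negatively
  out2 <- gsea_preranked(scores, "d", n_perm = 50, seed = 1)
  expect_lt(out2$es, 0)
  expect_error(gsea_preranked(scores, names(scores)), "proper subset")
  expect_error(gsea_preranked(scores, "zz"), "subset")

  set.seed(91)
  for (i in 1:10) {
    N <- sample(10:50, 1)
    sc <- stats::setNames(rnorm(N), sprintf("g%d", 1:N))
    gs <- sample(names(sc), sample(2:5, 1))
    got <- gsea_preranked(sc, gs, n_perm = 10, seed = 2)
    expect_equal(got$es, gsea_brute(sc, gs), tolerance = 1e-12)
  }

  # independent cross-check against fgsea's enrichment statistic
  skip_if_not_installed("fgsea")
  set.seed(92)
  sc3 <- stats::setNames(rnorm(40), sprintf("g%d", 1:40))
  gs3 <- sample(names(sc3), 6)
  srt <- sort(sc3, decreasing = TRUE)
  ref <- fgsea::calcGseaStat(srt,
                             selectedStats = which(names(srt) %in% gs3),
                             gseaParam = 1)
  expect_equal(gsea_preranked(sc3, gs3, n_perm = 5, seed = 1)$es, ref,
               tolerance = 1e-12)

  # weight 0: ES invariant under monotone rescaling of scores
  sc <- stats::setNames(rnorm(30), sprintf("g%d", 1:30))
  gs <- sprintf("g%d", 1:5)
  e1 <- gsea_preranked(sc, gs, weight = 0, n_perm = 10, seed = 3)$es
  e2 <- gsea_preranked(exp(2 * sc), gs, weight = 0, n_perm = 10, seed = 3)$es
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("Jaccard module clustering merges the most similar sets first", {
  sets <- list(A = sprintf("g%d", 1:20),
               B = sprintf("g%d", 3:20),      # shares 18/20 with A
               C = sprintf("h%d", 1:10))
  jc <- jaccard_module_cluster(sets)
  expect_equal(jc$dissimilarity["A", "C"], 1)   # disjoint
  expect_lt(jc$dissimilarity["A", "B"], 0.2)
  merge1 <- jc$tree$merge[1, ]
  expect_setequal(jc$tree$labels[-merge1], c("A", "B"))

  dup <- jaccard_module_cluster(list(x = c("a"), y = c("a")))
  expect_equal(dup$dissimilarity["x", "y"], 0)
  expect_error(jaccard_module_cluster(list(a = "g")), "at least 2")
  expect_message(jaccard_module_cluster(list(a = character(0),
                                             b = character(0))),
                 "empty")
})
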