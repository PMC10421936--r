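test_that("triplet classification implements the two-direction alpha rule", {
  expect_equal(classify_triplet(0.01, 0.30), "causal")
  expect_equal(classify_triplet(0.30, 0.01), "reactive")
  expect_equal(classify_triplet(0.30, 0.40), "independent")
  expect_equal(classify_triplet(0.01, 0.02), "non_inferable")
  # boundary: alpha itself is not significant
  expect_equal(classify_triplet(0.05, 0.05), "independent")
  expect_equal(classify_triplet(c(0.01, 0.3), c(0.3, 0.01)),
               c("causal", "reactive"))
  expect_error(classify_triplet(1.2, 0.5), "p_causal")
})

test_that("cit_test validates inputs and honors the omnibus max rule", {
  set.seed(61)
  tr <- make_triplet("causal", n = 100)
  expect_error(cit_test(tr$L[1:20], tr$G[1:20], tr$T[1:20]), "at least 30")
  expect_error(cit_test(rep(1, 100), tr$G, tr$T), "polymorphic")
  expect_error(cit_test(tr$L, rep(0, 100), tr$T), "constant")
  expect_warning(cit_test(tr$L, tr$G, tr$T, n_perm = 10, seed = 1), "coarse")

  # outcome pure noise with a strong L->M link: p1 dominates the omnibus
  set.seed(62)
  L <- rbinom(200, 2, 0.4)
  M <- as.numeric(scale(L)) * 1.5 + rnorm(200)
  T_noise <- rnorm(200)
  ct <- cit_test(L, M, T_noise, seed = 5)
  expect_equal(ct$p_causal, max(ct$p1, ct$p2, ct$p3, ct$p4))
  expect_gte(ct$p_causal, ct$p1)
  expect_gt(ct$p_causal, 0.05)
})

test_that("directional p-values are exactly symmetric under argument swap", {
  set.seed(63)
  tr <- make_triplet("causal", n = 150)
  a <- cit_test(tr$L, tr$G, tr$T, seed = 77)
  b <- cit_test(tr$L, tr$T, tr$G, seed = 77)
  expect_identical(a$p_causal, b$p_reactive)
  expect_identical(a$p_reactive, b$p_causal)
})

test_that("weakening the mediated link can only raise the causal p-value", {
  # common random numbers: same L and noise, shrinking the M->T slope
  set.seed(64)
  n <- 300
  L <- rbinom(n, 2, 0.3)
  Ls <- as.numeric(scale(L))
  e1 <- rnorm(n); e2 <- rnorm(n)
  G <- 0.8 * Ls + e1
  p_by_b <- vapply(c(0.8, 0.3, 0.05), function(b) {
    cit_test(L, G, b * G + e2, seed = 101)$p_causal
  }, numeric(1))
  expect_true(all(p_by_b[1] <= p_by_b[-1]))
})

test_that("cit_test classifies generated classes with covariate adjustment", {
  set.seed(65)
  n <- 300
  covs <- data.frame(age = rnorm(n), sex = factor(sample(c("m", "f"), n, TRUE)))
  L <- rbinom(n, 2, 0.3)
  Ls <- as.numeric(scale(L))
  cov_eff <- 0.5 * covs$age
  G <- 0.8 * Ls + cov_eff + rnorm(n)
  T_ <- 0.8 * (G - cov_eff) + cov_eff + rnorm(n)
  ct <- cit_test(L, G, T_, covariates = covs, seed = 9)
  expect_equal(ct$call, "causal")
  # factor coding agrees on the call for a strong triplet
  ct_f <- cit_test(L, G, T_, covariates = covs, seed = 9, coding = "factor")
  expect_equal(ct_f$call, "causal")
})

test_that("network construction keeps only eQTL-backed causal mediations", {
  cit <- data.frame(
    snp_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    mirna_id = c("m1", "m1", "m2", "m3", "m4"),
    gene_id = c("g1", "g1", "g2", "g3", "g4"),
    p_causal = c(0.01, 0.02, 0.01, 0.5, 0.01),
    p_reactive = c(0.5, 0.6, 0.7, 0.6, 0.5),
    call = c("causal", "causal", "causal", "independent", "causal"),
    stringsAsFactors = FALSE)
  eqtl <- data.frame(snp = c("rs1", "rs2", "rs3", "rs4"),
                     feature = c("m1", "m1", "m2", "m3"))
  net <- build_network(cit, eqtl, "COPD")
  # two causal triplets share the m1 -> g1 edge via different SNPs
  expect_equal(nrow(net$edges), 2)
  e1 <- net$edges[net$edges$mirna == "m1", ]
  expect_equal(e1$n_triplets, 2L)
  # m4 -> g4 causal but its SNP-miRNA pair is not an eQTL: excluded
  expect_false("m4" %in% net$edges$mirna)
  # independents never contribute
  expect_false("m3" %in% net$edges$mirna)

  empty <- build_network(cit[cit$call == "independent", ], eqtl, "ILD")
  expect_equal(nrow(empty$edges), 0)
  expect_equal(network_degrees(net)[["m1"]], 1L)
})

test_that("scale-free fit recovers a constructed power law", {
  # integer frequencies exactly proportional to d^-2
  d <- 1:6
  freq <- 3600 / d^2          # 3600 900 400 225 144 100, all integers
  degrees <- rep(d, freq)
  fit <- scale_free_fit(degrees)
  expect_equal(fit$slope, -2, tolerance = 1e-10)
  expect_equal(fit$r, -1, tolerance = 1e-10)

  expect_error(scale_free_fit(rep(3, 50)), "3 distinct")
  flat <- rep(1:5, each = 20)
  fit_flat <- scale_free_fit(flat)
  expect_equal(fit_flat$slope, 0, tolerance = 1e-10)
})

test_that("Fisher exact matches full enumeration and degenerate rules", {
  expect_equal(fisher_exact(matrix(0, 2, 2)), 1)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
  set.seed(67)
  for (i in 1:25) {
    tab <- matrix(rpois(4, sample(3:12, 1)), 2)
    if (sum(tab) > 30) tab <- tab %/% 2L
    expect_equal(fisher_exact(tab), fisher_enum(tab), tolerance = 1e-12)
  }
})

test_that("differential connectivity uses union-universe Fisher tables", {
  net_a <- structure(list(condition = "COPD", edges = data.frame(
    mirna = rep("m1", 30), gene = sprintf("g%d", 1:30),
    n_triplets = 1L)), class = "mirna_network")
  net_b <- structure(list(condition = "Control", edges = data.frame(
    mirna = rep("m1", 5), gene = sprintf("g%d", 1:5),
    n_triplets = 1L)), class = "mirna_network")
  universe <- sprintf("g%d", 1:100)
  out <- differential_connectivity(net_a, net_b, universe, universe)
  expect_equal(out$degree_a, 30L)
  expect_equal(out$degree_b, 5L)
  p_oracle <- fisher_enum(matrix(c(30, 70, 5, 95), 2, byrow = TRUE))
  expect_equal(out$p, p_oracle, tolerance = 1e-10)

  same <- differential_connectivity(net_a, net_a, universe, universe)
  expect_equal(same$p, 1)
  expect_false(same$differentially_connected)
})

test_that("a planted mini-cohort yields exactly the causal edges", {
  set.seed(69)
  cfg <- sim_config(n_subjects = 500, n_snps = 0, n_mirna = 0, n_gene = 0,
                    triplet_spec = data.frame(
                      class = c(rep("causal", 3), rep("independent", 2)),
                      effect_snp_mirna = 0.9, effect_mirna_gene = 0.9),
                    seed = 70)
  sim <- simulate_triplets(cfg)
  trips <- sim$truth[, c("snp_id", "mirna_id", "gene_id")]
  cit <- cit_scan(trips, sim$genotypes, sim$mirna, sim$gene, seed = 71)
  eqtl <- data.frame(snp = sim$truth$snp_id, feature = sim$truth$mirna_id)
  net <- build_network(cit, eqtl, "synthetic")
  expect_setequal(paste(net$edges$mirna, net$edges$gene),
                  paste(sim$truth$mirna_id[1:3], sim$truth$gene_id[1:3]))
})
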