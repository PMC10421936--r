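test_that("read counting follows the 1-base same-strand overlap rule", {
  loci <- make_loci()
  # containment, strand mismatch, boundary-touching
  reads <- rbind(
    make_read("chr1", 100, 122, "+", name = "inside"),
    make_read("chr1", 100, 122, "-", name = "wrong_strand"),
    make_read("chr1", 129, 150, "+", name = "one_base"),
    make_read("chr1", 130, 150, "+", name = "adjacent_no_overlap"),
    make_read("chr2", 100, 122, "-", name = "minus_ok"))
  cm <- count_reads_per_mirna(reads, loci)
  expect_s3_class(cm, "mirna_counts")
  expect_equal(unname(cm$counts["mir-a", "s1"]), 2L)  # inside + one_base
  expect_equal(unname(cm$counts["mir-c", "s1"]), 1L)
  expect_equal(unname(cm$sample_totals[["s1"]]), 3L)

  # a read spanning two loci increments both but counts once in the total
  loci2 <- data.frame(name = c("a", "b"), chrom = "chr1",
                      start = c(0L, 15L), end = c(20L, 40L), strand = "+")
  r2 <- make_read("chr1", 10, 25, "+")
  cm2 <- count_reads_per_mirna(r2, loci2)
  expect_equal(unname(cm2$counts[, "s1"]), c(1L, 1L))
  expect_equal(unname(cm2$sample_totals[["s1"]]), 1L)

  expect_error(count_reads_per_mirna(make_read("chr1", 50, 50, "+"), loci),
               "malformed")

  # conservation: all simulated reads at one locus land in its count
  locus <- loci[1, ]
  rr <- simulate_reads_at_locus(locus, c(`0` = .8, `-1` = .2), 1000, seed = 8)
  cm3 <- count_reads_per_mirna(rr, loci)
  expect_equal(sum(cm3$counts[, "sample_1"]), 1000L)
})

test_that("read-length QC flags profile outliers against the median profile", {
  peaked <- rep(22L, 200)
  samples <- c(replicate(9, peaked, simplify = FALSE),
               list(rep(15:36, each = 10)))
  names(samples) <- sprintf("s%d", 1:10)
  qc <- read_length_qc(samples, outlier_threshold = 5)
  expect_identical(qc$pass, c(rep(TRUE, 9), FALSE))
  expect_match(qc$reason[10], "outlier")

  all_same <- stats::setNames(replicate(4, peaked, simplify = FALSE),
                              paste0("x", 1:4))
  expect_true(all(read_length_qc(all_same)$pass))

  expect_error(read_length_qc(samples[1:2]), "at least 3")

  with_empty <- samples
  with_empty$s10 <- integer(0)
  qc2 <- read_length_qc(with_empty)
  expect_false(qc2$pass[10])
  expect_match(qc2$reason[10], "no reads")
})

test_that("RPM normalization is exact, pseudocounted and strictly monotone", {
  cm <- mirna_counts(matrix(c(999L, 0L), 2, 1,
                            dimnames = list(c("m1", "m2"), "s1")),
                     sample_totals = c(s1 = 1e6))
  nm <- rpm_normalize(cm)
  expect_equal(unname(nm$values["m1", 1]), log2(1000))
  expect_equal(unname(nm$values["m2", 1]), 0)

  set.seed(1)
  counts <- matrix(rpois(200, 50), 20, 10,
                   dimnames = list(sprintf("m%d", 1:20), sprintf("s%d", 1:10)))
  nm2 <- rpm_normalize(mirna_counts(counts))
  bumped <- counts; bumped[3, 4] <- bumped[3, 4] * 2L
  nm3 <- rpm_normalize(mirna_counts(bumped, sample_totals = colSums(counts)))
  expect_gt(nm3$values[3, 4], nm2$values[3, 4])

  bad <- mirna_counts(matrix(0L, 1, 2, dimnames = list("m", c("ok", "empty"))),
                      sample_totals = c(ok = 10, empty = 0))
  expect_error(rpm_normalize(bad), "empty")
})

test_that("detection filter applies the >= min_count in >= min_fraction rule", {
  m <- matrix(c(2, 2, 0, 0,
                2, 1, 1, 1,
                0, 0, 0, 0), 3, 4, byrow = TRUE,
              dimnames = list(c("kept", "dropped", "zero"), NULL))
  kept <- detection_filter(m)
  expect_identical(kept, "kept")
  expect_identical(detection_filter(matrix(0, 3, 4,
                                           dimnames = list(letters[1:3], NULL))),
                   character(0))
  # idempotence
  expect_identical(detection_filter(m[kept, , drop = FALSE]), kept)
})

test_that("isomiR grouping is strand-aware and conserves locus counts", {
  locus <- list(name = "mir-a", chrom = "chr1", start = 100L, end = 122L,
                strand = "+")
  reads <- rbind(
    do.call(rbind, replicate(70, make_read("chr1", 100, 122, "+"),
                             simplify = FALSE)),
    do.call(rbind, replicate(20, make_read("chr1", 99, 121, "+"),
                             simplify = FALSE)),
    do.call(rbind, replicate(10, make_read("chr1", 101, 123, "+"),
                             simplify = FALSE)))
  iso <- group_isomirs(reads, locus)
  expect_equal(iso$offset5, c(-1L, 0L, 1L))
  expect_equal(iso$count, c(20L, 70L, 10L))
  expect_equal(sum(iso$count), nrow(reads))

  single <- group_isomirs(make_read("chr1", 98, 120, "+"), locus)
  expect_equal(nrow(single), 1L)
  expect_equal(single$offset5, -2L)
  expect_equal(single$count, 1L)

  expect_message(
    both <- group_isomirs(rbind(make_read("chr1", 100, 122, "+"),
                                make_read("chr1", 100, 122, "-")), locus),
    "opposite strand")
  expect_equal(sum(both$count), 1L)

  # conservation on a random fixture drawn from the generator
  rr <- simulate_reads_at_locus(locus, c(`0` = .5, `-1` = .3, `2` = .2),
                                500, seed = 12)
  iso2 <- group_isomirs(rr, locus)
  expect_equal(sum(iso2$count), 500L)

  # minus-strand offsets come from the interval end
  locus_m <- list(name = "mir-m", chrom = "chr2", start = 100L, end = 122L,
                  strand = "-")
  iso_m <- group_isomirs(make_read("chr2", 101, 123, "-"), locus_m)
  expect_equal(iso_m$offset5, -1L)
})

test_that("batch adjustment: identity on one batch, error on singletons", {
  set.seed(2)
  vals <- matrix(rnorm(50), 5, 10,
                 dimnames = list(sprintf("m%d", 1:5), sprintf("s%d", 1:10)))
  nm <- structure(list(values = vals, pseudocount = 1,
                       batch_adjusted = FALSE, batch = rep("A", 10)),
                  class = "mirna_norm")
  out <- batch_adjust(nm, rep("A", 10))
  expect_identical(out$values, vals)
  expect_true(out$batch_adjusted)
  expect_error(batch_adjust(nm, c(rep("A", 9), "B")), "at least 2 samples")
})

test_that("batch adjustment removes a planted protocol shift while preserving biology", {
  set.seed(31)
  n <- 60; F <- 40
  base <- rnorm(2 * n)
  grp <- rep(rep(0:1, each = n / 2), 2)              # orthogonal to batch
  batch <- rep(c("p1", "p2"), each = n)
  vals <- matrix(rep(base, each = F), F) +
    matrix(rnorm(F * 2 * n, sd = 0.3), F)
  vals <- vals + 1.5 * matrix(rep(grp, each = F), F)  # biology
  vals[, batch == "p2"] <- vals[, batch == "p2"] + 2  # protocol shift
  dimnames(vals) <- list(sprintf("m%d", 1:F), sprintf("s%d", 1:(2 * n)))
  adj <- batch_adjust(vals, batch, covariates = data.frame(grp = factor(grp)))
  shift_left <- rowMeans(adj$values[, batch == "p2"]) -
    rowMeans(adj$values[, batch == "p1"])
  expect_lt(max(abs(shift_left)), 0.2)
  grp_effect <- mean(rowMeans(adj$values[, grp == 1]) -
                       rowMeans(adj$values[, grp == 0]))
  expect_lt(abs(grp_effect - 1.5), 0.15)
})
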