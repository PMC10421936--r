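#' Residualize expression on covariates
#'
#' Least-squares projection removing the covariate column space (plus an
#' intercept) from every feature row; residuals are orthogonal to the
#' covariates.
#'
#' @param mat numeric matrix, features x samples.
#' @param covariates data frame or matrix of per-sample covariates; factors
#'   are expanded to dummies. `NULL` removes only the mean.
#' @return residual matrix of the same dimensions.
#' @export
residualize <- function(mat, covariates = NULL) {
  mat <- as.matrix(mat)
  X <- .covariate_matrix(covariates, ncol(mat))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient covariates; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  t(qr.resid(qr_x, t(mat)))
}

.covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1,
                                         dimnames = list(NULL, "(Intercept)")))
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  if (nrow(X) != n) stop("covariates must have one row per sample")
  X
}

#' Covariate-adjusted eQTL scan
#'
#' Tests every SNP against every expression feature after projecting the
#' covariates out of the expression (and, in additive mode, the genotype).
#' `mode = "anova"` treats the genotype as a factor over its observed levels
#' (F-test); `mode = "additive"` uses the allele-dosage correlation of the
#' residualized variables (t-test with `n - c - 2` df, where c counts the
#' non-intercept covariate columns). Both are algebraically identical to the
#' per-pair regression `expr ~ covariates + genotype`. Monomorphic SNPs are
#' skipped with a message.
#'
#' @param genotypes integer matrix, SNPs x samples, coded 0/1/2 (NA allowed;
#'   samples with NA are dropped pairwise per SNP).
#' @param expression numeric matrix, features x samples.
#' @param covariates optional per-sample covariate table (age, gender,
#'   smoking, genotype principal components, ...).
#' @param p_threshold retain records with p below this (1 keeps everything).
#' @param mode `"anova"` or `"additive"`.
#' @return data frame of class `eqtl_records`: `snp`, `feature`,
#'   `statistic`, `df1`, `df2`, `p`, sorted by p.
#' @export
eqtl_scan <- function(genotypes, expression, covariates = NULL,
                      p_threshold = 5e-4, mode = c("anova", "additive")) {
  mode <- match.arg(mode)
  genotypes <- as.matrix(genotypes)
  expression <- as.matrix(expression)
  n <- ncol(expression)
  if (ncol(genotypes) != n) stop("genotypes and expression must share samples")
  if (!is.null(colnames(genotypes)) && !is.null(colnames(expression)) &&
      !identical(colnames(genotypes), colnames(expression)))
    stop("sample ordering differs between genotypes and expression")
  X <- .covariate_matrix(covariates, n)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("rank-deficient covariates")
  E <- t(qr.resid(qr_x, t(expression)))   # features x samples
  rss0 <- rowSums(E^2)
  c_extra <- ncol(X) - 1                  # non-intercept covariates
  snps <- rownames(genotypes)
  if (is.null(snps)) snps <- sprintf("snp_%d", seq_len(nrow(genotypes)))
  feats <- rownames(expression)
  if (is.null(feats)) feats <- sprintf("feature_%d", seq_len(nrow(expression)))
  out <- vector("list", nrow(genotypes))
  skipped <- 0L
  for (i in seq_len(nrow(genotypes))) {
    g <- as.numeric(genotypes[i, ])
    if (anyNA(g)) next_keep <- !is.na(g) else next_keep <- rep(TRUE, n)
    g_use <- g[next_keep]
    if (length(unique(g_use)) < 2) { skipped <- skipped + 1L; next }
    if (all(next_keep)) {
      Ei <- E; rss0i <- rss0; qr_i <- qr_x; ni <- n
    } else {
      Xi <- X[next_keep, , drop = FALSE]
      qr_i <- qr(Xi)
      Ei <- t(qr.resid(qr_i, t(expression[, next_keep, drop = FALSE])))
      rss0i <- rowSums(Ei^2)
      ni <- sum(next_keep)
    }
    if (mode == "additive") {
      gr <- qr.resid(qr_i, g_use)
      df2 <- ni - c_extra - 2
      gn <- sqrt(sum(gr^2))
      if (gn < 1e-12) { skipped <- skipped + 1L; next }
      b <- as.numeric(Ei %*% gr)
      r <- b / (gn * sqrt(rss0i))
      r <- pmin(pmax(r, -1), 1)
      tt <- r * sqrt(df2 / pmax(1 - r^2, 1e-300))
      p <- 2 * stats::pt(-abs(tt), df2)
      stat <- tt; df1 <- 1
    } else {
      D <- stats::model.matrix(~ factor(g_use))[, -1, drop = FALSE]
      Dr <- qr.resid(qr_i, D)
      qd <- qr(Dr)
      m <- qd$rank
      if (m < 1) { skipped <- skipped + 1L; next }
      Q <- qr.Q(qd)[, seq_len(m), drop = FALSE]
      proj <- Ei %*% Q
      rss1 <- pmax(rss0i - rowSums(proj^2), 0)
      df2 <- ni - c_extra - 1 - m
      stat <- (rss0i - rss1) / m / (rss1 / df2)
      p <- stats::pf(stat, m, df2, lower.tail = FALSE)
      df1 <- m
    }
    keep <- which(p < p_threshold | p_threshold >= 1)
    if (length(keep))
      out[[i]] <- data.frame(snp = snps[i], feature = feats[keep],
                             statistic = stat[keep], df1 = df1, df2 = df2,
                             p = p[keep], stringsAsFactors = FALSE)
  }
  if (skipped > 0) message(skipped, " monomorphic/degenerate SNP(s) skipped")
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(snp = character(), feature = character(),
                      statistic = numeric(), df1 = numeric(),
                      df2 = numeric(), p = numeric())
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("eqtl_records", "data.frame")
  res
}

#' Classify eQTL records as cis or trans
#'
#' cis iff SNP and feature lie on the same chromosome and the distance from
#' the SNP to the feature start is at most `window` (inclusive boundary);
#' everything else is trans. Records without positions are dropped with a
#' warning.
#'
#' @param records eQTL record data frame (`snp`, `feature`, ...).
#' @param snp_positions data frame: `id`, `chrom`, `pos`.
#' @param feature_positions data frame: `id`, `chrom`, `start`.
#' @param window cis window in bases (default 1 Mb).
#' @return `records` with an added `relationship` column.
#' @export
classify_cis_trans <- function(records, snp_positions, feature_positions,
                               window = 1e6) {
  si <- match(records$snp, snp_positions$id)
  fi <- match(records$feature, feature_positions$id)
  missing <- is.na(si) | is.na(fi)
  if (any(missing)) {
    warning(sum(missing), " record(s) dropped for missing positions")
    records <- records[!missing, , drop = FALSE]
    si <- si[!missing]; fi <- fi[!missing]
  }
  same_chrom <- snp_positions$chrom[si] == feature_positions$chrom[fi]
  dist <- abs(snp_positions$pos[si] - feature_positions$start[fi])
  records$relationship <- ifelse(same_chrom & dist <= window, "cis", "trans")
  records
}

#' Tabulate eQTL counts per condition with cross-condition ratios
#'
#' Builds the standard cohort-comparison summary: per condition, feature
#' type and cis/trans relationship, the number of eQTL pairs and the number
#' of unique features with at least one eQTL; unique counts must never
#' exceed pair counts.
#'
#' @param records_by_condition named list of classified eQTL record data
#'   frames, each with a `feature_type` column (`"gene"`/`"mirna"`); names
#'   are condition labels.
#' @return data frame: `condition`, `feature_type`, `relationship`,
#'   `n_pairs`, `n_unique`.
#' @export
tabulate_eqtl_summary <- function(records_by_condition) {
  rows <- list()
  for (cond in names(records_by_condition)) {
    rec <- records_by_condition[[cond]]
    for (ft in unique(rec$feature_type)) {
      for (rel in c("cis", "trans")) {
        sub <- rec[rec$feature_type == ft & rec$relationship == rel, ]
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond, feature_type = ft, relationship = rel,
          n_pairs = nrow(sub), n_unique = length(unique(sub$feature)),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  stopifnot(all(out$n_unique <= out$n_pairs))
  out
}

#' Cross-condition eQTL count ratio
#'
#' Ratio (rounded to 2 decimals) of a summary count between two conditions,
#' e.g. the unique-trans-gene ratio between a COPD and an ILD cohort.
#'
#' @param summary data frame as produced by [tabulate_eqtl_summary()] (or an
#'   equivalent printed reference table) with columns `condition`,
#'   `feature_type`, `relationship` and the count column.
#' @param feature_type,relationship which stratum to compare.
#' @param numerator,denominator condition labels.
#' @param count which count column to ratio (default `"n_unique"`).
#' @return the rounded ratio.
#' @export
eqtl_count_ratio <- function(summary, feature_type, relationship,
                             numerator, denominator, count = "n_unique") {
  pick <- function(cond) {
    v <- summary[summary$condition == cond &
                 summary$feature_type == feature_type &
                 summary$relationship == relationship, count]
    if (length(v) != 1) stop("summary stratum not found for ", cond)
    v
  }
  round(pick(numerator) / pick(denominator), 2)
}
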