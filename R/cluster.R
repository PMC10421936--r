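#' Partitioning around medoids
#'
#' BUILD + SWAP PAM on a dissimilarity matrix (delegates to
#' `cluster::pam`); the total dissimilarity of items to their medoids is a
#' local optimum under single-medoid swaps.
#'
#' @param d square symmetric nonnegative dissimilarity matrix.
#' @param k number of clusters, `1 <= k <= n` (`k = n` puts every item in
#'   its own cluster with objective 0).
#' @param seed unused (the algorithm is deterministic); kept so callers can
#'   treat all clustering entry points uniformly.
#' @return list: `assignments` (integer vector), `medoids` (indices),
#'   `objective` (sum of dissimilarities to assigned medoids).
#' @export
pam_cluster <- function(d, k, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (ncol(d) != n) stop("dissimilarity matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("dissimilarity matrix must be symmetric")
  if (any(d < 0)) stop("dissimilarities must be nonnegative")
  if (k > n) stop("k must not exceed the number of items")
  if (k < 1) stop("k must be at least 1")
  if (k == n) {
    return(list(assignments = seq_len(n), medoids = seq_len(n),
                objective = 0))
  }
  fit <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE,
                      nstart = 1L, variant = "original")
  med <- as.integer(fit$id.med)
  assign <- as.integer(fit$clustering)
  obj <- sum(d[cbind(seq_len(n), med[assign])])
  list(assignments = assign, medoids = med, objective = obj)
}

#' Consensus clustering by resampled PAM
#'
#' For each resample, a fraction of items is subsampled without replacement
#' and clustered with PAM on Euclidean distances; co-clustering counts are
#' normalized by co-sampling counts to give the consensus matrix at each k.
#' Final assignments come from average-linkage hierarchical clustering of
#' (1 - consensus).
#'
#' @param mat numeric matrix, features x items (items are clustered).
#' @param k_range integer vector of candidate cluster numbers.
#' @param n_resamples number of subsampling iterations.
#' @param item_fraction fraction of items drawn per resample.
#' @param seed integer seed for the resampling stream.
#' @return list of class `consensus_result`: per k the consensus matrix,
#'   `assignments`, `cophenetic` score and `avg_item_consensus`.
#' @export
consensus_cluster <- function(mat, k_range, n_resamples = 1000,
                              item_fraction = 0.8, seed = 1L) {
  n <- ncol(mat)
  if (n < 2) stop("need at least 2 items")
  if (max(k_range) >= n * item_fraction)
    stop("largest k must be below n * item_fraction")
  if (!is.null(seed)) set.seed(seed)
  d_full <- as.matrix(stats::dist(t(mat)))
  m <- max(2L, floor(item_fraction * n))
  subs <- replicate(n_resamples, sort(sample.int(n, m)), simplify = FALSE)
  items <- colnames(mat)
  if (is.null(items)) items <- sprintf("item_%d", seq_len(n))
  res <- list()
  co_sampled <- matrix(0, n, n)
  for (s in subs) co_sampled[s, s] <- co_sampled[s, s] + 1
  for (k in k_range) {
    co_clust <- matrix(0, n, n)
    for (s in subs) {
      cl <- pam_cluster(d_full[s, s, drop = FALSE], k)$assignments
      same <- outer(cl, cl, "==")
      co_clust[s, s] <- co_clust[s, s] + same
    }
    consensus <- co_clust / co_sampled
    consensus[co_sampled == 0] <- NaN
    diag(consensus)[diag(co_sampled) > 0] <- 1
    dimnames(consensus) <- list(items, items)
    dmat <- 1 - consensus
    dmat[is.nan(dmat)] <- 1
    hc <- stats::hclust(stats::as.dist(dmat), method = "average")
    assign <- stats::cutree(hc, k = k)
    coph <- suppressWarnings(
      stats::cor(stats::cophenetic(hc), stats::as.dist(dmat)))
    if (!is.finite(coph)) coph <- 1 # zero-spread distances: perfect tree
    aic <- mean(vapply(seq_len(n), function(i) {
      mates <- setdiff(which(assign == assign[i]), i)
      if (!length(mates)) return(1)
      mean(consensus[i, mates], na.rm = TRUE)
    }, numeric(1)), na.rm = TRUE)
    res[[as.character(k)]] <- list(k = k, consensus = consensus,
                                   assignments = assign,
                                   cophenetic = coph,
                                   avg_item_consensus = aic)
  }
  structure(list(by_k = res, k_range = k_range, n = n,
                 n_resamples = n_resamples), class = "consensus_result")
}

#' Select the number of clusters from a consensus result
#'
#' Composite rule formalizing the usual consensus-clustering heuristic: for
#' each candidate k the base score is the mean of the cophenetic score and
#' the average item consensus; the composite adds the drop of that base
#' score at k+1 (stable solutions just before a collapse are preferred).
#' Candidates producing a cluster smaller than `min_size` are excluded.
#' Ties go to the smallest k.
#'
#' @param cres a `consensus_result`.
#' @param min_size minimum admissible cluster size.
#' @return the selected k (integer).
#' @export
select_k <- function(cres, min_size = 2) {
  stopifnot(inherits(cres, "consensus_result"))
  ks <- cres$k_range
  if (length(ks) == 1) return(ks)
  base <- vapply(as.character(ks), function(k) {
    r <- cres$by_k[[k]]
    (r$cophenetic + r$avg_item_consensus) / 2
  }, numeric(1))
  drop <- c(base[-length(base)] - base[-1], 0)
  composite <- base + pmax(drop, 0)
  ok <- vapply(as.character(ks), function(k)
    min(table(cres$by_k[[k]]$assignments)) >= min_size, logical(1))
  if (!any(ok)) ok[] <- TRUE
  composite[!ok] <- -Inf
  best <- composite[ok]
  if (length(unique(round(best, 12))) == 1)
    message("select_k: scores tied across k; returning the smallest")
  ks[which.max(composite)] # which.max takes the first (smallest k) on ties
}

#' Module meta-score (PC1 of z-scored members)
#'
#' Member miRNAs are z-scored across samples and the first principal
#' component over samples is the meta-score. The sign is fixed so the score
#' correlates positively with the module's mean z-profile. Zero-variance
#' members are dropped with a warning.
#'
#' @param mat expression matrix, features x samples.
#' @param members feature names (>= 2) forming the module.
#' @return list of class `module_score`: `score` (zero-mean over samples),
#'   `sign_flipped`, `var_explained`, `members_used`.
#' @export
module_meta_score <- function(mat, members) {
  members <- intersect(members, rownames(mat))
  if (length(members) < 2) stop("module must have at least 2 members")
  x <- mat[members, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance member(s): ",
            paste(members[sds == 0], collapse = ", "))
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) < 2) stop("fewer than 2 members with variance")
  }
  z <- t(scale(t(x)))
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  score <- pc$x[, 1]
  flipped <- FALSE
  mean_prof <- colMeans(z)
  if (stats::sd(mean_prof) > 0 && stats::cor(score, mean_prof) < 0) {
    score <- -score
    flipped <- TRUE
  }
  structure(list(score = score, sign_flipped = flipped,
                 var_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
                 leading_eigenvalue = pc$sdev[1]^2,
                 members_used = rownames(z)),
            class = "module_score")
}

#' Associate sample clusters with an outcome
#'
#' Fits `outcome ~ cluster + covariates` with the control-enriched cluster
#' as the baseline level; `family = "logistic"` uses a binomial GLM (for
#' disease status), `family = "linear"` a Gaussian model (for clinical
#' phenotypes). Wald p-values are reported per non-baseline cluster term.
#' Separated logistic fits are flagged and refit with a ridge-penalized
#' likelihood (documented fallback).
#'
#' @param outcome numeric (linear) or 0/1-coercible (logistic) response.
#' @param cluster_labels per-sample cluster labels.
#' @param covariates optional data frame of adjustment covariates.
#' @param family `"linear"` or `"logistic"`.
#' @param baseline baseline cluster label (defaults to the first level).
#' @return data frame: `cluster`, `coefficient`, `se`, `p`, `separated`.
#' @export
associate_cluster <- function(outcome, cluster_labels, covariates = NULL,
                              family = c("linear", "logistic"),
                              baseline = NULL) {
  family <- match.arg(family)
  cl <- factor(cluster_labels)
  if (!is.null(baseline)) cl <- stats::relevel(cl, ref = as.character(baseline))
  dat <- data.frame(.y = outcome, .cluster = cl)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  separated <- FALSE
  if (family == "linear") {
    fit <- stats::lm(.y ~ ., data = dat)
    sm <- summary(fit)$coefficients
  } else {
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = dat, family = stats::binomial()))
    mu <- stats::fitted(fit)
    if (!fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8) ||
        any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
      separated <- TRUE
      sm <- .ridge_logistic(dat)
    } else sm <- summary(fit)$coefficients
  }
  idx <- grep("^\\.cluster", rownames(sm))
  data.frame(cluster = sub("^\\.cluster", "", rownames(sm)[idx]),
             coefficient = sm[idx, 1], se = sm[idx, 2],
             p = sm[idx, 4], separated = separated,
             row.names = NULL, stringsAsFactors = FALSE)
}

# ridge-penalized logistic fit (lambda/2 * ||beta||^2 on non-intercept
# terms) with Wald SEs from the penalized Hessian; used when the MLE is
# separated
.ridge_logistic <- function(dat, lambda = 1) {
  X <- stats::model.matrix(~ ., data = dat[setdiff(names(dat), ".y")])
  y <- as.numeric(dat$.y)
  pen <- c(0, rep(lambda, ncol(X) - 1))
  nll <- function(b) {
    eta <- X %*% b
    -sum(y * eta - log1p(exp(eta))) + sum(pen * b^2) / 2
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS", hessian = TRUE)
  se <- sqrt(diag(solve(opt$hessian)))
  z <- opt$par / se
  out <- cbind(Estimate = opt$par, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  rownames(out) <- colnames(X)
  out
}
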