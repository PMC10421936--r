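#' Fit a negative-binomial GLM to one miRNA's counts
#'
#' Log-link NB regression with theta estimated by maximum likelihood
#' (`MASS::glm.nb`, which alternates IRLS for the coefficients with 1-D
#' likelihood maximization for theta). When the ML alternation degenerates
#' (e.g. underdispersed or constant counts, where theta diverges), the fit
#' falls back to a method-of-moments theta, refined by `MASS::theta.ml`
#' where possible, inside a fixed-theta NB family fit. Theta is clamped to
#' [1e-3, 1e7].
#'
#' @param y nonnegative integer counts (not all zero).
#' @param design data frame of predictors (read depth, protocol, smoking,
#'   age, gender, disease terms, ...); `NULL` fits an intercept-only model.
#' @return list of class `nb_fit`: `coefficients` (natural-log scale),
#'   `theta`, `log_likelihood`, `converged`, `fitted`, `df`.
#' @export
fit_nb_glm <- function(y, design = NULL) {
  if (any(y < 0) || any(y != floor(y))) stop("counts must be nonnegative integers")
  if (all(y == 0)) stop("all-zero counts: no NB fit possible")
  dat <- if (is.null(design)) data.frame(y = y)
         else data.frame(y = y, design, check.names = TRUE)
  if (nrow(dat) <= ncol(dat)) stop("need more observations than predictors")
  fit <- tryCatch(
    withCallingHandlers(
      MASS::glm.nb(y ~ ., data = dat,
                   control = stats::glm.control(maxit = 100)),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  converged <- !is.null(fit) && isTRUE(fit$converged)
  if (is.null(fit) || !is.finite(fit$theta)) {
    pf <- suppressWarnings(stats::glm(y ~ ., data = dat,
                                      family = stats::poisson()))
    mu <- stats::fitted(pf)
    num <- sum((y - mu)^2 - mu)
    theta <- if (num <= 0) 1e7 else sum(mu^2) / num
    theta <- min(max(theta, 1e-3), 1e7)
    theta <- tryCatch(
      suppressWarnings(as.numeric(MASS::theta.ml(y, mu, limit = 50))),
      error = function(e) theta)
    theta <- min(max(theta, 1e-3), 1e7)
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = dat,
                 family = MASS::negative.binomial(theta = theta)))
    fit$theta <- theta
    converged <- isTRUE(fit$converged)
  }
  theta <- min(max(fit$theta, 1e-3), 1e7)
  mu <- stats::fitted(fit)
  ll <- sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
  structure(list(coefficients = stats::coef(fit), theta = theta,
                 log_likelihood = ll, converged = converged,
                 fitted = mu, df = length(stats::coef(fit)) + 1L),
            class = "nb_fit")
}

#' Likelihood-ratio test for the disease terms
#'
#' Compares a full NB fit (with COPD and ILD indicator terms) against the
#' nested reduced fit without them: statistic = 2 (llik_full - llik_reduced),
#' chi-squared with `df` degrees of freedom.
#'
#' @param full,reduced `nb_fit` objects, reduced nested in full.
#' @param df degrees of freedom of the test (2 for COPD + ILD).
#' @return list: `statistic`, `df`, `p`.
#' @export
lrt_disease <- function(full, reduced, df = 2) {
  stat <- 2 * (full$log_likelihood - reduced$log_likelihood)
  if (stat < -1e-6)
    warning("full model log-likelihood below reduced model; ",
            "statistic clipped at 0 (consider refitting)")
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values, `q = min over j >= rank of p(j) * n / j`, capped at 1.
#' `NA`/`NaN` p-values propagate and are excluded from `n`.
#'
#' @param pvalues numeric vector in [0, 1] (NA allowed).
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) stop("p-values must be in [0,1]")
  q <- rep(NA_real_, length(pvalues))
  q[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  q
}

#' Call differentially expressed miRNAs
#'
#' A miRNA is called when its BH q-value is below `q_thresh` and the larger
#' disease-coefficient magnitude exceeds `coef_thresh` on the natural-log
#' scale (0.22 corresponds to a fold change of 1.25).
#'
#' @param results data frame with `p_anova`, `coef_copd`, `coef_ild`.
#' @param q_thresh FDR threshold (default 0.1).
#' @param coef_thresh natural-log coefficient threshold (default 0.22).
#' @return `results` with added `q`, `fc_copd`, `fc_ild`, `called`.
#' @export
call_differential <- function(results, q_thresh = 0.1, coef_thresh = 0.22) {
  results$q <- bh_fdr(results$p_anova)
  results$fc_copd <- exp(results$coef_copd)
  results$fc_ild <- exp(results$coef_ild)
  results$called <- !is.na(results$q) & results$q < q_thresh &
    pmax(abs(results$coef_copd), abs(results$coef_ild)) > coef_thresh
  results
}

#' Negative-binomial differential-expression analysis
#'
#' Per miRNA, fits the full NB GLM (log read depth, protocol, smoking, age,
#' gender, COPD, ILD) and the reduced model without the two disease terms,
#' computes the 2-df likelihood-ratio p-value, adjusts with BH and applies
#' the q < `q_thresh`, |coef| > `coef_thresh` calling rule.
#'
#' @param cm a [mirna_counts()] object.
#' @param covariates data frame with per-sample `age`, `gender`, `smoking`,
#'   `batch` (protocol) and `disease` (factor with a control level plus
#'   "COPD"/"ILD").
#' @param q_thresh,coef_thresh calling thresholds.
#' @return data frame, one row per miRNA, with coefficients, p, q, FC, call.
#' @export
de_analysis <- function(cm, covariates, q_thresh = 0.1, coef_thresh = 0.22) {
  stopifnot(inherits(cm, "mirna_counts"))
  n <- ncol(cm$counts)
  stopifnot(nrow(covariates) == n)
  base <- data.frame(
    log_depth = log(cm$sample_totals),
    protocol = factor(covariates$batch),
    smoking = factor(covariates$smoking),
    age = covariates$age,
    gender = factor(covariates$gender)
  )
  # drop single-level factors so the model matrix stays full rank
  base <- base[, vapply(base, function(v)
    !is.factor(v) || nlevels(droplevels(v)) > 1, logical(1)), drop = FALSE]
  full <- cbind(base,
                copd = as.integer(covariates$disease == "COPD"),
                ild = as.integer(covariates$disease == "ILD"))
  out <- lapply(rownames(cm$counts), function(mir) {
    y <- cm$counts[mir, ]
    res <- data.frame(mirna = mir, p_anova = NA_real_,
                      coef_copd = NA_real_, coef_ild = NA_real_,
                      theta = NA_real_, converged = FALSE,
                      stringsAsFactors = FALSE)
    f_full <- tryCatch(fit_nb_glm(y, full), error = function(e) NULL)
    f_red <- tryCatch(fit_nb_glm(y, base), error = function(e) NULL)
    if (is.null(f_full) || is.null(f_red)) return(res)
    lrt <- suppressWarnings(lrt_disease(f_full, f_red, df = 2))
    res$p_anova <- lrt$p
    res$coef_copd <- unname(f_full$coefficients["copd"])
    res$coef_ild <- unname(f_full$coefficients["ild"])
    res$theta <- f_full$theta
    res$converged <- f_full$converged && f_red$converged
    res
  })
  call_differential(do.call(rbind, out), q_thresh, coef_thresh)
}
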