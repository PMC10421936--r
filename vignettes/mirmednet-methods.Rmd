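---
title: "Methods: integrative miRNA mediation-network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative miRNA mediation-network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmednet)
```

# Overview

`mirmednet` implements an integrative analysis of small-RNA sequencing in
chronic lung disease cohorts (COPD, interstitial lung disease, controls).
The pipeline runs in six stages:

1. **Quantification and QC** — counting aligned reads over mature miRNA
   loci, read-length quality control, log2 RPM normalization, detection
   filtering, and ComBat batch adjustment across sequencing protocols.
2. **Differential expression** — per-miRNA negative-binomial GLMs with a
   2-df likelihood-ratio test for the two disease terms.
3. **Consensus clustering** — resampled PAM clustering of samples and
   miRNAs with module meta-scores and cluster–phenotype association models.
4. **eQTL scanning** — covariate-adjusted association of SNP dosages with
   miRNA/mRNA expression, classified cis/trans.
5. **Causal networks** — the causality inference test (CIT) over
   SNP–miRNA–mRNA triplets, condition-specific network assembly, scale-free
   diagnostics, and differential connectivity.
6. **isomiR targets** — 5'-shifted seed extraction, seed-match target
   prediction in 3'UTRs, correlation-based target assessment, preranked
   GSEA, and Jaccard module clustering.

A synthetic-cohort generator provides ground truth for every stage, so the
entire pipeline is testable end to end without any protected data.

# Models and procedures

## Quantification and normalization

A read increments a mature miRNA locus when it overlaps it by at least one
base on the same strand; a read overlapping $k$ loci increments all $k$
(whole-count assignment — fractional weighting of multi-mapped reads is
deliberately not attempted, and column sums may therefore exceed the
per-sample total of assigned reads). Coordinates are 0-based half-open
internally; GFF3 input (1-based closed) is converted on read.

Normalized expression is
$\log_2\!\big((c + 1) / N \times 10^6\big)$,
where $c$ is the locus count and $N$ the raw (pre-pseudocount) per-sample
sum of locus-aligned reads. Keeping $N$ raw keeps the denominator
interpretable as sequencing depth; the pseudocount only floors the
numerator. The detection filter retains miRNAs with at least 2 counts in at
least 50% of samples (both configurable).

Read-length QC formalizes "clusters differently" as a median-profile rule:
each sample's read-length histogram over 15–36 nt bins (proportions) is
compared with the per-bin median profile, and a sample fails when its
Euclidean distance exceeds `outlier_threshold` (default 5) times the median
absolute deviation of all distances. Samples with no reads in range fail
with a reason.

## Batch adjustment

`batch_adjust()` delegates to parametric empirical-Bayes ComBat (the `sva`
package), passing biological covariates into the standardization model so
their signal is preserved. A single batch is returned unchanged; a
singleton batch is an error because its location/scale cannot be estimated.
One property worth knowing: EB shrinkage of per-feature batch effects
toward the across-feature mean means that generic heterogeneous features
retain a small shrinkage residual after adjustment; only when the
per-feature batch effects are homogeneous in-sample (as in the replicated
-profile fixtures used by the tests) is the equalization exact to machine
precision. That is inherent to the empirical-Bayes estimator, not a defect.

## Differential expression

Each miRNA's counts are modeled with a log-link negative-binomial GLM with
sequencing depth (log of the per-sample total), protocol, smoking status,
age, gender, and COPD/ILD indicator terms as predictors. Depth enters as a
covariate rather than an offset, mirroring the modeling choice of treating
depth as a predictor variable; the log transform keeps the fit stable.
Disease significance is a 2-df likelihood-ratio test between the full model
and the model without both disease terms, BH-adjusted across miRNAs. A
miRNA is called differential when $q < 0.1$ and the larger of the two
disease-coefficient magnitudes exceeds 0.22 on the natural-log scale
($e^{0.22} \approx 1.25$, i.e. a 1.25-fold change).

Fitting uses `MASS::glm.nb` (alternating IRLS and 1-D theta likelihood
maximization). Degenerate inputs where the theta iteration diverges
(constant or underdispersed counts) fall back to a method-of-moments theta
refined by `theta.ml` inside a fixed-theta NB family fit; theta is clamped
to $[10^{-3}, 10^7]$. With 350 samples the LRT's chi-squared approximation
is well calibrated (type-I error within the binomial 99% band at
$\alpha \in \{0.01, 0.05\}$ over 2000 null features); at much smaller
cohort sizes the test becomes mildly anticonservative, which is a known
small-sample property of likelihood-ratio tests with estimated dispersion.

## Consensus clustering

Samples (or miRNAs) are clustered with PAM (BUILD + SWAP, via
`cluster::pam`) on Euclidean distances inside a subsampling loop: each of
`n_resamples` iterations draws 80% of items without replacement, and
co-clustering counts are normalized by co-sampling counts. Resampling is
over items only — subsampling features as well adds variance without
changing the planted-structure recovery the procedure is meant to deliver.
Final assignments cut an average-linkage tree of $1 - \text{consensus}$.

`select_k()` formalizes the usual narrative heuristic into a composite: the
base score at $k$ is the mean of the cophenetic correlation and the average
item consensus, the composite adds the positive part of the drop of that
base score at $k+1$, candidates producing clusters smaller than `min_size`
are excluded, and ties go to the smallest $k$.

Module meta-scores are the first principal component over samples of the
z-scored member miRNAs, with the sign fixed so the score correlates
positively with the module's mean z-profile (PCA signs are otherwise
arbitrary, and a fixed convention is required to interpret up/down
regulation of a module). Cluster–phenotype models are linear (clinical
phenotypes) or logistic (disease status) regressions of the outcome on
cluster indicators plus depth/protocol/smoking/age/gender covariates, with
the control-enriched cluster as baseline; a separated logistic fit is
flagged and refit with a ridge-penalized likelihood so the Wald summaries
stay finite.

## eQTL scanning

Expression is residualized on the covariates (least-squares projection,
exactly equivalent to including them in each regression by
Frisch–Waugh–Lovell). The default test treats the genotype as a factor over
its observed levels (ANOVA F-test); the additive mode uses the
dosage–expression correlation of the residualized variables with a t-test
on $n - c - 2$ degrees of freedom. Both are verified against per-pair `lm`
fits to $10^{-8}$. Monomorphic SNPs are skipped with a message. Records
with $p$ below the retention threshold (default $5\times 10^{-4}$) are
kept; FDR-style summaries can be produced by re-running with
`p_threshold = 1` and adjusting. cis means same chromosome and SNP-to-
feature-start distance at most 1 Mb, boundary inclusive — the conventional
window, configurable because no single definition is universal.

## Causality inference test

For a triplet (SNP $L$, miRNA $G$, mRNA $T$), the causal direction
$L \to G \to T$ combines four component tests: (1) $T$ associated with
$L$; (2) $G$ associated with $L$ given $T$; (3) $T$ associated with $G$
given $L$; and (4) an equivalence test that $L$ is independent of $T$
given $G$. The omnibus $p_\text{causal}$ is the maximum of the four; the
reactive direction swaps $G$ and $T$. Calls at $\alpha = 0.05$: causal if
$p_c < \alpha \le p_r$; reactive if $p_r < \alpha \le p_c$; independent if
both $\ge \alpha$; non-inferable if both $< \alpha$. No multiple-testing
adjustment is applied to the omnibus before classification — the
classification operates at raw $\alpha$, as is standard for this test.

Test 4 cannot be an ordinary null-hypothesis test (one cannot "accept"
independence), so it is an equivalence test calibrated by permutation: the
observed F statistic for $L$ in $T \sim G + L$ is compared against F
statistics computed after permuting the *mediator within genotype strata*.
That permutation preserves the mediator's genotype association while
breaking its link to the outcome, so the permuted statistics represent the
no-mediation alternative, and
$p_4 = (1 + \#\{F^* \le F_\text{obs}\})/(n_\text{perm}+1)$ is small
exactly when conditioning on the true mediator absorbs the $L$–$T$
association. The permutation index matrix depends only on the genotype and
is shared by both directions, which makes the two directional p-values
exactly symmetric under swapping $G$ and $T$. Covariates are residualized
out of $G$ and $T$ before the component tests; the genotype is left raw
and enters additively by default (a 3-level factor coding is exposed).

With 100 permutations the smallest attainable $p_4$ is
$1/101 \approx 0.0099$, comfortably below $\alpha = 0.05$; raising
`n_perm` refines the tail at linear cost.

Candidate triplets pair every SNP–miRNA eQTL with every SNP–gene eQTL
sharing the SNP — triplets whose SNP is not associated with the miRNA are
never examined. A network edge miRNA → gene requires at least one causal-
called triplet whose SNP–miRNA pair passed the eQTL threshold; edges carry
their supporting-triplet count, and gene → miRNA edges are never emitted.
The scale-free diagnostic regresses $\log_{10}$ degree frequency on
$\log_{10}$ degree. Differential connectivity compares per-miRNA degrees
between two condition networks with a two-sided Fisher exact test on
[connected, not connected] × [condition a, b], using the union gene
universe of the pair as denominator (the choice of denominator is not
canonical; the union is the most symmetric option), BH-adjusted with a
$q < 0.2$ flag.

## isomiR seeds and targets

A 5' isomiR shifts the mature start by `offset5` (negative = upstream,
strand-aware: on the minus strand the 5' end is the interval end). The
seed is positions 2–8 of the shifted mature sequence, so a −1 shift of
the miR-34c-5p mature sequence (`AGGCAGTGTAGTTAGCTGATTGC`) turns the
canonical seed `GGCAGTG` into `AGGCAGT`. Target sites in a 3'UTR are pure
seed matches: 7mer-m8 (reverse complement of seed positions 2–8), 7mer-A1
(reverse complement of positions 2–7 followed by A), and 8mer (both), with
overlapping occurrences reported and an 8mer suppressing the 7mers it
contains. This replaces external context-scoring tools: the analysis only
needs the predicted-target *sets*, and seed matching reproduces that set
logic transparently. U and T are interchangeable; Ns never match.

Target assessment computes per-gene Spearman correlations with the miRNA
and compares each target group against non-targets with a two-sided
Wilcoxon rank-sum test. Anticorrelated target sets (default FDR
$q < 0.25$) are compared by percent-distinct and Jaccard statistics.
Preranked GSEA uses the weighted running-sum enrichment score with a
seeded gene-label permutation null; gene-label permutation is used because
sample-level data are not always available for phenotype permutation, and
this is a documented divergence from phenotype-permuted GSEA.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes:

* **Genotypes** — unlinked SNPs in Hardy–Weinberg equilibrium,
  $\text{Binomial}(2, \text{maf})$ per subject, maf drawn uniformly from a
  configurable range (default 0.2–0.5 so planted triplets are informative).
* **Mediation triplets** — causal ($G = a L + \varepsilon$,
  $T = b G + \varepsilon$), reactive, independent (shared driver), and
  null classes, with unit-variance Gaussian noise and standardized slopes
  so power is analytically predictable. The default effect size 0.8
  reflects the strong planted effects needed for a 400-subject cohort to
  support calibration/sensitivity checks; the source cohorts do not report
  eQTL effect-size distributions, so these defaults are chosen for
  testability, not realism.
* **Counts** — negative binomial with
  $\mu = \exp(\text{log-mean} + \log(N/\tilde N) + \text{batch shift})$
  and size $\theta$ (default 2, a typical miRNA-seq dispersion); library
  sizes 0.5–2 million reads.
* **Reads** — multinomial 5' offsets at a locus with sequences lifted from
  a supplied genome string, strand-aware.
* **Covariates** — age $\mathcal{N}(63, 10)$, gender, smoking
  (never/former/current at 25/65/10%), two sequencing protocols, disease
  labels (control/COPD/ILD at 20/40/40%), matching the demographic shape
  of a lung-tissue cohort.

What the generator does *not* emulate: linkage disequilibrium, sequencing
error, realistic genome sequence, count–expression coupling between the
miRNA count matrix and the continuous triplet expression values, and
realistic effect-size distributions. Passing tests therefore demonstrate
the statistical machinery is correct and calibrated under the assumed
generative structure — not that the biological conclusions transfer to any
particular real cohort.

# Numerical choices and problem sizes

* NB theta clamped to $[10^{-3}, 10^7]$; theta initialization by method of
  moments on the Poisson fit when `glm.nb` diverges.
* LRT statistics are clipped at 0 (with a warning) when the full model's
  log-likelihood falls below the reduced model's by more than $10^{-6}$.
* CIT p-values use the $+1$ permutation smoothing; `n_perm` below 20 warns.
* Consensus entries for never-co-sampled pairs are `NaN` and treated as
  maximal distance when cutting the tree.
* Ties in `select_k` go to the smallest $k$; ties in PAM follow
  `cluster::pam`'s deterministic BUILD order.
* The test and acceptance workloads use cohorts of 350–400 subjects,
  500 + 100 CIT calibration triplets, a 200-triplet network cohort, and
  2000 null features for LRT calibration — sizes at which the asymptotic
  approximations the methods rely on are demonstrably accurate.

# Known limitations

* Whole-count multi-locus assignment slightly inflates counts at
  overlapping loci; fractional weighting of multi-mapped reads is out of
  scope.
* The eQTL stage reports raw-p retention (plus BH summaries); permutation-
  based feature-level FDR and conditional eQTL mapping are not provided.
* CIT conclusions are only as good as the component linear models;
  non-linear mediation or unmodeled confounding will produce
  non-inferable or independent calls rather than being detected.
* GSEA significance is gene-label based, which treats genes as
  exchangeable and can be liberal under strong inter-gene correlation.
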