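#' Pipeline configuration
#'
#' Bundles every stage toggle, threshold and seed of the end-to-end
#' workflow. Thresholds default to the analysis' canonical values:
#' detection 2 counts in 50% of samples, DE q < 0.1 with |coef| > 0.22,
#' eQTL p < 5e-4, CIT alpha 0.05, differential-connectivity FDR 0.2,
#' anticorrelation FDR 0.25, cis window 1 Mb.
#'
#' @param out_dir run directory for stage outputs and the manifest.
#' @param stages named logical vector toggling stages (`quantify`,
#'   `diffexpr`, `cluster`, `eqtl`, `citnet`, `targets`).
#' @param detection_min_count,detection_min_fraction detection filter.
#' @param de_q,de_coef DE calling thresholds.
#' @param eqtl_p eQTL retention p-value threshold.
#' @param eqtl_mode `"anova"` or `"additive"`.
#' @param cit_alpha,cit_n_perm CIT classification level and permutations.
#' @param connectivity_fdr differential-connectivity flag threshold.
#' @param anticor_q anticorrelated-target FDR threshold.
#' @param cis_window cis window in bases.
#' @param consensus_k_range,consensus_resamples,consensus_item_fraction
#'   consensus-clustering controls.
#' @param seed master seed for all stochastic stages.
#' @param sim a [sim_config()] used when the run simulates its own cohort.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("mirmednet_run_"),
                            stages = c(quantify = TRUE, diffexpr = TRUE,
                                       cluster = TRUE, eqtl = TRUE,
                                       citnet = TRUE, targets = FALSE),
                            detection_min_count = 2,
                            detection_min_fraction = 0.5,
                            de_q = 0.1, de_coef = 0.22,
                            eqtl_p = 5e-4, eqtl_mode = "additive",
                            cit_alpha = 0.05, cit_n_perm = 100,
                            connectivity_fdr = 0.2, anticor_q = 0.25,
                            cis_window = 1e6,
                            consensus_k_range = 2:4,
                            consensus_resamples = 100,
                            consensus_item_fraction = 0.8,
                            seed = 1L, sim = sim_config()) {
  stopifnot(detection_min_fraction >= 0, detection_min_fraction <= 1,
            de_q > 0, de_q <= 1, eqtl_p > 0, eqtl_p <= 1,
            cit_alpha > 0, cit_alpha < 1,
            connectivity_fdr > 0, connectivity_fdr <= 1,
            anticor_q > 0, anticor_q <= 1, cis_window >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Checks sample-id concordance across matrices and the covariate table,
#' genotype alphabet, interval sanity of loci, and parseability of
#' FASTA/GFF3 paths. Returns a report instead of raising.
#'
#' @param inputs named list with any of `counts`, `mirna`, `gene`,
#'   `genotypes` (matrices), `covariates` (data frame), `loci` (data
#'   frame), `gff3`, `fasta` (paths).
#' @return data frame of failures (`check`, `detail`); zero rows when clean.
#' @export
validate_inputs <- function(inputs) {
  fails <- list()
  note <- function(check, detail)
    fails[[length(fails) + 1]] <<- data.frame(check = check, detail = detail,
                                              stringsAsFactors = FALSE)
  mats <- inputs[intersect(names(inputs),
                           c("counts", "mirna", "gene", "genotypes"))]
  ids <- lapply(mats, colnames)
  if (length(ids) > 1) {
    ref <- ids[[1]]
    for (nm in names(ids)[-1]) {
      if (!identical(sort(ref), sort(ids[[nm]]))) {
        diff <- union(setdiff(ref, ids[[nm]]), setdiff(ids[[nm]], ref))
        note("sample_ids", sprintf("%s vs %s differ: %s", names(ids)[1], nm,
                                   paste(diff, collapse = ",")))
      }
    }
  }
  if (!is.null(inputs$covariates) && length(ids)) {
    if (!identical(sort(inputs$covariates$sample), sort(ids[[1]])))
      note("sample_ids", "covariate table does not match matrix samples")
  }
  if (!is.null(inputs$genotypes)) {
    g <- inputs$genotypes
    if (!all(g[!is.na(g)] %in% 0:2))
      note("genotype_alphabet", "entries outside {0,1,2,NA}")
  }
  if (!is.null(inputs$loci)) {
    bad <- which(inputs$loci$end <= inputs$loci$start)
    if (length(bad))
      note("locus_intervals", sprintf("end <= start at row(s) %s",
                                      paste(bad, collapse = ",")))
  }
  if (!is.null(inputs$gff3)) {
    ok <- tryCatch({ read_loci_gff3(inputs$gff3); TRUE },
                   error = function(e) { note("gff3_parse",
                                              conditionMessage(e)); FALSE })
    if (ok) {
      loci <- read_loci_gff3(inputs$gff3)
      bad <- which(loci$end <= loci$start)
      if (length(bad))
        note("gff3_intervals", sprintf("end <= start at feature(s) %s",
                                       paste(loci$name[bad], collapse = ",")))
    }
  }
  if (!is.null(inputs$fasta)) {
    tryCatch(read_utrs_fasta(inputs$fasta),
             error = function(e) note("fasta_parse", conditionMessage(e)))
  }
  if (length(fails)) do.call(rbind, fails)
  else data.frame(check = character(), detail = character(),
                  stringsAsFactors = FALSE)
}

#' Run the end-to-end pipeline on a cohort
#'
#' Executes the stages in dependency order — normalization/QC/batch
#' adjustment, NB differential expression, consensus clustering of the
#' called miRNAs, eQTL scanning of miRNAs and genes, CIT network
#' construction with differential connectivity, and (optionally) isomiR
#' target analysis — writing each stage's tables plus a JSON manifest into
#' `config$out_dir`. All randomness derives from `config$seed`, so re-running
#' with an identical config reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional cohort list (as from [simulate_cohort()]); when
#'   `NULL` a cohort is simulated from `config$sim`.
#' @return list with the in-memory stage results and `manifest`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- function(stage, fmt, ...)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  manifest <- list(package_version = as.character(utils::packageVersion("mirmednet")),
                   seed = config$seed,
                   thresholds = config[c("detection_min_count",
                                         "detection_min_fraction", "de_q",
                                         "de_coef", "eqtl_p", "cit_alpha",
                                         "connectivity_fdr", "anticor_q",
                                         "cis_window")],
                   stages = list())
  if (is.null(cohort)) {
    logf("simulate", "generating synthetic cohort (seed %d)", config$sim$seed)
    cohort <- simulate_cohort(config$sim)
  }
  results <- list(cohort = cohort)
  st <- config$stages

  cm <- mirna_counts(cohort$counts,
                     sample_totals = colSums(cohort$counts),
                     batch = cohort$covariates$batch)
  norm <- NULL
  if (isTRUE(st[["quantify"]])) {
    norm <- rpm_normalize(cm)
    kept <- detection_filter(cm, config$detection_min_count,
                             config$detection_min_fraction)
    norm$values <- norm$values[kept, , drop = FALSE]
    norm <- batch_adjust(norm, cohort$covariates$batch,
                         covariates = data.frame(
                           disease = factor(cohort$covariates$disease)))
    write_matrix_tsv(round(norm$values, 6),
                     file.path(config$out_dir, "normalized_log2rpm.tsv"))
    manifest$stages$quantify <- list(n_mirna_retained = length(kept),
                                     n_samples = ncol(norm$values))
    logf("quantify", "%d miRNAs retained after detection filter", length(kept))
    results$normalized <- norm
  } else manifest$stages$quantify <- "skipped"

  de <- NULL
  if (isTRUE(st[["diffexpr"]])) {
    de <- de_analysis(cm, cohort$covariates, config$de_q, config$de_coef)
    utils::write.table(format(de, digits = 8), file.path(config$out_dir, "de_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$diffexpr <- list(n_tested = nrow(de),
                                     n_called = sum(de$called, na.rm = TRUE))
    logf("diffexpr", "%d of %d miRNAs called differential",
         sum(de$called, na.rm = TRUE), nrow(de))
    results$de <- de
  } else manifest$stages$diffexpr <- "skipped"

  if (isTRUE(st[["cluster"]]) && !is.null(norm)) {
    sel <- if (!is.null(de)) intersect(rownames(norm$values),
                                       de$mirna[de$called %in% TRUE])
           else rownames(norm$values)
    if (length(sel) < 3) sel <- rownames(norm$values)
    cres <- consensus_cluster(norm$values[sel, , drop = FALSE],
                              config$consensus_k_range,
                              n_resamples = config$consensus_resamples,
                              item_fraction = config$consensus_item_fraction,
                              seed = config$seed)
    k <- select_k(cres)
    assign <- cres$by_k[[as.character(k)]]$assignments
    utils::write.table(data.frame(sample = colnames(norm$values),
                                  cluster = assign),
                       file.path(config$out_dir, "sample_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$cluster <- list(selected_k = k,
                                    n_features_used = length(sel))
    logf("cluster", "selected k = %d", k)
    results$clustering <- list(result = cres, k = k, assignments = assign)
  } else manifest$stages$cluster <- "skipped"

  eq_mir <- eq_gene <- NULL
  if (isTRUE(st[["eqtl"]])) {
    covs <- data.frame(age = cohort$covariates$age,
                       gender = factor(cohort$covariates$gender),
                       smoking = factor(cohort$covariates$smoking))
    eq_mir <- eqtl_scan(cohort$genotypes, cohort$mirna, covs,
                        p_threshold = config$eqtl_p, mode = config$eqtl_mode)
    eq_gene <- eqtl_scan(cohort$genotypes, cohort$gene, covs,
                         p_threshold = config$eqtl_p, mode = config$eqtl_mode)
    utils::write.table(format(eq_mir, digits = 8),
                       file.path(config$out_dir, "eqtl_mirna.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(format(eq_gene, digits = 8),
                       file.path(config$out_dir, "eqtl_gene.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$eqtl <- list(n_mirna_eqtl = nrow(eq_mir),
                                 n_gene_eqtl = nrow(eq_gene))
    logf("eqtl", "%d miRNA and %d gene eQTL records below p < %g",
         nrow(eq_mir), nrow(eq_gene), config$eqtl_p)
    results$eqtl <- list(mirna = eq_mir, gene = eq_gene)
  } else manifest$stages$eqtl <- "skipped"

  if (isTRUE(st[["citnet"]]) && !is.null(eq_mir)) {
    cand <- candidate_triplets(eq_mir, eq_gene)
    cit <- if (nrow(cand)) cit_scan(cand, cohort$genotypes, cohort$mirna,
                                    cohort$gene, n_perm = config$cit_n_perm,
                                    seed = config$seed,
                                    alpha = config$cit_alpha)
           else cbind(cand, p_causal = numeric(0), p_reactive = numeric(0),
                      call = character(0))
    net <- build_network(cit, eq_mir, condition = "all")
    utils::write.table(format(cit, digits = 8),
                       file.path(config$out_dir, "cit_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(net$edges, file.path(config$out_dir,
                                            "network_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$citnet <- list(n_candidates = nrow(cand),
                                   n_causal = sum(cit$call == "causal"),
                                   n_edges = nrow(net$edges))
    logf("citnet", "%d candidates, %d causal calls, %d network edges",
         nrow(cand), sum(cit$call == "causal"), nrow(net$edges))
    results$citnet <- list(candidates = cand, cit = cit, network = net)
  } else manifest$stages$citnet <- "skipped"

  if (isTRUE(st[["targets"]]) && !is.null(cohort$utrs) &&
      !is.null(cohort$mature_sequence)) {
    canonical <- extract_seed(cohort$mature_sequence, 0)
    shifted <- extract_seed(cohort$mature_sequence, -1,
                            upstream = cohort$upstream %||% "")
    can_t <- scan_target_genes(canonical, cohort$utrs)
    iso_t <- scan_target_genes(shifted, cohort$utrs)
    groups <- categorize_genes(can_t, iso_t, names(cohort$utrs))
    utils::write.table(
      data.frame(gene = names(cohort$utrs),
                 group = vapply(names(cohort$utrs), function(g) {
                   if (g %in% groups$both) "both"
                   else if (g %in% groups$canonical_only) "canonical_only"
                   else if (g %in% groups$isomir_only) "isomir_only"
                   else "neither"
                 }, character(1))),
      file.path(config$out_dir, "target_groups.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$targets <- list(n_canonical = length(can_t),
                                    n_isomir = length(iso_t))
    logf("targets", "%d canonical / %d isomiR predicted targets",
         length(can_t), length(iso_t))
    results$targets <- groups
  } else manifest$stages$targets <- "skipped"

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
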