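#' Pipeline configuration
#'
#' Collects every stage's tunables with the workflow's standard defaults:
#' sample-QC SD multiplier 3, study-QC exclusion fraction 0.2, B = 1000
#' label permutations, BH FDR at 0.05, consensus over rOP.OC and REM,
#' compound significance at adjusted p < 0.01 with more than 5 significant
#' instances required.
#'
#' @param input Either a [synthetic_config()] (the pipeline simulates its
#'   own input) or a directory containing `*.expr.tsv` / `*.meta.tsv`
#'   studies.
#' @param gene_sets_gmt Optional GMT path; for synthetic input, sets are
#'   generated when this is NULL.
#' @param compounds_up_gmt,compounds_down_gmt Optional paired GMT paths for
#'   the compound library; for synthetic input a library is generated when
#'   NULL.
#' @param sample_qc_c IAC outlier cutoff multiplier.
#' @param exclusion_fraction Study-QC worst fraction excluded.
#' @param qc_n_perm,qc_n_top_genes Study-QC permutation count and
#'   co-expression gene count.
#' @param s0 DE penalty (`"auto"` or numeric).
#' @param B Label permutations per study.
#' @param methods Meta-analysis methods to run (suffix `.oc` applies the
#'   one-sided correction).
#' @param rop_r rOP order index or `"auto"` (`ceiling(0.7 K)`).
#' @param fdr_mode `"bh"` or `"permutation"`.
#' @param alpha Meta-analysis FDR threshold.
#' @param consensus_methods Methods intersected for the consensus
#'   signature.
#' @param compound_alpha,compound_min_sum Compound prioritization cutoffs.
#' @param seed Master seed; all stage seeds derive from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = synthetic_config(),
                            gene_sets_gmt = NULL,
                            compounds_up_gmt = NULL,
                            compounds_down_gmt = NULL,
                            sample_qc_c = 3, exclusion_fraction = 0.2,
                            qc_n_perm = 200, qc_n_top_genes = 200,
                            s0 = "auto", B = 1000,
                            methods = c("fisher", "stouffer", "maxp", "rop",
                                        "rop.oc", "fem", "rem"),
                            rop_r = "auto", fdr_mode = "bh", alpha = 0.05,
                            consensus_methods = c("rop.oc", "rem"),
                            compound_alpha = 0.01, compound_min_sum = 5,
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

run_meta_method <- function(spec_name, de_list, rop_r, rank_seed) {
  base <- sub("\\.oc$", "", spec_name)
  oc <- grepl("\\.oc$", spec_name)
  if (base %in% c("fisher", "stouffer", "maxp", "rop")) {
    combine_pvalues(de_list, method = base,
                    r = if (base == "rop") rop_r else "auto",
                    one_sided = oc)
  } else if (base %in% c("pr", "sr")) {
    combine_ranks(de_list, method = base, B_null = 100, seed = rank_seed)
  } else if (base %in% c("fem", "rem")) {
    combine_effects(de_list, model = base)
  } else stop("unknown meta method: ", spec_name)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full meta-analysis workflow
#'
#' Executes, in order: input acquisition (simulation or reading from disk),
#' gene harmonization, IAC sample QC, six-measure study QC with SMR
#' exclusion, per-study DE, meta-analysis combination, FDR, consensus
#' signature, over-representation analysis, and compound reversal
#' prioritization. Every intermediate is written as TSV into `out_dir`
#' together with a machine-readable `manifest.json` (config echo, derived
#' seeds, per-stage counts). Timestamps are deliberately excluded from the
#' manifest so identical runs produce identical files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; contents overwritten).
#' @return Invisibly, a list with all stage objects plus `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 6)
  names(seeds) <- c("simulate", "study_qc", "de", "rank_null",
                    "gene_sets", "compounds")
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  # -- stage 1: inputs ------------------------------------------------------
  truth <- NULL; sets <- NULL; lib <- NULL
  if (inherits(config$input, "synthetic_config")) {
    cfg <- config$input
    cfg$seed <- as.integer(seeds["simulate"] %% .Machine$integer.max)
    sim <- generate_collection(cfg)
    coll <- sim$collection; truth <- sim$truth
    note("simulated K=%d studies, G=%d genes", coll$K,
         nrow(coll$studies[[1]]$expr))
  } else {
    coll <- read_collection(config$input)
    note("read K=%d studies from %s", coll$K, config$input)
  }
  coll <- harmonize_genes(coll)
  universe <- coll$studies[[1]]$genes

  if (!is.null(config$gene_sets_gmt)) {
    sets <- read_gmt(config$gene_sets_gmt)
  } else if (!is.null(truth)) {
    n_de <- sum(truth$genes$is_de)
    max_size <- if (n_de > 0) max(5, min(40, floor(n_de / 0.8))) else 40
    gs <- generate_gene_sets(truth,
                             set_size_range = c(min(10, max_size), max_size),
                             n_enriched = if (n_de > 0) 5 else 0,
                             seed = seeds["gene_sets"])
    sets <- gs$sets; truth <- gs$truth
  }

  # -- stage 2: sample QC ---------------------------------------------------
  removed_samples <- character(0)
  qc_reports <- list()
  for (id in study_ids(coll)) {
    rep <- flag_outliers(compute_iac(coll$studies[[id]]), config$sample_qc_c)
    qc_reports[[id]] <- rep
    if (length(rep$flagged)) {
      note("sample QC: removing %s from %s (mean IAC below cutoff %.4f)",
           paste(rep$flagged, collapse = ","), id, rep$cutoff)
      coll$studies[[id]] <- drop_flagged(coll$studies[[id]], rep)
      removed_samples <- c(removed_samples, rep$flagged)
    }
  }
  sample_qc_tab <- do.call(rbind, lapply(qc_reports, function(r) {
    data.frame(study = r$study_id, sample = names(r$mean_iac),
               mean_iac = r$mean_iac, cutoff = r$cutoff,
               flagged = names(r$mean_iac) %in% r$flagged, row.names = NULL)
  }))
  write_tsv(sample_qc_tab, file.path(out_dir, "sample_qc.tsv"))

  # -- stage 3: study QC ----------------------------------------------------
  study_report <- NULL
  if (coll$K >= 3 && !is.null(sets)) {
    measures <- compute_qc_measures(coll, sets,
                                    n_top_genes = min(config$qc_n_top_genes,
                                                      length(universe)),
                                    n_perm = config$qc_n_perm,
                                    seed = seeds["study_qc"])
    study_report <- summarize_smr(measures, config$exclusion_fraction)
    for (id in study_report$excluded)
      note("study QC: excluding %s (SMR %.2f)", id, study_report$smr[id])
    keep <- setdiff(study_ids(coll), study_report$excluded)
    coll <- study_collection(coll$studies[keep])
    qc_tab <- data.frame(study = rownames(study_report$measures),
                         unclass(study_report$measures),
                         SMR = study_report$smr,
                         excluded = rownames(study_report$measures) %in%
                           study_report$excluded, row.names = NULL)
    write_tsv(qc_tab, file.path(out_dir, "study_qc.tsv"))
    if (!is.null(study_report$biplot)) {
      bp <- study_report$biplot
      write_tsv(data.frame(study = rownames(bp$scores), bp$scores),
                file.path(out_dir, "study_qc_biplot_scores.tsv"))
      write_tsv(data.frame(measure = rownames(bp$loadings), bp$loadings),
                file.path(out_dir, "study_qc_biplot_loadings.tsv"))
    }
  } else note("study QC skipped (K < 3 or no gene sets)")

  # -- stage 4: per-study DE ------------------------------------------------
  de_seeds <- derive_seeds(seeds["de"], coll$K)
  de_list <- vector("list", coll$K)
  for (k in seq_len(coll$K)) {
    de_list[[k]] <- de_study(coll$studies[[k]], s0 = config$s0,
                             B = config$B, seed = de_seeds[k])
    write_tsv(de_list[[k]],
              file.path(out_dir, paste0(study_ids(coll)[k], ".de.tsv")))
  }

  # -- stage 5: meta-analysis ----------------------------------------------
  results <- list()
  for (m in config$methods) {
    res <- run_meta_method(m, de_list, config$rop_r, seeds["rank_null"])
    res <- estimate_fdr(res, mode = "bh")
    results[[m]] <- res
    write_tsv(res, file.path(out_dir, paste0("meta_", m, ".tsv")))
  }
  conc <- if (length(results) >= 2) method_concordance(results) else NULL
  if (!is.null(conc))
    write_tsv(data.frame(method = rownames(conc), conc),
              file.path(out_dir, "method_concordance.tsv"))

  # -- stage 6: consensus signature ----------------------------------------
  cons_methods <- intersect(config$consensus_methods, names(results))
  if (!length(cons_methods)) cons_methods <- names(results)[1]
  sig <- consensus_signature(results[cons_methods], fdr = config$alpha)
  write_tsv(data.frame(gene = c(sig$up, sig$down),
                       direction = rep(c("up", "down"),
                                       c(length(sig$up), length(sig$down)))),
            file.path(out_dir, "consensus_signature.tsv"))
  note("consensus (%s): %d up, %d down, %d direction conflicts",
       paste(cons_methods, collapse = "+"), length(sig$up),
       length(sig$down), sig$provenance$n_direction_conflicts)

  # -- stage 7: enrichment --------------------------------------------------
  enrich <- NULL
  de_genes <- c(sig$up, sig$down)
  if (!is.null(sets) && length(de_genes)) {
    enrich <- ora_test(de_genes, universe, sets)
    write_tsv(enrich, file.path(out_dir, "enrichment.tsv"))
  }

  # -- stage 8: compounds ---------------------------------------------------
  compounds <- NULL
  if (!is.null(config$compounds_up_gmt)) {
    lib <- read_compound_library(config$compounds_up_gmt,
                                 config$compounds_down_gmt)
  } else if (!is.null(truth) && length(sig$up) && length(sig$down)) {
    cl <- generate_compound_library(sig$up, sig$down, universe,
                                    truth = truth, seed = seeds["compounds"])
    lib <- cl$library; truth <- cl$truth
  }
  if (!is.null(lib) && length(sig$up) && length(sig$down)) {
    compounds <- prioritize_compounds(sig, lib, universe,
                                      alpha = config$compound_alpha,
                                      min_sum = config$compound_min_sum)
    write_tsv(compounds, file.path(out_dir, "compounds.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("omnimeta")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config[setdiff(names(config), "input")],
    input = if (inherits(config$input, "synthetic_config"))
      unclass(config$input) else config$input,
    seeds = as.list(seeds),
    counts = list(
      studies_in = length(qc_reports),
      samples_removed = length(removed_samples),
      studies_excluded = if (is.null(study_report)) 0L else
        length(study_report$excluded),
      studies_analyzed = coll$K,
      genes_tested = length(universe),
      de_genes = length(de_genes),
      enriched_sets = if (is.null(enrich)) 0L else
        sum(enrich$q < config$alpha),
      compounds_reported = if (is.null(compounds)) 0L else nrow(compounds)),
    log = log_lines)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(collection = coll, truth = truth, sets = sets,
                 library = lib, sample_qc = qc_reports,
                 study_qc = study_report, de = de_list, meta = results,
                 concordance = conc, signature = sig, enrichment = enrich,
                 compounds = compounds, manifest = manifest,
                 out_dir = out_dir))
}
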