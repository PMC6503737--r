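#' Configuration for the synthetic multi-study generator
#'
#' Defines the study conditions emulated by [generate_collection()]: K
#' two-arm studies over a shared gene space, a fraction `pi_de` of truly DE
#' genes whose standardized effects are planted in all studies (`HS_A`),
#' a random 1..K subset (`HS_B`), or a fixed fraction of studies (`HS_r`),
#' with between-study heterogeneity `tau2`.
#'
#' @param K Number of studies.
#' @param G Number of genes (shared across studies).
#' @param n_case,n_control Per-study arm sizes; scalars or length-K vectors.
#' @param pi_de Fraction of genes that are truly differentially expressed.
#' @param scenario Hypothesis setting: `"HS_A"` (effect in all studies),
#'   `"HS_B"` (in one or more), `"HS_r"` (in `ceil(r_frac * K)` studies).
#' @param r_frac Fraction of studies carrying the effect under `HS_r`.
#' @param mu Mean standardized effect size of DE genes (in units of the
#'   residual SD).
#' @param tau2 Between-study variance of the standardized effect.
#' @param sigma Residual noise SD on the log2 scale.
#' @param n_outlier_samples Number of divergent samples to plant.
#' @param n_bad_studies Number of corrupted studies to plant.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(K = 6, G = 2000, n_case = 15, n_control = 15,
                             pi_de = 0.1,
                             scenario = c("HS_r", "HS_A", "HS_B"),
                             r_frac = 0.7, mu = 1, tau2 = 0.1, sigma = 1,
                             n_outlier_samples = 0, n_bad_studies = 0,
                             seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(K >= 1, G >= 1, pi_de >= 0, pi_de <= 1, tau2 >= 0,
            r_frac > 0, r_frac <= 1, sigma > 0)
  n_case <- rep_len(as.integer(n_case), K)
  n_control <- rep_len(as.integer(n_control), K)
  if (any(n_case < 2) || any(n_control < 2))
    stop("invalid design: each arm needs at least 2 samples")
  structure(list(K = as.integer(K), G = as.integer(G), n_case = n_case,
                 n_control = n_control, pi_de = pi_de, scenario = scenario,
                 r_frac = r_frac, mu = mu, tau2 = tau2, sigma = sigma,
                 n_outlier_samples = as.integer(n_outlier_samples),
                 n_bad_studies = as.integer(n_bad_studies),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# child seeds are drawn once from the config seed so each planting step is
# reproducible in isolation
derive_seeds <- function(seed, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a multi-study collection with known ground truth
#'
#' DE genes receive per-study standardized effects
#' `delta_gk ~ Normal(sign_g * mu, tau2)` in the scenario-selected carrier
#' studies and 0 elsewhere; the case-arm mean of gene g in study k is shifted
#' by `delta_gk * sigma`. Baseline expression per gene is Normal(7, 1.5) on
#' the log2 scale. If the config plants outliers or corrupted studies, the
#' corresponding planting operations are applied with derived child seeds.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `collection` (a [study_collection()]) and
#'   `truth` (a `truth_table`: per-gene DE flags, per-study effects `delta`,
#'   per-sample outlier flags, per-study corruption flags).
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  G <- config$G; K <- config$K
  genes <- sprintf("G%05d", seq_len(G))
  baseline <- stats::rnorm(G, 7, 1.5)

  n_de <- round(config$pi_de * G)
  de_idx <- if (n_de > 0) sort(sample.int(G, n_de)) else integer(0)
  sign_g <- integer(G)
  sign_g[de_idx] <- ifelse(stats::runif(n_de) < 0.5, 1L, -1L)

  delta <- matrix(0, G, K, dimnames = list(genes, NULL))
  for (g in de_idx) {
    carriers <- switch(config$scenario,
      HS_A = seq_len(K),
      HS_r = sort(sample.int(K, ceiling(config$r_frac * K))),
      HS_B = sort(sample.int(K, sample.int(K, 1))))
    delta[g, carriers] <- stats::rnorm(length(carriers),
                                       sign_g[g] * config$mu,
                                       sqrt(config$tau2))
  }

  platforms <- c("microarray", "rnaseq")
  regions <- c("PFC", "striatum", "hippocampus", "cerebellum", "ACC")
  studies <- vector("list", K)
  for (k in seq_len(K)) {
    n1 <- config$n_case[k]; n0 <- config$n_control[k]; N <- n1 + n0
    expr <- baseline + matrix(stats::rnorm(G * N, 0, config$sigma), G, N)
    group <- c(rep("control", n0), rep("case", n1))
    case_cols <- which(group == "case")
    expr[, case_cols] <- expr[, case_cols] + delta[, k] * config$sigma
    rownames(expr) <- genes
    colnames(expr) <- sprintf("ST%02d_S%03d", k, seq_len(N))
    meta <- data.frame(
      platform = sample(platforms, 1),
      region = sample(regions, 1),
      stringsAsFactors = FALSE)[rep(1, N), , drop = FALSE]
    studies[[k]] <- expression_study(expr, group, sprintf("STUDY%02d", k), meta)
  }
  coll <- study_collection(studies)
  colnames(delta) <- study_ids(coll)

  samples <- do.call(rbind, lapply(coll$studies, function(s) {
    data.frame(study_id = s$study_id, sample = colnames(s$expr),
               is_outlier = FALSE, stringsAsFactors = FALSE)
  }))
  rownames(samples) <- NULL
  truth <- structure(list(
    genes = data.frame(gene = genes, is_de = seq_len(G) %in% de_idx,
                       direction = sign_g, stringsAsFactors = FALSE),
    delta = delta,
    samples = samples,
    studies = data.frame(study_id = study_ids(coll), is_corrupted = FALSE,
                         stringsAsFactors = FALSE),
    gene_sets = NULL, compounds = NULL), class = "truth_table")

  child <- derive_seeds(config$seed, 2)
  if (config$n_outlier_samples > 0) {
    out <- plant_outlier_samples(coll, truth, config$n_outlier_samples, child[1])
    coll <- out$collection; truth <- out$truth
  }
  if (config$n_bad_studies > 0) {
    out <- plant_corrupted_study(coll, truth, config$n_bad_studies, child[2])
    coll <- out$collection; truth <- out$truth
  }
  list(collection = coll, truth = truth)
}

#' Plant divergent (outlier) samples
#'
#' Replaces `n` randomly chosen samples (drawn across the whole collection)
#' with independent Gaussian noise matched to the sample's marginal mean and
#' SD. This destroys the sample's correlation with every other sample while
#' leaving its marginal distribution intact, which is exactly the defect the
#' inter-array-correlation QC is designed to catch.
#'
#' @param coll A [study_collection()].
#' @param truth The matching `truth_table`.
#' @param n Number of samples to corrupt; must be smaller than the smallest
#'   study's sample count.
#' @param seed Integer seed.
#' @return A list with updated `collection` and `truth`.
#' @export
plant_outlier_samples <- function(coll, truth, n, seed = 1) {
  if (n == 0) return(list(collection = coll, truth = truth))
  min_n <- min(vapply(coll$studies, function(s) ncol(s$expr), integer(1)))
  if (n >= min_n)
    stop("n must be smaller than the smallest study's sample count")
  set.seed(seed)
  pool <- truth$samples[, c("study_id", "sample")]
  pick <- pool[sample.int(nrow(pool), n), , drop = FALSE]
  for (i in seq_len(nrow(pick))) {
    sid <- pick$study_id[i]; sm <- pick$sample[i]
    s <- coll$studies[[sid]]
    x <- s$expr[, sm]
    s$expr[, sm] <- stats::rnorm(length(x), mean(x), stats::sd(x))
    coll$studies[[sid]] <- s
    truth$samples$is_outlier[truth$samples$study_id == sid &
                               truth$samples$sample == sm] <- TRUE
  }
  list(collection = coll, truth = truth)
}

#' Plant corrupted studies
#'
#' In `n` randomly chosen (not yet corrupted) studies, every sample's gene
#' values are independently permuted. This preserves each sample's marginal
#' distribution but destroys both the gene-gene co-expression structure and
#' any case/control signal, emulating a study whose processing went wrong.
#'
#' @inheritParams plant_outlier_samples
#' @param n Number of studies to corrupt; must be `< K`.
#' @return A list with updated `collection` and `truth`.
#' @export
plant_corrupted_study <- function(coll, truth, n, seed = 1) {
  if (n == 0) return(list(collection = coll, truth = truth))
  if (n >= coll$K) stop("n must be smaller than the number of studies")
  set.seed(seed)
  candidates <- truth$studies$study_id[!truth$studies$is_corrupted]
  pick <- sample(candidates, n)
  for (sid in pick) {
    s <- coll$studies[[sid]]
    G <- nrow(s$expr)
    for (j in seq_len(ncol(s$expr)))
      s$expr[, j] <- s$expr[sample.int(G), j]
    coll$studies[[sid]] <- s
    truth$studies$is_corrupted[truth$studies$study_id == sid] <- TRUE
  }
  list(collection = coll, truth = truth)
}

#' Generate gene-set collections with planted enrichment
#'
#' `n_enriched` sets draw a fraction `enrich_frac` of their members from the
#' true DE genes recorded in `truth` and the remainder uniformly from the
#' other genes; all other sets are uniform draws from the whole gene space.
#'
#' @param truth A `truth_table` from [generate_collection()].
#' @param n_sets Number of gene sets.
#' @param set_size_range Length-2 integer range of set sizes (inclusive).
#' @param n_enriched Number of sets enriched for true DE genes.
#' @param enrich_frac Fraction of an enriched set drawn from true DE genes.
#' @param seed Integer seed.
#' @return A list with `sets` (named list of gene-id vectors) and the
#'   updated `truth` (data.frame `gene_sets` with `is_enriched` flags).
#' @export
generate_gene_sets <- function(truth, n_sets = 50, set_size_range = c(10, 40),
                               n_enriched = 5, enrich_frac = 0.8, seed = 1) {
  stopifnot(n_enriched <= n_sets, enrich_frac >= 0, enrich_frac <= 1)
  set.seed(seed)
  genes <- truth$genes$gene
  de_genes <- genes[truth$genes$is_de]
  other <- setdiff(genes, de_genes)
  size_pool <- seq(set_size_range[1], set_size_range[2])
  sizes <- size_pool[sample.int(length(size_pool), n_sets, replace = TRUE)]
  if (max(sizes) > length(genes)) stop("set sizes exceed gene count")
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  enriched <- seq_len(n_sets) <= n_enriched
  for (i in seq_len(n_sets)) {
    if (enriched[i]) {
      n_from_de <- round(enrich_frac * sizes[i])
      if (n_from_de > length(de_genes))
        stop("enrich_frac * set size exceeds the number of DE genes")
      sets[[i]] <- c(sample(de_genes, n_from_de),
                     sample(other, sizes[i] - n_from_de))
    } else {
      sets[[i]] <- sample(genes, sizes[i])
    }
  }
  truth$gene_sets <- data.frame(set = names(sets), is_enriched = enriched,
                                stringsAsFactors = FALSE)
  list(sets = sets, truth = truth)
}

#' Generate a compound perturbation library with planted reversers
#'
#' Reversal compounds' instances have up-sets overlapping the disease
#' down-signature (and down-sets overlapping the disease up-signature) by
#' `overlap_frac`; all other compounds' sets are uniform draws from the
#' universe. Instance names follow `compound|cell_line|dose`.
#'
#' @param disease_up,disease_down Character vectors: the disease signature.
#' @param universe Character vector: all gene ids sets may draw from.
#' @param n_compounds Number of compounds.
#' @param n_instances_per_compound Cell-line/dose instances per compound.
#' @param n_reversal Number of compounds planted as signature reversers.
#' @param overlap_frac Fraction of a reversal set drawn from the opposing
#'   disease set; in `[0, 1]`.
#' @param set_size Genes per instance up/down set.
#' @param truth Optional `truth_table` to receive `compounds` flags.
#' @param seed Integer seed.
#' @return A list with `library` (a [compound_library()]) and `truth`.
#' @export
generate_compound_library <- function(disease_up, disease_down, universe,
                                      n_compounds = 20,
                                      n_instances_per_compound = 5,
                                      n_reversal = 3, overlap_frac = 0.8,
                                      set_size = 50, truth = NULL, seed = 1) {
  if (!length(disease_up) || !length(disease_down))
    stop("disease signatures must be non-empty")
  if (overlap_frac < 0 || overlap_frac > 1)
    stop("overlap_frac must be in [0, 1]")
  set.seed(seed)
  compounds <- sprintf("CMPD_%03d", seq_len(n_compounds))
  reversal <- seq_len(n_compounds) <= n_reversal
  cells <- c("A375", "HT29", "MCF7", "PC3", "VCAP")
  doses <- c("0.1uM", "1uM", "10uM")

  draw_set <- function(k, from = NULL, frac = 0) {
    n_in <- round(frac * k)
    n_in <- min(n_in, length(from))
    c(if (n_in > 0) sample(from, n_in) else character(0),
      sample(setdiff(universe, from), k - n_in))
  }
  inst <- list(); up <- list(); down <- list()
  for (i in seq_len(n_compounds)) {
    for (j in seq_len(n_instances_per_compound)) {
      id <- paste(compounds[i], sample(cells, 1), sample(doses, 1), sep = "|")
      # ensure unique instance keys even if cell/dose repeat
      while (id %in% names(up))
        id <- paste(compounds[i], sample(cells, 1),
                    sprintf("%.2fuM", stats::runif(1, 0.1, 10)), sep = "|")
      if (reversal[i]) {
        u <- draw_set(set_size, disease_down, overlap_frac)
        d <- draw_set(set_size, disease_up, overlap_frac)
      } else {
        u <- sample(universe, set_size)
        d <- sample(setdiff(universe, u), set_size)
      }
      d <- setdiff(d, u)
      parts <- strsplit(id, "|", fixed = TRUE)[[1]]
      inst[[id]] <- data.frame(instance = id, compound = compounds[i],
                               cell_line = parts[2], dose = parts[3],
                               stringsAsFactors = FALSE)
      up[[id]] <- u; down[[id]] <- d
    }
  }
  lib <- compound_library(do.call(rbind, inst), up, down)
  if (!is.null(truth))
    truth$compounds <- data.frame(compound = compounds,
                                  is_reversal = reversal,
                                  stringsAsFactors = FALSE)
  list(library = lib, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Writes every study as `<id>.expr.tsv` / `<id>.meta.tsv`, the ground truth
#' as `truth.json`, plus `gene_sets.gmt` and `compounds_up.gmt` /
#' `compounds_down.gmt` when present.
#'
#' @param sim Output of [generate_collection()] (optionally augmented with
#'   `sets` and `library` elements).
#' @param dir Output directory.
#' @param force Overwrite an existing directory.
#' @return Invisibly, `dir`.
#' @export
simulate_to_dir <- function(sim, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("output directory exists; use force = TRUE to overwrite")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_collection(sim$collection, dir)
  truth <- sim$truth
  truth$delta <- NULL  # matrices are regenerable; keep the JSON compact
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  if (!is.null(sim$sets)) write_gmt(sim$sets, file.path(dir, "gene_sets.gmt"))
  if (!is.null(sim$library))
    write_compound_library(sim$library, file.path(dir, "compounds_up.gmt"),
                           file.path(dir, "compounds_down.gmt"))
  invisible(dir)
}
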