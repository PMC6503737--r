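# Study-level QC: six quality measures, each expressed as a -log10 p
# (larger = better), summarized by standardized mean rank (SMR) with the
# worst fraction excluded.
#
# The six measures (reconstructed permutation / Fisher-exact calibrations;
# see the methods vignette):
#   IQC  - homogeneity of the co-expression structure with the other studies
#   EQC  - consistency of co-expression with a pathway (gene-set) collection
#   AQCg - accuracy of DE gene detection vs a leave-one-out meta reference
#   AQCp - accuracy of enriched-pathway detection vs the same reference
#   CQCg - consistency of the DE gene *ranking* with the reference ranking
#   CQCp - consistency of the enriched-pathway ranking

perm_log10p <- function(n_exceed, n_perm) {
  -log10((1 + n_exceed) / (1 + n_perm))
}

fisher_overlap_log10p <- function(a, b, universe) {
  a <- intersect(a, universe); b <- intersect(b, universe)
  if (!length(a) || !length(b)) {
    warning("empty overlap universe; measure set to 0")
    return(0)
  }
  ov <- length(intersect(a, b))
  p <- stats::phyper(ov - 1, length(a), length(universe) - length(a),
                     length(b), lower.tail = FALSE)
  -log10(max(p, .Machine$double.xmin))
}

spearman_perm_log10p <- function(x, y, n_perm) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant evidence ranking; measure set to 0")
    return(0)
  }
  obs <- stats::cor(x, y, method = "spearman")
  perm <- vapply(seq_len(n_perm), function(b) {
    stats::cor(sample(x), y, method = "spearman")
  }, numeric(1))
  perm_log10p(sum(perm >= obs), n_perm)
}

#' Compute the six study-level QC measures
#'
#' Each measure is a nonnegative score on the -log10(p) scale (larger =
#' better). Permutation p-values use the add-one correction
#' `p = (1 + b) / (1 + n_perm)`, so permutation-calibrated measures are
#' bounded by `log10(n_perm + 1)`. Per-study DE evidence inside the
#' measures uses fast parametric pooled-t p-values; the leave-one-out meta
#' reference combines the other K - 1 studies by Fisher's method at
#' BH q < `alpha`.
#'
#' @param coll A [study_collection()] with K >= 3 studies sharing at least
#'   `n_top_genes` genes.
#' @param gene_sets Named list of gene-id vectors (pathway collection).
#' @param n_top_genes Number of highest pooled-variance common genes used
#'   for the co-expression measures (IQC, EQC).
#' @param n_perm Permutations per permutation-calibrated measure.
#' @param alpha Per-study and meta DE / enrichment significance threshold.
#' @param seed Integer seed for the permutation draws.
#' @return A K x 6 matrix (`study_qc_measures`) with columns IQC, EQC,
#'   AQCg, AQCp, CQCg, CQCp.
#' @export
compute_qc_measures <- function(coll, gene_sets, n_top_genes = 200,
                                n_perm = 200, alpha = 0.05, seed = 1) {
  stopifnot(inherits(coll, "study_collection"))
  if (coll$K < 3) stop("study-level QC needs at least 3 studies")
  coll <- harmonize_genes(coll)
  # canonical (sorted) gene order so results are invariant to the input's
  # gene and study ordering
  genes <- sort(coll$studies[[1]]$genes)
  coll$studies <- lapply(coll$studies, function(s) {
    expression_study(s$expr[genes, , drop = FALSE], s$group, s$study_id,
                     s$metadata)
  })
  if (length(genes) < n_top_genes)
    stop("fewer common genes than n_top_genes")
  set.seed(seed)
  K <- coll$K
  ids <- study_ids(coll)

  # top pooled-variance genes for the co-expression measures
  vars <- vapply(coll$studies, function(s) {
    apply(s$expr, 1, stats::var)
  }, numeric(length(genes)))
  top <- genes[order(-rowMeans(vars))[seq_len(n_top_genes)]]

  cors <- lapply(coll$studies, function(s) stats::cor(t(s$expr[top, ])))
  ut <- upper.tri(cors[[1]])
  cor_vecs <- vapply(cors, function(C) C[ut], numeric(sum(ut)))

  # per-study parametric evidence + leave-one-out Fisher meta reference
  pmat <- vapply(coll$studies, parametric_pvalues, numeric(length(genes)))
  loo_meta_p <- function(k) {
    P <- pmat[, -k, drop = FALSE]
    X <- -2 * rowSums(log(pmax(P, .Machine$double.xmin)))
    stats::pchisq(X, df = 2 * ncol(P), lower.tail = FALSE)
  }
  sets_common <- lapply(gene_sets, intersect, genes)
  sets_common <- sets_common[lengths(sets_common) >= 2]
  set_names <- names(sets_common)

  ora_logp <- function(de) {
    if (!length(de)) return(stats::setNames(numeric(length(set_names)),
                                            set_names))
    res <- ora_test(de, genes, sets_common)
    stats::setNames(-log10(pmax(res$p, .Machine$double.xmin)), res$set)
  }

  sets_top <- lapply(gene_sets, intersect, top)
  sets_top <- sets_top[lengths(sets_top) >= 2]

  measures <- matrix(NA_real_, K, 6,
                     dimnames = list(ids, c("IQC", "EQC", "AQCg", "AQCp",
                                            "CQCg", "CQCp")))
  for (k in seq_len(K)) {
    other_mean <- rowMeans(cor_vecs[, -k, drop = FALSE])
    rk_other <- rank(other_mean)

    # IQC: agreement of study k's gene-gene correlations with the others,
    # calibrated by shuffling gene identities in study k
    obs <- stats::cor(rank(cor_vecs[, k]), rk_other)
    Ck <- cors[[k]]
    perm <- vapply(seq_len(n_perm), function(b) {
      pidx <- sample.int(n_top_genes)
      stats::cor(rank(Ck[pidx, pidx][ut]), rk_other)
    }, numeric(1))
    measures[k, "IQC"] <- perm_log10p(sum(perm >= obs), n_perm)

    # EQC: within-set mean |cor| vs size-matched random sets
    Xk <- t(coll$studies[[k]]$expr)
    set_stat <- function(members) {
      C <- stats::cor(Xk[, members, drop = FALSE])
      mean(abs(C[upper.tri(C)]))
    }
    if (length(sets_top)) {
      obs_eqc <- mean(vapply(sets_top, set_stat, numeric(1)))
      perm_eqc <- vapply(seq_len(n_perm), function(b) {
        mean(vapply(lengths(sets_top), function(m) {
          set_stat(sample(top, m))
        }, numeric(1)))
      }, numeric(1))
      measures[k, "EQC"] <- perm_log10p(sum(perm_eqc >= obs_eqc), n_perm)
    } else {
      warning("no gene sets map into the top-gene space; EQC set to 0")
      measures[k, "EQC"] <- 0
    }

    # AQCg / AQCp: overlap of study-k hits with the leave-one-out reference
    p_loo <- loo_meta_p(k)
    q_loo <- stats::p.adjust(p_loo, "BH")
    de_k <- genes[pmat[, k] < alpha]
    de_loo <- genes[q_loo < alpha]
    measures[k, "AQCg"] <- fisher_overlap_log10p(de_k, de_loo, genes)

    logp_k <- ora_logp(de_k)
    logp_loo <- ora_logp(de_loo)
    q_k_sets <- stats::p.adjust(10^-logp_k, "BH")
    q_loo_sets <- stats::p.adjust(10^-logp_loo, "BH")
    measures[k, "AQCp"] <- fisher_overlap_log10p(
      set_names[q_k_sets < alpha], set_names[q_loo_sets < alpha], set_names)

    # CQCg / CQCp: rank consistency of evidence with the reference
    measures[k, "CQCg"] <- spearman_perm_log10p(
      -log10(pmax(pmat[, k], .Machine$double.xmin)),
      -log10(pmax(p_loo, .Machine$double.xmin)), n_perm)
    measures[k, "CQCp"] <- if (length(set_names) >= 3)
      spearman_perm_log10p(logp_k, logp_loo, n_perm) else 0
  }
  structure(measures, class = c("study_qc_measures", "matrix"))
}

#' Standardized mean rank summary and exclusion policy
#'
#' Each measure column is ranked within the collection (rank 1 = best =
#' largest value, average ranks on ties); SMR is a study's mean rank across
#' the six measures, so a *high* SMR means poor quality. The worst
#' `ceiling(exclusion_fraction * K)` studies by SMR are excluded; SMR ties
#' break deterministically by study id order.
#'
#' @param measures A `study_qc_measures` matrix from
#'   [compute_qc_measures()].
#' @param exclusion_fraction Fraction of studies to exclude, in `[0, 1)`.
#' @return An object of class `study_qc_report`: list with `measures`,
#'   `ranks`, `smr` (named vector), `excluded` (study ids), `biplot`
#'   (scores/loadings from [biplot_coordinates()]).
#' @export
summarize_smr <- function(measures, exclusion_fraction = 0.2) {
  if (exclusion_fraction < 0 || exclusion_fraction >= 1)
    stop("exclusion_fraction must be in [0, 1)")
  m <- unclass(measures)
  ranks <- apply(-m, 2, rank, ties.method = "average")
  smr <- rowMeans(ranks)
  n_excl <- ceiling(exclusion_fraction * nrow(m))
  ord <- order(-smr, rownames(m))
  excluded <- rownames(m)[ord][seq_len(n_excl)]
  structure(list(measures = measures, ranks = ranks, smr = smr,
                 excluded = excluded,
                 exclusion_fraction = exclusion_fraction,
                 biplot = tryCatch(suppressWarnings(biplot_coordinates(measures)),
                                   error = function(e) NULL)),
            class = "study_qc_report")
}

#' @export
print.study_qc_report <- function(x, ...) {
  cat(sprintf("<study_qc_report: %d studies, %d excluded (fraction %g)>\n",
              nrow(x$measures), length(x$excluded), x$exclusion_fraction))
  tab <- cbind(round(unclass(x$measures), 2), SMR = round(x$smr, 2),
               excluded = rownames(x$measures) %in% x$excluded)
  print(tab)
  invisible(x)
}

#' Principal-component biplot coordinates of the QC measures
#'
#' PCA of the column-standardized K x 6 measure matrix. Zero-variance
#' columns are dropped with a warning. Sign convention: within each of the
#' first two components, the loading element of largest magnitude is made
#' positive (and the scores flipped accordingly), so that "good" studies
#' project in the direction of the measure arrows.
#'
#' @param measures A `study_qc_measures` matrix (K >= 3).
#' @return List with `scores` (K x 2), `loadings` (measures x 2) and
#'   `sdev`.
#' @export
biplot_coordinates <- function(measures) {
  m <- unclass(measures)
  if (nrow(m) < 3) stop("biplot needs at least 3 studies")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance measure column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  if (!ncol(m)) stop("no informative (non-constant) measure columns")
  z <- scale(m)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ncomp <- min(2, ncol(pc$rotation))
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  loadings <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  if (ncomp < 2) {  # degenerate: pad a zero second component
    scores <- cbind(scores, PC2 = 0)
    loadings <- cbind(loadings, PC2 = 0)
  }
  for (j in 1:2) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores[, 1:2, drop = FALSE],
       loadings = loadings[, 1:2, drop = FALSE], sdev = pc$sdev)
}
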