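#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the DE list overlaps the set more than
#' expected under hypergeometric sampling from the universe (upper-tail
#' Fisher exact p of observing at least the seen overlap), with
#' Benjamini-Hochberg q-values across the collection. Sets are intersected
#' with the universe before testing; DE genes outside the universe are
#' dropped with a warning.
#'
#' @param de_genes Character vector of differentially expressed gene ids.
#' @param universe Character vector: all genes that could have been called
#'   DE (typically the harmonized common-gene space).
#' @param sets Named list of gene-id vectors.
#' @return An `enrichment_result` data.frame: `set`, `overlap`, `set_size`
#'   (within the universe), `universe_size`, `de_size`, `p`, `q`.
#' @export
ora_test <- function(de_genes, universe, sets) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% universe)) {
    warning("dropping DE genes outside the universe")
    de_genes <- intersect(de_genes, universe)
  }
  if (!length(de_genes)) stop("empty DE list")
  U <- length(universe); n_de <- length(de_genes)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    ov <- length(intersect(s, de_genes))
    p <- stats::phyper(ov - 1, length(s), U - length(s), n_de,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(s),
               universe_size = U, de_size = n_de, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' Score one compound instance against a disease signature
#'
#' A reversal relationship means the compound pushes expression opposite to
#' disease: its up-set should overlap the disease *down* genes and its
#' down-set the disease *up* genes. Each side is a hypergeometric upper-tail
#' (Fisher exact) test within the stated universe.
#'
#' @param sig A [consensus_signature()] (`de_signature`) with non-empty
#'   `up`/`down` lists.
#' @param instance List with `up` and `down` gene-id vectors.
#' @param universe Character vector of gene ids.
#' @return List with `p_up_down` (disease-up vs compound-down) and
#'   `p_down_up` (disease-down vs compound-up).
#' @export
score_compound_instance <- function(sig, instance, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  side <- function(disease, compound) {
    disease <- intersect(unique(disease), universe)
    compound <- intersect(unique(compound), universe)
    if (!length(disease) || !length(compound)) return(1)
    ov <- length(intersect(disease, compound))
    stats::phyper(ov - 1, length(compound),
                  length(universe) - length(compound), length(disease),
                  lower.tail = FALSE)
  }
  list(p_up_down = side(sig$up, instance$down),
       p_down_up = side(sig$down, instance$up))
}

#' Prioritize compounds by signature reversal
#'
#' Every instance (compound x cell line x dose) is scored in both reversal
#' directions; the resulting p-values are BH-adjusted across all instances
#' and directions in the library, and an instance counts toward a direction
#' when its adjusted p falls below `alpha`. Counts are summed per compound;
#' compounds with `sum > min_sum` are reported, sorted by total count
#' descending then compound name.
#'
#' @param sig A `de_signature`.
#' @param library A [compound_library()].
#' @param universe Character vector of gene ids.
#' @param alpha Adjusted-p significance cutoff per instance (default 0.01).
#' @param min_sum Report compounds with total count strictly greater than
#'   this (default 5).
#' @return data.frame: `compound`, `sig_down_cmp_up` (instances where the
#'   disease down-genes are enriched in the compound up-set),
#'   `sig_up_cmp_down` (the converse), `sum`. Attribute `instance_table`
#'   holds the per-instance adjusted p-values.
#' @export
prioritize_compounds <- function(sig, library, universe, alpha = 0.01,
                                 min_sum = 5) {
  stopifnot(inherits(library, "compound_library"))
  inst <- library$instances
  if (!nrow(inst)) stop("empty compound library")
  ps <- t(vapply(inst$instance, function(id) {
    s <- score_compound_instance(
      sig, list(up = library$up[[id]], down = library$down[[id]]), universe)
    c(s$p_down_up, s$p_up_down)
  }, numeric(2)))
  colnames(ps) <- c("p_down_up", "p_up_down")
  adj <- matrix(stats::p.adjust(as.vector(ps), method = "BH"),
                ncol = 2, dimnames = dimnames(ps))
  per_inst <- data.frame(inst, ps, padj_down_up = adj[, 1],
                         padj_up_down = adj[, 2], row.names = NULL)
  hit_du <- tapply(adj[, 1] < alpha, inst$compound, sum)
  hit_ud <- tapply(adj[, 2] < alpha, inst$compound, sum)
  out <- data.frame(compound = names(hit_du),
                    sig_down_cmp_up = as.integer(hit_du),
                    sig_up_cmp_down = as.integer(hit_ud[names(hit_du)]),
                    stringsAsFactors = FALSE)
  out$sum <- out$sig_down_cmp_up + out$sig_up_cmp_down
  out <- out[out$sum > min_sum, , drop = FALSE]
  out <- out[order(-out$sum, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "instance_table") <- per_inst
  out
}
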