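# Vectorized two-sample machinery. Ind is an N x B 0/1 matrix whose columns
# mark the "case" arm of each (re)labelling; all genes share the same
# labellings, which preserves gene-gene correlation under the null.
group_stats <- function(X, Ind) {
  n1 <- colSums(Ind)
  N <- nrow(Ind)
  n2 <- N - n1
  s1 <- X %*% Ind
  sq1 <- (X * X) %*% Ind
  s_all <- rowSums(X)
  sq_all <- rowSums(X * X)
  m1 <- sweep(s1, 2, n1, "/")
  m2 <- sweep(-s1 + s_all, 2, n2, "/")
  v1 <- sweep(sq1 - sweep(m1 * m1, 2, n1, "*"), 2, n1 - 1, "/")
  v2 <- sweep((sq_all - sq1) - sweep(m2 * m2, 2, n2, "*"), 2, n2 - 1, "/")
  sp2 <- sweep(sweep(v1, 2, n1 - 1, "*") + sweep(v2, 2, n2 - 1, "*"),
               2, N - 2, "/")
  se <- sqrt(sweep(sp2, 2, 1 / n1 + 1 / n2, "*"))
  list(diff = m1 - m2, se = se, sp2 = sp2, n1 = n1, n2 = n2)
}

case_indicator <- function(group) as.numeric(group == "case")

resolve_s0 <- function(se, s0) {
  if (identical(s0, "auto")) stats::median(se) else {
    stopifnot(is.numeric(s0), s0 >= 0)
    s0
  }
}

#' Penalized t statistic per gene
#'
#' `t_pen(g) = (mean_case - mean_control) / (se_g + s0)` with `se_g` the
#' pooled two-sample standard error. The additive penalty `s0` stabilizes
#' genes with tiny variance; `s0 = "auto"` (default) sets it to the median
#' pooled SE over genes, a robust, parameter-free choice. `s0 = 0` recovers
#' the classical pooled two-sample t.
#'
#' @param study An [expression_study()] with at least 2 samples per arm.
#' @param s0 Penalty constant, or `"auto"`.
#' @return Named numeric vector of penalized t statistics with attribute
#'   `s0` (the resolved value).
#' @export
penalized_t <- function(study, s0 = "auto") {
  stopifnot(inherits(study, "expression_study"))
  Ind <- matrix(case_indicator(study$group), ncol = 1)
  gs <- group_stats(study$expr, Ind)
  s0v <- resolve_s0(gs$se[, 1], s0)
  t_pen <- gs$diff[, 1] / (gs$se[, 1] + s0v)
  names(t_pen) <- study$genes
  attr(t_pen, "s0") <- s0v
  t_pen
}

#' Label-permutation p-values for the penalized t
#'
#' Group labels are permuted `B` times; each permutation is shared across
#' genes, preserving gene-gene correlation in the null. The two-sided
#' p-value uses the add-one correction
#' `p = (1 + #\{b : |t_b| >= |t_obs|\}) / (B + 1)`, so `p >= 1/(B+1)`. When
#' fewer than `B` distinct case-assignments exist (`choose(N, n1) <= B`), or
#' with `B = "exact"`, all assignments are enumerated and the p-value is the
#' exact fraction `#\{|t| >= |t_obs|\} / n_assignments` (the observed
#' labelling is among them).
#'
#' @inheritParams penalized_t
#' @param B Number of label permutations, or `"exact"`.
#' @param seed Integer seed (ignored in exact mode).
#' @return Named numeric vector of two-sided p-values with attributes
#'   `B` (permutations actually used) and `exact`.
#' @export
permutation_pvalues <- function(study, s0 = "auto", B = 1000, seed = 1) {
  stopifnot(inherits(study, "expression_study"))
  X <- study$expr
  N <- ncol(X)
  n1 <- sum(study$group == "case")
  ind_obs <- case_indicator(study$group)
  gs <- group_stats(X, matrix(ind_obs, ncol = 1))
  s0v <- resolve_s0(gs$se[, 1], s0)
  t_obs <- abs(gs$diff[, 1] / (gs$se[, 1] + s0v))

  n_distinct <- choose(N, n1)
  exact <- identical(B, "exact") || (is.numeric(B) && n_distinct <= B)
  if (exact) {
    if (!identical(B, "exact"))
      warning("fewer than B distinct label permutations; enumerating exactly")
    combs <- utils::combn(N, n1)
    Ind <- matrix(0, N, ncol(combs))
    Ind[cbind(as.vector(combs),
              rep(seq_len(ncol(combs)), each = n1))] <- 1
  } else {
    stopifnot(B >= 1)
    set.seed(seed)
    Ind <- replicate(B, ind_obs[sample.int(N)])
  }
  gp <- group_stats(X, Ind)
  Tb <- abs(gp$diff / (gp$se + s0v))
  exceed <- rowSums(Tb >= t_obs - 1e-12)
  p <- if (exact) exceed / ncol(Ind) else (1 + exceed) / (ncol(Ind) + 1)
  names(p) <- study$genes
  attr(p, "B") <- ncol(Ind)
  attr(p, "exact") <- exact
  p
}

#' Standardized effect sizes (Hedges g) per gene
#'
#' Cohen's d `(mean_case - mean_control) / s_pooled` with the small-sample
#' bias correction `g = d * (1 - 3 / (4(n1 + n2) - 9))` and analytic
#' variance `v = (n1 + n2) / (n1 n2) + g^2 / (2(n1 + n2))`.
#'
#' @inheritParams penalized_t
#' @return data.frame with columns `gene`, `g`, `v`.
#' @export
effect_size <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  Ind <- matrix(case_indicator(study$group), ncol = 1)
  gs <- group_stats(study$expr, Ind)
  sp <- sqrt(gs$sp2[, 1])
  if (any(sp == 0))
    stop("zero pooled SD for gene(s): ",
         paste(study$genes[sp == 0], collapse = ", "))
  n1 <- gs$n1[1]; n2 <- gs$n2[1]; n <- n1 + n2
  d <- gs$diff[, 1] / sp
  J <- 1 - 3 / (4 * n - 9)
  g <- d * J
  v <- n / (n1 * n2) + g^2 / (2 * n)
  data.frame(gene = study$genes, g = g, v = v, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Full per-study differential expression table
#'
#' Runs [penalized_t()], [permutation_pvalues()] and [effect_size()] on one
#' study and assembles the per-gene table consumed by the meta-analysis
#' stage.
#'
#' @inheritParams permutation_pvalues
#' @return An object of class `per_study_de`: a data.frame with columns
#'   `gene`, `t_pen`, `p_two`, `direction`, `g`, `v`, and attributes
#'   `study_id`, `s0`, `B`, `seed`.
#' @export
de_study <- function(study, s0 = "auto", B = 1000, seed = 1) {
  t_pen <- penalized_t(study, s0)
  p <- permutation_pvalues(study, s0, B, seed)
  es <- effect_size(study)
  out <- data.frame(gene = study$genes, t_pen = as.numeric(t_pen),
                    p_two = as.numeric(p),
                    direction = sign(as.numeric(t_pen)),
                    g = es$g, v = es$v, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, class = c("per_study_de", "data.frame"),
            study_id = study$study_id, s0 = attr(t_pen, "s0"),
            B = attr(p, "B"), seed = seed)
}

# Fast parametric pooled-t p-values (used internally by the study-level QC
# measures, where a deterministic per-study evidence ranking is needed).
parametric_pvalues <- function(study) {
  Ind <- matrix(case_indicator(study$group), ncol = 1)
  gs <- group_stats(study$expr, Ind)
  tt <- gs$diff[, 1] / gs$se[, 1]
  df <- nrow(Ind) - 2
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  names(p) <- study$genes
  p
}
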