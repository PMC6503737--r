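# Assemble aligned G x K matrices from a list of per-study DE tables.
collect_de <- function(de_list) {
  stopifnot(length(de_list) >= 1)
  genes <- de_list[[1]]$gene
  for (d in de_list) stopifnot(identical(d$gene, genes))
  ids <- vapply(de_list, function(d) {
    id <- attr(d, "study_id"); if (is.null(id)) NA_character_ else id
  }, character(1))
  if (anyNA(ids)) ids <- paste0("study", seq_along(de_list))
  grab <- function(col) {
    m <- vapply(de_list, function(d) d[[col]], numeric(length(genes)))
    dimnames(m) <- list(genes, ids)
    m
  }
  list(p = grab("p_two"), direction = grab("direction"),
       g = grab("g"), v = grab("v"), genes = genes, study_ids = ids)
}

hs_setting <- function(method) {
  switch(method, fisher = "HS_B", stouffer = "HS_B", maxp = "HS_A",
         rop = "HS_r", pr = "HS_B", sr = "HS_B", fem = "HS_A", rem = "HS_r")
}

clamp_p <- function(P) {
  if (any(P <= 0)) {
    warning("p-values of 0 clamped to machine minimum")
    P[P <= 0] <- .Machine$double.xmin
  }
  P[P > 1] <- 1
  P
}

majority_direction <- function(D) {
  s <- sign(rowSums(sign(D)))
  as.integer(s)
}

signed_z <- function(p_meta, direction) {
  direction * stats::qnorm(pmin(p_meta, 1) / 2, lower.tail = FALSE)
}

new_meta_result <- function(genes, statistic, p_meta, direction, method,
                            hs, extra = NULL, params = list()) {
  out <- data.frame(gene = genes, statistic = statistic, p_meta = p_meta,
                    q = NA_real_, z = signed_z(p_meta, direction),
                    direction = as.integer(direction),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  structure(out, class = c("meta_result", "data.frame"),
            method = method, hs = hs, params = params)
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result: method %s (%s), %d genes, %d with q < 0.05>\n",
              attr(x, "method"), attr(x, "hs"), nrow(x),
              if (all(is.na(x$q))) 0L else sum(x$q < 0.05, na.rm = TRUE)))
  invisible(x)
}

# closed-form combined p for one side / two-sided input
combine_closed_form <- function(P, method, r) {
  K <- ncol(P)
  switch(method,
    fisher = {
      X <- -2 * rowSums(log(P))
      list(stat = X, p = stats::pchisq(X, df = 2 * K, lower.tail = FALSE))
    },
    stouffer = {
      Z <- rowSums(stats::qnorm(P, lower.tail = FALSE)) / sqrt(K)
      list(stat = Z, p = stats::pnorm(Z, lower.tail = FALSE))
    },
    maxp = {
      m <- apply(P, 1, max)
      list(stat = m, p = m^K)
    },
    rop = {
      pr <- apply(P, 1, function(x) sort(x, partial = r)[r])
      list(stat = pr, p = stats::pbeta(pr, r, K - r + 1))
    })
}

#' Combine per-study p-values across studies
#'
#' Closed-form p-value combination targeting the three hypothesis settings:
#' Fisher and Stouffer (evidence in one or more studies, HS_B), maxP
#' (evidence in all studies, HS_A, via the Beta(K, 1) upper order
#' statistic), and rOP (the r-th smallest p-value referred to
#' Beta(r, K - r + 1); evidence in "most" studies, HS_r).
#'
#' With `one_sided = TRUE` the one-sided correction (OC) is applied: each
#' study's two-sided p is split by its observed direction into
#' `p_up = p/2` (if up) or `1 - p/2` (if down), the up- and down-sides are
#' combined separately, and `p_meta = min(1, 2 min(P_up, P_down))` with the
#' direction of the winning side. Only direction-concordant genes can score
#' well.
#'
#' @param P G x K matrix of two-sided per-study p-values (rownames genes),
#'   or a list of [de_study()] tables.
#' @param direction G x K matrix of per-study direction signs; required for
#'   `one_sided = TRUE` and for the consensus direction of the z-score.
#' @param method One of `"fisher"`, `"stouffer"`, `"maxp"`, `"rop"`.
#' @param r Order index for rOP (`1 <= r <= K`); `"auto"` uses
#'   `ceiling(0.7 K)`.
#' @param one_sided Apply the one-sided direction correction.
#' @return A `meta_result` data.frame: `gene`, `statistic`, `p_meta`, `q`
#'   (NA until [estimate_fdr()]), `z`, `direction`.
#' @export
combine_pvalues <- function(P, direction = NULL,
                            method = c("fisher", "stouffer", "maxp", "rop"),
                            r = "auto", one_sided = FALSE) {
  if (is.list(P) && !is.matrix(P)) {
    de <- collect_de(P); P <- de$p
    if (is.null(direction)) direction <- de$direction
  }
  method <- match.arg(method)
  P <- clamp_p(as.matrix(P))
  K <- ncol(P)
  if (method == "rop") {
    if (identical(r, "auto")) r <- ceiling(0.7 * K)
    if (!is.numeric(r) || r < 1 || r > K) stop("invalid r for rOP")
    r <- as.integer(r)
  } else r <- NULL

  if (one_sided) {
    if (is.null(direction)) stop("one_sided correction needs directions")
    D <- as.matrix(direction)
    P_up <- ifelse(D > 0, P / 2, ifelse(D < 0, 1 - P / 2, 0.5))
    P_up <- pmin(pmax(P_up, .Machine$double.xmin), 1)
    P_dn <- pmin(pmax(1 - P_up, .Machine$double.xmin), 1)
    up <- combine_closed_form(P_up, method, r)
    dn <- combine_closed_form(P_dn, method, r)
    p_meta <- pmin(1, 2 * pmin(up$p, dn$p))
    dir_out <- ifelse(up$p < dn$p, 1L, ifelse(dn$p < up$p, -1L, 0L))
    stat <- ifelse(up$p <= dn$p, up$stat, dn$stat)
    res <- new_meta_result(rownames(P), stat, p_meta, dir_out,
                           paste0(method, ".oc"), hs_setting(method),
                           params = list(r = r, one_sided = TRUE))
  } else {
    cf <- combine_closed_form(P, method, r)
    dir_out <- if (is.null(direction)) integer(nrow(P)) else
      majority_direction(as.matrix(direction))
    res <- new_meta_result(rownames(P), cf$stat, cf$p, dir_out, method,
                           hs_setting(method),
                           params = list(r = r, one_sided = FALSE))
  }
  res
}

#' Combine per-study evidence ranks across studies
#'
#' Within each study genes are ranked ascending by p-value (rank 1 = most
#' significant, average ranks on ties). The product of ranks (PR) uses the
#' statistic `sum_k log(rank_gk)` (log space avoids overflow); the sum of
#' ranks (SR) uses `sum_k rank_gk`. The null distribution is built by
#' independently shuffling each study's rank column `B_null` times and
#' pooling all G null statistics per shuffle; `p_meta = (1 + #\{null <=
#' obs\}) / (B_null G + 1)`. With `exact = TRUE` (feasible only for tiny G,
#' K) every per-study rank permutation is enumerated and the p-value is the
#' exact fraction without the add-one correction.
#'
#' @inheritParams combine_pvalues
#' @param method `"pr"` or `"sr"`.
#' @param B_null Number of null shuffles.
#' @param seed Integer seed.
#' @param exact Enumerate the full null (requires `(G!)^K` manageable).
#' @return A `meta_result`.
#' @export
combine_ranks <- function(P, direction = NULL, method = c("pr", "sr"),
                          B_null = 100, seed = 1, exact = FALSE) {
  if (is.list(P) && !is.matrix(P)) {
    de <- collect_de(P); P <- de$p
    if (is.null(direction)) direction <- de$direction
  }
  method <- match.arg(method)
  P <- as.matrix(P)
  G <- nrow(P); K <- ncol(P)
  if (G < 2) stop("rank combination needs at least 2 genes")
  R <- apply(P, 2, rank)
  stat_fun <- if (method == "pr") function(M) rowSums(log(M)) else rowSums
  obs <- stat_fun(R)

  if (exact) {
    if (factorial(G)^K > 2e5) stop("exact mode infeasible at this G, K")
    perms <- perms_of(seq_len(G))
    idx <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), K)))
    null_stats <- unlist(lapply(seq_len(nrow(idx)), function(i) {
      M <- vapply(seq_len(K), function(k) R[perms[idx[i, k], ], k],
                  numeric(G))
      stat_fun(M)
    }))
    p_meta <- vapply(obs, function(o) mean(null_stats <= o + 1e-9), numeric(1))
  } else {
    stopifnot(B_null >= 1)
    set.seed(seed)
    null_stats <- numeric(B_null * G)
    for (b in seq_len(B_null)) {
      M <- apply(R, 2, sample)
      null_stats[((b - 1) * G + 1):(b * G)] <- stat_fun(M)
    }
    sorted <- sort(null_stats)
    cnt <- findInterval(obs + 1e-9, sorted)
    p_meta <- (1 + cnt) / (length(sorted) + 1)
  }
  dir_out <- if (is.null(direction)) integer(G) else
    majority_direction(as.matrix(direction))
  new_meta_result(rownames(P), obs, p_meta, dir_out, method, hs_setting(method),
                  params = list(B_null = if (exact) NA else B_null,
                                exact = exact))
}

perms_of <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], perms_of(v[-i]))
  }))
  unname(out)
}

#' Pool standardized effect sizes across studies
#'
#' Fixed-effects model (FEM): inverse-variance weights `w_k = 1/v_k`,
#' `mu_hat = sum(w g) / sum(w)`, `se = 1/sqrt(sum(w))`. Random-effects
#' model (REM): the DerSimonian-Laird moment estimator
#' `tau2 = max(0, (Q - (K - 1)) / C)` with `Q = sum w (g - mu_fem)^2` and
#' `C = sum w - sum w^2 / sum w`, then FEM pooling with weights
#' `1/(v_k + tau2)`. `z = mu_hat / se`; the two-sided p is normal-theory.
#'
#' @param g G x K matrix of per-study Hedges g (or a list of [de_study()]
#'   tables, in which case `v` is taken from them).
#' @param v G x K matrix of matching variances (all positive).
#' @param model `"fem"` or `"rem"` (REM needs K >= 2).
#' @return A `meta_result` with additional columns `mu_hat`, `se` and, for
#'   REM, `tau2_hat` and `Q`.
#' @export
combine_effects <- function(g, v = NULL, model = c("fem", "rem")) {
  if (is.list(g) && !is.matrix(g)) {
    de <- collect_de(g); v <- de$v; g <- de$g
  }
  model <- match.arg(model)
  g <- as.matrix(g); v <- as.matrix(v)
  if (any(v <= 0)) stop("all effect-size variances must be positive")
  K <- ncol(g)
  if (model == "rem" && K < 2) stop("REM needs at least 2 studies")
  w <- 1 / v
  sw <- rowSums(w)
  mu_fem <- rowSums(w * g) / sw
  if (model == "fem") {
    mu <- mu_fem
    se <- 1 / sqrt(sw)
    extra <- data.frame(mu_hat = mu, se = se)
  } else {
    Q <- rowSums(w * (g - mu_fem)^2)
    C <- sw - rowSums(w * w) / sw
    tau2 <- pmax(0, (Q - (K - 1)) / C)
    ws <- 1 / (v + tau2)
    mu <- rowSums(ws * g) / rowSums(ws)
    se <- 1 / sqrt(rowSums(ws))
    extra <- data.frame(mu_hat = mu, se = se, tau2_hat = tau2, Q = Q)
  }
  z <- mu / se
  p_meta <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  res <- new_meta_result(rownames(g), z, p_meta, as.integer(sign(mu)),
                         model, hs_setting(model), extra = extra)
  res$z <- z  # effect-based z is mu/se itself (consistent magnitude)
  res
}

#' Attach FDR q-values to a meta-analysis result
#'
#' `mode = "bh"` applies Benjamini-Hochberg step-up q-values.
#' `mode = "permutation"` estimates, for each observed p, the median (over
#' null replicates) of the expected false-positive count at that threshold
#' divided by the observed count, enforced monotone in p and clipped to
#' `[0, 1]`. Null replicates are p-value vectors from re-running the
#' combination on label-permuted per-study statistics.
#'
#' @param result A `meta_result`.
#' @param mode `"bh"` or `"permutation"`.
#' @param null_p For permutation mode: a list of numeric vectors (one per
#'   replicate) or a matrix with one replicate per row.
#' @return The `meta_result` with its `q` column filled.
#' @export
estimate_fdr <- function(result, mode = c("bh", "permutation"),
                         null_p = NULL) {
  mode <- match.arg(mode)
  p <- result$p_meta
  if (mode == "bh") {
    result$q <- stats::p.adjust(p, method = "BH")
    return(result)
  }
  if (is.matrix(null_p)) null_p <- split(null_p, row(null_p))
  if (!length(null_p)) stop("permutation FDR needs non-empty null p-values")
  ord <- order(p)
  ps <- p[ord]
  n_obs <- seq_along(ps)
  qs_rep <- vapply(null_p, function(np) {
    fp <- findInterval(ps, sort(np)) * length(ps) / length(np)
    fp / n_obs
  }, numeric(length(ps)))
  q_sorted <- apply(as.matrix(qs_rep), 1, stats::median)
  q_sorted <- rev(cummin(rev(q_sorted)))  # monotone nondecreasing in p
  q_sorted <- pmin(pmax(q_sorted, 0), 1)
  q <- numeric(length(p))
  q[ord] <- q_sorted
  result$q <- q
  result
}

#' Consensus DE signature across meta-analysis methods
#'
#' A gene enters the signature when its q-value is below `fdr` in *every*
#' supplied result and its direction agrees across them; genes significant
#' everywhere but direction-discordant are excluded (and counted in the
#' `n_direction_conflicts` attribute). The per-gene signed z score is taken
#' from the first effect-size-based result (one carrying `mu_hat`) if
#' present, else from the first result.
#'
#' @param results List of `meta_result` objects over a shared gene universe,
#'   each with q-values filled.
#' @param fdr FDR threshold.
#' @return An object of class `de_signature`: list with `up`, `down`
#'   (gene-id vectors), `z` (named signed scores over all genes) and
#'   `provenance`.
#' @export
consensus_signature <- function(results, fdr = 0.05) {
  stopifnot(length(results) >= 1)
  genes <- results[[1]]$gene
  for (r in results) stopifnot(identical(r$gene, genes))
  sig <- Reduce(`&`, lapply(results, function(r) !is.na(r$q) & r$q < fdr))
  D <- vapply(results, function(r) r$direction, numeric(length(genes)))
  D <- as.matrix(D)
  concordant <- apply(D, 1, function(d) all(d == d[1]) && d[1] != 0)
  conflicts <- sum(sig & !concordant)
  keep <- sig & concordant
  has_mu <- vapply(results, function(r) "mu_hat" %in% names(r), logical(1))
  zsrc <- results[[if (any(has_mu)) which(has_mu)[1] else 1]]
  z <- stats::setNames(zsrc$z, genes)
  structure(list(
    up = genes[keep & D[, 1] > 0],
    down = genes[keep & D[, 1] < 0],
    z = z,
    provenance = list(
      methods = vapply(results, attr, character(1), "method"),
      fdr = fdr, n_direction_conflicts = conflicts)),
    class = "de_signature")
}

#' @export
print.de_signature <- function(x, ...) {
  cat(sprintf("<de_signature: %d up, %d down (methods: %s; FDR < %g)>\n",
              length(x$up), length(x$down),
              paste(x$provenance$methods, collapse = " & "),
              x$provenance$fdr))
  invisible(x)
}

#' Spearman concordance between meta-analysis methods
#'
#' @param results List of two or more `meta_result` objects over a shared
#'   gene universe.
#' @return Symmetric method x method matrix of Spearman correlations of
#'   `p_meta`.
#' @export
method_concordance <- function(results) {
  if (length(results) < 2) stop("need at least 2 results to compare")
  genes <- results[[1]]$gene
  for (r in results) stopifnot(identical(r$gene, genes))
  P <- vapply(results, function(r) r$p_meta, numeric(length(genes)))
  colnames(P) <- vapply(results, attr, character(1), "method")
  stats::cor(P, method = "spearman")
}

#' Spearman concordance of two signed gene scores
#'
#' Used to compare a meta-analysis Z signature against an independent one
#' (e.g. a replication panel) over their shared genes.
#'
#' @param z_a,z_b Named numeric vectors of per-gene signed scores.
#' @return Spearman's rho over the shared genes (at least 3 required).
#' @export
compare_signatures <- function(z_a, z_b) {
  shared <- intersect(names(z_a), names(z_b))
  if (length(shared) < 3) stop("need at least 3 shared genes")
  stats::cor(z_a[shared], z_b[shared], method = "spearman")
}
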