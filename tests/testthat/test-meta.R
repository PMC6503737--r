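pmat <- function(p, K = NULL, genes = NULL) {
  m <- if (is.matrix(p)) p else matrix(p, nrow = 1)
  if (is.null(genes)) genes <- sprintf("G%04d", seq_len(nrow(m)))
  dimnames(m) <- list(genes, paste0("s", seq_len(ncol(m))))
  m
}

test_that("closed-form p-value combinations match their oracles", {
  # Fisher on (0.05, 0.05): X = -2 * 2 * log(0.05), chi-square_4 upper tail
  f <- combine_pvalues(pmat(c(0.05, 0.05)), method = "fisher")
  expect_equal(f$statistic, -4 * log(0.05), tolerance = 1e-6)
  expect_equal(f$statistic, 11.9829, tolerance = 1e-4)
  expect_equal(f$p_meta, pchisq(-4 * log(0.05), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(f$p_meta, 0.01748, tolerance = 1e-3)

  # Stouffer at p = 0.5 everywhere: Z = 0, p = 0.5
  s <- combine_pvalues(pmat(c(0.5, 0.5, 0.5)), method = "stouffer")
  expect_equal(s$statistic, 0, tolerance = 1e-12)
  expect_equal(s$p_meta, 0.5, tolerance = 1e-12)

  # maxP: Beta(K, 1) CDF = x^K
  m <- combine_pvalues(pmat(c(0.2, 0.5)), method = "maxp")
  expect_equal(m$p_meta, 0.25, tolerance = 1e-12)

  # rOP K = 3, r = 2: Beta(2, 2) CDF = x^2 (3 - 2x) at the 2nd smallest p
  r <- combine_pvalues(pmat(c(0.1, 0.2, 0.9)), method = "rop", r = 2)
  expect_equal(r$statistic, 0.2, tolerance = 1e-12)
  expect_equal(r$p_meta, 0.2^2 * (3 - 2 * 0.2), tolerance = 1e-12)
  expect_equal(r$p_meta, 0.104, tolerance = 1e-12)

  expect_error(combine_pvalues(pmat(c(0.1, 0.2)), method = "rop", r = 5),
               "invalid r")
})

test_that("rOP at r = K is exactly maxP", {
  set.seed(41)
  P <- pmat(matrix(runif(500 * 5), 500, 5))
  a <- combine_pvalues(P, method = "rop", r = 5)
  b <- combine_pvalues(P, method = "maxp")
  expect_equal(a$p_meta, b$p_meta, tolerance = 1e-12)
})

test_that("decreasing a single p never increases fisher/stouffer/rop p_meta", {
  set.seed(42)
  for (rep in 1:20) {
    K <- sample(3:6, 1)
    p <- runif(K, 0.01, 0.99)
    j <- sample(K, 1)
    p2 <- p; p2[j] <- p[j] * runif(1)
    for (method in c("fisher", "stouffer", "rop")) {
      r <- if (method == "rop") sample(K, 1) else NULL
      before <- combine_pvalues(pmat(p), method = method, r = r)$p_meta
      after <- combine_pvalues(pmat(p2), method = method, r = r)$p_meta
      expect_lte(after, before + 1e-12)
    }
  }
})

test_that("the one-sided correction rewards direction concordance", {
  # worked pair: same magnitudes, concordant vs discordant directions
  P <- pmat(matrix(0.01, 2, 2))
  D <- matrix(c(1, 1, 1, -1), 2, 2, byrow = TRUE)
  res <- combine_pvalues(P, D, method = "fisher", one_sided = TRUE)
  expect_lt(res$p_meta[1], res$p_meta[2])
  expect_equal(res$direction[1], 1L)
  expect_equal(attr(res, "method"), "fisher.oc")

  # property: concordant never loses, over random magnitudes and methods
  set.seed(43)
  for (rep in 1:20) {
    K <- sample(2:6, 1)
    p <- runif(K, 0.001, 0.5)
    d_mixed <- sample(c(-1, 1), K, replace = TRUE)
    if (all(d_mixed == d_mixed[1])) d_mixed[1] <- -d_mixed[1]
    P2 <- pmat(rbind(p, p))
    D2 <- rbind(rep(1, K), d_mixed)
    for (method in c("fisher", "stouffer", "maxp", "rop")) {
      res2 <- combine_pvalues(P2, D2, method = method,
                              r = if (method == "rop") ceiling(0.7 * K) else "auto",
                              one_sided = TRUE)
      expect_lte(res2$p_meta[1], res2$p_meta[2] + 1e-12)
    }
  }
})

test_that("rank combination matches exhaustive enumeration at tiny size", {
  P <- pmat(matrix(c(0.1, 0.5, 0.9, 0.2, 0.8, 0.4), 3, 2))
  for (method in c("pr", "sr")) {
    res <- combine_ranks(P, method = method, exact = TRUE)
    # independent brute force over all (3!)^2 rank pairings
    R <- apply(P, 2, rank)
    perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    stat <- function(M) if (method == "pr") rowSums(log(M)) else rowSums(M)
    null <- c()
    for (pa in perms) for (pb in perms)
      null <- c(null, stat(cbind(R[pa, 1], R[pb, 2])))
    obs <- stat(R)
    oracle <- sapply(obs, function(o) mean(null <= o + 1e-9))
    expect_equal(res$p_meta, unname(oracle), tolerance = 1e-12)
  }

  # a gene ranked 1 everywhere attains the minimal statistic
  P3 <- pmat(matrix(c(0.01, 0.5, 0.9, 0.01, 0.6, 0.7), 3, 2))
  for (method in c("pr", "sr")) {
    res3 <- combine_ranks(P3, method = method, B_null = 50, seed = 2)
    expect_equal(which.min(res3$statistic), 1L)
  }

  # PR and SR order genes identically at K = 1
  P1 <- pmat(matrix(runif(20), 20, 1))
  o_pr <- order(combine_ranks(P1, method = "pr", B_null = 20, seed = 1)$statistic)
  o_sr <- order(combine_ranks(P1, method = "sr", B_null = 20, seed = 1)$statistic)
  expect_identical(o_pr, o_sr)
})

test_that("FEM and DerSimonian-Laird REM match hand arithmetic and metafor", {
  g <- pmat(c(0, 2)); v <- pmat(c(1, 1))
  fem <- combine_effects(g, v, model = "fem")
  expect_equal(fem$mu_hat, 1, tolerance = 1e-12)
  expect_equal(fem$se, sqrt(0.5), tolerance = 1e-12)
  expect_equal(fem$z, sqrt(2), tolerance = 1e-12)

  rem <- combine_effects(g, v, model = "rem")
  expect_equal(rem$Q, 2, tolerance = 1e-12)
  expect_equal(rem$tau2_hat, 1, tolerance = 1e-12)
  expect_equal(rem$mu_hat, 1, tolerance = 1e-12)
  expect_equal(rem$se, 1, tolerance = 1e-12)
  expect_equal(rem$z, 1, tolerance = 1e-12)

  # homogeneous data (Q <= K - 1): tau2 clamps to 0 and REM == FEM
  gh <- pmat(c(0.5, 0.52, 0.48)); vh <- pmat(c(0.2, 0.2, 0.2))
  remh <- combine_effects(gh, vh, model = "rem")
  femh <- combine_effects(gh, vh, model = "fem")
  expect_equal(remh$tau2_hat, 0)
  expect_equal(remh$mu_hat, femh$mu_hat, tolerance = 1e-12)
  expect_equal(remh$se, femh$se, tolerance = 1e-12)

  # independent oracle on random inputs
  skip_if_not_installed("metafor")
  set.seed(44)
  for (i in 1:5) {
    gi <- rnorm(6); vi <- runif(6, 0.05, 0.5)
    rma <- metafor::rma(yi = gi, vi = vi, method = "DL")
    mine <- combine_effects(pmat(gi), pmat(vi), model = "rem")
    expect_equal(mine$mu_hat, as.numeric(rma$beta), tolerance = 1e-8)
    expect_equal(mine$tau2_hat, rma$tau2, tolerance = 1e-8)
    expect_equal(mine$se, rma$se, tolerance = 1e-8)
  }
  expect_error(combine_effects(pmat(c(0, 1)), pmat(c(1, 0)), model = "fem"),
               "positive")
})

test_that("DL tau2 is recovered at scale", {
  set.seed(45)
  K <- 50; v <- 0.04; tau2 <- 0.25; reps <- 200
  est <- replicate(reps, {
    g <- rnorm(K, 0.5, sqrt(tau2 + v))
    combine_effects(pmat(g), pmat(rep(v, K)), model = "rem")$tau2_hat
  })
  expect_lt(abs(mean(est) - tau2) / tau2, 0.2)
})

test_that("FDR estimation follows BH and the permutation recipe", {
  res <- make_meta_stub(q = c(0.01, 0.02, 0.03, 0.04), direction = rep(1, 4))
  res$p_meta <- c(0.01, 0.02, 0.03, 0.04); res$q <- NA_real_
  bh <- estimate_fdr(res, mode = "bh")
  expect_equal(bh$q, rep(0.04, 4), tolerance = 1e-12)

  res1 <- res; res1$p_meta <- rep(1, 4)
  expect_equal(estimate_fdr(res1, "bh")$q, rep(1, 4))

  # permutation q on null-only data is ~1 for the median gene
  set.seed(46)
  resn <- make_meta_stub(q = runif(200), direction = rep(1, 200))
  resn$p_meta <- runif(200); resn$q <- NA_real_
  null_p <- lapply(1:20, function(i) runif(200))
  pq <- estimate_fdr(resn, mode = "permutation", null_p = null_p)
  expect_gte(median(pq$q), 0.8)
  expect_true(all(diff(pq$q[order(pq$p_meta)]) >= -1e-12))
  expect_true(all(pq$q >= 0 & pq$q <= 1))
  expect_error(estimate_fdr(resn, mode = "permutation", null_p = list()),
               "non-empty")
})

test_that("consensus signatures require joint significance and concordance", {
  q_a <- c(0.01, 0.01, 0.20, 0.01)
  q_b <- c(0.01, 0.30, 0.01, 0.01)
  d_a <- c(1, 1, 1, 1)
  d_b <- c(1, 1, 1, -1)
  a <- make_meta_stub(q_a, d_a, method = "rop.oc")
  b <- make_meta_stub(q_b, d_b, method = "rem")
  b$mu_hat <- d_b * 0.5
  sig <- consensus_signature(list(a, b), fdr = 0.05)
  expect_identical(sig$up, "G0001")           # joint q < 0.05, concordant
  expect_identical(sig$down, character(0))
  expect_equal(sig$provenance$n_direction_conflicts, 1)  # gene 4
  # z comes from the effect-based result
  expect_equal(unname(sig$z["G0001"]), b$z[1])

  dn <- make_meta_stub(c(0.01, 0.5), c(-1, -1), method = "m1")
  dn2 <- make_meta_stub(c(0.02, 0.5), c(-1, 1), method = "m2")
  sig2 <- consensus_signature(list(dn, dn2), fdr = 0.05)
  expect_identical(sig2$down, "G0001")
})

test_that("method concordance and signature comparison behave as correlations", {
  set.seed(47)
  P <- pmat(matrix(runif(300 * 4), 300, 4))
  r1 <- combine_pvalues(P, method = "fisher")
  r2 <- combine_pvalues(P, method = "rop", r = 4)
  r3 <- combine_pvalues(P, method = "maxp")
  M <- method_concordance(list(r1, r2, r3))
  expect_equal(diag(M), setNames(rep(1, 3), c("fisher", "rop", "maxp")))
  expect_equal(M, t(M))
  expect_equal(M["rop", "maxp"], 1, tolerance = 1e-12)  # rOP(r=K) == maxP
  expect_error(method_concordance(list(r1)), "at least 2")

  z <- setNames(rnorm(50), sprintf("G%04d", 1:50))
  expect_equal(compare_signatures(z, z), 1)
  expect_equal(compare_signatures(z, -z), -1)
  expect_error(compare_signatures(z[1:2], z[1:2]), "at least 3")
})

test_that("closed-form meta p-values are uniform under a uniform null", {
  set.seed(48)
  P <- pmat(matrix(runif(2000 * 5), 2000, 5))
  for (method in c("fisher", "stouffer", "maxp", "rop")) {
    res <- combine_pvalues(P, method = method,
                           r = if (method == "rop") 3 else "auto")
    expect_gt(ks.test(res$p_meta, "punif")$p.value, 0.01)
  }
})

test_that("hypothesis-setting taxonomy orders methods as targeted", {
  # HS_A signal (all studies) vs HS_B contaminant (one study): maxP prefers
  # the consistent gene
  K <- 5
  p_all <- rep(0.02, K)
  p_one <- c(1e-6, rep(0.6, K - 1))
  P <- pmat(rbind(p_all, p_one))
  mp <- combine_pvalues(P, method = "maxp")
  expect_lt(mp$p_meta[1], mp$p_meta[2])
  for (method in c("pr", "sr")) {
    rk <- combine_ranks(pmat(rbind(p_all, p_one,
                                   matrix(runif(20 * K, 0.1, 1), 20, K))),
                        method = method, B_null = 50, seed = 3)
    expect_lt(rk$statistic[1], rk$statistic[2])
  }

  # HS_r signal at r_frac = 0.7: rOP(ceil(0.7K)) beats maxP in sensitivity
  # at matched thresholds (carried by 7 of 10 studies)
  K <- 10
  p_hsr <- c(rep(0.001, 7), rep(0.7, 3))
  P2 <- pmat(rbind(p_hsr, rep(0.5, K)))
  rop <- combine_pvalues(P2, method = "rop", r = 7)
  mp2 <- combine_pvalues(P2, method = "maxp")
  expect_lt(rop$p_meta[1], mp2$p_meta[1])
})
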