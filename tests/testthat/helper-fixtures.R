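# Small deterministic fixtures used across the suite.

make_study <- function(G = 50, n_case = 5, n_control = 5, delta = 0,
                       sigma = 1, seed = 1, study_id = "S1") {
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(G))
  N <- n_case + n_control
  expr <- matrix(rnorm(G * N, 7, sigma), G, N,
                 dimnames = list(genes, sprintf("%s_%02d", study_id, 1:N)))
  group <- c(rep("control", n_control), rep("case", n_case))
  if (any(delta != 0))
    expr[, group == "case"] <- expr[, group == "case"] + delta
  expression_study(expr, group, study_id)
}

# an arm vector with exactly the requested mean and SD
exact_arm <- function(n, mean = 0, sd = 1) {
  x <- as.numeric(scale(seq_len(n)))
  x * sd + mean
}

# study where every gene has case - control difference `d` and both arm SDs
# exactly 1 (so pooled SD is exactly 1)
exact_effect_study <- function(G = 5, n = 10, d = 0.5, study_id = "EX") {
  row <- c(exact_arm(n, 0, 1), exact_arm(n, d, 1))
  expr <- matrix(row, G, 2 * n, byrow = TRUE,
                 dimnames = list(sprintf("G%03d", seq_len(G)),
                                 sprintf("%s_%02d", study_id, seq_len(2 * n))))
  expression_study(expr, c(rep("control", n), rep("case", n)), study_id)
}

make_de_table <- function(p, direction, g = NULL, v = NULL, study_id = "S1",
                          genes = sprintf("G%04d", seq_along(p))) {
  if (is.null(g)) g <- direction * 0.5
  if (is.null(v)) v <- rep(0.2, length(p))
  structure(
    data.frame(gene = genes, t_pen = direction * qnorm(1 - p / 2),
               p_two = p, direction = direction, g = g, v = v,
               stringsAsFactors = FALSE),
    class = c("per_study_de", "data.frame"), study_id = study_id,
    B = 1000, s0 = 0.1, seed = 1)
}

# aligned meta_result stub for consensus tests
make_meta_stub <- function(q, direction, method = "stub",
                           genes = sprintf("G%04d", seq_along(q))) {
  structure(
    data.frame(gene = genes, statistic = 0, p_meta = q, q = q,
               z = direction * 1, direction = as.integer(direction),
               stringsAsFactors = FALSE),
    class = c("meta_result", "data.frame"), method = method, hs = "HS_r",
    params = list())
}
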