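#' Inter-array correlation (IAC) sample QC
#'
#' The IAC of a pair of samples is the Pearson correlation of their full
#' expression vectors. A sample whose mean IAC with all other samples falls
#' far below the study average has a divergent expression profile and is an
#' outlier candidate.
#'
#' `compute_iac` builds the full N x N IAC matrix and per-sample mean IACs;
#' `flag_outliers` applies the mean - c * SD cutoff (c = 3 by default);
#' `drop_flagged` removes the flagged samples from the study. The overall
#' mean and SD are taken over the per-sample mean IACs, the quantity the
#' cutoff thresholds. Flagging is single-pass: the cutoff is applied once,
#' with no re-computation after removal.
#'
#' @param study An [expression_study()] with at least 3 samples.
#' @return `compute_iac`: an object of class `sample_qc` with elements
#'   `study_id`, `iac` (N x N matrix), `mean_iac`, `overall_mean`,
#'   `overall_sd`, and (after `flag_outliers`) `c`, `cutoff`, `flagged`.
#' @export
compute_iac <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  X <- study$expr
  if (ncol(X) < 3) stop("IAC QC needs at least 3 samples")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant expression vector for sample(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  C <- stats::cor(X)
  N <- ncol(X)
  mean_iac <- (rowSums(C) - 1) / (N - 1)
  structure(list(study_id = study$study_id, iac = C, mean_iac = mean_iac,
                 overall_mean = mean(mean_iac),
                 overall_sd = stats::sd(mean_iac),
                 c = NA_real_, cutoff = NA_real_, flagged = character(0)),
            class = "sample_qc")
}

#' @rdname compute_iac
#' @param report A `sample_qc` from `compute_iac`.
#' @param c SD multiplier for the cutoff `overall_mean - c * overall_sd`.
#' @export
flag_outliers <- function(report, c = 3) {
  stopifnot(inherits(report, "sample_qc"))
  report$c <- c
  report$cutoff <- report$overall_mean - c * report$overall_sd
  report$flagged <- if (report$overall_sd == 0) character(0) else
    names(report$mean_iac)[report$mean_iac < report$cutoff]
  report
}

#' @rdname compute_iac
#' @export
drop_flagged <- function(study, report) {
  stopifnot(inherits(study, "expression_study"),
            inherits(report, "sample_qc"))
  if (!length(report$flagged)) return(study)
  keep <- !(colnames(study$expr) %in% report$flagged)
  group <- study$group[keep]
  if (sum(group == "case") < 2 || sum(group == "control") < 2)
    stop("design degeneracy: removal leaves fewer than 2 samples in an arm")
  meta <- if (is.null(study$metadata)) NULL else
    study$metadata[keep, , drop = FALSE]
  expression_study(study$expr[, keep, drop = FALSE], group,
                   study$study_id, meta)
}

#' Classical MDS coordinates from the IAC matrix
#'
#' Companion visualization coordinates (distance `1 - IAC`); exported for
#' plotting but never used as a flagging rule.
#'
#' @param report A `sample_qc`.
#' @param k Number of dimensions.
#' @return N x k matrix of coordinates.
#' @export
mds_coordinates <- function(report, k = 2) {
  stats::cmdscale(stats::as.dist(1 - report$iac), k = k)
}

#' @export
print.sample_qc <- function(x, ...) {
  cat(sprintf("<sample_qc '%s': %d samples, mean IAC %.3f (SD %.4f)>\n",
              x$study_id, length(x$mean_iac), x$overall_mean, x$overall_sd))
  if (!is.na(x$cutoff))
    cat(sprintf("  cutoff %.4f (c = %g): %d flagged%s\n", x$cutoff, x$c,
                length(x$flagged),
                if (length(x$flagged))
                  paste0(" [", paste(x$flagged, collapse = ", "), "]") else ""))
  invisible(x)
}
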