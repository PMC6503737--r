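#' Construct a single expression study
#'
#' Bundles one study's normalized, log2-scale genes x samples expression
#' matrix with its two-arm design (case/control labels) and optional
#' per-sample metadata.
#'
#' @param expr Numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids). Values are assumed
#'   already normalized and on the log2 scale.
#' @param group Character or factor of length `ncol(expr)` with values
#'   `"case"` or `"control"`.
#' @param study_id Single string identifying the study.
#' @param metadata Optional data.frame of per-sample annotations
#'   (platform, brain region, ...), one row per sample.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(expr, group, study_id = "study1", metadata = NULL) {
  expr <- as.matrix(expr)
  if (!is.numeric(expr)) stop("expr must be numeric")
  if (anyNA(expr)) stop("expr contains missing values")
  if (is.null(rownames(expr))) stop("expr must have gene ids as rownames")
  if (anyDuplicated(rownames(expr))) stop("gene identifiers must be unique")
  if (is.null(colnames(expr)))
    colnames(expr) <- paste0("S", seq_len(ncol(expr)))
  group <- as.character(group)
  if (length(group) != ncol(expr))
    stop("group must have one label per sample")
  if (!all(group %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  if (sum(group == "case") < 2L || sum(group == "control") < 2L)
    stop("invalid design: each arm needs at least 2 samples")
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (nrow(metadata) != ncol(expr))
      stop("metadata must have one row per sample")
    rownames(metadata) <- colnames(expr)
  }
  structure(
    list(study_id = as.character(study_id)[1], expr = expr,
         genes = rownames(expr), group = group, metadata = metadata),
    class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study '%s': %d genes x %d samples (%d case / %d control)>\n",
              x$study_id, nrow(x$expr), ncol(x$expr),
              sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}

#' Construct a collection of expression studies
#'
#' @param studies List of [expression_study()] objects with unique ids.
#' @return An object of class `study_collection` (a list with elements
#'   `studies` and `K`).
#' @export
study_collection <- function(studies) {
  if (!length(studies)) stop("a collection needs at least one study")
  ok <- vapply(studies, inherits, logical(1), "expression_study")
  if (!all(ok)) stop("all elements must be expression_study objects")
  ids <- vapply(studies, function(s) s$study_id, character(1))
  if (anyDuplicated(ids)) stop("study ids must be unique")
  names(studies) <- ids
  structure(list(studies = studies, K = length(studies)),
            class = "study_collection")
}

#' @export
print.study_collection <- function(x, ...) {
  cat(sprintf("<study_collection: K = %d studies>\n", x$K))
  for (s in x$studies)
    cat(sprintf("  %s: %d genes x %d samples\n",
                s$study_id, nrow(s$expr), ncol(s$expr)))
  invisible(x)
}

study_ids <- function(coll) names(coll$studies)

#' Restrict all studies to their common gene space
#'
#' Every study is subset to the intersection of gene identifiers across the
#' collection, rows ordered identically (order of appearance in the first
#' study).
#'
#' @param coll A [study_collection()].
#' @return A `study_collection` over the common genes.
#' @export
harmonize_genes <- function(coll) {
  stopifnot(inherits(coll, "study_collection"))
  common <- Reduce(intersect, lapply(coll$studies, function(s) s$genes))
  if (!length(common)) stop("no genes are shared by all studies")
  studies <- lapply(coll$studies, function(s) {
    expression_study(s$expr[common, , drop = FALSE], s$group,
                     s$study_id, s$metadata)
  })
  study_collection(studies)
}

# -- on-disk layout: <id>.expr.tsv (gene + one column per sample, full
#    precision so matrices round-trip exactly) and <id>.meta.tsv ------------

#' Write one study as TSV files
#'
#' @param study An [expression_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ef <- file.path(dir, paste0(study$study_id, ".expr.tsv"))
  mf <- file.path(dir, paste0(study$study_id, ".meta.tsv"))
  m <- study$expr
  body <- cbind(gene = rownames(m),
                matrix(sprintf("%.17g", m), nrow(m), ncol(m),
                       dimnames = list(NULL, colnames(m))))
  utils::write.table(body, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample = colnames(m), group = study$group,
                     stringsAsFactors = FALSE)
  if (!is.null(study$metadata)) meta <- cbind(meta, study$metadata)
  utils::write.table(meta, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ef, mf))
}

#' Read one study from TSV files
#'
#' @param expr_path Path to the `<id>.expr.tsv` matrix (first column gene id).
#' @param meta_path Path to the matching `<id>.meta.tsv` sample table with at
#'   least `sample` and `group` columns.
#' @param study_id Study id; defaults to the expression file's basename.
#' @return An [expression_study()].
#' @export
read_study <- function(expr_path, meta_path,
                       study_id = sub("\\.expr\\.tsv$", "", basename(expr_path))) {
  tab <- utils::read.table(expr_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  m <- m[, meta$sample, drop = FALSE]
  extra <- meta[, setdiff(names(meta), c("sample", "group")), drop = FALSE]
  if (!ncol(extra)) extra <- NULL
  expression_study(m, meta$group, study_id, extra)
}

#' Write / read a whole collection
#'
#' `write_collection` writes each study's expression and metadata TSVs into
#' `dir`; `read_collection` re-assembles every `*.expr.tsv` found there.
#'
#' @param coll A [study_collection()].
#' @param dir Directory.
#' @return `write_collection`: invisibly, `dir`; `read_collection`: a
#'   `study_collection`.
#' @export
write_collection <- function(coll, dir) {
  for (s in coll$studies) write_study(s, dir)
  invisible(dir)
}

#' @rdname write_collection
#' @export
read_collection <- function(dir) {
  efs <- sort(list.files(dir, pattern = "\\.expr\\.tsv$", full.names = TRUE))
  if (!length(efs)) stop("no *.expr.tsv files in ", dir)
  studies <- lapply(efs, function(ef) {
    mf <- sub("\\.expr\\.tsv$", ".meta.tsv", ef)
    read_study(ef, mf)
  })
  study_collection(studies)
}

# -- GMT gene-set format ----------------------------------------------------

#' Read and write gene sets in GMT format
#'
#' GMT is the standard tab-separated gene-set format: one set per line as
#' `name <tab> description <tab> member1 <tab> member2 ...`.
#'
#' @param path File path.
#' @param sets Named list of character vectors (gene ids per set).
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `read_gmt`: a named list of character vectors; `write_gmt`:
#'   invisibly, `path`.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# -- compound perturbation signature libraries ------------------------------

#' Construct a compound signature library
#'
#' One perturbation *instance* is a compound tested in one cell line at one
#' dose, carrying an up-regulated and a down-regulated gene set. Instances
#' are keyed `compound|cell_line|dose`.
#'
#' @param instances data.frame with columns `instance`, `compound`,
#'   `cell_line`, `dose`.
#' @param up,down Named lists of gene-id vectors, names matching
#'   `instances$instance`.
#' @return An object of class `compound_library`.
#' @export
compound_library <- function(instances, up, down) {
  instances <- as.data.frame(instances)
  stopifnot(all(c("instance", "compound", "cell_line", "dose") %in%
                  names(instances)))
  if (!setequal(names(up), instances$instance) ||
      !setequal(names(down), instances$instance))
    stop("up/down sets must be named by instance id")
  for (id in instances$instance)
    if (length(intersect(up[[id]], down[[id]])))
      stop("instance ", id, " has overlapping up and down sets")
  structure(list(instances = instances,
                 up = up[instances$instance],
                 down = down[instances$instance]),
            class = "compound_library")
}

#' @export
print.compound_library <- function(x, ...) {
  cat(sprintf("<compound_library: %d instances, %d compounds>\n",
              nrow(x$instances), length(unique(x$instances$compound))))
  invisible(x)
}

#' Read / write a compound library as paired up/down GMT files
#'
#' Instance names follow the `compound|cell_line|dose` convention.
#'
#' @param up_path,down_path Paths to the `*_up.gmt` / `*_down.gmt` files.
#' @param library A [compound_library()].
#' @return `read_compound_library`: a `compound_library`;
#'   `write_compound_library`: invisibly, the two paths.
#' @export
read_compound_library <- function(up_path, down_path) {
  up <- read_gmt(up_path)
  down <- read_gmt(down_path)
  parts <- strsplit(names(up), "|", fixed = TRUE)
  instances <- data.frame(
    instance = names(up),
    compound = vapply(parts, `[`, character(1), 1),
    cell_line = vapply(parts, `[`, character(1), 2),
    dose = vapply(parts, `[`, character(1), 3),
    stringsAsFactors = FALSE)
  compound_library(instances, up, down)
}

#' @rdname read_compound_library
#' @export
write_compound_library <- function(library, up_path, down_path) {
  write_gmt(library$up, up_path)
  write_gmt(library$down, down_path)
  invisible(c(up_path, down_path))
}
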