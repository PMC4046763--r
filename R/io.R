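# Plain-text readers/writers for the pipeline's artifact formats:
# expression TSV (first column gene_id, header = sample IDs), annotation
# TSV, survival TSV, GMT, target-edge TSVs, ground-truth JSON.

#' Read / write an expression matrix TSV
#'
#' Layout: first column holds the feature IDs (header \code{gene_id}),
#' remaining columns one sample each, log2 values. Duplicate feature IDs
#' are collapsed to the row with the highest mean (probe collapsing is a
#' loader concern, keeping the statistics modules ID-unique). Missing
#' entries are rejected.
#'
#' @param path file path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  .assert(ncol(df) >= 2, "expression TSV needs an ID column plus samples")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  .assert(all(is.finite(m)), "expression TSV contains non-finite values")
  if (anyDuplicated(ids)) {
    keep <- tapply(seq_along(ids), ids, function(i)
      i[which.max(rowMeans(m[i, , drop = FALSE]))])
    keep <- sort(unlist(keep))
    m <- m[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  rownames(m) <- ids
  m
}

#' @rdname read_expression_tsv
#' @param m matrix to write.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample annotation and survival tables
#'
#' Annotation columns: \code{sample_id}, \code{patient_id} (empty for
#' unpaired normals), \code{tissue} in \{normal, peri, cancer\}. Survival
#' columns: \code{patient_id}, \code{time_months} (> 0), \code{event}
#' (0 censored / 1 death).
#'
#' @param path file path.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  .assert(all(c("sample_id", "patient_id", "tissue") %in% names(df)),
          "annotation TSV must have sample_id, patient_id, tissue")
  .assert(all(df$tissue %in% c("normal", "peri", "cancer")),
          "tissue must be one of normal, peri, cancer")
  df
}

#' @rdname read_annotation_tsv
#' @param df table to write.
#' @export
write_annotation_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname read_annotation_tsv
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("patient_id", "time_months", "event") %in% names(df)),
          "survival TSV must have patient_id, time_months, event")
  .assert(all(df$time_months > 0), "survival times must be positive")
  .assert(all(df$event %in% c(0, 1)), "event must be 0 or 1")
  df
}

#' @rdname read_annotation_tsv
#' @export
write_survival_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene-set collections in GMT format
#'
#' One set per line: name TAB description TAB member TAB member ... Reading
#' delegates to \code{fgsea::gmtPathways}.
#'
#' @param path file path.
#' @return named list of member-ID vectors, class
#'   \code{"gene_set_collection"}.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  .assert(!anyDuplicated(names(sets)), "duplicate set names in GMT")
  .assert(all(lengths(sets) > 0), "GMT contains an empty set")
  class(sets) <- "gene_set_collection"
  sets
}

#' @rdname read_gmt
#' @param sets named list of member vectors.
#' @param descriptions optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "categories")
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  }
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[[i]], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a miRNA-target edge table (mirna_id TAB gene_id)
#' @param path file path.
#' @export
read_target_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("mirna_id", "gene_id") %in% names(df)),
          "target TSV must have mirna_id and gene_id columns")
  df[!duplicated(df[c("mirna_id", "gene_id")]), ]
}

#' @rdname read_target_tsv
#' @param df edge table to write.
#' @export
write_target_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complete simulated study to a directory
#'
#' Emits every plain-text artifact of a \code{"grad_cohort"}: expression and
#' miRNA TSVs, annotation, survival, GMT, six target-database TSVs and the
#' ground-truth JSON.
#'
#' @param study a \code{"grad_cohort"}.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "grad_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(study$mrna, file.path(dir, "expression.tsv"))
  write_expression_tsv(study$mirna, file.path(dir, "mirna_expression.tsv"))
  write_annotation_tsv(study$annotation, file.path(dir, "annotation.tsv"))
  write_survival_tsv(study$survival, file.path(dir, "survival.tsv"))
  write_gmt(study$gene_sets, file.path(dir, "gene_sets.gmt"))
  for (nm in names(study$target_dbs))
    write_target_tsv(study$target_dbs[[nm]],
                     file.path(dir, paste0("targets_", nm, ".tsv")))
  truth <- study$truth
  truth$mu_gene <- NULL; truth$mu_mirna <- NULL  # bulky internals
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
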