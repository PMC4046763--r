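# Consensus miRNA-target mapping and miRNA substitution of gene sets.

# Matching keys: miRNA IDs are case-insensitive with the species prefix
# (e.g. "hsa-") stripped; gene symbols are upper-cased. Originals are
# preserved for output.
.mirna_key <- function(x) tolower(sub("^[a-z]{3}-", "", tolower(x)))
.gene_key <- function(x) toupper(x)

#' Build the consensus miRNA-target map by database voting
#'
#' An edge (miRNA, gene) is kept only when it appears in at least
#' \code{min_votes} distinct databases of those supplied, emulating a
#' "present in at least 3 of 6 target databases" consensus across
#' partially redundant target-prediction resources. Identifiers are
#' normalized for matching only (case-insensitive miRNA IDs without
#' species prefix, upper-case gene symbols); the first-seen original
#' spelling is reported.
#'
#' @param tables list of 1-6 edge tables (data.frames with
#'   \code{mirna_id}, \code{gene_id}); duplicate edges within one table
#'   count once.
#' @param min_votes minimum number of supporting databases (default 3).
#' @return data.frame of class \code{"consensus_map"}: \code{mirna_id},
#'   \code{gene_id}, \code{votes} (>= \code{min_votes}).
#' @export
build_consensus_map <- function(tables, min_votes = 3) {
  .assert(is.list(tables) && length(tables) >= 1 && length(tables) <= 6,
          "tables must be a list of 1-6 edge tables")
  .assert(.is_count(min_votes, 1) && min_votes <= length(tables),
          "min_votes must be a positive integer <= number of tables")
  per_db <- lapply(tables, function(tb) {
    .assert(all(c("mirna_id", "gene_id") %in% names(tb)),
            "edge tables need mirna_id and gene_id columns")
    key <- paste(.mirna_key(tb$mirna_id), .gene_key(tb$gene_id), sep = "\r")
    dup <- duplicated(key)
    data.frame(key = key[!dup], mirna_id = tb$mirna_id[!dup],
               gene_id = tb$gene_id[!dup], stringsAsFactors = FALSE)
  })
  all_edges <- do.call(rbind, per_db)
  if (is.null(all_edges) || nrow(all_edges) == 0) {
    out <- data.frame(mirna_id = character(0), gene_id = character(0),
                      votes = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("consensus_map", "data.frame")
    return(out)
  }
  votes <- table(all_edges$key)
  keep_keys <- names(votes)[votes >= min_votes]
  first <- all_edges[!duplicated(all_edges$key), ]
  kept <- first[first$key %in% keep_keys, ]
  out <- data.frame(mirna_id = kept$mirna_id, gene_id = kept$gene_id,
                    votes = as.integer(votes[kept$key]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("consensus_map", "data.frame")
  out
}

#' Substitute miRNAs for the gene members of a set
#'
#' Returns the union of miRNAs that target any of the supplied genes
#' under the consensus map. Matching uses the same identifier
#' normalization as \code{\link{build_consensus_map}}. An empty result is
#' allowed (flagged by attribute \code{empty}).
#'
#' @param gene_set_degs gene IDs (typically the DEG members of an
#'   enriched set).
#' @param map a \code{"consensus_map"}.
#' @return sorted character vector of miRNA IDs, attribute \code{empty}.
#' @export
substitute_mirnas <- function(gene_set_degs, map) {
  stopifnot(inherits(map, "consensus_map"))
  hits <- .gene_key(map$gene_id) %in% .gene_key(gene_set_degs)
  out <- sort(unique(map$mirna_id[hits]))
  attr(out, "empty") <- length(out) == 0
  out
}

#' Genes targeted by a miRNA under the consensus map
#' @param mirna_id one miRNA ID.
#' @param map a \code{"consensus_map"}.
#' @return sorted gene IDs.
#' @export
targets_of <- function(mirna_id, map) {
  stopifnot(inherits(map, "consensus_map"))
  sort(unique(map$gene_id[.mirna_key(map$mirna_id) == .mirna_key(mirna_id)]))
}
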