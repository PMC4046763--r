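#' Hypergeometric over-representation test
#'
#' Upper-tail (inclusive) hypergeometric probability of observing at least
#' \code{k} members of \code{gene_set} among the \code{deg_group} draws
#' from the measured universe. The gene set is intersected with the
#' universe before testing, so genes never measured cannot inflate the
#' overlap.
#'
#' @param deg_group gene-ID set of interest (must lie in the universe).
#' @param gene_set gene-ID set to test.
#' @param universe all measured gene IDs.
#' @return list with \code{k} (overlap count) and \code{hyper_p}
#'   (\code{P(X >= k)}).
#' @examples
#' hypergeometric_enrichment(letters[1:4], letters[1:5], letters[1:10])
#' @export
hypergeometric_enrichment <- function(deg_group, gene_set, universe) {
  universe <- unique(universe)
  .assert(length(universe) > 0, "empty universe")
  deg_group <- unique(deg_group)
  .assert(all(deg_group %in% universe),
          "deg_group must be a subset of the universe")
  set_u <- intersect(unique(gene_set), universe)
  k <- length(intersect(deg_group, set_u))
  N <- length(universe); K <- length(set_u); n <- length(deg_group)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, hyper_p = p)
}

#' Rank genes for GSEA
#'
#' Stable ordering by metric descending, gene ID ascending on ties, so
#' permutation results are reproducible.
#'
#' @param metric named numeric vector (e.g. moderated t per gene).
#' @return character vector of gene IDs in rank order.
#' @export
rank_genes <- function(metric) {
  .assert(is.numeric(metric) && all(is.finite(metric)) &&
            !is.null(names(metric)), "metric must be a finite named vector")
  names(metric)[order(-metric, names(metric), method = "radix")]
}

# Running-sum enrichment score over the full list (transparent reference
# form): P_hit uses |r|^p weights normalized by their in-set sum, P_miss
# counts non-members; ES is the signed maximum deviation of the
# difference.
.es_dense <- function(hit, absw_pow) {
  n_h <- sum(hit); n <- length(hit)
  n_r <- sum(absw_pow[hit])
  p_hit <- cumsum(ifelse(hit, absw_pow, 0)) /
    (if (n_r > 0) n_r else 1)
  p_miss <- cumsum(!hit) / (n - n_h)
  dev <- p_hit - p_miss
  unname(dev[which.max(abs(dev))])
}

# Same statistic evaluated only at hit positions and the indices just
# before them, O(set size) per evaluation; used for the permutation null.
.es_sparse <- function(pos, absw_pow, n) {
  pos <- sort(pos)
  h <- length(pos)
  w <- absw_pow[pos]
  n_r <- sum(w)
  cw <- cumsum(w) / (if (n_r > 0) n_r else 1)
  miss_at <- (pos - seq_len(h)) / (n - h)
  dev_at <- cw - miss_at                     # just after each hit
  dev_before <- c(0, cw[-h]) - (pos - 1 - (seq_len(h) - 1)) / (n - h)
  cand <- c(dev_at, dev_before)
  unname(cand[which.max(abs(cand))])
}

#' Weighted running-sum enrichment score
#'
#' The rank-based (Kolmogorov-Smirnov-like) GSEA statistic: walking down
#' the ranked list, the running sum gains \code{|r_i|^p / N_R} at set
#' members and loses \code{1 / (N - N_H)} at non-members; the enrichment
#' score is the signed maximum deviation. With \code{weight_exponent = 0}
#' it reduces to the classical two-sample KS statistic between member and
#' non-member rank positions.
#'
#' @param ranked_ids gene IDs in rank order (see \code{\link{rank_genes}}).
#' @param metric named numeric metric (matched to \code{ranked_ids}).
#' @param gene_set member gene IDs; must intersect the list but not cover
#'   it entirely.
#' @param weight_exponent exponent \code{p} on \code{|r|} (default 1).
#' @return the enrichment score in [-1, 1].
#' @export
gsea_score <- function(ranked_ids, metric, gene_set, weight_exponent = 1) {
  .assert(!anyDuplicated(ranked_ids), "duplicate IDs in ranked list")
  .assert(all(ranked_ids %in% names(metric)),
          "metric must cover every ranked gene")
  r <- metric[ranked_ids]
  .assert(all(is.finite(r)), "metric must be finite")
  hit <- ranked_ids %in% gene_set
  n_h <- sum(hit)
  .assert(n_h >= 1, "gene set does not intersect the ranked list")
  .assert(n_h < length(ranked_ids),
          "gene set covers the whole ranked list")
  .es_dense(hit, abs(r)^weight_exponent)
}

#' Gene-label permutation test for GSEA
#'
#' Computes the enrichment score of every set in a collection against a
#' ranked list, with a permutation null built by drawing random gene-label
#' sets of the same size (null ES shared across sets of equal size). The
#' permutation p-value uses add-one two-sided extremeness,
#' \code{(1 + #\{|null ES| >= |es|\}) / (1 + n_perm)}, so it is never
#' zero and is uniform for null sets. The normalized score divides the
#' observed ES by the mean magnitude of same-sign null scores.
#'
#' @param metric named numeric ranking metric over the full universe (all
#'   measured genes, not only DEGs); must not be constant.
#' @param collection named list of gene-ID sets.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @param weight_exponent passed to \code{\link{gsea_score}}.
#' @return data.frame: \code{set}, \code{size} (members in the universe),
#'   \code{es}, \code{nes}, \code{gsea_p}. Sets with no member in the
#'   universe get NA statistics.
#' @export
gsea_permutation_test <- function(metric, collection, n_perm = 1000,
                                  seed = 1, weight_exponent = 1) {
  .assert(.is_count(n_perm, 100), "n_perm must be an integer >= 100")
  .assert(is.numeric(metric) && all(is.finite(metric)) &&
            !is.null(names(metric)), "metric must be a finite named vector")
  .assert(stats::sd(metric) > 0, "degenerate metric: all values equal")
  ranked <- rank_genes(metric)
  n <- length(ranked)
  absw <- abs(metric[ranked])^weight_exponent

  sizes <- vapply(collection, function(s)
    length(intersect(s, ranked)), integer(1))
  .assert(all(sizes < n), "a gene set covers the whole universe")

  es_obs <- rep(NA_real_, length(collection))
  for (i in seq_along(collection)) {
    if (sizes[i] >= 1)
      es_obs[i] <- gsea_score(ranked, metric, collection[[i]],
                              weight_exponent)
  }

  null_by_size <- .with_stream(seed, function() {
    lapply(stats::setNames(nm = sort(unique(sizes[sizes >= 1]))),
           function(h) {
             h <- as.integer(h)
             vapply(seq_len(n_perm), function(j)
               .es_sparse(sample.int(n, h), absw, n), numeric(1))
           })
  })

  nes <- rep(NA_real_, length(collection))
  gsea_p <- rep(NA_real_, length(collection))
  for (i in seq_along(collection)) {
    if (sizes[i] < 1) next
    null_es <- null_by_size[[as.character(sizes[i])]]
    gsea_p[i] <- (1 + sum(abs(null_es) >= abs(es_obs[i]))) / (1 + n_perm)
    same_sign <- null_es[sign(null_es) == sign(es_obs[i])]
    nes[i] <- if (length(same_sign) > 0)
      es_obs[i] / mean(abs(same_sign)) else NA_real_
  }
  data.frame(set = names(collection), size = sizes, es = es_obs,
             nes = nes, gsea_p = gsea_p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dual-criterion enrichment verdict
#'
#' Adjusts the hypergeometric and GSEA p-values by Benjamini-Hochberg
#' separately within each (DEG group, criterion) family, then flags a set
#' as enriched only when both adjusted p-values are strictly below
#' \code{alpha}.
#'
#' @param records data.frame with columns \code{set}, \code{deg_group},
#'   \code{hyper_p}, \code{gsea_p} (NA GSEA p-values never pass).
#' @param alpha significance cutoff (default 0.05).
#' @return the records with added \code{hyper_adj_p}, \code{gsea_adj_p}
#'   and logical \code{enriched}.
#' @export
dual_criterion <- function(records, alpha = 0.05) {
  .assert(all(c("set", "deg_group", "hyper_p", "gsea_p") %in%
                names(records)),
          "records need set, deg_group, hyper_p, gsea_p")
  records$hyper_adj_p <- stats::ave(records$hyper_p, records$deg_group,
                                    FUN = benjamini_hochberg)
  adj_na <- function(p) {
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    if (any(ok)) out[ok] <- benjamini_hochberg(p[ok])
    out
  }
  records$gsea_adj_p <- stats::ave(records$gsea_p, records$deg_group,
                                   FUN = adj_na)
  records$enriched <- !is.na(records$hyper_adj_p) &
    !is.na(records$gsea_adj_p) &
    records$hyper_adj_p < alpha & records$gsea_adj_p < alpha
  records
}

#' Dual-criterion enrichment over the nine DEG groups
#'
#' Drives the enrichment stage: for each comparison (C/N, C/P, P/N) and
#' each of its DEG groups (all/up/down) every set in the collection gets a
#' hypergeometric over-representation p-value; GSEA runs once per
#' comparison on the full moderated-t ranking (the t-statistic blends
#' effect size and precision) and its per-set p-value is shared by the
#' comparison's three groups. Verdicts come from
#' \code{\link{dual_criterion}}.
#'
#' @param comparisons named list of \code{\link{moderated_t}} results
#'   (\code{"C/N"}, \code{"C/P"}, \code{"P/N"}).
#' @param partition a \code{\link{venn_partition}} result.
#' @param collection gene-set collection (named list).
#' @param n_perm,seed,alpha see \code{\link{gsea_permutation_test}} and
#'   \code{\link{dual_criterion}}.
#' @return data.frame of enrichment records: \code{set},
#'   \code{deg_group}, \code{k}, \code{hyper_p}, \code{es}, \code{nes},
#'   \code{gsea_p}, \code{hyper_adj_p}, \code{gsea_adj_p},
#'   \code{enriched}.
#' @export
enrich_deg_groups <- function(comparisons, partition, collection,
                              n_perm = 1000, seed = 1, alpha = 0.05) {
  cmp_names <- c("C/N", "C/P", "P/N")
  .assert(all(cmp_names %in% names(comparisons)),
          "comparisons must name C/N, C/P and P/N")
  records <- list()
  for (cmp in cmp_names) {
    res <- comparisons[[cmp]]
    universe <- res$gene_id
    metric <- stats::setNames(res$t, res$gene_id)
    gsea <- gsea_permutation_test(metric, collection, n_perm = n_perm,
                                  seed = .stream_seed(seed, "gsea") +
                                    match(cmp, cmp_names))
    for (grp in c("all", "up", "down")) {
      degs <- partition$per_comparison[[cmp]][[grp]]
      group_label <- paste0(gsub("/", "/", cmp), "_", grp)
      hyper <- lapply(collection, function(s)
        hypergeometric_enrichment(degs, s, universe))
      records[[group_label]] <- data.frame(
        set = names(collection),
        deg_group = group_label,
        k = vapply(hyper, `[[`, integer(1), "k"),
        hyper_p = vapply(hyper, `[[`, numeric(1), "hyper_p"),
        es = gsea$es, nes = gsea$nes, gsea_p = gsea$gsea_p,
        row.names = NULL, stringsAsFactors = FALSE
      )
    }
  }
  dual_criterion(do.call(rbind, records), alpha = alpha)
}
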