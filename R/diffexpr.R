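#' Empirical-Bayes moderated t-test between two sample groups
#'
#' Two-group differential expression with variance moderation. Per gene the
#' pooled two-sample variance \code{s_g^2} (with \code{d_g = n_a + n_b - 2}
#' degrees of freedom) is shrunk towards a prior \code{(d0, s0^2)}
#' estimated by moment-matching the log sample variances: with
#' \code{z = log(s_g^2)}, \code{var(z) - trigamma(d_g/2) = trigamma(d0/2)}
#' (solved by bisection to 1e-8) and the prior scale follows from
#' \code{mean(z)} via digamma terms. The posterior variance is
#' \code{(d0*s0^2 + d_g*s_g^2) / (d0 + d_g)} and the moderated statistic
#' \code{t = (mean_a - mean_b) / (s_tilde * sqrt(1/n_a + 1/n_b))} is
#' referred to a t-distribution with \code{d0 + d_g} degrees of freedom
#' (normal when the prior df is infinite). P-values are two-sided;
#' adjusted p-values use Benjamini-Hochberg.
#'
#' If the spread of log variances is at or below the theoretical minimum
#' \code{trigamma(d_g/2)}, the prior df is infinite (full shrinkage to
#' \code{s0^2}). Genes with zero sample variance are excluded from the
#' prior fit but still moderated through the posterior formula.
#'
#' @param expr genes x samples log2 matrix with unique dimnames.
#' @param group_a,group_b disjoint sample-ID vectors, each of size >= 2.
#'   \code{group_a} is the numerator class: \code{log2fc = mean(a) - mean(b)}.
#' @param comparison label stored on the result (e.g. \code{"C/N"}).
#' @param prior_df optional override of the estimated prior df; \code{0}
#'   gives the ordinary pooled-variance Student t, \code{Inf} full
#'   shrinkage.
#' @return data.frame (one row per gene): \code{gene_id}, \code{log2fc},
#'   \code{t}, \code{raw_p}, \code{adj_p}, \code{df_total},
#'   \code{posterior_sd}; attributes \code{comparison}, \code{prior_df},
#'   \code{prior_var}.
#' @examples
#' m <- matrix(rnorm(400), 20, 20,
#'             dimnames = list(paste0("g", 1:20), paste0("s", 1:20)))
#' res <- moderated_t(m, paste0("s", 1:10), paste0("s", 11:20))
#' head(res)
#' @export
moderated_t <- function(expr, group_a, group_b, comparison = "A/B",
                        prior_df = NULL) {
  .assert(is.matrix(expr) && is.numeric(expr) && all(is.finite(expr)),
          "expr must be a finite numeric matrix")
  .assert(!anyDuplicated(rownames(expr)) && !anyDuplicated(colnames(expr)),
          "expr dimnames must be unique")
  .assert(length(intersect(group_a, group_b)) == 0,
          "groups must be disjoint")
  .assert(length(group_a) >= 2 && length(group_b) >= 2,
          "each group needs at least 2 samples")
  missing <- setdiff(c(group_a, group_b), colnames(expr))
  .assert(length(missing) == 0,
          paste("unknown sample(s):", paste(missing, collapse = ", ")))

  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  d_g <- na + nb - 2
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  ss_a <- rowSums((a - mean_a)^2)
  ss_b <- rowSums((b - mean_b)^2)
  s2 <- (ss_a + ss_b) / d_g

  if (is.null(prior_df)) {
    prior <- .fit_var_prior(s2, d_g)
  } else {
    .assert(length(prior_df) == 1 && prior_df >= 0, "prior_df must be >= 0")
    prior <- list(
      d0 = prior_df,
      s02 = if (prior_df > 0) .fit_var_prior(s2, d_g)$s02 else NA_real_
    )
  }
  d0 <- prior$d0; s02 <- prior$s02

  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else if (d0 == 0) s2
             else (d0 * s02 + d_g * s2) / (d0 + d_g)
  se <- sqrt(s2_post) * sqrt(1 / na + 1 / nb)
  lfc <- mean_a - mean_b
  tstat <- lfc / se
  df_total <- d0 + d_g
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(
    gene_id = rownames(expr),
    log2fc = unname(lfc),
    t = unname(tstat),
    raw_p = unname(p),
    adj_p = benjamini_hochberg(unname(p)),
    df_total = df_total,
    posterior_sd = unname(sqrt(s2_post)),
    stringsAsFactors = FALSE
  )
  attr(out, "comparison") <- comparison
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  out
}

# Moment-matching fit of the scaled-inverse-chi-square variance prior.
# E[log s^2] = log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2)
# Var[log s^2] = trigamma(d/2) + trigamma(d0/2)
.fit_var_prior <- function(s2, d_g) {
  pos <- s2 > 0
  .assert(any(pos), "all genes have zero residual variance; cannot fit prior")
  z <- log(s2[pos])
  evar <- stats::var(z) - trigamma(d_g / 2)
  if (!is.finite(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(z) - digamma(d_g / 2) + log(d_g / 2))
  } else {
    d0 <- 2 * .trigamma_inverse(evar)
    s02 <- exp(mean(z) - digamma(d_g / 2) + log(d_g / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

# Solve trigamma(y) = x by bisection (trigamma is strictly decreasing).
.trigamma_inverse <- function(x, tol = 1e-8) {
  .assert(is.finite(x) && x > 0, "trigamma inverse needs x > 0")
  lo <- 1e-8; hi <- 1
  while (trigamma(hi) > x) hi <- hi * 2       # expand until bracketing
  while (trigamma(lo) < x) lo <- lo / 2
  while (hi - lo > tol * max(1, lo)) {
    mid <- (lo + hi) / 2
    if (trigamma(mid) > x) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies the BH step-up procedure (via
#' \code{stats::p.adjust}): monotone in rank order, capped at 1, input
#' order preserved.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  .assert(is.numeric(p_values) && all(is.finite(p_values)) &&
            all(p_values >= 0 & p_values <= 1),
          "p-values must lie in [0,1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Select up- and down-regulated DEGs at fixed thresholds
#'
#' A gene is an up-regulated DEG when \code{log2fc > lfc_threshold} and
#' \code{adj_p < alpha} (both strict); down-regulated when
#' \code{log2fc < -lfc_threshold} and \code{adj_p < alpha}. The defaults
#' (|log2 fold change| > 2, BH-adjusted p < 0.001) are the pipeline's
#' working definition of a DEG.
#'
#' @param result a \code{\link{moderated_t}} result.
#' @param lfc_threshold,alpha selection thresholds.
#' @return list with \code{up}, \code{down} and \code{all} (their union)
#'   gene-ID character vectors.
#' @export
select_degs <- function(result, lfc_threshold = 2, alpha = 0.001) {
  up <- result$gene_id[result$log2fc > lfc_threshold & result$adj_p < alpha]
  down <- result$gene_id[result$log2fc < -lfc_threshold & result$adj_p < alpha]
  list(up = up, down = down, all = union(up, down))
}

#' Run the three tissue comparisons of the gradual design
#'
#' Cancer/Normal (C/N), Cancer/Pericancerous (C/P) and
#' Pericancerous/Normal (P/N), each as an unpaired moderated t-test with
#' the first-named class as numerator.
#'
#' @param expr genes x samples matrix.
#' @param annotation sample annotation (\code{sample_id}, \code{tissue}).
#' @return named list of three comparison results
#'   (\code{"C/N"}, \code{"C/P"}, \code{"P/N"}).
#' @export
run_comparisons <- function(expr, annotation) {
  by_tissue <- split(annotation$sample_id, annotation$tissue)
  .assert(all(c("normal", "peri", "cancer") %in% names(by_tissue)),
          "annotation must contain normal, peri and cancer samples")
  list(
    "C/N" = moderated_t(expr, by_tissue$cancer, by_tissue$normal, "C/N"),
    "C/P" = moderated_t(expr, by_tissue$cancer, by_tissue$peri, "C/P"),
    "P/N" = moderated_t(expr, by_tissue$peri, by_tissue$normal, "P/N")
  )
}

# 7-cell decomposition of three sets; cells keyed by the comparisons a
# member belongs to, e.g. "C/N", "C/N&C/P", "C/N&C/P&P/N".
.venn3 <- function(sets) {
  nms <- names(sets)
  all_ids <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1) member <- matrix(member, nrow = 1,
                                             dimnames = list(NULL, nms))
  key <- apply(member, 1, function(r) paste(nms[r], collapse = "&"))
  cells <- split(all_ids, key)
  combos <- unlist(lapply(1:3, function(k)
    utils::combn(nms, k, paste, collapse = "&", simplify = FALSE)))
  out <- stats::setNames(vector("list", length(combos)), combos)
  for (cmb in combos) out[[cmb]] <- character(0)
  for (k in names(cells)) out[[k]] <- sort(cells[[k]])
  out
}

#' Three-way Venn partition of the DEG lists
#'
#' Builds the three 7-cell Venn decompositions over the comparisons
#' C/N, C/P and P/N: one diagram for all DEGs (up or down), one for the
#' up-regulated lists and one for the down-regulated lists. Because a gene
#' can be up-regulated in one comparison but down-regulated in another
#' (a sign switch across the gradual design), the up-diagram total plus
#' the down-diagram total can exceed the all-diagram total.
#'
#' @param deg_sets named list of the three comparisons (\code{"C/N"},
#'   \code{"C/P"}, \code{"P/N"}), each a list with \code{up} and
#'   \code{down} character vectors (as from \code{\link{select_degs}}).
#' @return list of class \code{"deg_partition"}: \code{per_comparison}
#'   (up/down/all per comparison), \code{venn} (cells for the
#'   \code{all}, \code{up}, \code{down} diagrams), \code{totals}
#'   (distinct genes per diagram).
#' @export
venn_partition <- function(deg_sets) {
  cmp <- c("C/N", "C/P", "P/N")
  .assert(all(cmp %in% names(deg_sets)),
          "deg_sets must name comparisons C/N, C/P and P/N")
  per <- lapply(deg_sets[cmp], function(d) {
    .assert(length(intersect(d$up, d$down)) == 0,
            "up and down overlap within one comparison")
    list(up = d$up, down = d$down, all = union(d$up, d$down))
  })
  venn <- list(
    all = .venn3(lapply(per, `[[`, "all")),
    up = .venn3(lapply(per, `[[`, "up")),
    down = .venn3(lapply(per, `[[`, "down"))
  )
  totals <- vapply(venn, function(v)
    length(unique(unlist(v, use.names = FALSE))), integer(1))
  out <- list(per_comparison = per, venn = venn, totals = totals)
  class(out) <- "deg_partition"
  out
}
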