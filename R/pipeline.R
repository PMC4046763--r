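#' Pipeline configuration
#'
#' Thresholds and file layout for an end-to-end run: DEG selection at
#' |log2 fold change| > \code{lfc} and BH-adjusted p < \code{de_alpha};
#' dual-criterion enrichment at \code{enrich_alpha}; consensus target
#' voting at \code{min_votes} of six databases; \code{n_perm} GSEA
#' permutations.
#'
#' @param out_dir directory for all artifacts.
#' @param synthetic a \code{\link{synthetic_config}} describing the
#'   simulated study.
#' @param lfc,de_alpha DEG thresholds.
#' @param enrich_alpha dual-criterion cutoff.
#' @param min_votes consensus vote threshold.
#' @param n_perm GSEA permutations.
#' @param seed master seed; overrides the synthetic config's seed.
#' @param validate whether to simulate and test a validation cohort.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(out_dir = tempfile("gradprog_run_"),
                            synthetic = synthetic_config(),
                            lfc = 2, de_alpha = 0.001,
                            enrich_alpha = 0.05, min_votes = 3,
                            n_perm = 1000, seed = 1, validate = TRUE) {
  .assert(lfc > 0 && de_alpha > 0 && enrich_alpha > 0,
          "thresholds must be positive")
  .assert(.is_count(min_votes, 1) && min_votes <= 6,
          "min_votes must be in 1..6")
  .assert(.is_count(n_perm, 100), "n_perm must be an integer >= 100")
  synthetic$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, synthetic = synthetic, lfc = lfc,
                 de_alpha = de_alpha, enrich_alpha = enrich_alpha,
                 min_votes = min_votes, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), validate = isTRUE(validate)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.mode_for_group <- function(deg_group) {
  cmp <- sub("_(all|up|down)$", "", deg_group)
  c("C/N" = "C", "C/P" = "C/P", "P/N" = "P/N")[[cmp]]
}

#' Run the full discovery pipeline on a simulated study
#'
#' Orchestrates simulate, differential expression, DEG selection and Venn
#' partition, dual-criterion enrichment, consensus target mapping, miRNA
#' substitution, and survival testing of every candidate classifier, with
#' optional validation on an independent simulated cohort (a classifier
#' validates when its Wald p < 0.05 with the discovery coefficient sign).
#' All intermediates are written as plain-text TSV/GMT/JSON under
#' \code{config$out_dir}, plus a \code{manifest.json} with per-stage
#' counts. Deterministic given the seed.
#'
#' Candidate gene classifiers are the DEG members (of the record's DEG
#' group) of each enriched set, scored with the profile matching the
#' comparison: absolute cancer expression for C/N groups, the paired
#' cancer/pericancerous ratio for C/P groups, the pericancerous/normal
#' ratio for P/N groups. Each gene classifier's miRNA counterpart is the
#' consensus-map substitution of its features, scored on absolute cancer
#' miRNA expression.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list of class \code{"gradprog_run"}: \code{manifest},
#'   \code{study}, \code{comparisons}, \code{partition},
#'   \code{enrichment}, \code{consensus}, \code{associations}
#'   (data.frame over classifiers and cohorts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  study <- .stage("simulate", simulate_study(config$synthetic))
  .stage("simulate", write_study(study, file.path(config$out_dir,
                                                  "discovery")))
  validation <- NULL
  if (config$validate) {
    validation <- .stage("simulate", simulate_validation(study))
    .stage("simulate", write_study(validation,
                                   file.path(config$out_dir, "validation")))
  }

  comparisons <- .stage("diffexpr",
                        run_comparisons(study$mrna, study$annotation))
  for (cmp in names(comparisons)) {
    f <- file.path(config$out_dir,
                   paste0("diffexpr_", gsub("/", "_", cmp), ".tsv"))
    utils::write.table(comparisons[[cmp]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  degs <- lapply(comparisons, select_degs,
                 lfc_threshold = config$lfc, alpha = config$de_alpha)
  partition <- .stage("diffexpr", venn_partition(degs))

  enr <- .stage("enrich",
                enrich_deg_groups(comparisons, partition, study$gene_sets,
                                  n_perm = config$n_perm,
                                  seed = config$seed,
                                  alpha = config$enrich_alpha))
  utils::write.table(enr, file.path(config$out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  consensus <- .stage("consensus",
                      build_consensus_map(study$target_dbs,
                                          min_votes = config$min_votes))
  write_target_tsv(consensus, file.path(config$out_dir, "consensus_map.tsv"))

  # Candidate classifiers from enriched records.
  hits <- enr[enr$enriched, , drop = FALSE]
  classifiers <- list()
  for (i in seq_len(nrow(hits))) {
    set_name <- hits$set[i]; grp <- hits$deg_group[i]
    cmp <- sub("_(all|up|down)$", "", grp)
    dir <- sub("^.*_", "", grp)
    feats <- intersect(study$gene_sets[[set_name]],
                       partition$per_comparison[[cmp]][[dir]])
    if (length(feats) == 0) next
    id <- paste0(set_name, "|", grp)
    classifiers[[id]] <- classifier(id, feats, kind = "gene",
                                    mode = .mode_for_group(grp))
    mirs <- substitute_mirnas(feats, consensus)
    if (length(mirs) > 0)
      classifiers[[paste0(id, "|miRNA")]] <-
        classifier(paste0(id, "|miRNA"), mirs, kind = "miRNA", mode = "C")
  }

  assoc <- .stage("survtest",
                  .evaluate_all(classifiers, study, validation))
  utils::write.table(assoc, file.path(config$out_dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  planted <- study$truth$prognostic_sets
  validated_sets <- sub("\\|.*$", "",
                        assoc$classifier[assoc$validated %in% TRUE])
  manifest <- list(
    seed = config$seed,
    n_genes = config$synthetic$n_genes,
    n_patients = config$synthetic$n_pairs,
    degs_per_comparison = lapply(partition$per_comparison,
                                 function(p) length(p$all)),
    venn_totals = as.list(partition$totals),
    enriched_per_group = as.list(
      tapply(enr$enriched, enr$deg_group, sum)),
    n_classifiers_tested = length(classifiers),
    n_pass_discovery = sum(assoc$pass_discovery, na.rm = TRUE),
    n_validated = sum(assoc$validated, na.rm = TRUE),
    planted_sets = planted,
    planted_validated = intersect(planted, unique(validated_sets))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out <- list(manifest = manifest, study = study, validation = validation,
              comparisons = comparisons, partition = partition,
              enrichment = enr, consensus = consensus,
              associations = assoc, classifiers = classifiers)
  class(out) <- "gradprog_run"
  out
}

# Evaluate every classifier on discovery (and, for those passing
# Wald p < 0.05, on validation). Per-classifier failures are recorded,
# not fatal.
.evaluate_all <- function(classifiers, study, validation) {
  rows <- lapply(names(classifiers), function(id) {
    clf <- classifiers[[id]]
    disc <- tryCatch(suppressMessages(evaluate_classifier(clf, study)),
                     error = function(e) e)
    if (inherits(disc, "error")) {
      return(data.frame(classifier = id, kind = clf$kind, mode = clf$mode,
                        n_features = length(clf$features),
                        beta = NA_real_, se_beta = NA_real_,
                        wald_p = NA_real_, logrank_p = NA_real_,
                        pass_discovery = FALSE, val_beta = NA_real_,
                        val_wald_p = NA_real_, validated = NA,
                        error = conditionMessage(disc),
                        stringsAsFactors = FALSE))
    }
    pass <- disc$wald_p < 0.05
    val_beta <- NA_real_; val_p <- NA_real_; validated <- NA
    if (pass && !is.null(validation)) {
      val <- tryCatch(suppressMessages(evaluate_classifier(clf, validation)),
                      error = function(e) NULL)
      if (!is.null(val)) {
        val_beta <- val$beta; val_p <- val$wald_p
        validated <- val$wald_p < 0.05 && sign(val$beta) == sign(disc$beta)
      } else validated <- FALSE
    }
    data.frame(classifier = id, kind = clf$kind, mode = clf$mode,
               n_features = disc$n_features_used,
               beta = disc$beta, se_beta = disc$se_beta,
               wald_p = disc$wald_p, logrank_p = disc$logrank_p,
               pass_discovery = pass, val_beta = val_beta,
               val_wald_p = val_p, validated = validated,
               error = NA_character_, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0)
    return(data.frame(classifier = character(0), kind = character(0),
                      mode = character(0), n_features = integer(0),
                      beta = numeric(0), se_beta = numeric(0),
                      wald_p = numeric(0), logrank_p = numeric(0),
                      pass_discovery = logical(0), val_beta = numeric(0),
                      val_wald_p = numeric(0), validated = logical(0),
                      error = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
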