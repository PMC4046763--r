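#' Construct a signature classifier
#'
#' A classifier is a named feature list (genes or miRNAs) plus the
#' expression profile used to score patients: \code{"C"} absolute
#' expression in the cancer sample; \code{"C/P"} paired cancer minus
#' pericancerous log2 ratio; \code{"P/N"} pericancerous minus the mean
#' over the normal reference samples; \code{"C/N"} cancer minus the
#' normal-reference mean.
#'
#' @param name classifier label (usually the source gene set).
#' @param features gene or miRNA IDs (>= 1).
#' @param kind \code{"gene"} or \code{"miRNA"}.
#' @param mode profile mode.
#' @return list of class \code{"classifier"}.
#' @export
classifier <- function(name, features, kind = c("gene", "miRNA"),
                       mode = c("C", "C/P", "P/N", "C/N")) {
  kind <- match.arg(kind); mode <- match.arg(mode)
  .assert(length(features) >= 1, "classifier needs at least one feature")
  structure(list(name = name, features = unique(features),
                 kind = kind, mode = mode),
            class = "classifier")
}

#' Per-patient profile matrix for a classifier mode
#'
#' The raw (pre-standardization) feature-by-patient values the signature
#' score is built from: cancer expression for mode C; paired cancer minus
#' pericancerous differences for C/P; pericancerous (or cancer) minus the
#' mean over normal reference samples for P/N (C/N). Patients lacking the
#' required samples are dropped with a warning.
#'
#' @param expr feature x sample matrix.
#' @param annotation sample annotation.
#' @param features feature IDs; those absent from \code{expr} are dropped
#'   and counted in attribute \code{n_missing}.
#' @param mode profile mode.
#' @return features x patients matrix with attribute \code{n_missing}.
#' @export
profile_matrix <- function(expr, annotation, features,
                           mode = c("C", "C/P", "P/N", "C/N")) {
  mode <- match.arg(mode)
  present <- intersect(features, rownames(expr))
  n_missing <- length(features) - length(present)
  .assert(length(present) > 0,
          "no classifier feature is measured in this cohort")
  ann <- annotation
  cancer <- ann[ann$tissue == "cancer", ]
  peri <- ann[ann$tissue == "peri", ]
  normal <- ann[ann$tissue == "normal", ]

  prof <- switch(mode,
    "C" = {
      .assert(nrow(cancer) > 0, "mode C requires cancer samples")
      m <- expr[present, cancer$sample_id, drop = FALSE]
      colnames(m) <- cancer$patient_id
      m
    },
    "C/P" = {
      .assert(nrow(cancer) > 0 && nrow(peri) > 0,
              "mode C/P requires paired cancer and pericancerous samples")
      paired <- intersect(cancer$patient_id, peri$patient_id)
      dropped <- setdiff(union(cancer$patient_id, peri$patient_id), paired)
      if (length(dropped) > 0)
        warning(length(dropped), " patient(s) dropped: missing pair for C/P")
      .assert(length(paired) > 0, "no complete cancer/pericancerous pairs")
      cs <- cancer$sample_id[match(paired, cancer$patient_id)]
      ps <- peri$sample_id[match(paired, peri$patient_id)]
      m <- expr[present, cs, drop = FALSE] - expr[present, ps, drop = FALSE]
      colnames(m) <- paired
      m
    },
    "P/N" = {
      .assert(nrow(peri) > 0 && nrow(normal) > 0,
              "mode P/N requires pericancerous and normal samples")
      ref <- rowMeans(expr[present, normal$sample_id, drop = FALSE])
      m <- expr[present, peri$sample_id, drop = FALSE] - ref
      colnames(m) <- peri$patient_id
      m
    },
    "C/N" = {
      .assert(nrow(cancer) > 0 && nrow(normal) > 0,
              "mode C/N requires cancer and normal samples")
      ref <- rowMeans(expr[present, normal$sample_id, drop = FALSE])
      m <- expr[present, cancer$sample_id, drop = FALSE] - ref
      colnames(m) <- cancer$patient_id
      m
    })
  attr(prof, "n_missing") <- n_missing
  prof
}

#' Per-patient signature risk score
#'
#' Mean of the per-feature z-scores of the classifier's profile matrix:
#' each feature is standardized across patients (zero-variance features
#' contribute 0), then averaged. Scale-free and direction-preserving, so
#' a positive Cox coefficient always reads "higher signature expression,
#' worse prognosis".
#'
#' @param clf a \code{\link{classifier}}.
#' @param mrna gene expression matrix.
#' @param annotation sample annotation.
#' @param mirna miRNA expression matrix (needed for miRNA classifiers).
#' @return named numeric score per patient; attributes
#'   \code{n_features_used}, \code{n_features_missing}.
#' @export
signature_score <- function(clf, mrna, annotation, mirna = NULL) {
  stopifnot(inherits(clf, "classifier"))
  expr <- if (clf$kind == "gene") mrna else {
    .assert(!is.null(mirna), "miRNA classifier needs a miRNA matrix")
    mirna
  }
  prof <- profile_matrix(expr, annotation, clf$features, clf$mode)
  z <- t(apply(prof, 1, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  if (nrow(prof) == 1) z <- matrix(z, nrow = 1,
                                   dimnames = dimnames(prof))
  score <- colMeans(z)
  names(score) <- colnames(prof)
  attr(score, "n_features_used") <- nrow(prof)
  attr(score, "n_features_missing") <- attr(prof, "n_missing")
  score
}

#' Univariate Cox proportional-hazards fit
#'
#' Maximizes the Efron-tie-corrected partial likelihood for a single
#' continuous covariate (Newton iterations via \code{survival::coxph},
#' convergence tolerance 1e-9) and reports the log hazard ratio with its
#' Wald test. Positive \code{beta} means a higher score carries a higher
#' hazard (worse prognosis).
#'
#' @param scores named numeric per-patient risk score.
#' @param survival_table data.frame with \code{patient_id},
#'   \code{time_months}, \code{event}; matched to \code{scores} by
#'   patient ID.
#' @return list: \code{beta}, \code{se_beta}, \code{wald_p}, \code{n},
#'   \code{n_events}.
#' @export
cox_fit_univariate <- function(scores, survival_table) {
  d <- .join_scores(scores, survival_table)
  .assert(sum(d$event) >= 2, "need at least 2 events for a Cox fit")
  .assert(stats::sd(d$score) > 0, "zero score variance")
  fit <- tryCatch(
    survival::coxph(survival::Surv(time_months, event) ~ score, data = d,
                    ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) stop("Cox fit did not converge cleanly: ",
                               conditionMessage(w), call. = FALSE)
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  .assert(is.finite(beta) && is.finite(se),
          "Cox fit failed to produce finite estimates")
  list(beta = beta, se_beta = se,
       wald_p = 2 * stats::pnorm(-abs(beta / se)),
       n = nrow(d), n_events = sum(d$event))
}

.join_scores <- function(scores, survival_table) {
  .assert(!is.null(names(scores)), "scores must be named by patient ID")
  .assert(all(c("patient_id", "time_months", "event") %in%
                names(survival_table)),
          "survival table needs patient_id, time_months, event")
  common <- intersect(names(scores), survival_table$patient_id)
  dropped <- length(scores) - length(common)
  if (dropped > 0)
    message(dropped, " patient(s) without survival data dropped")
  .assert(length(common) > 0, "no patients with both score and survival")
  idx <- match(common, survival_table$patient_id)
  data.frame(patient_id = common,
             score = unname(scores[common]),
             time_months = survival_table$time_months[idx],
             event = survival_table$event[idx],
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit estimate
#'
#' Survival step function for one group of patients: starts at 1, drops
#' at event times, censored subjects leave the risk set after their time.
#' Delegates to \code{survival::survfit}.
#'
#' @param survival_table data.frame with \code{time_months}, \code{event}.
#' @return data.frame: \code{time}, \code{n_risk}, \code{n_event},
#'   \code{surv} (rows at event/censoring times).
#' @export
kaplan_meier <- function(survival_table) {
  .assert(nrow(survival_table) > 0, "empty survival table")
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1,
    data = survival_table, conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

#' Two-group log-rank test on a median split
#'
#' Splits patients at the median score (high = strictly above the
#' median; with distinct scores the group sizes differ by at most one)
#' and compares survival with the standard 1-df log-rank chi-square
#' (\code{survival::survdiff}), i.e. summed observed-minus-expected
#' deaths over the 2x2 tables at each event time.
#'
#' @param scores named per-patient risk score.
#' @param survival_table survival data.frame.
#' @return list: \code{chi2}, \code{p}, \code{group} (named factor
#'   high/low), \code{n_high}, \code{n_low}.
#' @export
logrank_test <- function(scores, survival_table) {
  d <- .join_scores(scores, survival_table)
  .assert(stats::sd(d$score) > 0,
          "degenerate split: all scores identical")
  d$group <- factor(ifelse(d$score > stats::median(d$score),
                           "high", "low"), levels = c("low", "high"))
  .assert(all(table(d$group) > 0), "median split left an empty group")
  sd_fit <- survival::survdiff(
    survival::Surv(time_months, event) ~ group, data = d)
  chi2 <- unname(sd_fit$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       group = stats::setNames(d$group, d$patient_id),
       n_high = sum(d$group == "high"), n_low = sum(d$group == "low"))
}

#' Evaluate a classifier against postoperative survival
#'
#' Scores every patient with \code{\link{signature_score}}, fits the
#' univariate Cox model on the continuous score (the primary statistic),
#' and reports Kaplan-Meier curves and the log-rank test for the
#' presentational median split. A classifier is said to validate on a
#' second cohort when its Wald p is below 0.05 with the same coefficient
#' sign as in discovery.
#'
#' @param clf a \code{\link{classifier}}.
#' @param cohort list with \code{mrna}, \code{annotation},
#'   \code{survival}, optionally \code{mirna} (a \code{"grad_cohort"}
#'   works directly).
#' @return list of class \code{"survival_association"}: \code{classifier},
#'   \code{n}, \code{scores}, \code{beta}, \code{se_beta}, \code{wald_p},
#'   \code{hr_sign}, \code{logrank_chi2}, \code{logrank_p},
#'   \code{km_high}, \code{km_low}, \code{n_features_used},
#'   \code{n_features_missing}.
#' @export
evaluate_classifier <- function(clf, cohort) {
  stopifnot(inherits(clf, "classifier"))
  score <- signature_score(clf, cohort$mrna, cohort$annotation,
                           cohort$mirna)
  cox <- cox_fit_univariate(score, cohort$survival)
  lr <- logrank_test(score, cohort$survival)
  d <- .join_scores(score, cohort$survival)
  km <- lapply(split(d, lr$group[d$patient_id]), kaplan_meier)
  out <- list(
    classifier = clf, n = cox$n,
    scores = score,
    beta = cox$beta, se_beta = cox$se_beta, wald_p = cox$wald_p,
    hr_sign = sign(cox$beta),
    logrank_chi2 = lr$chi2, logrank_p = lr$p,
    km_high = km[["high"]], km_low = km[["low"]],
    n_features_used = attr(score, "n_features_used"),
    n_features_missing = attr(score, "n_features_missing")
  )
  class(out) <- "survival_association"
  out
}

#' @export
print.survival_association <- function(x, ...) {
  cat(sprintf(
    "Signature '%s' (%s, mode %s): n=%d, beta=%.3f (se %.3f), Wald p=%.3g, log-rank p=%.3g\n",
    x$classifier$name, x$classifier$kind, x$classifier$mode, x$n,
    x$beta, x$se_beta, x$wald_p, x$logrank_p))
  if (x$n_features_missing > 0)
    cat(sprintf("  %d feature(s) not measured in this cohort\n",
                x$n_features_missing))
  invisible(x)
}
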