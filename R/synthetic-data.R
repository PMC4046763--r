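#' Configuration for the synthetic cohort simulator
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the cohort structure the pipeline was designed for: ten
#' normal liver tissues plus forty-five patients each contributing a paired
#' pericancerous and cancer sample, with a subset of genes shifted gradually
#' (half effect in pericancerous tissue, full effect in cancer) on the log2
#' scale.
#'
#' @param n_normal number of normal-tissue samples (>= 2).
#' @param n_pairs number of patients with paired pericancerous/cancer
#'   samples (>= 3).
#' @param n_genes,n_mirnas sizes of the gene and microRNA universes.
#' @param n_sets number of gene sets to simulate.
#' @param set_size_range length-2 integer vector, inclusive bounds on set
#'   size (each >= 2).
#' @param frac_gradual_up,frac_gradual_down proportions of genes planted
#'   with a gradual up/down shift.
#' @param delta log2 effect size of the full cancer-vs-normal shift;
#'   pericancerous tissue gets \code{delta/2}. The default (5) keeps the
#'   half-shift above the DEG fold-change cutoff (2), so all three
#'   comparisons yield DEGs, as in the cohorts the simulator emulates.
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param beta_surv log-hazard per unit of standardized risk score for the
#'   planted prognostic set.
#' @param censor_frac target proportion of censored patients.
#' @param db_recall,db_fpr per-database probabilities that a true target
#'   edge is reported / that a spurious edge is reported.
#' @param seed master RNG seed; every stage derives its own sub-stream.
#' @return A validated list of class \code{"synthetic_config"}.
#' @examples
#' cfg <- synthetic_config(n_genes = 200, n_pairs = 10, seed = 7)
#' @export
synthetic_config <- function(n_normal = 10, n_pairs = 45,
                             n_genes = 2000, n_mirnas = 150,
                             n_sets = 50, set_size_range = c(10L, 30L),
                             frac_gradual_up = 0.05, frac_gradual_down = 0.05,
                             delta = 5, noise_sd = 0.5,
                             beta_surv = 1, censor_frac = 0.2,
                             db_recall = 0.7, db_fpr = 0.01,
                             seed = 1L) {
  .assert(.is_count(n_normal, 2), "n_normal must be an integer >= 2")
  .assert(.is_count(n_pairs, 3), "n_pairs must be an integer >= 3")
  .assert(.is_count(n_genes, 1), "n_genes must be a positive integer")
  .assert(.is_count(n_mirnas, 1), "n_mirnas must be a positive integer")
  .assert(.is_count(n_sets, 1), "n_sets must be a positive integer")
  .assert(length(set_size_range) == 2 && all(set_size_range >= 2) &&
            set_size_range[1] <= set_size_range[2],
          "set_size_range must be two integers >= 2, low <= high")
  .assert(.is_prob(frac_gradual_up) && .is_prob(frac_gradual_down) &&
            frac_gradual_up + frac_gradual_down <= 1,
          "gradual fractions must lie in [0,1] and sum to <= 1")
  .assert(length(delta) == 1 && is.finite(delta) && delta > 0,
          "delta must be a positive finite number")
  .assert(length(noise_sd) == 1 && is.finite(noise_sd) && noise_sd >= 0,
          "noise_sd must be a finite non-negative number")
  .assert(length(beta_surv) == 1 && is.finite(beta_surv),
          "beta_surv must be finite")
  .assert(.is_prob(censor_frac) && censor_frac < 1,
          "censor_frac must lie in [0,1)")
  .assert(.is_prob(db_recall), "db_recall must lie in [0,1]")
  .assert(.is_prob(db_fpr), "db_fpr must lie in [0,1]")
  .assert(.is_count(seed, 0), "seed must be a non-negative integer")
  cfg <- list(
    n_normal = as.integer(n_normal), n_pairs = as.integer(n_pairs),
    n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
    n_sets = as.integer(n_sets),
    set_size_range = as.integer(set_size_range),
    frac_gradual_up = frac_gradual_up, frac_gradual_down = frac_gradual_down,
    delta = delta, noise_sd = noise_sd,
    beta_surv = beta_surv, censor_frac = censor_frac,
    db_recall = db_recall, db_fpr = db_fpr,
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

# Class-specific shift of a gene: 0 in normal, delta/2 in pericancerous,
# delta in cancer for gradual-up genes; negated for gradual-down.
.class_shift <- function(tissue, delta) {
  unname(c(normal = 0, peri = delta / 2, cancer = delta)[tissue])
}

#' Simulate a three-tissue expression cohort with planted gradual genes
#'
#' Generates the mRNA and microRNA expression matrices, the sample
#' annotation, and the ground truth. Each gene has a baseline
#' \code{mu_g ~ N(8, 1.5)} (typical log2 array intensities). Planted
#' gradual-up genes gain 0 / \code{delta/2} / \code{delta} log2 units in
#' normal / pericancerous / cancer tissue (negated for gradual-down genes);
#' all other genes are null. Gaussian noise with \code{noise_sd} is added
#' per measurement. microRNA expression is generated anti-correlated
#' (coefficient -0.5) with the standardized mean expression of the miRNA's
#' true targets, so the miRNA-substitution stage has signal to find.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param truth optionally, a ground-truth object from a previous call;
#'   when supplied, the planted structure (gene baselines, gradual genes,
#'   target edges) is reused and only the samples and noise are redrawn.
#'   Used to simulate an independent validation cohort.
#' @param stream which RNG sub-stream to draw samples from
#'   (\code{"cohort"} for discovery, \code{"validation"} for a second
#'   cohort sharing the same truth).
#' @return list with elements \code{mrna} (genes x samples matrix),
#'   \code{mirna} (miRNAs x samples matrix), \code{annotation}
#'   (data.frame: sample_id, patient_id, tissue), and \code{truth}.
#' @export
generate_cohort <- function(config, truth = NULL,
                            stream = c("cohort", "validation")) {
  stopifnot(inherits(config, "synthetic_config"))
  stream <- match.arg(stream)
  n_g <- config$n_genes
  n_m <- config$n_mirnas

  if (is.null(truth)) {
    truth <- .with_stream(.stream_seed(config$seed, "cohort"), function() {
      gene_ids <- sprintf("G%05d", seq_len(n_g))
      mirna_ids <- sprintf("hsa-miR-%03d", seq_len(n_m))
      n_up <- round(config$frac_gradual_up * n_g)
      n_down <- round(config$frac_gradual_down * n_g)
      planted <- sample(gene_ids, n_up + n_down)
      edges_per_mirna <- pmin(sample(4:12, n_m, replace = TRUE), n_g)
      edges <- data.frame(
        mirna_id = rep(mirna_ids, edges_per_mirna),
        gene_id = unlist(lapply(edges_per_mirna, function(k)
          sample(gene_ids, k))),
        stringsAsFactors = FALSE
      )
      list(
        gene_ids = gene_ids,
        mirna_ids = mirna_ids,
        mu_gene = stats::rnorm(n_g, mean = 8, sd = 1.5),
        mu_mirna = stats::rnorm(n_m, mean = 6, sd = 1),
        gradual_up = sort(planted[seq_len(n_up)]),
        gradual_down = sort(planted[n_up + seq_len(n_down)]),
        true_target_edges = edges,
        prognostic_sets = character(0),
        prognostic_members = list()
      )
    })
  }

  sample_seed <- .stream_seed(config$seed, stream)
  .with_stream(sample_seed, function() {
    patient_id <- sprintf("PT%03d", seq_len(config$n_pairs))
    annotation <- data.frame(
      sample_id = c(sprintf("N%02d", seq_len(config$n_normal)),
                    paste0(patient_id, "_peri"),
                    paste0(patient_id, "_cancer")),
      patient_id = c(rep(NA_character_, config$n_normal),
                     patient_id, patient_id),
      tissue = c(rep("normal", config$n_normal),
                 rep("peri", config$n_pairs),
                 rep("cancer", config$n_pairs)),
      stringsAsFactors = FALSE
    )
    n_s <- nrow(annotation)

    shift_sign <- numeric(n_g)
    names(shift_sign) <- truth$gene_ids
    shift_sign[truth$gradual_up] <- 1
    shift_sign[truth$gradual_down] <- -1
    class_shift <- .class_shift(annotation$tissue, config$delta)

    mrna <- truth$mu_gene +
      outer(shift_sign, class_shift) +
      matrix(stats::rnorm(n_g * n_s, sd = config$noise_sd), n_g, n_s)
    dimnames(mrna) <- list(truth$gene_ids, annotation$sample_id)

    # miRNA = baseline - 0.5 * standardized mean of true targets + residual,
    # residual scaled so the signal has unit variance overall.
    target_idx <- split(match(truth$true_target_edges$gene_id, truth$gene_ids),
                        truth$true_target_edges$mirna_id)
    mirna <- matrix(stats::rnorm(n_m * n_s), n_m, n_s,
                    dimnames = list(truth$mirna_ids, annotation$sample_id))
    for (m in seq_len(n_m)) {
      idx <- target_idx[[truth$mirna_ids[m]]]
      if (!is.null(idx) && length(idx) > 0) {
        tm <- colMeans(mrna[idx, , drop = FALSE])
        z <- if (stats::sd(tm) > 0) as.numeric(scale(tm)) else numeric(n_s)
        mirna[m, ] <- -0.5 * z + sqrt(1 - 0.25) * mirna[m, ]
      }
    }
    mirna <- mirna + truth$mu_mirna

    list(mrna = mrna, mirna = mirna, annotation = annotation, truth = truth)
  })
}

#' Simulate a gene-set collection with planted enriched sets
#'
#' Emits \code{n_sets} gene sets over the simulated universe. Designated
#' "enriched" sets (20\% of the collection, at least one) draw 75\% of
#' their members from the planted gradual genes (alternating up- and
#' down-type sets); the remainder are null sets drawn uniformly. Enriched
#' sets double as the planted prognostic sets.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param truth ground truth from \code{\link{generate_cohort}}.
#' @return named list of member-ID vectors (class
#'   \code{"gene_set_collection"}) with attributes \code{enriched_sets},
#'   \code{categories}.
#' @export
generate_gene_sets <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  lo <- config$set_size_range[1]; hi <- config$set_size_range[2]
  .assert(hi <= config$n_genes,
          "set size range exceeds the gene universe")
  .with_stream(.stream_seed(config$seed, "sets"), function() {
    n_enriched <- max(1L, round(0.2 * config$n_sets))
    names_all <- sprintf("SET_%03d", seq_len(config$n_sets))
    up_pool <- truth$gradual_up
    down_pool <- truth$gradual_down
    sets <- vector("list", config$n_sets)
    for (i in seq_len(config$n_sets)) {
      size <- if (lo == hi) lo else sample(lo:hi, 1)
      if (i <= n_enriched) {
        pool <- if (i %% 2 == 1) up_pool else down_pool
        if (length(pool) == 0) pool <- c(up_pool, down_pool)
        # without planted gradual genes the "enriched" sets are just null
        if (length(pool) == 0) pool <- truth$gene_ids
        rest_pool <- setdiff(truth$gene_ids, pool)
        n_sig <- min(ceiling(0.75 * size), length(pool))
        n_rest <- min(size - n_sig, length(rest_pool))
        n_sig <- size - n_rest
        members <- c(sample(pool, n_sig),
                     if (n_rest > 0) sample(rest_pool, n_rest))
      } else {
        members <- sample(truth$gene_ids, size)
      }
      sets[[i]] <- sort(members)
    }
    names(sets) <- names_all
    attr(sets, "enriched_sets") <- names_all[seq_len(n_enriched)]
    attr(sets, "categories") <- stats::setNames(
      rep_len(c("GO", "pathway", "TFT"), config$n_sets), names_all)
    class(sets) <- "gene_set_collection"
    sets
  })
}

#' Simulate six noisy redundant miRNA-target databases
#'
#' Each of the six databases reports every true target edge independently
#' with probability \code{db_recall} and every non-edge with probability
#' \code{db_fpr}, emulating partially overlapping target-prediction
#' resources. The consensus vote across databases is what the
#' \code{\link{build_consensus_map}} stage recovers.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param truth ground truth carrying \code{true_target_edges} and the
#'   miRNA/gene universes.
#' @return named list of six data.frames (\code{mirna_id}, \code{gene_id}).
#' @export
generate_target_databases <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  n_g <- length(truth$gene_ids)
  n_m <- length(truth$mirna_ids)
  true_idx <- (match(truth$true_target_edges$mirna_id, truth$mirna_ids) - 1) *
    n_g + match(truth$true_target_edges$gene_id, truth$gene_ids)
  total <- n_m * n_g
  .with_stream(.stream_seed(config$seed, "targets"), function() {
    non_idx <- if (config$db_fpr > 0) setdiff(seq_len(total), true_idx)
               else integer(0)
    dbs <- lapply(seq_len(6), function(d) {
      keep_true <- true_idx[stats::runif(length(true_idx)) < config$db_recall]
      n_fp <- if (length(non_idx)) stats::rbinom(1, length(non_idx),
                                                 config$db_fpr) else 0L
      fp <- if (n_fp > 0) sample(non_idx, n_fp) else integer(0)
      idx <- c(keep_true, fp)
      data.frame(
        mirna_id = truth$mirna_ids[(idx - 1) %/% n_g + 1],
        gene_id = truth$gene_ids[(idx - 1) %% n_g + 1],
        stringsAsFactors = FALSE
      )
    })
    names(dbs) <- paste0("db", seq_len(6))
    dbs
  })
}

#' Simulate postoperative survival linked to a planted signature
#'
#' Event times are exponential with hazard
#' \code{h0 * exp(beta_surv * z)}, where \code{z} is the standardized mean
#' cancer-sample expression of the first planted prognostic set and
#' \code{h0 = log(2)/24} (median survival 24 months at z = 0). Censoring is
#' independent uniform on \code{(0, u)} with \code{u} tuned numerically so
#' the expected censored fraction equals \code{censor_frac}.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param truth ground truth with \code{prognostic_members} filled in
#'   (see \code{\link{simulate_study}}).
#' @param mrna mRNA expression matrix of the cohort.
#' @param annotation sample annotation of the cohort.
#' @return data.frame (\code{patient_id}, \code{time_months}, \code{event})
#'   with the per-patient latent risk as attribute \code{latent_risk}.
#' @export
generate_survival <- function(config, truth, mrna, annotation) {
  stopifnot(inherits(config, "synthetic_config"))
  .assert(is.finite(config$beta_surv), "beta_surv must be finite")
  cancer <- annotation[annotation$tissue == "cancer", ]
  .assert(nrow(cancer) > 0, "no cancer samples in the cohort")
  members <- if (length(truth$prognostic_members) > 0)
    truth$prognostic_members[[1]] else truth$gradual_up
  members <- intersect(members, rownames(mrna))
  .assert(length(members) > 0, "prognostic set has no measured members")

  m <- colMeans(mrna[members, cancer$sample_id, drop = FALSE])
  z <- if (stats::sd(m) > 0) as.numeric(scale(m)) else numeric(length(m))

  h0 <- log(2) / 24
  lambda <- h0 * exp(config$beta_surv * z)
  .with_stream(.stream_seed(config$seed, "survival"), function() {
    t_event <- stats::rexp(length(lambda), rate = lambda)
    if (config$censor_frac == 0) {
      time <- t_event; event <- rep(1L, length(lambda))
    } else {
      # E[censored | u] = mean_i (1 - exp(-lambda_i u)) / (lambda_i u),
      # monotone decreasing in u; solve for the target fraction.
      cens_frac <- function(u) mean((1 - exp(-lambda * u)) / (lambda * u))
      u <- stats::uniroot(function(u) cens_frac(u) - config$censor_frac,
                          lower = 1e-6, upper = 1e7, tol = 1e-8)$root
      c_time <- stats::runif(length(lambda), 0, u)
      time <- pmin(t_event, c_time)
      event <- as.integer(t_event <= c_time)
    }
    out <- data.frame(patient_id = cancer$patient_id,
                      time_months = time, event = event,
                      stringsAsFactors = FALSE)
    attr(out, "latent_risk") <- stats::setNames(z, cancer$patient_id)
    out
  })
}

#' Simulate a complete study bundle
#'
#' Convenience wrapper running \code{\link{generate_cohort}},
#' \code{\link{generate_gene_sets}}, \code{\link{generate_target_databases}}
#' and \code{\link{generate_survival}} in order, wiring the planted
#' prognostic sets into the ground truth.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list of class \code{"grad_cohort"}: \code{mrna}, \code{mirna},
#'   \code{annotation}, \code{survival}, \code{gene_sets},
#'   \code{target_dbs}, \code{truth}, \code{config}.
#' @examples
#' study <- simulate_study(synthetic_config(n_genes = 300, n_pairs = 12,
#'                                          n_sets = 10, seed = 3))
#' dim(study$mrna)
#' @export
simulate_study <- function(config) {
  cohort <- generate_cohort(config)
  sets <- generate_gene_sets(config, cohort$truth)
  truth <- cohort$truth
  truth$prognostic_sets <- attr(sets, "enriched_sets")
  truth$prognostic_members <- sets[truth$prognostic_sets]
  dbs <- generate_target_databases(config, truth)
  surv <- generate_survival(config, truth, cohort$mrna, cohort$annotation)
  truth$latent_risk <- attr(surv, "latent_risk")
  out <- list(mrna = cohort$mrna, mirna = cohort$mirna,
              annotation = cohort$annotation, survival = surv,
              gene_sets = sets, target_dbs = dbs,
              truth = truth, config = config)
  class(out) <- "grad_cohort"
  out
}

#' Simulate an independent validation cohort sharing the planted truth
#'
#' Redraws samples, noise and survival from a separate RNG stream while
#' keeping the gene universe, baselines, gradual genes, gene sets and true
#' target edges of the discovery study, emulating an external cohort
#' measured on the same platform.
#'
#' @param study a \code{"grad_cohort"} from \code{\link{simulate_study}}.
#' @return a second \code{"grad_cohort"} with the same truth.
#' @export
simulate_validation <- function(study) {
  stopifnot(inherits(study, "grad_cohort"))
  config <- study$config
  val_config <- config
  val_config$seed <- .stream_seed(config$seed, "validation")
  cohort <- generate_cohort(config, truth = study$truth,
                            stream = "validation")
  surv <- generate_survival(val_config, study$truth,
                            cohort$mrna, cohort$annotation)
  truth <- study$truth
  truth$latent_risk <- attr(surv, "latent_risk")
  out <- list(mrna = cohort$mrna, mirna = cohort$mirna,
              annotation = cohort$annotation, survival = surv,
              gene_sets = study$gene_sets, target_dbs = study$target_dbs,
              truth = truth, config = config)
  class(out) <- "grad_cohort"
  out
}

#' Plant a deterministic expression pattern for one gene
#'
#' Overwrites one gene's row with \code{8 + means[tissue]} (no noise),
#' giving exact class differences. Used to construct degenerate or
#' sign-switching cases, e.g. a gene up-regulated in pericancerous vs
#' normal but down-regulated in cancer vs pericancerous.
#'
#' @param mrna expression matrix.
#' @param annotation sample annotation matching its columns.
#' @param gene_id row to overwrite (must exist).
#' @param means named numeric: \code{normal}, \code{peri}, \code{cancer}.
#' @return the modified matrix.
#' @export
plant_gene_pattern <- function(mrna, annotation, gene_id, means) {
  .assert(gene_id %in% rownames(mrna), "gene_id not in matrix")
  .assert(all(c("normal", "peri", "cancer") %in% names(means)),
          "means must name normal, peri and cancer")
  mrna[gene_id, ] <- 8 + unname(means[annotation$tissue])
  mrna
}
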