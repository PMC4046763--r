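surv_df <- function(time, event, id = sprintf("P%02d", seq_along(time))) {
  data.frame(patient_id = id, time_months = time, event = event,
             stringsAsFactors = FALSE)
}

test_that("Kaplan-Meier matches hand product-limit computations", {
  km <- kaplan_meier(surv_df(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # censoring at 2: risk set at t=3 is a single patient
  km2 <- kaplan_meier(surv_df(c(1, 2, 3), c(1, 0, 1)))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)
  # without censoring the curve is the empirical survivor function
  set.seed(3)
  t <- sort(sample(1:50, 12))
  km3 <- kaplan_meier(surv_df(t, rep(1, 12)))
  expect_equal(km3$surv, brute_km(t, rep(1, 12))$surv)
  expect_equal(km3$surv, 1 - seq_along(t) / 12)
  # curves start at 1 and never increase
  expect_true(all(diff(c(1, km3$surv)) <= 0))
})

test_that("Cox fit matches 1-D partial-likelihood maximization", {
  sv <- surv_df(1:4, rep(1, 4))
  sc <- stats::setNames(c(1, 0, 1, 0), sv$patient_id)
  fit <- cox_fit_univariate(sc, sv)
  ref <- stats::optimize(function(b)
    efron_loglik(b, sv$time_months, sv$event, unname(sc)),
    c(-8, 8), maximum = TRUE)$maximum
  expect_equal(fit$beta, ref, tolerance = 1e-4)
  # random small datasets, including ties
  set.seed(22)
  for (i in 1:12) {
    n <- sample(6:12, 1)
    sv <- surv_df(sample(1:6, n, replace = TRUE),
                  rbinom(n, 1, 0.8))
    if (sum(sv$event) < 2) next
    sc <- stats::setNames(rnorm(n), sv$patient_id)
    fit <- cox_fit_univariate(sc, sv)
    ref <- stats::optimize(function(b)
      efron_loglik(b, sv$time_months, sv$event, unname(sc)),
      c(-8, 8), maximum = TRUE, tol = 1e-9)$maximum
    expect_equal(fit$beta, ref, tolerance = 1e-4)
  }
})

test_that("Cox fit rejects degenerate inputs", {
  sv <- surv_df(1:4, rep(1, 4))
  expect_error(cox_fit_univariate(
    stats::setNames(rep(2, 4), sv$patient_id), sv), "variance")
  sv0 <- surv_df(1:4, c(1, 0, 0, 0))
  expect_error(cox_fit_univariate(
    stats::setNames(c(1, 2, 3, 4), sv0$patient_id), sv0), "events")
})

test_that("log-rank test matches hand tables and the Cox score test", {
  # two groups with identical survival experience: chi2 = 0, p = 1
  sv <- surv_df(c(5, 6, 5, 6), c(1, 0, 1, 0))
  sc <- stats::setNames(c(1, 2, 3, 4), sv$patient_id)  # split: {1,2} vs {3,4}
  lr <- logrank_test(sc, sv)
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  expect_equal(lr$n_high, 2); expect_equal(lr$n_low, 2)
  # early-death group vs late-death group, hand 2x2 computation
  sv2 <- surv_df(c(1, 2, 3, 4), rep(1, 4))
  sc2 <- stats::setNames(c(10, 9, 1, 2), sv2$patient_id)
  lr2 <- logrank_test(sc2, sv2)
  expect_equal(lr2$chi2,
               brute_logrank(sv2$time_months, sv2$event,
                             c("high", "high", "low", "low")),
               tolerance = 1e-10)
  # equals the Cox score test at beta = 0 for the binary indicator
  # (exact identity requires untied event times)
  set.seed(31)
  for (i in 1:20) {
    n <- sample(8:16, 1)
    sv3 <- surv_df(sample(1:50, n), rbinom(n, 1, 0.7))
    sc3 <- stats::setNames(rnorm(n), sv3$patient_id)
    if (sum(sv3$event) < 2 || sd(sc3) == 0) next
    lr3 <- logrank_test(sc3, sv3)
    grp <- as.integer(lr3$group[sv3$patient_id] == "high")
    score_test <- survival::coxph(
      survival::Surv(sv3$time_months, sv3$event) ~ grp,
      ties = "breslow")$score
    expect_equal(lr3$chi2, unname(score_test), tolerance = 1e-6)
  }
  expect_error(logrank_test(stats::setNames(rep(1, 4), sv$patient_id), sv),
               "identical")
})

test_that("median split sizes differ by at most one for distinct scores", {
  set.seed(40)
  for (n in c(9, 10, 15)) {
    sv <- surv_df(seq_len(n) + 1, rep(1, n))
    sc <- stats::setNames(sample(seq_len(n)), sv$patient_id)
    lr <- logrank_test(sc, sv)
    expect_lte(abs(lr$n_high - lr$n_low), 1)
  }
})

test_that("signature scores are means of per-feature z-scores", {
  # 3 cancer patients, 1 normal; two features
  ann <- data.frame(
    sample_id = c("n1", "p1_c", "p2_c", "p3_c"),
    patient_id = c(NA, "p1", "p2", "p3"),
    tissue = c("normal", "cancer", "cancer", "cancer"),
    stringsAsFactors = FALSE)
  m <- rbind(gA = c(0, 1, 2, 3), gB = c(0, 3, 2, 1))
  colnames(m) <- ann$sample_id
  # single feature: score equals that gene's z-score across cancer samples
  s1 <- signature_score(classifier("one", "gA", mode = "C"), m, ann)
  expect_equal(unname(s1), as.numeric(scale(c(1, 2, 3))),
               ignore_attr = TRUE)
  # two features with opposite z-scores cancel
  s2 <- signature_score(classifier("two", c("gA", "gB"), mode = "C"), m, ann)
  expect_equal(unname(s2), rep(0, 3), ignore_attr = TRUE)
  # missing features are dropped and counted; all-missing errors
  s3 <- signature_score(classifier("m", c("gA", "ghost"), mode = "C"), m, ann)
  expect_equal(attr(s3, "n_features_missing"), 1)
  expect_equal(attr(s3, "n_features_used"), 1)
  expect_error(signature_score(classifier("none", "ghost", mode = "C"),
                               m, ann), "measured")
})

test_that("paired C/P profile recovers the planted half-shift exactly", {
  cfg <- tiny_config(noise_sd = 0, delta = 4)
  ch <- generate_cohort(cfg)
  feats <- ch$truth$gradual_up[1:4]
  prof <- profile_matrix(ch$mrna, ch$annotation, feats, mode = "C/P")
  expect_true(all(abs(prof - 2) < 1e-12))   # delta/2 per gene, per patient
  prof_pn <- profile_matrix(ch$mrna, ch$annotation, feats, mode = "P/N")
  expect_true(all(abs(prof_pn - 2) < 1e-12))
  prof_cn <- profile_matrix(ch$mrna, ch$annotation, feats, mode = "C/N")
  expect_true(all(abs(prof_cn - 4) < 1e-12))
})

test_that("C/P mode drops patients without a complete pair", {
  cfg <- tiny_config()
  ch <- generate_cohort(cfg)
  ann <- ch$annotation[ch$annotation$sample_id != "PT001_peri", ]
  expect_warning(
    prof <- profile_matrix(ch$mrna, ann, ch$truth$gradual_up[1:3], "C/P"),
    "missing pair")
  expect_false("PT001" %in% colnames(prof))
})

test_that("classifier evaluation proceeds when some features are unmeasured", {
  cfg <- tiny_config(seed = 33)
  st <- simulate_study(cfg)
  feats <- c(st$truth$prognostic_members[[1]], "UNMEASURED_1", "UNMEASURED_2")
  sa <- evaluate_classifier(classifier("planted+ghosts", feats, mode = "C"),
                            st)
  expect_equal(sa$n_features_missing, 2)
  expect_gt(sa$n_features_used, 0)
  expect_true(is.finite(sa$beta) && is.finite(sa$logrank_p))
  # KM curves are proper survival step functions
  for (km in list(sa$km_high, sa$km_low)) {
    expect_true(all(km$surv >= 0 & km$surv <= 1))
    expect_true(all(diff(c(1, km$surv)) <= 1e-12))
  }
  # positive beta convention: planted set carries beta_surv = 1 > 0
  expect_gt(sa$beta, 0)
})
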