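make_groups_matrix <- function(n_genes, na, nb, sd = 1, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (na + nb), mean = 8, sd = sd),
              n_genes, na + nb,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(na + nb))))
  list(m = m, a = colnames(m)[seq_len(na)],
       b = colnames(m)[na + seq_len(nb)])
}

test_that("benjamini_hochberg matches the brute-force step-up", {
  expect_equal(benjamini_hochberg(0.05), 0.05)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(c(1, 1)), c(1, 1))
  expect_error(benjamini_hochberg(c(0.2, 1.4)), "\\[0,1\\]")
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(1:20, 1))
    expect_equal(benjamini_hochberg(p), brute_bh(p))
  }
})

test_that("moderated t reduces to the ordinary pooled t when prior df is 0", {
  d <- make_groups_matrix(50, 5, 7, seed = 3)
  res <- moderated_t(d$m, d$a, d$b, prior_df = 0)
  # hand pooled-variance t
  for (i in c(1, 17, 50)) {
    a <- d$m[i, d$a]; b <- d$m[i, d$b]
    s2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    t_hand <- (mean(a) - mean(b)) /
      sqrt(s2 * (1 / length(a) + 1 / length(b)))
    expect_equal(res$t[i], t_hand, tolerance = 1e-12)
    expect_equal(res$raw_p[i],
                 unname(t.test(a, b, var.equal = TRUE)$p.value),
                 tolerance = 1e-12)
  }
  expect_equal(res$df_total[1], 10)
})

test_that("infinite prior df shrinks every posterior variance to s0^2", {
  d <- make_groups_matrix(80, 4, 4, seed = 5)
  res <- moderated_t(d$m, d$a, d$b, prior_df = Inf)
  expect_equal(length(unique(round(res$posterior_sd, 12))), 1)
  expect_equal(unique(res$posterior_sd)^2, attr(res, "prior_var"),
               tolerance = 1e-10)
})

test_that("a planted effect is estimated and called significant", {
  d <- make_groups_matrix(500, 10, 10, sd = 0.1, seed = 7)
  d$m["g001", d$a] <- d$m["g001", d$a] + 4
  res <- moderated_t(d$m, d$a, d$b)
  i <- match("g001", res$gene_id)
  expect_gt(res$log2fc[i], 3.8)
  expect_lt(res$log2fc[i], 4.2)
  expect_lt(res$adj_p[i], 0.001)
})

test_that("moderated t agrees with the limma reference implementation", {
  library(limma)
  set.seed(19)
  # heterogeneous true variances so moderation actually does something
  n <- 400; na <- 5; nb <- 6
  sds <- sqrt(1 / rgamma(n, shape = 3, rate = 3))
  m <- matrix(rnorm(n * (na + nb), sd = rep(sds, na + nb)), n, na + nb,
              dimnames = list(sprintf("g%03d", 1:n),
                              sprintf("s%02d", 1:(na + nb))))
  a <- colnames(m)[1:na]; b <- colnames(m)[na + 1:nb]
  mine <- moderated_t(m, a, b)
  design <- cbind(Intercept = 1, grp = c(rep(1, na), rep(0, nb)))
  fit <- eBayes(lmFit(m, design))
  expect_equal(attr(mine, "prior_df"), fit$df.prior, tolerance = 0.05)
  expect_equal(attr(mine, "prior_var"), fit$s2.prior, tolerance = 0.02)
  expect_equal(mine$t, fit$t[, "grp"], tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(mine$raw_p, fit$p.value[, "grp"], tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("group validation rejects malformed inputs", {
  d <- make_groups_matrix(10, 3, 3)
  expect_error(moderated_t(d$m, d$a, c(d$b, d$a[1])), "disjoint")
  expect_error(moderated_t(d$m, d$a[1], d$b), "at least 2")
  expect_error(moderated_t(d$m, c(d$a, "ghost"), d$b), "ghost")
})

test_that("DEG selection applies strict thresholds on both criteria", {
  res <- data.frame(
    gene_id = c("up_ok", "boundary", "p_fail", "down_ok"),
    log2fc = c(2.5, 2.0, -3, -2.4),
    adj_p = c(1e-4, 1e-6, 0.01, 1e-5)
  )
  sel <- select_degs(res)
  expect_identical(sel$up, "up_ok")
  expect_identical(sel$down, "down_ok")
  expect_false("boundary" %in% sel$all)
  expect_false("p_fail" %in% sel$all)
})

test_that("venn partition handles monotone and sign-switching genes", {
  degs <- list(
    "C/N" = list(up = c("DKK1x", "EGR1x", "only_cn"), down = "kcnn2"),
    "C/P" = list(up = "DKK1x", down = c("EGR1x", "kcnn2")),
    "P/N" = list(up = c("DKK1x", "EGR1x"), down = "kcnn2")
  )
  part <- venn_partition(degs)
  # monotone up gene sits in the center of the up- and all-diagrams
  expect_true("DKK1x" %in% part$venn$up[["C/N&C/P&P/N"]])
  expect_true("DKK1x" %in% part$venn$all[["C/N&C/P&P/N"]])
  # the sign switcher reaches the all-center but neither signed center
  expect_true("EGR1x" %in% part$venn$all[["C/N&C/P&P/N"]])
  expect_false("EGR1x" %in% part$venn$up[["C/N&C/P&P/N"]])
  expect_false("EGR1x" %in% part$venn$down[["C/N&C/P&P/N"]])
  # up + down totals exceed the all total because of the switch
  expect_gt(part$totals[["up"]] + part$totals[["down"]],
            part$totals[["all"]])
  # cells partition the union
  cells <- unlist(part$venn$all, use.names = FALSE)
  expect_identical(sort(cells), sort(unique(cells)))
  expect_setequal(cells, unique(unlist(lapply(part$per_comparison,
                                              `[[`, "all"))))
})

test_that("venn partition of empty inputs is empty", {
  degs <- list("C/N" = list(up = character(0), down = character(0)),
               "C/P" = list(up = character(0), down = character(0)),
               "P/N" = list(up = character(0), down = character(0)))
  part <- venn_partition(degs)
  expect_true(all(lengths(unlist(part$venn, recursive = FALSE)) == 0))
  expect_identical(unname(part$totals), c(0L, 0L, 0L))
})

test_that("venn cell counts are invariant to gene order", {
  set.seed(8)
  genes <- sprintf("g%02d", 1:30)
  mk <- function(perm) {
    list("C/N" = list(up = perm[1:12], down = perm[20:25]),
         "C/P" = list(up = perm[5:15], down = perm[26:28]),
         "P/N" = list(up = perm[10:20], down = perm[29:30]))
  }
  p1 <- venn_partition(mk(genes))
  shuffled <- lapply(mk(genes), function(d) lapply(d, sample))
  p2 <- venn_partition(shuffled)   # same sets, shuffled membership order
  expect_identical(lapply(p1$venn$all, sort), lapply(p2$venn$all, sort))
})
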