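test_that("cell-means fits match hand ANOVA arithmetic", {
  design <- full_design(2)
  # one gene, 2 replicates in each of the 6 cells
  vals <- c(8.0, 8.4,  7.0, 7.2,  9.1, 8.9,  6.5, 6.9,  8.2, 8.0,  5.0, 5.8)
  expr <- matrix(vals, 1, 12, dimnames = list("g1", design$sample_id))
  fit <- fit_gene_models(expr, design)

  # oracle: explicit per-cell means and pooled within-cell sum of squares
  cells <- paste(design$group, design$hemisphere, sep = "_")
  means_ref <- tapply(vals, cells, mean)
  sse_ref <- sum(unlist(lapply(split(vals, cells),
                               function(v) sum((v - mean(v))^2))))
  expect_equal(fit$means[1, names(means_ref)], c(means_ref))
  expect_equal(fit$df, 12 - 6)
  expect_equal(fit$s2[["g1"]], sse_ref / 6)
})

test_that("balanced triplicate designs give d_g = 12 and constant genes s2 = 0", {
  design <- full_design(3)
  set.seed(5)
  expr <- null_expr(design, 20)
  expr["g0001", ] <- 7.5  # constant gene
  fit <- fit_gene_models(expr, design)
  expect_equal(fit$df, 12)
  expect_equal(fit$s2[["g0001"]], 0)
  prior <- list(df_prior = 0, var_prior = 1)
  for (cn in lateral_contrasts()$name) {
    res <- moderated_t(fit, prior, cn)
    expect_equal(res$log2fc[res$gene == "g0001"], 0)
    expect_equal(res$t[res$gene == "g0001"], 0)
  }
})

test_that("a condition with fewer than two replicates is refused by name", {
  design <- full_design(2)[-1, ]
  expr <- null_expr(design, 5)
  expect_error(fit_gene_models(expr, design), "control_L")
})

test_that("the EB prior is recovered from its own hierarchy", {
  # sample variances s2 ~ s0^2 d0/chisq_d0 * chisq_d/d at 20000 genes
  set.seed(19)
  d0 <- 4; s02 <- 0.05; d <- 12; n <- 20000
  sigma2 <- s02 * d0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, d) / d
  prior <- estimate_eb_prior(s2, d)
  expect_lt(abs(prior$df_prior - d0) / d0, 0.15)
  expect_lt(abs(prior$var_prior - s02) / s02, 0.05)
})

test_that("prior estimation agrees with the reference moment estimator", {
  set.seed(23)
  s2 <- 0.1 * 6 / rchisq(3000, 6) * rchisq(3000, 10) / 10
  prior <- estimate_eb_prior(s2, 10)
  ref <- limma::fitFDist(s2, df1 = 10)
  expect_equal(prior$df_prior, ref$df2, tolerance = 1e-6)
  expect_equal(prior$var_prior, ref$scale, tolerance = 1e-6)
})

test_that("prior degenerates sensibly", {
  expect_error(estimate_eb_prior(rep(0, 100), 10), "degenerate")
  # equal variances: no spread beyond the sampling floor -> d0 = Inf
  eq <- suppressWarnings(estimate_eb_prior(rep(0.25, 200), 1e6))
  expect_identical(eq$df_prior, Inf)
  expect_equal(eq$var_prior, 0.25, tolerance = 1e-3)
  # two well-separated variance populations -> finite d0
  two <- estimate_eb_prior(rep(c(0.01, 1), each = 300), 50)
  expect_true(is.finite(two$df_prior))
})

test_that("moderated t reduces to the classical pooled t at d0 = 0", {
  set.seed(31)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    design <- two_cell_design(n1, n2)
    a <- rnorm(n1, 8, 0.5); b <- rnorm(n2, 8, 0.5)
    expr <- matrix(c(a, b), 1, n1 + n2,
                   dimnames = list("g1", design$sample_id))
    fit <- fit_gene_models(expr, design)
    res <- moderated_t(fit, list(df_prior = 0, var_prior = 1), "control_LvsR")
    ref <- classical_pooled_t(a, b)
    expect_equal(res$t, ref$t, tolerance = 1e-12)
    expect_equal(res$df_total, ref$df)
    expect_equal(res$p, ref$p, tolerance = 1e-12)
  }
})

test_that("moderated t uses s0^2 everywhere at d0 = Inf and matches the
           formula at finite d0", {
  design <- full_design(3)
  set.seed(37)
  expr <- null_expr(design, 10)
  fit <- fit_gene_models(expr, design)

  inf <- moderated_t(fit, list(df_prior = Inf, var_prior = 0.04),
                     "susceptible_LvsR")
  delta <- fit$means[, "susceptible_L"] - fit$means[, "susceptible_R"]
  expect_equal(inf$t, unname(delta / sqrt(0.04 * (1 / 3 + 1 / 3))))
  expect_equal(inf$p, unname(2 * pnorm(-abs(inf$t))))

  # hand-plugged moderation formula, d0 = 4, s0^2 = 0.05
  fin <- moderated_t(fit, list(df_prior = 4, var_prior = 0.05),
                     "susceptible_LvsR")
  s2post <- (4 * 0.05 + 12 * fit$s2) / (4 + 12)
  t_ref <- delta / sqrt(s2post * (2 / 3))
  expect_equal(fin$t, unname(t_ref), tolerance = 1e-12)
  expect_equal(fin$df_total, rep(16, 10))
  expect_equal(fin$p, unname(2 * pt(-abs(t_ref), 16)), tolerance = 1e-12)

  expect_error(moderated_t(fit, list(df_prior = 4, var_prior = 0.05),
                           "no_such_contrast"), "unknown contrast")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, "BH"))
    expect_true(all(q >= p))
    # monotone in raw-p rank
    expect_true(all(diff(q[order(p)]) >= 0))
  }
})

test_that("run_contrasts produces the seven tables with shared gene sets", {
  cfg <- sim_config(n_genes = 400, seed = 6L)
  sim <- simulate_bilateral_expression(cfg)
  de <- run_contrasts(sim$expr, sim$design)
  expect_named(de$tables, lateral_contrasts()$name)
  genes <- de$tables[[1]]$gene
  for (tb in de$tables) {
    expect_identical(tb$gene, genes)
    expect_true(all(tb$fdr >= tb$p - 1e-12))
    expect_true(all(tb$fdr >= 0 & tb$fdr <= 1))
    # log2fc sign equals the sign of the mean difference by construction
    expect_identical(sign(tb$t), sign(tb$log2fc))
  }
  # planted susceptible L/R effects concentrate in their own contrast
  hits <- vapply(de$tables, function(tb) sum(tb$significant), integer(1))
  expect_gt(hits[["susceptible_LvsR"]], 50)
  expect_lt(max(hits[c("resilient_LvsR", "control_LvsR")]), 5)
  called <- de$tables$susceptible_LvsR
  planted <- sim$truth$gene[sim$truth$lateral_susceptible]
  expect_gt(mean(called$significant[match(planted, called$gene)]), 0.6)
})

test_that("null data yield almost no discoveries", {
  cfg <- sim_config(n_genes = 1000, n_lateral_genes = 0, seed = 17L)
  sim <- simulate_bilateral_expression(cfg)
  de <- run_contrasts(sim$expr, sim$design)
  total <- sum(vapply(de$tables, function(tb) sum(tb$significant), integer(1)))
  expect_lte(total, 3)
})
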