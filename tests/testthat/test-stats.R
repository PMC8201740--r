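test_that("Student's t matches hand pooled-variance arithmetic", {
  same <- student_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic[["t"]], 0)
  expect_equal(same$p, 1)

  res <- student_t(c(1, 2, 3), c(4, 5, 6))
  # pooled s2 = 1, se = sqrt(2/3), t = -3 / se, df = 4
  t_ref <- -3 / sqrt(2 / 3)
  expect_equal(res$statistic[["t"]], t_ref, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-abs(t_ref), 4), tolerance = 1e-12)

  zero_diff <- student_t(c(5, 6, 7), c(5, 6, 7), paired = TRUE)
  expect_equal(zero_diff$p, 1)
  pair <- student_t(c(2, 4, 6, 8), c(1, 3, 5, 9), paired = TRUE)
  ref <- t.test(c(1, 1, 1, -1))
  expect_equal(pair$statistic[["t"]], unname(ref$statistic))
  expect_equal(pair$df, 3)

  expect_error(student_t(1, c(1, 2)), ">= 2")
  expect_error(student_t(c(1, 2), c(1, 2, 3), paired = TRUE), "equal")
  # all values equal across both groups: p = 1 convention, not an error
  flat <- student_t(rep(2, 3), rep(2, 4))
  expect_equal(flat$p, 1)
})

test_that("Mann-Whitney T is the smaller group's rank sum, with exact
           enumeration agreeing with an independent oracle", {
  # completely separated samples: extremal T
  lo <- mann_whitney(c(1, 2, 3), c(10, 11, 12, 13))
  expect_equal(lo$statistic[["T"]], 1 + 2 + 3)
  hi <- mann_whitney(c(10, 11, 12), c(1, 2, 3, 4))
  expect_equal(hi$statistic[["T"]], 5 + 6 + 7)
  # identical multisets: p about 1
  eq <- mann_whitney(c(1, 2, 3), c(3, 2, 1))
  expect_gt(eq$p, 0.99)

  set.seed(51)
  for (i in 1:10) {
    a <- round(rnorm(5, 0, 2), 1)
    b <- round(rnorm(9, 0.5, 2), 1)
    res <- mann_whitney(a, b, method = "exact")
    # independent oracle: loop over every assignment of pooled ranks
    r <- rank(c(a, b))
    T_ref <- sum(r[1:5])
    expect_equal(res$statistic[["T"]], T_ref)
    idx <- combn(14, 5)
    mu <- 5 * 15 / 2
    count <- 0L
    for (j in seq_len(ncol(idx)))
      if (abs(sum(r[idx[, j]]) - mu) >= abs(T_ref - mu) - 1e-12)
        count <- count + 1L
    expect_equal(res$p, count / ncol(idx))
  }

  # no-ties exact p agrees with the reference distribution implementation
  a <- c(1.1, 3.2, 5.6, 7.1); b <- c(2.2, 4.1, 6.3, 8.4, 9.9)
  expect_equal(mann_whitney(a, b, method = "exact")$p,
               wilcox.test(a, b, exact = TRUE)$p.value)
})

test_that("Mann-Whitney normal approximation tracks the exact p", {
  set.seed(53)
  worst <- 0
  for (i in 1:30) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    a <- round(rnorm(n1), 1); b <- round(rnorm(n2, 0.4), 1)
    pe <- mann_whitney(a, b, method = "exact")$p
    pa <- mann_whitney(a, b, method = "approx")$p
    worst <- max(worst, abs(pe - pa))
  }
  expect_lt(worst, 0.05)
})

test_that("Kruskal-Wallis H matches hand tie-corrected arithmetic", {
  same <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3),
                              c = c(1, 2, 3)))
  expect_equal(same$statistic[["H"]], 0)
  expect_equal(same$df, 2)

  g <- list(a = c(2.1, 2.1, 3.5), b = c(4.2, 5.0, 5.0, 6.1), c = c(1.0, 7.3))
  res <- kruskal_wallis(g)
  # oracle: H = [12/(N(N+1)) sum R_i^2/n_i - 3(N+1)] / tie correction
  x <- unlist(g); r <- rank(x); N <- length(x)
  Ri <- tapply(r, rep(names(g), lengths(g)), sum)
  H0 <- 12 / (N * (N + 1)) * sum(Ri^2 / lengths(g)) - 3 * (N + 1)
  ties <- table(r)
  H_ref <- H0 / (1 - sum(ties^3 - ties) / (N^3 - N))
  expect_equal(res$statistic[["H"]], H_ref, tolerance = 1e-12)
  expect_equal(res$df, length(g) - 1)

  expect_error(kruskal_wallis(list(a = 1:3, b = numeric(0), c = 1:3)),
               "empty")
  expect_error(kruskal_wallis(list(a = 1:3, b = 1:3)), ">= 3")
})

test_that("Kruskal-Wallis post hoc flags the separated group", {
  g <- list(ctl = c(5.1, 5.4, 5.2, 5.3, 5.5, 5.15, 5.45, 5.25),
            res = c(5.2, 5.5, 5.3, 5.6, 5.4, 5.35, 5.55, 5.65),
            sus = c(8.1, 8.4, 8.2, 8.6, 8.3, 8.15, 8.45, 8.25))
  res <- kruskal_wallis(g)
  expect_lt(res$p, 0.05)
  ph <- res$post_hoc
  expect_equal(nrow(ph), 3)
  expect_true(ph$significant[ph$comparison == "ctl vs sus"])
  expect_true(ph$significant[ph$comparison == "res vs sus"])
  expect_false(ph$significant[ph$comparison == "ctl vs res"])
  # no post hoc without a significant omnibus
  null <- kruskal_wallis(list(a = c(1, 5, 3), b = c(2, 4, 6), c = c(3, 1, 5)))
  expect_null(null$post_hoc)
})

test_that("two-way ANOVA recovers a hand-computed balanced decomposition", {
  df <- data.frame(
    y = c(10, 12, 20, 22, 11, 13, 30, 34),
    a = rep(c("a1", "a2"), each = 4),
    b = rep(rep(c("b1", "b2"), each = 2), 2))
  res <- two_way_anova(df, "y", "a", "b")
  # oracle: explicit balanced two-way sums of squares
  gm <- mean(df$y)
  ma <- tapply(df$y, df$a, mean); mb <- tapply(df$y, df$b, mean)
  mc <- tapply(df$y, interaction(df$a, df$b), mean)
  ss_a <- 4 * sum((ma - gm)^2)
  ss_b <- 4 * sum((mb - gm)^2)
  ss_cells <- 2 * sum((mc - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_err <- sum((df$y - mc[interaction(df$a, df$b)])^2)
  expect_equal(res$terms$statistic,
               c(ss_a / (ss_err / 4), ss_b / (ss_err / 4),
                 ss_ab / (ss_err / 4)), tolerance = 1e-10)
  # conservation: total SS = sum of term SS + residual
  expect_equal(ss_a + ss_b + ss_ab + ss_err, sum((df$y - gm)^2),
               tolerance = 1e-10)
  expect_true(res$balanced)
  expect_equal(res$ms_residual, ss_err / 4)
})

test_that("two-way ANOVA handles additive, unbalanced and degenerate input", {
  # additive construction: interaction F essentially zero
  grid <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"), r = 1:3)
  grid$y <- ifelse(grid$a == "a2", 2, 0) + ifelse(grid$b == "b2", 5, 0) +
    c(-0.1, 0, 0.1)[grid$r]  # replicate offsets shared by all cells
  add <- two_way_anova(grid, "y", "a", "b")
  expect_lt(add$terms$statistic[3], 1e-10)

  # unbalanced data switch to Type-II SS and still run
  unb <- grid[-1, ]
  res <- two_way_anova(unb, "y", "a", "b")
  expect_false(res$balanced)
  expect_equal(nrow(res$terms), 3)

  bad <- grid[grid$a != "a1" | grid$b != "b1", ]
  expect_error(two_way_anova(bad, "y", "a", "b"), "empty cell")
})

test_that("two-way ANOVA post hoc runs Holm-Sidak simple effects", {
  set.seed(61)
  df <- expand.grid(g = c("ctl", "sus"), hemi = c("L", "R"), r = 1:6)
  df$y <- rnorm(nrow(df), 0, 0.5) +
    ifelse(df$g == "sus" & df$hemi == "R", 3, 0)
  res <- two_way_anova(df, "y", "g", "hemi")
  expect_lt(res$p, 0.05)  # interaction driven by the sus/R cell
  ph <- res$post_hoc
  expect_false(is.null(ph))
  expect_true(all(ph$p_adj >= ph$p_raw - 1e-12))
  hit <- ph$significant[grepl("ctl vs sus \\(within R\\)", ph$comparison)]
  miss <- ph$significant[grepl("ctl vs sus \\(within L\\)", ph$comparison)]
  expect_true(hit)
  expect_false(miss)
})

test_that("mixed RM ANOVA matches hand-computed sums of squares", {
  # 2 groups x 4 subjects x 2 within levels
  df <- data.frame(
    subj = rep(paste0("s", 1:8), each = 2),
    grp = rep(c("ctl", "str"), each = 8),
    cond = rep(c("no_target", "target"), 8),
    y = c(30, 55, 28, 60, 35, 58, 31, 52,   # ctl subjects
          33, 36, 29, 31, 36, 30, 32, 35))  # str subjects
  res <- two_way_rm_anova(df, "y", "grp", "cond", "subj")

  # oracle: textbook mixed-design decomposition from cell/subject means
  gm <- mean(df$y)
  mg <- tapply(df$y, df$grp, mean)
  mw <- tapply(df$y, df$cond, mean)
  ms <- tapply(df$y, df$subj, mean)
  cell <- tapply(df$y, interaction(df$grp, df$cond), mean)
  subj_grp <- tapply(df$grp, df$subj, function(x) x[1])
  ss_b <- 8 * sum((mg - gm)^2)
  ss_subj <- 2 * sum((ms - mg[subj_grp[names(ms)]])^2)
  ss_w <- 8 * sum((mw - gm)^2)
  ss_cells <- 4 * sum((cell - gm)^2)
  ss_int <- ss_cells - ss_b - ss_w
  ss_tot <- sum((df$y - gm)^2)
  ss_err <- ss_tot - ss_b - ss_subj - ss_w - ss_int

  expect_equal(unname(res$ss),
               c(ss_b, ss_subj, ss_w, ss_int, ss_err), tolerance = 1e-10)
  # F ratios against the correct error strata
  expect_equal(res$terms$statistic[1], (ss_b / 1) / (ss_subj / 6),
               tolerance = 1e-10)
  expect_equal(res$terms$statistic[2], (ss_w / 1) / (ss_err / 6),
               tolerance = 1e-10)
  expect_equal(res$terms$statistic[3], (ss_int / 1) / (ss_err / 6),
               tolerance = 1e-10)
  # exact SS conservation
  expect_equal(sum(res$ss), ss_tot, tolerance = 1e-12)
  # the interaction here is real: post hoc present with adjusted >= raw
  expect_false(is.null(res$post_hoc))
  expect_true(all(res$post_hoc$p_adj >= res$post_hoc$p_raw - 1e-12))
})

test_that("RM ANOVA rejects incomplete subjects and flat within effects
           give F near zero", {
  df <- data.frame(subj = rep(paste0("s", 1:6), each = 2),
                   grp = rep(c("g1", "g2"), each = 6),
                   cond = rep(c("w1", "w2"), 6),
                   y = rnorm(12))
  expect_error(two_way_rm_anova(df[-1, ], "y", "grp", "cond", "subj"),
               "every within-factor level")

  # per-subject deviations that cancel within each group: the condition
  # cell means are identical, so the within-factor F is exactly zero while
  # residual error stays positive
  base <- c(10, 11, 12, 20, 21, 22)
  e <- c(1, -1, 0, 2, -2, 0)
  flat <- data.frame(subj = rep(paste0("s", 1:6), each = 2),
                     grp = rep(c("g1", "g2"), each = 6),
                     cond = rep(c("w1", "w2"), 6),
                     y = as.vector(rbind(base + e, base - e)))
  res <- two_way_rm_anova(flat, "y", "grp", "cond", "subj")
  expect_lt(res$terms$statistic[2], 1e-10)
})

test_that("Holm-Sidak adjustment follows its closed form", {
  expect_equal(holm_sidak(0.2), 0.2)
  expect_equal(holm_sidak(0), 0)
  p <- rep(0.03, 4)
  expect_equal(holm_sidak(p), rep(1 - (1 - 0.03)^4, 4))
  set.seed(81)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    adj <- holm_sidak(p)
    expect_true(all(adj >= p - 1e-12))
    # independent oracle: loop over the sorted step-down definition
    o <- order(p)
    ref <- numeric(length(p))
    running <- 0
    for (k in seq_along(p)) {
      val <- 1 - (1 - p[o[k]])^(length(p) - k + 1)
      running <- max(running, val)
      ref[o[k]] <- min(1, running)
    }
    expect_equal(adj, ref)
  }
})
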