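#' Holm-Sidak step-down adjustment
#'
#' Sort p-values ascending; the i-th smallest becomes
#' \eqn{1 - (1 - p_{(i)})^{m - i + 1}}, then a running maximum enforces
#' monotonicity; values are returned in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order; always >= the input.
#' @export
holm_sidak <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

new_test_result <- function(test, statistic, df, p, post_hoc = NULL, ...) {
  structure(c(list(test = test, statistic = statistic, df = df, p = p,
                   post_hoc = post_hoc), list(...)),
            class = "lat_test")
}

#' @export
print.lat_test <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s: %s = %.4g, df = %s, p = %.4g\n", x$test,
              names(x$statistic)[1] %||% "stat", x$statistic[1], dfs, x$p))
  if (!is.null(x$terms)) {
    cat("terms:\n"); print(x$terms, row.names = FALSE)
  }
  if (!is.null(x$post_hoc) && nrow(x$post_hoc)) {
    cat("post hoc:\n"); print(x$post_hoc, row.names = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-tailed Student's t-test
#'
#' Pooled-variance two-sample t, or (paired) a one-sample t on the
#' differences. Degenerate spread with equal means yields t = 0, p = 1 rather
#' than an error, so constant synthetic inputs flow through the pipeline.
#'
#' @param group_a,group_b Numeric vectors; n >= 2 each, equal n if paired.
#' @param paired Logical.
#' @return A \code{"lat_test"} result with \code{statistic} (t), \code{df},
#'   \code{p}.
#' @export
student_t <- function(group_a, group_b, paired = FALSE) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (paired && length(a) != length(b))
    stopf("paired test needs equal group sizes")
  if (length(a) < 2L || length(b) < 2L)
    stopf("need >= 2 observations per group")
  if (paired) {
    d <- a - b
    if (var(d) == 0) {
      t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
      return(new_test_result("paired t-test", c(t = t), length(d) - 1L, p))
    }
    ht <- t.test(d)
    return(new_test_result("paired t-test", c(t = unname(ht$statistic)),
                           unname(ht$parameter), ht$p.value))
  }
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    delta <- mean(a) - mean(b)
    t <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
    return(new_test_result("Student's t-test", c(t = t),
                           length(a) + length(b) - 2L, p))
  }
  ht <- t.test(a, b, var.equal = TRUE)
  new_test_result("Student's t-test", c(t = unname(ht$statistic)),
                  unname(ht$parameter), ht$p.value)
}

#' Mann-Whitney rank-sum test
#'
#' The reported statistic T is the sum of the ranks of the smaller group
#' (ties in size resolved toward the first argument) — the convention of
#' rank-sum software reports such as "T = 54". The p-value comes from exact
#' enumeration of rank assignments when the smaller group has <= 8
#' observations (or when forced), otherwise from the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param group_a,group_b Numeric vectors, n >= 1 each.
#' @param method \code{"auto"} (exact when min(n) <= 8), \code{"exact"}, or
#'   \code{"approx"}.
#' @return A \code{"lat_test"} result with \code{statistic} (T), \code{p} and
#'   \code{method}; df is NA (rank test).
#' @export
mann_whitney <- function(group_a, group_b,
                         method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (!length(a) || !length(b)) stopf("both groups need >= 1 observation")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  ra <- sum(r[seq_len(n1)]); rb <- sum(r) - ra
  small_first <- n1 <= n2
  T_obs <- if (small_first) ra else rb
  n_small <- min(n1, n2)
  if (method == "auto") method <- if (n_small <= 8L) "exact" else "approx"
  if (method == "exact") {
    sums <- combn(r, n_small, FUN = sum)
    mu <- n_small * (N + 1) / 2
    p <- mean(abs(sums - mu) >= abs(T_obs - mu) - 1e-12)
  } else {
    mu <- n_small * (N + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    v <- n1 * n2 / 12 * (N + 1 - tie_term)
    z <- (abs(T_obs - mu) - 0.5) / sqrt(v)
    p <- 2 * stats::pnorm(-max(z, 0))
  }
  new_test_result("Mann-Whitney rank sum test", c(T = T_obs), NA_real_,
                  min(p, 1), method = method)
}

#' Kruskal-Wallis test with Tukey-type post hoc on mean ranks
#'
#' Tie-corrected H on k - 1 degrees of freedom (via \code{kruskal.test}).
#' When significant at \code{alpha}, pairwise groups are compared by a
#' Tukey-type test on mean ranks: the studentized-range statistic
#' \eqn{q = |\bar R_i - \bar R_j| / \sqrt{(S^2/2)(1/n_i + 1/n_j)}} with
#' \eqn{S^2} the tie-corrected rank variance \eqn{N(N+1)/12 \cdot c},
#' referred to the range distribution with infinite df.
#'
#' @param groups Named list of numeric vectors (>= 3 groups, none empty).
#' @param alpha Post-hoc trigger and flag threshold (default 0.05).
#' @return A \code{"lat_test"} result: \code{statistic} (H), \code{df},
#'   \code{p}, and \code{post_hoc} (comparison, q, adjusted p, significant)
#'   when triggered.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 3L)
    stopf("need a list of >= 3 groups")
  if (any(!lengths(groups))) stopf("empty group in Kruskal-Wallis input")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  ht <- kruskal.test(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  r <- rank(x)
  N <- length(x)
  rbar <- tapply(r, g, mean)[names(groups)]
  n <- lengths(groups)
  ties <- table(r)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  S2 <- N * (N + 1) / 12 * correction
  post <- NULL
  if (ht$p.value < alpha) {
    prs <- combn(names(groups), 2, simplify = FALSE)
    post <- do.call(rbind, lapply(prs, function(pr) {
      q <- abs(rbar[pr[1]] - rbar[pr[2]]) /
        sqrt(S2 / 2 * (1 / n[pr[1]] + 1 / n[pr[2]]))
      p_adj <- ptukey(q, nmeans = length(groups), df = Inf,
                      lower.tail = FALSE)
      data.frame(comparison = paste(pr, collapse = " vs "),
                 q = unname(q), p_adj = unname(p_adj),
                 significant = p_adj < alpha, stringsAsFactors = FALSE)
    }))
  }
  new_test_result("Kruskal-Wallis rank ANOVA",
                  c(H = unname(ht$statistic)), unname(ht$parameter),
                  ht$p.value, post_hoc = post)
}

#' Two-way ANOVA with Holm-Sidak simple-effect post hoc
#'
#' Type-I (sequential) sums of squares on balanced data, Type-II on
#' unbalanced. When any main effect or interaction is significant at
#' \code{alpha}, simple effects are tested: pairwise comparisons of one
#' factor's levels within each level of the other, using the model's pooled
#' residual variance, adjusted by Holm-Sidak within each comparison family.
#'
#' @param data Long-format data.frame.
#' @param response,factor_a,factor_b Column names.
#' @param alpha Post-hoc trigger / flag threshold.
#' @return A \code{"lat_test"} result: \code{terms} (data.frame of df, F, p
#'   per term), headline \code{statistic}/\code{df}/\code{p} taken from the
#'   interaction, and \code{post_hoc} when triggered.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b, alpha = 0.05) {
  df <- as.data.frame(data)
  for (col in c(response, factor_a, factor_b))
    if (!col %in% names(df)) stopf("column '%s' not in data", col)
  df$.y <- df[[response]]
  df$.A <- factor(df[[factor_a]])
  df$.B <- factor(df[[factor_b]])
  counts <- table(df$.A, df$.B)
  if (any(counts == 0)) stopf("empty cell in the two-way design")
  balanced <- length(unique(as.vector(counts))) == 1L
  fit <- lm(.y ~ .A * .B, data = df)
  if (balanced) {
    an <- anova(fit)
  } else {
    an <- car::Anova(fit, type = 2)
  }
  rn <- rownames(an)
  keep <- rn %in% c(".A", ".B", ".A:.B")
  label <- c(.A = factor_a, .B = factor_b,
             `.A:.B` = paste0(factor_a, " x ", factor_b))
  terms <- data.frame(term = unname(label[rn[keep]]),
                      df = an$Df[keep],
                      statistic = an$`F value`[keep],
                      p = an$`Pr(>F)`[keep], stringsAsFactors = FALSE)
  res_row <- which(rn == "Residuals")
  df_res <- an$Df[res_row]
  ms_res <- an$`Sum Sq`[res_row] / df_res
  post <- NULL
  if (any(terms$p < alpha, na.rm = TRUE))
    post <- simple_effects(df, ms_res, df_res, factor_a, factor_b, alpha)
  inter <- nrow(terms)
  new_test_result("two-way ANOVA",
                  c(F = terms$statistic[inter]),
                  c(terms$df[inter], df_res), terms$p[inter],
                  post_hoc = post, terms = terms,
                  balanced = balanced, ms_residual = ms_res)
}

# Pairwise simple-effect t comparisons for a two-factor layout, using a
# common residual variance; Holm-Sidak adjusted within each family
# ("factor X within <level of the other>").
simple_effects <- function(df, ms_err, df_err, factor_a, factor_b, alpha,
                           between_only = NULL) {
  fams <- list(c(".A", ".B", factor_a), c(".B", ".A", factor_b))
  rows <- list()
  for (fam in fams) {
    vary <- fam[1]; fix <- fam[2]; vary_name <- fam[3]
    for (lv in levels(df[[fix]])) {
      sub <- df[df[[fix]] == lv, ]
      lvls <- levels(droplevels(sub[[vary]]))
      if (length(lvls) < 2L) next
      prs <- combn(lvls, 2, simplify = FALSE)
      fam_rows <- lapply(prs, function(pr) {
        y1 <- sub$.y[sub[[vary]] == pr[1]]
        y2 <- sub$.y[sub[[vary]] == pr[2]]
        se <- sqrt(ms_err * (1 / length(y1) + 1 / length(y2)))
        t <- (mean(y1) - mean(y2)) / se
        data.frame(comparison = sprintf("%s: %s vs %s (within %s)",
                                        vary_name, pr[1], pr[2], lv),
                   t = t, p_raw = 2 * pt(-abs(t), df_err),
                   stringsAsFactors = FALSE)
      })
      fam_df <- do.call(rbind, fam_rows)
      fam_df$p_adj <- holm_sidak(fam_df$p_raw)
      rows[[length(rows) + 1L]] <- fam_df
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Two-way repeated-measures (mixed) ANOVA
#'
#' One between-subjects factor and one within-subjects factor, every subject
#' measured at every within level. The between effect is tested against the
#' subjects-within-groups mean square; the within effect and the interaction
#' against the within x subjects residual. Holm-Sidak simple effects follow
#' when any term is significant: the within factor compared inside each group
#' (against the within-subjects error), and groups compared inside each
#' within level (against the pooled between/within error).
#'
#' @param data Long-format data.frame.
#' @param response,between,within,subject Column names.
#' @param alpha Post-hoc trigger / flag threshold.
#' @return A \code{"lat_test"} result with \code{terms}, headline interaction
#'   \code{statistic}/\code{df}/\code{p}, the stratum sums of squares
#'   (\code{ss}), and \code{post_hoc} when triggered.
#' @export
two_way_rm_anova <- function(data, response, between, within, subject,
                             alpha = 0.05) {
  df <- as.data.frame(data)
  for (col in c(response, between, within, subject))
    if (!col %in% names(df)) stopf("column '%s' not in data", col)
  df$.y <- df[[response]]
  df$.B <- factor(df[[between]])
  df$.W <- factor(df[[within]])
  df$.S <- factor(df[[subject]])
  tab <- table(df$.S, df$.W)
  if (any(tab != 1L))
    stopf("each subject must be measured exactly once at every within-factor level")
  # subjects must be nested in the between factor
  if (any(rowSums(table(df$.S, df$.B) > 0) != 1L))
    stopf("each subject must belong to exactly one between-factor group")

  fit <- aov(.y ~ .B * .W + Error(.S), data = df)
  sm <- summary(fit)
  between_tab <- sm[["Error: .S"]][[1]]
  within_tab <- sm[["Error: Within"]][[1]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    list(df = tab$Df[i], ss = tab$`Sum Sq`[i], f = tab$`F value`[i],
         p = tab$`Pr(>F)`[i])
  }
  bet <- pick(between_tab, ".B")
  subj <- pick(between_tab, "Residuals")
  wit <- pick(within_tab, ".W")
  inter <- pick(within_tab, ".B:.W")
  err <- pick(within_tab, "Residuals")

  terms <- data.frame(
    term = c(between, within, paste0(between, " x ", within)),
    df = c(bet$df, wit$df, inter$df),
    df_error = c(subj$df, err$df, err$df),
    statistic = c(bet$f, wit$f, inter$f),
    p = c(bet$p, wit$p, inter$p), stringsAsFactors = FALSE)
  ss <- c(between = bet$ss, subjects = subj$ss, within = wit$ss,
          interaction = inter$ss, error = err$ss)

  post <- NULL
  if (any(terms$p < alpha, na.rm = TRUE)) {
    ms_w <- err$ss / err$df
    ms_pooled <- (subj$ss + err$ss) / (subj$df + err$df)
    rows <- list()
    # within-factor simple effects inside each group
    for (g in levels(df$.B)) {
      sub <- df[df$.B == g, ]
      prs <- combn(levels(df$.W), 2, simplify = FALSE)
      fam <- do.call(rbind, lapply(prs, function(pr) {
        m1 <- mean(sub$.y[sub$.W == pr[1]])
        m2 <- mean(sub$.y[sub$.W == pr[2]])
        n_g <- length(unique(sub$.S))
        t <- (m1 - m2) / sqrt(2 * ms_w / n_g)
        data.frame(comparison = sprintf("%s: %s vs %s (within %s %s)",
                                        within, pr[1], pr[2], between, g),
                   t = t, p_raw = 2 * pt(-abs(t), err$df),
                   stringsAsFactors = FALSE)
      }))
      fam$p_adj <- holm_sidak(fam$p_raw)
      rows[[length(rows) + 1L]] <- fam
    }
    # between-factor simple effects inside each within level (pooled error)
    df_pool <- subj$df + err$df
    for (w in levels(df$.W)) {
      sub <- df[df$.W == w, ]
      prs <- combn(levels(df$.B), 2, simplify = FALSE)
      fam <- do.call(rbind, lapply(prs, function(pr) {
        y1 <- sub$.y[sub$.B == pr[1]]; y2 <- sub$.y[sub$.B == pr[2]]
        t <- (mean(y1) - mean(y2)) /
          sqrt(ms_pooled * (1 / length(y1) + 1 / length(y2)))
        data.frame(comparison = sprintf("%s: %s vs %s (within %s %s)",
                                        between, pr[1], pr[2], within, w),
                   t = t, p_raw = 2 * pt(-abs(t), df_pool),
                   stringsAsFactors = FALSE)
      }))
      fam$p_adj <- holm_sidak(fam$p_raw)
      rows[[length(rows) + 1L]] <- fam
    }
    post <- do.call(rbind, rows)
    post$significant <- post$p_adj < alpha
    rownames(post) <- NULL
  }
  new_test_result("two-way RM ANOVA",
                  c(F = inter$f), c(inter$df, err$df), inter$p,
                  post_hoc = post, terms = terms, ss = ss)
}
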