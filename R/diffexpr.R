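#' The seven pairwise contrasts of the bilateral stress design
#'
#' Three within-group left-vs-right contrasts and four group-vs-control
#' contrasts within hemisphere. Each contrast is the difference of condition
#' means, first-named cell minus second, so the left-vs-right contrasts equal
#' the per-gene laterality score (log2 L/R) of their group.
#'
#' @return data.frame with columns \code{name}, \code{cellA}, \code{cellB}
#'   (cells labelled \code{group_hemisphere}).
#' @export
lateral_contrasts <- function() {
  data.frame(
    name = c("susceptible_LvsR", "resilient_LvsR", "control_LvsR",
             "susceptible_vs_control_L", "susceptible_vs_control_R",
             "resilient_vs_control_R", "resilient_vs_control_L"),
    cellA = c("susceptible_L", "resilient_L", "control_L",
              "susceptible_L", "susceptible_R", "resilient_R", "resilient_L"),
    cellB = c("susceptible_R", "resilient_R", "control_R",
              "control_L", "control_R", "control_R", "control_L"),
    stringsAsFactors = FALSE)
}

#' Fit per-gene cell-means linear models
#'
#' One linear model per gene over all arrays, parameterized by the condition
#' (group x hemisphere) cell means, with a single pooled residual variance
#' s_g^2 on d_g = n - (number of cells) degrees of freedom. For the balanced
#' 3 x 2 design with r replicates, d_g = 6(r - 1) for every gene.
#'
#' @param expr Gene x sample matrix of (normalized) log2 intensities.
#' @param design Sample design data.frame (\code{sample_id}, \code{group},
#'   \code{hemisphere}); every condition must have >= 2 replicates.
#' @return Object of class \code{"gene_fits"}: list with
#'   \code{means} (gene x cell matrix), \code{s2} (residual variances),
#'   \code{df} (residual df, scalar), and \code{cells} (data.frame of cell
#'   label, group, hemisphere, n).
#' @export
fit_gene_models <- function(expr, design) {
  expr <- as.matrix(expr)
  design <- check_design(design, colnames(expr))
  cell <- paste(design$group, design$hemisphere, sep = "_")
  tab <- table(cell)
  thin <- names(tab)[tab < 2L]
  if (length(thin))
    stopf("condition(s) with < 2 replicates: %s", paste(thin, collapse = ", "))
  cells <- sort(names(tab))
  # indicator matrix scaled to compute cell means by one multiplication
  Z <- vapply(cells, function(cl) (cell == cl) / sum(cell == cl),
              numeric(length(cell)))
  means <- expr %*% Z
  fitted <- means[, match(cell, cells), drop = FALSE]
  resid_df <- ncol(expr) - length(cells)
  s2 <- rowSums((expr - fitted)^2) / resid_df
  cell_info <- data.frame(cell = cells,
                          group = sub("_[LR]$", "", cells),
                          hemisphere = sub("^.*_", "", cells),
                          n = as.integer(tab[cells]),
                          stringsAsFactors = FALSE)
  structure(list(means = means, s2 = s2, df = resid_df, cells = cell_info),
            class = "gene_fits")
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled inverse-chi-square hierarchy
#' \eqn{\sigma_g^2 \sim s_0^2 d_0 / \chi^2_{d_0}} to the observed residual
#' variances by moment-matching on the log scale: under the hierarchy,
#' \eqn{\log s_g^2} is \eqn{\log(s_0^2 d_0 / d_g)} plus the log of an
#' F-distributed ratio, whose mean and variance have closed digamma/trigamma
#' forms. When the spread of \eqn{\log s_g^2} does not exceed its sampling
#' floor \eqn{\psi'(d_g/2)}, the prior degrees of freedom are infinite (all
#' gene variances equal \eqn{s_0^2}).
#'
#' @param s2 Per-gene residual variances (>= 0; zeros are dropped with a
#'   warning).
#' @param df Residual degrees of freedom, scalar or per-gene.
#' @return Object of class \code{"eb_prior"}: list with \code{df_prior} (d0,
#'   possibly \code{Inf}) and \code{var_prior} (s0^2).
#' @export
estimate_eb_prior <- function(s2, df) {
  s2 <- as.numeric(s2)
  df <- rep_len(as.numeric(df), length(s2))
  keep <- is.finite(s2) & s2 > 0 & df > 0
  if (!any(keep)) stopf("degenerate prior: no positive residual variances")
  if (sum(!keep))
    warnf("dropping %d gene(s) with zero or missing variance from prior fit",
          sum(!keep))
  s2 <- s2[keep]; df <- df[keep]
  if (length(s2) < 2L) stopf("need >= 2 genes to estimate the prior")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    var_prior <- exp(emean)
  }
  structure(list(df_prior = df_prior, var_prior = var_prior),
            class = "eb_prior")
}

#' @export
print.eb_prior <- function(x, ...) {
  cat(sprintf("Empirical-Bayes variance prior: d0 = %s, s0^2 = %.5g\n",
              format(x$df_prior, digits = 4), x$var_prior))
  invisible(x)
}

# Solve trigamma(y) = x by Newton iteration on 1/trigamma (monotone convex).
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Moderated t-statistics for one contrast
#'
#' Shrinks each gene's residual variance toward the prior,
#' \deqn{\tilde{s}_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},}
#' and tests the contrast of condition means with
#' \deqn{t_g = \frac{\Delta_g}{\tilde{s}_g \sqrt{1/n_A + 1/n_B}}}
#' on \eqn{d_0 + d_g} degrees of freedom (two-sided p). With \eqn{d_0 = 0}
#' this is the ordinary pooled-variance t on the same cells; with
#' \eqn{d_0 = \infty} every gene uses \eqn{s_0^2} and the reference
#' distribution is normal.
#'
#' @param fit A [fit_gene_models()] result.
#' @param prior An [estimate_eb_prior()] result (or a list with
#'   \code{df_prior}, \code{var_prior}).
#' @param contrast A contrast name from [lateral_contrasts()], or a list with
#'   \code{cellA}, \code{cellB} naming two fitted cells.
#' @return data.frame with \code{gene}, \code{log2fc}, \code{t},
#'   \code{df_total}, \code{p}.
#' @export
moderated_t <- function(fit, prior, contrast) {
  stopifnot(inherits(fit, "gene_fits"))
  cc <- resolve_contrast(contrast, fit$cells$cell)
  d0 <- prior$df_prior; s02 <- prior$var_prior
  if (is.null(d0) || is.null(s02) || d0 < 0 || (is.finite(d0) && s02 <= 0 && d0 > 0))
    stopf("invalid prior: need df_prior >= 0 and var_prior > 0")
  dg <- fit$df
  s2_post <- if (is.infinite(d0)) rep(s02, length(fit$s2)) else
    (d0 * s02 + dg * fit$s2) / (d0 + dg)
  nA <- fit$cells$n[match(cc$cellA, fit$cells$cell)]
  nB <- fit$cells$n[match(cc$cellB, fit$cells$cell)]
  delta <- fit$means[, cc$cellA] - fit$means[, cc$cellB]
  se <- sqrt(s2_post * (1 / nA + 1 / nB))
  t <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, sign(delta) * Inf))
  df_total <- d0 + dg
  p <- 2 * pt(-abs(t), df = df_total)
  data.frame(gene = rownames(fit$means), log2fc = delta, t = t,
             df_total = df_total, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

resolve_contrast <- function(contrast, cells) {
  if (is.character(contrast) && length(contrast) == 1L) {
    cons <- lateral_contrasts()
    i <- match(contrast, cons$name)
    if (is.na(i)) stopf("unknown contrast '%s'; see lateral_contrasts()",
                        contrast)
    contrast <- cons[i, ]
  }
  if (!all(c("cellA", "cellB") %in% names(contrast)))
    stopf("a contrast needs cellA and cellB")
  for (cl in c(contrast$cellA, contrast$cellB))
    if (!cl %in% cells) stopf("contrast cell '%s' absent from the fit", cl)
  contrast
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted value for the i-th smallest p is
#' \eqn{\min_{j \ge i} \min(1, m p_{(j)} / j)}, returned in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (q-values) in input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q <- pmin(1, m * p[o] / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Run the seven pairwise contrasts with FDR control
#'
#' Full differential-expression pass: fit the per-gene cell-means models,
#' estimate the variance prior across genes, compute moderated t-statistics
#' for each of the seven contrasts, and adjust p-values by Benjamini-Hochberg
#' within each contrast independently.
#'
#' @param expr Normalized gene x sample log2 matrix.
#' @param design Sample design data.frame.
#' @param alpha FDR significance threshold (default 0.05).
#' @param prior Optional pre-estimated prior; by default estimated from
#'   the fit.
#' @return Object of class \code{"de_results"}: list with \code{tables} (a
#'   named list of seven data.frames, each adding \code{fdr} and
#'   \code{significant} to the [moderated_t()] columns), \code{fits},
#'   \code{prior} and \code{alpha}.
#' @export
run_contrasts <- function(expr, design, alpha = 0.05, prior = NULL) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  fit <- fit_gene_models(expr, design)
  if (is.null(prior)) prior <- estimate_eb_prior(fit$s2, fit$df)
  cons <- lateral_contrasts()
  tables <- lapply(seq_len(nrow(cons)), function(i) {
    res <- moderated_t(fit, prior, cons$name[i])
    res$fdr <- bh_adjust(res$p)
    res$significant <- res$fdr < alpha
    res
  })
  names(tables) <- cons$name
  structure(list(tables = tables, fits = fit, prior = prior, alpha = alpha),
            class = "de_results")
}

#' @export
print.de_results <- function(x, ...) {
  cat(sprintf("Differential expression over %d genes, %d contrasts (FDR < %g)\n",
              nrow(x$fits$means), length(x$tables), x$alpha))
  print(x$prior)
  counts <- vapply(x$tables, function(tb) sum(tb$significant), integer(1))
  for (nm in names(counts))
    cat(sprintf("  %-26s %5d significant\n", nm, counts[nm]))
  invisible(x)
}

#' Write one TSV per contrast
#'
#' @param de A [run_contrasts()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of paths written.
#' @export
write_contrast_tables <- function(de, dir) {
  stopifnot(inherits(de, "de_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(de$tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(de$tables[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
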