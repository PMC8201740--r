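#' Configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the simulated study: cohort sizes, the bilateral
#' expression model, the planted laterality effects, and the per-group
#' sociability-index (SI) distributions. Defaults emulate the design the
#' pipeline targets: three groups (control, resilient, susceptible) x two
#' hemispheres (L, R) with triplicate arrays, gene-wise variances drawn from a
#' scaled inverse-chi-square hierarchy, a block of lateralized genes planted in
#' the susceptible group, and housekeeping genes with no effects at all.
#'
#' @param n_mice_per_group Mice simulated per behavioral group.
#' @param n_genes Total number of genes on the simulated array.
#' @param n_lateral_genes Number of genes planted with a susceptible-group
#'   left/right effect.
#' @param lateral_effect_range Length-2 numeric: planted effect magnitudes
#'   (log2 L minus R) are drawn uniformly from this interval.
#' @param frac_lateral_right_dominant Fraction of planted genes whose effect is
#'   right-dominant (negative log2 L/R).
#' @param frac_lateral_other_groups Fraction of planted genes that additionally
#'   receive an (independently drawn) effect in the resilient and control
#'   groups; default 0, i.e. laterality is susceptible-specific.
#' @param n_housekeeping Number of genes flagged housekeeping (zero group and
#'   hemisphere effects everywhere). The first three are named
#'   \code{Actb}, \code{Gapdh}, \code{B2m} so [housekeeping_check()] finds its
#'   canonical targets.
#' @param n_replicates Arrays per group x hemisphere condition.
#' @param variance_prior_df,variance_prior_scale Hyperparameters d0 and s0^2 of
#'   the scaled inverse-chi-square variance hierarchy
#'   sigma_g^2 ~ s0^2 * d0 / chisq(d0).
#' @param baseline_mean_range Length-2 numeric: per-gene baseline log2
#'   intensities are uniform on this interval.
#' @param si_distributions Named list (control, resilient, susceptible) of
#'   \code{c(mean, sd)} for the group SI distribution. Defaults 1.5/1.5/0.8
#'   match the average SI of non-defeat control, resilient and susceptible
#'   cohorts in the emulated design.
#' @param detection_fail_rate Fraction of probe x sample cells whose detection
#'   p-value exceeds 0.05 ("not detected").
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return An object of class \code{"sim_config"} (a validated list).
#' @seealso [simulate_bilateral_expression()], [simulate_behavior_cohort()]
#' @export
sim_config <- function(n_mice_per_group = 8L,
                       n_genes = 2000L,
                       n_lateral_genes = 100L,
                       lateral_effect_range = c(1, 2),
                       frac_lateral_right_dominant = 0.5,
                       frac_lateral_other_groups = 0,
                       n_housekeeping = 50L,
                       n_replicates = 3L,
                       variance_prior_df = 4,
                       variance_prior_scale = 0.05,
                       baseline_mean_range = c(6, 12),
                       si_distributions = list(
                         control = c(mean = 1.5, sd = 0.4),
                         resilient = c(mean = 1.5, sd = 0.4),
                         susceptible = c(mean = 0.8, sd = 0.3)),
                       detection_fail_rate = 0.02,
                       seed = 1L) {
  cfg <- list(n_mice_per_group = as.integer(n_mice_per_group),
              n_genes = as.integer(n_genes),
              n_lateral_genes = as.integer(n_lateral_genes),
              lateral_effect_range = as.numeric(lateral_effect_range),
              frac_lateral_right_dominant = frac_lateral_right_dominant,
              frac_lateral_other_groups = frac_lateral_other_groups,
              n_housekeeping = as.integer(n_housekeeping),
              n_replicates = as.integer(n_replicates),
              variance_prior_df = variance_prior_df,
              variance_prior_scale = variance_prior_scale,
              baseline_mean_range = as.numeric(baseline_mean_range),
              si_distributions = si_distributions,
              detection_fail_rate = detection_fail_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L || cfg$n_replicates < 1L || cfg$n_mice_per_group < 1L)
    stopf("counts (n_genes, n_replicates, n_mice_per_group) must be positive")
  if (cfg$n_lateral_genes < 0L || cfg$n_housekeeping < 0L)
    stopf("n_lateral_genes and n_housekeeping must be non-negative")
  if (cfg$n_lateral_genes + cfg$n_housekeeping > cfg$n_genes)
    stopf("n_lateral_genes + n_housekeeping (%d) exceeds n_genes (%d)",
          cfg$n_lateral_genes + cfg$n_housekeeping, cfg$n_genes)
  if (cfg$variance_prior_df <= 0 || cfg$variance_prior_scale <= 0)
    stopf("variance prior (d0, s0^2) must be positive")
  for (fr in c(cfg$frac_lateral_right_dominant, cfg$frac_lateral_other_groups,
               cfg$detection_fail_rate))
    if (fr < 0 || fr > 1) stopf("fractions must lie in [0, 1]")
  if (length(cfg$lateral_effect_range) != 2L ||
      any(cfg$lateral_effect_range < 0) ||
      diff(cfg$lateral_effect_range) < 0)
    stopf("lateral_effect_range must be an increasing non-negative pair")
  groups <- c("control", "resilient", "susceptible")
  if (!all(groups %in% names(cfg$si_distributions)))
    stopf("si_distributions must name control, resilient and susceptible")
  for (g in groups) {
    d <- cfg$si_distributions[[g]]
    if (length(d) != 2L || d[2] < 0)
      stopf("si_distributions$%s must be c(mean, sd) with sd >= 0", g)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  genes: %d (%d lateral, %d housekeeping)\n",
              x$n_genes, x$n_lateral_genes, x$n_housekeeping))
  cat(sprintf("  design: 3 groups x 2 hemispheres x %d replicates\n",
              x$n_replicates))
  cat(sprintf("  variance prior: d0 = %g, s0^2 = %g; seed = %d\n",
              x$variance_prior_df, x$variance_prior_scale, x$seed))
  invisible(x)
}

sim_gene_ids <- function(cfg) {
  ids <- sprintf("gene%05d", seq_len(cfg$n_genes))
  # canonical housekeeping names so the control report finds them
  hk_names <- c("Actb", "Gapdh", "B2m")
  n_named <- min(cfg$n_housekeeping, length(hk_names))
  if (n_named > 0L) {
    hk_idx <- hk_gene_index(cfg)
    ids[hk_idx[seq_len(n_named)]] <- hk_names[seq_len(n_named)]
  }
  ids
}

# lateral genes occupy the head of the index, housekeeping the tail
lateral_gene_index <- function(cfg) seq_len(cfg$n_lateral_genes)
hk_gene_index <- function(cfg) {
  if (cfg$n_housekeeping == 0L) return(integer(0))
  seq.int(cfg$n_genes - cfg$n_housekeeping + 1L, cfg$n_genes)
}

#' Simulate a bilateral expression study with planted lateral effects
#'
#' Draws a gene x sample log2-intensity matrix under the model
#' \deqn{x_{gs} = \mu_g + \beta_{group(s), hemi(s), g} + \epsilon_{gs},
#'   \quad \epsilon_{gs} \sim N(0, \sigma_g^2),
#'   \quad \sigma_g^2 \sim s_0^2 d_0 / \chi^2_{d_0},}
#' with a planted set of lateralized genes in the susceptible group:
#' each receives a signed effect delta (drawn from
#' \code{lateral_effect_range}) split symmetrically, +delta/2 on the left and
#' -delta/2 on the right hemisphere, so the true log2 L/R equals delta
#' exactly. Housekeeping genes carry no effects in any group. Detection
#' p-values are independent per cell: a \code{detection_fail_rate} fraction is
#' uniform on (0.05, 1] ("not detected"), the rest uniform on [0, 0.05].
#'
#' @param config A [sim_config()] object.
#' @return A list of class \code{"bilateral_sim"}:
#' \describe{
#'   \item{expr}{numeric gene x sample matrix of log2 intensities.}
#'   \item{detection_p}{matching matrix of detection p-values.}
#'   \item{design}{data.frame with \code{sample_id}, \code{group},
#'     \code{hemisphere}, \code{replicate}.}
#'   \item{truth}{ground-truth data.frame: per-gene housekeeping flag, true
#'     variance, and per-group lateral flag plus signed log2 L-R effect.}
#' }
#' @examples
#' sim <- simulate_bilateral_expression(sim_config(n_genes = 200, seed = 7))
#' dim(sim$expr)
#' head(sim$truth)
#' @export
simulate_bilateral_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  groups <- c("control", "resilient", "susceptible")
  hemis <- c("L", "R")

  design <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        hemisphere = hemis, group = groups,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("group", "hemisphere", "replicate")]
  design$sample_id <- sprintf("%s_%s_%d", design$group, design$hemisphere,
                              design$replicate)
  design <- design[, c("sample_id", "group", "hemisphere", "replicate")]

  gene_ids <- sim_gene_ids(cfg)
  with_seed(cfg$seed, {
    sigma2 <- cfg$variance_prior_scale * cfg$variance_prior_df /
      rchisq(cfg$n_genes, df = cfg$variance_prior_df)
    mu <- runif(cfg$n_genes, cfg$baseline_mean_range[1],
                cfg$baseline_mean_range[2])

    # per-group signed log2 L-R effects
    effect <- matrix(0, cfg$n_genes, 3L, dimnames = list(NULL, groups))
    lateral <- matrix(FALSE, cfg$n_genes, 3L, dimnames = list(NULL, groups))
    if (cfg$n_lateral_genes > 0L) {
      idx <- lateral_gene_index(cfg)
      draw_effect <- function(n) {
        delta <- runif(n, cfg$lateral_effect_range[1],
                       cfg$lateral_effect_range[2])
        sign <- ifelse(runif(n) < cfg$frac_lateral_right_dominant, -1, 1)
        delta * sign
      }
      effect[idx, "susceptible"] <- draw_effect(length(idx))
      lateral[idx, "susceptible"] <- TRUE
      if (cfg$frac_lateral_other_groups > 0) {
        for (g in c("resilient", "control")) {
          also <- idx[runif(length(idx)) < cfg$frac_lateral_other_groups]
          effect[also, g] <- draw_effect(length(also))
          lateral[also, g] <- TRUE
        }
      }
    }

    hemi_sign <- ifelse(design$hemisphere == "L", 0.5, -0.5)
    beta <- effect[, design$group, drop = FALSE] *
      rep(hemi_sign, each = cfg$n_genes)
    expr <- mu + beta +
      matrix(rnorm(cfg$n_genes * nrow(design), sd = sqrt(sigma2)),
             cfg$n_genes, nrow(design))
    dimnames(expr) <- list(gene_ids, design$sample_id)

    fail <- matrix(runif(length(expr)) < cfg$detection_fail_rate,
                   nrow(expr), ncol(expr))
    detp <- matrix(runif(length(expr)), nrow(expr), ncol(expr))
    detp[fail] <- 0.05 + detp[fail] * 0.95
    detp[!fail] <- detp[!fail] * 0.05
    dimnames(detp) <- dimnames(expr)
  })

  truth <- data.frame(gene = gene_ids,
                      is_housekeeping = seq_len(cfg$n_genes) %in%
                        hk_gene_index(cfg),
                      true_variance = sigma2,
                      stringsAsFactors = FALSE)
  for (g in groups) {
    truth[[paste0("lateral_", g)]] <- lateral[, g]
    truth[[paste0("effect_", g)]] <- effect[, g]
  }
  structure(list(expr = expr, detection_p = detp, design = design,
                 truth = truth, config = cfg),
            class = "bilateral_sim")
}

#' Simulate a behavioral cohort with group-specific sociability indices
#'
#' Each simulated mouse spends a fixed 50 s in the interaction zone without a
#' target; its with-target time is 50 s times an SI draw from the group's
#' \code{c(mean, sd)} normal distribution truncated at zero, so all times are
#' positive and the SI ratio follows the configured distribution. Stressed
#' mice (resilient/susceptible simulants) are then classified with
#' [classify_mouse()] under the default 0.9-1.1 exclusion band.
#'
#' @param config A [sim_config()] object.
#' @param n_per_group Number of mice per group; defaults to
#'   \code{config$n_mice_per_group}.
#' @return data.frame with \code{mouse_id}, \code{group} (the generating
#'   group), \code{stressed}, \code{time_no_target_s}, \code{time_target_s},
#'   \code{si}, and the pipeline's \code{cohort_label}.
#' @export
simulate_behavior_cohort <- function(config,
                                     n_per_group = config$n_mice_per_group) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  groups <- c("control", "resilient", "susceptible")
  no_target <- 50
  with_seed(config$seed + 1L, {
    rows <- lapply(groups, function(g) {
      par <- config$si_distributions[[g]]
      si <- rnorm_truncated0(n_per_group, par[[1]], par[[2]])
      data.frame(mouse_id = sprintf("%s_m%03d", g, seq_len(n_per_group)),
                 group = g,
                 stressed = g != "control",
                 time_no_target_s = no_target,
                 time_target_s = no_target * si,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  out$si <- compute_si(out$time_target_s, out$time_no_target_s)
  out$cohort_label <- classify_mouse(out$si, out$stressed)
  rownames(out) <- NULL
  out
}

# N(mean, sd) truncated at zero, by rejection; sd = 0 degenerates to the mean.
rnorm_truncated0 <- function(n, mean, sd) {
  if (sd < 0) stopf("negative sd in SI distribution")
  if (sd == 0) return(rep(mean, n))
  if (mean < 0) stopf("SI distribution mean must be non-negative")
  out <- rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

#' Write a simulated study to disk as plain-text files
#'
#' Writes the expression matrix and detection p-values as TSV (genes in rows,
#' header of sample ids), the design, truth and behavior tables as CSV, and
#' the configuration as YAML.
#'
#' @param sim Result of [simulate_bilateral_expression()].
#' @param dir Output directory (created if absent).
#' @param behavior Optional data.frame from [simulate_behavior_cohort()].
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(sim, dir, behavior = NULL) {
  stopifnot(inherits(sim, "bilateral_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expr = file.path(dir, "expression.tsv"),
             detection_p = file.path(dir, "detection_p.tsv"),
             design = file.path(dir, "design.csv"),
             truth = file.path(dir, "truth.csv"),
             config = file.path(dir, "config.yaml"))
  write_expression_tsv(sim$expr, paths[["expr"]])
  write_expression_tsv(sim$detection_p, paths[["detection_p"]])
  write.csv(sim$design, paths[["design"]], row.names = FALSE, quote = FALSE)
  write.csv(sim$truth, paths[["truth"]], row.names = FALSE, quote = FALSE)
  cfg <- unclass(sim$config)
  cfg$si_distributions <- lapply(cfg$si_distributions, as.list)
  yaml::write_yaml(cfg, paths[["config"]])
  if (!is.null(behavior)) {
    paths[["behavior"]] <- file.path(dir, "behavior.csv")
    write.csv(behavior, paths[["behavior"]], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}
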