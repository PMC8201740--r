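#' Per-gene laterality score (log2 L/R)
#'
#' The laterality score of a gene in a group is the log2 ratio of its mean
#' expression intensity between the left and right hemispheres. On the log2
#' scale this is simply the difference of condition means; positive scores are
#' left-dominant, negative right-dominant.
#'
#' @param mean_left,mean_right Condition means on the log2 scale. Vectorized.
#' @return \code{mean_left - mean_right}.
#' @export
laterality_score <- function(mean_left, mean_right) {
  mean_left - mean_right
}

group_lvr_contrast <- function(group) paste0(group, "_LvsR")

#' Screen genes for significant laterality per group
#'
#' A gene is lateral in a group when its left-vs-right contrast in that group
#' reaches FDR < \code{alpha}. The screened list is the union over the three
#' groups — genes lateral in at least one of control, resilient, susceptible.
#'
#' @param de A [run_contrasts()] result containing the three
#'   \code{*_LvsR} tables.
#' @param alpha FDR threshold (default, the threshold stored in \code{de}).
#' @return list with \code{sets} (named list of per-group lateral gene id
#'   vectors) and \code{union} (sorted union).
#' @export
screen_lateral_genes <- function(de, alpha = de$alpha) {
  stopifnot(inherits(de, "de_results"))
  groups <- c("control", "resilient", "susceptible")
  sets <- lapply(groups, function(g) {
    nm <- group_lvr_contrast(g)
    tb <- de$tables[[nm]]
    if (is.null(tb)) stopf("missing contrast table '%s'", nm)
    sort(tb$gene[tb$fdr < alpha])
  })
  names(sets) <- groups
  list(sets = sets, union = sort(unique(unlist(sets, use.names = FALSE))))
}

#' Per-gene laterality records over the screened gene list
#'
#' Assembles, for every gene in the screened union, its log2 L/R score in each
#' group (taken from the left-vs-right contrast estimates), the per-group
#' lateral significance flags, and its rank by the chosen group's score
#' (descending: most left-dominant first; ties broken lexicographically by
#' gene id).
#'
#' @param de A [run_contrasts()] result.
#' @param alpha FDR threshold for the lateral flags.
#' @param rank_by Group whose score orders the list (default susceptible).
#' @return data.frame with \code{gene}, \code{log2lr_<group>} and
#'   \code{lateral_<group>} per group, and \code{rank}; rows ordered by rank.
#' @export
laterality_records <- function(de, alpha = de$alpha,
                               rank_by = c("susceptible", "resilient",
                                           "control")) {
  rank_by <- match.arg(rank_by)
  screen <- screen_lateral_genes(de, alpha)
  genes <- screen$union
  rec <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (g in c("control", "resilient", "susceptible")) {
    tb <- de$tables[[group_lvr_contrast(g)]]
    i <- match(genes, tb$gene)
    rec[[paste0("log2lr_", g)]] <- tb$log2fc[i]
    rec[[paste0("lateral_", g)]] <- genes %in% screen$sets[[g]]
  }
  rec <- rank_order(rec, by = rank_by)
  rec
}

#' Rank genes by laterality score
#'
#' Orders laterality records descending by the chosen group's log2 L/R, so
#' strongly left-dominant genes head the list and strongly right-dominant
#' genes close it. Ties are broken lexicographically by gene id for
#' reproducibility.
#'
#' @param records data.frame with \code{gene} and \code{log2lr_<by>} columns.
#' @param by Group whose score orders the list.
#' @return The records reordered, with a \code{rank} column 1..n.
#' @export
rank_order <- function(records, by = "susceptible") {
  col <- paste0("log2lr_", by)
  if (!col %in% names(records)) stopf("records lack column '%s'", col)
  if (nrow(records) == 0L) {
    records$rank <- integer(0)
    return(records)
  }
  o <- order(-records[[col]], records$gene)
  records <- records[o, , drop = FALSE]
  records$rank <- seq_len(nrow(records))
  rownames(records) <- NULL
  records
}

#' Three-set Venn region counts
#'
#' Counts the seven regions of a three-set Venn diagram; region counts sum to
#' the size of the union.
#'
#' @param sets Named list of three character vectors (e.g. the per-group
#'   lateral gene sets from [screen_lateral_genes()]).
#' @return Named integer vector: one exclusive region per set
#'   (\code{"<name>_only"}), three pairwise-only intersections
#'   (\code{"<a>&<b>"}) and the triple intersection (\code{"all"}).
#' @export
venn_counts <- function(sets) {
  stopifnot(length(sets) == 3L)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", 1:3)
  sets <- lapply(sets, unique)
  nm <- names(sets)
  members <- unique(unlist(sets, use.names = FALSE))
  inA <- members %in% sets[[1]]
  inB <- members %in% sets[[2]]
  inC <- members %in% sets[[3]]
  out <- c(sum(inA & !inB & !inC), sum(!inA & inB & !inC),
           sum(!inA & !inB & inC), sum(inA & inB & !inC),
           sum(inA & !inB & inC), sum(!inA & inB & inC),
           sum(inA & inB & inC))
  names(out) <- c(paste0(nm, "_only"),
                  paste0(nm[1], "&", nm[2]), paste0(nm[1], "&", nm[3]),
                  paste0(nm[2], "&", nm[3]), "all")
  out
}

#' Housekeeping-gene laterality control
#'
#' Differential hemispheric expression of housekeeping genes would indicate
#' unequal RNA input rather than biology. For each named gene this reports the
#' raw left-vs-right p-value in every group and a pass flag — all p-values
#' above the floor (default 0.05), i.e. no detectable laterality. Genes absent
#' from the matrix are flagged, not fatal.
#'
#' @param de A [run_contrasts()] result.
#' @param genes Gene ids to check; defaults to the canonical trio.
#' @param p_floor Pass threshold on the raw p-values.
#' @return data.frame with \code{gene}, \code{present}, \code{p_<group>},
#'   \code{min_p}, \code{pass}.
#' @export
housekeeping_check <- function(de, genes = c("Actb", "Gapdh", "B2m"),
                               p_floor = 0.05) {
  stopifnot(inherits(de, "de_results"))
  groups <- c("control", "resilient", "susceptible")
  if (!length(genes)) {
    out <- data.frame(gene = character(0), present = logical(0))
    for (g in groups) out[[paste0("p_", g)]] <- numeric(0)
    out$min_p <- numeric(0); out$pass <- logical(0)
    return(out)
  }
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  universe <- de$tables[[1]]$gene
  out$present <- genes %in% universe
  for (g in groups) {
    tb <- de$tables[[group_lvr_contrast(g)]]
    out[[paste0("p_", g)]] <- tb$p[match(genes, tb$gene)]
  }
  pcols <- paste0("p_", groups)
  out$min_p <- suppressWarnings(
    apply(as.matrix(out[, pcols]), 1, min, na.rm = TRUE))
  out$min_p[!out$present] <- NA_real_
  out$pass <- out$present & out$min_p > p_floor
  out
}

#' Row ordering and score matrix for a laterality heatmap
#'
#' Display helper: the screened genes in rank order (identical to
#' [rank_order()]) with their per-group log2 L/R scores as a matrix, ready for
#' a red/blue heatmap (positive = left-dominant).
#'
#' @param records Laterality records from [laterality_records()].
#' @return list with \code{order} (gene ids, ranked) and \code{scores}
#'   (gene x group matrix of log2 L/R).
#' @export
heatmap_order <- function(records) {
  groups <- c("control", "resilient", "susceptible")
  cols <- paste0("log2lr_", groups)
  if (nrow(records) == 0L)
    return(list(order = character(0),
                scores = matrix(numeric(0), 0, 3,
                                dimnames = list(NULL, groups))))
  if (!"rank" %in% names(records) || is.unsorted(records$rank))
    records <- rank_order(records)
  scores <- as.matrix(records[, cols])
  dimnames(scores) <- list(records$gene, groups)
  list(order = records$gene, scores = scores)
}

#' Write laterality outputs
#'
#' The laterality table as TSV and the Venn region counts as JSON.
#'
#' @param records Laterality records data.frame.
#' @param counts Venn counts from [venn_counts()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_laterality <- function(records, counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(table = file.path(dir, "laterality.tsv"),
             venn = file.path(dir, "venn_counts.json"))
  write.table(records, paths[["table"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(as.list(counts), paths[["venn"]], auto_unbox = TRUE)
  invisible(paths)
}
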