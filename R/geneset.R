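#' Read gene sets from a GMT file
#'
#' GMT is tab-delimited: set name, description, then member genes. Duplicate
#' members within a set are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of gene sets; each element is a character vector of
#'   member ids with a \code{description} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), names = character(0)))
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stopf("malformed GMT line %d: need name, description and >= 1 member",
            i)
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warnf("GMT set '%s' (line %d): dropping %d duplicate member(s)",
            fields[1], i, sum(duplicated(members)))
      members <- unique(members)
    }
    if (!length(members)) stopf("malformed GMT line %d: empty member list", i)
    sets[[fields[1]]] <- structure(members, description = fields[2])
  }
  sets
}

#' Per-hemisphere log2 fold changes of a gene set versus control
#'
#' For each member gene, the log2 fold change of the chosen group relative to
#' same-hemisphere controls: left from the \code{<group>_vs_control_L}
#' contrast, right from \code{<group>_vs_control_R}. Members absent from the
#' matrix are dropped with a warning. This is the dot-plot layout for
#' set-level lateralization: x = left fold change, y = right fold change.
#'
#' @param de A [run_contrasts()] result.
#' @param set Character vector of member gene ids (one [read_gmt()] element).
#' @param group \code{"susceptible"} or \code{"resilient"}.
#' @return list with \code{left} and \code{right} (named numeric vectors over
#'   the members with data) and \code{missing} (dropped member ids).
#' @export
set_log2fc <- function(de, set, group = c("susceptible", "resilient")) {
  stopifnot(inherits(de, "de_results"))
  group <- match.arg(group)
  set <- unique(as.character(set))
  tbL <- de$tables[[paste0(group, "_vs_control_L")]]
  tbR <- de$tables[[paste0(group, "_vs_control_R")]]
  present <- set[set %in% tbL$gene]
  missing <- setdiff(set, present)
  if (!length(present))
    stopf("no gene-set member present in the expression matrix")
  if (length(missing))
    warnf("dropping %d gene-set member(s) absent from the matrix: %s",
          length(missing), paste(head(missing, 5), collapse = ", "))
  list(left = setNames(tbL$log2fc[match(present, tbL$gene)], present),
       right = setNames(tbR$log2fc[match(present, tbR$gene)], present),
       missing = missing)
}

#' Two-sample t-test for gene-set lateralization
#'
#' Compares a set's left- and right-hemisphere log2 fold changes with a
#' classical pooled-variance Student t across member genes, df = 2n - 2.
#' Member genes are treated as the sampling unit — the convention of the
#' printed set-level box-plot statistics this reproduces — even though gene
#' fold changes are not independent observations.
#'
#' @param log2fc_left,log2fc_right Equal-length numeric vectors (one value per
#'   member gene), n >= 2; typically the output of [set_log2fc()].
#' @param set_name Optional label carried into the result.
#' @return list of class \code{"set_lateral_test"}: \code{set}, \code{n},
#'   \code{df} (= 2n - 2), \code{t}, \code{p}, and the member means
#'   \code{mean_left}, \code{mean_right}. Identical inputs give t = 0, p = 1.
#' @export
set_lateral_test <- function(log2fc_left, log2fc_right, set_name = NA_character_) {
  x <- as.numeric(log2fc_left); y <- as.numeric(log2fc_right)
  if (length(x) != length(y)) stopf("left and right lists differ in length")
  n <- length(x)
  if (n < 2L) stopf("insufficient data: need >= 2 member genes per side")
  df <- 2L * n - 2L
  sp2 <- ((n - 1) * var(x) + (n - 1) * var(y)) / df
  se <- sqrt(sp2 * 2 / n)
  delta <- mean(x) - mean(y)
  t <- if (se > 0) delta / se else if (delta == 0) 0 else sign(delta) * Inf
  p <- 2 * pt(-abs(t), df = df)
  structure(list(set = set_name, n = n, df = df, t = t, p = p,
                 mean_left = mean(x), mean_right = mean(y)),
            class = "set_lateral_test")
}

#' @export
print.set_lateral_test <- function(x, ...) {
  cat(sprintf("Set lateralization%s: t(%d) = %.3f, p = %.3g (n = %d genes)\n",
              if (is.na(x$set)) "" else paste0(" [", x$set, "]"),
              x$df, x$t, x$p, x$n))
  invisible(x)
}

#' Test every gene set in a collection for lateralization
#'
#' @param de A [run_contrasts()] result.
#' @param sets Named list of gene sets, e.g. from [read_gmt()].
#' @param group Group compared against control (default susceptible).
#' @return data.frame with one row per set: \code{set}, \code{n}, \code{df},
#'   \code{t}, \code{p}, \code{mean_left}, \code{mean_right}.
#' @export
test_gene_sets <- function(de, sets, group = c("susceptible", "resilient")) {
  group <- match.arg(group)
  rows <- lapply(names(sets), function(nm) {
    fc <- set_log2fc(de, sets[[nm]], group)
    res <- set_lateral_test(fc$left, fc$right, set_name = nm)
    as.data.frame(unclass(res), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
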