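#' Log2-transform a raw intensity matrix
#'
#' @param raw Numeric matrix of raw (positive) intensities.
#' @return Matrix of log2 intensities, dimnames preserved.
#' @export
log2_transform <- function(raw) {
  raw <- as.matrix(raw)
  bad <- which(!is.finite(raw) | raw <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    rn <- rownames(raw); cn <- colnames(raw)
    cell <- sprintf("[%s, %s]",
                    if (is.null(rn)) bad[1, 1] else rn[bad[1, 1]],
                    if (is.null(cn)) bad[1, 2] else cn[bad[1, 2]])
    stopf("non-positive or non-finite raw intensity at %s (%d offending cell%s)",
          cell, nrow(bad), if (nrow(bad) > 1) "s" else "")
  }
  log2(raw)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the same empirical distribution — the
#' mean of the row-sorted columns — while preserving within-column rank order.
#' Delegates to the standard algorithm in \code{limma::normalizeQuantiles}.
#'
#' @param x Numeric matrix, samples in columns. With a single column the
#'   matrix is returned unchanged with a warning.
#' @param ties Average tied values (passed through to limma). Default TRUE.
#' @return Normalized matrix with dimnames preserved.
#' @export
quantile_normalize <- function(x, ties = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) {
    warnf("quantile normalization needs >= 2 samples; returning input")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = ties)
  dimnames(out) <- dimnames(x)
  out
}

#' Remove genes that fail the array detection call
#'
#' Illumina-style detection p-values call whether a probe's signal exceeds
#' array background (p > alpha means "not detected"). Policies:
#' \describe{
#'   \item{majority (default)}{exclude a gene if, in any group x hemisphere
#'     condition, more than half of its replicates are undetected — requires
#'     \code{design}.}
#'   \item{any}{exclude a gene if any sample is undetected (the strictest
#'     reading of a per-gene detection rule).}
#'   \item{all}{exclude only genes undetected in every sample.}
#' }
#'
#' @param expr Gene x sample log2 matrix.
#' @param detection_p Matching matrix of detection p-values.
#' @param design Sample design data.frame (\code{sample_id}, \code{group},
#'   \code{hemisphere}); required for the majority policy.
#' @param alpha Detection threshold in (0, 1); default 0.05.
#' @param policy One of \code{"majority"}, \code{"any"}, \code{"all"}.
#' @return list with \code{expr}, \code{detection_p} (filtered) and
#'   \code{removed} (character vector of excluded gene ids).
#' @export
detection_filter <- function(expr, detection_p, design = NULL, alpha = 0.05,
                             policy = c("majority", "any", "all")) {
  policy <- match.arg(policy)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  expr <- as.matrix(expr); detection_p <- as.matrix(detection_p)
  if (!all(dim(expr) == dim(detection_p)))
    stopf("expr and detection_p dimensions disagree")
  undetected <- detection_p > alpha
  drop <- switch(policy,
    any = rowSums(undetected) > 0,
    all = rowSums(undetected) == ncol(expr),
    majority = {
      if (is.null(design))
        stopf("the majority policy needs the sample design")
      design <- check_design(design, colnames(expr))
      cond <- interaction(design$group, design$hemisphere, drop = TRUE)
      per_cond <- vapply(levels(cond), function(lv) {
        cols <- which(cond == lv)
        rowSums(undetected[, cols, drop = FALSE]) > length(cols) / 2
      }, logical(nrow(expr)))
      rowSums(as.matrix(per_cond)) > 0
    })
  removed <- rownames(expr)[drop]
  if (is.null(removed)) removed <- which(drop)
  list(expr = expr[!drop, , drop = FALSE],
       detection_p = detection_p[!drop, , drop = FALSE],
       removed = removed)
}

# Validate a sample design table against the expression columns and return it
# ordered to match them.
check_design <- function(design, sample_ids = NULL) {
  need <- c("sample_id", "group", "hemisphere")
  missing <- setdiff(need, names(design))
  if (length(missing))
    stopf("design lacks column(s): %s", paste(missing, collapse = ", "))
  if (!all(design$group %in% c("control", "resilient", "susceptible")))
    stopf("design groups must be control/resilient/susceptible")
  if (!all(design$hemisphere %in% c("L", "R")))
    stopf("design hemisphere must be L or R")
  if (!is.null(sample_ids)) {
    if (!setequal(design$sample_id, sample_ids))
      stopf("design sample ids do not match expression columns")
    design <- design[match(sample_ids, design$sample_id), , drop = FALSE]
  }
  design
}

#' Read and write expression matrices as TSV
#'
#' Genes in rows (first column \code{gene}), samples in columns.
#'
#' @param path File path.
#' @return \code{read_expression_tsv}: numeric matrix with gene row names.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    drop <- rowSums(is.na(m)) > 0
    warnf("dropping %d gene(s) with missing values", sum(drop))
    m <- m[!drop, , drop = FALSE]
  }
  m
}

#' @rdname read_expression_tsv
#' @param x Gene x sample matrix.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design CSV
#'
#' Columns \code{sample_id, group, hemisphere, replicate}.
#'
#' @param path File path.
#' @return Validated design data.frame.
#' @export
read_design_csv <- function(path) {
  check_design(read.csv(path, stringsAsFactors = FALSE))
}

#' Read the expression table of a GEO series-matrix file
#'
#' Minimal parser for the plain-text "series matrix" export format: the
#' tab-separated block between \code{!series_matrix_table_begin} and
#' \code{!series_matrix_table_end}, with probe ids in the first column
#' (\code{ID_REF}) and one column per sample. Sample titles and accessions
#' from the header are attached as attributes when present.
#'
#' @param path Path to an (uncompressed) series-matrix TXT file.
#' @return Numeric probe x sample matrix, with attributes
#'   \code{sample_title} and \code{sample_accession} when the header carries
#'   them.
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin)
    stopf("no series-matrix table block found in %s", path)
  tab <- read.delim(text = lines[(begin + 1L):(end - 1L)],
                    check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  grab <- function(tag) {
    ln <- grep(paste0("^!", tag, "\t"), lines, value = TRUE)
    if (!length(ln)) return(NULL)
    gsub("^\"|\"$", "", strsplit(ln[1], "\t")[[1]][-1])
  }
  attr(m, "sample_title") <- grab("Sample_title")
  attr(m, "sample_accession") <- grab("Sample_geo_accession")
  m
}
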