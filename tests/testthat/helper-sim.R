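# Shared fixtures for the test suite; everything is built in code.

# A balanced 3-group x 2-hemisphere design with r replicates per cell.
full_design <- function(r = 3L) {
  d <- expand.grid(replicate = seq_len(r), hemisphere = c("L", "R"),
                   group = c("control", "resilient", "susceptible"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$sample_id <- sprintf("%s_%s_%d", d$group, d$hemisphere, d$replicate)
  d[, c("sample_id", "group", "hemisphere", "replicate")]
}

# A two-cell (left vs right, one group) design for two-sample checks.
two_cell_design <- function(n1, n2, group = "control") {
  d <- data.frame(
    sample_id = c(sprintf("%s_L_%d", group, seq_len(n1)),
                  sprintf("%s_R_%d", group, seq_len(n2))),
    group = group,
    hemisphere = rep(c("L", "R"), c(n1, n2)),
    replicate = c(seq_len(n1), seq_len(n2)),
    stringsAsFactors = FALSE)
  d
}

# Null expression matrix (no effects) for a given design.
null_expr <- function(design, n_genes, sd = 0.3) {
  m <- matrix(rnorm(n_genes * nrow(design), mean = 8, sd = sd),
              n_genes, nrow(design),
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              design$sample_id))
  m
}

# Independently coded classical pooled-variance two-sample t (the oracle
# against which the moderated t at d0 = 0 is compared).
classical_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean(a) - mean(b)) / se
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}
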