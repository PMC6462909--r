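#' Signed linear fold change from group mean log2 intensities
#'
#' Converts a case/control difference of mean log2 intensities into the
#' signed-linear convention common in microarray reporting: the linear ratio
#' `r = 2^(case - control)` is returned as `r` when `r >= 1` and as `-1/r`
#' otherwise, so values always satisfy `|fc| >= 1` and a 2-fold down-regulation
#' prints as -2 rather than 0.5.
#'
#' @param mean_case_log2,mean_ctrl_log2 Numeric vectors of group mean log2
#'   intensities (recycled to a common length).
#' @return Numeric vector of signed linear fold changes.
#' @examples
#' signed_fold_change(6, 5)      #  2
#' signed_fold_change(5, 5.848)  # ~ -1.8
#' @export
signed_fold_change <- function(mean_case_log2, mean_ctrl_log2) {
  if (!is.numeric(mean_case_log2) || !is.numeric(mean_ctrl_log2) ||
      any(!is.finite(mean_case_log2)) || any(!is.finite(mean_ctrl_log2)))
    stop_lncnet("lncnet_invalid_input", "group means must be finite numbers")
  d <- mean_case_log2 - mean_ctrl_log2
  ifelse(d >= 0, 2^d, -2^(-d))
}

#' Two-sample equal-variance (Student) t test
#'
#' The pooled-variance unpaired t test, computed from explicit formulas. A
#' degenerate gene (zero pooled variance) yields `t = 0, p = 1` when the group
#' means are also equal; unequal means with zero pooled variance raise a
#' `lncnet_degenerate_variance` error rather than reporting p = 0.
#'
#' @param case_values,ctrl_values Numeric vectors (each of length >= 2).
#' @param welch If `TRUE`, use the Welch unequal-variance form instead of the
#'   pooled form. Default `FALSE` (Student).
#' @return List with elements `t`, `df` and two-sided `p`.
#' @examples
#' unpaired_t_test(c(2.1, 2.9, 2.5, 2.7), c(1.1, 1.5, 1.3, 0.9))
#' @export
unpaired_t_test <- function(case_values, ctrl_values, welch = FALSE) {
  for (v in list(case_values, ctrl_values)) {
    if (!is.numeric(v) || any(!is.finite(v)))
      stop_lncnet("lncnet_invalid_input", "group values must be finite numbers")
    if (length(v) < 2L)
      stop_lncnet("lncnet_insufficient_replicates", "each group needs >= 2 values")
  }
  n1 <- length(case_values); n2 <- length(ctrl_values)
  m1 <- mean(case_values); m2 <- mean(ctrl_values)
  v1 <- sum((case_values - m1)^2) / (n1 - 1)
  v2 <- sum((ctrl_values - m2)^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  if (se2 == 0) {
    if (m1 == m2) return(list(t = 0, df = df, p = 1))
    stop_lncnet("lncnet_degenerate_variance",
                "zero pooled variance with unequal group means")
  }
  tstat <- (m1 - m2) / sqrt(se2)
  list(t = tstat, df = df, p = 2 * pt(abs(tstat), df, lower.tail = FALSE))
}

#' Bonferroni adjustment
#'
#' @param p_raw Vector of raw p-values in `[0, 1]`.
#' @param m Number of tests in the family (>= 1).
#' @return `min(1, p_raw * m)`, vectorized over `p_raw`.
#' @export
bonferroni <- function(p_raw, m) {
  m <- assert_count(m, "m", min = 1L)
  if (!is.numeric(p_raw) || any(!is.finite(p_raw)) || any(p_raw < 0) || any(p_raw > 1))
    stop_lncnet("lncnet_invalid_parameter", "`p_raw` must be in [0, 1]")
  pmin(1, p_raw * m)
}

#' Per-gene differential-expression statistics for a whole matrix
#'
#' Vectorized pooled-t statistics, signed linear fold changes and Bonferroni
#' adjusted p-values for every gene in the matrix. Genes with zero pooled
#' variance and unequal group means cannot be assigned a p-value; they are
#' flagged in the `degenerate` column (p set to `NA`) and excluded by
#' [call_degs()] with a warning, never silently given p = 0.
#'
#' @param em An [expression_matrix()].
#' @param m Bonferroni family size; defaults to the number of genes in the
#'   matrix. The study-wide transcript panel can be supplied instead when the
#'   matrix is a filtered subset.
#' @return Data frame with one row per gene: `gene_id`, `mean_case`,
#'   `mean_ctrl`, `fold_change`, `t`, `df`, `p_raw`, `p_adj`, `direction`,
#'   `degenerate`, in input gene order.
#' @export
de_stats <- function(em, m = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  if (is.null(m)) m <- nrow(em$values)
  m <- assert_count(m, "m", min = 1L)
  x <- em$values[, em$labels == "case", drop = FALSE]
  y <- em$values[, em$labels == "control", drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  ss1 <- rowSums((x - m1)^2); ss2 <- rowSums((y - m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, (m1 - m2) / se, 0)
  p_raw <- ifelse(se > 0, 2 * pt(abs(tstat), df, lower.tail = FALSE),
                  ifelse(m1 == m2, 1, NA_real_))
  degenerate <- se == 0 & m1 != m2
  fc <- signed_fold_change(m1, m2)
  data.frame(
    gene_id = rownames(em$values),
    mean_case = m1, mean_ctrl = m2,
    fold_change = fc, t = tstat, df = df,
    p_raw = p_raw,
    p_adj = pmin(1, p_raw * m),
    direction = ifelse(fc > 0, "up", "down"),
    degenerate = degenerate,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Call differentially expressed genes
#'
#' A gene is called a DEG when both criteria hold (both thresholds inclusive):
#' `|fold_change| >= fc_threshold` and Bonferroni-adjusted `p_adj <=
#' p_threshold`. The Bonferroni family size defaults to the number of genes in
#' the input matrix.
#'
#' @inheritParams de_stats
#' @param fc_threshold Signed-linear fold-change threshold (default 1.5).
#' @param p_threshold Adjusted p-value threshold (default 0.01).
#' @return Data frame of passing genes sorted by `gene_id`, with columns
#'   `gene_id`, `fold_change`, `p_raw`, `p_adj`, `direction`. The full
#'   per-gene statistics table is attached as attribute `"stats"` and any
#'   degenerate-variance genes as attribute `"degenerate"`.
#' @export
call_degs <- function(em, fc_threshold = 1.5, p_threshold = 0.01, m = NULL) {
  fc_threshold <- assert_number(fc_threshold, "fc_threshold", lower = 1)
  p_threshold <- assert_number(p_threshold, "p_threshold", lower = 0, upper = 1)
  st <- de_stats(em, m = m)
  if (any(st$degenerate))
    warning(sprintf("%d gene(s) with zero within-group variance and unequal means flagged and excluded",
                    sum(st$degenerate)))
  keep <- !st$degenerate & abs(st$fold_change) >= fc_threshold & st$p_adj <= p_threshold
  out <- st[keep, c("gene_id", "fold_change", "p_raw", "p_adj", "direction")]
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stats") <- st
  attr(out, "degenerate") <- st[st$degenerate, , drop = FALSE]
  out
}

#' Collapse probe-level DEG records to gene symbols
#'
#' Target maps are symbol-keyed, so probe-level records mapping to the same
#' symbol are merged before intersection: the probe with the smallest raw
#' p-value supplies the representative statistics.
#'
#' @param degs A DEG table (as from [call_degs()]) whose `gene_id` column holds
#'   probe identifiers.
#' @param probe_to_symbol Named character vector mapping probe id -> symbol.
#'   Probes absent from the map keep their identifier.
#' @return DEG table keyed by symbol, sorted by `gene_id`.
#' @export
collapse_probes <- function(degs, probe_to_symbol) {
  sym <- probe_to_symbol[degs$gene_id]
  sym[is.na(sym)] <- degs$gene_id[is.na(sym)]
  degs$gene_id <- unname(sym)
  degs <- degs[order(degs$gene_id, degs$p_raw), , drop = FALSE]
  degs <- degs[!duplicated(degs$gene_id), , drop = FALSE]
  rownames(degs) <- NULL
  degs
}
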