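#' Relative expression from qPCR threshold cycles (2^-dCt)
#'
#' Fold expression of a gene relative to a reference gene from their
#' threshold cycles: `2^-(ct_gene - ct_ref)`. Adding a constant to both Ct
#' values leaves the fold unchanged.
#'
#' @param ct_gene,ct_ref finite Ct values (vectorized).
#' @return Fold expression.
#' @examples
#' relative_expression_ddct(25, 20)  # 2^-5
#' @export
relative_expression_ddct <- function(ct_gene, ct_ref) {
  stopifnot(all(is.finite(ct_gene)), all(is.finite(ct_ref)))
  2^(-(ct_gene - ct_ref))
}

#' Rescale values so the control-group mean equals 1
#'
#' Used for reporting expression ratios (e.g. lytic over latency gene,
#' ORF50/ORF73 or BZLF1/EBNA1) relative to the untreated or virus-only
#' control condition.
#'
#' @param x numeric values (e.g. per-sample expression ratios).
#' @param is_control logical vector marking the control samples.
#' @return `x / mean(x[is_control])`; the control mean of the result is
#'   exactly 1.
#' @export
rescale_to_control <- function(x, is_control) {
  stopifnot(length(x) == length(is_control), any(is_control))
  m <- mean(x[is_control])
  if (m == 0) stop("control mean is zero")
  x / m
}

#' Per-sample expression ratio of two genes with control anchoring
#'
#' Computes the ratio of two genes' 2^-dCt expressions per sample (the
#' reference gene cancels, so the ratio is `2^-(ct_num - ct_den)`) and
#' rescales so that the control group's mean ratio is 1.
#'
#' @param df long-format data.frame with columns `sample`, `group`, `gene`,
#'   `ct`.
#' @param gene_num,gene_den numerator and denominator genes (e.g. the lytic
#'   and latency genes).
#' @param control_group group whose mean ratio anchors the scale.
#' @return data.frame: `sample`, `group`, `ratio` (control mean = 1).
#' @export
expression_ratio <- function(df, gene_num, gene_den, control_group) {
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(df))) stop("df needs columns: ",
                                      paste(need, collapse = ", "))
  num <- df[df$gene == gene_num, ]
  den <- df[df$gene == gene_den, ]
  i <- match(num$sample, den$sample)
  if (anyNA(i)) stop("samples missing the denominator gene: ",
                     paste(num$sample[is.na(i)], collapse = ", "))
  ratio <- relative_expression_ddct(num$ct, den$ct[i])
  out <- data.frame(sample = num$sample, group = num$group, ratio = ratio,
                    stringsAsFactors = FALSE)
  if (!any(out$group == control_group)) stop("control group not found: ",
                                             control_group)
  out$ratio <- rescale_to_control(out$ratio, out$group == control_group)
  out
}

#' Consistent fold-change overlap filter
#'
#' Generic table operation selecting features regulated consistently against
#' every control: a feature is `up` when its value in every case group is at
#' least `threshold` times its value in every control group, and `down`
#' under the symmetric rule (at most 1/threshold times). Boundaries are
#' inclusive ("at least"). The up and down sets are disjoint by construction
#' for threshold > 1.
#'
#' @param fc_table numeric matrix or data.frame, features x groups, of
#'   positive expression values or fold changes on a common scale.
#' @param case_groups,control_groups column names to compare.
#' @param threshold fold-change threshold (>= 1; default 1.5).
#' @return List with integer vectors `up` and `down` (row indices; named if
#'   the table has rownames).
#' @export
overlap_filter <- function(fc_table, case_groups, control_groups,
                           threshold = 1.5) {
  stopifnot(threshold >= 1)
  fc_table <- as.matrix(fc_table)
  missing_cols <- setdiff(c(case_groups, control_groups), colnames(fc_table))
  if (length(missing_cols)) stop("missing group column(s): ",
                                 paste(missing_cols, collapse = ", "))
  up <- setNames(rep(TRUE, nrow(fc_table)), rownames(fc_table))
  down <- setNames(rep(TRUE, nrow(fc_table)), rownames(fc_table))
  for (ca in case_groups) {
    for (co in control_groups) {
      ratio <- fc_table[, ca, drop = TRUE] / fc_table[, co, drop = TRUE]
      up <- up & ratio >= threshold
      down <- down & ratio <= 1 / threshold
    }
  }
  if (threshold == 1) down <- down & !up   # degenerate threshold: keep disjoint
  list(up = which(up), down = which(down))
}
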