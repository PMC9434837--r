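#' Wilcoxon rank-sum test between two cell groups
#'
#' Exact enumeration when both sides have fewer than 30 cells and the data
#' are tie-free; otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param values_a,values_b numeric vectors (each >= 3 values).
#' @return list with `statistic` (the Mann-Whitney U for the first group)
#'   and `p` (two-sided).
#' @export
wilcoxon_test <- function(values_a, values_b) {
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("each group needs at least 3 cells")
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- !ties && length(values_a) < 30 && length(values_b) < 30
  ht <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Effect statistics for a two-group expression contrast
#'
#' `avg_log2FC = log2(mean(A) + 1) - log2(mean(B) + 1)` on normalized values
#' (the +1 pseudocount keeps all-zero genes finite); `pct.1` / `pct.2` are
#' the detection fractions (nonzero cells) in each group.
#'
#' @param values_a,values_b numeric vectors of normalized expression.
#' @return list with `avg_log2FC`, `pct1`, `pct2`.
#' @export
effect_stats <- function(values_a, values_b) {
  list(avg_log2FC = log2(mean(values_a) + 1) - log2(mean(values_b) + 1),
       pct1 = mean(values_a > 0),
       pct2 = mean(values_b > 0))
}

de_contrast <- function(mat, in_a, in_b, context) {
  genes <- colnames(mat)
  m <- length(genes)
  rows <- lapply(genes, function(g) {
    va <- mat[in_a, g]; vb <- mat[in_b, g]
    wt <- wilcoxon_test(va, vb)
    ef <- effect_stats(va, vb)
    data.frame(gene = g, context = context, avg_log2FC = ef$avg_log2FC,
               pct.1 = ef$pct1, pct.2 = ef$pct2, p = wt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- pmin(1, out$p * m)       # Bonferroni over genes in the contrast
  out$significant <- out$adj_p < 0.05 & out$pct.1 > 0.2
  out
}

#' Differential-expression screen
#'
#' Wilcoxon rank-sum per gene with Bonferroni correction over the genes
#' tested in each contrast, `avg_log2FC` and detection fractions, and the
#' significance filter `adj_p < 0.05 & pct.1 > 0.2`. Two modes:
#' `"one_vs_rest"` contrasts each level of `grouping` against all other
#' cells; `"pairwise_groups"` contrasts consecutive levels of `grouping` (in
#' the order given by `levels`), the natural ordering for staged disease
#' groups. Contrasts where either side has fewer than 3 cells are skipped
#' with a warning.
#'
#' @param mat numeric matrix (cells x genes) of normalized expression.
#' @param grouping per-cell labels aligned with rows.
#' @param mode `"one_vs_rest"` or `"pairwise_groups"`.
#' @param levels optional explicit ordering of group levels.
#' @return a `de_result` data.frame: `gene`, `context`, `avg_log2FC`,
#'   `pct.1`, `pct.2`, `p`, `adj_p`, `significant`.
#' @export
de_screen <- function(mat, grouping, mode = c("one_vs_rest", "pairwise_groups"),
                      levels = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(grouping) == nrow(mat))
  lv <- levels %||% unique(grouping)
  contrasts <- if (mode == "one_vs_rest") {
    lapply(lv, function(g) list(a = grouping == g, b = grouping != g,
                                context = sprintf("%s_vs_rest", g)))
  } else {
    lapply(seq_len(length(lv) - 1), function(i)
      list(a = grouping == lv[i], b = grouping == lv[i + 1],
           context = sprintf("%s_vs_%s", lv[i], lv[i + 1])))
  }
  out <- list()
  for (cn in contrasts) {
    if (sum(cn$a) < 3 || sum(cn$b) < 3) {
      warning(sprintf("contrast %s skipped: fewer than 3 cells on one side",
                      cn$context))
      next
    }
    out[[cn$context]] <- de_contrast(mat, cn$a, cn$b, cn$context)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene = character(0), context = character(0),
                      avg_log2FC = numeric(0), pct.1 = numeric(0),
                      pct.2 = numeric(0), p = numeric(0),
                      adj_p = numeric(0), significant = logical(0))
  rownames(res) <- NULL
  class(res) <- c("de_result", class(res))
  res
}
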