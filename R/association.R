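#' Default antibody-to-gene map for the synthetic panel
#'
#' Pairs each of the 19 signature antibodies with its same-named transcript
#' in the targeted panel.
#'
#' @return data.frame with columns `antibody`, `gene`.
#' @export
default_antibody_gene_map <- function() {
  nm <- default_markers()[1:19]
  data.frame(antibody = nm, gene = nm, stringsAsFactors = FALSE)
}

#' Filtered Spearman screen of antibody-gene pairs
#'
#' For each mapped (antibody, gene) pair within each cell-type context:
#' cells below the antibody's threshold (zero after thresholding) or with a
#' zero gene count are discarded; a pair left with 10 or fewer cells is
#' deemed insignificant (reported coefficient 0); otherwise the Spearman
#' rank correlation and its t-approximation p-value are computed, and
#' non-significant coefficients (p > 0.05) are also reported as 0. An
#' antibody or gene is *selected* when it has at least one reported
#' coefficient with absolute value >= `select_cut`.
#'
#' @param adt_thresholded thresholded CLR matrix (cells x markers).
#' @param rna_norm normalized expression matrix (cells x genes).
#' @param map data.frame with `antibody`, `gene` columns; unmapped
#'   antibodies in the matrix are skipped silently, antibodies in the map
#'   but absent from the matrix are skipped with a warning.
#' @param cell_type per-cell type labels (contexts); use a constant vector
#'   for a global screen.
#' @param min_cells minimum surviving cells for a pair to be testable
#'   (default 11, i.e. "10 cells or less" is insignificant).
#' @param alpha significance level for zeroing coefficients.
#' @param select_cut absolute reported-coefficient cut for selection.
#' @return a `correlation_records` data.frame: `antibody`, `gene`,
#'   `cell_type`, `n_cells`, `rho`, `p`, `reported_rho`, `selected`.
#' @export
correlation_screen <- function(adt_thresholded, rna_norm, map,
                               cell_type = rep("all", nrow(adt_thresholded)),
                               min_cells = 11, alpha = 0.05,
                               select_cut = 0.25) {
  stopifnot(length(cell_type) == nrow(adt_thresholded))
  rna_norm <- as.matrix(rna_norm)
  missing_ab <- setdiff(map$antibody, colnames(adt_thresholded))
  if (length(missing_ab))
    warning(sprintf("antibody(ies) not in the matrix, skipped: %s",
                    paste(missing_ab, collapse = ", ")))
  map <- map[map$antibody %in% colnames(adt_thresholded) &
               map$gene %in% colnames(rna_norm), , drop = FALSE]
  rows <- list()
  for (ctx in unique(cell_type)) {
    in_ctx <- cell_type == ctx
    for (i in seq_len(nrow(map))) {
      ab <- map$antibody[i]; gn <- map$gene[i]
      a <- adt_thresholded[in_ctx, ab]
      r <- rna_norm[in_ctx, gn]
      keep <- a > 0 & r > 0
      nk <- sum(keep)
      if (nk < min_cells) {
        rows[[length(rows) + 1L]] <- data.frame(
          antibody = ab, gene = gn, cell_type = ctx, n_cells = nk,
          rho = NA_real_, p = NA_real_, reported_rho = 0,
          stringsAsFactors = FALSE)
        next
      }
      ct <- suppressWarnings(
        cor.test(a[keep], r[keep], method = "spearman", exact = FALSE))
      rho <- unname(ct$estimate)
      rows[[length(rows) + 1L]] <- data.frame(
        antibody = ab, gene = gn, cell_type = ctx, n_cells = nk,
        rho = rho, p = ct$p.value,
        reported_rho = if (ct$p.value > alpha) 0 else rho,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  strong <- abs(out$reported_rho) >= select_cut
  out$selected <- out$antibody %in% out$antibody[strong] |
    out$gene %in% out$gene[strong]
  class(out) <- c("correlation_records", class(out))
  out
}

#' Iterated random-forest gene importance across disease conditions
#'
#' Per iteration: a balanced resample (`cells_per_condition` cells from each
#' condition, with replacement when a condition is smaller), a seeded
#' random-forest classifier, per-gene importance, and scaling of that
#' iteration's scores to a 0-100 range. The table reports the mean scaled
#' importance over iterations and the resulting rank; a higher score means
#' more power to tell the conditions apart.
#'
#' @param mat normalized expression matrix (cells x genes).
#' @param condition per-cell condition labels (>= 2 distinct).
#' @param cells_per_condition balanced sample size per condition.
#' @param iterations resampling iterations (default 15).
#' @param ntree trees per forest (default 500).
#' @param importance `"impurity"` (Gini impurity decrease, default) or
#'   `"permutation"` (out-of-bag). Impurity importance has a positive
#'   baseline for every gene, so pure-noise panels stay near-flat;
#'   permutation importance centres on zero under the null, which makes
#'   max-scaled noise scores unstable.
#' @param min_node minimum node size for the trees.
#' @param seed master seed; each iteration derives a substream.
#' @return an `importance_table` data.frame: `gene`, `mean_importance`,
#'   `rank`, with the per-iteration scaled score matrix in
#'   `attr(, "iterations")`.
#' @export
rf_importance <- function(mat, condition, cells_per_condition = 1000,
                          iterations = 15, ntree = 500,
                          importance = c("impurity", "permutation"),
                          min_node = 5, seed = 0) {
  importance <- match.arg(importance)
  mat <- as.matrix(mat)
  stopifnot(length(condition) == nrow(mat))
  lv <- sort(unique(condition))
  if (length(lv) < 2) stop("need at least 2 conditions")
  short <- lv[table(factor(condition, lv)) < cells_per_condition]
  if (length(short))
    message(sprintf("condition(s) smaller than %d, sampling with replacement: %s",
                    cells_per_condition, paste(short, collapse = ", ")))
  scaled <- matrix(NA_real_, ncol(mat), iterations,
                   dimnames = list(colnames(mat), NULL))
  for (it in seq_len(iterations)) {
    it_seed <- substream_seed(seed, sprintf("rf-iter-%d", it))
    idx <- with_seed(it_seed, unlist(lapply(lv, function(g) {
      pool <- which(condition == g)
      sample(pool, cells_per_condition, replace = length(pool) < cells_per_condition)
    })))
    y <- as.integer(factor(condition[idx], lv)) - 1L
    imp <- cpp_rf_importance(mat[idx, , drop = FALSE], y, length(lv),
                             as.integer(ntree),
                             as.integer(floor(sqrt(ncol(mat)))),
                             as.integer(min_node), it_seed,
                             importance == "permutation")
    imp[imp < 0] <- 0
    scaled[, it] <- if (max(imp) > 0) imp / max(imp) * 100 else imp
  }
  out <- data.frame(gene = colnames(mat),
                    mean_importance = rowMeans(scaled),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$mean_importance, ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "iterations") <- scaled
  class(out) <- c("importance_table", class(out))
  out
}
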