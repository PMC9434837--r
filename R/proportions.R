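#' Per-participant cluster proportions within a parent major type
#'
#' For every participant and cluster: the number of the participant's cells
#' in the cluster, the participant's total cells of the parent major type,
#' and the proportion (cluster cells / parent cells). Participants with zero
#' parent cells are excluded with a warning.
#'
#' @param assignment a `cluster_assignment` data.frame (cell_id, major_type,
#'   cluster).
#' @param cell_table per-cell metadata with `cell_id`, `participant`,
#'   `group`.
#' @return a `proportion_table` data.frame: `participant`, `group`,
#'   `major_type`, `cluster`, `n_cluster`, `n_parent`, `p`, `logodds`.
#' @export
proportions_per_participant <- function(assignment, cell_table) {
  meta <- cell_table[match(assignment$cell_id, cell_table$cell_id),
                     c("participant", "group")]
  df <- cbind(assignment[, c("cell_id", "major_type", "cluster")], meta)
  df <- df[!is.na(df$participant), ]
  parent <- table(df$participant, df$major_type)
  out <- list()
  for (ty in unique(df$major_type)) {
    sub <- df[df$major_type == ty, ]
    clusters <- sort(unique(sub$cluster))
    for (pp in unique(df$participant)) {
      np <- parent[pp, ty]
      if (np == 0) next
      cnt <- table(factor(sub$cluster[sub$participant == pp],
                          levels = clusters))
      out[[paste(ty, pp)]] <- data.frame(
        participant = pp,
        group = df$group[match(pp, df$participant)],
        major_type = ty, cluster = clusters,
        n_cluster = as.integer(cnt), n_parent = as.integer(np),
        stringsAsFactors = FALSE)
    }
  }
  skipped <- rownames(parent)[apply(parent == 0, 1, any)]
  if (length(skipped))
    warning(sprintf("participant(s) with zero cells in some parent type: %s",
                    paste(unique(skipped), collapse = ", ")))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p <- res$n_cluster / res$n_parent
  res$logodds <- logodds(res$n_cluster, res$n_parent)
  class(res) <- c("proportion_table", class(res))
  res
}

#' Continuity-corrected log-odds of a cluster proportion
#'
#' `ln(p' / (1 - p'))` with `p' = (k + 0.5) / (n + 1)`, finite for `k = 0`
#' and `k = n`. The correction makes empty clusters usable in the ANOVA
#' instead of mapping to `-Inf`.
#'
#' @param k cells in the cluster.
#' @param n cells in the parent type (must be > 0).
#' @return numeric vector of log-odds values.
#' @export
logodds <- function(k, n) {
  stopifnot(all(n > 0), all(k >= 0), all(k <= n))
  p <- (k + 0.5) / (n + 1)
  log(p / (1 - p))
}

#' One-way ANOVA with Tukey HSD on transformed cluster proportions
#'
#' Tests whether a cluster's abundance differs across participant groups:
#' one-way ANOVA on the log-odds values, followed by Tukey's studentized-
#' range test for all pairwise group contrasts. Group summaries are reported
#' on the percentage scale for readability. Groups with fewer than 2
#' participants are dropped with a warning.
#'
#' @param values transformed (log-odds) per-participant values.
#' @param groups group label per value.
#' @return list with `f`, `p` (ANOVA), `tukey` (data.frame: contrast,
#'   diff, adj_p), and `group_summary` (mean and SEM of the proportion-scale
#'   values per group, where `percent = 100 / (1 + exp(-logodds))`).
#' @export
anova_tukey <- function(values, groups) {
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning(sprintf("group(s) with < 2 participants dropped: %s",
                    paste(small, collapse = ", ")))
    keep <- !groups %in% small
    values <- values[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  g <- factor(groups)
  fit <- aov(values ~ g)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  pct <- 100 / (1 + exp(-values))
  gs <- do.call(rbind, lapply(levels(g), function(lv) data.frame(
    group = lv, mean_pct = mean(pct[g == lv]),
    sem_pct = sd(pct[g == lv]) / sqrt(sum(g == lv)),
    stringsAsFactors = FALSE)))
  list(f = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       tukey = data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                          adj_p = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE),
       group_summary = gs)
}

#' Test every cluster's abundance across participant groups
#'
#' Runs [anova_tukey()] on the log-odds proportions of each cluster.
#'
#' @param prop_table a `proportion_table` from
#'   [proportions_per_participant()].
#' @return a data.frame with one row per (cluster, Tukey contrast):
#'   `major_type`, `cluster`, `anova_f`, `anova_p`, `contrast`, `diff`,
#'   `tukey_adj_p`.
#' @export
proportion_tests <- function(prop_table) {
  out <- list()
  for (cl in unique(prop_table$cluster)) {
    sub <- prop_table[prop_table$cluster == cl, ]
    res <- tryCatch(anova_tukey(sub$logodds, sub$group),
                    error = function(e) NULL)
    if (is.null(res)) next
    out[[cl]] <- data.frame(major_type = sub$major_type[1], cluster = cl,
                            anova_f = res$f, anova_p = res$p,
                            contrast = res$tukey$contrast,
                            diff = res$tukey$diff,
                            tukey_adj_p = res$tukey$adj_p,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
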