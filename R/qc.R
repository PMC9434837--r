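#' Demultiplex sample tags into singlet / doublet / undetermined calls
#'
#' Each plate is stained with a small set of sample tags (one per pooled
#' participant). A tag is called positive when its count reaches that tag's
#' threshold; cells with exactly one positive tag are singlets of that tag,
#' cells with two or more are cross-sample doublets, and cells with none are
#' undetermined (excluded downstream).
#'
#' @param tags a `"TAG"` [count_matrix()].
#' @param per_tag_threshold named numeric vector, one count threshold per tag
#'   column; see [tag_thresholds()] for a data-driven default.
#' @return a data.frame with `cell_id`, `tag_call` (`"singlet"`, `"doublet"`,
#'   `"undetermined"`) and `tag` (the positive tag for singlets, else `NA`).
#' @export
demux_tags <- function(tags, per_tag_threshold) {
  stopifnot(inherits(tags, "count_matrix"), tags$feature_class == "TAG")
  tag_names <- feature_ids(tags)
  missing <- setdiff(tag_names, names(per_tag_threshold))
  if (length(missing))
    stop(sprintf("no threshold supplied for tag(s): %s",
                 paste(missing, collapse = ", ")))
  m <- as.matrix(tags$counts)
  pos <- sweep(m, 2, per_tag_threshold[tag_names], ">=")
  npos <- rowSums(pos)
  call <- ifelse(npos == 1L, "singlet",
                 ifelse(npos >= 2L, "doublet", "undetermined"))
  tag <- rep(NA_character_, nrow(m))
  one <- npos == 1L
  tag[one] <- tag_names[max.col(pos[one, , drop = FALSE] * 1, "first")]
  data.frame(cell_id = cell_ids(tags), tag_call = call, tag = tag,
             stringsAsFactors = FALSE)
}

#' Data-driven per-tag positivity thresholds
#'
#' Reuses the antibody mixture-threshold machinery: each tag's counts are
#' log-transformed, a two-component Gaussian mixture is fitted, and the
#' inter-Gaussian intersection (back-transformed to the count scale)
#' separates ambient from dominant tag signal.
#'
#' @param tags a `"TAG"` [count_matrix()].
#' @param seed seed for the EM restarts.
#' @return named numeric vector of count-scale thresholds.
#' @export
tag_thresholds <- function(tags, seed = 0) {
  stopifnot(inherits(tags, "count_matrix"), tags$feature_class == "TAG")
  m <- as.matrix(tags$counts)
  out <- setNames(numeric(ncol(m)), colnames(m))
  for (j in seq_len(ncol(m))) {
    v <- log(m[, j] + 1)
    fit <- fit_mixture_1d(v, seed = seed)
    if (!fit$converged)
      stop(sprintf("mixture fit failed for tag '%s'", colnames(m)[j]))
    out[j] <- exp(gaussian_intersection(fit)) - 1
  }
  out
}

#' Flag likely expression doublets with an artificial-doublet kNN score
#'
#' A simplified artificial-nearest-neighbour doublet detector: artificial
#' doublets are synthesized by summing the raw counts of random cell pairs,
#' real and artificial cells are embedded together by PCA on normalized
#' features (CLR for antibodies, total-count scaling + log for transcripts),
#' and each real cell is scored by the fraction of artificial cells among its
#' k nearest neighbours. The top `expected_rate` fraction of real cells by
#' score is flagged — a quota contract mirroring a doublet formation rate.
#'
#' @param adt an `"ADT"` [count_matrix()].
#' @param rna optional `"RNA"` [count_matrix()] over the same cells.
#' @param expected_rate expected doublet fraction, in (0, 0.5).
#' @param k neighbours used for the score.
#' @param n_pcs principal components for the embedding.
#' @param art_ratio artificial doublets per real cell.
#' @param seed RNG seed for pair sampling.
#' @return logical vector named by cell id (`TRUE` = flagged), with the
#'   per-cell score in `attr(, "score")`.
#' @export
flag_expression_doublets <- function(adt, rna = NULL, expected_rate = 0.075,
                                     k = 25, n_pcs = 10, art_ratio = 1,
                                     seed = 0) {
  stopifnot(inherits(adt, "count_matrix"))
  if (expected_rate <= 0 || expected_rate >= 0.5)
    stop("expected_rate must lie in (0, 0.5)")
  n <- nrow(adt$counts)
  if (n < 100) stop("need at least 100 cells to score doublets")
  ids <- cell_ids(adt)
  if (!is.null(rna)) stopifnot(identical(cell_ids(rna), ids))

  n_art <- round(n * art_ratio)
  pairs <- with_seed(seed, cbind(sample.int(n, n_art, replace = TRUE),
                                 sample.int(n, n_art, replace = TRUE)))
  same <- pairs[, 1] == pairs[, 2]
  pairs[same, 2] <- (pairs[same, 2] %% n) + 1L

  build <- function(cm, normalizer) {
    raw <- cm$counts
    art <- raw[pairs[, 1], , drop = FALSE] + raw[pairs[, 2], , drop = FALSE]
    rownames(art) <- sprintf("art%06d", seq_len(n_art))
    all_counts <- rbind(raw, art)
    normalizer(all_counts)
  }
  feats <- build(adt, function(m) suppressWarnings(
    clr_normalize(count_matrix(m, "ADT"))))
  if (!is.null(rna)) {
    rn <- build(rna, function(m) {
      tot <- Matrix::rowSums(m)
      tot[tot == 0] <- 1
      log1p(as.matrix(m / tot * 1000))
    })
    feats <- cbind(feats, rn)
  }
  # column z-scale, drop constant columns, then PCA
  sdv <- apply(feats, 2, sd)
  feats <- scale(feats[, sdv > 0, drop = FALSE])
  n_pcs <- min(n_pcs, ncol(feats))
  pcs <- prcomp(feats, rank. = n_pcs, center = FALSE, scale. = FALSE)$x
  nn <- cpp_knn(pcs, as.integer(min(k, n + n_art - 1)))
  is_art <- c(rep(FALSE, n), rep(TRUE, n_art))
  score <- rowMeans(matrix(is_art[nn[seq_len(n), , drop = FALSE]], n))

  quota <- floor(n * expected_rate)
  flag <- rep(FALSE, n)
  if (quota > 0) flag[order(-score, ids)[seq_len(quota)]] <- TRUE
  names(flag) <- ids
  attr(flag, "score") <- setNames(score, ids)
  flag
}

#' Keep cells with at least `floor` total antibody molecules
#'
#' Cells with fewer antibody molecules than the floor are too noisy for
#' surface phenotyping; strictly fewer than `floor` molecules is removed, so
#' a cell at exactly the floor is kept.
#'
#' @param adt an `"ADT"` [count_matrix()].
#' @param floor minimum total antibody count (default 128 = 2^7).
#' @return character vector of kept cell ids.
#' @export
filter_antibody_floor <- function(adt, floor = 128) {
  stopifnot(inherits(adt, "count_matrix"))
  tot <- Matrix::rowSums(adt$counts)
  cell_ids(adt)[tot >= floor]
}

#' Centered log-ratio normalization of antibody counts, on a log2 scale
#'
#' Per marker across cells: `y = (ln(x + 1) - mean(ln(x + 1))) / ln 2`. The
#' margin (per marker) and pseudocount (1) follow the standard ADT
#' convention; dividing by `ln 2` expresses the values in log2 units.
#'
#' @param adt an `"ADT"` [count_matrix()].
#' @return dense numeric matrix (cells x markers) of log2-scale CLR values.
#' @export
clr_normalize <- function(adt) {
  stopifnot(inherits(adt, "count_matrix"))
  m <- log(as.matrix(adt$counts) + 1)
  zero <- colSums(m != 0) == 0
  if (any(zero))
    warning(sprintf("marker(s) with all-zero counts: %s",
                    paste(colnames(m)[zero], collapse = ", ")))
  sweep(m, 2, colMeans(m)) / log(2)
}

#' Total-count normalization of transcript counts
#'
#' Each cell's counts are divided by its total and scaled up so that every
#' kept cell sums to `scale`. Cells with zero total are excluded with a
#' warning (they carry no transcript information).
#'
#' @param rna an `"RNA"` [count_matrix()].
#' @param scale target row sum (default 1000).
#' @return sparse numeric matrix (cells x genes); zero-total cells dropped.
#' @export
normalize_rna <- function(rna, scale = 1000) {
  stopifnot(inherits(rna, "count_matrix"))
  tot <- Matrix::rowSums(rna$counts)
  if (any(tot == 0)) {
    warning(sprintf("%d cell(s) with zero total counts excluded",
                    sum(tot == 0)))
  }
  keep <- tot > 0
  m <- rna$counts[keep, , drop = FALSE]
  out <- Matrix::Diagonal(x = scale / tot[keep]) %*% m
  dimnames(out) <- dimnames(m)
  as(out, "CsparseMatrix")
}

#' Run the QC waterfall: tag doublets, expression doublets, antibody floor
#'
#' Applies the three filters in their canonical order — cross-sample tag
#' doublets first, then expression doublets among tag singlets, then the
#' antibody-molecule floor — and returns the per-cell QC table plus
#' normalized matrices for the surviving cells. Cell counts are monotone
#' non-increasing across the stages.
#'
#' @param adt,rna,tags [count_matrix()] objects over identical cells.
#' @param sample_map data.frame mapping `(plate, tag)` to `participant` and
#'   `group` (as produced by [generate_cohort()]).
#' @param cells data.frame with `cell_id` and `plate`.
#' @param floor antibody-molecule floor.
#' @param doublet_rate expected expression-doublet rate.
#' @param seed RNG seed (tag threshold EM restarts + doublet detector).
#' @return a list with `cell_table` (one row per input cell: tag call,
#'   doublet flags, total ADT, `qc_pass`), `adt_clr` and `rna_norm`
#'   (normalized matrices over QC-passing cells), `thresholds_tags`, and a
#'   `provenance` data.frame of per-stage cell counts.
#' @export
qc_run <- function(adt, rna, tags, sample_map, cells, floor = 128,
                   doublet_rate = 0.075, seed = 0) {
  ids <- cell_ids(adt)
  stopifnot(identical(cell_ids(tags), ids), identical(cell_ids(rna), ids))
  prov <- list(c(stage = "input", n = length(ids)))

  thr <- tag_thresholds(tags, seed = substream_seed(seed, "tag-thresholds"))
  dmx <- demux_tags(tags, thr)
  singlet <- dmx$tag_call == "singlet"
  prov <- c(prov, list(c(stage = "tag_singlets", n = sum(singlet))))

  keep1 <- ids[singlet]
  xdbl <- flag_expression_doublets(
    subset_cells(adt, keep1), subset_cells(rna, keep1),
    expected_rate = doublet_rate,
    seed = substream_seed(seed, "expression-doublets"))
  keep2 <- keep1[!xdbl]
  prov <- c(prov, list(c(stage = "post_expression_doublets", n = length(keep2))))

  keep3 <- filter_antibody_floor(subset_cells(adt, keep2), floor = floor)
  prov <- c(prov, list(c(stage = "post_antibody_floor", n = length(keep3))))

  ct <- data.frame(cell_id = ids, plate = cells$plate[match(ids, cells$cell_id)],
                   tag_call = dmx$tag_call, tag = dmx$tag,
                   stringsAsFactors = FALSE)
  ct$expression_doublet <- FALSE
  ct$expression_doublet[match(names(xdbl)[xdbl], ids)] <- TRUE
  ct$total_adt <- as.numeric(Matrix::rowSums(adt$counts))
  ct$qc_pass <- ids %in% keep3
  mk <- match(paste(ct$plate, ct$tag), paste(sample_map$plate, sample_map$tag))
  ct$participant <- sample_map$participant[mk]
  ct$group <- sample_map$group[mk]

  kept_adt <- subset_cells(adt, keep3)
  kept_rna <- subset_cells(rna, keep3)
  list(cell_table = ct,
       adt_clr = clr_normalize(kept_adt),
       rna_norm = normalize_rna(kept_rna),
       thresholds_tags = thr,
       provenance = do.call(rbind, lapply(prov, function(x)
         data.frame(stage = x[["stage"]], n = as.integer(x[["n"]]),
                    stringsAsFactors = FALSE))))
}
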