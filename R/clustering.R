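#' Per-major-type Louvain resolutions
#'
#' Subclustering granularity differs by compartment: B cells 0.8, CD4+ T
#' cells 1.0, CD8+ T cells 1.3, classical monocytes 0.5, intermediate
#' monocytes 0.4, nonclassical monocytes 0.4, NK cells 0.3.
#'
#' @return named numeric vector of resolutions.
#' @export
default_resolutions <- function()
  c(B = 0.8, CD4T = 1.0, CD8T = 1.3, CM = 0.5, INT = 0.4, NCM = 0.4, NK = 0.3)

#' Build a shared-nearest-neighbour graph on antibody features
#'
#' Euclidean k-nearest neighbours on the (scaled) feature matrix, re-weighted
#' by the Jaccard overlap of the two cells' neighbourhoods (shared nearest
#' neighbours). Clustering consumes only antibody features — a matrix carrying
#' a `"RNA"` modality attribute is rejected, which keeps the transcriptomes
#' out of the clustering by construction.
#'
#' @param features numeric matrix (cells x markers).
#' @param k neighbours per cell; reduced with a warning when fewer than
#'   `k + 1` cells are available.
#' @param prune minimum shared-neighbour Jaccard weight for an edge to be
#'   kept (default 1/15).
#' @return an `igraph` weighted undirected graph with cell ids as vertex
#'   names; the number of connected components is reported in
#'   `attr(, "n_components")`.
#' @export
build_neighbor_graph <- function(features, k = 20, prune = 1 / 15) {
  modality <- attr(features, "modality")
  if (!is.null(modality) && modality != "ADT")
    stop("clustering consumes antibody features only; got modality ", modality)
  n <- nrow(features)
  if (n < 3) stop("need at least 3 cells to build a graph")
  if (n < k + 1) {
    warning(sprintf("only %d cells; reducing k from %d to %d", n, k, n - 1))
    k <- n - 1
  }
  nn <- cpp_knn(unname(as.matrix(features)), as.integer(k))
  ed <- cpp_snn_edges(nn, prune)
  dedup <- !duplicated(paste(ed$from, ed$to))
  g <- igraph::graph_from_data_frame(
    data.frame(from = rownames(features)[ed$from[dedup]],
               to = rownames(features)[ed$to[dedup]],
               weight = ed$weight[dedup]),
    directed = FALSE,
    vertices = data.frame(name = rownames(features)))
  attr(g, "n_components") <- igraph::count_components(g)
  g
}

#' Louvain community detection at a given resolution
#'
#' Modularity-based clustering of the shared-nearest-neighbour graph.
#' Deterministic given the seed; labels are renumbered by decreasing cluster
#' size (1 = largest).
#'
#' @param graph an igraph graph from [build_neighbor_graph()].
#' @param resolution Louvain resolution parameter.
#' @param seed RNG seed.
#' @return integer cluster labels named by cell id.
#' @export
modularity_cluster <- function(graph, resolution = 1, seed = 0) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  cl <- with_seed(seed,
    igraph::cluster_louvain(graph, resolution = resolution))
  mem <- igraph::membership(cl)
  sizes <- sort(table(mem), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  setNames(as.integer(relabel[as.character(mem)]),
           igraph::V(graph)$name)
}

#' Subcluster each major cell type on its non-negative antibodies
#'
#' For each major type: keep the analysis markers that are genuinely
#' detected in that type (nonzero after thresholding in at least
#' `min_pos_frac` of its cells), z-scale each marker, build the
#' shared-nearest-neighbour graph and run Louvain at the type's resolution.
#' Transcripts never enter this stage.
#'
#' @param thresholded numeric matrix (cells x markers) from
#'   [apply_thresholds()].
#' @param major_type character vector of per-cell type labels (named by cell
#'   id or aligned with rows).
#' @param resolutions named resolutions per type, see
#'   [default_resolutions()].
#' @param analysis_markers markers eligible for clustering (after
#'   [exclude_marker()]).
#' @param k neighbours for the graph.
#' @param min_pos_frac minimum positive-cell fraction for a marker to count
#'   as non-negative in a type.
#' @param min_cells types with fewer cells are left as a single cluster.
#' @param seed master seed; each type gets its own substream.
#' @return a `cluster_assignment` data.frame: `cell_id`, `major_type`,
#'   `cluster` (e.g. `"CD4T_2"`), `resolution`.
#' @export
cluster_major_types <- function(thresholded, major_type,
                                resolutions = default_resolutions(),
                                analysis_markers = colnames(thresholded),
                                k = 20, min_pos_frac = 0.05, min_cells = 50,
                                seed = 0) {
  stopifnot(length(major_type) == nrow(thresholded))
  out <- list()
  for (ty in intersect(names(resolutions), unique(major_type))) {
    idx <- which(major_type == ty)
    sub <- thresholded[idx, analysis_markers, drop = FALSE]
    if (length(idx) < min_cells) {
      out[[ty]] <- data.frame(cell_id = rownames(sub), major_type = ty,
                              cluster = paste0(ty, "_1"),
                              resolution = NA_real_, stringsAsFactors = FALSE)
      next
    }
    pos_frac <- colMeans(sub > 0)
    use <- names(pos_frac)[pos_frac >= min_pos_frac]
    feats <- scale(sub[, use, drop = FALSE])
    feats <- feats[, apply(is.finite(feats), 2, all), drop = FALSE]
    attr(feats, "modality") <- "ADT"
    g <- build_neighbor_graph(feats, k = k)
    cl <- modularity_cluster(g, resolution = resolutions[[ty]],
                             seed = substream_seed(seed, ty))
    out[[ty]] <- data.frame(cell_id = names(cl), major_type = ty,
                            cluster = paste0(ty, "_", cl),
                            resolution = resolutions[[ty]],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cluster_assignment", class(res))
  res
}

#' Define a marker-based cluster split
#'
#' @param cluster label of the cluster to split.
#' @param markers markers whose joint positivity defines the "hi" side.
#' @param relative `"threshold"` (hi = nonzero after thresholding) or
#'   `"median"` (hi = above the cluster median of each marker).
#' @return a `split_rule` object.
#' @export
split_rule <- function(cluster, markers, relative = c("threshold", "median")) {
  structure(list(cluster = cluster, markers = markers,
                 relative = match.arg(relative)), class = "split_rule")
}

#' Split a cluster on marker expression
#'
#' Partitions the target cluster into a `hi` side (every rule marker
#' positive) and a `lo` side, labelled `<cluster>a` / `<cluster>b`. A split
#' leaving either side empty is rejected and the assignment returned
#' unchanged with a warning. Provenance (`original_cluster`, `split_rule`)
#' is recorded so a split can be reversed.
#'
#' @param assignment a `cluster_assignment` data.frame.
#' @param thresholded the thresholded marker matrix the assignment was built
#'   from.
#' @param rule a [split_rule()].
#' @return the updated assignment.
#' @export
split_cluster <- function(assignment, thresholded, rule) {
  stopifnot(inherits(rule, "split_rule"))
  idx <- which(assignment$cluster == rule$cluster)
  if (!length(idx)) stop(sprintf("no cells in cluster '%s'", rule$cluster))
  miss <- setdiff(rule$markers, colnames(thresholded))
  if (length(miss))
    stop(sprintf("unknown marker(s): %s", paste(miss, collapse = ", ")))
  vals <- thresholded[assignment$cell_id[idx], rule$markers, drop = FALSE]
  cut <- if (rule$relative == "threshold") rep(0, ncol(vals)) else
    apply(vals, 2, median)
  hi <- rowSums(sweep(vals, 2, cut, ">")) == ncol(vals)
  if (all(hi) || !any(hi)) {
    warning(sprintf("split of '%s' on %s leaves one side empty; rejected",
                    rule$cluster, paste(rule$markers, collapse = "+")))
    return(assignment)
  }
  if (!"original_cluster" %in% names(assignment)) {
    assignment$original_cluster <- NA_character_
    assignment$split_rule <- NA_character_
  }
  assignment$original_cluster[idx] <- rule$cluster
  assignment$split_rule[idx] <- sprintf("%s:%s", rule$relative,
                                        paste(rule$markers, collapse = "+"))
  assignment$cluster[idx] <- paste0(rule$cluster, ifelse(hi, "a", "b"))
  assignment
}

#' Undo a recorded cluster split
#'
#' @param assignment a `cluster_assignment` with split provenance.
#' @param cluster the original (pre-split) cluster label to restore.
#' @return the assignment with the split reversed.
#' @export
unsplit_cluster <- function(assignment, cluster) {
  idx <- which(!is.na(assignment$original_cluster) &
                 assignment$original_cluster == cluster)
  if (!length(idx)) stop(sprintf("no recorded split for '%s'", cluster))
  assignment$cluster[idx] <- cluster
  assignment$original_cluster[idx] <- NA_character_
  assignment$split_rule[idx] <- NA_character_
  assignment
}

#' Two-dimensional embedding for diagnostics
#'
#' A principal-component projection of the (scaled) feature matrix onto two
#' axes, for plotting only — never an input to any statistic. Signs are fixed
#' deterministically, so the embedding is reproducible.
#'
#' @param features numeric matrix (cells x markers).
#' @param seed unused by the PCA backend, kept for interface stability.
#' @return numeric matrix (cells x 2).
#' @export
embed_2d <- function(features, seed = 0) {
  feats <- as.matrix(features)
  keep <- apply(feats, 2, function(v) sd(v) > 0)
  p <- prcomp(feats[, keep, drop = FALSE], rank. = 2, scale. = TRUE)
  xy <- p$x[, 1:2, drop = FALSE]
  # deterministic sign convention: largest-magnitude loading positive
  for (j in 1:2) if (p$rotation[which.max(abs(p$rotation[, j])), j] < 0)
    xy[, j] <- -xy[, j]
  colnames(xy) <- c("dim1", "dim2")
  rownames(xy) <- rownames(features)
  xy
}
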