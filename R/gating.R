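#' Define a Boolean immunophenotype gate
#'
#' A gate is a named conjunction of marker positivity/negativity predicates
#' with an optional parent gate, mirroring a flow-cytometry gating tree.
#' Predicates are written `"CD19+"` / `"CD3-"`: `+` means strictly positive
#' after thresholding (nonzero), `-` means exactly zero.
#'
#' @param name gate name.
#' @param predicates character vector of `"<marker>+"` / `"<marker>-"` terms.
#' @param parent name of the parent gate, or `NULL` for a root gate.
#' @param priority integer; lower wins when a cell satisfies several terminal
#'   gates of equal depth.
#' @return a `gate_def` object.
#' @export
gate_def <- function(name, predicates, parent = NULL, priority = 0L) {
  sign <- substring(predicates, nchar(predicates))
  if (!all(sign %in% c("+", "-")))
    stop("each predicate must end in '+' or '-'")
  structure(list(name = name,
                 predicates = data.frame(
                   marker = substring(predicates, 1, nchar(predicates) - 1L),
                   sign = sign, stringsAsFactors = FALSE),
                 parent = parent, priority = as.integer(priority)),
            class = "gate_def")
}

#' The default 8-gate major PBMC type scheme
#'
#' B cells CD19+CD3-; T cells CD19-CD3+ with CD4+CD8- and CD8+CD4- children;
#' monocytes CD19-CD3-CD56- with classical (CD14+CD16-), intermediate
#' (CD14+CD16+) and nonclassical (CD14-CD16+CD56-) children; NK cells
#' CD4-CD56+CD14-CD20-CD123-CD206-. The structural T and monocyte parents
#' carry no label of their own: a CD3+CD4+CD8+ cell satisfies neither T
#' child and stays unassigned. The nonclassical gate repeats CD56- although
#' the parent already requires it; the redundancy is kept as printed in the
#' scheme this reproduces.
#'
#' @return a named list of [gate_def()] objects.
#' @export
default_gates <- function() {
  gates <- list(
    gate_def("B",    c("CD19+", "CD3-"),          priority = 1L),
    gate_def("T",    c("CD19-", "CD3+"),          priority = 2L),
    gate_def("CD4T", c("CD4+", "CD8-"),  parent = "T", priority = 3L),
    gate_def("CD8T", c("CD8+", "CD4-"),  parent = "T", priority = 4L),
    gate_def("M",    c("CD19-", "CD3-", "CD56-"), priority = 5L),
    gate_def("CM",   c("CD14+", "CD16-"), parent = "M", priority = 6L),
    gate_def("INT",  c("CD14+", "CD16+"), parent = "M", priority = 7L),
    gate_def("NCM",  c("CD14-", "CD16+", "CD56-"), parent = "M", priority = 8L),
    gate_def("NK",   c("CD4-", "CD56+", "CD14-", "CD20-", "CD123-", "CD206-"),
             priority = 9L))
  setNames(gates, vapply(gates, `[[`, character(1), "name"))
}

gate_depth <- function(gate, gates) {
  d <- 1L
  p <- gate$parent
  seen <- gate$name
  while (!is.null(p)) {
    if (p %in% seen) stop(sprintf("cyclic parent chain at gate '%s'", p))
    seen <- c(seen, p)
    if (is.null(gates[[p]])) stop(sprintf("unknown parent gate '%s'", p))
    d <- d + 1L
    p <- gates[[p]]$parent
  }
  d
}

gate_matrix_eval <- function(mat, gate) {
  miss <- setdiff(gate$predicates$marker, colnames(mat))
  if (length(miss))
    stop(sprintf("gate '%s' references marker(s) missing from the profile: %s",
                 gate$name, paste(miss, collapse = ", ")))
  ok <- rep(TRUE, nrow(mat))
  for (i in seq_len(nrow(gate$predicates))) {
    v <- mat[, gate$predicates$marker[i]]
    ok <- ok & if (gate$predicates$sign[i] == "+") v > 0 else v == 0
  }
  ok
}

#' Evaluate one gate (including its parent chain) on a single cell
#'
#' @param profile named numeric vector, the cell's thresholded marker values
#'   (zero = negative).
#' @param gate a [gate_def()].
#' @param gates the full gate set (needed to resolve parents).
#' @return `TRUE` iff every `+` predicate is strictly positive, every `-`
#'   predicate is zero, and the parent gate (if any) is also true.
#' @export
evaluate_gate <- function(profile, gate, gates = default_gates()) {
  mat <- matrix(profile, 1, dimnames = list("cell", names(profile)))
  ok <- gate_matrix_eval(mat, gate)
  if (ok && !is.null(gate$parent))
    ok <- evaluate_gate(profile, gates[[gate$parent]], gates)
  unname(ok)
}

#' Assign major cell types from a thresholded marker matrix
#'
#' Each cell receives the deepest terminal gate (a gate no other gate names
#' as parent) that it satisfies along its full parent chain; cells
#' satisfying no terminal gate are `"unassigned"`, and cells satisfying
#' several are resolved by gate priority (the ambiguity count is recorded in
#' `attr(, "n_ambiguous")`).
#'
#' @param mat numeric matrix (cells x markers), thresholded so zero means
#'   negative.
#' @param gates a named list of [gate_def()]s, e.g. [default_gates()].
#' @return character vector of type labels named by cell id.
#' @export
assign_major_types <- function(mat, gates = default_gates()) {
  n <- nrow(mat)
  if (!length(gates))
    return(setNames(rep("unassigned", n), rownames(mat)))
  parents <- unlist(lapply(gates, `[[`, "parent"))
  terminal <- setdiff(names(gates), parents)
  depth <- vapply(gates, gate_depth, integer(1), gates = gates)
  # satisfaction of each gate including its parent chain
  sat <- vapply(gates, function(g) gate_matrix_eval(mat, g), logical(n))
  sat <- matrix(sat, nrow = n, dimnames = list(rownames(mat), names(gates)))
  for (nm in names(gates)) {
    p <- gates[[nm]]$parent
    while (!is.null(p)) {
      sat[, nm] <- sat[, nm] & sat[, p]
      p <- gates[[p]]$parent
    }
  }
  sat_t <- sat[, terminal, drop = FALSE]
  # rank terminal gates: deepest first, then by priority
  pr <- vapply(gates[terminal], `[[`, integer(1), "priority")
  ord <- order(-depth[terminal], pr)
  sat_t <- sat_t[, ord, drop = FALSE]
  labels <- rep("unassigned", n)
  n_hits <- rowSums(sat_t)
  hit <- n_hits > 0
  labels[hit] <- colnames(sat_t)[
    max.col(sat_t[hit, , drop = FALSE] * 1, "first")]
  out <- setNames(labels, rownames(mat))
  attr(out, "n_ambiguous") <- sum(n_hits > 1)
  out
}
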