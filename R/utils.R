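#' Derive a reproducible substream seed from a master seed and a stage name
#'
#' A single master seed fans out to named substreams so that each pipeline
#' stage draws from its own reproducible stream: re-running one stage never
#' perturbs another. The derived seed is a deterministic 31-bit hash of the
#' master seed and the stream name.
#'
#' @param master integer master seed.
#' @param name character stream name, e.g. `"adt"`, `"doublets"`.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  m <- 2147483647            # 2^31 - 1, keeps seeds valid R integers
  h <- as.numeric(master) %% m
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  as.integer(h)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed`, so library code never clobbers the
#' caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hash a configuration list for provenance records
#'
#' A small deterministic polynomial hash of the deparsed object; every output
#' table carries it so results can be traced to the exact configuration.
#'
#' @param x any R object.
#' @return an 8-character hexadecimal string.
#' @export
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
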