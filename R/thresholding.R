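#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Every antibody shows both non-specific (background) and specific (signal)
#' binding; on the CLR scale the two appear as overlapping normal
#' distributions. This fits the two-component mixture by
#' expectation-maximization: initialization splits the data at the median
#' (component means = means of the two halves), with additional seeded random
#' restarts initialized from random pairs of data points; the best
#' log-likelihood wins. Convergence when the log-likelihood improves by less
#' than `tol` or after `max_iter` iterations. The log-likelihood is asserted
#' non-decreasing at every iteration.
#'
#' @param values numeric vector (at least 50 finite values).
#' @param k number of components; only 2 is supported.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param n_restarts random restarts in addition to the median-split start.
#' @param seed seed for the restarts.
#' @return an object of class `mixture_fit`: `pi`, `mu`, `sigma` (length-2,
#'   ordered so `mu[1] <= mu[2]`), `loglik`, `n_iter`, `n_cells`,
#'   `converged`. Degenerate data (zero variance) yields `converged = FALSE`.
#' @export
fit_mixture_1d <- function(values, k = 2, max_iter = 500, tol = 1e-8,
                           n_restarts = 5, seed = 0) {
  if (k != 2) stop("only k = 2 mixtures are supported")
  x <- values[is.finite(values)]
  if (length(x) < 50) stop("need at least 50 finite values")
  bad <- structure(list(pi = c(NA, NA), mu = c(NA, NA), sigma = c(NA, NA),
                        loglik = -Inf, n_iter = 0L, n_cells = length(x),
                        converged = FALSE), class = "mixture_fit")
  if (var(x) == 0) return(bad)

  run_em <- function(mu, sg, pw) {
    n <- length(x)
    ll_prev <- -Inf
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      d1 <- pw[1] * dnorm(x, mu[1], sg[1])
      d2 <- pw[2] * dnorm(x, mu[2], sg[2])
      tot <- d1 + d2
      if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
      ll <- sum(log(tot))
      # EM guarantees monotone likelihood; a decrease means a numerical fault
      stopifnot(ll >= ll_prev - 1e-7 * max(1, abs(ll_prev)))
      if (is.finite(ll_prev) && ll - ll_prev < tol) { converged <- TRUE; break }
      ll_prev <- ll
      r <- d1 / tot
      n1 <- sum(r); n2 <- n - n1
      if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
      mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
      sg <- sqrt(c(sum(r * (x - mu[1])^2) / n1,
                   sum((1 - r) * (x - mu[2])^2) / n2))
      if (any(sg < 1e-6)) return(NULL)
      pw <- c(n1, n2) / n
    }
    list(pi = pw, mu = mu, sigma = sg, loglik = ll, n_iter = it,
         converged = converged)
  }

  med <- median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (!length(hi)) hi <- max(x)
  starts <- list(list(mu = c(mean(lo), mean(hi)),
                      sg = pmax(c(sd(x), sd(x)) / 2, 1e-3),
                      pw = c(0.5, 0.5)))
  starts <- c(starts, with_seed(seed, lapply(seq_len(n_restarts), function(i) {
    mu0 <- sort(sample(x, 2))
    if (diff(mu0) < 1e-8) mu0 <- mu0 + c(-1, 1) * sd(x) / 10
    u <- runif(1, 0.3, 0.7)
    list(mu = mu0, sg = pmax(rep(sd(x) / 2, 2), 1e-3), pw = c(u, 1 - u))
  })))

  best <- NULL
  for (s in starts) {
    fit <- run_em(s$mu, s$sg, s$pw)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best)) return(bad)
  ord <- order(best$mu)
  structure(list(pi = best$pi[ord], mu = best$mu[ord], sigma = best$sigma[ord],
                 loglik = best$loglik, n_iter = best$n_iter,
                 n_cells = length(x), converged = best$converged),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> pi=(%.3f, %.3f) mu=(%.3f, %.3f) sigma=(%.3f, %.3f)\n  loglik=%.4f, %d iterations, converged=%s\n",
    x$pi[1], x$pi[2], x$mu[1], x$mu[2], x$sigma[1], x$sigma[2],
    x$loglik, x$n_iter, x$converged))
  invisible(x)
}

#' Intersection of the two mixture components
#'
#' Solves `pi1 * phi(x; mu1, sigma1) = pi2 * phi(x; mu2, sigma2)` for the
#' crossing point between the component means — the point where a value
#' becomes more likely to come from the signal component than from the
#' background, used as the minimum expression threshold. With equal
#' variances the closed-form root is used; with unequal variances the
#' quadratic has two roots and the one inside `[mu1, mu2]` is returned. If no
#' root falls in the interval (extreme weight imbalance), the midpoint is
#' returned with a warning. The result is invariant under swapping component
#' labels.
#'
#' @param fit a converged `mixture_fit`, or a list with `pi`, `mu`, `sigma`.
#' @return the threshold (numeric scalar).
#' @export
gaussian_intersection <- function(fit) {
  if (inherits(fit, "mixture_fit") && !fit$converged)
    stop("mixture did not converge; use threshold_from_negative_population() ",
         "or supply a manual threshold")
  ord <- order(fit$mu)
  p <- fit$pi[ord]; mu <- fit$mu[ord]; sg <- fit$sigma[ord]
  stopifnot(all(sg > 0), mu[1] < mu[2])
  if (isTRUE(all.equal(sg[1], sg[2]))) {
    s2 <- mean(sg)^2
    return((mu[1] + mu[2]) / 2 + s2 * log(p[1] / p[2]) / (mu[2] - mu[1]))
  }
  a <- 1 / sg[2]^2 - 1 / sg[1]^2
  b <- 2 * (mu[1] / sg[1]^2 - mu[2] / sg[2]^2)
  cc <- mu[2]^2 / sg[2]^2 - mu[1]^2 / sg[1]^2 +
    2 * log(p[1] * sg[2] / (p[2] * sg[1]))
  disc <- b^2 - 4 * a * cc
  roots <- if (disc < 0) numeric(0) else
    (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots >= mu[1] & roots <= mu[2]]
  if (!length(inside)) {
    warning("no intersection between the component means; using the midpoint")
    return((mu[1] + mu[2]) / 2)
  }
  inside[1]
}

#' Threshold from a declared negative cell population
#'
#' Fallback route when mixture deconvolution fails or a known negative
#' population exists (e.g. a B-cell marker on T cells): the threshold is an
#' upper quantile of the negative population's CLR values.
#'
#' @param values_neg CLR values of the negative population (>= 50 cells).
#' @param quantile probability of the upper quantile (default 0.99).
#' @return the threshold (numeric scalar).
#' @export
threshold_from_negative_population <- function(values_neg, quantile = 0.99) {
  x <- values_neg[is.finite(values_neg)]
  if (length(x) < 50) stop("need at least 50 negative cells")
  stopifnot(quantile > 0, quantile <= 1)
  unname(stats::quantile(x, quantile))
}

#' Zero out sub-threshold surface expression
#'
#' Values strictly below a marker's threshold are set to zero ("below the
#' threshold" is strict: a value exactly at the threshold is kept). After
#' this step a zero unambiguously means "not expressed", which is what the
#' Boolean gates consume.
#'
#' @param clr numeric matrix (cells x markers) of CLR values.
#' @param thresholds named numeric vector or a `marker_thresholds` table.
#' @return the thresholded matrix, with per-marker zeroed-cell counts in
#'   `attr(, "n_zeroed")`.
#' @export
apply_thresholds <- function(clr, thresholds) {
  if (is.data.frame(thresholds))
    thresholds <- setNames(thresholds$threshold, thresholds$marker)
  missing <- setdiff(colnames(clr), names(thresholds))
  if (length(missing))
    stop(sprintf("no threshold for marker(s): %s",
                 paste(missing, collapse = ", ")))
  thr <- thresholds[colnames(clr)]
  below <- sweep(clr, 2, thr, "<")
  out <- clr
  out[below] <- 0
  attr(out, "n_zeroed") <- colSums(below)
  out
}

#' Remove a marker from the analysis marker set
#'
#' Some antibodies (typically chemokine receptors such as CD197/CCR7) have
#' inherent background that thresholding cannot rescue; they are dropped from
#' all downstream clustering and gating.
#'
#' @param markers character vector, the current analysis marker set.
#' @param exclude markers to remove; unknown names are a warning no-op.
#' @return the reduced marker set.
#' @export
exclude_marker <- function(markers, exclude = "CD197") {
  unknown <- setdiff(exclude, markers)
  if (length(unknown))
    warning(sprintf("marker(s) not in the analysis set: %s",
                    paste(unknown, collapse = ", ")))
  setdiff(markers, exclude)
}

#' Fit per-marker expression thresholds for a CLR matrix
#'
#' Runs [fit_mixture_1d()] per marker and takes the [gaussian_intersection()]
#' as the threshold. When EM fails for a marker, a declared negative
#' population (if any) provides the [threshold_from_negative_population()]
#' route; otherwise a manual threshold must be supplied.
#'
#' @param clr numeric matrix (cells x markers) of CLR values.
#' @param negative_cells optional named list: marker -> cell ids of a known
#'   negative population.
#' @param manual optional named numeric vector of manual thresholds.
#' @param quantile quantile for the negative-population route.
#' @param seed EM restart seed.
#' @return a `marker_thresholds` data.frame: `marker`, `method`, `pi1`,
#'   `mu1`, `sigma1`, `pi2`, `mu2`, `sigma2`, `threshold`, `converged`,
#'   `n_cells`.
#' @export
fit_thresholds <- function(clr, negative_cells = NULL, manual = NULL,
                           quantile = 0.99, seed = 0) {
  rows <- lapply(colnames(clr), function(mk) {
    v <- clr[, mk]
    fit <- fit_mixture_1d(v, seed = substream_seed(seed, mk))
    row <- data.frame(marker = mk, method = "mixture",
                      pi1 = fit$pi[1], mu1 = fit$mu[1], sigma1 = fit$sigma[1],
                      pi2 = fit$pi[2], mu2 = fit$mu[2], sigma2 = fit$sigma[2],
                      threshold = NA_real_, converged = fit$converged,
                      n_cells = fit$n_cells, stringsAsFactors = FALSE)
    if (fit$converged) {
      row$threshold <- gaussian_intersection(fit)
    } else if (!is.null(negative_cells[[mk]])) {
      row$method <- "negative_population"
      row$threshold <- threshold_from_negative_population(
        v[negative_cells[[mk]]], quantile = quantile)
    } else if (!is.null(manual) && mk %in% names(manual)) {
      row$method <- "manual"
      row$threshold <- manual[[mk]]
    } else {
      stop(sprintf(
        "mixture fit failed for marker '%s' and no negative population or manual threshold was supplied", mk))
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("marker_thresholds", class(out))
  out
}
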