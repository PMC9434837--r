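test_that("EM recovers a well-separated mixture and beats a grid oracle", {
  set.seed(123)
  n <- 5000
  z <- runif(n) < 0.6
  x <- ifelse(z, rnorm(n, 0, 1), rnorm(n, 4, 1))
  fit <- fit_mixture_1d(x, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$mu[1] - 0), 0.1)
  expect_lt(abs(fit$mu[2] - 4), 0.1)
  expect_lt(abs(fit$pi[1] - 0.6), 0.03)

  # brute-force ML oracle: grid over (mu1, mu2) with sigma and pi fixed at
  # the generating values; EM (free parameters) must do at least as well
  grid <- seq(-0.5, 4.5, by = 0.01)
  best <- -Inf
  for (m1 in grid[grid < 2]) {
    lls <- vapply(grid[grid > 2], function(m2)
      mix_loglik(x, 0.6, m1, 1, m2, 1), numeric(1))
    best <- max(best, max(lls))
  }
  expect_gte(fit$loglik, best - 1e-4)
})

test_that("degenerate input gives converged = FALSE and intersection refuses it", {
  fit <- fit_mixture_1d(rep(2.5, 100))
  expect_false(fit$converged)
  expect_error(gaussian_intersection(fit), "negative")
  expect_error(fit_mixture_1d(rnorm(10)), "at least 50")
})

test_that("gaussian_intersection closed forms and grid oracle", {
  eq <- list(pi = c(0.5, 0.5), mu = c(0, 4), sigma = c(1, 1))
  expect_equal(gaussian_intersection(eq), 2)
  skew <- list(pi = c(0.9, 0.1), mu = c(0, 4), sigma = c(1, 1))
  expect_equal(gaussian_intersection(skew), 2 + log(9) / 4, tolerance = 1e-6)
  # label-swap invariance
  swapped <- list(pi = c(0.1, 0.9), mu = c(4, 0), sigma = c(1, 1))
  expect_equal(gaussian_intersection(swapped), gaussian_intersection(skew))

  # unequal variances: verify against a sign-change scan at 1e-6 resolution
  uneq <- list(pi = c(0.5, 0.5), mu = c(0, 4), sigma = c(1, 2))
  root <- gaussian_intersection(uneq)
  expect_true(root > 0 && root < 4)
  f <- function(x) 0.5 * dnorm(x, 0, 1) - 0.5 * dnorm(x, 4, 2)
  xs <- seq(root - 1e-5, root + 1e-5, by = 1e-6)
  expect_true(any(sign(f(head(xs, -1))) != sign(f(xs[-1]))))
})

test_that("negative-population thresholds follow the stated quantile", {
  neg <- runif(200, 0, 1)
  expect_lte(threshold_from_negative_population(neg, 0.99), 1.0)
  set.seed(5)
  big <- rnorm(1e5)
  expect_equal(threshold_from_negative_population(big, 0.99),
               qnorm(0.99), tolerance = 0.05)
  expect_equal(threshold_from_negative_population(neg, 1.0), max(neg))
  expect_error(threshold_from_negative_population(rnorm(20)), "50")
})

test_that("apply_thresholds zeroes strictly-below values only", {
  m <- matrix(c(0.9, 1.0, 1.1, 2.0), 4, 1,
              dimnames = list(paste0("c", 1:4), "CD3"))
  out <- apply_thresholds(m, c(CD3 = 1.0))
  expect_equal(as.numeric(out), c(0, 1.0, 1.1, 2.0))  # at threshold kept
  expect_identical(unname(attr(out, "n_zeroed")["CD3"]), 1)
  all_below <- apply_thresholds(m, c(CD3 = 5))
  expect_true(all(all_below == 0))
  expect_error(apply_thresholds(m, c(CD8 = 1)), "CD3")
})

test_that("thresholds separate true positives from negatives on a cohort", {
  coh <- small_cohort(seed = 37)
  clr <- clr_normalize(coh$adt)
  tab <- fit_thresholds(clr, seed = 2)
  expect_true(all(tab$converged))
  # threshold lies between the component means
  expect_true(all(tab$threshold >= tab$mu1 & tab$threshold <= tab$mu2))
  th <- apply_thresholds(clr, tab)
  tr <- coh$truth$cells
  sig <- coh$truth$signatures
  sub <- coh$truth$sub_signatures
  sens <- spec <- c()
  for (ty in rownames(sig)) {
    in_ty <- tr$true_type == ty
    for (mk in colnames(sig)) {
      if (mk %in% names(sub[[ty]])) next   # probabilistic in this type
      v <- th[in_ty, mk]
      if (sig[ty, mk]) sens <- c(sens, mean(v > 0))
      else spec <- c(spec, mean(v == 0))
    }
  }
  expect_true(all(sens >= 0.90))
  expect_true(all(spec >= 0.95))
  # spec as false-positive bound: true-negative cells above threshold <= 5%
  expect_true(all(1 - spec <= 0.05))
})

test_that("exclude_marker shrinks the analysis set and warns on unknowns", {
  mk <- default_markers()
  expect_length(exclude_marker(mk, "CD197"), 39)
  expect_length(exclude_marker(mk, character(0)), 40)
  expect_warning(out <- exclude_marker(mk, "CD999"), "CD999")
  expect_length(out, 40)
})

test_that("fit_thresholds falls back to the negative-population route", {
  set.seed(9)
  # constant marker: EM cannot converge; declare a negative population
  m <- cbind(noise = rep(0, 300), real = rpois(300, 5))
  rownames(m) <- sprintf("c%03d", 1:300)
  clr <- suppressWarnings(clr_normalize(count_matrix(m, "ADT")))
  clr[, "noise"] <- 0  # degenerate
  # suppressWarnings: the Poisson marker may trigger the midpoint fallback
  tab <- suppressWarnings(
    fit_thresholds(clr, negative_cells = list(noise = rownames(m)[1:100]),
                   seed = 1))
  expect_identical(tab$method[tab$marker == "noise"], "negative_population")
  expect_error(suppressWarnings(fit_thresholds(clr, seed = 1)), "noise")
})
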