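test_that("config validation rejects bad fields by name", {
  expect_error(synthetic_config(doublet_rate = 0.6), "doublet_rate")
  expect_error(synthetic_config(type_fractions = c(B = 0.5, CD4T = 0.4)),
               "type_fractions")
  expect_error(synthetic_config(adt_signal = list(meanlog = 1, sdlog = -1)),
               "sdlog")
  expect_error(synthetic_config(planted_de = data.frame(
    gene = "nope", type = "CD4T", group = "HIVneg", lfc = 1)), "planted_de")
  expect_error(synthetic_config(
    sub_signatures = list(CD4T = c(NOPE = 0.5))), "sub_signatures")
})

test_that("doublet_rate = 0 yields no doublets; same seed is bit-identical", {
  cfg <- synthetic_config(n_per_group = 1, cells_per_participant = 80,
                          doublet_rate = 0, seed = 3)
  coh <- generate_cohort(cfg)
  expect_false(any(coh$truth$cells$is_doublet))
  expect_identical(coh$truth$n_doublet, 0L)

  cfg2 <- synthetic_config(n_per_group = 1, cells_per_participant = 80, seed = 5)
  a <- generate_cohort(cfg2)
  b <- generate_cohort(cfg2)
  expect_identical(as.matrix(a$adt$counts), as.matrix(b$adt$counts))
  expect_identical(as.matrix(a$rna$counts), as.matrix(b$rna$counts))
  expect_identical(as.matrix(a$tags$counts), as.matrix(b$tags$counts))
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("cohort structure: unique ids, aligned matrices, plate pairing", {
  coh <- small_cohort(seed = 11)
  ids <- cell_ids(coh$adt)
  expect_false(anyDuplicated(ids) > 0)
  expect_identical(cell_ids(coh$rna), ids)
  expect_identical(cell_ids(coh$tags), ids)
  expect_identical(coh$truth$cells$cell_id, ids)
  # doublet constituents always share a plate
  db <- coh$truth$cells[coh$truth$cells$is_doublet, ]
  sm <- coh$sample_map
  expect_true(all(sm$plate[match(db$participant, sm$participant)] ==
                    sm$plate[match(db$participant2, sm$participant)]))
  # each plate holds one participant per group under the default design
  expect_true(all(table(sm$plate, sm$group) == 1))
})

test_that("doublet count is binomial around the configured rate at study scale", {
  # full stated design: 4 groups x 8 participants x 1300 cells
  cfg <- synthetic_config(seed = 101)
  coh <- generate_cohort(cfg)
  n_singlet <- coh$truth$n_singlet
  expect_identical(n_singlet, 41600L)
  d <- coh$truth$n_doublet
  expect_lt(abs(d - 0.075 * n_singlet), 3 * sqrt(n_singlet * 0.075 * 0.925))
  # observed fraction of doublets among drawn singlets tracks the rate
  expect_lt(abs(d / n_singlet - 0.075), 3 * sqrt(0.075 * 0.925 / n_singlet))
})

test_that("positive-marker CLR distributions are bimodal (2-component BIC wins)", {
  coh <- small_cohort(seed = 13, n_per_group = 2, cells = 300)
  clr <- clr_normalize(coh$adt)
  expect_gte(nrow(clr), 2000)
  for (mk in c("CD3", "CD19", "CD14", "CD56")) {
    v <- clr[, mk]
    fit2 <- fit_mixture_1d(v, seed = 1)
    bic2 <- -2 * fit2$loglik + 5 * log(length(v))
    bic1 <- -2 * sum(dnorm(v, mean(v), sd(v), log = TRUE)) + 2 * log(length(v))
    expect_lt(bic2, bic1)
  }
})

test_that("singlet tag counts are dominated by one tag", {
  coh <- small_cohort(seed = 17)
  tr <- coh$truth$cells
  m <- as.matrix(coh$tags$counts)[!tr$is_doublet, ]
  srt <- t(apply(m, 1, sort, decreasing = TRUE))
  ratio <- srt[, 1] / pmax(srt[, 2], 1)
  expect_gte(mean(ratio >= 5), 0.99)
})

test_that("truth_report echoes planted effects row by row", {
  cfg0 <- synthetic_config(n_per_group = 1, cells_per_participant = 60,
                           planted_de = data.frame(gene = character(0),
                                                   type = character(0),
                                                   group = character(0),
                                                   lfc = numeric(0)),
                           planted_prop_shift = data.frame(
                             type = "INT", group = "HIVposCVDpos",
                             multiplier = 2))
  rep0 <- truth_report(generate_cohort(cfg0)$truth)
  expect_identical(sum(rep0$effect == "de"), 0L)
  expect_equal(rep0$value[rep0$effect == "proportion_shift"], 2.0)

  coh <- small_cohort(seed = 19)   # default config plants 3 DE genes
  rep1 <- truth_report(coh$truth)
  expect_identical(sum(rep1$effect == "de"), 3L)
  expect_setequal(rep1$target[rep1$effect == "de"], c("G021", "G022", "G023"))
})
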