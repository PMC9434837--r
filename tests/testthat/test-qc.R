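make_tags <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("Tag0", seq_len(ncol(m)))
  rownames(m) <- sprintf("c%03d", seq_len(nrow(m)))
  count_matrix(m, "TAG")
}

test_that("demux_tags calls singlet / doublet / undetermined", {
  tags <- make_tags(list(c(50, 0, 1, 0), c(40, 35, 0, 0), c(3, 2, 0, 1)))
  thr <- setNames(rep(10, 4), paste0("Tag0", 1:4))
  out <- demux_tags(tags, thr)
  expect_identical(out$tag_call, c("singlet", "doublet", "undetermined"))
  expect_identical(out$tag, c("Tag01", NA, NA))
  expect_error(demux_tags(tags, thr[1:3]), "Tag04")
})

test_that("demux on synthetic tags is essentially perfect", {
  coh <- small_cohort(seed = 23)
  out <- demux_tags(coh$tags, tag_thresholds(coh$tags, seed = 1))
  tr <- coh$truth$cells
  sing <- !tr$is_doublet
  expect_gte(mean(out$tag_call[sing] == "singlet"), 0.99)
  # recovered tag matches the participant's tag
  sm <- coh$sample_map
  truth_tag <- sm$tag[match(tr$participant, sm$participant)]
  ok <- sing & out$tag_call == "singlet"
  expect_gte(mean(out$tag[ok] == truth_tag[ok]), 0.99)
  # cross-tag doublets are called doublets
  cross <- tr$is_doublet &
    sm$tag[match(tr$participant, sm$participant)] !=
    sm$tag[match(tr$participant2, sm$participant)]
  expect_gte(mean(out$tag_call[cross] == "doublet"), 0.95)
})

test_that("antibody floor keeps >= 128 and drops < 128", {
  m <- rbind(c(100, 27), c(100, 28), c(0, 0), c(500, 0))
  adt <- cm(m)
  kept <- filter_antibody_floor(adt, floor = 128)
  expect_identical(kept, c("c0002", "c0004"))
})

test_that("clr_normalize matches the ratio-then-log oracle", {
  set.seed(42)
  m <- matrix(rpois(250, 8), 50, 5)
  adt <- cm(m)
  expect_equal(clr_normalize(adt), clr_oracle(as.matrix(adt$counts)),
               tolerance = 1e-12)
  # {0, 15} on one marker -> {-2, +2} log2 units
  two <- cm(matrix(c(0, 15), 2, 1))
  expect_equal(as.numeric(clr_normalize(two)), c(-2, 2))
  # constant marker -> all zeros
  const <- cm(matrix(7, 10, 1))
  expect_true(all(clr_normalize(const) == 0))
  expect_warning(clr_normalize(cm(matrix(0, 10, 1))), "all-zero")
})

test_that("normalize_rna scales every kept cell to the target total", {
  rna <- cm(rbind(c(10, 90), c(1000, 0), c(0, 0)), "RNA")
  expect_warning(out <- normalize_rna(rna), "zero total")
  expect_identical(nrow(out), 2L)
  expect_equal(as.numeric(out[1, ]), c(100, 900))
  expect_equal(as.numeric(out[2, ]), c(1000, 0))
  expect_equal(unname(Matrix::rowSums(out)), rep(1000, 2), tolerance = 1e-9)
})

test_that("expression-doublet detector honours the quota contract", {
  set.seed(1)
  adt <- cm(matrix(rpois(200 * 10, 20), 200, 10))
  # rate below 1/n -> zero flags
  fl0 <- flag_expression_doublets(adt, expected_rate = 0.004, seed = 1)
  expect_identical(sum(fl0), 0L)
  # exactly floor(n * rate) flags
  fl <- flag_expression_doublets(adt, expected_rate = 0.10, seed = 1)
  expect_identical(sum(fl), 20L)
  expect_error(flag_expression_doublets(adt, expected_rate = 0.6), "expected_rate")
  expect_error(flag_expression_doublets(cm(matrix(1, 50, 4))), "100 cells")
})

test_that("detector recovers injected doublets (recall >= 0.6 at ~5k cells)", {
  coh <- generate_cohort(synthetic_config(n_per_group = 4,
                                          cells_per_participant = 320,
                                          seed = 29))
  tr <- coh$truth$cells
  expect_gte(nrow(tr), 5000)
  rate <- mean(tr$is_doublet)
  fl <- flag_expression_doublets(coh$adt, coh$rna, expected_rate = rate,
                                 seed = 5)
  recall <- sum(fl & tr$is_doublet) / sum(tr$is_doublet)
  expect_gte(recall, 0.6)
})

test_that("qc_run applies the filters in order with monotone cell counts", {
  coh <- small_cohort(seed = 31)
  qc <- suppressWarnings(qc_run(coh$adt, coh$rna, coh$tags, coh$sample_map,
                                coh$cells, seed = 3))
  expect_identical(qc$provenance$stage,
                   c("input", "tag_singlets", "post_expression_doublets",
                     "post_antibody_floor"))
  expect_true(all(diff(qc$provenance$n) <= 0))
  ct <- qc$cell_table
  # qc_pass implies singlet, not expression doublet, and above the floor
  expect_true(all(ct$tag_call[ct$qc_pass] == "singlet"))
  expect_false(any(ct$expression_doublet[ct$qc_pass]))
  expect_true(all(ct$total_adt[ct$qc_pass] >= 128))
  expect_identical(rownames(qc$adt_clr), ct$cell_id[ct$qc_pass])
})
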