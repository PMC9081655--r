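tpm_tbl <- function(mat, genes = sprintf("g%02d", seq_len(nrow(mat)))) {
  dplyr::bind_cols(tibble::tibble(gene = genes),
                   tibble::as_tibble(mat, .name_repair = "minimal"))
}

test_that("log2 transform maps TPM+1 and inverts exactly", {
  m <- tpm_tbl(matrix(c(0, 7, 3, 15), 2, 2,
                      dimnames = list(NULL, c("s1", "s2"))))
  lg <- log2_matrix(m)
  expect_equal(lg$s1, c(0, 3))        # log2(0+1), log2(7+1)
  expect_equal(lg$s2, c(2, 4))
  back <- 2^as.matrix(lg[, -1]) - 1
  expect_equal(unname(back), matrix(c(0, 7, 3, 15), 2, 2),
               tolerance = 1e-9)
  expect_error(log2_matrix(tpm_tbl(matrix(-1))), class = "cwmyb_input_error")
})

test_that("deg_screen computes fold changes, tests and the pass rule", {
  vals <- rbind(
    flat  = c(4, 4, 4, 4, 4, 4),
    up4x  = c(8, 8.1, 7.9, 2, 2.05, 1.95),
    off   = c(0, 0, 0, 5, 5.2, 4.8),
    small = c(3, 3.1, 2.9, 2.5, 2.6, 2.4)
  )
  colnames(vals) <- c("A1", "A2", "A3", "B1", "B2", "B3")
  m <- tpm_tbl(vals, genes = rownames(vals))
  deg <- deg_screen(m, c("A1", "A2", "A3"), c("B1", "B2", "B3"))
  deg <- deg[match(rownames(vals), deg$gene), ]
  expect_equal(deg$log2fc[1], 0)
  expect_false(deg$passes[1])
  expect_equal(deg$log2fc[2], 2, tolerance = 0.02)
  expect_true(deg$passes[2])
  # off gene: large |lfc| driven by the pseudocount, expressed in one group
  expect_true(deg$expressed[3])
  expect_lt(deg$log2fc[3], -1)
  # small fold change fails the |lfc| > 1 filter
  expect_false(deg$passes[4])
  # output sorted by gene id
  expect_equal(deg_screen(m, paste0("A", 1:3), paste0("B", 1:3))$gene,
               sort(rownames(vals)))
})

test_that("deg_screen validates groups and supports precomputed p-values", {
  m <- tpm_tbl(matrix(1:4, 1, 4, dimnames = list(NULL, c("A1", "A2",
                                                         "B1", "B2"))))
  expect_error(deg_screen(m, c("A1", "A9"), c("B1", "B2")), "A9",
               class = "cwmyb_input_error")
  expect_error(deg_screen(m, "A1", c("B1", "B2")), "replicates",
               class = "cwmyb_input_error")
  pv <- c(g01 = 0.001)
  one <- deg_screen(m, "A1", c("B1", "B2"), pvalues = pv)
  expect_equal(one$pvalue, 0.001)
})

test_that("deg_screen is invariant to sample permutation within groups", {
  sim <- gen_expression(synthetic_expression_spec(n_genes = 50, n_de = 5,
                                                  seed = 5))
  d1 <- deg_screen(sim$matrix, sim$group_a, sim$group_b)
  d2 <- deg_screen(sim$matrix, rev(sim$group_a), rev(sim$group_b))
  expect_equal(d1, d2)
})

test_that("ddct reproduces hand-computed fold changes", {
  trt <- list(ct_target = c(22, 22, 22), ct_reference = c(15, 15, 15))
  ctl <- list(ct_target = c(25, 25, 25), ct_reference = c(15, 15, 15))
  res <- ddct(trt, ctl)
  expect_equal(res$ddct, -3)   # (22-15) - (25-15)
  expect_equal(res$fold, 8)
  # self vs self: fold exactly 1, p = 1 for constant replicates
  self <- ddct(ctl, ctl)
  expect_identical(self$fold, 1)
  expect_equal(self$pvalue, 1)
  expect_equal(self$signif, "")
  # ddCt of -2 means fold 4
  t2 <- list(ct_target = c(23, 23), ct_reference = c(15, 15))
  expect_equal(ddct(t2, ctl)$fold, 4)
})

test_that("ddct flags significance and rejects bad input", {
  withr::local_seed(7)
  trt <- list(ct_target = 20 + rnorm(4, 0, 0.05),
              ct_reference = 15 + rnorm(4, 0, 0.05))
  ctl <- list(ct_target = 25 + rnorm(4, 0, 0.05),
              ct_reference = 15 + rnorm(4, 0, 0.05))
  res <- ddct(trt, ctl)
  expect_equal(res$signif, "**")
  expect_error(ddct(list(ct_target = 1:3), ctl), "reference",
               class = "cwmyb_input_error")
  expect_error(ddct(list(ct_target = c(20, 0), ct_reference = c(15, 15)),
                    ctl), "non-positive", class = "cwmyb_input_error")
})

test_that("qpcr_screen applies ddct per gene/condition/timepoint", {
  withr::local_seed(11)
  tab <- dplyr::bind_rows(
    gen_qpcr(8, replicates = 3, noise_sd = 0, gene = "CwMYB10",
             condition = "NaCl", timepoint = 6),
    gen_qpcr(0.5, replicates = 3, noise_sd = 0, gene = "CwMYB10",
             condition = "MeJA", timepoint = 6))
  res <- qpcr_screen(tab)
  expect_equal(nrow(res), 2)
  expect_equal(res$fold[res$condition == "NaCl"], 8)
  expect_equal(res$fold[res$condition == "MeJA"], 0.5)
  g <- glance(res)
  expect_equal(g$n_comparisons, 2)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
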