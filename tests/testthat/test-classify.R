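classify_seq <- function(seq, config = myb_classify_config()) {
  recs <- rec_tbl(seq, ids = "q")
  classify_protein("q", detect_repeats(recs, config$scan),
                   scan_motifs(recs), config)
}

r2b <- function() paste0("W", strrep("A", 19), "W", strrep("A", 19), "W")
r3b <- function() paste0("F", strrep("A", 18), "W", strrep("A", 18), "W")
rrb <- function() paste0("W", strrep("A", 19), "W", strrep("A", 19), "Y")

test_that("repeat chains map to the R2R3/3R/4R subfamilies", {
  expect_equal(classify_seq(paste0(r2b(), strrep("G", 5), r3b()))$subfamily,
               "R2R3")
  three <- paste0(r2b(), strrep("G", 12), r2b(), strrep("G", 12), r3b())
  expect_equal(classify_seq(three)$subfamily, "R3_MYB")
  four <- paste0(r2b(), strrep("G", 12), r2b(), strrep("G", 12),
                 r2b(), strrep("G", 12), r3b())
  expect_equal(classify_seq(four)$subfamily, "R4_MYB")
  # repeats separated by more than the tandem gap do not chain
  apart <- paste0(r2b(), strrep("G", 40), r3b())
  call <- classify_seq(apart)
  expect_equal(call$subfamily, "MYB_RELATED")
  expect_equal(call$related_type, "UNCLASSIFIED")
})

test_that("MYB-related types follow the signature-motif rules", {
  base <- strrep("A", 30)
  expect_equal(classify_seq(paste0(base, "SHAQKYF", base))$related_type,
               "CCA1_LIKE")
  expect_equal(classify_seq(paste0(base, "LKDKWRN", base))$related_type,
               "TBP_LIKE")
  expect_equal(classify_seq(paste0(base, "SHLQKAR", base))$related_type,
               "GARP_LIKE")
  expect_equal(classify_seq(paste0(base, "SHLQMGR", base))$related_type,
               "GARP_LIKE")
  cc <- paste0(base, "SHLQKAR", strrep("A", 30), "LHEQLE", base)
  expect_equal(classify_seq(cc)$related_type, "MYB_CC")
  rr <- paste0(rrb(), strrep("A", 60), "SHAQKFF", base)
  expect_equal(classify_seq(rr)$related_type, "R_R")
  # same layout but the motif too close to the repeat: falls back to CCA1
  near <- paste0(rrb(), strrep("A", 20), "SHAQKFF", base)
  expect_equal(classify_seq(near)$related_type, "CCA1_LIKE")
  expect_equal(classify_seq(strrep("A", 60))$subfamily, "NOT_MYB")
})

test_that("rule precedence: TBP outranks SHLQ, SHLQ outranks SHAQK", {
  both <- paste0("LKDKWRN", strrep("A", 10), "SHLQKAR", strrep("A", 10))
  expect_equal(classify_seq(both)$related_type, "TBP_LIKE")
  shs <- paste0("SHLQKAR", strrep("A", 10), "SHAQKYF", strrep("A", 10))
  expect_equal(classify_seq(shs)$related_type, "GARP_LIKE")
})

test_that("names follow the family scheme and input order", {
  calls <- tibble::tibble(
    subfamily = c("R2R3", "MYB_RELATED", "R2R3", "R3_MYB", "R4_MYB",
                  "R3_MYB", "NOT_MYB"))
  named <- assign_names(calls)
  expect_equal(named$assigned_name,
               c("CwMYB1", "CwMYBR1", "CwMYB2", "CwMYB3R1", "CwMYB4R1",
                 "CwMYB3R2", NA))
  expect_equal(nrow(assign_names(calls[0, , drop = FALSE])), 0)
})

test_that("family summary counts mirror the calls and sum to n", {
  spec <- synthetic_family_spec(counts = c(R2R3 = 2, CCA1_LIKE = 1,
                                           NOT_MYB = 1), seed = 3)
  calls <- classify_proteins(gen_family_set(spec))
  s <- summarize_family(calls)
  expect_equal(sum(s$n), nrow(calls))
  expect_equal(s$n[s$subfamily == "R2R3"], 2)
  expect_equal(s$n[!is.na(s$related_type) &
                     s$related_type == "CCA1_LIKE"], 1)
  expect_equal(s$n[s$subfamily == "NOT_MYB"], 1)
})

test_that("classification is deterministic and order-insensitive", {
  spec <- synthetic_family_spec(counts = c(R2R3 = 2, TBP_LIKE = 2,
                                           GARP_LIKE = 1), seed = 9)
  recs <- gen_family_set(spec)
  c1 <- classify_proteins(recs)
  c2 <- classify_proteins(recs)
  expect_identical(tidy(c1), tidy(c2))
  perm <- recs[rev(seq_len(nrow(recs))), ]
  c3 <- classify_proteins(perm)
  merged <- dplyr::inner_join(tidy(c1), tidy(c3), by = "seq_id",
                              suffix = c("_a", "_b"))
  expect_equal(merged$subfamily_a, merged$subfamily_b)
  expect_equal(merged$related_type_a, merged$related_type_b)
  # naming differs with order, classification does not
  expect_false(identical(tidy(c1)$assigned_name,
                         tidy(c3)[match(c1$seq_id, c3$seq_id), ]$assigned_name))
})

test_that("tidy/glance/autoplot work on classification results", {
  spec <- synthetic_family_spec(counts = c(R2R3 = 2, R_R = 1), seed = 2)
  calls <- classify_proteins(gen_family_set(spec))
  flat <- tidy(calls)
  expect_s3_class(flat, "tbl_df")
  expect_false("repeats" %in% names(flat))
  g <- glance(calls)
  expect_equal(g$n, 3)
  expect_equal(g$n_r2r3, 2)
  p <- ggplot2::autoplot(calls)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_domain_map(calls), "ggplot")
})
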