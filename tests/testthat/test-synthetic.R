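test_that("generated proteins carry their planted class by construction", {
  withr::local_seed(3)
  for (cl in c("R2R3", "R3_MYB", "R4_MYB", "CCA1_LIKE", "R_R", "TBP_LIKE",
               "MYB_CC", "GARP_LIKE")) {
    rec <- gen_myb_protein(cl)
    call <- classify_protein(rec$id, detect_repeats(rec), scan_motifs(rec))
    expect_equal(call$subfamily, rec$true_subfamily, label = cl)
    if (!is.na(rec$true_related_type)) {
      expect_equal(call$related_type, rec$true_related_type, label = cl)
    }
  }
})

test_that("NOT_MYB backbones contain no repeat or signature-motif hits", {
  withr::local_seed(19)
  for (i in 1:5) {
    rec <- gen_myb_protein("NOT_MYB")
    expect_equal(nrow(detect_repeats(rec)), 0)
    expect_equal(nrow(scan_motifs(rec)), 0)
  }
})

test_that("different seeds give different backbones, same classification", {
  set.seed(7); r7 <- gen_myb_protein("TBP_LIKE")
  set.seed(8); r8 <- gen_myb_protein("TBP_LIKE")
  expect_false(identical(r7$sequence, r8$sequence))
  for (r in list(r7, r8)) {
    call <- classify_protein(r$id, detect_repeats(r), scan_motifs(r))
    expect_equal(call$related_type, "TBP_LIKE")
  }
})

test_that("family sets are reproducible and FASTA-identical per seed", {
  spec <- synthetic_family_spec(seed = 42)
  s1 <- gen_family_set(spec)
  s2 <- gen_family_set(spec)
  expect_identical(s1$sequence, s2$sequence)
  expect_equal(nrow(s1), 45)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(s1, f1)
  write_fasta(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("structure-preserving mutation never changes the true label", {
  spec <- synthetic_family_spec(counts = c(R2R3 = 3, R_R = 3, MYB_CC = 3),
                                mutation_rate = 0.1,
                                mutation_mode = "structure_preserving",
                                seed = 31)
  recs <- gen_family_set(spec)
  calls <- tidy(classify_proteins(recs))
  expect_equal(calls$subfamily, recs$true_subfamily)
  expect_equal(calls$related_type, recs$true_related_type)
})

test_that("corrupting mutation degrades accuracy monotonically on average", {
  acc <- function(rate, seed) {
    spec <- synthetic_family_spec(
      counts = c(R2R3 = 3, CCA1_LIKE = 3, TBP_LIKE = 3),
      mutation_rate = rate, mutation_mode = "corrupting", seed = seed)
    recs <- gen_family_set(spec)
    calls <- tidy(classify_proteins(recs))
    ok <- calls$subfamily == recs$true_subfamily &
      (is.na(recs$true_related_type) |
         calls$related_type == recs$true_related_type)
    mean(ok)
  }
  zero <- mean(vapply(1:5, function(s) acc(0, s), numeric(1)))
  mid <- mean(vapply(1:5, function(s) acc(0.2, s), numeric(1)))
  expect_equal(zero, 1)
  expect_lt(mid, 1)
})

test_that("planted expression effects are recovered by the screen", {
  sim <- gen_expression(synthetic_expression_spec(
    n_genes = 100, n_de = 10, log2fc = 3, replicates = 3, noise_sd = 0.1,
    seed = 13))
  deg <- deg_screen(sim$matrix, sim$group_a, sim$group_b)
  joined <- dplyr::inner_join(deg, sim$truth, by = "gene")
  expect_true(all(joined$passes[joined$is_de]))
  # reproducible for a fixed seed
  sim2 <- gen_expression(synthetic_expression_spec(
    n_genes = 100, n_de = 10, log2fc = 3, replicates = 3, noise_sd = 0.1,
    seed = 13))
  expect_identical(sim$matrix, sim2$matrix)
})

test_that("qPCR generator plants exact fold changes at zero noise", {
  withr::local_seed(3)
  for (f in c(1, 8, 0.25)) {
    tab <- gen_qpcr(f, noise_sd = 0)
    res <- qpcr_screen(tab)
    expect_equal(res$fold, f)
  }
  # Monte-Carlo recovery at moderate noise
  folds <- vapply(1:100, function(i) {
    qpcr_screen(gen_qpcr(4, replicates = 3, noise_sd = 0.1))$fold
  }, numeric(1))
  expect_lt(abs(mean(folds) - 4) / 4, 0.1)
})
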