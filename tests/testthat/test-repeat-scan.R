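r2_block <- function(fill = "A") {
  paste0("W", strrep(fill, 19), "W", strrep(fill, 19), "W")
}
r3_block <- function(fill = "A", first = "F") {
  paste0(first, strrep(fill, 18), "W", strrep(fill, 18), "W")
}

test_that("pattern compilation parses the consensus dash notation", {
  p <- compile_pattern("W-x(19)-W-x(19)-W", name = "R2")
  anchors <- Filter(function(e) e$type == "anchor", p$elements)
  spacers <- Filter(function(e) e$type == "spacer", p$elements)
  expect_length(anchors, 3)
  expect_true(all(vapply(anchors, function(e) identical(e$set, "W"),
                         logical(1))))
  expect_equal(vapply(spacers, function(e) c(e$min, e$max), numeric(2)),
               matrix(19, 2, 2))
  p3 <- compile_pattern("[FILM]-x(18)-W-x(18)-W")
  expect_setequal(p3$elements[[1]]$set, c("F", "I", "L", "M"))
  expect_equal(p3$elements[[2]]$min, 18)
  pr <- compile_pattern("W-x(2,5)-W")
  expect_equal(c(pr$elements[[2]]$min, pr$elements[[2]]$max), c(2, 5))
})

test_that("malformed patterns are rejected", {
  expect_error(compile_pattern("x(5)"), "no anchor",
               class = "cwmyb_pattern_error")
  expect_error(compile_pattern("W-x(5,2)-W"), "min > max",
               class = "cwmyb_pattern_error")
  expect_error(compile_pattern("W-foo-W"), "offset 3",
               class = "cwmyb_pattern_error")
  expect_error(compile_pattern("W-[XZ]-W"), class = "cwmyb_pattern_error")
})

test_that("find_motif locates exact and alternative-set matches", {
  hits <- find_motif(rec_tbl("AASHAQKYFAA"), myb_motifs()$SHAQK)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 3)          # 1-based
  expect_equal(hits$matched, "SHAQKYF")
  tbp <- find_motif(rec_tbl("LKDKWRN"), myb_motifs()$TBP)
  expect_equal(tbp$matched, "LKDKWRN")
  expect_equal(c(tbp$start, tbp$end), c(1, 7))
  # X never satisfies an anchor position
  expect_equal(nrow(find_motif(rec_tbl("SHAQKXF"), myb_motifs()$SHAQK)), 0)
})

test_that("anchor-free alphabets yield no motif or repeat hits", {
  withr::local_seed(11)
  seq <- random_protein(200, alphabet = c("A", "G", "S"))
  recs <- rec_tbl(seq)
  for (p in myb_motifs()[c("SHAQK", "TBP", "LHEQLE")]) {
    expect_equal(nrow(find_motif(recs, p)), 0)
  }
  expect_equal(nrow(detect_repeats(recs)), 0)
})

test_that("exact consensus blocks are detected with the right class", {
  h2 <- detect_repeats(rec_tbl(r2_block()))
  expect_equal(nrow(h2), 1)
  expect_equal(h2$repeat_class, "R2_CONSENSUS")
  expect_equal(c(h2$anchor1, h2$anchor2, h2$anchor3), c(1, 21, 41))
  expect_equal(h2$end, 41)             # tail clipped at sequence end
  h3 <- detect_repeats(rec_tbl(r3_block()))
  expect_equal(h3$repeat_class, "R3_CONSENSUS")
  expect_equal(c(h3$anchor1, h3$anchor2, h3$anchor3), c(1, 20, 39))
  hr <- detect_repeats(rec_tbl(paste0("W", strrep("A", 19), "W",
                                      strrep("A", 19), "Y")))
  expect_equal(hr$repeat_class, "RR_FIRST")
})

test_that("tandem R2+R3 blocks give two ordered non-overlapping hits", {
  seq <- paste0(r2_block(), strrep("G", 5), r3_block())
  hits <- detect_repeats(rec_tbl(seq))
  expect_equal(hits$repeat_class, c("R2_CONSENSUS", "R3_CONSENSUS"))
  expect_equal(hits$anchor1, c(1, 47))
  expect_equal(hit_key(hits), hit_key(oracle_detect(seq)))
})

test_that("scanner output equals exhaustive triple enumeration", {
  withr::local_seed(42)
  for (rep in 1:100) {
    n <- sample(60:200, 1)
    seq <- random_protein(n)
    got <- detect_repeats(rec_tbl(seq))
    want <- oracle_detect(seq)
    expect_identical(hit_key(got), hit_key(want))
    if (nrow(got) > 1) {
      # no two hits overlap on their anchor spans; sorted by start
      expect_true(all(diff(got$start) > 0))
      expect_true(all(got$anchor3[-nrow(got)] < got$start[-1]))
    }
  }
})

test_that("planted consensus position does not depend on the backbone", {
  withr::local_seed(5)
  for (rep in 1:20) {
    p <- sample(0:150, 1)
    backbone <- random_protein(200,
                               alphabet = strsplit("ACDEGHIKLMNPQRSTV",
                                                   "")[[1]])
    seq <- paste0(substr(backbone, 1, p), r2_block(),
                  substr(backbone, p + 1, 200))
    hits <- detect_repeats(rec_tbl(seq))
    expect_equal(nrow(hits), 1)
    expect_equal(c(hits$anchor1, hits$anchor2, hits$anchor3),
                 c(p + 1, p + 21, p + 41))
  }
})

test_that("scanning is invariant under appending residues after last hit", {
  seq <- paste0(strrep("A", 7), r2_block())
  base <- detect_repeats(rec_tbl(seq))
  ext <- detect_repeats(rec_tbl(paste0(seq, strrep("G", 40))))
  expect_equal(ext[c("anchor1", "anchor2", "anchor3", "repeat_class")],
               base[c("anchor1", "anchor2", "anchor3", "repeat_class")])
})

test_that("spacer slack configuration widens and narrows detection", {
  # spacers 20/18 pass at slack 1, fail at slack 0
  seq <- paste0("W", strrep("A", 20), "W", strrep("A", 18), "W")
  expect_equal(nrow(detect_repeats(rec_tbl(seq), myb_scan_config(slack = 1))),
               1)
  expect_equal(nrow(detect_repeats(rec_tbl(seq), myb_scan_config(slack = 0))),
               0)
})

test_that("EAR hits are reported outside repeats only", {
  hits <- scan_ear(rec_tbl("AALKLALAA"),
                   detect_repeats(rec_tbl("AALKLALAA")))
  expect_equal(hits$matched, "LKLAL")
  expect_equal(hits$start, 3)
  # overlapping EAR matches are all returned: LLLLLL has starts 1 and 2
  six <- scan_ear(rec_tbl("LLLLLL"), detect_repeats(rec_tbl("LLLLLL")))
  expect_equal(six$start, c(1, 2))
  expect_equal(six$start, oracle_ear("LLLLLL"))
  # the same pentapeptide inside a repeat interval is excluded
  seq <- paste0("W", strrep("A", 14), "LKLAL", "W", strrep("A", 19), "W")
  reps <- detect_repeats(rec_tbl(seq))
  expect_equal(nrow(reps), 1)
  expect_equal(nrow(scan_ear(rec_tbl(seq), reps)), 0)
})
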