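#' Configuration for the MYB R-repeat scanner
#'
#' The scanner looks for three regularly spaced anchor residues per repeat.
#' Consensus classes, in priority order:
#' \describe{
#'   \item{R2_CONSENSUS}{`W-x(19)-W-x(19)-W`}
#'   \item{R3_CONSENSUS}{`[FILM]-x(18)-W-x(18)-W` (first tryptophan commonly
#'     replaced by F/I/L/M)}
#'   \item{RR_FIRST}{`W-x(19)-W-x(19)-Y` — the N-terminal repeat of R-R type
#'     MYB-related proteins, whose third tryptophan is replaced by tyrosine}
#'   \item{GENERIC_R}{first anchor in `{W,F,I,L,M}`, second `W`, third in
#'     `{W,F,Y}`, spacers spanning the R2/R3 range — a catch-all degenerate
#'     repeat}
#' }
#' Each spacer tolerates `slack` residues of play around its consensus
#' length (the repeats are only approximately 52 residues long in real
#' families). A triple satisfying several classes is assigned the
#' highest-priority one.
#'
#' @param slack Non-negative integer; spacer tolerance (default 1, i.e.
#'   19±1 for R2, 18±1 for R3).
#' @param tail Residues reported beyond the third anchor (default 12,
#'   completing the ~52-residue repeat: 41-residue anchor span plus helix-3
#'   tail). Affects the reported `end`, EAR exclusion and non-MYB region
#'   boundaries only — overlap resolution between candidate repeats uses the
#'   anchor span.
#' @return A list of class `myb_scan_config`.
#' @export
myb_scan_config <- function(slack = 1L, tail = 12L) {
  stopifnot(slack >= 0L, tail >= 0L)
  slack <- as.integer(slack)
  classes <- list(
    R2_CONSENSUS = list(a1 = "W", a2 = "W", a3 = "W",
                        sp1 = c(19L - slack, 19L + slack),
                        sp2 = c(19L - slack, 19L + slack)),
    R3_CONSENSUS = list(a1 = c("F", "I", "L", "M"), a2 = "W", a3 = "W",
                        sp1 = c(18L - slack, 18L + slack),
                        sp2 = c(18L - slack, 18L + slack)),
    RR_FIRST     = list(a1 = "W", a2 = "W", a3 = "Y",
                        sp1 = c(19L - slack, 19L + slack),
                        sp2 = c(19L - slack, 19L + slack)),
    GENERIC_R    = list(a1 = c("W", "F", "I", "L", "M"), a2 = "W",
                        a3 = c("W", "F", "Y"),
                        sp1 = c(18L - slack, 19L + slack),
                        sp2 = c(18L - slack, 19L + slack))
  )
  structure(list(slack = slack, tail = as.integer(tail), classes = classes),
            class = "myb_scan_config")
}

# enumerate every anchor triple (i, j, k) satisfying at least one repeat
# class, with the class assigned by priority; returns one row per triple
enumerate_triples <- function(letters, config) {
  n <- length(letters)
  classes <- config$classes
  a1_union <- unique(unlist(lapply(classes, `[[`, "a1")))
  a3_union <- unique(unlist(lapply(classes, `[[`, "a3")))
  sp_lo <- min(vapply(classes, function(cl) cl$sp1[1], integer(1)))
  sp_hi <- max(vapply(classes, function(cl) cl$sp1[2], integer(1)))
  p1 <- which(letters %in% a1_union)
  p2 <- which(letters == "W")
  p3 <- which(letters %in% a3_union)
  if (length(p1) == 0L || length(p2) == 0L || length(p3) == 0L) {
    return(empty_triples())
  }
  rows <- list()
  for (j in p2) {
    is <- p1[(j - p1 - 1L) >= sp_lo & (j - p1 - 1L) <= sp_hi]
    ks <- p3[(p3 - j - 1L) >= sp_lo & (p3 - j - 1L) <= sp_hi]
    if (length(is) == 0L || length(ks) == 0L) next
    grid <- expand.grid(i = is, k = ks, KEEP.OUT.ATTRS = FALSE)
    grid$j <- j
    rows[[length(rows) + 1L]] <- grid
  }
  if (length(rows) == 0L) return(empty_triples())
  g <- do.call(rbind, rows)
  sp1 <- g$j - g$i - 1L
  sp2 <- g$k - g$j - 1L
  cls <- rep(NA_character_, nrow(g))
  for (cname in names(classes)) {      # priority = list order
    cl <- classes[[cname]]
    ok <- is.na(cls) &
      letters[g$i] %in% cl$a1 & letters[g$k] %in% cl$a3 &
      sp1 >= cl$sp1[1] & sp1 <= cl$sp1[2] &
      sp2 >= cl$sp2[1] & sp2 <= cl$sp2[2]
    cls[ok] <- cname
  }
  keep <- !is.na(cls)
  tibble(anchor1 = g$i[keep], anchor2 = g$j[keep], anchor3 = g$k[keep],
         repeat_class = cls[keep])
}

empty_triples <- function() {
  tibble(anchor1 = integer(0), anchor2 = integer(0), anchor3 = integer(0),
         repeat_class = character(0))
}

REPEAT_CLASS_PRIORITY <- c("R2_CONSENSUS", "R3_CONSENSUS", "RR_FIRST",
                           "GENERIC_R")

# size of a maximum mutually non-overlapping subset (overlap on anchor
# spans): weighted-interval-scheduling count DP
max_compatible_count <- function(start, span_end) {
  m <- length(start)
  if (m == 0L) return(0L)
  ord <- order(start, span_end)
  start <- start[ord]
  span_end <- span_end[ord]
  cnt <- integer(m + 1L)
  for (i in m:1) {
    j <- which(start > span_end[i])
    after <- if (length(j) == 0L) 0L else cnt[min(j)]
    cnt[i] <- max(cnt[i + 1L], 1L + after)
  }
  cnt[1L]
}

# deterministic selection of a maximum set of mutually non-overlapping
# candidate hits (overlap judged on anchor spans): maximize the number of
# hits, then lexicographically minimize the selected key sequence, where
# key = (class priority, start, anchor2, anchor3) — so among equal-size
# solutions a consensus-class repeat beats a generic one, and leftmost
# wins within a class
select_hits <- function(cand) {
  if (nrow(cand) <= 1L) return(cand)
  prio <- match(cand$repeat_class, REPEAT_CLASS_PRIORITY)
  key_ord <- order(prio, cand$anchor1, cand$anchor2, cand$anchor3)
  cand <- cand[key_ord, , drop = FALSE]
  live <- seq_len(nrow(cand))
  chosen <- integer(0)
  target <- max_compatible_count(cand$anchor1, cand$anchor3)
  while (target > 0L) {
    for (h in live) {          # live is in key order
      compat <- live[cand$anchor1[live] > cand$anchor3[h] |
                       cand$anchor3[live] < cand$anchor1[h]]
      if (1L + max_compatible_count(cand$anchor1[compat],
                                    cand$anchor3[compat]) == target) {
        chosen <- c(chosen, h)
        live <- compat
        target <- target - 1L
        break
      }
    }
  }
  cand[sort(chosen), , drop = FALSE]
}

#' Detect MYB R repeats in protein records
#'
#' Enumerates every anchor triple satisfying any repeat consensus class
#' (see [myb_scan_config()]), assigns each triple its highest-priority
#' class, then deterministically selects a maximum set of mutually
#' non-overlapping repeats, preferring more hits, then higher class
#' priority, then leftmost starts and anchors. Priority outranks position
#' so that a planted or biological consensus repeat is never displaced by
#' an overlapping generic triple that happens to start a few residues
#' earlier.
#'
#' Coordinates are 1-based inclusive. `start` is the first anchor; `end`
#' extends `tail` residues past the third anchor (clipped at the sequence
#' end). Overlap between candidate repeats is judged on the anchor span
#' `start..anchor3`, so tandem repeats whose tails run into the next
#' repeat's first anchor are still reported side by side.
#'
#' @param records A tibble of protein records (`id`, `sequence`).
#' @param config A [myb_scan_config()].
#' @return A tibble with columns `seq_id`, `start`, `end`, `repeat_class`,
#'   `anchor1`, `anchor2`, `anchor3`, `anchor_residues`, sorted by sequence
#'   then start.
#' @examples
#' r2 <- paste0("W", strrep("A", 19), "W", strrep("A", 19), "W")
#' detect_repeats(tibble::tibble(id = "p", description = "", sequence = r2))
#' @export
detect_repeats <- function(records, config = myb_scan_config()) {
  stopifnot(inherits(config, "myb_scan_config"))
  records <- validate_records(records)
  res <- purrr::map2_dfr(records$id, records$sequence, function(id, seq) {
    letters_i <- strsplit(seq, "", fixed = TRUE)[[1L]]
    cand <- enumerate_triples(letters_i, config)
    sel <- select_hits(cand)
    if (nrow(sel) == 0L) return(NULL)
    sel <- sel[order(sel$anchor1), , drop = FALSE]
    tibble(
      seq_id = id,
      start = sel$anchor1,
      end = pmin(sel$anchor3 + config$tail, length(letters_i)),
      repeat_class = sel$repeat_class,
      anchor1 = sel$anchor1, anchor2 = sel$anchor2, anchor3 = sel$anchor3,
      anchor_residues = paste(letters_i[sel$anchor1], letters_i[sel$anchor2],
                              letters_i[sel$anchor3], sep = ",")
    )
  })
  if (nrow(res) == 0L) {
    res <- tibble(seq_id = character(0), start = integer(0), end = integer(0),
                  repeat_class = character(0), anchor1 = integer(0),
                  anchor2 = integer(0), anchor3 = integer(0),
                  anchor_residues = character(0))
  }
  res
}
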