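# Independent oracles used by the property tests. These restate the repeat
# definitions from first principles and use exhaustive enumeration, so they
# share no code with the scanner under test.

rec_tbl <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  tibble::tibble(id = ids, description = "", sequence = seqs)
}

# exhaustive anchor-triple enumeration for the repeat classes; slack fixed
# at 1 (the scanner default); returns (anchor1, anchor2, anchor3, class)
oracle_triples <- function(letters) {
  defs <- list(
    R2_CONSENSUS = list(a1 = "W", a2 = "W", a3 = "W", sp1 = 18:20,
                        sp2 = 18:20),
    R3_CONSENSUS = list(a1 = c("F", "I", "L", "M"), a2 = "W", a3 = "W",
                        sp1 = 17:19, sp2 = 17:19),
    RR_FIRST = list(a1 = "W", a2 = "W", a3 = "Y", sp1 = 18:20, sp2 = 18:20),
    GENERIC_R = list(a1 = c("W", "F", "I", "L", "M"), a2 = "W",
                     a3 = c("W", "F", "Y"), sp1 = 17:20, sp2 = 17:20)
  )
  seen <- character(0)
  out <- list()
  for (cls in names(defs)) {
    d <- defs[[cls]]
    p1 <- which(letters %in% d$a1)
    p2 <- which(letters %in% d$a2)
    p3 <- which(letters %in% d$a3)
    for (i in p1) for (j in p2[p2 > i]) {
      if (!(j - i - 1) %in% d$sp1) next
      for (k in p3[p3 > j]) {
        if (!(k - j - 1) %in% d$sp2) next
        key <- paste(i, j, k)
        if (!key %in% seen) {
          seen <- c(seen, key)
          out[[length(out) + 1L]] <- list(anchor1 = i, anchor2 = j,
                                          anchor3 = k, repeat_class = cls)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(anchor1 = integer(0), anchor2 = integer(0),
                          anchor3 = integer(0), repeat_class = character(0)))
  }
  dplyr::bind_rows(out)
}

# exhaustive enumeration of every non-overlapping subset (overlap on the
# anchor span), picking the best by: most hits, then the lexicographically
# smallest sorted key sequence with key = (class priority, start,
# anchor2, anchor3) — class priority outranks position
oracle_select <- function(cand) {
  if (nrow(cand) <= 1L) return(cand)
  prio <- match(cand$repeat_class,
                c("R2_CONSENSUS", "R3_CONSENSUS", "RR_FIRST", "GENERIC_R"))
  key_rank <- order(order(prio, cand$anchor1, cand$anchor2, cand$anchor3))
  ord <- order(cand$anchor1, cand$anchor3)
  cand <- cand[ord, , drop = FALSE]
  key_rank <- key_rank[ord]
  m <- nrow(cand)
  subsets <- list(integer(0))
  extend <- function(chosen) {
    last_end <- if (length(chosen) == 0L) -Inf else
      max(cand$anchor3[chosen])
    for (j in which(cand$anchor1 > last_end)) {
      new <- c(chosen, j)
      subsets[[length(subsets) + 1L]] <<- new
      extend(new)
    }
  }
  extend(integer(0))
  best <- subsets[[1L]]
  better <- function(a, b) {
    if (length(a) != length(b)) return(length(a) > length(b))
    if (length(a) == 0L) return(FALSE)
    ka <- sort(key_rank[a])
    kb <- sort(key_rank[b])
    d <- which(ka != kb)
    length(d) > 0L && ka[d[1L]] < kb[d[1L]]
  }
  for (s in subsets) if (better(s, best)) best <- s
  cand[sort(best), , drop = FALSE]
}

oracle_detect <- function(seq, tail = 12L) {
  letters <- strsplit(seq, "", fixed = TRUE)[[1L]]
  sel <- oracle_select(oracle_triples(letters))
  if (nrow(sel) == 0L) return(sel)
  sel <- sel[order(sel$anchor1), , drop = FALSE]
  sel$start <- sel$anchor1
  sel$end <- pmin(sel$anchor3 + tail, length(letters))
  sel
}

hit_key <- function(h) {
  if (nrow(h) == 0L) return(character(0))
  sort(paste(h$anchor1, h$anchor2, h$anchor3, h$repeat_class))
}

# exhaustive LxLxL window check
oracle_ear <- function(seq, repeat_intervals = NULL) {
  letters <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(letters)
  starts <- integer(0)
  if (n >= 5L) {
    for (s in 1:(n - 4L)) {
      if (letters[s] == "L" && letters[s + 2L] == "L" &&
          letters[s + 4L] == "L") {
        outside <- TRUE
        if (!is.null(repeat_intervals) && nrow(repeat_intervals) > 0L) {
          outside <- all(s + 4L < repeat_intervals$start |
                           s > repeat_intervals$end)
        }
        if (outside) starts <- c(starts, s)
      }
    }
  }
  starts
}

# greedy dedupe re-run with explicit O(n^2) bookkeeping: precompute the
# full identity matrix, then trace the keep/absorb decisions
oracle_dedupe <- function(records, threshold = 0.80) {
  n <- nrow(records)
  idm <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      idm[i, j] <- pairwise_identity(records$sequence[i],
                                     records$sequence[j])$identity
    }
  }
  ord <- order(-nchar(records$sequence), records$id)
  kept <- integer(0)
  rep_of <- character(n)
  for (i in ord) {
    hit <- kept[idm[i, kept] >= threshold]
    if (length(hit) > 0L) {
      rep_of[i] <- records$id[hit[1L]]
    } else {
      kept <- c(kept, i)
      rep_of[i] <- records$id[i]
    }
  }
  list(kept_ids = sort(records$id[kept]), rep_of = rep_of)
}

random_protein <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                  "")[[1L]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# redundancy chain a~b >= 0.8, b~c >= 0.8, a~c < 0.8, lengths a > b > c;
# the greedy procedure must keep {a, c} and absorb b into a
chain_records <- function() {
  withr::with_seed(17, {
    a <- random_protein(100, alphabet = strsplit("ACDEGHIKLMNPQRSTV",
                                                 "")[[1]])
    al <- strsplit(a, "")[[1]]
    bl <- al[1:80]
    bl[41:54] <- "W"              # 14 mismatches: identity(a,b) = 66/80
    b <- paste(bl, collapse = "")
    c_ <- paste(bl[21:80], collapse = "")  # identity(b,c)=1; (a,c)=46/60
    rec_tbl(c(a, b, c_), ids = c("a", "b", "c"))
  })
}
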