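# identity scoring: match +1, mismatch 0, affine gaps (open 10, extend 1),
# no substitution matrix — identity is counted matches over a denominator
identity_submat <- function() {
  letters_all <- c(Biostrings::AA_ALPHABET)
  m <- diag(1, length(letters_all))
  dimnames(m) <- list(letters_all, letters_all)
  m
}

#' Pairwise sequence identity
#'
#' Aligns two protein sequences (Needleman–Wunsch by default, via
#' `Biostrings::pairwiseAlignment` with match +1, mismatch 0, gap open 10,
#' gap extend 1) and reports the fraction of identical aligned positions.
#' The default denominator is the length of the shorter sequence (the
#' convention of greedy clustering tools); `"longer"` and `"alignment"`
#' (number of alignment columns) are also available.
#'
#' @param a,b Sequences (strings) or one-row record tibbles.
#' @param denominator One of `"shorter"`, `"longer"`, `"alignment"`.
#' @param mode Alignment mode, `"global"` or `"local"`.
#' @return A one-row tibble `id_a`, `id_b`, `identity`, `aligned_length`,
#'   `matches`.
#' @examples
#' pairwise_identity("AAAA", "AATA")  # identity 0.75
#' @export
pairwise_identity <- function(a, b,
                              denominator = c("shorter", "longer",
                                              "alignment"),
                              mode = c("global", "local")) {
  denominator <- match.arg(denominator)
  mode <- match.arg(mode)
  as_rec <- function(x, fallback) {
    if (is.data.frame(x)) {
      stopifnot(nrow(x) == 1L)
      list(id = x$id, seq = x$sequence)
    } else {
      list(id = fallback, seq = x)
    }
  }
  ra <- as_rec(a, "a")
  rb <- as_rec(b, "b")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ra$seq), Biostrings::AAString(rb$seq),
    substitutionMatrix = identity_submat(),
    gapOpening = 10, gapExtension = 1, type = mode)
  matches <- Biostrings::nmatch(aln)
  denom <- switch(denominator,
                  shorter = min(nchar(ra$seq), nchar(rb$seq)),
                  longer = max(nchar(ra$seq), nchar(rb$seq)),
                  alignment = Biostrings::nchar(aln))
  tibble(id_a = ra$id, id_b = rb$id,
         identity = matches / denom,
         aligned_length = Biostrings::nchar(aln),
         matches = matches)
}

#' Remove redundant sequences at an identity cutoff
#'
#' Greedy representative selection: records are sorted by length
#' (descending, ties broken by id), and each record is kept if its identity
#' to every already-kept record is below `threshold`; otherwise it joins
#' the cluster of the first kept record at or above the threshold. This
#' mirrors the standard greedy clustering used to collapse transcript
#' isoforms before family analysis (default cutoff: 80% identity).
#'
#' @param records A tibble of protein records.
#' @param threshold Identity cutoff in \[0, 1\] (default 0.80); a record at
#'   or above this identity to a representative is absorbed.
#' @param denominator,mode Passed to [pairwise_identity()].
#' @return A list with `kept` (the representative records, original order
#'   preserved) and `clusters` (tibble `member`, `representative`).
#' @export
dedupe <- function(records, threshold = 0.80,
                   denominator = "shorter", mode = "global") {
  records <- validate_records(records)
  stopifnot(nrow(records) >= 1L, threshold > 0, threshold <= 1)
  ord <- order(-nchar(records$sequence), records$id)
  kept_idx <- integer(0)
  rep_of <- character(nrow(records))
  for (i in ord) {
    absorbed <- FALSE
    for (k in kept_idx) {
      idy <- pairwise_identity(records$sequence[i], records$sequence[k],
                               denominator = denominator,
                               mode = mode)$identity
      if (idy >= threshold) {
        rep_of[i] <- records$id[k]
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) {
      kept_idx <- c(kept_idx, i)
      rep_of[i] <- records$id[i]
    }
  }
  kept <- records[sort(kept_idx), , drop = FALSE]
  clusters <- tibble(member = records$id, representative = rep_of)
  list(kept = kept, clusters = clusters)
}
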