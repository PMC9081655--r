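#' Configuration for subfamily classification
#'
#' @param tandem_gap Maximum number of residues allowed between the end of
#'   one repeat and the start of the next for the two to count as tandem
#'   (default 10). The repeat `end` here includes the helix-3 tail, so
#'   back-to-back ~52-residue repeats chain naturally.
#' @param rr_min_separation Minimum number of residues between the end of
#'   the N-terminal `RR_FIRST` repeat and the start of the SHAQK motif for
#'   an R-R type call (default 40): the two repeats of R-R proteins sit far
#'   apart, at the N-terminus and the middle of the sequence.
#' @param scan A [myb_scan_config()] used when scanning is performed on
#'   behalf of the classifier.
#' @return A list of class `myb_classify_config`.
#' @export
myb_classify_config <- function(tandem_gap = 10L, rr_min_separation = 40L,
                                scan = myb_scan_config()) {
  stopifnot(tandem_gap >= 0L, rr_min_separation >= 0L,
            inherits(scan, "myb_scan_config"))
  structure(list(tandem_gap = as.integer(tandem_gap),
                 rr_min_separation = as.integer(rr_min_separation),
                 scan = scan),
            class = "myb_classify_config")
}

SUBFAMILIES <- c("R2R3", "R3_MYB", "R4_MYB", "MYB_RELATED", "NOT_MYB")
RELATED_TYPES <- c("CCA1_LIKE", "R_R", "TBP_LIKE", "MYB_CC", "GARP_LIKE",
                   "UNCLASSIFIED")
FULL_REPEAT_CLASSES <- c("R2_CONSENSUS", "R3_CONSENSUS", "GENERIC_R")

# longest run of full repeats in which each next hit starts no more than
# `gap` residues after the previous hit's (tail-inclusive) end
longest_tandem_chain <- function(repeats, gap) {
  full <- repeats[repeats$repeat_class %in% FULL_REPEAT_CLASSES, ,
                  drop = FALSE]
  if (nrow(full) == 0L) return(0L)
  full <- full[order(full$start), , drop = FALSE]
  best <- run <- 1L
  if (nrow(full) > 1L) {
    for (i in 2:nrow(full)) {
      if (full$start[i] - full$end[i - 1L] <= gap) {
        run <- run + 1L
      } else {
        run <- 1L
      }
      best <- max(best, run)
    }
  }
  best
}

#' Classify one protein from its repeat and motif hits
#'
#' Decision procedure, in order:
#' 1. Count the longest tandem chain of full repeats
#'    (`R2_CONSENSUS`/`R3_CONSENSUS`/`GENERIC_R`, each starting at most
#'    `tandem_gap` after the previous one's end): a chain of 4 or more is
#'    `R4_MYB`, exactly 3 is `R3_MYB`, exactly 2 is `R2R3`.
#' 2. Otherwise type as MYB-related, first rule that fires wins:
#'    `TBP_LIKE` (TBP motif present); `MYB_CC` (SHLQK motif present and an
#'    LHEQLE hit lies outside every repeat interval); `GARP_LIKE` (SHLQK
#'    present); `R_R` (SHAQK present and an `RR_FIRST` repeat ends at least
#'    `rr_min_separation` residues before the motif start); `CCA1_LIKE`
#'    (SHAQK present); `UNCLASSIFIED` (any repeat or signature motif hit).
#' 3. `NOT_MYB` when there is no evidence at all.
#'
#' EAR hits are annotation only and never count as classification evidence.
#'
#' @param seq_id Record id (used to filter `repeats`/`motifs`).
#' @param repeats Repeat hits from [detect_repeats()].
#' @param motifs Signature motif hits from [scan_motifs()].
#' @param config A [myb_classify_config()].
#' @return A one-row tibble: `seq_id`, `subfamily`, `related_type`,
#'   `chain_length`, `n_repeats`, `n_motifs`.
#' @export
classify_protein <- function(seq_id, repeats, motifs,
                             config = myb_classify_config()) {
  stopifnot(inherits(config, "myb_classify_config"))
  rp <- repeats[repeats$seq_id == seq_id, , drop = FALSE]
  mt <- motifs[motifs$seq_id == seq_id &
                 motifs$motif_name != "EAR", , drop = FALSE]
  chain <- longest_tandem_chain(rp, config$tandem_gap)
  subfamily <- NA_character_
  related <- NA_character_
  if (chain >= 4L) {
    subfamily <- "R4_MYB"
  } else if (chain == 3L) {
    subfamily <- "R3_MYB"
  } else if (chain == 2L) {
    subfamily <- "R2R3"
  } else {
    has <- function(name) any(mt$motif_name == name)
    lheqle_outside <- function() {
      h <- mt[mt$motif_name == "LHEQLE", , drop = FALSE]
      if (nrow(h) == 0L) return(FALSE)
      if (nrow(rp) == 0L) return(TRUE)
      any(vapply(seq_len(nrow(h)), function(i) {
        all(h$end[i] < rp$start | h$start[i] > rp$end)
      }, logical(1)))
    }
    rr_far_before_shaqk <- function() {
      sh <- mt[mt$motif_name == "SHAQK", , drop = FALSE]
      rr <- rp[rp$repeat_class == "RR_FIRST", , drop = FALSE]
      if (nrow(sh) == 0L || nrow(rr) == 0L) return(FALSE)
      any(outer(sh$start, rr$end, `-`) >= config$rr_min_separation)
    }
    if (has("TBP")) {
      subfamily <- "MYB_RELATED"; related <- "TBP_LIKE"
    } else if (has("SHLQK") && lheqle_outside()) {
      subfamily <- "MYB_RELATED"; related <- "MYB_CC"
    } else if (has("SHLQK")) {
      subfamily <- "MYB_RELATED"; related <- "GARP_LIKE"
    } else if (has("SHAQK") && rr_far_before_shaqk()) {
      subfamily <- "MYB_RELATED"; related <- "R_R"
    } else if (has("SHAQK")) {
      subfamily <- "MYB_RELATED"; related <- "CCA1_LIKE"
    } else if (nrow(rp) > 0L || nrow(mt) > 0L) {
      subfamily <- "MYB_RELATED"; related <- "UNCLASSIFIED"
    } else {
      subfamily <- "NOT_MYB"
    }
  }
  tibble(seq_id = seq_id, subfamily = subfamily, related_type = related,
         chain_length = chain, n_repeats = nrow(rp), n_motifs = nrow(mt))
}

#' Assign family member names
#'
#' Implements the conventional naming scheme: R2R3 members are numbered
#' `<prefix>1..n` in input order, MYB-related members `<prefix>R1..m`,
#' 3R members `<prefix>3R<k>` and 4R members `<prefix>4R<k>`. `NOT_MYB`
#' records stay unnamed.
#'
#' @param calls A classification tibble (one row per protein, in naming
#'   order) with a `subfamily` column.
#' @param prefix Name prefix token (default `"CwMYB"`).
#' @return `calls` with an `assigned_name` column.
#' @export
assign_names <- function(calls, prefix = "CwMYB") {
  n <- nrow(calls)
  name <- rep(NA_character_, n)
  counters <- c(R2R3 = 0L, MYB_RELATED = 0L, R3_MYB = 0L, R4_MYB = 0L)
  infix <- c(R2R3 = "", MYB_RELATED = "R", R3_MYB = "3R", R4_MYB = "4R")
  for (i in seq_len(n)) {
    sf <- calls$subfamily[i]
    if (sf %in% names(counters)) {
      counters[sf] <- counters[sf] + 1L
      name[i] <- paste0(prefix, infix[[sf]], counters[[sf]])
    }
  }
  calls$assigned_name <- name
  calls
}

#' Classify a whole record set
#'
#' Convenience pipeline: scans repeats and signature motifs, classifies
#' every record, assigns names, and annotates EAR motifs outside the
#' repeats. This is the main entry point for family identification.
#'
#' @param records A tibble of protein records (`id`, `description`,
#'   `sequence`).
#' @param config A [myb_classify_config()].
#' @param prefix Naming prefix passed to [assign_names()].
#' @return A tibble of class `myb_calls` with one row per record:
#'   `seq_id`, `subfamily`, `related_type`, `assigned_name`,
#'   `chain_length`, `n_repeats`, `n_motifs`, `n_ear`, and nested
#'   list-columns `repeats` and `motifs` holding the per-record evidence.
#' @examples
#' recs <- gen_family_set(synthetic_family_spec(counts = c(R2R3 = 2), seed = 1))
#' classify_proteins(recs)
#' @export
classify_proteins <- function(records, config = myb_classify_config(),
                              prefix = "CwMYB") {
  records <- validate_records(records)
  repeats <- detect_repeats(records, config$scan)
  motifs <- scan_motifs(records)
  ear <- scan_ear(records, repeats)
  calls <- purrr::map_dfr(records$id, classify_protein,
                          repeats = repeats, motifs = motifs, config = config)
  calls <- assign_names(calls, prefix = prefix)
  calls$n_ear <- vapply(calls$seq_id,
                        function(id) sum(ear$seq_id == id), integer(1),
                        USE.NAMES = FALSE)
  calls$repeats <- lapply(calls$seq_id,
                          function(id) repeats[repeats$seq_id == id, ])
  calls$motifs <- lapply(calls$seq_id, function(id) {
    rbind(motifs[motifs$seq_id == id, ], ear[ear$seq_id == id, ])
  })
  calls <- calls[, c("seq_id", "subfamily", "related_type", "assigned_name",
                     "chain_length", "n_repeats", "n_motifs", "n_ear",
                     "repeats", "motifs")]
  class(calls) <- c("myb_calls", class(calls))
  calls
}

#' Summarize a classified family
#'
#' Produces the family summary table: one row per subfamily, with the
#' MYB-related subfamily broken down by type.
#'
#' @param calls A classification tibble with `subfamily` and `related_type`.
#' @return A tibble `subfamily`, `related_type`, `n`; counts sum to
#'   `nrow(calls)`.
#' @export
summarize_family <- function(calls) {
  base <- tibble(subfamily = SUBFAMILIES)
  totals <- dplyr::count(as_tibble(calls)[, c("subfamily", "related_type")],
                         .data$subfamily, .data$related_type, name = "n")
  out <- dplyr::left_join(
    tidyr::expand_grid(subfamily = SUBFAMILIES[SUBFAMILIES != "MYB_RELATED"],
                       related_type = NA_character_) |>
      dplyr::bind_rows(tidyr::expand_grid(subfamily = "MYB_RELATED",
                                          related_type = RELATED_TYPES)),
    totals, by = c("subfamily", "related_type"))
  out$n[is.na(out$n)] <- 0L
  out$subfamily <- factor(out$subfamily, levels = SUBFAMILIES)
  out <- dplyr::arrange(out, .data$subfamily)
  out$subfamily <- as.character(out$subfamily)
  out
}
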