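#' Compile a degenerate motif pattern
#'
#' Parses the dash-separated consensus notation used for MYB repeat and
#' signature motifs into a pattern object. Tokens are a single residue
#' (`W`), a residue alternative set (`[FILM]`), or a spacer of arbitrary
#' residues: `x(19)` for exactly 19, `x(18,19)` for a range.
#'
#' `X` in a sequence never satisfies an anchor position, only spacers.
#'
#' @param spec Pattern string, e.g. `"W-x(19)-W-x(19)-W"`.
#' @param name Optional pattern name (token).
#' @return An object of class `myb_pattern`.
#' @examples
#' compile_pattern("W-x(19)-W-x(19)-W", name = "R2")
#' compile_pattern("S-H-A-Q-K-[YF]-F", name = "SHAQK")
#' @export
compile_pattern <- function(spec, name = spec) {
  stopifnot(is.character(spec), length(spec) == 1L, nchar(spec) > 0L)
  tokens <- strsplit(spec, "-", fixed = TRUE)[[1L]]
  offsets <- cumsum(c(1L, nchar(tokens) + 1L))[seq_along(tokens)]
  elements <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    off <- offsets[i]
    if (nchar(tok) == 1L && tok %in% AA_STANDARD) {
      elements[[i]] <- list(type = "anchor", set = tok)
    } else if (grepl("^\\[[A-Z]+\\]$", tok)) {
      set <- unique(strsplit(substr(tok, 2L, nchar(tok) - 1L), "")[[1L]])
      if (!all(set %in% AA_STANDARD)) {
        abort(paste0("non-residue letter in set token '", tok,
                     "' at offset ", off), class = "cwmyb_pattern_error")
      }
      elements[[i]] <- list(type = "anchor", set = set)
    } else if (grepl("^x\\([0-9]+\\)$", tok)) {
      n <- as.integer(sub("^x\\(([0-9]+)\\)$", "\\1", tok))
      elements[[i]] <- list(type = "spacer", min = n, max = n)
    } else if (grepl("^x\\([0-9]+,[0-9]+\\)$", tok)) {
      mn <- as.integer(sub("^x\\(([0-9]+),[0-9]+\\)$", "\\1", tok))
      mx <- as.integer(sub("^x\\([0-9]+,([0-9]+)\\)$", "\\1", tok))
      if (mn > mx) {
        abort(paste0("spacer min > max in token '", tok, "' at offset ", off),
              class = "cwmyb_pattern_error")
      }
      elements[[i]] <- list(type = "spacer", min = mn, max = mx)
    } else {
      abort(paste0("malformed pattern token '", tok, "' at offset ", off),
            class = "cwmyb_pattern_error")
    }
  }
  if (!any(vapply(elements, function(e) e$type == "anchor", logical(1)))) {
    abort("pattern has no anchor position (spacers only)",
          class = "cwmyb_pattern_error")
  }
  structure(list(name = name, spec = spec, elements = elements),
            class = "myb_pattern")
}

#' @export
print.myb_pattern <- function(x, ...) {
  cat("<myb_pattern> ", x$name, ": ", x$spec, "\n", sep = "")
  invisible(x)
}

#' Built-in signature motif patterns
#'
#' The signature motifs used to type MYB-related proteins, plus the EAR
#' repression motif:
#' \describe{
#'   \item{SHAQK}{`S-H-A-Q-K-[YF]-F` — CCA1-like / R-R second repeat}
#'   \item{TBP}{`L-K-D-K-W-[RK]-[NT]` — telomere-binding-protein-like}
#'   \item{SHLQK}{`S-H-L-Q-[KM]-x(1)-R` — GARP-like / Myb-CC}
#'   \item{LHEQLE}{`L-H-E-Q-L-E` — namesake hexapeptide of the Myb-CC
#'     coiled-coil region, searched outside the repeats}
#'   \item{EAR}{`L-x(1)-L-x(1)-L` — repression-associated motif}
#' }
#'
#' @return A named list of `myb_pattern` objects.
#' @export
myb_motifs <- function() {
  list(
    SHAQK  = compile_pattern("S-H-A-Q-K-[YF]-F", name = "SHAQK"),
    TBP    = compile_pattern("L-K-D-K-W-[RK]-[NT]", name = "TBP"),
    SHLQK  = compile_pattern("S-H-L-Q-[KM]-x(1)-R", name = "SHLQK"),
    LHEQLE = compile_pattern("L-H-E-Q-L-E", name = "LHEQLE"),
    EAR    = compile_pattern("L-x(1)-L-x(1)-L", name = "EAR")
  )
}

# all (start, end) matches of a compiled pattern in a letters vector;
# 1-based inclusive coordinates; overlapping matches included
match_pattern <- function(letters, pattern) {
  n <- length(letters)
  elems <- pattern$elements
  # positions the pattern can reach next, starting from `pos`, consuming
  # elements i..end; returns exclusive end positions
  reach <- function(pos, i) {
    if (i > length(elems)) return(pos)
    e <- elems[[i]]
    if (e$type == "anchor") {
      ok <- pos <= n & letters[pmin(pos, n)] %in% e$set
      pos <- pos[ok] + 1L
      if (length(pos) == 0L) return(integer(0))
      reach(pos, i + 1L)
    } else {
      nxt <- unique(unlist(lapply(pos, function(p) p + e$min:e$max)))
      nxt <- nxt[nxt <= n + 1L]
      if (length(nxt) == 0L) return(integer(0))
      reach(nxt, i + 1L)
    }
  }
  hits <- list()
  for (s in seq_len(n)) {
    ends <- reach(s, 1L)
    for (e in unique(ends)) {
      hits[[length(hits) + 1L]] <- c(start = s, end = e - 1L)
    }
  }
  if (length(hits) == 0L) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  out <- as_tibble(do.call(rbind, hits))
  dplyr::arrange(out, .data$start, .data$end)
}

#' Find all matches of a motif pattern in protein records
#'
#' Returns every match, including overlapping ones, sorted by sequence and
#' start. Coordinates are 1-based inclusive.
#'
#' @param records A tibble of protein records (`id`, `sequence`), as from
#'   [read_fasta()].
#' @param pattern A `myb_pattern` from [compile_pattern()], or a pattern
#'   string which will be compiled.
#' @return A tibble with columns `seq_id`, `motif_name`, `start`, `end`,
#'   `matched`.
#' @examples
#' recs <- tibble::tibble(id = "p", description = "", sequence = "AASHAQKYFAA")
#' find_motif(recs, myb_motifs()$SHAQK)
#' @export
find_motif <- function(records, pattern) {
  if (is.character(pattern)) pattern <- compile_pattern(pattern)
  stopifnot(inherits(pattern, "myb_pattern"))
  records <- validate_records(records)
  res <- purrr::map2_dfr(records$id, records$sequence, function(id, seq) {
    letters_i <- strsplit(seq, "", fixed = TRUE)[[1L]]
    m <- match_pattern(letters_i, pattern)
    if (nrow(m) == 0L) return(NULL)
    tibble(seq_id = id, motif_name = pattern$name,
           start = m$start, end = m$end,
           matched = substr(rep(seq, nrow(m)), m$start, m$end))
  })
  if (nrow(res) == 0L) {
    res <- tibble(seq_id = character(0), motif_name = character(0),
                  start = integer(0), end = integer(0),
                  matched = character(0))
  }
  res
}

#' Scan records for all signature motifs
#'
#' Runs [find_motif()] for the four classification signature motifs
#' (SHAQK, TBP, SHLQK, LHEQLE). EAR is scanned separately by [scan_ear()]
#' because its definition excludes the repeat regions.
#'
#' @inheritParams find_motif
#' @return A combined motif-hit tibble.
#' @export
scan_motifs <- function(records) {
  sig <- myb_motifs()[c("SHAQK", "TBP", "SHLQK", "LHEQLE")]
  purrr::map_dfr(sig, function(p) find_motif(records, p))
}

#' Scan for EAR (LxLxL) motifs outside the MYB repeats
#'
#' The EAR repression motif is only meaningful outside the DNA-binding
#' domain, so matches whose span intersects any detected repeat interval
#' (including the repeat tail) are discarded.
#'
#' @param records A tibble of protein records.
#' @param repeats Repeat hits for the same records, as from
#'   [detect_repeats()].
#' @return A motif-hit tibble (`motif_name` = `"EAR"`).
#' @export
scan_ear <- function(records, repeats) {
  hits <- find_motif(records, myb_motifs()$EAR)
  if (nrow(hits) == 0L || nrow(repeats) == 0L) return(hits)
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    r <- repeats[repeats$seq_id == hits$seq_id[i], , drop = FALSE]
    if (nrow(r) == 0L) return(TRUE)
    all(hits$end[i] < r$start | hits$start[i] > r$end)
  }, logical(1))
  hits[keep, , drop = FALSE]
}
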