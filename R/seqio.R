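#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Residue alphabet: the 20 standard amino acids plus X (unknown). X never
# satisfies an anchor or motif position, only spacer positions.
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
AA_ALPHABET_X <- c(AA_STANDARD, "X")

#' Read protein sequences from a FASTA file
#'
#' Parses a multi-record FASTA file into a tibble of protein records. The
#' record id is the first whitespace-delimited token of the header; the rest
#' of the header becomes the description. Sequences are uppercased and a
#' single trailing `*` (stop symbol) is stripped.
#'
#' Files that look like nucleotide sequence (more than 90% of letters in
#' ACGTUN over more than 50 residues) are rejected with advice to translate
#' first: this reader consumes proteins only.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `sequence`, one row per
#'   record.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 a MYB", "MKWAA", ">p2", "MSHAQKYF"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "cwmyb_input_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("could not parse FASTA file '", path, "': ",
                   conditionMessage(e)),
            class = "cwmyb_input_error")
    }
  )
  if (length(set) == 0L) {
    abort(paste0("FASTA file '", path, "' contains no records"),
          class = "cwmyb_input_error")
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- unname(toupper(as.character(set)))
  # strip stop symbol from the end only
  seqs <- sub("\\*$", "", seqs)
  validate_records(tibble(id = ids, description = desc, sequence = seqs),
                   check_nucleotide = TRUE)
}

#' Validate a tibble of protein records
#'
#' Checks id uniqueness, non-empty sequences, the amino-acid alphabet
#' (20 standard residues plus X), and rejects records that look like
#' nucleotide sequence.
#'
#' @param records A tibble with columns `id`, `description`, `sequence`.
#' @param check_nucleotide Apply the nucleotide-lookalike heuristic
#'   (default `FALSE`; [read_fasta()] enables it so nucleotide FASTA files
#'   are caught at the door, while programmatically built protein records
#'   with a biased composition are not second-guessed).
#' @return The validated tibble, invisibly identical to the input.
#' @export
validate_records <- function(records, check_nucleotide = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  if (!"description" %in% names(records)) records$description <- ""
  records <- as_tibble(records)[, c("id", "description", "sequence")]
  if (any(records$id == "" | is.na(records$id))) {
    abort("empty record id", class = "cwmyb_input_error")
  }
  dup <- unique(records$id[duplicated(records$id)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate record id(s): ", paste(dup, collapse = ", ")),
          class = "cwmyb_input_error")
  }
  if (any(nchar(records$sequence) == 0L)) {
    bad <- records$id[nchar(records$sequence) == 0L][1L]
    abort(paste0("empty sequence for record '", bad, "'"),
          class = "cwmyb_input_error")
  }
  if (any(grepl("\\s", records$sequence))) {
    abort("whitespace inside sequence", class = "cwmyb_input_error")
  }
  for (i in seq_len(nrow(records))) {
    s <- records$sequence[i]
    letters_i <- strsplit(s, "", fixed = TRUE)[[1L]]
    bad <- which(!letters_i %in% AA_ALPHABET_X)
    if (length(bad) > 0L) {
      abort(paste0("record '", records$id[i], "': non-amino-acid character '",
                   letters_i[bad[1L]], "' at position ", bad[1L]),
            class = "cwmyb_input_error")
    }
    nuc <- mean(letters_i %in% c("A", "C", "G", "T", "U", "N"))
    if (check_nucleotide && nchar(s) > 50L && nuc > 0.9) {
      abort(paste0("record '", records$id[i], "' looks like nucleotide ",
                   "sequence (", round(100 * nuc), "% ACGTUN); translate to ",
                   "protein before reading"),
            class = "cwmyb_input_error")
    }
  }
  records
}

#' Write protein records to a FASTA file
#'
#' @param records A tibble with columns `id`, `description`, `sequence`.
#' @param path Output path.
#' @param wrap Line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  if (nrow(records) == 0L) {
    warn("writing empty FASTA file (no records)")
    writeLines(character(0), path)
    return(invisible(path))
  }
  records <- validate_records(records)
  headers <- ifelse(records$description == "", records$id,
                    paste(records$id, records$description))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = as.integer(wrap))
  invisible(path)
}

#' Read a TPM or Ct table from TSV
#'
#' Expects a header row; the first column holds unique row ids, all other
#' columns are numeric. `kind = "tpm"` forbids negative cells; `kind = "ct"`
#' forbids non-positive cells.
#'
#' @param path Path to a tab-separated file.
#' @param kind Either `"tpm"` or `"ct"`.
#' @return A tibble whose first column is the row id.
#' @export
read_table <- function(path, kind = c("tpm", "ct")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(paste0("table not found: ", path), class = "cwmyb_input_error")
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    abort(paste0("empty table: ", path), class = "cwmyb_input_error")
  }
  hdr <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  if (length(hdr) >= 2L &&
      any(suppressWarnings(!is.na(as.numeric(hdr[-1L]))))) {
    abort(paste0("table '", path, "' appears to lack a header row ",
                 "(numeric value in header position)"),
          class = "cwmyb_input_error")
  }
  if (anyDuplicated(hdr)) {
    abort(paste0("duplicate column label(s) in '", path, "'"),
          class = "cwmyb_input_error")
  }
  tab <- withCallingHandlers(
    tryCatch(
      readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                      col_types = readr::cols(
                        readr::col_character(),
                        .default = readr::col_double())),
      error = function(e) abort(paste0("could not parse TSV '", path, "': ",
                                       conditionMessage(e)),
                                class = "cwmyb_input_error")
    ),
    warning = function(w) invokeRestart("muffleWarning")
  )
  prob <- readr::problems(tab)
  if (nrow(prob) > 0L) {
    abort(paste0("non-numeric or ragged cell in '", path, "' at row ",
                 prob$row[1L], ", column ", prob$col[1L]),
          class = "cwmyb_input_error")
  }
  if (ncol(tab) < 2L) {
    abort(paste0("table '", path, "' needs a row-id column plus at least ",
                 "one numeric column"), class = "cwmyb_input_error")
  }
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate row id(s) in '", path, "': ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "cwmyb_input_error")
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    abort(paste0("missing/non-numeric cell in '", path, "' at row id '",
                 ids[idx[1L]], "', column '", colnames(vals)[idx[2L]], "'"),
          class = "cwmyb_input_error")
  }
  if (kind == "tpm" && any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1L, ]
    abort(paste0("negative TPM at row id '", ids[idx[1L]], "', column '",
                 colnames(vals)[idx[2L]], "'"), class = "cwmyb_input_error")
  }
  if (kind == "ct" && any(vals <= 0)) {
    idx <- which(vals <= 0, arr.ind = TRUE)[1L, ]
    abort(paste0("non-positive Ct at row id '", ids[idx[1L]], "', column '",
                 colnames(vals)[idx[2L]], "'"), class = "cwmyb_input_error")
  }
  tab
}
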