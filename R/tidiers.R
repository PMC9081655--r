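#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a family classification result
#'
#' @param x A `myb_calls` tibble from [classify_proteins()].
#' @param ... Unused.
#' @return A flat tibble (one row per protein) without the nested evidence
#'   columns.
#' @method tidy myb_calls
#' @export
tidy.myb_calls <- function(x, ...) {
  as_tibble(x)[, c("seq_id", "subfamily", "related_type", "assigned_name",
                   "chain_length", "n_repeats", "n_motifs", "n_ear")]
}

#' One-row summary of a family classification
#'
#' @inheritParams tidy.myb_calls
#' @return A one-row tibble with the total and per-subfamily member counts.
#' @method glance myb_calls
#' @export
glance.myb_calls <- function(x, ...) {
  tibble(n = nrow(x),
         n_r2r3 = sum(x$subfamily == "R2R3"),
         n_myb_related = sum(x$subfamily == "MYB_RELATED"),
         n_3r = sum(x$subfamily == "R3_MYB"),
         n_4r = sum(x$subfamily == "R4_MYB"),
         n_not_myb = sum(x$subfamily == "NOT_MYB"))
}

#' Tidy a DEG screen result
#'
#' @param x A `myb_deg` tibble from [deg_screen()].
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy myb_deg
#' @export
tidy.myb_deg <- function(x, ...) as_tibble(x)

#' One-row summary of a DEG screen
#'
#' @inheritParams tidy.myb_deg
#' @return A one-row tibble: genes tested, genes passing, and the numbers
#'   failing each filter.
#' @method glance myb_deg
#' @export
glance.myb_deg <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_pass = sum(x$passes),
         n_expressed = sum(x$expressed),
         n_large_fc = sum(abs(x$log2fc) > 1),
         n_significant = sum(!is.na(x$pvalue) & x$pvalue < 0.05))
}

#' Tidy a qPCR screen result
#'
#' @param x A `myb_ddct` tibble from [qpcr_screen()].
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy myb_ddct
#' @export
tidy.myb_ddct <- function(x, ...) as_tibble(x)

#' One-row summary of a qPCR screen
#'
#' @inheritParams tidy.myb_ddct
#' @return A one-row tibble with comparison counts and significance tallies.
#' @method glance myb_ddct
#' @export
glance.myb_ddct <- function(x, ...) {
  tibble(n_comparisons = nrow(x),
         n_p05 = sum(x$signif %in% c("*", "**")),
         n_p01 = sum(x$signif == "**"),
         max_fold = max(x$fold),
         min_fold = min(x$fold))
}
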