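write_tsv_quiet <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

run_manifest <- function(out_dir, inputs, params, seed = NA_integer_) {
  manifest <- list(
    package = "cwmyb",
    version = as.character(utils::packageVersion("cwmyb")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    params = params
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run family identification end to end
#'
#' Reads a protein FASTA, removes redundant sequences at the identity
#' cutoff, scans repeats and motifs, classifies and names every kept
#' record, computes physicochemical properties, and writes the results
#' (calls TSV/JSON, family summary TSV, properties TSV, cluster map TSV,
#' run manifest) to `out_dir`.
#'
#' @param fasta Path to a protein FASTA file.
#' @param out_dir Output directory (created if needed).
#' @param config A [myb_classify_config()].
#' @param redundancy_threshold Identity cutoff for [dedupe()] (default
#'   0.80); `NULL` skips redundancy removal.
#' @param prefix Naming prefix.
#' @return Invisibly, a list with `calls`, `summary`, `props`, `clusters`.
#' @export
run_identify <- function(fasta, out_dir, config = myb_classify_config(),
                         redundancy_threshold = 0.80, prefix = "CwMYB") {
  records <- read_fasta(fasta)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(redundancy_threshold)) {
    dd <- dedupe(records, threshold = redundancy_threshold)
    records <- dd$kept
    clusters <- dd$clusters
  } else {
    clusters <- tibble(member = records$id, representative = records$id)
  }
  calls <- classify_proteins(records, config = config, prefix = prefix)
  summary <- summarize_family(calls)
  props <- protein_props(records)
  flat <- tidy(calls)
  write_tsv_quiet(flat, file.path(out_dir, "calls.tsv"))
  write_tsv_quiet(summary, file.path(out_dir, "summary.tsv"))
  write_tsv_quiet(props, file.path(out_dir, "props.tsv"))
  write_tsv_quiet(clusters, file.path(out_dir, "clusters.tsv"))
  evidence <- lapply(seq_len(nrow(calls)), function(i) {
    list(seq_id = calls$seq_id[i],
         subfamily = calls$subfamily[i],
         related_type = calls$related_type[i],
         assigned_name = calls$assigned_name[i],
         repeats = calls$repeats[[i]],
         motifs = calls$motifs[[i]])
  })
  jsonlite::write_json(evidence, file.path(out_dir, "calls.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  run_manifest(out_dir, inputs = list(fasta = fasta),
               params = list(redundancy_threshold = redundancy_threshold,
                             tandem_gap = config$tandem_gap,
                             rr_min_separation = config$rr_min_separation,
                             slack = config$scan$slack,
                             tail = config$scan$tail,
                             prefix = prefix))
  invisible(list(calls = calls, summary = summary, props = props,
                 clusters = clusters))
}

#' Run the expression screen end to end
#'
#' Reads a TPM TSV, writes the heatmap-ready log2 matrix and the DEG
#' report.
#'
#' @param tpm Path to a TPM TSV (first column gene id).
#' @param group_a,group_b Sample labels of the compared groups.
#' @param out_dir Output directory.
#' @param ... Passed to [deg_screen()].
#' @return Invisibly, a list with `deg` and `log2` tibbles.
#' @export
run_expression <- function(tpm, group_a, group_b, out_dir, ...) {
  m <- read_table(tpm, kind = "tpm")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lg <- log2_matrix(m)
  deg <- deg_screen(m, group_a, group_b, ...)
  write_tsv_quiet(lg, file.path(out_dir, "log2_matrix.tsv"))
  write_tsv_quiet(as_tibble(deg), file.path(out_dir, "deg.tsv"))
  run_manifest(out_dir, inputs = list(tpm = tpm),
               params = list(group_a = group_a, group_b = group_b))
  invisible(list(deg = deg, log2 = lg))
}

#' Run the qPCR screen end to end
#'
#' Reads a long-format Ct TSV (`gene`, `condition`, `timepoint`,
#' `replicate`, `ct_target`, `ct_reference`) and writes the fold-change
#' report with significance flags.
#'
#' @param ct_table Path to the Ct TSV.
#' @param out_dir Output directory.
#' @param control_condition Control condition label.
#' @return Invisibly, the `myb_ddct` report.
#' @export
run_qpcr <- function(ct_table, out_dir, control_condition = "control") {
  if (!file.exists(ct_table)) {
    abort(paste0("Ct table not found: ", ct_table),
          class = "cwmyb_input_error")
  }
  ct <- readr::read_tsv(ct_table, show_col_types = FALSE, progress = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- qpcr_screen(ct, control_condition = control_condition)
  write_tsv_quiet(as_tibble(res), file.path(out_dir, "qpcr.tsv"))
  run_manifest(out_dir, inputs = list(ct_table = ct_table),
               params = list(control_condition = control_condition))
  invisible(res)
}
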