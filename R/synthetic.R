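# Backbone alphabet for synthetic proteins: the 20 standard residues minus
# every repeat anchor letter (W/Y/F and the first-anchor substitutes
# I/L/M), so a backbone can never contribute an anchor to any repeat
# triple and the planted structure is the only signal.
BACKBONE_ALPHABET <- setdiff(AA_STANDARD, c("W", "Y", "F", "I", "L", "M"))

SYNTH_CLASSES <- c("R2R3", "R3_MYB", "R4_MYB", "CCA1_LIKE", "R_R",
                   "TBP_LIKE", "MYB_CC", "GARP_LIKE", "NOT_MYB")

synth_class_truth <- function(class) {
  if (class %in% c("R2R3", "R3_MYB", "R4_MYB", "NOT_MYB")) {
    list(subfamily = class, related_type = NA_character_)
  } else {
    list(subfamily = "MYB_RELATED", related_type = class)
  }
}

bb <- function(n, alphabet = BACKBONE_ALPHABET) {
  if (n == 0L) return(character(0))
  sample(alphabet, n, replace = TRUE)
}

# a planted cassette: letters plus the indices (within the cassette) of the
# structure-defining positions (anchors and motif letters; spacers excluded)
cassette <- function(class) {
  r2 <- function() {
    l <- c("W", bb(19), "W", bb(19), "W")
    list(letters = l, structural = c(1L, 21L, 41L))
  }
  r3 <- function() {
    l <- c(sample(c("F", "I", "L", "M"), 1L), bb(18), "W", bb(18), "W")
    list(letters = l, structural = c(1L, 20L, 39L))
  }
  rr <- function() {
    l <- c("W", bb(19), "W", bb(19), "Y")
    list(letters = l, structural = c(1L, 21L, 41L))
  }
  motif <- function(s) {
    l <- strsplit(s, "", fixed = TRUE)[[1L]]
    list(letters = l, structural = seq_along(l))
  }
  join <- function(parts, linkers) {
    letters_all <- character(0)
    structural <- integer(0)
    for (i in seq_along(parts)) {
      if (i > 1L) letters_all <- c(letters_all, bb(linkers[i - 1L]))
      structural <- c(structural, parts[[i]]$structural + length(letters_all))
      letters_all <- c(letters_all, parts[[i]]$letters)
    }
    list(letters = letters_all, structural = structural)
  }
  switch(class,
    # R2 + 5-residue linker + R3: chain of two full repeats
    R2R3 = join(list(r2(), r3()), 5L),
    # three/four tandem repeats, 12 backbone residues between anchor spans
    R3_MYB = join(list(r2(), r2(), r3()), c(12L, 12L)),
    R4_MYB = join(list(r2(), r2(), r2(), r3()), c(12L, 12L, 12L)),
    CCA1_LIKE = motif("SHAQKYF"),
    # N-terminal repeat with third anchor Y, long spacer, then the SHAQK
    # motif of the second repeat
    R_R = join(list(rr(), motif("SHAQKFF")), 60L),
    TBP_LIKE = motif("LKDKWRN"),
    MYB_CC = join(list(motif("SHLQKAR"), motif("LHEQLE")), 30L),
    GARP_LIKE = motif("SHLQKAR"),
    NOT_MYB = list(letters = character(0), structural = integer(0)),
    abort(paste0("unknown synthetic class '", class, "'"),
          class = "cwmyb_input_error")
  )
}

#' Generate one synthetic MYB protein of a given class
#'
#' Draws a random backbone over the 14-letter alphabet that excludes every
#' repeat anchor residue (W/Y/F and the first-anchor substitutes I/L/M),
#' and plants the class-defining cassette (repeat blocks and/or signature
#' motifs) at a random position. Because the backbone can never produce a
#' spurious anchor, the planted structure is the only classification
#' signal, which makes recovery tests exact.
#'
#' Uses the current RNG state; seed via `set.seed()` or through
#' [gen_family_set()].
#'
#' @param class One of `R2R3`, `R3_MYB`, `R4_MYB`, `CCA1_LIKE`, `R_R`,
#'   `TBP_LIKE`, `MYB_CC`, `GARP_LIKE`, `NOT_MYB`.
#' @param id Record id.
#' @param length_range Two integers: range of the backbone length (the
#'   cassette is inserted on top of this).
#' @param realistic_backbone If `TRUE`, the backbone uses all 20 residues
#'   (admitting spurious anchors) for stress testing.
#' @return A one-row tibble: `id`, `description`, `sequence`,
#'   `true_class`, `true_subfamily`, `true_related_type`, and a
#'   list-column `structural_positions` with the planted positions that
#'   structure-preserving mutation must not touch.
#' @export
gen_myb_protein <- function(class, id = paste0("syn_", class),
                            length_range = c(150L, 250L),
                            realistic_backbone = FALSE) {
  stopifnot(class %in% SYNTH_CLASSES)
  alphabet <- if (realistic_backbone) AA_STANDARD else BACKBONE_ALPHABET
  cas <- cassette(class)
  n_bb <- sample(length_range[1]:length_range[2], 1L)
  backbone <- bb(n_bb, alphabet)
  off <- sample(0:n_bb, 1L)
  letters_full <- c(backbone[seq_len(off)], cas$letters,
                    backbone[seq_len(n_bb - off) + off])
  structural <- cas$structural + off
  truth <- synth_class_truth(class)
  tibble(id = id,
         description = paste0("synthetic class=", class),
         sequence = paste(letters_full, collapse = ""),
         true_class = class,
         true_subfamily = truth$subfamily,
         true_related_type = truth$related_type,
         structural_positions = list(structural))
}

#' Specification for a synthetic family set
#'
#' @param counts Named integer vector of per-class counts; names from the
#'   class set of [gen_myb_protein()]. Defaults to 5 per class for all 9
#'   classes.
#' @param length_range Backbone length range.
#' @param mutation_rate Per-residue substitution probability in \[0, 1).
#' @param mutation_mode `"structure_preserving"` (planted positions are
#'   immune and substitutions are drawn from the backbone alphabet, so the
#'   true label cannot change) or `"corrupting"` (all positions mutable,
#'   substitutions from the full alphabet).
#' @param realistic_backbone See [gen_myb_protein()].
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `synthetic_family_spec`.
#' @export
synthetic_family_spec <- function(counts = NULL,
                                  length_range = c(150L, 250L),
                                  mutation_rate = 0,
                                  mutation_mode = c("structure_preserving",
                                                    "corrupting"),
                                  realistic_backbone = FALSE,
                                  seed = 1L) {
  mutation_mode <- match.arg(mutation_mode)
  if (is.null(counts)) {
    counts <- stats::setNames(rep(5L, length(SYNTH_CLASSES)), SYNTH_CLASSES)
  }
  stopifnot(all(names(counts) %in% SYNTH_CLASSES), all(counts >= 0L),
            mutation_rate >= 0, mutation_rate < 1)
  structure(list(counts = counts, length_range = length_range,
                 mutation_rate = mutation_rate,
                 mutation_mode = mutation_mode,
                 realistic_backbone = realistic_backbone,
                 seed = as.integer(seed)),
            class = "synthetic_family_spec")
}

mutate_sequence <- function(seq, rate, mode, protected) {
  if (rate == 0) return(seq)
  l <- strsplit(seq, "", fixed = TRUE)[[1L]]
  eligible <- seq_along(l)
  sub_alphabet <- AA_STANDARD
  if (mode == "structure_preserving") {
    eligible <- setdiff(eligible, protected)
    sub_alphabet <- BACKBONE_ALPHABET
  }
  hit <- eligible[stats::runif(length(eligible)) < rate]
  for (p in hit) {
    l[p] <- sample(setdiff(sub_alphabet, l[p]), 1L)
  }
  paste(l, collapse = "")
}

#' Generate a labeled synthetic family set
#'
#' @param spec A [synthetic_family_spec()].
#' @return A tibble of labeled records (see [gen_myb_protein()]); byte
#'   identical across runs for a fixed seed. The seed is recorded in every
#'   record description.
#' @examples
#' recs <- gen_family_set(synthetic_family_spec(seed = 7))
#' nrow(recs)  # 45
#' @export
gen_family_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_family_spec"))
  set.seed(spec$seed)
  recs <- purrr::map_dfr(names(spec$counts), function(cl) {
    k <- spec$counts[[cl]]
    if (k == 0L) return(NULL)
    purrr::map_dfr(seq_len(k), function(i) {
      gen_myb_protein(cl, id = paste0("syn_", cl, "_", i),
                      length_range = spec$length_range,
                      realistic_backbone = spec$realistic_backbone)
    })
  })
  recs$sequence <- vapply(seq_len(nrow(recs)), function(i) {
    mutate_sequence(recs$sequence[i], spec$mutation_rate,
                    spec$mutation_mode, recs$structural_positions[[i]])
  }, character(1))
  recs$description <- paste0(recs$description, " seed=", spec$seed,
                             " mutation=", spec$mutation_rate, "/",
                             spec$mutation_mode)
  recs
}

#' Specification for a synthetic TPM expression matrix
#'
#' @param n_genes Total genes.
#' @param n_de Number of differentially expressed genes (`<= n_genes`).
#' @param log2fc Planted absolute log2 fold change for DE genes (sign
#'   randomized per gene).
#' @param replicates Replicates per group (>= 2).
#' @param noise_sd Replicate noise standard deviation on the log2 scale.
#' @param baseline_mean,baseline_sd Per-gene baseline log2-TPM distribution
#'   (Normal; defaults 5 and 2).
#' @param seed Integer seed.
#' @return A list of class `synthetic_expression_spec`.
#' @export
synthetic_expression_spec <- function(n_genes = 1000L, n_de = 10L,
                                      log2fc = 2, replicates = 3L,
                                      noise_sd = 0.1, baseline_mean = 5,
                                      baseline_sd = 2, seed = 1L) {
  stopifnot(n_de <= n_genes, replicates >= 2L, noise_sd >= 0)
  structure(list(n_genes = as.integer(n_genes), n_de = as.integer(n_de),
                 log2fc = log2fc, replicates = as.integer(replicates),
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, seed = as.integer(seed)),
            class = "synthetic_expression_spec")
}

#' Generate a TPM matrix with planted differential expression
#'
#' Per-gene baseline log2-TPM is Normal(`baseline_mean`, `baseline_sd`);
#' DE genes are shifted by the planted log2 fold change (random sign) in
#' group A; replicate noise is Normal(0, `noise_sd`) on the log2 scale;
#' TPM is `2^value - 1` floored at 0 (the inverse of the `log2(TPM + 1)`
#' heatmap transform).
#'
#' @param spec A [synthetic_expression_spec()].
#' @return A list: `matrix` (tibble `gene`, then group A and B replicate
#'   columns), `truth` (tibble `gene`, `is_de`, `true_log2fc`), `group_a`,
#'   `group_b` (column labels).
#' @export
gen_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_expression_spec"))
  set.seed(spec$seed)
  genes <- sprintf("gene_%04d", seq_len(spec$n_genes))
  base <- stats::rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
  is_de <- seq_len(spec$n_genes) <= spec$n_de
  sign_de <- ifelse(stats::runif(spec$n_genes) < 0.5, -1, 1)
  shift <- ifelse(is_de, sign_de * spec$log2fc, 0)
  reps <- spec$replicates
  mk <- function(mu) {
    vapply(seq_len(reps), function(r) {
      v <- mu + stats::rnorm(spec$n_genes, 0, spec$noise_sd)
      pmax(2^v - 1, 0)
    }, numeric(spec$n_genes))
  }
  a <- mk(base + shift)
  b <- mk(base)
  colnames(a) <- paste0("A", seq_len(reps))
  colnames(b) <- paste0("B", seq_len(reps))
  mat <- dplyr::bind_cols(tibble(gene = genes), as_tibble(a), as_tibble(b))
  list(matrix = mat,
       truth = tibble(gene = genes, is_de = is_de,
                      true_log2fc = shift),
       group_a = colnames(a), group_b = colnames(b))
}

#' Generate a synthetic qPCR Ct table with a known fold change
#'
#' Emulates the relative-quantification design: a constant-expression
#' reference gene (internal control) at a fixed Ct, and a target whose
#' treated Ct is shifted by `-log2(true_fold)` relative to control, so the
#' expected `2^-ddCt` equals `true_fold`. Metadata mimics a stress
#' time-course design (treatment label and sampling timepoint).
#'
#' Uses the current RNG state; call `set.seed()` first for reproducibility.
#'
#' @param true_fold Planted fold change (> 0).
#' @param replicates Replicates per condition.
#' @param noise_sd Ct noise standard deviation (cycles).
#' @param gene Gene label.
#' @param condition Treatment label (e.g. `"NaCl"`, `"MeJA"`, `"cold"`).
#' @param timepoint Sampling timepoint in hours (design uses
#'   0/1/3/6/12/24 h).
#' @param ref_ct,base_target_ct Reference-gene and control target Ct
#'   levels.
#' @return A long-format tibble `gene`, `condition`, `timepoint`,
#'   `replicate`, `ct_target`, `ct_reference` containing control and
#'   treated rows, ready for [qpcr_screen()].
#' @export
gen_qpcr <- function(true_fold, replicates = 3L, noise_sd = 0.1,
                     gene = "target", condition = "NaCl", timepoint = 24,
                     ref_ct = 15, base_target_ct = 25) {
  stopifnot(true_fold > 0, replicates >= 1L, noise_sd >= 0)
  noise <- function() stats::rnorm(replicates, 0, noise_sd)
  ctl <- tibble(gene = gene, condition = "control", timepoint = timepoint,
                replicate = seq_len(replicates),
                ct_target = base_target_ct + noise(),
                ct_reference = ref_ct + noise())
  trt <- tibble(gene = gene, condition = condition, timepoint = timepoint,
                replicate = seq_len(replicates),
                ct_target = base_target_ct - log2(true_fold) + noise(),
                ct_reference = ref_ct + noise())
  dplyr::bind_rows(ctl, trt)
}
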