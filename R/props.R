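# Average (isotope-weighted) residue masses in Daltons, as used by the
# standard protein Mw calculators; a peptide's mass is the sum of residue
# masses plus one water.
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01528

#' Bjellqvist pKa set
#'
#' The pKa parameterization used by the standard theoretical-pI calculators:
#' residue-specific N-terminal pKa values, a C-terminal pKa (residue-specific
#' for terminal D and E), and side-chain pKa values for the seven ionizable
#' residues. All values are pH units.
#'
#' @return A list of class `pka_set` with elements `nterm` (named vector,
#'   `default` plus residue-specific entries), `cterm` (likewise) and
#'   `sidechain` (named vector for C, D, E, H, K, R, Y with their charge
#'   sign).
#' @export
pka_bjellqvist <- function() {
  structure(list(
    nterm = c(default = 7.5, A = 7.59, M = 7.00, S = 6.93, P = 8.36,
              T = 6.82, V = 7.44, E = 7.70, G = 7.50),
    cterm = c(default = 3.55, D = 4.55, E = 4.75),
    sidechain = list(
      acidic = c(C = 9.00, D = 4.05, E = 4.45, Y = 10.00),
      basic  = c(H = 5.98, K = 10.00, R = 12.00)
    )
  ), class = "pka_set")
}

seq_letters <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.01528 Da). Sequences
#' containing `X` are rejected rather than imputed: an unknown residue would
#' silently corrupt extreme-value reports.
#'
#' @param seq Amino-acid sequence (string over the 20 standard residues).
#' @return Mass in Daltons.
#' @examples
#' compute_mw("G")  # 75.07 Da
#' @export
compute_mw <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) {
    abort("cannot compute molecular weight of an empty sequence",
          class = "cwmyb_input_error")
  }
  l <- seq_letters(seq)
  if (any(l == "X")) {
    abort("sequence contains X (unknown residue); molecular weight undefined",
          class = "cwmyb_input_error")
  }
  bad <- which(!l %in% names(AA_AVG_MASS))
  if (length(bad) > 0L) {
    abort(paste0("non-standard residue '", l[bad[1L]], "' at position ",
                 bad[1L]), class = "cwmyb_input_error")
  }
  sum(AA_AVG_MASS[l]) + WATER_MASS
}

#' Net charge of a protein at a given pH
#'
#' Henderson–Hasselbalch sum over the ionizable groups: the N-terminal
#' amine, the C-terminal carboxyl, and the side chains of C, D, E, H, K, R
#' and Y. Basic groups contribute `+1/(1 + 10^(pH - pKa))`, acidic groups
#' `-1/(1 + 10^(pKa - pH))`.
#'
#' @param seq Amino-acid sequence (X permitted; it carries no charge).
#' @param pH pH at which to evaluate the charge.
#' @param pka A pKa set, default [pka_bjellqvist()].
#' @return Net charge in elementary charge units.
#' @export
net_charge <- function(seq, pH, pka = pka_bjellqvist()) {
  stopifnot(inherits(pka, "pka_set"), nchar(seq) >= 1L)
  l <- seq_letters(seq)
  basic_part <- function(pk) 1 / (1 + 10^(pH - pk))
  acidic_part <- function(pk) 1 / (1 + 10^(pk - pH))
  nt <- if (l[1L] %in% names(pka$nterm)) pka$nterm[[l[1L]]] else
    pka$nterm[["default"]]
  last <- l[length(l)]
  ct <- if (last %in% names(pka$cterm)) pka$cterm[[last]] else
    pka$cterm[["default"]]
  charge <- basic_part(nt) - acidic_part(ct)
  for (res in names(pka$sidechain$basic)) {
    k <- sum(l == res)
    if (k > 0L) charge <- charge + k * basic_part(pka$sidechain$basic[[res]])
  }
  for (res in names(pka$sidechain$acidic)) {
    k <- sum(l == res)
    if (k > 0L) charge <- charge - k * acidic_part(pka$sidechain$acidic[[res]])
  }
  unname(charge)
}

#' Theoretical isoelectric point
#'
#' Bisection on [net_charge()] over pH 0..14. The net charge is strictly
#' decreasing in pH for any peptide (every group's contribution is), so the
#' zero crossing is unique.
#'
#' @inheritParams net_charge
#' @param tol Convergence tolerance on the absolute net charge
#'   (default 1e-4).
#' @return pI in pH units.
#' @examples
#' compute_pi("GG")  # (7.5 + 3.55) / 2 = 5.525
#' @export
compute_pi <- function(seq, pka = pka_bjellqvist(), tol = 1e-4) {
  lo <- 0
  hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid, pka)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Physicochemical property report for a record set
#'
#' Computes length, average molecular weight (Da and kDa) and theoretical
#' pI for every record. Reported kDa and pI are rounded to two decimals,
#' matching the precision conventionally printed in family surveys; the
#' unrounded Mw in Daltons is retained.
#'
#' @param records A tibble of protein records (`id`, `sequence`).
#' @param pka pKa set for the pI computation.
#' @return A tibble `seq_id`, `length`, `mw_da`, `mw_kda`, `pi`.
#' @export
protein_props <- function(records, pka = pka_bjellqvist()) {
  records <- validate_records(records)
  purrr::map2_dfr(records$id, records$sequence, function(id, seq) {
    mw <- compute_mw(seq)
    tibble(seq_id = id,
           length = nchar(seq),
           mw_da = mw,
           mw_kda = round(mw / 1000, 2),
           pi = round(compute_pi(seq, pka), 2))
  })
}
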