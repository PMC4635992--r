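#' Deduced protein length from ORF length
#'
#' Uses the convention that the ORF nucleotide length excludes the stop
#' codon, so the deduced polypeptide has `orf_len / 3` residues
#' (2814 nt -> 938 aa). An ORF length not divisible by 3 is internally
#' inconsistent; by default this errors, but `partial = "warn"` returns
#' `floor(orf_len / 3)` with a warning, which is useful when screening
#' published tables that contain typos.
#'
#' @param orf_len ORF length(s) in nucleotides.
#' @param partial `"error"` (default) or `"warn"` for lengths not
#'   divisible by 3.
#' @return Integer vector of amino-acid counts.
#' @export
#' @examples
#' deduced_length(2814) # 938
#' deduced_length(933)  # 311
deduced_length <- function(orf_len, partial = c("error", "warn")) {
  partial <- match.arg(partial)
  if (any(!is.finite(orf_len)) || any(orf_len <= 0)) {
    stop_arffam("orf_len must be positive")
  }
  rem <- orf_len %% 3
  if (any(rem != 0)) {
    msg <- paste0(
      "ORF length(s) not divisible by 3: ",
      paste0(orf_len[rem != 0], " (remainder ", rem[rem != 0], ")",
             collapse = ", ")
    )
    if (partial == "error") {
      stop_arffam(msg, class = "arffam_orf_divisibility",
                  remainder = rem[rem != 0])
    }
    warn(msg, class = "arffam_orf_divisibility_warning")
  }
  as.integer(orf_len %/% 3)
}

#' Average residue masses (Da)
#'
#' Average (isotope-abundance weighted) masses of the 20 standard
#' amino-acid residues, i.e. the free amino-acid mass minus one water.
#' One water (18.0153 Da) is added back per chain by
#' [molecular_weight()].
#'
#' @return Named numeric vector of residue masses.
#' @export
aa_residue_masses <- function() {
  c(
    A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
  )
}

WATER_MASS <- 18.0153

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water (18.0153 Da), the usual
#' average-mass convention for intact chains.
#'
#' @param aa_seq Character vector of amino-acid sequences (standard
#'   20-letter alphabet).
#' @return Numeric vector of masses in daltons.
#' @export
#' @examples
#' molecular_weight("G") # 75.0672
molecular_weight <- function(aa_seq) {
  masses <- aa_residue_masses()
  vapply(aa_seq, function(s) {
    if (!nzchar(s)) stop_arffam("empty sequence")
    res <- strsplit(s, "")[[1]]
    bad <- which(!res %in% names(masses))
    if (length(bad) > 0L) {
      stop_arffam(paste0(
        "non-standard residue '", res[bad[1]], "' at position ", bad[1]
      ))
    }
    sum(masses[res]) + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

#' pKa sets for isoelectric-point calculation
#'
#' Side-chain and termini pKa values. `"expasy"` follows the
#' Bjellqvist values used by the ExPASy Compute pI tool; `"emboss"`
#' follows the EMBOSS iep defaults. The set is swappable because
#' published pI values depend on the tool that produced them.
#'
#' @param set `"expasy"` or `"emboss"`.
#' @return Named numeric vector with entries `Nterm`, `Cterm`, `C`,
#'   `D`, `E`, `H`, `K`, `R`, `Y`.
#' @export
arf_pka <- function(set = c("expasy", "emboss")) {
  set <- match.arg(set)
  switch(set,
    expasy = c(
      Nterm = 9.094, Cterm = 3.55, C = 9.0, D = 4.05, E = 4.45,
      H = 5.98, K = 10.0, R = 12.0, Y = 10.0
    ),
    emboss = c(
      Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
      H = 6.5, K = 10.8, R = 12.5, Y = 10.1
    )
  )
}

# Henderson-Hasselbalch net charge at a given pH (vectorized over pH)
protein_net_charge <- function(aa_seq, pH, pka = arf_pka()) {
  res <- strsplit(aa_seq, "")[[1]]
  counts <- table(factor(res, levels = AA_ALPHABET))
  pos <- c(Nterm = 1, H = unname(counts[["H"]]),
           K = unname(counts[["K"]]), R = unname(counts[["R"]]))
  neg <- c(Cterm = 1, D = unname(counts[["D"]]), E = unname(counts[["E"]]),
           C = unname(counts[["C"]]), Y = unname(counts[["Y"]]))
  charge <- rep(0, length(pH))
  for (g in names(pos)) {
    charge <- charge + pos[[g]] / (1 + 10^(pH - pka[[g]]))
  }
  for (g in names(neg)) {
    charge <- charge - neg[[g]] / (1 + 10^(pka[[g]] - pH))
  }
  charge
}

#' Protein isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge (free termini plus
#' D, E, C, Y, H, K, R side chains) is zero, found by bisection. The
#' charge function is strictly decreasing in pH, so the root is unique.
#'
#' @inheritParams molecular_weight
#' @param pka pKa set, see [arf_pka()].
#' @param tol Bisection tolerance in pH units.
#' @return Numeric vector of pI values.
#' @export
isoelectric_point <- function(aa_seq, pka = arf_pka(), tol = 1e-4) {
  vapply(aa_seq, function(s) {
    if (!nzchar(s)) stop_arffam("empty sequence")
    res <- strsplit(s, "")[[1]]
    if (any(!res %in% AA_ALPHABET)) {
      stop_arffam("non-standard residue in sequence")
    }
    lo <- 0; hi <- 14
    f_lo <- protein_net_charge(s, lo, pka)
    f_hi <- protein_net_charge(s, hi, pka)
    if (f_lo < 0 || f_hi > 0) {
      stop_arffam("bisection bracket failure (internal error)")
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (protein_net_charge(s, mid, pka) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1), USE.NAMES = FALSE)
}

#' Characterize a set of proteins
#'
#' Convenience wrapper computing deduced length, molecular weight (kDa)
#' and isoelectric point for a protein table.
#'
#' @param proteins Tibble with columns `id`, `seq` (amino acids), and
#'   optionally `orf_len`.
#' @param pka pKa set for [isoelectric_point()].
#' @return Tibble `id`, `length_aa`, `mol_wt_kda`, `pi`, plus
#'   `orf_len` and `orf_consistent` when ORF lengths are supplied
#'   (`orf_len == 3 * length_aa`; violations are flagged, not fatal).
#' @export
characterize_proteins <- function(proteins, pka = arf_pka()) {
  out <- tibble(
    id = proteins$id,
    length_aa = nchar(proteins$seq),
    mol_wt_kda = molecular_weight(proteins$seq) / 1000,
    pi = isoelectric_point(proteins$seq, pka = pka)
  )
  if ("orf_len" %in% names(proteins)) {
    out$orf_len <- proteins$orf_len
    out$orf_consistent <- proteins$orf_len == 3L * out$length_aa
    if (any(!out$orf_consistent, na.rm = TRUE)) {
      warn(paste0(
        "ORF length inconsistent with 3 x protein length for: ",
        paste(out$id[!out$orf_consistent], collapse = ", ")
      ))
    }
  }
  out
}
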