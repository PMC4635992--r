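#' Published characteristics of the papaya ARF family
#'
#' The curated summary of the 11 *Carica papaya* ARF genes as reported
#' in the genome survey of the family: locus id, supercontig location,
#' orientation, ORF length (nt), intron count, deduced polypeptide
#' length (aa), molecular weight (kDa) and isoelectric point. Note the
#' CpARF2 row is internally inconsistent (1855 nt is not divisible by
#' 3 yet 619 aa is printed); [deduced_length()] flags it.
#'
#' @return A tibble with one row per CpARF gene.
#' @export
papaya_arf_family <- function() {
  path <- system.file("extdata", "papaya_arf_family.tsv",
                      package = "arffam", mustWork = TRUE)
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Published activator/repressor assignments of the papaya ARFs
#'
#' The reported functional classification of the 11 CpARFs: four
#' activators with QSL-rich middle regions (CpARF5/7/10/16), three
#' repressors with a CTD (CpARF1/4/11), three CTD-less repressors
#' (CpARF2/3/17), and one DBD-only protein (CpARF6).
#'
#' @return A tibble with columns `protein_id`, `category`, usable as a
#'   [classify_arf()] override or directly in [family_summary()].
#' @export
papaya_arf_classes <- function() {
  tibble(
    protein_id = c(
      "CpARF5", "CpARF7", "CpARF10", "CpARF16",
      "CpARF1", "CpARF4", "CpARF11",
      "CpARF2", "CpARF3", "CpARF17",
      "CpARF6"
    ),
    category = c(
      rep("activator", 4),
      rep("repressor_with_CTD", 3),
      rep("repressor_no_CTD", 3),
      "dbd_only"
    )
  )
}
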