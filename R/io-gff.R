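#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon features (via [rtracklayer::import()]) into one
#' gene model per mRNA. Coordinates stay 1-based inclusive as in GFF3;
#' exons are stored in ascending genomic order regardless of strand.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with one row per mRNA: `gene_id` (the mRNA ID),
#'   `contig`, `strand` (`"+"` or `"-"`), `exons` (list column of tibbles
#'   with `start`, `end`), and `n_exons`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) {
    stop_arffam(paste0("GFF3 file not found: ", path))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  mrna <- gr[typ %in% c("mRNA", "transcript")]
  if (length(mrna) == 0L) {
    stop_arffam("GFF3 contains no mRNA/transcript features")
  }
  ex <- gr[typ == "exon"]
  if (length(ex) == 0L) {
    # fall back to CDS features when no exons are annotated
    ex <- gr[typ == "CDS"]
  }
  if (length(ex) == 0L) {
    stop_arffam("GFF3 contains no exon or CDS features")
  }
  bad_strand <- !as.character(BiocGenerics::strand(mrna)) %in% c("+", "-")
  if (any(bad_strand)) {
    stop_arffam(paste0(
      "unknown strand for mRNA(s): ",
      paste(mrna$ID[bad_strand], collapse = ", ")
    ))
  }
  parent <- vapply(
    as.list(ex$Parent),
    function(p) if (length(p) >= 1L) p[[1]] else NA_character_,
    character(1)
  )
  models <- purrr::map(seq_along(mrna), function(i) {
    id <- mrna$ID[i]
    sel <- parent == id
    exons <- tibble(
      start = BiocGenerics::start(ex)[sel],
      end = BiocGenerics::end(ex)[sel]
    ) |> arrange(.data$start)
    if (nrow(exons) == 0L) {
      stop_arffam(paste0("mRNA ", id, " has no exon/CDS children"))
    }
    span <- c(BiocGenerics::start(mrna)[i], BiocGenerics::end(mrna)[i])
    if (any(exons$start < span[1] | exons$end > span[2])) {
      stop_arffam(paste0("exon outside mRNA span for ", id))
    }
    if (any(exons$end < exons$start)) {
      stop_arffam(paste0("exon with end < start for ", id))
    }
    if (nrow(exons) > 1L &&
        any(exons$start[-1] <= exons$end[-nrow(exons)])) {
      stop_arffam(paste0("overlapping exons for ", id))
    }
    n_ex <- nrow(exons)
    tibble(
      gene_id = id,
      contig = as.character(GenomeInfoDb::seqnames(mrna))[i],
      strand = as.character(BiocGenerics::strand(mrna))[i],
      exons = list(exons),
      n_exons = n_ex
    )
  })
  bind_rows(models)
}
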