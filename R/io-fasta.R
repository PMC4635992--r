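#' Read sequences from a FASTA file
#'
#' Thin tidy wrapper around [Biostrings::readBStringSet()]. Sequences are
#' upper-cased and returned one row per record, in file order.
#'
#' @param path Path to a FASTA file.
#' @param moltype Either `"dna"` or `"protein"`; controls alphabet
#'   validation. IUPAC ambiguity codes are accepted for DNA.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header), `seq` and `moltype`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "AC", "GT"), f)
#' read_fasta(f, "dna")
read_fasta <- function(path, moltype = c("dna", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) {
    stop_arffam(paste0("FASTA file not found: ", path))
  }
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    stop_arffam(paste0("empty FASTA file: ", path))
  }
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop_arffam(paste0(
      "duplicate sequence id(s) in ", path, ": ",
      paste(unique(dup), collapse = ", ")
    ))
  }
  seqs <- toupper(as.character(ss))
  if (any(!nzchar(seqs))) {
    stop_arffam("FASTA contains empty sequence(s)")
  }
  validate_alphabet(seqs, ids, moltype)
  tibble(id = unname(ids), seq = unname(seqs), moltype = moltype)
}

validate_alphabet <- function(seqs, ids, moltype) {
  allowed <- if (moltype == "dna") {
    c("A", "C", "G", "T", "U", names(IUPAC_CODES), "N", "-")
  } else {
    c(AA_ALPHABET, "X", "*", "-")
  }
  ok <- !grepl(paste0("[^", paste(unique(allowed), collapse = ""), "]"), seqs)
  if (any(!ok)) {
    stop_arffam(paste0(
      "sequence(s) inconsistent with moltype '", moltype, "': ",
      paste(ids[!ok], collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param x A tibble with columns `id` and `seq` (as returned by
#'   [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  ss <- Biostrings::BStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
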