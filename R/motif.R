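# IUPAC nucleotide ambiguity codes (beyond ACGT)
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Expand an IUPAC-degenerate pattern to concrete sequences
#'
#' Cartesian expansion of each ambiguity code (V = A/C/G, Y = C/T,
#' S = C/G, ...). `TGTVYS` expands to 3 x 2 x 2 = 12 hexamers.
#'
#' @param pattern IUPAC nucleotide string.
#' @return Character vector of concrete sequences.
#' @export
compile_iupac <- function(pattern) {
  if (!nzchar(pattern)) stop_arffam("empty pattern")
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad) > 0L) {
    stop_arffam(paste0("invalid IUPAC character(s): ",
                       paste(unique(bad), collapse = ", ")))
  }
  sets <- IUPAC_CODES[chars]
  apply(do.call(expand.grid,
                c(rev(sets), stringsAsFactors = FALSE)),
        1, function(r) paste(rev(r), collapse = "")) |> unname()
}

iupac_to_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad) > 0L) {
    stop_arffam(paste0("invalid IUPAC character(s): ",
                       paste(unique(bad), collapse = ", ")))
  }
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_CODES[[ch]]
    if (length(opts) == 1L) opts else
      paste0("[", paste(opts, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' @param seq Nucleotide string (IUPAC codes allowed).
#' @return The reverse complement.
#' @export
revcomp_iupac <- function(seq) {
  chars <- rev(strsplit(toupper(seq), "")[[1]])
  bad <- setdiff(chars, names(IUPAC_COMPLEMENT))
  if (length(bad) > 0L) {
    stop_arffam(paste0("invalid IUPAC character(s): ",
                       paste(unique(bad), collapse = ", ")))
  }
  paste(IUPAC_COMPLEMENT[chars], collapse = "")
}

#' Canonical AuxRE motif presets
#'
#' The auxin response element as defined in two common forms:
#' `"methods"` — AUX1 = `TGTCTC` (the canonical AuxRE core) and the
#' less stringent AUX2 = `TGTVYS`; `"figure7"` — the variant spellings
#' AUX1 = `TGTGTC` and AUX2 = `TGTNYS` (with the non-IUPAC `X`
#' read as `N`) that circulate in figure legends.
#'
#' @param preset `"methods"` (default) or `"figure7"`.
#' @return Tibble with columns `motif_id`, `pattern`.
#' @export
aux_motifs <- function(preset = c("methods", "figure7")) {
  preset <- match.arg(preset)
  switch(preset,
    methods = tibble(motif_id = c("AUX1", "AUX2"),
                     pattern = c("TGTCTC", "TGTVYS")),
    figure7 = tibble(motif_id = c("AUX1", "AUX2"),
                     pattern = c("TGTGTC", "TGTNYS"))
  )
}

#' Scan promoters for degenerate motifs
#'
#' Reports every position x motif match on the forward strand and (in
#' `"both"` mode) matches of each pattern's reverse complement, with
#' forward coordinates and strand `"-"`. Overlapping hits are all
#' reported. Offsets are 0-based on the promoter string, so for a
#' 1500-bp upstream region offset 0 is position -1500 relative to the
#' start codon.
#'
#' @param promoters Tibble with columns `id` (or `gene_id`) and `seq`.
#' @param motifs Tibble `motif_id`, `pattern` (IUPAC), e.g.
#'   [aux_motifs()].
#' @param strands `"both"` (default) or `"forward_only"`.
#' @return Tibble `gene_id`, `motif_id`, `start` (0-based), `strand`,
#'   `matched` (the motif as read on the hit strand), sorted by
#'   `gene_id`, `start`, `motif_id`.
#' @export
scan_promoter <- function(promoters, motifs = aux_motifs(),
                          strands = c("both", "forward_only")) {
  strands <- match.arg(strands)
  idcol <- if ("gene_id" %in% names(promoters)) "gene_id" else "id"
  hits <- purrr::map(seq_len(nrow(promoters)), function(i) {
    seq <- toupper(promoters$seq[i])
    gene <- promoters[[idcol]][i]
    per_motif <- purrr::map(seq_len(nrow(motifs)), function(k) {
      pat <- motifs$pattern[k]
      fwd <- regex_hits(seq, iupac_to_regex(pat))
      out <- list()
      if (length(fwd) > 0L) {
        out$f <- tibble(
          gene_id = gene, motif_id = motifs$motif_id[k],
          start = fwd - 1L, strand = "+",
          matched = substring(seq, fwd, fwd + nchar(pat) - 1L)
        )
      }
      if (strands == "both") {
        rc <- revcomp_iupac(pat)
        rev_ <- regex_hits(seq, iupac_to_regex(rc))
        if (length(rev_) > 0L) {
          out$r <- tibble(
            gene_id = gene, motif_id = motifs$motif_id[k],
            start = rev_ - 1L, strand = "-",
            matched = vapply(
              substring(seq, rev_, rev_ + nchar(pat) - 1L),
              revcomp_iupac, character(1), USE.NAMES = FALSE
            )
          )
        }
      }
      bind_rows(out)
    })
    bind_rows(per_motif)
  }) |> bind_rows()
  if (nrow(hits) == 0L) {
    return(tibble(gene_id = character(0), motif_id = character(0),
                  start = integer(0), strand = character(0),
                  matched = character(0)))
  }
  arrange(hits, .data$gene_id, .data$start, .data$motif_id, .data$strand)
}

# all (overlapping) 1-based match starts of a regex
regex_hits <- function(seq, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Per-gene AuxRE summary
#'
#' @param hits Output of [scan_promoter()].
#' @param gene_set Character vector of all genes scanned (genes without
#'   hits are included as zero rows).
#' @return Tibble with one row per gene: a count column `n_<motif_id>`
#'   per motif and `has_any`; the number of genes with at least one hit
#'   is stored in attribute `n_with_hits`.
#' @export
promoter_summary <- function(hits, gene_set) {
  extra <- setdiff(hits$gene_id, gene_set)
  if (length(extra) > 0L) {
    stop_arffam(paste0("hits contain gene(s) outside gene_set: ",
                       paste(extra, collapse = ", ")))
  }
  motif_ids <- sort(unique(hits$motif_id))
  if (length(motif_ids) == 0L) motif_ids <- c("AUX1", "AUX2")
  counts <- hits |>
    group_by(.data$gene_id, .data$motif_id) |>
    summarise(n = n(), .groups = "drop")
  out <- tibble(gene_id = gene_set)
  for (mid in motif_ids) {
    cc <- counts[counts$motif_id == mid, ]
    out[[paste0("n_", mid)]] <-
      ifelse(out$gene_id %in% cc$gene_id,
             cc$n[match(out$gene_id, cc$gene_id)], 0L)
  }
  ncols <- grep("^n_", names(out), value = TRUE)
  out$has_any <- rowSums(as.matrix(out[, ncols, drop = FALSE])) > 0
  attr(out, "n_with_hits") <- sum(out$has_any)
  out
}
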