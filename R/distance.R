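#' Pairwise distances from a protein alignment
#'
#' p-distance is the fraction of mismatched residues over
#' pairwise-complete columns (both sequences non-gap, i.e. pairwise
#' deletion); the Poisson correction `-ln(1 - p)` accounts for multiple
#' hits. `gap = "complete"` restricts all pairs to columns without any
#' gap.
#'
#' @param aln Alignment tibble (`id`, `seq`; equal-length gapped
#'   protein sequences, gap character `-`).
#' @param model `"poisson"` (default) or `"p_distance"`.
#' @param gap `"pairwise"` (default) or `"complete"` deletion.
#' @return A symmetric numeric matrix with zero diagonal, labelled by
#'   sequence id.
#' @export
pairwise_distance <- function(aln, model = c("poisson", "p_distance"),
                              gap = c("pairwise", "complete")) {
  model <- match.arg(model)
  gap <- match.arg(gap)
  m <- alignment_matrix(aln)
  if (gap == "complete") {
    keep <- colSums(m == 0L) == 0L
    if (!any(keep)) stop_arffam("no gap-free columns for complete deletion")
    m <- m[, keep, drop = FALSE]
  }
  dist_from_codes(m, model)
}

# alignment tibble -> integer matrix (0 = gap, 1..k = residue code)
alignment_matrix <- function(aln) {
  stopifnot(all(c("id", "seq") %in% names(aln)))
  if (nrow(aln) < 2L) stop_arffam("alignment needs >= 2 sequences")
  lens <- nchar(aln$seq)
  if (length(unique(lens)) != 1L) {
    stop_arffam("alignment sequences have unequal lengths")
  }
  if (anyDuplicated(aln$id)) stop_arffam("duplicate ids in alignment")
  chars <- do.call(rbind, strsplit(toupper(aln$seq), ""))
  lv <- setdiff(sort(unique(as.vector(chars))), c("-", ".", "X"))
  m <- matrix(match(chars, lv, nomatch = 0L), nrow = nrow(chars))
  rownames(m) <- aln$id
  attr(m, "levels") <- lv
  m
}

# distances via indicator cross-products (fast enough for bootstrap loops)
dist_from_codes <- function(m, model) {
  n <- nrow(m)
  valid <- (m != 0L) * 1
  shared <- tcrossprod(valid)       # pairwise-complete column counts
  k <- max(m)
  matches <- matrix(0, n, n)
  for (r in seq_len(k)) {
    xr <- (m == r) * 1
    matches <- matches + tcrossprod(xr)
  }
  if (any(shared[upper.tri(shared)] < 2)) {
    stop_arffam("sequence pair with < 2 shared (ungapped) columns")
  }
  p <- (shared - matches) / shared
  diag(p) <- 0
  d <- if (model == "poisson") {
    if (any(p[upper.tri(p)] >= 1)) {
      stop_arffam(paste0(
        "p-distance of 1 cannot be Poisson-corrected; ",
        "use model = 'p_distance'"
      ))
    }
    -log(1 - p)
  } else {
    p
  }
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}
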