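# Independent oracles and small fixture builders used across tests.

# additive distance matrix from a phylo tree (path sums)
additive_matrix <- function(tree) {
  ape::cophenetic.phylo(tree)
}

# least-squares residual of a distance matrix on a fixed topology
# (fit branch lengths by ordinary least squares over path-edge incidence)
ls_residual <- function(tree, d) {
  tips <- tree$tip.label
  n <- length(tips)
  pairs <- t(utils::combn(n, 2))
  ne <- nrow(tree$edge)
  A <- matrix(0, nrow(pairs), ne)
  for (e in seq_len(ne)) {
    under <- phangorn::Descendants(tree, tree$edge[e, 2], "tips")[[1]]
    ina <- seq_len(n) %in% under
    A[xor(ina[pairs[, 1]], ina[pairs[, 2]]), e] <- 1
  }
  y <- d[cbind(tips[pairs[, 1]], tips[pairs[, 2]])]
  sum(stats::lm.fit(A, y)$residuals^2)
}

# brute-force degenerate-motif scan: slide every expanded word
brute_force_scan <- function(seq, motifs, strands = "both") {
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- list()
  for (k in seq_len(nrow(motifs))) {
    pat <- motifs$pattern[k]
    w <- nchar(pat)
    if (w > n) next
    windows <- substring(seq, 1:(n - w + 1), w:n)
    fwd_set <- compile_iupac(pat)
    idx <- which(windows %in% fwd_set)
    if (length(idx) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        motif_id = motifs$motif_id[k], start = idx - 1L, strand = "+",
        matched = windows[idx]
      )
    }
    if (strands == "both") {
      rev_set <- compile_iupac(revcomp_iupac(pat))
      idx <- which(windows %in% rev_set)
      if (length(idx) > 0) {
        out[[length(out) + 1]] <- tibble::tibble(
          motif_id = motifs$motif_id[k], start = idx - 1L, strand = "-",
          matched = vapply(windows[idx], revcomp_iupac, "",
                           USE.NAMES = FALSE)
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(motif_id = character(0), start = integer(0),
                          strand = character(0), matched = character(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), start, motif_id, strand)
}

# independent net-charge formula + grid-scan pI oracle
grid_pi_oracle <- function(aa_seq, pka = arf_pka(), step = 1e-5) {
  res <- strsplit(aa_seq, "")[[1]]
  nD <- sum(res == "D"); nE <- sum(res == "E"); nC <- sum(res == "C")
  nY <- sum(res == "Y"); nH <- sum(res == "H"); nK <- sum(res == "K")
  nR <- sum(res == "R")
  ph <- seq(0, 14, by = step)
  pos_frac <- function(pk) 1 / (1 + 10^(ph - pk))
  neg_frac <- function(pk) -1 / (1 + 10^(pk - ph))
  q <- pos_frac(pka[["Nterm"]]) + nH * pos_frac(pka[["H"]]) +
    nK * pos_frac(pka[["K"]]) + nR * pos_frac(pka[["R"]]) +
    neg_frac(pka[["Cterm"]]) + nD * neg_frac(pka[["D"]]) +
    nE * neg_frac(pka[["E"]]) + nC * neg_frac(pka[["C"]]) +
    nY * neg_frac(pka[["Y"]])
  ph[which.min(abs(q))]
}

random_peptide <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
        collapse = "")
}

# toy four-sequence protein alignment with known mismatch structure
toy_alignment <- function() {
  tibble::tibble(
    id = c("a", "b", "c", "d"),
    seq = c("AAAAAAAAAA",
            "AAAAAAAAAC",   # 1 mismatch vs a in 10 columns
            "CCCCCAAAAA",
            "CCCCCAAAAC"),
    moltype = "protein"
  )
}

# write a tiny fixture file and return its path
write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
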