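#' Evolve a protein alignment along a tree
#'
#' Uniform-replacement (Jukes-Cantor-style) amino-acid substitution:
#' along a branch of length `b` (substitutions/site) each site receives
#' a Poisson(`b`) number of events, each replacing the residue with one
#' of the other 19 uniformly. No indels, so the leaf sequences are an
#' alignment by construction. For small path lengths the expected
#' pairwise p-distance approaches the path length.
#'
#' @param tree A `phylo` tree with branch lengths in
#'   substitutions/site.
#' @param root_seq Amino-acid string at the root.
#' @param seed Integer seed; the generator is a pure function of
#'   `(tree, root_seq, seed)`.
#' @return Alignment tibble (`id`, `seq`, `moltype = "protein"`), tips
#'   in `tree$tip.label` order.
#' @export
evolve_alignment <- function(tree, root_seq, seed = 1L) {
  if (!nzchar(root_seq)) stop_arffam("zero-length root sequence")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tree <- ape::reorder.phylo(tree, "cladewise")
  root <- ntip + 1L
  seqs <- vector("list", ntip + nnode)
  seqs[[root]] <- strsplit(root_seq, "")[[1]]
  withr::with_seed(seed, {
    for (e in seq_len(nrow(tree$edge))) {
      a <- tree$edge[e, 1]
      b <- tree$edge[e, 2]
      seqs[[b]] <- mutate_seq(seqs[[a]], tree$edge.length[e])
    }
  })
  tibble(
    id = tree$tip.label,
    seq = vapply(seqs[seq_len(ntip)], paste, "", collapse = ""),
    moltype = "protein"
  )
}

mutate_seq <- function(res, len) {
  if (len < 0) stop_arffam("negative branch length in true tree")
  k <- rpois(length(res), len)
  hit <- which(k > 0)
  for (i in hit) {
    for (j in seq_len(k[i])) {
      res[i] <- sample(setdiff(AA_ALPHABET, res[i]), 1L)
    }
  }
  res
}

#' Plant motifs in an otherwise motif-free promoter
#'
#' Background bases are uniform over ACGT, rejection-resampled so that
#' no match of any target motif (either strand) exists outside the
#' planted windows; the planted hits are exactly as requested. The hit
#' manifest records every motif each planted window realizes (a
#' concrete AUX1 core also satisfies a degenerate AUX2 pattern).
#'
#' @param seq_len Promoter length in bp.
#' @param motifs Motif tibble (`motif_id`, `pattern`), e.g.
#'   [aux_motifs()].
#' @param positions Tibble `motif_id`, `start` (0-based) of planted
#'   instances; must be non-overlapping and in bounds. `NULL` plants
#'   nothing.
#' @param seed Integer seed.
#' @param max_attempts Rejection-resampling bound.
#' @return List with `seq` (the promoter string) and `hits` (manifest
#'   tibble `motif_id`, `start`, `strand`, `matched`).
#' @export
plant_motifs <- function(seq_len, motifs = aux_motifs(),
                         positions = NULL, seed = 1L,
                         max_attempts = 500L) {
  if (is.null(positions)) {
    positions <- tibble(motif_id = character(0), start = integer(0))
  }
  if (nrow(positions) > 0L) {
    widths <- nchar(motifs$pattern[match(positions$motif_id,
                                         motifs$motif_id)])
    if (any(is.na(widths))) stop_arffam("planted motif_id not in motifs")
    if (any(positions$start < 0L) ||
        any(positions$start + widths > seq_len)) {
      stop_arffam("planted position out of bounds")
    }
    o <- order(positions$start)
    ps <- positions$start[o]; pw <- widths[o]
    if (any(ps[-1] < (ps + pw)[-length(ps)])) {
      stop_arffam("planted positions overlap")
    }
  }
  withr::with_seed(seed, {
    plant_motifs_impl(seq_len, motifs, positions, max_attempts)
  })
}

plant_motifs_impl <- function(seq_len, motifs, positions, max_attempts) {
  bases <- c("A", "C", "G", "T")
  seq <- sample(bases, seq_len, replace = TRUE)
  planted_mask <- rep(FALSE, seq_len)
  manifest <- list()
  # plant concrete realizations
  if (nrow(positions) > 0L) {
    for (i in seq_len(nrow(positions))) {
      pat <- motifs$pattern[motifs$motif_id == positions$motif_id[i]][1]
      concrete <- sample(compile_iupac(pat), 1L)
      s0 <- positions$start[i]                    # 0-based
      idx <- (s0 + 1L):(s0 + nchar(pat))
      seq[idx] <- strsplit(concrete, "")[[1]]
      planted_mask[idx] <- TRUE
    }
  }
  # expected manifest: every motif each planted window satisfies
  if (nrow(positions) > 0L) {
    for (i in seq_len(nrow(positions))) {
      s0 <- positions$start[i]
      for (k in seq_len(nrow(motifs))) {
        w <- nchar(motifs$pattern[k])
        word <- paste(seq[(s0 + 1L):(s0 + w)], collapse = "")
        if (word %in% compile_iupac(motifs$pattern[k])) {
          manifest[[length(manifest) + 1L]] <- tibble(
            motif_id = motifs$motif_id[k], start = s0,
            strand = "+", matched = word
          )
        }
        rc <- revcomp_iupac(motifs$pattern[k])
        if (word %in% compile_iupac(rc)) {
          manifest[[length(manifest) + 1L]] <- tibble(
            motif_id = motifs$motif_id[k], start = s0,
            strand = "-", matched = revcomp_iupac(word)
          )
        }
      }
    }
  }
  manifest <- if (length(manifest) > 0L) {
    bind_rows(manifest) |> arrange(.data$start, .data$motif_id)
  } else {
    tibble(motif_id = character(0), start = integer(0),
           strand = character(0), matched = character(0))
  }
  wanted <- paste(manifest$motif_id, manifest$start, manifest$strand)
  for (attempt in seq_len(max_attempts)) {
    s <- paste(seq, collapse = "")
    found <- scan_promoter(tibble(id = "x", seq = s), motifs, "both")
    stray <- found[!paste(found$motif_id, found$start, found$strand)
                   %in% wanted, ]
    if (nrow(stray) == 0L) {
      return(list(seq = s, hits = manifest))
    }
    # redraw background bases inside stray windows
    redrawn <- FALSE
    for (r in seq_len(nrow(stray))) {
      w <- nchar(motifs$pattern[motifs$motif_id == stray$motif_id[r]][1])
      idx <- (stray$start[r] + 1L):(stray$start[r] + w)
      bg <- idx[!planted_mask[idx]]
      if (length(bg) > 0L) {
        seq[bg] <- sample(bases, length(bg), replace = TRUE)
        redrawn <- TRUE
      }
    }
    if (!redrawn) break
  }
  stop_arffam(paste0(
    "could not build a motif-free background after ", max_attempts,
    " attempts; use a longer sequence or fewer planted motifs"
  ))
}

#' Simulate a long-format qRT-PCR Ct table with planted expression
#'
#' Reference-gene Ct values are drawn around a baseline; each target
#' replicate gets `Ct = baseline - log2(level) + N(0, noise_sd)` where
#' `level` is the planted expression relative to the reference. With
#' `noise_sd = 0` every derived fold change is exact.
#'
#' @param levels Tibble `gene`, `condition`, `level` (planted relative
#'   expression, > 0).
#' @param reference_gene Reference gene name added to every condition.
#' @param baseline_ct Reference-gene Ct baseline (cycles).
#' @param noise_sd Gaussian replicate noise in cycles (>= 0).
#' @param n_reps Replicates per gene x condition (>= 2).
#' @param seed Integer seed.
#' @return A [ct_table()].
#' @export
simulate_ct <- function(levels, reference_gene = "ACTIN",
                        baseline_ct = 22, noise_sd = 0.2,
                        n_reps = 5L, seed = 1L) {
  if (any(levels$level <= 0)) stop_arffam("planted levels must be > 0")
  if (noise_sd < 0) stop_arffam("noise_sd must be >= 0")
  if (n_reps < 2L) stop_arffam("n_reps must be >= 2")
  conds <- unique(levels$condition)
  withr::with_seed(seed, {
    ref <- tidyr::expand_grid(condition = conds,
                              replicate = seq_len(n_reps)) |>
      mutate(gene = reference_gene,
             ct = baseline_ct + stats::rnorm(dplyr::n(), 0, noise_sd))
    tgt <- levels |>
      tidyr::expand_grid(replicate = seq_len(n_reps)) |>
      mutate(ct = baseline_ct - log2(.data$level) +
               stats::rnorm(dplyr::n(), 0, noise_sd))
  })
  df <- bind_rows(
    ref[, c("gene", "condition", "replicate", "ct")],
    tgt[, c("gene", "condition", "replicate", "ct")]
  )
  ct_table(df, reference_gene)
}
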