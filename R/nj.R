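#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimizing
#' the Q-criterion `Q_ij = (n-2) d_ij - r_i - r_j` is joined, with
#' branch lengths `v_i = d_ij/2 + (r_i - r_j) / (2(n-2))`. Q ties are
#' broken deterministically on the lexicographically smallest pair of
#' cluster labels (the smallest leaf label inside each cluster).
#' Negative branch-length estimates are clamped to zero with a message.
#'
#' @param dm Symmetric distance matrix with row/column names (>= 3
#'   taxa), e.g. from [pairwise_distance()].
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(dm) {
  d <- as.matrix(dm)
  labs <- rownames(d)
  if (is.null(labs) || is.null(colnames(d))) {
    stop_arffam("distance matrix must be labelled")
  }
  n <- nrow(d)
  if (n < 3L) stop_arffam("neighbor joining needs >= 3 taxa")
  if (max(abs(d - t(d))) > 1e-12) {
    stop_arffam("distance matrix is not symmetric (tolerance 1e-12)")
  }
  frag <- labs          # newick fragment per active cluster
  key <- labs           # smallest leaf label per cluster (tie-break key)
  n_clamped <- 0L

  clamp <- function(x) {
    if (x < 0) {
      n_clamped <<- n_clamped + 1L
      0
    } else {
      x
    }
  }

  while (n > 3L) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    tol <- 1e-9 * max(1, abs(qmin))
    cand <- which(q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: lexicographic on sorted cluster keys
    pair_keys <- apply(cand, 1, function(ij) {
      paste(sort(c(key[ij[1]], key[ij[2]])), collapse = "\r")
    })
    best <- cand[order(pair_keys)[1], ]
    i <- best[[1]]; j <- best[[2]]

    vi <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    vj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], vi, frag[j], vj)
    new_key <- min(key[i], key[j])

    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
    n <- n - 1L
  }

  va <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  vb <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  vc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  newick <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                    frag[1], va, frag[2], vb, frag[3], vc)
  if (n_clamped > 0L) {
    inform(paste0("neighbor_joining: clamped ", n_clamped,
                  " negative branch length(s) to 0"))
  }
  ape::read.tree(text = newick)
}
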