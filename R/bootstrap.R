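#' Bootstrap support for a neighbor-joining tree
#'
#' Standard Felsenstein procedure: alignment columns are resampled with
#' replacement `n_reps` times, a NJ tree is built per replicate, and
#' the support of each internal bipartition of the original-alignment
#' tree is the percentage of replicate trees containing it. Replicates
#' whose distance matrix is degenerate (e.g. Poisson correction
#' impossible) are skipped with a message, never fatal.
#'
#' @param aln Alignment tibble (`id`, `seq`).
#' @param model Distance model, see [pairwise_distance()].
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed; same seed, same supports.
#' @param gap Gap treatment, see [pairwise_distance()].
#' @return The NJ tree of the full alignment, with `node.label` holding
#'   per-node support in `[0, 100]` (`NA` on the root) and attributes
#'   `n_reps` (replicates used) and `n_skipped`. Class
#'   `c("arf_boot_tree", "phylo")`.
#' @export
bootstrap_support <- function(aln, model = "poisson", n_reps = 100L,
                              seed = 1L, gap = "pairwise") {
  if (n_reps < 1L) stop_arffam("n_reps must be >= 1")
  m <- alignment_matrix(aln)
  if (nrow(m) < 4L) {
    stop_arffam("bootstrap support needs >= 4 taxa")
  }
  base_tree <- neighbor_joining(dist_from_codes(sub_cols(m, gap), model))
  ncol_aln <- ncol(m)
  rep_trees <- list()
  n_skipped <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(n_reps)) {
      idx <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
      mb <- m[, idx, drop = FALSE]
      tb <- tryCatch(
        suppressMessages(
          neighbor_joining(dist_from_codes(sub_cols(mb, gap), model))
        ),
        error = function(e) NULL
      )
      if (is.null(tb)) {
        n_skipped <- n_skipped + 1L
      } else {
        rep_trees[[length(rep_trees) + 1L]] <- tb
      }
    }
  })
  if (n_skipped > 0L) {
    inform(paste0("bootstrap_support: skipped ", n_skipped,
                  " degenerate replicate(s)"))
  }
  n_used <- length(rep_trees)
  if (n_used == 0L) stop_arffam("all bootstrap replicates degenerate")
  class(rep_trees) <- "multiPhylo"
  counts <- suppressMessages(
    ape::prop.clades(base_tree, rep_trees, rooted = FALSE)
  )
  support <- 100 * counts / n_used
  # the basal node of the stored (arbitrarily rooted) representation is
  # not a real bipartition
  support[1] <- NA_real_
  base_tree$node.label <- round(support, 6)
  attr(base_tree, "n_reps") <- n_used
  attr(base_tree, "n_skipped") <- n_skipped
  class(base_tree) <- c("arf_boot_tree", "phylo")
  base_tree
}

sub_cols <- function(m, gap) {
  if (gap == "complete") {
    keep <- colSums(m == 0L) == 0L
    if (!any(keep)) stop_arffam("no gap-free columns")
    m <- m[, keep, drop = FALSE]
  }
  m
}

#' @export
print.arf_boot_tree <- function(x, ...) {
  cat("Neighbor-joining tree with bootstrap support\n")
  cat("  replicates used:", attr(x, "n_reps"),
      " skipped:", attr(x, "n_skipped"), "\n")
  y <- x
  class(y) <- "phylo"
  print(y, ...)
  invisible(x)
}

#' @describeIn bootstrap_support Tidy per-bipartition supports:
#'   one row per internal node with columns `node`, `support`, and
#'   `n_tips` (tips in the clade as stored).
#' @param x An `arf_boot_tree`.
#' @param ... Unused.
#' @export
tidy.arf_boot_tree <- function(x, ...) {
  ntip <- length(x$tip.label)
  nnode <- x$Nnode
  nodes <- ntip + seq_len(nnode)
  y <- x
  class(y) <- "phylo"
  sizes <- vapply(nodes, function(nd) {
    length(tips_under(y, nd))
  }, integer(1))
  tibble(
    node = nodes,
    support = as.numeric(x$node.label),
    n_tips = sizes
  )
}

#' @describeIn bootstrap_support One-row summary: taxon count,
#'   replicates used/skipped, median support.
#' @export
glance.arf_boot_tree <- function(x, ...) {
  tibble(
    n_taxa = length(x$tip.label),
    n_reps = attr(x, "n_reps"),
    n_skipped = attr(x, "n_skipped"),
    median_support = stats::median(as.numeric(x$node.label), na.rm = TRUE)
  )
}

# tip indices under an internal node (iterative, edge-table based)
tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack) > 0L) {
    nd <- stack[[1]]
    stack <- stack[-1]
    ch <- kids[[as.character(nd)]]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  sort(out)
}
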