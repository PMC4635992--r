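#' Cross-species sister pairs (cherries) with bootstrap support
#'
#' A sister pair is a cherry — two leaves joined to the same internal
#' node with no third leaf — whose members belong to two different
#' species and whose bootstrap support meets the threshold.
#'
#' @param tree A `phylo` tree with `node.label` bootstrap supports
#'   (e.g. from [bootstrap_support()]).
#' @param species_map Tibble with columns `leaf`, `species` covering
#'   every tip.
#' @param min_support Minimum support percentage (default 99).
#' @return Tibble `leaf_a`, `leaf_b`, `species_a`, `species_b`,
#'   `support`, sorted by decreasing support.
#' @export
find_sister_pairs <- function(tree, species_map, min_support = 99) {
  if (is.null(tree$node.label)) {
    stop_arffam("tree has no support values (node.label)")
  }
  missing <- setdiff(tree$tip.label, species_map$leaf)
  if (length(missing) > 0L) {
    stop_arffam(paste0("leaf/leaves missing from species_map: ",
                       paste(missing, collapse = ", ")))
  }
  sp <- setNames(species_map$species, species_map$leaf)
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  support <- suppressWarnings(as.numeric(tree$node.label))
  rows <- list()
  for (node in as.integer(names(kids))) {
    ch <- kids[[as.character(node)]]
    if (length(ch) == 2L && all(ch <= ntip)) {
      pair <- sort(tree$tip.label[ch])
      a <- pair[1]
      b <- pair[2]
      s <- support[node - ntip]
      if (!is.na(s) && s >= min_support && sp[[a]] != sp[[b]]) {
        rows[[length(rows) + 1L]] <- tibble(
          leaf_a = a, leaf_b = b,
          species_a = sp[[a]], species_b = sp[[b]],
          support = s
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(
      leaf_a = character(0), leaf_b = character(0),
      species_a = character(0), species_b = character(0),
      support = numeric(0)
    ))
  }
  bind_rows(rows) |> arrange(dplyr::desc(.data$support), .data$leaf_a)
}

#' Propagate reference group labels across a tree
#'
#' Each unlabelled leaf inherits the group of the smallest enclosing
#' clade (walking rootward from its parent, in the stored rooted
#' representation) that contains at least one reference leaf and whose
#' reference leaves all carry one group. Leaves whose every enclosing
#' clade mixes groups are labelled `"unplaced"`.
#'
#' @param tree A `phylo` tree.
#' @param reference_groups Tibble with columns `leaf`, `group` for the
#'   reference leaves.
#' @return Tibble `leaf`, `group` for every tip (reference leaves keep
#'   their given group).
#' @export
assign_groups <- function(tree, reference_groups) {
  ref <- setNames(reference_groups$group, reference_groups$leaf)
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]

  group_of_node <- function(node) {
    tips <- tips_under_any(tree, node, ntip)
    g <- unique(ref[intersect(tree$tip.label[tips], names(ref))])
    if (length(g) == 1L) g else if (length(g) == 0L) NA_character_ else "mixed"
  }

  purrr::map(seq_len(ntip), function(i) {
    lf <- tree$tip.label[i]
    if (lf %in% names(ref)) {
      return(tibble(leaf = lf, group = ref[[lf]]))
    }
    node <- parent[i]
    repeat {
      g <- group_of_node(node)
      if (!is.na(g) && g != "mixed") {
        return(tibble(leaf = lf, group = g))
      }
      if (!is.na(g) && g == "mixed") {
        return(tibble(leaf = lf, group = "unplaced"))
      }
      if (node == root) return(tibble(leaf = lf, group = "unplaced"))
      node <- parent[node]
    }
  }) |> bind_rows()
}

tips_under_any <- function(tree, node, ntip) {
  if (node <= ntip) return(node)
  tips_under(tree, node)
}
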