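#' Select ARF candidates from domain annotations
#'
#' A protein is retained as an ARF candidate when it carries at least one
#' B3 DNA-binding domain (`DBD`) and at least one auxin-response domain
#' (`AUX_RESP`). Proteins with only an `AUX_IAA` domain are Aux/IAA
#' family members, not ARFs, and are excluded. DBD-only proteins are
#' excluded by default but can be admitted through `allow_list`
#' (truncated ARFs lacking the AUX_RESP annotation do occur).
#'
#' @param annotations Domain annotations as from [read_domain_table()]:
#'   columns `protein_id`, `domain_id`, `start`, `end`.
#' @param allow_list Character vector of protein ids retained even when
#'   they fail the architecture rule (as long as they have a DBD).
#' @return A tibble with one row per protein: `protein_id`, `status`
#'   (`"retained"`/`"excluded"`), `exclusion_reason` (empty string when
#'   retained), and domain counts `n_dbd`, `n_aux_resp`, `n_aux_iaa`.
#' @export
filter_arf_candidates <- function(annotations, allow_list = character()) {
  if (is.null(annotations) || nrow(annotations) == 0L) {
    stop_arffam("empty domain-annotation set")
  }
  bad <- setdiff(unique(annotations$domain_id), ARF_DOMAINS)
  if (length(bad) > 0L) {
    stop_arffam(paste0("unknown domain id(s): ", paste(bad, collapse = ", ")))
  }
  counts <- annotations |>
    group_by(.data$protein_id) |>
    summarise(
      n_dbd = sum(.data$domain_id == "DBD"),
      n_aux_resp = sum(.data$domain_id == "AUX_RESP"),
      n_aux_iaa = sum(.data$domain_id == "AUX_IAA"),
      .groups = "drop"
    )
  counts |>
    mutate(
      allow = .data$protein_id %in% allow_list,
      status = dplyr::case_when(
        n_dbd >= 1L & (n_aux_resp >= 1L | allow) ~ "retained",
        TRUE ~ "excluded"
      ),
      exclusion_reason = dplyr::case_when(
        status == "retained" ~ "",
        n_dbd == 0L & n_aux_iaa >= 1L ~ "Aux/IAA architecture (no DBD)",
        n_dbd == 0L ~ "no DBD domain",
        TRUE ~ "DBD only (no AUX_RESP; not on allow-list)"
      )
    ) |>
    select("protein_id", "status", "exclusion_reason",
           "n_dbd", "n_aux_resp", "n_aux_iaa") |>
    arrange(.data$protein_id)
}

#' Collapse exact-duplicate candidate sequences
#'
#' Retained candidates whose protein sequences are byte-identical are
#' collapsed to a single representative (the lexicographically smallest
#' id); the others are marked excluded. Idempotent.
#'
#' @param candidates Output of [filter_arf_candidates()].
#' @param sequences Protein sequences as from [read_fasta()] (columns
#'   `id`, `seq`).
#' @return `candidates` with duplicates marked
#'   `status = "excluded"`, `exclusion_reason = "duplicate of <id>"`.
#' @export
dedupe_candidates <- function(candidates, sequences) {
  retained <- candidates$protein_id[candidates$status == "retained"]
  missing <- setdiff(retained, sequences$id)
  if (length(missing) > 0L) {
    stop_arffam(paste0(
      "candidate(s) lacking a sequence: ", paste(missing, collapse = ", ")
    ))
  }
  seqs <- setNames(sequences$seq, sequences$id)[retained]
  if (length(seqs) == 0L) return(candidates)
  rep_of <- tapply(names(seqs), unname(seqs), function(ids) min(ids))
  keeper <- unname(rep_of[seqs])
  dup <- retained[keeper != retained]
  if (length(dup) > 0L) {
    inform(paste0(
      "dedupe_candidates: collapsed ", length(dup),
      " duplicate sequence(s): ", paste(dup, collapse = ", ")
    ))
  }
  candidates |>
    mutate(
      is_dup = .data$protein_id %in% dup,
      exclusion_reason = ifelse(
        .data$is_dup,
        paste0("duplicate of ",
               keeper[match(.data$protein_id, retained)]),
        .data$exclusion_reason
      ),
      status = ifelse(.data$is_dup, "excluded", .data$status)
    ) |>
    select(-"is_dup")
}

#' Name family members after their nearest reference homolog
#'
#' Each focal-species leaf inherits the numeric suffix of its nearest
#' reference leaf: its cherry partner when the two form a sister pair,
#' otherwise the reference leaf at minimum patristic distance. Distance
#' ties go to the lowest-numbered reference name; name collisions get a
#' letter suffix (`b`, `c`, ...) in order of assignment and a warning.
#'
#' @param tree An unrooted `phylo` tree containing focal and reference
#'   leaves.
#' @param species_map Tibble with columns `leaf`, `species`.
#' @param reference_names Tibble with columns `leaf`, `name` giving the
#'   published names of reference leaves (e.g. `AtARF5`).
#' @param focal_species Species label of the leaves to be named.
#' @param prefix Prefix for assigned names; the numeric suffix of the
#'   nearest reference name is appended.
#' @return Tibble `protein_id`, `assigned_name`, `nearest_reference`,
#'   `evidence` (`"tree_cherry"` or `"min_distance"`).
#' @export
assign_names <- function(tree, species_map, reference_names,
                         focal_species, prefix = "ARF") {
  ref_leaves <- intersect(reference_names$leaf, tree$tip.label)
  if (length(ref_leaves) == 0L) {
    stop_arffam("tree contains no reference leaves")
  }
  focal <- species_map$leaf[species_map$species == focal_species]
  focal <- intersect(focal, tree$tip.label)
  if (length(focal) == 0L) {
    stop_arffam("tree contains no focal-species leaves")
  }
  pat <- ape::cophenetic.phylo(tree)
  cherries <- tree_cherries(tree)
  ref_name <- setNames(reference_names$name, reference_names$leaf)
  ref_num <- suppressWarnings(as.integer(gsub("\\D", "", ref_name)))
  names(ref_num) <- reference_names$leaf

  res <- purrr::map(sort(focal), function(lf) {
    partner <- cherry_partner(cherries, lf)
    if (!is.na(partner) && partner %in% ref_leaves) {
      tibble(protein_id = lf, nearest_reference = ref_name[[partner]],
             suffix = ref_num[[partner]], evidence = "tree_cherry")
    } else {
      d <- pat[lf, ref_leaves]
      nearest <- ref_leaves[d <= min(d) + 1e-12]
      # tie-break: lowest-numbered reference name
      nearest <- nearest[order(ref_num[nearest], ref_name[nearest])][1]
      tibble(protein_id = lf, nearest_reference = ref_name[[nearest]],
             suffix = ref_num[[nearest]], evidence = "min_distance")
    }
  }) |> bind_rows()

  # resolve collisions in assignment order
  base <- paste0(prefix, res$suffix)
  assigned <- character(length(base))
  for (i in seq_along(base)) {
    nm <- base[i]
    k <- 1L
    while (nm %in% assigned[seq_len(i - 1L)]) {
      k <- k + 1L
      nm <- paste0(base[i], letters[k])
    }
    assigned[i] <- nm
  }
  if (any(assigned != base)) {
    warn(paste0(
      "assign_names: name collision(s) resolved with letter suffixes: ",
      paste(assigned[assigned != base], collapse = ", ")
    ))
  }
  res |>
    mutate(assigned_name = assigned) |>
    select("protein_id", "assigned_name", "nearest_reference", "evidence")
}

# cherries as a two-column matrix of tip labels
tree_cherries <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- list()
  for (node in names(kids)) {
    ch <- kids[[node]]
    tips <- ch[ch <= ntip]
    if (length(ch) == 2L && length(tips) == 2L) {
      out[[node]] <- tree$tip.label[tips]
    }
  }
  if (length(out) == 0L) {
    matrix(character(0), ncol = 2)
  } else {
    do.call(rbind, unname(out))
  }
}

cherry_partner <- function(cherries, leaf) {
  if (nrow(cherries) == 0L) return(NA_character_)
  i <- which(cherries[, 1] == leaf | cherries[, 2] == leaf)
  if (length(i) == 0L) return(NA_character_)
  pair <- cherries[i[1], ]
  pair[pair != leaf][1]
}
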