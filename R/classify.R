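#' Extract the middle region (MR) of ARF proteins
#'
#' The MR lies strictly between the end of the B3 DNA-binding domain
#' (DBD) and the start of the C-terminal dimerization domain (the
#' AUX_IAA annotation), or runs to the sequence end when no CTD is
#' present. Its amino-acid composition predicts activator vs repressor
#' function.
#'
#' @param proteins Tibble with columns `id`, `seq`.
#' @param domains Domain annotations (`protein_id`, `domain_id`,
#'   `start`, `end`).
#' @return Tibble with one row per protein that has a DBD: `protein_id`,
#'   `mr_start`, `mr_end` (1-based, `NA` when the MR is empty),
#'   `mr_seq`, `has_ctd`, and `freq` (list column: named per-residue
#'   fraction vector over the 20-letter alphabet, summing to 1).
#' @export
extract_mr <- function(proteins, domains) {
  ids <- intersect(proteins$id,
                   domains$protein_id[domains$domain_id == "DBD"])
  if (length(ids) == 0L) {
    stop_arffam("no protein with a DBD annotation")
  }
  purrr::map(ids, function(pid) {
    seq <- proteins$seq[proteins$id == pid][1]
    len <- nchar(seq)
    dd <- domains[domains$protein_id == pid, ]
    dbd_end <- max(dd$end[dd$domain_id == "DBD"])
    ctd_start <- if (any(dd$domain_id == "AUX_IAA")) {
      min(dd$start[dd$domain_id == "AUX_IAA"])
    } else {
      len + 1L
    }
    mr_start <- dbd_end + 1L
    mr_end <- ctd_start - 1L
    if (mr_end < mr_start) {
      # DBD abuts the CTD or the sequence end: absent-MR marker
      return(tibble(
        protein_id = pid, mr_start = NA_integer_, mr_end = NA_integer_,
        mr_seq = NA_character_, has_ctd = ctd_start <= len,
        freq = list(NULL)
      ))
    }
    mr <- substr(seq, mr_start, mr_end)
    tibble(
      protein_id = pid, mr_start = mr_start, mr_end = mr_end,
      mr_seq = mr, has_ctd = ctd_start <= len,
      freq = list(aa_frequencies(mr))
    )
  }) |> bind_rows()
}

#' Per-residue amino-acid fractions
#'
#' @param seq An amino-acid string.
#' @return Named numeric vector over the 20-letter alphabet, summing
#'   to 1.
#' @export
aa_frequencies <- function(seq) {
  res <- strsplit(seq, "")[[1]]
  counts <- table(factor(res, levels = AA_ALPHABET))
  setNames(as.numeric(counts) / length(res), AA_ALPHABET)
}

#' Classify ARFs as activators or repressors
#'
#' Classification follows the middle-region composition rule:
#' glutamine-rich (QSL-rich) MRs mark transcriptional activators, while
#' serine/proline/glycine-rich (SPGL-rich or G-rich) MRs mark
#' repressors. Since serine and leucine appear in both descriptions,
#' the operative monotone separator is `freq(Q) > freq(P) + freq(G)`.
#' Repressors are split by CTD presence; a protein with neither MR nor
#' CTD is `dbd_only`. An override table reproduces published calls
#' irrespective of the rule.
#'
#' @param mr Output of [extract_mr()].
#' @param override Optional tibble `protein_id`, `category` that
#'   bypasses the rule (`source` becomes `"override"`).
#' @return Tibble `protein_id`, `category` (one of `activator`,
#'   `repressor_with_CTD`, `repressor_no_CTD`, `dbd_only`),
#'   `rule_score` (`freq(Q) - freq(P) - freq(G)`; `NA` without MR) and
#'   `source` (`"rule"` or `"override"`).
#' @export
classify_arf <- function(mr, override = NULL) {
  valid <- c("activator", "repressor_with_CTD", "repressor_no_CTD",
             "dbd_only")
  if (!is.null(override)) {
    bad <- setdiff(override$category, valid)
    if (length(bad) > 0L) {
      stop_arffam(paste0("unknown override category: ",
                         paste(bad, collapse = ", ")))
    }
  }
  out <- purrr::pmap(
    list(mr$protein_id, mr$freq, mr$has_ctd),
    function(pid, fr, has_ctd) {
      if (is.null(fr)) {
        cat_ <- if (has_ctd) "repressor_with_CTD" else "dbd_only"
        return(tibble(protein_id = pid, category = cat_,
                      rule_score = NA_real_, source = "rule"))
      }
      score <- fr[["Q"]] - fr[["P"]] - fr[["G"]]
      cat_ <- if (score > 0) {
        "activator"
      } else if (has_ctd) {
        "repressor_with_CTD"
      } else {
        "repressor_no_CTD"
      }
      tibble(protein_id = pid, category = cat_, rule_score = score,
             source = "rule")
    }
  ) |> bind_rows()
  if (!is.null(override)) {
    hit <- match(out$protein_id, override$protein_id)
    out$category[!is.na(hit)] <- override$category[hit[!is.na(hit)]]
    out$source[!is.na(hit)] <- "override"
  }
  out
}

#' Summarise an ARF family classification
#'
#' Counts categories and derives the activator/repressor ratio and the
#' percentage of CTD-truncated members. `dbd_only` proteins count as
#' repressors by default (they lack the activation-competent MR);
#' CTD-truncated members are those with `repressor_no_CTD` or
#' `dbd_only` calls.
#'
#' @param classifications Output of [classify_arf()].
#' @param dbd_only_policy `"count_as_repressor"` (default) or
#'   `"exclude"` for the ratio denominator.
#' @return One-row tibble: `n_activators`, `n_repressors`,
#'   `n_ctd_truncated`, `n_total`, `activator_repressor_ratio` (`NA`
#'   when there are no repressors) and `ctd_truncated_pct`.
#' @export
family_summary <- function(classifications,
                           dbd_only_policy = c("count_as_repressor",
                                               "exclude")) {
  dbd_only_policy <- match.arg(dbd_only_policy)
  if (nrow(classifications) == 0L) {
    stop_arffam("no classifications supplied")
  }
  n_act <- sum(classifications$category == "activator")
  n_rep_ctd <- sum(classifications$category == "repressor_with_CTD")
  n_rep_noctd <- sum(classifications$category == "repressor_no_CTD")
  n_dbd <- sum(classifications$category == "dbd_only")
  n_total <- nrow(classifications)
  n_rep <- n_rep_ctd + n_rep_noctd +
    if (dbd_only_policy == "count_as_repressor") n_dbd else 0L
  ratio <- if (n_rep > 0L) n_act / n_rep else NA_real_
  n_trunc <- n_rep_noctd + n_dbd
  tibble(
    n_activators = n_act,
    n_repressors = n_rep,
    n_ctd_truncated = n_trunc,
    n_total = n_total,
    activator_repressor_ratio = ratio,
    ctd_truncated_pct = 100 * n_trunc / n_total
  )
}
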