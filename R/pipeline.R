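#' Run the full ARF-family characterization workflow
#'
#' Ties the stages together in dependency order — candidate
#' identification, protein characterization and classification, gene
#' structure, phylogeny with bootstrap and sister pairs, promoter motif
#' scanning, and expression profiling — on an in-memory bundle (e.g.
#' from [simulate_arf_family()]) or an equivalent list of file paths.
#' Any subset of stages can be requested; each stage checks its inputs
#' before any work is done.
#'
#' @param inputs An `arf_bundle`, or a named list with (depending on
#'   stages) `proteins`, `domains`, `gene_models`, `alignment`,
#'   `species_map`, `promoters`, `ct_*` components (tibbles), plus
#'   optionally `allow_list` and `override`.
#' @param config An [arf_config()].
#' @param stages Character vector among `"identify"`,
#'   `"characterize"`, `"structure"`, `"phylo"`, `"motifs"`,
#'   `"expression"` (default: all).
#' @return A list of class `arf_report` with one element per executed
#'   stage plus `config`, `seed` and `version`.
#' @export
run_arf_pipeline <- function(inputs, config = arf_config(),
                             stages = c("identify", "characterize",
                                        "structure", "phylo",
                                        "motifs", "expression")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!inherits(config, "arf_config")) {
    stop_arffam("config must be an arf_config")
  }
  needs <- list(
    identify = c("proteins", "domains"),
    characterize = c("proteins", "domains"),
    structure = "gene_models",
    phylo = c("alignment", "species_map"),
    motifs = "promoters",
    expression = character(0)
  )
  for (st in stages) {
    missing <- setdiff(needs[[st]], names(inputs))
    if (length(missing) > 0L) {
      stop_arffam(paste0("stage '", st, "' needs input(s): ",
                         paste(missing, collapse = ", ")))
    }
  }
  if ("expression" %in% stages &&
      !any(grepl("^ct", names(inputs)))) {
    stop_arffam("stage 'expression' needs at least one ct_* input")
  }

  report <- list()
  if ("identify" %in% stages) {
    allow <- inputs$allow_list %||%
      inputs$manifest$allow_list %||% character()
    cand <- filter_arf_candidates(inputs$domains, allow_list = allow)
    cand <- dedupe_candidates(cand, inputs$proteins)
    report$candidates <- cand
  }
  if ("characterize" %in% stages) {
    retained <- inputs$proteins
    if (!is.null(report$candidates)) {
      keep <- report$candidates$protein_id[
        report$candidates$status == "retained"
      ]
      retained <- retained[retained$id %in% keep, ]
    }
    chars <- characterize_proteins(retained)
    mr <- extract_mr(retained, inputs$domains)
    cls <- classify_arf(mr, override = inputs$override %||% NULL)
    report$characteristics <- chars
    report$classifications <- cls
    report$family_summary <- family_summary(cls)
  }
  if ("structure" %in% stages) {
    report$structure <- family_structure_table(inputs$gene_models)
  }
  if ("phylo" %in% stages) {
    tree <- bootstrap_support(
      inputs$alignment,
      n_reps = config$bootstrap_reps,
      seed = config$rng_seed
    )
    report$tree <- tree
    report$sister_pairs <- find_sister_pairs(
      tree, inputs$species_map,
      min_support = config$sister_pair_min_support
    )
  }
  if ("motifs" %in% stages) {
    hits <- scan_promoter(inputs$promoters, aux_motifs("methods"),
                          strands = "both")
    idcol <- if ("gene_id" %in% names(inputs$promoters)) "gene_id"
             else "id"
    report$motif_hits <- hits
    report$promoter_summary <- promoter_summary(
      hits, inputs$promoters[[idcol]]
    )
  }
  if ("expression" %in% stages) {
    for (nm in grep("^ct", names(inputs), value = TRUE)) {
      expr <- relative_expression(inputs[[nm]],
                                  scale = config$reference_scale)
      hm <- heatmap_matrix(expr)
      report[[paste0("expression_", sub("^ct_?", "", nm))]] <-
        list(expression = expr, heatmap = hm)
    }
  }
  report$config <- config
  report$seed <- config$rng_seed
  report$version <- as.character(utils::packageVersion("arffam"))
  class(report) <- "arf_report"
  report
}

#' @export
print.arf_report <- function(x, ...) {
  cat("<arf_report> arffam", x$version, "seed", x$seed, "\n")
  cat("  stages:", paste(setdiff(names(x),
                                 c("config", "seed", "version")),
                         collapse = ", "), "\n")
  if (!is.null(x$family_summary)) {
    fs <- x$family_summary
    cat("  family:", fs$n_activators, "activators /",
        fs$n_repressors, "repressors (ratio",
        round(fs$activator_repressor_ratio, 2), "),",
        round(fs$ctd_truncated_pct, 1), "% CTD-truncated\n")
  }
  if (!is.null(x$sister_pairs)) {
    cat("  sister pairs:", nrow(x$sister_pairs), "\n")
  }
  if (!is.null(x$promoter_summary)) {
    cat("  promoters with AuxRE:",
        attr(x$promoter_summary, "n_with_hits"), "/",
        nrow(x$promoter_summary), "\n")
  }
  invisible(x)
}
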