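#' Simulate a complete ARF-family data bundle with a ground-truth
#' manifest
#'
#' Generates every input the pipeline consumes — focal protein and CDS
#' sequences with planted domain architectures and middle-region
#' composition classes, gene models with planted intron counts, a true
#' phylogeny with planted cross-species cherries and an alignment
#' evolved on it, promoters with planted AuxREs, and Ct tables with
#' planted expression — together with a manifest that fully determines
#' every expected pipeline output. The defaults emulate a small
#' dicot ARF family: 11 focal genes (4 activators, 3 repressors with a
#' CTD, 3 CTD-less repressors, 1 DBD-only), 23 + 25 reference proteins
#' from two outgroup species, 7 planted focal/At cherries, 27 promoters
#' of which 16 carry at least one AuxRE, and five-replicate Ct tables.
#'
#' @param n_focal Number of focal-species genes.
#' @param n_reference Named integer vector of reference-species leaf
#'   counts (names become species labels).
#' @param params Optional list overriding defaults: `mr_len`,
#'   `dbd_len`, `ctd_len`, `margin` (MR composition margin, < 1),
#'   `aln_len`, `n_promoters`, `n_with_motifs`, `promoter_length`,
#'   `noise_sd`, `n_reps`, `intron_counts`.
#' @param seed Integer seed; the bundle is a pure function of
#'   `(arguments, seed)`.
#' @param dir Optional directory; when given, the bundle is also
#'   written as FASTA/GFF3/TSV files.
#' @return A list of class `arf_bundle`: `proteins`, `cds`,
#'   `gene_models`, `domains`, `alignment`, `species_map`,
#'   `promoters`, `ct_stage`, `ct_tissue`, `ct_sex`, and `manifest`.
#' @export
simulate_arf_family <- function(n_focal = 11L,
                                n_reference = c(At = 23L, Os = 25L),
                                params = list(), seed = 1L,
                                dir = NULL) {
  if (n_focal + sum(n_reference) < 3L) {
    stop_arffam("need at least 3 taxa in total")
  }
  p <- utils::modifyList(list(
    mr_len = 150L, dbd_len = 100L, ctd_len = 80L, margin = 0.05,
    aln_len = 300L, n_promoters = 27L, n_with_motifs = 16L,
    promoter_length = 1500L, noise_sd = 0.2, n_reps = 5L,
    intron_counts = NULL
  ), params)
  if (p$margin >= 1 || p$margin <= 0) {
    stop_arffam("infeasible MR margin (need 0 < margin < 1)")
  }
  if (p$n_with_motifs > p$n_promoters) {
    stop_arffam("n_with_motifs cannot exceed n_promoters")
  }

  focal_ids <- sprintf("Cp%02d", seq_len(n_focal))
  categories <- default_categories(n_focal)
  introns <- p$intron_counts %||% default_introns(n_focal)
  if (length(introns) != n_focal) {
    stop_arffam("intron_counts must have one entry per focal gene")
  }

  withr::with_seed(seed, {
    arch <- build_architectures(focal_ids, categories, p)
    gm <- build_gene_models(arch$proteins, introns)
    phylo_part <- build_true_phylogeny(focal_ids, n_reference, p)
    proms <- build_promoters(p)
    expr_part <- build_expression(focal_ids, categories, p)
  })

  manifest <- list(
    seed = seed,
    params = p,
    categories = tibble(protein_id = focal_ids, category = categories),
    allow_list = focal_ids[categories == "dbd_only"],
    introns = tibble(gene_id = focal_ids, n_introns = introns),
    tree = phylo_part$tree,
    cherries = phylo_part$cherries,
    species = phylo_part$species_map,
    motif_hits = proms$manifest,
    n_with_motifs = p$n_with_motifs,
    expression = expr_part$levels
  )
  bundle <- structure(list(
    proteins = arch$proteins,
    cds = arch$cds,
    domains = arch$domains,
    gene_models = gm,
    alignment = phylo_part$alignment,
    species_map = phylo_part$species_map,
    promoters = proms$promoters,
    ct_stage = expr_part$ct_stage,
    ct_tissue = expr_part$ct_tissue,
    ct_sex = expr_part$ct_sex,
    manifest = manifest
  ), class = "arf_bundle")
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

#' @export
print.arf_bundle <- function(x, ...) {
  cat("<arf_bundle>\n")
  cat("  focal proteins :", nrow(x$proteins), "\n")
  cat("  alignment taxa :", nrow(x$alignment), "\n")
  cat("  promoters      :", nrow(x$promoters), "\n")
  cat("  planted cherries:", nrow(x$manifest$cherries), "\n")
  invisible(x)
}

default_categories <- function(n_focal) {
  # 4:3:3:1 split scaled to the family size, at least one dbd_only
  base <- c("activator", "repressor_with_CTD", "repressor_no_CTD",
            "dbd_only")
  counts <- pmax(round(n_focal * c(4, 3, 3, 1) / 11), c(1, 1, 1, 1))
  while (sum(counts) > n_focal) counts[which.max(counts)] <-
    counts[which.max(counts)] - 1L
  while (sum(counts) < n_focal) counts[1] <- counts[1] + 1L
  rep(base, counts)
}

default_introns <- function(n_focal) {
  pool <- c(13L, 11L, 10L, 11L, 13L, 8L, 12L, 4L, 13L, 2L, 1L)
  if (n_focal <= length(pool)) {
    pool[seq_len(n_focal)]
  } else {
    c(pool, sample(1:13, n_focal - length(pool), replace = TRUE))
  }
}

# ---- protein architecture ------------------------------------------------

random_aa <- function(n, freq = NULL) {
  if (is.null(freq)) {
    sample(AA_ALPHABET, n, replace = TRUE)
  } else {
    sample(AA_ALPHABET, n, replace = TRUE, prob = freq[AA_ALPHABET])
  }
}

# MR residue sampler with guaranteed realized composition margin
random_mr <- function(len, class, margin) {
  freq <- setNames(rep(1, 20), AA_ALPHABET)
  if (class == "activator") {
    freq[c("Q", "S", "L")] <- c(4.5, 3, 3)
    freq[c("P", "G")] <- 0.5
  } else {
    freq[c("S", "P", "G", "L")] <- c(3, 2.5, 2.5, 3)
    freq["Q"] <- 0.5
  }
  freq <- freq / sum(freq)
  for (attempt in 1:200) {
    res <- random_aa(len, freq)
    fr <- aa_frequencies(paste(res, collapse = ""))
    score <- fr[["Q"]] - fr[["P"]] - fr[["G"]]
    ok <- if (class == "activator") score >= margin else score <= -margin
    if (ok) return(res)
  }
  stop_arffam("could not realize MR composition margin")
}

build_architectures <- function(focal_ids, categories, p) {
  # conserved blocks shared by the family, mutated per gene
  dbd_block <- random_aa(p$dbd_len)
  ctd_block <- random_aa(p$ctd_len)
  personalize <- function(block, n_sub = max(2L, length(block) %/% 20L)) {
    idx <- sample(seq_along(block), n_sub)
    block[idx] <- random_aa(n_sub)
    block
  }
  rows <- purrr::map(seq_along(focal_ids), function(i) {
    cat_ <- categories[i]
    dbd <- personalize(dbd_block)
    parts <- list(dbd)
    doms <- tibble(protein_id = focal_ids[i], domain_id = "DBD",
                   start = 1L, end = p$dbd_len, source = "synthetic")
    if (cat_ != "dbd_only") {
      mr_class <- if (cat_ == "activator") "activator" else "repressor"
      mr <- random_mr(p$mr_len, mr_class, p$margin)
      parts <- c(parts, list(mr))
      # the auxin-response domain sits inside the N-terminal region
      doms <- bind_rows(doms, tibble(
        protein_id = focal_ids[i], domain_id = "AUX_RESP",
        start = 20L, end = p$dbd_len - 10L, source = "synthetic"
      ))
      if (cat_ %in% c("activator", "repressor_with_CTD")) {
        ctd <- personalize(ctd_block)
        ctd_start <- p$dbd_len + p$mr_len + 1L
        parts <- c(parts, list(ctd))
        doms <- bind_rows(doms, tibble(
          protein_id = focal_ids[i], domain_id = "AUX_IAA",
          start = ctd_start, end = ctd_start + p$ctd_len - 1L,
          source = "synthetic"
        ))
      }
    }
    seq <- paste(unlist(parts), collapse = "")
    list(
      protein = tibble(id = focal_ids[i], seq = seq,
                       moltype = "protein"),
      domains = doms
    )
  })
  proteins <- bind_rows(purrr::map(rows, "protein"))
  domains <- bind_rows(purrr::map(rows, "domains"))
  cds <- tibble(
    id = proteins$id,
    seq = vapply(proteins$seq, reverse_translate, "",
                 USE.NAMES = FALSE),
    moltype = "dna"
  )
  list(proteins = proteins, domains = domains, cds = cds)
}

# one fixed codon per amino acid (deterministic reverse translation)
AA_CODON <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", E = "GAA",
  Q = "CAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT"
)

reverse_translate <- function(aa_seq) {
  paste(AA_CODON[strsplit(aa_seq, "")[[1]]], collapse = "")
}

# ---- gene models ---------------------------------------------------------

build_gene_models <- function(proteins, introns) {
  purrr::map(seq_len(nrow(proteins)), function(i) {
    orf_len <- 3L * nchar(proteins$seq[i])
    n_exons <- introns[i] + 1L
    # random composition of the ORF into exon lengths (each >= 3)
    cuts <- sort(sample(seq_len(orf_len - 1L), n_exons - 1L))
    lens <- diff(c(0L, cuts, orf_len))
    while (any(lens < 3L)) {
      cuts <- sort(sample(seq_len(orf_len - 1L), n_exons - 1L))
      lens <- diff(c(0L, cuts, orf_len))
    }
    intron_len <- 120L
    start0 <- 1000L
    starts <- start0 + cumsum(c(0L, head(lens, -1L) + intron_len))
    exons <- tibble(start = starts, end = starts + lens - 1L)
    tibble(
      gene_id = proteins$id[i],
      contig = sprintf("ctg_%02d", i),
      strand = if (i %% 2L == 0L) "-" else "+",
      exons = list(exons),
      n_exons = n_exons,
      orf_len = orf_len
    )
  }) |> bind_rows()
}

# ---- phylogeny -----------------------------------------------------------

balance_join <- function(units, bl) {
  while (length(units) > 1L) {
    nxt <- character(0)
    k <- 1L
    while (k + 1L <= length(units)) {
      nxt <- c(nxt, sprintf("(%s:%g,%s:%g)",
                            units[k], bl, units[k + 1L], bl))
      k <- k + 2L
    }
    if (k == length(units)) nxt <- c(nxt, units[k])
    units <- nxt
  }
  units
}

build_true_phylogeny <- function(focal_ids, n_reference, p) {
  ref_ids <- purrr::imap(as.list(n_reference), function(n, sp) {
    sprintf("%sARF%d", sp, seq_len(n))
  })
  sp1 <- names(n_reference)[1]
  n_pairs <- min(7L, length(focal_ids), n_reference[[1]])
  # pair the first n_pairs focal genes with distinct first-species refs
  pair_refs <- ref_ids[[1]][seq_len(n_pairs)]
  cherries <- tibble(leaf_a = focal_ids[seq_len(n_pairs)],
                     leaf_b = pair_refs)
  units <- sprintf("(%s:0.02,%s:0.02)", cherries$leaf_a,
                   cherries$leaf_b)
  # remaining focal genes attach next to a cherry unit so they never
  # form a cross-species cherry themselves
  extra_focal <- setdiff(focal_ids, cherries$leaf_a)
  for (i in seq_along(extra_focal)) {
    k <- ((i - 1L) %% length(units)) + 1L
    units[k] <- sprintf("((%s):0.08,%s:0.1)",
                        sub("^\\((.*)\\)$", "\\1", units[k]),
                        extra_focal[i])
  }
  extra_ref1 <- setdiff(ref_ids[[1]], pair_refs)
  frag1 <- balance_join(c(units, extra_ref1), 0.05)
  frags <- c(frag1, purrr::map_chr(ref_ids[-1],
                                   ~ balance_join(.x, 0.05)))
  if (length(frags) == 1L) {
    newick <- paste0(frags, ";")
  } else if (length(frags) == 2L) {
    newick <- sprintf("(%s:0.08,%s:0.08);", frags[1], frags[2])
  } else {
    newick <- sprintf("(%s:0.08,%s:0.08,%s:0.08);",
                      frags[1], frags[2], frags[3])
  }
  tree <- ape::read.tree(text = newick)
  species_map <- tibble(
    leaf = c(focal_ids, unlist(ref_ids)),
    species = c(rep("Cp", length(focal_ids)),
                rep(names(n_reference), lengths(ref_ids)))
  )
  root_seq <- paste(random_aa(p$aln_len), collapse = "")
  alignment <- evolve_alignment(tree, root_seq,
                                seed = sample.int(2^31 - 1L, 1L))
  list(tree = tree, cherries = cherries, species_map = species_map,
       alignment = alignment)
}

# ---- promoters -----------------------------------------------------------

build_promoters <- function(p) {
  gene_ids <- sprintf("prom%02d", seq_len(p$n_promoters))
  motifs <- aux_motifs("methods")
  rows <- list()
  hits <- list()
  for (i in seq_len(p$n_promoters)) {
    if (i <= p$n_with_motifs) {
      n_inst <- sample(1:3, 1L)
      starts <- sample_spaced_positions(
        p$promoter_length - 6L, n_inst, min_gap = 10L
      )
      pos <- tibble(
        motif_id = sample(motifs$motif_id, n_inst, replace = TRUE),
        start = starts
      )
    } else {
      pos <- NULL
    }
    planted <- plant_motifs(p$promoter_length, motifs, pos,
                            seed = sample.int(2^31 - 1L, 1L))
    rows[[i]] <- tibble(gene_id = gene_ids[i], seq = planted$seq)
    if (nrow(planted$hits) > 0L) {
      hits[[length(hits) + 1L]] <-
        mutate(planted$hits, gene_id = gene_ids[i], .before = 1L)
    }
  }
  manifest <- if (length(hits) > 0L) bind_rows(hits) else
    tibble(gene_id = character(0), motif_id = character(0),
           start = integer(0), strand = character(0),
           matched = character(0))
  list(promoters = bind_rows(rows), manifest = manifest)
}

sample_spaced_positions <- function(max_start, n, min_gap) {
  for (attempt in 1:200) {
    s <- sort(sample(0:max_start, n))
    if (n == 1L || all(diff(s) >= min_gap)) return(s)
  }
  stop_arffam("could not place motifs with the requested spacing")
}

# ---- expression ----------------------------------------------------------

build_expression <- function(focal_ids, categories, p) {
  n <- length(focal_ids)
  stages <- sprintf("stage%d", 1:8)
  tissues <- c("leaf", "shoot", "root", "flower", "fruit")
  sexes <- c("male", "female", "hermaphrodite")

  # flower stages: the DBD-only gene ramps 8-fold up; the first five
  # genes decline 8-fold; the rest stay flat
  ramp_gene <- focal_ids[which(categories == "dbd_only")[1]]
  decline <- head(setdiff(focal_ids, ramp_gene), 5L)
  stage_levels <- purrr::map(focal_ids, function(g) {
    lev <- if (identical(g, ramp_gene)) {
      8^((0:7) / 7)
    } else if (g %in% decline) {
      4 * 8^(-(0:7) / 7)
    } else {
      rep(2, 8)
    }
    tibble(gene = g, condition = stages, level = lev)
  }) |> bind_rows()

  # tissues: five fruit-specific genes (share ~0.89), one flower gene
  fruit_specific <- focal_ids[unique(pmin(n, c(2L, 6L, 8L, n - 1L, n)))]
  flower_gene <- setdiff(focal_ids, fruit_specific)[1]
  tissue_levels <- purrr::map(focal_ids, function(g) {
    lev <- if (g %in% fruit_specific) {
      c(0.25, 0.25, 0.25, 0.25, 8)
    } else if (identical(g, flower_gene)) {
      c(1, 1, 1, 5, 1)
    } else {
      c(1, 1, 1, 1, 1)
    }
    tibble(gene = g, condition = tissues, level = lev)
  }) |> bind_rows()

  # sex types: five male-dominant genes, one hermaphrodite-dominant
  male_dominant <- focal_ids[unique(pmin(n, c(3L, 6L, 9L, n - 1L, n)))]
  herm_gene <- setdiff(focal_ids, male_dominant)[2]
  sex_levels <- purrr::map(focal_ids, function(g) {
    lev <- if (g %in% male_dominant) {
      c(8, 1, 1)
    } else if (identical(g, herm_gene)) {
      c(0.2, 1, 6)
    } else {
      c(1, 1.2, 1)
    }
    tibble(gene = g, condition = sexes, level = lev)
  }) |> bind_rows()

  mk_ct <- function(lv) {
    simulate_ct(lv, reference_gene = "ACTIN", baseline_ct = 22,
                noise_sd = p$noise_sd, n_reps = p$n_reps,
                seed = sample.int(2^31 - 1L, 1L))
  }
  list(
    levels = list(stage = stage_levels, tissue = tissue_levels,
                  sex = sex_levels,
                  ramp_gene = ramp_gene, decline = decline,
                  fruit_specific = fruit_specific,
                  male_dominant = male_dominant),
    ct_stage = mk_ct(stage_levels),
    ct_tissue = mk_ct(tissue_levels),
    ct_sex = mk_ct(sex_levels)
  )
}

# ---- serialization -------------------------------------------------------

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$proteins, file.path(dir, "proteins.fasta"))
  write_fasta(bundle$cds, file.path(dir, "cds.fasta"))
  write_fasta(
    bundle$promoters |> rename(id = "gene_id"),
    file.path(dir, "promoters.fasta")
  )
  write_fasta(bundle$alignment, file.path(dir, "alignment.fasta"))
  write_gff3(bundle$gene_models, file.path(dir, "genes.gff3"))
  write_tsv_plain(bundle$domains |>
                    rename(accession = "domain_id") |>
                    mutate(accession = dplyr::recode(
                      .data$accession, DBD = "PF02362",
                      AUX_RESP = "PF06507", AUX_IAA = "PF02309"
                    )),
                  file.path(dir, "domains.tsv"))
  write_tsv_plain(bundle$species_map, file.path(dir, "species_map.tsv"))
  for (nm in c("ct_stage", "ct_tissue", "ct_sex")) {
    write_tsv_plain(as_tibble(bundle[[nm]]),
                    file.path(dir, paste0(nm, ".tsv")))
  }
  ape::write.tree(bundle$manifest$tree, file.path(dir, "true_tree.nwk"))
  write_tsv_plain(bundle$manifest$categories,
                  file.path(dir, "manifest_categories.tsv"))
  write_tsv_plain(bundle$manifest$introns,
                  file.path(dir, "manifest_introns.tsv"))
  write_tsv_plain(bundle$manifest$cherries,
                  file.path(dir, "manifest_cherries.tsv"))
  write_tsv_plain(bundle$manifest$motif_hits,
                  file.path(dir, "manifest_motif_hits.tsv"))
  kv <- c(
    paste0("seed = ", bundle$manifest$seed),
    paste0("n_with_motifs = ", bundle$manifest$n_with_motifs)
  )
  writeLines(kv, file.path(dir, "manifest.cfg"))
  invisible(dir)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write gene models as GFF3
#'
#' @param models Gene-model table (as from [read_gff3()] or
#'   [simulate_arf_family()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    ex <- g$exons[[1]]
    span <- c(min(ex$start), max(ex$end))
    gid <- g$gene_id
    lines <- c(
      lines,
      paste(g$contig, "arffam", "gene", span[1], span[2], ".",
            g$strand, ".", sprintf("ID=gene:%s", gid), sep = "\t"),
      paste(g$contig, "arffam", "mRNA", span[1], span[2], ".",
            g$strand, ".",
            sprintf("ID=%s;Parent=gene:%s", gid, gid), sep = "\t"),
      vapply(seq_len(nrow(ex)), function(k) {
        paste(g$contig, "arffam", "exon", ex$start[k], ex$end[k], ".",
              g$strand, ".",
              sprintf("ID=%s.exon%d;Parent=%s", gid, k, gid),
              sep = "\t")
      }, character(1))
    )
  }
  writeLines(lines, path)
  invisible(path)
}
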