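#' Reference-scaled relative expression from Ct values
#'
#' For each replicate, relative expression is
#' `scale * 2^-(ct_target - ct_reference)`; replicates are paired by
#' replicate index (`paired = FALSE` pairs each target replicate with
#' the mean reference Ct instead). The mean and standard deviation over
#' replicates are reported. With the default `scale = 1000`, a gene
#' expressed exactly like the reference gets value 1000.
#'
#' @param ct A [ct_table()].
#' @param scale Value assigned to reference-level expression.
#' @param paired Pair target and reference Ct by replicate index.
#' @return Tibble `gene`, `condition`, `rel_expr`, `n_reps`, `sd`
#'   (reference gene excluded).
#' @export
relative_expression <- function(ct, scale = 1000, paired = TRUE) {
  ref_gene <- attr(ct, "reference_gene")
  if (is.null(ref_gene)) stop_arffam("ct must be a ct_table")
  ref <- ct[ct$gene == ref_gene, c("condition", "replicate", "ct")]
  targets <- ct[ct$gene != ref_gene, ]
  if (paired) {
    joined <- left_join(
      targets, ref,
      by = c("condition", "replicate"), suffix = c("", "_ref")
    )
    if (any(is.na(joined$ct_ref))) {
      bad <- unique(joined$condition[is.na(joined$ct_ref)])
      stop_arffam(paste0(
        "missing reference replicate(s) in condition(s): ",
        paste(bad, collapse = ", "),
        "; use paired = FALSE for unbalanced tables"
      ))
    }
  } else {
    ref_mean <- ref |>
      group_by(.data$condition) |>
      summarise(ct_ref = mean(.data$ct), .groups = "drop")
    joined <- left_join(targets, ref_mean, by = "condition")
  }
  joined |>
    mutate(value = scale * 2^(-(.data$ct - .data$ct_ref))) |>
    group_by(.data$gene, .data$condition) |>
    summarise(
      rel_expr = mean(.data$value),
      n_reps = n(),
      sd = if (n() > 1L) stats::sd(.data$value) else 0,
      .groups = "drop"
    )
}

#' Comparative-Ct (2^-ddCt) fold change between two conditions
#'
#' `2^-[(ct_target - ct_reference)_test - (ct_target - ct_reference)_control]`
#' computed from replicate-mean Ct values. Equals the ratio of
#' [relative_expression()] means up to replicate-noise convexity
#' (exactly, when computed on noiseless tables).
#'
#' @param ct A [ct_table()].
#' @param gene Target gene.
#' @param condition_test,condition_control Condition labels.
#' @return A single fold-change value.
#' @export
ddct_fold_change <- function(ct, gene, condition_test,
                             condition_control) {
  ref_gene <- attr(ct, "reference_gene")
  if (is.null(ref_gene)) stop_arffam("ct must be a ct_table")
  mean_ct <- function(g, cond) {
    v <- ct$ct[ct$gene == g & ct$condition == cond]
    if (length(v) == 0L) {
      stop_arffam(paste0("no Ct values for ", g, " in ", cond))
    }
    mean(v)
  }
  dct_test <- mean_ct(gene, condition_test) -
    mean_ct(ref_gene, condition_test)
  dct_ctrl <- mean_ct(gene, condition_control) -
    mean_ct(ref_gene, condition_control)
  2^(-(dct_test - dct_ctrl))
}

#' Fold-change significance by the 2x rule
#'
#' `"up"` when `fold >= cutoff`, `"down"` when `fold <= 1/cutoff`,
#' otherwise `"unchanged"`; the boundary is inclusive.
#'
#' @param fold Positive fold-change value(s).
#' @param cutoff Cutoff (default 2).
#' @return Character vector in `{"up", "down", "unchanged"}`.
#' @export
significance_flag <- function(fold, cutoff = 2) {
  if (any(!is.finite(fold)) || any(fold <= 0)) {
    stop_arffam("fold changes must be positive")
  }
  dplyr::case_when(
    fold >= cutoff ~ "up",
    fold <= 1 / cutoff ~ "down",
    TRUE ~ "unchanged"
  )
}

#' Replicate-level ddCt test (secondary significance flag)
#'
#' Optional Welch two-sample t-test on per-replicate delta-Ct values
#' between two conditions, complementing the primary 2x rule.
#'
#' @inheritParams ddct_fold_change
#' @return One-row tibble `gene`, `fold`, `p_value`.
#' @export
ddct_test <- function(ct, gene, condition_test, condition_control) {
  ref_gene <- attr(ct, "reference_gene")
  if (is.null(ref_gene)) stop_arffam("ct must be a ct_table")
  dct <- function(cond) {
    t_ <- ct[ct$gene == gene & ct$condition == cond, ]
    r_ <- ct[ct$gene == ref_gene & ct$condition == cond, ]
    j <- left_join(t_, r_, by = "replicate", suffix = c("", "_ref"))
    j$ct - j$ct_ref
  }
  a <- dct(condition_test)
  b <- dct(condition_control)
  tt <- stats::t.test(a, b)
  tibble(
    gene = gene,
    fold = 2^(-(mean(a) - mean(b))),
    p_value = tt$p.value
  )
}

#' Row-normalized log2 heatmap matrix
#'
#' Each cell becomes `log2(value / row maximum)`, so every row's
#' maximum is exactly 0 and all entries are <= 0 — the usual
#' "highest-to-lowest per gene" display. Zeros are replaced by a
#' pseudocount of the row's smallest positive value times 1e-3 (with a
#' message).
#'
#' @param expr Long tibble `gene`, `condition`, `rel_expr` (e.g. from
#'   [relative_expression()]).
#' @return A genes x conditions numeric matrix of class
#'   `arf_heatmap`.
#' @export
heatmap_matrix <- function(expr) {
  wide <- expr |>
    select("gene", "condition", "rel_expr") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = "rel_expr")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene
  if (any(is.na(m))) stop_arffam("missing gene x condition cells")
  if (any(m < 0)) stop_arffam("negative expression values")
  zero_rows <- rowSums(m > 0) == 0
  if (any(zero_rows)) {
    stop_arffam(paste0("all-zero expression row(s): ",
                       paste(rownames(m)[zero_rows], collapse = ", ")))
  }
  n_zero <- sum(m == 0)
  if (n_zero > 0L) {
    inform(paste0("heatmap_matrix: replaced ", n_zero,
                  " zero(s) with row-wise pseudocounts"))
    for (i in seq_len(nrow(m))) {
      z <- m[i, ] == 0
      if (any(z)) m[i, z] <- min(m[i, m[i, ] > 0]) * 1e-3
    }
  }
  out <- log2(m / apply(m, 1, max))
  class(out) <- c("arf_heatmap", class(out))
  out
}

#' @export
print.arf_heatmap <- function(x, ...) {
  cat("<arf_heatmap> ", nrow(x), " genes x ", ncol(x),
      " conditions (log2, row max = 0)\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Tidy a heatmap matrix into long form
#'
#' @param x An `arf_heatmap`.
#' @param ... Unused.
#' @return Tibble `gene`, `condition`, `log2_ratio`.
#' @export
tidy.arf_heatmap <- function(x, ...) {
  m <- unclass(x)
  tibble(
    gene = rep(rownames(m), times = ncol(m)),
    condition = rep(colnames(m), each = nrow(m)),
    log2_ratio = as.vector(m)
  )
}

#' @rdname tidy.arf_heatmap
#' @param object An `arf_heatmap`.
#' @export
autoplot.arf_heatmap <- function(object, ...) {
  df <- tidy(object)
  df$condition <- factor(df$condition, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$gene,
                                   fill = .data$log2_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "darkgreen", high = "red",
                                 name = "log2 ratio") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Expression share across categories
#'
#' Normalizes each gene's expression across categories (tissues, sex
#' types, ...) to fractions summing to 1 and flags the dominant
#' category and whether its share exceeds 0.5.
#'
#' @param expr Long tibble `gene`, `condition`, `rel_expr`.
#' @return Tibble `gene`, `condition`, `share`, `is_max`, `dominant`
#'   (share > 0.5 for the arg-max category).
#' @export
abundance_share <- function(expr) {
  if (length(unique(expr$condition)) < 2L) {
    stop_arffam("abundance shares need >= 2 categories")
  }
  if (any(expr$rel_expr < 0)) stop_arffam("negative expression values")
  totals <- tapply(expr$rel_expr, expr$gene, sum)
  if (any(totals <= 0)) {
    stop_arffam(paste0("zero total expression for gene(s): ",
                       paste(names(totals)[totals <= 0], collapse = ", ")))
  }
  expr |>
    group_by(.data$gene) |>
    mutate(
      share = .data$rel_expr / sum(.data$rel_expr),
      is_max = .data$share == max(.data$share),
      dominant = .data$is_max & .data$share > 0.5
    ) |>
    ungroup() |>
    select("gene", "condition", "share", "is_max", "dominant")
}

#' Tissue-specificity labels
#'
#' A gene is `<tissue>-specific` when that tissue's share of its total
#' expression reaches the threshold.
#'
#' @param expr Long tibble `gene`, `condition`, `rel_expr` where
#'   `condition` is a tissue.
#' @param threshold Minimum share (default 0.5).
#' @return Tibble `gene`, `label` (`NA` when no tissue qualifies).
#' @export
tissue_specificity <- function(expr, threshold = 0.5) {
  shares <- abundance_share(expr)
  shares |>
    group_by(.data$gene) |>
    summarise(
      label = {
        top <- which(.data$share >= threshold)
        if (length(top) >= 1L) {
          paste0(.data$condition[top[which.max(.data$share[top])]],
                 "-specific")
        } else {
          NA_character_
        }
      },
      .groups = "drop"
    )
}
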