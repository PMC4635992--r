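#' Intron count of a gene model
#'
#' Introns are defined purely as gaps between consecutive exons
#' (UTR introns included), so the count is `n_exons - 1`.
#'
#' @param model A one-row gene-model tibble as returned by
#'   [read_gff3()], or the whole table (vectorized).
#' @return Integer vector of intron counts.
#' @export
intron_count <- function(model) {
  stopifnot("n_exons" %in% names(model))
  as.integer(model$n_exons - 1L)
}

#' Exon-intron drawing track in transcript orientation
#'
#' Converts a gene model to alternating exon boxes and intron segments
#' with position 0 at the transcription start; minus-strand models are
#' reversed so the first box is the highest-coordinate exon.
#'
#' @param model A one-row gene-model tibble (columns `gene_id`,
#'   `strand`, `exons`).
#' @return Tibble with columns `gene_id`, `type` (`"exon"`/`"intron"`),
#'   `t_start`, `t_end` (0-based half-open transcript offsets) and
#'   `length`.
#' @export
structure_track <- function(model) {
  stopifnot(nrow(model) == 1L)
  ex <- model$exons[[1]]
  ex <- ex[order(ex$start), , drop = FALSE]
  if (model$strand == "-") {
    ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  } else if (model$strand != "+") {
    stop_arffam(paste0("unknown strand: ", model$strand))
  }
  exon_len <- ex$end - ex$start + 1L
  intron_len <- if (nrow(ex) > 1L) {
    if (model$strand == "-") {
      ex$start[-nrow(ex)] - ex$end[-1] - 1L
    } else {
      ex$start[-1] - ex$end[-nrow(ex)] - 1L
    }
  } else {
    integer(0)
  }
  lens <- integer(0)
  types <- character(0)
  for (i in seq_len(nrow(ex))) {
    lens <- c(lens, exon_len[i])
    types <- c(types, "exon")
    if (i < nrow(ex)) {
      lens <- c(lens, intron_len[i])
      types <- c(types, "intron")
    }
  }
  ends <- cumsum(lens)
  tibble(
    gene_id = model$gene_id,
    type = types,
    t_start = c(0L, head(ends, -1L)),
    t_end = ends,
    length = lens
  )
}

#' Family-wide gene-structure summary
#'
#' @param models Gene-model table as from [read_gff3()].
#' @return Tibble `gene_id`, `n_exons`, `n_introns`, `span` (genomic
#'   span in bp from first exon start to last exon end).
#' @export
family_structure_table <- function(models) {
  if (is.null(models) || nrow(models) == 0L) {
    stop_arffam("no gene models supplied")
  }
  models |>
    mutate(
      n_introns = intron_count(models),
      span = purrr::map_int(.data$exons,
                            ~ max(.x$end) - min(.x$start) + 1L)
    ) |>
    select("gene_id", "n_exons", "n_introns", "span")
}

#' Plot exon-intron structures
#'
#' Draws one horizontal track per gene: exons as boxes, introns as thin
#' segments, in transcript orientation.
#'
#' @param models Gene-model table as from [read_gff3()].
#' @return A ggplot object.
#' @export
plot_gene_structures <- function(models) {
  tracks <- purrr::map(seq_len(nrow(models)),
                       ~ structure_track(models[.x, ])) |>
    bind_rows()
  tracks$y <- as.numeric(factor(tracks$gene_id))
  ggplot2::ggplot(tracks) +
    ggplot2::geom_segment(
      data = ~ dplyr::filter(.x, .data$type == "intron"),
      ggplot2::aes(x = .data$t_start, xend = .data$t_end,
                   y = .data$y, yend = .data$y),
      linewidth = 0.4, colour = "grey50"
    ) +
    ggplot2::geom_rect(
      data = ~ dplyr::filter(.x, .data$type == "exon"),
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = .data$y - 0.35, ymax = .data$y + 0.35),
      fill = "steelblue"
    ) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(levels(factor(tracks$gene_id))),
      labels = levels(factor(tracks$gene_id))
    ) +
    ggplot2::labs(x = "position from transcription start (bp)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
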