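#' Default Pfam accession to ARF domain vocabulary mapping
#'
#' Maps the three Pfam families that define an ARF architecture onto the
#' controlled vocabulary used throughout the package: PF02362 (B3
#' DNA-binding domain) -> `DBD`, PF06507 (auxin response factor domain)
#' -> `AUX_RESP`, PF02309 (AUX/IAA family, the C-terminal dimerization
#' domain when found on an ARF) -> `AUX_IAA`.
#'
#' @return A tibble with columns `accession` and `domain_id`.
#' @export
pfam_domain_map <- function() {
  tibble(
    accession = c("PF02362", "PF06507", "PF02309"),
    domain_id = c("DBD", "AUX_RESP", "AUX_IAA")
  )
}

#' Read a domain-annotation table
#'
#' Reads an InterProScan-style delimited table of per-protein domain
#' calls and maps source accessions to the `{DBD, AUX_RESP, AUX_IAA}`
#' vocabulary. Rows with accessions outside the mapping are dropped (a
#' message reports how many).
#'
#' @param path Delimited text file with columns `protein_id`,
#'   `accession`, `start`, `end` (header required; tab- or
#'   comma-separated). Extra columns are ignored. An optional `source`
#'   column records the scan program.
#' @param mapping Accession-to-domain mapping, as [pfam_domain_map()].
#' @return A tibble with columns `protein_id`, `domain_id`, `start`,
#'   `end`, `source`.
#' @export
read_domain_table <- function(path, mapping = pfam_domain_map()) {
  if (!file.exists(path)) {
    stop_arffam(paste0("domain table not found: ", path))
  }
  sep <- detect_sep(path)
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("protein_id", "accession", "start", "end")
  if (!all(need %in% names(df))) {
    stop_arffam(paste0(
      "domain table must have columns ",
      paste(need, collapse = ", "), "; found: ",
      paste(names(df), collapse = ", ")
    ))
  }
  if (!"source" %in% names(df)) df$source <- "unknown"
  df <- as_tibble(df[, c(need, "source")])
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop_arffam("non-numeric start/end in domain table")
  }
  if (any(df$start > df$end) || any(df$start < 1L)) {
    stop_arffam("invalid domain coordinates (need 1 <= start <= end)")
  }
  # strip Pfam version suffixes like PF02362.21
  acc <- sub("\\..*$", "", df$accession)
  hit <- match(acc, mapping$accession)
  n_drop <- sum(is.na(hit))
  if (n_drop > 0L) {
    inform(paste0(
      "read_domain_table: dropped ", n_drop,
      " row(s) with accessions outside the ARF vocabulary"
    ))
  }
  df <- df[!is.na(hit), ]
  df$domain_id <- mapping$domain_id[hit[!is.na(hit)]]
  select(df, "protein_id", "domain_id", "start", "end", "source")
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
}

#' Read a long-format qRT-PCR Ct table
#'
#' @param path Delimited text with columns `gene`, `condition`,
#'   `replicate`, `ct`.
#' @param reference_gene Name of the internal-standard gene; every
#'   condition must carry Ct values for it.
#' @return A tibble of class `ct_table` with the reference gene stored in
#'   attribute `reference_gene`.
#' @export
read_ct_table <- function(path, reference_gene) {
  if (!file.exists(path)) {
    stop_arffam(paste0("Ct table not found: ", path))
  }
  sep <- detect_sep(path)
  df <- as_tibble(read.delim(path, sep = sep, stringsAsFactors = FALSE))
  ct_table(df, reference_gene)
}

#' Construct and validate a Ct table from a data frame
#'
#' @param df Data frame with columns `gene`, `condition`, `replicate`,
#'   `ct`.
#' @inheritParams read_ct_table
#' @return The validated tibble, classed `ct_table`.
#' @export
ct_table <- function(df, reference_gene) {
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(df))) {
    stop_arffam(paste0(
      "Ct table needs columns ", paste(need, collapse = ", ")
    ))
  }
  df <- as_tibble(df[, need])
  df$replicate <- as.integer(df$replicate)
  df$ct <- as.numeric(df$ct)
  if (any(is.na(df$ct)) || any(df$ct < 0)) {
    stop_arffam("Ct values must be non-negative numbers")
  }
  if (any(is.na(df$replicate)) || any(df$replicate < 1L)) {
    stop_arffam("replicate indices must be integers >= 1")
  }
  conds <- unique(df$condition)
  ref_conds <- unique(df$condition[df$gene == reference_gene])
  missing <- setdiff(conds, ref_conds)
  if (length(missing) > 0L) {
    stop_arffam(paste0(
      "condition(s) lacking reference gene '", reference_gene, "': ",
      paste(missing, collapse = ", ")
    ))
  }
  structure(df,
    class = c("ct_table", class(df)),
    reference_gene = reference_gene
  )
}

#' @export
print.ct_table <- function(x, ...) {
  cat(
    "<ct_table> reference gene:", attr(x, "reference_gene"), "\n"
  )
  NextMethod()
}
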