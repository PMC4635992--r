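#' Pipeline configuration
#'
#' Bundles the tunable parameters shared across stages. Defaults follow
#' common practice for plant gene-family surveys: 1500-bp promoters,
#' 1000 bootstrap iterations, sister pairs called at >= 99 % support,
#' a 2x fold-change significance cutoff, and reference-gene scaling to
#' 1000.
#'
#' @param promoter_length Promoter length in bp.
#' @param bootstrap_reps Number of bootstrap replicates.
#' @param sister_pair_min_support Minimum bootstrap support (percent)
#'   for a cross-species sister pair.
#' @param fold_change_cutoff Fold-change cutoff for significance calls.
#' @param reference_scale Value assigned to expression equal to the
#'   reference gene.
#' @param rng_seed Integer seed for all stochastic stages.
#' @return A list of class `arf_config`.
#' @export
arf_config <- function(promoter_length = 1500,
                       bootstrap_reps = 1000,
                       sister_pair_min_support = 99,
                       fold_change_cutoff = 2,
                       reference_scale = 1000,
                       rng_seed = 1L) {
  cfg <- list(
    promoter_length = as.numeric(promoter_length),
    bootstrap_reps = as.numeric(bootstrap_reps),
    sister_pair_min_support = as.numeric(sister_pair_min_support),
    fold_change_cutoff = as.numeric(fold_change_cutoff),
    reference_scale = as.numeric(reference_scale),
    rng_seed = as.integer(rng_seed)
  )
  num <- unlist(cfg[setdiff(names(cfg), "rng_seed")])
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop_arffam("all numeric config fields must be positive")
  }
  if (cfg$sister_pair_min_support > 100) {
    stop_arffam("sister_pair_min_support must be <= 100")
  }
  structure(cfg, class = "arf_config")
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a
#' comment. Unknown keys raise a warning and are ignored.
#'
#' @param path Path to the config file.
#' @return An `arf_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_arffam(paste0("config file not found: ", path))
  }
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop_arffam(paste0("unparseable config line(s): ",
                       paste(lines[bad], collapse = "; ")))
  }
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  known <- names(formals(arf_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0L) {
    warn(paste0("ignoring unknown config key(s): ",
                paste(unknown, collapse = ", ")))
  }
  args <- lapply(vals[keys %in% known], as.numeric)
  names(args) <- keys[keys %in% known]
  if (any(is.na(unlist(args)))) {
    stop_arffam("non-numeric value for numeric config key")
  }
  do.call(arf_config, args)
}

#' @export
print.arf_config <- function(x, ...) {
  cat("<arf_config>\n")
  for (k in names(x)) cat("  ", k, " = ", x[[k]], "\n", sep = "")
  invisible(x)
}
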