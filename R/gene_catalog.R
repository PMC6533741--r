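#' Normalize a gene symbol
#'
#' Canonical form used throughout the package: leading/trailing and internal
#' whitespace removed, uppercased. Total and idempotent; empty input maps to
#' the empty string.
#'
#' @param x character vector of raw symbols.
#' @return character vector of normalized symbols.
#' @examples
#' normalize_symbol(c(" irf6 ", "NECTIN1", "hsa miR x"))
#' @export
normalize_symbol <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  toupper(gsub("[[:space:]]+", "", x))
}

#' Load a candidate-gene catalog from TSV
#'
#' Reads the curated catalog that defines the foreground gene set for the
#' enrichment analyses. The file must be tab-separated with a header row
#' containing at least `symbol`, `locus` and `syndromic_status`; optional
#' columns `gene_name`, `aliases` (comma-separated) and `syndrome_names`
#' (comma-separated) are carried along. Lines starting with `#` are ignored.
#'
#' Symbols are normalized with [normalize_symbol()]. Rows that collapse to a
#' duplicate normalized symbol are dropped with a warning (first occurrence
#' kept, row order preserved). An alias that collides with another record's
#' normalized symbol is dropped with a warning; the primary symbol wins.
#'
#' @param path path to the catalog TSV.
#' @param name label for the catalog (defaults to the file name).
#' @return an object of class `gene_catalog`: a list with elements
#'   `records` (data.frame with columns `symbol`, `gene_name`, `locus`,
#'   `syndromic_status`, `aliases` and `syndrome_names`, the last two being
#'   list columns) and `name`.
#' @seealso [write_gene_catalog()], [catalog_symbols()]
#' @export
load_gene_catalog <- function(path, name = basename(path)) {
  df <- cm_read_tsv(path)
  cm_require_columns(df, c("symbol", "locus", "syndromic_status"), path)
  if (nrow(df) == 0) stop_empty("%s: catalog file has no data rows", path)

  records <- data.frame(
    symbol = normalize_symbol(df$symbol),
    gene_name = if ("gene_name" %in% names(df)) as.character(df$gene_name) else NA_character_,
    locus = ifelse(is.na(df$locus), "", trimws(as.character(df$locus))),
    syndromic_status = tolower(trimws(as.character(df$syndromic_status))),
    stringsAsFactors = FALSE
  )
  records$aliases <- if ("aliases" %in% names(df)) {
    lapply(cm_split(df$aliases), normalize_symbol)
  } else rep(list(character(0)), nrow(df))
  records$syndrome_names <- if ("syndrome_names" %in% names(df)) {
    lapply(cm_split(ifelse(is.na(df$syndrome_names), "", df$syndrome_names)), trimws)
  } else rep(list(character(0)), nrow(df))

  if (any(!nzchar(records$symbol)))
    stop_format("%s: empty gene symbol after normalization", path)
  bad <- setdiff(unique(records$syndromic_status),
                 c("nonsyndromic", "syndromic", "both"))
  if (length(bad) > 0)
    stop_format("%s: invalid syndromic_status value(s): %s", path,
                paste(bad, collapse = ", "))

  dup <- duplicated(records$symbol)
  if (any(dup)) {
    warning(sprintf("catalog %s: %d duplicate symbol row(s) collapsed (%s)",
                    name, sum(dup),
                    paste(unique(records$symbol[dup]), collapse = ", ")),
            call. = FALSE)
    records <- records[!dup, , drop = FALSE]
  }

  # alias collisions resolve in favor of the primary symbol
  records$aliases <- lapply(seq_len(nrow(records)), function(i) {
    al <- setdiff(records$aliases[[i]], records$symbol[i])
    clash <- al %in% records$symbol
    if (any(clash))
      warning(sprintf("catalog %s: alias(es) %s of %s collide with primary symbols; dropped",
                      name, paste(al[clash], collapse = ", "),
                      records$symbol[i]), call. = FALSE)
    al[!clash]
  })
  rownames(records) <- NULL

  structure(list(records = records, name = name), class = "gene_catalog")
}

#' Write a gene catalog back to TSV
#'
#' Emits the same dialect [load_gene_catalog()] reads, so a catalog
#' round-trips losslessly.
#'
#' @param catalog a `gene_catalog`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_gene_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  r <- catalog$records
  out <- data.frame(
    symbol = r$symbol,
    gene_name = ifelse(is.na(r$gene_name), "", r$gene_name),
    locus = r$locus,
    syndromic_status = r$syndromic_status,
    aliases = cm_join(r$aliases),
    syndrome_names = cm_join(r$syndrome_names),
    stringsAsFactors = FALSE
  )
  cm_write_tsv(out, path)
}

#' Gene symbols of a catalog
#'
#' @param catalog a `gene_catalog`.
#' @return character vector of normalized symbols, in catalog order.
#' @export
catalog_symbols <- function(catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  catalog$records$symbol
}

#' @export
print.gene_catalog <- function(x, ...) {
  tab <- table(x$records$syndromic_status)
  cat(sprintf("<gene_catalog '%s'>: %d genes (%s)\n", x$name,
              nrow(x$records),
              paste(sprintf("%s %s", tab, names(tab)), collapse = ", ")))
  invisible(x)
}

#' @export
length.gene_catalog <- function(x) nrow(x$records)

#' Path to a packaged example data file
#'
#' Convenience accessor for the plain-text fixtures shipped under
#' `inst/extdata/` (the curated CL/P gene catalog, the published
#' miRNA-target lists, the seed-family map and the multi-family rollup).
#'
#' @param file file name; with no argument, lists available files.
#' @return full path (or a vector of file names).
#' @examples
#' clp_example()
#' cat <- load_gene_catalog(clp_example("clp_gene_catalog.tsv"))
#' @export
clp_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "cleftminer")))
  path <- system.file("extdata", file, package = "cleftminer")
  if (!nzchar(path)) stop_lookup("no packaged file named %s", file)
  path
}
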