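#' Load miRNA-target interaction tables
#'
#' Reads one or more TSV exports of miRNA-target interaction evidence
#' (columns `source`, `mirna`, `gene`, and optionally `validated`) and
#' concatenates them into a single interaction table. Gene symbols are
#' normalized with [normalize_symbol()]; miRNA identifiers are matched
#' case-insensitively but their first-seen spelling (including any `hsa-`
#' prefix) is preserved verbatim. Exact duplicates (same source, miRNA and
#' gene) are collapsed, keeping `validated = TRUE` if any copy was
#' validated.
#'
#' @param paths character vector of TSV file paths (at least one).
#' @return data.frame with columns `source`, `mirna`, `gene`, `validated`.
#' @export
load_interactions <- function(paths) {
  if (length(paths) == 0) stop_empty("no interaction files given")
  tabs <- lapply(paths, function(p) {
    df <- cm_read_tsv(p)
    cm_require_columns(df, c("source", "mirna", "gene"), p)
    if (!"validated" %in% names(df)) df$validated <- FALSE
    data.frame(source = trimws(as.character(df$source)),
               mirna = trimws(as.character(df$mirna)),
               gene = normalize_symbol(df$gene),
               validated = parse_flag(df$validated, p),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, tabs)
  if (any(!nzchar(all$source) | !nzchar(all$mirna) | !nzchar(all$gene)))
    stop_format("interaction records must have non-empty source, mirna and gene")

  # case-insensitive miRNA matching, first-seen spelling kept
  key <- tolower(all$mirna)
  spelling <- all$mirna[!duplicated(key)]
  names(spelling) <- key[!duplicated(key)]
  all$mirna <- unname(spelling[key])

  grp <- paste(all$source, tolower(all$mirna), all$gene, sep = "\r")
  validated <- tapply(all$validated, grp, any)
  first <- !duplicated(grp)
  out <- all[first, , drop = FALSE]
  out$validated <- unname(validated[paste(out$source, tolower(out$mirna),
                                          out$gene, sep = "\r")])
  rownames(out) <- NULL
  out
}

parse_flag <- function(x, path) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  v <- tolower(trimws(as.character(x)))
  out <- v %in% c("true", "t", "1", "yes")
  bad <- !v %in% c("true", "t", "1", "yes", "false", "f", "0", "no", "", "na")
  if (any(bad))
    stop_format("%s: unparseable 'validated' value(s): %s", path,
                paste(unique(v[bad]), collapse = ", "))
  out
}

#' Consensus miRNA-gene pairs across prediction sources
#'
#' Counts, for each (miRNA, gene) pair, the number of distinct *prediction*
#' sources supporting it and keeps pairs with at least `min_sources`
#' supporters. A source counts as a prediction source only if it
#' contributes at least one unvalidated (predicted) record in the loaded
#' table; sources consisting solely of validated records (an experimental
#' validation database such as a miRTarbase export) support the validation
#' filter, not the consensus count.
#'
#' With `min_sources = 1` the result is the union of all predicted pairs;
#' the retained set shrinks monotonically as `min_sources` grows. Asking
#' for more sources than exist yields an empty set, not an error.
#'
#' @param interactions data.frame from [load_interactions()].
#' @param min_sources minimum number of distinct prediction sources
#'   (default 2, a two-of-three consensus).
#' @return data.frame with columns `mirna`, `gene`, `n_sources`.
#' @export
consensus_pairs <- function(interactions, min_sources = 2) {
  if (!is.numeric(min_sources) || length(min_sources) != 1 ||
      is.na(min_sources) || min_sources < 1)
    stop_domain("min_sources must be a positive integer")
  pred_sources <- unique(interactions$source[!interactions$validated])
  pred <- interactions[interactions$source %in% pred_sources, , drop = FALSE]
  if (nrow(pred) == 0)
    return(data.frame(mirna = character(0), gene = character(0),
                      n_sources = integer(0)))
  key <- paste(tolower(pred$mirna), pred$gene, sep = "\r")
  n_src <- tapply(pred$source, key, function(s) length(unique(s)))
  first <- !duplicated(key)
  out <- data.frame(mirna = pred$mirna[first], gene = pred$gene[first],
                    n_sources = as.integer(n_src[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[out$n_sources >= min_sources, , drop = FALSE]
  out <- out[order(tolower(out$mirna), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only experimentally validated pairs
#'
#' Retains the subset of `pairs` for which any source in `interactions`
#' records `validated = TRUE` for that (miRNA, gene) pair. Always a subset
#' of its input; empty input yields empty output.
#'
#' @param pairs data.frame with columns `mirna`, `gene` (e.g. from
#'   [consensus_pairs()]).
#' @param interactions data.frame from [load_interactions()].
#' @return the validated subset of `pairs`, same columns.
#' @export
filter_validated <- function(pairs, interactions) {
  if (nrow(pairs) == 0) return(pairs)
  val <- interactions[interactions$validated, , drop = FALSE]
  val_key <- unique(paste(tolower(val$mirna), val$gene, sep = "\r"))
  keep <- paste(tolower(pairs$mirna), pairs$gene, sep = "\r") %in% val_key
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a miRNA target map over a declared gene universe
#'
#' Assembles the mapping miRNA -> target gene set used by
#' [mirna_enrichment()], together with the background universe the
#' enrichment tests count over. By default the universe is the union of
#' all target genes in `pairs`; an explicit universe (e.g. all
#' protein-coding genes) may be supplied and must contain every target
#' gene.
#'
#' @param pairs non-empty data.frame with columns `mirna`, `gene`
#'   (optionally `n_sources`, carried into the provenance table).
#' @param universe optional explicit character vector of gene symbols.
#' @return an object of class `target_map`: list with `universe` (sorted
#'   character vector), `targets` (named list, miRNA -> sorted gene
#'   vector), and `provenance` (the deduplicated input pairs).
#' @export
build_target_map <- function(pairs, universe = NULL) {
  if (is.null(pairs) || nrow(pairs) == 0)
    stop_empty("no miRNA-gene pairs to build a target map from")
  pairs <- pairs[!duplicated(paste(tolower(pairs$mirna), pairs$gene, sep = "\r")), ,
                 drop = FALSE]
  genes <- sort(unique(pairs$gene))
  if (is.null(universe)) {
    universe <- genes
  } else {
    universe <- sort(unique(normalize_symbol(universe)))
    missing <- setdiff(genes, universe)
    if (length(missing) > 0)
      stop_domain("explicit universe is missing %d target gene(s): %s",
                  length(missing),
                  paste(utils::head(missing, 5), collapse = ", "))
  }
  targets <- lapply(split(pairs$gene, pairs$mirna), function(g) sort(unique(g)))
  targets <- targets[vapply(targets, length, 1L) > 0]
  targets <- targets[order(tolower(names(targets)), names(targets))]
  rownames(pairs) <- NULL
  structure(list(universe = universe, targets = targets, provenance = pairs),
            class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("<target_map>: %d miRNAs, %d genes in universe, %d pairs\n",
              length(x$targets), length(x$universe),
              sum(vapply(x$targets, length, 1L))))
  invisible(x)
}

#' Serialize / read a target map as TSV
#'
#' One row per (miRNA, gene) pair with columns `mirna`, `gene`,
#' `n_sources`, `validated`. The universe of a map read back from disk is
#' the union of its target genes; re-supply an explicit universe to
#' [build_target_map()] if a wider background is wanted.
#'
#' @param map a `target_map`.
#' @param path file path.
#' @return `write_target_map()` the path invisibly; `read_target_map()` a
#'   `target_map`.
#' @export
write_target_map <- function(map, path) {
  stopifnot(inherits(map, "target_map"))
  rows <- data.frame(
    mirna = rep(names(map$targets), vapply(map$targets, length, 1L)),
    gene = unlist(map$targets, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  prov <- map$provenance
  if (!is.null(prov) && "n_sources" %in% names(prov)) {
    key <- paste(tolower(prov$mirna), prov$gene, sep = "\r")
    ns <- setNames(prov$n_sources, key)
    rows$n_sources <- as.integer(ns[paste(tolower(rows$mirna), rows$gene, sep = "\r")])
  } else rows$n_sources <- NA_integer_
  rows$validated <- TRUE
  cm_write_tsv(rows, path)
}

#' @rdname write_target_map
#' @param universe optional explicit universe passed to [build_target_map()].
#' @export
read_target_map <- function(path, universe = NULL) {
  df <- cm_read_tsv(path)
  cm_require_columns(df, c("mirna", "gene"), path)
  df$gene <- normalize_symbol(df$gene)
  build_target_map(df, universe = universe)
}
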