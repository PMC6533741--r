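#' Assemble and validate a pipeline run configuration
#'
#' Gathers the file paths and thresholds consumed by
#' [run_mirna_pipeline()] and [run_tdt_pipeline()]. Thresholds default to
#' the values used throughout the package: miRNA FDR 0.1, pathway FDR
#' 0.05, TDT alpha 0.05, minimum pathway overlap 5, two-source prediction
#' consensus, family rollup at two or more families, zero flank.
#'
#' @param catalog path to the candidate-gene catalog TSV (optional if
#'   `foreground` is given).
#' @param interactions character vector of interaction TSVs.
#' @param target_map path to a pre-built target-map TSV (bypasses
#'   consensus/validation stages when set).
#' @param foreground path to a foreground gene list (one symbol per line,
#'   or a TSV with a `symbol` column); defaults to the catalog symbols.
#' @param family_map path to the miRNA family map TSV.
#' @param gmt path to a GMT annotation collection.
#' @param ped,map,genes_bed trio genotype and gene-interval paths.
#' @param universe optional path to an explicit background gene list.
#' @param fdr_threshold,pathway_fdr,alpha,min_overlap,min_sources,min_families,flank
#'   analysis thresholds (see the stage functions).
#' @param family_scope count families over `"significant"` rows only
#'   (default) or over `"all"` tested miRNAs.
#' @param seed integer recorded in run metadata (and used by any stage
#'   with randomness).
#' @param out_dir optional output directory; when set, stages write TSV
#'   results plus a `run_metadata.json`.
#' @return list of class `run_config`.
#' @export
run_config <- function(catalog = NULL, interactions = NULL, target_map = NULL,
                       foreground = NULL, family_map = NULL, gmt = NULL,
                       ped = NULL, map = NULL, genes_bed = NULL,
                       universe = NULL,
                       fdr_threshold = 0.1, pathway_fdr = 0.05, alpha = 0.05,
                       min_overlap = 5, min_sources = 2, min_families = 2,
                       flank = 0, family_scope = c("significant", "all"),
                       seed = 1L, out_dir = NULL) {
  cm_as_probability(fdr_threshold, "fdr_threshold")
  cm_as_probability(pathway_fdr, "pathway_fdr")
  cm_as_probability(alpha, "alpha")
  family_scope <- match.arg(family_scope)
  for (p in c(catalog, interactions, target_map, foreground, family_map,
              gmt, ped, map, genes_bed, universe))
    if (!is.null(p) && !file.exists(p)) stop_format("file not found: %s", p)
  structure(list(catalog = catalog, interactions = interactions,
                 target_map = target_map, foreground = foreground,
                 family_map = family_map, gmt = gmt, ped = ped, map = map,
                 genes_bed = genes_bed, universe = universe,
                 fdr_threshold = fdr_threshold, pathway_fdr = pathway_fdr,
                 alpha = alpha, min_overlap = min_overlap,
                 min_sources = min_sources, min_families = min_families,
                 flank = flank, family_scope = family_scope,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

read_gene_list <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first) || grepl("^symbol$", trimws(first))) {
    df <- cm_read_tsv(path)
    cm_require_columns(df, "symbol", path)
    normalize_symbol(df$symbol)
  } else {
    x <- readLines(path)
    x <- x[nzchar(trimws(x)) & !startsWith(trimws(x), "#")]
    normalize_symbol(x)
  }
}

with_stage <- function(stage, expr) {
  tryCatch(expr, cleftminer_error = function(e) {
    cm_stop(class(e)[1], "[stage %s] %s", stage, conditionMessage(e))
  })
}

pipeline_metadata <- function(config, extra) {
  c(list(tool = "cleftminer",
         version = as.character(packageVersion("cleftminer")),
         seed = config$seed,
         thresholds = list(fdr_threshold = config$fdr_threshold,
                           pathway_fdr = config$pathway_fdr,
                           alpha = config$alpha,
                           min_overlap = config$min_overlap,
                           min_sources = config$min_sources,
                           min_families = config$min_families,
                           flank = config$flank)),
    extra)
}

write_outputs <- function(out_dir, tables, metadata) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) cm_write_tsv(tables[[nm]], file.path(out_dir, nm))
  jsonlite::write_json(metadata, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

flatten_enrichment <- function(rows) {
  out <- rows[, setdiff(names(rows), "overlap_genes"), drop = FALSE]
  out$overlap_genes <- cm_join(rows$overlap_genes)
  out
}

#' Run the miRNA target enrichment pipeline end to end
#'
#' Stages: load interaction tables, form the prediction consensus, keep
#' experimentally validated pairs, build the target map, test each miRNA
#' for enrichment of the foreground, and roll significant results up to
#' genes targeted by multiple seed families. A pre-built target map (via
#' `config$target_map`) skips the first three stages. All output tables
#' are deterministically ordered; metadata records thresholds, universe
#' size, seed and package version, enough to replay the run.
#'
#' @param config a [run_config()].
#' @return list with `enrichment` (per-miRNA rows), `families` (per-gene
#'   rollup) and `metadata`; also written as TSV/JSON under
#'   `config$out_dir` when set.
#' @export
run_mirna_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tmap <- if (!is.null(config$target_map)) {
    with_stage("target_map", read_target_map(
      config$target_map,
      universe = if (!is.null(config$universe)) read_gene_list(config$universe)))
  } else {
    inter <- with_stage("load_interactions",
                        load_interactions(config$interactions))
    pairs <- with_stage("consensus",
                        consensus_pairs(inter, min_sources = config$min_sources))
    pairs <- with_stage("validated_filter", filter_validated(pairs, inter))
    with_stage("target_map", build_target_map(
      pairs,
      universe = if (!is.null(config$universe)) read_gene_list(config$universe)))
  }
  fg <- if (!is.null(config$foreground)) {
    read_gene_list(config$foreground)
  } else if (!is.null(config$catalog)) {
    catalog_symbols(load_gene_catalog(config$catalog))
  } else stop_empty("config needs a foreground list or a catalog")
  fmap <- if (!is.null(config$family_map)) load_family_map(config$family_map)

  rows <- with_stage("enrichment",
                     mirna_enrichment(tmap, fg, family_map = fmap,
                                      fdr_threshold = config$fdr_threshold))
  fam_rows <- if (config$family_scope == "all") rows else
    rows[rows$significant, , drop = FALSE]
  families <- if (nrow(fam_rows) > 0) {
    count_families_per_gene(fam_rows, min_families = config$min_families)
  } else data.frame(gene = character(0), n_families = integer(0),
                    families = character(0))

  metadata <- pipeline_metadata(config, list(
    analysis = "mirna_enrichment",
    universe_size = length(tmap$universe),
    foreground_in_universe = length(intersect(unique(normalize_symbol(fg)),
                                              tmap$universe)),
    n_mirnas_tested = nrow(rows),
    n_significant = sum(rows$significant),
    family_scope = config$family_scope))
  write_outputs(config$out_dir,
                list("mirna_enrichment.tsv" = flatten_enrichment(rows),
                     "gene_family_counts.tsv" = families),
                metadata)
  list(enrichment = rows, families = families, metadata = metadata)
}

#' Run the trio TDT pipeline end to end
#'
#' Reads PED/MAP trios, assigns SNPs to gene intervals, runs the TDT scan
#' and reports per-SNP and per-gene (top-marker) tables with tier labels.
#' The candidate-wise threshold is `alpha` divided by the number of genes
#' actually tested.
#'
#' @param config a [run_config()] with `ped`, `map` and optionally
#'   `genes_bed` set.
#' @return list with `per_snp`, `per_gene`, `tiers` and `metadata`; also
#'   written under `config$out_dir` when set.
#' @export
run_tdt_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$ped) || is.null(config$map))
    stop_empty("config needs ped and map paths")
  panel <- with_stage("read_trios", read_trios(config$ped, config$map))
  assignment <- if (!is.null(config$genes_bed)) {
    with_stage("assign_genes",
               assign_genes(panel, config$genes_bed, flank_bp = config$flank))
  }
  scan <- with_stage("tdt_scan",
                     tdt_scan(panel, gene_assignment = assignment,
                              alpha = config$alpha))
  metadata <- pipeline_metadata(config, list(
    analysis = "trio_tdt",
    n_trios = nrow(panel$trios),
    n_snps = nrow(panel$snps),
    n_informative_snps = nrow(scan$per_snp),
    n_genes_tested = nrow(scan$per_gene),
    candidate_wise_threshold = scan$tiers$candidate_wise))
  write_outputs(config$out_dir,
                list("tdt_per_snp.tsv" = scan$per_snp,
                     "tdt_per_gene.tsv" = scan$per_gene),
                metadata)
  list(per_snp = scan$per_snp, per_gene = scan$per_gene, tiers = scan$tiers,
       metadata = metadata)
}
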