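#' One-sided Fisher's exact (hypergeometric upper-tail) probability
#'
#' Probability of observing at least `k` foreground genes in a sample of
#' `n` from a universe of `N` genes of which `K` are foreground, i.e.
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. This is the one-sided
#' (enrichment-only) Fisher's exact test for the 2x2 table underlying each
#' miRNA or annotation-term test. Computed through the numerically stable
#' hypergeometric tail in [stats::phyper()].
#'
#' @param k observed overlap count, `0 <= k <= min(K, n)`.
#' @param K foreground size in the universe.
#' @param n sample (target-set or term) size in the universe.
#' @param N universe size, `N > 0`.
#' @return probability in `[0, 1]`. Vectorized over `k`, `K`, `n`, `N`.
#' @examples
#' fisher_exact_one_sided(3, 5, 4, 20)  # 155/4845
#' @export
fisher_exact_one_sided <- function(k, K, n, N) {
  m <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(as.numeric(k), m); K <- rep_len(as.numeric(K), m)
  n <- rep_len(as.numeric(n), m); N <- rep_len(as.numeric(N), m)
  if (any(is.na(k) | is.na(K) | is.na(n) | is.na(N)))
    stop_domain("NA in hypergeometric arguments")
  if (any(k != floor(k) | K != floor(K) | n != floor(n) | N != floor(N)))
    stop_domain("hypergeometric arguments must be integers")
  if (any(N <= 0)) stop_domain("universe size N must be positive")
  if (any(K > N | n > N)) stop_domain("K and n must not exceed N")
  if (any(k < 0 | k > pmin(K, n)))
    stop_domain("overlap k must satisfy 0 <= k <= min(K, n)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Adjusts a vector of p-values by the Benjamini-Hochberg false discovery
#' rate procedure: `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1,
#' returned in the input order. Ties share a q-value, and q is monotone
#' non-decreasing in p. Thin, domain-checked wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues non-empty numeric vector of probabilities in `[0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) stop_empty("empty p-value vector")
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_domain("p-values must lie in [0, 1] with no NA")
  p.adjust(pvalues, method = "BH")
}

#' Load a miRNA -> seed-family map
#'
#' TSV with columns `mirna` and `family`. Empty or `NA` family fields, and
#' miRNAs absent from the map altogether, are reported as `"UNKNOWN"` by
#' [mirna_family()]; unknown-family miRNAs are still tested for enrichment
#' but never contribute to the family rollup.
#'
#' @param path family map TSV.
#' @return named character vector (names are lower-cased miRNA ids).
#' @export
load_family_map <- function(path) {
  df <- cm_read_tsv(path)
  cm_require_columns(df, c("mirna", "family"), path)
  fam <- trimws(as.character(df$family))
  fam[is.na(fam) | fam %in% c("", "NA", "na")] <- NA_character_
  setNames(fam, tolower(trimws(df$mirna)))
}

#' @rdname load_family_map
#' @param family_map named vector from [load_family_map()] (or `NULL`).
#' @param mirnas character vector of miRNA identifiers.
#' @export
mirna_family <- function(family_map, mirnas) {
  if (is.null(family_map)) return(rep("UNKNOWN", length(mirnas)))
  fam <- unname(family_map[tolower(mirnas)])
  ifelse(is.na(fam), "UNKNOWN", fam)
}

#' Per-miRNA enrichment of a candidate gene set
#'
#' For every miRNA in the target map, tests whether its target set is
#' enriched for the foreground (candidate) genes by the one-sided Fisher's
#' exact test on the 2x2 table (targets vs non-targets, foreground vs
#' background) over the map's universe, then adjusts across all tested
#' miRNAs with Benjamini-Hochberg FDR. Counts follow the usual convention:
#' `N` universe size, `K` foreground genes in the universe, `n` target-set
#' size, `k` overlap.
#'
#' @param target_map a `target_map` from [build_target_map()].
#' @param foreground character vector of candidate gene symbols (normalized
#'   internally; only the intersection with the universe is used).
#' @param family_map optional named vector from [load_family_map()].
#' @param fdr_threshold rows with `q < fdr_threshold` are flagged
#'   significant (default 0.1).
#' @return data.frame with one row per miRNA, columns `mirna`, `family`,
#'   `k`, `K`, `n`, `N`, `p`, `q`, `significant` and list column
#'   `overlap_genes`; sorted by `(q, p, mirna)`.
#' @export
mirna_enrichment <- function(target_map, foreground, family_map = NULL,
                             fdr_threshold = 0.1) {
  stopifnot(inherits(target_map, "target_map"))
  cm_as_probability(fdr_threshold, "fdr_threshold")
  fg <- intersect(unique(normalize_symbol(foreground)), target_map$universe)
  if (length(fg) == 0)
    stop_empty("foreground has no genes in the target-map universe")
  N <- length(target_map$universe)
  K <- length(fg)
  mirnas <- names(target_map$targets)
  overlap <- lapply(target_map$targets, function(t) sort(intersect(t, fg)))
  k <- vapply(overlap, length, 1L)
  n <- vapply(target_map$targets, length, 1L)
  p <- fisher_exact_one_sided(k, K, n, N)
  q <- bh_fdr(p)
  out <- data.frame(mirna = mirnas, family = mirna_family(family_map, mirnas),
                    k = k, K = K, n = n, N = N, p = p, q = q,
                    significant = q < fdr_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$overlap_genes <- unname(overlap)
  ord <- order(out$q, out$p, out$mirna)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count distinct miRNA seed families targeting each gene
#'
#' Rolls enrichment rows up to the gene level: for every gene appearing in
#' any row's overlap set, counts the distinct *known* families (rows with
#' family `"UNKNOWN"` contribute their genes but never a family) among the
#' supplied rows. Pass only the significant rows to mirror the published
#' "genes targeted by at least two miRNA families" presentation.
#'
#' @param rows data.frame with columns `mirna`, `family` and list column
#'   `overlap_genes` (e.g. the significant subset of [mirna_enrichment()]
#'   output).
#' @param min_families keep genes with at least this many known families
#'   (default 1; use 2 for the published rollup).
#' @return data.frame with columns `gene`, `n_families`, `families`
#'   (comma-joined, sorted), ordered by descending `n_families` then gene.
#' @export
count_families_per_gene <- function(rows, min_families = 1) {
  if (is.null(rows) || nrow(rows) == 0) stop_empty("no enrichment rows given")
  if (!is.numeric(min_families) || min_families < 0)
    stop_domain("min_families must be a non-negative integer")
  genes <- sort(unique(unlist(rows$overlap_genes, use.names = FALSE)))
  per_row_genes <- rows$overlap_genes
  fam <- rows$family
  fams_by_gene <- lapply(genes, function(g) {
    hit <- vapply(per_row_genes, function(og) g %in% og, logical(1))
    sort(unique(fam[hit & fam != "UNKNOWN" & !is.na(fam)]))
  })
  out <- data.frame(gene = genes,
                    n_families = vapply(fams_by_gene, length, 1L),
                    families = vapply(fams_by_gene, paste, character(1),
                                      collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[out$n_families >= min_families, , drop = FALSE]
  out <- out[order(-out$n_families, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect (term, description, then tab-separated member
#' genes), parsed with [fgsea::gmtPathways()]; member symbols are
#' normalized with [normalize_symbol()].
#'
#' @param path GMT file path.
#' @return named list of character vectors (term -> genes).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  sets <- fgsea::gmtPathways(path)
  if (length(sets) == 0) stop_empty("%s: no gene sets in GMT file", path)
  lapply(sets, function(g) sort(unique(normalize_symbol(g))))
}

#' Hypergeometric gene-set enrichment over an annotation collection
#'
#' Generic over-representation analysis of a foreground gene set against
#' GMT-style annotation terms (GO, KEGG, HPO, ...): per-term hypergeometric
#' upper-tail p (identical to [fisher_exact_one_sided()]), BH adjustment
#' across the tested terms. Terms whose foreground overlap is below
#' `min_overlap` are excluded *before* testing (and before the BH family is
#' formed), matching the usual "at least four/five genes per category"
#' filters of DAVID- and WebGestalt-style runs.
#'
#' @param foreground candidate gene symbols.
#' @param annotation_sets named list of gene vectors (see [read_gmt()]).
#' @param universe background gene symbols; must contain the foreground.
#' @param min_overlap minimum foreground genes per term (default 5).
#' @param fdr_threshold rows with `q < fdr_threshold` are flagged
#'   significant (default 0.05).
#' @return data.frame with columns `term`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `significant` and list column `overlap_genes`, sorted by `(q, p,
#'   term)`.
#' @export
geneset_enrichment <- function(foreground, annotation_sets, universe,
                               min_overlap = 5, fdr_threshold = 0.05) {
  if (length(annotation_sets) == 0) stop_empty("empty annotation collection")
  if (is.null(names(annotation_sets)) || any(!nzchar(names(annotation_sets))))
    stop_format("annotation sets must be named")
  cm_as_probability(fdr_threshold, "fdr_threshold")
  if (!is.numeric(min_overlap) || min_overlap < 0)
    stop_domain("min_overlap must be a non-negative integer")
  universe <- unique(normalize_symbol(universe))
  fg <- unique(normalize_symbol(foreground))
  if (length(setdiff(fg, universe)) > 0)
    stop_domain("universe must contain every foreground gene")
  N <- length(universe)
  K <- length(fg)
  sets <- lapply(annotation_sets, function(g)
    intersect(unique(normalize_symbol(g)), universe))
  overlap <- lapply(sets, function(g) sort(intersect(g, fg)))
  k <- vapply(overlap, length, 1L)
  keep <- k >= min_overlap & vapply(sets, length, 1L) > 0
  if (!any(keep)) {
    out <- data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), significant = logical(0))
    out$overlap_genes <- list()
    return(out)
  }
  term <- names(sets)[keep]
  n <- vapply(sets[keep], length, 1L)
  k <- k[keep]
  p <- fisher_exact_one_sided(k, K, n, N)
  q <- bh_fdr(p)
  out <- data.frame(term = term, k = k, K = K, n = n, N = N, p = p, q = q,
                    significant = q < fdr_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$overlap_genes <- unname(overlap[keep])
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` between two
#' equal-length label vectors (e.g. two screeners' include/exclude calls on
#' the same citations). When expected agreement `p_e` is 1 (both raters
#' constant and identical) the statistic is defined as 1.
#'
#' @param ratings_a,ratings_b label vectors of equal non-zero length.
#' @return kappa in `[-1, 1]`.
#' @examples
#' cohen_kappa(c(1, 1, 0, 0), c(0, 0, 1, 1))  # -1
#' @export
cohen_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b))
    stop_domain("rating vectors must have equal length")
  if (length(ratings_a) == 0) stop_empty("empty rating vectors")
  a <- as.character(ratings_a)
  b <- as.character(ratings_b)
  if (any(is.na(a)) || any(is.na(b))) stop_domain("NA ratings not allowed")
  p_o <- mean(a == b)
  cats <- union(unique(a), unique(b))
  p_e <- sum(vapply(cats, function(x) mean(a == x) * mean(b == x), 1.0))
  if (p_e >= 1) return(1.0)
  (p_o - p_e) / (1 - p_e)
}
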