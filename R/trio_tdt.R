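# Transmission disequilibrium test over parent-offspring trios.
#
# Genotypes are held internally as counts of allele_a (0/1/2, NA missing)
# in three SNP-by-trio integer matrices (father, mother, child). allele_a
# is the lexicographically smaller of the two alleles observed at a SNP;
# the TDT statistic is invariant to that labeling choice.

#' Read parent-offspring trios from PLINK-style PED/MAP text
#'
#' Assembles trios from pedigree links: every individual whose father and
#' mother ids both resolve to genotyped individuals in the same family
#' becomes the child of one trio. Individuals without both parents in the
#' file are ignored (a child referencing an absent parent is skipped with
#' a warning). The missing genotype code `0` is honored; SNPs with more
#' than two observed alleles are dropped with a warning (only biallelic
#' SNPs are testable).
#'
#' @param ped_path whitespace-delimited PED file (family, individual,
#'   father, mother, sex, phenotype, then two allele columns per SNP).
#' @param map_path MAP file aligned with the PED genotype columns
#'   (chromosome, SNP id, genetic distance, base-pair position; the
#'   3-column variant without genetic distance is also accepted).
#' @return an object of class `trio_panel`: list with `snps` (data.frame
#'   `id`, `chr`, `pos`, `allele_a`, `allele_b`), `trios` (data.frame of
#'   family/child/father/mother ids) and genotype matrices `father`,
#'   `mother`, `child` (SNPs in rows, trios in columns, entries = count of
#'   `allele_a`, NA = missing).
#' @seealso [write_trios()], [tdt_scan()]
#' @export
read_trios <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop_format("PED file not found: %s", ped_path)
  if (!file.exists(map_path)) stop_format("MAP file not found: %s", map_path)

  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(map) == 4) {
    snps <- data.frame(id = as.character(map[[2]]), chr = as.character(map[[1]]),
                       pos = as.integer(map[[4]]), stringsAsFactors = FALSE)
  } else if (ncol(map) == 3) {
    snps <- data.frame(id = as.character(map[[2]]), chr = as.character(map[[1]]),
                       pos = as.integer(map[[3]]), stringsAsFactors = FALSE)
  } else stop_format("%s: MAP files need 3 or 4 columns, found %d",
                     map_path, ncol(map))
  n_snps <- nrow(snps)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_empty("%s: empty PED file", ped_path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  wid <- lengths(fields)
  if (any(wid != 6 + 2 * n_snps))
    stop_format("%s: line(s) %s have %s fields, expected %d (6 + 2 x %d SNPs)",
                ped_path, paste(utils::head(which(wid != 6 + 2 * n_snps), 3),
                                collapse = ","),
                paste(unique(wid[wid != 6 + 2 * n_snps]), collapse = "/"),
                6 + 2 * n_snps, n_snps)
  ped <- do.call(rbind, fields)
  fid <- ped[, 1]; iid <- ped[, 2]; pat <- ped[, 3]; mat <- ped[, 4]
  ukey <- paste(fid, iid, sep = "\r")
  if (anyDuplicated(ukey))
    stop_format("%s: duplicated individual id(s) within a family", ped_path)

  # allele-pair columns per SNP: 6 + 2j-1, 6 + 2j
  a1 <- ped[, 6 + 2 * seq_len(n_snps) - 1, drop = FALSE]
  a2 <- ped[, 6 + 2 * seq_len(n_snps), drop = FALSE]

  # per-SNP allele dictionary; drop multiallelic SNPs
  alleles <- lapply(seq_len(n_snps), function(j) {
    obs <- c(a1[, j], a2[, j])
    sort(unique(obs[obs != "0"]))
  })
  n_all <- lengths(alleles)
  if (any(n_all > 2)) {
    warning(sprintf("dropping %d multiallelic SNP(s): %s", sum(n_all > 2),
                    paste(utils::head(snps$id[n_all > 2], 5), collapse = ", ")),
            call. = FALSE)
    keep <- n_all <= 2
    snps <- snps[keep, , drop = FALSE]
    a1 <- a1[, keep, drop = FALSE]; a2 <- a2[, keep, drop = FALSE]
    alleles <- alleles[keep]
    n_snps <- nrow(snps)
  }
  snps$allele_a <- vapply(alleles, function(x) if (length(x) >= 1) x[1] else NA_character_,
                          character(1))
  snps$allele_b <- vapply(alleles, function(x) if (length(x) >= 2) x[2] else NA_character_,
                          character(1))

  # genotype -> count of allele_a per individual (rows) and SNP (cols)
  counts <- matrix(NA_integer_, nrow = nrow(ped), ncol = n_snps)
  for (j in seq_len(n_snps)) {
    aa <- snps$allele_a[j]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    cnt <- (a1[, j] == aa) + (a2[, j] == aa)
    cnt[miss | is.na(aa)] <- NA_integer_
    counts[, j] <- cnt
  }

  is_child <- pat != "0" & mat != "0"
  pat_key <- paste(fid, pat, sep = "\r")
  mat_key <- paste(fid, mat, sep = "\r")
  both_here <- is_child & pat_key %in% ukey & mat_key %in% ukey
  orphan <- is_child & !both_here
  if (any(orphan))
    warning(sprintf("%d child(ren) reference a parent absent from the file; excluded (%s)",
                    sum(orphan), paste(utils::head(iid[orphan], 5), collapse = ", ")),
            call. = FALSE)
  child_rows <- which(both_here)
  if (length(child_rows) == 0)
    warning("no complete parent-offspring trios found in PED file", call. = FALSE)

  row_of <- setNames(seq_along(ukey), ukey)
  f_rows <- unname(row_of[pat_key[child_rows]])
  m_rows <- unname(row_of[mat_key[child_rows]])
  trios <- data.frame(family = fid[child_rows], child = iid[child_rows],
                      father = pat[child_rows], mother = mat[child_rows],
                      stringsAsFactors = FALSE)

  structure(list(
    snps = snps, trios = trios,
    father = t(counts[f_rows, , drop = FALSE]),
    mother = t(counts[m_rows, , drop = FALSE]),
    child = t(counts[child_rows, , drop = FALSE])
  ), class = "trio_panel")
}

#' Write a trio panel as PLINK-style PED/MAP text
#'
#' Emits one father, mother and child row per trio (child phenotype coded
#' affected); the result parses losslessly with [read_trios()].
#'
#' @param panel a `trio_panel`.
#' @param ped_path,map_path output paths.
#' @return invisible list of the two paths.
#' @export
write_trios <- function(panel, ped_path, map_path) {
  stopifnot(inherits(panel, "trio_panel"))
  s <- panel$snps
  map <- data.frame(chr = s$chr, id = s$id, cm = 0L, pos = s$pos)
  write.table(map, map_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  gt_string <- function(cnt) {
    # count of allele_a -> "a a" / "a b" / "b b" / "0 0"
    n_snps <- nrow(s)
    g1 <- ifelse(is.na(cnt), "0", ifelse(cnt >= 1, s$allele_a, s$allele_b))
    g2 <- ifelse(is.na(cnt), "0", ifelse(cnt == 2, s$allele_a, s$allele_b))
    paste(paste(g1, g2), collapse = " ")
  }
  n_trios <- nrow(panel$trios)
  out <- character(3 * n_trios)
  for (i in seq_len(n_trios)) {
    tr <- panel$trios[i, ]
    out[3 * i - 2] <- paste(tr$family, tr$father, 0, 0, 1, 1,
                            gt_string(panel$father[, i]))
    out[3 * i - 1] <- paste(tr$family, tr$mother, 0, 0, 2, 1,
                            gt_string(panel$mother[, i]))
    out[3 * i] <- paste(tr$family, tr$child, tr$father, tr$mother, 1, 2,
                        gt_string(panel$child[, i]))
  }
  writeLines(out, ped_path)
  invisible(list(ped = ped_path, map = map_path))
}

#' @export
print.trio_panel <- function(x, ...) {
  cat(sprintf("<trio_panel>: %d trios x %d SNPs\n", nrow(x$trios), nrow(x$snps)))
  invisible(x)
}

# Vectorized transmission counting for all SNPs at once. For each trio-SNP
# with complete genotypes, homozygous parents transmit deterministically
# (lo = forced allele_a transmissions); the child's allele_a count minus lo
# is the number of allele_a transmissions from heterozygous parents. A
# het x het -> het trio thus contributes one transmission of each allele.
# Mendelian-inconsistent or incomplete trio-SNPs contribute nothing.
transmissions_all <- function(panel) {
  f <- panel$father; m <- panel$mother; ch <- panel$child
  lo <- (f == 2L) + (m == 2L)
  hi <- (f >= 1L) + (m >= 1L)
  ok <- !is.na(f) & !is.na(m) & !is.na(ch)
  consistent <- ok & ch >= lo & ch <= hi
  consistent[is.na(consistent)] <- FALSE
  n_het <- (f == 1L) + (m == 1L)
  b_term <- ch - lo
  c_term <- n_het - b_term
  b_term[!consistent] <- 0L; c_term[!consistent] <- 0L
  mend <- ok & !consistent
  mend[is.na(mend)] <- FALSE
  data.frame(snp = panel$snps$id,
             b = as.integer(rowSums(b_term)),
             c = as.integer(rowSums(c_term)),
             n_mendel_errors = as.integer(rowSums(mend)),
             stringsAsFactors = FALSE)
}

#' Count allele transmissions from heterozygous parents at one SNP
#'
#' For each Mendelian-consistent, fully genotyped trio, every heterozygous
#' parent contributes one transmission: `b` counts transmissions of
#' `allele_a`, `c` of `allele_b`. Homozygous parents are uninformative. A
#' het x het -> het trio contributes one transmission of each allele (the
#' standard resolution of the phase ambiguity). Mendelian-inconsistent
#' trios are excluded at this SNP only and reported via a message.
#'
#' @param panel a `trio_panel`.
#' @param snp_id SNP identifier present in the panel.
#' @return list with integer counts `b`, `c` and `n_mendel_errors`.
#' @export
count_transmissions <- function(panel, snp_id) {
  stopifnot(inherits(panel, "trio_panel"))
  i <- match(snp_id, panel$snps$id)
  if (is.na(i)) stop_lookup("unknown SNP id: %s", snp_id)
  sub <- panel
  sub$snps <- panel$snps[i, , drop = FALSE]
  sub$father <- panel$father[i, , drop = FALSE]
  sub$mother <- panel$mother[i, , drop = FALSE]
  sub$child <- panel$child[i, , drop = FALSE]
  tc <- transmissions_all(sub)
  if (tc$n_mendel_errors[1] > 0)
    message(sprintf("SNP %s: %d Mendelian-inconsistent trio(s) excluded",
                    snp_id, tc$n_mendel_errors[1]))
  list(b = tc$b[1], c = tc$c[1], n_mendel_errors = tc$n_mendel_errors[1])
}

#' TDT chi-square statistic and p-value
#'
#' McNemar-type statistic `chi2 = (b - c)^2 / (b + c)` on the transmission
#' counts from heterozygous parents, referred to the upper tail of the
#' chi-square distribution with 1 degree of freedom.
#'
#' @param b,c transmission counts (vectors allowed).
#' @return list with `chi2` and `p`. `b + c = 0` (no informative
#'   transmissions) raises a condition of class
#'   `cleftminer_uninformative_error`; scan code skips such SNPs.
#' @examples
#' tdt_statistic(20, 5)  # chi2 = 9, p ~ 0.0027
#' @export
tdt_statistic <- function(b, c) {
  if (any(b < 0 | c < 0) || any(b != floor(b) | c != floor(c)))
    stop_domain("transmission counts must be non-negative integers")
  if (any(b + c == 0))
    cm_stop("cleftminer_uninformative_error",
            "uninformative SNP: no transmissions from heterozygous parents")
  chi2 <- (b - c)^2 / (b + c)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Bonferroni significance threshold over tested genes
#'
#' The candidate-wise threshold `alpha / n_genes` used when each gene's top
#' marker is taken as its association signal.
#'
#' @param alpha overall significance level in (0, 1].
#' @param n_genes number of genes tested (>= 1).
#' @return the per-gene threshold.
#' @examples
#' bonferroni_threshold(0.05, 179)  # 2.79e-4
#' @export
bonferroni_threshold <- function(alpha, n_genes) {
  cm_as_probability(alpha, "alpha")
  if (!is.numeric(n_genes) || length(n_genes) != 1 || is.na(n_genes) ||
      n_genes < 1 || n_genes != floor(n_genes))
    stop_domain("n_genes must be a positive integer")
  alpha / n_genes
}

#' Tiered significance thresholds for the TDT scan
#'
#' Three tiers, strongest first: genome-wide (default `5e-8`), gene-wide
#' (default `2.5e-6`), and candidate-wise (`alpha / n_genes`, Bonferroni
#' over the genes actually tested).
#'
#' @param n_genes number of genes tested.
#' @param alpha overall level for the candidate-wise tier (default 0.05).
#' @param genome_wide,gene_wide fixed upper-tier thresholds.
#' @return list of class `significance_tiers`.
#' @export
significance_tiers <- function(n_genes, alpha = 0.05, genome_wide = 5e-8,
                               gene_wide = 2.5e-6) {
  structure(list(genome_wide = genome_wide, gene_wide = gene_wide,
                 candidate_wise = bonferroni_threshold(alpha, n_genes),
                 alpha = alpha, n_genes = as.integer(n_genes)),
            class = "significance_tiers")
}

tier_label <- function(p, tiers) {
  ifelse(p < tiers$genome_wide, "genome_wide",
         ifelse(p < tiers$gene_wide, "gene_wide",
                ifelse(p < tiers$candidate_wise, "candidate_wise", "none")))
}

#' Assign SNPs to genes by interval overlap
#'
#' Maps each SNP to every gene whose interval, widened by `flank_bp` on
#' both sides, contains it. Gene intervals come from a BED file (0-based,
#' half-open, name column = gene symbol) or an equivalent
#' [GenomicRanges::GRanges]; SNP positions are 1-based as in MAP files.
#' The conversion is done explicitly via `GRanges` import (BED start+1 =
#' 1-based start), so a SNP at 1-based position `p` is assigned to a BED
#' interval `[s, e)` iff `s - flank <= p - 1 < e + flank`.
#'
#' @param snps data.frame with columns `id`, `chr`, `pos` (e.g.
#'   `panel$snps`), or a `trio_panel`.
#' @param intervals BED file path or a `GRanges` with a `name` column.
#' @param flank_bp non-negative flank in base pairs (default 0).
#' @return named list: SNP id -> character vector of gene symbols (possibly
#'   empty, sorted).
#' @export
assign_genes <- function(snps, intervals, flank_bp = 0) {
  if (inherits(snps, "trio_panel")) snps <- snps$snps
  if (!is.numeric(flank_bp) || length(flank_bp) != 1 || flank_bp < 0)
    stop_domain("flank_bp must be a single non-negative number")
  if (is.character(intervals)) {
    if (!file.exists(intervals)) stop_format("BED file not found: %s", intervals)
    gr <- tryCatch(rtracklayer::import(intervals, format = "BED"),
                   error = function(e)
                     stop_format("malformed BED file %s: %s", intervals,
                                 conditionMessage(e)))
  } else if (is(intervals, "GRanges")) {
    gr <- intervals
  } else stop_domain("intervals must be a BED path or a GRanges")
  if (is.null(gr$name) || any(is.na(gr$name)))
    stop_format("gene intervals must carry a name (gene symbol) column")

  chr_levels <- union(unique(as.character(snps$chr)),
                      as.character(GenomeInfoDb::seqlevels(gr)))
  GenomeInfoDb::seqlevels(gr) <- chr_levels
  snp_gr <- GenomicRanges::GRanges(
    seqnames = factor(as.character(snps$chr), levels = chr_levels),
    ranges = IRanges::IRanges(start = snps$pos, width = 1)
  )
  if (flank_bp > 0)
    gr <- suppressWarnings(GenomicRanges::resize(
      gr, width = GenomicRanges::width(gr) + 2 * flank_bp, fix = "center"))
  hits <- GenomicRanges::findOverlaps(snp_gr, gr, ignore.strand = TRUE)
  out <- rep(list(character(0)), nrow(snps))
  names(out) <- snps$id
  if (length(hits) > 0) {
    by_snp <- split(gr$name[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits))
    for (q in names(by_snp))
      out[[as.integer(q)]] <- sort(unique(by_snp[[q]]))
  }
  out
}

#' TDT association scan with per-gene summary
#'
#' Runs the transmission disequilibrium test at every informative biallelic
#' SNP of a trio panel, labels each result with the strongest significance
#' tier it reaches, and summarizes per gene by the top (minimum-p) marker —
#' mirroring the one-row-per-gene presentation used for candidate-gene
#' scans (no intra-gene multiplicity correction: SNPs within a gene are
#' typically in strong linkage disequilibrium).
#'
#' @param panel a `trio_panel`.
#' @param gene_assignment optional named list from [assign_genes()]; SNPs
#'   mapping to no gene appear in the per-SNP table with an empty gene
#'   field and are absent from the per-gene summary.
#' @param alpha level for the candidate-wise Bonferroni tier (default
#'   0.05); the divisor is the number of genes actually tested.
#' @param tiers optional pre-built [significance_tiers()] overriding
#'   `alpha`.
#' @return list of class `tdt_scan` with `per_snp` (snp, chr, pos, gene,
#'   b, c, chi2, p, tier), `per_gene` (gene, top_marker, b, c, chi2, p,
#'   tier; sorted by p) and `tiers`.
#' @export
tdt_scan <- function(panel, gene_assignment = NULL, alpha = 0.05,
                     tiers = NULL) {
  stopifnot(inherits(panel, "trio_panel"))
  if (nrow(panel$snps) == 0 || nrow(panel$trios) == 0)
    stop_empty("empty trio panel")
  tc <- transmissions_all(panel)
  informative <- tc$b + tc$c > 0
  if (!any(informative))
    warning("no informative SNPs (no transmissions from heterozygous parents)",
            call. = FALSE)
  gene_chr <- if (is.null(gene_assignment)) rep("", nrow(panel$snps)) else {
    vapply(panel$snps$id, function(s)
      paste(gene_assignment[[s]], collapse = ","), character(1))
  }
  per_snp <- data.frame(snp = panel$snps$id, chr = panel$snps$chr,
                        pos = panel$snps$pos, gene = gene_chr,
                        b = tc$b, c = tc$c, stringsAsFactors = FALSE)
  per_snp <- per_snp[informative, , drop = FALSE]
  if (nrow(per_snp) > 0) {
    st <- tdt_statistic(per_snp$b, per_snp$c)
    per_snp$chi2 <- st$chi2
    per_snp$p <- st$p
  } else {
    per_snp$chi2 <- numeric(0); per_snp$p <- numeric(0)
  }

  # genes actually tested: >= 1 informative assigned SNP
  snp_genes <- cm_split(per_snp$gene)
  tested_genes <- sort(unique(unlist(snp_genes, use.names = FALSE)))
  if (is.null(tiers)) {
    tiers <- significance_tiers(max(length(tested_genes), 1L), alpha = alpha)
  }
  per_snp$tier <- if (nrow(per_snp) > 0) tier_label(per_snp$p, tiers) else character(0)
  rownames(per_snp) <- NULL

  per_gene <- data.frame(gene = character(0), top_marker = character(0),
                         b = integer(0), c = integer(0), chi2 = numeric(0),
                         p = numeric(0), tier = character(0),
                         stringsAsFactors = FALSE)
  if (length(tested_genes) > 0) {
    rows <- lapply(tested_genes, function(g) {
      hit <- vapply(snp_genes, function(x) g %in% x, logical(1))
      sub <- per_snp[hit, , drop = FALSE]
      sub <- sub[order(sub$p, -sub$chi2, sub$snp), , drop = FALSE]
      data.frame(gene = g, top_marker = sub$snp[1], b = sub$b[1], c = sub$c[1],
                 chi2 = sub$chi2[1], p = sub$p[1], tier = sub$tier[1],
                 stringsAsFactors = FALSE)
    })
    per_gene <- do.call(rbind, rows)
    per_gene <- per_gene[order(per_gene$p, per_gene$gene), , drop = FALSE]
    rownames(per_gene) <- NULL
  }
  structure(list(per_snp = per_snp, per_gene = per_gene, tiers = tiers),
            class = "tdt_scan")
}

#' @export
print.tdt_scan <- function(x, ...) {
  cat(sprintf("<tdt_scan>: %d informative SNPs, %d genes (candidate-wise p < %.3g)\n",
              nrow(x$per_snp), nrow(x$per_gene), x$tiers$candidate_wise))
  invisible(x)
}
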