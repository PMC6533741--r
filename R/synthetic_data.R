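#' Parameters for the synthetic-data generators
#'
#' One validated parameter object drives both generators. Defaults match
#' the regimes the package's statistical checks are run under: a universe
#' of 3000 genes with a 150-gene foreground, 50 miRNAs with target sets of
#' 30-80 genes of which 3 are planted at enrichment odds 10; and 300 trios
#' x 100 SNPs at minor-allele frequency 0.3 with fair transmission
#' (tau = 0.5) unless distorted per SNP.
#'
#' @param seed integer seed; every draw in a generator call descends from a
#'   single stream seeded with it.
#' @param n_genes_universe,n_foreground universe and foreground sizes
#'   (foreground is a subset of the universe).
#' @param n_mirnas,planted_mirnas number of miRNAs simulated and how many
#'   of them oversample the foreground.
#' @param target_size_range inclusive (min, max) target-set size.
#' @param enrichment_odds relative sampling weight of foreground genes for
#'   planted miRNAs (1 = null).
#' @param n_trios,n_snps trio-panel dimensions.
#' @param maf allele frequency of `allele_a` in (0, 0.5].
#' @param tau probability that a heterozygous parent transmits `allele_a`
#'   (0.5 = Mendelian fairness).
#' @param distorted_snps optional data.frame with columns `snp` (index)
#'   and `tau` overriding `tau` at chosen SNPs.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_genes_universe = 3000L, n_foreground = 150L,
                           n_mirnas = 50L, target_size_range = c(30L, 80L),
                           planted_mirnas = 3L, enrichment_odds = 10,
                           n_trios = 300L, n_snps = 100L,
                           maf = 0.3, tau = 0.5, distorted_snps = NULL) {
  chk_count <- function(x, what, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
        x != floor(x))
      stop_domain("%s must be an integer >= %d", what, min)
    as.integer(x)
  }
  spec <- list(
    seed = chk_count(seed, "seed", min = 0),
    n_genes_universe = chk_count(n_genes_universe, "n_genes_universe"),
    n_foreground = chk_count(n_foreground, "n_foreground"),
    n_mirnas = chk_count(n_mirnas, "n_mirnas"),
    target_size_range = c(chk_count(target_size_range[1], "target size min"),
                          chk_count(target_size_range[2], "target size max")),
    planted_mirnas = chk_count(planted_mirnas, "planted_mirnas", min = 0),
    enrichment_odds = enrichment_odds,
    n_trios = chk_count(n_trios, "n_trios"),
    n_snps = chk_count(n_snps, "n_snps"),
    maf = maf, tau = tau, distorted_snps = distorted_snps
  )
  if (spec$n_foreground > spec$n_genes_universe)
    stop_domain("n_foreground must not exceed n_genes_universe")
  if (spec$planted_mirnas > spec$n_mirnas)
    stop_domain("planted_mirnas must not exceed n_mirnas")
  if (spec$target_size_range[1] > spec$target_size_range[2])
    stop_domain("target_size_range must be (min, max) with min <= max")
  if (spec$target_size_range[2] > spec$n_genes_universe)
    stop_domain("target sizes cannot exceed the universe size")
  if (!is.numeric(spec$enrichment_odds) || spec$enrichment_odds <= 0)
    stop_domain("enrichment_odds must be a positive real")
  if (!is.numeric(spec$maf) || spec$maf <= 0 || spec$maf > 0.5)
    stop_domain("maf must lie in (0, 0.5]")
  if (!is.numeric(spec$tau) || spec$tau <= 0 || spec$tau > 1)
    stop_domain("tau must lie in (0, 1]")
  if (!is.null(distorted_snps)) {
    if (!is.data.frame(distorted_snps) ||
        !all(c("snp", "tau") %in% names(distorted_snps)))
      stop_domain("distorted_snps must be a data.frame with columns snp, tau")
    if (any(distorted_snps$snp < 1 | distorted_snps$snp > spec$n_snps))
      stop_domain("distorted_snps indices out of range")
    if (any(distorted_snps$tau <= 0 | distorted_snps$tau > 1))
      stop_domain("distorted_snps tau values must lie in (0, 1]")
  }
  structure(spec, class = "synthetic_spec")
}

#' Simulate a miRNA target map with planted enrichment
#'
#' Null miRNAs draw their target sets uniformly without replacement from
#' the universe. Planted miRNAs draw with foreground genes weighted
#' `enrichment_odds : 1`, so at odds 1 planted and null miRNAs are
#' indistinguishable and as the odds grow the planted targets concentrate
#' in the foreground. Fully reproducible from the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `target_map` (universe = the full simulated gene set),
#'   `foreground` (character vector) and `truth` (data.frame `mirna`,
#'   `planted`).
#' @export
simulate_target_universe <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  genes <- sprintf("G%05d", seq_len(spec$n_genes_universe))
  foreground <- sort(sample(genes, spec$n_foreground))
  mirnas <- sprintf("sim-miR-%03d", seq_len(spec$n_mirnas))
  planted <- seq_len(spec$n_mirnas) <= spec$planted_mirnas
  w_null <- rep(1, spec$n_genes_universe)
  w_plant <- ifelse(genes %in% foreground, spec$enrichment_odds, 1)
  size_choices <- seq(spec$target_size_range[1], spec$target_size_range[2])
  sizes <- size_choices[sample.int(length(size_choices), spec$n_mirnas,
                                   replace = TRUE)]
  pairs <- do.call(rbind, lapply(seq_len(spec$n_mirnas), function(i) {
    w <- if (planted[i]) w_plant else w_null
    data.frame(mirna = mirnas[i],
               gene = sample(genes, sizes[i], prob = w),
               stringsAsFactors = FALSE)
  }))
  list(target_map = build_target_map(pairs, universe = genes),
       foreground = foreground,
       truth = data.frame(mirna = mirnas, planted = planted,
                          stringsAsFactors = FALSE))
}

#' Simulate parent-offspring trio genotypes
#'
#' Parental genotypes are drawn under Hardy-Weinberg equilibrium at the
#' spec's allele frequency; each homozygous parent transmits its allele,
#' each heterozygous parent transmits `allele_a` with probability `tau`
#' (per-SNP overrides honored). Loci are independent (no linkage
#' disequilibrium). Reproducible from the spec's seed; optionally writes
#' the panel as PED/MAP text.
#'
#' @param spec a [synthetic_spec()].
#' @param ped_path,map_path optional output paths for [write_trios()].
#' @return a `trio_panel` (invisibly carries nothing extra; write the
#'   files via the path arguments if needed).
#' @export
simulate_trios <- function(spec, ped_path = NULL, map_path = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_snps <- spec$n_snps; n_trios <- spec$n_trios
  tau <- rep(spec$tau, n_snps)
  if (!is.null(spec$distorted_snps))
    tau[spec$distorted_snps$snp] <- spec$distorted_snps$tau

  draw_parent <- function()
    matrix(rbinom(n_snps * n_trios, 2, spec$maf), nrow = n_snps)
  transmit <- function(gt) {
    # hom parents transmit their allele; het transmit allele_a w.p. tau[snp]
    het_draw <- matrix(rbinom(n_snps * n_trios, 1, rep(tau, n_trios)),
                       nrow = n_snps)
    (gt == 2L) * 1L + (gt == 1L) * het_draw
  }
  father <- draw_parent()
  mother <- draw_parent()
  child <- transmit(father) + transmit(mother)

  fam <- sprintf("F%05d", seq_len(n_trios))
  panel <- structure(list(
    snps = data.frame(id = sprintf("rs%06d", seq_len(n_snps)),
                      chr = "1", pos = 1000L * seq_len(n_snps),
                      allele_a = "A", allele_b = "B",
                      stringsAsFactors = FALSE),
    trios = data.frame(family = fam, child = paste0(fam, "_C"),
                       father = paste0(fam, "_F"), mother = paste0(fam, "_M"),
                       stringsAsFactors = FALSE),
    father = father, mother = mother, child = child
  ), class = "trio_panel")
  if (!is.null(ped_path) && !is.null(map_path))
    write_trios(panel, ped_path, map_path)
  panel
}
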