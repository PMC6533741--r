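test_that("the one-sided Fisher tail matches hand-enumerable cases", {
  expect_equal(fisher_exact_one_sided(0, 5, 4, 20), 1.0)
  expect_equal(fisher_exact_one_sided(5, 5, 5, 5), 1.0)
  # C(5,3)C(15,1)/C(20,4) + C(5,4)C(15,0)/C(20,4) = (150 + 5)/4845
  expect_equal(fisher_exact_one_sided(3, 5, 4, 20), 155 / 4845,
               tolerance = 1e-12)

  expect_error(fisher_exact_one_sided(6, 5, 4, 20),
               class = "cleftminer_domain_error")
  expect_error(fisher_exact_one_sided(1, 5, 4, 0),
               class = "cleftminer_domain_error")
  expect_error(fisher_exact_one_sided(1, 25, 4, 20),
               class = "cleftminer_domain_error")
  expect_error(fisher_exact_one_sided(1.5, 5, 4, 20),
               class = "cleftminer_domain_error")
})

test_that("the Fisher tail agrees with the enumeration oracle on moderate universes", {
  for (N in c(7, 13, 24)) {
    for (K in 0:N) {
      for (n in 0:N) {
        ks <- max(0, K + n - N):min(K, n)
        got <- fisher_exact_one_sided(ks, K, n, N)
        want <- vapply(ks, hyper_tail_oracle, 1.0, K = K, n = n, N = N)
        expect_equal(got, want, tolerance = 1e-11)
      }
    }
  }
})

test_that("BH adjustment matches the hand-computed step-up examples", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_error(bh_fdr(numeric(0)), class = "cleftminer_empty_input_error")
  expect_error(bh_fdr(c(0.1, 1.2)), class = "cleftminer_domain_error")
})

test_that("q-values are monotone in p and tied p-values share a q", {
  set.seed(31)
  p <- round(runif(40), 2)  # rounding forces ties
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  for (pv in unique(p)) expect_length(unique(q[p == pv]), 1L)
})

test_that("per-miRNA enrichment flags a planted miRNA and orders deterministically", {
  sim <- simulate_target_universe(synthetic_spec(seed = 7, n_mirnas = 51,
                                                 planted_mirnas = 1,
                                                 enrichment_odds = 10))
  rows <- mirna_enrichment(sim$target_map, sim$foreground,
                           fdr_threshold = 0.1)
  planted <- sim$truth$mirna[sim$truth$planted]
  expect_equal(rows$mirna[1], planted)  # smallest q first
  expect_true(rows$significant[1])
  expect_true(all(rows$k <= pmin(rows$K, rows$n)))
  expect_true(all(rows$n <= rows$N))
  expect_identical(order(rows$q, rows$p, rows$mirna), seq_len(nrow(rows)))
  expect_equal(vapply(rows$overlap_genes, length, 1L), rows$k)

  # rerun with the same seed reproduces the same table
  sim2 <- simulate_target_universe(synthetic_spec(seed = 7, n_mirnas = 51,
                                                  planted_mirnas = 1,
                                                  enrichment_odds = 10))
  rows2 <- mirna_enrichment(sim2$target_map, sim2$foreground,
                            fdr_threshold = 0.1)
  expect_identical(rows, rows2)
})

test_that("degenerate foregrounds behave as the 2x2 table dictates", {
  tm <- fixture_target_map()
  # foreground == universe: every test saturated, p = 1, nothing significant
  rows <- mirna_enrichment(tm, tm$universe, fdr_threshold = 0.1)
  expect_true(all(rows$p == 1))
  expect_false(any(rows$significant))
  expect_true(all(rows$k == rows$n))

  expect_error(mirna_enrichment(tm, c("NOT_A_GENE")),
               class = "cleftminer_empty_input_error")
})

test_that("false-positive miRNA calls are controlled under the null", {
  hits <- vapply(1:200, function(s) {
    sim <- simulate_target_universe(synthetic_spec(
      seed = 5000 + s, n_genes_universe = 600, n_foreground = 60,
      n_mirnas = 30, target_size_range = c(10, 30),
      planted_mirnas = 0, enrichment_odds = 1))
    rows <- mirna_enrichment(sim$target_map, sim$foreground,
                             fdr_threshold = 0.1)
    any(rows$significant)
  }, logical(1))
  expect_lte(mean(hits), 0.15)
})

test_that("family counting excludes unknown families and ignores row order", {
  rows <- fixture_enrichment_rows()
  counts <- count_families_per_gene(rows, min_families = 1)

  # genes reached only through the unknown-family miRNA get no family
  na_only <- setdiff(rows$overlap_genes[[which(rows$mirna == "hsa-miR-3678-3p")]],
                     unlist(rows$overlap_genes[rows$family != "UNKNOWN"]))
  expect_true(all(counts$n_families[counts$gene %in% na_only] == 0))

  shuffled <- rows[sample(nrow(rows)), ]
  expect_identical(count_families_per_gene(shuffled, min_families = 1), counts)

  one <- rows[rows$mirna == "hsa-miR-497-5p", ]
  counts1 <- count_families_per_gene(one)
  expect_true(all(counts1$n_families == 1L))
  expect_setequal(counts1$gene, one$overlap_genes[[1]])
})

test_that("gene-set enrichment agrees with the Fisher tail and applies its filters", {
  universe <- sprintf("U%02d", 1:20)
  fg <- universe[1:5]
  sets <- list(matching = universe[c(1, 2, 3, 6)],   # k=3, n=4
               small = universe[c(1, 19)],           # k=1 < min_overlap
               background = universe[11:18])         # k=0
  res <- geneset_enrichment(fg, sets, universe, min_overlap = 3,
                            fdr_threshold = 0.05)
  expect_equal(res$term, "matching")
  expect_equal(res$p, 155 / 4845, tolerance = 1e-12)
  expect_equal(res$p, fisher_exact_one_sided(3, 5, 4, 20))

  # a term identical to the foreground is the strongest possible signal
  sets2 <- list(self = fg, other = universe[6:10])
  res2 <- geneset_enrichment(fg, sets2, universe, min_overlap = 0)
  expect_equal(res2$term[1], "self")
  expect_equal(res2$p[1], min(res2$p))

  expect_error(geneset_enrichment(fg, list(), universe),
               class = "cleftminer_empty_input_error")
  expect_error(geneset_enrichment(fg, sets, universe[2:20]),
               class = "cleftminer_domain_error")
})

test_that("GMT files parse into normalized gene sets", {
  gmt <- write_tmp_tsv(c("term1\tdesc\tg1\tg2\tg3",
                         "term2\tdesc\tg2\tg4"), ext = ".gmt")
  sets <- read_gmt(gmt)
  expect_named(sets, c("term1", "term2"))
  expect_equal(sets$term1, c("G1", "G2", "G3"))
})

test_that("Cohen's kappa covers agreement, disagreement and chance levels", {
  expect_equal(cohen_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1.0)
  expect_equal(cohen_kappa(c(1, 1, 0, 0), c(0, 0, 1, 1)), -1.0)
  expect_equal(cohen_kappa(rep(1, 5), rep(1, 5)), 1.0)  # p_e == 1 edge case
  expect_error(cohen_kappa(c(1, 0), c(1, 0, 1)),
               class = "cleftminer_domain_error")

  set.seed(41)
  a <- rbinom(10000, 1, 0.5)
  b <- rbinom(10000, 1, 0.5)
  expect_lt(abs(cohen_kappa(a, b)), 0.05)
})
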